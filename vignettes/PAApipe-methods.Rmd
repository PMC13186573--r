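---
title: "PAApipe: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PAApipe: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette explains what each stage of PAApipe computes, the
assumptions behind it, the parameters that matter, and the design
choices we made where more than one reasonable definition exists. The
package addresses a concrete annotation problem: phenylacetate-CoA
ligase (PAL, PaaK) — the committed first step of the hybrid
phenylacetic-acid (PAA) degradation pathway — is an ANL-superfamily
enzyme whose AMP-binding domains are shared with many acyl- and
aryl-CoA ligases, so no single evidence layer identifies it reliably.
PAApipe therefore chains three independent layers (domain architecture,
sequence motifs, genomic context) and adds a cophylogenetic module for
the PaaA/PaaC epoxidase subunits that serve as genomic markers of the
pathway.

## Domain-architecture resolution

`hmmscan` reports every profile match, and matches overlap freely. The
representative architecture of a protein is defined as the pairwise
non-overlapping subset of hits (i-Evalue ≤ `evalue_max`) that covers
the largest number of residues; among equally covering subsets the one
with the smallest total ln i-Evalue wins, and any remaining tie goes to
the lexicographically smallest vector of alignment starts, which makes
the result unique and order-independent. `resolveArchitecture()` finds
the optimum by weighted-interval-scheduling dynamic programming over
hits sorted by alignment end (weight = alignment length, the ln-E sum
carried as a secondary objective); the lexicographic tie-break is
enforced by a greedy reconstruction that keeps a hit only if an optimal
completion still exists. The tests compare this against exhaustive
subset enumeration on a thousand random instances.

Choices worth stating:

* The e-value threshold is applied inclusively (≤ 0.001) and exposed as
  a parameter.
* Overlap means any shared residue, judged on the *alignment*
  (`ali`) coordinates — the span that actually occupies the protein —
  not envelope or HMM coordinates. Real Pfam hits often abut with a
  residue or two of slack, so `overlap_tol` (default 0) lets abutting
  hits coexist when raised.
* Domains are keyed on accession; display names ride along. The role
  map (`defaultRoleMap()`) is data, not code, so a different Pfam
  release only requires a different map. The shipped accessions are
  defaults in that spirit.
* With every hit filtered away the architecture is empty with coverage
  0 — a legitimate result, not an error.

PAL is recognised positionally: an AMP-binding tile first, an
AMP-binding_C_2 tile last, interior domains permitted (a known PAL-like
paralog carries an extra ECH_1 domain between them). An AMP-binding
domain alone — the typical ANL decoy — never matches. Two shared
architectures are deliberate: PaaA and PaaC resolve to one architecture
(`PaaA_PaaC`), as do the enoyl-CoA hydratase/isomerase pair PaaG and
PaaF (`PaaG_PaaF`); disambiguation happens at the context stage. Any
architecture containing the TetR-family domain counts as PaaR. This
over-calls TetR regulators inside windows by design (the alternative,
under-calling the pathway's documented TetR-family regulator, is
worse); calls are flagged so downstream users can tighten the map.

## Motif scanning

Scanning follows the classical MAST construction so that no external
binary is needed. Probabilities become integer log-odds scores at scale
100 (centibits) with a background-proportional pseudocount of 0.01; the
exact distribution of a site score under the background is obtained by
convolving the per-position score distributions, giving a survival
function `P(score ≥ s)` with no asymptotic approximation. The best site
of a motif in a sequence of m scannable positions gets
`best_pvalue = 1 − (1 − p_site)^m`, and the best p-values of the
required motifs combine by QFAST,
`q · Σ_{i=0}^{k−1} (−ln q)^i / i!` with `q` the product. A sequence
passes when every required motif meets the site threshold (default
1e-4) and the combined p-value meets the combined threshold (default
1e-5). Both thresholds are deliberately permissive: in the full
pipeline the genomic context is the decisive filter, and the motif
stage only needs to remove clear non-PALs.

Integer scaling at 100 balances p-value resolution against table size
(score supports stay in the tens of thousands for width-30 motifs).
Ambiguity codes (X, B, Z, J, U, O) score as the background-weighted
average of their expansions — a neutral contribution instead of a hard
failure on real proteomes. The calibration test checks that
`best_pvalue` is approximately uniform on background sequences
(Kolmogorov–Smirnov D < 0.02 at 10,000 sequences of length 500), the
residual discreteness of integer scores being well below that bound.

## Genomic-context classification

The context of a PAL anchor is the window of `W = 20` genes up- and
downstream on the same replicon — wide enough to hold the largest
experimentally characterised clusters (≥ 14 genes) plus interrupting
genes, and truncated at linear replicon ends (a `circular` flag wraps
instead, deduplicating). Strand is recorded but ignored: the
classification is membership-based, so permuting genes within a window
never changes the call.

The decision list runs FP → UP → EM → PM → OC over role sets that are
plain data (`defaultConfigurationRules()`):

* epoxidation module: PaaA, PaaB, PaaC, PaaE — PaaD optional, matching
  the PaaABC(D)E convention;
* upper pathway: the module plus PaaG and PaaZ (PaaZ sits at the ring
  cleavage step; a flag excludes it for users who count it separately);
* lower pathway: PaaF, PaaH, PaaJ — PaaI optional.

Shared architectures are disambiguated by counting: two `PaaA_PaaC`
genes in a window count as one PaaA and one PaaC; exactly one satisfies
only the PM predicate and flags the call as ambiguous. The same
counting applies to `PaaG_PaaF`, a single copy counting as PaaG
(upper). Regulator state is PaaR–X, PaaX, PaaR or NP by window
membership, and PaaY is a separate flag. Every context classifies
(OC is the total fallthrough), and the classes are nested by
construction: any FP window also satisfies the UP and EM predicates, so
deleting genes walks calls monotonically down the list.

`palCandidatePipeline()` composes the funnel: PAL architecture AND
motif pass, then context classification; candidates in FP/UP/EM/PM are
retained as probable orthologues, the rest are kept — not discarded —
as OC paralogs, since paralogous PAL copies lacking the epoxidation
module are themselves biologically informative. Pseudogene rescue is
out of scope: a disrupted gene is simply an absent role.

## Cophylogeny of the PaaA/PaaC markers

`paco()` implements the Procrustean chain. Patristic distance matrices
(path sums of branch lengths) need not be Euclidean-embeddable, so the
Cailliez constant — the largest real eigenvalue of the standard 2n × 2n
companion matrix — is added to off-diagonal entries first (computed
exactly, zero when the matrix is already embeddable). Principal
coordinates retain every axis with eigenvalue above 1e-8 of the
largest, the usual PACo convention that drops numerical-noise
dimensions. The second configuration is superimposed on the first by
least-squares translation, rotation (reflection allowed) and isotropic
scaling via SVD; the global fit is m² = Σ residuals².

The permutation null shuffles the link assignment. With the 1:1
identity association used for paired gene trees this is exactly the
binary-matrix row-randomization null of the original method
specialised to bijective links; a non-bijective link table is shuffled
the same way, row-wise. The p-value counts permuted m² values at or
below the observed one — small m² means congruence — with the standard
+1 correction, so the minimum attainable p is 1/(nperm + 1). Defaults
are 1000 permutations and seed 42, and the seed is stored in the result
object.

Residuals are the direct per-link Procrustes distances (not jackknife
estimates). `classifyResiduals()` bands them by dataset-specific
quantiles under the type-7 (linear interpolation) definition: low
[0, Q1), medium [Q1, Q3], upper-medium (Q3, p90), high [p90, ∞), and
extreme outliers beyond Q3 + 3·IQR. Quantile definitions differ across
software, so the choice is fixed and documented; with all residuals
equal everything is medium and nothing is extreme. Fixed threshold sets
can replace the data-driven quantiles; the package ships the published
PaaA–PaaC threshold sets (`publishedBandThresholds()`), which carry two
variants of the 90th percentile (3.45 and 3.39) because the source
reports both roundings — both are preserved, flagged by set name.

Robinson–Foulds distances are computed on non-trivial bipartitions and
normalized by the attainable maximum — the total internal edge count of
the two unrooted trees, which is 2(n − 3) for binary trees and smaller
in the presence of polytomies.

The association stage cross-tabulates configuration against residual
band. Effect size is Bergsma's bias-corrected Cramér's V (the
uncorrected V is upward-biased exactly in the sparse, uneven tables
this analysis produces); inference leans on the permutation
independence test (default 9,999 resamples) rather than the asymptotic
χ², again because of sparseness; and the cells driving departures are
read from *adjusted* standardized residuals
(O − E)/√(E(1 − rᵢ/n)(1 − cⱼ/n)) — the default, with plain Pearson
residuals behind a flag, since "standardized residual" is used for both
in practice. Zero expected counts yield flagged NaN, never a silent 0.

## What the generator emulates — and what it does not

`simulationConfig()` fixes the study conditions for all tests:

* **Genomes** (default 200-gene replicons): one planted cluster per
  genome drawn from a configuration mixture (FP 0.35, UP 0.20, EM 0.15,
  PM 0.15, OC 0.15 — complete pathways most common, mirroring the
  predominance of FP among retained contexts), regulator mixture
  (PaaX 0.35, PaaR 0.30, NP 0.25, PaaR–X 0.10), PaaY probability 0.3,
  cluster layouts taken from the experimentally characterised gene
  orders, 10% interruption probability, Poisson(1) AMP-binding-only
  decoys, optional deletions (off by default so the clean-recovery
  contract is exact).
* **Domain hits**: per-role canonical architectures with ±3-residue
  coordinate jitter, i-Evalues 1e-60..1e-10, plus spurious overlapping
  hits at rate 0.1 — half above the e-value threshold (the filter must
  drop them), half below but strictly nested inside a true tile (the
  maximal-coverage objective must exclude them).
* **Motifs**: widths 12–30 and anchor-column probability 0.95. Both
  come from a detectability calculation rather than taste: a 6-residue
  motif cannot clear the default site threshold in a 500-residue
  sequence even at consensus (~24 bits at best against the ~22.5
  needed), and indeed the short conserved cores (SSGTGG-like) of real
  PAL motifs are reported *inside* wider MEME motifs; near-invariant
  columns (0.95) model exactly those cores. Positives receive one
  sampled site of every motif at non-overlapping positions; negatives
  are pure background over a fixed average amino-acid composition
  shipped as data.
* **Tree pairs**: a Yule tree (default 30 tips, birth rate 1) copied,
  branch lengths jittered by multiplicative lognormal noise
  (sdlog 0.05 — mild rate heterogeneity that keeps lengths positive),
  and `n_tip_swaps = 2` disjoint label exchanges. Swapped pairs are
  constrained to tips at least the median patristic distance apart:
  exchanging sister tips relabels the tree without changing it, so an
  unconstrained "swap" can carry a false truth label; distant
  exchanges emulate between-lineage transfer and guarantee each planted
  link a real signal. Tip swaps (not SPR moves) are used because they
  perturb exactly the planted links, matching the per-link residual
  analysis.
* **Association labels**: configuration from a fixed marginal; band
  from a configuration-specific point distribution with probability
  `effect`, else from the pooled marginal — exact independence at
  effect 0, a deterministic map at effect 1. Five band levels
  (including extreme) keep the supports disjoint across the five
  configurations.

Everything is seeded and byte-deterministic. What the generator does
*not* emulate: real sequence evolution (no substitution models),
operon transcription, pseudogenes, assembly or annotation error, and
database-scale homology structure. Passing tests therefore demonstrate
the correctness and calibration of the inference chain under its own
assumptions — not the field accuracy of the default thresholds on any
particular genome compendium.

## Problem sizes and numerical tolerances

The test suite and the acceptance script run at sizes chosen to give
stable statistics on a single core: 1,000 random tiling instances
(≤ 12 hits) against exhaustive enumeration; 10⁶ Monte-Carlo draws for
QFAST; 10,000 background sequences for scan calibration and 300 for
sensitivity; 200 genomes for configuration recovery; 500 independent
20-tip tree pairs at 199 permutations for null calibration; 100
replicates of 30-tip pairs for residual localization; n = 5,000 label
pairs for Cramér's V consistency. Numerical tolerances: PCoA distance
reconstruction to 1e-6 relative; eigenvalue cutoffs at 1e-8 of the
maximum; ln-E tie comparisons at 1e-9 relative; identity-tree m²
below 1e-10 of the configuration's total sum of squares.

## Known limitations

* Role recognition is exact-signature based (plus the PAL and TetR
  predicates); clan-aware overlap resolution and discontinuous domains
  are out of scope.
* PaaG/PaaF and single-copy PaaA/PaaC calls are counting heuristics
  and flagged ambiguous rather than resolved by synteny or phylogeny.
* Motif thresholds are calibrated for discrimination inside the
  detection funnel, not as stand-alone classifiers.
* The permutation null assumes exchangeable links; strong phylogenetic
  autocorrelation of link quality is interpreted by the residual bands,
  not modelled.
* Trees are consumed, never inferred; branch-length error propagates
  directly into patristic distances and hence residuals.
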