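#' @import methods
NULL

## Amino-acid alphabet used throughout (MEME protein ordering).
AA_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y")

#' Representative domain architecture of one protein
#'
#' An ordered, pairwise non-overlapping tiling of HMM domain hits along a
#' protein, as produced by [resolveArchitecture()]. The `tiles` slot is a
#' data.frame with one row per retained hit (columns `domain_name`,
#' `domain_accession`, `ali_start`, `ali_end`, `i_evalue`, `bit_score`),
#' sorted N-terminus to C-terminus.
#'
#' @slot protein_id single protein identifier.
#' @slot protein_length protein length in residues.
#' @slot tiles data.frame of retained, non-overlapping domain hits.
#' @slot signature domain names joined N-to-C with `+`.
#' @slot coverage fraction of residues covered by the tiles, in [0, 1].
#' @exportClass ProteinArchitecture
setClass("ProteinArchitecture",
  representation(
    protein_id     = "character",
    protein_length = "integer",
    tiles          = "data.frame",
    signature      = "character",
    coverage       = "numeric"
  )
)

setValidity("ProteinArchitecture", function(object) {
  msg <- character()
  t <- object@tiles
  if (length(object@protein_id) != 1L) msg <- c(msg, "protein_id must be length 1")
  if (object@protein_length < 0L) msg <- c(msg, "protein_length must be >= 0")
  if (nrow(t) > 0L) {
    if (is.unsorted(t$ali_start)) msg <- c(msg, "tiles must be sorted by ali_start")
    if (any(t$ali_start > t$ali_end)) msg <- c(msg, "tile with ali_start > ali_end")
    if (nrow(t) > 1L && any(t$ali_end[-nrow(t)] >= t$ali_start[-1L] + attr(t, "overlap_tol") %||% 0))
      msg <- c(msg, "tiles overlap beyond tolerance")
  }
  if (object@coverage < 0 || object@coverage > 1 + 1e-9)
    msg <- c(msg, "coverage must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Position-probability matrix for one protein motif
#'
#' A MEME-style motif: a width x 20 position-probability matrix over the
#' standard amino-acid alphabet, with background residue frequencies.
#'
#' @slot motif_id motif identifier (e.g. `PAL-1`).
#' @slot ppm numeric matrix, width rows x 20 columns (alphabet order
#'   `ACDEFGHIKLMNPQRSTVWY`); each row sums to 1.
#' @slot background length-20 background frequency vector summing to 1.
#' @slot nsites number of sites the motif was built from (0 if unknown).
#' @exportClass MotifMatrix
setClass("MotifMatrix",
  representation(
    motif_id   = "character",
    ppm        = "matrix",
    background = "numeric",
    nsites     = "integer"
  )
)

setValidity("MotifMatrix", function(object) {
  msg <- character()
  p <- object@ppm
  if (ncol(p) != 20L) msg <- c(msg, "ppm must have 20 columns")
  if (nrow(p) < 1L) msg <- c(msg, "ppm must have at least 1 row")
  if (any(p < 0)) msg <- c(msg, "ppm entries must be non-negative")
  if (nrow(p) >= 1L && any(abs(rowSums(p) - 1) > 1e-6))
    msg <- c(msg, "each ppm row must sum to 1 (tolerance 1e-6)")
  if (length(object@background) != 20L)
    msg <- c(msg, "background must have 20 entries")
  else if (abs(sum(object@background) - 1) > 1e-6)
    msg <- c(msg, "background must sum to 1 (tolerance 1e-6)")
  if (length(msg)) msg else TRUE
})

#' Gene neighbourhood around a PAL anchor
#'
#' The ordered window of genes within W positions of a PAL anchor gene on
#' one replicon. `window` is a slice of the gene table (plus a `role`
#' column when roles have been assigned).
#'
#' @slot genome_id genome identifier.
#' @slot replicon_id replicon identifier.
#' @slot anchor gene_id of the PAL anchor.
#' @slot window data.frame of genes within the window, in gene order.
#' @slot W half-window size in genes.
#' @exportClass GenomicContext
setClass("GenomicContext",
  representation(
    genome_id   = "character",
    replicon_id = "character",
    anchor      = "character",
    window      = "data.frame",
    W           = "integer"
  )
)

setValidity("GenomicContext", function(object) {
  msg <- character()
  if (nrow(object@window) > 2L * object@W + 1L)
    msg <- c(msg, "window larger than 2W + 1 genes")
  if (nrow(object@window) && !all(object@window$replicon_id == object@replicon_id))
    msg <- c(msg, "window genes must share the context replicon")
  if (!object@anchor %in% object@window$gene_id)
    msg <- c(msg, "anchor gene must be inside the window")
  if (length(msg)) msg else TRUE
})

#' Pathway configuration call for one genomic context
#'
#' @slot configuration one of `FP`, `UP`, `EM`, `PM`, `OC`.
#' @slot regulator_state one of `PaaR-X`, `PaaX`, `PaaR`, `NP`.
#' @slot paaY_present logical, PaaY inside the window.
#' @slot ambiguous logical; `TRUE` when a single shared-architecture gene
#'   (PaaA_PaaC or PaaG/PaaF) had to stand in for both paralogues.
#' @exportClass PathwayConfiguration
setClass("PathwayConfiguration",
  representation(
    configuration   = "character",
    regulator_state = "character",
    paaY_present    = "logical",
    ambiguous       = "logical"
  )
)

setValidity("PathwayConfiguration", function(object) {
  msg <- character()
  if (!object@configuration %in% c("FP", "UP", "EM", "PM", "OC"))
    msg <- c(msg, "configuration must be one of FP/UP/EM/PM/OC")
  if (!object@regulator_state %in% c("PaaR-X", "PaaX", "PaaR", "NP"))
    msg <- c(msg, "regulator_state must be one of PaaR-X/PaaX/PaaR/NP")
  if (length(msg)) msg else TRUE
})

#' Result of a Procrustean cophylogenetic analysis
#'
#' @slot m2 global sum of squared Procrustes residuals.
#' @slot p_value permutation p-value; small values indicate congruence.
#' @slot nperm number of permutations.
#' @slot seed RNG seed used for the permutations.
#' @slot residuals per-link Procrustes residuals, named `tipA--tipB`.
#' @slot links the link table used (columns `tip_a`, `tip_b`).
#' @exportClass PACoResult
setClass("PACoResult",
  representation(
    m2        = "numeric",
    p_value   = "numeric",
    nperm     = "integer",
    seed      = "integer",
    residuals = "numeric",
    links     = "data.frame"
  )
)

setValidity("PACoResult", function(object) {
  msg <- character()
  if (object@m2 < 0) msg <- c(msg, "m2 must be non-negative")
  if (object@p_value <= 0 || object@p_value > 1)
    msg <- c(msg, "p_value must lie in (0, 1]")
  if (any(object@residuals < 0)) msg <- c(msg, "residuals must be non-negative")
  if (abs(sum(object@residuals^2) - object@m2) >
      1e-6 * max(1, object@m2))
    msg <- c(msg, "m2 must equal the sum of squared residuals")
  if (length(msg)) msg else TRUE
})

#' Quantile banding of Procrustes residuals
#'
#' @slot thresholds named numeric vector `q1`, `q3`, `p90`, `extreme`
#'   (`extreme = q3 + 3 * (q3 - q1)`).
#' @slot band per-link factor with levels low/medium/upper-medium/high.
#' @slot extreme_outlier logical per link; residual above the extreme
#'   threshold.
#' @exportClass ResidualBands
setClass("ResidualBands",
  representation(
    thresholds      = "numeric",
    band            = "factor",
    extreme_outlier = "logical"
  )
)

setValidity("ResidualBands", function(object) {
  msg <- character()
  th <- object@thresholds
  if (!all(c("q1", "q3", "p90", "extreme") %in% names(th)))
    msg <- c(msg, "thresholds must contain q1, q3, p90, extreme")
  else if (!(th["q1"] <= th["q3"] && th["q3"] <= th["p90"] + 1e-12))
    msg <- c(msg, "thresholds must satisfy q1 <= q3 <= p90")
  if (length(object@band) != length(object@extreme_outlier))
    msg <- c(msg, "band and extreme_outlier lengths differ")
  if (any(object@extreme_outlier &
          !object@band %in% c("upper-medium", "high")))
    msg <- c(msg, "extreme outliers must fall in upper-medium or high bands")
  if (length(msg)) msg else TRUE
})

`%||%` <- function(a, b) if (is.null(a)) b else a
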