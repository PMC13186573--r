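## Role recognition: map resolved architectures to pathway roles.
## Domains are keyed on Pfam-style accessions (display names kept for
## humans); the whole map is plain data so users can override it for a
## different Pfam release.

#' Default role map for the PAA degradation pathway
#'
#' Associates each pathway role with the accession signature(s) of its
#' representative domain architecture. PaaA and PaaC share one
#' architecture and are mapped to the single role `PaaA_PaaC`; likewise
#' the enoyl-CoA hydratase/isomerase architecture is shared by PaaG and
#' PaaF (`PaaG_PaaF`). PAL is recognised by a positional predicate (see
#' [isPalArchitecture()]) rather than an exact signature. Any architecture
#' containing the TetR-family regulator domain counts as PaaR; this
#' deliberately over-calls TetR regulators and is flagged in downstream
#' outputs. All accessions are defaults and can be replaced wholesale.
#'
#' @param amp_binding accession of the N-terminal AMP-binding domain.
#' @param amp_binding_c accession of the C-terminal companion domain.
#' @return A list with elements `signatures` (named list role ->
#'   character vector of acceptable accession signatures), `tetr_accession`,
#'   `amp_binding`, `amp_binding_c`, `priority` (role evaluation order) and
#'   `domain_names` (accession -> display name).
#' @export
defaultRoleMap <- function(amp_binding = "PF00501",
                           amp_binding_c = "PF14535") {
  domain_names <- c(
    PF00501 = "AMP-binding",     PF14535 = "AMP-binding_C_2",
    PF05138 = "PaaA_PaaC",       PF06243 = "PaaB",
    PF01883 = "FeS_assembly_P",  PF00970 = "FAD_binding_6",
    PF00175 = "NAD_binding_1",   PF00378 = "ECH_1",
    PF02737 = "3HCDH_N",         PF00725 = "3HCDH",
    PF03061 = "4HBT",            PF00108 = "Thiolase_N",
    PF02803 = "Thiolase_C",      PF00171 = "Aldedh",
    PF00132 = "Hexapep",         PF07848 = "PaaX",
    PF08223 = "PaaX_C",          PF00440 = "TetR_N")
  names(domain_names)[1:2] <- c(amp_binding, amp_binding_c)
  sig <- function(...) paste(c(...), collapse = "+")
  list(
    amp_binding = amp_binding,
    amp_binding_c = amp_binding_c,
    tetr_accession = "PF00440",
    domain_names = domain_names,
    ## exact accession signatures per role (N-to-C)
    signatures = list(
      PaaA_PaaC = sig("PF05138"),
      PaaB      = sig("PF06243"),
      PaaD      = sig("PF01883"),
      PaaE      = c(sig("PF00970", "PF00175"), sig("PF00970")),
      PaaG_PaaF = sig("PF00378"),
      PaaH      = c(sig("PF02737", "PF00725"), sig("PF00725")),
      PaaI      = sig("PF03061"),
      PaaJ      = sig("PF00108", "PF02803"),
      PaaZ      = sig("PF00171", "PF00378"),
      PaaY      = sig("PF00132"),
      PaaX      = c(sig("PF07848", "PF08223"), sig("PF07848"))
    ),
    ## PAL first so AMP-binding decoys never shadow it; PaaZ before
    ## PaaG_PaaF is irrelevant for exact signatures but documents intent.
    priority = c("PAL", "PaaA_PaaC", "PaaB", "PaaD", "PaaE", "PaaZ",
                 "PaaG_PaaF", "PaaH", "PaaI", "PaaJ", "PaaY", "PaaX",
                 "PaaR")
  )
}

accessionSignature <- function(arch) {
  paste(arch@tiles$domain_accession, collapse = "+")
}

#' Is an architecture the PAL (phenylacetate-CoA ligase) signature?
#'
#' True when the first (most N-terminal) tile is the AMP-binding domain
#' and the last (most C-terminal) tile is its C-terminal companion
#' domain; interior domains are permitted. Proteins with the AMP-binding
#' domain alone — the typical ANL-superfamily decoy — are rejected.
#'
#' @param arch a [ProteinArchitecture-class].
#' @param role_map a role map, see [defaultRoleMap()].
#' @return logical scalar.
#' @export
isPalArchitecture <- function(arch, role_map = defaultRoleMap()) {
  t <- arch@tiles
  if (nrow(t) < 2L) return(FALSE)
  t$domain_accession[1L] == role_map$amp_binding &&
    t$domain_accession[nrow(t)] == role_map$amp_binding_c &&
    t$ali_start[1L] < t$ali_start[nrow(t)]
}

#' Assign a pathway role to a resolved architecture
#'
#' Roles are evaluated in the map's documented priority order: the PAL
#' predicate first (so that AMP-binding-only decoys are never promoted),
#' then exact accession-signature matches, then the TetR-family predicate
#' for PaaR. Returns `NA` when nothing matches.
#'
#' @inheritParams isPalArchitecture
#' @return A role name (character scalar) or `NA_character_`.
#' @export
assignRole <- function(arch, role_map = defaultRoleMap()) {
  acc_sig <- accessionSignature(arch)
  if (!nzchar(acc_sig)) return(NA_character_)
  for (role in role_map$priority) {
    hit <- switch(role,
      PAL = isPalArchitecture(arch, role_map),
      PaaR = role_map$tetr_accession %in% arch@tiles$domain_accession,
      acc_sig %in% role_map$signatures[[role]])
    if (isTRUE(hit)) return(role)
  }
  NA_character_
}

#' Resolve architectures and assign roles for a whole hit table
#'
#' Groups a domain-hit table by protein, resolves each protein's
#' representative architecture and assigns its pathway role.
#'
#' @param hits domain-hit data.frame ([readDomtblout()] layout, including
#'   `protein_length`).
#' @param role_map see [defaultRoleMap()].
#' @param evalue_max,overlap_tol passed to [resolveArchitecture()].
#' @return A data.frame with one row per protein: `protein_id`,
#'   `signature`, `accession_signature`, `coverage`, `n_tiles`, `role`,
#'   `is_pal`. The list of [ProteinArchitecture-class] objects is attached
#'   as attribute `"architectures"`.
#' @export
architectureTable <- function(hits, role_map = defaultRoleMap(),
                              evalue_max = 0.001, overlap_tol = 0L) {
  split_hits <- split(hits, hits$protein_id)
  archs <- lapply(split_hits, function(h)
    resolveArchitecture(h, protein_length = max(h$protein_length),
                        evalue_max = evalue_max, overlap_tol = overlap_tol))
  out <- data.frame(
    protein_id = names(archs),
    signature = vapply(archs, archSignature, character(1)),
    accession_signature = vapply(archs, accessionSignature, character(1)),
    coverage = vapply(archs, archCoverage, numeric(1)),
    n_tiles = vapply(archs, function(a) nrow(a@tiles), integer(1)),
    role = vapply(archs, assignRole, character(1), role_map = role_map),
    stringsAsFactors = FALSE)
  out$is_pal <- !is.na(out$role) & out$role == "PAL"
  rownames(out) <- NULL
  attr(out, "architectures") <- archs
  out
}
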