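## Genomic-context extraction and pathway-configuration classification.

#' Default configuration rules
#'
#' Gene sets underlying the configuration decision list. The epoxidation
#' module is PaaABC(D)E — PaaD optional; the upper pathway adds PaaG and
#' PaaZ; the lower pathway is PaaF, PaaH, PaaJ with PaaI optional. The
#' decision list is evaluated in the fixed order FP, UP, EM, PM, OC. The
#' whole rule set is data, not code: override any element.
#'
#' @param include_paaZ_in_upper logical; whether PaaZ is required for the
#'   upper pathway (default `TRUE`).
#' @return A list with elements `epoxidase_module`, `upper_extra`,
#'   `lower_core`, `optional` and `include_paaZ_in_upper`.
#' @export
defaultConfigurationRules <- function(include_paaZ_in_upper = TRUE) {
  list(
    epoxidase_module = c("PaaA", "PaaB", "PaaC", "PaaE"),  # PaaD optional
    upper_extra = c("PaaG", if (include_paaZ_in_upper) "PaaZ"),
    lower_core = c("PaaF", "PaaH", "PaaJ"),                # PaaI optional
    optional = c("PaaD", "PaaI"),
    include_paaZ_in_upper = include_paaZ_in_upper
  )
}

#' Extract the gene window around a PAL anchor
#'
#' Returns the genes within `W` positions of the anchor on the same
#' replicon. At linear replicon ends the window is truncated; on circular
#' replicons it wraps around, with each gene appearing at most once.
#'
#' @param genes a gene table (see [readGeneTable()]); a `role` column, if
#'   present, is carried through.
#' @param anchor `gene_id` of the PAL anchor.
#' @param W half-window size in genes (default 20).
#' @param circular treat the replicon as circular (default `FALSE`).
#' @return A [GenomicContext-class].
#' @export
extractContext <- function(genes, anchor, W = 20L, circular = FALSE) {
  i <- which(genes$gene_id == anchor)
  if (length(i) != 1L)
    stop("anchor gene ", anchor, if (length(i)) " is ambiguous" else " not found",
         " in the gene table")
  g0 <- genes$genome_id[i]
  rep0 <- genes$replicon_id[i]
  sub <- genes[genes$genome_id == g0 & genes$replicon_id == rep0, , drop = FALSE]
  sub <- sub[order(sub$position_index), , drop = FALSE]
  n <- nrow(sub)
  pos0 <- genes$position_index[i]
  if (circular) {
    d <- abs(sub$position_index - pos0)
    d <- pmin(d, n - d)
    win <- sub[d <= W, , drop = FALSE]
  } else {
    win <- sub[abs(sub$position_index - pos0) <= W, , drop = FALSE]
  }
  rownames(win) <- NULL
  new("GenomicContext", genome_id = g0, replicon_id = rep0,
      anchor = anchor, window = win, W = as.integer(W))
}

## Effective role presence in a window, handling shared-architecture
## paralogues. Returns a list of logical presence per role plus ambiguity.
roleCensus <- function(roles) {
  roles <- roles[!is.na(roles)]
  n_ac <- sum(roles == "PaaA_PaaC")
  n_gf <- sum(roles == "PaaG_PaaF")
  list(
    paaA = n_ac >= 2L, paaC = n_ac >= 2L, n_paaAC = n_ac,
    paaG = n_gf >= 1L,            # a single shared gene counts as PaaG
    paaF = n_gf >= 2L,
    ambiguous = (n_ac == 1L) || (n_gf == 1L),
    has = function(r) r %in% roles,
    roles = roles
  )
}

#' Classify a genomic context into a pathway configuration
#'
#' Applies the decision list FP, UP, EM, PM, OC over role membership of
#' the window (gene order within the window is irrelevant):
#' \itemize{
#'   \item FP: upper pathway and lower pathway both present;
#'   \item UP: upper pathway present, lower absent;
#'   \item EM: epoxidation module PaaABC(D)E present but not the full
#'     upper pathway;
#'   \item PM: PaaA and PaaC present without the complete module;
#'   \item OC: everything else (PaaA or PaaC missing).
#' }
#' Two genes with the shared PaaA/PaaC architecture count as one PaaA and
#' one PaaC; exactly one such gene satisfies only the PM predicate and
#' flags the call as ambiguous. The shared PaaG/PaaF architecture is
#' handled the same way: one copy counts as PaaG (upper), a second as
#' PaaF (lower). The regulator state is PaaR-X / PaaX / PaaR / NP from
#' window membership, and the PaaY flag is window membership of PaaY.
#'
#' @param ctx a [GenomicContext-class] whose window has a `role` column.
#' @param rules see [defaultConfigurationRules()].
#' @return A [PathwayConfiguration-class].
#' @export
classifyConfiguration <- function(ctx, rules = defaultConfigurationRules()) {
  win <- ctx@window
  if (!"role" %in% names(win))
    stop("context window has no 'role' column; assign roles first")
  cen <- roleCensus(win$role)
  present <- function(role) switch(role,
    PaaA = cen$paaA, PaaC = cen$paaC, PaaG = cen$paaG, PaaF = cen$paaF,
    cen$has(role))
  em <- all(vapply(rules$epoxidase_module, present, logical(1)))
  upper <- em && all(vapply(rules$upper_extra, present, logical(1)))
  lower <- all(vapply(rules$lower_core, present, logical(1)))
  cfg <- if (upper && lower) "FP"
    else if (upper) "UP"
    else if (em) "EM"
    else if ((cen$paaA && cen$paaC) || cen$n_paaAC == 1L) "PM"
    else "OC"
  has_x <- cen$has("PaaX"); has_r <- cen$has("PaaR")
  reg <- if (has_x && has_r) "PaaR-X" else if (has_x) "PaaX"
    else if (has_r) "PaaR" else "NP"
  new("PathwayConfiguration", configuration = cfg, regulator_state = reg,
      paaY_present = cen$has("PaaY"),
      ambiguous = cen$ambiguous)
}

#' Co-occurrence summary over a set of contexts
#'
#' Counts, for each observed combination of pathway roles, how many
#' contexts exhibit exactly that combination (UpSet-style intersection
#' sizes), and per role how often it occurs inside versus outside any PAL
#' window.
#'
#' @param contexts list of [GenomicContext-class] objects with assigned
#'   roles.
#' @param genes optional full gene table with a `role` column, used for
#'   the outside counts; when omitted, outside counts are `NA`.
#' @return list with `combinations` (data.frame: roles, n_contexts) and
#'   `role_counts` (data.frame: role, inside, outside).
#' @export
coOccurrenceSummary <- function(contexts, genes = NULL) {
  combos <- vapply(contexts, function(ctx) {
    r <- ctx@window$role
    paste(sort(unique(r[!is.na(r)])), collapse = "+")
  }, character(1))
  tab <- table(combos)
  combinations <- data.frame(roles = names(tab),
                             n_contexts = as.integer(tab),
                             stringsAsFactors = FALSE)
  combinations <- combinations[order(-combinations$n_contexts), ]
  rownames(combinations) <- NULL
  inside_ids <- unique(unlist(lapply(contexts, function(ctx)
    ctx@window$gene_id)))
  all_roles <- sort(unique(unlist(lapply(contexts, function(ctx) {
    r <- ctx@window$role; r[!is.na(r)]
  }))))
  if (!is.null(genes) && "role" %in% names(genes))
    all_roles <- sort(unique(c(all_roles,
                               genes$role[!is.na(genes$role)])))
  role_counts <- data.frame(role = all_roles, stringsAsFactors = FALSE)
  if (!is.null(genes) && "role" %in% names(genes)) {
    inside <- genes$gene_id %in% inside_ids
    role_counts$inside <- vapply(all_roles, function(r)
      sum(genes$role == r & inside, na.rm = TRUE), integer(1))
    role_counts$outside <- vapply(all_roles, function(r)
      sum(genes$role == r & !inside, na.rm = TRUE), integer(1))
  } else {
    counts <- table(unlist(lapply(contexts, function(ctx) {
      r <- ctx@window$role; r[!is.na(r)]
    })))
    role_counts$inside <- as.integer(counts[all_roles])
    role_counts$outside <- NA_integer_
  }
  list(combinations = combinations, role_counts = role_counts)
}

#' Full PAL-candidate funnel for one genome set
#'
#' Combines the three evidence layers: candidates are proteins whose
#' architecture satisfies the PAL predicate *and* whose motif profile
#' passes the scan filter; each candidate's genomic context is then
#' classified, and candidates whose context is FP/UP/EM/PM are retained
#' as probable orthologues while the rest are kept separately as OC
#' paralogs.
#'
#' @param arch_table output of [architectureTable()].
#' @param profiles motif profile data.frame ([scanSequences()]
#'   `$profiles`), keyed by `sequence_id` = protein id.
#' @param genes gene table covering every protein in `arch_table`.
#' @param rules see [defaultConfigurationRules()].
#' @param W,circular passed to [extractContext()].
#' @return data.frame with one row per PAL candidate: `genome_id`,
#'   `gene_id`, `protein_id`, `configuration`, `regulator_state`,
#'   `paaY_present`, `ambiguous`, `retained`.
#' @export
palCandidatePipeline <- function(arch_table, profiles, genes,
                                 rules = defaultConfigurationRules(),
                                 W = 20L, circular = FALSE) {
  genes$role <- arch_table$role[match(genes$protein_id,
                                      arch_table$protein_id)]
  cand <- arch_table$protein_id[arch_table$is_pal]
  passed <- profiles$sequence_id[profiles$passes_filter]
  orphans <- setdiff(passed, arch_table$protein_id)
  if (length(orphans))
    stop("motif profiles reference unknown proteins: ",
         paste(orphans, collapse = ", "))
  cand <- intersect(cand, passed)
  if (!length(cand))
    return(data.frame(genome_id = character(), gene_id = character(),
                      protein_id = character(), configuration = character(),
                      regulator_state = character(), paaY_present = logical(),
                      ambiguous = logical(), retained = logical(),
                      stringsAsFactors = FALSE))
  miss <- setdiff(cand, genes$protein_id)
  if (length(miss))
    stop("PAL candidates missing from the gene table: ",
         paste(miss, collapse = ", "))
  rows <- lapply(cand, function(p) {
    gi <- genes[genes$protein_id == p, , drop = FALSE][1, ]
    ctx <- extractContext(genes, gi$gene_id, W = W, circular = circular)
    cfg <- classifyConfiguration(ctx, rules)
    data.frame(genome_id = gi$genome_id, gene_id = gi$gene_id,
               protein_id = p,
               configuration = cfg@configuration,
               regulator_state = cfg@regulator_state,
               paaY_present = cfg@paaY_present,
               ambiguous = cfg@ambiguous,
               retained = cfg@configuration %in% c("FP", "UP", "EM", "PM"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
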