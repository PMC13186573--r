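## Architecture resolution: choose, among all pairwise non-overlapping
## subsets of the e-value-filtered domain hits, the one covering the most
## residues; ties broken by minimal sum of ln(i-Evalue), then by the
## lexicographically smallest ali_start list.

LN_EVALUE_FLOOR <- log(.Machine$double.xmin)

#' Resolve the representative domain architecture of a protein
#'
#' Domain hits below the e-value threshold are tiled so that the retained
#' hits are pairwise non-overlapping and cover the maximum number of
#' residues; among equally covering subsets the one with the smallest
#' total `ln(i_evalue)` wins, and remaining ties go to the
#' lexicographically smallest vector of alignment starts. The optimum is
#' found by weighted-interval-scheduling dynamic programming over hits
#' sorted by alignment end; the lexicographic tie-break is enforced by a
#' greedy reconstruction that keeps a hit only when an optimal completion
#' still exists.
#'
#' @param hits data.frame of domain hits for one protein (columns as
#'   returned by [readDomtblout()]).
#' @param protein_length protein length in residues; must be at least the
#'   largest `ali_end`.
#' @param evalue_max inclusive i-Evalue threshold (default 0.001).
#' @param overlap_tol residues of shared overlap tolerated between
#'   consecutive tiles (default 0: any shared residue is an overlap).
#' @return A [ProteinArchitecture-class] object. With no hit surviving the
#'   filter the architecture has zero tiles and coverage 0.
#' @examples
#' hits <- data.frame(protein_id = "p1", protein_length = 210L,
#'   domain_name = c("A", "B", "C"), domain_accession = c("PF1", "PF2", "PF3"),
#'   ali_start = c(10L, 90L, 110L), ali_end = c(100L, 200L, 200L),
#'   i_evalue = c(1e-50, 1e-30, 1e-10), bit_score = c(100, 80, 60))
#' resolveArchitecture(hits, 210L)
#' @export
resolveArchitecture <- function(hits, protein_length,
                                evalue_max = 0.001, overlap_tol = 0L) {
  pid <- unique(hits$protein_id)
  if (length(pid) > 1L)
    stop("hits span multiple proteins: ", paste(pid, collapse = ", "))
  if (length(pid) == 0L) pid <- NA_character_
  protein_length <- as.integer(protein_length)
  if (nrow(hits) && protein_length < max(hits$ali_end))
    stop("protein_length smaller than the largest ali_end")
  h <- hits[hits$i_evalue <= evalue_max, , drop = FALSE]
  sel <- selectTiles(h, overlap_tol)
  tiles <- h[sel, , drop = FALSE]
  tiles <- tiles[order(tiles$ali_start), , drop = FALSE]
  rownames(tiles) <- NULL
  attr(tiles, "overlap_tol") <- as.integer(overlap_tol)
  covered <- if (nrow(tiles)) sum(tiles$ali_end - tiles$ali_start + 1L) else 0L
  new("ProteinArchitecture",
      protein_id = pid,
      protein_length = protein_length,
      tiles = tiles,
      signature = paste(tiles$domain_name, collapse = "+"),
      coverage = if (protein_length > 0L) min(1, covered / protein_length) else 0)
}

## DP value of the best tiling of hits (rows of h); returns c(coverage,
## -sum ln e-value) maximised lexicographically.
tilingValue <- function(h, overlap_tol) {
  n <- nrow(h)
  if (!n) return(c(0, 0))
  o <- order(h$ali_end, h$ali_start)
  s <- h$ali_start[o]; e <- h$ali_end[o]
  w <- e - s + 1
  lnE <- pmax(log(h$i_evalue[o]), LN_EVALUE_FLOOR)
  best_cov <- numeric(n + 1L)  # best over first i hits (by end)
  best_ln  <- numeric(n + 1L)  # ln-sum companion (to minimise)
  for (i in seq_len(n)) {
    # last hit compatible before hit i: end <= start_i - 1 + overlap_tol
    j <- findInterval(s[i] - 1L + overlap_tol, e)
    cov_take <- best_cov[j + 1L] + w[i]
    ln_take  <- best_ln[j + 1L] + lnE[i]
    if (cov_take > best_cov[i] ||
        (cov_take == best_cov[i] && ln_take < best_ln[i])) {
      best_cov[i + 1L] <- cov_take
      best_ln[i + 1L]  <- ln_take
    } else {
      best_cov[i + 1L] <- best_cov[i]
      best_ln[i + 1L]  <- best_ln[i]
    }
  }
  c(best_cov[n + 1L], -best_ln[n + 1L])
}

## Row indices (into h) of the optimal tiling, lexicographically smallest
## ali_start list among the (coverage, ln-sum) optima. Greedy: walk hits in
## (ali_start, ali_end, lnE) order and keep a hit iff an optimal completion
## of the partial solution still exists.
selectTiles <- function(h, overlap_tol) {
  n <- nrow(h)
  if (!n) return(integer())
  opt <- tilingValue(h, overlap_tol)
  ord <- order(h$ali_start, h$ali_end,
               pmax(log(h$i_evalue), LN_EVALUE_FLOOR))
  chosen <- integer()
  cov_acc <- 0; ln_acc <- 0
  last_end <- -Inf
  remaining <- ord
  while (length(remaining)) {
    i <- remaining[1L]
    remaining <- remaining[-1L]
    if (h$ali_start[i] - 1L + overlap_tol < last_end) next
    # value if we fix hit i and optimally complete with later-starting,
    # compatible hits
    tail_rows <- remaining[h$ali_start[remaining] - 1L + overlap_tol >=
                             h$ali_end[i]]
    v_tail <- tilingValue(h[tail_rows, , drop = FALSE], overlap_tol)
    cov_i <- cov_acc + (h$ali_end[i] - h$ali_start[i] + 1) + v_tail[1L]
    ln_i <- -( -ln_acc - pmax(log(h$i_evalue[i]), LN_EVALUE_FLOOR) + v_tail[2L])
    take <- (cov_i == opt[1L]) && (abs(ln_i - (-opt[2L])) <= 1e-9 * max(1, abs(opt[2L])))
    if (take) {
      chosen <- c(chosen, i)
      cov_acc <- cov_acc + (h$ali_end[i] - h$ali_start[i] + 1)
      ln_acc <- ln_acc + pmax(log(h$i_evalue[i]), LN_EVALUE_FLOOR)
      last_end <- h$ali_end[i]
      remaining <- remaining[h$ali_start[remaining] - 1L + overlap_tol >=
                               last_end]
    }
  }
  chosen
}
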