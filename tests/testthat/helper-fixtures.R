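## Shared fixtures and independent oracles used across test files.

## ---- random domain-hit instances -------------------------------------

randomHitInstance <- function(n_hits, protein_length = 300L) {
  a <- sample.int(protein_length - 10L, n_hits, replace = TRUE)
  len <- sample(5:80, n_hits, replace = TRUE)
  b <- pmin(a + len, protein_length)
  data.frame(
    protein_id = "px", protein_length = protein_length,
    domain_name = paste0("D", seq_len(n_hits)),
    domain_accession = paste0("PF", sprintf("%05d", seq_len(n_hits))),
    ali_start = as.integer(a), ali_end = as.integer(b),
    i_evalue = 10^runif(n_hits, -60, -4),
    bit_score = runif(n_hits, 10, 300),
    stringsAsFactors = FALSE)
}

## Brute-force tiling oracle: enumerate every subset, keep pairwise
## compatible ones, maximise (coverage, -sum ln e-value), and report the
## optimal value plus the lexicographically smallest start list among the
## optima. Independent of the DP (bitmask enumeration).
bruteForceTiling <- function(h, overlap_tol = 0L) {
  n <- nrow(h)
  best <- c(0, 0)  # coverage, -sum ln
  best_starts <- integer()
  compat <- outer(seq_len(n), seq_len(n), function(i, j)
    h$ali_end[i] <= h$ali_start[j] - 1L + overlap_tol |
    h$ali_end[j] <= h$ali_start[i] - 1L + overlap_tol)
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(idx) > 1L) {
      prs <- utils::combn(idx, 2L)
      if (!all(compat[cbind(prs[1, ], prs[2, ])])) next
    }
    cov <- sum(h$ali_end[idx] - h$ali_start[idx] + 1)
    ln <- -sum(log(h$i_evalue[idx]))
    starts <- sort(h$ali_start[idx])
    if (cov > best[1] ||
        (cov == best[1] && ln > best[2] + 1e-9) ||
        (cov == best[1] && abs(ln - best[2]) <= 1e-9 &&
         lexLess(starts, best_starts))) {
      best <- c(cov, ln)
      best_starts <- starts
    }
  }
  list(coverage = best[1], neg_ln_sum = best[2], starts = best_starts)
}

lexLess <- function(a, b) {
  k <- min(length(a), length(b))
  if (k > 0) for (i in seq_len(k)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

## ---- gene-table construction from a role layout ----------------------

## Build a one-replicon gene table from a vector of roles (NA =
## background gene), e.g. layoutGenome(c(NA, "PaaZ", "PAL", NA)).
layoutGenome <- function(roles, genome_id = "gtest", pad = 25L) {
  roles <- c(rep(NA_character_, pad), roles, rep(NA_character_, pad))
  n <- length(roles)
  data.frame(
    genome_id = genome_id, replicon_id = "chr",
    position_index = 0:(n - 1L),
    strand = "+",
    gene_id = sprintf("%s_g%03d", genome_id, seq_len(n)),
    protein_id = sprintf("%s_p%03d", genome_id, seq_len(n)),
    role = roles,
    stringsAsFactors = FALSE)
}

anchorOf <- function(genes) genes$gene_id[which(genes$role == "PAL")[1]]

classifyLayout <- function(roles, ...) {
  g <- layoutGenome(roles)
  classifyConfiguration(extractContext(g, anchorOf(g), ...))
}

## ---- independent patristic oracle ------------------------------------

## All-pairs path sums over the tree's edge list via breadth-first search
## on the undirected edge graph (independent of ape's cophenetic).
bfsPatristic <- function(tree) {
  n <- ape::Ntip(tree)
  nv <- n + tree$Nnode
  adj <- vector("list", nv)
  for (e in seq_len(nrow(tree$edge))) {
    i <- tree$edge[e, 1]; j <- tree$edge[e, 2]; w <- tree$edge.length[e]
    adj[[i]] <- rbind(adj[[i]], c(j, w))
    adj[[j]] <- rbind(adj[[j]], c(i, w))
  }
  D <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (s in seq_len(n)) {
    dist <- rep(NA_real_, nv); dist[s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- adj[[v]]
      if (is.null(nb)) next
      for (r in seq_len(nrow(nb))) {
        u <- nb[r, 1]
        if (is.na(dist[u])) {
          dist[u] <- dist[v] + nb[r, 2]
          queue <- c(queue, u)
        }
      }
    }
    D[s, ] <- dist[seq_len(n)]
  }
  D
}

## ---- misc ------------------------------------------------------------

randomEuclideanD <- function(n, k = 3) {
  P <- matrix(rnorm(n * k), n)
  as.matrix(stats::dist(P))
}

writeLinesTmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
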