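## Categorical association between pathway configuration and residual
## band: Pearson chi-squared, bias-corrected Cramer's V (Bergsma),
## permutation independence test, adjusted standardized residuals.

asContingency <- function(t, drop_empty = FALSE) {
  t <- as.matrix(t)
  if (any(t < 0) || any(t != round(t)))
    stop("contingency table must hold non-negative integer counts")
  if (drop_empty) {
    t <- t[rowSums(t) > 0, colSums(t) > 0, drop = FALSE]
  }
  if (any(rowSums(t) == 0) || any(colSums(t) == 0))
    stop("zero row or column margin (use drop_empty = TRUE to drop)")
  if (nrow(t) < 2L || ncol(t) < 2L)
    stop("need at least 2 rows and 2 columns")
  t
}

#' Pearson chi-squared test for a contingency table
#'
#' Plain Pearson test (no continuity correction) through
#' [stats::chisq.test()].
#'
#' @param t contingency table (matrix of counts).
#' @param drop_empty drop all-zero rows/columns instead of erroring.
#' @return list with `statistic`, `df`, `p_value`, `expected`.
#' @export
chi2Test <- function(t, drop_empty = FALSE) {
  t <- asContingency(t, drop_empty)
  ct <- suppressWarnings(stats::chisq.test(t, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value), expected = ct$expected)
}

#' Bias-corrected Cramer's V
#'
#' Bergsma's bias-corrected version:
#' `phi2 = chi2 / n`; `phi2~ = max(0, phi2 - (r-1)(c-1)/(n-1))`;
#' `r~ = r - (r-1)^2/(n-1)`; `c~ = c - (c-1)^2/(n-1)`;
#' `V = sqrt(phi2~ / min(r~ - 1, c~ - 1))`.
#'
#' @inheritParams chi2Test
#' @return V in [0, 1].
#' @examples
#' cramersV(matrix(c(10, 0, 0, 10), 2))  # exactly 1
#' @export
cramersV <- function(t, drop_empty = FALSE) {
  t <- asContingency(t, drop_empty)
  n <- sum(t)
  r <- nrow(t); cc <- ncol(t)
  chi2 <- suppressWarnings(stats::chisq.test(t, correct = FALSE))$statistic
  phi2 <- unname(chi2) / n
  phi2c <- max(0, phi2 - (r - 1) * (cc - 1) / (n - 1))
  rt <- r - (r - 1)^2 / (n - 1)
  ct <- cc - (cc - 1)^2 / (n - 1)
  denom <- min(rt - 1, ct - 1)
  if (denom <= 0) {
    warning("degenerate corrected dimensions; returning V = 0")
    return(0)
  }
  sqrt(phi2c / denom)
}

#' Permutation test of independence for paired categorical labels
#'
#' The observed Pearson chi-squared statistic of the cross-tabulation is
#' compared with its distribution under random reassignment of the second
#' label vector. Because both margins are fixed under permutation, the
#' expected counts are computed once.
#' `p = (1 + #\{chi2_perm >= chi2_obs\}) / (1 + nperm)`.
#'
#' @param labels_a,labels_b equal-length label vectors.
#' @param nperm number of permutations (default 9999).
#' @param seed RNG seed (default 42).
#' @return list with `p_value`, `statistic`, `nperm`, `seed`.
#' @export
permutationIndependence <- function(labels_a, labels_b,
                                    nperm = 9999L, seed = 42L) {
  if (length(labels_a) != length(labels_b))
    stop("label vectors must have equal length")
  a <- factor(labels_a); b <- factor(labels_b)
  a <- droplevels(a); b <- droplevels(b)
  if (nlevels(a) < 2L || nlevels(b) < 2L)
    stop("need at least 2 levels in each label vector")
  ai <- as.integer(a); bi <- as.integer(b)
  r <- nlevels(a); cc <- nlevels(b)
  n <- length(ai)
  E <- outer(tabulate(ai, r), tabulate(bi, cc)) / n
  chi2_of <- function(bperm) {
    O <- matrix(tabulate((ai - 1L) * cc + bperm, r * cc),
                nrow = r, byrow = TRUE)
    sum((O - E)^2 / E)
  }
  obs <- chi2_of(bi)
  nperm <- as.integer(nperm)
  count <- 0L
  withSeed(as.integer(seed), {
    for (k in seq_len(nperm)) {
      if (chi2_of(bi[sample.int(n)]) >= obs - 1e-12) count <- count + 1L
    }
  })
  list(p_value = (1 + count) / (1 + nperm), statistic = obs,
       nperm = nperm, seed = as.integer(seed))
}

#' Standardized residuals of a contingency table
#'
#' Adjusted standardized residuals by default:
#' `(O - E) / sqrt(E (1 - row_i/n) (1 - col_j/n))`; positive values mark
#' over-represented cells, negative under-represented ones. `type =
#' "pearson"` gives `(O - E) / sqrt(E)`. Cells with zero expected count
#' yield `NaN` (flagged by a warning) rather than a silent 0.
#'
#' @inheritParams chi2Test
#' @param type `"adjusted"` (default) or `"pearson"`.
#' @return numeric matrix of residuals, same dimnames as `t`.
#' @export
standardizedResiduals <- function(t, type = c("adjusted", "pearson"),
                                  drop_empty = FALSE) {
  type <- match.arg(type)
  t <- asContingency(t, drop_empty)
  n <- sum(t)
  E <- outer(rowSums(t), colSums(t)) / n
  if (any(E == 0)) warning("zero expected counts produce undefined residuals")
  if (type == "pearson") return((t - E) / sqrt(E))
  adj <- sqrt(E * outer(1 - rowSums(t) / n, 1 - colSums(t) / n))
  (t - E) / adj
}
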