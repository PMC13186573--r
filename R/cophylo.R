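## Procrustean cophylogeny: patristic distances -> Cailliez correction ->
## principal coordinates -> Procrustes superimposition -> permutation test
## -> quantile residual bands; plus normalized Robinson-Foulds distance.

#' Patristic distance matrix of a tree
#'
#' Sum of branch lengths along the path between every pair of tips
#' (cophenetic distances), computed with [ape::cophenetic.phylo()].
#'
#' @param tree an [ape::phylo] with branch lengths.
#' @return symmetric numeric matrix with tip labels as dimnames.
#' @export
patristicMatrix <- function(tree) {
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("tree has missing branch lengths")
  ape::cophenetic.phylo(tree)
}

#' Cailliez correction of a dissimilarity matrix
#'
#' Finds the smallest constant `c` such that adding `c` to every
#' off-diagonal dissimilarity makes the matrix Euclidean-embeddable:
#' the largest real eigenvalue of the standard 2n x 2n companion matrix
#' built from the doubly centred `-D^2/2` and `-D/2` matrices. Matrices
#' that are already Euclidean get `c = 0`.
#'
#' @param D symmetric dissimilarity matrix with zero diagonal.
#' @param tol eigenvalue tolerance for deciding `D` is already Euclidean.
#' @return list with `D_corrected` and the constant `c`.
#' @export
cailliezCorrection <- function(D, tol = 1e-8) {
  D <- as.matrix(D)
  if (!isSymmetric(unname(D), tol = 1e-8))
    stop("D must be symmetric")
  n <- nrow(D)
  if (minGramEigenvalue(D) >= -tol * max(1, max(abs(D)))) {
    return(list(D_corrected = D, c = 0))
  }
  delta1 <- doubleCentre(-0.5 * D^2)
  delta2 <- doubleCentre(-0.5 * D)
  companion <- rbind(cbind(matrix(0, n, n), 2 * delta1),
                     cbind(-diag(n), -4 * delta2))
  ev <- eigen(companion, only.values = TRUE)$values
  cc <- max(Re(ev[abs(Im(ev)) < 1e-8 * max(1, abs(Re(ev)))]))
  cc <- max(cc, 0)
  Dc <- D + cc
  diag(Dc) <- 0
  list(D_corrected = Dc, c = cc)
}

doubleCentre <- function(M) {
  n <- nrow(M)
  J <- diag(n) - matrix(1 / n, n, n)
  J %*% M %*% J
}

minGramEigenvalue <- function(D) {
  G <- doubleCentre(-0.5 * D^2)
  min(eigen((G + t(G)) / 2, symmetric = TRUE, only.values = TRUE)$values)
}

#' Principal-coordinates embedding of a dissimilarity matrix
#'
#' Classical PCoA: the doubly centred Gram matrix is
#' eigen-decomposed and coordinates are eigenvectors scaled by the square
#' roots of the eigenvalues. Axes with eigenvalue below
#' `tol * max(eigenvalue)` are dropped.
#'
#' @param D symmetric dissimilarity matrix (Euclidean-embeddable; apply
#'   [cailliezCorrection()] first if needed).
#' @param tol relative eigenvalue cutoff for retained axes (default 1e-8).
#' @return numeric matrix, one row per object, rownames preserved.
#' @export
pcoaCoords <- function(D, tol = 1e-8) {
  D <- as.matrix(D)
  G <- doubleCentre(-0.5 * D^2)
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  keep <- e$values > tol * max(e$values, 0)
  if (!any(keep)) {
    out <- matrix(0, nrow(D), 1L)
    rownames(out) <- rownames(D)
    return(out)
  }
  out <- e$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(e$values[keep]), sum(keep))
  rownames(out) <- rownames(D)
  out
}

#' Procrustes superimposition of two configurations
#'
#' Least-squares translation, orthogonal rotation (reflection allowed)
#' and isotropic scaling of `Y` onto `X` via the singular-value
#' decomposition of the centred cross-product. The narrower configuration
#' is zero-padded so both have the same number of columns.
#'
#' @param X,Y numeric matrices with matched rows (n x k).
#' @return list with `m2` (sum of squared residuals), `residuals`
#'   (per-row distances between `X` and fitted `Y`), `rotation`, `scale`.
#' @export
procrustesSuperimpose <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same number of rows")
  if (nrow(X) < 3L) stop("need at least 3 matched rows")
  k <- max(ncol(X), ncol(Y))
  X <- cbind(X, matrix(0, nrow(X), k - ncol(X)))
  Y <- cbind(Y, matrix(0, nrow(Y), k - ncol(Y)))
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  sv <- svd(crossprod(Xc, Yc))
  R <- sv$v %*% t(sv$u)
  trY <- sum(Yc^2)
  s <- if (trY > 0) sum(sv$d) / trY else 1
  fit <- s * Yc %*% R
  res <- sqrt(rowSums((Xc - fit)^2))
  list(m2 = sum((Xc - fit)^2), residuals = res, rotation = R, scale = s)
}

#' Procrustean cophylogenetic analysis (PACo)
#'
#' Runs the full chain for two trees and a tip association table:
#' patristic distances, Cailliez correction, principal coordinates, link
#' selection, Procrustes superimposition of the second tree's
#' configuration onto the first, and a permutation test in which the link
#' assignment is randomly shuffled. With the 1:1 identity association this
#' link-shuffling null is the binary-matrix ("r2"-style) row
#' randomization specialised to bijective links. Small `m2` and small
#' p-values indicate congruence; the p-value counts permuted `m2` values
#' at or below the observed one:
#' `p = (1 + #\{m2_perm <= m2_obs\}) / (1 + nperm)`.
#'
#' @param tree_a,tree_c [ape::phylo] trees (e.g. PaaA and PaaC gene
#'   trees).
#' @param links data.frame with columns `tip_a`, `tip_b`; every value
#'   must be a tip of the corresponding tree. Default: identity links over
#'   the shared tip labels.
#' @param nperm number of permutations (default 1000).
#' @param seed RNG seed for the permutations (default 42).
#' @return a [PACoResult-class].
#' @export
paco <- function(tree_a, tree_c, links = NULL, nperm = 1000L, seed = 42L) {
  if (is.null(links)) {
    shared <- intersect(tree_a$tip.label, tree_c$tip.label)
    links <- data.frame(tip_a = shared, tip_b = shared,
                        stringsAsFactors = FALSE)
  }
  if (nrow(links) < 3L) stop("need at least 3 links")
  if (!all(links$tip_a %in% tree_a$tip.label))
    stop("links reference tips absent from tree A")
  if (!all(links$tip_b %in% tree_c$tip.label))
    stop("links reference tips absent from tree C")
  XA <- pcoaCoords(cailliezCorrection(patristicMatrix(tree_a))$D_corrected)
  XC <- pcoaCoords(cailliezCorrection(patristicMatrix(tree_c))$D_corrected)
  X <- XA[links$tip_a, , drop = FALSE]
  Y <- XC[links$tip_b, , drop = FALSE]
  obs <- procrustesSuperimpose(X, Y)
  nperm <- as.integer(nperm)
  seed <- as.integer(seed)
  n <- nrow(Y)
  count <- 0L
  withSeed(seed, {
    for (b in seq_len(nperm)) {
      perm <- sample.int(n)
      m2p <- procrustesM2(X, Y[perm, , drop = FALSE])
      if (m2p <= obs$m2) count <- count + 1L
    }
  })
  res <- obs$residuals
  names(res) <- paste0(links$tip_a, "--", links$tip_b)
  new("PACoResult", m2 = obs$m2,
      p_value = (1 + count) / (1 + nperm),
      nperm = nperm, seed = seed, residuals = res,
      links = links[, c("tip_a", "tip_b")])
}

## m2 only (no residuals): trace shortcut for the permutation loop.
procrustesM2 <- function(X, Y) {
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  d <- svd(crossprod(Xc, Yc), nu = 0, nv = 0)$d
  trY <- sum(Yc^2)
  sum(Xc^2) - if (trY > 0) sum(d)^2 / trY else 0
}

## Evaluate expr with a local RNG state restored afterwards.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  eval.parent(substitute(expr))
}

#' Quantile banding of Procrustes residuals
#'
#' Classifies residuals into bands using dataset-specific quantiles
#' (linear interpolation between order statistics, R quantile type 7):
#' low `[0, Q1)`, medium `[Q1, Q3]`, upper-medium `(Q3, p90)`, high
#' `[p90, Inf)`; extreme outliers exceed `Q3 + 3 * IQR`. Fixed
#' thresholds — for example ones published for another dataset — can be
#' supplied instead of computing them from the data.
#'
#' @param residuals non-negative residual vector (or a
#'   [PACoResult-class]).
#' @param thresholds optional named vector with `q1`, `q3`, `p90` (and
#'   optionally `extreme`); when omitted they are computed from the data,
#'   which then requires at least 4 residuals.
#' @return a [ResidualBands-class]; band names follow the residual names.
#' @export
classifyResiduals <- function(residuals, thresholds = NULL) {
  if (methods::is(residuals, "PACoResult"))
    residuals <- pacoResiduals(residuals)
  if (is.null(thresholds)) {
    if (length(residuals) < 4L)
      stop("need at least 4 residuals to estimate quantile thresholds")
    q <- stats::quantile(residuals, c(0.25, 0.75, 0.90), type = 7,
                         names = FALSE)
    thresholds <- c(q1 = q[1], q3 = q[2], p90 = q[3])
  }
  if (!all(c("q1", "q3", "p90") %in% names(thresholds)))
    stop("thresholds must name q1, q3 and p90")
  if (!"extreme" %in% names(thresholds))
    thresholds["extreme"] <- thresholds[["q3"]] +
      3 * (thresholds[["q3"]] - thresholds[["q1"]])
  band <- ifelse(residuals < thresholds[["q1"]], "low",
          ifelse(residuals <= thresholds[["q3"]], "medium",
          ifelse(residuals < thresholds[["p90"]], "upper-medium", "high")))
  band <- factor(band, levels = c("low", "medium", "upper-medium", "high"))
  names(band) <- names(residuals)
  new("ResidualBands",
      thresholds = thresholds[c("q1", "q3", "p90", "extreme")],
      band = band,
      extreme_outlier = unname(residuals > thresholds[["extreme"]]))
}

#' Published residual-band thresholds
#'
#' Frozen example threshold sets for [classifyResiduals()], as reported
#' for the PaaA-PaaC marker analysis: `q1 = 1.40`, `q3 = 2.40`, extreme
#' `= 5.42`, with the 90th percentile reported both as 3.45 (methods
#' set) and 3.39 (results set) — both are shipped, flagged by name.
#'
#' @param set `"methods"` (default) or `"results"`.
#' @return named numeric vector `q1`, `q3`, `p90`, `extreme` suitable for
#'   the `thresholds` argument of [classifyResiduals()].
#' @export
publishedBandThresholds <- function(set = c("methods", "results")) {
  set <- match.arg(set)
  f <- system.file("extdata", "pal_residual_band_thresholds.tsv",
                   package = "PAApipe", mustWork = TRUE)
  tab <- utils::read.delim(f, stringsAsFactors = FALSE)
  row <- tab[tab$set == set, ]
  c(q1 = row$q1, q3 = row$q3, p90 = row$p90, extreme = row$extreme)
}

#' Normalized Robinson-Foulds distance
#'
#' Symmetric-difference count of non-trivial bipartitions
#' (via [phangorn::RF.dist()]), normalized by the attainable maximum: the
#' total number of internal edges in the two unrooted trees, which equals
#' `2(n - 3)` for a pair of binary trees.
#'
#' @param tree_a,tree_b [ape::phylo] trees over the same tip set.
#' @return numeric in [0, 1]; 0 for identical topologies.
#' @export
normalizedRF <- function(tree_a, tree_b) {
  if (!setequal(tree_a$tip.label, tree_b$tip.label))
    stop("trees must share an identical tip set")
  raw <- phangorn::RF.dist(tree_a, tree_b, normalize = FALSE,
                           check.labels = TRUE)
  maxrf <- internalEdges(tree_a) + internalEdges(tree_b)
  if (maxrf == 0) return(0)
  as.numeric(raw) / maxrf
}

internalEdges <- function(tree) {
  tr <- ape::unroot(tree)
  sum(tr$edge[, 2] > ape::Ntip(tr))
}

#' Export a tanglegram bundle
#'
#' Writes the two trees as Newick plus a link-annotation TSV (link,
#' residual, band, extreme flag and a hex colour per band) sufficient to
#' redraw a mirror-tree figure in any viewer.
#'
#' @param tree_a,tree_c the two trees.
#' @param result a [PACoResult-class].
#' @param bands a [ResidualBands-class] for the same links.
#' @param prefix output path prefix; files `<prefix>_treeA.nwk`,
#'   `<prefix>_treeC.nwk` and `<prefix>_links.tsv` are created.
#' @return character vector of the three file paths, invisibly.
#' @export
exportTanglegram <- function(tree_a, tree_c, result, bands, prefix) {
  stopifnot(methods::is(result, "PACoResult"),
            methods::is(bands, "ResidualBands"))
  fa <- paste0(prefix, "_treeA.nwk")
  fc <- paste0(prefix, "_treeC.nwk")
  fl <- paste0(prefix, "_links.tsv")
  ape::write.tree(tree_a, fa)
  ape::write.tree(tree_c, fc)
  cols <- c(low = "#2166AC", medium = "#92C5DE",
            `upper-medium` = "#F4A582", high = "#B2182B")
  df <- data.frame(tip_a = result@links$tip_a,
                   tip_b = result@links$tip_b,
                   residual = unname(result@residuals),
                   band = as.character(bandOf(bands)),
                   extreme_outlier = extremeOutliers(bands),
                   colour = unname(cols[as.character(bandOf(bands))]),
                   stringsAsFactors = FALSE)
  utils::write.table(df, fl, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fa, fc, fl))
}
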