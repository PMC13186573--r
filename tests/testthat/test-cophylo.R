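test_that("patristic distances are path sums", {
  t2 <- ape::read.tree(text = "(A:1.5,B:2.5);")
  expect_equal(patristicMatrix(t2)["A", "B"], 4.0)
  t3 <- ape::read.tree(text = "((A:1,B:1):2,C:1);")
  D <- patristicMatrix(t3)
  expect_equal(D["A", "B"], 2)
  expect_equal(D["A", "C"], 4)
  expect_equal(D["B", "C"], 4)
})

test_that("patristic matrix matches an independent path-search oracle", {
  set.seed(5)
  tr <- ape::rphylo(10, 1, 0)
  D <- patristicMatrix(tr)
  O <- bfsPatristic(tr)
  expect_equal(D[rownames(O), colnames(O)], O, tolerance = 1e-12)
})

test_that("Cailliez correction is zero for Euclidean input and repairs others", {
  # points on a line at 0, 1, 3
  D <- as.matrix(dist(c(0, 1, 3)))
  cc <- cailliezCorrection(D)
  expect_equal(cc$c, 0)
  expect_equal(cc$D_corrected, D)
  # a decidedly non-Euclidean dissimilarity
  set.seed(11)
  D2 <- randomEuclideanD(8)^3
  dimnames(D2) <- NULL
  cc2 <- cailliezCorrection(D2)
  G <- PAApipe:::doubleCentre(-0.5 * cc2$D_corrected^2)
  ev <- eigen((G + t(G)) / 2, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8 * max(ev))
  expect_gt(cc2$c, 0)
  expect_error(cailliezCorrection(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("principal coordinates reproduce the input distances", {
  D <- matrix(c(0, 4, 4, 0), 2)
  X <- pcoaCoords(D)
  expect_equal(ncol(X), 1L)
  expect_equal(as.numeric(dist(X)), 4)
  # collinear points: a single positive axis
  D3 <- as.matrix(dist(c(0, 1, 3)))
  expect_equal(ncol(pcoaCoords(D3)), 1L)
  set.seed(2)
  D8 <- randomEuclideanD(8, k = 4)
  X8 <- pcoaCoords(D8)
  expect_lt(max(abs(as.matrix(dist(X8)) - D8)), 1e-6)
})

test_that("pcoa agrees with the ape reference implementation", {
  set.seed(13)
  D <- randomEuclideanD(9, k = 3)
  ours <- as.matrix(dist(pcoaCoords(D)))
  ref <- as.matrix(dist(ape::pcoa(D)$vectors))
  expect_equal(ours, ref, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("Procrustes superimposition removes similarity transforms", {
  set.seed(4)
  X <- matrix(rnorm(20), 10)
  expect_lt(procrustesSuperimpose(X, X)$m2, 1e-20)
  th <- pi / 2
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  Y <- 2 * X %*% R + 5
  expect_lt(procrustesSuperimpose(X, Y)$m2, 1e-18)
  expect_error(procrustesSuperimpose(X[1:2, ], X[1:2, ]), "at least 3")
})

test_that("Procrustes m2 matches the vegan reference on random instances", {
  skip_if_not_installed("vegan")
  set.seed(9)
  for (i in 1:5) {
    X <- matrix(rnorm(24), 8)
    Y <- matrix(rnorm(24), 8)
    ours <- procrustesSuperimpose(X, Y)
    ref <- vegan::procrustes(X, Y, scale = TRUE, symmetric = FALSE)
    expect_equal(ours$m2, ref$ss, tolerance = 1e-10)
    expect_equal(unname(ours$residuals), unname(stats::residuals(ref)),
                 tolerance = 1e-8)
  }
})

test_that("identical trees give m2 near zero and tiny p", {
  tp <- simulateTreePair(simulationConfig(seed = 3, n_tip_swaps = 0,
                                          bl_sigma = 0))
  pr <- paco(tp$tree_a, tp$tree_c, nperm = 99)
  scale <- sum(pcoaCoords(cailliezCorrection(
    patristicMatrix(tp$tree_a))$D_corrected)^2)
  expect_lt(pacoM2(pr) / scale, 1e-10)
  expect_equal(pacoPvalue(pr), 1 / 100)
  expect_equal(sum(pacoResiduals(pr)^2), pacoM2(pr), tolerance = 1e-9)
})

test_that("paco m2 is invariant under link order and seeded-reproducible", {
  tp <- simulateTreePair(simulationConfig(seed = 8))
  links <- data.frame(tip_a = tp$tree_a$tip.label,
                      tip_b = tp$tree_a$tip.label,
                      stringsAsFactors = FALSE)
  p1 <- paco(tp$tree_a, tp$tree_c, links, nperm = 49, seed = 7)
  perm <- sample(nrow(links))
  p2 <- paco(tp$tree_a, tp$tree_c, links[perm, ], nperm = 49, seed = 7)
  expect_equal(pacoM2(p1), pacoM2(p2), tolerance = 1e-8)
  expect_equal(pacoResiduals(p1), pacoResiduals(p2)[names(pacoResiduals(p1))],
               tolerance = 1e-8)
  p3 <- paco(tp$tree_a, tp$tree_c, links, nperm = 49, seed = 7)
  expect_identical(pacoPvalue(p1), pacoPvalue(p3))
  expect_error(paco(tp$tree_a, tp$tree_c, links[1:2, ]), "at least 3")
})

test_that("swapped tips surface as the largest residuals", {
  tp <- simulateTreePair(simulationConfig(seed = 15, n_tips = 30,
                                          n_tip_swaps = 2))
  pr <- paco(tp$tree_a, tp$tree_c, nperm = 0)
  r <- sort(pacoResiduals(pr), decreasing = TRUE)
  top4 <- sub("--.*", "", names(r)[1:4])
  expect_setequal(top4, tp$swapped)
})

test_that("residual banding follows the linear-interpolation quantile rule", {
  b <- classifyResiduals(as.numeric(1:100))
  th <- bandThresholds(b)
  expect_equal(unname(th["q1"]), 25.75)
  expect_equal(unname(th["q3"]), 75.25)
  expect_equal(unname(th["p90"]), 90.1)
  expect_equal(unname(th["extreme"]), 75.25 + 3 * (75.25 - 25.75))
  counts <- table(bandOf(b))
  expect_equal(unname(counts["low"]), 25L)        # 1..25 < 25.75
  expect_equal(unname(counts["medium"]), 50L)     # 26..75 in [q1, q3]
  expect_equal(unname(counts["upper-medium"]), 15L)
  expect_equal(unname(counts["high"]), 10L)
  expect_equal(sum(extremeOutliers(b)), 0L)
  # degenerate: all residuals equal -> everything medium, no extremes
  b2 <- classifyResiduals(rep(2.2, 10))
  expect_true(all(bandOf(b2) == "medium"))
  expect_false(any(extremeOutliers(b2)))
  expect_error(classifyResiduals(c(1, 2, 3)), "at least 4")
})

test_that("published threshold sets band residuals at the stated boundaries", {
  th <- publishedBandThresholds("methods")
  expect_equal(unname(th), c(1.40, 2.40, 3.45, 5.42))
  r <- c(0.5, 1.39, 1.40, 2.40, 2.41, 3.44, 3.45, 5.41, 5.43)
  b <- classifyResiduals(r, thresholds = th)
  expect_equal(as.character(bandOf(b)),
               c("low", "low", "medium", "medium", "upper-medium",
                 "upper-medium", "high", "high", "high"))
  expect_equal(which(extremeOutliers(b)), 9L)
  th2 <- publishedBandThresholds("results")
  expect_equal(unname(th2["p90"]), 3.39)
})

test_that("normalized Robinson-Foulds behaves as a distance", {
  t1 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1,E:1);")
  t2 <- ape::read.tree(text = "((A:1,C:1):1,(B:1,D:1):1,E:1);")
  expect_equal(normalizedRF(t1, t1), 0)
  expect_equal(normalizedRF(t1, t2), 1.0)
  expect_equal(normalizedRF(t1, t2), normalizedRF(t2, t1))
  set.seed(10)
  tr <- ape::rtree(12)
  nni <- phangorn::rNNI(tr, moves = 1)
  if (as.numeric(phangorn::RF.dist(tr, nni)) > 0)
    expect_equal(normalizedRF(tr, nni), 2 / (2 * (12 - 3)))
  t3 <- ape::rtree(6); t4 <- ape::rtree(7)
  expect_error(normalizedRF(t3, t4), "tip set")
})

test_that("tanglegram export round-trips and annotates bands", {
  tp <- simulateTreePair(simulationConfig(seed = 23))
  pr <- paco(tp$tree_a, tp$tree_c, nperm = 9)
  bands <- classifyResiduals(pr)
  prefix <- tempfile()
  files <- exportTanglegram(tp$tree_a, tp$tree_c, pr, bands, prefix)
  expect_true(all(file.exists(files)))
  back <- readNewickTree(files[1])
  expect_setequal(back$tip.label, tp$tree_a$tip.label)
  ann <- utils::read.delim(files[3])
  expect_equal(nrow(ann), length(pacoResiduals(pr)))
  expect_equal(length(unique(ann$colour[!is.na(ann$colour)])),
               length(unique(as.character(bandOf(bands)))))
})
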