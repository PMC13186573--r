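test_that("the generator is fully deterministic given its seed", {
  cfg <- simulationConfig(seed = 99, n_genomes = 4)
  s1 <- simulateGenomes(cfg); s2 <- simulateGenomes(cfg)
  expect_identical(s1, s2)
  h1 <- simulateDomainHits(s1$genes, cfg)
  h2 <- simulateDomainHits(s2$genes, cfg)
  expect_identical(h1, h2)
  m1 <- simulateSequencesWithMotifs(cfg, 10)
  m2 <- simulateSequencesWithMotifs(cfg, 10)
  expect_identical(m1$sequences, m2$sequences)
  t1 <- simulateTreePair(cfg); t2 <- simulateTreePair(cfg)
  expect_identical(ape::write.tree(t1$tree_c), ape::write.tree(t2$tree_c))
})

test_that("planted clusters classify to their intended configuration at zero noise", {
  cfg <- simulationConfig(seed = 17, n_genomes = 30,
                          gene_deletion_prob = 0)
  sim <- simulateGenomes(cfg)
  hits <- simulateDomainHits(sim$genes, cfg)
  at <- architectureTable(hits)
  g <- sim$genes
  g$role <- at$role[match(g$protein_id, at$protein_id)]
  for (i in seq_len(nrow(sim$truth))) {
    cl <- classifyConfiguration(extractContext(g, sim$truth$anchor[i]))
    expect_equal(configurationOf(cl), sim$truth$configuration[i])
    expect_equal(regulatorState(cl), sim$truth$regulator_state[i])
    expect_equal(cl@paaY_present, sim$truth$paaY_present[i])
  }
})

test_that("noisy domain hits still tile to the truth architecture", {
  cfg <- simulationConfig(seed = 55, n_genomes = 10,
                          overlap_noise_rate = 1)  # force noise everywhere
  sim <- simulateGenomes(cfg)
  hits <- simulateDomainHits(sim$genes, cfg)
  at <- architectureTable(hits)
  planted <- sim$genes[!is.na(sim$genes$role) &
                       sim$genes$role != "decoy_ANL", ]
  roles <- at$role[match(planted$protein_id, at$protein_id)]
  expect_gte(mean(roles == planted$role, na.rm = TRUE), 0.99)
  expect_false(any(is.na(roles)))
  # sub-threshold spurious hits are present in the raw table but excluded
  expect_true(any(hits$domain_accession == "PF99999" &
                  hits$i_evalue <= 0.001))
})

test_that("decoy genes carry AMP-binding only and are never PAL", {
  cfg <- simulationConfig(seed = 23, n_genomes = 10, decoy_rate = 3)
  sim <- simulateGenomes(cfg)
  hits <- simulateDomainHits(sim$genes, cfg)
  at <- architectureTable(hits)
  decoys <- sim$genes$protein_id[!is.na(sim$genes$role) &
                                 sim$genes$role == "decoy_ANL"]
  expect_gt(length(decoys), 0)
  expect_false(any(at$is_pal[at$protein_id %in% decoys]))
})

test_that("motif widths respect the configured bounds and plant_prob 0 is all-negative", {
  cfg <- simulationConfig(seed = 3)
  sm <- simulateSequencesWithMotifs(cfg, 5)
  w <- vapply(sm$motifs, motifWidth, integer(1))
  expect_true(all(w >= 6 & w <= 30))
  expect_true(all(w >= cfg$motif_width_range[1] &
                  w <= cfg$motif_width_range[2]))
  cfg0 <- simulationConfig(seed = 3, plant_prob = 0)
  sm0 <- simulateSequencesWithMotifs(cfg0, 30)
  expect_false(any(sm0$truth$positive))
  expect_error(simulationConfig(motif_width_range = c(4, 30)), "\\[6, 30\\]")
  expect_error(simulationConfig(configuration_mix = c(FP = 1)),
               "configuration_mix")
})

test_that("tree pairs degrade monotonically with the number of tip swaps", {
  base <- function(k, seed) {
    tp <- simulateTreePair(simulationConfig(seed = 1, n_tips = 24,
                                            n_tip_swaps = k,
                                            bl_sigma = 0), seed = seed)
    normalizedRF(tp$tree_a, tp$tree_c)
  }
  mrf <- vapply(c(0, 2, 4), function(k)
    mean(vapply(1:15, function(s) base(k, 1000 + 7 * s + k), numeric(1))),
    numeric(1))
  expect_equal(mrf[1], 0)
  expect_lt(mrf[1], mrf[2])
  expect_lt(mrf[2], mrf[3])
  tp0 <- simulateTreePair(simulationConfig(seed = 2, n_tip_swaps = 0,
                                           bl_sigma = 0))
  expect_identical(ape::write.tree(tp0$tree_a), ape::write.tree(tp0$tree_c))
  tp2 <- simulateTreePair(simulationConfig(seed = 2, n_tip_swaps = 2))
  expect_length(tp2$swapped, 4L)
  expect_equal(anyDuplicated(tp2$swapped), 0L)
})

test_that("config-residual pairs are independent at effect 0 and deterministic at 1", {
  p0 <- simulateConfigResidualPairs(0, 5000, seed = 4)
  expect_lt(cramersV(table(p0$configuration, p0$band)), 0.05)
  p1 <- simulateConfigResidualPairs(1, 2000, seed = 4)
  map <- unique(p1[, c("configuration", "band")])
  expect_equal(nrow(map), length(unique(p1$configuration)))
  expect_gt(cramersV(table(p1$configuration, p1$band)), 0.99)
})
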