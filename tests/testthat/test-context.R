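test_that("window extraction truncates at replicon ends and wraps circularly", {
  g <- data.frame(genome_id = "g", replicon_id = "r",
                  position_index = 0:99, strand = "+",
                  gene_id = sprintf("g%03d", 1:100),
                  protein_id = sprintf("p%03d", 1:100),
                  stringsAsFactors = FALSE)
  ctx <- extractContext(g, "g006", W = 20)  # anchor at position 5
  expect_equal(nrow(contextWindow(ctx)), 26L)
  expect_equal(range(contextWindow(ctx)$position_index), c(0L, 25L))
  ctx2 <- extractContext(g, "g051", W = 20)
  expect_equal(nrow(contextWindow(ctx2)), 41L)
  g30 <- g[1:30, ]
  ctx3 <- extractContext(g30, "g001", W = 20, circular = TRUE)
  expect_equal(nrow(contextWindow(ctx3)), 30L)
  expect_equal(anyDuplicated(contextWindow(ctx3)$gene_id), 0L)
  expect_error(extractContext(g, "nope"), "not found")
})

## Gene organisations of the three experimentally characterised model
## clusters, encoded as role layouts.
ecoliK12 <- c("PaaZ", "PaaA_PaaC", "PaaB", "PaaA_PaaC", "PaaD", "PaaE",
              "PaaG_PaaF", "PaaG_PaaF", "PaaH", "PaaI", "PaaJ", "PAL",
              "PaaX", "PaaY")
pputidaKT2440 <- c("PaaX", "PaaY", "PaaZ", "PaaA_PaaC", "PaaB",
                   "PaaA_PaaC", "PaaD", "PaaE", "PaaG_PaaF", "PaaG_PaaF",
                   "PaaH", "PaaI", "PaaJ", "PAL")
rjostiiRHA1 <- c("PaaR", "PaaZ", "PaaA_PaaC", "PaaB", "PaaA_PaaC",
                 "PaaD", "PaaE", "PaaG_PaaF", "PaaG_PaaF", "PaaH",
                 "PaaI", "PaaJ", "PAL")

test_that("model-organism cluster layouts classify as full pathways", {
  cl <- classifyLayout(ecoliK12)
  expect_equal(configurationOf(cl), "FP")
  expect_equal(regulatorState(cl), "PaaX")
  expect_true(cl@paaY_present)
  cl2 <- classifyLayout(pputidaKT2440)
  expect_equal(configurationOf(cl2), "FP")
  expect_equal(regulatorState(cl2), "PaaX")
  cl3 <- classifyLayout(rjostiiRHA1)
  expect_equal(configurationOf(cl3), "FP")
  expect_equal(regulatorState(cl3), "PaaR")
  expect_false(cl3@paaY_present)
})

test_that("the decision list covers the partial and fallthrough cases", {
  pm <- classifyLayout(c("PaaA_PaaC", "PaaA_PaaC", "PAL"))
  expect_equal(configurationOf(pm), "PM")
  expect_equal(regulatorState(pm), "NP")
  expect_false(pm@paaY_present)
  oc <- classifyLayout("PAL")
  expect_equal(configurationOf(oc), "OC")
  em <- classifyLayout(c("PaaA_PaaC", "PaaB", "PaaA_PaaC", "PaaE", "PAL"))
  expect_equal(configurationOf(em), "EM")   # PaaD optional
  up <- classifyLayout(c("PaaZ", "PaaA_PaaC", "PaaB", "PaaA_PaaC",
                         "PaaE", "PaaG_PaaF", "PAL"))
  expect_equal(configurationOf(up), "UP")
  # single shared-architecture PaaA/PaaC gene: PM only, ambiguous
  amb <- classifyLayout(c("PaaA_PaaC", "PaaB", "PaaE", "PAL"))
  expect_equal(configurationOf(amb), "PM")
  expect_true(amb@ambiguous)
  # regulator states
  rx <- classifyLayout(c("PaaA_PaaC", "PaaA_PaaC", "PAL", "PaaX", "PaaR"))
  expect_equal(regulatorState(rx), "PaaR-X")
})

test_that("classification is membership-based: window order is irrelevant", {
  set.seed(77)
  for (i in 1:10) {
    roles <- sample(ecoliK12)
    expect_equal(configurationOf(classifyLayout(roles)), "FP")
  }
})

test_that("configuration classes are nested by required gene sets", {
  # FP layouts also satisfy the UP and EM predicates; dropping genes moves
  # the call monotonically down the decision list
  expect_equal(configurationOf(classifyLayout(
    ecoliK12[ecoliK12 != "PaaH"])), "UP")
  expect_equal(configurationOf(classifyLayout(
    ecoliK12[!ecoliK12 %in% c("PaaH", "PaaZ")])), "EM")
  expect_equal(configurationOf(classifyLayout(
    c("PaaA_PaaC", "PaaA_PaaC", "PAL"))), "PM")
})

test_that("co-occurrence summaries count combinations and outside roles", {
  g1 <- layoutGenome(c("PaaA_PaaC", "PaaA_PaaC", "PAL"), genome_id = "a")
  g2 <- layoutGenome(c("PaaA_PaaC", "PaaA_PaaC", "PAL"), genome_id = "b")
  # a PaaI planted far outside any window
  g2$role[1] <- "PaaI"
  genes <- rbind(g1, g2)
  ctxs <- list(extractContext(genes, anchorOf(g1)),
               extractContext(genes, anchorOf(g2)))
  s <- coOccurrenceSummary(ctxs, genes)
  expect_equal(s$combinations$n_contexts, 2L)
  expect_equal(s$combinations$roles, "PAL+PaaA_PaaC")
  pi <- s$role_counts[s$role_counts$role == "PaaI", ]
  expect_equal(pi$inside, 0L)
  expect_equal(pi$outside, 1L)
})

test_that("the candidate funnel retains orthologues and sidelines paralogs", {
  cfg <- simulationConfig(seed = 42, n_genomes = 6,
                          configuration_mix = c(FP = 1, UP = 0, EM = 0,
                                                PM = 0, OC = 0),
                          decoy_rate = 2)
  sim <- simulateGenomes(cfg)
  hits <- simulateDomainHits(sim$genes, cfg)
  at <- architectureTable(hits)
  # pretend every PAL-architecture protein passes the motif stage
  profiles <- data.frame(sequence_id = at$protein_id[at$is_pal],
                         combined_pvalue = 1e-10, passes_filter = TRUE,
                         stringsAsFactors = FALSE)
  res <- palCandidatePipeline(at, profiles, sim$genes[, PAApipe:::GENE_TABLE_COLS])
  expect_equal(nrow(res), 6L)
  expect_true(all(res$configuration == "FP"))
  expect_true(all(res$retained))
  # decoys never make it into the candidate table
  decoys <- sim$genes$protein_id[!is.na(sim$genes$role) &
                                 sim$genes$role == "decoy_ANL"]
  expect_false(any(res$protein_id %in% decoys))
})

test_that("a second PAL copy without the epoxidation module is kept as OC paralog", {
  g1 <- layoutGenome(ecoliK12, genome_id = "dup")
  extra <- layoutGenome(c("PaaI", "PAL"), genome_id = "dup")
  extra$gene_id <- sub("_g", "_h", extra$gene_id)
  extra$protein_id <- sub("_p", "_q", extra$protein_id)
  extra$replicon_id <- "chr2"
  extra$position_index <- seq_len(nrow(extra)) - 1L
  genes <- rbind(g1, extra)
  at <- data.frame(protein_id = genes$protein_id,
                   role = genes$role, stringsAsFactors = FALSE)
  at$is_pal <- !is.na(at$role) & at$role == "PAL"
  profiles <- data.frame(sequence_id = at$protein_id[at$is_pal],
                         combined_pvalue = 0, passes_filter = TRUE,
                         stringsAsFactors = FALSE)
  res <- palCandidatePipeline(at, profiles, genes[, PAApipe:::GENE_TABLE_COLS])
  expect_equal(sort(res$configuration), c("FP", "OC"))
  expect_equal(sum(res$retained), 1L)
})

test_that("an empty genome set yields an empty candidate table", {
  at <- data.frame(protein_id = character(), role = character(),
                   is_pal = logical(), stringsAsFactors = FALSE)
  profiles <- data.frame(sequence_id = character(),
                         combined_pvalue = numeric(),
                         passes_filter = logical(), stringsAsFactors = FALSE)
  genes <- layoutGenome("PaaZ")[0, ]
  res <- palCandidatePipeline(at, profiles, genes)
  expect_equal(nrow(res), 0L)
})
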