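mkHits <- function(starts, ends, evalues, pid = "p1", plen = 300L) {
  data.frame(protein_id = pid, protein_length = plen,
             domain_name = paste0("D", seq_along(starts)),
             domain_accession = paste0("PF0000", seq_along(starts)),
             ali_start = as.integer(starts), ali_end = as.integer(ends),
             i_evalue = evalues, bit_score = 100,
             stringsAsFactors = FALSE)
}

test_that("identical spans are resolved to the lowest e-value hit", {
  h <- mkHits(c(10, 10), c(100, 100), c(1e-5, 1e-50))
  a <- resolveArchitecture(h, 300L)
  expect_equal(nrow(archTiles(a)), 1L)
  expect_equal(archTiles(a)$i_evalue, 1e-50)
})

test_that("a single hit gives the forced coverage", {
  h <- mkHits(10, 100, 1e-10)
  a <- resolveArchitecture(h, 210L)
  expect_equal(archCoverage(a), 91 / 210)
  expect_equal(archSignature(a), "D1")
})

test_that("overlapping triple resolves to the maximal-coverage pair", {
  h <- mkHits(c(10, 90, 110), c(100, 200, 200), c(1e-50, 1e-30, 1e-10),
              plen = 210L)
  a <- resolveArchitecture(h, 210L)
  expect_equal(archTiles(a)$ali_start, c(10L, 110L))
  expect_equal(archCoverage(a), 182 / 210)
  o <- bruteForceTiling(h)
  expect_equal(sum(archTiles(a)$ali_end - archTiles(a)$ali_start + 1),
               o$coverage)
})

test_that("e-value filtering and degenerate inputs behave as documented", {
  h <- mkHits(c(10, 120), c(100, 200), c(1e-10, 0.01))
  a <- resolveArchitecture(h, 300L)
  expect_equal(nrow(archTiles(a)), 1L)          # 0.01 filtered at 0.001
  a2 <- resolveArchitecture(h, 300L, evalue_max = 0.1)
  expect_equal(nrow(archTiles(a2)), 2L)
  expect_gte(archCoverage(a2), archCoverage(a)) # filter monotonicity
  empty <- resolveArchitecture(h[0, ], 300L)
  expect_equal(nrow(archTiles(empty)), 0L)
  expect_equal(archCoverage(empty), 0)
  h2 <- h; h2$protein_id <- c("a", "b")
  expect_error(resolveArchitecture(h2, 300L), "multiple proteins")
})

test_that("DP tiling equals brute-force enumeration on random instances", {
  set.seed(202)
  for (rep in 1:300) {
    h <- randomHitInstance(sample(1:10, 1))
    a <- resolveArchitecture(h, 300L, evalue_max = 1)
    o <- bruteForceTiling(h)
    t <- archTiles(a)
    expect_equal(sum(t$ali_end - t$ali_start + 1), o$coverage)
    expect_equal(-sum(log(t$i_evalue)), o$neg_ln_sum, tolerance = 1e-9)
    expect_equal(sort(t$ali_start), o$starts)
    # tiles never overlap
    if (nrow(t) > 1)
      expect_true(all(t$ali_end[-nrow(t)] < t$ali_start[-1]))
    expect_true(archCoverage(a) >= 0 && archCoverage(a) <= 1)
  }
})

test_that("overlap tolerance admits abutting hits with small slack", {
  h <- mkHits(c(10, 100), c(101, 200), c(1e-20, 1e-20))
  expect_equal(nrow(archTiles(resolveArchitecture(h, 300L))), 1L)
  expect_equal(nrow(archTiles(resolveArchitecture(h, 300L,
                                                  overlap_tol = 2L))), 2L)
})

test_that("PAL architecture predicate enforces terminal domain order", {
  rm <- defaultRoleMap()
  mk <- function(accs, names = accs) {
    h <- data.frame(protein_id = "p", protein_length = 500L,
                    domain_name = names, domain_accession = accs,
                    ali_start = seq(10, by = 150,
                                    length.out = length(accs)),
                    ali_end = seq(100, by = 150, length.out = length(accs)),
                    i_evalue = 1e-30, bit_score = 100,
                    stringsAsFactors = FALSE)
    resolveArchitecture(h, 600L)
  }
  expect_true(isPalArchitecture(mk(c("PF00501", "PF14535")), rm))
  expect_false(isPalArchitecture(mk(c("PF14535", "PF00501")), rm))
  expect_true(isPalArchitecture(mk(c("PF00501", "PF00378", "PF14535")), rm))
  expect_false(isPalArchitecture(mk("PF00501"), rm))   # ANL decoy
  h0 <- mkHits(10, 100, 1e-5)[0, ]
  expect_false(isPalArchitecture(resolveArchitecture(h0, 100L), rm))
})

test_that("role assignment follows the documented priority", {
  rm <- defaultRoleMap()
  mk <- function(accs) {
    h <- data.frame(protein_id = "p", protein_length = 900L,
                    domain_name = unname(rm$domain_names[accs]),
                    domain_accession = accs,
                    ali_start = seq(10, by = 200, length.out = length(accs)),
                    ali_end = seq(150, by = 200, length.out = length(accs)),
                    i_evalue = 1e-30, bit_score = 100,
                    stringsAsFactors = FALSE)
    resolveArchitecture(h, 1000L)
  }
  expect_equal(assignRole(mk("PF05138"), rm), "PaaA_PaaC")
  expect_equal(assignRole(mk(c("PF00501", "PF14535")), rm), "PAL")
  expect_equal(assignRole(mk("PF00501"), rm), NA_character_)  # decoy
  expect_equal(assignRole(mk(c("PF00171", "PF00378")), rm), "PaaZ")
  expect_equal(assignRole(mk("PF00378"), rm), "PaaG_PaaF")
  expect_equal(assignRole(mk("PF00440"), rm), "PaaR")
  expect_equal(assignRole(mk("PF91234"), rm), NA_character_)
})
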