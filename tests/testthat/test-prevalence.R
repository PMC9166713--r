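pmFromMatrix <- function(m, sites) {
  new("PresenceMatrix", presence = m,
      siteMap = setNames(sites, colnames(m)))
}

test_that("the presence matrix marks samples whose catalog matches each lectin", {
  set.seed(1)
  l1 <- randomAA(60); l2 <- randomAA(60)
  l2hom <- lectiscope:::.mutateExact(l2, 3)    # 95% identity homolog
  lect <- c(L1 = l1, L2 = l2)
  cats <- list(
    GeneCatalog("A", "stool", c(g1 = l1, g2 = l2hom, g3 = randomAA(80))),
    GeneCatalog("B", "stool", c(g1 = randomAA(70))),
    GeneCatalog("C", "stool", character(0)))
  pm <- buildPresenceMatrix(lect, cats)
  expect_equal(presence(pm),
               matrix(c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE), 2,
                      dimnames = list(c("L1", "L2"), c("A", "B", "C"))))
  # duplicate sample ids are rejected
  expect_error(buildPresenceMatrix(lect, c(cats[1], cats[1])), "duplicate")
  # invariance to gene and sample order
  cats_r <- list(cats[[3]], cats[[2]],
                 GeneCatalog("A", "stool", c(g3 = randomAA(80), g2 = l2hom,
                                             g1 = l1)))
  pm_r <- buildPresenceMatrix(lect, cats_r)
  expect_equal(presence(pm_r)[, colnames(presence(pm))], presence(pm))
})

test_that("prevalence summaries count richness and per-person means", {
  m <- matrix(c(TRUE, TRUE), 2, 1, dimnames = list(c("a", "b"), "S1"))
  ps <- prevalenceSummary(pmFromMatrix(m, "stool"))
  expect_equal(ps$sites$richness, 2L)
  expect_equal(ps$sites$mean_per_sample, 2.0)

  m0 <- matrix(FALSE, 2, 3, dimnames = list(c("a", "b"), c("S1", "S2", "S3")))
  ps0 <- prevalenceSummary(pmFromMatrix(m0, rep("stool", 3)))
  expect_equal(ps0$sites$richness, 0L)
  expect_equal(ps0$sites$mean_per_sample, 0.0)

  m1 <- matrix(c(TRUE, TRUE, TRUE, FALSE), 1, 4,
               dimnames = list("a", paste0("S", 1:4)))
  ps1 <- prevalenceSummary(pmFromMatrix(m1, rep("stool", 4)))
  expect_equal(unname(ps1$lectin_counts[, "stool"]), 3L)
  expect_equal(ps1$sites$mean_per_sample, 0.75)
})

test_that("site overlap computes shared and site-specific fractions", {
  m <- matrix(c(TRUE, FALSE,   # a: stool only
                TRUE, TRUE,    # b: both
                FALSE, TRUE),  # c: buccal only
              3, 2, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("S1", "S2")))
  ov <- siteOverlap(pmFromMatrix(m, c("stool", "buccal_mucosa")))
  expect_equal(ov$shared_fraction, 1 / 3)
  expect_equal(ov$site_specific[["stool"]], 1 / 2)
  expect_equal(ov$site_specific[["buccal_mucosa"]], 1 / 2)
  expect_equal(ov$pairwise["stool", "buccal_mucosa"], 1L)
  expect_equal(unname(ov$venn[["buccal_mucosa&stool"]]), 1L)
  # single site: nothing can be shared
  ov1 <- siteOverlap(pmFromMatrix(m[, 1, drop = FALSE], "stool"))
  expect_equal(ov1$shared_fraction, 0)
  # saturated matrix: all shared, nothing specific
  mall <- matrix(TRUE, 3, 2, dimnames = dimnames(m))
  ov2 <- siteOverlap(pmFromMatrix(mall, c("stool", "buccal_mucosa")))
  expect_equal(ov2$shared_fraction, 1)
  expect_true(all(unlist(ov2$site_specific) == 0))
  # partition identity: shared + site-exclusive fractions sum to one
  set.seed(8)
  pm <- pmFromMatrix(matrix(runif(60) < 0.4, 10, 6,
                            dimnames = list(sprintf("L%02d", 1:10),
                                            sprintf("S%02d", 1:6))),
                     rep(c("stool", "buccal_mucosa", "tongue_dorsum"), each = 2))
  ov3 <- siteOverlap(pm)
  nsites <- lengths(ov3$site_sets)
  expect_equal(sum(nsites >= 2) / sum(nsites >= 1) +
                 sum(nsites == 1) / sum(nsites >= 1), 1)
})

test_that("top-prevalent selection uses ceiling and accession tie-breaks", {
  counts <- c(9, 9, 3, 2, 1)
  m <- matrix(FALSE, 5, 9, dimnames = list(paste0("L", 1:5), paste0("S", 1:9)))
  for (i in 1:5) m[i, seq_len(counts[i])] <- TRUE
  pm <- pmFromMatrix(m, rep("stool", 9))
  expect_equal(topPrevalent(pm, "stool", 0.5), c("L1", "L2", "L3"))  # ceil(2.5)=3
  expect_setequal(topPrevalent(pm, "stool", 1.0), paste0("L", 1:5))
  m10 <- matrix(FALSE, 10, 10,
                dimnames = list(sprintf("L%02d", 1:10), paste0("S", 1:10)))
  for (i in 1:10) m10[i, seq_len(11 - i)] <- TRUE
  expect_equal(topPrevalent(pmFromMatrix(m10, rep("stool", 10)), "stool", 0.1),
               "L01")
  mz <- matrix(FALSE, 2, 2, dimnames = list(c("a", "b"), c("S1", "S2")))
  expect_equal(topPrevalent(pmFromMatrix(mz, rep("stool", 2)), "stool", 0.1),
               character(0))
})

test_that("analytic rarefaction matches the exhaustive subset average", {
  m <- matrix(FALSE, 3, 4, dimnames = list(paste0("L", 1:3), paste0("S", 1:4)))
  m[1, 1] <- TRUE                 # incidence 1
  m[2, c(1, 3)] <- TRUE           # incidence 2
  m[3, ] <- TRUE                  # incidence 4
  pm <- pmFromMatrix(m, rep("stool", 4))
  rc <- rarefactionCurve(pm, "stool")
  expect_equal(rc$expected_richness[2], exhaustiveRarefaction(m, 2),
               tolerance = 1e-12)
  expect_equal(rc$expected_richness[4], 3)           # S(N) = observed richness
  expect_equal(rc$expected_richness[1], mean(colSums(m)))  # S(1) = mean richness
  expect_error(rarefactionCurve(pm, "stool", n = 5), "1\\.\\.4")

  # property: monotone non-decreasing and concave, equal to the oracle
  set.seed(12)
  for (i in 1:10) {
    N <- sample(3:7, 1)
    pmr <- randomPresence(sample(2:8, 1), N, runif(1, 0.2, 0.8))
    rcr <- rarefactionCurve(pmr, "stool")
    S <- rcr$expected_richness
    expect_true(all(diff(S) >= -1e-12))
    if (length(S) >= 3) expect_true(all(diff(diff(S)) <= 1e-9))
    for (n in seq_len(N))
      expect_equal(S[n], exhaustiveRarefaction(presence(pmr), n),
                   tolerance = 1e-9)
  }
})

test_that("analytic rarefaction agrees with vegan's exact species accumulation", {
  set.seed(99)
  pm <- randomPresence(12, 8, 0.35)
  rc <- rarefactionCurve(pm, "stool")
  sp <- vegan::specaccum(t(presence(pm) * 1L), method = "exact")
  expect_equal(rc$expected_richness, as.numeric(sp$richness), tolerance = 1e-9)
})

test_that("resampled rarefaction SDs are seeded and reproducible", {
  pm <- randomPresence(6, 5, 0.5)
  r1 <- rarefactionCurve(pm, "stool", nboot = 30, seed = 4)
  r2 <- rarefactionCurve(pm, "stool", nboot = 30, seed = 4)
  expect_identical(r1, r2)
  expect_true(all(r1$sd[c(1, nrow(r1))] >= 0))
  expect_equal(r1$sd[nrow(r1)], 0)   # full sample has no variance
})

test_that("planted-prevalence catalogs are recovered cell-for-cell without mutation", {
  set.seed(21)
  lect <- setNames(vapply(1:4, function(i) randomAA(60), character(1)),
                   paste0("L", 1:4))
  syn <- genCatalogs(lect, sites = c(stool = 0.5, buccal_mucosa = 0.2),
                     nSamples = 8, nBackground = 3, mutationRate = 0, seed = 3)
  pm <- buildPresenceMatrix(lect, syn$catalogs)
  expect_identical(presence(pm), syn$truth)
  # degenerate probabilities
  syn1 <- genCatalogs(lect, sites = c(stool = 1.0), nSamples = 4,
                      nBackground = 0, seed = 5)
  expect_true(all(buildPresenceMatrix(lect, syn1$catalogs)@presence))
  syn0 <- genCatalogs(lect, sites = c(stool = 0.0), nSamples = 4,
                      nBackground = 2, seed = 5)
  expect_false(any(buildPresenceMatrix(lect, syn0$catalogs)@presence))
})

test_that("catalogs round-trip through per-sample FASTAs and a manifest", {
  set.seed(33)
  lect <- setNames(vapply(1:3, function(i) randomAA(50), character(1)),
                   paste0("L", 1:3))
  syn <- genCatalogs(lect, sites = c(stool = 0.9), nSamples = 3,
                     nBackground = 2, seed = 6)
  dir <- tempfile(); man <- writeCatalogs(syn$catalogs, dir)
  back <- readManifest(man)
  expect_equal(vapply(back, function(ct) ct$sample_id, character(1)),
               syn$manifest$sample_id)
  expect_equal(lapply(back, function(ct) unname(ct$genes)),
               lapply(syn$catalogs, function(ct) unname(ct$genes)))
})
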