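test_that("motif containment respects codes, linkage carbons and anomerics", {
  g <- parseGlycan("Galb1-3GlcNAcb1-2Mana1-3Man")
  expect_true(containsMotif(g, parseGlycan("Galb1-3GlcNAc")))
  expect_true(containsMotif(g, g))                       # identity embedding
  expect_false(containsMotif(parseGlycan("Galb1-3GlcNAcb1-2Man"),
                             parseGlycan("Galb1-4GlcNAc")))  # carbon mismatch
  expect_false(containsMotif(g, parseGlycan("Gala1-3GlcNAc")))  # anomeric mismatch
  # unknown anomeric on the data side matches any motif anomeric
  q <- parseGlycan("Gal?1-3GlcNAc")
  expect_true(containsMotif(q, parseGlycan("Galb1-3GlcNAc")))
  # placement is unanchored: motif can sit at internal nodes
  expect_true(containsMotif(g, parseGlycan("GlcNAcb1-2Man")))
  # decorations must match exactly
  expect_false(containsMotif(parseGlycan("Gal6Sb1-4GlcNAc"),
                             parseGlycan("Galb1-4GlcNAc")))
})

test_that("containment agrees with the brute-force embedding oracle", {
  set.seed(13)
  for (i in 1:60) {
    g <- randomGlycan(sample(3:8, 1))
    m <- randomGlycan(sample(1:4, 1))
    expect_identical(containsMotif(g, m), embedOracle(g, m),
                     label = sprintf("glycan %s motif %s", glycanToText(g),
                                     glycanToText(m)))
  }
})

test_that("containment is monotone through intermediate motifs", {
  # if M embeds in M2 and M2 embeds in G then M embeds in G
  set.seed(17)
  checked <- 0L
  for (i in 1:200) {
    g <- randomGlycan(sample(4:8, 1))
    subs <- enumerateSubglycans(g, 4)
    if (length(subs) < 2) next
    m2 <- subs[[sample(length(subs), 1)]]
    inner <- enumerateSubglycans(m2, glycanSize(m2))
    m <- inner[[sample(length(inner), 1)]]
    expect_true(containsMotif(g, m2))
    expect_true(containsMotif(m2, m))
    expect_true(containsMotif(g, m))
    checked <- checked + 1L
    if (checked >= 40L) break
  }
  expect_gte(checked, 20L)
})

test_that("subglycan enumeration finds every connected subtree once", {
  g <- parseGlycan("Mana1-3(Mana1-6)Manb1-4GlcNAc")
  subs <- enumerateSubglycans(g)
  oracle <- subtreeOracle(g, glycanSize(g))
  expect_setequal(names(subs), names(oracle))
  # capped enumeration
  subs2 <- enumerateSubglycans(g, 2)
  expect_true(all(vapply(subs2, glycanSize, integer(1)) <= 2))
  expect_setequal(names(subs2), names(subtreeOracle(g, 2)))
})

test_that("motif mining agrees with the exhaustive oracle on small libraries", {
  set.seed(23)
  for (rep in 1:4) {
    nb <- sample(2:5, 1); nn <- sample(0:4, 1)
    binders <- lapply(seq_len(nb), function(i) randomGlycan(sample(2:6, 1)))
    nonbinders <- lapply(seq_len(nn), function(i) randomGlycan(sample(2:6, 1)))
    got <- mineMotifs(binders, nonbinders, maxSize = 4)
    exp <- mineOracle(binders, nonbinders, maxSize = 4)
    expect_equal(got[c("motif", "size", "binder_coverage",
                       "nonbinder_frequency", "score")], exp)
  }
})

test_that("mining edge behaviour matches the contracts", {
  expect_error(mineMotifs(list()), "non-empty")
  # single binder, no nonbinders: every connected sub-glycan appears with coverage 1
  g <- parseGlycan("Galb1-3GlcNAcb1-2Man")
  mm <- mineMotifs(list(g), maxSize = glycanSize(g))
  expect_true(all(mm$binder_coverage == 1))
  # maximality collapses everything onto the full glycan
  expect_equal(mm$motif, glycanToText(g))
  # identical binder and nonbinder sets: no motif scores above zero
  set.seed(29)
  lib <- lapply(1:4, function(i) randomGlycan(4))
  mm2 <- mineMotifs(lib, lib, maxSize = 3)
  expect_true(all(mm2$score <= 0 + 1e-12))
})

test_that("the planted motif is recovered from a noise-free synthetic array", {
  syn <- genGlycanArray(nBinders = 6, nNonbinders = 6, noiseSd = 0,
                        outlierProb = 0, seed = 31)
  prof <- bindingProfile(syn$array, threshold = 0.1)
  structs <- lapply(syn$array$structure, parseGlycan)
  names(structs) <- syn$array$glycan_id
  expect_setequal(prof$glycan_id[prof$binder], syn$truth$binders)
  mm <- mineMotifs(structs[prof$glycan_id[prof$binder]],
                   structs[!prof$binder], maxSize = 4)
  expect_equal(mm$motif[1], syn$truth$motif)
  expect_equal(mm$binder_coverage[1], 1.0)
  expect_equal(mm$nonbinder_frequency[1], 0.0)
  # unique top scorer at its size
  at_size <- mm[mm$size == 4, ]
  expect_equal(sum(at_size$score == max(mm$score)), 1L)
})
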