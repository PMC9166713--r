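seq40 <- function() paste(rep("ACDEFGHIKL", 100), collapse = "")

test_that("classification applies the CBM / catalytic / keyword / reviewed rules", {
  cfg <- FilterConfig()
  seqs <- setNames(rep(seq40(), 3), c("P1", "P2", "P3"))
  dom <- rbind(
    domRow("P1", "IPR003961", 30, 120, "other"),
    domRow("P1", "IPR033803", 700, 950, "carbohydrate_binding"),
    domRow("P2", "IPR033803", 10, 60, "carbohydrate_binding"),
    domRow("P2", "IPR017853", 100, 200, "catalytic"),
    domRow("P3", "IPR033803", 10, 60, "carbohydrate_binding"))
  ps <- ProteinSet(seqs, dom,
                   description = c(P1 = "uncharacterized protein",
                                   P2 = "uncharacterized protein",
                                   P3 = "putative fimbrial protein"))
  cls <- classifyRecords(ps, cfg)
  expect_equal(cls$reason, c("accept", "catalytic", "keyword"))
  expect_equal(cls$accept, c(TRUE, FALSE, FALSE))
})

test_that("keyword matching is token-wise: Fim does not fire inside fimbriae-like words", {
  cfg <- FilterConfig()
  seqs <- setNames(rep(seq40(), 3), c("A", "B", "C"))
  dom <- rbind(domRow("A", "IPR033803", 1, 50, "carbohydrate_binding"),
               domRow("B", "IPR033803", 1, 50, "carbohydrate_binding"),
               domRow("C", "IPR033803", 1, 50, "carbohydrate_binding"))
  ps <- ProteinSet(seqs, dom,
                   description = c(A = "fimbrillin-like protein",   # no whole-token hit
                                   B = "fim operon protein",        # 'Fim' as token
                                   C = "protein with fimbriae"))    # 'Fimbriae' as token
  cls <- classifyRecords(ps, cfg)
  expect_equal(cls$reason, c("accept", "keyword", "keyword"))
  # case-sensitive mode only fires on exact case
  cfgCS <- FilterConfig(caseSensitive = TRUE)
  expect_equal(classifyRecords(ps, cfgCS)$reason, c("accept", "accept", "accept"))
})

test_that("records failing several rules report the first reason in fixed order", {
  cfg <- FilterConfig()
  kw <- "putative fimbrial protein"; clean <- "uncharacterized protein"
  combos <- expand.grid(cbm = c(TRUE, FALSE), cat = c(TRUE, FALSE),
                        kw = c(TRUE, FALSE), rev = c(TRUE, FALSE))
  for (r in seq_len(nrow(combos))) {
    dom <- NULL
    if (combos$cbm[r]) dom <- rbind(dom, domRow("X", "IPR033803", 1, 40,
                                                "carbohydrate_binding"))
    else dom <- rbind(dom, domRow("X", "IPR003961", 1, 40, "other"))
    if (combos$cat[r]) dom <- rbind(dom, domRow("X", "IPR017853", 50, 90,
                                                "catalytic"))
    ps <- ProteinSet(c(X = seq40()), dom,
                     reviewed = combos$rev[r],
                     description = if (combos$kw[r]) kw else clean)
    want <- if (!combos$cbm[r]) "no_cbm" else if (combos$cat[r]) "catalytic"
            else if (combos$kw[r]) "keyword" else if (combos$rev[r]) "reviewed"
            else "accept"
    expect_equal(classifyRecords(ps, cfg)$reason, want,
                 label = paste(combos[r, ], collapse = "/"))
  }
})

test_that("classification is order-invariant and exact on planted universes", {
  for (s in c(7L, 19L)) {
    u <- genProteinUniverse(nTrue = 30, nDecoys = 24, seed = s)
    cls <- classifyRecords(u$proteins)
    expect_identical(cls$reason, u$truth$reason)
    expect_identical(cls$accept, u$truth$is_lectin)
    # permuting records permutes but never changes the decisions
    perm <- sample(cls$accession)
    cls2 <- classifyRecords(subsetProteins(u$proteins, perm))
    expect_identical(cls2$reason[match(cls$accession, cls2$accession)],
                     cls$reason)
  }
})

test_that("domain architectures follow start/end/id ordering with duplicates kept", {
  seqs <- c(A = seq40(), B = seq40(), C = seq40())
  dom <- rbind(
    domRow("A", "IPR033803", 700, 950, "carbohydrate_binding"),
    domRow("A", "IPR003961", 30, 120, "other"),
    domRow("B", "IPR900002", 10, 50, "other"),   # tie on start: end decides
    domRow("B", "IPR900001", 10, 40, "other"),
    domRow("C", "IPR033803", 1, 30, "carbohydrate_binding"),
    domRow("C", "IPR033803", 60, 90, "carbohydrate_binding"))
  dt <- rbind(defaultDomainTable(),
              data.frame(domain_id = c("IPR900001", "IPR900002"),
                         category = "other", name = c("x", "y")))
  ps <- ProteinSet(seqs, dom)
  arch <- domainArchitectures(ps)
  expect_equal(arch$A, c("IPR003961", "IPR033803"))
  expect_equal(arch$B, c("IPR900001", "IPR900002"))
  expect_equal(arch$C, c("IPR033803", "IPR033803"))
  ps_empty <- ProteinSet(c(D = seq40()))
  expect_equal(domainArchitectures(ps_empty)$D, character(0))
})

test_that("candidate summaries count sequences, architectures and domain classes", {
  cfg <- FilterConfig()
  seqs <- setNames(rep(seq40(), 3), c("R1", "R2", "R3"))
  dom <- rbind(
    domRow("R1", "IPR033803", 1, 40, "carbohydrate_binding"),
    domRow("R2", "IPR033803", 1, 40, "carbohydrate_binding"),
    domRow("R2", "IPR003961", 60, 100, "other"),
    domRow("R3", "IPR024361", 1, 40, "carbohydrate_binding"),
    domRow("R3", "IPR003961", 60, 100, "other"))
  ps <- ProteinSet(seqs, dom)
  s <- summarizeCandidates(ps, cfg)
  expect_equal(s, list(n_sequences = 3L, n_architectures = 3L,
                       n_cbm_domains = 2L, n_secondary_domains = 1L))
  # two records sharing one architecture
  ps2 <- ProteinSet(setNames(rep(seq40(), 2), c("R1", "R2")),
                    rbind(domRow("R1", "IPR033803", 1, 40, "carbohydrate_binding"),
                          domRow("R1", "IPR003961", 60, 100, "other"),
                          domRow("R2", "IPR033803", 1, 40, "carbohydrate_binding"),
                          domRow("R2", "IPR003961", 60, 100, "other")))
  expect_equal(summarizeCandidates(ps2, cfg),
               list(n_sequences = 2L, n_architectures = 1L,
                    n_cbm_domains = 1L, n_secondary_domains = 1L))
  empty <- ProteinSet(Biostrings::AAStringSet(character(0)))
  expect_equal(summarizeCandidates(empty, cfg),
               list(n_sequences = 0L, n_architectures = 0L,
                    n_cbm_domains = 0L, n_secondary_domains = 0L))
})

test_that("co-occurrence counts each CBM/secondary pair once per record", {
  cfg <- FilterConfig()
  seqs <- setNames(rep(seq40(), 3), c("R1", "R2", "R3"))
  dom <- rbind(
    domRow("R1", "IPR033803", 1, 40, "carbohydrate_binding"),
    domRow("R1", "IPR003961", 60, 100, "other"),
    domRow("R1", "IPR011990", 120, 160, "other"),
    domRow("R2", "IPR033803", 1, 40, "carbohydrate_binding"),  # CBM only
    domRow("R3", "IPR033803", 1, 40, "carbohydrate_binding"),
    domRow("R3", "IPR033803", 50, 90, "carbohydrate_binding"), # copy ignored in pairing
    domRow("R3", "IPR003961", 100, 140, "other"))
  ps <- ProteinSet(seqs, dom)
  co <- cooccurrenceMatrix(ps, cfg)
  expect_equal(co$matrix["IPR033803", "IPR003961"], 2L)
  expect_equal(co$matrix["IPR033803", "IPR011990"], 1L)
  expect_equal(co$totals[["IPR033803"]], 3L)
  expect_equal(co$totals[["IPR003961"]], 2L)
  expect_true(all(co$matrix >= 0L))
  # row sum bound: >= records with that CBM and at least one secondary
  expect_gte(sum(co$matrix["IPR033803", ]), 2L)
})

test_that("protein sets round-trip through FASTA plus annotation TSV", {
  u <- genProteinUniverse(nTrue = 6, nDecoys = 6, seed = 3)
  fa <- tempfile(fileext = ".fa"); ann <- tempfile(fileext = ".tsv")
  writeProteinSet(u$proteins, fa, ann)
  back <- readProteinSet(fa, ann)
  expect_equal(as.character(proteinSequences(back)),
               as.character(proteinSequences(u$proteins)))
  expect_equal(proteinMeta(back), proteinMeta(u$proteins))
  o <- do.call(order, proteinAnnotations(back))
  o2 <- do.call(order, proteinAnnotations(u$proteins))
  expect_equal(proteinAnnotations(back)[o, ],
               proteinAnnotations(u$proteins)[o2, ],
               ignore_attr = TRUE)
  expect_identical(classifyRecords(back)$reason, u$truth$reason)
})
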