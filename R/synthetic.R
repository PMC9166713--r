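# Seeded synthetic-data generators with ground truth for every pipeline
# stage.  Each generator is a pure function of its arguments and seed: it
# seeds its own RNG stream and restores the caller's RNG state on exit, so
# identical calls are byte-identical and callers are never perturbed.

.AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

.randSeq <- function(len) paste(sample(.AA, len, replace = TRUE), collapse = "")

.mutateSeq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  hit <- runif(length(ch)) < rate
  if (any(hit)) {
    ch[hit] <- vapply(ch[hit], function(x) sample(setdiff(.AA, x), 1L),
                      character(1))
  }
  paste(ch, collapse = "")
}

.cleanDescriptions <- c("uncharacterized protein", "hypothetical protein",
                        "conserved protein of unknown function",
                        "domain-containing protein")

.plantDomains <- function(len, ids, categories) {
  k <- length(ids)
  width <- pmin(60L, max(10L, len %/% (k + 1L)))
  starts <- sort(sample(seq_len(max(1L, len - width)), k))
  data.frame(domain_id = ids, start = as.integer(starts),
             end = as.integer(pmin(starts + width - 1L, len)),
             category = categories, stringsAsFactors = FALSE)
}

#' Generate a synthetic annotated protein universe
#'
#' True lectins carry at least one CBM domain, no catalytic domain, a clean
#' description and `reviewed = FALSE`.  Decoys each violate exactly one
#' filtering rule, split across the four violation classes by `decoyMix`.
#'
#' @param nTrue number of true lectins.
#' @param nDecoys number of decoys.
#' @param decoyMix named numeric weights for the violation classes
#'   `catalytic`, `keyword`, `reviewed`, `no_cbm`; must not sum above 1
#'   (weights are renormalized, counts by largest remainder).
#' @param lengthRange sequence length range.
#' @param config a [FilterConfig-class] defining CBM ids and keywords.
#' @param domainTable domain table supplying secondary/catalytic ids.
#' @param seed RNG seed.
#' @return list with `proteins` (a [ProteinSet-class]) and `truth`
#'   (data.frame `accession`, `is_lectin`, `reason`).
#' @export
genProteinUniverse <- function(nTrue = 100L, nDecoys = 100L,
                               decoyMix = c(catalytic = 0.25, keyword = 0.25,
                                            reviewed = 0.25, no_cbm = 0.25),
                               lengthRange = c(120L, 300L),
                               config = FilterConfig(),
                               domainTable = defaultDomainTable(),
                               seed = 1L) .withSeed(seed, {
  if (sum(decoyMix) > 1 + 1e-9)
    stop("decoyMix fractions must not sum above 1", call. = FALSE)
  classes <- c("catalytic", "keyword", "reviewed", "no_cbm")
  w <- decoyMix[classes]; w[is.na(w)] <- 0
  if (sum(w) <= 0 && nDecoys > 0L)
    stop("decoyMix must have positive weight for some class", call. = FALSE)
  # largest-remainder apportionment of decoys over classes
  raw <- if (nDecoys > 0L) nDecoys * w / sum(w) else rep(0, 4L)
  cnt <- floor(raw)
  extra <- order(raw - cnt, decreasing = TRUE)[seq_len(nDecoys - sum(cnt))]
  cnt[extra] <- cnt[extra] + 1L
  cbm <- config@cbmDomains
  sec <- domainTable$domain_id[domainTable$category == "other"]
  cat_ids <- domainTable$domain_id[domainTable$category == "catalytic"]
  labels <- c(rep("accept", nTrue), rep(classes, times = cnt))
  n <- length(labels)
  acc <- sprintf("SYN%04d", seq_len(n))
  seqs <- character(n); reviewed <- logical(n); descr <- character(n)
  ann <- vector("list", n)
  for (i in seq_len(n)) {
    len <- sample(seq(lengthRange[1], lengthRange[2]), 1L)
    seqs[i] <- .randSeq(len)
    descr[i] <- sample(.cleanDescriptions, 1L)
    lab <- labels[i]
    ids <- sample(cbm, 1L); cats <- "carbohydrate_binding"
    nsec <- sample(0:2, 1L)
    if (nsec > 0L) {
      ids <- c(ids, sample(sec, nsec))
      cats <- c(cats, rep("other", nsec))
    }
    if (lab == "catalytic") {
      ids <- c(ids, sample(cat_ids, 1L)); cats <- c(cats, "catalytic")
    } else if (lab == "keyword") {
      kw <- sample(config@exclusionKeywords, 1L)
      descr[i] <- paste("putative", tolower(kw), "protein")
    } else if (lab == "reviewed") {
      reviewed[i] <- TRUE
    } else if (lab == "no_cbm") {
      ids <- sample(sec, max(1L, nsec)); cats <- rep("other", length(ids))
    }
    d <- .plantDomains(len, ids, cats)
    d$accession <- acc[i]
    ann[[i]] <- d
  }
  ann <- do.call(rbind, ann)[, c("accession", "domain_id", "start", "end",
                                 "category")]
  proteins <- ProteinSet(setNames(seqs, acc), ann,
                         reviewed = setNames(reviewed, acc),
                         description = setNames(descr, acc))
  list(proteins = proteins,
       truth = data.frame(accession = acc, is_lectin = labels == "accept",
                          reason = labels, stringsAsFactors = FALSE))
})

.mutateExact <- function(seq, k) {
  if (k <= 0L) return(seq)
  ch <- strsplit(seq, "")[[1]]
  at <- sample(length(ch), k)
  ch[at] <- vapply(ch[at], function(x) sample(setdiff(.AA, x), 1L),
                   character(1))
  paste(ch, collapse = "")
}

#' Generate synthetic sequence families
#'
#' Each family is a random ancestor plus members carrying substitutions at
#' `withinDivergence`: every member differs from the ancestor at exactly
#' `round(withinDivergence * seqLength)` positions (sampled uniformly, no
#' indels).  Fixing the substitution count rather than drawing it per site
#' makes within-family identity bounds exact: any two members differ at no
#' more than twice that count of positions, so at 5 percent divergence the
#' member-to-member identity never falls below 0.90 and clustering at the
#' inclusive 0.90 threshold recovers the families deterministically.
#' Different families are independent random sequences.
#'
#' @param nFamilies,familySize family structure.
#' @param withinDivergence per-site substitution fraction in `[0, 1)`.
#' @param seqLength ancestor length.
#' @param seed RNG seed.
#' @return list with `sequences` (named character), `truth` (data.frame
#'   `accession`, `family`).
#' @export
genSequenceFamilies <- function(nFamilies = 5L, familySize = 6L,
                                withinDivergence = 0.05, seqLength = 120L,
                                seed = 1L) .withSeed(seed, {
  stopifnot(withinDivergence >= 0, withinDivergence < 1)
  k <- as.integer(round(withinDivergence * seqLength))
  seqs <- character(0); fam <- character(0)
  for (f in seq_len(nFamilies)) {
    anc <- .randSeq(seqLength)
    for (m in seq_len(familySize)) {
      seqs <- c(seqs, .mutateExact(anc, k))
      fam <- c(fam, sprintf("F%02d", f))
    }
  }
  acc <- sprintf("%s_M%02d", fam,
                 unlist(lapply(unname(table(fam)[unique(fam)]), seq_len)))
  names(seqs) <- acc
  list(sequences = seqs,
       truth = data.frame(accession = acc, family = fam,
                          stringsAsFactors = FALSE))
})

#' Generate per-sample gene catalogs with planted lectin presence
#'
#' Each sample of each body site contains lectin `i` with that site's
#' inclusion probability (optionally as a mutated copy), plus background
#' random genes.  The planted presence is recorded as ground truth.
#'
#' @param lectins named character vector of lectin sequences.
#' @param sites data.frame with columns `site`, `n_samples` and
#'   `inclusion_prob`, or a named numeric vector
#'   `site = inclusion_prob` with `nSamples` samples each.
#' @param nSamples samples per site when `sites` is a named vector.
#' @param nBackground background genes per sample.
#' @param mutationRate per-site substitution rate applied to planted copies
#'   (0 = exact copies).
#' @param backgroundLength length of background genes.
#' @param seed RNG seed.
#' @return list with `catalogs` (list of [GeneCatalog()]), `manifest`
#'   (data.frame `sample_id`, `body_site`) and `truth` (logical matrix,
#'   lectins x samples, the planted presence).
#' @export
genCatalogs <- function(lectins, sites = c(stool = 0.5, buccal_mucosa = 0.3),
                        nSamples = 20L, nBackground = 5L, mutationRate = 0,
                        backgroundLength = 150L, seed = 1L) .withSeed(seed, {
  stopifnot(length(lectins) > 0L, !is.null(names(lectins)))
  if (!is.data.frame(sites)) {
    sites <- data.frame(site = names(sites),
                        n_samples = nSamples,
                        inclusion_prob = as.numeric(sites),
                        stringsAsFactors = FALSE)
  }
  stopifnot(all(sites$inclusion_prob >= 0 & sites$inclusion_prob <= 1))
  catalogs <- list(); sid <- character(0); bsite <- character(0)
  truth <- matrix(FALSE, length(lectins), 0, dimnames = list(names(lectins), NULL))
  for (r in seq_len(nrow(sites))) {
    for (k in seq_len(sites$n_samples[r])) {
      id <- sprintf("%s_S%03d", sites$site[r], k)
      inc <- runif(length(lectins)) < sites$inclusion_prob[r]
      genes <- character(0)
      if (any(inc)) {
        copies <- vapply(as.character(lectins[inc]), .mutateSeq, character(1),
                         rate = mutationRate)
        names(copies) <- paste0(id, "_g", seq_len(sum(inc)))
        genes <- copies
      }
      if (nBackground > 0L) {
        bg <- vapply(seq_len(nBackground), function(j)
          .randSeq(backgroundLength), character(1))
        names(bg) <- paste0(id, "_bg", seq_len(nBackground))
        genes <- c(genes, bg)
      }
      catalogs[[length(catalogs) + 1L]] <- GeneCatalog(id, sites$site[r], genes)
      truth <- cbind(truth, matrix(inc, ncol = 1, dimnames = list(NULL, id)))
      sid <- c(sid, id); bsite <- c(bsite, sites$site[r])
    }
  }
  list(catalogs = catalogs,
       manifest = data.frame(sample_id = sid, body_site = bsite,
                             stringsAsFactors = FALSE),
       truth = truth)
})

.randomGlycanTree <- function(size, codes) {
  code <- sample(codes, size, replace = TRUE)
  nd <- data.frame(id = seq_len(size), code = code,
                   decoration = rep("", size), stringsAsFactors = FALSE)
  if (size == 1L) {
    ed <- data.frame(child = integer(0), parent = integer(0),
                     anomeric = character(0), child_pos = integer(0),
                     parent_pos = integer(0), stringsAsFactors = FALSE)
    return(new("GlycanStructure", nodes = nd, edges = ed, root = 1L))
  }
  parent <- integer(0); ppos <- integer(0)
  used <- list()  # occupied parent carbons per node
  for (i in 2:size) {
    repeat {
      p <- sample(seq_len(i - 1L), 1L)
      free <- setdiff(2:6, used[[as.character(p)]])
      if (length(free) > 0L) break
    }
    pos <- if (length(free) == 1L) free else sample(free, 1L)
    used[[as.character(p)]] <- c(used[[as.character(p)]], pos)
    parent <- c(parent, p); ppos <- c(ppos, pos)
  }
  ed <- data.frame(child = 2:size, parent = parent,
                   anomeric = sample(c("a", "b"), size - 1L, replace = TRUE),
                   child_pos = sample(1:2, size - 1L, replace = TRUE),
                   parent_pos = ppos, stringsAsFactors = FALSE)
  new("GlycanStructure", nodes = nd, edges = ed, root = 1L)
}

.graftResidues <- function(g, k, codes) {
  nd <- g@nodes; ed <- g@edges
  for (j in seq_len(k)) {
    repeat {
      p <- sample(nd$id, 1L)
      free <- setdiff(2:6, ed$parent_pos[ed$parent == p])
      if (length(free) > 0L) break
    }
    pos <- if (length(free) == 1L) free else sample(free, 1L)
    id <- max(nd$id) + 1L
    nd <- rbind(nd, data.frame(id = id, code = sample(codes, 1L),
                               decoration = "", stringsAsFactors = FALSE))
    ed <- rbind(ed, data.frame(child = id, parent = p,
                               anomeric = sample(c("a", "b"), 1L),
                               child_pos = sample(1:2, 1L),
                               parent_pos = pos, stringsAsFactors = FALSE))
  }
  new("GlycanStructure", nodes = nd, edges = ed, root = g@root)
}

#' Generate a synthetic glycan-array screen with a planted motif
#'
#' Binder glycans contain the planted motif grafted into random tree
#' context; nonbinders are random trees verified at generation time not to
#' contain the motif.  Replicate RFUs are the class mean plus Gaussian
#' noise; with probability `outlierProb` a replicate is replaced by a
#' tenfold outlier to exercise trimming.
#'
#' @param nBinders,nNonbinders library composition.
#' @param motif planted motif in condensed notation.
#' @param binderMean,nonbinderMean class mean RFUs.
#' @param noiseSd replicate Gaussian noise SD (0 = noise-free).
#' @param outlierProb per-replicate outlier probability.
#' @param nReplicates replicates per glycan (the screen uses 6).
#' @param proteinId,concentration metadata columns.
#' @param seed RNG seed.
#' @return list with `array` (data.frame: `glycan_id`, `structure`,
#'   `protein_id`, `concentration`, `rep1..repK`) and `truth` (list:
#'   `binders` ids, `motif` canonical text).
#' @export
genGlycanArray <- function(nBinders = 12L, nNonbinders = 12L,
                           motif = "Galb1-3GlcNAcb1-2Mana1-3Man",
                           binderMean = 10000, nonbinderMean = 200,
                           noiseSd = 500, outlierProb = 0.05,
                           nReplicates = 6L, proteinId = "CBM5",
                           concentration = "50 ug/ml",
                           seed = 1L) .withSeed(seed, {
  m <- parseGlycan(motif)
  codes <- monosaccharideCodes()
  structs <- list(); is_binder <- logical(0)
  for (i in seq_len(nBinders)) {
    g <- .graftResidues(m, sample(1:3, 1L), codes)
    structs[[length(structs) + 1L]] <- g; is_binder <- c(is_binder, TRUE)
  }
  for (i in seq_len(nNonbinders)) {
    tries <- 0L
    repeat {
      g <- .randomGlycanTree(sample(4:8, 1L), codes)
      if (!containsMotif(g, m)) break
      tries <- tries + 1L
      if (tries > 200L) stop("could not generate a motif-free nonbinder",
                             call. = FALSE)
    }
    structs[[length(structs) + 1L]] <- g; is_binder <- c(is_binder, FALSE)
  }
  n <- length(structs)
  ids <- sprintf("G%03d", seq_len(n))
  reps <- matrix(0, n, nReplicates,
                 dimnames = list(NULL, paste0("rep", seq_len(nReplicates))))
  for (i in seq_len(n)) {
    mu <- if (is_binder[i]) binderMean else nonbinderMean
    v <- rnorm(nReplicates, mu, noiseSd)
    out <- runif(nReplicates) < outlierProb
    v[out] <- v[out] * 10
    reps[i, ] <- v
  }
  arr <- data.frame(glycan_id = ids,
                    structure = vapply(structs, glycanToText, character(1)),
                    protein_id = proteinId, concentration = concentration,
                    stringsAsFactors = FALSE)
  arr <- cbind(arr, as.data.frame(reps))
  list(array = arr,
       truth = list(binders = ids[is_binder], motif = glycanToText(m)))
})
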