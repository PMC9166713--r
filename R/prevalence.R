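# Presence/absence matrix across gene catalogs; prevalence, body-site
# overlap, top-prevalence selection and analytic sample-based rarefaction.

#' Construct a GeneCatalog
#'
#' @param sample_id sample identifier.
#' @param body_site body-site label.
#' @param genes named character vector (or `AAStringSet`) of predicted
#'   protein sequences; may be empty.
#' @return a list of class `GeneCatalog`.
#' @export
GeneCatalog <- function(sample_id, body_site, genes = character(0)) {
  structure(list(sample_id = as.character(sample_id),
                 body_site = as.character(body_site),
                 genes = as.character(genes) |>
                   setNames(if (length(genes)) names(genes) else character(0))),
            class = "GeneCatalog")
}

#' Read a sample manifest and its per-sample FASTAs
#'
#' @param path manifest TSV with columns `sample_id`, `body_site`,
#'   `fasta_path` (relative paths resolved against the manifest directory).
#' @return list of [GeneCatalog()] objects.
#' @export
readManifest <- function(path) {
  man <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "body_site", "fasta_path")
  if (!all(need %in% names(man)))
    stop("manifest must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  base <- dirname(normalizePath(path))
  lapply(seq_len(nrow(man)), function(i) {
    fp <- man$fasta_path[i]
    if (!file.exists(fp)) fp <- file.path(base, fp)
    genes <- Biostrings::readAAStringSet(fp)
    GeneCatalog(man$sample_id[i], man$body_site[i],
                setNames(as.character(genes), sub("\\s.*$", "", names(genes))))
  })
}

#' Build the lectin-by-sample Boolean presence matrix
#'
#' Cell `(i, s)` is `TRUE` when lectin `i` matches at least one gene of
#' sample `s` under [matchToSet()] (identity strictly above `threshold`,
#' aligned query coverage at least `minCoverage`).  An empty catalog gives
#' an all-`FALSE` column.
#'
#' @param lectins named character vector or `AAStringSet` of lectin
#'   sequences.
#' @param catalogs list of [GeneCatalog()] objects with unique sample ids.
#' @param threshold,minCoverage matching parameters, shared with the
#'   clustering stage.
#' @return a [PresenceMatrix-class].
#' @export
buildPresenceMatrix <- function(lectins, catalogs, threshold = 0.9,
                                minCoverage = 0.8) {
  lec <- as.character(lectins)
  acc <- names(lectins)
  if (length(lec) == 0L) stop("lectins must be non-empty", call. = FALSE)
  if (is.null(acc) || anyDuplicated(acc))
    stop("lectins must be uniquely named", call. = FALSE)
  if (length(catalogs) == 0L) stop("catalogs must be non-empty", call. = FALSE)
  sids <- vapply(catalogs, function(ct) ct$sample_id, character(1))
  if (anyDuplicated(sids)) stop("duplicate sample_id in catalogs", call. = FALSE)
  sites <- vapply(catalogs, function(ct) ct$body_site, character(1))
  m <- matrix(FALSE, length(lec), length(sids), dimnames = list(acc, sids))
  # one alignment batch per lectin across every gene of every catalog;
  # per-cell semantics are those of matchToSet (strict identity + coverage)
  genes <- unlist(lapply(catalogs, function(ct) unname(ct$genes)))
  gene_sample <- rep(seq_along(catalogs),
                     vapply(catalogs, function(ct) length(ct$genes), integer(1)))
  if (length(genes) > 0L) {
    for (i in seq_along(lec)) {
      exact <- genes == lec[i]
      hit <- exact & 1 > threshold
      if (any(!exact)) {
        st <- .alignStats(lec[i], genes[!exact])
        hit[!exact] <- st$identity > threshold & st$coverage >= minCoverage
      }
      m[i, unique(gene_sample[hit])] <- TRUE
    }
  }
  new("PresenceMatrix", presence = m, siteMap = setNames(sites, sids))
}

#' Presence matrix accessor
#' @param x a [PresenceMatrix-class].
#' @return logical matrix (lectins x samples).
#' @export
presence <- function(x) x@presence

#' Sample-to-body-site map accessor
#' @param x a [PresenceMatrix-class].
#' @return named character vector.
#' @export
siteMap <- function(x) x@siteMap

setMethod("show", "PresenceMatrix", function(object) {
  cat("PresenceMatrix:", nrow(object@presence), "lectins x",
      ncol(object@presence), "samples across",
      length(unique(object@siteMap)), "body sites\n")
})

.siteCols <- function(pm, site) {
  cols <- names(pm@siteMap)[pm@siteMap == site]
  if (length(cols) == 0L) stop("no samples for site ", sQuote(site), call. = FALSE)
  cols
}

#' Per-site prevalence summary
#'
#' @param pm a [PresenceMatrix-class].
#' @return list with `sites` (data.frame: `site`, `n_samples`, `richness` =
#'   lectins present in >= 1 site sample, `mean_per_sample` = average lectin
#'   count per sample, one sample per person) and `lectin_counts` (integer
#'   matrix, lectins x sites, number of site samples containing each lectin).
#' @export
prevalenceSummary <- function(pm) {
  stopifnot(is(pm, "PresenceMatrix"))
  sites <- sort(unique(pm@siteMap))
  counts <- sapply(sites, function(st) {
    cols <- .siteCols(pm, st)
    rowSums(pm@presence[, cols, drop = FALSE])
  })
  counts <- matrix(as.integer(counts), nrow = nrow(pm@presence),
                   dimnames = list(rownames(pm@presence), sites))
  df <- data.frame(
    site = sites,
    n_samples = vapply(sites, function(st) length(.siteCols(pm, st)), integer(1)),
    richness = apply(counts > 0L, 2L, sum),
    mean_per_sample = vapply(sites, function(st) {
      cols <- .siteCols(pm, st)
      mean(colSums(pm@presence[, cols, drop = FALSE]))
    }, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  list(sites = df, lectin_counts = counts)
}

#' Body-site overlap of lectins
#'
#' @param pm a [PresenceMatrix-class].
#' @return list with `site_sets` (per-lectin character vector of sites with
#'   >= 1 positive sample), `shared_fraction` (lectins found in >= 2 sites
#'   over lectins found in >= 1 site), `site_specific` (named numeric: per
#'   site, the fraction of its lectins found in that site only), `pairwise`
#'   (site x site shared-lectin counts) and, for up to 6 sites, `venn`
#'   (named counts of lectins whose site set is exactly each non-empty site
#'   combination).
#' @export
siteOverlap <- function(pm) {
  stopifnot(is(pm, "PresenceMatrix"))
  sites <- sort(unique(pm@siteMap))
  counts <- prevalenceSummary(pm)$lectin_counts
  site_sets <- apply(counts > 0L, 1L, function(r) sites[r], simplify = FALSE)
  nsites <- lengths(site_sets)
  present <- nsites >= 1L
  shared_fraction <- if (any(present)) sum(nsites >= 2L) / sum(present) else 0
  site_specific <- vapply(sites, function(st) {
    here <- vapply(site_sets, function(s) st %in% s, logical(1))
    if (!any(here)) return(0)
    sum(here & nsites == 1L) / sum(here)
  }, numeric(1))
  pairwise <- matrix(0L, length(sites), length(sites),
                     dimnames = list(sites, sites))
  for (a in sites) for (b in sites)
    pairwise[a, b] <- sum(vapply(site_sets, function(s) a %in% s && b %in% s,
                                 logical(1)))
  out <- list(site_sets = site_sets, shared_fraction = shared_fraction,
              site_specific = site_specific, pairwise = pairwise)
  if (length(sites) <= 6L && length(sites) >= 1L) {
    keys <- vapply(site_sets[present], paste, character(1), collapse = "&")
    out$venn <- table(keys)
  }
  out
}

#' Most prevalent lectins at a body site
#'
#' Ranks the site's present lectins by within-site sample count (ties broken
#' by accession) and returns the top `ceiling(fraction * richness)`.
#'
#' @param pm a [PresenceMatrix-class].
#' @param site body-site label.
#' @param fraction fraction of the site's richness to return, in (0, 1];
#'   default 0.1 (the "top 10 percent").
#' @return character vector of lectin accessions; empty when the site has no
#'   present lectins.
#' @export
topPrevalent <- function(pm, site, fraction = 0.1) {
  stopifnot(is(pm, "PresenceMatrix"), fraction > 0, fraction <= 1)
  cols <- .siteCols(pm, site)
  cnt <- rowSums(pm@presence[, cols, drop = FALSE])
  cnt <- cnt[cnt > 0L]
  if (length(cnt) == 0L) return(character(0))
  o <- order(-cnt, names(cnt), method = "radix")
  names(cnt)[o][seq_len(ceiling(fraction * length(cnt)))]
}

#' Analytic sample-based rarefaction curve for a body site
#'
#' For a site with `N` samples and per-lectin incidence counts `N_i`, the
#' expected richness in a random subset of `n` samples is
#' `S(n) = sum_i (1 - choose(N - N_i, n) / choose(N, n))`, evaluated in
#' log space (`lchoose`) for stability.  `S(1)` equals the mean per-sample
#' richness and `S(N)` the observed site richness.  Optionally, seeded
#' resampling provides standard deviations.
#'
#' @param pm a [PresenceMatrix-class].
#' @param site body-site label (must have >= 1 sample).
#' @param n subset sizes; defaults to `1:N`.
#' @param nboot number of resampling replicates for SDs (0 = analytic only).
#' @param seed RNG seed used when `nboot > 0`.
#' @return data.frame with columns `site`, `n`, `expected_richness` and,
#'   when `nboot > 0`, `sd`.
#' @export
rarefactionCurve <- function(pm, site, n = NULL, nboot = 0L, seed = 1L) {
  stopifnot(is(pm, "PresenceMatrix"))
  cols <- .siteCols(pm, site)
  N <- length(cols)
  if (is.null(n)) n <- seq_len(N)
  if (any(n < 1L | n > N)) stop("n must lie in 1..", N, call. = FALSE)
  Ni <- rowSums(pm@presence[, cols, drop = FALSE])
  Ni <- Ni[Ni >= 1L]
  S <- vapply(n, function(k) {
    miss <- ifelse(k > N - Ni, 0, exp(lchoose(N - Ni, k) - lchoose(N, k)))
    sum(1 - miss)
  }, numeric(1))
  out <- data.frame(site = site, n = as.integer(n), expected_richness = S,
                    stringsAsFactors = FALSE)
  if (nboot > 0L) {
    sub <- pm@presence[, cols, drop = FALSE]
    out$sd <- .withSeed(seed, vapply(n, function(k) {
      reps <- vapply(seq_len(nboot), function(b)
        sum(rowSums(sub[, sample(N, k), drop = FALSE]) > 0L), numeric(1))
      stats::sd(reps)
    }, numeric(1)))
  }
  out
}

#' Write a presence matrix as 0/1 TSV
#' @param pm a [PresenceMatrix-class].
#' @param path output TSV path.
#' @return invisibly, the path.
#' @export
writePresenceMatrix <- function(pm, path) {
  m <- pm@presence * 1L
  df <- data.frame(lectin = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
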