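# End-to-end orchestration: mine -> cluster -> presence -> prevalence /
# overlap / rarefaction -> co-occurrence -> (optional) array analysis.

.reportJSON <- function(report) {
  jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                   null = "null")
}

#' Run the lectin discovery pipeline
#'
#' Composes the pipeline stages on in-memory inputs: candidate filtering
#' ([classifyRecords()]), greedy centroid clustering of accepted sequences
#' ([greedyCluster()]), the Boolean presence matrix over gene catalogs
#' ([buildPresenceMatrix()]) with per-site prevalence, overlap and
#' rarefaction, the CBM x secondary-domain co-occurrence, and, when array
#' data is supplied, binding-profile and motif-mining analysis.  The run is
#' fully deterministic: the same inputs and configuration give byte-identical
#' reports.
#'
#' @param proteins a [ProteinSet-class] (the annotated universe); required.
#' @param catalogs optional list of [GeneCatalog()] objects.
#' @param array optional glycan-array data.frame (see [readGlycanArray()] /
#'   [genGlycanArray()]).
#' @param filterConfig a [FilterConfig-class].
#' @param clusterThreshold identity threshold for clustering (inclusive).
#' @param matchThreshold identity threshold for catalog matching (strict).
#' @param minCoverage minimum aligned query coverage for matching.
#' @param topFraction fraction for [topPrevalent()] per site.
#' @param binderThreshold normalized-score threshold for binder calls.
#' @param maxMotifSize maximum motif size for [mineMotifs()].
#' @param outDir optional output directory; when given, writes `report.json`,
#'   `candidates.tsv`, `clusters.tsv`, `presence.tsv` and `rarefaction.tsv`.
#' @return the report, a nested list (invisibly identical to the JSON
#'   written to `outDir`).
#' @export
runDiscoveryPipeline <- function(proteins, catalogs = NULL, array = NULL,
                                 filterConfig = FilterConfig(),
                                 clusterThreshold = 0.9,
                                 matchThreshold = 0.9, minCoverage = 0.8,
                                 topFraction = 0.1, binderThreshold = 0.1,
                                 maxMotifSize = 5L, outDir = NULL) {
  stopifnot(is(proteins, "ProteinSet"))
  cls <- classifyRecords(proteins, filterConfig)
  accepted <- cls$accession[cls$accept]
  report <- list(
    mining = list(n_input = nrow(cls), n_accepted = length(accepted),
                  rejects = as.list(table(cls$reason[!cls$accept]))))
  cands <- NULL; cs <- NULL
  if (length(accepted) > 0L) {
    cands <- subsetProteins(proteins, accepted)
    cs <- greedyCluster(setNames(as.character(proteinSequences(cands)),
                                 accepted), clusterThreshold)
    summ <- summarizeCandidates(cands, filterConfig)
    report$candidates <- list(
      n_sequences = summ$n_sequences,
      n_unique = length(unique(clusterTable(cs)$cluster_id)),
      n_architectures = summ$n_architectures,
      n_cbm_domains = summ$n_cbm_domains,
      n_secondary_domains = summ$n_secondary_domains)
    co <- cooccurrenceMatrix(cands, filterConfig)
    report$cooccurrence <- list(
      n_pairs = sum(co$matrix > 0L),
      max_pair_count = if (length(co$matrix)) max(co$matrix) else 0L,
      totals = as.list(co$totals))
  }
  pm <- NULL; rar <- NULL
  if (!is.null(catalogs) && length(catalogs) > 0L && !is.null(cs)) {
    cents <- clusterCentroids(cs)
    lect <- setNames(as.character(proteinSequences(proteins)[cents]), cents)
    pm <- buildPresenceMatrix(lect, catalogs, matchThreshold, minCoverage)
    prev <- prevalenceSummary(pm)
    ov <- siteOverlap(pm)
    sites <- prev$sites$site
    rar <- do.call(rbind, lapply(sites, function(st) rarefactionCurve(pm, st)))
    report$prevalence <- list(
      sites = prev$sites,
      shared_fraction = ov$shared_fraction,
      site_specific = as.list(ov$site_specific),
      top_prevalent = lapply(setNames(sites, sites), function(st)
        topPrevalent(pm, st, topFraction)))
  }
  prof <- NULL
  if (!is.null(array)) {
    prof <- bindingProfile(array, binderThreshold)
    structs <- lapply(array$structure, parseGlycan)
    names(structs) <- array$glycan_id
    b <- prof$glycan_id[prof$binder]
    nb <- prof$glycan_id[!prof$binder]
    motifs <- mineMotifs(structs[b], structs[nb], maxMotifSize)
    top <- utils::head(motifs, 10L)
    report$array <- list(
      n_glycans = nrow(prof), n_binders = length(b),
      top_motifs = data.frame(top[c("motif", "size", "binder_coverage",
                                    "nonbinder_frequency", "score")]))
  }
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeLines(.reportJSON(report), file.path(outDir, "report.json"))
    write.table(cls, file.path(outDir, "candidates.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (!is.null(cs)) writeClusterTable(cs, file.path(outDir, "clusters.tsv"))
    if (!is.null(pm)) {
      writePresenceMatrix(pm, file.path(outDir, "presence.tsv"))
      write.table(rar, file.path(outDir, "rarefaction.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    if (!is.null(prof))
      write.table(prof, file.path(outDir, "binding_profile.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
  }
  invisible(report)
}
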