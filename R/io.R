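# Plain-text writers mirroring the readers, used by the command-line tool
# and for materializing synthetic datasets.

#' Write a ProteinSet as FASTA plus annotation TSV
#'
#' The annotation TSV layout matches [readProteinSet()]: one row per domain
#' with the record's `reviewed` flag and `description` repeated; a record
#' without domains gets one row with an empty `domain_id`.
#'
#' @param proteins a [ProteinSet-class].
#' @param fasta,annotations output paths.
#' @return invisibly, the annotation path.
#' @export
writeProteinSet <- function(proteins, fasta, annotations) {
  stopifnot(is(proteins, "ProteinSet"))
  Biostrings::writeXStringSet(proteinSequences(proteins), fasta)
  meta <- proteinMeta(proteins)
  ann <- proteinAnnotations(proteins)
  rows <- lapply(meta$accession, function(a) {
    d <- ann[ann$accession == a, , drop = FALSE]
    if (nrow(d) == 0L)
      d <- data.frame(accession = a, domain_id = "", start = NA_integer_,
                      end = NA_integer_, category = "", stringsAsFactors = FALSE)
    i <- match(a, meta$accession)
    data.frame(accession = a, reviewed = meta$reviewed[i],
               description = meta$description[i], domain_id = d$domain_id,
               start = d$start, end = d$end, stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, rows), annotations, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(annotations)
}

#' Write gene catalogs as per-sample FASTAs plus a manifest TSV
#'
#' @param catalogs list of [GeneCatalog()] objects.
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest path.
#' @export
writeCatalogs <- function(catalogs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(catalogs, function(ct) {
    fp <- paste0(ct$sample_id, ".fa")
    Biostrings::writeXStringSet(Biostrings::AAStringSet(ct$genes),
                                file.path(dir, fp))
    data.frame(sample_id = ct$sample_id, body_site = ct$body_site,
               fasta_path = fp, stringsAsFactors = FALSE)
  })
  man <- file.path(dir, "manifest.tsv")
  write.table(do.call(rbind, rows), man, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(man)
}
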