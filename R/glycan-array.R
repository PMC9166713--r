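# Glycan microarray processing: replicate trimming, top-binder normalization,
# binder calling.

#' Trimmed mean of array replicates
#'
#' Removes exactly one occurrence of the maximum and one occurrence of the
#' minimum, then averages the remaining values (the screen's six replicates
#' become a mean of four).  Negative, background-subtracted RFUs are kept.
#'
#' @param rfus numeric vector of replicate relative-fluorescence units,
#'   length >= 3.
#' @return the trimmed mean.
#' @examples
#' aggregateReplicates(c(1, 2, 3, 4, 5, 100))  # 3.5
#' @export
aggregateReplicates <- function(rfus) {
  if (!is.numeric(rfus) || length(rfus) < 3L)
    stop("need at least 3 replicate values to trim and average", call. = FALSE)
  if (any(!is.finite(rfus))) stop("replicate RFUs must be finite", call. = FALSE)
  keep <- sort(rfus)[2:(length(rfus) - 1L)]
  mean(keep)
}

#' Normalize aggregated RFUs to the top binder
#'
#' Negative aggregated values are clipped to zero, then all values are
#' divided by the maximum so the top glycan binder scores exactly 1.
#'
#' @param aggregated named numeric vector, one aggregated RFU per glycan id.
#' @return named numeric vector of scores in `[0, 1]`.
#' @export
normalizeProfile <- function(aggregated) {
  if (length(aggregated) == 0L)
    stop("no aggregated values to normalize", call. = FALSE)
  if (is.null(names(aggregated)) || anyDuplicated(names(aggregated)))
    stop("aggregated values must be uniquely named by glycan id", call. = FALSE)
  clipped <- pmax(aggregated, 0)
  top <- max(clipped)
  if (top <= 0)
    stop("all aggregated RFUs are <= 0; no positive binder to anchor the scale",
         call. = FALSE)
  clipped / top
}

#' Call binder glycans from normalized scores
#'
#' @param scores named numeric vector of normalized scores (from
#'   [normalizeProfile()]).
#' @param threshold fraction of the top binder's signal required, in
#'   `[0, 1]`; default 0.1.
#' @return character vector of binder glycan ids.
#' @export
callBinders <- function(scores, threshold = 0.1) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold >= 0, threshold <= 1)
  names(scores)[scores >= threshold]
}

#' Build a binding profile from a glycan-array table
#'
#' Aggregates each glycan's replicates with [aggregateReplicates()],
#' normalizes with [normalizeProfile()] and flags binders at `threshold`.
#'
#' @param array data.frame as returned by [readGlycanArray()] or
#'   [genGlycanArray()]: columns `glycan_id` plus `rep1`, `rep2`, ...
#' @param threshold binder-calling threshold on the normalized score.
#' @return data.frame with columns `glycan_id`, `aggregated_rfu`,
#'   `normalized_score`, `binder`.
#' @export
bindingProfile <- function(array, threshold = 0.1) {
  repcols <- grep("^rep\\d+$", names(array), value = TRUE)
  if (length(repcols) < 3L)
    stop("array must have at least 3 rep<k> columns", call. = FALSE)
  if (anyDuplicated(array$glycan_id))
    stop("glycan_id must be unique", call. = FALSE)
  agg <- apply(as.matrix(array[repcols]), 1L, aggregateReplicates)
  names(agg) <- array$glycan_id
  sc <- normalizeProfile(agg)
  data.frame(glycan_id = array$glycan_id, aggregated_rfu = unname(agg),
             normalized_score = unname(sc),
             binder = unname(sc >= threshold), stringsAsFactors = FALSE)
}

#' Read a glycan-array CSV
#'
#' Expects a UTF-8 CSV with header columns `glycan_id`, `structure` (condensed
#' notation), `protein_id`, `concentration` and replicate columns
#' `rep1`..`repK` (K >= 3).  Structures are parsed eagerly so malformed rows
#' fail at read time.
#'
#' @param path CSV file path.
#' @return data.frame with the original columns plus a list column
#'   `structure_tree` of [GlycanStructure-class] objects.
#' @export
readGlycanArray <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("glycan_id", "structure", "protein_id", "concentration")
  if (!all(need %in% names(x)))
    stop("array CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (length(grep("^rep\\d+$", names(x))) < 3L)
    stop("array CSV must have at least 3 rep<k> columns", call. = FALSE)
  x$structure_tree <- I(lapply(x$structure, parseGlycan))
  x
}
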