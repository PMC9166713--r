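# Percent-identity backend and greedy centroid clustering.
#
# Global (Needleman-Wunsch) alignments are computed with
# Biostrings::pairwiseAlignment under BLOSUM62 with affine gaps; identity is
# matches / alignment columns, counting every column including terminal gaps,
# so identity 1 holds iff the sequences are identical.

.matrixCache <- new.env(parent = emptyenv())

# resolve a substitution matrix name to the matrix itself once per session;
# passing the object to pairwiseAlignment avoids a per-call lookup
.substMatrix <- function(m) {
  if (!is.character(m)) return(m)
  if (is.null(.matrixCache[[m]])) {
    e <- new.env()
    utils::data(list = m, package = "Biostrings", envir = e)
    .matrixCache[[m]] <- get(m, envir = e)
  }
  .matrixCache[[m]]
}

.alignScoreParams <- function(substitutionMatrix = "BLOSUM62",
                              gapOpening = 11, gapExtension = 1) {
  list(substitutionMatrix = .substMatrix(substitutionMatrix),
       gapOpening = gapOpening, gapExtension = gapExtension)
}

# vectorized: one query against many references; returns matches, columns,
# coverage (query positions aligned to a residue / query length), score.
# For a global alignment every residue of both sequences occupies a column,
# so columns = len(a) + len(b) - (aligned residue pairs); this avoids
# materializing the aligned strings, which dominates runtime otherwise.
.alignStats <- function(query, refs, params = .alignScoreParams()) {
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(refs), subject = query, type = "global",
    substitutionMatrix = params$substitutionMatrix,
    gapOpening = params$gapOpening, gapExtension = params$gapExtension)
  matches <- Biostrings::nmatch(pa)
  paired <- matches + Biostrings::nmismatch(pa)   # both-residue columns
  columns <- nchar(refs) + nchar(query) - paired
  data.frame(matches = matches, columns = columns,
             identity = matches / columns,
             coverage = paired / nchar(query),
             score = BiocGenerics::score(pa))
}

#' Global alignment identity between two sequences
#'
#' Needleman-Wunsch global alignment (BLOSUM62, affine gaps: opening 11,
#' extension 1 by default).  Identity is the number of identical aligned
#' residue pairs divided by the total number of alignment columns, terminal
#' gap columns included; it equals 1 exactly when the sequences are
#' identical.
#'
#' @param a,b non-empty amino-acid strings.
#' @param substitutionMatrix,gapOpening,gapExtension scoring parameters.
#' @return list with `matches`, `columns`, `identity`, `score`.
#' @examples
#' globalAlignIdentity("ACDE", "ACDF")$identity  # 0.75
#' @export
globalAlignIdentity <- function(a, b, substitutionMatrix = "BLOSUM62",
                                gapOpening = 11, gapExtension = 1) {
  a <- as.character(a); b <- as.character(b)
  if (!nzchar(a) || !nzchar(b))
    stop("sequences must be non-empty", call. = FALSE)
  st <- .alignStats(a, b, .alignScoreParams(substitutionMatrix, gapOpening,
                                            gapExtension))
  list(matches = st$matches, columns = st$columns, identity = st$identity,
       score = st$score)
}

#' Match a query sequence against a reference set
#'
#' A reference matches when global-alignment identity is strictly greater
#' than `threshold` (the "> 90% identity" rule) and the aligned query
#' coverage (query residues aligned opposite a reference residue, as a
#' fraction of query length) is at least `minCoverage`.
#'
#' @param query non-empty amino-acid string.
#' @param references named character vector or `AAStringSet` of reference
#'   sequences.
#' @param threshold identity threshold (strict inequality); default 0.9.
#' @param minCoverage minimum aligned query coverage; default 0.8.
#' @return data.frame with columns `accession`, `identity`, sorted by
#'   identity descending; zero rows when nothing matches.
#' @export
matchToSet <- function(query, references, threshold = 0.9, minCoverage = 0.8) {
  query <- as.character(query)
  refs <- as.character(references)
  if (!nzchar(query)) stop("query must be non-empty", call. = FALSE)
  if (length(refs) == 0L) stop("references must be non-empty", call. = FALSE)
  acc <- names(references)
  if (is.null(acc)) acc <- as.character(seq_along(refs))
  identity <- numeric(length(refs)); coverage <- numeric(length(refs))
  exact <- refs == query
  identity[exact] <- 1; coverage[exact] <- 1
  if (any(!exact)) {
    st <- .alignStats(query, refs[!exact])
    identity[!exact] <- st$identity
    coverage[!exact] <- st$coverage
  }
  hit <- identity > threshold & coverage >= minCoverage
  out <- data.frame(accession = acc[hit], identity = identity[hit],
                    stringsAsFactors = FALSE)
  out[order(-out$identity, out$accession, method = "radix"), , drop = FALSE]
}

#' Greedy centroid clustering at an identity threshold
#'
#' USEARCH-style greedy clustering: sequences are processed sorted by
#' (length descending, accession ascending); the first founds a cluster, and
#' each subsequent sequence joins the centroid of best identity provided
#' that identity is `>= threshold` (ties go to the earliest-created
#' centroid), otherwise it founds a new cluster.  This defines the "unique"
#' lectin sequences.
#'
#' @param sequences named character vector or `AAStringSet`.
#' @param threshold identity fraction in (0, 1]; default 0.9.
#' @return a [ClusterSet-class].
#' @export
greedyCluster <- function(sequences, threshold = 0.9) {
  seqs <- as.character(sequences)
  acc <- names(sequences)
  if (length(seqs) == 0L) stop("sequences must be non-empty", call. = FALSE)
  if (is.null(acc) || anyDuplicated(acc))
    stop("sequences must be uniquely named", call. = FALSE)
  stopifnot(threshold > 0, threshold <= 1)
  o <- order(-nchar(seqs), acc, method = "radix")
  seqs <- seqs[o]; acc <- acc[o]
  cent_seq <- character(0); cent_acc <- character(0)
  rows <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    best_id <- -Inf; best_k <- 0L
    if (length(cent_seq) > 0L) {
      identity <- numeric(length(cent_seq))
      exact <- cent_seq == seqs[i]
      identity[exact] <- 1
      if (any(!exact))
        identity[!exact] <- .alignStats(seqs[i], cent_seq[!exact])$identity
      best_k <- which.max(identity)   # first max = earliest-created centroid
      best_id <- identity[best_k]
    }
    if (best_id >= threshold) {
      rows[[i]] <- data.frame(cluster_id = best_k, centroid = cent_acc[best_k],
                              member = acc[i], identity = best_id,
                              stringsAsFactors = FALSE)
    } else {
      cent_seq <- c(cent_seq, seqs[i]); cent_acc <- c(cent_acc, acc[i])
      rows[[i]] <- data.frame(cluster_id = length(cent_acc),
                              centroid = acc[i], member = acc[i], identity = 1,
                              stringsAsFactors = FALSE)
    }
  }
  cl <- do.call(rbind, rows)
  cl <- cl[order(cl$cluster_id, cl$member, method = "radix"), , drop = FALSE]
  rownames(cl) <- NULL
  new("ClusterSet", clusters = cl, threshold = threshold)
}

#' Cluster membership table
#' @param x a [ClusterSet-class].
#' @return data.frame with columns `cluster_id`, `centroid`, `member`,
#'   `identity`.
#' @export
clusterTable <- function(x) x@clusters

#' Centroid accessions of a ClusterSet
#' @param x a [ClusterSet-class].
#' @return character vector, one centroid per cluster in cluster order.
#' @export
clusterCentroids <- function(x) {
  cl <- x@clusters
  cl$centroid[match(sort(unique(cl$cluster_id)), cl$cluster_id)]
}

#' Identity threshold of a ClusterSet
#' @param x a [ClusterSet-class].
#' @return numeric threshold.
#' @export
identityThreshold <- function(x) x@threshold

setMethod("show", "ClusterSet", function(object) {
  cat("ClusterSet:", length(unique(object@clusters$cluster_id)),
      "clusters over", nrow(object@clusters), "sequences at identity >=",
      object@threshold, "\n")
})

#' Write a cluster table TSV
#' @param x a [ClusterSet-class].
#' @param path output TSV path.
#' @return invisibly, the path.
#' @export
writeClusterTable <- function(x, path) {
  write.table(clusterTable(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
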