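#' @import methods
#' @importFrom Biostrings AAStringSet pairwiseAlignment nmatch nmismatch width
#' @importFrom BiocGenerics score
#' @importFrom stats rnorm runif setNames sd
#' @importFrom utils read.delim write.table read.csv head
NULL

#' GlycanStructure: a rooted glycan tree
#'
#' A glycan is stored as a rooted tree of monosaccharide nodes.  The root is
#' the reducing-end residue; edges point from a child residue towards its
#' parent (i.e. towards the reducing end) and carry the anomeric configuration
#' (`"a"`, `"b"` or `"?"` when unknown) together with the child and parent
#' linkage carbons.
#'
#' @slot nodes data.frame with columns `id` (integer), `code` (monosaccharide
#'   code, e.g. `"Gal"`, `"GlcNAc"`) and `decoration` (substituent such as
#'   `"6S"`, or `""`).
#' @slot edges data.frame with columns `child`, `parent` (node ids),
#'   `anomeric`, `child_pos`, `parent_pos`.
#' @slot root integer id of the reducing-end node.
#'
#' @seealso [parseGlycan()], [glycanToText()], [containsMotif()]
#' @export
setClass("GlycanStructure",
  representation(nodes = "data.frame", edges = "data.frame", root = "integer"))

setValidity("GlycanStructure", function(object) {
  nd <- object@nodes; ed <- object@edges
  if (nrow(nd) < 1L) return("glycan must contain at least one node")
  if (!all(c("id", "code", "decoration") %in% names(nd)))
    return("nodes must have columns id, code, decoration")
  if (!all(c("child", "parent", "anomeric", "child_pos", "parent_pos") %in% names(ed)))
    return("edges must have columns child, parent, anomeric, child_pos, parent_pos")
  if (anyDuplicated(nd$id)) return("node ids must be unique")
  if (!(object@root %in% nd$id)) return("root must be a node id")
  if (nrow(ed) != nrow(nd) - 1L)
    return("a tree on n nodes must have exactly n - 1 edges")
  if (nrow(ed) > 0L) {
    if (anyDuplicated(ed$child)) return("every non-root node must have one parent")
    if (object@root %in% ed$child) return("root cannot have a parent")
    if (!all(ed$child %in% nd$id) || !all(ed$parent %in% nd$id))
      return("edge endpoints must be node ids")
    if (!all(ed$anomeric %in% c("a", "b", "?")))
      return("anomeric configuration must be 'a', 'b' or '?'")
  }
  # reachability from root guarantees no cycles given the edge count
  seen <- object@root
  repeat {
    nxt <- ed$child[ed$parent %in% seen & !(ed$child %in% seen)]
    if (length(nxt) == 0L) break
    seen <- c(seen, nxt)
  }
  if (length(seen) != nrow(nd)) return("every node must be reachable from the root")
  TRUE
})

#' FilterConfig: rules that define a candidate lectin
#'
#' Holds the carbohydrate-binding module (CBM) domain identifiers, the
#' description keywords that disqualify a record (transport, cell-structure
#' and adhesion functions), and whether curated/reviewed entries are dropped.
#'
#' @slot cbmDomains character vector of CBM domain identifiers (InterPro-style).
#' @slot exclusionKeywords character vector of disqualifying keywords,
#'   matched case-insensitively against whole tokens of the description by
#'   default.
#' @slot requireUnreviewed logical; reject records flagged as reviewed.
#' @slot caseSensitive logical; keyword matching case sensitivity.
#'
#' @seealso [FilterConfig()], [classifyRecords()]
#' @export
setClass("FilterConfig",
  representation(cbmDomains = "character", exclusionKeywords = "character",
                 requireUnreviewed = "logical", caseSensitive = "logical"))

setValidity("FilterConfig", function(object) {
  if (length(object@cbmDomains) == 0L) return("cbmDomains must be non-empty")
  if (length(object@requireUnreviewed) != 1L || is.na(object@requireUnreviewed))
    return("requireUnreviewed must be TRUE or FALSE")
  if (length(object@caseSensitive) != 1L || is.na(object@caseSensitive))
    return("caseSensitive must be TRUE or FALSE")
  TRUE
})

#' ProteinSet: sequences with domain annotations
#'
#' The container for a domain-annotated protein universe: amino-acid
#' sequences, one row per domain annotation, and per-record metadata
#' (reviewed flag, free-text description).
#'
#' @slot sequences [Biostrings::AAStringSet] named by accession.
#' @slot annotations data.frame with columns `accession`, `domain_id`,
#'   `start`, `end`, `category` (one of `"carbohydrate_binding"`,
#'   `"catalytic"`, `"other"`); zero rows for a record without domains.
#' @slot meta data.frame with columns `accession`, `reviewed` (logical),
#'   `description`.
#'
#' @seealso [ProteinSet()], [classifyRecords()], [domainArchitectures()]
#' @export
setClass("ProteinSet",
  representation(sequences = "AAStringSet", annotations = "data.frame",
                 meta = "data.frame"))

setValidity("ProteinSet", function(object) {
  acc <- names(object@sequences)
  if (length(object@sequences) > 0L && (is.null(acc) || anyDuplicated(acc)))
    return("sequences must be uniquely named by accession")
  if (is.null(acc)) acc <- character(0)
  if (!all(c("accession", "domain_id", "start", "end", "category") %in%
           names(object@annotations)))
    return("annotations must have columns accession, domain_id, start, end, category")
  if (!all(c("accession", "reviewed", "description") %in% names(object@meta)))
    return("meta must have columns accession, reviewed, description")
  if (!setequal(object@meta$accession, acc) || anyDuplicated(object@meta$accession))
    return("meta must have exactly one row per sequence accession")
  ann <- object@annotations
  if (nrow(ann) > 0L) {
    if (!all(ann$accession %in% acc))
      return("annotation accessions must match sequence names")
    if (!all(ann$category %in% c("carbohydrate_binding", "catalytic", "other")))
      return("domain category must be carbohydrate_binding, catalytic or other")
    len <- setNames(Biostrings::width(object@sequences), acc)
    if (any(ann$start < 1L) || any(ann$end < ann$start) ||
        any(ann$end > len[ann$accession]))
      return("domain intervals must satisfy 1 <= start <= end <= sequence length")
  }
  TRUE
})

#' ClusterSet: greedy centroid clustering result
#'
#' A partition of input sequences into clusters, each represented by a
#' centroid; every member aligns to its centroid at identity >= the
#' clustering threshold.
#'
#' @slot clusters data.frame with columns `cluster_id` (integer), `centroid`,
#'   `member` (accessions) and `identity` (member-to-centroid identity).
#' @slot threshold numeric identity threshold in (0, 1].
#'
#' @seealso [greedyCluster()], [clusterTable()]
#' @export
setClass("ClusterSet",
  representation(clusters = "data.frame", threshold = "numeric"))

setValidity("ClusterSet", function(object) {
  cl <- object@clusters
  if (!all(c("cluster_id", "centroid", "member", "identity") %in% names(cl)))
    return("clusters must have columns cluster_id, centroid, member, identity")
  if (anyDuplicated(cl$member)) return("each sequence must belong to exactly one cluster")
  if (length(object@threshold) != 1L || object@threshold <= 0 || object@threshold > 1)
    return("threshold must be a single value in (0, 1]")
  if (nrow(cl) > 0L) {
    if (!all(cl$centroid %in% cl$member))
      return("every centroid must itself be a member of its cluster")
    if (any(cl$identity < object@threshold - 1e-12))
      return("every member must reach the threshold identity to its centroid")
  }
  TRUE
})

#' PresenceMatrix: lectin-by-sample incidence
#'
#' Boolean matrix recording whether each lectin sequence was matched in each
#' sample's gene catalog, plus the sample-to-body-site map.
#'
#' @slot presence logical matrix, rows = lectin accessions, columns = sample
#'   ids.
#' @slot siteMap named character vector mapping sample id to body site.
#'
#' @seealso [buildPresenceMatrix()], [prevalenceSummary()], [siteOverlap()],
#'   [rarefactionCurve()]
#' @export
setClass("PresenceMatrix",
  representation(presence = "matrix", siteMap = "character"))

setValidity("PresenceMatrix", function(object) {
  m <- object@presence
  if (!is.logical(m)) return("presence must be a logical matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    return("presence must have lectin rownames and sample colnames")
  if (anyDuplicated(colnames(m))) return("sample ids must be unique")
  if (anyDuplicated(rownames(m))) return("lectin accessions must be unique")
  if (!identical(sort(names(object@siteMap)), sort(colnames(m))))
    return("siteMap must name exactly the sample columns")
  TRUE
})
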