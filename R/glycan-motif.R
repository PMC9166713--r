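# Rooted-subtree embedding and motif mining over glycan trees.

.childEdges <- function(g, id) g@edges[g@edges$parent == id, , drop = FALSE]

# can motif node m (with its whole subtree) map onto glycan node v?
.matchAt <- function(g, m, vg, vm) {
  ig <- match(vg, g@nodes$id); im <- match(vm, m@nodes$id)
  if (g@nodes$code[ig] != m@nodes$code[im]) return(FALSE)
  if (g@nodes$decoration[ig] != m@nodes$decoration[im]) return(FALSE)
  me <- .childEdges(m, vm)
  if (nrow(me) == 0L) return(TRUE)
  ge <- .childEdges(g, vg)
  if (nrow(ge) < nrow(me)) return(FALSE)
  # compatibility of motif child i with glycan child j: linkage carbons exact,
  # anomeric exact unless the data edge is "?", then recurse
  comp <- matrix(FALSE, nrow(me), nrow(ge))
  for (i in seq_len(nrow(me))) for (j in seq_len(nrow(ge))) {
    if (me$child_pos[i] == ge$child_pos[j] &&
        me$parent_pos[i] == ge$parent_pos[j] &&
        (me$anomeric[i] == ge$anomeric[j] || ge$anomeric[j] == "?" ||
         me$anomeric[i] == "?")) {
      comp[i, j] <- .matchAt(g, m, ge$child[j], me$child[i])
    }
  }
  # injective assignment of motif children to glycan children (backtracking)
  assign_ok <- function(i, used) {
    if (i > nrow(me)) return(TRUE)
    for (j in which(comp[i, ])) {
      if (!used[j] && assign_ok(i + 1L, `[<-`(used, j, TRUE))) return(TRUE)
    }
    FALSE
  }
  assign_ok(1L, rep(FALSE, nrow(ge)))
}

#' Test whether a glycan contains a motif
#'
#' A motif is contained in a glycan when its nodes can be mapped injectively
#' onto glycan nodes preserving residue code and decoration, parent/child
#' relations, anomeric configuration and both linkage carbons of every motif
#' edge.  The placement is unanchored: the motif root may land on any glycan
#' node.  An `"?"` (unknown) anomeric configuration on a glycan edge matches
#' any motif anomeric.
#'
#' @param glycan,motif [GlycanStructure-class] objects.
#' @return logical.
#' @examples
#' containsMotif(parseGlycan("Galb1-3GlcNAcb1-2Mana1-3Man"),
#'               parseGlycan("Galb1-3GlcNAc"))
#' @export
containsMotif <- function(glycan, motif) {
  stopifnot(is(glycan, "GlycanStructure"), is(motif, "GlycanStructure"))
  if (nrow(motif@nodes) > nrow(glycan@nodes)) return(FALSE)
  for (v in glycan@nodes$id) {
    if (.matchAt(glycan, motif, v, motif@root)) return(TRUE)
  }
  FALSE
}

# build a GlycanStructure from a subset of node ids of g that forms a
# connected rooted subtree (every node but the topmost has its parent in ids)
.subGlycan <- function(g, ids) {
  keep <- g@edges$child %in% ids & g@edges$parent %in% ids
  ed <- g@edges[keep, , drop = FALSE]
  root <- setdiff(ids, ed$child)
  remap <- setNames(seq_along(ids), ids)
  nd <- g@nodes[match(ids, g@nodes$id), , drop = FALSE]
  nd$id <- as.integer(remap[as.character(ids)])
  ed$child <- as.integer(remap[as.character(ed$child)])
  ed$parent <- as.integer(remap[as.character(ed$parent)])
  rownames(nd) <- NULL; rownames(ed) <- NULL
  new("GlycanStructure", nodes = nd, edges = ed,
      root = as.integer(remap[as.character(root)]))
}

#' Enumerate the connected sub-glycans of a glycan
#'
#' Returns every connected subtree (rooted at some node of `g`) with at most
#' `maxSize` residues, as a list of [GlycanStructure-class] objects named by
#' canonical serialization; duplicates (same canonical form at different
#' placements) are collapsed.
#'
#' @param g a [GlycanStructure-class].
#' @param maxSize maximum number of residues per sub-glycan.
#' @return named list of `GlycanStructure`.
#' @export
enumerateSubglycans <- function(g, maxSize = glycanSize(g)) {
  stopifnot(is(g, "GlycanStructure"), maxSize >= 1)
  # subtree node-sets hanging from v (v included), capped at maxSize
  sets_at <- function(v) {
    kids <- .childEdges(g, v)$child
    acc <- list(v)
    for (k in kids) {
      ksets <- sets_at(k)
      grown <- list()
      for (a in acc) for (ks in ksets) {
        if (length(a) + length(ks) <= maxSize) grown[[length(grown) + 1L]] <- c(a, ks)
      }
      acc <- c(acc, grown)
    }
    acc
  }
  out <- list()
  for (v in g@nodes$id) {
    for (ids in sets_at(v)) {
      sg <- .subGlycan(g, ids)
      key <- glycanToText(sg)
      if (is.null(out[[key]])) out[[key]] <- sg
    }
  }
  out
}

#' Mine conserved binding motifs from bound vs unbound glycans
#'
#' Enumerates every connected sub-glycan (up to `maxSize` residues) occurring
#' in at least one binder, computes the fraction of binders and of nonbinders
#' containing it (via [containsMotif()]), and scores each candidate as
#' `binder_coverage - nonbinder_frequency`.  Candidates are ranked by
#' (score desc, size desc, canonical text asc) and reduced to maximal motifs:
#' a motif is dropped when a strict super-motif achieves an equal or better
#' score.
#'
#' @param binders non-empty list of [GlycanStructure-class] (bound glycans).
#' @param nonbinders list of [GlycanStructure-class] (unbound glycans); may be
#'   empty.
#' @param maxSize maximum motif size in residues.
#' @return data.frame with columns `motif` (canonical text), `size`,
#'   `binder_coverage`, `nonbinder_frequency`, `score`, plus a list column
#'   `structure` of the motif trees.
#' @export
mineMotifs <- function(binders, nonbinders = list(), maxSize = 5L) {
  if (length(binders) == 0L) stop("binders must be non-empty", call. = FALSE)
  stopifnot(maxSize >= 1)
  cand <- list()
  for (b in binders) {
    for (key in names(sg <- enumerateSubglycans(b, maxSize))) {
      if (is.null(cand[[key]])) cand[[key]] <- sg[[key]]
    }
  }
  keys <- names(cand)
  cov <- vapply(cand, function(m)
    mean(vapply(binders, containsMotif, logical(1), motif = m)), numeric(1))
  nbf <- if (length(nonbinders) == 0L) rep(0, length(cand)) else
    vapply(cand, function(m)
      mean(vapply(nonbinders, containsMotif, logical(1), motif = m)), numeric(1))
  size <- vapply(cand, glycanSize, integer(1))
  score <- cov - nbf
  o <- order(-score, -size, keys, method = "radix")
  keys <- keys[o]; cov <- cov[o]; nbf <- nbf[o]; size <- size[o]
  score <- score[o]; cand <- cand[o]
  # maximality: drop m when some strictly larger motif containing m scores >= m
  keep <- rep(TRUE, length(cand))
  for (i in seq_along(cand)) {
    for (j in seq_along(cand)) {
      if (size[j] > size[i] && score[j] >= score[i] &&
          containsMotif(cand[[j]], cand[[i]])) { keep[i] <- FALSE; break }
    }
  }
  out <- data.frame(motif = keys[keep], size = size[keep],
                    binder_coverage = cov[keep], nonbinder_frequency = nbf[keep],
                    score = score[keep], stringsAsFactors = FALSE)
  out$structure <- I(unname(cand[keep]))
  rownames(out) <- NULL
  out
}
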