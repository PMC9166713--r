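#' Monosaccharide codes recognised by the glycan parser
#'
#' The default residue vocabulary of the condensed glycan dialect.  Codes are
#' matched longest-first, so `GlcNAc` is never mis-read as `Glc` + junk.  A
#' residue may carry a substituent decoration (`<carbon>S` sulfation or
#' `<carbon>P` phosphorylation, e.g. `Gal6S`), which is kept on the node and
#' must match exactly during motif search.
#'
#' @return character vector of residue codes.
#' @export
monosaccharideCodes <- function() {
  c("GlcNAc", "GalNAc", "ManNAc", "Neu5Ac", "Neu5Gc", "GlcA", "IdoA",
    "Gal", "Glc", "Man", "Fuc", "Xyl", "Rha", "Ara", "Rib", "Kdn")
}

.glyError <- function(msg, text, pos = NA_integer_) {
  if (is.na(pos)) stop(sprintf("glycan parse error: %s in %s", msg, sQuote(text)),
                       call. = FALSE)
  stop(sprintf("glycan parse error at position %d: %s in %s", pos, msg,
               sQuote(text)), call. = FALSE)
}

#' Parse a glycan in condensed linear notation
#'
#' Reads strings such as `"Galb1-3GlcNAcb1-2Mana1-3Man"` or the branched
#' `"Mana1-3(Mana1-6)Manb1-4GlcNAc"` into a rooted [GlycanStructure-class].
#' The rightmost residue is the reducing end (tree root); a linkage token
#' `a1-3` means the residue on its left is attached through its carbon 1 to
#' carbon 3 of the residue on its right, with alpha anomeric configuration
#' (`b` beta, `?` unknown).  Parenthesised groups are branches attached to
#' the residue immediately to their right.  A trailing spacer suffix
#' (`-Sp<digits>`) is stripped.
#'
#' @param text glycan string.
#' @param codes residue vocabulary, by default [monosaccharideCodes()].
#' @return a [GlycanStructure-class].
#' @examples
#' g <- parseGlycan("Galb1-3GlcNAcb1-2Mana1-3Man")
#' glycanToText(g)
#' @export
parseGlycan <- function(text, codes = monosaccharideCodes()) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text))
    stop("text must be a single non-empty string", call. = FALSE)
  raw <- text
  s <- sub("-Sp\\d+$", "", text)
  if (!nzchar(s)) .glyError("empty structure after removing spacer", raw)
  codes <- codes[order(nchar(codes), decreasing = TRUE)]

  nodes_code <- character(0); nodes_dec <- character(0)
  e_child <- integer(0); e_parent <- integer(0)
  e_anom <- character(0); e_cpos <- integer(0); e_ppos <- integer(0)
  # stack of pending lists; each pending entry: node id + linkage (or NA)
  stack <- list(list(node = integer(0), anom = character(0),
                     cpos = integer(0), ppos = integer(0)))
  pos <- 1L; n <- nchar(s)

  push_pending <- function(fr, id, anom, cpos, ppos) {
    fr$node <- c(fr$node, id); fr$anom <- c(fr$anom, anom)
    fr$cpos <- c(fr$cpos, cpos); fr$ppos <- c(fr$ppos, ppos)
    fr
  }

  while (pos <= n) {
    ch <- substr(s, pos, pos)
    if (ch == "(") {
      stack[[length(stack) + 1L]] <- list(node = integer(0), anom = character(0),
                                          cpos = integer(0), ppos = integer(0))
      pos <- pos + 1L
    } else if (ch == ")") {
      if (length(stack) == 1L) .glyError("unbalanced ')'", raw, pos)
      fr <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      if (length(fr$node) != 1L || is.na(fr$anom[1L]))
        .glyError("branch must end with a residue and its linkage", raw, pos)
      stack[[length(stack)]] <- push_pending(stack[[length(stack)]],
                                             fr$node[1L], fr$anom[1L],
                                             fr$cpos[1L], fr$ppos[1L])
      pos <- pos + 1L
    } else {
      hit <- ""
      for (cd in codes) {
        if (substr(s, pos, pos + nchar(cd) - 1L) == cd) { hit <- cd; break }
      }
      if (!nzchar(hit)) {
        tok <- regmatches(s, regexpr("^[A-Za-z0-9?]+", substr(s, pos, n)))
        if (length(tok) == 0L) tok <- substr(s, pos, pos)
        .glyError(sprintf("unknown monosaccharide code %s", sQuote(tok)), raw, pos)
      }
      pos <- pos + nchar(hit)
      dec <- ""
      dm <- regexpr("^\\d[SP]", substr(s, pos, n))
      if (dm == 1L) {
        dec <- substr(s, pos, pos + 1L)
        pos <- pos + 2L
      }
      id <- length(nodes_code) + 1L
      nodes_code <- c(nodes_code, hit); nodes_dec <- c(nodes_dec, dec)
      fr <- stack[[length(stack)]]
      if (length(fr$node) > 0L && anyNA(fr$anom))
        .glyError("two residues without a connecting linkage", raw, pos)
      # everything pending in this frame becomes a child of the new residue
      if (length(fr$node) > 0L) {
        e_child <- c(e_child, fr$node); e_parent <- c(e_parent, rep(id, length(fr$node)))
        e_anom <- c(e_anom, fr$anom); e_cpos <- c(e_cpos, fr$cpos)
        e_ppos <- c(e_ppos, fr$ppos)
      }
      fr <- list(node = integer(0), anom = character(0),
                 cpos = integer(0), ppos = integer(0))
      lm <- regexpr("^([ab?])(\\d)-(\\d)", substr(s, pos, n))
      if (lm == 1L) {
        len <- attr(lm, "match.length")
        lk <- substr(s, pos, pos + len - 1L)
        fr <- push_pending(fr, id, substr(lk, 1L, 1L),
                           as.integer(substr(lk, 2L, 2L)),
                           as.integer(substr(lk, len, len)))
        pos <- pos + len
      } else if (pos <= n && !(substr(s, pos, pos) %in% c("(", ")"))) {
        .glyError("malformed linkage", raw, pos)
      } else {
        fr <- push_pending(fr, id, NA_character_, NA_integer_, NA_integer_)
      }
      stack[[length(stack)]] <- fr
    }
  }
  if (length(stack) != 1L) .glyError("unbalanced '('", raw, n)
  fr <- stack[[1L]]
  if (length(fr$node) != 1L || !is.na(fr$anom[1L]))
    .glyError("structure must end with an unlinked reducing-end residue", raw, n)
  new("GlycanStructure",
      nodes = data.frame(id = seq_along(nodes_code), code = nodes_code,
                         decoration = nodes_dec, stringsAsFactors = FALSE),
      edges = data.frame(child = e_child, parent = e_parent, anomeric = e_anom,
                         child_pos = e_cpos, parent_pos = e_ppos,
                         stringsAsFactors = FALSE),
      root = fr$node[1L])
}

.nodeLabel <- function(g, id) {
  i <- match(id, g@nodes$id)
  paste0(g@nodes$code[i], g@nodes$decoration[i])
}

#' Serialize a glycan to its canonical condensed text
#'
#' Children of every node are ordered by (parent linkage carbon, residue
#' code, recursive serialization); the first child continues the linear
#' chain and the rest are written as parenthesised branches.  The canonical
#' form round-trips: `parseGlycan(glycanToText(g))` reproduces `g` up to
#' node numbering.
#'
#' @param g a [GlycanStructure-class].
#' @return a single string.
#' @export
glycanToText <- function(g) {
  stopifnot(is(g, "GlycanStructure"))
  ser <- function(id) {
    ed <- g@edges[g@edges$parent == id, , drop = FALSE]
    lab <- .nodeLabel(g, id)
    if (nrow(ed) == 0L) return(lab)
    kid_txt <- vapply(ed$child, ser, character(1))
    kid_lab <- vapply(ed$child, function(k) .nodeLabel(g, k), character(1))
    o <- order(ed$parent_pos, kid_lab, kid_txt, method = "radix")
    ed <- ed[o, , drop = FALSE]; kid_txt <- kid_txt[o]
    link <- paste0(ed$anomeric, ed$child_pos, "-", ed$parent_pos)
    parts <- paste0(kid_txt, link)
    if (length(parts) > 1L)
      parts <- c(parts[1L], paste0("(", parts[-1L], ")"))
    paste0(paste(parts, collapse = ""), lab)
  }
  ser(g@root)
}

#' Number of residues in a glycan
#' @param g a [GlycanStructure-class].
#' @return integer node count.
#' @export
glycanSize <- function(g) nrow(g@nodes)

#' Node table of a glycan
#' @param g a [GlycanStructure-class].
#' @return data.frame of node id, code, decoration.
#' @export
glycanNodes <- function(g) g@nodes

#' Edge table of a glycan
#' @param g a [GlycanStructure-class].
#' @return data.frame of child, parent, anomeric, child_pos, parent_pos.
#' @export
glycanEdges <- function(g) g@edges

#' Reducing-end node id of a glycan
#' @param g a [GlycanStructure-class].
#' @return integer node id.
#' @export
glycanRoot <- function(g) g@root

setMethod("show", "GlycanStructure", function(object) {
  cat("GlycanStructure with", nrow(object@nodes), "residues:",
      glycanToText(object), "\n")
})
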