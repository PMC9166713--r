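# Independent oracles used across the suite.  Each re-derives the expected
# quantity by brute force or closed form, without touching the code paths it
# checks.

# --- Gotoh affine-gap DP, score only (the optimal score is unique) ---------
data(BLOSUM62, package = "Biostrings", envir = environment())

gotohScore <- function(a, b, open = 11, ext = 1, mat = BLOSUM62) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(open + i * ext)
  for (j in seq_len(m)) Y[1, j + 1] <- -(open + j * ext)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- mat[A[i], B[j]]
    M[i + 1, j + 1] <- s + max(M[i, j], X[i, j], Y[i, j])
    X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, X[i, j + 1] - ext,
                           Y[i, j + 1] - open - ext)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Y[i + 1, j] - ext,
                           X[i + 1, j] - open - ext)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

randomAA <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len, replace = TRUE),
        collapse = "")
}

# --- step-by-step greedy clustering replay --------------------------------
greedyOracle <- function(seqs, threshold) {
  acc <- names(seqs)
  o <- order(-nchar(seqs), acc, method = "radix")
  seqs <- seqs[o]; acc <- acc[o]
  cent <- integer(0)   # indices of centroids in processing order
  assign <- integer(length(seqs)); ident <- numeric(length(seqs))
  for (i in seq_along(seqs)) {
    best <- 0; bestk <- 0L
    for (k in seq_along(cent)) {
      id <- globalAlignIdentity(seqs[i], seqs[cent[k]])$identity
      if (id > best) { best <- id; bestk <- k }   # first max wins ties
    }
    if (bestk > 0L && best >= threshold) {
      assign[i] <- bestk; ident[i] <- best
    } else {
      cent <- c(cent, i); assign[i] <- length(cent); ident[i] <- 1
    }
  }
  data.frame(member = acc, cluster_id = assign,
             centroid = acc[cent[assign]], identity = ident,
             stringsAsFactors = FALSE)
}

# --- exhaustive sample-based rarefaction ----------------------------------
exhaustiveRarefaction <- function(mat, n) {
  N <- ncol(mat)
  subs <- utils::combn(N, n, simplify = FALSE)
  mean(vapply(subs, function(s)
    sum(rowSums(mat[, s, drop = FALSE]) > 0L), numeric(1)))
}

randomPresence <- function(nLectins, nSamples, p = 0.4, site = "stool") {
  m <- matrix(runif(nLectins * nSamples) < p, nLectins, nSamples,
              dimnames = list(sprintf("L%02d", seq_len(nLectins)),
                              sprintf("S%02d", seq_len(nSamples))))
  new("PresenceMatrix", presence = m,
      siteMap = setNames(rep(site, nSamples), colnames(m)))
}

# --- brute-force subtree embedding ----------------------------------------
embedOracle <- function(glycan, motif) {
  gn <- glycanNodes(glycan); ge <- glycanEdges(glycan)
  mn <- glycanNodes(motif); me <- glycanEdges(motif)
  if (nrow(mn) > nrow(gn)) return(FALSE)
  gparent <- setNames(ge$parent, ge$child)
  gedge <- ge; rownames(gedge) <- ge$child
  ok_edge <- function(mrow, gc) {
    gp <- gparent[as.character(gc)]
    if (is.na(gp)) return(FALSE)
    grow <- gedge[as.character(gc), ]
    mp_img <- map[match(mrow$parent, mn$id)]
    gp == mp_img && grow$child_pos == mrow$child_pos &&
      grow$parent_pos == mrow$parent_pos &&
      (grow$anomeric == mrow$anomeric || grow$anomeric == "?" ||
       mrow$anomeric == "?")
  }
  map <- integer(nrow(mn))
  try_node <- function(k) {
    if (k > nrow(mn)) {
      # all nodes placed; verify every motif edge
      for (r in seq_len(nrow(me))) {
        if (!ok_edge(me[r, ], map[match(me$child[r], mn$id)])) return(FALSE)
      }
      return(TRUE)
    }
    for (v in gn$id) {
      if (v %in% map[seq_len(k - 1L)]) next
      if (gn$code[match(v, gn$id)] != mn$code[k]) next
      if (gn$decoration[match(v, gn$id)] != mn$decoration[k]) next
      map[k] <<- v
      if (try_node(k + 1L)) return(TRUE)
    }
    map[k] <<- 0L
    FALSE
  }
  try_node(1L)
}

# --- independent subtree enumeration + scoring for motif mining -----------
subtreeOracle <- function(g, maxSize) {
  nd <- glycanNodes(g); ed <- glycanEdges(g)
  parent <- setNames(ed$parent, ed$child)
  out <- list()
  ids <- nd$id
  for (mask in seq_len(2^length(ids)) - 1L) {
    sel <- ids[bitwAnd(mask, 2^(seq_along(ids) - 1L)) > 0L]
    if (length(sel) < 1L || length(sel) > maxSize) next
    # rooted-connected: every selected node but one has its parent selected
    tops <- vapply(sel, function(v) {
      p <- parent[as.character(v)]
      is.na(p) || !(p %in% sel)
    }, logical(1))
    if (sum(tops) != 1L) next
    keep <- ed$child %in% sel & ed$parent %in% sel
    sed <- ed[keep, , drop = FALSE]
    remap <- setNames(seq_along(sel), sel)
    snd <- nd[match(sel, nd$id), , drop = FALSE]
    snd$id <- as.integer(remap[as.character(sel)])
    sed$child <- as.integer(remap[as.character(sed$child)])
    sed$parent <- as.integer(remap[as.character(sed$parent)])
    rownames(snd) <- NULL; rownames(sed) <- NULL
    sg <- new("GlycanStructure", nodes = snd, edges = sed,
              root = as.integer(remap[as.character(sel[tops])]))
    out[[glycanToText(sg)]] <- sg
  }
  out
}

mineOracle <- function(binders, nonbinders, maxSize) {
  cand <- list()
  for (b in binders) for (key in names(sg <- subtreeOracle(b, maxSize)))
    if (is.null(cand[[key]])) cand[[key]] <- sg[[key]]
  keys <- names(cand)
  cov <- vapply(cand, function(m)
    mean(vapply(binders, embedOracle, logical(1), motif = m)), numeric(1))
  nbf <- if (length(nonbinders) == 0L) rep(0, length(cand)) else
    vapply(cand, function(m)
      mean(vapply(nonbinders, embedOracle, logical(1), motif = m)), numeric(1))
  size <- vapply(cand, glycanSize, integer(1))
  score <- cov - nbf
  o <- order(-score, -size, keys, method = "radix")
  keys <- keys[o]; cov <- cov[o]; nbf <- nbf[o]; size <- size[o]
  score <- score[o]; cand <- cand[o]
  keep <- rep(TRUE, length(cand))
  for (i in seq_along(cand)) for (j in seq_along(cand)) {
    if (size[j] > size[i] && score[j] >= score[i] &&
        embedOracle(cand[[j]], cand[[i]])) { keep[i] <- FALSE; break }
  }
  data.frame(motif = keys[keep], size = size[keep], binder_coverage = cov[keep],
             nonbinder_frequency = nbf[keep], score = score[keep],
             stringsAsFactors = FALSE, row.names = NULL)
}

randomGlycan <- function(size) lectiscope:::.randomGlycanTree(size, monosaccharideCodes())

# --- tiny ProteinSet builder ----------------------------------------------
makeProteins <- function(seqs, domains = NULL, reviewed = FALSE,
                         description = "uncharacterized protein") {
  ProteinSet(seqs, domains, reviewed = reviewed, description = description)
}

domRow <- function(accession, domain_id, start, end, category) {
  data.frame(accession = accession, domain_id = domain_id,
             start = as.integer(start), end = as.integer(end),
             category = category, stringsAsFactors = FALSE)
}
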