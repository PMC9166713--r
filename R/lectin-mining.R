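# Candidate-lectin filtering, domain architectures and domain co-occurrence.

#' Default description keywords that disqualify a candidate lectin
#'
#' Proteins whose descriptions indicate carbohydrate transport, cell
#' structure or known adhesive/flagellar functions are excluded from the
#' uncharacterized-lectin set.  Matching is against whole description tokens,
#' case-insensitive by default, so `Fim` does not fire on `fimbriae`
#' (`Fimbriae` is its own entry).
#'
#' @return character vector of keywords.
#' @export
defaultExclusionKeywords <- function() {
  c("TonB", "Transport", "Channel", "Porin", "OmpA", "Anchor", "Receptor",
    "Dockerin", "Cohesin", "Flagella", "Lamin", "Lipoprotein", "Secretion",
    "RagB", "SusD", "ScaA", "ScaB", "Scaffoldin", "Septum", "Spore", "SusE",
    "Wall", "Fimbrial", "Fim", "FimH", "Adhesin", "PapG", "Membrane",
    "Fimbriae", "Adhesion")
}

#' Default domain table
#'
#' A small packaged table of InterPro-style domain identifiers with their
#' category (`carbohydrate_binding`, `catalytic`, `other`) and a readable
#' name.  The CBM entries include the CBM6-CBM35-CBM36-like module
#' (IPR033803) and the Bacteroidetes-associated carbohydrate-binding
#' often-N-terminal domain (IPR024361).  Real analyses should supply the
#' full curated table via [readDomainTable()].
#'
#' @return data.frame with columns `domain_id`, `category`, `name`.
#' @export
defaultDomainTable <- function() {
  data.frame(
    domain_id = c("IPR033803", "IPR024361", "IPR008965", "IPR005087",
                  "IPR003961", "IPR011990", "IPR013783", "IPR036465",
                  "IPR017853", "IPR000322", "IPR001547"),
    category = c("carbohydrate_binding", "carbohydrate_binding",
                 "carbohydrate_binding", "carbohydrate_binding",
                 "other", "other", "other", "other",
                 "catalytic", "catalytic", "catalytic"),
    name = c("CBM6-CBM35-CBM36_like_2", "BACON domain",
             "CBM4/9 superfamily", "Carbohydrate-binding domain 9",
             "Fibronectin type III", "TPR-like helical",
             "Immunoglobulin-like fold", "vWA domain superfamily",
             "Glycoside hydrolase superfamily", "Glycosyl hydrolase family 31",
             "Glycosyl hydrolase family 5"),
    stringsAsFactors = FALSE)
}

#' Construct a FilterConfig
#'
#' @param cbmDomains character vector of CBM domain ids; defaults to the
#'   CBM entries of [defaultDomainTable()].
#' @param exclusionKeywords keyword list; defaults to
#'   [defaultExclusionKeywords()].
#' @param requireUnreviewed drop records flagged as reviewed (default TRUE).
#' @param caseSensitive keyword matching case sensitivity (default FALSE).
#' @return a [FilterConfig-class].
#' @export
FilterConfig <- function(cbmDomains = NULL,
                         exclusionKeywords = defaultExclusionKeywords(),
                         requireUnreviewed = TRUE, caseSensitive = FALSE) {
  if (is.null(cbmDomains)) {
    dt <- defaultDomainTable()
    cbmDomains <- dt$domain_id[dt$category == "carbohydrate_binding"]
  }
  new("FilterConfig", cbmDomains = cbmDomains,
      exclusionKeywords = exclusionKeywords,
      requireUnreviewed = requireUnreviewed, caseSensitive = caseSensitive)
}

setMethod("show", "FilterConfig", function(object) {
  cat("FilterConfig:", length(object@cbmDomains), "CBM domain ids,",
      length(object@exclusionKeywords), "exclusion keywords,",
      if (object@requireUnreviewed) "unreviewed only\n" else "reviewed allowed\n")
})

#' Construct a ProteinSet
#'
#' @param sequences named character vector or [Biostrings::AAStringSet] of
#'   amino-acid sequences, named by accession.
#' @param annotations data.frame with columns `accession`, `domain_id`,
#'   `start`, `end`, `category`; zero rows allowed.
#' @param reviewed logical vector (recycled) or named by accession.
#' @param description character vector (recycled) or named by accession.
#' @return a [ProteinSet-class].
#' @export
ProteinSet <- function(sequences, annotations = NULL, reviewed = FALSE,
                       description = "") {
  seqs <- if (is(sequences, "AAStringSet")) sequences else
    Biostrings::AAStringSet(sequences)
  acc <- names(seqs)
  if (is.null(acc)) acc <- character(0)
  if (is.null(annotations))
    annotations <- data.frame(accession = character(0), domain_id = character(0),
                              start = integer(0), end = integer(0),
                              category = character(0), stringsAsFactors = FALSE)
  pick <- function(x) {
    if (!is.null(names(x))) return(unname(x[acc]))
    rep_len(x, length(acc))
  }
  meta <- data.frame(accession = acc, reviewed = pick(reviewed),
                     description = pick(description), stringsAsFactors = FALSE)
  new("ProteinSet", sequences = seqs, annotations = annotations, meta = meta)
}

#' @describeIn ProteinSet sequences accessor.
#' @param x a `ProteinSet`.
#' @export
proteinSequences <- function(x) x@sequences

#' @describeIn ProteinSet domain annotation accessor.
#' @export
proteinAnnotations <- function(x) x@annotations

#' @describeIn ProteinSet metadata accessor (reviewed flag, description).
#' @export
proteinMeta <- function(x) x@meta

setMethod("show", "ProteinSet", function(object) {
  cat("ProteinSet with", length(object@sequences), "sequences and",
      nrow(object@annotations), "domain annotations\n")
})

#' Subset a ProteinSet by accession
#' @param x a [ProteinSet-class].
#' @param accessions accessions to keep.
#' @return a `ProteinSet`.
#' @export
subsetProteins <- function(x, accessions) {
  new("ProteinSet", sequences = x@sequences[accessions],
      annotations = x@annotations[x@annotations$accession %in% accessions, ,
                                  drop = FALSE],
      meta = x@meta[match(accessions, x@meta$accession), , drop = FALSE])
}

.tokenize <- function(description) {
  toks <- strsplit(description, "[^A-Za-z0-9]+")[[1]]
  toks[nzchar(toks)]
}

.classifyOne <- function(domain_ids, categories, reviewed, description, config) {
  has_cbm <- any(domain_ids %in% config@cbmDomains)
  has_cat <- any(categories == "catalytic")
  toks <- .tokenize(description)
  kws <- config@exclusionKeywords
  if (!config@caseSensitive) { toks <- tolower(toks); kws <- tolower(kws) }
  has_kw <- any(toks %in% kws)
  # fixed reporting order for records failing several rules
  if (!has_cbm) return("no_cbm")
  if (has_cat) return("catalytic")
  if (has_kw) return("keyword")
  if (config@requireUnreviewed && isTRUE(reviewed)) return("reviewed")
  "accept"
}

#' Classify protein records as candidate lectins
#'
#' A record is accepted when it has at least one carbohydrate-binding module
#' domain, no catalytic domain, no disqualifying description keyword, and
#' (by default) is not a reviewed entry.  A record failing several rules
#' reports the first reason in the fixed order `no_cbm`, `catalytic`,
#' `keyword`, `reviewed`.
#'
#' @param proteins a [ProteinSet-class].
#' @param config a [FilterConfig-class].
#' @return data.frame with columns `accession`, `accept` (logical), `reason`
#'   (`"accept"` or the first failing rule).
#' @export
classifyRecords <- function(proteins, config = FilterConfig()) {
  stopifnot(is(proteins, "ProteinSet"), is(config, "FilterConfig"))
  ann <- proteins@annotations
  meta <- proteins@meta
  reason <- vapply(meta$accession, function(a) {
    rows <- ann$accession == a
    .classifyOne(ann$domain_id[rows], ann$category[rows],
                 meta$reviewed[match(a, meta$accession)],
                 meta$description[match(a, meta$accession)], config)
  }, character(1))
  data.frame(accession = meta$accession, accept = reason == "accept",
             reason = unname(reason), stringsAsFactors = FALSE, row.names = NULL)
}

#' Derive N-to-C domain architectures
#'
#' For each record, the ordered tuple of its domain ids sorted by
#' (start asc, end asc, domain_id asc); repeated domains at different
#' positions are kept.  Architecture equality ignores inter-domain spacing.
#'
#' @param proteins a [ProteinSet-class].
#' @return named list (by accession) of character vectors; a record without
#'   domains yields `character(0)`.
#' @export
domainArchitectures <- function(proteins) {
  stopifnot(is(proteins, "ProteinSet"))
  ann <- proteins@annotations
  out <- lapply(proteins@meta$accession, function(a) {
    d <- ann[ann$accession == a, , drop = FALSE]
    if (nrow(d) == 0L) return(character(0))
    d$domain_id[order(d$start, d$end, d$domain_id, method = "radix")]
  })
  names(out) <- proteins@meta$accession
  out
}

.archKey <- function(arch) vapply(arch, paste, character(1), collapse = "+")

#' Summarize a candidate-lectin set
#'
#' @param proteins a [ProteinSet-class] of (already deduplicated) candidates.
#' @param config a [FilterConfig-class] (defines which domains count as CBM).
#' @return list with `n_sequences`, `n_architectures` (distinct ordered
#'   domain tuples), `n_cbm_domains` and `n_secondary_domains` (distinct
#'   non-CBM domain ids present).
#' @export
summarizeCandidates <- function(proteins, config = FilterConfig()) {
  stopifnot(is(proteins, "ProteinSet"), is(config, "FilterConfig"))
  arch <- domainArchitectures(proteins)
  ids <- unique(proteins@annotations$domain_id)
  list(n_sequences = length(proteins@sequences),
       n_architectures = length(unique(.archKey(arch))),
       n_cbm_domains = sum(ids %in% config@cbmDomains),
       n_secondary_domains = sum(!(ids %in% config@cbmDomains)))
}

#' CBM-by-secondary-domain co-occurrence
#'
#' Counts, over all records, the co-occurrence of each carbohydrate-binding
#' module with each secondary (non-CBM) domain: a record containing CBM `X`
#' and secondary `P` increments cell `(X, P)` by one, once per pair per
#' record regardless of copy number.  Totals count records containing each
#' domain.
#'
#' @param proteins a [ProteinSet-class].
#' @param config a [FilterConfig-class].
#' @return list with `matrix` (integer, CBM rows x secondary columns) and
#'   `totals` (named integer, records containing each domain).
#' @export
cooccurrenceMatrix <- function(proteins, config = FilterConfig()) {
  stopifnot(is(proteins, "ProteinSet"), is(config, "FilterConfig"))
  ann <- proteins@annotations
  per <- split(ann$domain_id, ann$accession)
  per <- lapply(per, unique)
  all_ids <- sort(unique(ann$domain_id))
  cbm <- all_ids[all_ids %in% config@cbmDomains]
  sec <- all_ids[!(all_ids %in% config@cbmDomains)]
  m <- matrix(0L, length(cbm), length(sec), dimnames = list(cbm, sec))
  for (ids in per) {
    for (x in intersect(ids, cbm)) for (p in intersect(ids, sec))
      m[x, p] <- m[x, p] + 1L
  }
  totals <- vapply(all_ids, function(d)
    sum(vapply(per, function(ids) d %in% ids, logical(1))), integer(1))
  list(matrix = m, totals = totals)
}

#' Read a protein annotation table with its FASTA
#'
#' The annotation TSV has one row per domain with columns `accession`,
#' `reviewed` (true/false), `description`, `domain_id`, `start`, `end`;
#' a record without domains appears as one row with an empty `domain_id`.
#' Domain categories are taken from the domain table (never guessed from the
#' id string).
#'
#' @param fasta path to the protein FASTA (names = accessions).
#' @param annotations path to the annotation TSV.
#' @param domainTable data.frame as from [readDomainTable()] or
#'   [defaultDomainTable()].
#' @return a [ProteinSet-class].
#' @export
readProteinSet <- function(fasta, annotations,
                           domainTable = defaultDomainTable()) {
  seqs <- Biostrings::readAAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  ann <- read.delim(annotations, stringsAsFactors = FALSE)
  need <- c("accession", "reviewed", "description", "domain_id", "start", "end")
  if (!all(need %in% names(ann)))
    stop("annotation TSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  meta <- unique(ann[c("accession", "reviewed", "description")])
  dom <- ann[!is.na(ann$domain_id) & nzchar(ann$domain_id), , drop = FALSE]
  cat_of <- setNames(domainTable$category, domainTable$domain_id)
  unknown <- setdiff(dom$domain_id, names(cat_of))
  if (length(unknown))
    stop("domains missing from the domain table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  dom <- data.frame(accession = dom$accession, domain_id = dom$domain_id,
                    start = as.integer(dom$start), end = as.integer(dom$end),
                    category = unname(cat_of[dom$domain_id]),
                    stringsAsFactors = FALSE)
  ProteinSet(seqs, dom,
             reviewed = setNames(as.logical(meta$reviewed), meta$accession),
             description = setNames(meta$description, meta$accession))
}

#' Read a domain table TSV
#'
#' @param path TSV with columns `domain_id`, `category`, `name`.
#' @return data.frame.
#' @export
readDomainTable <- function(path) {
  dt <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("domain_id", "category") %in% names(dt)))
    stop("domain table must have columns domain_id, category", call. = FALSE)
  dt
}
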