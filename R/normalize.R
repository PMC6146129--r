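# Knowledge-based gene normalization.
#
# A mention is mapped to a single gene identifier (or NULL) by (1) looking
# the surface form up in a ranked name index, then (2) returning the first
# candidate, in rank order, that the primary document-level gene index
# lists for the article's PMID, else (3) the first candidate listed by the
# secondary fallback index, else (4) NULL -- in which case the span is
# dropped from the pipeline. The primary index is the more precise source;
# the fallback trades precision for recall, and consulting them
# sequentially (rather than as a union) keeps that ordering advantage.
#
# All knowledge lives in a `knowledge_bundle` of plain lookup tables so
# every run is offline and reproducible; lookups go through a small cache
# with a backend-call counter so caching behavior is observable.

#' Construct a knowledge bundle
#'
#' @param name_index named list: mention string -> ranked character vector
#'   of candidate gene IDs (duplicate-free).
#' @param doc_index_primary named list: PMID -> character vector of gene IDs
#'   (the precise document-level source).
#' @param doc_index_fallback named list: PMID -> character vector of gene
#'   IDs (the secondary, recall-oriented source).
#' @param lexicon named list: gene name -> character vector of gene IDs.
#' @param homolog_map named character vector: gene ID -> homology-group ID.
#' @param max_candidates ranked-list truncation (default 100, mirroring the
#'   retmax of a ranked name query).
#' @return an object of class `knowledge_bundle`.
#' @export
knowledge_bundle <- function(name_index = list(), doc_index_primary = list(),
                             doc_index_fallback = list(), lexicon = list(),
                             homolog_map = character(0),
                             max_candidates = 100L) {
  stopifnot(all(!vapply(name_index, anyDuplicated, 1L) > 0))
  kb <- new.env(parent = emptyenv())
  kb$name_index <- name_index
  kb$doc_index_primary <- doc_index_primary
  kb$doc_index_fallback <- doc_index_fallback
  kb$lexicon <- lexicon
  kb$homolog_map <- homolog_map
  kb$max_candidates <- as.integer(max_candidates)
  kb$cache <- new.env(parent = emptyenv())
  kb$backend_calls <- 0L
  class(kb) <- "knowledge_bundle"
  kb
}

#' @export
print.knowledge_bundle <- function(x, ...) {
  cat("<knowledge_bundle>", length(x$name_index), "names,",
      length(x$doc_index_primary), "primary /",
      length(x$doc_index_fallback), "fallback PMIDs,",
      length(x$lexicon), "lexicon entries,",
      length(x$homolog_map), "homolog-mapped IDs\n")
  invisible(x)
}

# Cached table access; a cache miss counts as one backend call.
kb_fetch <- function(kb, table, key) {
  ck <- paste0(table, "\r", key)
  hit <- kb$cache[[ck]]
  if (!is.null(hit)) return(hit$value)
  kb$backend_calls <- kb$backend_calls + 1L
  value <- kb[[table]][[key]]
  if (is.null(value)) value <- character(0)
  kb$cache[[ck]] <- list(value = value)
  value
}

# Whitespace-normalize and strip flanking punctuation from a mention
# before lookup.
clean_mention <- function(mention) {
  m <- gsub("[[:space:]]+", " ", trimws(mention))
  gsub("^[[:punct:]]+|[[:punct:]]+$", "", m)
}

#' Ranked candidate gene IDs for a mention
#'
#' Case-sensitive lookup first, case-insensitive retry second; the ranked
#' list is truncated at `max_candidates`.
#'
#' @param kb a `knowledge_bundle`.
#' @param mention nonempty mention string.
#' @return character vector of gene IDs in rank order (possibly empty).
#' @export
gene_name_lookup <- function(kb, mention) {
  if (!nzchar(mention)) stop("empty mention")
  key <- clean_mention(mention)
  ids <- kb_fetch(kb, "name_index", key)
  if (!length(ids)) {
    lower <- tolower(key)
    hits <- which(tolower(names(kb$name_index)) == lower)
    if (length(hits)) ids <- kb$name_index[[hits[1L]]]
  }
  utils::head(ids, kb$max_candidates)
}

#' Document-level gene IDs for a PMID (primary source)
#'
#' @param kb a `knowledge_bundle`.
#' @param pmid article identifier.
#' @return character vector of gene IDs (possibly empty).
#' @export
gene_pmid_lookup <- function(kb, pmid) {
  kb_fetch(kb, "doc_index_primary", as.character(pmid))
}

#' Document-level gene IDs for a PMID (secondary fallback source)
#'
#' @inheritParams gene_pmid_lookup
#' @return character vector of gene IDs (possibly empty).
#' @export
pubtator_pmid_lookup <- function(kb, pmid) {
  kb_fetch(kb, "doc_index_fallback", as.character(pmid))
}

#' Normalize one mention to a gene ID or NULL
#'
#' Candidates from [gene_name_lookup()] are tried in rank order against the
#' primary document index; if none matches, against the fallback index; if
#' still none, `NULL` is returned (the span is to be ignored downstream).
#' With `mode = "union"` both document indexes are pooled before the rank
#' scan.
#'
#' @param kb a `knowledge_bundle`.
#' @param mention mention string.
#' @param pmid article identifier providing the document context.
#' @param mode `"sequential"` (default; primary first, then fallback) or
#'   `"union"`.
#' @return a single gene ID, or `NULL` when no candidate is supported by
#'   the document context.
#' @export
normalize_mention <- function(kb, mention, pmid,
                              mode = c("sequential", "union")) {
  mode <- match.arg(mode)
  cand <- gene_name_lookup(kb, mention)
  if (!length(cand)) return(NULL)
  primary <- gene_pmid_lookup(kb, pmid)
  fallback <- pubtator_pmid_lookup(kb, pmid)
  if (mode == "union") {
    hit <- cand[cand %in% union(primary, fallback)]
    return(if (length(hit)) hit[1L] else NULL)
  }
  hit <- cand[cand %in% primary]
  if (length(hit)) return(hit[1L])
  hit <- cand[cand %in% fallback]
  if (length(hit)) return(hit[1L])
  NULL
}

#' Normalize a document's mentions
#'
#' Each mention is normalized independently; mentions with no supported
#' candidate are removed. The distinct surviving IDs form the document's
#' candidate set for relation classification.
#'
#' @param kb a `knowledge_bundle`.
#' @param doc a `ppim_document`.
#' @param mentions mention data frame (tagger output plus lexicon matches).
#' @param mode see [normalize_mention()].
#' @return mention data frame with `gene_id` filled in; null-mapped rows
#'   dropped.
#' @export
normalize_document <- function(kb, doc, mentions,
                               mode = c("sequential", "union")) {
  mode <- match.arg(mode)
  if (nrow(mentions) == 0L) return(mentions)
  ids <- vapply(mentions$text, function(m) {
    r <- normalize_mention(kb, m, doc$pmid, mode)
    if (is.null(r)) NA_character_ else r
  }, character(1))
  mentions$gene_id <- unname(ids)
  out <- mentions[!is.na(mentions$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## ---- bundle (de)serialization -----------------------------------------------

# TSV layouts: names.tsv `name rank gene_id`; doc_primary.tsv /
# doc_fallback.tsv `pmid gene_id`; lexicon.tsv `name id[,id...]`;
# homologs.tsv `group gene_id`.

#' Write / read a knowledge bundle as TSV files
#'
#' @param kb a `knowledge_bundle`.
#' @param dir directory for the TSV files (created if needed).
#' @export
write_knowledge_bundle <- function(kb, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (nm in names(kb$name_index)) {
    ids <- kb$name_index[[nm]]
    rows[[length(rows) + 1L]] <- data.frame(
      name = nm, rank = seq_along(ids), gene_id = ids, stringsAsFactors = FALSE)
  }
  nd <- if (length(rows)) do.call(rbind, rows) else
    data.frame(name = character(0), rank = integer(0), gene_id = character(0))
  utils::write.table(nd, file.path(dir, "names.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_doc_index <- function(index, file) {
    lines <- character(0)
    for (pmid in names(index)) {
      lines <- c(lines, paste(pmid, index[[pmid]], sep = "\t"))
    }
    writeLines(lines, file.path(dir, file))
  }
  write_doc_index(kb$doc_index_primary, "doc_primary.tsv")
  write_doc_index(kb$doc_index_fallback, "doc_fallback.tsv")
  writeLines(vapply(names(kb$lexicon), function(nm) {
    paste(nm, paste(kb$lexicon[[nm]], collapse = ","), sep = "\t")
  }, character(1)), file.path(dir, "lexicon.tsv"))
  writeLines(paste(unname(kb$homolog_map), names(kb$homolog_map), sep = "\t"),
             file.path(dir, "homologs.tsv"))
  invisible(dir)
}

#' @rdname write_knowledge_bundle
#' @export
read_knowledge_bundle <- function(dir) {
  read_tsv <- function(file, n_col) {
    path <- file.path(dir, file)
    lines <- if (file.exists(path)) readLines(path, warn = FALSE) else character(0)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) return(NULL)
    do.call(rbind, lapply(lines, function(l) {
      f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
      if (length(f) != n_col) stop("malformed line in ", file, ": ", l)
      as.data.frame(as.list(f), stringsAsFactors = FALSE, col.names = paste0("V", 1:n_col))
    }))
  }
  nd <- read_tsv("names.tsv", 3L)
  name_index <- list()
  if (!is.null(nd)) {
    nd$V2 <- as.integer(nd$V2)
    for (nm in unique(nd$V1)) {
      sub <- nd[nd$V1 == nm, , drop = FALSE]
      name_index[[nm]] <- sub$V3[order(sub$V2)]
    }
  }
  doc_index <- function(file) {
    dd <- read_tsv(file, 2L)
    if (is.null(dd)) return(list())
    lapply(split(dd$V2, dd$V1), unique)
  }
  ld <- read_tsv("lexicon.tsv", 2L)
  lexicon <- if (is.null(ld)) list() else
    stats::setNames(strsplit(ld$V2, ",", fixed = TRUE), ld$V1)
  hd <- read_tsv("homologs.tsv", 2L)
  homolog_map <- if (is.null(hd)) character(0) else
    stats::setNames(hd$V1, hd$V2)
  knowledge_bundle(name_index, doc_index("doc_primary.tsv"),
                   doc_index("doc_fallback.tsv"), lexicon, homolog_map)
}
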