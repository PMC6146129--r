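# Corpus containers and PubTator-style I/O.
#
# A document is a title + abstract pair; its working text is
# `full_text = title <space> abstract` and every span in the package is a
# 0-based half-open character interval into that string. Gene mentions,
# gold interaction pairs and token/sentence segmentations all live on this
# coordinate system.

TAG_SET <- c("O", "I-GENE", "B-GENE")

#' Fold text to ASCII, preserving character offsets
#'
#' Greek letters (and a few other common symbols) are transliterated to a
#' single ASCII letter; any remaining non-ASCII character becomes `?`. The
#' mapping is strictly one character to one character so that all span
#' offsets computed on the folded text are valid on the original.
#'
#' @param x character vector.
#' @return character vector of the same length, ASCII only.
#' @export
ascii_fold <- function(x) {
  nonascii <- grepl("[^\x01-\x7f]", x, perl = TRUE)
  if (!any(nonascii)) return(x)
  from <- strsplit(paste0("αβγδεζηθικλμνξοπρστυφχψω",
                          "ΑΒΓΔΕΖΗΘΙΚΛΜΝΞΟΠΡΣΤΥΦΧΨΩ",
                          "–—‘’“”·"), "")[[1L]]
  to <- strsplit(paste0("abgdezhqiklmnxoprstufcyw",
                        "ABGDEZHQIKLMNXOPRSTUFCYW",
                        "--''\"\"."), "")[[1L]]
  y <- x[nonascii]
  for (k in seq_along(from)) y <- gsub(from[k], to[k], y, fixed = TRUE)
  x[nonascii] <- gsub("[^\x01-\x7f]", "?", y, perl = TRUE)
  x
}

slice_text <- function(full_text, start, end) {
  # 0-based half-open interval
  substr(full_text, start + 1L, end)
}

#' Construct a document
#'
#' @param pmid article identifier (coerced to character).
#' @param title,abstract article title and abstract text; folded to ASCII.
#' @param segment segment sentences and tokens immediately (default TRUE).
#' @return an object of class `ppim_document` with fields `pmid`, `title`,
#'   `abstract`, `full_text`, and (if segmented) data frames `sentences`
#'   and `tokens` of 0-based half-open offsets into `full_text`.
#' @export
ppim_document <- function(pmid, title, abstract = "", segment = TRUE) {
  doc <- structure(list(
    pmid = as.character(pmid),
    title = ascii_fold(title),
    abstract = ascii_fold(abstract),
    full_text = ascii_fold(paste(title, abstract)),
    sentences = NULL,
    tokens = NULL
  ), class = "ppim_document")
  if (segment) doc <- segment_document(doc) else doc
}

#' @export
print.ppim_document <- function(x, ...) {
  cat("<ppim_document>", x$pmid, "\n")
  cat("  title   :", substr(x$title, 1, 70), "\n")
  cat("  abstract:", nchar(x$abstract), "chars,",
      if (is.null(x$sentences)) "unsegmented" else
        paste(nrow(x$sentences), "sentences /", nrow(x$tokens), "tokens"), "\n")
  invisible(x)
}

# Sentence boundaries: terminal punctuation followed by whitespace and an
# upper-case letter, digit or opening quote/paren. Returns a data.frame of
# 0-based half-open (start, end) spans; leading/trailing whitespace of each
# sentence is excluded.
split_sentences <- function(text) {
  n <- nchar(text)
  if (n == 0L || !grepl("[^[:space:]]", text)) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  m <- gregexpr("[.!?]+(?=[[:space:]]+[\"'(]?[A-Z0-9])", text, perl = TRUE)[[1L]]
  cut_after <- if (m[1L] == -1L) integer(0) else
    as.integer(m) + attr(m, "match.length") - 1L  # 1-based last char of sentence
  starts1 <- c(1L, cut_after + 1L)
  ends1 <- c(cut_after, n)
  out <- data.frame(start = integer(0), end = integer(0))
  for (k in seq_along(starts1)) {
    seg <- substr(text, starts1[k], ends1[k])
    lead <- regexpr("[^[:space:]]", seg)
    if (lead == -1L) next
    trail <- regexpr("[[:space:]]*$", seg)
    s1 <- starts1[k] + as.integer(lead) - 1L
    e1 <- starts1[k] + as.integer(trail) - 2L
    out <- rbind(out, data.frame(start = s1 - 1L, end = e1))
  }
  out
}

# Tokens: maximal alphanumeric runs (digits stay attached to letters, so
# "Shank3" is one token) or single punctuation characters.
tokenize_span <- function(text, offset = 0L) {
  m <- gregexpr("[A-Za-z0-9]+|[^A-Za-z0-9[:space:]]", text)[[1L]]
  if (m[1L] == -1L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  start <- as.integer(m) - 1L + offset
  data.frame(start = start, end = start + attr(m, "match.length"))
}

#' Segment a document into sentences and tokens
#'
#' Sentence splitting runs separately over the title and the abstract (the
#' title always ends a sentence) using a rule-based boundary detector;
#' tokens are maximal alphanumeric runs or single punctuation marks.
#'
#' @param doc a `ppim_document`.
#' @return the document with `sentences` (data frame `start`, `end`) and
#'   `tokens` (data frame `sentence`, `start`, `end`) filled in.
#' @export
segment_document <- function(doc) {
  title_s <- split_sentences(doc$title)
  abs_s <- split_sentences(doc$abstract)
  off <- nchar(doc$title) + 1L
  if (nrow(abs_s)) {
    abs_s$start <- abs_s$start + off
    abs_s$end <- abs_s$end + off
  }
  sent <- rbind(title_s, abs_s)
  toks <- lapply(seq_len(nrow(sent)), function(i) {
    td <- tokenize_span(slice_text(doc$full_text, sent$start[i], sent$end[i]),
                        offset = sent$start[i])
    if (nrow(td)) td$sentence <- i
    td
  })
  toks <- do.call(rbind, c(list(data.frame(start = integer(0), end = integer(0),
                                           sentence = integer(0))), toks))
  keep <- vapply(seq_len(nrow(sent)), function(i) any(toks$sentence == i), TRUE)
  if (!all(keep)) {  # drop token-free sentences, renumber
    sent <- sent[keep, , drop = FALSE]
    toks$sentence <- match(toks$sentence, which(keep))
    rownames(sent) <- NULL
  }
  doc$sentences <- sent
  doc$tokens <- toks[, c("sentence", "start", "end")]
  rownames(doc$tokens) <- NULL
  doc
}

empty_mentions <- function() {
  data.frame(start = integer(0), end = integer(0), text = character(0),
             provenance = character(0), gene_id = character(0),
             stringsAsFactors = FALSE)
}

make_mentions <- function(start, end, text, provenance, gene_id = NA_character_) {
  data.frame(start = as.integer(start), end = as.integer(end),
             text = as.character(text), provenance = as.character(provenance),
             gene_id = as.character(gene_id), stringsAsFactors = FALSE)
}

empty_pairs <- function() {
  data.frame(id1 = character(0), id2 = character(0), stringsAsFactors = FALSE)
}

# Canonical unordered pair set: id1 <= id2 lexicographically, deduplicated,
# sorted by (id1, id2).
canonical_pairs <- function(id1, id2) {
  if (length(id1) == 0L) return(empty_pairs())
  a <- as.character(id1); b <- as.character(id2)
  lo <- ifelse(a <= b, a, b)
  hi <- ifelse(a <= b, b, a)
  df <- unique(data.frame(id1 = lo, id2 = hi, stringsAsFactors = FALSE))
  df <- df[order(df$id1, df$id2), , drop = FALSE]
  rownames(df) <- NULL
  df
}

new_corpus <- function(documents = list(), mentions = list(), pairs = list()) {
  structure(list(documents = documents, mentions = mentions, pairs = pairs),
            class = "ppim_corpus")
}

#' @export
print.ppim_corpus <- function(x, ...) {
  np <- sum(vapply(x$pairs, nrow, 1L))
  nm <- sum(vapply(x$mentions, nrow, 1L))
  cat("<ppim_corpus>", length(x$documents), "documents,", nm, "mentions,",
      np, "gold pairs\n")
  invisible(x)
}

#' Parse a PubTator-style corpus
#'
#' Reads the delimited text format used for title/abstract corpora with
#' mention and relation annotations: `PMID|t|title`, `PMID|a|abstract`,
#' tab-separated mention lines (`pmid start end text type [id]`) and
#' relation lines (`pmid type id1 id2`); a blank line separates documents.
#' Mention offsets are interpreted over `full_text` (the abstract starts at
#' `nchar(title) + 1`). Mention lines whose type does not contain "gene"
#' (case-insensitive) are dropped.
#'
#' @param text a single string, character vector of lines, or file path.
#' @return a `ppim_corpus`.
#' @export
parse_pubtator <- function(text) {
  lines <- if (length(text) == 1L && file.exists(text)) {
    readLines(text, warn = FALSE, encoding = "UTF-8")
  } else if (length(text) == 1L) {
    strsplit(text, "\n", fixed = TRUE)[[1L]]
  } else text

  docs <- list(); mentions <- list(); pairs <- list()
  cur <- NULL  # list(pmid, title, abstract, m = list of rows, p = ...)
  flush_doc <- function() {
    if (is.null(cur)) return(invisible(NULL))
    doc <- ppim_document(cur$pmid, cur$title, cur$abstract)
    md <- if (length(cur$m)) do.call(rbind, cur$m) else empty_mentions()
    for (i in seq_len(nrow(md))) {
      got <- slice_text(doc$full_text, md$start[i], md$end[i])
      if (got != md$text[i]) {
        stop(sprintf(
          "mention text mismatch in document %s: annotation '%s' vs text '%s' at [%d,%d)",
          cur$pmid, md$text[i], got, md$start[i], md$end[i]))
      }
    }
    pd <- if (length(cur$p)) {
      pp <- do.call(rbind, cur$p)
      canonical_pairs(pp$id1, pp$id2)
    } else empty_pairs()
    if (cur$pmid %in% names(docs)) stop("duplicate PMID: ", cur$pmid)
    docs[[cur$pmid]] <<- doc
    mentions[[cur$pmid]] <<- md
    pairs[[cur$pmid]] <<- pd
    cur <<- NULL
    invisible(NULL)
  }

  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    if (!nzchar(line)) { flush_doc(); next }
    tm <- regmatches(line, regexec("^([^|\t]+)\\|([ta])\\|(.*)$", line))[[1L]]
    if (length(tm) == 4L) {
      pmid <- tm[2L]; field <- tm[3L]; value <- tm[4L]
      if (is.null(cur)) cur <- list(pmid = pmid, title = "", abstract = "",
                                    m = list(), p = list())
      if (cur$pmid != pmid) stop("line ", ln, ": PMID changes without blank separator")
      if (field == "t") cur$title <- value else cur$abstract <- value
      next
    }
    f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (is.null(cur)) stop("line ", ln, ": annotation before any title line")
    if (length(f) %in% c(5L, 6L) && grepl("^[0-9]+$", f[2L]) &&
        grepl("^[0-9]+$", f[3L])) {
      if (f[1L] != cur$pmid) stop("line ", ln, ": PMID mismatch in mention line")
      if (!grepl("gene", f[5L], ignore.case = TRUE)) next
      cur$m[[length(cur$m) + 1L]] <- make_mentions(
        as.integer(f[2L]), as.integer(f[3L]), ascii_fold(f[4L]), "gold",
        if (length(f) == 6L && nzchar(f[6L])) f[6L] else NA_character_)
    } else if (length(f) == 4L) {
      if (f[1L] != cur$pmid) stop("line ", ln, ": PMID mismatch in relation line")
      cur$p[[length(cur$p) + 1L]] <- data.frame(id1 = f[3L], id2 = f[4L],
                                                stringsAsFactors = FALSE)
    } else {
      stop("line ", ln, ": malformed annotation line: ", line)
    }
  }
  flush_doc()
  new_corpus(docs, mentions, pairs)
}

#' Serialize a corpus to PubTator-style text
#'
#' Canonical form: title line, abstract line, mention lines sorted by
#' (start, end), relation lines with `id1 <= id2` sorted lexicographically,
#' one blank line after each document. `parse_pubtator(write_pubtator(x))`
#' recovers `x`.
#'
#' @param corpus a `ppim_corpus`.
#' @param path optional file to write to.
#' @return the serialized text (one string), invisibly when `path` is given.
#' @export
write_pubtator <- function(corpus, path = NULL) {
  out <- character(0)
  for (pmid in names(corpus$documents)) {
    doc <- corpus$documents[[pmid]]
    out <- c(out, paste0(pmid, "|t|", doc$title), paste0(pmid, "|a|", doc$abstract))
    md <- corpus$mentions[[pmid]]
    if (!is.null(md) && nrow(md)) {
      md <- md[order(md$start, md$end), , drop = FALSE]
      for (i in seq_len(nrow(md))) {
        id <- if (is.na(md$gene_id[i])) "" else md$gene_id[i]
        ml <- paste(pmid, md$start[i], md$end[i], md$text[i], "Gene", sep = "\t")
        if (nzchar(id)) ml <- paste(ml, id, sep = "\t")
        out <- c(out, ml)
      }
    }
    pd <- corpus$pairs[[pmid]]
    if (!is.null(pd) && nrow(pd)) {
      pd <- canonical_pairs(pd$id1, pd$id2)
      out <- c(out, paste(pmid, "PPIm", pd$id1, pd$id2, sep = "\t"))
    }
    out <- c(out, "")
  }
  txt <- if (length(out)) paste0(paste(out, collapse = "\n"), "\n") else ""
  if (!is.null(path)) {
    writeLines(out, path, useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}

## ---- IOB projection / decoding ---------------------------------------------

#' Check IOB1 validity
#'
#' Under IOB1 a `B-GENE` tag is legal only immediately after another gene
#' tag (it exists solely to separate two adjacent spans).
#'
#' @param labels character vector of tags from `O`, `I-GENE`, `B-GENE`.
#' @return TRUE or FALSE.
#' @export
iob_valid <- function(labels) {
  if (!all(labels %in% TAG_SET)) return(FALSE)
  for (i in seq_along(labels)) {
    if (labels[i] == "B-GENE" &&
        (i == 1L || labels[i - 1L] == "O")) return(FALSE)
  }
  TRUE
}

# Map each token to the index of the mention covering it (0 = none).
# Mentions with boundaries inside a token are snapped outward (warning).
token_mention_index <- function(doc, mentions) {
  toks <- doc$tokens
  idx <- integer(nrow(toks))
  if (nrow(mentions) == 0L) return(idx)
  mentions <- mentions[order(mentions$start), , drop = FALSE]
  for (k in seq_len(nrow(mentions))) {
    cover <- which(toks$start < mentions$end[k] & toks$end > mentions$start[k])
    if (!length(cover)) next
    if (any(idx[cover] != 0L)) {
      stop("overlapping mentions at [", mentions$start[k], ",",
           mentions$end[k], ") in document ", doc$pmid)
    }
    if (toks$start[min(cover)] != mentions$start[k] ||
        toks$end[max(cover)] != mentions$end[k]) {
      warning(sprintf(
        "document %s: mention [%d,%d) snapped outward to token boundaries [%d,%d)",
        doc$pmid, mentions$start[k], mentions$end[k],
        toks$start[min(cover)], toks$end[max(cover)]))
    }
    idx[cover] <- k
  }
  idx
}

#' Project mentions onto IOB1 label sequences
#'
#' Produces one labeled sequence per sentence. Span-initial tokens receive
#' `I-GENE` unless the immediately preceding token ends a different gene
#' span, in which case `B-GENE` marks the new span (IOB1).
#'
#' @param doc a segmented `ppim_document`.
#' @param mentions mention data frame (`start`, `end`, ...); overlapping
#'   mentions are an error.
#' @return list of `labeled_sequence` objects: `list(sentence, tokens, labels)`.
#' @export
project_to_iob <- function(doc, mentions) {
  idx <- token_mention_index(doc, mentions)
  toks <- doc$tokens
  out <- list()
  for (s in seq_len(nrow(doc$sentences))) {
    rows <- which(toks$sentence == s)
    mi <- idx[rows]
    labels <- rep("O", length(rows))
    for (j in seq_along(rows)) {
      if (mi[j] == 0L) next
      new_span <- j == 1L || mi[j - 1L] != mi[j]
      prev_gene <- j > 1L && mi[j - 1L] != 0L
      labels[j] <- if (new_span && prev_gene) "B-GENE" else "I-GENE"
    }
    out[[s]] <- structure(list(sentence = s,
                               tokens = toks[rows, c("start", "end"), drop = FALSE],
                               labels = labels),
                          class = "labeled_sequence")
  }
  out
}

#' Decode an IOB1 label sequence to mention spans
#'
#' Maximal runs of gene tags form mentions; `B-GENE` starts a new span.
#' Invalid sequences are repaired with [repair_iob()] first.
#'
#' @param labels character tag vector for one sentence.
#' @param tokens data frame of the sentence's token offsets (`start`, `end`).
#' @param full_text the document text the offsets index into.
#' @param provenance provenance recorded on the decoded mentions.
#' @return mention data frame.
#' @export
decode_iob <- function(labels, tokens, full_text, provenance = "model") {
  labels <- repair_iob(labels)
  out <- empty_mentions()
  n <- length(labels)
  i <- 1L
  while (i <= n) {
    if (labels[i] == "O") { i <- i + 1L; next }
    j <- i
    while (j + 1L <= n && labels[j + 1L] == "I-GENE") j <- j + 1L
    s <- tokens$start[i]; e <- tokens$end[j]
    out <- rbind(out, make_mentions(s, e, slice_text(full_text, s, e), provenance))
    i <- j + 1L
  }
  out
}

#' Corpus statistics
#'
#' @param corpus a nonempty `ppim_corpus`.
#' @return list with `n_articles`, `n_pairs`, `mean_pairs_per_article`
#'   (exact) and `mean_pairs_per_article_2dp` (rounded to 2 decimals).
#' @export
corpus_statistics <- function(corpus) {
  n_doc <- length(corpus$documents)
  if (n_doc == 0L) stop("empty corpus")
  n_pairs <- sum(vapply(corpus$pairs, nrow, 1L))
  mean_pp <- n_pairs / n_doc
  list(n_articles = n_doc, n_pairs = n_pairs,
       mean_pairs_per_article = mean_pp,
       mean_pairs_per_article_2dp = round(mean_pp, 2))
}

#' Read / write per-document pair predictions
#'
#' TSV exchange format `pmid<TAB>id1<TAB>id2`; pairs are canonicalized
#' (`id1 <= id2` lexicographically) and deduplicated.
#'
#' @param path file path.
#' @return named list (by PMID) of canonical pair data frames.
#' @export
read_pairs <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in seq_along(lines)) {
    f <- strsplit(lines[[ln]], "\t", fixed = TRUE)[[1L]]
    if (length(f) != 3L) stop("line ", ln, ": expected 3 tab-separated columns")
    out[[f[1L]]] <- rbind(out[[f[1L]]],
                          data.frame(id1 = f[2L], id2 = f[3L],
                                     stringsAsFactors = FALSE))
  }
  lapply(out, function(df) canonical_pairs(df$id1, df$id2))
}

#' @rdname read_pairs
#' @param pairs_by_doc named list (by PMID) of pair data frames (`id1`, `id2`).
#' @export
write_pairs <- function(pairs_by_doc, path = NULL) {
  out <- character(0)
  for (pmid in names(pairs_by_doc)) {
    pd <- pairs_by_doc[[pmid]]
    if (is.null(pd) || nrow(pd) == 0L) next
    pd <- canonical_pairs(pd$id1, pd$id2)
    out <- c(out, paste(pmid, pd$id1, pd$id2, sep = "\t"))
  }
  if (!is.null(path)) writeLines(out, path) else out
}
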