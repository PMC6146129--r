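# Scoring predicted pair sets against gold pair sets.
#
# Two matching modes: exact gene-ID matching, and homology-group matching
# in which gene IDs belonging to the same homology group count as
# equivalent (IDs absent from the group map canonicalize to themselves).
# Micro scores pool true/false positives and negatives over all documents;
# macro (example-based) scores average per-document precision, recall and
# F1 across documents.

#' Canonicalize an unordered gene-ID pair
#'
#' Each ID is replaced by its homology-group ID when a map is given
#' (missing IDs map to themselves); the pair is then stored order-free
#' (sorted), so `(B, A)` and `(A, B)` canonicalize identically.
#'
#' @param pair character vector of 2 gene IDs.
#' @param homolog_map optional named character vector `gene ID -> group ID`.
#' @return sorted character vector of 2 canonical IDs.
#' @export
canonicalize_pair <- function(pair, homolog_map = NULL) {
  ids <- as.character(pair)
  stopifnot(length(ids) == 2L)
  if (!is.null(homolog_map) && length(homolog_map)) {
    mapped <- homolog_map[ids]
    ids <- ifelse(is.na(mapped), ids, mapped)
  }
  sort(unname(ids))
}

# Canonical key set (deduplicated) for one document's pair data frame.
pair_keys <- function(pairs, homolog_map = NULL) {
  if (is.null(pairs) || nrow(pairs) == 0L) return(character(0))
  unique(vapply(seq_len(nrow(pairs)), function(i) {
    paste(canonicalize_pair(c(pairs$id1[i], pairs$id2[i]), homolog_map),
          collapse = "|")
  }, character(1)))
}

check_same_docs <- function(gold, pred) {
  if (!setequal(names(gold), names(pred))) {
    stop("gold and prediction document sets differ: ",
         paste(union(setdiff(names(gold), names(pred)),
                     setdiff(names(pred), names(gold))), collapse = ", "))
  }
}

prf <- function(tp, fp, fn, empty_both = FALSE) {
  if (empty_both) return(list(P = 1, R = 1, F1 = 1))
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  list(P = p, R = r, F1 = f)
}

#' Micro precision / recall / F1 over documents
#'
#' Pairs are canonicalized (and per-document deduplicated) before counting;
#' true/false positives and false negatives are pooled over all documents.
#'
#' @param gold,pred named lists (by PMID, same key sets) of pair data
#'   frames (`id1`, `id2`).
#' @param homolog_map optional named character vector `gene ID -> group ID`
#'   enabling homology-group matching.
#' @return list with elements `P`, `R`, `F1`.
#' @export
micro_scores <- function(gold, pred, homolog_map = NULL) {
  check_same_docs(gold, pred)
  tp <- 0L; fp <- 0L; fn <- 0L
  for (pmid in names(gold)) {
    g <- pair_keys(gold[[pmid]], homolog_map)
    p <- pair_keys(pred[[pmid]], homolog_map)
    tp <- tp + length(intersect(g, p))
    fp <- fp + length(setdiff(p, g))
    fn <- fn + length(setdiff(g, p))
  }
  prf(tp, fp, fn)
}

#' Macro (example-based) precision / recall / F1
#'
#' Per-document precision, recall and F1 are computed with the micro
#' conventions (a document with empty gold and empty prediction scores 1;
#' empty gold with nonempty prediction scores 0) and averaged across
#' documents.
#'
#' @inheritParams micro_scores
#' @return list with elements `P`, `R`, `F1`.
#' @export
macro_scores <- function(gold, pred, homolog_map = NULL) {
  check_same_docs(gold, pred)
  ps <- rs <- fs <- numeric(0)
  for (pmid in names(gold)) {
    g <- pair_keys(gold[[pmid]], homolog_map)
    p <- pair_keys(pred[[pmid]], homolog_map)
    sc <- prf(length(intersect(g, p)), length(setdiff(p, g)),
              length(setdiff(g, p)),
              empty_both = length(g) == 0L && length(p) == 0L)
    ps <- c(ps, sc$P); rs <- c(rs, sc$R); fs <- c(fs, sc$F1)
  }
  list(P = mean(ps), R = mean(rs), F1 = mean(fs))
}

#' Read a homology-group table
#'
#' Accepts either a 2-column TSV `group<TAB>gene_id` or the 6-column
#' homologene.data layout (group, taxid, gene id, symbol, protein gi,
#' protein accession), using columns 1 and 3.
#'
#' @param path file path.
#' @return named character vector `gene ID -> group ID`.
#' @export
read_homolog_map <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(character(0))
  out <- character(0)
  for (ln in seq_along(lines)) {
    f <- strsplit(lines[[ln]], "\t", fixed = TRUE)[[1L]]
    if (length(f) == 2L) {
      out[f[2L]] <- f[1L]
    } else if (length(f) >= 3L) {
      out[f[3L]] <- f[1L]
    } else {
      stop("line ", ln, ": expected 2 or >= 3 tab-separated columns")
    }
  }
  out
}

#' Evaluate prediction files against gold
#'
#' Convenience wrapper: computes micro and macro P/R/F1 under exact
#' matching and, when a homolog map is given, under homology-group
#' matching. Documents present in gold but absent from predictions count
#' as empty predictions.
#'
#' @param gold,pred named lists of pair data frames (see [read_pairs()]).
#' @param homolog_map optional named character vector.
#' @return data frame with columns `matching`, `level`, `P`, `R`, `F1`.
#' @export
evaluate_predictions <- function(gold, pred, homolog_map = NULL) {
  for (pm in setdiff(names(gold), names(pred))) pred[[pm]] <- empty_pairs()
  pred <- pred[names(gold)]
  rows <- list(
    c(list(matching = "exact", level = "micro"), micro_scores(gold, pred)),
    c(list(matching = "exact", level = "macro"), macro_scores(gold, pred)))
  if (!is.null(homolog_map) && length(homolog_map)) {
    rows <- c(rows, list(
      c(list(matching = "homolog", level = "micro"),
        micro_scores(gold, pred, homolog_map)),
      c(list(matching = "homolog", level = "macro"),
        macro_scores(gold, pred, homolog_map))))
  }
  do.call(rbind, lapply(rows, as.data.frame, stringsAsFactors = FALSE))
}
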