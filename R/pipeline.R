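# End-to-end extraction: tag -> lexicon scan -> normalize -> classify.
#
# The input is one article (title + abstract); the output is a set of
# unordered gene-ID pairs. Per-document failures never abort a corpus run;
# they are recorded in the run report and reflected in the exit summary.

#' Extract PPIm pairs from one document
#'
#' Runs the full pipeline: ensemble NER tagging, lexicon-based recall
#' post-processing, knowledge-based normalization (null-mapped spans
#' dropped), candidate-pair generation and ensemble relation
#' classification with the 0.5 threshold and single-best fallback.
#' Deterministic given frozen models and bundle.
#'
#' @param doc a segmented `ppim_document`.
#' @param ner_ensemble a trained `ner_ensemble` (or `ner_model`).
#' @param kb a `knowledge_bundle`.
#' @param rc_ensemble a trained `rc_ensemble` (or `rc_model`).
#' @param use_lexicon run the lexicon scan stage (default TRUE; disabling
#'   it supports ablation studies).
#' @param mode normalization mode, see [normalize_mention()].
#' @return list with `pairs` (canonical pair data frame; empty when no
#'   mention normalizes) and `counts` (per-stage accounting: `tagged`,
#'   `lexicon_added`, `normalized`, `dropped_null`, `candidates`,
#'   `predicted`).
#' @export
extract_document <- function(doc, ner_ensemble, kb, rc_ensemble,
                             use_lexicon = TRUE,
                             mode = c("sequential", "union")) {
  mode <- match.arg(mode)
  tagged <- tag_document(ner_ensemble, doc)
  lex <- if (use_lexicon) lexicon_scan(doc, kb$lexicon, existing = tagged)
         else empty_mentions()
  all_mentions <- rbind(tagged, lex)
  normalized <- normalize_document(kb, doc, all_mentions, mode = mode)
  candidates <- unique(normalized$gene_id)
  pairs <- if (length(candidates)) {
    predict_pairs(rc_ensemble, doc, normalized)
  } else empty_pairs()
  list(pairs = pairs,
       counts = c(tagged = nrow(tagged), lexicon_added = nrow(lex),
                  normalized = nrow(normalized),
                  dropped_null = nrow(all_mentions) - nrow(normalized),
                  candidates = length(candidates), predicted = nrow(pairs)))
}

#' Run the extraction pipeline over a corpus
#'
#' Applies [extract_document()] to every article. A failing document is
#' marked in the report and the run continues.
#'
#' @param corpus a `ppim_corpus`.
#' @param ner_ensemble,kb,rc_ensemble trained pipeline components.
#' @param out optional path for the prediction TSV (see [write_pairs()]).
#' @param use_lexicon,mode passed to [extract_document()].
#' @return list with `predictions` (named list of pair data frames),
#'   `report` (per-document stage counts and status) and `n_failed`.
#' @export
run_corpus <- function(corpus, ner_ensemble, kb, rc_ensemble, out = NULL,
                       use_lexicon = TRUE, mode = c("sequential", "union")) {
  mode <- match.arg(mode)
  predictions <- list()
  rows <- list()
  for (pmid in names(corpus$documents)) {
    res <- tryCatch(
      extract_document(corpus$documents[[pmid]], ner_ensemble, kb, rc_ensemble,
                       use_lexicon = use_lexicon, mode = mode),
      error = function(e) e)
    if (inherits(res, "error")) {
      predictions[[pmid]] <- empty_pairs()
      rows[[pmid]] <- data.frame(pmid = pmid, status = "failed",
                                 error = conditionMessage(res),
                                 t(c(tagged = NA_integer_, lexicon_added = NA_integer_,
                                     normalized = NA_integer_, dropped_null = NA_integer_,
                                     candidates = NA_integer_, predicted = NA_integer_)),
                                 stringsAsFactors = FALSE)
    } else {
      predictions[[pmid]] <- res$pairs
      rows[[pmid]] <- data.frame(pmid = pmid, status = "ok", error = "",
                                 t(res$counts), stringsAsFactors = FALSE)
    }
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  if (!is.null(out)) write_pairs(predictions, out)
  list(predictions = predictions, report = report,
       n_failed = sum(report$status == "failed"))
}
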