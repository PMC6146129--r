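# Annotation augmentation: folding document-level tool annotations into a
# gold-annotated corpus, and repairing label sequences to valid IOB1.
#
# Gold gene annotations in PPIm training data only cover genes taking part
# in an interaction, which feeds the tagger contradictory signals (the same
# surface form is a gene in one sentence and O in the next). External
# annotations from a document-level tool are merged in wherever they land
# entirely on tokens still labeled O; anything touching a gold token is
# discarded so gold annotation is never altered.

#' Merge external gene annotations into gold annotations
#'
#' An external mention is inserted only if every token it covers is
#' currently unlabeled (`O`); external mentions sharing even one token with
#' a gold mention -- or with a previously inserted external mention -- are
#' discarded. Gold mentions are never removed or modified.
#'
#' @param doc a segmented `ppim_document`.
#' @param gold gold mention data frame (non-overlapping).
#' @param external external mention data frame (e.g. parsed from a
#'   PubTator-format file produced by a document-level annotator).
#' @return combined mention data frame; inserted rows keep
#'   `provenance = "external"`.
#' @export
merge_external_annotations <- function(doc, gold, external) {
  occupied <- token_mention_index(doc, gold) != 0L
  toks <- doc$tokens
  out <- gold
  if (nrow(external) == 0L) return(out)
  external <- external[order(external$start, -(external$end - external$start)), ,
                       drop = FALSE]
  for (k in seq_len(nrow(external))) {
    cover <- which(toks$start < external$end[k] & toks$end > external$start[k])
    if (!length(cover) || any(occupied[cover])) next
    row <- external[k, , drop = FALSE]
    row$provenance <- "external"
    out <- rbind(out, row)
    occupied[cover] <- TRUE
  }
  rownames(out) <- NULL
  out
}

#' Repair a tag sequence to valid IOB1
#'
#' Minimal correction: a `B-GENE` not immediately preceded by a gene tag
#' (sequence-initial or after `O`) becomes `I-GENE`; every other tag is
#' left unchanged. The result always satisfies [iob_valid()] and the
#' operation is idempotent.
#'
#' @param labels character vector of tags from `O`, `I-GENE`, `B-GENE`.
#' @return repaired tag vector.
#' @export
repair_iob <- function(labels) {
  if (!all(labels %in% TAG_SET)) {
    stop("unknown tag(s): ", paste(setdiff(labels, TAG_SET), collapse = ", "))
  }
  for (i in seq_along(labels)) {
    if (labels[i] == "B-GENE" && (i == 1L || labels[i - 1L] == "O")) {
      labels[i] <- "I-GENE"
    }
  }
  labels
}
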