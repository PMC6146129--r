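# Document-level relation classification of candidate gene-ID pairs.
#
# Every pair of distinct candidate gene IDs in a document yields two
# entity-blinded instances -- orders (A, B) and (B, A) -- in which A's
# mentions are replaced by GENE_A tokens, B's by GENE_B, and mentions of
# every other candidate by GENE_N; each candidate additionally yields one
# self-interaction instance using GENE_S. The classifier is a multi-window
# CNN over word embeddings (window sizes 3/4/5, max-over-time pooling,
# dropout, binary softmax); four zero-vectors are padded at the start and
# end of the text and between sentences. A pair's score is the ensemble
# mean over members and both orders; pairs scoring > 0.5 are positive, and
# if none does, the single highest-scoring pair is predicted.

RC_GENE_TOKENS <- c("GENE_A", "GENE_B", "GENE_S", "GENE_N")

#' RC model configuration
#'
#' Defaults follow the full-scale architecture: windows 3, 4 and 5 with 200
#' filters each (pooled feature length 600), 200-dim word embeddings, 50%
#' dropout, 4 padding vectors.
#'
#' @param windows convolution window sizes.
#' @param n_filters filters per window size.
#' @param word_emb_dim word embedding dimension.
#' @param dropout dropout rate on the pooled feature vector (training only).
#' @param pad number of zero-vectors padded at text start/end and between
#'   sentences.
#' @param max_tokens instance-length cap; longer instances are truncated
#'   from the end (never past the first occurrence of a bound gene token).
#' @return list of class `rc_model_config`.
#' @export
rc_model_config <- function(windows = c(3L, 4L, 5L), n_filters = 200L,
                            word_emb_dim = 200L, dropout = 0.5, pad = 4L,
                            max_tokens = 1500L) {
  structure(list(windows = as.integer(windows), n_filters = as.integer(n_filters),
                 word_emb_dim = as.integer(word_emb_dim), dropout = dropout,
                 pad = as.integer(pad), max_tokens = as.integer(max_tokens)),
            class = "rc_model_config")
}

#' RC training configuration
#'
#' Defaults: 30 epochs of RMSProp at learning rate 0.001 with mini-batches
#' of 8, per-epoch checkpointing keeping the best development pair-F1,
#' ensembles of 10 members each trained on an independent 80/20
#' document-level train/dev split with a distinct seed.
#'
#' @param epochs,learning_rate,batch_size,rho optimizer controls.
#' @param ensemble_size number of ensemble members.
#' @param dev_fraction fraction of documents held out per member.
#' @param grad_clip global gradient-norm clip.
#' @return list of class `rc_train_config`.
#' @export
rc_train_config <- function(epochs = 30L, learning_rate = 0.001,
                            batch_size = 8L, rho = 0.9,
                            ensemble_size = 10L, dev_fraction = 0.2,
                            grad_clip = 5) {
  stopifnot(dev_fraction > 0, dev_fraction < 1)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), rho = rho,
                 ensemble_size = as.integer(ensemble_size),
                 dev_fraction = dev_fraction, grad_clip = grad_clip),
            class = "rc_train_config")
}

## ---- instance generation ----------------------------------------------------

# Blinding template for a document: per sentence, a list of slots
# (text, gene_id or NA). Multi-token mentions collapse into one slot;
# overlapping mention spans are resolved longest-first.
rc_blinding_template <- function(doc, mentions) {
  toks <- doc$tokens
  mention_of <- integer(nrow(toks))
  if (nrow(mentions)) {
    ord <- order(-(mentions$end - mentions$start), mentions$start)
    for (k in ord) {
      cover <- which(toks$start < mentions$end[k] & toks$end > mentions$start[k])
      if (!length(cover) || any(mention_of[cover] != 0L)) next
      mention_of[cover] <- k
    }
  }
  sentences <- list()
  for (s in seq_len(nrow(doc$sentences))) {
    rows <- which(toks$sentence == s)
    slots <- list()
    j <- 1L
    while (j <= length(rows)) {
      i <- rows[j]
      if (mention_of[i] == 0L) {
        slots[[length(slots) + 1L]] <- list(
          text = tolower(slice_text(doc$full_text, toks$start[i], toks$end[i])),
          gene_id = NA_character_)
        j <- j + 1L
      } else {
        m <- mention_of[i]
        span <- j
        while (j + 1L <= length(rows) && mention_of[rows[j + 1L]] == m) j <- j + 1L
        slots[[length(slots) + 1L]] <- list(text = NA_character_,
                                            gene_id = mentions$gene_id[m])
        j <- j + 1L
      }
    }
    sentences[[s]] <- slots
  }
  sentences
}

rc_instance_tokens <- function(template, id_a, id_b) {
  self <- id_a == id_b
  lapply(template, function(slots) {
    vapply(slots, function(sl) {
      if (is.na(sl$gene_id)) return(sl$text)
      if (self && sl$gene_id == id_a) "GENE_S"
      else if (sl$gene_id == id_a) "GENE_A"
      else if (sl$gene_id == id_b) "GENE_B"
      else "GENE_N"
    }, character(1))
  })
}

#' Generate entity-blinded classification instances for a document
#'
#' For a candidate gene-ID set G (the distinct IDs on the normalized
#' mentions), emits `|G|^2` instances: both orders (A, B) and (B, A) for
#' every unordered pair of distinct IDs, plus one GENE_S self instance per
#' ID. When `gold_pairs` is supplied, labels are assigned
#' order-insensitively.
#'
#' @param doc a segmented `ppim_document`.
#' @param mentions normalized mention data frame (`gene_id` set).
#' @param gold_pairs optional gold pair data frame (`id1`, `id2`).
#' @param config an [rc_model_config()] (for the length cap).
#' @return list of `rc_instance` objects: `list(pmid, id_a, id_b, self,
#'   label, sentences)`.
#' @export
generate_instances <- function(doc, mentions, gold_pairs = NULL,
                               config = rc_model_config()) {
  mentions <- mentions[!is.na(mentions$gene_id), , drop = FALSE]
  G <- sort(unique(mentions$gene_id))
  if (!length(G)) return(list())
  template <- rc_blinding_template(doc, mentions)
  gold_keys <- if (!is.null(gold_pairs) && nrow(gold_pairs)) {
    cp <- canonical_pairs(gold_pairs$id1, gold_pairs$id2)
    paste(cp$id1, cp$id2, sep = "|")
  } else character(0)
  label_of <- function(a, b) {
    if (is.null(gold_pairs)) return(NA_integer_)
    key <- paste(min(a, b), max(a, b), sep = "|")
    as.integer(key %in% gold_keys)
  }
  out <- list()
  add <- function(a, b) {
    sent <- rc_truncate(rc_instance_tokens(template, a, b), config$max_tokens)
    out[[length(out) + 1L]] <<- structure(
      list(pmid = doc$pmid, id_a = a, id_b = b, self = a == b,
           label = label_of(a, b), sentences = sent),
      class = "rc_instance")
    invisible(NULL)
  }
  for (a in G) for (b in G) add(a, b)
  out
}

# Truncate an instance to at most `max_tokens` tokens, dropping trailing
# sentences/tokens but never cutting before the first occurrence of a
# bound gene token.
rc_truncate <- function(sentences, max_tokens) {
  lens <- vapply(sentences, length, 1L)
  if (sum(lens) <= max_tokens) return(sentences)
  flat <- unlist(sentences)
  first_bound <- which(flat %in% c("GENE_A", "GENE_B", "GENE_S"))
  first_bound <- if (length(first_bound)) first_bound[1L] else 1L
  keep <- max(max_tokens, first_bound)
  out <- list(); used <- 0L
  for (s in sentences) {
    if (used >= keep) break
    take <- min(length(s), keep - used)
    out[[length(out) + 1L]] <- s[seq_len(take)]
    used <- used + take
  }
  out
}

## ---- model ------------------------------------------------------------------

build_rc_vocab <- function(instances) {
  toks <- unique(unlist(lapply(instances, function(i) unlist(i$sentences))))
  toks <- sort(unique(c(toks, RC_GENE_TOKENS)))
  # index 1 = PAD (fixed zero embedding), 2 = UNK
  stats::setNames(seq_along(toks) + 2L, toks)
}

rc_init_params <- function(cfg, vocab, word_vectors = NULL) {
  d <- cfg$word_emb_dim
  n_words <- length(vocab) + 2L
  E <- embedding_init(n_words, d)
  E[1L, ] <- 0  # PAD row stays zero
  if (!is.null(word_vectors)) {
    stopifnot(ncol(word_vectors$mat) == d)
    hit <- match(names(vocab), tolower(word_vectors$words))
    ok <- which(!is.na(hit))
    E[unname(vocab)[ok], ] <- word_vectors$mat[hit[ok], , drop = FALSE]
  }
  params <- list(E = ad_param(E))
  for (w in cfg$windows) {
    params[[paste0("W", w)]] <- ad_param(glorot_uniform(w * d, cfg$n_filters))
    params[[paste0("b", w)]] <- ad_param(matrix(0, 1L, cfg$n_filters))
  }
  params$W_dense <- ad_param(glorot_uniform(length(cfg$windows) * cfg$n_filters, 2L))
  params$b_dense <- ad_param(matrix(0, 1L, 2L))
  params
}

new_rc_model <- function(cfg, vocab, word_vectors = NULL, seed = 1L) {
  set.seed(seed)
  structure(list(cfg = cfg, vocab = vocab,
                 params = rc_init_params(cfg, vocab, word_vectors),
                 seed = seed, history = NULL, best_f1 = NA_real_),
            class = "rc_model")
}

#' @export
print.rc_model <- function(x, ...) {
  cat("<rc_model> windows {", paste(x$cfg$windows, collapse = ","), "} x ",
      x$cfg$n_filters, " filters; |vocab| = ", length(x$vocab), "\n", sep = "")
  if (!is.na(x$best_f1)) cat("  best dev pair-F1:", round(x$best_f1, 4), "\n")
  invisible(x)
}

# Token index sequence with PAD (index 1) blocks at the start, end and
# between sentences.
rc_token_ids <- function(model, instance) {
  pad <- rep(1L, model$cfg$pad)
  ids <- pad
  for (s in instance$sentences) {
    idx <- unname(model$vocab[s])
    idx[is.na(idx)] <- 2L  # UNK
    ids <- c(ids, idx, pad)
  }
  ids
}

# Forward pass; returns logits node (1 x 2). A dropout mask (inverted
# dropout) is applied to the pooled feature vector during training.
rc_forward_tape <- function(tape, model, instance, train = FALSE) {
  cfg <- model$cfg; p <- model$params
  ids <- rc_token_ids(model, instance)
  X <- ad_embed(tape, p$E, ids)
  pooled <- lapply(cfg$windows, function(w) {
    ad_conv_pool(tape, X, 1L, length(ids), p[[paste0("W", w)]],
                 p[[paste0("b", w)]], w)
  })
  feat <- ad_cbind(tape, pooled)
  if (train && cfg$dropout > 0) {
    keep <- stats::rbinom(ncol(feat$val), 1L, 1 - cfg$dropout) / (1 - cfg$dropout)
    feat <- ad_mul(tape, feat, ad_const(tape, matrix(keep, 1L)))
  }
  ad_add(tape, ad_matmul(tape, feat, ad_use(tape, p$W_dense)),
         ad_use(tape, p$b_dense))
}

#' Positive-class probability of one instance
#'
#' Inference-mode forward pass (dropout disabled).
#'
#' @param model an `rc_model`.
#' @param instance an `rc_instance`.
#' @return probability in (0, 1).
#' @export
rc_forward <- function(model, instance) {
  tape <- ad_tape()
  logits <- rc_forward_tape(tape, model, instance)
  softmax_rows(logits$val)[1L, 2L]
}

## ---- training ---------------------------------------------------------------

# Pair-level predictions for a set of labeled instances grouped by
# document, using the threshold + argmax-fallback decision rule.
rc_pair_predictions <- function(models, instances) {
  if (inherits(models, "rc_model")) models <- list(models)
  key <- vapply(instances, function(i) {
    paste(i$pmid, min(i$id_a, i$id_b), max(i$id_a, i$id_b), sep = "\r")
  }, character(1))
  scores <- vapply(instances, function(inst) {
    mean(vapply(models, rc_forward, numeric(1), instance = inst))
  }, numeric(1))
  pair_score <- tapply(scores, key, mean)
  parts <- strsplit(names(pair_score), "\r", fixed = TRUE)
  df <- data.frame(pmid = vapply(parts, `[[`, character(1), 1L),
                   id1 = vapply(parts, `[[`, character(1), 2L),
                   id2 = vapply(parts, `[[`, character(1), 3L),
                   score = as.numeric(pair_score), stringsAsFactors = FALSE)
  out <- list()
  for (pmid in unique(df$pmid)) {
    out[[pmid]] <- decide_pairs(df[df$pmid == pmid, c("id1", "id2", "score")])
  }
  out
}

#' Decide a document's positive pairs from candidate-pair scores
#'
#' The decision rule of the pipeline, separated from scoring: every pair
#' with score strictly above 0.5 is positive; when none is and candidates
#' exist, the single highest-scoring pair is predicted (ties broken by the
#' lexicographically smallest canonical pair).
#'
#' @param pair_scores data frame with columns `id1`, `id2`, `score` for one
#'   document's candidate pairs.
#' @return canonical pair data frame (empty iff `pair_scores` is empty).
#' @export
decide_pairs <- function(pair_scores) {
  if (is.null(pair_scores) || nrow(pair_scores) == 0L) return(empty_pairs())
  pos <- pair_scores[pair_scores$score > 0.5, , drop = FALSE]
  if (nrow(pos) == 0L) {
    ord <- order(-pair_scores$score, pmin(pair_scores$id1, pair_scores$id2),
                 pmax(pair_scores$id1, pair_scores$id2))
    pos <- pair_scores[ord[1L], , drop = FALSE]
  }
  canonical_pairs(pos$id1, pos$id2)
}

rc_gold_pairs_of <- function(instances) {
  out <- list()
  for (inst in instances) {
    if (is.na(inst$label) || inst$label != 1L) next
    out[[inst$pmid]] <- rbind(out[[inst$pmid]],
                              data.frame(id1 = inst$id_a, id2 = inst$id_b,
                                         stringsAsFactors = FALSE))
  }
  lapply(out, function(df) canonical_pairs(df$id1, df$id2))
}

# Document-level micro pair-F1 of a model on labeled instances.
rc_dev_f1 <- function(model, instances) {
  pmids <- unique(vapply(instances, `[[`, character(1), "pmid"))
  gold <- rc_gold_pairs_of(instances)
  for (pm in pmids) if (is.null(gold[[pm]])) gold[[pm]] <- empty_pairs()
  pred <- rc_pair_predictions(model, instances)
  for (pm in pmids) if (is.null(pred[[pm]])) pred[[pm]] <- empty_pairs()
  micro_scores(gold[pmids], pred[pmids])$F1
}

#' Train a single relation-classification model
#'
#' RMSProp on mean cross-entropy over mini-batches of instances, with
#' per-epoch checkpointing that keeps the parameters achieving the best
#' document-level pair-F1 (both orders averaged, matching inference) on
#' the development instances.
#'
#' @param train_instances,dev_instances labeled `rc_instance` lists; the
#'   training set must contain both classes.
#' @param model_cfg an [rc_model_config()].
#' @param train_cfg an [rc_train_config()].
#' @param seed integer RNG seed.
#' @param word_vectors optional `list(words, mat)`.
#' @param vocab optional prebuilt vocabulary shared across members.
#' @return a trained `rc_model`.
#' @export
train_rc <- function(train_instances, dev_instances,
                     model_cfg = rc_model_config(),
                     train_cfg = rc_train_config(),
                     seed = 1L, word_vectors = NULL, vocab = NULL) {
  if (length(train_instances) < 2L) stop("need at least 2 labeled instances")
  labels <- vapply(train_instances, `[[`, integer(1), "label")
  if (anyNA(labels) || length(unique(labels)) < 2L) {
    stop("training set must contain both positive and negative instances")
  }
  if (is.null(vocab)) vocab <- build_rc_vocab(c(train_instances, dev_instances))
  model <- new_rc_model(model_cfg, vocab, word_vectors, seed)
  params <- model$params
  best <- list(f1 = -1, snap = NULL, epoch = 0L)
  history <- data.frame(epoch = integer(0), dev_f1 = numeric(0))
  n <- length(train_instances)
  for (epoch in seq_len(train_cfg$epochs)) {
    ord <- sample.int(n)
    for (start in seq(1L, n, by = train_cfg$batch_size)) {
      batch <- ord[start:min(start + train_cfg$batch_size - 1L, n)]
      for (b in batch) {
        inst <- train_instances[[b]]
        tape <- ad_tape()
        logits <- rc_forward_tape(tape, model, inst, train = TRUE)
        loss <- ad_mean_xent(tape, logits, inst$label + 1L)
        ad_backward(tape, loss, seed = 1 / length(batch))
      }
      params$E$grad[1L, ] <- 0  # PAD embedding stays zero
      rmsprop_step(params, train_cfg$learning_rate, rho = train_cfg$rho,
                   clip = train_cfg$grad_clip)
    }
    f1 <- if (length(dev_instances)) rc_dev_f1(model, dev_instances) else NA_real_
    history <- rbind(history, data.frame(epoch = epoch, dev_f1 = f1))
    if (!is.na(f1) && f1 > best$f1 + 1e-9) {
      best <- list(f1 = f1, snap = params_snapshot(params), epoch = epoch)
      if (f1 >= 1) break
    }
  }
  if (!is.null(best$snap)) params_restore(params, best$snap)
  model$history <- history
  model$best_f1 <- if (best$f1 >= 0) best$f1 else NA_real_
  model$train_cfg <- train_cfg
  model
}

#' Train an RC ensemble
#'
#' Members are trained with distinct seeds on independent document-level
#' train/dev splits (default 80/20); all members share one vocabulary.
#'
#' @param instances labeled `rc_instance` list covering >= 2 documents.
#' @inheritParams train_rc
#' @return an `rc_ensemble`.
#' @export
train_rc_ensemble <- function(instances,
                              model_cfg = rc_model_config(),
                              train_cfg = rc_train_config(),
                              seed = 1L, word_vectors = NULL) {
  if (train_cfg$ensemble_size < 1L) stop("ensemble_size must be >= 1")
  pmids <- unique(vapply(instances, `[[`, character(1), "pmid"))
  if (length(pmids) < 2L) stop("need instances from at least 2 documents")
  vocab <- build_rc_vocab(instances)
  inst_pmid <- vapply(instances, `[[`, character(1), "pmid")
  n_dev <- max(1L, round(train_cfg$dev_fraction * length(pmids)))
  members <- vector("list", train_cfg$ensemble_size)
  base <- (as.integer(seed) %% 1000000L) * 1000L
  for (k in seq_len(train_cfg$ensemble_size)) {
    member_seed <- base + 500L + k
    set.seed(member_seed)
    dev_pmids <- sample(pmids, n_dev)
    members[[k]] <- train_rc(instances[!(inst_pmid %in% dev_pmids)],
                             instances[inst_pmid %in% dev_pmids],
                             model_cfg, train_cfg, seed = member_seed,
                             word_vectors = word_vectors, vocab = vocab)
    members[[k]]$dev_pmids <- dev_pmids
  }
  structure(list(members = members, model_cfg = model_cfg,
                 train_cfg = train_cfg, seed = seed),
            class = "rc_ensemble")
}

#' @export
print.rc_ensemble <- function(x, ...) {
  cat("<rc_ensemble>", length(x$members), "members; best dev pair-F1:",
      paste(round(vapply(x$members, `[[`, 1, "best_f1"), 3), collapse = " "),
      "\n")
  invisible(x)
}

## ---- scoring and prediction -------------------------------------------------

rc_members <- function(ensemble) {
  if (inherits(ensemble, "rc_model")) list(ensemble) else ensemble$members
}

#' Score an unordered candidate pair
#'
#' Mean positive-class probability over all ensemble members and both
#' instance orders (the single GENE_S instance for a self pair); symmetric
#' in the pair by construction.
#'
#' @param ensemble an `rc_ensemble` or single `rc_model`.
#' @param instances the document's instance list from
#'   [generate_instances()].
#' @param pair character vector of 2 gene IDs (may be identical).
#' @return probability in (0, 1).
#' @export
score_pair <- function(ensemble, instances, pair) {
  a <- min(pair[1L], pair[2L]); b <- max(pair[1L], pair[2L])
  sel <- Filter(function(i) min(i$id_a, i$id_b) == a && max(i$id_a, i$id_b) == b,
                instances)
  if (!length(sel)) stop("pair (", a, ", ", b, ") not in the candidate set")
  mean(vapply(sel, function(inst) {
    mean(vapply(rc_members(ensemble), rc_forward, numeric(1), instance = inst))
  }, numeric(1)))
}

#' Predict a document's positive pairs
#'
#' All candidate pairs scoring strictly above 0.5 are predicted positive;
#' when none does and candidates exist, the single highest-scoring pair is
#' predicted (ties broken by the lexicographically smallest canonical
#' pair).
#'
#' @param ensemble an `rc_ensemble` or single `rc_model`.
#' @param doc a segmented `ppim_document`.
#' @param mentions normalized mention data frame (candidate IDs).
#' @param config an [rc_model_config()] used for instance generation.
#' @return canonical pair data frame (possibly empty).
#' @export
predict_pairs <- function(ensemble, doc, mentions, config = NULL) {
  if (is.null(config)) {
    config <- if (inherits(ensemble, "rc_model")) ensemble$cfg else ensemble$model_cfg
  }
  instances <- generate_instances(doc, mentions, config = config)
  if (!length(instances)) return(empty_pairs())
  pred <- rc_pair_predictions(rc_members(ensemble), instances)
  pred[[doc$pmid]]
}
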