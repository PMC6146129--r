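# Gene-mention tagger: a character-CNN + bidirectional LSTM sequence labeler
# over IOB1 tags {O, I-GENE, B-GENE}.
#
# Each token is represented as the concatenation of (i) a character-level
# feature vector obtained by convolving width-3 filters over the token's
# lowercased character embeddings paired with 8-dim character-type
# embeddings (lowercase / uppercase / punctuation / other) and max-over-time
# pooling, (ii) a word embedding and (iii) a word-shape ("word type")
# embedding. A Bi-LSTM contextualizes the sequence and a per-token softmax
# produces the 3-way tag distribution; training minimizes mean categorical
# cross-entropy per sentence. Ensembles average per-token tag probabilities.

CHAR_TYPES <- c("lowercase", "uppercase", "punctuation", "other")
WORD_TYPES <- c("all_lower", "mixed", "cap_first", "all_upper", "other")

#' Character type of a single character
#'
#' One of `lowercase`, `uppercase`, `punctuation` or `other` (digits,
#' spaces and anything unclassified fall under `other`).
#'
#' @param ch single character.
#' @return one of [CHAR_TYPES].
#' @export
char_type <- function(ch) {
  stopifnot(nchar(ch) == 1L)
  if (grepl("[a-z]", ch)) "lowercase"
  else if (grepl("[A-Z]", ch)) "uppercase"
  else if (grepl("[[:punct:]]", ch)) "punctuation"
  else "other"
}

#' Word shape class of a token
#'
#' Classified over the token's alphabetic characters only: `all_lower`,
#' `all_upper`, `cap_first` (initial capital, rest lowercase), `mixed`, or
#' `other` for tokens without any letter.
#'
#' @param w nonempty token string.
#' @return one of [WORD_TYPES].
#' @export
word_type <- function(w) {
  if (!nzchar(w)) stop("empty token")
  chars <- strsplit(w, "")[[1L]]
  letters_mask <- grepl("[A-Za-z]", chars)
  if (!any(letters_mask)) return("other")
  lets <- chars[letters_mask]
  lower <- grepl("[a-z]", lets); upper <- !lower
  if (all(lower)) return("all_lower")
  if (all(upper)) return("all_upper")
  if (upper[1L] && all(lower[-1L])) return("cap_first")
  "mixed"
}

#' NER model configuration
#'
#' Defaults follow the full-scale architecture: 32-dim character embeddings
#' plus 8-dim character-type embeddings convolved by 50 width-3 filters,
#' 200-dim word embeddings, 32-dim word-type embeddings, and a Bi-LSTM with
#' 200 hidden units per direction feeding a 3-way softmax.
#'
#' @param char_emb_dim,char_type_emb_dim,char_filters,char_window character
#'   CNN dimensions.
#' @param word_emb_dim,word_type_emb_dim,lstm_hidden word-level dimensions.
#' @param n_tags number of output tags (3).
#' @return list of class `ner_model_config`.
#' @export
ner_model_config <- function(char_emb_dim = 32L, char_type_emb_dim = 8L,
                             char_filters = 50L, char_window = 3L,
                             word_emb_dim = 200L, word_type_emb_dim = 32L,
                             lstm_hidden = 200L, n_tags = 3L) {
  cfg <- list(char_emb_dim = char_emb_dim, char_type_emb_dim = char_type_emb_dim,
              char_filters = char_filters, char_window = char_window,
              word_emb_dim = word_emb_dim, word_type_emb_dim = word_type_emb_dim,
              lstm_hidden = lstm_hidden, n_tags = n_tags)
  stopifnot(all(unlist(cfg) > 0))
  structure(cfg, class = "ner_model_config")
}

#' NER training configuration
#'
#' Defaults: SGD with learning rate decayed exponentially at rate 0.95 per
#' checkpoint, at most 10000 iterations of mini-batches of 20 sentences,
#' checkpoint (dev span-F1 evaluation) every 100 iterations, early stop
#' after 10 non-improving checkpoints; ensembles of 10 members each trained
#' on an independent random 50% subset of sentences, the complementary 50%
#' serving as that member's development set.
#'
#' @param learning_rate initial SGD learning rate.
#' @param decay multiplicative decay applied each checkpoint interval.
#' @param max_iterations,batch_size,checkpoint_every,early_stop_patience
#'   training-loop controls.
#' @param ensemble_size,subset_fraction ensemble controls.
#' @param grad_clip global gradient-norm clip.
#' @return list of class `ner_train_config`.
#' @export
ner_train_config <- function(learning_rate = 0.05, decay = 0.95,
                             max_iterations = 10000L, batch_size = 20L,
                             checkpoint_every = 100L, early_stop_patience = 10L,
                             ensemble_size = 10L, subset_fraction = 0.5,
                             grad_clip = 5) {
  stopifnot(early_stop_patience >= 1L,
            subset_fraction > 0, subset_fraction <= 1)
  structure(list(learning_rate = learning_rate, decay = decay,
                 max_iterations = as.integer(max_iterations),
                 batch_size = as.integer(batch_size),
                 checkpoint_every = as.integer(checkpoint_every),
                 early_stop_patience = as.integer(early_stop_patience),
                 ensemble_size = as.integer(ensemble_size),
                 subset_fraction = subset_fraction, grad_clip = grad_clip),
            class = "ner_train_config")
}

## ---- vocabularies -----------------------------------------------------------

printable_ascii <- function() strsplit(rawToChar(as.raw(33:126)), "")[[1L]]

# Character and word vocabularies from training token strings. Characters
# are lowercased; index 1 is the padding character, index 2 the unknown
# character. Words are lowercased; index 1 is the unknown word.
build_ner_vocab <- function(token_texts) {
  chars <- sort(unique(c(printable_ascii(),
                         unlist(strsplit(tolower(token_texts), "")))))
  words <- sort(unique(tolower(token_texts)))
  list(chars = stats::setNames(seq_along(chars) + 2L, chars),
       words = stats::setNames(seq_along(words) + 1L, words),
       n_chars = length(chars) + 2L, n_words = length(words) + 1L)
}

char_indices <- function(vocab, word) {
  cs <- strsplit(tolower(word), "")[[1L]]
  idx <- unname(vocab$chars[cs])
  idx[is.na(idx)] <- 2L  # UNK char
  idx
}

word_index <- function(vocab, word) {
  i <- vocab$words[tolower(word)]
  if (is.na(i)) 1L else unname(i)  # UNK word
}

# Per-token lookup indices, cached per surface form on the model.
token_features <- function(model, word) {
  hit <- model$cache[[word]]
  if (!is.null(hit)) return(hit)
  w <- model$cfg$char_window
  ci <- char_indices(model$vocab, word)
  orig <- strsplit(word, "")[[1L]]
  zi <- match(vapply(orig, char_type, character(1)), CHAR_TYPES)
  if (length(ci) < w) {  # pad short words with the reserved PAD character
    pad <- w - length(ci)
    ci <- c(ci, rep(1L, pad))
    zi <- c(zi, rep(4L, pad))  # PAD counts as "other"
  }
  ft <- list(ci = ci, zi = zi,
             wi = word_index(model$vocab, word),
             wt = match(word_type(word), WORD_TYPES))
  model$cache[[word]] <- ft
  ft
}

## ---- model construction -----------------------------------------------------

# Initialize all trainable parameters. `word_vectors` (list(words, mat)) in
# word2vec layout seeds matching rows of the word embedding.
ner_init_params <- function(cfg, vocab, word_vectors = NULL) {
  a <- cfg$char_emb_dim; ct <- cfg$char_type_emb_dim
  k <- cfg$char_filters; w <- cfg$char_window
  d <- cfg$word_emb_dim; wt <- cfg$word_type_emb_dim; pi <- cfg$lstm_hidden
  in_dim <- k + d + wt
  E_word <- embedding_init(vocab$n_words, d)
  if (!is.null(word_vectors)) {
    stopifnot(ncol(word_vectors$mat) == d)
    hit <- match(names(vocab$words), tolower(word_vectors$words))
    ok <- which(!is.na(hit))
    E_word[unname(vocab$words)[ok], ] <- word_vectors$mat[hit[ok], , drop = FALSE]
  }
  lstm <- function() {
    b <- matrix(0, 1L, 4L * pi)
    b[1L, (pi + 1L):(2L * pi)] <- 1  # forget-gate bias
    list(Wx = ad_param(glorot_uniform(in_dim, 4L * pi)),
         Wh = ad_param(glorot_uniform(pi, 4L * pi)),
         b = ad_param(b))
  }
  fw <- lstm(); bw <- lstm()
  list(E_char = ad_param(embedding_init(vocab$n_chars, a)),
       E_ctype = ad_param(embedding_init(4L, ct)),
       E_word = ad_param(E_word),
       E_wtype = ad_param(embedding_init(5L, wt)),
       W_char = ad_param(glorot_uniform(w * (a + ct), k)),
       b_char = ad_param(matrix(0, 1L, k)),
       Wx_f = fw$Wx, Wh_f = fw$Wh, b_f = fw$b,
       Wx_b = bw$Wx, Wh_b = bw$Wh, b_b = bw$b,
       W_out = ad_param(glorot_uniform(2L * pi, cfg$n_tags)),
       b_out = ad_param(matrix(0, 1L, cfg$n_tags)))
}

new_ner_model <- function(cfg, vocab, word_vectors = NULL, seed = 1L) {
  set.seed(seed)
  structure(list(cfg = cfg, vocab = vocab,
                 params = ner_init_params(cfg, vocab, word_vectors),
                 tags = TAG_SET, seed = seed,
                 cache = new.env(parent = emptyenv()),
                 history = NULL, best_f1 = NA_real_),
            class = "ner_model")
}

#' @export
print.ner_model <- function(x, ...) {
  cat("<ner_model> char-CNN(", x$cfg$char_filters, " filters) + BiLSTM(",
      x$cfg$lstm_hidden, ") -> ", x$cfg$n_tags, " tags; |words| = ",
      x$vocab$n_words, "\n", sep = "")
  if (!is.na(x$best_f1)) cat("  best dev span-F1:", round(x$best_f1, 4), "\n")
  invisible(x)
}

## ---- forward passes ---------------------------------------------------------

# Character-composition vectors for all tokens of a sentence at once: the
# tokens' (padded) character sequences are concatenated into one embedding
# matrix and convolved/pooled per token segment. Returns an n x kappa node.
ner_char_block <- function(tape, model, fts) {
  p <- model$params
  ci <- unlist(lapply(fts, `[[`, "ci"))
  zi <- unlist(lapply(fts, `[[`, "zi"))
  lens <- vapply(fts, function(f) length(f$ci), 1L)
  seg_end <- cumsum(lens)
  seg_start <- seg_end - lens + 1L
  B <- ad_cbind(tape, list(ad_embed(tape, p$E_char, ci),
                           ad_embed(tape, p$E_ctype, zi)))
  ad_conv_pool(tape, B, seg_start, seg_end, p$W_char, p$b_char,
               model$cfg$char_window)
}

# Full forward pass over one sentence; returns the logits node (n x 3) and
# the context matrix node H (n x 2*pi).
ner_forward <- function(tape, model, tokens) {
  p <- model$params
  fts <- lapply(tokens, token_features, model = model)
  X <- ad_cbind(tape, list(
    ner_char_block(tape, model, fts),
    ad_embed(tape, p$E_word, vapply(fts, `[[`, 1L, "wi")),
    ad_embed(tape, p$E_wtype, vapply(fts, `[[`, 1L, "wt"))))
  H <- ad_cbind(tape, list(
    ad_lstm(tape, X, p$Wx_f, p$Wh_f, p$b_f, reverse = FALSE),
    ad_lstm(tape, X, p$Wx_b, p$Wh_b, p$b_b, reverse = TRUE)))
  logits <- ad_add(tape, ad_matmul(tape, H, ad_use(tape, p$W_out)),
                   ad_use(tape, p$b_out))
  list(logits = logits, H = H)
}

#' Character-composition vector of a word
#'
#' Runs the character CNN alone: embeds the lowercased characters and their
#' character types, convolves width-3 filters with ReLU activation and
#' max-over-time pools each filter's feature map. Words shorter than the
#' window are padded with a reserved padding character.
#'
#' @param model a `ner_model`.
#' @param word token string.
#' @return numeric vector of length `char_filters`.
#' @export
encode_word_chars <- function(model, word) {
  tape <- ad_tape()
  u <- ner_char_block(tape, model, list(token_features(model, word)))
  as.numeric(u$val)
}

#' Bi-LSTM context vectors for a token sequence
#'
#' @param model a `ner_model`.
#' @param tokens character vector of token strings.
#' @return numeric matrix, one row per token, `2 * lstm_hidden` columns
#'   (forward state followed by backward state).
#' @export
encode_sequence <- function(model, tokens) {
  stopifnot(length(tokens) > 0L)
  tape <- ad_tape()
  fwd <- ner_forward(tape, model, tokens)
  fwd$H$val
}

#' Tag distribution from a context vector
#'
#' Applies the output layer `q = h W_out + b_out` and a numerically stable
#' softmax, giving the categorical distribution over tags.
#'
#' @param model a `ner_model`.
#' @param h context vector (length `2 * lstm_hidden`) or matrix of rows.
#' @return probability matrix, rows summing to 1.
#' @export
token_distribution <- function(model, h) {
  if (!is.matrix(h)) h <- matrix(h, nrow = 1L)
  q <- h %*% model$params$W_out$value +
    rep(model$params$b_out$value, each = nrow(h))
  softmax_rows(q)
}

#' Mean categorical cross-entropy over a sequence
#'
#' `-(1/n) * sum_i sum_j y[i,j] log p[i,j]` for per-token probability rows
#' `p` and one-hot gold rows `y`.
#'
#' @param p probability matrix (n x m).
#' @param y one-hot matrix of the same shape, or an integer vector of gold
#'   class indices.
#' @return nonnegative scalar loss.
#' @export
sequence_loss <- function(p, y) {
  if (!is.matrix(y)) {
    yi <- as.integer(y)
    y <- matrix(0, nrow(p), ncol(p))
    y[cbind(seq_len(nrow(p)), yi)] <- 1
  }
  stopifnot(all(dim(p) == dim(y)))
  -mean(rowSums(y * log(pmax(p, 1e-12))))
}

# Per-token tag probabilities for one sentence (plain matrix).
ner_sentence_probs <- function(model, tokens) {
  tape <- ad_tape()
  fwd <- ner_forward(tape, model, tokens)
  softmax_rows(fwd$logits$val)
}

## ---- span utilities ---------------------------------------------------------

# Token-index spans ("start:end", inclusive) from an IOB1 label vector.
spans_from_labels <- function(labels) {
  out <- character(0)
  n <- length(labels); i <- 1L
  while (i <= n) {
    if (labels[i] == "O") { i <- i + 1L; next }
    j <- i
    while (j + 1L <= n && labels[j + 1L] == "I-GENE") j <- j + 1L
    out <- c(out, paste0(i, ":", j))
    i <- j + 1L
  }
  out
}

# Micro span-level F1 between two lists of label vectors.
span_f1 <- function(pred_labels, gold_labels) {
  tp <- 0L; fp <- 0L; fn <- 0L
  for (k in seq_along(gold_labels)) {
    ps <- spans_from_labels(pred_labels[[k]])
    gs <- spans_from_labels(gold_labels[[k]])
    tp <- tp + length(intersect(ps, gs))
    fp <- fp + length(setdiff(ps, gs))
    fn <- fn + length(setdiff(gs, ps))
  }
  if (tp == 0L) return(0)
  p <- tp / (tp + fp); r <- tp / (tp + fn)
  2 * p * r / (p + r)
}

# Predicted (repaired) label vector for a token sequence.
ner_predict_labels <- function(model, tokens) {
  probs <- ner_sentence_probs(model, tokens)
  repair_iob(TAG_SET[max.col(probs, ties.method = "first")])
}

## ---- training ---------------------------------------------------------------

#' Extract labeled training sequences from a corpus
#'
#' Projects each document's mentions to IOB1 and pairs sentence token
#' strings with their tags.
#'
#' @param corpus a `ppim_corpus`.
#' @return list of `list(tokens = <character>, labels = <character>)`.
#' @export
labeled_sequences <- function(corpus) {
  out <- list()
  for (pmid in names(corpus$documents)) {
    doc <- corpus$documents[[pmid]]
    seqs <- project_to_iob(doc, corpus$mentions[[pmid]])
    for (s in seqs) {
      toks <- vapply(seq_len(nrow(s$tokens)), function(i) {
        slice_text(doc$full_text, s$tokens$start[i], s$tokens$end[i])
      }, character(1))
      out[[length(out) + 1L]] <- list(tokens = toks, labels = s$labels)
    }
  }
  out
}

#' Train a single NER model
#'
#' Mini-batch SGD on mean per-sentence cross-entropy, with the learning
#' rate decayed exponentially each checkpoint interval, span-level F1
#' evaluated on the development set at every checkpoint, the best
#' checkpoint's parameters retained, and early stopping after
#' `early_stop_patience` non-improving checkpoints. Fully reproducible for
#' a fixed seed.
#'
#' @param train_seqs,dev_seqs lists of `list(tokens, labels)` (see
#'   [labeled_sequences()]); `dev_seqs` must be nonempty.
#' @param model_cfg a [ner_model_config()].
#' @param train_cfg a [ner_train_config()].
#' @param seed integer RNG seed.
#' @param word_vectors optional `list(words, mat)` from
#'   [read_word_vectors()].
#' @param vocab optional prebuilt vocabulary (shared across ensemble
#'   members); built from `train_seqs` + `dev_seqs` when NULL.
#' @param target_f1 optional dev span-F1 at which training halts early.
#' @return a trained `ner_model` with checkpoint `history`.
#' @export
train_ner <- function(train_seqs, dev_seqs,
                      model_cfg = ner_model_config(),
                      train_cfg = ner_train_config(),
                      seed = 1L, word_vectors = NULL, vocab = NULL,
                      target_f1 = NULL) {
  if (length(train_seqs) == 0L) stop("empty training set")
  if (length(dev_seqs) == 0L) stop("empty development set")
  if (is.null(vocab)) {
    vocab <- build_ner_vocab(unlist(lapply(c(train_seqs, dev_seqs),
                                           `[[`, "tokens")))
  }
  model <- new_ner_model(model_cfg, vocab, word_vectors, seed)
  params <- model$params
  gold_dev <- lapply(dev_seqs, `[[`, "labels")
  dev_f1 <- function() {
    pred <- lapply(dev_seqs, function(s) ner_predict_labels(model, s$tokens))
    span_f1(pred, gold_dev)
  }
  best <- list(f1 = -1, snap = NULL, iteration = 0L)
  bad <- 0L
  history <- data.frame(iteration = integer(0), dev_f1 = numeric(0),
                        lr = numeric(0))
  n <- length(train_seqs)
  tc <- train_cfg
  for (it in seq_len(tc$max_iterations)) {
    lr <- tc$learning_rate * tc$decay^((it - 1L) %/% tc$checkpoint_every)
    batch <- sample.int(n, min(tc$batch_size, n), replace = n < tc$batch_size)
    for (b in batch) {
      s <- train_seqs[[b]]
      tape <- ad_tape()
      fwd <- ner_forward(tape, model, s$tokens)
      loss <- ad_mean_xent(tape, fwd$logits, match(s$labels, TAG_SET))
      ad_backward(tape, loss, seed = 1 / length(batch))
    }
    sgd_step(params, lr, clip = tc$grad_clip)
    if (it %% tc$checkpoint_every == 0L) {
      f1 <- dev_f1()
      history <- rbind(history, data.frame(iteration = it, dev_f1 = f1, lr = lr))
      if (f1 > best$f1 + 1e-9) {
        best <- list(f1 = f1, snap = params_snapshot(params), iteration = it)
        bad <- 0L
      } else {
        bad <- bad + 1L
      }
      if (!is.null(target_f1) && f1 >= target_f1) break
      if (bad >= tc$early_stop_patience) break
    }
  }
  if (!is.null(best$snap)) params_restore(params, best$snap)
  model$history <- history
  model$best_f1 <- max(best$f1, 0)
  model$train_cfg <- tc
  model
}

#' Train an NER ensemble
#'
#' Each member is trained with its own seed on an independent random
#' subset (`subset_fraction`, default 50%) of the sentences; the
#' complementary sentences are that member's development set. All members
#' share one vocabulary.
#'
#' @param sequences list of labeled sequences (>= 2).
#' @inheritParams train_ner
#' @return a `ner_ensemble` (list of `ner_model` members).
#' @export
train_ner_ensemble <- function(sequences,
                               model_cfg = ner_model_config(),
                               train_cfg = ner_train_config(),
                               seed = 1L, word_vectors = NULL,
                               target_f1 = NULL) {
  if (train_cfg$ensemble_size < 1L) stop("ensemble_size must be >= 1")
  n <- length(sequences)
  if (n < 2L) stop("need at least 2 sequences")
  n_sub <- max(1L, round(train_cfg$subset_fraction * n))
  if (n_sub >= n) {
    stop("subset_fraction leaves no held-out sentences for the development set; ",
         "reserve a dev fraction")
  }
  vocab <- build_ner_vocab(unlist(lapply(sequences, `[[`, "tokens")))
  members <- vector("list", train_cfg$ensemble_size)
  base <- (as.integer(seed) %% 1000000L) * 1000L
  for (k in seq_len(train_cfg$ensemble_size)) {
    member_seed <- base + k
    set.seed(member_seed)
    sub <- sample.int(n, n_sub)
    members[[k]] <- train_ner(sequences[sub], sequences[-sub],
                              model_cfg, train_cfg,
                              seed = member_seed,
                              word_vectors = word_vectors, vocab = vocab,
                              target_f1 = target_f1)
    members[[k]]$train_subset <- sub
  }
  structure(list(members = members, model_cfg = model_cfg,
                 train_cfg = train_cfg, seed = seed),
            class = "ner_ensemble")
}

#' @export
print.ner_ensemble <- function(x, ...) {
  cat("<ner_ensemble>", length(x$members), "members; best dev span-F1:",
      paste(round(vapply(x$members, `[[`, 1, "best_f1"), 3), collapse = " "),
      "\n")
  invisible(x)
}

#' Tag a document with an NER ensemble
#'
#' Per token, the members' 3-way tag distributions are averaged; the argmax
#' tag sequence is repaired to valid IOB1 and decoded to character spans.
#'
#' @param ensemble a `ner_ensemble` (or single `ner_model`).
#' @param doc a segmented `ppim_document`.
#' @return mention data frame with `provenance = "model"`.
#' @export
tag_document <- function(ensemble, doc) {
  members <- if (inherits(ensemble, "ner_model")) list(ensemble) else ensemble$members
  out <- empty_mentions()
  for (s in seq_len(nrow(doc$sentences))) {
    rows <- which(doc$tokens$sentence == s)
    if (!length(rows)) next
    toks <- vapply(rows, function(i) {
      slice_text(doc$full_text, doc$tokens$start[i], doc$tokens$end[i])
    }, character(1))
    probs <- Reduce(`+`, lapply(members, ner_sentence_probs, tokens = toks)) /
      length(members)
    labels <- repair_iob(TAG_SET[max.col(probs, ties.method = "first")])
    out <- rbind(out, decode_iob(labels, doc$tokens[rows, , drop = FALSE],
                                 doc$full_text, provenance = "model"))
  }
  out
}

## ---- lexicon post-processing ------------------------------------------------

#' Scan a document for lexicon gene names
#'
#' Greedy matching of lexicon names against the token sequence:
#' case-insensitive, anchored at token boundaries, longer matches
#' prioritized over shorter ones (by character length, then leftmost), and
#' candidates overlapping an existing mention span or a previously accepted
#' lexicon match are skipped.
#'
#' @param doc a segmented `ppim_document`.
#' @param lexicon named list: gene name -> character vector of gene IDs.
#' @param existing mention data frame of spans already claimed (e.g. the
#'   tagger's output).
#' @return mention data frame with `provenance = "lexicon"`.
#' @export
lexicon_scan <- function(doc, lexicon, existing = empty_mentions()) {
  stopifnot(all(nzchar(names(lexicon))))
  toks <- doc$tokens
  if (nrow(toks) == 0L || length(lexicon) == 0L) return(empty_mentions())
  tok_text <- tolower(vapply(seq_len(nrow(toks)), function(i) {
    slice_text(doc$full_text, toks$start[i], toks$end[i])
  }, character(1)))
  cand <- list()
  for (name in names(lexicon)) {
    ntoks <- tolower(tokenize_tokens(name))
    L <- length(ntoks)
    if (L == 0L) next
    for (i in seq_len(nrow(toks) - L + 1L)) {
      js <- i:(i + L - 1L)
      if (length(unique(toks$sentence[js])) != 1L) next
      if (!all(tok_text[js] == ntoks)) next
      cand[[length(cand) + 1L]] <- c(start = toks$start[i],
                                     end = toks$end[i + L - 1L])
    }
  }
  if (!length(cand)) return(empty_mentions())
  cd <- unique(do.call(rbind, cand))
  cd <- cd[order(-(cd[, "end"] - cd[, "start"]), cd[, "start"]), , drop = FALSE]
  taken <- existing[, c("start", "end"), drop = FALSE]
  out <- empty_mentions()
  for (r in seq_len(nrow(cd))) {
    s <- cd[r, "start"]; e <- cd[r, "end"]
    if (nrow(taken) && any(taken$start < e & taken$end > s)) next
    out <- rbind(out, make_mentions(s, e, slice_text(doc$full_text, s, e),
                                    "lexicon"))
    taken <- rbind(taken, data.frame(start = s, end = e))
  }
  out[order(out$start), , drop = FALSE]
}

# Token strings of a free-standing text (same tokenizer as documents).
tokenize_tokens <- function(text) {
  td <- tokenize_span(text)
  vapply(seq_len(nrow(td)), function(i) substr(text, td$start[i] + 1L, td$end[i]),
         character(1))
}

## ---- word vectors and checkpoints -------------------------------------------

#' Read word vectors in word2vec text format
#'
#' First line `count dim` (optional), then one `word v1 v2 ...` row per
#' word.
#'
#' @param path file path.
#' @return `list(words = <character>, mat = <matrix>)`.
#' @export
read_word_vectors <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) && grepl("^[0-9]+ [0-9]+$", lines[1L])) lines <- lines[-1L]
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  words <- vapply(parts, `[[`, character(1), 1L)
  mat <- do.call(rbind, lapply(parts, function(p) as.numeric(p[-1L])))
  list(words = words, mat = mat)
}

#' @rdname read_word_vectors
#' @param words character vector of words.
#' @param mat numeric matrix, one row per word.
#' @export
write_word_vectors <- function(words, mat, path) {
  lines <- c(paste(length(words), ncol(mat)),
             vapply(seq_along(words), function(i) {
               paste(words[i], paste(sprintf("%.8g", mat[i, ]), collapse = " "))
             }, character(1)))
  writeLines(lines, path)
}

#' Save / load a trained ensemble checkpoint
#'
#' The checkpoint directory is self-describing (configuration, vocabularies
#' and weights); loading never needs the training corpus.
#'
#' @param ensemble a `ner_ensemble` or `rc_ensemble`.
#' @param dir checkpoint directory (created if needed).
#' @export
save_ensemble <- function(ensemble, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cls <- class(ensemble)[1L]
  jsonlite::write_json(list(class = cls, members = length(ensemble$members)),
                       file.path(dir, "checkpoint.json"), auto_unbox = TRUE)
  saveRDS(ensemble, file.path(dir, "ensemble.rds"))
  invisible(dir)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(dir) {
  readRDS(file.path(dir, "ensemble.rds"))
}
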