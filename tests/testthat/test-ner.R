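# Unit tests for the tagger's building blocks; the learning behavior
# itself (memorization) is exercised in the acceptance suite.

tiny_ner_cfg <- function() {
  ner_model_config(char_emb_dim = 3L, char_type_emb_dim = 2L,
                   char_filters = 4L, word_emb_dim = 5L,
                   word_type_emb_dim = 2L, lstm_hidden = 4L)
}

tiny_ner_model <- function(words = c("GeneX", "binds", "it", "."), seed = 5L) {
  ppimx:::new_ner_model(tiny_ner_cfg(), ppimx:::build_ner_vocab(words),
                        seed = seed)
}

test_that("character and word shape classes are total and correct", {
  expect_equal(char_type("a"), "lowercase")
  expect_equal(char_type("A"), "uppercase")
  expect_equal(char_type("3"), "other")    # digits are none of the named classes
  expect_equal(char_type("-"), "punctuation")
  expect_equal(char_type(" "), "other")
  expect_equal(word_type("shank"), "all_lower")
  expect_equal(word_type("Shank"), "cap_first")
  expect_equal(word_type("SHANK3"), "all_upper")  # classified over letters only
  expect_equal(word_type("ShANK"), "mixed")
  expect_equal(word_type("123"), "other")
  expect_error(word_type(""), "empty")
})

test_that("char-CNN composition: zero weights give zero features and a
           single-window case matches hand computation", {
  m <- tiny_ner_model()
  for (p in m$params) p$value[] <- 0
  expect_equal(encode_word_chars(m, "abc"), rep(0, 4L))

  # 3-char word, window 3: one window; u_1 = ReLU(sum(W * B) + b)
  m2 <- tiny_ner_model(seed = 6L)
  v <- m2$vocab
  B <- do.call(rbind, lapply(c("a", "b", "c"), function(ch) {
    c(m2$params$E_char$value[v$chars[[ch]], ],
      m2$params$E_ctype$value[match(char_type(ch), ppimx:::CHAR_TYPES), ])
  }))
  u <- encode_word_chars(m2, "abc")
  for (j in 1:4) {
    W_j <- matrix(m2$params$W_char$value[, j], nrow = 3L, byrow = TRUE)
    expected <- max(0, sum(W_j * B) + m2$params$b_char$value[1L, j])
    expect_equal(u[j], expected, tolerance = 1e-10)
  }
  # short words are padded to the window length instead of failing
  expect_length(encode_word_chars(m2, "ab"), 4L)
  expect_length(encode_word_chars(m2, "a"), 4L)
})

test_that("context encoding has dimension 2*pi and vanishes at zero weights", {
  m <- tiny_ner_model()
  H <- encode_sequence(m, c("GeneX", "binds", "it"))
  expect_equal(dim(H), c(3L, 8L))
  for (p in m$params) p$value[] <- 0
  expect_equal(encode_sequence(m, c("GeneX", "binds")),
               matrix(0, 2L, 8L))
})

test_that("tag distribution is a proper softmax of the output layer", {
  m <- tiny_ner_model()
  h0 <- rep(0, 8L)
  m$params$b_out$value[] <- 0
  expect_equal(as.numeric(token_distribution(m, h0)), rep(1 / 3, 3L))
  m$params$b_out$value[] <- c(1, 2, 3)
  p <- as.numeric(token_distribution(m, h0))
  expect_equal(p, exp(1:3) / sum(exp(1:3)), tolerance = 1e-9)
  expect_equal(round(p, 4L), c(0.0900, 0.2447, 0.6652))
  set.seed(8)
  pr <- token_distribution(m, matrix(rnorm(16), 2L))
  expect_equal(rowSums(pr), c(1, 1))
  expect_true(all(pr > 0))
})

test_that("sequence loss is mean cross-entropy with the expected values", {
  y <- diag(3L)
  expect_equal(sequence_loss(y, y), 0, tolerance = 1e-9)
  unif <- matrix(1 / 3, 4L, 3L)
  expect_equal(sequence_loss(unif, c(1L, 3L, 2L, 1L)), log(3), tolerance = 1e-12)
  p <- rbind(c(0.5, 0.25, 0.25), c(0.1, 0.8, 0.1))
  expect_equal(sequence_loss(p, c(1L, 2L)), (-log(0.5) - log(0.8)) / 2,
               tolerance = 1e-12)
  expect_equal(round(sequence_loss(p, c(1L, 2L)), 4L), 0.4581)
})

test_that("training is reproducible and respects the patience arithmetic", {
  seqs <- memorization_sequences(8L)
  mcfg <- tiny_ner_cfg()
  tcfg <- ner_train_config(learning_rate = 0.2, max_iterations = 30L,
                           batch_size = 4L, checkpoint_every = 10L,
                           early_stop_patience = 2L)
  m1 <- train_ner(seqs[1:6], seqs[7:8], mcfg, tcfg, seed = 21L)
  m2 <- train_ner(seqs[1:6], seqs[7:8], mcfg, tcfg, seed = 21L)
  expect_identical(lapply(m1$params, function(p) p$value),
                   lapply(m2$params, function(p) p$value))
  expect_identical(m1$history, m2$history)
  p1 <- lapply(seqs, function(s) ppimx:::ner_predict_labels(m1, s$tokens))
  p2 <- lapply(seqs, function(s) ppimx:::ner_predict_labels(m2, s$tokens))
  expect_identical(p1, p2)

  # zero learning rate freezes dev F1, so early stopping fires after
  # (1 + patience) checkpoints
  tcfg0 <- ner_train_config(learning_rate = 0, max_iterations = 1000L,
                            batch_size = 4L, checkpoint_every = 5L,
                            early_stop_patience = 3L)
  m0 <- train_ner(seqs[1:6], seqs[7:8], tiny_ner_cfg(), tcfg0, seed = 4L)
  expect_equal(nrow(m0$history), 4L)
  expect_equal(max(m0$history$iteration), 4L * 5L)
  expect_equal(length(unique(m0$history$dev_f1)), 1L)

  expect_error(train_ner(seqs[1:6], list(), mcfg, tcfg, seed = 1L),
               "development")
})

test_that("ensemble members train on distinct subsets and tagging averages
           member distributions", {
  seqs <- memorization_sequences(10L)
  mcfg <- tiny_ner_cfg()
  tcfg <- ner_train_config(learning_rate = 0.2, max_iterations = 20L,
                           batch_size = 4L, checkpoint_every = 10L,
                           ensemble_size = 2L, subset_fraction = 0.5)
  ens <- train_ner_ensemble(seqs, mcfg, tcfg, seed = 3L)
  expect_length(ens$members, 2L)
  expect_false(identical(ens$members[[1L]]$train_subset,
                         ens$members[[2L]]$train_subset))
  expect_identical(ens$members[[1L]]$vocab, ens$members[[2L]]$vocab)

  # subset_fraction = 1 leaves no dev set
  expect_error(train_ner_ensemble(seqs, mcfg,
                                  ner_train_config(subset_fraction = 1,
                                                   ensemble_size = 1L),
                                  seed = 1L),
               "dev")

  doc <- generate_fixture_bundle(
    fixture_config(n_articles = 4L, seed = 2L))$corpus$train$documents[[1L]]
  got <- tag_document(ens, doc)
  # brute-force oracle: average per-token distributions, argmax, repair,
  # decode, per sentence
  oracle <- ppimx:::empty_mentions()
  for (s in seq_len(nrow(doc$sentences))) {
    rows <- which(doc$tokens$sentence == s)
    toks <- vapply(rows, function(i) {
      substr(doc$full_text, doc$tokens$start[i] + 1L, doc$tokens$end[i])
    }, character(1))
    pr <- (ppimx:::ner_sentence_probs(ens$members[[1L]], toks) +
             ppimx:::ner_sentence_probs(ens$members[[2L]], toks)) / 2
    labels <- repair_iob(ppimx:::TAG_SET[max.col(pr, ties.method = "first")])
    oracle <- rbind(oracle, decode_iob(labels, doc$tokens[rows, , drop = FALSE],
                                       doc$full_text, "model"))
  }
  expect_equal(got, oracle)
  # all members agreeing reduces to any single member
  ens1 <- ens; ens1$members <- ens$members[c(1L, 1L)]
  expect_equal(tag_document(ens1, doc), tag_document(ens$members[[1L]], doc))
})

test_that("lexicon scan is leftmost-longest, boundary-anchored and skips
           overlaps with existing spans", {
  doc <- ppim_document("1", "Sharpin studies.",
                       "Shank3 binds Sharpin. A Shank protein too.")
  lex <- list(Sharpin = "64763", Shank = "50944", Shank3 = "85358")
  hits <- lexicon_scan(doc, lex)
  # "Shank3" matched as a whole, not its prefix "Shank"
  expect_true("Shank3" %in% hits$text)
  expect_false(any(hits$text == "Shank" & hits$start == 17L))
  expect_equal(sort(unique(hits$text)), c("Shank", "Shank3", "Sharpin"))
  expect_true(all(hits$provenance == "lexicon"))
  # spans already claimed by the tagger are skipped
  existing <- ppimx:::make_mentions(17L, 23L, "Shank3", "model")
  hits2 <- lexicon_scan(doc, lex, existing)
  expect_false(any(hits2$start < 23L & hits2$end > 17L))
  # matching is case-insensitive and token-anchored (no match inside a token)
  doc2 <- ppim_document("2", "T.", "SHARPIN and notSharpinword.")
  hits3 <- lexicon_scan(doc2, lex)
  expect_equal(hits3$text, "SHARPIN")
})

test_that("lexicon scan equals the brute-force leftmost-longest oracle", {
  set.seed(77)
  vocab_words <- c("alpha", "beta", "binds", "the", "protein", "complex")
  lex_names <- c("Abc1", "DEF2", "Abc1 DEF2", "ghi", "kLm9")
  for (rep in 1:60) {
    words <- sample(c(vocab_words, lex_names), sample(4:12, 1L), replace = TRUE)
    doc <- ppim_document(as.character(rep), "T.",
                         paste0(paste(words, collapse = " "), "."))
    lex <- stats::setNames(as.list(as.character(seq_along(lex_names))),
                           lex_names)
    n_ex <- sample(0:1, 1L)
    existing <- if (n_ex && nrow(doc$tokens) > 2L) {
      i <- sample(nrow(doc$tokens) - 1L, 1L)
      ppimx:::make_mentions(doc$tokens$start[i], doc$tokens$end[i], "x", "model")
    } else ppimx:::empty_mentions()
    got <- lexicon_scan(doc, lex, existing)
    want <- oracle_lexicon(doc, lex, existing)
    expect_equal(got[, c("start", "end")],
                 as.data.frame(want)[, c("start", "end")],
                 ignore_attr = TRUE)
  }
})

test_that("word vectors round-trip and seed the embedding rows", {
  path <- withr::local_tempfile(fileext = ".txt")
  words <- c("genex", "binds")
  mat <- matrix(c(0.1, -0.2, 0.3, 0.4, 0.5, -0.6), 2L, byrow = TRUE)
  write_word_vectors(words, mat, path)
  got <- read_word_vectors(path)
  expect_equal(got$words, words)
  expect_equal(got$mat, mat, ignore_attr = TRUE)
  cfg <- ner_model_config(char_emb_dim = 3L, char_type_emb_dim = 2L,
                          char_filters = 4L, word_emb_dim = 3L,
                          word_type_emb_dim = 2L, lstm_hidden = 4L)
  vocab <- ppimx:::build_ner_vocab(c("GeneX", "binds", "it"))
  model <- ppimx:::new_ner_model(cfg, vocab, word_vectors = got, seed = 2L)
  expect_equal(model$params$E_word$value[vocab$words[["genex"]], ],
               mat[1L, ], ignore_attr = TRUE)
})

test_that("ensemble checkpoints are self-contained on disk", {
  seqs <- memorization_sequences(6L)
  tcfg <- ner_train_config(learning_rate = 0.2, max_iterations = 10L,
                           batch_size = 4L, checkpoint_every = 5L,
                           ensemble_size = 1L, subset_fraction = 0.5)
  ens <- train_ner_ensemble(seqs, tiny_ner_cfg(), tcfg, seed = 2L)
  dir <- withr::local_tempdir()
  save_ensemble(ens, dir)
  back <- load_ensemble(dir)
  doc <- generate_fixture_bundle(
    fixture_config(n_articles = 3L, seed = 6L))$corpus$train$documents[[1L]]
  expect_equal(tag_document(back, doc), tag_document(ens, doc))
})
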