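# Instance generation, the CNN forward pass, training contracts and the
# pair decision rule.

rc_demo_doc <- function(ids = c("1", "2", "3")) {
  nm <- c("Aaa1", "Bbb2", "Ccc3", "Ddd4", "Eee5", "Fff6")[seq_along(ids)]
  body <- paste(paste(nm, collapse = " binds "), ", and more text follows .")
  doc <- ppim_document("42", "A title .", body)
  mlist <- gregexpr(paste(nm, collapse = "|"), doc$full_text)
  pos <- mlist[[1L]]
  texts <- regmatches(doc$full_text, mlist)[[1L]]
  mentions <- ppimx:::make_mentions(
    as.integer(pos) - 1L, as.integer(pos) - 1L + attr(pos, "match.length"),
    texts, "model", ids[match(texts, nm)])
  list(doc = doc, mentions = mentions, names = nm)
}

test_that("instance generation produces |G|^2 blinded instances with the
           right placeholder tokens", {
  for (g in 1:6) {
    ids <- as.character(seq_len(g))
    dm <- rc_demo_doc(ids)
    inst <- generate_instances(dm$doc, dm$mentions)
    expect_length(inst, g^2)
    n_self <- sum(vapply(inst, `[[`, TRUE, "self"))
    expect_equal(n_self, g)
    # no candidate surface string survives in any instance
    toks <- unlist(lapply(inst, function(i) unlist(i$sentences)))
    expect_false(any(tolower(dm$names[seq_len(g)]) %in% tolower(toks)))
    for (i in inst) {
      flat <- unlist(i$sentences)
      if (i$self) {
        expect_true("GENE_S" %in% flat)
        expect_false(any(c("GENE_A", "GENE_B") %in% flat))
      } else {
        expect_true(all(c("GENE_A", "GENE_B") %in% flat))
      }
    }
  }
  # mentions of third candidates become GENE_N in the (A,B) instance
  dm <- rc_demo_doc(c("1", "2", "3"))
  inst <- generate_instances(dm$doc, dm$mentions)
  ab <- Filter(function(i) i$id_a == "1" && i$id_b == "2", inst)[[1L]]
  expect_true("GENE_N" %in% unlist(ab$sentences))
  # empty candidate set -> no instances
  expect_length(generate_instances(dm$doc, ppimx:::empty_mentions()), 0L)
})

test_that("labels are assigned order-insensitively from gold pairs", {
  dm <- rc_demo_doc(c("1", "2"))
  gold <- data.frame(id1 = "2", id2 = "1", stringsAsFactors = FALSE)
  inst <- generate_instances(dm$doc, dm$mentions, gold)
  labs <- vapply(inst, function(i) {
    paste(i$id_a, i$id_b, i$label, sep = "/")
  }, character(1))
  expect_setequal(labs, c("1/2/1", "2/1/1", "1/1/0", "2/2/0"))
})

test_that("forward pass: zero weights give probability one-half and the
           tiny fixed-weight case matches a hand computation", {
  cfg <- rc_model_config(windows = c(3L, 4L, 5L), n_filters = 1L,
                         word_emb_dim = 2L, dropout = 0, pad = 4L)
  inst <- structure(list(pmid = "1", id_a = "A", id_b = "A", self = TRUE,
                         label = NA_integer_,
                         sentences = list(c("GENE_S", "acts"))),
                    class = "rc_instance")
  vocab <- ppimx:::build_rc_vocab(list(inst))
  model <- ppimx:::new_rc_model(cfg, vocab, seed = 1L)
  for (p in model$params) p$value[] <- 0
  expect_equal(rc_forward(model, inst), 0.5)

  # fixed small weights; padded length = 4 + 2 + 4 = 10
  model$params$E$value[] <- 0
  model$params$E$value[vocab[["GENE_S"]], ] <- c(1, -1)
  model$params$E$value[vocab[["acts"]], ] <- c(0.5, 2)
  for (w in c(3L, 4L, 5L)) {
    model$params[[paste0("W", w)]]$value[] <- seq(0.1, by = 0.1,
                                                  length.out = w * 2L)
    model$params[[paste0("b", w)]]$value[] <- 0.05
  }
  model$params$W_dense$value[] <- c(0.3, -0.2, 0.1, 0.4, -0.5, 0.6)
  model$params$b_dense$value[] <- c(0.01, -0.02)
  # independent hand computation with plain loops
  ids <- ppimx:::rc_token_ids(model, inst)
  E <- model$params$E$value
  X <- E[ids, , drop = FALSE]
  feat <- numeric(0)
  for (w in c(3L, 4L, 5L)) {
    Wf <- model$params[[paste0("W", w)]]$value
    best <- -Inf
    for (j in seq_len(nrow(X) - w + 1L)) {
      # windows are concatenated row-blocks: (row j, row j+1, ...)
      win <- as.numeric(do.call(cbind, lapply(0:(w - 1L), function(k) {
        X[j + k, , drop = FALSE]
      })))
      v <- max(0, sum(win * Wf[, 1L]) + 0.05)
      best <- max(best, v)
    }
    feat <- c(feat, best)
  }
  q <- as.numeric(feat %*% model$params$W_dense$value) + c(0.01, -0.02)
  want <- exp(q[2L] - max(q)) / sum(exp(q - max(q)))
  expect_equal(rc_forward(model, inst), want, tolerance = 1e-10)
})

test_that("padding arithmetic gives feature maps of length L - w + 1", {
  cfg <- rc_model_config(n_filters = 2L, word_emb_dim = 3L, dropout = 0,
                         pad = 4L)
  inst <- structure(list(pmid = "1", id_a = "A", id_b = "A", self = TRUE,
                         label = NA_integer_, sentences = list("GENE_S")),
                    class = "rc_instance")
  vocab <- ppimx:::build_rc_vocab(list(inst))
  model <- ppimx:::new_rc_model(cfg, vocab, seed = 1L)
  ids <- ppimx:::rc_token_ids(model, inst)
  expect_length(ids, 9L)  # 4 + 1 + 4
  for (w in c(3L, 4L, 5L)) {
    tape <- ppimx:::ad_tape()
    X <- ppimx:::ad_embed(tape, model$params$E, ids)
    cp <- ppimx:::ad_conv_pool(tape, X, 1L, 9L, model$params[[paste0("W", w)]],
                               model$params[[paste0("b", w)]], w)
    expect_equal(dim(cp$val), c(1L, 2L))
  }
  # the window count itself: L - w + 1 = 7, 6, 5
  expect_equal(vapply(c(3L, 4L, 5L), function(w) 9L - w + 1L, 1L), c(7L, 6L, 5L))
})

test_that("training is seed-reproducible, rejects single-class data and
           gives members distinct splits", {
  fb <- generate_fixture_bundle(fixture_config(n_articles = 14L, seed = 23L))
  inst <- corpus_rc_instances(fb$corpus$train)
  mcfg <- rc_model_config(n_filters = 4L, word_emb_dim = 8L)
  tcfg <- rc_train_config(epochs = 2L, ensemble_size = 2L)
  m1 <- train_rc(inst[1:30], inst[31:40], mcfg, tcfg, seed = 3L)
  m2 <- train_rc(inst[1:30], inst[31:40], mcfg, tcfg, seed = 3L)
  expect_identical(m1$history, m2$history)
  expect_identical(lapply(m1$params, function(p) p$value),
                   lapply(m2$params, function(p) p$value))

  pos_only <- Filter(function(i) i$label == 1L, inst)
  expect_error(train_rc(pos_only, inst[1:4], mcfg, tcfg, seed = 1L),
               "both positive and negative")

  ens <- train_rc_ensemble(inst, mcfg, tcfg, seed = 9L)
  expect_length(ens$members, 2L)
  expect_false(identical(sort(ens$members[[1L]]$dev_pmids),
                         sort(ens$members[[2L]]$dev_pmids)))
})

test_that("pair scores are symmetric and equal the brute-force mean over
           members and orders", {
  fb <- generate_fixture_bundle(fixture_config(n_articles = 14L, seed = 24L))
  inst_all <- corpus_rc_instances(fb$corpus$train)
  mcfg <- rc_model_config(n_filters = 4L, word_emb_dim = 8L)
  tcfg <- rc_train_config(epochs = 1L, ensemble_size = 2L)
  ens <- train_rc_ensemble(inst_all, mcfg, tcfg, seed = 5L)
  pm <- names(fb$corpus$train$documents)[1L]
  doc <- fb$corpus$train$documents[[pm]]
  mentions <- fb$corpus$train$mentions[[pm]]
  inst <- generate_instances(doc, mentions, config = mcfg)
  ids <- sort(unique(mentions$gene_id))
  a <- ids[1L]; b <- ids[min(2L, length(ids))]
  s1 <- score_pair(ens, inst, c(a, b))
  s2 <- score_pair(ens, inst, c(b, a))
  expect_equal(s1, s2)
  sel <- Filter(function(i) setequal(c(i$id_a, i$id_b), c(a, b)), inst)
  brute <- mean(unlist(lapply(sel, function(i) {
    vapply(ens$members, rc_forward, numeric(1), instance = i)
  })))
  expect_equal(s1, brute, tolerance = 1e-12)
  expect_error(score_pair(ens, inst, c("no", "pe")), "not in the candidate")
})

test_that("the pair decision rule thresholds at strictly 0.5 with an
           argmax fallback and deterministic tie-break", {
  sc <- function(...) {
    df <- rbind(...)
    data.frame(id1 = df[, 1L], id2 = df[, 2L],
               score = as.numeric(df[, 3L]), stringsAsFactors = FALSE)
  }
  # above-threshold pairs only
  got <- decide_pairs(sc(c("A", "B", 0.7), c("A", "C", 0.2)))
  expect_equal(got, data.frame(id1 = "A", id2 = "B", stringsAsFactors = FALSE))
  # none above: argmax fallback even below 0.5
  got <- decide_pairs(sc(c("A", "B", 0.4), c("A", "C", 0.3)))
  expect_equal(got, data.frame(id1 = "A", id2 = "B", stringsAsFactors = FALSE))
  # exactly 0.5 is not positive, but wins the fallback as the max
  got <- decide_pairs(sc(c("A", "B", 0.5), c("A", "C", 0.2)))
  expect_equal(got, data.frame(id1 = "A", id2 = "B", stringsAsFactors = FALSE))
  # tie broken by lexicographically smallest canonical pair
  got <- decide_pairs(sc(c("B", "A", 0.3), c("C", "A", 0.3)))
  expect_equal(got, data.frame(id1 = "A", id2 = "B", stringsAsFactors = FALSE))
  expect_equal(nrow(decide_pairs(NULL)), 0L)
  # two pairs above threshold are both kept
  got <- decide_pairs(sc(c("A", "B", 0.7), c("A", "C", 0.6), c("B", "C", 0.1)))
  expect_equal(nrow(got), 2L)
})

test_that("prediction returns at least one pair whenever candidates exist", {
  fb <- generate_fixture_bundle(fixture_config(n_articles = 14L, seed = 25L))
  inst_all <- corpus_rc_instances(fb$corpus$train)
  mcfg <- rc_model_config(n_filters = 4L, word_emb_dim = 8L)
  ens <- train_rc_ensemble(inst_all, mcfg,
                           rc_train_config(epochs = 1L, ensemble_size = 1L),
                           seed = 2L)
  for (pm in names(fb$corpus$dev$documents)) {
    doc <- fb$corpus$dev$documents[[pm]]
    mentions <- fb$corpus$dev$mentions[[pm]]
    got <- predict_pairs(ens, doc, mentions)
    expect_gte(nrow(got), 1L)
    expect_true(all(got$id1 <= got$id2))
  }
  # no candidates -> empty prediction
  doc0 <- fb$corpus$dev$documents[[1L]]
  expect_equal(nrow(predict_pairs(ens, doc0, ppimx:::empty_mentions())), 0L)
})
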