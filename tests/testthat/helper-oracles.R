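# Independent brute-force oracles and small shared fixtures. These are
# deliberately naive re-implementations kept free of the package's own
# code paths, so tests compare two independent routes to the same answer.

# Enumerate gene spans from an IOB1 label vector by scanning every
# position (quadratic, unlike the package's linear decoder).
oracle_spans <- function(labels) {
  n <- length(labels)
  spans <- character(0)
  i <- 1L
  while (i <= n) {
    if (labels[i] %in% c("I-GENE", "B-GENE")) {
      j <- i
      while (j < n && labels[j + 1L] == "I-GENE") j <- j + 1L
      spans <- c(spans, paste0(i, ":", j))
      i <- j + 1L
    } else i <- i + 1L
  }
  spans
}

# Random valid IOB1 labeling of length n: random non-overlapping spans;
# adjacent spans produce the I,B boundary.
random_iob <- function(n) {
  labels <- rep("O", n)
  i <- 1L
  prev_gene_end <- -1L
  while (i <= n) {
    if (stats::runif(1) < 0.4) {
      len <- sample(1:min(3L, n - i + 1L), 1L)
      labels[i] <- if (i - 1L == prev_gene_end) "B-GENE" else "I-GENE"
      if (len > 1L) labels[(i + 1L):(i + len - 1L)] <- "I-GENE"
      prev_gene_end <- i + len - 1L
      i <- i + len
    } else {
      i <- i + 1L
      # a gap breaks adjacency
    }
  }
  labels
}

# Brute-force micro/macro scorer over per-document pair sets given as
# named lists of data.frames (id1, id2). Canonicalization is re-derived
# here from scratch.
oracle_keys <- function(pairs, hmap) {
  if (is.null(pairs) || nrow(pairs) == 0L) return(character(0))
  ks <- character(0)
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$id1[i]; b <- pairs$id2[i]
    if (!is.null(hmap)) {
      if (!is.na(hmap[a])) a <- unname(hmap[a])
      if (!is.na(hmap[b])) b <- unname(hmap[b])
    }
    ks <- c(ks, paste(sort(c(a, b)), collapse = "+"))
  }
  unique(ks)
}

oracle_micro <- function(gold, pred, hmap = NULL) {
  tp <- fp <- fn <- 0L
  for (pm in names(gold)) {
    g <- oracle_keys(gold[[pm]], hmap); p <- oracle_keys(pred[[pm]], hmap)
    tp <- tp + sum(p %in% g); fp <- fp + sum(!(p %in% g))
    fn <- fn + sum(!(g %in% p))
  }
  P <- if (tp + fp > 0) tp / (tp + fp) else 0
  R <- if (tp + fn > 0) tp / (tp + fn) else 0
  F1 <- if (P + R > 0) 2 * P * R / (P + R) else 0
  list(P = P, R = R, F1 = F1)
}

oracle_macro <- function(gold, pred, hmap = NULL) {
  Ps <- Rs <- Fs <- numeric(0)
  for (pm in names(gold)) {
    g <- oracle_keys(gold[[pm]], hmap); p <- oracle_keys(pred[[pm]], hmap)
    if (length(g) == 0L && length(p) == 0L) {
      P <- R <- F1 <- 1
    } else {
      tp <- sum(p %in% g)
      P <- if (length(p) > 0) tp / length(p) else 0
      R <- if (length(g) > 0) tp / length(g) else 0
      F1 <- if (P + R > 0) 2 * P * R / (P + R) else 0
    }
    Ps <- c(Ps, P); Rs <- c(Rs, R); Fs <- c(Fs, F1)
  }
  list(P = mean(Ps), R = mean(Rs), F1 = mean(Fs))
}

# Random per-document pair-set configurations for scorer comparisons.
random_pair_config <- function(n_docs, ids = as.character(1:8)) {
  gold <- list(); pred <- list()
  for (d in seq_len(n_docs)) {
    pm <- paste0("pm", d)
    rpairs <- function(k) {
      if (k == 0L) return(data.frame(id1 = character(0), id2 = character(0),
                                     stringsAsFactors = FALSE))
      data.frame(id1 = sample(ids, k, replace = TRUE),
                 id2 = sample(ids, k, replace = TRUE),
                 stringsAsFactors = FALSE)
    }
    gold[[pm]] <- rpairs(sample(0:3, 1L))
    pred[[pm]] <- rpairs(sample(0:3, 1L))
  }
  list(gold = gold, pred = pred)
}

random_homolog_map <- function(ids) {
  grouped <- sample(ids, length(ids) %/% 2L)
  if (!length(grouped)) return(NULL)
  stats::setNames(paste0("H", sample(1:3, length(grouped), replace = TRUE)),
                  grouped)
}

# Leftmost-longest lexicon matching oracle: enumerate every token-aligned
# substring, keep those in the lexicon (case-insensitive), sort by
# (char length desc, start asc), greedily accept non-overlapping.
oracle_lexicon <- function(doc, lexicon, existing) {
  toks <- doc$tokens
  names_lc <- tolower(names(lexicon))
  cand <- list()
  for (i in seq_len(nrow(toks))) {
    for (j in i:nrow(toks)) {
      if (toks$sentence[i] != toks$sentence[j]) break
      txt <- substr(doc$full_text, toks$start[i] + 1L, toks$end[j])
      # collapse whitespace the way the package tokenizer sees the name
      norm <- tolower(paste(unlist(regmatches(txt,
        gregexpr("[A-Za-z0-9]+|[^A-Za-z0-9[:space:]]", txt))), collapse = " "))
      hit <- FALSE
      for (nm in names_lc) {
        nmt <- tolower(paste(unlist(regmatches(nm,
          gregexpr("[A-Za-z0-9]+|[^A-Za-z0-9[:space:]]", nm))), collapse = " "))
        if (nmt == norm) { hit <- TRUE; break }
      }
      if (hit) {
        cand[[length(cand) + 1L]] <- c(start = toks$start[i], end = toks$end[j])
      }
    }
  }
  if (!length(cand)) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  cd <- unique(do.call(rbind, cand))
  cd <- cd[order(-(cd[, "end"] - cd[, "start"]), cd[, "start"]), , drop = FALSE]
  taken <- existing[, c("start", "end"), drop = FALSE]
  keep <- list()
  for (r in seq_len(nrow(cd))) {
    s <- cd[r, "start"]; e <- cd[r, "end"]
    if (nrow(taken) && any(taken$start < e & taken$end > s)) next
    keep[[length(keep) + 1L]] <- c(start = unname(s), end = unname(e))
    taken <- rbind(taken, data.frame(start = unname(s), end = unname(e)))
  }
  if (!length(keep)) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  out <- as.data.frame(do.call(rbind, keep))
  out[order(out$start), , drop = FALSE]
}

# Canonical-form two-document corpus used by round-trip tests.
tiny_pubtator_text <- function() {
  paste0(
    "7|t|AB.\n",
    "7|a|p53 binds MDM2.\n",
    "7\t4\t7\tp53\tGene\t7157\n",
    "7\t14\t18\tMDM2\tGene\t4193\n",
    "7\tPPIm\t4193\t7157\n",
    "\n",
    "8|t|A title only document.\n",
    "8|a|\n",
    "\n")
}

# Small labeled corpus for quick NER checks: reduced fixture sentences.
memorization_sequences <- function(n = 20L, seed = 11L) {
  fb <- generate_fixture_bundle(fixture_config(n_articles = 10L, seed = seed))
  labeled_sequences(fb$corpus$train)[seq_len(n)]
}

# Reduced model/training configurations used by the learning tests.
reduced_ner_model_cfg <- function() {
  ner_model_config(char_filters = 20L, lstm_hidden = 50L,
                   word_emb_dim = 50L, word_type_emb_dim = 8L)
}

reduced_ner_train_cfg <- function(max_iterations = 500L, ...) {
  ner_train_config(learning_rate = 0.5, max_iterations = max_iterations,
                   batch_size = 20L, checkpoint_every = 50L, ...)
}

reduced_rc_model_cfg <- function() {
  rc_model_config(n_filters = 32L, word_emb_dim = 32L)
}

# Labeled RC instances for a whole corpus (oracle mention IDs).
corpus_rc_instances <- function(corpus, config = reduced_rc_model_cfg()) {
  out <- list()
  for (pm in names(corpus$documents)) {
    out <- c(out, generate_instances(corpus$documents[[pm]],
                                     corpus$mentions[[pm]],
                                     corpus$pairs[[pm]], config = config))
  }
  out
}

# Majority vote over per-seed pass/fail runs; stops as soon as the
# majority is decided.
majority_pass <- function(seeds, run_one) {
  passes <- 0L; fails <- 0L
  need <- length(seeds) %/% 2L + 1L
  for (s in seeds) {
    if (isTRUE(run_one(s))) passes <- passes + 1L else fails <- fails + 1L
    if (passes >= need || fails >= need) break
  }
  passes > fails
}

# Finite-difference gradient check on randomly probed parameter entries.
gradient_check <- function(params, loss_fn, n_probe = 4L, eps = 1e-5) {
  r <- loss_fn()
  ad_backward <- get("ad_backward", envir = asNamespace("ppimx"))
  ad_backward(r$tape, r$loss)
  worst <- 0
  for (nm in names(params)) {
    p <- params[[nm]]
    for (k in seq_len(n_probe)) {
      i <- sample(length(p$value), 1L)
      g <- p$grad[i]
      old <- p$value[i]
      p$value[i] <- old + eps
      lp <- loss_fn()$loss$val[1L, 1L]
      p$value[i] <- old - eps
      lm <- loss_fn()$loss$val[1L, 1L]
      p$value[i] <- old
      num <- (lp - lm) / (2 * eps)
      if (abs(num - g) > 1e-6) {
        worst <- max(worst, abs(num - g) / max(1e-8, abs(num) + abs(g)))
      }
    }
    p$grad[] <- 0
  }
  worst
}
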