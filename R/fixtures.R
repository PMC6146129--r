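# Deterministic synthetic fixtures.
#
# Generates annotated corpora, a consistent knowledge bundle, a lexicon, a
# homology map and word vectors with the statistical structure the
# pipeline assumes: every article has at least one gold pair; positive
# pairs co-occur with an interaction cue phrase and a mutation phrase
# (sometimes across sentence bounds); negative co-mentions lack cues; gene
# names mix case/digit shapes so the character-level features of the
# tagger have signal; a configurable share of gene names is plain
# lowercase and appears only in test articles, so only the lexicon
# post-processor can recover them. Sentences are templated natural-ish
# prose rather than token soup so both the tagger (shape cues) and the
# relation classifier (lexical cues) are learnable at tiny scale.

#' Fixture generator configuration
#'
#' @param n_articles number of articles to generate.
#' @param n_genes gene inventory size.
#' @param p_cross_sentence fraction of non-self gold pairs expressed across
#'   two sentences.
#' @param p_self fraction of gold pairs that are self-interactions.
#' @param p_second_pair probability an article carries a second gold pair.
#' @param homolog_confuser_rate fraction of genes whose name also maps to a
#'   second gene ID of the same homology group (species confusers).
#' @param lexicon_only_rate fraction of genes given plain lowercase names
#'   and restricted to test articles (recoverable only via the lexicon).
#' @param p_distractor probability an article carries a cue-free
#'   distractor sentence mentioning extra genes.
#' @param split train/dev/test article fractions (sums to 1).
#' @param word_vec_dim dimension of the emitted random word vectors.
#' @param seed integer seed fixing every random draw.
#' @return list of class `fixture_config`.
#' @export
fixture_config <- function(n_articles = 50L, n_genes = 20L,
                           p_cross_sentence = 0.25, p_self = 0.1,
                           p_second_pair = 0.3,
                           homolog_confuser_rate = 0.15,
                           lexicon_only_rate = 0.1,
                           p_distractor = 0.5,
                           split = c(train = 0.6, dev = 0.2, test = 0.2),
                           word_vec_dim = 50L, seed = 1L) {
  fr <- c(p_cross_sentence, p_self, p_second_pair, homolog_confuser_rate,
          lexicon_only_rate, p_distractor)
  stopifnot(all(fr >= 0 & fr <= 1), abs(sum(split) - 1) < 1e-9)
  if (n_genes < 2L && p_self < 1) {
    stop("gene inventory of size < 2 requires p_self = 1")
  }
  structure(list(n_articles = as.integer(n_articles),
                 n_genes = as.integer(n_genes),
                 p_cross_sentence = p_cross_sentence, p_self = p_self,
                 p_second_pair = p_second_pair,
                 homolog_confuser_rate = homolog_confuser_rate,
                 lexicon_only_rate = lexicon_only_rate,
                 p_distractor = p_distractor, split = split,
                 word_vec_dim = as.integer(word_vec_dim),
                 seed = as.integer(seed)),
            class = "fixture_config")
}

# Gene inventory: names mixing case/digit shapes. Lexicon-only genes get
# plain lowercase names (no shape cue for the tagger); confusers get a
# sibling ID sharing the name and the homology group.
fixture_genes <- function(cfg) {
  n <- cfg$n_genes
  cons <- strsplit("bcdfgklmnprstvz", "")[[1L]]
  vows <- strsplit("aeiou", "")[[1L]]
  syll <- function() paste0(sample(cons, 1L), sample(vows, 1L))
  names_seen <- character(0)
  fresh_name <- function(maker) {
    repeat {
      nm <- maker()
      if (!(tolower(nm) %in% tolower(names_seen))) {
        names_seen <<- c(names_seen, nm)
        return(nm)
      }
    }
  }
  n_lex <- round(cfg$lexicon_only_rate * n)
  rows <- list()
  for (i in seq_len(n)) {
    lex_only <- i <= n_lex
    shape <- i %% 3L
    nm <- if (lex_only) {
      fresh_name(function() paste0(syll(), syll(), syll()))
    } else if (shape == 0L) {
      fresh_name(function() paste0(toupper(sample(cons, 1L)), syll(),
                                   sample(1:9, 1L)))
    } else if (shape == 1L) {
      fresh_name(function() paste0(toupper(paste0(sample(cons, 2L), collapse = "")),
                                   toupper(sample(vows, 1L)), sample(1:9, 1L)))
    } else {
      fresh_name(function() paste0(syll(), sample(cons, 1L), "-", sample(1:9, 1L)))
    }
    rows[[i]] <- data.frame(id = as.character(1000L + i), name = nm,
                            lexicon_only = lex_only,
                            confuser = FALSE, sibling_id = NA_character_,
                            group = NA_character_, stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, rows)
  n_conf <- round(cfg$homolog_confuser_rate * n)
  if (n_conf > 0L) {
    conf <- sample(which(!genes$lexicon_only), min(n_conf, sum(!genes$lexicon_only)))
    genes$confuser[conf] <- TRUE
    genes$sibling_id[conf] <- paste0("9", genes$id[conf])
    genes$group[conf] <- paste0("HG", genes$id[conf])
  }
  genes
}

CUE_PHRASES <- c("interacts with", "binds directly to",
                 "forms a stable complex with", "promotes sumoylation of")
MUT_PHRASES <- c("a missense mutation in", "the truncating variant of",
                 "a germline mutation affecting")
FILLER_SENTENCES <- c(
  "These findings suggest a role in disease progression .",
  "Samples were processed using standard protocols .",
  "The clinical relevance of this pathway remains under investigation .")

# A sentence is a list of elements; each element is list(text, id) where id
# is NA for plain words and a gene ID for a mention of that gene.
fx_w <- function(text) list(text = text, id = NA_character_)

# length-safe sample: always treats `x` as the candidate set
sample_from <- function(x, size) x[sample.int(length(x), size)]
fx_g <- function(gene_row) list(text = gene_row$name, id = gene_row$id)

fx_positive_sentences <- function(A, B, cue, mut, cross) {
  if (A$id == B$id) {
    return(list(list(fx_g(A), fx_w(cue), fx_w("itself , and"), fx_w(mut),
                     fx_g(A), fx_w("abolishes this self association ."))))
  }
  if (cross) {
    list(list(fx_w(toupper_first(mut)), fx_g(A),
              fx_w("was identified in affected families .")),
         list(fx_w("The mutant protein"), fx_w(cue), fx_g(B), fx_w("in vivo .")))
  } else {
    list(list(fx_w("Here we show that"), fx_g(A), fx_w(cue), fx_g(B),
              fx_w(", and"), fx_w(mut), fx_g(A),
              fx_w("disrupts this interaction .")))
  }
}

fx_distractor_sentence <- function(genes_rows) {
  if (length(genes_rows) == 1L) {
    list(fx_g(genes_rows[[1L]]), fx_w("was also detected in these samples ."))
  } else {
    list(fx_g(genes_rows[[1L]]), fx_w("and"), fx_g(genes_rows[[2L]]),
         fx_w("were used as controls ."))
  }
}

toupper_first <- function(x) {
  paste0(toupper(substr(x, 1L, 1L)), substr(x, 2L, nchar(x)))
}

# Assemble title + sentences into a document with mention offsets.
fx_assemble <- function(pmid, title_elems, sentence_list) {
  mentions <- empty_mentions()
  render <- function(elems, offset) {
    parts <- character(0); pos <- offset
    for (el in elems) {
      if (length(parts)) pos <- pos + 1L  # joining space
      if (!is.na(el$id)) {
        mentions <<- rbind(mentions, make_mentions(
          pos, pos + nchar(el$text), el$text, "gold", el$id))
      }
      parts <- c(parts, el$text)
      pos <- pos + nchar(el$text)
    }
    paste(parts, collapse = " ")
  }
  title <- render(title_elems, 0L)
  abstract_parts <- character(0)
  pos <- nchar(title) + 1L
  for (s in sentence_list) {
    txt <- render(s, pos)
    abstract_parts <- c(abstract_parts, txt)
    pos <- pos + nchar(txt) + 1L
  }
  doc <- ppim_document(pmid, title, paste(abstract_parts, collapse = " "))
  list(doc = doc, mentions = mentions)
}

#' Generate a complete fixture bundle
#'
#' Returns train/dev/test corpora, an oracle-consistent knowledge bundle
#' (each gold mention's ID is ranked first for its name and present in
#' both document indexes), a lexicon covering every gene name, a homology
#' map covering the confuser siblings, and seeded random word vectors.
#' Regeneration under the same seed is byte-identical.
#'
#' @param cfg a [fixture_config()].
#' @return list with elements `corpus` (list `train`, `dev`, `test`),
#'   `full_corpus`, `kb`, `lexicon`, `homolog_map`, `word_vectors`,
#'   `genes`, `config`.
#' @export
generate_fixture_bundle <- function(cfg = fixture_config()) {
  set.seed(cfg$seed)
  genes <- fixture_genes(cfg)
  usable <- which(!genes$lexicon_only)
  lex_only <- which(genes$lexicon_only)
  n <- cfg$n_articles
  split_n <- c(train = floor(cfg$split[["train"]] * n),
               dev = floor(cfg$split[["dev"]] * n))
  split_n <- c(split_n, test = n - sum(split_n))
  split_of <- rep(names(split_n), split_n)

  docs <- list(); mentions <- list(); pairs <- list(); cross_flags <- list()
  for (a in seq_len(n)) {
    pmid <- sprintf("9%05d", a)
    in_test <- split_of[a] == "test"
    pool <- if (in_test && length(lex_only)) c(usable, lex_only) else usable
    n_pairs <- 1L + stats::rbinom(1L, 1L, cfg$p_second_pair)
    sent <- list(); doc_pairs <- empty_pairs(); doc_cross <- logical(0)
    first_gene <- NULL
    for (k in seq_len(n_pairs)) {
      self <- stats::runif(1) < cfg$p_self
      if (self) {
        gi <- sample_from(pool, 1L)
        A <- genes[gi, ]; B <- A
      } else {
        gi <- sample_from(pool, 2L)
        A <- genes[gi[1L], ]; B <- genes[gi[2L], ]
      }
      if (is.null(first_gene)) first_gene <- A
      cross <- !self && stats::runif(1) < cfg$p_cross_sentence
      sent <- c(sent, fx_positive_sentences(A, B, sample(CUE_PHRASES, 1L),
                                            sample(MUT_PHRASES, 1L), cross))
      doc_pairs <- rbind(doc_pairs, data.frame(id1 = A$id, id2 = B$id,
                                               stringsAsFactors = FALSE))
      doc_cross <- c(doc_cross, cross)
    }
    if (stats::runif(1) < cfg$p_distractor) {
      nd <- sample(1:2, 1L)
      cand <- setdiff(usable, match(unique(c(doc_pairs$id1, doc_pairs$id2)),
                                    genes$id))
      if (length(cand) >= nd) {
        dg <- lapply(sample_from(cand, nd), function(i) genes[i, ])
        sent <- c(sent, list(fx_distractor_sentence(dg)))
      }
    }
    sent <- c(sent, list(list(fx_w(sample(FILLER_SENTENCES, 1L)))))
    title <- list(fx_w("Functional analysis of"), fx_g(first_gene),
                  fx_w("in human disease"))
    built <- fx_assemble(pmid, title, sent)
    docs[[pmid]] <- built$doc
    mentions[[pmid]] <- built$mentions
    pairs[[pmid]] <- canonical_pairs(doc_pairs$id1, doc_pairs$id2)
    cross_flags[[pmid]] <- doc_cross
  }

  full <- new_corpus(docs, mentions, pairs)
  sub_corpus <- function(which_split) {
    idx <- which(split_of == which_split)
    pm <- names(docs)[idx]
    new_corpus(docs[pm], mentions[pm], pairs[pm])
  }

  # knowledge bundle: oracle-consistent
  name_index <- list(); lexicon <- list(); homolog_map <- character(0)
  for (i in seq_len(nrow(genes))) {
    ids <- genes$id[i]
    if (genes$confuser[i]) {
      ids <- c(ids, genes$sibling_id[i])
      homolog_map[genes$id[i]] <- genes$group[i]
      homolog_map[genes$sibling_id[i]] <- genes$group[i]
    }
    ids <- c(ids, paste0("D", genes$id[i]))  # unsupported decoy candidate
    name_index[[genes$name[i]]] <- ids
    lexicon[[genes$name[i]]] <- ids[seq_len(min(2L, length(ids)))]
  }
  doc_ids <- lapply(names(docs), function(pmid) {
    unique(mentions[[pmid]]$gene_id)
  })
  names(doc_ids) <- names(docs)
  kb <- knowledge_bundle(name_index, doc_ids, doc_ids, lexicon, homolog_map)

  # word vectors over the fixture vocabulary
  vocab_words <- sort(unique(c(
    tolower(unlist(lapply(docs, function(d) {
      vapply(seq_len(nrow(d$tokens)), function(i) {
        slice_text(d$full_text, d$tokens$start[i], d$tokens$end[i])
      }, character(1))
    }))), tolower(RC_GENE_TOKENS))))
  wv <- list(words = vocab_words,
             mat = matrix(stats::runif(length(vocab_words) * cfg$word_vec_dim,
                                       -0.1, 0.1),
                          nrow = length(vocab_words)))

  list(corpus = list(train = sub_corpus("train"), dev = sub_corpus("dev"),
                     test = sub_corpus("test")),
       full_corpus = full, kb = kb, lexicon = lexicon,
       homolog_map = homolog_map, word_vectors = wv, genes = genes,
       cross_flags = cross_flags, config = cfg)
}

#' Degrade a knowledge bundle's primary index
#'
#' Removes each primary document-index entry independently with
#' probability `drop_rate`, leaving the fallback index intact -- the
#' degraded bundle exercises the fallback path of normalization.
#'
#' @param kb a `knowledge_bundle`.
#' @param drop_rate probability in [0, 1] of dropping each PMID entry.
#' @param seed integer seed.
#' @return a new `knowledge_bundle`.
#' @export
corrupt_knowledge <- function(kb, drop_rate, seed = 1L) {
  stopifnot(drop_rate >= 0, drop_rate <= 1)
  set.seed(seed)
  keep <- stats::runif(length(kb$doc_index_primary)) >= drop_rate
  knowledge_bundle(kb$name_index, kb$doc_index_primary[keep],
                   kb$doc_index_fallback, kb$lexicon, kb$homolog_map,
                   kb$max_candidates)
}

#' Write a fixture bundle to disk in the package's exchange formats
#'
#' Emits PubTator text per split, the knowledge-bundle TSVs, the homolog
#' TSV and word2vec-format vectors.
#'
#' @param bundle output of [generate_fixture_bundle()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_fixture_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sp in names(bundle$corpus)) {
    write_pubtator(bundle$corpus[[sp]], file.path(dir, paste0(sp, ".pubtator.txt")))
  }
  write_knowledge_bundle(bundle$kb, file.path(dir, "kb"))
  write_word_vectors(bundle$word_vectors$words, bundle$word_vectors$mat,
                     file.path(dir, "vectors.txt"))
  invisible(dir)
}
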