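---
title: "Methods: document-level extraction of mutation-affected protein interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: document-level extraction of mutation-affected protein interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppimx)
```

## The extraction problem and its assumptions

The unit of extraction is an unordered pair of gene identifiers per
article: proteins A and B interact, and the interaction is affected by a
genetic mutation. Three properties shape the design. Self-interactions are
legal, so the candidate space for a document with candidate-ID set $G$ is
all of $G \times G$ rather than only distinct pairs. Direction is
immaterial, so pairs are canonicalized (sorted) everywhere and a pair's
classification score averages both ordered forms. A pair's evidence may
span sentences, so classification operates on the whole document (title +
abstract), not on single sentences. The pipeline also relies on one
guarantee of the task setting — every relevant article carries at least
one gold pair — which motivates the fallback rule of always predicting the
best-scoring pair when nothing clears the decision threshold.

All character offsets in the package are 0-based half-open intervals into
`full_text = title + " " + abstract`. Input text is folded to ASCII with a
strictly length-preserving single-character transliteration (Greek letters
to Latin look-alikes, anything else unknown to `?`) so that gold offsets
survive; full Unicode normalization (which can change string length) is
deliberately not applied. The cost is that a mention like `α-fodrin`
becomes `a-fodrin`, which a lexicon keyed on `alpha-fodrin` will not
match — a documented limitation rather than a silent offset corruption.

## Gene-mention tagger

Tokens are maximal alphanumeric runs or single punctuation marks — chosen
so that mixed tokens such as `Shank3` remain single units, because the
character-level features carry much of the gene-name signal (capitals and
trailing digits). Sentences are split by a rule-based detector (terminal
punctuation followed by whitespace and an upper-case letter or digit; the
title always ends a sentence). No published tokenizer choice exists for
this pipeline, so both are deterministic, documented rules; sentence
counts on real corpora will differ from other toolchains' counts.

The labeler follows the CNN–LSTM hybrid design: per token, a matrix $B$
stacks the lowercased characters' embeddings (dimension $\alpha = 32$)
concatenated with 8-dimensional character-type embeddings (lowercase /
uppercase / punctuation / other — digits are deliberately *other*);
$\kappa = 50$ width-3 filters are convolved over $B$ with ReLU and
max-over-time pooling. Words shorter than the window are padded with a
reserved padding character so the feature map is never empty. The pooled
vector is concatenated with a $d = 200$ word embedding (lowercased lookup;
out-of-vocabulary tokens share a trained UNK row) and a 32-dimensional
word-shape embedding (all-lower / mixed / capitalized-first / all-upper /
other), fed to a Bi-LSTM with $\pi = 200$ units per direction, and each
position's concatenated state goes through a 3-way softmax over the IOB1
tags. IOB1 (not IOB2) is used throughout: span-initial tokens take
`I-GENE`, and `B-GENE` appears only between two adjacent spans. The
training loss is the mean per-token categorical cross-entropy per
sentence.

Training is plain SGD on mini-batches of 20 sentences for at most 10000
iterations, evaluating span-level F1 on a development set every 100
iterations, keeping the best checkpoint and stopping after 10 checkpoints
without improvement. The learning rate decays by a factor 0.95 per
checkpoint interval. Two training details are the package's own choices
where no published value exists: the initial learning rate (default 0.05
at full scale; the reduced test configurations use 0.5, which the small
fixtures tolerate and need for fast convergence) and global-norm gradient
clipping at 5.0 for LSTM stability. Weights use Glorot-uniform
initialization, embeddings uniform ±0.05, and the forget-gate bias starts
at 1. The ensemble trains 10 models, each with its own seed on an
independent random 50% of the sentences; each member's development set is
its complementary 50% — the natural choice given that members must see
only half the data anyway. At tagging time the members' per-token
distributions are averaged (the smoothest combination rule, and one that
makes the ensemble's behavior exactly testable against an
average-then-decode oracle), the argmax sequence is repaired to valid IOB1
(`B-GENE` after `O` or at sequence start becomes `I-GENE` — the minimal
edit), and spans are decoded.

Two recall devices surround the tagger. Document-level annotations from an
external tool can be merged into gold training annotations wherever they
cover only tokens currently labeled `O`; anything overlapping a gold token
is discarded, so gold annotation is never altered. Overlap is judged at
token granularity because labels live on tokens. After tagging, a lexicon
scanner adds dictionary gene names the model missed: case-insensitive,
anchored at token boundaries, longer matches prioritized (character
length, then leftmost), never overlapping a tagger span or an earlier
accepted match. The scanner is intentionally precision-poor; the
normalization stage is the filter.

## Knowledge-based normalization

A `knowledge_bundle` holds four tables: a ranked name index
(mention string → candidate IDs, truncated at 100 candidates), two
document-level indexes (PMID → gene-ID set; one precise *primary* source
and one recall-oriented *fallback*), a lexicon, and a homolog map.
Normalization of a mention is: take the ranked candidates for the cleaned
surface form (whitespace squeezed, flanking punctuation stripped;
case-sensitive lookup with a case-insensitive retry); return the first
candidate present in the primary set for the article's PMID; else the
first present in the fallback set; else NULL, and the span is dropped.
Sequential consultation (primary before fallback, each scanned in rank
order) is the default because the precise source should win
disagreements; a `mode = "union"` switch pools both sets for comparison.
Only file/table-backed bundles are implemented — every run and test is
offline and reproducible; the table accessors still go through a cache
with a backend-call counter so the caching contract is observable.

## Relation classifier

For candidate set $G$, the package generates $|G|^2$ entity-blinded
instances per document: both orders for each unordered distinct pair plus
one `GENE_S` instance per self pair, with every mention of the bound pair
replaced by `GENE_A`/`GENE_B` (or `GENE_S`), every mention of any other
candidate by `GENE_N`, and multi-token mentions collapsing to a single
placeholder (overlapping spans resolved longest-first). No candidate's
surface string survives in any instance, which the tests enforce by
scanning. The classifier is a text CNN: word embeddings of dimension 200,
window sizes 3/4/5 with 200 filters each, ReLU (the package's choice,
matching the tagger), max-over-time pooling into a 600-long feature
vector, dropout 0.5 (inverted dropout, disabled at inference), and a
2-way softmax whose positive component is "the probability". Four
zero-vectors pad the start, the end, and each sentence boundary, so even a
1-token document supports the width-5 window. The padding token's
embedding row is pinned to zero during training.

Training is RMSProp (learning rate 0.001, batch size 8) for 30 epochs,
checkpointing each epoch and keeping the parameters with the best
development F1. The development metric is *pair-level* document F1 with
both orders averaged — matching how the model is used at inference — and
each ensemble member draws its own 80/20 split at *document* granularity,
so no document's instances leak across the split (the split granularity is
a package decision; instance-level splitting would leak near-duplicate
reversed instances). At prediction time a pair's score is the mean over
members and both orders (symmetric by construction); pairs with score
strictly above 0.5 are positive, and when none is, the best-scoring pair
is predicted with ties broken by the lexicographically smallest canonical
pair — a deterministic rule that matters only in degenerate score ties.
Instances longer than 1500 tokens are truncated from the end (never before
the first bound-token occurrence); abstracts never approach this.

## Evaluation

Micro scores pool TP/FP/FN over documents after canonicalization and
per-document deduplication; macro (example-based) scores average
per-document precision, recall and F1. Under homolog matching each ID is
first replaced by its homology-group ID (IDs absent from the map stand
for themselves), and both gold and predicted sets are deduplicated *after*
canonicalization, so colliding gold pairs merge. Degenerate documents
score by convention: empty gold and empty prediction count 1.0, empty gold
with predictions counts 0; real task data guarantees nonempty gold, so the
conventions only matter for synthetic edge cases. Canonicalization merges,
never splits, equivalence classes, so homolog scores are never below exact
scores on the same input.

## The synthetic-fixture generator

`generate_fixture_bundle()` is first-class, tested code that emulates the
statistical structure the pipeline assumes: every article has at least one
gold pair (a second with probability 0.3, giving roughly 1.3–1.4 pairs per
article, matching the task's density); positive pairs co-occur with an
interaction cue ("interacts with", "promotes sumoylation of", …) and a
mutation phrase, within one sentence or — for a configurable fraction,
default 0.25 — across two sentences; self-interactions occur at a
configurable rate (default 0.1); distractor genes are mentioned without
cues, supplying negative instances. Sentences are templated natural-ish
prose rather than token soup so that the tagger has learnable shape cues
and the classifier learnable lexical cues at tiny scale. Gene names mix
case/digit shapes (`Xbp7`, `TRK9`, `abc-1`) to exercise the
character-type and word-shape features; a configurable fraction of genes
gets plain lowercase names and appears only in test articles, so only the
lexicon stage can recover them — the ablation that demonstrates the
lexicon's recall value. Homolog "confusers" give one name two IDs sharing
a homology group, reproducing the species-variant error mode that exact
matching punishes and homolog matching forgives. The knowledge bundle is
oracle-consistent (every gold mention's ID ranked first for its name and
present in the document indexes), and `corrupt_knowledge()` drops primary
entries to force the fallback path. A single seed fixes every draw;
regeneration is byte-identical.

What the generator does *not* emulate: real PubMed syntax and vocabulary
breadth, ambiguous gene names whose resolution needs more context than a
document-ID set, species mixtures, and incomplete annotation. Passing
tests therefore demonstrate that the machinery is correct and that the
architectures can learn the intended signals — not that the full-scale
system reaches any particular accuracy on the genuine challenge corpus,
which would additionally require the original training data, large
pre-trained embeddings and live knowledge services.

## Numerical choices and problem sizes

The neural models run on a small reverse-mode autodiff core written in
base R; the LSTM recurrence and the convolution+pooling blocks are fused
operations with hand-derived, batched backward passes, validated against
central finite differences in the test suite (relative error below
$10^{-3}$ at probe points). Softmax subtracts the row maximum before
exponentiation; cross-entropy clamps probabilities at $10^{-12}$.
Checkpoint comparisons use a $10^{-9}$ improvement margin so floating-point
noise cannot masquerade as progress. Training stops early when a
configured target F1 is reached, when the patience budget is exhausted, or
(for the classifier) when development F1 hits 1.

The test and acceptance runs use reduced problem sizes chosen to exercise
the full machinery at desk scale: tagger memorization uses
$\kappa = 20, \pi = 50$, $d = 50$ on 20 sentences within 500 iterations;
classifier recovery uses 32 filters and 32-dimensional embeddings on a
200-article corpus with 3-member ensembles and 12 epochs; the end-to-end
run uses 100 articles with a 2-member tagger ensemble and a 3-member
classifier ensemble. Fixture word vectors are seeded uniform random —
pre-trained vectors are consumed through the same word2vec-format reader
when available but are not required at fixture scale.

## Known limitations

The sentence splitter and tokenizer are simple rules; on real abstracts
with abbreviations ("E. coli") they will over-split, shifting sentence
counts (mention offsets are unaffected). The ASCII folding is lossy for
lexicon matching of Greek-letter names. Live E-utilities/annotation-service
adapters are not included; the knowledge bundle must be materialized as
files. The LSTM processes sentences individually (no cross-sentence state
in the tagger), and the classifier has no attention mechanism — context
arrives only through convolution windows over the blinded document.
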