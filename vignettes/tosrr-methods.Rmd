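---
title: "Tree-organized self-reflective retrieval: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tree-organized self-reflective retrieval: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tosrr)
```

## The problem

Knowledge-intensive question answering in domains with a strongly
hierarchical curriculum — the motivating case is Traditional Chinese
Medicine, whose licensing exams draw on facts scattered across dozens of
textbooks — strains both of the usual retrieval-augmented generation (RAG)
knowledge representations. Flat text chunks lose the hierarchy, so retrieval
fragments knowledge; bare subject–predicate–object (SPO) triples keep the
structure but lose the surrounding semantics a generator needs. `tosrr`
implements a composite representation and retrieval loop that keeps both:

* **SPO-T units**: each triple stays bound to the text chunk it was
  extracted from, together with a generated summary and Q&A pairs.
* **A knowledge tree**: book → chapter → title → knowledge point, with
  chunks attached to leaves through the reserved `include` predicate, so
  every retrieved unit carries its root-to-leaf context path.
* **Dual-path recall with fixed quotas**: keyword matching over triples and
  cosine similarity over embedded content, fused into a top-15 prompt
  budget.
* **A self-reflective generate–verify loop**: retrieved evidence is
  filtered for relevance, drafts are checked for evidential support and
  helpfulness, and the question is decomposed or reformulated when checks
  fail — all under hard iteration caps.

Every model-dependent stage (embedder, triple extractor, content generator,
judges, decomposer, reformulator) is a pluggable function with a
deterministic offline default, so the full pipeline runs, and is tested, on
synthetic corpora with no network or model access.

## Corpus ingestion and segmentation

Documents enter in a plain-text heading dialect: `n` leading `#` characters
mark a level-`n` heading, blank lines separate paragraphs. This deliberately
replaces document-layout analysis (OCR, mixed-layout recognition), which is
out of scope; any upstream converter that can emit headings and paragraphs
can feed the pipeline.

One counting rule is used everywhere (`count_words()`): whitespace-delimited
tokens, with every CJK character counting as one word. Sentences end at
`. ! ?` or their full-width forms. Chunking greedily packs consecutive
paragraphs **within a single section**: a chunk closes once it reaches
`min_words` (default 200) or when the next paragraph would push it past
`max_words` (default 300). Two consequences are intentional:

* Sections shorter than 200 words become one short chunk and are never
  merged across headings — merging would detach a chunk from its place in
  the tree. Chunks also never merge paragraphs across sub-headings below the
  deepest level; the tree mapping takes precedence over chunk-size
  uniformity.
* A single paragraph longer than 300 words is split at sentence boundaries
  into pieces of at most 300 words (a single over-long sentence is split at
  word boundaries as a last resort), so every source word lands in exactly
  one chunk and no chunk exceeds the band when its section has enough
  material.

## The knowledge tree and SPO-T units

Each document becomes one tree root. Node kinds are assigned by depth (book,
chapter, title), with any leaf below the root classified as a knowledge
point; a depth-1 document is the degenerate case of a root that is also a
leaf, which is allowed and yields single-label context paths. Unit and chunk
identifiers are content hashes, so rebuilding the same corpus reproduces the
same ids and serialized knowledge bases diff cleanly.

Triple extraction is pluggable. The deterministic default emits
`(deepest heading label, predicate, following key-phrase)` for every
vocabulary predicate whose surface form appears in the chunk; an LLM adapter
can replace it without touching the vocabulary contract: predicates outside
the configured vocabulary are dropped (the reserved `include` is never
accepted from an extractor), and duplicates keep their first occurrence. The
shipped default vocabulary (`treats`, `composed_of`, `manifests_as`,
`belongs_to`, `contraindicated_with`) is a placeholder for a
domain-curated predicate list, which is configuration, not code.

Summaries and Q&A pairs are generated per chunk by a pluggable generator
invoked `n_candidates` times (default 2); a selector retains one candidate.
Expert review of candidates is out of scope, so the default selector is the
documented deterministic proxy: highest lexical overlap between the
candidate summary and the chunk, ties keeping the earliest candidate.
Summaries and Q&A pairs are modelled as *fields of the unit* that are
independently embedded (rather than as separate retrievable items); this is
a documented choice where both readings are defensible.

## Embedding, indexing, and recall

The default embedder is seeded feature hashing: token counts hashed into 256
buckets and L2-normalized. It is not a semantic model — it exists so that
cosine geometry, index mechanics and the whole pipeline are exactly
reproducible offline; a remote embedding service plugs in through the same
`function(texts) -> matrix` contract. Cosine similarity of a zero vector is
defined as 0 (with a warning) to avoid NaN propagation.

The vector index stores one entry per unit and content kind (chunk, summary,
Q&A). Search is exact — a dense matrix product over unit-normalized rows —
up to `brute_threshold` (default 1000) entries, which makes the k-NN
contract directly testable against brute force; above the threshold a
navigable-small-world-style graph (exact k-NN neighbour graph of out-degree
`m_neighbors = 16`, greedy best-first beam search of width `ef_search = 64`)
provides near-exact approximate search. Ties in similarity break by
ascending insertion order. A unit recalled through several content kinds is
scored by the **maximum** over its kinds — another documented choice where
the alternative (separate entries per kind) was equally plausible.

Keyword recall scores each unit by the number of *distinct* query tokens
occurring among its triple's subject/predicate/object tokens (so the score
is invariant to token order and duplication in the query), sorts by
descending score with ties by ascending unit id, and drops zero scores. The
default analyzer lowercases and keeps letter/digit runs, with an optional
CJK character-bigram mode standing in for dictionary-based analyzers.

Fusion takes up to 5 keyword hits, then vector hits (skipping unit ids
already taken — deduplication keyed on unit id with the keyword path taking
precedence) until the list holds 15 entries or candidates run out. A keyword
deficit enlarges the vector share; a vector deficit never enlarges the
keyword share — only that direction is specified, and only it is
implemented. Keyword entries precede vector entries in the rendered prompt,
each path in its own rank order; the source is silent on the fused ordering,
and placing the structured hits first mirrors their role as importance
hints. The prompt template is plain text with `{role}`, `{task}`,
`{knowledge}`, `{question}` placeholders; the shipped default is in
`inst/extdata/default_template.txt` and is used identically across
backends.

## The reflection loop

The loop implements a four-step generate–verify cycle:

1. retrieve for the active question, judge each recalled unit's relevance,
   discard the rest;
2. if nothing survives, decompose the question into sub-questions, retrieve
   and filter each independently, and pool the survivors; otherwise generate
   a draft from the surviving evidence;
3. check the draft is supported by that evidence, regenerating while the
   check fails and regeneration credits remain;
4. check the draft addresses the *original* question; if not, reformulate
   and restart from retrieval.

The source design bounds none of this explicitly ("multiple iterations"), so
the caps are package parameters with conservative defaults: 3 regenerations,
2 reformulations, 1 decomposition, all counters global across restarts. That
gives a closed-form bound of `reform + 1 + regen` generator calls (6 at the
defaults), verified by a property test over arbitrary judge behaviours.
Three further decisions: a failing judge is a *negative* verdict (fail-safe
— bad evidence is dropped, unsupported drafts are not accepted);
sub-questions are never decomposed again (depth 1); and cap exhaustion is a
terminal status (`cap_exhausted`) carrying the last draft as best-effort,
not an error.

The offline judges are lexical-overlap heuristics with documented
thresholds: relevance and helpfulness need at least one shared distinct
token; support needs at least half of the draft's distinct tokens grounded
in the relevant units' text. They are deliberately crude — their job is to
make the state machine's branches reachable and deterministic in tests, not
to approximate a model judge.

With all-approve judges the loop reduces exactly to single-pass RAG over the
same fused recall, which is the package's ablation surface:
`answer_question()` exposes `tosrr` (full loop), `spot_rag` (same retrieval,
no reflection), `rag` (vector-only retrieval) and `baseline` (no retrieval).

## Evaluation machinery

Exam rounds are `n = 600` one-point multiple-choice items by default, 70%
factual and 30% case analysis. Free-text answers are mapped to options by
the documented grammar: the first standalone option label in the text;
abstentions score zero. Reported percentages use half-up rounding to two
decimals — reproducing printed two-decimal scores depends on this, since
IEEE round-half-even differs on ties. `sample_round()` excludes items whose
normalized stem hash matches a knowledge-base chunk before sampling, so test
items never leak from the corpus.

Recall accuracy averages 0/1 expert judgments of retrieved entries over
raters × items × entries. With 10 raters, 10 items and 15 entries each, a
per-rater average total of 57 positive judgments corresponds to an accuracy
of 57/150 = 0.38; the package adopts this per-rater-denominator reading (the
only one consistent with both printed numbers) and exposes both quantities
(`recall_accuracy()`, `recall_total_score()`).

Of the seven RAGAs-style metrics, the four that admit deterministic
definitions are implemented with documented formulas: context precision is
average precision over the retrieved list; context recall is the fraction of
ground-truth fact strings whose tokens all occur within a single retrieved
context; context entity recall is the fraction of ground-truth entities
present in the contexts; semantic similarity is embedder cosine rescaled to
[0, 1]. The three that require a model judge (faithfulness, answer
relevancy, answer correctness) ship only as a pluggable-judge surface
(`llm_judged_metric()`) with no offline default and no offline guarantees —
an honest subset rather than a lexical imitation of judge metrics.

The statistics are implemented to their standard formulas and cross-checked
in the test suite against independent implementations (`vegan`, `stats`):
Kendall's W with mid-rank tie correction and the identity
`chi-square = m(n-1)W` on `n-1` degrees of freedom (a single rater is
degenerate with W = 1); McNemar's test with continuity correction
`max(|b-c|-1, 0)^2/(b+c)`, switching to the exact binomial when `b + c <
25`; paired t with paired Cohen's d (`mean(diff)/sd(diff)`, degenerate at
zero-variance differences); and a seeded percentile bootstrap of the mean
(default 10000 resamples of the per-question or per-rater unit that was
scored).

## The synthetic corpus generator

The generator emulates the *structure* of a multi-book curriculum, not its
content: `n_books x chapters_per_book x points_per_chapter` knowledge
points, each owning a distinct cluster of pseudo-words, opening with one
planted fact sentence ("subject predicate object"), padded with
cluster-internal filler to `words_per_point` words (default 250, the middle
of the chunking band, so each point maps to one chunk). With probability
`cross_link_rate` a point closes with a `belongs to` sentence naming a
point in another chapter plus a few of its tokens — the minimal instance of
cross-chapter association, and the basis for case-analysis items, which
always span exactly two cross-linked points. Factual items ask for the
object of one planted triple with distractors drawn from sibling points.
Everything is integer-seeded and locale-independent; identical seeds give
byte-identical corpora.

The companion *oracle embedder* maps every token to its owning point's
dimension, the idealized limit of a perfect semantic model: distinct points
are exactly orthogonal. Under it, planted-unit recall@15 equals 1 for
factual items — a mechanics guarantee, not a performance claim.

Synthetic rater matrices mix a latent item quality with rater-specific
uniform noise; the mixing weight monotonically controls expected concordance
from independent rankings (expected W near `1/m`) to identity (W = 1).

**What passing tests do and do not show.** The synthetic corpora have
disjoint topic vocabularies, unambiguous facts, and distractors that share
no tokens with the stem. Passing the suite therefore certifies the
*mechanics* — segmentation bounds, tree integrity, quota arithmetic, loop
termination, metric formulas — under ideal separability. It says nothing
about performance on real prose, where topics overlap lexically, facts are
paraphrased, extraction is noisy, and judges err; the headline accuracy of
any deployment rests entirely on the quality of the plugged-in model
backends.

## Problem sizes and runtime choices

The test suite and the reproduction script run on deliberately small
instances chosen as the package's own desk-scale defaults: 2 x 3 x 3-point
corpora (36–47 units) for retrieval and reflection tests, 1200 x 12 seeded
vectors for the approximate-search recall check, 600-item rounds for scoring
arithmetic, 10 x 30–50 rater matrices for concordance, and 500–10000
bootstrap resamples. These sizes keep the whole suite under a minute while
exercising every code path, including the above-threshold graph search.

## Known limitations

* The default extractor and judges are lexical; they are scaffolding for
  the state machine, not competitive components.
* Entity normalization and ontology alignment across books are out of
  scope: identical concepts under different labels become distinct subjects.
* The vector index rebuilds its neighbour graph from scratch (no
  incremental insertion); corpora of millions of entries would need an
  external ANN backend behind the same `knn_search()` contract.
* `rag` mode retrieves over the same SPO-T units (vector path only) rather
  than an independently chunked flat corpus, so it is an ablation of the
  retrieval paths, not a faithful replica of a chunk-only RAG stack.
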