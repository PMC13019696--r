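# tosrr

Tree-organized self-reflective retrieval for question answering over
hierarchical knowledge.

## What problem this solves

Question answering in domains with a strongly hierarchical curriculum —
medical licensing material is the motivating case — defeats both standard
retrieval-augmented generation (RAG) representations. Flat text chunks lose
the book → chapter → knowledge-point structure, so retrieval fragments
knowledge across sections; bare knowledge-graph triples (subject, predicate,
object) keep structure but are too sparse for a generator to write a
grounded answer from. `tosrr` implements a framework that keeps both sides:

* **SPO-T knowledge base** — each SPO triple stays bound to the text chunk
  it came from (plus a generated summary and Q&A pairs), and chunks hang off
  the leaves of a book → chapter → title → knowledge-point tree via the
  reserved `include` predicate, so every retrieved unit carries its
  root-to-leaf context path.
* **Dual-path recall with fixed quotas** — keyword matching over triples
  supplies up to 5 candidates and cosine similarity over embedded content
  supplies 10 more, fused into a top-15 prompt budget; a keyword deficit is
  backfilled from the vector path.
* **Self-reflective generation** — a bounded generate–verify loop filters
  recalled evidence for relevance, checks drafts for evidential support and
  helpfulness, and decomposes or reformulates the question when checks fail.
* **Evaluation machinery** — exam-round scoring (600 one-point items, 70%
  factual / 30% case analysis, half-up two-decimal percentages), expert
  recall-accuracy aggregation, retrieval metrics (context precision/recall,
  entity recall, semantic similarity), Kendall's W with
  `chi-square = m(n-1)W`, McNemar's paired test, paired t with Cohen's d,
  and a seeded percentile bootstrap.
* **Synthetic corpora** — a seeded generator of multi-book corpora with
  planted facts, cross-chapter links, question banks and rater matrices, so
  the whole pipeline runs and is tested offline.

Every model-dependent stage (embedder, triple extractor, content generator,
judges, decomposer, reformulator) is a pluggable function with a
deterministic offline default; production deployments swap in LLM adapters
with the same contracts.

## Worked example

```r
library(tosrr)

spec    <- corpus_spec(n_books = 2, chapters_per_book = 3,
                       points_per_chapter = 3, cross_link_rate = 0.5, seed = 42)
corpus  <- generate_corpus(spec)
kb      <- build_knowledge_base(corpus$documents)
kb
#> <knowledge_base> 2 tree(s), 26 node(s), 42 unit(s), 18 chunk(s)

indexes <- build_indexes(kb, embedder = oracle_embedder(corpus))
mcq     <- generate_mcq(corpus, 10, seed = 7)
q       <- mcq$bank[[1]]$stem
q
#> Which of the following does entity_b2c1p1 contraindicated with?

multi_way_recall(kb, indexes, q)
#> <recall_result> 15 entries (3 keyword + 12 vector)
```

Three units share tokens with the question, so the keyword path contributes
3 of the 15 entries and the vector path backfills the remaining 12. The
reflective loop then answers in one pass, with every branch decision logged:

```r
ans <- answer_question(q, kb, indexes, offline_backends(), mode = "tosrr")
ans$trace
#> <generation_trace> 5 event(s), terminal status: answered
#>   recall             'Which of the following does entity_b2c1p1 contraindicated with?' -> 15 entries
#>   relevance_filter   [TRUE] 8 of 15 kept
#>   generate           draft of 141 token(s)
#>   support_check      [TRUE]
#>   helpfulness_check  [TRUE]
substr(ans$answer, 1, 80)
#> 1. (entity_b2c1p1 | contraindicated_with | finding_b2c1p1) [Book 2 > Chapter 2.1
```

The answer opens with the planted fact — subject, predicate and the correct
object `finding_b2c1p1` — together with its context path in the knowledge
tree. Exam scoring follows the published arithmetic: 324 factual + 130
case-analysis points out of 600 converts to 75.67%:

```r
items <- c(lapply(1:420, function(i) mcq_item(paste0("f", i), "s",
                                              c(A = "a", B = "b"), "A", "factual")),
           lapply(1:180, function(i) mcq_item(paste0("c", i), "s",
                                              c(A = "a", B = "b"), "A", "case_analysis")))
score_exam(items, c(rep("A", 324), rep("B", 96), rep("A", 130), rep("B", 50)))
#> <exam_result> factual 324 + case 130 = 454 / 600 (75.67%)
```

## Command line

A thin wrapper over the package functions lives at `inst/cli/tosrr.R`:

```sh
Rscript inst/cli/tosrr.R simulate --out demo --n-items 100 --seed 5
Rscript inst/cli/tosrr.R ask --kb demo/kb --question "..." [--no-reflect]
Rscript inst/cli/tosrr.R evaluate --kb demo/kb --bank demo/bank.jsonl --backend spot-rag --n 100
```

`--no-reflect` / `--backend` switch between the full loop and its ablations
(`spot-rag`: same retrieval without reflection; `rag`: vector-only
retrieval; `baseline`: no retrieval).

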