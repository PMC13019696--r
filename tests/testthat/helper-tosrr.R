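# shared fixtures, all built in code

# n distinct pseudo-words with a common prefix
make_words <- function(n, prefix = "word") {
  paste(sprintf("%s%03d", prefix, seq_len(n)), collapse = " ")
}

# a two-chapter, two-point document in the heading dialect
tiny_doc_text <- function() {
  paste(
    "# Anatomy Primer", "",
    "## Organs", "",
    "### heart", "",
    "The heart treats circulation problems. It pumps blood through vessels.", "",
    "### lung", "",
    "The lung belongs to the respiratory system. Gas exchange happens here.", "",
    "## Vessels", "",
    "### artery", "",
    "An artery composed of elastic walls. It carries blood away.", "",
    "### vein", "",
    "A vein manifests as a low pressure channel. Valves prevent backflow.", "",
    sep = "\n")
}

tiny_kb <- function() {
  build_knowledge_base(list(tiny_doc_text()))
}

# independent brute-force cosine top-k oracle
brute_force_knn <- function(vectors, query, k) {
  nq <- sqrt(sum(query^2)); if (nq > 0) query <- query / nq
  nr <- sqrt(rowSums(vectors^2)); nz <- nr > 0
  vectors[nz, ] <- vectors[nz, , drop = FALSE] / nr[nz]
  sims <- as.vector(vectors %*% query)
  ord <- order(-sims, seq_along(sims))[seq_len(min(k, length(sims)))]
  list(idx = ord, sims = sims[ord])
}

# standard small synthetic world used across retrieval/reflection tests
synthetic_world <- function(seed = 42, cross_link_rate = 0.5,
                            embedder = NULL, ...) {
  spec <- corpus_spec(n_books = 2L, chapters_per_book = 3L,
                      points_per_chapter = 3L, cross_link_rate = cross_link_rate,
                      seed = seed, ...)
  corpus <- generate_corpus(spec)
  kb <- build_knowledge_base(corpus$documents)
  if (is.null(embedder)) embedder <- oracle_embedder(corpus)
  list(corpus = corpus, kb = kb,
       indexes = build_indexes(kb, embedder = embedder))
}
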