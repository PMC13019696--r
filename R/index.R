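#' Build the vector index over knowledge content
#'
#' Every SPO-T unit contributes up to three entries — its chunk text, its
#' summary, and its Q&A pairs — each embedded separately. Search is by cosine
#' similarity: exact (dense matrix product over unit-normalized vectors) up
#' to `brute_threshold` entries, and above that a navigable-small-world style
#' graph (a k-nearest-neighbour graph over the stored vectors, traversed by
#' greedy best-first beam search of width `ef_search`) gives near-exact
#' approximate search. Rows are stored L2-normalized so dot product equals
#' cosine.
#'
#' @param kb a `knowledge_base`.
#' @param embedder batch embedder (see [hash_embedder()]).
#' @param kinds which content kinds to index.
#' @param brute_threshold entry count up to which search is exact.
#' @param m_neighbors graph out-degree for the approximate structure.
#' @param ef_search beam width for approximate search.
#' @return a `vector_index`.
#' @export
build_vector_index <- function(kb, embedder = hash_embedder(),
                               kinds = c("chunk", "summary", "qa"),
                               brute_threshold = 1000L, m_neighbors = 16L,
                               ef_search = 64L) {
  texts <- character(0); unit_ids <- character(0); content_kinds <- character(0)
  for (u in kb$units) {
    add <- function(kind, text) {
      if (nzchar(text)) {
        texts[[length(texts) + 1L]] <<- text
        unit_ids[[length(unit_ids) + 1L]] <<- u$unit_id
        content_kinds[[length(content_kinds) + 1L]] <<- kind
      }
    }
    if ("chunk" %in% kinds) add("chunk", kb$chunks[[u$chunk_id]]$text)
    if ("summary" %in% kinds) add("summary", u$summary %||% "")
    if ("qa" %in% kinds && length(u$qa_pairs))
      add("qa", paste(vapply(u$qa_pairs,
                             function(qa) paste(qa$question, qa$answer),
                             character(1)), collapse = " "))
  }
  vectors <- if (length(texts)) embedder(texts) else matrix(0, 0, 0)
  nrm <- sqrt(rowSums(vectors^2))
  nz <- nrm > 0
  vectors[nz, ] <- vectors[nz, , drop = FALSE] / nrm[nz]
  structure(list(unit_ids = unit_ids, content_kinds = content_kinds,
                 vectors = vectors,
                 params = list(brute_threshold = as.integer(brute_threshold),
                               m_neighbors = as.integer(m_neighbors),
                               ef_search = as.integer(ef_search)),
                 cache = new.env(parent = emptyenv())),
            class = "vector_index")
}

#' @rdname build_vector_index
#' @param vectors numeric matrix, one row per entry.
#' @param unit_ids,content_kinds entry metadata (defaults: row index as id,
#'   kind `"chunk"`).
#' @export
vector_index_from_matrix <- function(vectors, unit_ids = NULL,
                                     content_kinds = NULL,
                                     brute_threshold = 1000L,
                                     m_neighbors = 16L, ef_search = 64L) {
  vectors <- as.matrix(vectors)
  n <- nrow(vectors)
  unit_ids <- unit_ids %||% sprintf("u%05d", seq_len(n))
  content_kinds <- content_kinds %||% rep("chunk", n)
  nrm <- sqrt(rowSums(vectors^2))
  nz <- nrm > 0
  vectors[nz, ] <- vectors[nz, , drop = FALSE] / nrm[nz]
  structure(list(unit_ids = unit_ids, content_kinds = content_kinds,
                 vectors = vectors,
                 params = list(brute_threshold = as.integer(brute_threshold),
                               m_neighbors = as.integer(m_neighbors),
                               ef_search = as.integer(ef_search)),
                 cache = new.env(parent = emptyenv())),
            class = "vector_index")
}

#' @export
print.vector_index <- function(x, ...) {
  cat(sprintf("<vector_index> %d entries, dim %d (%s search)\n",
              length(x$unit_ids),
              if (length(x$unit_ids)) ncol(x$vectors) else 0L,
              if (length(x$unit_ids) <= x$params$brute_threshold) "exact"
              else "graph"), sep = "")
  invisible(x)
}

# k-NN neighbour graph for the approximate path; O(n^2) dense build, done once
# and cached in the index environment.
index_graph <- function(index) {
  g <- index$cache$graph
  if (!is.null(g)) return(g)
  V <- index$vectors
  n <- nrow(V)
  m <- min(index$params$m_neighbors, n - 1L)
  sims <- tcrossprod(V)
  g <- matrix(0L, nrow = n, ncol = m)
  for (i in seq_len(n)) {
    ord <- order(-sims[i, ], seq_len(n))
    g[i, ] <- ord[ord != i][seq_len(m)]
  }
  index$cache$graph <- g
  g
}

knn_exact <- function(index, q, k) {
  sims <- as.vector(index$vectors %*% q)
  ord <- order(-sims, seq_along(sims))[seq_len(min(k, length(sims)))]
  data.frame(unit_id = index$unit_ids[ord],
             content_kind = index$content_kinds[ord],
             similarity = sims[ord], stringsAsFactors = FALSE)
}

knn_graph <- function(index, q, k) {
  g <- index_graph(index)
  n <- nrow(index$vectors)
  ef <- max(index$params$ef_search, k)
  sim_of <- function(ids) as.vector(index$vectors[ids, , drop = FALSE] %*% q)
  # deterministic, spread entry points
  entries <- unique(as.integer(round(seq(1L, n, length.out = min(8L, n)))))
  visited <- logical(n); visited[entries] <- TRUE
  cand_ids <- entries; cand_sims <- sim_of(entries)
  expanded <- logical(n)
  repeat {
    open <- which(!expanded[cand_ids])
    if (!length(open)) break
    best <- open[which.max(cand_sims[open])]
    node <- cand_ids[best]
    expanded[node] <- TRUE
    nbrs <- g[node, ]
    nbrs <- nbrs[!visited[nbrs]]
    if (length(nbrs)) {
      visited[nbrs] <- TRUE
      cand_ids <- c(cand_ids, nbrs)
      cand_sims <- c(cand_sims, sim_of(nbrs))
      if (length(cand_ids) > 4L * ef) {
        keep <- order(-cand_sims, cand_ids)[seq_len(2L * ef)]
        keep <- sort(keep)
        cand_ids <- cand_ids[keep]; cand_sims <- cand_sims[keep]
      }
    }
  }
  ord <- order(-cand_sims, cand_ids)[seq_len(min(k, length(cand_ids)))]
  idx <- cand_ids[ord]
  data.frame(unit_id = index$unit_ids[idx],
             content_kind = index$content_kinds[idx],
             similarity = cand_sims[ord], stringsAsFactors = FALSE)
}

#' k-nearest-neighbour search
#'
#' Top-`k` index entries by cosine similarity to `query`, sorted in
#' descending similarity with ties broken by ascending insertion order. Exact
#' below the brute-force threshold; graph-based approximate search (recall
#' near 1 at the default parameters) above it. An empty index returns an
#' empty result.
#'
#' @param index a `vector_index`.
#' @param query numeric query vector (same dimension as the index).
#' @param k number of neighbours (>= 1).
#' @return data.frame with `unit_id`, `content_kind`, `similarity`.
#' @export
knn_search <- function(index, query, k) {
  stopifnot(inherits(index, "vector_index"), k >= 1L)
  if (!length(index$unit_ids))
    return(data.frame(unit_id = character(0), content_kind = character(0),
                      similarity = numeric(0), stringsAsFactors = FALSE))
  if (length(query) != ncol(index$vectors))
    stop_tosrr("query dimension does not match index", "tosrr_input_error")
  nq <- sqrt(sum(query^2))
  if (nq > 0) query <- query / nq
  if (length(index$unit_ids) <= index$params$brute_threshold)
    knn_exact(index, query, k)
  else
    knn_graph(index, query, k)
}

#' Build the keyword inverted index over SPO triples
#'
#' Postings map analyzer tokens of each unit's subject, predicate and object
#' to the unit ids containing them (sorted ascending).
#'
#' @param kb a `knowledge_base`.
#' @param analyzer tokenizer, see [tokenize()].
#' @return a `keyword_index`.
#' @export
build_keyword_index <- function(kb, analyzer = tokenize) {
  unit_tokens <- list()
  postings <- new.env(parent = emptyenv())
  for (u in kb$units) {
    toks <- unique(analyzer(paste(u$triple$subject, u$triple$predicate,
                                  u$triple$object)))
    unit_tokens[[u$unit_id]] <- toks
    for (t in toks) postings[[t]] <- c(postings[[t]], u$unit_id)
  }
  plist <- as.list(postings)
  plist <- lapply(plist, function(ids) sort(unique(ids)))
  structure(list(postings = plist, unit_tokens = unit_tokens,
                 analyzer = analyzer),
            class = "keyword_index")
}

#' Keyword matching over SPO triples
#'
#' Scores each unit by the number of distinct query tokens present among its
#' triple tokens; results are sorted by descending score with ties broken by
#' ascending unit id, zero-score units excluded. The score is invariant to
#' token order and duplication in the query.
#'
#' @param index a `keyword_index`.
#' @param query_text query string.
#' @param limit maximum number of hits.
#' @return data.frame with `unit_id`, `score`.
#' @export
keyword_match <- function(index, query_text, limit = Inf) {
  qt <- unique(index$analyzer(query_text))
  hits <- unlist(lapply(qt, function(t) index$postings[[t]]), use.names = FALSE)
  if (!length(hits))
    return(data.frame(unit_id = character(0), score = integer(0),
                      stringsAsFactors = FALSE))
  ids <- sort(unique(hits))
  scores <- vapply(ids, function(id) sum(qt %in% index$unit_tokens[[id]]),
                   integer(1))
  ord <- order(-scores, ids)
  n <- min(limit, length(ids))
  data.frame(unit_id = ids[ord][seq_len(n)], score = scores[ord][seq_len(n)],
             stringsAsFactors = FALSE)
}
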