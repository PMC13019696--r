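#' Feature-hashing text embedder
#'
#' The default offline embedder: token counts are hashed into `dim` buckets
#' (seeded, so the mapping is stable but configurable) and the bucket-count
#' vector is L2-normalized. It is fully deterministic and needs no model,
#' which makes the retrieval pipeline testable end to end; a production
#' deployment swaps in an adapter for a remote embedding service with the
#' same `function(texts) -> matrix` contract.
#'
#' @param dim embedding dimension (default 256).
#' @param seed integer salt for the token-to-bucket hash.
#' @return a function mapping a character vector of texts to an
#'   `length(texts) x dim` numeric matrix with unit-norm rows (all-zero rows
#'   stay zero).
#' @export
hash_embedder <- function(dim = 256L, seed = 1L) {
  force(dim); force(seed)
  bucket_cache <- new.env(parent = emptyenv())
  bucket_of <- function(token) {
    b <- bucket_cache[[token]]
    if (is.null(b)) {
      h <- digest::digest(paste0(seed, "\x1f", token), algo = "xxhash32")
      # 28 low-order bits keep strtoi within integer range
      b <- strtoi(substr(h, 2, 8), 16L) %% dim + 1L
      bucket_cache[[token]] <- b
    }
    b
  }
  function(texts) {
    out <- matrix(0, nrow = length(texts), ncol = dim)
    for (i in seq_along(texts)) {
      toks <- tokenize(texts[[i]])
      if (!length(toks)) next
      for (t in toks) out[i, bucket_of(t)] <- out[i, bucket_of(t)] + 1
      nrm <- sqrt(sum(out[i, ]^2))
      if (nrm > 0) out[i, ] <- out[i, ] / nrm
    }
    out
  }
}

#' Embed a single text
#'
#' @param text non-empty character scalar.
#' @param embedder a batch embedder, e.g. [hash_embedder()].
#' @return numeric embedding vector.
#' @export
embed <- function(text, embedder = hash_embedder()) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text))
    stop_tosrr("embed() requires a non-empty character scalar", "tosrr_input_error")
  as.numeric(embedder(text)[1, ])
}

#' Cosine similarity
#'
#' `a . b / (|a| |b|)`; if either vector is all zeros the similarity is
#' defined as 0 (with a warning) rather than NaN.
#'
#' @param a,b numeric vectors of equal length.
#' @return similarity in `[-1, 1]`.
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b))
    stop_tosrr("cosine_similarity: dimension mismatch", "tosrr_input_error")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    warning("cosine similarity of a zero vector defined as 0")
    return(0)
  }
  sum(a * b) / (na * nb)
}
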