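#' Default predicate vocabulary
#'
#' The controlled vocabulary for content triples. The predicate `"include"`
#' is reserved for the structural edge linking a tree leaf to a text chunk
#' and is never accepted from an extractor. The set is configurable: pass any
#' character vector wherever a vocabulary is accepted, or load one from a
#' plain-text file (one predicate per line) with [read_vocabulary()].
#'
#' @return character vector of predicates.
#' @export
default_vocabulary <- function() {
  c("treats", "composed_of", "manifests_as", "belongs_to",
    "contraindicated_with")
}

#' @rdname default_vocabulary
#' @param path text file with one predicate per line; `#` comments allowed.
#' @export
read_vocabulary <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  unique(lines)
}

new_spo_triple <- function(subject, predicate, object) {
  stopifnot(nzchar(subject), nzchar(predicate), nzchar(object))
  list(subject = subject, predicate = predicate, object = object)
}

#' Create an empty knowledge base
#'
#' A knowledge base holds one tree per source document (book -> chapter ->
#' title -> knowledge point), an id-addressed collection of SPO-T units
#' (a subject-predicate-object triple bound to the text chunk it came from,
#' plus that chunk's summary and Q&A pairs), and the chunks themselves.
#'
#' @return an empty `knowledge_base`.
#' @export
new_knowledge_base <- function() {
  structure(list(roots = character(0), nodes = list(), units = list(),
                 chunks = list()),
            class = "knowledge_base")
}

#' @export
print.knowledge_base <- function(x, ...) {
  cat(sprintf("<knowledge_base> %d tree(s), %d node(s), %d unit(s), %d chunk(s)\n",
              length(x$roots), length(x$nodes), length(x$units),
              length(x$chunks)))
  invisible(x)
}

# level_kind by depth, with leaves (below the root) always knowledge points.
node_level_kind <- function(depth, is_leaf) {
  if (is_leaf && depth > 1L) return("knowledge_point")
  c("book", "chapter", "title")[min(depth, 3L)]
}

#' Build the document tree and attach chunks
#'
#' Adds one tree root per document to `kb`; every heading becomes a node and
#' each chunk is attached to the leaf matching its `heading_path` through a
#' structural SPO-T unit with the reserved predicate `"include"` (subject =
#' leaf label, object = chunk id).
#'
#' @param kb a `knowledge_base` (a fresh one by default).
#' @param doc a `source_document`.
#' @param chunks chunks produced from `doc` by [segment_chunks()].
#' @return the updated `knowledge_base`.
#' @export
build_tree <- function(doc, chunks, kb = new_knowledge_base()) {
  stopifnot(inherits(doc, "source_document"), inherits(kb, "knowledge_base"))
  add_node <- function(node, parent_id, depth) {
    node_id <- content_id("node", doc$doc_id, parent_id %||% "", node$heading_text,
                          length(kb$nodes))
    kb$nodes[[node_id]] <<- list(
      node_id = node_id, label = node$heading_text,
      level_kind = node_level_kind(depth, !length(node$children)),
      parent_id = parent_id, children = character(0),
      unit_ids = character(0))
    if (is.null(parent_id)) {
      kb$roots <<- c(kb$roots, node_id)
    } else {
      kb$nodes[[parent_id]]$children <<- c(kb$nodes[[parent_id]]$children, node_id)
    }
    for (ch in node$children) add_node(ch, node_id, depth + 1L)
    node_id
  }
  for (nd in doc$nodes) add_node(nd, NULL, 1L)

  for (ch in chunks) {
    leaf_id <- find_node_by_path(kb, ch$heading_path)
    if (is.null(leaf_id))
      stop_tosrr(sprintf("chunk %s: heading path '%s' not present in document tree",
                         ch$chunk_id, paste(ch$heading_path, collapse = " / ")),
                 "tosrr_consistency_error")
    kb$chunks[[ch$chunk_id]] <- ch
    unit <- new_spot_unit(
      triple = new_spo_triple(kb$nodes[[leaf_id]]$label, "include", ch$chunk_id),
      chunk_id = ch$chunk_id, node_id = leaf_id)
    kb <- add_unit(kb, unit)
  }
  kb
}

new_spot_unit <- function(triple, chunk_id, node_id,
                          summary = "", qa_pairs = list()) {
  unit_id <- content_id("unit", triple$subject, triple$predicate, triple$object,
                        chunk_id)
  structure(list(unit_id = unit_id, triple = triple, chunk_id = chunk_id,
                 node_id = node_id, summary = summary, qa_pairs = qa_pairs),
            class = "spot_unit")
}

add_unit <- function(kb, unit) {
  if (!is.null(kb$units[[unit$unit_id]])) return(kb)  # content-hash idempotence
  kb$units[[unit$unit_id]] <- unit
  kb$nodes[[unit$node_id]]$unit_ids <-
    c(kb$nodes[[unit$node_id]]$unit_ids, unit$unit_id)
  kb
}

find_node_by_path <- function(kb, heading_path) {
  cur <- NULL
  candidates <- kb$roots
  for (label in heading_path) {
    hit <- NULL
    for (id in candidates) {
      if (kb$nodes[[id]]$label == label) { hit <- id; break }
    }
    if (is.null(hit)) return(NULL)
    cur <- hit
    candidates <- kb$nodes[[cur]]$children
  }
  cur
}

#' Default deterministic triple extractor
#'
#' A rule-based stand-in for an LLM extractor: for every vocabulary predicate
#' whose surface form (underscores read as spaces) appears in the chunk text,
#' it emits the triple (deepest heading label, predicate, following
#' key-phrase), where the key-phrase is the text after the predicate up to
#' the next punctuation mark.
#'
#' @param vocabulary predicate vocabulary (character vector).
#' @return a function `chunk -> list of triples` usable as the `extractor`
#'   argument of [extract_triples()].
#' @export
default_triple_extractor <- function(vocabulary = default_vocabulary()) {
  force(vocabulary)
  function(chunk) {
    subject <- chunk$heading_path[[length(chunk$heading_path)]]
    out <- list()
    for (pred in vocabulary) {
      surface <- gsub("_", " ", pred, fixed = TRUE)
      re <- paste0("\\b", surface, "\\b[[:space:]]+([^.!?,;:。！？]+)")
      for (m in regmatches(chunk$text, gregexpr(re, chunk$text))[[1]]) {
        obj <- trimws(sub(re, "\\1", m))
        if (nzchar(obj)) out[[length(out) + 1L]] <- new_spo_triple(subject, pred, obj)
      }
    }
    out
  }
}

#' Extract SPO triples from a chunk
#'
#' Runs a pluggable extractor and enforces the vocabulary contract: triples
#' whose predicate is outside the vocabulary (or the reserved `"include"`)
#' are dropped with a message; duplicates are removed keeping the first
#' occurrence. Extractor errors are re-signalled with the chunk id attached.
#'
#' @param chunk a `text_chunk`.
#' @param extractor function `chunk -> list of triples`; see
#'   [default_triple_extractor()].
#' @param vocabulary allowed predicates.
#' @return list of triples (`subject`, `predicate`, `object`).
#' @export
extract_triples <- function(chunk,
                            extractor = default_triple_extractor(vocabulary),
                            vocabulary = default_vocabulary()) {
  raw <- tryCatch(extractor(chunk), error = function(e) {
    stop_tosrr(sprintf("triple extractor failed on chunk %s: %s",
                       chunk$chunk_id, conditionMessage(e)),
               "tosrr_extractor_error")
  })
  out <- list(); seen <- character(0)
  for (tr in raw) {
    if (!tr$predicate %in% vocabulary) {
      message(sprintf("dropping triple with out-of-vocabulary predicate '%s' (chunk %s)",
                      tr$predicate, chunk$chunk_id))
      next
    }
    key <- paste(tr$subject, tr$predicate, tr$object, sep = "\x1f")
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- tr
  }
  out
}

#' Default deterministic content generator
#'
#' Stand-in for an LLM summarizer: the summary is the chunk's leading
#' sentences up to ~30 words, and one Q&A pair asks what the section covers,
#' answered by the first sentence.
#'
#' @return a function `(chunk, candidate) -> list(summary, qa_pairs)`.
#' @export
default_content_generator <- function() {
  function(chunk, candidate = 1L) {
    sentences <- split_sentences(chunk$text)
    if (!length(sentences)) sentences <- chunk$text
    summary <- sentences[[1]]
    i <- 2L
    while (count_words(summary) < 30L && i <= length(sentences)) {
      summary <- paste(summary, sentences[[i]]); i <- i + 1L
    }
    heading <- chunk$heading_path[[length(chunk$heading_path)]]
    list(summary = summary,
         qa_pairs = list(list(
           question = paste0("What does the section '", heading, "' describe?"),
           answer = sentences[[1]])))
  }
}

# Lexical-overlap candidate selector: fraction of candidate summary tokens
# that occur in the chunk; ties keep the earliest candidate.
overlap_score <- function(text, reference_tokens) {
  toks <- tokenize(text)
  if (!length(toks)) return(0)
  mean(toks %in% reference_tokens)
}

#' Generate summary and Q&A content for a chunk
#'
#' Invokes a pluggable generator `n_candidates` times and retains one
#' candidate through a selector (default: highest lexical overlap of the
#' candidate summary with the chunk text; ties keep the first candidate).
#' With `n_candidates = 1` the selector is bypassed.
#'
#' @param chunk a `text_chunk`.
#' @param generator function `(chunk, candidate) -> list(summary, qa_pairs)`.
#' @param n_candidates number of candidates to draw (>= 1).
#' @param selector function `(candidates, chunk) -> index`; `NULL` for the
#'   default overlap selector.
#' @return list with `summary` and `qa_pairs`.
#' @export
generate_content <- function(chunk, generator = default_content_generator(),
                             n_candidates = 2L, selector = NULL) {
  stopifnot(n_candidates >= 1L)
  candidates <- list(); failures <- character(0)
  for (i in seq_len(n_candidates)) {
    cand <- tryCatch(generator(chunk, i),
                     error = function(e) conditionMessage(e))
    if (is.character(cand)) failures <- c(failures, cand)
    else candidates[[length(candidates) + 1L]] <- cand
  }
  if (!length(candidates))
    stop_tosrr(sprintf("content generator failed on all %d candidate(s) for chunk %s: %s",
                       n_candidates, chunk$chunk_id,
                       paste(unique(failures), collapse = "; ")),
               "tosrr_content_error")
  if (length(candidates) == 1L) return(candidates[[1]])
  if (is.null(selector)) {
    ref <- tokenize(chunk$text)
    scores <- vapply(candidates, function(c) overlap_score(c$summary, ref),
                     numeric(1))
    best <- which.max(scores)  # which.max keeps the first of tied maxima
  } else {
    best <- selector(candidates, chunk)
  }
  candidates[[best]]
}

#' Hierarchical context path of a unit
#'
#' The root-to-leaf node labels above a unit's attachment point; this path is
#' rendered next to every recalled unit so cross-chapter provenance stays
#' visible to the generator.
#'
#' @param kb a `knowledge_base`.
#' @param unit_id unit identifier.
#' @return character vector of node labels, root first.
#' @export
get_context_path <- function(kb, unit_id) {
  unit <- kb$units[[unit_id]]
  if (is.null(unit))
    stop_tosrr(sprintf("unknown unit id '%s'", unit_id), "tosrr_lookup_error")
  labels <- character(0)
  id <- unit$node_id
  while (!is.null(id)) {
    labels <- c(kb$nodes[[id]]$label, labels)
    id <- kb$nodes[[id]]$parent_id
  }
  labels
}

#' Validate knowledge-base referential integrity
#'
#' Checks that unit ids are unique and resolve, every unit's chunk and node
#' exist, units are attached only to leaf nodes, parent/child links are
#' consistent, and every chunk is attached through exactly one `"include"`
#' unit.
#'
#' @param kb a `knowledge_base`.
#' @return `TRUE` invisibly; signals a consistency error otherwise.
#' @export
validate_kb <- function(kb) {
  fail <- function(msg) stop_tosrr(msg, "tosrr_consistency_error")
  if (anyDuplicated(names(kb$units))) fail("duplicate unit ids")
  for (u in kb$units) {
    if (is.null(kb$chunks[[u$chunk_id]]))
      fail(sprintf("unit %s references missing chunk %s", u$unit_id, u$chunk_id))
    nd <- kb$nodes[[u$node_id]]
    if (is.null(nd))
      fail(sprintf("unit %s references missing node %s", u$unit_id, u$node_id))
    if (length(nd$children))
      fail(sprintf("unit %s attached to non-leaf node %s", u$unit_id, nd$node_id))
    if (!u$unit_id %in% nd$unit_ids)
      fail(sprintf("unit %s missing from node %s attachment list", u$unit_id, nd$node_id))
  }
  for (nd in kb$nodes) {
    for (cid in nd$children) {
      if (is.null(kb$nodes[[cid]]) || !identical(kb$nodes[[cid]]$parent_id, nd$node_id))
        fail(sprintf("broken parent/child link at node %s", nd$node_id))
    }
    for (uid in nd$unit_ids) if (is.null(kb$units[[uid]]))
      fail(sprintf("node %s lists missing unit %s", nd$node_id, uid))
  }
  include_per_chunk <- table(vapply(
    Filter(function(u) u$triple$predicate == "include", kb$units),
    function(u) u$chunk_id, character(1)))
  for (cid in names(kb$chunks)) {
    if (is.na(include_per_chunk[cid]) || include_per_chunk[cid] != 1L)
      fail(sprintf("chunk %s is not attached through exactly one include unit", cid))
  }
  invisible(TRUE)
}

#' Build a knowledge base end to end
#'
#' Convenience pipeline: parse raw documents (unless already parsed), segment
#' them into chunks, build the trees, then extract content triples and
#' generate summaries/Q&A pairs for every chunk, attaching all resulting
#' SPO-T units to the chunk's leaf.
#'
#' @param docs list of raw document texts or `source_document`s.
#' @param vocabulary predicate vocabulary.
#' @param extractor,generator pluggable backends (deterministic defaults).
#' @param min_words,max_words segmentation band.
#' @param n_candidates content candidates per chunk.
#' @return a validated `knowledge_base`.
#' @export
build_knowledge_base <- function(docs, vocabulary = default_vocabulary(),
                                 extractor = default_triple_extractor(vocabulary),
                                 generator = default_content_generator(),
                                 min_words = 200L, max_words = 300L,
                                 n_candidates = 2L) {
  kb <- new_knowledge_base()
  for (doc in docs) {
    if (!inherits(doc, "source_document")) doc <- parse_document(doc)
    chunks <- segment_chunks(doc, min_words, max_words)
    kb <- build_tree(doc, chunks, kb)
    for (ch in chunks) {
      leaf_id <- find_node_by_path(kb, ch$heading_path)
      content <- generate_content(ch, generator, n_candidates)
      for (tr in extract_triples(ch, extractor, vocabulary)) {
        kb <- add_unit(kb, new_spot_unit(tr, ch$chunk_id, leaf_id,
                                         summary = content$summary,
                                         qa_pairs = content$qa_pairs))
      }
      # attach the generated content to the structural include unit as well,
      # so chunks with no vocabulary hits still carry retrievable content
      inc <- Filter(function(u) u$triple$predicate == "include" &&
                      u$chunk_id == ch$chunk_id, kb$units)[[1]]
      kb$units[[inc$unit_id]]$summary <- content$summary
      kb$units[[inc$unit_id]]$qa_pairs <- content$qa_pairs
    }
  }
  validate_kb(kb)
  kb
}
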