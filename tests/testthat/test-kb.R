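test_that("build_tree attaches every chunk to its leaf via an include unit", {
  doc <- parse_document(tiny_doc_text())
  chunks <- segment_chunks(doc)
  kb <- build_tree(doc, chunks)
  expect_length(kb$roots, 1L)
  expect_length(kb$units, 4L)
  expect_true(all(vapply(kb$units, function(u) u$triple$predicate,
                         character(1)) == "include"))
  validate_kb(kb)
  # depth 3: book -> chapter -> knowledge point
  leaf_kinds <- vapply(kb$nodes, function(n) n$level_kind, character(1))
  expect_equal(sum(leaf_kinds == "knowledge_point"), 4L)
  expect_equal(sum(leaf_kinds == "chapter"), 2L)
  expect_equal(sum(leaf_kinds == "book"), 1L)

  u1 <- kb$units[[1]]
  expect_equal(get_context_path(kb, u1$unit_id),
               kb$chunks[[u1$chunk_id]]$heading_path)
})

test_that("empty chunk lists and merged documents behave", {
  doc <- parse_document(tiny_doc_text())
  kb <- build_tree(doc, list())
  expect_length(kb$units, 0L)

  doc2 <- parse_document("# Other Book\n\n## C\n\n### pt\n\nsome treats text here.\n")
  kb2 <- build_tree(doc2, segment_chunks(doc2), kb = build_tree(doc, segment_chunks(doc)))
  expect_length(kb2$roots, 2L)
  expect_false(anyDuplicated(names(kb2$nodes)) > 0)
  validate_kb(kb2)
})

test_that("a chunk with an unknown heading path is a consistency error", {
  doc <- parse_document(tiny_doc_text())
  chunks <- segment_chunks(doc)
  chunks[[1]]$heading_path <- c("Anatomy Primer", "No Such Chapter")
  expect_error(build_tree(doc, chunks), "heading path",
               class = "tosrr_consistency_error")
})

test_that("default extractor emits (heading, predicate, key-phrase) per hit", {
  ch <- structure(list(chunk_id = "c1", doc_id = "d",
                       heading_path = c("Book", "ginseng"),
                       text = "Ginseng treats fatigue. It also treats weak qi, among others.",
                       word_count = 11L), class = "text_chunk")
  trs <- extract_triples(ch)
  expect_equal(trs, list(
    list(subject = "ginseng", predicate = "treats", object = "fatigue"),
    list(subject = "ginseng", predicate = "treats", object = "weak qi")))

  no_hit <- ch; no_hit$text <- "Nothing of note here."
  expect_equal(extract_triples(no_hit), list())
})

test_that("extractor output is vocabulary-filtered and deduplicated", {
  ch <- structure(list(chunk_id = "c1", doc_id = "d", heading_path = "h",
                       text = "x", word_count = 1L), class = "text_chunk")
  fake <- function(chunk) list(
    list(subject = "s", predicate = "treats", object = "o"),
    list(subject = "s", predicate = "cures", object = "o"),      # out of vocab
    list(subject = "s", predicate = "include", object = "o"),    # reserved
    list(subject = "s", predicate = "treats", object = "o"))     # duplicate
  expect_message(trs <- extract_triples(ch, fake), "out-of-vocabulary")
  expect_equal(trs, list(list(subject = "s", predicate = "treats", object = "o")))

  failing <- function(chunk) stop("backend down")
  expect_error(extract_triples(ch, failing), "c1",
               class = "tosrr_extractor_error")
})

test_that("content generation selects the highest-overlap candidate", {
  ch <- structure(list(chunk_id = "c1", doc_id = "d", heading_path = "h",
                       text = "alpha beta gamma delta epsilon.",
                       word_count = 5L), class = "text_chunk")
  gen <- function(chunk, candidate) {
    if (candidate == 1L) list(summary = "alpha beta gamma unrelated", qa_pairs = list())
    else list(summary = "zeta eta theta iota", qa_pairs = list())
  }
  # independent overlap computation: 3/4 vs 0/4
  out <- generate_content(ch, gen, n_candidates = 2L)
  expect_equal(out$summary, "alpha beta gamma unrelated")

  # ties keep the first candidate
  tie_gen <- function(chunk, candidate)
    list(summary = c("alpha one", "beta one")[candidate], qa_pairs = list())
  expect_equal(generate_content(ch, tie_gen, n_candidates = 2L)$summary,
               "alpha one")

  # n_candidates = 1 bypasses the selector entirely
  expect_equal(generate_content(ch, gen, n_candidates = 1L,
                                selector = function(...) stop("never"))$summary,
               "alpha beta gamma unrelated")

  expect_error(generate_content(ch, function(...) stop("down"), 2L),
               class = "tosrr_content_error")
  # one failing candidate is tolerated when another succeeds
  flaky <- function(chunk, candidate)
    if (candidate == 1L) stop("down") else list(summary = "alpha", qa_pairs = list())
  expect_equal(generate_content(ch, flaky, 2L)$summary, "alpha")
})

test_that("context paths run root to leaf and unknown ids error", {
  kb <- tiny_kb()
  uid <- names(kb$units)[[1]]
  path <- get_context_path(kb, uid)
  expect_equal(path[1], "Anatomy Primer")
  expect_length(path, 3L)
  expect_error(get_context_path(kb, "nope"), class = "tosrr_lookup_error")

  # degenerate depth-1 document: single-label path
  d1 <- parse_document(paste("# Lone", make_words(20, "x"), sep = "\n\n"))
  kb1 <- build_tree(d1, segment_chunks(d1))
  expect_equal(get_context_path(kb1, names(kb1$units)[[1]]), "Lone")
})

test_that("triple count is monotone as chunks are added", {
  doc <- parse_document(tiny_doc_text())
  chunks <- segment_chunks(doc)
  sizes <- vapply(seq_along(chunks), function(k)
    length(build_tree(doc, chunks[seq_len(k)])$units), integer(1))
  expect_true(all(diff(sizes) >= 0))
  ids_small <- names(build_tree(doc, chunks[1:2])$units)
  ids_big <- names(build_tree(doc, chunks)$units)
  expect_true(all(ids_small %in% ids_big))
})

test_that("knowledge bases round-trip losslessly through the JSONL format", {
  kb <- tiny_kb()
  dir <- withr::local_tempdir()
  save_kb(kb, dir)
  expect_equal(load_kb(dir), kb)

  # empty knowledge base round-trips too
  dir2 <- withr::local_tempdir()
  save_kb(new_knowledge_base(), dir2)
  expect_equal(load_kb(dir2), new_knowledge_base())

  # truncated file is a format error
  units_file <- file.path(dir, "units.jsonl")
  lines <- readLines(units_file)
  writeLines(lines[-length(lines)], units_file)
  expect_error(load_kb(dir), "truncated", class = "tosrr_format_error")
  writeLines(lines, units_file)

  # schema version mismatch is a format error
  mpath <- file.path(dir, "manifest.json")
  m <- jsonlite::fromJSON(mpath)
  m$schema_version <- 99L
  writeLines(as.character(jsonlite::toJSON(m, auto_unbox = TRUE)), mpath)
  expect_error(load_kb(dir), "schema version", class = "tosrr_format_error")
})

test_that("the full build pipeline yields a valid knowledge base with content", {
  kb <- tiny_kb()
  expect_true(validate_kb(kb))
  preds <- vapply(kb$units, function(u) u$triple$predicate, character(1))
  expect_setequal(unique(preds),
                  c("include", "treats", "belongs_to", "composed_of",
                    "manifests_as"))
  # every include unit carries the generated summary and Q&A content
  inc <- Filter(function(u) u$triple$predicate == "include", kb$units)
  expect_true(all(vapply(inc, function(u) nzchar(u$summary), logical(1))))
  expect_true(all(vapply(inc, function(u) length(u$qa_pairs) > 0, logical(1))))
})
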