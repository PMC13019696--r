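# generator wrapper that counts invocations
counting_generator <- function(inner = extractive_generator()) {
  calls <- 0L
  gen <- function(prompt_bundle, state = NULL) {
    calls <<- calls + 1L
    inner(prompt_bundle, state)
  }
  list(generator = gen, calls = function() calls)
}

test_that("with all-approve judges the loop answers in one pass", {
  w <- synthetic_world(seed = 42)
  cg <- counting_generator()
  bk <- backends(cg$generator, static_judge(), split_decomposer(),
                 suffix_reformulator())
  pt <- w$corpus$points[[1]]
  q <- sprintf("Which of the following does %s %s?", pt$subject,
               gsub("_", " ", pt$predicate))
  res <- run_reflection_loop(q, w$kb, w$indexes, bk)
  expect_equal(res$status, "answered")
  expect_equal(cg$calls(), 1L)
  expect_equal(res$state$regen_count, 0L)
  steps <- vapply(res$trace$events, function(e) e$step, character(1))
  expect_equal(steps, c("recall", "relevance_filter", "generate",
                        "support_check", "helpfulness_check"))
})

test_that("relevance filtering keeps exactly the approved units in order", {
  w <- synthetic_world(seed = 42)
  q <- "Which of the following does entity_b1c1p1 treats?"
  rec <- multi_way_recall(w$kb, w$indexes, q)
  ids <- rec$entries$unit_id
  expect_equal(as.character(assess_relevance(rec, q, static_judge(), w$kb)), ids)
  expect_length(assess_relevance(rec, q, static_judge(relevance = FALSE), w$kb), 0L)
  keep <- ids[c(1, 3)]
  expect_equal(as.character(assess_relevance(rec, q, relevance_table_judge(keep), w$kb)),
               keep)
  # a failing judge is a conservative negative verdict
  failing <- function(kind, payload) stop("judge offline")
  expect_length(assess_relevance(rec, q, failing, w$kb), 0L)
})

test_that("empty recall enters decomposition before any generation", {
  kb <- new_knowledge_base()
  idx <- build_indexes(kb)
  cg <- counting_generator()
  decompose_calls <- 0L
  dec <- function(q) { decompose_calls <<- decompose_calls + 1L; q }
  bk <- backends(cg$generator, static_judge(), dec, suffix_reformulator())
  res <- run_reflection_loop("anything", kb, idx, bk)
  expect_equal(decompose_calls, 1L)
  expect_equal(cg$calls(), 0L)
  expect_equal(res$status, "cap_exhausted")
  expect_true(is.na(res$answer))
  steps <- vapply(res$trace$events, function(e) e$step, character(1))
  expect_true("decompose" %in% steps)
  expect_false("generate" %in% steps)
  # decomposition happens at most decomp_cap times across the whole run
  expect_equal(sum(steps == "decompose"), 1L)
  expect_equal(sum(steps == "reformulate"), 2L)
})

test_that("decomposed sub-questions pool relevant units from disjoint points", {
  w <- synthetic_world(seed = 42, cross_link_rate = 0)
  pts <- w$corpus$points
  qa <- sprintf("tell me about %s", pts[[1]]$subject)
  qb <- sprintf("tell me about %s", pts[[5]]$subject)
  q <- paste(qa, "and", qb)
  # a judge that only accepts units when the active question names exactly one entity
  judge <- function(kind, payload) {
    if (kind != "relevance") return(list(verdict = TRUE, rationale = ""))
    ents <- grep("^entity_", tokenize(payload$question), value = TRUE)
    list(verdict = length(ents) == 1L &&
           ents %in% tokenize(payload$unit_text), rationale = "")
  }
  bk <- backends(extractive_generator(), judge, split_decomposer(" and "),
                 suffix_reformulator())
  res <- run_reflection_loop(q, w$kb, w$indexes, bk)
  expect_equal(res$state$sub_questions, c(qa, qb))
  ua <- point_units(w$kb, pts[[1]])$unit_ids
  ub <- point_units(w$kb, pts[[5]])$unit_ids
  expect_true(any(res$state$relevant_units %in% ua))
  expect_true(any(res$state$relevant_units %in% ub))
  expect_true(all(res$state$relevant_units %in% c(ua, ub)))
})

test_that("a rejecting support judge regenerates up to the cap then reformulates", {
  w <- synthetic_world(seed = 42)
  cg <- counting_generator()
  bk <- backends(cg$generator, static_judge(support = FALSE),
                 split_decomposer(), suffix_reformulator())
  q <- "Which of the following does entity_b1c1p1 treats?"
  res <- run_reflection_loop(q, w$kb, w$indexes, bk,
                             caps = reflection_caps(regen = 3L, reform = 2L))
  steps <- vapply(res$trace$events, function(e) e$step, character(1))
  # 1 + 3 generations on the first pass, then one per reformulated pass
  first_reform <- which(steps == "reformulate")[1]
  expect_equal(sum(steps[seq_len(first_reform)] == "generate"), 4L)
  expect_equal(cg$calls(), 4L + 2L)
  expect_equal(res$state$regen_count, 3L)
  expect_equal(res$state$reform_count, 2L)
  expect_equal(res$status, "cap_exhausted")
  expect_false(is.na(res$answer))  # best-effort draft retained
})

test_that("an unhelpful answer triggers reformulation until the cap", {
  w <- synthetic_world(seed = 42)
  cg <- counting_generator()
  reform_seen <- character(0)
  ref <- function(q) { reform_seen <<- c(reform_seen, q); q }  # echoes unchanged
  bk <- backends(cg$generator, static_judge(helpfulness = FALSE),
                 split_decomposer(), ref)
  q <- "Which of the following does entity_b1c1p1 treats?"
  res <- run_reflection_loop(q, w$kb, w$indexes, bk)
  expect_equal(cg$calls(), 3L)  # one generation per pass, reform cap 2
  expect_equal(res$state$reform_count, 2L)
  # an identical reformulation still consumes a credit
  expect_length(reform_seen, 2L)
  expect_equal(res$status, "cap_exhausted")
})

test_that("the loop terminates within the closed-form call bound for any judge", {
  w <- synthetic_world(seed = 42)
  q <- "Which of the following does entity_b1c1p1 treats?"
  caps <- reflection_caps(regen = 2L, reform = 2L, decomp = 1L)
  bound <- caps$reform + 1L + caps$regen
  set.seed(77)
  for (i in 1:12) {
    verdict_table <- stats::runif(200) < stats::runif(1)
    call_idx <- 0L
    judge <- function(kind, payload) {
      call_idx <<- call_idx + 1L
      list(verdict = verdict_table[call_idx], rationale = "scripted")
    }
    cg <- counting_generator()
    bk <- backends(cg$generator, judge, split_decomposer(),
                   suffix_reformulator())
    res <- run_reflection_loop(q, w$kb, w$indexes, bk, caps = caps)
    expect_true(res$status %in% c("answered", "cap_exhausted"))
    expect_lte(cg$calls(), bound)
    expect_lte(res$state$regen_count, caps$regen)
    expect_lte(res$state$reform_count, caps$reform)
    expect_lte(res$state$decomp_count, caps$decomp)
  }
})

test_that("replaying a trace's verdicts reproduces the branch sequence", {
  w <- synthetic_world(seed = 42)
  q <- "Which of the following does entity_b1c1p1 treats?"
  set.seed(123)
  verdict_table <- stats::runif(300) < 0.6
  make_scripted <- function() {
    call_idx <- 0L
    function(kind, payload) {
      call_idx <<- call_idx + 1L
      list(verdict = verdict_table[call_idx], rationale = "scripted")
    }
  }
  run <- function() {
    bk <- backends(extractive_generator(), make_scripted(), split_decomposer(),
                   suffix_reformulator())
    run_reflection_loop(q, w$kb, w$indexes, bk)
  }
  r1 <- run(); r2 <- run()
  s1 <- vapply(r1$trace$events, function(e) e$step, character(1))
  s2 <- vapply(r2$trace$events, function(e) e$step, character(1))
  expect_identical(s1, s2)
  expect_identical(r1$status, r2$status)
  expect_identical(r1$answer, r2$answer)
})

test_that("with all-approve judges the reflective loop equals plain SPO-T RAG", {
  w <- synthetic_world(seed = 42)
  bk <- backends(extractive_generator(), static_judge(), split_decomposer(),
                 suffix_reformulator())
  mcq <- generate_mcq(w$corpus, 6L, seed = 8L)
  for (item in mcq$bank) {
    full <- answer_question(item$stem, w$kb, w$indexes, bk, mode = "tosrr")
    ablation <- answer_question(item$stem, w$kb, w$indexes, bk, mode = "spot_rag")
    expect_identical(full$answer, ablation$answer)
  }
})

test_that("generation retries once and then errors; traces export as JSONL", {
  w <- synthetic_world(seed = 42)
  flaky_calls <- 0L
  flaky <- function(prompt_bundle, state = NULL) {
    flaky_calls <<- flaky_calls + 1L
    if (flaky_calls == 1L) stop("transient") else "recovered answer"
  }
  pb <- assemble_prompt(multi_way_recall(w$kb, w$indexes, "entity_b1c1p1"),
                        "q", w$kb)
  expect_equal(generate_answer(NULL, flaky, pb), "recovered answer")
  expect_error(generate_answer(NULL, function(...) stop("down"), pb),
               class = "tosrr_generation_error")

  bk <- backends(extractive_generator(), static_judge(), split_decomposer(),
                 suffix_reformulator())
  res <- run_reflection_loop("entity_b1c1p1 treats what?", w$kb, w$indexes, bk)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_trace_jsonl(res$trace, path)
  lines <- readLines(path)
  expect_length(lines, length(res$trace$events) + 1L)
  last <- jsonlite::fromJSON(lines[length(lines)])
  expect_equal(last$terminal_status, res$status)
})
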