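make_items <- function(n_factual, n_case) {
  opts <- c(A = "alpha", B = "beta", C = "gamma", D = "delta", E = "epsilon")
  c(lapply(seq_len(n_factual), function(i)
      mcq_item(sprintf("f%03d", i), sprintf("factual stem %d", i), opts, "A",
               "factual")),
    lapply(seq_len(n_case), function(i)
      mcq_item(sprintf("c%03d", i), sprintf("case stem %d", i), opts, "B",
               "case_analysis")))
}

# responses hitting exactly k correct within each category
responses_hitting <- function(items, k_factual, k_case) {
  vapply(items, function(it) it$answer_key, character(1)) -> keys
  cat <- vapply(items, function(it) it$category, character(1))
  out <- character(length(items))
  fi <- which(cat == "factual"); ci <- which(cat == "case_analysis")
  out[fi] <- c(rep(keys[fi[1]], k_factual),
               rep(setdiff(LETTERS[1:5], keys[fi[1]])[1],
                   length(fi) - k_factual))
  out[ci] <- c(rep(keys[ci[1]], k_case),
               rep(setdiff(LETTERS[1:5], keys[ci[1]])[1],
                   length(ci) - k_case))
  out
}

test_that("choice extraction finds the first standalone label", {
  expect_equal(extract_choice("The answer is C."), "C")
  expect_equal(extract_choice("B) is right but A is wrong"), "B")
  expect_equal(extract_choice("no label present"), NA_character_)
  expect_equal(extract_choice("CAB is not a label, but (D) is"), "D")
  expect_equal(extract_choice("answer: e is not a label either"), NA_character_)
  expect_equal(extract_choice(""), NA_character_)
})

test_that("exam scoring reproduces the published score arithmetic", {
  items <- make_items(420L, 180L)
  r1 <- score_exam(items, responses_hitting(items, 324L, 130L))
  expect_equal(r1$factual_score, 324L)
  expect_equal(r1$case_score, 130L)
  expect_equal(r1$total_score, 454L)
  expect_equal(r1$percentage, 75.67)

  r2 <- score_exam(items, responses_hitting(items, 204L, 95L))
  expect_equal(r2$total_score, 299L)
  expect_equal(r2$percentage, 49.83)

  all_right <- vapply(items, function(it) it$answer_key, character(1))
  expect_equal(score_exam(items, all_right)$percentage, 100)

  # conservation: total equals the per-item correctness sum
  expect_equal(r1$total_score, sum(r1$correct))
  # abstentions score zero
  expect_equal(score_exam(items[1:2], c(NA, "A"))$total_score, 1L)
})

test_that("percentages round half up, away from the IEEE even rule", {
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(75.665, 2), 75.67)
  expect_equal(round_half_up(-0.125, 2), -0.13)
  expect_equal(round(0.125, 2), 0.12)  # the behaviour we are avoiding
})

test_that("round sampling is seeded, uniform, and excludes KB-overlapping items", {
  items <- make_items(70L, 30L)
  s1 <- sample_round(items, 40L, seed = 5L)
  s2 <- sample_round(items, 40L, seed = 5L)
  expect_identical(s1, s2)
  expect_length(unique(vapply(s1, function(it) it$item_id, character(1))), 40L)

  perm <- sample_round(items, length(items), seed = 1L)
  expect_setequal(vapply(perm, function(it) it$item_id, character(1)),
                  vapply(items, function(it) it$item_id, character(1)))

  # an item whose stem equals a KB chunk text is excluded before sampling
  kb <- tiny_kb()
  leak <- mcq_item("leak", kb$chunks[[1]]$text,
                   c(A = "x", B = "y"), "A", "factual")
  bank <- c(items, list(leak))
  got <- sample_round(bank, length(items), seed = 2L, kb = kb)
  expect_false("leak" %in% vapply(got, function(it) it$item_id, character(1)))

  expect_error(sample_round(items, 1000L), class = "tosrr_input_error")
})

test_that("question banks round-trip through JSONL", {
  items <- make_items(3L, 2L)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_bank_jsonl(items, path)
  expect_equal(read_bank_jsonl(path), items)
})

test_that("recall accuracy averages entry judgments over raters and items", {
  # 10 raters x 10 items x 15 entries with 570 positive judgments
  judgments <- list()
  pos_left <- 570L
  for (r in 1:10) for (i in 1:10) {
    k <- min(pos_left, 6L)
    if (r == 10 && i == 10) k <- pos_left
    pos_left <- pos_left - k
    judgments[[length(judgments) + 1L]] <- list(
      rater_id = r, item_id = i, entry_scores = c(rep(1, k), rep(0, 15 - k)))
  }
  expect_equal(sum(unlist(lapply(judgments, `[[`, "entry_scores"))), 570)
  expect_equal(recall_accuracy(judgments), 0.38)
  expect_equal(recall_total_score(judgments), 57)

  ones <- list(list(rater_id = 1, item_id = 1, entry_scores = rep(1, 15)))
  expect_equal(recall_accuracy(ones), 1)
  zeros <- list(list(rater_id = 1, item_id = 1, entry_scores = rep(0, 15)))
  expect_equal(recall_accuracy(zeros), 0)
})

test_that("context precision equals average precision over the retrieved list", {
  expect_equal(context_precision(c(1, 1, 1)), 1)
  expect_equal(context_precision(c(1, 0, 1)), (1 + 2/3) / 2)
  expect_equal(context_precision(c(0, 0, 0)), 0)

  ap_oracle <- function(labels) {
    ks <- which(labels == 1)
    if (!length(ks)) return(0)
    mean(vapply(ks, function(k) sum(labels[1:k]) / k, numeric(1)))
  }
  set.seed(4)
  for (i in 1:30) {
    labels <- stats::rbinom(sample(1:20, 1), 1, 0.4)
    expect_equal(context_precision(labels), ap_oracle(labels))
  }
})

test_that("context recall, entity recall and semantic similarity behave", {
  ctx <- c("ginseng treats fatigue in deficient patients",
           "ephedra contraindicated with hypertension")
  expect_equal(context_recall(ctx, c("ginseng treats fatigue",
                                     "ephedra contraindicated")), 1)
  expect_equal(context_recall(ctx, c("ginseng treats fatigue",
                                     "rhubarb purges heat")), 0.5)
  expect_equal(context_entity_recall(ctx, c("ginseng", "ephedra", "rhubarb",
                                            "licorice")), 0.5)
  expect_equal(semantic_similarity("same words here", "same words here"), 1)
  s <- semantic_similarity("completely different", "unrelated text")
  expect_gte(s, 0); expect_lte(s, 1)
})

test_that("judge-scored metrics are a pluggable surface with no offline default", {
  expect_error(llm_judged_metric("faithfulness", "q", "a"),
               class = "tosrr_input_error")
  judge <- function(metric, payload) if (metric == "faithfulness") 0.75 else 0.5
  expect_equal(llm_judged_metric("faithfulness", "q", "a", judge = judge), 0.75)
  expect_equal(llm_judged_metric("answer_relevancy", "q", "a", judge = judge), 0.5)
})

test_that("all proportion metrics stay within their ranges", {
  set.seed(6)
  for (i in 1:10) {
    labels <- stats::rbinom(10, 1, 0.5)
    expect_gte(context_precision(labels), 0)
    expect_lte(context_precision(labels), 1)
  }
  items <- make_items(7L, 3L)
  res <- score_exam(items, sample(LETTERS[1:5], 10, replace = TRUE))
  expect_gte(res$percentage, 0); expect_lte(res$percentage, 100)
})
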