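#' Multiple-choice question items
#'
#' An item has a stem, labelled options (A..E), an answer key, a category
#' (`"factual"` for knowledge-recall items, `"case_analysis"` for items
#' requiring combined reasoning), and a point value (default 1).
#'
#' @param item_id opaque identifier.
#' @param stem question text.
#' @param options named character vector, names from `LETTERS`.
#' @param answer_key label of the correct option.
#' @param category `"factual"` or `"case_analysis"`.
#' @param points integer point value.
#' @return an `mcq_item`.
#' @export
mcq_item <- function(item_id, stem, options, answer_key,
                     category = c("factual", "case_analysis"), points = 1L) {
  category <- match.arg(category)
  stopifnot(!is.null(names(options)), all(names(options) %in% LETTERS),
            answer_key %in% names(options))
  structure(list(item_id = item_id, stem = stem, options = options,
                 answer_key = answer_key, category = category,
                 points = as.integer(points)),
            class = "mcq_item")
}

#' Read / write question banks as JSONL
#'
#' One item per line with fields `item_id`, `stem`, `options` (object keyed
#' by label), `answer_key`, `category`, `points`.
#'
#' @param bank list of `mcq_item`s.
#' @param path file path.
#' @return `read_bank_jsonl()` returns the item list.
#' @export
write_bank_jsonl <- function(bank, path) {
  lines <- vapply(bank, function(it)
    as.character(jsonlite::toJSON(list(
      item_id = it$item_id, stem = it$stem, options = as.list(it$options),
      answer_key = it$answer_key, category = it$category, points = it$points),
      auto_unbox = TRUE)), character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_bank_jsonl
#' @export
read_bank_jsonl <- function(path) {
  lapply(readLines(path, warn = FALSE), function(l) {
    x <- jsonlite::fromJSON(l)
    mcq_item(x$item_id, x$stem, unlist(x$options), x$answer_key, x$category,
             x$points)
  })
}

#' Extract the chosen option from free-text model output
#'
#' Grammar: the first standalone option label (not embedded in a longer
#' alphanumeric token) decides the choice; if no label occurs the model
#' abstains (`NA`), which scores zero.
#'
#' @param answer_text model answer text.
#' @param option_labels candidate labels (default `A`-`E`).
#' @return a label or `NA_character_` (abstain).
#' @export
extract_choice <- function(answer_text, option_labels = LETTERS[1:5]) {
  if (is.na(answer_text) || !nzchar(answer_text)) return(NA_character_)
  re <- paste0("(?<![A-Za-z0-9])(", paste(option_labels, collapse = "|"),
               ")(?![A-Za-z0-9])")
  m <- regexpr(re, answer_text, perl = TRUE)
  if (m == -1L) return(NA_character_)
  regmatches(answer_text, m)
}

#' Score an exam round
#'
#' One response per item: a bare label, or free text from which the label is
#' extracted by [extract_choice()]. Scores are summed per category and the
#' percentage is `100 * total_score / total_points`, rounded half-up to two
#' decimals.
#'
#' @param items list of `mcq_item`s.
#' @param responses character vector of responses, one per item.
#' @return an `exam_result`: `correct` (logical per item), `factual_score`,
#'   `case_score`, `total_score`, `total_points`, `percentage`.
#' @export
score_exam <- function(items, responses) {
  stopifnot(length(items) == length(responses))
  labels <- vapply(seq_along(items), function(i) {
    r <- responses[[i]]
    if (!is.na(r) && r %in% names(items[[i]]$options)) r
    else extract_choice(r, names(items[[i]]$options))
  }, character(1))
  correct <- vapply(seq_along(items), function(i)
    !is.na(labels[i]) && labels[i] == items[[i]]$answer_key, logical(1))
  points <- vapply(items, function(it) it$points, integer(1))
  category <- vapply(items, function(it) it$category, character(1))
  factual_score <- sum(points[correct & category == "factual"])
  case_score <- sum(points[correct & category == "case_analysis"])
  total_points <- sum(points)
  total_score <- factual_score + case_score
  structure(list(correct = correct, factual_score = factual_score,
                 case_score = case_score, total_score = total_score,
                 total_points = total_points,
                 percentage = round_half_up(100 * total_score / total_points, 2)),
            class = "exam_result")
}

#' @export
print.exam_result <- function(x, ...) {
  cat(sprintf("<exam_result> factual %d + case %d = %d / %d (%.2f%%)\n",
              x$factual_score, x$case_score, x$total_score, x$total_points,
              x$percentage))
  invisible(x)
}

normalize_text_hash <- function(text) {
  digest::digest(tolower(gsub("\\s+", " ", trimws(text))), algo = "xxhash64")
}

#' Sample an exam round from a question bank
#'
#' Uniform sample of `n` items without replacement, deterministic under
#' `seed`. If a knowledge base is supplied, items whose normalized stem text
#' hash matches any knowledge-base chunk are excluded before sampling, so the
#' test set never overlaps the retrieval corpus.
#'
#' @param bank list of `mcq_item`s.
#' @param n round size (default 600).
#' @param seed integer seed.
#' @param kb optional `knowledge_base` used for the overlap check.
#' @return list of sampled `mcq_item`s.
#' @export
sample_round <- function(bank, n = 600L, seed = 1L, kb = NULL) {
  if (!is.null(kb)) {
    chunk_hashes <- vapply(kb$chunks, function(ch) normalize_text_hash(ch$text),
                           character(1))
    bank <- Filter(function(it) !(normalize_text_hash(it$stem) %in% chunk_hashes),
                   bank)
  }
  if (n > length(bank))
    stop_tosrr(sprintf("cannot sample %d items from a bank of %d", n,
                       length(bank)), "tosrr_input_error")
  with_seed(seed, bank[sample.int(length(bank), n)])
}

#' Recall accuracy from expert entry judgments
#'
#' Each judgment scores the retrieved entries of one item for one rater with
#' 0/1 ("contributed to correctness"). Accuracy is the grand mean: the sum of
#' all entry scores divided by raters x items x entries per item.
#' `recall_total_score()` is the companion per-rater average total (sum of
#' scores / number of raters).
#'
#' @param judgments list of records `list(rater_id, item_id, entry_scores)`.
#' @return proportion in `[0, 1]`.
#' @export
recall_accuracy <- function(judgments) {
  scores <- unlist(lapply(judgments, function(j) j$entry_scores))
  if (!length(scores)) return(0)
  stopifnot(all(scores %in% c(0, 1)))
  mean(scores)
}

#' @rdname recall_accuracy
#' @export
recall_total_score <- function(judgments) {
  raters <- unique(vapply(judgments, function(j) as.character(j$rater_id),
                          character(1)))
  sum(unlist(lapply(judgments, function(j) j$entry_scores))) / length(raters)
}

#' Retrieval-side quality metrics
#'
#' `context_precision()` takes the 0/1 relevance labels of the retrieved
#' contexts in rank order and averages precision-at-k over the relevant
#' positions (0 when nothing relevant was retrieved) — classical average
#' precision restricted to the retrieved list. `context_recall()` is the
#' fraction of ground-truth fact strings whose tokens are all contained in at
#' least one retrieved context. `context_entity_recall()` is the fraction of
#' ground-truth entities occurring in the retrieved contexts.
#' `semantic_similarity()` is the cosine of the embedded answer and
#' reference, rescaled from `[-1, 1]` to `[0, 1]`.
#'
#' @param relevance_labels 0/1 vector in rank order.
#' @return a proportion in `[0, 1]`.
#' @export
context_precision <- function(relevance_labels) {
  rel <- as.numeric(relevance_labels)
  stopifnot(all(rel %in% c(0, 1)))
  if (!sum(rel)) return(0)
  k <- which(rel == 1)
  mean(cumsum(rel)[k] / k)
}

#' @rdname context_precision
#' @param retrieved_contexts character vector of retrieved context texts.
#' @param ground_truth_facts character vector of fact strings.
#' @export
context_recall <- function(retrieved_contexts, ground_truth_facts) {
  if (!length(ground_truth_facts)) return(NA_real_)
  ctx_tokens <- lapply(retrieved_contexts, function(x) unique(tokenize(x)))
  covered <- vapply(ground_truth_facts, function(f) {
    ft <- unique(tokenize(f))
    any(vapply(ctx_tokens, function(ct) all(ft %in% ct), logical(1)))
  }, logical(1))
  mean(covered)
}

#' @rdname context_precision
#' @param ground_truth_entities character vector of entity strings.
#' @export
context_entity_recall <- function(retrieved_contexts, ground_truth_entities) {
  if (!length(ground_truth_entities)) return(NA_real_)
  ctx_tokens <- unique(unlist(lapply(retrieved_contexts, tokenize)))
  found <- vapply(ground_truth_entities, function(e) {
    et <- unique(tokenize(e))
    length(et) > 0 && all(et %in% ctx_tokens)
  }, logical(1))
  mean(found)
}

#' @rdname context_precision
#' @param answer,reference texts to compare.
#' @param embedder batch embedder.
#' @export
semantic_similarity <- function(answer, reference, embedder = hash_embedder()) {
  (cosine_similarity(embed(answer, embedder), embed(reference, embedder)) + 1) / 2
}

#' Judge-scored generation metrics (stub)
#'
#' Faithfulness, answer relevancy and answer correctness require a model
#' judge; this package ships only the pluggable surface, with no offline
#' default and no offline guarantees. The judge receives the metric name and
#' a payload (`question`, `answer`, `contexts`, `reference`) and must return
#' a number in `[0, 1]`.
#'
#' @param metric one of `"faithfulness"`, `"answer_relevancy"`,
#'   `"answer_correctness"`.
#' @param question,answer,contexts,reference the evaluation payload.
#' @param judge scoring function; required.
#' @return the judge's score.
#' @export
llm_judged_metric <- function(metric = c("faithfulness", "answer_relevancy",
                                         "answer_correctness"),
                              question, answer, contexts = character(0),
                              reference = NULL, judge = NULL) {
  metric <- match.arg(metric)
  if (is.null(judge))
    stop_tosrr(sprintf("metric '%s' needs a model judge; none is configured",
                       metric), "tosrr_input_error")
  score <- judge(metric, list(question = question, answer = answer,
                              contexts = contexts, reference = reference))
  stopifnot(is.numeric(score), length(score) == 1L, score >= 0, score <= 1)
  score
}
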