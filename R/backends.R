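#' Model backend interfaces
#'
#' Every model-dependent stage is a plain function behind a documented
#' contract, so remote LLM adapters and offline deterministic defaults are
#' interchangeable:
#'
#' * `generator(prompt_bundle, state)` returns the answer text for a rendered
#'   prompt.
#' * `judge(kind, payload)` returns `list(verdict = logical, rationale =
#'   character)`. `kind` is `"relevance"` (payload: `question`, `unit_id`,
#'   `unit_text`), `"support"` (payload: `draft`, `unit_texts`) or
#'   `"helpfulness"` (payload: `draft`, `question`).
#' * `decomposer(question)` returns a character vector of sub-questions.
#' * `reformulator(question)` returns the reformulated question text.
#'
#' An LLM adapter implements the same signatures; judges parse the model
#' reply by the grammar "first standalone `yes`/`no` token decides the
#' verdict, remainder is the rationale".
#'
#' @param generator,judge,decomposer,reformulator backend functions.
#' @return a `tosrr_backends` bundle.
#' @export
backends <- function(generator, judge, decomposer, reformulator) {
  stopifnot(is.function(generator), is.function(judge),
            is.function(decomposer), is.function(reformulator))
  structure(list(generator = generator, judge = judge,
                 decomposer = decomposer, reformulator = reformulator),
            class = "tosrr_backends")
}

#' Offline deterministic backends
#'
#' Desk-scale defaults needing no model: an extractive generator, lexical
#' judges with documented thresholds, a conjunction-splitting decomposer and
#' a clarifying reformulator.
#'
#' @param support_threshold minimum fraction of draft tokens that must occur
#'   in the relevant unit texts for a "supported" verdict (default 0.5).
#' @param relevance_min_overlap,helpfulness_min_overlap minimum number of
#'   shared distinct tokens for a positive verdict (default 1).
#' @return a `tosrr_backends` bundle.
#' @export
offline_backends <- function(support_threshold = 0.5,
                             relevance_min_overlap = 1L,
                             helpfulness_min_overlap = 1L) {
  backends(generator = extractive_generator(),
           judge = lexical_judge(support_threshold, relevance_min_overlap,
                                 helpfulness_min_overlap),
           decomposer = split_decomposer(),
           reformulator = suffix_reformulator())
}

#' Extractive answer generator
#'
#' Deterministic offline generator: it answers with the rendered knowledge
#' entries of the prompt (up to `max_entries`), i.e. a purely extractive
#' draft, which is always lexically supported by the evidence it cites.
#'
#' @param max_entries number of leading knowledge entries echoed.
#' @return a generator function.
#' @export
extractive_generator <- function(max_entries = 3L) {
  force(max_entries)
  function(prompt_bundle, state = NULL) {
    if (identical(prompt_bundle$knowledge_block, "[no knowledge retrieved]"))
      return(paste("No supporting knowledge was retrieved for:",
                   prompt_bundle$question_text))
    lines <- strsplit(prompt_bundle$knowledge_block, "\n", fixed = TRUE)[[1]]
    paste(utils::head(lines, max_entries), collapse = " ")
  }
}

#' Lexical-overlap judge
#'
#' Deterministic offline judge. Relevance: the unit text (triple plus
#' attached text) shares at least `relevance_min_overlap` distinct analyzer
#' tokens with the question. Support: at least `support_threshold` of the
#' draft's distinct tokens occur in the union of relevant unit texts.
#' Helpfulness: draft and question share at least `helpfulness_min_overlap`
#' distinct tokens.
#'
#' @inheritParams offline_backends
#' @return a judge function.
#' @export
lexical_judge <- function(support_threshold = 0.5,
                          relevance_min_overlap = 1L,
                          helpfulness_min_overlap = 1L) {
  function(kind, payload) {
    if (kind == "relevance") {
      shared <- intersect(unique(tokenize(payload$question)),
                          unique(tokenize(payload$unit_text)))
      list(verdict = length(shared) >= relevance_min_overlap,
           rationale = sprintf("%d shared token(s)", length(shared)))
    } else if (kind == "support") {
      dt <- unique(tokenize(payload$draft))
      if (!length(dt)) return(list(verdict = FALSE, rationale = "empty draft"))
      ut <- unique(tokenize(paste(payload$unit_texts, collapse = " ")))
      frac <- mean(dt %in% ut)
      list(verdict = frac >= support_threshold,
           rationale = sprintf("%.2f of draft tokens grounded", frac))
    } else if (kind == "helpfulness") {
      shared <- intersect(unique(tokenize(payload$draft)),
                          unique(tokenize(payload$question)))
      list(verdict = length(shared) >= helpfulness_min_overlap,
           rationale = sprintf("%d shared token(s)", length(shared)))
    } else {
      stop_tosrr(sprintf("unknown judge kind '%s'", kind), "tosrr_input_error")
    }
  }
}

#' Mock backends for testing and ablation
#'
#' `static_judge()` returns fixed verdicts per kind; `relevance_table_judge()`
#' keeps exactly the listed unit ids (other kinds approved);
#' `split_decomposer()` splits on a conjunction; `echo_decomposer()` returns
#' the question unchanged; `suffix_reformulator()` appends a clarifier.
#'
#' @param relevance,support,helpfulness fixed verdicts.
#' @return backend functions with the documented contracts.
#' @export
static_judge <- function(relevance = TRUE, support = TRUE, helpfulness = TRUE) {
  fixed <- c(relevance = relevance, support = support, helpfulness = helpfulness)
  function(kind, payload) list(verdict = unname(fixed[[kind]]),
                               rationale = "static verdict")
}

#' @rdname static_judge
#' @param keep unit ids to judge relevant.
#' @export
relevance_table_judge <- function(keep) {
  function(kind, payload) {
    if (kind == "relevance")
      list(verdict = payload$unit_id %in% keep, rationale = "table lookup")
    else list(verdict = TRUE, rationale = "approved")
  }
}

#' @rdname static_judge
#' @param conjunction separator on which questions are split.
#' @export
split_decomposer <- function(conjunction = " and ") {
  function(question) {
    parts <- trimws(strsplit(question, conjunction, fixed = TRUE)[[1]])
    parts[nzchar(parts)]
  }
}

#' @rdname static_judge
#' @export
echo_decomposer <- function() function(question) question

#' @rdname static_judge
#' @param suffix clarifier appended on reformulation.
#' @export
suffix_reformulator <- function(suffix = "(answer with key terms)") {
  function(question) paste(question, suffix)
}
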