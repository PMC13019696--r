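#' Iteration caps for the reflection loop
#'
#' The loop is bounded by global counters: `regen` answer regenerations after
#' a failed support check, `reform` question reformulations after a failed
#' helpfulness check (or empty evidence), and `decomp` question
#' decompositions on empty recall. With caps `(g, r, d)` the generator is
#' called at most `r + 1 + g` times and every run terminates.
#'
#' @param regen,reform,decomp non-negative integer caps (defaults 3, 2, 1).
#' @return named list of caps.
#' @export
reflection_caps <- function(regen = 3L, reform = 2L, decomp = 1L) {
  stopifnot(regen >= 0L, reform >= 0L, decomp >= 0L)
  list(regen = as.integer(regen), reform = as.integer(reform),
       decomp = as.integer(decomp))
}

judge_safely <- function(judge, kind, payload) {
  tryCatch({
    v <- judge(kind, payload)
    list(verdict = isTRUE(v$verdict), rationale = v$rationale %||% "")
  }, error = function(e) {
    # conservative: a failing judge is a negative verdict
    list(verdict = FALSE,
         rationale = paste("judge failure:", conditionMessage(e)))
  })
}

unit_evidence_text <- function(kb, unit_id) {
  u <- kb$units[[unit_id]]
  paste(u$triple$subject, u$triple$predicate, u$triple$object,
        u$summary %||% "", kb$chunks[[u$chunk_id]]$text)
}

#' Relevance filtering of recalled entries
#'
#' Keeps exactly the entries with a positive relevance verdict from the
#' judge, preserving order; a judge failure counts as a negative verdict.
#'
#' @param result a `recall_result`.
#' @param question the active question.
#' @param judge judge backend.
#' @param kb the `knowledge_base`.
#' @return character vector of surviving unit ids (with the per-unit verdicts
#'   in attribute `"verdicts"`).
#' @export
assess_relevance <- function(result, question, judge, kb) {
  ids <- result$entries$unit_id
  verdicts <- lapply(ids, function(uid)
    c(list(kind = "relevance", subject_id = uid),
      judge_safely(judge, "relevance",
                   list(question = question, unit_id = uid,
                        unit_text = unit_evidence_text(kb, uid)))))
  kept <- ids[vapply(verdicts, function(v) v$verdict, logical(1))]
  structure(kept, verdicts = verdicts)
}

#' Decompose a question into sub-questions
#'
#' Invoked only when no relevant evidence survived filtering. A decomposer
#' failure or empty output yields `character(0)` and the loop proceeds to
#' the reformulation path. Sub-questions are never decomposed further.
#'
#' @param question the active question.
#' @param decomposer decomposer backend.
#' @return character vector of sub-questions (possibly empty).
#' @export
decompose_question <- function(question, decomposer) {
  out <- tryCatch(decomposer(question), error = function(e) character(0))
  out <- as.character(out)
  out[nzchar(trimws(out))]
}

#' Generate a draft answer
#'
#' Calls the generator once; on error it retries once, then signals a
#' generation error.
#'
#' @param state the current reflection state (passed through to the backend).
#' @param generator generator backend.
#' @param prompt_bundle rendered prompt from [assemble_prompt()].
#' @return draft answer text.
#' @export
generate_answer <- function(state, generator, prompt_bundle) {
  tryCatch(generator(prompt_bundle, state), error = function(e1) {
    tryCatch(generator(prompt_bundle, state), error = function(e2) {
      stop_tosrr(paste("answer generation failed twice:",
                       conditionMessage(e2)), "tosrr_generation_error")
    })
  })
}

#' Support and helpfulness checks
#'
#' `check_support()` asks the judge whether the draft is grounded in the
#' relevant units' evidence; `check_helpfulness()` whether it addresses the
#' original question. Judge failures return `FALSE`.
#'
#' @param draft draft answer text.
#' @param relevant_units unit ids that survived relevance filtering.
#' @param judge judge backend.
#' @param kb the `knowledge_base`.
#' @return logical verdict.
#' @export
check_support <- function(draft, relevant_units, judge, kb) {
  texts <- vapply(relevant_units, function(uid) unit_evidence_text(kb, uid),
                  character(1))
  judge_safely(judge, "support", list(draft = draft, unit_texts = texts))$verdict
}

#' @rdname check_support
#' @param original_question the user's original question.
#' @export
check_helpfulness <- function(draft, original_question, judge) {
  judge_safely(judge, "helpfulness",
               list(draft = draft, question = original_question))$verdict
}

#' Reformulate the active question
#'
#' Returns the reformulator's output (the question itself if the backend
#' fails); the caller consumes one reformulation credit either way.
#'
#' @param question the active question.
#' @param reformulator reformulator backend.
#' @return new question text.
#' @export
reformulate_question <- function(question, reformulator) {
  out <- tryCatch(reformulator(question), error = function(e) question)
  if (!is.character(out) || length(out) != 1L || !nzchar(trimws(out))) question
  else out
}

subset_recall <- function(result, keep_ids) {
  entries <- result$entries[result$entries$unit_id %in% keep_ids, , drop = FALSE]
  rownames(entries) <- NULL
  structure(list(entries = entries,
                 quota_used = c(
                   n_keyword = sum(entries$source == "keyword"),
                   n_vector = sum(entries$source == "vector"))),
            class = "recall_result")
}

merge_recalls <- function(results) {
  seen <- character(0); rows <- list()
  for (r in results) {
    for (i in seq_len(nrow(r$entries))) {
      uid <- r$entries$unit_id[i]
      if (uid %in% seen) next
      seen <- c(seen, uid)
      rows[[length(rows) + 1L]] <- r$entries[i, , drop = FALSE]
    }
  }
  entries <- if (length(rows)) do.call(rbind, rows) else
    data.frame(unit_id = character(0), source = character(0),
               score = numeric(0), rank = integer(0), stringsAsFactors = FALSE)
  rownames(entries) <- NULL
  structure(list(entries = entries,
                 quota_used = c(n_keyword = sum(entries$source == "keyword"),
                                n_vector = sum(entries$source == "vector"))),
            class = "recall_result")
}

#' Run the self-reflective retrieval-generation loop
#'
#' Implements the generate-verify state machine: (a) retrieve for the active
#' question and filter the recalled SPO-T entries for relevance; (b) if no
#' relevant evidence remains, decompose the question into sub-questions,
#' retrieve and filter each independently and pool the survivors — otherwise
#' generate a draft from the relevant entries; (c) check the draft is
#' supported by the evidence, regenerating while the support check fails and
#' regeneration credits remain; (d) check the draft helps answer the original
#' question — if yes terminate, if no reformulate the question and restart
#' from retrieval. All counters are global across restarts, so the loop
#' always terminates; exhausting the caps is not an error and yields
#' `terminal_status = "cap_exhausted"` with the last draft flagged
#' best-effort.
#'
#' @param question the question to answer.
#' @param kb a `knowledge_base`.
#' @param indexes from [build_indexes()].
#' @param backends a `tosrr_backends` bundle.
#' @param caps from [reflection_caps()].
#' @param keyword_quota,vector_quota recall quotas.
#' @param template a `prompt_template`.
#' @return list with `answer` (character or `NA`), `status`, `state`, and
#'   `trace` (a `generation_trace`: ordered step events plus terminal
#'   status).
#' @export
run_reflection_loop <- function(question, kb, indexes, backends,
                                caps = reflection_caps(),
                                keyword_quota = 5L, vector_quota = 10L,
                                template = default_prompt_template()) {
  stopifnot(inherits(backends, "tosrr_backends"))
  state <- list(original_question = question, active_question = question,
                sub_questions = character(0), relevant_units = character(0),
                draft_answer = NULL, regen_count = 0L, reform_count = 0L,
                decomp_count = 0L)
  events <- list()
  log_event <- function(step, info = "", verdict = NULL) {
    events[[length(events) + 1L]] <<- list(
      step = step, info = info, verdict = verdict,
      counters = c(regen = state$regen_count, reform = state$reform_count,
                   decomp = state$decomp_count))
  }
  finish <- function(status, answer) {
    trace <- structure(list(events = events, terminal_status = status),
                       class = "generation_trace")
    list(answer = answer, status = status, state = state, trace = trace)
  }
  recall_and_filter <- function(q) {
    rec <- multi_way_recall(kb, indexes, q, keyword_quota, vector_quota)
    log_event("recall", sprintf("'%s' -> %d entries", q, nrow(rec$entries)))
    kept <- assess_relevance(rec, q, backends$judge, kb)
    log_event("relevance_filter",
              sprintf("%d of %d kept", length(kept), nrow(rec$entries)),
              length(kept) > 0L)
    list(recall = rec, kept = as.character(kept))
  }

  repeat {
    rf <- recall_and_filter(state$active_question)
    state$relevant_units <- rf$kept
    evidence <- subset_recall(rf$recall, rf$kept)

    if (!length(state$relevant_units) && state$decomp_count < caps$decomp) {
      state$decomp_count <- state$decomp_count + 1L
      subs <- decompose_question(state$active_question, backends$decomposer)
      state$sub_questions <- subs
      log_event("decompose", sprintf("%d sub-question(s)", length(subs)),
                length(subs) > 0L)
      if (length(subs)) {
        sub_rf <- lapply(subs, recall_and_filter)
        state$relevant_units <-
          unique(unlist(lapply(sub_rf, function(x) x$kept)))
        evidence <- merge_recalls(
          lapply(sub_rf, function(x) subset_recall(x$recall, x$kept)))
      }
    }

    if (length(state$relevant_units)) {
      prompt <- assemble_prompt(evidence, state$active_question, kb, template)
      repeat {
        draft <- generate_answer(state, backends$generator, prompt)
        state$draft_answer <- draft
        log_event("generate", sprintf("draft of %d token(s)", count_tokens(draft)))
        supported <- check_support(draft, state$relevant_units,
                                   backends$judge, kb)
        log_event("support_check", "", supported)
        if (!supported) {
          if (state$regen_count < caps$regen) {
            state$regen_count <- state$regen_count + 1L
            next
          }
          break  # support cap exhausted -> reformulation path
        }
        helpful <- check_helpfulness(draft, state$original_question,
                                     backends$judge)
        log_event("helpfulness_check", "", helpful)
        if (helpful) return(finish("answered", draft))
        break     # unhelpful -> reformulation path
      }
    } else {
      log_event("no_evidence", "no relevant units after filtering", FALSE)
    }

    if (state$reform_count < caps$reform) {
      state$reform_count <- state$reform_count + 1L
      state$active_question <- reformulate_question(state$active_question,
                                                    backends$reformulator)
      log_event("reformulate", state$active_question)
    } else {
      return(finish("cap_exhausted",
                    state$draft_answer %||% NA_character_))
    }
  }
}

#' @export
print.generation_trace <- function(x, ...) {
  cat(sprintf("<generation_trace> %d event(s), terminal status: %s\n",
              length(x$events), x$terminal_status))
  for (e in x$events)
    cat(sprintf("  %-18s %s%s\n", e$step,
                if (!is.null(e$verdict)) sprintf("[%s] ", e$verdict) else "",
                e$info))
  invisible(x)
}

#' Export a generation trace as a JSONL event log
#'
#' @param trace a `generation_trace`.
#' @param path file path.
#' @return `path` invisibly.
#' @export
write_trace_jsonl <- function(trace, path) {
  lines <- vapply(trace$events, function(e) {
    as.character(jsonlite::toJSON(
      list(step = e$step, info = e$info, verdict = e$verdict,
           counters = as.list(e$counters)),
      auto_unbox = TRUE, null = "null"))
  }, character(1))
  writeLines(c(lines, as.character(jsonlite::toJSON(
    list(terminal_status = trace$terminal_status), auto_unbox = TRUE))),
    path, useBytes = TRUE)
  invisible(path)
}

#' Answer a question under a named pipeline configuration
#'
#' The ablation surface: `"tosrr"` runs the full self-reflective loop over
#' dual-path recall; `"spot_rag"` is the same retrieval without reflection
#' (one generation pass); `"rag"` disables the keyword/SPO path (vector-only
#' recall, no reflection); `"baseline"` generates with no retrieved
#' knowledge. With all-approve judges, `"tosrr"` and `"spot_rag"` produce
#' identical answers.
#'
#' @inheritParams run_reflection_loop
#' @param mode pipeline configuration.
#' @return list with `answer`, `status`, `recall`, `prompt`, and (for
#'   `"tosrr"`) `trace`.
#' @export
answer_question <- function(question, kb, indexes, backends,
                            mode = c("tosrr", "spot_rag", "rag", "baseline"),
                            caps = reflection_caps(),
                            keyword_quota = 5L, vector_quota = 10L,
                            template = default_prompt_template()) {
  mode <- match.arg(mode)
  if (mode == "tosrr") {
    res <- run_reflection_loop(question, kb, indexes, backends, caps,
                               keyword_quota, vector_quota, template)
    return(list(answer = res$answer, status = res$status, recall = NULL,
                prompt = NULL, trace = res$trace))
  }
  recall <- switch(mode,
    spot_rag = multi_way_recall(kb, indexes, question, keyword_quota,
                                vector_quota),
    rag = multi_way_recall(kb, indexes, question, 0L,
                           keyword_quota + vector_quota),
    baseline = structure(list(entries = data.frame(
      unit_id = character(0), source = character(0), score = numeric(0),
      rank = integer(0), stringsAsFactors = FALSE),
      quota_used = c(n_keyword = 0L, n_vector = 0L)), class = "recall_result"))
  prompt <- assemble_prompt(recall, question, kb, template)
  draft <- generate_answer(NULL, backends$generator, prompt)
  list(answer = draft, status = "answered", recall = recall, prompt = prompt,
       trace = NULL)
}
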