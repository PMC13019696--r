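#' Build both retrieval indexes for a knowledge base
#'
#' Bundles the keyword inverted index over SPO triples, the cosine vector
#' index over unit content, and the embedder used for queries.
#'
#' @param kb a `knowledge_base`.
#' @param embedder batch embedder used for both indexing and queries.
#' @param analyzer keyword analyzer.
#' @param ... passed to [build_vector_index()].
#' @return list with elements `keyword`, `vector`, `embedder`.
#' @export
build_indexes <- function(kb, embedder = hash_embedder(), analyzer = tokenize,
                          ...) {
  list(keyword = build_keyword_index(kb, analyzer),
       vector = build_vector_index(kb, embedder, ...),
       embedder = embedder)
}

#' Dual-path recall with fixed fusion quotas
#'
#' Runs keyword matching over SPO triples and vector similarity over unit
#' content, then fuses the two lists: up to `keyword_quota` keyword hits are
#' taken first, followed by vector hits (each unit scored by the maximum
#' similarity over its indexed content kinds, units already taken by the
#' keyword path skipped) until the list reaches `keyword_quota +
#' vector_quota` entries or candidates run out. A keyword deficit is
#' backfilled from the vector path, so a question matching fewer than
#' `keyword_quota` SPO triples still yields a full list when vector
#' candidates suffice; a vector deficit never enlarges the keyword share.
#' Keyword entries precede vector entries and each path keeps its own rank
#' order.
#'
#' @param kb a `knowledge_base`.
#' @param indexes from [build_indexes()].
#' @param query_text the question.
#' @param keyword_quota,vector_quota per-path quotas (defaults 5 and 10,
#'   giving the top-15 prompt budget).
#' @return a `recall_result`: `entries` (data.frame `unit_id`, `source`,
#'   `score`, `rank`) and `quota_used` (`n_keyword`, `n_vector`).
#' @export
multi_way_recall <- function(kb, indexes, query_text, keyword_quota = 5L,
                             vector_quota = 10L) {
  total_quota <- keyword_quota + vector_quota
  empty <- data.frame(unit_id = character(0), source = character(0),
                      score = numeric(0), rank = integer(0),
                      stringsAsFactors = FALSE)

  kw <- if (keyword_quota > 0L)
    keyword_match(indexes$keyword, query_text, limit = keyword_quota)
  else data.frame(unit_id = character(0), score = integer(0))
  kw_entries <- if (nrow(kw)) {
    data.frame(unit_id = kw$unit_id, source = "keyword",
               score = as.numeric(kw$score), rank = seq_len(nrow(kw)),
               stringsAsFactors = FALSE)
  } else empty

  vector_target <- total_quota - nrow(kw_entries)
  vec_entries <- empty
  n_index <- length(indexes$vector$unit_ids)
  if (vector_target > 0L && n_index > 0L && nzchar(trimws(query_text))) {
    qvec <- embed(query_text, indexes$embedder)
    taken <- kw_entries$unit_id
    k <- min(n_index, 3L * total_quota + 3L * length(taken))
    repeat {
      hits <- knn_search(indexes$vector, qvec, k)
      seen <- character(0); units <- character(0); scores <- numeric(0)
      for (i in seq_len(nrow(hits))) {
        uid <- hits$unit_id[i]
        if (uid %in% seen) next
        seen <- c(seen, uid)
        if (uid %in% taken) next
        units <- c(units, uid); scores <- c(scores, hits$similarity[i])
        if (length(units) >= vector_target) break
      }
      if (length(units) >= vector_target || k >= n_index) break
      k <- min(n_index, 2L * k)
    }
    if (length(units))
      vec_entries <- data.frame(unit_id = units, source = "vector",
                                score = scores, rank = seq_along(units),
                                stringsAsFactors = FALSE)
  }
  entries <- rbind(kw_entries, vec_entries)
  structure(list(entries = entries,
                 quota_used = c(n_keyword = nrow(kw_entries),
                                n_vector = nrow(vec_entries))),
            class = "recall_result")
}

#' @export
print.recall_result <- function(x, ...) {
  cat(sprintf("<recall_result> %d entries (%d keyword + %d vector)\n",
              nrow(x$entries), x$quota_used[["n_keyword"]],
              x$quota_used[["n_vector"]]))
  invisible(x)
}

#' Prompt templates
#'
#' A template is the full prompt text with the named placeholders `{role}`,
#' `{task}`, `{knowledge}` and `{question}`, plus the role and task strings
#' substituted into it. The default template (shipped verbatim in
#' `inst/extdata/default_template.txt`) is used identically across model
#' backends. `read_prompt_template()` loads the text from a plain-text file.
#'
#' @param text template text; must contain `{knowledge}` and `{question}`.
#' @param role,task strings substituted for `{role}` / `{task}`.
#' @return a `prompt_template`.
#' @export
prompt_template <- function(text, role = default_role_text(),
                            task = default_task_text()) {
  for (ph in c("{knowledge}", "{question}")) {
    if (!grepl(ph, text, fixed = TRUE))
      stop_tosrr(sprintf("prompt template is missing required placeholder %s", ph),
                 "tosrr_template_error")
  }
  structure(list(text = text, role = role, task = task),
            class = "prompt_template")
}

default_role_text <- function() {
  "You are a careful assistant answering questions from a curated knowledge base."
}
default_task_text <- function() {
  paste("Answer the question using the knowledge entries below.",
        "Each entry gives a (subject | predicate | object) assertion, its",
        "location in the knowledge tree, and its source text. The structured",
        "assertions signal the most important content; prefer them over prior",
        "beliefs.")
}

#' @rdname prompt_template
#' @export
default_prompt_template <- function() {
  path <- system.file("extdata", "default_template.txt", package = "tosrr")
  prompt_template(paste(readLines(path, warn = FALSE), collapse = "\n"))
}

#' @rdname prompt_template
#' @param path plain-text template file.
#' @inheritParams prompt_template
#' @export
read_prompt_template <- function(path, role = default_role_text(),
                                 task = default_task_text()) {
  prompt_template(paste(readLines(path, warn = FALSE), collapse = "\n"),
                  role = role, task = task)
}

render_entry <- function(kb, unit_id, i) {
  u <- kb$units[[unit_id]]
  path <- paste(get_context_path(kb, unit_id), collapse = " > ")
  text <- if (nzchar(u$summary %||% "")) u$summary else kb$chunks[[u$chunk_id]]$text
  sprintf("%d. (%s | %s | %s) [%s] %s", i, u$triple$subject,
          u$triple$predicate, u$triple$object, path, text)
}

#' Assemble the generation prompt
#'
#' Renders the fused recall entries — triple, hierarchical context path, and
#' attached text — into the template, in fused order. An empty recall renders
#' an explicit empty-knowledge marker. Rendering is deterministic.
#'
#' @param result a `recall_result`.
#' @param question_text the question.
#' @param kb the `knowledge_base` the entries refer to.
#' @param template a `prompt_template`.
#' @return a `prompt_bundle`: `system_text`, `knowledge_block`,
#'   `question_text`, `token_estimate`, and the fully rendered `text`.
#' @export
assemble_prompt <- function(result, question_text, kb,
                            template = default_prompt_template()) {
  stopifnot(inherits(result, "recall_result"),
            inherits(template, "prompt_template"))
  ids <- result$entries$unit_id
  knowledge_block <- if (length(ids)) {
    paste(vapply(seq_along(ids),
                 function(i) render_entry(kb, ids[i], i), character(1)),
          collapse = "\n")
  } else {
    "[no knowledge retrieved]"
  }
  text <- template$text
  text <- gsub("{role}", template$role, text, fixed = TRUE)
  text <- gsub("{task}", template$task, text, fixed = TRUE)
  text <- gsub("{knowledge}", knowledge_block, text, fixed = TRUE)
  text <- gsub("{question}", question_text, text, fixed = TRUE)
  structure(list(system_text = paste(template$role, template$task, sep = "\n"),
                 knowledge_block = knowledge_block,
                 question_text = question_text,
                 token_estimate = count_tokens(text),
                 text = text),
            class = "prompt_bundle")
}
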