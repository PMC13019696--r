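KB_SCHEMA_VERSION <- 1L

#' Save / load a knowledge base
#'
#' The on-disk layout is a directory of JSONL files plus a manifest:
#' `manifest.json` (`schema_version`, record counts), `nodes.jsonl`
#' (`node_id`, `label`, `level_kind`, `parent_id`, `children`, `unit_ids`),
#' `units.jsonl` (`unit_id`, `triple.{subject,predicate,object}`, `chunk_id`,
#' `node_id`, `summary`, `qa_pairs`), `chunks.jsonl` (see
#' [write_chunks_jsonl()]), with `roots` listed in the manifest. Loading a
#' saved knowledge base reproduces it structurally: `load_kb(save_kb(kb))`
#' equals `kb`.
#'
#' @param kb a `knowledge_base`.
#' @param dir target directory (created if missing).
#' @return `save_kb()` returns `dir` invisibly; `load_kb()` the
#'   `knowledge_base`.
#' @export
save_kb <- function(kb, dir) {
  stopifnot(inherits(kb, "knowledge_base"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_jsonl <- function(records, file) {
    lines <- vapply(records, function(r) {
      as.character(jsonlite::toJSON(r, auto_unbox = TRUE, null = "null"))
    }, character(1))
    writeLines(lines, file.path(dir, file), useBytes = TRUE)
  }
  write_jsonl(unname(kb$nodes), "nodes.jsonl")
  write_jsonl(lapply(unname(kb$units), unclass), "units.jsonl")
  write_jsonl(lapply(unname(kb$chunks), unclass), "chunks.jsonl")
  manifest <- list(schema_version = KB_SCHEMA_VERSION, roots = as.list(kb$roots),
                   n_nodes = length(kb$nodes), n_units = length(kb$units),
                   n_chunks = length(kb$chunks))
  writeLines(as.character(jsonlite::toJSON(manifest, auto_unbox = TRUE)),
             file.path(dir, "manifest.json"), useBytes = TRUE)
  invisible(dir)
}

read_jsonl_records <- function(dir, file, expected_n) {
  path <- file.path(dir, file)
  if (!file.exists(path))
    stop_tosrr(sprintf("missing knowledge-base file '%s'", file),
               "tosrr_format_error")
  lines <- readLines(path, warn = FALSE)
  if (length(lines) != expected_n)
    stop_tosrr(sprintf("'%s' has %d record(s), manifest expects %d (truncated or corrupt file)",
                       file, length(lines), expected_n), "tosrr_format_error")
  lapply(lines, function(l) {
    tryCatch(jsonlite::fromJSON(l, simplifyVector = FALSE),
             error = function(e) stop_tosrr(
               sprintf("malformed JSON record in '%s': %s", file,
                       conditionMessage(e)), "tosrr_format_error"))
  })
}

#' @rdname save_kb
#' @export
load_kb <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath))
    stop_tosrr("missing manifest.json", "tosrr_format_error")
  manifest <- jsonlite::fromJSON(mpath, simplifyVector = FALSE)
  if (!identical(as.integer(manifest$schema_version), KB_SCHEMA_VERSION))
    stop_tosrr(sprintf("knowledge-base schema version %s not supported (expected %d)",
                       manifest$schema_version %||% "<missing>", KB_SCHEMA_VERSION),
               "tosrr_format_error")
  kb <- new_knowledge_base()
  kb$roots <- vapply(manifest$roots, as.character, character(1))

  for (r in read_jsonl_records(dir, "nodes.jsonl", manifest$n_nodes)) {
    kb$nodes[[r$node_id]] <- list(
      node_id = r$node_id, label = r$label, level_kind = r$level_kind,
      parent_id = r$parent_id,
      children = vapply(r$children, as.character, character(1)),
      unit_ids = vapply(r$unit_ids, as.character, character(1)))
  }
  for (r in read_jsonl_records(dir, "chunks.jsonl", manifest$n_chunks)) {
    kb$chunks[[r$chunk_id]] <- structure(list(
      chunk_id = r$chunk_id, doc_id = r$doc_id,
      heading_path = vapply(r$heading_path, as.character, character(1)),
      text = r$text, word_count = as.integer(r$word_count)),
      class = "text_chunk")
  }
  for (r in read_jsonl_records(dir, "units.jsonl", manifest$n_units)) {
    kb$units[[r$unit_id]] <- structure(list(
      unit_id = r$unit_id,
      triple = list(subject = r$triple$subject, predicate = r$triple$predicate,
                    object = r$triple$object),
      chunk_id = r$chunk_id, node_id = r$node_id, summary = r$summary,
      qa_pairs = lapply(r$qa_pairs, function(qa)
        list(question = qa$question, answer = qa$answer))),
      class = "spot_unit")
  }
  validate_kb(kb)
  kb
}
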