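#' Parse a hierarchically structured plain-text document
#'
#' The input dialect is Markdown-like: a line of `n` leading `#` characters
#' followed by a space is a heading of level `n` (level 1 = book/top), and
#' blank-line-separated runs of non-heading lines are paragraphs attached to
#' the most recent heading. Heading levels must nest properly: a heading may
#' be at most one level deeper than the heading it follows.
#'
#' @param raw character scalar (whole document) or character vector of lines.
#' @param doc_id opaque document identifier; defaults to a content hash.
#' @param title document title; defaults to the first level-1 heading.
#' @return a `source_document`: list with `doc_id`, `title` and `nodes`, an
#'   ordered list of heading nodes (`level`, `heading_text`, `paragraphs`,
#'   `children`).
#' @export
parse_document <- function(raw, doc_id = NULL, title = NULL) {
  lines <- if (length(raw) == 1L) strsplit(raw, "\n", fixed = TRUE)[[1]] else raw
  doc_id <- doc_id %||% content_id("doc", paste(lines, collapse = "\n"))

  new_node <- function(level, text) {
    list(level = level, heading_text = text,
         paragraphs = character(0), children = list())
  }
  roots <- list()
  # stack of index paths into `roots` for the open heading chain
  stack <- list()   # each element: list(level =, path = integer vector)
  para_buf <- character(0)

  get_node <- function(path) {
    node <- roots[[path[1]]]
    for (i in path[-1]) node <- node$children[[i]]
    node
  }
  set_node <- function(path, node) {
    if (length(path) == 1L) {
      roots[[path[1]]] <<- node
    } else {
      parent_path <- path[-length(path)]
      parent <- get_node(parent_path)
      parent$children[[path[length(path)]]] <- node
      set_node(parent_path, parent)
    }
  }
  flush_para <- function() {
    if (!length(para_buf)) return(invisible())
    text <- trimws(paste(para_buf, collapse = " "))
    para_buf <<- character(0)
    if (!nzchar(text)) return(invisible())
    if (!length(stack))
      stop_tosrr("paragraph text before any heading", "tosrr_structure_error")
    path <- stack[[length(stack)]]$path
    node <- get_node(path)
    node$paragraphs <- c(node$paragraphs, text)
    set_node(path, node)
    invisible()
  }

  for (i in seq_along(lines)) {
    line <- lines[[i]]
    m <- regmatches(line, regexec("^(#+)\\s+(.*\\S)\\s*$", line))[[1]]
    if (length(m) == 3L) {
      flush_para()
      level <- nchar(m[2])
      cur_level <- if (length(stack)) stack[[length(stack)]]$level else 0L
      if (level > cur_level + 1L)
        stop_tosrr(sprintf(
          "line %d: heading '%s' at level %d under level %d (may nest at most one deeper)",
          i, m[3], level, cur_level), "tosrr_structure_error")
      while (length(stack) && stack[[length(stack)]]$level >= level)
        stack[[length(stack)]] <- NULL
      node <- new_node(level, m[3])
      if (!length(stack)) {
        roots[[length(roots) + 1L]] <- node
        path <- length(roots)
      } else {
        ppath <- stack[[length(stack)]]$path
        parent <- get_node(ppath)
        parent$children[[length(parent$children) + 1L]] <- node
        set_node(ppath, parent)
        path <- c(ppath, length(parent$children))
      }
      stack[[length(stack) + 1L]] <- list(level = level, path = path)
    } else if (!nzchar(trimws(line))) {
      flush_para()
    } else {
      para_buf <- c(para_buf, line)
    }
  }
  flush_para()

  if (is.null(title)) {
    title <- if (length(roots)) roots[[1]]$heading_text else doc_id
  }
  structure(list(doc_id = doc_id, title = title, nodes = roots),
            class = "source_document")
}

#' @export
print.source_document <- function(x, ...) {
  n_sections <- length(doc_sections(x))
  cat(sprintf("<source_document> %s: '%s', %d top-level heading(s), %d section(s)\n",
              x$doc_id, x$title, length(x$nodes), n_sections))
  invisible(x)
}

# Flatten a document into sections: every heading node contributes one section
# holding its own paragraphs (possibly none), identified by its heading path.
doc_sections <- function(doc) {
  out <- list()
  walk <- function(node, path) {
    path <- c(path, node$heading_text)
    out[[length(out) + 1L]] <<- list(heading_path = path,
                                     paragraphs = node$paragraphs)
    for (ch in node$children) walk(ch, path)
  }
  for (nd in doc$nodes) walk(nd, character(0))
  out
}

# Split one over-long paragraph at sentence boundaries into pieces <= max_words,
# packing sentences greedily; a single sentence longer than max_words is split
# at word boundaries.
split_long_paragraph <- function(text, max_words) {
  sentences <- split_sentences(text)
  pieces <- character(0)
  buf <- character(0); buf_wc <- 0L
  flush <- function() {
    if (length(buf)) pieces[[length(pieces) + 1L]] <<- paste(buf, collapse = " ")
    buf <<- character(0); buf_wc <<- 0L
  }
  for (s in sentences) {
    w <- count_words(s)
    if (w > max_words) {
      flush()
      words <- split_words(s)
      for (start in seq(1L, length(words), by = max_words)) {
        end <- min(start + max_words - 1L, length(words))
        pieces[[length(pieces) + 1L]] <- paste(words[start:end], collapse = " ")
      }
    } else {
      if (buf_wc + w > max_words) flush()
      buf <- c(buf, s); buf_wc <- buf_wc + w
    }
  }
  flush()
  pieces
}

#' Segment a document into word-bounded text chunks
#'
#' Greedy packing of consecutive paragraphs within a single section (the
#' paragraphs directly under one heading): a chunk is closed once it reaches
#' `min_words`, or when the next paragraph would push it past `max_words`.
#' Chunks never span heading boundaries, so a short section yields one short
#' chunk rather than being merged with its neighbours. A single paragraph
#' longer than `max_words` is first split at sentence boundaries into pieces
#' of at most `max_words` words. Every source word lands in exactly one chunk.
#'
#' @param doc a `source_document` from [parse_document()].
#' @param min_words,max_words chunk size band in words (defaults 200 and 300,
#'   counted by [count_words()]).
#' @return list of `text_chunk` records: `chunk_id`, `doc_id`, `heading_path`
#'   (root-to-section heading texts), `text`, `word_count`.
#' @export
segment_chunks <- function(doc, min_words = 200L, max_words = 300L) {
  stopifnot(inherits(doc, "source_document"), min_words < max_words,
            min_words >= 1L)
  chunks <- list()
  for (sec in doc_sections(doc)) {
    if (!length(sec$paragraphs)) next
    paras <- unlist(lapply(sec$paragraphs, function(p) {
      if (count_words(p) > max_words) split_long_paragraph(p, max_words) else p
    }))
    buf <- character(0); buf_wc <- 0L
    emit <- function() {
      if (!length(buf)) return(invisible())
      text <- paste(buf, collapse = " ")
      chunks[[length(chunks) + 1L]] <<- structure(list(
        chunk_id = content_id("chunk", doc$doc_id,
                              paste(sec$heading_path, collapse = "/"),
                              length(chunks), text),
        doc_id = doc$doc_id,
        heading_path = sec$heading_path,
        text = text,
        word_count = count_words(text)), class = "text_chunk")
      buf <<- character(0); buf_wc <<- 0L
      invisible()
    }
    for (p in paras) {
      w <- count_words(p)
      if (buf_wc + w > max_words) emit()
      buf <- c(buf, p); buf_wc <- buf_wc + w
      if (buf_wc >= min_words) emit()
    }
    emit()
  }
  chunks
}

#' Write / read chunks as JSONL
#'
#' One chunk per line with fields `chunk_id`, `doc_id`, `heading_path`,
#' `text`, `word_count`.
#'
#' @param chunks list of `text_chunk` records.
#' @param path file path.
#' @return `read_chunks_jsonl()` returns the chunk list.
#' @export
write_chunks_jsonl <- function(chunks, path) {
  lines <- vapply(chunks, function(ch) {
    jsonlite::toJSON(unclass(ch), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_chunks_jsonl
#' @export
read_chunks_jsonl <- function(path) {
  lapply(readLines(path, warn = FALSE), function(l) {
    x <- jsonlite::fromJSON(l)
    x$heading_path <- as.character(x$heading_path)
    structure(x, class = "text_chunk")
  })
}
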