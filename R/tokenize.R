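#' Word and token utilities
#'
#' One documented counting rule is used everywhere in the package (chunk
#' sizing, token estimates, lexical judges): text is split into
#' whitespace-delimited tokens, and every CJK character counts as one word on
#' its own regardless of surrounding whitespace. This mirrors how word counts
#' behave for Chinese source material while remaining natural for the English
#' synthetic corpora used in tests.
#'
#' @param text character scalar.
#' @return `count_words()` returns an integer; `split_words()` the word
#'   tokens in order.
#' @examples
#' count_words("a b c")        # 3
#' count_words("中医 treats fever")  # 2 CJK chars + 2 words = 4
#' @export
count_words <- function(text) {
  length(split_words(text))
}

cjk_re <- "[\\x{4E00}-\\x{9FFF}\\x{3400}-\\x{4DBF}\\x{F900}-\\x{FAFF}\\x{3040}-\\x{30FF}]"

#' @rdname count_words
#' @export
split_words <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(trimws(text))) return(character(0))
  # isolate each CJK character as its own token
  text <- gsub(paste0("(*UTF)(", cjk_re, ")"), " \\1 ", text, perl = TRUE)
  toks <- strsplit(trimws(text), "\\s+")[[1]]
  toks[nzchar(toks)]
}

#' Analyzer: normalized index tokens
#'
#' The keyword index and the lexical judges tokenize through a pluggable
#' analyzer. The default lowercases and keeps letter/digit runs; CJK text can
#' be indexed as overlapping character bigrams (`mode = "cjk_bigram"`), the
#' usual substitute for dictionary-based Chinese analyzers.
#'
#' @param text character scalar.
#' @param mode `"word"` (default) or `"cjk_bigram"`.
#' @return character vector of normalized tokens.
#' @export
tokenize <- function(text, mode = c("word", "cjk_bigram")) {
  mode <- match.arg(mode)
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) return(character(0))
  text <- tolower(text)
  if (mode == "cjk_bigram") {
    cjk <- regmatches(text,
                      gregexpr(paste0("(*UTF)", cjk_re, "+"), text,
                               perl = TRUE))[[1]]
    bigrams <- unlist(lapply(cjk, function(run) {
      ch <- strsplit(run, "")[[1]]
      if (length(ch) == 1L) return(ch)
      paste0(ch[-length(ch)], ch[-1])
    }))
    latin <- regmatches(text, gregexpr("[a-z0-9_]+", text, perl = TRUE))[[1]]
    return(c(latin, bigrams))
  }
  regmatches(text, gregexpr(paste0("(*UTF)[a-z0-9_]+|", cjk_re), text,
                            perl = TRUE))[[1]]
}

#' Split text into sentences
#'
#' Language-agnostic terminal-punctuation rule: a sentence ends at `.`, `!`,
#' `?` or their full-width CJK forms, with the terminator kept on the
#' sentence. Trailing text without a terminator forms a final sentence.
#'
#' @param text character scalar.
#' @return character vector of sentences (trimmed, non-empty).
#' @export
split_sentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(trimws(text))) return(character(0))
  parts <- regmatches(
    text,
    gregexpr("[^.!?。！？]*[.!?。！？]+|[^.!?。！？]+$",
             text, perl = TRUE)
  )[[1]]
  parts <- trimws(parts)
  parts[nzchar(parts)]
}

#' Count tokens in a text
#'
#' Plumbing for prompt-size accounting. The default counter is the package
#' word-counting rule ([count_words()]); a custom counter (e.g. a model
#' tokenizer adapter) may be supplied.
#'
#' @param text character scalar.
#' @param counter function `text -> integer`.
#' @return integer token count.
#' @export
count_tokens <- function(text, counter = count_words) {
  as.integer(counter(text))
}
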