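#' @keywords internal
"_PACKAGE"

# Run code with a temporary RNG state so callers' streams are untouched.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

content_id <- function(...) {
  digest::digest(paste(unlist(list(...)), collapse = "\x1f"), algo = "xxhash64")
}

#' Round half away from zero
#'
#' Reported percentages use conventional half-up rounding (`0.005 -> 0.01`)
#' rather than the IEEE round-half-even rule, so printed two-decimal scores
#' match hand arithmetic.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_tosrr <- function(msg, class) {
  stop(structure(class = c(class, "tosrr_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
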