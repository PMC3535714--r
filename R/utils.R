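`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global random-number generator seeded at `seed`,
#' restoring the caller's RNG state afterwards, so that generators are pure
#' functions of their arguments.  With `seed = NULL` the expression runs
#' against the current RNG stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Reverse complement of a DNA string
#'
#' @param x Single character string over `{A,C,G,T,N}`.
#' @return The reverse-complemented string.
#' @export
#' @examples
#' revcomp("CGTGG")
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Normalize a raw sequence: uppercase, RNA U -> T.  Returns the string or
# stops with an error naming `label` and the first offending position.
normalize_sequence <- function(x, label = "sequence") {
  s <- chartr("U", "T", toupper(x))
  bad <- regexpr("[^ACGTN]", s)
  if (bad > 0L) {
    stop(sprintf(
      "illegal character '%s' at position %d in %s",
      substr(s, bad, bad), as.integer(bad), label
    ), call. = FALSE)
  }
  if (!nzchar(s)) stop(sprintf("empty sequence in %s", label), call. = FALSE)
  s
}

count_pattern_chars <- function(x, chars) {
  v <- strsplit(x, "", fixed = TRUE)[[1L]]
  sum(v %in% chars)
}
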