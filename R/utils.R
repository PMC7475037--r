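## Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded simulators do not
#' disturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single non-missing number", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T, case-insensitive).
#' @return character vector of reverse complements.
#' @noRd
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Random DNA sequence
#'
#' Uniform i.i.d. bases; used to build synthetic references and elements.
#' Draws from the current RNG stream (callers seed via `with_seed`).
#'
#' @param n sequence length in bp.
#' @return a single character string of length `n`.
#' @noRd
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Count occurrences of a pattern in a subject, overlap-aware, both strands
#' @noRd
count_occurrences <- function(pattern, subject, both_strands = TRUE) {
  hit <- function(p) {
    m <- stringi::stri_locate_all_fixed(subject, p, overlap = TRUE)[[1]]
    sum(!is.na(m[, 1L]))
  }
  n <- hit(pattern)
  if (both_strands) {
    rc <- revcomp(pattern)
    # avoid double counting palindromic patterns
    if (!identical(rc, pattern)) n <- n + hit(rc)
  }
  n
}

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must be a single value in [0, 1]", name), call. = FALSE)
  }
}

stopifnot_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop(sprintf("'%s' must be a single positive number", name), call. = FALSE)
  }
}
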