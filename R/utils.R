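#' @importFrom rlang %||% abort warn
#' @import tibble
NULL

BASES <- c("A", "C", "G", "T")

# Evaluate `code` with a temporary RNG state; the caller's .Random.seed is
# restored afterwards so package functions never perturb user randomness.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a reproducible per-stage seed (< 2^31) from a single run seed.
stage_seed <- function(seed, stage) {
  h <- rlang::hash(paste0("numtaudit::", seed, "::", stage))
  (strtoi(substr(h, 1, 7), base = 16L) %% 2147483646L) + 1L
}

random_dna <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

#' Reverse complement of DNA strings
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()].
#'
#' @param x Character vector of A/C/G/T sequences.
#' @return Character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  unname(as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x))))
}

complement_base <- function(x) {
  chartr("ACGT", "TGCA", x)
}

# Hamming distance between paired equal-length strings (vectorised over pairs).
hamming_pairs <- function(a, b) {
  if (length(a) == 0) return(integer(0))
  mapply(function(x, y) sum(charToRaw(x) != charToRaw(y)), a, b, USE.NAMES = FALSE)
}

#' Hamming distance between two equal-length sequences
#'
#' @param a,b Single DNA strings of equal length.
#' @return Integer count of mismatching positions.
#' @export
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    abort("hamming() requires equal-length sequences")
  }
  sum(charToRaw(a) != charToRaw(b))
}

assert_dna <- function(sequence, what = "sequence") {
  bad <- regmatches(sequence, regexpr("[^ACGT]", sequence))
  if (length(bad) > 0 && nzchar(bad)) {
    pos <- regexpr("[^ACGT]", sequence)
    abort(sprintf("%s contains non-ACGT character '%s' at position %d",
                  what, bad, as.integer(pos)))
  }
  invisible(TRUE)
}
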