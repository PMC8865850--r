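#' @useDynLib peartools, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' @param x character vector of DNA strings (A/C/G/T, uppercase).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  assert_dna(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

assert_dna <- function(x, what = "sequence") {
  if (!is.character(x) || anyNA(x)) {
    stop(what, " must be a character vector of DNA strings", call. = FALSE)
  }
  if (any(grepl("[^ACGT]", x))) {
    stop(what, " contains characters outside A/C/G/T ",
         "(degenerate or lowercase bases are rejected)", call. = FALSE)
  }
  invisible(x)
}

assert_probability <- function(p, what) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    stop(what, " must be a probability in [0, 1]", call. = FALSE)
  }
  invisible(p)
}

# Run code under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# DNA -> RNA transliteration (T -> U), 5'->3' preserved.
dna_to_rna <- function(x) chartr("T", "U", x)
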