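DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement a DNA string
#'
#' @param x character(1) DNA sequence (alphabet A/C/G/T/N).
#' @return character(1), the reverse complement.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive a per-stage child seed from a global seed
#'
#' One global seed fans out to stable per-stage seeds so stages can be rerun
#' in isolation and still reproduce a full-pipeline run.
#'
#' @param seed integer global seed.
#' @param stage integer or character stage identifier.
#' @return integer seed in [0, 2^31).
#' @export
derive_seed <- function(seed, stage) {
  if (is.character(stage)) {
    stage <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  }
  as.integer((as.double(seed) * 48271 + as.double(stage) * 16807 + 12345) %%
               2147483647)
}

#' Generate a random DNA sequence
#'
#' Bases are drawn i.i.d. with the requested GC content.
#'
#' @param n sequence length in bp.
#' @param gc_content probability that a base is G or C.
#' @param seed optional integer seed.
#' @return character(1) DNA string of length `n`.
#' @export
random_dna <- function(n, gc_content = 0.5, seed = NULL) {
  stopifnot(n >= 0, gc_content >= 0, gc_content <= 1)
  p <- c(A = (1 - gc_content) / 2, C = gc_content / 2,
         G = gc_content / 2, T = (1 - gc_content) / 2)
  draw <- function() paste(sample(DNA_BASES, n, replace = TRUE, prob = p),
                           collapse = "")
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

## Internal validators ---------------------------------------------------

assert_dna <- function(x, what = "sequence", allow_n = FALSE) {
  stopifnot(is.character(x), length(x) == 1L)
  alphabet <- if (allow_n) "ACGTN" else "ACGT"
  if (grepl(sprintf("[^%s]", alphabet), x)) {
    stop(sprintf("%s contains characters outside {%s}", what,
                 paste(strsplit(alphabet, "")[[1]], collapse = ",")),
         call. = FALSE)
  }
  invisible(x)
}

assert_fraction <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("%s must be a single value in [0, 1]", what), call. = FALSE)
  }
  invisible(x)
}

## Split a DNA string into a character vector of single bases.
dna_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]
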