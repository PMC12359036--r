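# Internal helpers shared across modules.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' @noRd
bx_error <- function(class, msg, ...) {
  stop(errorCondition(msg, ..., class = c(class, "bxbtag_error", "error")))
}

# Validate and normalize a DNA string: uppercase ACGT only (U rejected).
#' @noRd
as_dna <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    bx_error("bxbtag_bad_dna", sprintf("%s must be a single character string", what))
  x <- toupper(x)
  if (grepl("[^ACGT]", x))
    bx_error("bxbtag_bad_dna",
             sprintf("%s contains characters other than A/C/G/T", what))
  x
}

#' @noRd
revcomp <- function(x) {
  if (nchar(x) == 0L) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Split a DNA string into in-frame codons, dropping any trailing partial codon.
#' @noRd
codons <- function(x) {
  n <- nchar(x)
  if (n < 3L) return(character(0))
  substring(x, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
}

#' @noRd
translate_dna <- function(x) {
  n <- nchar(x) - nchar(x) %% 3L
  if (n < 3L) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(substr(x, 1L, n)),
                                     no.init.codon = TRUE))
}

# Deterministic local RNG scope: runs `code` under set.seed(seed) and restores
# the caller's random state afterwards (no leakage of global random state).
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' @noRd
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# round() uses banker's rounding; reports use conventional half-up rounding so
# printed percentages match hand arithmetic.
#' @noRd
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
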