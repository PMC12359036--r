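# Shared test helpers: compact fixture bundles and an independent
# brute-force Smith-Waterman (Gotoh) oracle used to cross-check the
# classifier's internal scorer.

small_fixture <- function(seed = 1L, terminus = "N") {
  make_fixture(seed, terminus = terminus,
               upstream = 500L, downstream = 550L, cds_length = 600L)
}

tiny_fixture <- function(seed = 1L, terminus = "N") {
  make_fixture(seed, terminus = terminus,
               upstream = 300L, downstream = 330L, cds_length = 300L)
}

# Plain-R local affine-gap aligner, written independently of the package
# scorer: full dynamic-programming matrices, gap of length L costs
# open + L * ext.
sw_oracle_score <- function(pattern, subject, match = 2, mismatch = -4,
                            open = 4, ext = 2) {
  p <- strsplit(pattern, "")[[1]]
  s <- strsplit(subject, "")[[1]]
  n <- length(p)
  m <- length(s)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
      F[i, j] <- max(H[i - 1, j] - open - ext, F[i - 1, j] - ext)
      sub <- if (p[i - 1] == s[j - 1]) match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + sub, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# oracle assignment: arg-max category over both read orientations
sw_oracle_assign <- function(read, refs) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  sc <- vapply(refs, function(r) {
    max(sw_oracle_score(read, r), sw_oracle_score(rc, r))
  }, 0)
  best <- max(sc)
  winners <- names(sc)[sc == best]
  if (length(winners) > 1L) "ambiguous" else winners
}
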