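# Attachment-site registry: Bxb1 attP/attB variants and heterotypic
# compatibility rules.
#
# Length classes used throughout:
#   * 58 bp attP  - single-cassette ssODN landing site
#   * 48 bp attP  - dual-cassette core landing site (middle 48 bp of the 58)
#   * 53 bp attP  - core attP carrying the 5 bp extension taken from the
#                   58 bp variant (appended 3' for N-terminal designs,
#                   prepended 5' for C-terminal designs)
#   * 46 bp attB  - donor-side site
# Recombination of attP x attB yields attR (P-left + dinucleotide + B-right)
# and attL (B-left + dinucleotide + P-right): 58 x 46 -> 52 + 52 bp,
# 48 x 46 -> 47 + 47 bp.

# Canonical Bxb1 site cores, central dinucleotide (GT) flanked by equal arms.
BXB1_ATTP_CORE_LEFT  <- "GGTTTGTCTGGTCAACCACCGCG"   # 23 nt
BXB1_ATTP_CORE_RIGHT <- "CTCAGTGGTGTACGGTACAAACC"   # 23 nt
BXB1_ATTB_CORE_LEFT  <- "GGCTTGTCGACGACGGCG"        # 18 nt
BXB1_ATTB_CORE_RIGHT <- "CTCCGTCGTCAGGATCAT"        # 18 nt

# Symmetric pads extending the cores to the working lengths (58/46 bp).
# Chosen so that every attR/attL junction is stop-codon-free in the fusion
# reading frame for all four dinucleotide variants (see the methods vignette).
BXB1_ATTP_PAD <- "CGGTG"   # 5 nt each side: 48 -> 58
BXB1_ATTB_PAD_LEFT  <- "CACC"   # 4 nt: 38 -> 46
BXB1_ATTB_PAD_RIGHT <- "GGCC"

#' Central-dinucleotide variants accepted by default
#'
#' The four heterotypic central dinucleotides used for orthogonal attP/attB
#' pairs. Matched dinucleotides are required for recombination; mismatched
#' pairs show minimal crosstalk and are treated as non-recombining.
#' @export
DINUCLEOTIDE_VARIANTS <- c("GT", "GA", "CT", "AG")

#' Construct an attachment site
#'
#' An attachment site is a directional recombination site composed of a left
#' arm, a central 2-nt crossover dinucleotide, and a right arm. `kind` is one
#' of `"P"`/`"B"` (pre-recombination attP/attB) or `"L"`/`"R"`
#' (post-recombination hybrid junctions).
#'
#' @param name Identifier, e.g. `"attP58-GT"`.
#' @param kind One of `"P"`, `"B"`, `"L"`, `"R"`.
#' @param left_arm,right_arm DNA arms flanking the central dinucleotide.
#' @param dinucleotide 2-nt central crossover dinucleotide.
#' @param orientation `"+"` or `"-"`; reverse-complementing a site flips the
#'   orientation rather than creating a new site.
#' @param source Provenance label (e.g. `"fallback"` for the built-in
#'   canonical-core sequences, or `"user"` for registry files).
#' @return An object of class `att_site`.
#' @export
att_site <- function(name, kind, left_arm, dinucleotide, right_arm,
                     orientation = "+", source = "user") {
  kind <- match.arg(kind, c("P", "B", "L", "R"))
  orientation <- match.arg(orientation, c("+", "-"))
  left_arm <- as_dna(left_arm, "left_arm")
  right_arm <- as_dna(right_arm, "right_arm")
  dinucleotide <- as_dna(dinucleotide, "dinucleotide")
  if (nchar(dinucleotide) != 2L)
    bx_error("bxbtag_invalid_variant", "central dinucleotide must be 2 nt")
  structure(list(name = name, kind = kind, left_arm = left_arm,
                 dinucleotide = dinucleotide, right_arm = right_arm,
                 orientation = orientation, source = source),
            class = "att_site")
}

#' @export
print.att_site <- function(x, ...) {
  cat(sprintf("att%s site '%s' (%s): %d bp [%s|%s|%s], strand %s\n",
              x$kind, x$name, x$source, site_length(x),
              x$left_arm, x$dinucleotide, x$right_arm, x$orientation))
  invisible(x)
}

#' Full sequence of an attachment site
#'
#' @param site An `att_site`.
#' @return `left_arm + dinucleotide + right_arm` as a character string
#'   (reverse-complemented when the site's orientation is `"-"`).
#' @export
site_sequence <- function(site) {
  s <- paste0(site$left_arm, site$dinucleotide, site$right_arm)
  if (site$orientation == "-") revcomp(s) else s
}

#' @rdname site_sequence
#' @export
site_length <- function(site) {
  nchar(site$left_arm) + 2L + nchar(site$right_arm)
}

#' Reverse-complement an attachment site
#'
#' The reverse complement of a site is the same site with flipped
#' orientation, never a distinct registry entry.
#' @param site An `att_site`.
#' @return The same site with `orientation` toggled.
#' @export
flip_site <- function(site) {
  site$orientation <- if (site$orientation == "+") "-" else "+"
  site
}

#' Substitute the central dinucleotide of a site
#'
#' Creates a heterotypic variant of `site`: identical arms, central
#' dinucleotide replaced. Length is unchanged.
#'
#' @param site An `att_site`.
#' @param dinucleotide Replacement 2-nt dinucleotide.
#' @param whitelist Accepted dinucleotides (default the four variants used
#'   for orthogonal pairing).
#' @return A new `att_site`.
#' @export
make_variant <- function(site, dinucleotide, whitelist = DINUCLEOTIDE_VARIANTS) {
  if (!is.character(dinucleotide) || length(dinucleotide) != 1L ||
      !(toupper(dinucleotide) %in% whitelist))
    bx_error("bxbtag_invalid_variant",
             sprintf("dinucleotide must be one of %s",
                     paste(whitelist, collapse = ", ")))
  dinucleotide <- toupper(dinucleotide)
  site$dinucleotide <- dinucleotide
  site$name <- sub("-[ACGT]{2}$", "", site$name)
  site$name <- paste0(site$name, "-", dinucleotide)
  site
}

#' Can two attachment sites recombine?
#'
#' Bxb1 recombines an attP with an attB only; the central dinucleotides must
#' match (heterotypic variants are mutually orthogonal). attP x attP,
#' attB x attB and attR x attL pairings never recombine.
#'
#' @param a,b `att_site` objects.
#' @return `TRUE` iff `{a$kind, b$kind} == {P, B}` and the central
#'   dinucleotides are identical.
#' @export
compatible <- function(a, b) {
  setequal(c(a$kind, b$kind), c("P", "B")) &&
    a$dinucleotide == b$dinucleotide
}

registry_key <- function(kind, length, dinuc) sprintf("%s%d-%s", kind, length, dinuc)

#' Build the default attachment-site registry
#'
#' Populates every length class (58/48/53 bp attP, 46 bp attB) for each of
#' the four central-dinucleotide variants (GT, GA, CT, AG). Sequences are the
#' built-in defaults: canonical Bxb1 cores extended symmetrically to the
#' working lengths, labelled `source = "fallback"`. A registry loaded from a
#' TSV of bench-validated sequences (see [read_site_registry()]) replaces
#' them transparently.
#'
#' The 53 bp attP class is the 48 bp core carrying the preferred 5 bp
#' extension (the terminal 5 bp of the 58 bp variant) on its 3' arm, as used
#' on N-terminal dual-cassette ssODNs; [attp_extended()] builds the
#' 5'-extended form used for C-terminal designs.
#'
#' @return A `site_registry` object.
#' @export
build_default_registry <- function() {
  sites <- list()
  for (d in DINUCLEOTIDE_VARIANTS) {
    p58 <- att_site(paste0("attP58-", d), "P",
                    paste0(BXB1_ATTP_PAD, BXB1_ATTP_CORE_LEFT), d,
                    paste0(BXB1_ATTP_CORE_RIGHT, BXB1_ATTP_PAD),
                    source = "fallback")
    p48 <- att_site(paste0("attP48-", d), "P",
                    BXB1_ATTP_CORE_LEFT, d, BXB1_ATTP_CORE_RIGHT,
                    source = "fallback")
    p53 <- att_site(paste0("attP53-", d), "P",
                    BXB1_ATTP_CORE_LEFT, d,
                    paste0(BXB1_ATTP_CORE_RIGHT, BXB1_ATTP_PAD),
                    source = "fallback")
    b46 <- att_site(paste0("attB46-", d), "B",
                    paste0(BXB1_ATTB_PAD_LEFT, BXB1_ATTB_CORE_LEFT), d,
                    paste0(BXB1_ATTB_CORE_RIGHT, BXB1_ATTB_PAD_RIGHT),
                    source = "fallback")
    sites[[registry_key("P", 58L, d)]] <- p58
    sites[[registry_key("P", 48L, d)]] <- p48
    sites[[registry_key("P", 53L, d)]] <- p53
    sites[[registry_key("B", 46L, d)]] <- b46
  }
  structure(list(sites = sites), class = "site_registry")
}

#' @export
print.site_registry <- function(x, ...) {
  cat(sprintf("site_registry with %d sites:\n", length(x$sites)))
  for (s in x$sites)
    cat(sprintf("  %-12s %s %2d bp (%s)\n", s$name, s$kind, site_length(s), s$source))
  invisible(x)
}

#' Look up a site in a registry
#'
#' @param registry A `site_registry`.
#' @param kind `"P"` or `"B"`.
#' @param length Length class (58, 48, 53 for attP; 46 for attB).
#' @param dinucleotide Central dinucleotide variant.
#' @return An `att_site`.
#' @export
get_site <- function(registry, kind, length, dinucleotide = "GT") {
  key <- registry_key(kind, as.integer(length), toupper(dinucleotide))
  s <- registry$sites[[key]]
  if (is.null(s))
    bx_error("bxbtag_missing_site", sprintf("no site '%s' in registry", key))
  s
}

#' Extended attP element for dual-cassette ssODNs
#'
#' Returns the 53 bp attP element: the 48 bp core with the preferred 5 bp
#' extension from the 58 bp variant. For N-terminal designs the extension
#' follows the core (3' side, lengthening the resulting attL); for C-terminal
#' designs it precedes the core (5' side, lengthening the resulting attR).
#'
#' @param registry A `site_registry`.
#' @param dinucleotide Central dinucleotide variant.
#' @param side `"3prime"` (N-terminal use) or `"5prime"` (C-terminal use).
#' @return An `att_site` of total length 53.
#' @export
attp_extended <- function(registry, dinucleotide = "GT",
                          side = c("3prime", "5prime")) {
  side <- match.arg(side)
  core <- get_site(registry, "P", 48L, dinucleotide)
  p58 <- get_site(registry, "P", 58L, dinucleotide)
  ext_len <- 5L
  if (side == "3prime") {
    ext <- substr(p58$right_arm, nchar(p58$right_arm) - ext_len + 1L,
                  nchar(p58$right_arm))
    att_site(paste0("attP53-", core$dinucleotide), "P", core$left_arm,
             core$dinucleotide, paste0(core$right_arm, ext),
             source = core$source)
  } else {
    ext <- substr(p58$left_arm, 1L, ext_len)
    att_site(paste0("attP53x5-", core$dinucleotide), "P",
             paste0(ext, core$left_arm), core$dinucleotide, core$right_arm,
             source = core$source)
  }
}

#' Serialize a registry to TSV / load it back
#'
#' The TSV dialect has columns `name`, `kind`, `sequence`,
#' `dinucleotide_variant`, `source`. Arms are recovered by splitting the
#' sequence symmetrically when possible, otherwise at the first central
#' occurrence of the dinucleotide.
#'
#' @param registry A `site_registry`.
#' @param path Output TSV path.
#' @return `path`, invisibly (`write_site_registry`); a `site_registry`
#'   (`read_site_registry`).
#' @export
write_site_registry <- function(registry, path) {
  df <- data.frame(
    name = vapply(registry$sites, `[[`, "", "name"),
    kind = vapply(registry$sites, `[[`, "", "kind"),
    sequence = vapply(registry$sites, site_sequence, ""),
    dinucleotide_variant = vapply(registry$sites, `[[`, "", "dinucleotide"),
    source = vapply(registry$sites, `[[`, "", "source"),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_site_registry
#' @export
read_site_registry <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, colClasses = "character")
  sites <- list()
  for (i in seq_len(nrow(df))) {
    seq <- as_dna(df$sequence[i], df$name[i])
    d <- toupper(df$dinucleotide_variant[i])
    n <- nchar(seq)
    # symmetric split when the centre matches the dinucleotide, else first
    # near-central match
    mid <- (n - 2L) %/% 2L
    if (n %% 2L == 0L && substr(seq, mid + 1L, mid + 2L) == d) {
      la <- substr(seq, 1L, mid); ra <- substr(seq, mid + 3L, n)
    } else {
      hits <- gregexpr(d, seq, fixed = TRUE)[[1]]
      if (hits[1] == -1L)
        bx_error("bxbtag_bad_registry",
                 sprintf("site '%s': dinucleotide %s not found", df$name[i], d))
      pos <- hits[which.min(abs(hits - (mid + 1L)))]
      la <- substr(seq, 1L, pos - 1L); ra <- substr(seq, pos + 2L, n)
    }
    s <- att_site(df$name[i], df$kind[i], la, d, ra,
                  source = df$source[i] %||% "user")
    sites[[registry_key(s$kind, site_length(s), d)]] <- s
  }
  structure(list(sites = sites), class = "site_registry")
}

#' Export all registry site sequences as FASTA
#'
#' @param registry A `site_registry`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_registry_fasta <- function(registry, path) {
  seqs <- Biostrings::DNAStringSet(vapply(registry$sites, site_sequence, ""))
  names(seqs) <- vapply(registry$sites, `[[`, "", "name")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
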