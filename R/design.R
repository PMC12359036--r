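# ssODN designer: landing-pad cassettes, reading-frame spacer arithmetic and
# sgRNA re-cutting checks.
#
# Frame arithmetic: post-integration the coding sequence must read through
# the hybrid junction (attL for N-terminal tags, attR for C-terminal tags).
# The single-cassette junction is 52 bp (remainder 1 mod 3), so the minimal
# donor-side spacer is 2 nt, giving 54 = 18 codons. Dual-cassette junctions
# are 47 bp; the designer restores the 52 bp arithmetic by extending the
# relevant core attP with 5 bp from the 58 bp variant (a 53 bp element), so
# the same donor plasmids serve both systems.

#' Minimal spacer length restoring codon phase across a junction
#'
#' Returns the smallest spacer length that makes `junction_len + spacer`
#' divisible by 3, i.e. `(3 - junction_len %% 3) %% 3`. For the 52 bp
#' single-cassette junction this is 2 (52 + 2 = 54, divisible by 3).
#'
#' @param junction_len Junction length in nt (>= 0).
#' @return Integer in `{0, 1, 2}`.
#' @export
required_spacer_length <- function(junction_len) {
  if (any(!is.finite(junction_len)) || any(junction_len < 0) ||
      any(junction_len != floor(junction_len)))
    bx_error("bxbtag_invalid_length", "junction_len must be a non-negative integer")
  as.integer((3L - junction_len %% 3L) %% 3L)
}

#' Synthesize a frame-neutral DNA spacer
#'
#' Generates a spacer of the requested length whose codons - read in the
#' fusion frame together with the flanking context - contain no stop codon
#' (TAA/TAG/TGA) and, when `forbid_start = TRUE`, no ATG. Candidates are
#' enumerated exhaustively for short spacers (seed-shuffled order) so the
#' result is deterministic for a fixed seed.
#'
#' @param length Spacer length in nt (>= 0).
#' @param frame_offset Codon position (0, 1 or 2) of the spacer's first base
#'   in the fusion reading frame.
#' @param flanks List with `left` and `right` DNA context strings (codons
#'   overlapping the spacer are completed from these).
#' @param forbid_start Also reject ATG in codons overlapping the spacer.
#' @param seed Integer seed controlling the candidate order.
#' @return A DNA string of the requested length (`""` for length 0).
#' @export
make_spacer <- function(length, frame_offset = 0L,
                        flanks = list(left = "", right = ""),
                        forbid_start = TRUE, seed = 1L) {
  if (!is.finite(length) || length < 0 || length != floor(length))
    bx_error("bxbtag_invalid_length", "spacer length must be a non-negative integer")
  length <- as.integer(length)
  if (length == 0L) return("")
  frame_offset <- as.integer(frame_offset) %% 3L
  left <- if (nchar(flanks$left %||% "")) as_dna(flanks$left, "left flank") else ""
  right <- if (nchar(flanks$right %||% "")) as_dna(flanks$right, "right flank") else ""
  ok <- function(spacer) {
    spacer_ok_in_frame(spacer, frame_offset, left, right, forbid_start)
  }
  bases <- c("A", "C", "G", "T")
  if (length <= 6L) {
    grid <- do.call(expand.grid,
                    c(rep(list(bases), length), stringsAsFactors = FALSE))
    cand <- apply(grid, 1L, paste, collapse = "")
    cand <- with_seed(seed, sample(cand))
    for (s in cand) if (ok(s)) return(s)
    bx_error("bxbtag_unsatisfiable_spacer",
             sprintf("no %d-nt spacer satisfies the frame constraints in this context", length))
  }
  with_seed(seed, {
    for (i in seq_len(5000L)) {
      s <- random_dna(length)
      if (ok(s)) return(s)
    }
    bx_error("bxbtag_unsatisfiable_spacer",
             sprintf("no %d-nt spacer found after 5000 draws", length))
  })
}

# Check the codons overlapping a spacer for stops (and optionally ATG) in a
# given frame, completing partial codons from the flanking context.
#' @noRd
spacer_ok_in_frame <- function(spacer, frame_offset, left, right, forbid_start) {
  need_left <- frame_offset
  if (need_left > nchar(left)) return(FALSE)   # cannot phase without context
  ctx_left <- if (need_left > 0L)
    substr(left, nchar(left) - need_left + 1L, nchar(left)) else ""
  tail_len <- (3L - (need_left + nchar(spacer)) %% 3L) %% 3L
  if (tail_len > nchar(right)) tail_len <- nchar(right)
  ctx_right <- if (tail_len > 0L) substr(right, 1L, tail_len) else ""
  ctx <- paste0(ctx_left, spacer, ctx_right)
  cs <- codons(ctx)
  cs <- cs[nchar(cs) == 3L]
  if (any(cs %in% STOP_CODONS)) return(FALSE)
  if (forbid_start && any(cs == "ATG")) return(FALSE)
  TRUE
}

#' Enumerate candidate sgRNA guides near a position
#'
#' Scans both strands of the locus for 20-nt protospacers adjacent to an NGG
#' PAM and reports the blunt cut site (between positions 17 and 18 of the
#' protospacer, 3 bp from the PAM).
#'
#' @param sequence Locus DNA string.
#' @param around 0-based position of interest (e.g. insertion point);
#'   used for the `distance` column.
#' @param window Only report guides whose cut site is within this many nt of
#'   `around` (default 50).
#' @return data.frame with columns `spacer`, `strand`, `pam`,
#'   `protospacer_start` (0-based), `cut` (0-based coordinate of the cut,
#'   i.e. the bond before this base), `distance`.
#' @export
find_guides <- function(sequence, around, window = 50L) {
  sequence <- as_dna(sequence)
  n <- nchar(sequence)
  chars <- strsplit(sequence, "")[[1]]
  rows <- list()
  # plus strand: protospacer [p, p+20), PAM [p+20, p+23) == NGG
  for (p0 in seq_len(n - 22L) - 1L) {
    if (chars[p0 + 22L] == "G" && chars[p0 + 23L] == "G") {
      cut <- p0 + 17L
      if (abs(cut - around) > window) next
      rows[[length(rows) + 1L]] <- data.frame(
        spacer = substr(sequence, p0 + 1L, p0 + 20L), strand = "+",
        pam = substr(sequence, p0 + 21L, p0 + 23L),
        protospacer_start = p0, cut = cut,
        distance = abs(cut - around), stringsAsFactors = FALSE)
    }
  }
  # minus strand: PAM CCN at [p, p+3), protospacer [p+3, p+23) (top-strand coords)
  for (p0 in seq_len(n - 22L) - 1L) {
    if (chars[p0 + 1L] == "C" && chars[p0 + 2L] == "C") {
      cut <- p0 + 6L
      if (abs(cut - around) > window) next
      rows[[length(rows) + 1L]] <- data.frame(
        spacer = revcomp(substr(sequence, p0 + 4L, p0 + 23L)), strand = "-",
        pam = revcomp(substr(sequence, p0 + 1L, p0 + 3L)),
        protospacer_start = p0 + 3L, cut = cut,
        distance = abs(cut - around), stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(spacer = character(), strand = character(),
                      pam = character(), protospacer_start = integer(),
                      cut = integer(), distance = integer(),
                      stringsAsFactors = FALSE))
  g <- do.call(rbind, rows)
  g[order(g$distance, g$protospacer_start), , drop = FALSE]
}

# seed-match count of a guide's PAM-proximal 12-mer within the locus (both
# strands); used only to break distance ties between candidate guides.
#' @noRd
seed_matches <- function(sequence, spacer) {
  seed <- substr(spacer, 9L, 20L)
  cnt <- function(pat, subj) {
    length(Biostrings::matchPattern(pat, Biostrings::DNAString(subj)))
  }
  cnt(seed, sequence) + cnt(revcomp(seed), sequence)
}

#' Design the ssODN HDR template for a tagging knock-in
#'
#' Builds the single- or dual-cassette attP ssODN that replaces the start
#' codon (N-terminal tag) or stop codon (C-terminal tag) of the annotated
#' CDS, flanked by homology arms copied from the reference.
#'
#' Single mode inserts the 58 bp attP. Dual mode inserts two heterotypic
#' attP elements: the 48 bp core plus a 53 bp extended element (core + the
#' preferred 5 bp extension from the 58 bp variant). For N-terminal designs
#' the extension follows the second attP (lengthening the downstream attL to
#' 52 bp); for C-terminal designs it precedes the first attP (lengthening
#' the upstream attR to 52 bp), so the post-integration coding junction
#' always carries the 52 + 2 = 54 nt arithmetic.
#'
#' @param locus List with `seq` (DNA string), `cds_start`/`cds_end` (0-based
#'   half-open CDS coordinates), optional `cds_strand` (`"+"` default;
#'   minus-strand CDSs are normalised internally) and optional `id`.
#' @param terminus `"N"` or `"C"`.
#' @param mode `"single"` or `"dual"`.
#' @param registry A `site_registry` (default [build_default_registry()]).
#' @param dinucleotides Central-dinucleotide plan: one variant for single
#'   mode (default `"GT"`), two distinct variants for dual mode (default
#'   `c("GA", "GT")`, genomic order).
#' @param arm_length Homology arm length per side; default 70 nt (single) or
#'   50 nt (dual).
#' @param guide Optional guide spec: 20-nt spacer string. When `NULL`, the
#'   guide whose cut site is closest to the insertion point is selected
#'   (ties broken by fewer seed matches within the locus).
#' @param coding_strand Emit the ssODN on the CDS coding strand (default
#'   `TRUE`); `FALSE` emits the reverse complement.
#' @return A `tagging_design` object.
#' @export
design_ssodn <- function(locus, terminus = c("N", "C"),
                         mode = c("single", "dual"),
                         registry = build_default_registry(),
                         dinucleotides = NULL, arm_length = NULL,
                         guide = NULL, coding_strand = TRUE) {
  terminus <- match.arg(terminus)
  mode <- match.arg(mode)
  seq <- as_dna(locus$seq, "locus")
  cds_start <- as.integer(locus$cds_start)
  cds_end <- as.integer(locus$cds_end)
  strand <- locus$cds_strand %||% "+"
  if (strand == "-") {
    n <- nchar(seq)
    seq <- revcomp(seq)
    tmp <- n - cds_end
    cds_end <- n - cds_start
    cds_start <- tmp
  }
  if (cds_end - cds_start < 6L || (cds_end - cds_start) %% 3L != 0L)
    bx_error("bxbtag_annotation", "CDS span must be a multiple of 3 and >= 6 nt")
  if (substr(seq, cds_start + 1L, cds_start + 3L) != "ATG")
    bx_error("bxbtag_annotation", "annotated CDS does not begin with ATG")
  if (!(substr(seq, cds_end - 2L, cds_end) %in% STOP_CODONS))
    bx_error("bxbtag_annotation", "annotated CDS does not end with a stop codon")

  if (is.null(dinucleotides))
    dinucleotides <- if (mode == "single") "GT" else c("GA", "GT")
  dinucleotides <- toupper(dinucleotides)
  if (mode == "single" && length(dinucleotides) != 1L)
    bx_error("bxbtag_invalid_variant", "single mode takes one dinucleotide variant")
  if (mode == "dual" &&
      (length(dinucleotides) != 2L || dinucleotides[1] == dinucleotides[2]))
    bx_error("bxbtag_invalid_variant",
             "dual mode takes two distinct dinucleotide variants")
  if (is.null(arm_length)) arm_length <- if (mode == "single") 70L else 50L
  arm_length <- as.integer(arm_length)

  # replaced codon: start codon (N) or stop codon (C), 0-based half-open
  repl <- if (terminus == "N") c(cds_start, cds_start + 3L) else
    c(cds_end - 3L, cds_end)
  if (repl[1] - arm_length < 0L || repl[2] + arm_length > nchar(seq))
    bx_error("bxbtag_annotation", "homology arms extend past the locus ends")

  if (mode == "single") {
    sites <- list(get_site(registry, "P", 58L, dinucleotides[1]))
  } else if (terminus == "N") {
    sites <- list(get_site(registry, "P", 48L, dinucleotides[1]),
                  attp_extended(registry, dinucleotides[2], side = "3prime"))
  } else {
    sites <- list(attp_extended(registry, dinucleotides[1], side = "5prime"),
                  get_site(registry, "P", 48L, dinucleotides[2]))
  }
  cassette <- paste(vapply(sites, site_sequence, ""), collapse = "")
  arm_left <- substr(seq, repl[1] - arm_length + 1L, repl[1])
  arm_right <- substr(seq, repl[2] + 1L, repl[2] + arm_length)
  ssodn <- paste0(arm_left, cassette, arm_right)

  # guide selection
  insertion_point <- repl[1]
  cands <- find_guides(seq, insertion_point)
  if (is.null(guide)) {
    if (nrow(cands) == 0L)
      bx_error("bxbtag_no_guide", "no NGG guide found near the insertion point")
    best <- cands[cands$distance == min(cands$distance), , drop = FALSE]
    if (nrow(best) > 1L) {
      sm <- vapply(best$spacer, function(s) seed_matches(seq, s), 0L)
      best <- best[order(sm), , drop = FALSE]
    }
    guide_row <- best[1L, ]
  } else {
    spacer <- as_dna(guide, "guide spacer")
    hit <- cands[cands$spacer == spacer, , drop = FALSE]
    if (nrow(hit) == 0L) {
      all_g <- find_guides(seq, insertion_point, window = nchar(seq))
      hit <- all_g[all_g$spacer == spacer, , drop = FALSE]
    }
    if (nrow(hit) == 0L)
      bx_error("bxbtag_guide_not_on_reference",
               "supplied guide spacer (with NGG PAM) not found on the reference")
    guide_row <- hit[1L, ]
  }

  # post-integration coding-junction bookkeeping: N-terminal reads through
  # the downstream attL, C-terminal through the upstream attR; both are 52 bp
  # by construction, needing a 2 nt donor-side spacer.
  junction_len <- if (terminus == "N") {
    s <- sites[[length(sites)]]
    b <- get_site(registry, "B", 46L, s$dinucleotide)
    site_length(recombine_sites(s, b)$attL)
  } else {
    s <- sites[[1L]]
    b <- get_site(registry, "B", 46L, s$dinucleotide)
    site_length(recombine_sites(s, b)$attR)
  }

  structure(list(
    locus_id = locus$id %||% "locus",
    locus_seq = seq, cds_start = cds_start, cds_end = cds_end,
    cds_strand = "+", input_strand = strand,
    terminus = terminus, mode = mode,
    dinucleotide_plan = dinucleotides,
    homology_arm_length = arm_length,
    replaced_span = repl,
    cassette = cassette, cassette_sites = sites,
    ssodn = if (coding_strand) ssodn else revcomp(ssodn),
    ssodn_strand = if (coding_strand) "coding" else "template",
    guide = guide_row,
    coding_junction_len = junction_len,
    donor_spacer_len = required_spacer_length(junction_len),
    registry_source = sites[[1]]$source
  ), class = "tagging_design")
}

#' @export
print.tagging_design <- function(x, ...) {
  cat(sprintf("tagging_design: %s-terminal %s-cassette at '%s' (%s)\n",
              x$terminus, x$mode, x$locus_id,
              paste(x$dinucleotide_plan, collapse = "/")))
  cat(sprintf("  ssODN %d nt (%d nt arms + %d nt cassette), %s strand\n",
              nchar(x$ssodn), x$homology_arm_length, nchar(x$cassette),
              x$ssodn_strand))
  cat(sprintf("  cassette elements: %s\n",
              paste(sprintf("%s (%d bp)",
                            vapply(x$cassette_sites, `[[`, "", "name"),
                            vapply(x$cassette_sites, site_length, 0L)),
                    collapse = " + ")))
  cat(sprintf("  guide %s (%s strand, cut at %d, %d nt from insertion)\n",
              x$guide$spacer, x$guide$strand, x$guide$cut, x$guide$distance))
  cat(sprintf("  coding junction %d bp -> donor spacer %d nt (sum %d)\n",
              x$coding_junction_len, x$donor_spacer_len,
              x$coding_junction_len + x$donor_spacer_len))
  invisible(x)
}

#' The HDR-edited locus implied by a design
#'
#' Perfect arm-mediated HDR: the replaced start/stop codon is substituted by
#' the attP cassette; everything else matches the reference.
#'
#' @param design A `tagging_design`.
#' @return DNA string of the ssODN-integrated locus.
#' @export
hdr_locus <- function(design) {
  paste0(substr(design$locus_seq, 1L, design$replaced_span[1]),
         design$cassette,
         substr(design$locus_seq, design$replaced_span[2] + 1L,
                nchar(design$locus_seq)))
}

# does sequence contain the 20-nt protospacer with an adjacent NGG PAM, on
# either strand?
#' @noRd
protospacer_intact <- function(sequence, spacer) {
  hit_on <- function(subj, sp) {
    m <- Biostrings::matchPattern(sp, Biostrings::DNAString(subj))
    for (st in Biostrings::start(m)) {
      pam <- substr(subj, st + 21L, st + 22L)  # GG of the NGG PAM
      if (pam == "GG") return(TRUE)
    }
    FALSE
  }
  hit_on(sequence, spacer) || hit_on(revcomp(sequence), spacer)
}

#' Check whether correct integration blocks the sgRNA from re-cutting
#'
#' Scans the predicted ssODN-integrated and fully-integrated alleles for the
#' intact 20-nt protospacer adjacent to an NGG PAM (both strands). If the
#' guide survives integration, suggests PAM-destroying edits inside the
#' homology arms: synonymous codon substitutions where the PAM lies in the
#' native coding frame, any base change in non-coding context.
#'
#' @param design A `tagging_design` with a selected guide.
#' @param alleles An `allele_set` from [predict_alleles()] (or any list of
#'   sequences/`integrated_allele`s to scan; the `wildtype` entry is
#'   ignored).
#' @return A `recut_report`: list with `verdict` (`"blocked"` or
#'   `"at_risk"`), `reason`, and `suggested_edits` (data.frame with columns
#'   `position` (0-based locus coordinate), `ref_base`, `alt_base`,
#'   `synonymous`).
#' @export
check_recut <- function(design, alleles) {
  spacer <- design$guide$spacer
  if (!protospacer_intact(design$locus_seq, spacer))
    bx_error("bxbtag_guide_not_on_reference",
             "design guide has no intact protospacer + NGG on the reference")
  seqs <- alleles$alleles %||% alleles
  at_risk <- FALSE
  risky <- character()
  for (nm in names(seqs)) {
    if (nm == "wildtype") next
    s <- seqs[[nm]]
    s <- if (inherits(s, "integrated_allele")) s$sequence else s
    if (protospacer_intact(s, spacer)) { at_risk <- TRUE; risky <- c(risky, nm) }
  }
  if (!at_risk) {
    return(structure(list(verdict = "blocked",
                          reason = "integration disrupts the protospacer/PAM on every edited allele",
                          suggested_edits = empty_edits()),
                     class = "recut_report"))
  }
  edits <- suggest_pam_edits(design)
  structure(list(verdict = "at_risk",
                 reason = sprintf("intact protospacer + NGG found on predicted allele(s): %s",
                                  paste(risky, collapse = ", ")),
                 suggested_edits = edits),
            class = "recut_report")
}

#' @export
print.recut_report <- function(x, ...) {
  cat(sprintf("recut check: %s\n  %s\n", x$verdict, x$reason))
  if (nrow(x$suggested_edits)) {
    cat("  suggested PAM edits:\n")
    print(x$suggested_edits)
  }
  invisible(x)
}

empty_edits <- function() {
  data.frame(position = integer(), ref_base = character(),
             alt_base = character(), synonymous = logical(),
             stringsAsFactors = FALSE)
}

# Propose PAM-destroying edits within the homology arms. Coding positions
# only accept synonymous substitutions (checked in the native frame).
#' @noRd
suggest_pam_edits <- function(design) {
  seq <- design$locus_seq
  g <- design$guide
  # PAM occupies, in top-strand coordinates:
  pam_pos <- if (g$strand == "+")
    (g$protospacer_start + 20L):(g$protospacer_start + 22L)
  else (g$protospacer_start - 3L):(g$protospacer_start - 1L)
  # the two G positions of the NGG (C positions on the top strand for "-")
  gg_pos <- if (g$strand == "+") pam_pos[2:3] else pam_pos[1:2]
  arm_lo <- design$replaced_span[1] - design$homology_arm_length
  arm_hi <- design$replaced_span[2] + design$homology_arm_length
  in_arms <- function(p) (p >= arm_lo && p < design$replaced_span[1]) ||
    (p >= design$replaced_span[2] && p < arm_hi)
  in_cds <- function(p) p >= design$cds_start && p < design$cds_end
  edits <- empty_edits()
  try_edit <- function(p0) {
    if (!in_arms(p0)) return(NULL)
    ref <- substr(seq, p0 + 1L, p0 + 1L)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      if (in_cds(p0)) {
        off <- (p0 - design$cds_start) %% 3L
        c0 <- p0 - off
        codon <- substr(seq, c0 + 1L, c0 + 3L)
        mutated <- codon
        substr(mutated, off + 1L, off + 1L) <- alt
        if (translate_dna(codon) != translate_dna(mutated)) next
        return(data.frame(position = p0, ref_base = ref, alt_base = alt,
                          synonymous = TRUE, stringsAsFactors = FALSE))
      }
      return(data.frame(position = p0, ref_base = ref, alt_base = alt,
                        synonymous = FALSE, stringsAsFactors = FALSE))
    }
    NULL
  }
  for (p0 in c(gg_pos, setdiff(pam_pos, gg_pos))) {
    e <- try_edit(p0)
    if (!is.null(e)) edits <- rbind(edits, e)
  }
  edits
}
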