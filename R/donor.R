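# Donor toolkit: Type IIS excision/circularization of single-cassette donors
# and structural validation of donor constructs.

#' BbsI (or another Type IIS) enzyme specification
#'
#' BbsI recognises GAAGAC and cuts downstream: top strand 2 nt and bottom
#' strand 6 nt past the recognition site, leaving 4-nt 5' overhangs.
#'
#' @param name Enzyme name.
#' @param recognition Recognition sequence (given 5'->3' on the strand the
#'   enzyme reads).
#' @param cut_top,cut_bottom Cut offsets past the recognition 3' end on the
#'   top and bottom strands.
#' @return An `enzyme_spec` list.
#' @export
bbsi_spec <- function(name = "BbsI", recognition = "GAAGAC",
                      cut_top = 2L, cut_bottom = 6L) {
  list(name = name, recognition = as_dna(recognition, "recognition"),
       cut_top = as.integer(cut_top), cut_bottom = as.integer(cut_bottom))
}

#' Construct a donor object
#'
#' @param sequence Donor DNA (top strand of the circle/plasmid).
#' @param topology `"circle"` (backbone-free circularized donor) or
#'   `"plasmid"` (dual-cassette donor with backbone).
#' @param spacer Annotated donor-side frame spacer sequence.
#' @param linker Annotated linker sequence (GGSGGGSG codons).
#' @param insert_span Optional 0-based half-open cargo coordinates.
#' @return A `donor_construct`.
#' @export
donor_construct <- function(sequence, topology = c("circle", "plasmid"),
                            spacer = NULL, linker = NULL, insert_span = NULL) {
  topology <- match.arg(topology)
  structure(list(sequence = as_dna(sequence, "donor"), topology = topology,
                 spacer = spacer, linker = linker, insert_span = insert_span),
            class = "donor_construct")
}

#' @export
print.donor_construct <- function(x, ...) {
  cat(sprintf("donor_construct (%s): %d bp%s%s\n", x$topology,
              nchar(x$sequence),
              if (!is.null(x$spacer)) sprintf(", spacer %d nt", nchar(x$spacer)) else "",
              if (!is.null(x$linker)) ", linker annotated" else ""))
  invisible(x)
}

find_recognition <- function(sequence, enzyme) {
  fwd <- gregexpr(enzyme$recognition, sequence, fixed = TRUE)[[1]]
  rev <- gregexpr(revcomp(enzyme$recognition), sequence, fixed = TRUE)[[1]]
  fwd <- fwd[fwd > 0L]; rev <- rev[rev > 0L]
  list(fwd = as.integer(fwd) - 1L, rev = as.integer(rev) - 1L)  # 0-based
}

#' Excise the attB cargo from a producer plasmid and self-circularize it
#'
#' In-silico model of the single-cassette donor prep: the producer plasmid
#' carries two inward-facing Type IIS recognition sites flanking the
#' attB-cargo region; digestion excises the cargo fragment with 4-nt 5'
#' overhangs, and perfect monomeric self-ligation yields the circular donor.
#' The recognition sites stay in the backbone and are absent from the
#' product. Conservation: fragment length + backbone length equals the
#' plasmid length.
#'
#' @param plasmid Producer plasmid DNA (circular; given as its top strand).
#' @param enzyme An `enzyme_spec` (default [bbsi_spec()]).
#' @param dimer Also build the head-to-tail circular dimer species (ligation
#'   by-product) and attach it as `$dimer`.
#' @return A `donor_construct` with `topology = "circle"`; attributes
#'   `fragment_length` and `backbone_length` record the digestion
#'   arithmetic.
#' @export
excise_and_circularize <- function(plasmid, enzyme = bbsi_spec(), dimer = FALSE) {
  seq <- as_dna(plasmid, "plasmid")
  L <- nchar(seq)
  hits <- find_recognition(seq, enzyme)
  n_sites <- length(hits$fwd) + length(hits$rev)
  if (n_sites != 2L)
    bx_error("bxbtag_digest",
             sprintf("expected exactly 2 %s recognition sites, found %d (positions %s)",
                     enzyme$name, n_sites,
                     paste(sort(c(hits$fwd, hits$rev)), collapse = ", ")))
  if (length(hits$fwd) != 1L || length(hits$rev) != 1L)
    bx_error("bxbtag_digest",
             sprintf("%s sites are not inward-facing (need one per strand)", enzyme$name))
  p0 <- hits$fwd; q0 <- hits$rev
  rl <- nchar(enzyme$recognition)
  # top-strand cut coordinates (0-based bond positions)
  t1 <- p0 + rl + enzyme$cut_top
  t2 <- q0 - enzyme$cut_bottom
  if (t1 >= t2)
    bx_error("bxbtag_digest",
             "recognition sites face outward or overlap; cannot excise a fragment between them")
  ov <- enzyme$cut_bottom - enzyme$cut_top
  if (t1 + ov > L || t2 + ov > L)
    bx_error("bxbtag_digest", "cut site extends past the provided sequence")
  over1 <- substr(seq, t1 + 1L, t1 + ov)
  over2 <- substr(seq, t2 + 1L, t2 + ov)
  if (over1 != over2)
    bx_error("bxbtag_ligation",
             sprintf("fragment overhangs %s / %s are not compatible for self-ligation",
                     over1, over2))
  circle <- substr(seq, t1 + 1L, t2)
  inner <- find_recognition(circle, enzyme)
  if (length(inner$fwd) + length(inner$rev) > 0L)
    bx_error("bxbtag_digest",
             sprintf("internal %s site inside the cargo at position(s) %s",
                     enzyme$name,
                     paste(sort(c(inner$fwd, inner$rev)), collapse = ", ")))
  out <- donor_construct(circle, "circle")
  attr(out, "fragment_length") <- nchar(circle)
  attr(out, "backbone_length") <- L - nchar(circle)
  if (dimer) out$dimer <- donor_construct(paste0(circle, circle), "circle")
  out
}

#' Build the head-to-tail dimer of a circular donor
#'
#' Ligation by-product species used as a classifier contaminant fixture.
#'
#' @param donor A `donor_construct` (circle).
#' @return A `donor_construct` of twice the length.
#' @export
donor_dimer <- function(donor) {
  seq <- if (inherits(donor, "donor_construct")) donor$sequence else
    as_dna(donor, "donor")
  donor_construct(paste0(seq, seq),
                  if (inherits(donor, "donor_construct")) donor$topology else "circle")
}

check_row <- function(check, status, detail = "") {
  data.frame(check = check, status = status, detail = detail,
             stringsAsFactors = FALSE)
}

#' Validate a donor against a tagging design
#'
#' Runs the structural checks a donor must satisfy before integration is
#' predicted: attB count and variants matching the cassette mode and the
#' design's dinucleotide plan, the donor-side frame spacer's modulo-3
#' arithmetic against the post-integration coding junction, absence of stop
#' codons (and of ATG for N-terminal designs) in the junction reading frame,
#' an in-frame GGSGGGSG linker, and no stray Type IIS recognition site.
#' Failures are report entries, never errors; validation does not modify the
#' donor.
#'
#' @param donor A `donor_construct`.
#' @param mode `"single"` or `"dual"`.
#' @param design The `tagging_design` the donor serves.
#' @param registry A `site_registry`.
#' @param enzyme `enzyme_spec` used for the stray-site check.
#' @return A `validation_report`: list with `passed` (logical) and `checks`
#'   (data.frame check/status/detail).
#' @export
validate_donor <- function(donor, mode = c("single", "dual"), design,
                           registry = build_default_registry(),
                           enzyme = bbsi_spec()) {
  mode <- match.arg(mode)
  checks <- list()
  add <- function(name, ok, detail = "") {
    checks[[length(checks) + 1L]] <<- check_row(name, if (ok) "pass" else "fail", detail)
  }
  seq <- donor$sequence
  occ <- locate_sites(seq, registry, kinds = "B", prune_nested = TRUE)

  expected_n <- if (mode == "single") 1L else 2L
  add("attb_count", nrow(occ) == expected_n,
      sprintf("found %d attB site(s), expected %d", nrow(occ), expected_n))

  plan <- design$dinucleotide_plan
  if (mode == "single") {
    ok <- nrow(occ) >= 1L && plan[1] %in% occ$dinucleotide
    add("variant_match", ok,
        sprintf("donor attB variant(s) %s vs design %s",
                paste(occ$dinucleotide, collapse = "/"), plan[1]))
  } else {
    distinct <- nrow(occ) == 2L && occ$dinucleotide[1] != occ$dinucleotide[2]
    add("heterotypic_sites", distinct,
        sprintf("donor attB variants: %s", paste(occ$dinucleotide, collapse = "/")))
    occ_sorted <- occ[order(occ$start), , drop = FALSE]
    ok_order <- nrow(occ) == 2L && identical(occ_sorted$dinucleotide, plan)
    add("variant_order", ok_order,
        sprintf("donor order %s vs design plan %s",
                paste(occ_sorted$dinucleotide, collapse = ","),
                paste(plan, collapse = ",")))
  }

  # frame spacer: its length must complement the coding junction to a
  # multiple of 3, and it must sit against the attB on the junction side
  jlen <- design$coding_junction_len
  req <- required_spacer_length(jlen)
  sp <- donor$spacer
  if (is.null(sp)) {
    add("frame_spacer", FALSE, "donor carries no annotated frame spacer")
  } else {
    ok_len <- nchar(sp) %% 3L == req
    add("frame_spacer", ok_len,
        sprintf("spacer %d nt, junction %d nt: sum %d (%s), required remainder %d",
                nchar(sp), jlen, nchar(sp) + jlen,
                if (ok_len) "divisible by 3" else "not divisible by 3", req))
    adj <- if (design$terminus == "N")
      spacer_adjacent(seq, sp, occ, before = TRUE)
    else spacer_adjacent(seq, sp, occ, before = FALSE)
    add("spacer_placement", adj,
        if (design$terminus == "N") "spacer must immediately precede the attB (3' end of the insert)"
        else "spacer must immediately follow the attB (5' end of the insert)")
    # codon content in the post-integration junction frame
    add("spacer_codons",
        spacer_frame_clean(sp, design, registry),
        "junction frame must be free of stop codons (and ATG for N-terminal designs)")
  }

  lk <- donor$linker
  if (is.null(lk)) {
    add("linker_present", FALSE, "donor carries no annotated linker")
  } else {
    present <- grepl(lk, seq, fixed = TRUE)
    pep <- translate_dna(lk)
    add("linker_present", present && pep == "GGSGGGSG",
        sprintf("linker peptide '%s'", pep))
  }

  scan_span <- if (mode == "single") seq else {
    if (nrow(occ) == 2L) {
      o <- occ[order(occ$start), , drop = FALSE]
      substr(seq, o$start[1] + 1L, o$end[2])
    } else seq
  }
  stray <- find_recognition(scan_span, enzyme)
  add("no_stray_typeiis", length(stray$fwd) + length(stray$rev) == 0L,
      sprintf("%s recognition within the cargo region", enzyme$name))

  checks <- do.call(rbind, checks)
  structure(list(passed = all(checks$status == "pass"), checks = checks),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("donor validation: %s\n", if (x$passed) "PASSED" else "FAILED"))
  print(x$checks)
  invisible(x)
}

# is the annotated spacer immediately adjacent to an attB occurrence?
#' @noRd
spacer_adjacent <- function(seq, spacer, occ, before = TRUE) {
  if (nchar(spacer) == 0L) return(TRUE)
  for (i in seq_len(nrow(occ))) {
    if (before) {
      lo <- occ$start[i] - nchar(spacer)
      if (lo >= 0L && substr(seq, lo + 1L, occ$start[i]) == spacer) return(TRUE)
    } else {
      hi <- occ$end[i] + nchar(spacer)
      if (hi <= nchar(seq) && substr(seq, occ$end[i] + 1L, hi) == spacer) return(TRUE)
    }
  }
  FALSE
}

# check the full post-integration junction frame (spacer + hybrid site) for
# stop codons / ATG
#' @noRd
spacer_frame_clean <- function(spacer, design, registry) {
  forbid_start <- design$terminus == "N"
  if (design$terminus == "N") {
    # ... linker | spacer | attL | native CDS: spacer starts on a codon boundary
    s <- design$cassette_sites[[length(design$cassette_sites)]]
    b <- get_site(registry, "B", 46L, s$dinucleotide)
    attL <- site_sequence(recombine_sites(s, b)$attL)
    ctx <- paste0(spacer, attL)
  } else {
    # native CDS | attR | spacer | linker ...: attR starts on a codon boundary
    s <- design$cassette_sites[[1L]]
    b <- get_site(registry, "B", 46L, s$dinucleotide)
    attR <- site_sequence(recombine_sites(s, b)$attR)
    ctx <- paste0(attR, spacer)
  }
  cs <- codons(ctx)
  if (any(cs %in% STOP_CODONS)) return(FALSE)
  if (forbid_start && any(cs == "ATG")) return(FALSE)
  TRUE
}
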