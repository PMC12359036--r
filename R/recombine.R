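# In-silico Bxb1 recombination engine.
#
# Crossover model: strand exchange at the central dinucleotide, so
#   attR = attP.left_arm + dinucleotide + attB.right_arm
#   attL = attB.left_arm + dinucleotide + attP.right_arm
# which conserves total site length (58 x 46 -> 52 + 52; 48 x 46 -> 47 + 47)
# and total sequence for every event type. Recombination is directional:
# attR x attL, attP x attP and attB x attB are never recombined.

#' Recombine an attP with an attB site
#'
#' Models the Bxb1 crossover at the central dinucleotide. The attP arms end
#' up split between the two hybrid junctions: attR carries the attP left arm
#' and the attB right arm; attL carries the attB left arm and the attP right
#' arm. Total length is conserved.
#'
#' @param attP,attB `att_site` objects of kind `"P"` and `"B"` with matching
#'   central dinucleotides.
#' @return A list with elements `attR` and `attL` (both `att_site`).
#' @export
recombine_sites <- function(attP, attB) {
  if (attP$kind == "B" && attB$kind == "P") { tmp <- attP; attP <- attB; attB <- tmp }
  if (!compatible(attP, attB))
    bx_error("bxbtag_incompatible_sites",
             sprintf("cannot recombine %s (%s) x %s (%s): need attP x attB with matching central dinucleotide",
                     attP$name, attP$dinucleotide, attB$name, attB$dinucleotide))
  d <- attP$dinucleotide
  list(
    attR = att_site(paste0("attR-", d), "R", attP$left_arm, d, attB$right_arm,
                    source = attP$source),
    attL = att_site(paste0("attL-", d), "L", attB$left_arm, d, attP$right_arm,
                    source = attP$source))
}

#' Locate attachment-site occurrences in a sequence
#'
#' Exact matches of every registry site are reported on both strands with
#' 0-based half-open coordinates. Because the 48 bp core attP is a substring
#' of the 53 and 58 bp variants, nested hits are reported by default;
#' `prune_nested = TRUE` keeps only maximal occurrences (what the
#' recombination engine uses).
#'
#' @param sequence DNA string to scan.
#' @param registry A `site_registry`.
#' @param kinds Site kinds to search for (default P and B).
#' @param prune_nested Drop occurrences wholly contained in a longer one.
#' @return A data.frame with columns `name`, `kind`, `dinucleotide`, `start`
#'   (0-based), `end` (half-open), `strand`, `length`.
#' @export
locate_sites <- function(sequence, registry, kinds = c("P", "B"),
                         prune_nested = FALSE) {
  sequence <- as_dna(sequence)
  subject <- Biostrings::DNAString(sequence)
  rows <- list()
  for (s in registry$sites) {
    if (!(s$kind %in% kinds)) next
    pat <- site_sequence(s)
    for (strand in c("+", "-")) {
      q <- if (strand == "+") pat else revcomp(pat)
      if (nchar(q) > length(subject)) next
      m <- Biostrings::matchPattern(q, subject)
      if (length(m) == 0L) next
      rows[[length(rows) + 1L]] <- data.frame(
        name = s$name, kind = s$kind, dinucleotide = s$dinucleotide,
        start = Biostrings::start(m) - 1L, end = Biostrings::end(m),
        strand = strand, length = site_length(s), stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(name = character(), kind = character(),
                      dinucleotide = character(), start = integer(),
                      end = integer(), strand = character(),
                      length = integer(), stringsAsFactors = FALSE))
  occ <- do.call(rbind, rows)
  occ <- occ[order(occ$start, -occ$length), , drop = FALSE]
  rownames(occ) <- NULL
  if (prune_nested && nrow(occ) > 1L) {
    keep <- rep(TRUE, nrow(occ))
    for (i in seq_len(nrow(occ))) {
      for (j in seq_len(nrow(occ))) {
        if (i == j || !keep[j]) next
        if (occ$start[j] <= occ$start[i] && occ$end[i] <= occ$end[j] &&
            occ$length[i] < occ$length[j]) { keep[i] <- FALSE; break }
      }
    }
    occ <- occ[keep, , drop = FALSE]
    rownames(occ) <- NULL
  }
  occ
}

site_from_occurrence <- function(registry, occ_row) {
  # recover the registry att_site for a located occurrence
  for (s in registry$sites) {
    if (s$name == occ_row$name) return(s)
  }
  bx_error("bxbtag_missing_site", sprintf("site '%s' not in registry", occ_row$name))
}

new_allele <- function(name, sequence, junctions, provenance = list()) {
  structure(list(name = name, sequence = sequence,
                 junctions = junctions, provenance = provenance),
            class = "integrated_allele")
}

#' @export
print.integrated_allele <- function(x, ...) {
  cat(sprintf("integrated_allele '%s': %d bp, %d junction(s)\n",
              x$name, nchar(x$sequence), nrow(x$junctions)))
  if (nrow(x$junctions)) print(x$junctions)
  invisible(x)
}

junction_row <- function(name, kind, dinuc, start, len) {
  data.frame(name = name, kind = kind, dinucleotide = dinuc,
             start = as.integer(start), end = as.integer(start + len),
             stringsAsFactors = FALSE)
}

# Extract the attB occurrences of a circular donor sequence, normalising the
# orientation: if all attBs lie on the minus strand the circle is flipped.
donor_attb <- function(donor_seq, registry) {
  occ <- locate_sites(donor_seq, registry, kinds = "B", prune_nested = TRUE)
  if (nrow(occ) > 0L && all(occ$strand == "-")) {
    donor_seq <- revcomp(donor_seq)
    occ <- locate_sites(donor_seq, registry, kinds = "B", prune_nested = TRUE)
  }
  list(seq = donor_seq, occ = occ)
}

#' Integrate a circular donor at a single genomic attP
#'
#' Models Bxb1 integration of a circular (backbone-free) donor: the genomic
#' attP and the donor attB are replaced by attR and attL, and the entire
#' donor circle is inserted between them (`attR - insert - attL`, where the
#' insert is the donor circle minus its attB). Total sequence length is
#' conserved: `nchar(allele) == nchar(genome) + nchar(donor)`.
#'
#' @param genome DNA string carrying exactly one attP.
#' @param donor Circular donor: a DNA string or a `donor_construct`.
#'   A donor whose attB lies on the minus strand is integrated in the
#'   flipped orientation.
#' @param registry A `site_registry`.
#' @param name Allele category label.
#' @param multimer_ok Permit donors with more than one attB (circular
#'   multimers): the first attB recombines and the remaining copies ride
#'   along intact. Default `FALSE` (ambiguous donors are an error).
#' @return An `integrated_allele`.
#' @export
integrate_single <- function(genome, donor, registry, name = "fully_integrated",
                             multimer_ok = FALSE) {
  genome <- as_dna(genome, "genome")
  donor_seq <- if (inherits(donor, "donor_construct")) donor$sequence else
    as_dna(donor, "donor")
  p_occ <- locate_sites(genome, registry, kinds = "P", prune_nested = TRUE)
  if (nrow(p_occ) == 0L)
    bx_error("bxbtag_no_target_site", "no attP landing site found in the genome")
  d <- donor_attb(donor_seq, registry)
  b_occ <- d$occ
  donor_seq <- d$seq
  if (nrow(b_occ) == 0L)
    bx_error("bxbtag_no_target_site", "no attB site found on the donor circle")
  # restrict to variant-compatible pairs
  p_occ <- p_occ[p_occ$dinucleotide %in% b_occ$dinucleotide, , drop = FALSE]
  if (nrow(p_occ) == 0L)
    bx_error("bxbtag_incompatible_sites",
             "no genomic attP matches the donor attB central dinucleotide")
  if (nrow(p_occ) > 1L)
    bx_error("bxbtag_ambiguous_target",
             sprintf("%d compatible genomic attP sites; expected one", nrow(p_occ)))
  b_use <- b_occ[b_occ$dinucleotide == p_occ$dinucleotide[1], , drop = FALSE]
  if (nrow(b_use) > 1L && !multimer_ok)
    bx_error("bxbtag_ambiguous_target",
             sprintf("donor circle carries %d attB sites; expected one (multimer_ok = FALSE)",
                     nrow(b_use)))
  b1 <- b_use[1L, ]
  if (p_occ$strand[1] == "-") {
    # integrate into the reverse complement, then flip back
    allele <- integrate_single(revcomp(genome), donor_seq, registry,
                               name = name, multimer_ok = multimer_ok)
    L <- nchar(allele$sequence)
    allele$sequence <- revcomp(allele$sequence)
    j <- allele$junctions
    if (nrow(j)) {
      new_start <- L - j$end
      j$end <- L - j$start
      j$start <- new_start
      j$kind <- ifelse(j$kind == "R", "L", "R")
      j$name <- sub("^att[RL]", "", j$name)
      j$name <- paste0(ifelse(j$kind == "R", "attR", "attL"), j$name)
      allele$junctions <- j[order(j$start), , drop = FALSE]
    }
    return(allele)
  }
  attP <- site_from_occurrence(registry, p_occ[1L, ])
  attB <- site_from_occurrence(registry, b1)
  rec <- recombine_sites(attP, attB)
  # insert = donor circle opened at its attB (everything except the attB)
  insert <- paste0(substr(donor_seq, b1$end + 1L, nchar(donor_seq)),
                   substr(donor_seq, 1L, b1$start))
  left <- substr(genome, 1L, p_occ$start[1])
  right <- substr(genome, p_occ$end[1] + 1L, nchar(genome))
  attR_seq <- site_sequence(rec$attR)
  attL_seq <- site_sequence(rec$attL)
  seq_out <- paste0(left, attR_seq, insert, attL_seq, right)
  jR <- junction_row(rec$attR$name, "R", attP$dinucleotide,
                     nchar(left), nchar(attR_seq))
  jL <- junction_row(rec$attL$name, "L", attP$dinucleotide,
                     nchar(left) + nchar(attR_seq) + nchar(insert),
                     nchar(attL_seq))
  new_allele(name, seq_out, rbind(jR, jL),
             provenance = list(event = "single_integration",
                               attP = attP$name, attB = attB$name,
                               donor_length = nchar(donor_seq)))
}

#' Dual-cassette exchange: integrate a cargo between two heterotypic attPs
#'
#' Models recombinase-mediated cassette exchange between a genomic landing
#' pad carrying two heterotypic attP sites (variants X then Y) and a donor
#' plasmid whose cargo is flanked by the matching attB variants in the same
#' order and orientation. The cargo replaces the genomic inter-attP segment
#' between an attR-X and an attL-Y junction; the plasmid backbone plus the
#' genomic spacer is returned as the excised circle. Sequence is conserved:
#' `nchar(allele) + nchar(excised) == nchar(genome) + nchar(donor)`.
#'
#' When the donor carries only one attB variant matching a genomic attP, a
#' partial event is reported instead: the whole plasmid integrates at the
#' matching site (allele named `"whole_plasmid"`, `excised = NULL`).
#'
#' @param genome DNA string with two heterotypic attP occurrences.
#' @param donor Donor plasmid: DNA string (circular; cargo read between the
#'   two attBs in string order) or a `donor_construct`.
#' @param registry A `site_registry`.
#' @param multimer_ok Permit plasmid-dimer donors: the outermost matching
#'   attB pair recombines and one backbone copy is retained in the allele.
#' @return A list with elements `allele` (`integrated_allele`), `excised`
#'   (DNA string of the excised circle, or `NULL` for a partial event), and
#'   `partial` (logical).
#' @export
exchange_dual <- function(genome, donor, registry, multimer_ok = FALSE) {
  genome <- as_dna(genome, "genome")
  donor_seq <- if (inherits(donor, "donor_construct")) donor$sequence else
    as_dna(donor, "donor")
  p_occ <- locate_sites(genome, registry, kinds = "P", prune_nested = TRUE)
  if (nrow(p_occ) < 2L)
    bx_error("bxbtag_no_target_site",
             sprintf("dual exchange needs two genomic attP sites; found %d", nrow(p_occ)))
  if (nrow(p_occ) > 2L)
    bx_error("bxbtag_ambiguous_target",
             sprintf("%d genomic attP sites; expected two", nrow(p_occ)))
  if (any(p_occ$strand == "-"))
    bx_error("bxbtag_geometry",
             "genomic attP sites must lie on the plus strand in matching orientation")
  p_occ <- p_occ[order(p_occ$start), , drop = FALSE]
  vx <- p_occ$dinucleotide[1]; vy <- p_occ$dinucleotide[2]
  if (vx == vy)
    bx_error("bxbtag_geometry", "the two genomic attP sites must be heterotypic")
  b_occ <- locate_sites(donor_seq, registry, kinds = "B", prune_nested = TRUE)
  if (any(b_occ$strand == "-"))
    bx_error("bxbtag_geometry",
             "inverted donor attB orientation is not a modelled recombination substrate")
  bx <- b_occ[b_occ$dinucleotide == vx, , drop = FALSE]
  by <- b_occ[b_occ$dinucleotide == vy, , drop = FALSE]
  if (nrow(bx) == 0L && nrow(by) == 0L)
    bx_error("bxbtag_incompatible_sites",
             "donor carries no attB matching either genomic attP variant")
  if (nrow(bx) == 0L || nrow(by) == 0L) {
    # partial event: single-site recombination integrates the whole plasmid
    v <- if (nrow(bx) > 0L) vx else vy
    idx <- which(p_occ$dinucleotide == v)
    sub_occ <- p_occ[idx, , drop = FALSE]
    other <- p_occ[-idx, , drop = FALSE]
    # mask the unmatched attP so integrate_single sees a single landing site
    allele <- integrate_whole_plasmid(genome, donor_seq, registry, sub_occ)
    return(list(allele = allele, excised = NULL, partial = TRUE))
  }
  if ((nrow(bx) > 1L || nrow(by) > 1L) && !multimer_ok)
    bx_error("bxbtag_ambiguous_target",
             "donor carries duplicated attB variants; expected one of each (multimer_ok = FALSE)")
  # outermost pair: first X, last Y (a head-to-tail dimer then retains one
  # intact backbone copy between them)
  bX <- bx[1L, ]
  bY <- by[nrow(by), ]
  if (bY$start < bX$end)
    bx_error("bxbtag_geometry",
             "donor attB variant order does not match the genomic attP order")
  attPX <- site_from_occurrence(registry, p_occ[1L, ])
  attPY <- site_from_occurrence(registry, p_occ[2L, ])
  attBX <- site_from_occurrence(registry, bX)
  attBY <- site_from_occurrence(registry, bY)
  recX <- recombine_sites(attPX, attBX)   # attR-X in the allele, attL-X excised
  recY <- recombine_sites(attPY, attBY)   # attL-Y in the allele, attR-Y excised
  insert <- substr(donor_seq, bX$end + 1L, bY$start)
  backbone <- paste0(substr(donor_seq, bY$end + 1L, nchar(donor_seq)),
                     substr(donor_seq, 1L, bX$start))
  g_left <- substr(genome, 1L, p_occ$start[1])
  g_mid <- substr(genome, p_occ$end[1] + 1L, p_occ$start[2])
  g_right <- substr(genome, p_occ$end[2] + 1L, nchar(genome))
  attR_seq <- site_sequence(recX$attR)
  attL_seq <- site_sequence(recY$attL)
  seq_out <- paste0(g_left, attR_seq, insert, attL_seq, g_right)
  jR <- junction_row(recX$attR$name, "R", vx, nchar(g_left), nchar(attR_seq))
  jL <- junction_row(recY$attL$name, "L", vy,
                     nchar(g_left) + nchar(attR_seq) + nchar(insert),
                     nchar(attL_seq))
  allele <- new_allele("fully_integrated", seq_out, rbind(jR, jL),
                       provenance = list(event = "dual_exchange",
                                         attP = c(attPX$name, attPY$name),
                                         attB = c(attBX$name, attBY$name),
                                         donor_length = nchar(donor_seq)))
  # excised circle: attR-Y + backbone + attL-X + genomic inter-attP segment
  excised <- paste0(site_sequence(recY$attR), backbone,
                    site_sequence(recX$attL), g_mid)
  list(allele = allele, excised = excised, partial = FALSE)
}

# Whole-plasmid integration at one of several genomic attPs (partial dual
# event). sub_occ is the single matching attP occurrence row.
integrate_whole_plasmid <- function(genome, donor_seq, registry, sub_occ) {
  b_occ <- locate_sites(donor_seq, registry, kinds = "B", prune_nested = TRUE)
  b1 <- b_occ[b_occ$dinucleotide == sub_occ$dinucleotide[1], , drop = FALSE][1L, ]
  attP <- site_from_occurrence(registry, sub_occ[1L, ])
  attB <- site_from_occurrence(registry, b1)
  rec <- recombine_sites(attP, attB)
  insert <- paste0(substr(donor_seq, b1$end + 1L, nchar(donor_seq)),
                   substr(donor_seq, 1L, b1$start))
  left <- substr(genome, 1L, sub_occ$start[1])
  right <- substr(genome, sub_occ$end[1] + 1L, nchar(genome))
  attR_seq <- site_sequence(rec$attR)
  attL_seq <- site_sequence(rec$attL)
  seq_out <- paste0(left, attR_seq, insert, attL_seq, right)
  jR <- junction_row(rec$attR$name, "R", attP$dinucleotide, nchar(left),
                     nchar(attR_seq))
  jL <- junction_row(rec$attL$name, "L", attP$dinucleotide,
                     nchar(left) + nchar(attR_seq) + nchar(insert),
                     nchar(attL_seq))
  new_allele("whole_plasmid", seq_out, rbind(jR, jL),
             provenance = list(event = "partial_dual_whole_plasmid",
                               attP = attP$name, attB = attB$name,
                               donor_length = nchar(donor_seq)))
}

#' Export allele junction annotations
#'
#' Junctions are written as BED (0-based half-open) and optionally as a JSON
#' event log including the provenance record.
#'
#' @param allele An `integrated_allele`.
#' @param bed_path Output BED path (or `NULL` to skip).
#' @param json_path Output JSON path (or `NULL` to skip).
#' @return The junction data.frame, invisibly.
#' @export
write_junctions <- function(allele, bed_path = NULL, json_path = NULL) {
  j <- allele$junctions
  if (!is.null(bed_path)) {
    bed <- data.frame(chrom = allele$name, chromStart = j$start,
                      chromEnd = j$end, name = j$name, score = 0L,
                      strand = "+", stringsAsFactors = FALSE)
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(allele = allele$name,
                              length = nchar(allele$sequence),
                              junctions = j, provenance = allele$provenance),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(j)
}
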