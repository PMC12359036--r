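# Predicted allele reference sequences for a tagging design, and fusion
# reading-frame verification.

ALLELE_CATEGORIES <- c("wildtype", "ssodn_only", "fully_integrated",
                       "whole_plasmid", "backbone_retained", "circular_dimer")

#' Predict the allele reference set for a design
#'
#' Builds reference sequences for every allele category expected at the
#' target locus:
#' \describe{
#'   \item{wildtype}{the unedited reference locus}
#'   \item{ssodn_only}{perfect HDR of the attP cassette (start/stop codon
#'     replaced), no recombination}
#'   \item{fully_integrated}{the recombination engine applied to the
#'     ssODN-edited locus and the donor: \code{attR - insert - attL}}
#'   \item{whole_plasmid}{dual mode, `contaminants = TRUE`: partial
#'     single-site recombination integrating the entire plasmid}
#'   \item{backbone_retained}{dual mode, `contaminants = TRUE`: plasmid-dimer
#'     integration retaining one backbone copy}
#'   \item{circular_dimer}{single mode, `contaminants = TRUE`: integration
#'     of the circular-dimer ligation by-product}
#' }
#'
#' @param design A `tagging_design`.
#' @param donor A `donor_construct` (circle for single mode, plasmid for
#'   dual), or `NULL` for wildtype + ssodn_only only.
#' @param registry A `site_registry`.
#' @param contaminants Also build the contaminant categories.
#' @return An `allele_set`: list with `alleles` (named list of
#'   `integrated_allele`) and `design`.
#' @export
predict_alleles <- function(design, donor = NULL,
                            registry = build_default_registry(),
                            contaminants = FALSE) {
  locus <- design$locus_seq
  alleles <- list()
  alleles$wildtype <- new_allele("wildtype", locus, empty_junctions(),
                                 provenance = list(event = "none"))
  edited <- hdr_locus(design)
  cass_start <- design$replaced_span[1]
  jr <- junction_row(paste0("attP_cassette"), "P",
                     design$dinucleotide_plan[1], cass_start,
                     nchar(design$cassette))
  alleles$ssodn_only <- new_allele("ssodn_only", edited, jr,
                                   provenance = list(event = "hdr_ssodn"))
  if (!is.null(donor)) {
    if (design$mode == "single") {
      alleles$fully_integrated <-
        integrate_single(edited, donor, registry, name = "fully_integrated")
      if (contaminants) {
        dim_allele <- integrate_single(edited, donor_dimer(donor), registry,
                                       name = "circular_dimer", multimer_ok = TRUE)
        alleles$circular_dimer <- dim_allele
      }
    } else {
      res <- exchange_dual(edited, donor, registry)
      if (res$partial)
        bx_error("bxbtag_geometry",
                 "dual design/donor pair only recombines at one site; fully_integrated allele undefined")
      alleles$fully_integrated <- res$allele
      if (contaminants) {
        b_occ <- locate_sites(donor$sequence, registry, kinds = "B",
                              prune_nested = TRUE)
        # whole-plasmid: single-site recombination at the first genomic attP
        p_occ <- locate_sites(edited, registry, kinds = "P", prune_nested = TRUE)
        p_occ <- p_occ[order(p_occ$start), , drop = FALSE]
        alleles$whole_plasmid <-
          integrate_whole_plasmid(edited, donor$sequence, registry,
                                  p_occ[1L, , drop = FALSE])
        # backbone retained: head-to-tail plasmid dimer as the substrate
        dim_res <- exchange_dual(edited, donor_dimer(donor), registry,
                                 multimer_ok = TRUE)
        dim_res$allele$name <- "backbone_retained"
        alleles$backbone_retained <- dim_res$allele
      }
    }
  }
  structure(list(alleles = alleles, design = design), class = "allele_set")
}

empty_junctions <- function() {
  data.frame(name = character(), kind = character(),
             dinucleotide = character(), start = integer(), end = integer(),
             stringsAsFactors = FALSE)
}

#' @export
print.allele_set <- function(x, ...) {
  cat(sprintf("allele_set for '%s' (%s-terminal, %s mode): %d categories\n",
              x$design$locus_id, x$design$terminus, x$design$mode,
              length(x$alleles)))
  for (nm in names(x$alleles))
    cat(sprintf("  %-18s %d bp\n", nm, nchar(x$alleles[[nm]]$sequence)))
  invisible(x)
}

#' Export an allele set as multi-FASTA plus a junction BED
#'
#' Writes one FASTA record per allele category (the references the read
#' classifier consumes) and, optionally, a BED of all junction annotations.
#'
#' @param allele_set An `allele_set`.
#' @param fasta_path Output FASTA path.
#' @param bed_path Optional BED output path.
#' @return `fasta_path`, invisibly.
#' @export
write_allele_set <- function(allele_set, fasta_path, bed_path = NULL) {
  seqs <- Biostrings::DNAStringSet(
    vapply(allele_set$alleles, `[[`, "", "sequence"))
  names(seqs) <- names(allele_set$alleles)
  Biostrings::writeXStringSet(seqs, fasta_path)
  if (!is.null(bed_path)) {
    beds <- lapply(names(allele_set$alleles), function(nm) {
      j <- allele_set$alleles[[nm]]$junctions
      if (nrow(j) == 0L) return(NULL)
      data.frame(chrom = nm, chromStart = j$start, chromEnd = j$end,
                 name = j$name, score = 0L, strand = "+",
                 stringsAsFactors = FALSE)
    })
    beds <- do.call(rbind, beds)
    if (!is.null(beds))
      utils::write.table(beds, bed_path, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
  }
  invisible(fasta_path)
}

#' Verify the fusion open reading frame of a predicted allele
#'
#' Translates the fusion CDS implied by the design and the allele's junction
#' annotations and reports frame integrity. For N-terminal tags translation
#' starts at the cargo ATG (just downstream of attR) and must run through
#' tag, linker, spacer and attL into the native CDS, terminating at the
#' native stop. For C-terminal tags it starts at the native ATG and must run
#' through attR, spacer, linker and tag, terminating at the tag's stop. The
#' wildtype allele is translated over its native CDS.
#'
#' @param allele An `integrated_allele` (from [predict_alleles()]).
#' @param design The `tagging_design`.
#' @return An `orf_report`: list with `in_frame`, `premature_stop_at`
#'   (0-based allele coordinate of the first premature stop, or `NULL`),
#'   `fusion_protein` (amino-acid string, stop excluded) and `linker_found`.
#' @export
check_fusion_orf <- function(allele, design) {
  seq <- allele$sequence
  locus_len <- nchar(design$locus_seq)
  if (allele$name == "wildtype") {
    start <- design$cds_start
    expected_stop_end <- design$cds_end
  } else if (nrow(allele$junctions) == 0L) {
    bx_error("bxbtag_annotation", "allele carries no junction annotations")
  } else if (allele$name == "ssodn_only") {
    # cassette interrupts the CDS; there is no intact fusion ORF to verify
    return(structure(list(in_frame = FALSE, premature_stop_at = NULL,
                          fusion_protein = "", linker_found = FALSE,
                          note = "ssODN cassette interrupts the CDS (pre-recombination state)"),
                     class = "orf_report"))
  } else if (design$terminus == "N") {
    jR <- allele$junctions[allele$junctions$kind == "R", , drop = FALSE]
    if (nrow(jR) == 0L) bx_error("bxbtag_annotation", "no attR junction annotated")
    start <- find_atg_after(seq, jR$end[1])
    shift <- nchar(seq) - locus_len
    expected_stop_end <- design$cds_end + shift
  } else {
    start <- design$cds_start   # upstream of the insertion, unchanged
    jL <- allele$junctions[allele$junctions$kind == "L", , drop = FALSE]
    if (nrow(jL) == 0L) bx_error("bxbtag_annotation", "no attL junction annotated")
    # tag cargo supplies the stop; it must fall just before attL (allowing
    # non-coding padding between stop and attL)
    expected_stop_end <- NA_integer_
    expected_before <- jL$start[nrow(jL)]
  }
  # translate from `start` until the first stop
  span <- substr(seq, start + 1L, nchar(seq))
  span <- substr(span, 1L, nchar(span) - nchar(span) %% 3L)
  pep_full <- translate_dna(span)
  stop_idx <- regexpr("*", pep_full, fixed = TRUE)
  if (stop_idx < 0L) {
    return(structure(list(in_frame = FALSE, premature_stop_at = NULL,
                          fusion_protein = pep_full, linker_found = grepl("GGSGGGSG", pep_full),
                          note = "no stop codon reached"),
                     class = "orf_report"))
  }
  pep <- substr(pep_full, 1L, stop_idx - 1L)
  stop_end <- start + 3L * stop_idx       # 0-based end of the stop codon
  if (design$terminus == "C" && allele$name != "wildtype") {
    in_frame <- stop_end <= expected_before &&
      (expected_before - stop_end) < 30L   # stop within the cargo 3' end
    premature <- if (in_frame) NULL else stop_end - 3L
  } else {
    in_frame <- stop_end == expected_stop_end
    premature <- if (in_frame) NULL else stop_end - 3L
  }
  structure(list(in_frame = in_frame, premature_stop_at = premature,
                 fusion_protein = pep, linker_found = grepl("GGSGGGSG", pep)),
            class = "orf_report")
}

#' @export
print.orf_report <- function(x, ...) {
  cat(sprintf("fusion ORF: %s%s; linker %s; peptide %d aa\n",
              if (x$in_frame) "in frame" else "DISRUPTED",
              if (!is.null(x$premature_stop_at))
                sprintf(" (premature stop at %d)", x$premature_stop_at) else "",
              if (x$linker_found) "found" else "absent",
              nchar(x$fusion_protein)))
  invisible(x)
}

# first ATG at or shortly after a 0-based position
#' @noRd
find_atg_after <- function(seq, pos, window = 60L) {
  sub <- substr(seq, pos + 1L, min(nchar(seq), pos + window))
  hit <- regexpr("ATG", sub, fixed = TRUE)
  if (hit < 0L)
    bx_error("bxbtag_annotation",
             sprintf("no cargo ATG found within %d nt after the attR junction", window))
  pos + as.integer(hit) - 1L
}
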