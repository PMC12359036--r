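# Long-read allele classifier: best-alignment-score assignment, fraction
# reporting and ddPCR copy-number arithmetic.

#' Classifier configuration
#'
#' @param min_length Reads shorter than this are filtered (default 300 nt).
#' @param match,mismatch Local-alignment match bonus and mismatch penalty.
#' @param gap_open,gap_extend Affine gap penalties (positive numbers; a gap
#'   of length L costs `gap_open + L * gap_extend`).
#' @param external_scores Optional data.frame of pre-computed scores with
#'   columns `read_id`, `reference_id`, `score`; when supplied, the internal
#'   aligner is bypassed.
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(min_length = 300L, match = 2, mismatch = -4,
                              gap_open = 4, gap_extend = 2,
                              external_scores = NULL) {
  if (min_length < 0L) bx_error("bxbtag_config", "min_length must be >= 0")
  if (match <= 0) bx_error("bxbtag_config", "match bonus must be positive")
  list(min_length = as.integer(min_length), match = match, mismatch = mismatch,
       gap_open = gap_open, gap_extend = gap_extend,
       external_scores = external_scores)
}

# normalise read input to a named character vector of sequences
#' @noRd
as_reads <- function(reads) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", reads)) "fastq" else "fasta"
    x <- Biostrings::readDNAStringSet(reads, format = fmt)
    out <- as.character(x)
    names(out) <- sub("\\s.*$", "", names(x))
    return(out)
  }
  if (inherits(reads, "DNAStringSet")) {
    out <- as.character(reads)
    names(out) <- sub("\\s.*$", "", names(reads))
    return(out)
  }
  if (is.character(reads)) {
    if (is.null(names(reads)))
      names(reads) <- sprintf("read%d", seq_along(reads))
    return(reads)
  }
  bx_error("bxbtag_parse", "reads must be a FASTQ/FASTA path, DNAStringSet or named character vector")
}

# local affine-gap alignment scores of many reads against one reference
#' @noRd
score_against <- function(reads, reference, config) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = config$match, mismatch = config$mismatch, baseOnly = TRUE)
  Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(reads),
    subject = Biostrings::DNAString(reference),
    type = "local", substitutionMatrix = mat,
    gapOpening = config$gap_open, gapExtension = config$gap_extend,
    scoreOnly = TRUE)
}

#' Assign long reads to allele categories by best alignment score
#'
#' Each read of at least `min_length` nt is scored against every allele
#' reference with a local affine-gap aligner (or looked up in
#' `config$external_scores`) and assigned to the arg-max category. Reads
#' shorter than `min_length` are reported as `filtered_short`; exact score
#' ties between categories are reported as `ambiguous`, never broken
#' arbitrarily. The result is deterministic and independent of read order.
#'
#' @param reads FASTQ/FASTA path, `DNAStringSet`, or named character vector.
#' @param allele_set An `allele_set` (or named character vector of reference
#'   sequences; at least two).
#' @param config A [classifier_config()].
#' @return A data.frame with columns `read_id`, `category`, `score`,
#'   `margin` (best minus second-best score; `NA` for filtered reads).
#' @export
classify_reads <- function(reads, allele_set, config = classifier_config()) {
  refs <- if (inherits(allele_set, "allele_set"))
    vapply(allele_set$alleles, `[[`, "", "sequence") else unlist(allele_set)
  if (length(refs) < 2L)
    bx_error("bxbtag_no_references", "need at least two allele references")
  reads <- as_reads(reads)
  if (length(reads) == 0L)
    return(data.frame(read_id = character(), category = character(),
                      score = numeric(), margin = numeric(),
                      stringsAsFactors = FALSE))
  if (any(!grepl("^[ACGTNacgtn]*$", reads)))
    bx_error("bxbtag_parse",
             sprintf("malformed read record at index %d",
                     which(!grepl("^[ACGTNacgtn]*$", reads))[1]))
  lens <- nchar(reads)
  short <- lens < config$min_length
  out <- data.frame(read_id = names(reads),
                    category = rep(NA_character_, length(reads)),
                    score = NA_real_, margin = NA_real_,
                    stringsAsFactors = FALSE)
  out$category[short] <- "filtered_short"
  keep <- which(!short)
  if (length(keep)) {
    if (!is.null(config$external_scores)) {
      es <- config$external_scores
      smat <- matrix(-Inf, nrow = length(keep), ncol = length(refs),
                     dimnames = list(names(reads)[keep], names(refs)))
      for (i in seq_len(nrow(es))) {
        r <- as.character(es$read_id[i]); f <- as.character(es$reference_id[i])
        if (r %in% rownames(smat) && f %in% colnames(smat))
          smat[r, f] <- as.numeric(es$score[i])
      }
    } else {
      # score each read both as given and reverse-complemented; long-read
      # sequencing reads either strand
      smat <- sapply(refs, function(ref) {
        fwd <- score_against(reads[keep], ref, config)
        rev <- score_against(vapply(reads[keep], revcomp, ""), ref, config)
        pmax(fwd, rev)
      })
      smat <- matrix(smat, nrow = length(keep),
                     dimnames = list(names(reads)[keep], names(refs)))
    }
    for (i in seq_along(keep)) {
      sc <- smat[i, ]
      best <- max(sc)
      winners <- names(sc)[sc == best]
      second <- if (length(sc) > 1L) max(sc[-which.max(sc)]) else -Inf
      out$score[keep[i]] <- best
      out$margin[keep[i]] <- best - second
      out$category[keep[i]] <- if (length(winners) > 1L) "ambiguous" else winners
    }
  }
  out
}

#' Write classified reads into per-category FASTQ files
#'
#' @param reads The same read input given to [classify_reads()].
#' @param assignments The classifier output.
#' @param dir Output directory; one `<category>.fastq` per category.
#' @return Named character vector of written paths, invisibly.
#' @export
write_category_fastq <- function(reads, assignments, dir) {
  reads <- as_reads(reads)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (cat in unique(assignments$category)) {
    ids <- assignments$read_id[assignments$category == cat]
    ids <- intersect(ids, names(reads))
    if (length(ids) == 0L) next
    x <- Biostrings::DNAStringSet(reads[ids])
    q <- Biostrings::BStringSet(vapply(nchar(reads[ids]),
                                       function(n) strrep("I", n), ""))
    path <- file.path(dir, paste0(cat, ".fastq"))
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
    paths[cat] <- path
  }
  invisible(paths)
}

#' Summarize read assignments into allele fractions
#'
#' Counts and percentages per category. Main-category percentages use the
#' assigned-read denominator (filtered reads excluded). Contaminant
#' subcategories (circular dimer, retained backbone, whole plasmid) are
#' additionally reported against the fully-integrated denominator - the
#' total of correctly and imperfectly integrated reads - with one-decimal
#' and integer rounding.
#'
#' @param assignments Output of [classify_reads()].
#' @param contaminant_categories Categories counted as imperfect
#'   integrations within the fully-integrated denominator.
#' @param digits Decimal places for percentages (default 1).
#' @return An `allele_fraction_report`.
#' @export
summarize_assignments <- function(assignments,
                                  contaminant_categories = c("circular_dimer",
                                                             "backbone_retained",
                                                             "whole_plasmid"),
                                  digits = 1L) {
  assigned <- assignments[assignments$category != "filtered_short", , drop = FALSE]
  if (nrow(assigned) == 0L)
    bx_error("bxbtag_empty_denominator", "no reads passed the length filter")
  counts <- table(assigned$category)
  counts <- stats::setNames(as.integer(counts), names(counts))
  total <- sum(counts)
  percentages <- round_half_up(100 * counts / total, digits)
  fi_den <- sum(counts[names(counts) %in%
                         c("fully_integrated", contaminant_categories)])
  sub <- list()
  for (cc in intersect(contaminant_categories, names(counts))) {
    sub[[cc]] <- list(count = counts[[cc]], denominator = fi_den,
                      percent = ratio_percent(counts[[cc]], fi_den, digits),
                      percent_integer = ratio_percent(counts[[cc]], fi_den, 0L))
  }
  structure(list(counts = counts, total_assigned = total,
                 percentages = percentages,
                 fully_integrated_denominator = fi_den,
                 subcategory_ratios = sub,
                 n_filtered = sum(assignments$category == "filtered_short")),
            class = "allele_fraction_report")
}

#' @export
print.allele_fraction_report <- function(x, ...) {
  cat(sprintf("allele fractions (%d assigned reads, %d filtered <min length):\n",
              x$total_assigned, x$n_filtered))
  for (nm in names(x$counts))
    cat(sprintf("  %-18s %5d  (%s%%)\n", nm, x$counts[[nm]],
                format(x$percentages[[nm]], nsmall = 1)))
  if (length(x$subcategory_ratios)) {
    cat(sprintf("  of %d fully-integrated reads:\n", x$fully_integrated_denominator))
    for (nm in names(x$subcategory_ratios)) {
      s <- x$subcategory_ratios[[nm]]
      cat(sprintf("    %-16s %d/%d (%s%%)\n", nm, s$count, s$denominator,
                  format(s$percent, nsmall = 1)))
    }
  }
  invisible(x)
}

#' Percentage of a count ratio with conventional rounding
#'
#' `ratio_percent(1, 88)` is 1.1 (one decimal); `ratio_percent(2, 184, 0)`
#' is 1 (integer rounding).
#'
#' @param count,denominator Non-negative counts; `denominator > 0`.
#' @param digits Decimal places.
#' @return Numeric percentage.
#' @export
ratio_percent <- function(count, denominator, digits = 1L) {
  if (denominator <= 0)
    bx_error("bxbtag_empty_denominator", "denominator must be positive")
  round_half_up(100 * count / denominator, digits)
}

#' Read externally computed alignment scores from SAM/BAM
#'
#' Extracts per-alignment scores (the `AS` tag a long-read mapper emits)
#' from a SAM or BAM file into the score-table dialect accepted by
#' [classifier_config()] (`read_id`, `reference_id`, `score`). When a read
#' has several alignments to the same reference, the best score is kept.
#'
#' @param path SAM or BAM file path (SAM is converted on the fly).
#' @return data.frame with columns `read_id`, `reference_id`, `score`.
#' @export
read_alignment_scores <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    path <- Rsamtools::asBam(path,
                             destination = tempfile(),
                             overwrite = TRUE, indexDestination = FALSE)
  }
  b <- Rsamtools::scanBam(path,
                          param = Rsamtools::ScanBamParam(
                            what = c("qname", "rname"), tag = "AS"))[[1]]
  df <- data.frame(read_id = b$qname,
                   reference_id = as.character(b$rname),
                   score = as.numeric(b$tag$AS),
                   stringsAsFactors = FALSE)
  df <- df[!is.na(df$score) & !is.na(df$reference_id), , drop = FALSE]
  if (nrow(df) == 0L) return(df)
  best <- stats::aggregate(score ~ read_id + reference_id, data = df, FUN = max)
  best[order(best$read_id, best$reference_id), , drop = FALSE]
}

#' Transgene copy number from ddPCR positive-droplet counts
#'
#' The copy number of the target locus is the ratio of target-positive to
#' reference-positive droplets, multiplied by 2 (the copy number of the
#' diploid reference gene).
#'
#' @param positive_target,positive_reference Positive-droplet counts.
#' @return `2 * positive_target / positive_reference`.
#' @export
copy_number <- function(positive_target, positive_reference) {
  if (positive_reference <= 0)
    bx_error("bxbtag_empty_denominator",
             "reference-positive droplet count must be positive")
  2 * positive_target / positive_reference
}
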