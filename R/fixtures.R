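# Deterministic synthetic fixtures: toy loci, guides, donors, allele sets
# and error-bearing long reads, so every module is testable without any
# external data. All randomness is locally seeded; regenerating with the
# same seed is byte-identical.

# GGSGGGSG linker codons (24 nt)
LINKER_GGSGGGSG <- "GGAGGCTCAGGTGGCGGAAGCGGC"

FORBIDDEN_MOTIFS <- function(registry, enzyme = bbsi_spec()) {
  pats <- c(enzyme$recognition, revcomp(enzyme$recognition))
  for (s in registry$sites) {
    sq <- site_sequence(s)
    pats <- c(pats, sq, revcomp(sq))
  }
  unique(pats)
}

# random DNA free of attachment sites, Type IIS recognition and (optionally)
# ATG/stop codons in frame 0; frame-clean sequences are drawn codon-wise
# from the allowed codon alphabet
#' @noRd
clean_random_dna <- function(n, motifs, frame_clean = FALSE) {
  if (frame_clean) {
    bases <- c("A", "C", "G", "T")
    allowed <- setdiff(apply(expand.grid(bases, bases, bases), 1L,
                             paste, collapse = ""),
                       c(STOP_CODONS, "ATG"))
    stopifnot(n %% 3L == 0L)
    gen <- function() paste(sample(allowed, n %/% 3L, replace = TRUE),
                            collapse = "")
  } else {
    gen <- function() random_dna(n)
  }
  repeat {
    s <- gen()
    if (!any(vapply(motifs, function(m) grepl(m, s, fixed = TRUE), TRUE)))
      return(s)
  }
}

#' Simulate a toy gene locus
#'
#' ~3 kb locus with a central CDS (default 900 nt: ATG + stop-free codons +
#' TAA), free of attachment-site and Type IIS motifs so designed elements
#' are the only hits. Deterministic per seed.
#'
#' @param seed Integer seed.
#' @param upstream,downstream Flank lengths.
#' @param cds_length CDS length in nt (multiple of 3, >= 9).
#' @param registry A `site_registry` (motif exclusion list).
#' @return A list with `seq`, `cds_start`, `cds_end`, `cds_strand`, `id`.
#' @export
make_toy_locus <- function(seed = 1L, upstream = 1000L, downstream = 1100L,
                           cds_length = 900L,
                           registry = build_default_registry()) {
  stopifnot(cds_length %% 3L == 0L, cds_length >= 9L)
  motifs <- FORBIDDEN_MOTIFS(registry)
  with_seed(seed, {
    up <- clean_random_dna(upstream, motifs)
    body <- clean_random_dna(cds_length - 6L, motifs, frame_clean = TRUE)
    down <- clean_random_dna(downstream, motifs)
    cds <- paste0("ATG", body, "TAA")
    list(seq = paste0(up, cds, down),
         cds_start = upstream, cds_end = upstream + cds_length,
         cds_strand = "+", id = sprintf("toylocus_seed%d", seed))
  })
}

#' Build a synthetic tag cargo ORF
#'
#' Stop-free random codons emulating a fluorescent-protein tag (synthetic
#' stand-in; not any real tag sequence).
#'
#' @param seed Integer seed.
#' @param length ORF length in nt excluding ATG/stop (multiple of 3).
#' @param registry Motif exclusion list.
#' @return DNA string of `length` nt (no ATG, no stop in frame 0).
#' @export
make_tag_orf <- function(seed = 1L, length = 300L,
                         registry = build_default_registry()) {
  stopifnot(length %% 3L == 0L)
  motifs <- FORBIDDEN_MOTIFS(registry)
  with_seed(seed + 7L, clean_random_dna(length, motifs, frame_clean = TRUE))
}

#' Build a single-cassette producer plasmid and its donors
#'
#' Lays out `backbone - GAAGAC NN - [fragment] - OVHG NN GTCTTC - backbone`
#' where the fragment (the future circle) is, for N-terminal designs,
#' `OVHG + ATG + tag + linker + spacer + attB`, and for C-terminal designs
#' `OVHG + attB + spacer + linker + tag + stop`. The 4-nt overhang regions
#' match so the excised fragment self-circularizes.
#'
#' @param design A `tagging_design` (single mode).
#' @param registry A `site_registry`.
#' @param tag Tag ORF (default generated from `seed`).
#' @param seed Integer seed.
#' @param backbone_length Total backbone length.
#' @return List with `plasmid` (DNA string), `circle` (`donor_construct`),
#'   `dimer` (`donor_construct`).
#' @export
make_single_donor <- function(design, registry = build_default_registry(),
                              tag = NULL, seed = 1L, backbone_length = 1200L) {
  stopifnot(design$mode == "single")
  if (is.null(tag)) tag <- make_tag_orf(seed, registry = registry)
  attB <- site_sequence(get_site(registry, "B", 46L,
                                 design$dinucleotide_plan[1]))
  ovhg <- "CGCA"
  spacer <- make_spacer(design$donor_spacer_len, frame_offset = 0L,
                        flanks = spacer_flanks(design, registry),
                        forbid_start = design$terminus == "N", seed = seed)
  fragment <- if (design$terminus == "N")
    paste0(ovhg, "ATG", tag, LINKER_GGSGGGSG, spacer, attB)
  else
    paste0(ovhg, attB, spacer, LINKER_GGSGGGSG, tag, "TAA")
  motifs <- FORBIDDEN_MOTIFS(registry)
  bb <- with_seed(seed + 13L, {
    list(a = clean_random_dna(backbone_length %/% 2L, motifs),
         b = clean_random_dna(backbone_length - backbone_length %/% 2L, motifs))
  })
  plasmid <- paste0(bb$a, "GAAGAC", "AT", fragment, ovhg, "CA", "GTCTTC", bb$b)
  circle <- excise_and_circularize(plasmid)
  circle$spacer <- spacer
  circle$linker <- LINKER_GGSGGGSG
  list(plasmid = plasmid, circle = circle, dimer = donor_dimer(circle))
}

#' Build a dual-cassette donor plasmid
#'
#' Circular plasmid `backbone1 - attB-X - insert - attB-Y - backbone2` with
#' the insert `ATG + tag + linker + spacer` (N-terminal) or
#' `spacer + linker + tag + stop` (C-terminal), attB variants in the
#' design's genomic order.
#'
#' @inheritParams make_single_donor
#' @return A `donor_construct` with `topology = "plasmid"`.
#' @export
make_dual_donor <- function(design, registry = build_default_registry(),
                            tag = NULL, seed = 1L, backbone_length = 1500L) {
  stopifnot(design$mode == "dual")
  if (is.null(tag)) tag <- make_tag_orf(seed, registry = registry)
  plan <- design$dinucleotide_plan
  attBX <- site_sequence(get_site(registry, "B", 46L, plan[1]))
  attBY <- site_sequence(get_site(registry, "B", 46L, plan[2]))
  spacer <- make_spacer(design$donor_spacer_len, frame_offset = 0L,
                        flanks = spacer_flanks(design, registry),
                        forbid_start = design$terminus == "N", seed = seed)
  insert <- if (design$terminus == "N")
    paste0("ATG", tag, LINKER_GGSGGGSG, spacer)
  else paste0(spacer, LINKER_GGSGGGSG, tag, "TAA")
  motifs <- FORBIDDEN_MOTIFS(registry)
  bb <- with_seed(seed + 17L, {
    list(a = clean_random_dna(backbone_length %/% 2L, motifs),
         b = clean_random_dna(backbone_length - backbone_length %/% 2L, motifs))
  })
  d <- donor_construct(paste0(bb$a, attBX, insert, attBY, bb$b), "plasmid",
                       spacer = spacer, linker = LINKER_GGSGGGSG)
  d$insert_span <- c(nchar(bb$a) + 46L, nchar(bb$a) + 46L + nchar(insert))
  d
}

# flanking context for the donor frame spacer (post-integration junction)
#' @noRd
spacer_flanks <- function(design, registry) {
  if (design$terminus == "N") {
    s <- design$cassette_sites[[length(design$cassette_sites)]]
    b <- get_site(registry, "B", 46L, s$dinucleotide)
    list(left = LINKER_GGSGGGSG,
         right = site_sequence(recombine_sites(s, b)$attL))
  } else {
    s <- design$cassette_sites[[1L]]
    b <- get_site(registry, "B", 46L, s$dinucleotide)
    list(left = site_sequence(recombine_sites(s, b)$attR),
         right = LINKER_GGSGGGSG)
  }
}

#' Generate a complete, internally consistent fixture bundle
#'
#' One call produces a toy locus, single- and dual-cassette N-terminal
#' designs, their donors (producer plasmid, circle, dimer, dual plasmid) and
#' the predicted allele sets (contaminant categories included). The bundle
#' is constructed so that donor validation passes and the fully-integrated
#' fusion ORF is intact; regenerating with the same seed is byte-identical.
#'
#' @param seed Integer seed.
#' @param terminus `"N"` (default) or `"C"`.
#' @param registry A `site_registry`.
#' @param upstream,downstream,cds_length Toy-locus dimensions, passed to
#'   [make_toy_locus()]; smaller loci make exhaustive alignment checks
#'   cheap.
#' @return A `fixture_bundle` list: `locus`, `designs` (`$single`, `$dual`),
#'   `donors` (`$plasmid`, `$circle`, `$dimer`, `$dual`), `allele_sets`
#'   (`$single`, `$dual`), `registry`, `seed`.
#' @export
make_fixture <- function(seed = 1L, terminus = "N",
                         registry = build_default_registry(),
                         upstream = 1000L, downstream = 1100L,
                         cds_length = 900L) {
  locus <- make_toy_locus(seed, upstream = upstream, downstream = downstream,
                          cds_length = cds_length, registry = registry)
  d_single <- design_ssodn(locus, terminus = terminus, mode = "single",
                           registry = registry)
  d_dual <- design_ssodn(locus, terminus = terminus, mode = "dual",
                         registry = registry)
  tag <- make_tag_orf(seed, registry = registry)
  sd <- make_single_donor(d_single, registry, tag = tag, seed = seed)
  dd <- make_dual_donor(d_dual, registry, tag = tag, seed = seed)
  as_single <- predict_alleles(d_single, sd$circle, registry,
                               contaminants = TRUE)
  as_dual <- predict_alleles(d_dual, dd, registry, contaminants = TRUE)
  structure(list(locus = locus,
                 designs = list(single = d_single, dual = d_dual),
                 donors = list(plasmid = sd$plasmid, circle = sd$circle,
                               dimer = sd$dimer, dual = dd),
                 allele_sets = list(single = as_single, dual = as_dual),
                 registry = registry, seed = seed),
            class = "fixture_bundle")
}

#' Read-simulation configuration
#'
#' @param n_reads Reads per allele category.
#' @param sub_rate,ins_rate,del_rate Per-base error rates in `[0, 1)`.
#' @param length_mean,length_sd,length_min Read-length distribution
#'   (normal, truncated at `length_min` and at the allele length). The
#'   defaults emulate Cas9-enrichment sequencing of the toy locus, where
#'   most reads span the excised fragment and hence the cassette junctions;
#'   shorter settings produce junction-blind reads that the classifier can
#'   only call ambiguous.
#' @param seed Integer seed.
#' @return A `read_sim_config` list.
#' @export
read_sim_config <- function(n_reads = 100L, sub_rate = 0.03,
                            ins_rate = 0.01, del_rate = 0.01,
                            length_mean = 2500, length_sd = 200,
                            length_min = 400L, seed = 1L) {
  rates <- c(sub_rate, ins_rate, del_rate)
  if (any(rates < 0) || any(rates >= 1))
    bx_error("bxbtag_config", "error rates must lie in [0, 1)")
  if (length_min < 1L) bx_error("bxbtag_config", "length_min must be >= 1")
  list(n_reads = as.integer(n_reads), sub_rate = sub_rate,
       ins_rate = ins_rate, del_rate = del_rate,
       length_mean = length_mean, length_sd = length_sd,
       length_min = as.integer(length_min), seed = as.integer(seed))
}

# apply the substitution/indel error process to one read (RNG already seeded)
#' @noRd
mutate_read <- function(seq, sub_rate, ins_rate, del_rate) {
  b <- strsplit(seq, "")[[1]]
  n <- length(b)
  bases <- c("A", "C", "G", "T")
  u <- stats::runif(n)
  subs <- which(u < sub_rate)
  for (i in subs) b[i] <- sample(setdiff(bases, b[i]), 1L)
  dels <- stats::runif(n) < del_rate
  ins <- stats::runif(n) < ins_rate
  out <- character(0)
  ins_bases <- sample(bases, sum(ins), replace = TRUE)
  k <- 0L
  for (i in seq_len(n)) {
    if (!dels[i]) out[length(out) + 1L] <- b[i]
    if (ins[i]) { k <- k + 1L; out[length(out) + 1L] <- ins_bases[k] }
  }
  paste(out, collapse = "")
}

#' Simulate error-bearing long reads from an allele set
#'
#' Reads are sampled from uniform random start positions of each allele
#' reference, with normally distributed lengths and independent per-base
#' substitution/insertion/deletion errors (constant base quality; no
#' platform-specific bias modelling). Read names encode the generating
#' category (`<category>_read<i>`) as ground truth for tests. Deterministic
#' per seed.
#'
#' @param allele_set An `allele_set` or named character vector of reference
#'   sequences.
#' @param config A [read_sim_config()].
#' @param categories Which categories to sample (default all in the set).
#' @param proportions Optional named proportions; when given, a total of
#'   `config$n_reads` reads is drawn with these expected category weights
#'   (multinomial), instead of `n_reads` per category.
#' @param fastq Optional path; when given, reads are also written as FASTQ.
#' @return Named character vector of read sequences.
#' @export
simulate_reads <- function(allele_set, config = read_sim_config(),
                           categories = NULL, proportions = NULL,
                           fastq = NULL) {
  refs <- if (inherits(allele_set, "allele_set"))
    vapply(allele_set$alleles, `[[`, "", "sequence") else unlist(allele_set)
  if (length(refs) == 0L)
    bx_error("bxbtag_no_references", "allele set is empty")
  if (is.null(categories)) categories <- names(refs)
  refs <- refs[categories]
  if (any(config$length_min > nchar(refs)))
    bx_error("bxbtag_config", "length_min exceeds an allele length")
  with_seed(config$seed, {
    if (!is.null(proportions)) {
      proportions <- proportions[categories] / sum(proportions[categories])
      draws <- sample(categories, config$n_reads, replace = TRUE,
                      prob = proportions)
      n_per <- table(factor(draws, levels = categories))
    } else {
      n_per <- stats::setNames(rep(config$n_reads, length(categories)),
                               categories)
    }
    out <- character(0)
    for (cat in categories) {
      ref <- refs[[cat]]
      L <- nchar(ref)
      n <- as.integer(n_per[[cat]])
      if (n == 0L) next
      lens <- round(stats::rnorm(n, config$length_mean, config$length_sd))
      lens <- pmin(pmax(lens, config$length_min), L)
      starts <- vapply(lens, function(l) sample.int(L - l + 1L, 1L), 1L)
      for (i in seq_len(n)) {
        raw <- substr(ref, starts[i], starts[i] + lens[i] - 1L)
        if (stats::runif(1) < 0.5) raw <- revcomp(raw)
        mut <- mutate_read(raw, config$sub_rate, config$ins_rate,
                           config$del_rate)
        out[sprintf("%s_read%d", cat, i)] <- mut
      }
    }
    if (!is.null(fastq)) {
      x <- Biostrings::DNAStringSet(out)
      q <- Biostrings::BStringSet(vapply(nchar(out),
                                         function(n) strrep("I", n), ""))
      Biostrings::writeXStringSet(x, fastq, format = "fastq", qualities = q)
    }
    out
  })
}
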