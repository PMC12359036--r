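reg <- build_default_registry()

test_that("frame solver returns the minimal spacer completing a codon", {
  expect_equal(required_spacer_length(52), 2L)   # 52 + 2 = 54, divisible by 3
  expect_equal(required_spacer_length(54), 0L)
  expect_equal(required_spacer_length(47), 1L)
  expect_error(required_spacer_length(-1), class = "bxbtag_invalid_length")
  # property: junction + spacer is always a codon multiple, spacer minimal
  for (j in 0:300) {
    s <- required_spacer_length(j)
    expect_true(s %in% 0:2)
    expect_equal((j + s) %% 3L, 0L)
  }
})

test_that("make_spacer honours length, frame, stop and start constraints", {
  expect_identical(make_spacer(0), "")
  # 2-nt spacer ahead of an attL: first codon is s1 s2 L1
  attL <- site_sequence(recombine_sites(get_site(reg, "P", 58),
                                        get_site(reg, "B", 46))$attL)
  sp <- make_spacer(2, frame_offset = 0, flanks = list(left = "", right = attL),
                    forbid_start = TRUE, seed = 3)
  expect_equal(nchar(sp), 2L)
  codon <- paste0(sp, substr(attL, 1, 1))
  expect_false(codon %in% c("TAA", "TAG", "TGA", "ATG"))
  # deterministic per seed
  expect_identical(sp, make_spacer(2, 0, list(left = "", right = attL),
                                   TRUE, seed = 3))
  # exhaustive cross-check: the returned dinucleotide is among the
  # independently enumerated valid ones
  dinucs <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T")),
                  1, paste, collapse = "")
  valid <- dinucs[!paste0(dinucs, substr(attL, 1, 1)) %in%
                    c("TAA", "TAG", "TGA", "ATG")]
  expect_true(sp %in% valid)
  # satisfiable despite a stop-prone context: codon T _ A admits TCA/TTA
  sp1 <- make_spacer(1, frame_offset = 1,
                     flanks = list(left = "T", right = "ACCACC"),
                     forbid_start = FALSE, seed = 1)
  expect_false(paste0("T", sp1, "A") %in% c("TAA", "TAG", "TGA"))
  # unsatisfiable: the requested frame cannot be phased from the context
  expect_error(make_spacer(1, frame_offset = 2,
                           flanks = list(left = "", right = "AAA")),
               class = "bxbtag_unsatisfiable_spacer")
})

test_that("single-cassette ssODN replaces the terminal codon with the 58 bp attP", {
  locus <- make_toy_locus(6, upstream = 500, downstream = 550, cds_length = 600)
  d <- design_ssodn(locus, terminus = "N", mode = "single", registry = reg)
  expect_equal(nchar(d$ssodn), 70 + 58 + 70)   # 198 nt
  expect_equal(d$homology_arm_length, 70L)
  # the start codon is gone from the edited locus at the insertion point
  edited <- hdr_locus(d)
  expect_identical(substr(edited, locus$cds_start - 69, locus$cds_start),
                   substr(locus$seq, locus$cds_start - 69, locus$cds_start))
  expect_identical(substr(edited, locus$cds_start + 1, locus$cds_start + 58),
                   site_sequence(get_site(reg, "P", 58, "GT")))
  # homology arms match the reference exactly
  arms <- c(substr(d$ssodn, 1, 70), substr(d$ssodn, 129, 198))
  expect_true(grepl(arms[1], locus$seq, fixed = TRUE))
  expect_true(grepl(arms[2], locus$seq, fixed = TRUE))
  # C-terminal: the stop codon is replaced instead
  dc <- design_ssodn(locus, terminus = "C", mode = "single", registry = reg)
  edited_c <- hdr_locus(dc)
  expect_identical(substr(edited_c, locus$cds_end - 2, locus$cds_end + 55),
                   site_sequence(get_site(reg, "P", 58, "GT")))
})

test_that("dual-cassette ssODNs carry a 48 bp core plus a 53 bp extended attP", {
  locus <- make_toy_locus(7, upstream = 500, downstream = 550, cds_length = 600)
  dn <- design_ssodn(locus, terminus = "N", mode = "dual", registry = reg)
  expect_equal(nchar(dn$ssodn), 50 + 48 + 53 + 50)
  lens <- vapply(dn$cassette_sites, site_length, 0L)
  expect_equal(lens, c(48L, 53L))               # extension after the second attP
  expect_equal(vapply(dn$cassette_sites, `[[`, "", "dinucleotide"),
               c("GA", "GT"))
  # the 53 bp element ends with the final 5 bp of the 58 bp variant
  p58 <- site_sequence(get_site(reg, "P", 58, "GT"))
  el2 <- site_sequence(dn$cassette_sites[[2]])
  expect_equal(substr(el2, 49, 53), substr(p58, 54, 58))
  # C-terminal: extension before the first attP (first 5 bp of the 58-mer)
  dc <- design_ssodn(locus, terminus = "C", mode = "dual", registry = reg)
  lens_c <- vapply(dc$cassette_sites, site_length, 0L)
  expect_equal(lens_c, c(53L, 48L))
  el1 <- site_sequence(dc$cassette_sites[[1]])
  p58_ga <- site_sequence(get_site(reg, "P", 58, "GA"))
  expect_equal(substr(el1, 1, 5), substr(p58_ga, 1, 5))
  # dual designs always carry two distinct variants
  expect_error(design_ssodn(locus, "N", "dual", reg,
                            dinucleotides = c("GA", "GA")),
               class = "bxbtag_invalid_variant")
})

test_that("designer frame arithmetic survives the engine: junction + spacer is a codon multiple", {
  for (seed in 1:3) {
    for (terminus in c("N", "C")) {
      for (mode in c("single", "dual")) {
        locus <- make_toy_locus(seed, upstream = 400, downstream = 440,
                                cds_length = 300)
        d <- design_ssodn(locus, terminus = terminus, mode = mode,
                          registry = reg)
        expect_equal((d$coding_junction_len + d$donor_spacer_len) %% 3L, 0L)
        expect_equal(d$coding_junction_len, 52L)   # both systems by design
      }
    }
  }
})

test_that("annotation and locus-boundary errors are raised", {
  locus <- make_toy_locus(8, upstream = 500, downstream = 550, cds_length = 600)
  bad <- locus
  bad$cds_start <- bad$cds_start + 1L   # no longer starts with ATG
  expect_error(design_ssodn(bad, "N", "single", reg),
               class = "bxbtag_annotation")
  near_edge <- list(seq = substr(locus$seq, locus$cds_start - 9, nchar(locus$seq)),
                    cds_start = 10L, cds_end = 10L + 600L, id = "edge")
  expect_error(design_ssodn(near_edge, "N", "single", reg),
               class = "bxbtag_annotation")
})

test_that("minus-strand CDS input is normalised to the coding strand", {
  locus <- make_toy_locus(9, upstream = 500, downstream = 550, cds_length = 600)
  n <- nchar(locus$seq)
  flipped <- list(
    seq = as.character(Biostrings::reverseComplement(Biostrings::DNAString(locus$seq))),
    cds_start = n - locus$cds_end, cds_end = n - locus$cds_start,
    cds_strand = "-", id = locus$id)
  d_plus <- design_ssodn(locus, "N", "single", reg)
  d_minus <- design_ssodn(flipped, "N", "single", reg)
  expect_identical(d_minus$ssodn, d_plus$ssodn)
})

test_that("re-cutting is blocked when the cassette interrupts the protospacer", {
  fb <- small_fixture(2)
  rep <- check_recut(fb$designs$single, fb$allele_sets$single)
  # the auto-selected guide cuts at the insertion point; integration should
  # normally interrupt it
  expect_true(rep$verdict %in% c("blocked", "at_risk"))
  if (rep$verdict == "at_risk") {
    expect_gt(nrow(rep$suggested_edits), 0)
    # suggested edits sit inside the homology arms and are synonymous when coding
    d <- fb$designs$single
    lo <- d$replaced_span[1] - d$homology_arm_length
    hi <- d$replaced_span[2] + d$homology_arm_length
    expect_true(all(rep$suggested_edits$position >= lo &
                      rep$suggested_edits$position < hi))
  }
})

test_that("a guide fully inside one homology arm is flagged at_risk with edits", {
  fb <- small_fixture(5)
  d <- fb$designs$single
  # pick a guide well upstream of the insertion point, inside the left arm
  g <- find_guides(d$locus_seq, d$replaced_span[1], window = 60)
  far <- g[g$strand == "+" &
             g$protospacer_start + 23 <= d$replaced_span[1] &
             g$protospacer_start >= d$replaced_span[1] - d$homology_arm_length, ,
           drop = FALSE]
  expect_gt(nrow(far), 0)   # this fixture carries arm-contained guides
  d2 <- design_ssodn(fb$locus, "N", "single", reg, guide = far$spacer[1])
  alleles <- predict_alleles(d2, fb$donors$circle, reg)
  rep <- check_recut(d2, alleles)
  expect_equal(rep$verdict, "at_risk")
  expect_gt(nrow(rep$suggested_edits), 0)
  coding <- rep$suggested_edits$position >= d2$cds_start &
    rep$suggested_edits$position < d2$cds_end
  expect_true(all(rep$suggested_edits$synonymous[coding]))
})

test_that("a guide absent from the reference is an error", {
  fb <- small_fixture(2)
  expect_error(check_recut(modifyList(fb$designs$single,
                                      list(guide = data.frame(
                                        spacer = strrep("A", 20), strand = "+",
                                        pam = "AGG", protospacer_start = 0L,
                                        cut = 17L, distance = 0L))),
               fb$allele_sets$single),
               class = "bxbtag_guide_not_on_reference")
})
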