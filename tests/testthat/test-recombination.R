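reg <- build_default_registry()

test_that("crossover lengths reproduce the printed recombinant-site sizes", {
  for (d in DINUCLEOTIDE_VARIANTS) {
    # single cassette: 58 x 46 -> 52 + 52
    rec <- recombine_sites(get_site(reg, "P", 58, d), get_site(reg, "B", 46, d))
    expect_equal(site_length(rec$attR), 52)
    expect_equal(site_length(rec$attL), 52)
    # dual core: 48 x 46 -> 47 + 47
    rec <- recombine_sites(get_site(reg, "P", 48, d), get_site(reg, "B", 46, d))
    expect_equal(site_length(rec$attR), 47)
    expect_equal(site_length(rec$attL), 47)
  }
  # length identity across every attP class x variant pairing
  for (d in DINUCLEOTIDE_VARIANTS) {
    for (len in c(58, 48, 53)) {
      p <- get_site(reg, "P", len, d)
      b <- get_site(reg, "B", 46, d)
      rec <- recombine_sites(p, b)
      expect_equal(site_length(rec$attR) + site_length(rec$attL),
                   site_length(p) + site_length(b))
      expect_equal(rec$attR$dinucleotide, d)
      expect_equal(rec$attL$dinucleotide, d)
    }
  }
})

test_that("recombination is variant-specific and directional", {
  pGT <- get_site(reg, "P", 58, "GT")
  bGA <- get_site(reg, "B", 46, "GA")
  bGT <- get_site(reg, "B", 46, "GT")
  expect_error(recombine_sites(pGT, bGA), class = "bxbtag_incompatible_sites")
  expect_error(recombine_sites(pGT, pGT), class = "bxbtag_incompatible_sites")
  expect_error(recombine_sites(bGT, bGT), class = "bxbtag_incompatible_sites")
  rec <- recombine_sites(pGT, bGT)
  expect_error(recombine_sites(rec$attR, rec$attL),
               class = "bxbtag_incompatible_sites")
  # argument order does not matter
  rec2 <- recombine_sites(bGT, pGT)
  expect_identical(site_sequence(rec2$attR), site_sequence(rec$attR))
})

test_that("locate_sites finds embedded sites on both strands with exact coordinates", {
  p <- site_sequence(get_site(reg, "P", 58, "GT"))
  b <- site_sequence(get_site(reg, "B", 46, "GA"))
  pad <- withr::with_seed(11, {
    paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE), collapse = "")
  })
  seq <- paste0(pad, p, pad)
  occ <- locate_sites(seq, reg, prune_nested = TRUE)
  expect_equal(nrow(occ), 1L)
  expect_equal(occ$start, 100L)
  expect_equal(occ$end, 158L)
  expect_equal(occ$strand, "+")
  # reverse-complemented attB
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(b)))
  occ2 <- locate_sites(paste0(pad, rc, pad), reg, prune_nested = TRUE)
  expect_equal(nrow(occ2), 1L)
  expect_equal(occ2$strand, "-")
  expect_equal(occ2$dinucleotide, "GA")
  # site-free sequence (the toy-locus generator scrubs all site motifs)
  clean <- make_toy_locus(5, upstream = 400, downstream = 401,
                          cds_length = 199 * 3)$seq
  expect_equal(nrow(locate_sites(clean, reg)), 0L)
  # nested reporting: the 48 bp core inside a 58 bp attP
  expect_gt(nrow(locate_sites(seq, reg, prune_nested = FALSE)), 1L)
})

test_that("single-circle integration conserves sequence and annotates junctions", {
  fb <- small_fixture(2)
  genome <- hdr_locus(fb$designs$single)
  circle <- fb$donors$circle
  allele <- integrate_single(genome, circle, reg)
  expect_equal(nchar(allele$sequence),
               nchar(genome) + nchar(circle$sequence))
  j <- allele$junctions
  expect_equal(j$kind, c("R", "L"))
  # annotated junctions match the embedded sequences
  for (i in seq_len(nrow(j))) {
    emb <- substr(allele$sequence, j$start[i] + 1L, j$end[i])
    rec <- recombine_sites(get_site(reg, "P", 58, j$dinucleotide[i]),
                           get_site(reg, "B", 46, j$dinucleotide[i]))
    expected <- if (j$kind[i] == "R") rec$attR else rec$attL
    expect_identical(emb, site_sequence(expected))
  }
  # no attP in the genome models the no-ssODN control
  expect_error(integrate_single(fb$locus$seq, circle, reg),
               class = "bxbtag_no_target_site")
  # identical inputs give byte-identical output
  expect_identical(integrate_single(genome, circle, reg)$sequence,
                   allele$sequence)
})

test_that("a minus-strand donor attB integrates the insert in flipped orientation", {
  # hand-built toy: expectation constructed by direct string surgery
  p <- get_site(reg, "P", 58, "GT")
  b <- get_site(reg, "B", 46, "GT")
  rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
  left <- "AAAAAAAAAA"; right <- "CCCCCCCCCC"
  x <- "AAACCCGGGTTTAAACCCGGG"; y <- "TTTGGGAAACCCTTTGGGAAA"
  genome <- paste0(left, site_sequence(p), right)
  donor <- paste0(x, rc(site_sequence(b)), y)   # attB on the minus strand
  allele <- integrate_single(genome, donor, reg)
  rec <- recombine_sites(p, b)
  # the engine flips the whole circle, so the insert is the flipped donor
  # opened at its (now plus-strand) attB: rc(x) then rc(y)
  expect_identical(allele$sequence,
                   paste0(left, site_sequence(rec$attR), rc(x), rc(y),
                          site_sequence(rec$attL), right))
  expect_equal(nchar(allele$sequence), nchar(genome) + nchar(donor))
})

test_that("dual exchange integrates the cargo, excises the backbone, conserves bases", {
  fb <- small_fixture(3)
  genome <- hdr_locus(fb$designs$dual)
  donor <- fb$donors$dual
  res <- exchange_dual(genome, donor, reg)
  expect_false(res$partial)
  expect_equal(nchar(res$allele$sequence) + nchar(res$excised),
               nchar(genome) + nchar(donor$sequence))
  # no backbone bases in the allele
  expect_false(grepl(substr(donor$sequence, 1, 60), res$allele$sequence,
                     fixed = TRUE))
  # cargo present
  expect_true(grepl(donor$linker, res$allele$sequence, fixed = TRUE))
  # junction order: attR (first variant) then attL (second variant)
  expect_equal(res$allele$junctions$kind, c("R", "L"))
  expect_equal(res$allele$junctions$dinucleotide,
               fb$designs$dual$dinucleotide_plan)
})

test_that("swapped donor attB order is refused as a geometry error", {
  fb <- small_fixture(3)
  genome <- hdr_locus(fb$designs$dual)   # genomic order GA then GT
  donor <- fb$donors$dual
  bGA <- site_sequence(get_site(reg, "B", 46, "GA"))
  bGT <- site_sequence(get_site(reg, "B", 46, "GT"))
  swapped <- donor$sequence
  swapped <- sub(bGA, "XGA", swapped, fixed = TRUE)
  swapped <- sub(bGT, bGA, swapped, fixed = TRUE)
  swapped <- sub("XGA", bGT, swapped, fixed = TRUE)
  expect_error(exchange_dual(genome, swapped, reg), class = "bxbtag_geometry")
  # inverted attB orientation is likewise refused
  inverted <- sub(bGA,
                  as.character(Biostrings::reverseComplement(Biostrings::DNAString(bGA))),
                  donor$sequence, fixed = TRUE)
  expect_error(exchange_dual(genome, inverted, reg), class = "bxbtag_geometry")
})

test_that("a plasmid dimer donor retains one backbone copy; a single-site donor gives a whole-plasmid event", {
  fb <- small_fixture(4)
  genome <- hdr_locus(fb$designs$dual)
  donor <- fb$donors$dual
  dimer <- donor_dimer(donor)
  res <- exchange_dual(genome, dimer, reg, multimer_ok = TRUE)
  mono <- exchange_dual(genome, donor, reg)
  expect_equal(nchar(res$allele$sequence) + nchar(res$excised),
               nchar(genome) + nchar(dimer$sequence))
  # dimer allele is longer than the clean allele by one full monomer
  expect_equal(nchar(res$allele$sequence) - nchar(mono$allele$sequence),
               nchar(donor$sequence))
  # and it contains backbone sequence
  expect_true(grepl(substr(donor$sequence, 1, 60), res$allele$sequence,
                    fixed = TRUE))
  # partial: strip the second attB variant from the donor
  bGT <- site_sequence(get_site(reg, "B", 46, "GT"))
  oneb <- sub(bGT, strrep("A", 46), donor$sequence, fixed = TRUE)
  part <- exchange_dual(genome, oneb, reg)
  expect_true(part$partial)
  expect_equal(part$allele$name, "whole_plasmid")
  expect_null(part$excised)
  expect_equal(nchar(part$allele$sequence), nchar(genome) + nchar(oneb))
})

test_that("sequence conservation holds over many randomised toy events", {
  rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
  n_single <- 150L; n_dual <- 150L; n_dimer <- 100L
  withr::with_seed(99, {
    rnd <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                             collapse = "")
    for (i in seq_len(n_single)) {
      d <- sample(DINUCLEOTIDE_VARIANTS, 1)
      len <- sample(c(58, 48, 53), 1)
      g <- paste0(rnd(sample(30:120, 1)),
                  site_sequence(get_site(reg, "P", len, d)),
                  rnd(sample(30:120, 1)))
      bseq <- site_sequence(get_site(reg, "B", 46, d))
      if (runif(1) < 0.3) bseq <- rc(bseq)
      circ <- paste0(rnd(sample(20:80, 1)), bseq, rnd(sample(20:80, 1)))
      allele <- integrate_single(g, circ, reg)
      expect_equal(nchar(allele$sequence), nchar(g) + nchar(circ))
    }
    for (i in seq_len(n_dual + n_dimer)) {
      dd <- sample(DINUCLEOTIDE_VARIANTS, 2)
      g <- paste0(rnd(sample(30:100, 1)),
                  site_sequence(get_site(reg, "P", 48, dd[1])),
                  rnd(sample(5:40, 1)),
                  site_sequence(get_site(reg, "P", 53, dd[2])),
                  rnd(sample(30:100, 1)))
      plasmid <- paste0(rnd(sample(20:60, 1)),
                        site_sequence(get_site(reg, "B", 46, dd[1])),
                        rnd(sample(20:90, 1)),
                        site_sequence(get_site(reg, "B", 46, dd[2])),
                        rnd(sample(20:60, 1)))
      if (i > n_dual) plasmid <- paste0(plasmid, plasmid)   # dimer event
      res <- exchange_dual(g, plasmid, reg, multimer_ok = TRUE)
      expect_equal(nchar(res$allele$sequence) + nchar(res$excised),
                   nchar(g) + nchar(plasmid))
    }
  })
})
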