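---
title: "Designing Bxb1-mediated knock-in tags: models, arithmetic and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing Bxb1-mediated knock-in tags}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bxbtag)
```

## The editing strategy this package models

Endogenous protein tagging with large cargo is hard to achieve by
homology-directed repair (HDR) alone, because HDR efficiency collapses with
insert size. A two-activity workaround splits the job: CRISPR–Cas9 plus a
short single-stranded oligodeoxynucleotide (ssODN) first installs a small
serine-integrase attachment site (attP) at the target codon — a payload small
enough for efficient ssODN-templated HDR — and the Bxb1 integrase then
recombines that genomic attP with an attB on a circular DNA donor, inserting
the cargo unidirectionally. Because Bxb1 only acts on double-stranded DNA,
cargo integration is conditional on prior HDR success; because attP×attB
recombination yields attL/attR hybrids that Bxb1 alone cannot reverse, the
insertion is stable.

`bxbtag` implements the desk half of that workflow: designing the ssODN and
donor, predicting every plausible post-editing allele in silico, checking
reading frames and re-cutting, and genotyping long reads against the
predicted alleles.

## Attachment sites and the crossover model

An attachment site is modelled as `left_arm + central dinucleotide +
right_arm`. The registry ships four length classes:

* 58 bp attP — the single-cassette genomic landing site,
* 48 bp attP — the dual-cassette core (the central 48 bp of the 58-mer),
* 53 bp attP — the core plus a 5 bp extension borrowed from the 58-mer,
* 46 bp attB — the donor-side site,

each in four central-dinucleotide variants (GT, GA, CT, AG). Matching
dinucleotides are required for recombination; mismatched ("heterotypic")
pairs are treated as fully orthogonal. On the bench, mismatched pairs retain
roughly tenfold-reduced leakage activity; the engine models this as a hard
error rather than simulating leakage, because the design rules (and the
allele categories worth genotyping) are built on the orthogonality
assumption.

Recombination is modelled as a symmetric strand exchange at the central
dinucleotide:

```
attR = attP.left + dinucleotide + attB.right
attL = attB.left + dinucleotide + attP.right
```

This is the unique site-level decomposition that reproduces both observed
recombinant lengths — 58 × 46 → 52 + 52 and 48 × 46 → 47 + 47 — while
conserving total sequence, and it is applied uniformly to every event type
(single-circle integration, dual-cassette exchange, multimer integration).

```{r crossover}
reg <- build_default_registry()
rec <- recombine_sites(get_site(reg, "P", 58, "GT"), get_site(reg, "B", 46, "GT"))
site_length(rec$attR); site_length(rec$attL)
```

### Built-in site sequences

The registry's built-in sequences are constructed, not measured: the
canonical Bxb1 attP (48 bp, GT core) and attB (38 bp) sequences are extended
symmetrically with fixed pads to the working lengths above, and the variants
are derived by substituting the central dinucleotide. They are labelled
`source = "fallback"` throughout, and a TSV registry of bench-validated
sequences can replace them via `read_site_registry()` without touching any
other code. The pad bases (`CGGTG` on each attP flank; `CACC`/`GGCC` on
attB) were chosen once, by exhaustive search, so that every attR/attL
junction is free of stop codons in the fusion reading frame for all four
dinucleotide variants — a property any bench-validated site set must also
have, and a precondition for the frame arithmetic below to be meaningful.
Consequently all length and frame conclusions transfer to user-supplied
registries, while base-level sequence outputs (ssODNs, predicted alleles)
are exactly right only for the registry actually used.

## Reading-frame arithmetic

After integration the coding sequence must read straight through one hybrid
junction: the downstream attL for N-terminal tags (tag → linker → spacer →
attL → native CDS) or the upstream attR for C-terminal tags (native CDS →
attR → spacer → linker → tag). The single-cassette junction is 52 bp,
i.e. remainder 1 mod 3, so the donor carries a spacer of length ≡ 2 (mod 3)
adjacent to its attB; 52 + 2 = 54 restores the codon phase.
`required_spacer_length()` is exactly this arithmetic, and `make_spacer()`
synthesizes spacer sequences whose codons — completed from the flanking
context — contain no stop codon and, for N-terminal designs, no ATG. Start
codons are excluded on both the ssODN and donor sides; only stop codons are
strictly fatal, but an in-frame AUG upstream of the native start is a
translation-initiation hazard with no offsetting benefit, so the designer is
conservative on both.

Dual-cassette junctions would be 47 bp (remainder 2), which would demand
different donors than the single-cassette system. Rather than fork the donor
design, the ssODN restores the 52 bp arithmetic: the attP whose junction
lands in coding sequence is extended by 5 bp taken from the 58 bp variant —
appended after the second attP for N-terminal designs (lengthening the
attL), prepended before the first attP for C-terminal designs (lengthening
the attR). The extended element is 48 + 5 = 53 bp, and one universal set of
donors (spacer ≡ 2 mod 3) then serves both cassette systems.

```{r frame}
required_spacer_length(52)          # minimal donor spacer, single cassette
locus <- make_toy_locus(1, upstream = 500, downstream = 550, cds_length = 600)
d <- design_ssodn(locus, terminus = "N", mode = "dual")
vapply(d$cassette_sites, site_length, 0L)   # 48 bp core + 53 bp extended
```

## ssODN design choices

* **Replaced codon.** N-terminal cassettes replace the start codon;
  C-terminal cassettes replace the stop codon. For C-terminal tags the
  cargo supplies the stop.
* **Homology arms.** Defaults are 70 nt per side for single-cassette
  ssODNs and 50 nt for dual (whose cassette is nearly twice as long, and
  synthesis length is the binding constraint); both are configurable. The
  totals (198 nt and 201 nt) are reported as-is rather than forced to a
  round number.
* **Strand.** The ssODN is emitted on the CDS coding strand by default,
  with a flag to flip it; strand choice does not change any arithmetic.
* **Guide selection.** Among NGG protospacers near the insertion point the
  designer picks the cut site closest to the insertion point, breaking ties
  by fewer PAM-proximal 12-mer seed matches within the supplied locus (no
  genome-wide search is attempted — that belongs to dedicated off-target
  tools). A guide spanning the insertion point is naturally destroyed by
  correct integration; `check_recut()` verifies this against the predicted
  alleles rather than trusting geometry, and otherwise proposes
  PAM-destroying edits that are synonymous wherever they land in coding
  sequence.
* **Dinucleotide plan.** Dual designs default to GA (first site) and GT
  (second); any two distinct variants from the whitelist are accepted, and
  duplicated variants are rejected because heterotypic pairing is what
  prevents backbone integration.

## Donors and in-silico circularization

Single-cassette donors are backbone-free circles produced from a producer
plasmid carrying inward-facing BbsI sites (`GAAGAC`, cutting 2/6 nt
downstream, 4-nt 5' overhangs). `excise_and_circularize()` models digestion
plus perfect monomeric self-ligation: the fragment between the two
top-strand cuts becomes the circle, recognition sites stay in the backbone,
and incompatible overhangs or extra recognition sites are errors. The bench
reality — some 40–50% circular monomer, plus linear species and multimers —
is deliberately not simulated; the one by-product the genotyping step must
know about, the head-to-tail circular dimer, is constructed explicitly by
`donor_dimer()` as a classifier reference. The exact overhang sequence is
not constrained beyond self-compatibility.

Dual-cassette donors are used as plasmids: two heterotypic attB sites flank
the cargo, recombination integrates only the insert, and the backbone plus
the genomic inter-attP spacer leaves as an excised circle.
`validate_donor()` runs the structural checklist (site count, variant
identity and order, spacer arithmetic and placement, junction-frame codon
content, in-frame GGSGGGSG linker, no stray BbsI sites) as independent
report entries rather than errors, so a failed donor yields a complete
diagnosis in one pass.

## Predicted alleles and genotyping

`predict_alleles()` builds the reference set the long-read classifier
consumes: wildtype, ssODN-only (HDR without recombination — modelled as
perfect arm-mediated replacement; NHEJ indel spectra are out of scope),
fully integrated (`attR – insert – attL`), and on request the contaminant
categories: whole-plasmid integration (one-sided dual recombination),
backbone-retained (plasmid-dimer exchange) and circular-dimer integration.
`check_fusion_orf()` then validates the designer against the engine rather
than against itself: it translates the predicted fusion from its actual
start codon and requires the first stop to be the expected terminator, with
the GGSGGGSG linker present in the peptide.

`classify_reads()` assigns each read to the reference with the highest
local-alignment score (affine gaps; defaults match +2, mismatch −4, gap
open 4, extend 2, a gap of length L costing `open + L·extend`), scoring
both read orientations. Reads shorter than 300 nt are filtered — at that
length a read rarely spans a junction informatively. Exact score ties are
reported as `ambiguous`, never broken arbitrarily; with contaminant
references in the set, ties are expected for reads that cover only one
junction (a dimer allele contains the clean allele's junctions as
substrings), which is why routine fraction estimation classifies against
the three primary references and reserves the contaminant references for
targeted re-classification. Pre-computed scores (e.g. a long-read mapper's
AS tags) can be supplied as a TSV and used verbatim. Contaminant
subcategories are reported against the fully-integrated denominator with
conventional half-up rounding (1/88 → 1.1%; 2/184 → 1% at integer
precision). `copy_number()` implements the ddPCR estimate
`2 × target-positive / reference-positive`; no Poisson occupancy correction
is applied, because the estimate is defined as a raw positive-droplet
ratio — a known limitation at high droplet occupancy.

## Synthetic fixtures: what they do and do not show

All tests run on generated data. `make_toy_locus()` builds a locus (default
~3 kb, 900 nt CDS; smaller in most tests) whose random portions are scrubbed
of attachment-site and BbsI motifs and whose CDS is drawn codon-wise without
internal stops or ATGs. `simulate_reads()` samples reads from random start
positions with truncated-normal lengths, random orientation, and independent
per-base substitution/insertion/deletion errors at configured rates
(defaults 3%/1%/1%, read length 2500 ± 200 nt, minimum 400 nt — emulating
Cas9-enrichment long reads that span the excised locus fragment). Every
random draw happens under an explicit local seed; the caller's RNG state is
never touched, and identical seeds give byte-identical bundles.

What passing these tests shows: the arithmetic, the event models, and the
classifier's decision rule are internally consistent and match an
independent brute-force Smith–Waterman oracle. What they do not show:
performance on real nanopore data (no homopolymer bias, no quality-string
structure, no chimeras), behaviour at real loci (repeats, homology-arm
SNPs), or any wet-lab efficiency — tagging rates are a property of cells,
not of this software.

## Numerical and degenerate-input policy

Coordinates are 0-based half-open everywhere; strand `-` occurrences are
handled by reverse complementing. Sites are uppercase DNA only (U is
rejected). The engine refuses rather than guesses: no attP → `NoTargetSite`
(the no-ssODN control), several candidate sites → ambiguous-target error
unless multimers are explicitly allowed, inverted or order-swapped donor
attB geometry → geometry error (the inversion product is not modelled
because its bench behaviour is uncharacterized). Partial dual events are
emitted as a named `whole_plasmid` allele instead of failing silently,
because genotyping explicitly looks for them. Problem sizes in the test
suite (locus 0.9–1.7 kb, reads 90–900 nt, 1000-event property sweeps,
n = 1000 mixtures) were chosen so exhaustive oracles stay tractable on one
CPU; they are stated in the tests themselves.
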