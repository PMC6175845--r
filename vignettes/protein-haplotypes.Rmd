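---
title: "Reconstructing protein haplotypes from phased genotypes"
author: "ProteinHaplotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing protein haplotypes from phased genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ProteinHaplotypes)
```

## The problem

Most variant-annotation tools consider one DNA variant at a time. A protein,
however, is translated from one *phased copy* of a gene: the combination of
variants carried together on the same chromosome determines the actual amino
acid sequence in a cell. For applications where the full-length sequence
matters — notably the selection of target protein sequences in drug (and in
particular monoclonal antibody) development — the per-variant view is
insufficient: the unit of interest is the **protein haplotype**, the
translation of one phased CDS copy, and its frequency in a population.

This package reconstructs CDS and protein haplotypes for each sample and
phase of a phased VCF, names them compactly by their alignment-derived
differences from the reference translation, and aggregates them across
cohorts into per-population frequency statistics.

## The procedure

For a transcript and a phased VCF the pipeline performs, per sample and
phase:

1. **Fetch** genotypes overlapping the span of the transcript's exons;
   drop genotypes homozygous for the reference allele. Haploid genotypes
   (male X/Y) are detected from the GT field and yield a single haplotype.
2. **Split phases**: each heterozygous phased genotype contributes its
   alternate allele to one parental haplotype; homozygous-alternate
   genotypes contribute to both.
3. **Project** each allele into spliced CDS coordinates. Shared flanking
   bases between REF and ALT are trimmed first, so VCF anchor bases do not
   affect classification. A variant is applied only if its trimmed
   reference span lies wholly within coding exonic bases; variants
   touching intron, splice or UTR bases are skipped and recorded. On
   minus-strand transcripts alleles are reverse-complemented and
   coordinates flipped.
4. **Edit** the reference CDS, applying edits in 3'→5' order so that
   insertions and deletions cannot shift the coordinates of edits not yet
   applied; the result is independent of input order.
5. **Translate** (standard genetic code) from position 1, stopping at the
   first stop codon. A premature stop is retained as a final `*` residue;
   a terminal stop — the reference's own, or the natural terminus after an
   in-frame indel — is never included.
6. **Re-align and name**: each haplotype is globally re-aligned to its
   reference sequence with an affine-gap (Gotoh) aligner, contiguous
   difference blocks are extracted and rendered in a compact HGVS-like
   notation (`299D>G`, `577R>*`, `578del(325)`, `6ins(A)`), and joined
   with the transcript's display name:
   `TLR4-001:299D>G,399T>I`. A haplotype identical to the reference is
   named `<display>:REF`.

Aggregation across samples produces a `TranscriptHaplotypeContainer`
holding the unique CDS and protein haplotypes (keyed by exact sequence, so
synonymous CDS changes merge at protein level), carrier lists with
zygosity, diplotype tallies and per-population denominators.

```{r example}
pop <- generatePopulationVcf(simulationConfig(seed = 42, nSamples = 60))
fa <- tempfile(fileext = ".fa"); cat(pop$fasta, file = fa)
gf <- tempfile(fileext = ".gff3"); cat(pop$gff, file = gf)
vc <- tempfile(fileext = ".vcf"); cat(pop$vcf, file = vc)
pn <- tempfile(fileext = ".panel"); cat(pop$panel, file = pn)

containers <- runHaplotypes(fa, gf, vc, panel = pn,
                            gene = "GENE001", canonicalOnly = TRUE)
ct <- containers[[1]]
ct
head(haplotypeTable(ct)[, c("haplotype_name", "count_ALL", "FoO_ALL")])
```

## Frequency of occurrence and diplotypes

The frequency of occurrence (FoO) of a haplotype is its observation count
in a population divided by the population's total haplotype observation
count — twice the number of diploid individuals, with haploid samples
contributing one observation. Denominators are per-transcript: samples
excluded because of unphased or missing genotypes reduce the denominator,
keeping FoO a proper frequency. Haplotypes with FoO at or above a
threshold (1% by default, inclusive) are called *common*; genes are
classified by their number of common haplotypes (one / two-or-three /
four-plus), a practical measure of how much protein variability a drug
programme must anticipate.

A drug validated against a fraction $c$ of haplotype observations is
guaranteed, under random pairing, to cover at least $c^2$ of individuals
(both copies covered): 99% haplotype coverage implies at least 98.01%
diplotype coverage. `diplotypeCoverageBound()` computes this bound, and
the diplotype tallies in the container give the exact cohort answer.

Variant-level frequencies are derived from haplotypes:
`variantFoo()` sums the FoO of every haplotype containing a given
difference (identified by position, reference and alternate residues). A
variant can be *diluted* — common in aggregate while no single haplotype
containing it is common. `variantsVsHaplotypesPoint()` quantifies this:
its `y` value counts common haplotypes plus the minimal top-up of
highest-frequency haplotypes needed to represent every common variant,
computed greedily in descending FoO (the greedy result is cross-checked
against a brute-force minimum in the test-suite).

## Design choices

Several aspects of the procedure were genuinely open; the package fixes
them as follows.

* **Splice policy.** Only variants whose trimmed span lies wholly inside
  coding exonic bases are applied. This is the strictest consistent
  reading of "no changes in introns or splice sites": a boundary-spanning
  indel could silently change splicing, which a CDS-space editor cannot
  model. Skipped variants are recorded with reasons.
* **Alignment and tie-breaking.** The aligner scores match +1,
  mismatch −1, gap open 2, gap extend 0.5 (a gap of length $L$ costs
  $2 + 0.5L$); haplotypes are near-identical to their reference, so block
  recovery is insensitive to the exact scheme, and the parameters are
  configurable. Among co-optimal alignments the traceback places gap runs
  at their 3'-most equivalent position — the HGVS normalisation
  convention — so a premature stop renders as a substitution followed by
  a tail deletion (`577R>*,578del(325)`), not the reverse. The full-matrix
  computation is quadratic in space, ample at CDS/protein lengths; score
  optimality is verified in the tests against an independently formulated
  quadratic dynamic-programming oracle and against
  `Biostrings::pairwiseAlignment`.
* **Difference blocks.** Maximal runs of non-match alignment columns are
  split into type-uniform blocks (substitution / insertion / deletion), so
  a mismatch adjacent to a gap run yields two blocks. Frameshift tails
  therefore render as a series of blocks; the diff set always
  reconstructs the haplotype exactly when applied back to the reference
  (a round-trip invariant in the tests).
* **Stop handling.** Stop-gain: translation stops and the `*` is kept as
  a residue so that `R>*` substitutions can be named. Stop-loss:
  translation continues into downstream CDS sequence only — the CDS is
  the universe of the method, there is no 3'-UTR read-through — and the
  haplotype is flagged. Start-loss: translated anyway from position 1 and
  flagged; the tool is a sequence transformer, not an NMD predictor.
* **Unphased or missing genotypes.** The method's premise is
  chromosomally phased input. A sample with an unphased heterozygous or
  missing genotype within the transcript is excluded from that
  transcript's tallies (with a warning), and the denominators adjust.
  Overlapping alternate alleles on one phase keep the earlier-starting
  variant, deterministically.
* **Canonical transcripts.** Per gene: longest CCDS-tagged translation
  without internal stops, else longest merged-annotation translation
  without internal stops, else longest translation without internal
  stops; ties break lexicographically on transcript id (the upstream
  annotation system's tie rule is unspecified; lexicographic order makes
  runs reproducible).
* **Monoploidy and denominators.** Haploid samples contribute one
  haplotype observation and no diplotype. Denominators are true
  observation counts rather than "2 × individuals", which matters for
  X-linked genes in mixed-sex cohorts.

## The synthetic-data module and what the tests show

`generateToyReference()` builds a deterministic toy chromosome carrying
multi-exon transcripts on both strands and a single-exon transcript, each
with an ATG start, GT..AG introns, optional UTRs and a terminal stop.
`generateMutationSeries()` emits one phased sample per mutation class —
SNV (het and hom), multi-nucleotide substitution, in-frame and frameshift
indels, stop gain and loss, first/last CDS base, intronic SNV,
splice-overlapping deletion, plus a haploid sample.
`generatePopulationVcf()` draws haplotype classes i.i.d. from configured
per-population frequencies and pairs them randomly (Hardy–Weinberg) into
phased diploids, with known ground truth.

`oracleHaplotypes()` is an independently implemented validation path: it
applies VCF alleles to the whole genomic sequence, shifts annotation
coordinates by net indel lengths (naively, without splice awareness),
re-splices and translates, sharing no computation with the pipeline.
Agreement over all exonic scenarios and randomized exonic variant sets is
asserted in the test-suite; splice-overlapping variants are the expected,
explicitly enumerated disagreement regime (the oracle applies them, the
pipeline does not).

The generator emulates structure (multi-exon, both strands, UTRs,
haploidy, HWE, population-specific frequencies) but not realistic
mutation-rate spectra, linkage beyond the configured haplotype classes,
sequencing error or phasing error. Passing tests therefore demonstrate
the correctness of the coordinate arithmetic, editing, translation,
naming and counting machinery — not robustness to miscalled or misphased
real-world input, which this method takes as given.

Problem sizes used by the test-suite and the acceptance script were
chosen to exercise every code path at small scale: toy chromosomes of a
few kilobases, CDS lengths of 90–180 nt (and engineered 2–2.7 kb CDS for
the notation regressions), cohorts of 30–60 samples for structural
checks and 500 diploids for statistical recovery, 200 random sequence
pairs (length ≤ 200) for alignment optimality.

## Known limitations

* Structural variants beyond simple substitutions and indels are out of
  scope, as are selenocysteine recoding and non-standard genetic codes.
* No functional-consequence prediction (NMD, pathogenicity scores); the
  output is the sequence and its frequency.
* The FoO of a haplotype is an estimate from the cohort; no sampling
  uncertainty is attached.
* Exact-sequence protein mapping (`mapToExternalProteins()`) is strict
  string equality after stripping a trailing stop; isoform-level fuzzy
  matching is deliberately not attempted.
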