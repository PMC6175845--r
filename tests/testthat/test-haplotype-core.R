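test_that("variant projection maps SNVs into CDS frame and skips non-coding spans", {
  fix <- toyPlusTranscript()
  # chr1 position 10 is CDS base 5 ("A"); A->G
  r <- makeRecord("chr1", 10, "A", "G")
  e <- projectVariant(fix$tx, fix$genome, r)
  expect_true(is.na(e$skip))
  expect_equal(e[c("cdsStart", "cdsEnd", "ref", "alt")],
               list(cdsStart = 5L, cdsEnd = 5L, ref = "A", alt = "G"))
  # intronic SNV -> skip marker, not an error
  ri <- makeRecord("chr1", 18, "T", "C")
  expect_equal(projectVariant(fix$tx, fix$genome, ri)$skip, "intronic")
  # UTR SNV -> outside
  ru <- makeRecord("chr1", 3, "C", "T")
  expect_equal(projectVariant(fix$tx, fix$genome, ru)$skip, "outside")
  # span crossing a CDS/intron boundary -> splice
  rs <- makeRecord("chr1", 13, "CCG", "C")
  expect_equal(projectVariant(fix$tx, fix$genome, rs)$skip, "splice")
  # REF inconsistent with the genome is a hard error
  rb <- makeRecord("chr1", 10, "C", "T")
  expect_error(projectVariant(fix$tx, fix$genome, rb), "does not match")
})

test_that("minus-strand projection reverse-complements alleles and flips coordinates", {
  fixm <- toyMinusTranscript()
  # CDS base 5 is genomic position n-10+1 on the flipped chromosome; its
  # plus-strand base is the complement "T"
  map <- cdsGenomicMap(fixm$tx)
  g5 <- map[5]
  refBase <- genomeSubseq(fixm$genome, "chr1", g5, g5)
  expect_equal(refBase, "T")  # complement of CDS-strand "A"
  r <- makeRecord("chr1", g5, "T", "C")
  e <- projectVariant(fixm$tx, fixm$genome, r)
  expect_equal(e[c("cdsStart", "cdsEnd", "ref", "alt")],
               list(cdsStart = 5L, cdsEnd = 5L, ref = "A", alt = "G"))
})

test_that("anchored indels are trimmed before classification", {
  fix <- toyPlusTranscript()
  # deletion of CDS bases 5-6 anchored at CDS base 4 (genomic 9):
  r <- makeRecord("chr1", 9, "AAA", "A")
  e <- projectVariant(fix$tx, fix$genome, r)
  expect_equal(e[c("cdsStart", "cdsEnd", "ref", "alt")],
               list(cdsStart = 5L, cdsEnd = 6L, ref = "AA", alt = ""))
  # insertion between CDS 4 and 5
  ri <- makeRecord("chr1", 9, "A", "AGGG")
  ei <- projectVariant(fix$tx, fix$genome, ri)
  expect_equal(ei[c("cdsStart", "cdsEnd", "ref", "alt")],
               list(cdsStart = 5L, cdsEnd = 4L, ref = "", alt = "GGG"))
  # anchored deletion whose trimmed span lies in the intron -> not coding
  rx <- makeRecord("chr1", 16, "TTTT", "T")
  expect_false(is.na(projectVariant(fix$tx, fix$genome, rx)$skip))
})

test_that("edits apply 3'-to-5' and the result is order-independent", {
  ref <- "ATGAAACCCTAA"
  expect_equal(applyEdits(ref, list()), ref)
  sub4 <- list(cdsStart = 4L, cdsEnd = 4L, ref = "A", alt = "G",
               variantId = ".", pos = 0, skip = NA)
  expect_equal(applyEdits(ref, list(sub4)), "ATGGAACCCTAA")
  del <- list(cdsStart = 4L, cdsEnd = 6L, ref = "AAA", alt = "",
              variantId = ".", pos = 0, skip = NA)
  sub10 <- list(cdsStart = 10L, cdsEnd = 10L, ref = "T", alt = "G",
                variantId = ".", pos = 0, skip = NA)
  expect_equal(applyEdits(ref, list(del, sub10)), "ATGCCCGAA")
  expect_equal(applyEdits(ref, list(sub10, del)), "ATGCCCGAA")
  # random permutations of a larger edit set give identical results
  set.seed(42)
  edits <- list(
    del, sub10,
    list(cdsStart = 2L, cdsEnd = 1L, ref = "", alt = "C",
         variantId = ".", pos = 0, skip = NA),
    list(cdsStart = 8L, cdsEnd = 8L, ref = "C", alt = "T",
         variantId = ".", pos = 0, skip = NA))
  out <- applyEdits(ref, edits)
  for (i in 1:10)
    expect_identical(applyEdits(ref, sample(edits)), out)
  # overlap is rejected
  expect_error(applyEdits(ref, list(del, list(
    cdsStart = 5L, cdsEnd = 5L, ref = "A", alt = "T",
    variantId = ".", pos = 0, skip = NA))), "overlap")
})

test_that("translation keeps a premature stop as '*' and drops a terminal stop", {
  expect_equal(translateCds("ATGTAA", 1)$protein, "M")
  tr <- translateCds("ATGTGATAA", 2)
  expect_equal(tr$protein, "M*")
  expect_true("contains_stop_change" %in% tr$flags)
  tr2 <- translateCds("ATGGC")
  expect_equal(tr2$protein, "M")
  expect_true("incomplete_cds" %in% tr2$flags)
  # in-frame deletion: the natural terminus is not rendered as premature
  expect_equal(translateCds("ATGTAA", 2)$protein, "M")
  # stop loss: translation runs to the end of the provided CDS and is flagged
  tr3 <- translateCds("ATGAAAGGG", 2)
  expect_equal(tr3$protein, "MKG")
  expect_true("contains_stop_change" %in% tr3$flags)
  expect_error(translateCds("AT"), "at least one codon")
})

test_that("reference translation of a well-formed CDS carries no stop and no flags", {
  for (fix in list(toyPlusTranscript(), toyMinusTranscript())) {
    tr <- translateCds(splicedCds(fix$tx, fix$genome))
    expect_equal(tr$protein, fix$refProtein)
    expect_false(grepl("*", tr$protein, fixed = TRUE))
    expect_length(tr$flags, 0)
  }
})

test_that("per-sample haplotype construction produces one pair per phase and honours ploidy", {
  fix <- toyPlusTranscript()
  # no non-reference alleles: both phases reference
  s0 <- makeSampleAlleles("S0")
  hp <- buildSampleHaplotypes(fix$tx, fix$genome, s0)
  expect_length(hp, 2L)
  for (ph in hp) {
    expect_true("is_reference" %in% haplotypeFlags(ph$protein))
    expect_equal(haplotypeSequence(ph$protein), fix$refProtein)
    expect_match(haplotypeName(ph$protein), ":REF$")
  }
  # het SNV 1|0: phase 0 carries the edit, phase 1 is reference
  r <- makeRecord("chr1", 10, "A", "G", id = "rs77")
  s1 <- makeSampleAlleles("S1", phase0 = list(phasedEntry(r)))
  hp1 <- buildSampleHaplotypes(fix$tx, fix$genome, s1)
  expect_equal(length(hp1[[1]]$edits), 1L)
  expect_false("is_reference" %in% haplotypeFlags(hp1[[1]]$protein))
  expect_true("is_reference" %in% haplotypeFlags(hp1[[2]]$protein))
  expect_equal(haplotypeDiffs(hp1[[1]]$protein)$variantId, "rs77")
  # haploid sample: exactly one haplotype emitted
  sh <- makeSampleAlleles("SH", phase0 = list(phasedEntry(r)), ploidy = 1L)
  hph <- buildSampleHaplotypes(fix$tx, fix$genome, sh)
  expect_length(hph, 1L)
  # skipped variants are recorded per haplotype
  ri <- makeRecord("chr1", 18, "T", "C")
  s2 <- makeSampleAlleles("S2", phase0 = list(phasedEntry(ri)))
  hp2 <- buildSampleHaplotypes(fix$tx, fix$genome, s2)
  expect_length(hp2[[1]]$skipped, 1L)
  expect_true("is_reference" %in% haplotypeFlags(hp2[[1]]$protein))
})
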