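# a small fully-wired cohort: 3 diploids + 1 haploid on the hand-built
# plus-strand transcript, with a panel of two populations
smallCohort <- function() {
  fix <- toyPlusTranscript()
  r1 <- makeRecord("chr1", 10, "A", "G", id = "rsA")  # CDS 5, K>R-ish
  r2 <- makeRecord("chr1", 26, "G", "T", id = "rsB")  # CDS 11, missense
  perSample <- list(
    D1 = makeSampleAlleles("D1", phase0 = list(phasedEntry(r1))),
    D2 = makeSampleAlleles("D2", phase0 = list(phasedEntry(r1)),
                           phase1 = list(phasedEntry(r1))),
    D3 = makeSampleAlleles("D3"),
    H1 = makeSampleAlleles("H1", phase0 = list(phasedEntry(r2)),
                           ploidy = 1L))
  haps <- lapply(perSample, function(sa)
    buildSampleHaplotypes(fix$tx, fix$genome, sa, name = FALSE))
  panel <- data.frame(sample = c("D1", "D2", "D3", "H1"),
                      pop = c("GBR", "GBR", "JPT", "JPT"),
                      superPop = c("EUR", "EUR", "EAS", "EAS"),
                      sex = c("female", "female", "female", "male"),
                      stringsAsFactors = FALSE)
  ct <- aggregateHaplotypes(haps, fix$tx, fix$genome, panel = panel)
  list(fix = fix, ct = ct, panel = panel)
}

test_that("aggregation counts observations, zygosity and diplotypes correctly", {
  ct <- smallCohort()$ct
  # 3 diploids + 1 haploid = 7 haplotype observations, 3 diplotypes
  expect_equal(unname(denominators(ct)[["ALL"]]), 7)
  expect_length(ct@diplotypes, 3L)
  expect_equal(unname(ct@diploidCounts[["ALL"]]), 3)
  # one diploid sample alone would give 2 observations and 1 diplotype
  one <- smallCohort()
  haps1 <- list(D3 = buildSampleHaplotypes(one$fix$tx, one$fix$genome,
                                           makeSampleAlleles("D3"),
                                           name = FALSE))
  ct1 <- aggregateHaplotypes(haps1, one$fix$tx, one$fix$genome)
  expect_equal(unname(denominators(ct1)[["ALL"]]), 2)
  expect_length(ct1@diplotypes, 1L)
  # headline arithmetic of the counting rule: observations scale as
  # 2 x samples x genes, diplotypes as samples x genes
  expect_equal(2 * 2504 * 20166, 100991328)
  expect_equal(2504 * 20166, 50495664)
  # duplicated sample is rejected
  expect_error(aggregateHaplotypes(c(haps1, haps1), one$fix$tx,
                                   one$fix$genome), "twice")
})

test_that("zygosity copies sum to counts and carriers record het/hom state", {
  ct <- smallCohort()$ct
  for (rec in ct@proteinHaplotypes)
    expect_equal(sum(rec$carriers), unname(rec$counts[["ALL"]]))
  tab <- haplotypeTable(ct)
  hom <- tab[grepl("2K>R", tab$haplotype_name, fixed = TRUE), ]
  # D2 carries the rsA haplotype twice (hom), D1 once (het)
  expect_equal(hom$n_hom_carriers, 1L)
  expect_equal(hom$n_het_carriers, 1L)
  expect_equal(hom$count_ALL, 3L)
})

test_that("FoO is count over haplotype observations, per population", {
  ct <- smallCohort()$ct
  nm <- vapply(ct@proteinHaplotypes, function(r)
    haplotypeName(r$haplotype), character(1))
  refName <- nm[grepl(":REF$", nm)]
  # REF observations: D1 phase1, D3 both = 3 of 7
  expect_equal(frequencyOfOccurrence(ct, refName), 3 / 7)
  expect_equal(frequencyOfOccurrence(ct, refName, "EUR"), 1 / 4)
  expect_equal(frequencyOfOccurrence(ct, refName, "JPT"), 2 / 3)
  expect_equal(frequencyOfOccurrence(ct, "no-such", "ALL"), 0)
  expect_error(frequencyOfOccurrence(ct, refName, "XXX"), "unknown")
  # normalisation: FoO sums to 1 in every population
  for (p in populations(ct)) {
    foo <- vapply(nm, frequencyOfOccurrence, numeric(1),
                  container = ct, population = p)
    expect_equal(sum(foo), 1, tolerance = 1e-9)
  }
})

test_that("common-haplotype lists are inclusive at the threshold and monotone", {
  ct <- makeCountContainer(c(A = 60, B = 30, C = 9, D = 1),
                           list(B = simpleDiff(2, "K", "R"),
                                C = simpleDiff(3, "L", "P"),
                                D = simpleDiff(4, "F", "S")))
  expect_equal(commonHaplotypes(ct, 0.01)$name,
               commonHaplotypes(ct, 0)$name)  # 1/100 = 0.01 inclusive
  expect_equal(nrow(commonHaplotypes(ct, 0)), 4L)
  sizes <- vapply(c(0.002, 0.01, 0.05, 0.2), function(th)
    nrow(commonHaplotypes(ct, th)), numeric(1))
  expect_true(all(diff(sizes) <= 0))
  # sorted by FoO descending
  expect_equal(commonHaplotypes(ct, 0.05)$foo, c(0.6, 0.3, 0.09))
})

test_that("gene complexity categories follow the common-haplotype count", {
  ctA <- makeCountContainer(c(A = 99, B = 1),
                            list(B = simpleDiff(2, "K", "R")))
  expect_equal(classifyGene(ctA, 0.02)$category, "single")
  ctB <- makeCountContainer(c(A = 60, B = 25, C = 15),
                            list(B = simpleDiff(2, "K", "R"),
                                 C = simpleDiff(3, "L", "P")))
  cg <- classifyGene(ctB, 0.01)
  expect_equal(cg$category, "two_or_three")
  expect_equal(cg$nCommon, 3L)
  expect_false(cg$mostCommonDiffersFromReference)
  ctC <- makeCountContainer(
    c(A = 40, B = 25, C = 20, D = 15),
    list(A = simpleDiff(299, "D", "G"),
         B = simpleDiff(2, "K", "R"), C = simpleDiff(3, "L", "P"),
         D = simpleDiff(4, "F", "S")))
  cgC <- classifyGene(ctC, 0.01)
  expect_equal(cgC$category, "four_plus")
  # most common haplotype carries 299D>G while the reference does not
  expect_true(cgC$mostCommonDiffersFromReference)
  expect_match(cgC$mostCommon[["ALL"]], "299D>G")
})

test_that("variant FoO sums over containing haplotypes", {
  dA <- simpleDiff(5, "A", "V")
  ct <- makeCountContainer(
    c(REF = 80, H1 = 20),
    list(H1 = dA), denominator = 100)
  vf <- variantFoo(ct)
  expect_equal(vf$foo[vf$name == "5A>V"], 0.2)
  # the same diff in two haplotypes accumulates
  ct2 <- makeCountContainer(
    c(REF = 982, H1 = 9, H2 = 9),
    list(H1 = dA, H2 = rbind(dA, simpleDiff(7, "L", "P"))),
    denominator = 1000)
  vf2 <- variantFoo(ct2)
  expect_equal(vf2$foo[vf2$name == "5A>V"], 0.018)
  expect_equal(vf2$foo[vf2$name == "7L>P"], 0.009)
  expect_false("1M>V" %in% vf2$name)
})

test_that("the variants-vs-haplotypes point counts diluted variants via a minimal top-up", {
  dA <- simpleDiff(5, "A", "V"); dB <- simpleDiff(7, "L", "P")
  dC <- simpleDiff(9, "F", "S")
  # {REF 0.973, A 0.009, A+B 0.009, A+C 0.009}: variant A has FoO 0.027
  # (diluted); one top-up haplotype suffices
  ct <- makeCountContainer(
    c(REF = 973, HA = 9, HAB = 9, HAC = 9),
    list(HA = dA, HAB = rbind(dA, dB), HAC = rbind(dA, dC)),
    denominator = 1000)
  pt <- variantsVsHaplotypesPoint(ct, 0.01)
  expect_equal(pt$x, 1L)
  expect_equal(pt$nCommon, 1L)
  expect_equal(pt$y, 2L)
  expect_equal(pt$y - pt$nCommon, bruteForceTopUp(ct, 0.01))
  # all significant variants inside common haplotypes: y = |common|
  ct2 <- makeCountContainer(c(REF = 70, HA = 30), list(HA = dA),
                            denominator = 100)
  pt2 <- variantsVsHaplotypesPoint(ct2, 0.01)
  expect_equal(pt2$y, pt2$nCommon)
  expect_equal(pt2$topUp, character(0))
  # no variants at all
  ct3 <- makeCountContainer(c(REF = 100), denominator = 100)
  pt3 <- variantsVsHaplotypesPoint(ct3, 0.01)
  expect_equal(pt3$x, 0L)
  expect_equal(pt3$y, pt3$nCommon)
  # y is never below the common-haplotype count
  expect_true(pt$y >= pt$nCommon && pt2$y >= pt2$nCommon)
})

test_that("diplotype coverage bound is the squared haplotype coverage", {
  expect_equal(diplotypeCoverageBound(0.99), 0.9801)
  expect_true(diplotypeCoverageBound(0.99) >= 0.98)
  expect_equal(diplotypeCoverageBound(1), 1)
  expect_equal(diplotypeCoverageBound(0.9), 0.81)
  expect_error(diplotypeCoverageBound(1.2), "within")
})

test_that("variant-combination enumeration yields 2^n hypothetical haplotypes", {
  expect_length(enumerateVariantCombinations(paste0("v", 1:5)), 32L)
  expect_equal(enumerateVariantCombinations(character()), list(character()))
  expect_length(enumerateVariantCombinations(c("a", "b", "c")), 8L)
  expect_error(enumerateVariantCombinations(paste0("v", 1:20)), "cap")
})

test_that("external protein mapping is exact, stop-stripped, and reports all duplicates", {
  cohort <- smallCohort()
  ct <- cohort$ct
  refProt <- cohort$fix$refProtein
  fa <- writeTempText(paste0(">P1 uniprot\n", refProt, "\n>P2\n", refProt,
                             "\n>P3\nMXYZ\n"), ".fa")
  mp <- mapToExternalProteins(ct, fa)
  refName <- paste0("TP-001:REF")
  expect_setequal(mp$matches[[refName]], c("P1", "P2"))
  expect_equal(mp$unmatchedExternal, "P3")
  empty <- writeTempText(">Q1\nWWWW\n", ".fa")
  mp2 <- mapToExternalProteins(ct, empty)
  expect_length(mp2$matches, 0L)
})

test_that("threshold sensitivity counts are monotone and match direct evaluation", {
  ct <- makeCountContainer(c(A = 60, B = 30, C = 10),
                           list(B = simpleDiff(2, "K", "R"),
                                C = simpleDiff(3, "L", "P")))
  tab <- thresholdSensitivity(list(ct), c(0.05, 0.2, 0.5))
  expect_equal(tab$n_significant, c(3, 2, 1))
  expect_true(all(diff(tab$n_significant) <= 0))
  one <- makeCountContainer(c(A = 10))
  expect_equal(thresholdSensitivity(list(one), 1)$n_significant, 1)
})
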