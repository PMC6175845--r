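test_that("FASTA loading normalises case, concatenates wrapped lines and rejects duplicates", {
  p <- writeTempText(">chr1\nACGT\n", ".fa")
  g <- loadReference(p)
  expect_equal(as.character(g[["chr1"]]), "ACGT")

  wrapped <- writeTempText(">chr1 description\nacgtac\ngtACGT\n", ".fa")
  g2 <- loadReference(wrapped)
  expect_equal(as.character(g2[["chr1"]]), "ACGTACGTACGT")

  dup <- writeTempText(">chr1\nACGT\n>chr1\nTTTT\n", ".fa")
  expect_error(loadReference(dup), "duplicate")
  expect_error(loadReference(tempfile()), "not found")
})

test_that("genomeSubseq returns 1-based inclusive intervals and checks bounds", {
  g <- Biostrings::DNAStringSet(c(chr1 = "ACGTACGT"))
  expect_equal(genomeSubseq(g, "chr1", 2, 4), "CGT")
  expect_equal(nchar(genomeSubseq(g, "chr1", 1, 8)), 8L)
  expect_error(genomeSubseq(g, "chr1", 0, 3), "out of bounds")
  expect_error(genomeSubseq(g, "chr2", 1, 3), "not in genome")
})

test_that("GFF3 and GTF dialects load to identical transcript models", {
  gff <- paste(
    "##gff-version 3",
    "chr1\tt\tgene\t1\t37\t.\t+\t.\tID=g1;Name=G1",
    "chr1\tt\tmRNA\t1\t37\t.\t+\t.\tID=t1;Parent=g1;Name=G1-001;biotype=protein_coding;tag=CCDS",
    "chr1\tt\texon\t1\t14\t.\t+\t.\tParent=t1",
    "chr1\tt\texon\t25\t37\t.\t+\t.\tParent=t1",
    "chr1\tt\tCDS\t6\t14\t.\t+\t0\tParent=t1",
    "chr1\tt\tCDS\t25\t33\t.\t+\t0\tParent=t1",
    sep = "\n")
  gtf <- paste(
    'chr1\tt\tgene\t1\t37\t.\t+\t.\tgene_id "g1"; gene_name "G1";',
    'chr1\tt\ttranscript\t1\t37\t.\t+\t.\tgene_id "g1"; transcript_id "t1"; transcript_name "G1-001"; transcript_biotype "protein_coding"; tag "CCDS";',
    'chr1\tt\texon\t1\t14\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tt\texon\t25\t37\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tt\tCDS\t6\t14\t.\t+\t0\tgene_id "g1"; transcript_id "t1";',
    'chr1\tt\tCDS\t25\t33\t.\t+\t0\tgene_id "g1"; transcript_id "t1";',
    sep = "\n")
  for (spec in list(c(gff, ".gff3"), c(gtf, ".gtf"))) {
    genes <- loadGeneModels(writeTempText(paste0(spec[1], "\n"), spec[2]))
    expect_named(genes, "g1")
    tx <- genes$g1@transcripts[[1]]
    expect_equal(txId(tx), "t1")
    expect_equal(displayName(tx), "G1-001")
    expect_equal(txStrand(tx), 1L)
    expect_true("CCDS" %in% tx@tags)
    expect_equal(IRanges::start(cdsRanges(tx)), c(6L, 25L))
    expect_equal(IRanges::end(cdsRanges(tx)), c(14L, 33L))
  }
})

test_that("minus-strand models keep genomic-order intervals; bad CDS placement errors", {
  gffm <- paste(
    "##gff-version 3",
    "chr1\tt\tgene\t10\t60\t.\t-\t.\tID=g2",
    "chr1\tt\tmRNA\t10\t60\t.\t-\t.\tID=t2;Parent=g2",
    "chr1\tt\texon\t40\t60\t.\t-\t.\tParent=t2",
    "chr1\tt\texon\t10\t20\t.\t-\t.\tParent=t2",
    "chr1\tt\tCDS\t40\t60\t.\t-\t0\tParent=t2",
    "chr1\tt\tCDS\t12\t20\t.\t-\t0\tParent=t2",
    sep = "\n")
  genes <- loadGeneModels(writeTempText(paste0(gffm, "\n"), ".gff3"))
  tx <- genes[[1]]@transcripts[[1]]
  expect_equal(txStrand(tx), -1L)
  expect_equal(IRanges::start(cdsRanges(tx)), c(12L, 40L))

  bad <- paste(
    "##gff-version 3",
    "chr1\tt\tmRNA\t1\t30\t.\t+\t.\tID=t3",
    "chr1\tt\texon\t1\t10\t.\t+\t.\tParent=t3",
    "chr1\tt\tCDS\t20\t28\t.\t+\t0\tParent=t3",
    sep = "\n")
  expect_error(loadGeneModels(writeTempText(paste0(bad, "\n"), ".gff3")),
               "outside all exons")
  orphan <- paste(
    "##gff-version 3",
    "chr1\tt\tCDS\t20\t28\t.\t+\t0\tParent=missing",
    sep = "\n")
  expect_error(loadGeneModels(writeTempText(paste0(orphan, "\n"), ".gff3")),
               "no parent")
})

test_that("spliced CDS concatenates intervals and reverse-complements minus strand", {
  g <- Biostrings::DNAStringSet(c(chr1 = "ATGAAATAA"))
  tx <- TranscriptModel("t", "g", chrom = "chr1", strand = 1L,
                        exons = IRanges::IRanges(1, 9),
                        cds = IRanges::IRanges(1, 9))
  expect_equal(splicedCds(tx, g), "ATGAAATAA")

  # minus strand: plus-strand pieces "TTA"+"GGG" = "TTAGGG", revcomp CCCTAA
  g2 <- Biostrings::DNAStringSet(c(chr1 = "TTACATGGGCAT"))
  txm <- TranscriptModel("t2", "g2", chrom = "chr1", strand = -1L,
                         exons = IRanges::IRanges(c(1, 7), c(3, 9)),
                         cds = IRanges::IRanges(c(1, 7), c(3, 9)))
  expect_equal(splicedCds(txm, g2), "CCCTAA")

  g3 <- Biostrings::DNAStringSet(c(chr1 = "AAATGCCCGGGTTT"))
  tx3 <- TranscriptModel("t3", "g3", chrom = "chr1", strand = 1L,
                         exons = IRanges::IRanges(c(3, 9), c(5, 11)),
                         cds = IRanges::IRanges(c(3, 9), c(5, 11)))
  expect_equal(splicedCds(tx3, g3), "ATGGGG")

  fix <- toyPlusTranscript()
  expect_equal(splicedCds(fix$tx, fix$genome), fix$refCds)
  fixm <- toyMinusTranscript()
  expect_equal(splicedCds(fixm$tx, fixm$genome), fix$refCds)
})

test_that("spliced CDS length equals the sum of interval widths", {
  for (fix in list(toyPlusTranscript(), toyMinusTranscript())) {
    expect_equal(nchar(splicedCds(fix$tx, fix$genome)),
                 sum(IRanges::width(cdsRanges(fix$tx))))
  }
})

test_that("genomic<->CDS projection is exact on both strands and flags non-coding", {
  fix <- toyPlusTranscript()
  expect_equal(genomicToCds(fix$tx, 6)$start, 1L)  # first CDS base
  expect_equal(genomicToCds(fix$tx, 25)$start, 10L)  # across the intron
  expect_equal(genomicToCds(fix$tx, 18)$status, "intronic")
  expect_equal(genomicToCds(fix$tx, 3)$status, "outside")   # 5' UTR
  expect_equal(genomicToCds(fix$tx, 35)$status, "outside")  # 3' UTR
  expect_equal(genomicToCds(fix$tx, 13, 26)$status, "splice")
  expect_equal(genomicToCds(fix$tx, 55)$status, "outside")

  fixm <- toyMinusTranscript()
  cr <- cdsRanges(fixm$tx)
  # last base of the highest-coordinate CDS interval maps to CDS pos 1
  expect_equal(genomicToCds(fixm$tx, max(IRanges::end(cr)))$start, 1L)

  # per-base round trip, both strands (exhaustive over the CDS)
  for (f in list(fix, fixm)) {
    map <- cdsGenomicMap(f$tx)
    for (k in seq_along(map)) {
      cc <- genomicToCds(f$tx, map[k])
      expect_equal(cc$status, "coding")
      expect_equal(cc$start, k)
    }
  }
})

test_that("canonical transcript selection follows CCDS > merged > longest with stop disqualification", {
  # chromosome with three single-exon CDS: lengths 12 (CCDS), 18, 15
  chrom <- paste0("ATGAAACCCTAA", "ATGAAACCCGGGTTTTAA", "ATGAAACCCGGGTAA",
                  "ATGTAAACCTAA")
  g <- Biostrings::DNAStringSet(stats::setNames(chrom, "c"))
  mk <- function(id, start, len, tags = character()) {
    TranscriptModel(id, "g1", chrom = "c", strand = 1L,
                    exons = IRanges::IRanges(start, start + len - 1L),
                    cds = IRanges::IRanges(start, start + len - 1L),
                    tags = tags)
  }
  ccds <- mk("t_ccds", 1, 12, "CCDS")
  long <- mk("t_long", 13, 18)
  mid <- mk("t_mid", 31, 15)
  gene <- GeneModel("g1", transcripts = list(long, ccds, mid))
  # CCDS tier wins although shorter
  expect_equal(txId(selectCanonical(gene, g)), "t_ccds")
  # without tags: longest translation wins
  gene2 <- GeneModel("g1", transcripts = list(mid, long))
  expect_equal(txId(selectCanonical(gene2, g)), "t_long")
  # equal lengths tie-break lexicographically
  twinA <- mk("tB", 1, 12); twinB <- mk("tA", 1, 12)
  gene3 <- GeneModel("g1", transcripts = list(twinA, twinB))
  expect_equal(txId(selectCanonical(gene3, g)), "tA")
  # internal stop disqualifies within a tier
  stopTx <- mk("t_stop", 46, 12, "CCDS")  # ATGTAAACCTAA has internal TAA
  gene4 <- GeneModel("g1", transcripts = list(stopTx, mid))
  expect_equal(txId(selectCanonical(gene4, g)), "t_mid")
})
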