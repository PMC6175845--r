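# In-code fixtures shared across test files. Everything is generated at
# test time; nothing binary is stored.

writeTempText <- function(text, ext) {
  path <- tempfile(fileext = ext)
  cat(text, file = path)
  path
}

# a minimal hand-built genome/transcript pair used by the coordinate tests:
# chr1, 60 bp; plus-strand transcript with two CDS exons and UTRs
toyPlusTranscript <- function() {
  #           1         2         3         4         5
  #  123456789012345678901234567890123456789012345678901234567890
  #  UUUUUAAAAAAAAAiiiiiiiiiiBBBBBBBBBUUUU  (A/B = CDS, U = UTR, i = intron)
  chromSeq <- paste0(
    "CCCCC", "ATGAAACCC", "GTTTTTTTAG", "GGGTTTTAA", "CCCC",
    strrep("A", 60 - 5 - 9 - 10 - 9 - 4))
  genome <- Biostrings::DNAStringSet(chromSeq)
  names(genome) <- "chr1"
  tx <- TranscriptModel(
    "txp", "gp", displayName = "TP-001", chrom = "chr1", strand = 1L,
    exons = IRanges::IRanges(start = c(1, 25), end = c(14, 37)),
    cds = IRanges::IRanges(start = c(6, 25), end = c(14, 33)))
  list(genome = genome, tx = tx,
       refCds = "ATGAAACCCGGGTTTTAA", refProtein = "MKPGF")
}

# minus-strand version of the same CDS content
toyMinusTranscript <- function() {
  plus <- toyPlusTranscript()
  chromSeq <- as.character(Biostrings::reverseComplement(
    plus$genome[["chr1"]]))
  genome <- Biostrings::DNAStringSet(chromSeq)
  names(genome) <- "chr1"
  n <- nchar(chromSeq)
  flip <- function(r) {
    IRanges::IRanges(start = n - IRanges::end(r) + 1L,
                     end = n - IRanges::start(r) + 1L)
  }
  tx <- TranscriptModel(
    "txm", "gm", displayName = "TM-001", chrom = "chr1", strand = -1L,
    exons = flip(exonRanges(plus$tx)), cds = flip(cdsRanges(plus$tx)))
  list(genome = genome, tx = tx,
       refCds = plus$refCds, refProtein = plus$refProtein)
}

# single-exon transcript whose chromosome IS its CDS; protein template is
# given as a residue vector and reverse-translated with fixed codons
codonFor <- local({
  tab <- NULL
  function(aa) {
    if (is.null(tab)) {
      gc <- Biostrings::GENETIC_CODE
      tab <<- vapply(unique(gc), function(a)
        names(gc)[gc == a][1], character(1))
      names(tab) <- unique(gc)
    }
    unname(tab[aa])
  }
})

proteinTemplateTranscript <- function(residues, displayName, txid = "txe") {
  cds <- paste(c(codonFor(residues), "TAA"), collapse = "")
  genome <- Biostrings::DNAStringSet(cds)
  names(genome) <- "chrT"
  tx <- TranscriptModel(
    txid, paste0(txid, "_gene"), displayName = displayName,
    chrom = "chrT", strand = 1L,
    exons = IRanges::IRanges(1, nchar(cds)),
    cds = IRanges::IRanges(1, nchar(cds)))
  list(genome = genome, tx = tx, cds = cds,
       protein = paste(residues, collapse = ""))
}

# variant record in the fetchGenotypes shape
makeRecord <- function(chrom, pos, ref, alt, id = ".") {
  list(chrom = chrom, pos = pos, id = id, ref = ref, alts = alt)
}

# per-sample phased-allele structure in the splitPhases shape
makeSampleAlleles <- function(sampleId, phase0 = list(),
                              phase1 = list(), ploidy = 2L) {
  phases <- if (ploidy == 2L) list(phase0, phase1) else list(phase0)
  list(sampleId = sampleId, ploidy = ploidy, phases = phases)
}

phasedEntry <- function(record, altIndex = 1L) {
  list(record = record, altIndex = altIndex)
}

# construct a container directly from (name -> count) and
# (name -> diff data.frame), for the popstats unit tests
makeCountContainer <- function(counts, diffsByName = list(),
                               display = "G-001", denominator = NULL) {
  if (is.null(denominator)) denominator <- sum(counts)
  recs <- lapply(seq_along(counts), function(i) {
    nm <- names(counts)[i]
    diffs <- diffsByName[[nm]]
    if (is.null(diffs)) diffs <- ProteinHaplotypes:::.emptyDiffs()
    seq <- if (nrow(diffs)) paste0("SEQ_", nm) else "SEQREF"
    hap <- new("SequenceHaplotype", transcriptId = "txc",
               type = "protein", sequence = seq, diffs = diffs,
               name = haplotypeName(display, diffs),
               flags = character(), sampleId = character(),
               phase = integer())
    carriers <- stats::setNames(rep(1L, counts[i]),
                                paste0("c", i, "_", seq_len(counts[i])))
    list(haplotype = hap,
         counts = c(ALL = unname(counts[i])), carriers = carriers)
  })
  new("TranscriptHaplotypeContainer", transcriptId = "txc",
      displayName = display, refCds = "NNN", refProtein = "SEQREF",
      proteinHaplotypes = recs, cdsHaplotypes = list(),
      diplotypes = list(), denominators = c(ALL = denominator),
      diploidCounts = c(ALL = denominator / 2),
      samples = character(), excludedSamples = character())
}

simpleDiff <- function(pos, ref, alt) {
  d <- data.frame(kind = "substitution", refPos = as.integer(pos),
                  ref = ref, alt = alt, name = NA_character_,
                  variantId = NA_character_, stringsAsFactors = FALSE)
  d$name <- paste0(pos, ref, ">", alt)
  d
}
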