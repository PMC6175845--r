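#' Simulation configuration for synthetic fixtures
#'
#' Describes the toy genome, transcript structures and cohort that the
#' synthetic generators produce. Defaults give a small three-transcript
#' genome (multi-exon plus strand, multi-exon minus strand, single exon)
#' with phased diploid samples drawn under Hardy-Weinberg pairing from a
#' specified haplotype-frequency distribution.
#'
#' @param seed integer random seed; all generators are pure functions of
#'   (config, seed).
#' @param nSamples number of individuals.
#' @param chromLength toy chromosome length in bp.
#' @param transcripts list of transcript recipes: each a list with `nExons`,
#'   `strand` (+1/-1), `cdsLength` (multiple of 3, includes the stop
#'   codon), and optional `utr` (UTR padding in bp on each side within the
#'   terminal exons).
#' @param hapFrequencies named list per population of numeric haplotype
#'   class frequencies (must sum to 1; class 1 is the reference
#'   haplotype), e.g. `list(POP1 = c(0.7, 0.2, 0.1))`. Used by
#'   [generatePopulationVcf()].
#' @param fractionHaploid fraction of samples that are haploid (emulating
#'   male X), default 0.
#' @return list of class "simulationConfig".
#' @export
simulationConfig <- function(seed = 1L, nSamples = 100L,
                             chromLength = 3000L,
                             transcripts = list(
                               list(nExons = 3L, strand = 1L,
                                    cdsLength = 180L, utr = 12L),
                               list(nExons = 2L, strand = -1L,
                                    cdsLength = 120L, utr = 0L),
                               list(nExons = 1L, strand = 1L,
                                    cdsLength = 90L, utr = 6L)),
                             hapFrequencies = list(
                               POP1 = c(0.7, 0.2, 0.1),
                               POP2 = c(0.4, 0.4, 0.2)),
                             fractionHaploid = 0) {
  for (f in hapFrequencies) {
    stopifnot(all(f > 0), abs(sum(f) - 1) < 1e-9)
  }
  for (t in transcripts) stopifnot(t$cdsLength %% 3L == 0L)
  structure(list(seed = as.integer(seed), nSamples = as.integer(nSamples),
                 chromLength = as.integer(chromLength),
                 transcripts = transcripts,
                 hapFrequencies = hapFrequencies,
                 fractionHaploid = fractionHaploid),
            class = "simulationConfig")
}

.randCodingCds <- function(nCodons) {
  # ATG + random non-stop codons + stop; nCodons counts all codons
  stopifnot(nCodons >= 2L)
  bases <- c("A", "C", "G", "T")
  stops <- c("TAA", "TAG", "TGA")
  mid <- character(nCodons - 2L)
  i <- 1L
  while (i <= length(mid)) {
    cod <- paste(sample(bases, 3L, replace = TRUE), collapse = "")
    if (!cod %in% stops) { mid[i] <- cod; i <- i + 1L }
  }
  paste0("ATG", paste(mid, collapse = ""), sample(stops, 1L))
}

.randSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

#' Generate a toy reference genome and annotation
#'
#' Builds a deterministic (seeded) toy chromosome carrying the configured
#' transcripts: the CDS of each is constructed first (ATG start, no
#' internal stops, terminal stop), split across exons with GT..AG introns,
#' optionally padded with UTR, and placed on the chromosome; minus-strand
#' transcripts are placed as the reverse complement. Returns FASTA and
#' GFF3 text consumable by [loadReference()] and [loadGeneModels()].
#'
#' @param config a [simulationConfig()].
#' @return list with `fasta` (character(1) FASTA text), `gff`
#'   (character(1) GFF3 text), and `layout` — per transcript: the genomic
#'   exon/CDS intervals, strand and reference CDS/protein sequence.
#' @export
generateToyReference <- function(config) {
  set.seed(config$seed)
  chrom <- "chrSim"
  txs <- config$transcripts
  # space transcripts evenly along the chromosome
  slots <- length(txs)
  slotLen <- config$chromLength %/% slots
  layout <- list()
  chromSeq <- strsplit(.randSeq(config$chromLength), "")[[1L]]
  gff <- c("##gff-version 3",
           sprintf("##sequence-region %s 1 %d", chrom, config$chromLength))

  for (k in seq_along(txs)) {
    t <- txs[[k]]
    utr <- if (is.null(t$utr)) 0L else as.integer(t$utr)
    cds <- .randCodingCds(t$cdsLength %/% 3L)
    # split CDS into nExons pieces of roughly equal size (>= 1 nt each)
    nEx <- t$nExons
    cuts <- if (nEx > 1L)
      sort(sample(seq_len(t$cdsLength - 1L), nEx - 1L)) else integer()
    pieceStart <- c(1L, cuts + 1L)
    pieceEnd <- c(cuts, t$cdsLength)
    intronLen <- 30L
    # transcript-orientation coordinates first
    need <- utr * 2L + t$cdsLength + (nEx - 1L) * intronLen
    if (need > slotLen - 20L)
      stop("infeasible recipe: transcript ", k, " needs ", need,
           " bp but slot is ", slotLen)
    offset <- (k - 1L) * slotLen + 10L
    # build the transcript-strand genomic segment: UTR5 + exons/introns + UTR3
    segment <- character()
    exLocal <- matrix(integer(), ncol = 2L)
    cdsLocal <- matrix(integer(), ncol = 2L)
    cursor <- 0L
    if (utr > 0L) { segment <- c(segment, .randSeq(utr)); cursor <- utr }
    for (e in seq_len(nEx)) {
      piece <- substr(cds, pieceStart[e], pieceEnd[e])
      exStart <- cursor + 1L
      cdsStart <- cursor + 1L
      if (e == 1L && utr > 0L) exStart <- 1L  # 5' UTR joins first exon
      segment <- c(segment, piece)
      cursor <- cursor + nchar(piece)
      cdsLocal <- rbind(cdsLocal, c(cdsStart, cursor))
      exEnd <- cursor
      if (e == nEx && utr > 0L) {
        segment <- c(segment, .randSeq(utr))
        cursor <- cursor + utr
        exEnd <- cursor
      }
      exLocal <- rbind(exLocal, c(exStart, exEnd))
      if (e < nEx) {
        intron <- paste0("GT", .randSeq(intronLen - 4L), "AG")
        segment <- c(segment, intron)
        cursor <- cursor + intronLen
      }
    }
    segment <- paste(segment, collapse = "")
    segLen <- nchar(segment)
    minus <- t$strand < 0L
    if (minus) {
      placed <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(segment)))
      # local (transcript-strand) interval [a,b] maps to genomic
      # [offset + segLen - b + 1, offset + segLen - a + 1] - 1-based
      toGenomic <- function(m) {
        g <- cbind(offset + segLen - m[, 2L] + 1L,
                   offset + segLen - m[, 1L] + 1L)
        g[order(g[, 1L]), , drop = FALSE]
      }
    } else {
      placed <- segment
      toGenomic <- function(m) {
        g <- cbind(offset + m[, 1L], offset + m[, 2L])
        g[order(g[, 1L]), , drop = FALSE]
      }
    }
    chromSeq[(offset + 1L):(offset + segLen)] <-
      strsplit(placed, "")[[1L]]
    exG <- toGenomic(exLocal)
    cdsG <- toGenomic(cdsLocal)
    tid <- sprintf("TX%03d", k)
    gid <- sprintf("GENE%03d", k)
    strandChar <- if (minus) "-" else "+"
    tags <- if (k == 1L) "tag=CCDS" else NULL
    gff <- c(gff,
      sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
              chrom, min(exG[, 1L]), max(exG[, 2L]), strandChar, gid, gid),
      sprintf(paste0("%s\tsim\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s;",
                     "Name=%s-001;biotype=protein_coding%s"),
              chrom, min(exG[, 1L]), max(exG[, 2L]), strandChar, tid, gid,
              gid, if (is.null(tags)) "" else paste0(";", tags)))
    for (i in seq_len(nrow(exG)))
      gff <- c(gff, sprintf("%s\tsim\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                            chrom, exG[i, 1L], exG[i, 2L], strandChar, tid))
    for (i in seq_len(nrow(cdsG)))
      gff <- c(gff, sprintf("%s\tsim\tCDS\t%d\t%d\t.\t%s\t0\tParent=%s",
                            chrom, cdsG[i, 1L], cdsG[i, 2L], strandChar,
                            tid))
    layout[[tid]] <- list(transcriptId = tid, geneId = gid,
                          chrom = chrom, strand = t$strand,
                          exons = exG, cds = cdsG,
                          cdsSeq = cds,
                          protein = paste(
                            .translateCodons(cds)[-(t$cdsLength %/% 3L)],
                            collapse = ""))
  }
  full <- paste(chromSeq, collapse = "")
  starts <- seq.int(1L, nchar(full), by = 60L)
  fasta <- paste0(">", chrom, "\n",
                  paste(substring(full, starts,
                                  pmin(starts + 59L, nchar(full))),
                        collapse = "\n"),
                  "\n")
  list(fasta = fasta, gff = paste(c(gff, ""), collapse = "\n"),
       layout = layout)
}

.vcfHeader <- function(chrom, chromLength, samples) {
  c("##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", chrom, chromLength),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

.vcfLine <- function(chrom, pos, id, ref, alt, gts) {
  paste(c(chrom, pos, id, ref, alt, ".", "PASS", ".", "GT", gts),
        collapse = "\t")
}

.pickMissenseAlt <- function(codon, baseInCodon = 2L) {
  # deterministic single-base change that alters the amino acid and does
  # not create a stop codon
  tab <- .codonTable()
  refBase <- substr(codon, baseInCodon, baseInCodon)
  for (b in c("A", "C", "G", "T")) {
    if (b == refBase) next
    cand <- codon
    substr(cand, baseInCodon, baseInCodon) <- b
    if (tab[[cand]] != "*" && tab[[cand]] != tab[[codon]])
      return(b)
  }
  stop("no missense substitution available for codon ", codon)
}

.cdsEditToVcf <- function(transcript, genome, cdsStart, cdsEnd, altCds) {
  # convert an edit expressed in spliced-CDS coordinates (CDS-strand alt
  # sequence; cdsEnd = cdsStart - 1 encodes a pure insertion after
  # cdsStart - 1) into an anchored VCF (pos, ref, alt) triple. The CDS span
  # must be genomically contiguous (single exon).
  map <- cdsGenomicMap(transcript)
  minus <- txStrand(transcript) < 0L
  if (cdsEnd >= cdsStart) {
    g <- sort(map[cdsStart:cdsEnd])
    if (length(g) > 1L && any(diff(g) != 1L))
      stop("CDS span not genomically contiguous")
    gStart <- g[1L]; gEnd <- g[length(g)]
    refG <- genomeSubseq(genome, transcript@chrom, gStart, gEnd)
    altG <- if (minus) .revcomp(altCds) else altCds
    if (nchar(altCds) == nchar(refG)) {
      list(pos = gStart, ref = refG, alt = altG)
    } else {
      # deletion or length change: anchor on the preceding genomic base
      anchor <- genomeSubseq(genome, transcript@chrom, gStart - 1L,
                             gStart - 1L)
      list(pos = gStart - 1L, ref = paste0(anchor, refG),
           alt = paste0(anchor, altG))
    }
  } else {
    # insertion after CDS position cdsEnd (= cdsStart - 1)
    insAfter <- cdsEnd
    gA <- map[insAfter]; gB <- map[insAfter + 1L]
    if (abs(gA - gB) != 1L) stop("insertion point at a splice boundary")
    gAnchor <- min(gA, gB)
    anchor <- genomeSubseq(genome, transcript@chrom, gAnchor, gAnchor)
    altIns <- if (minus) .revcomp(altCds) else altCds
    list(pos = gAnchor, ref = anchor, alt = paste0(anchor, altIns))
  }
}

#' Generate a comprehensive mutation-series VCF for one transcript
#'
#' Emits one scenario per sample covering the mutation classes used to
#' validate the pipeline: exonic SNV (het and hom-alt), multi-nucleotide
#' substitution, in-frame insertion and deletion, frameshift insertion and
#' deletion, stop gain, stop loss, variants at the first and last CDS
#' bases, an intronic SNV, and a splice-boundary-overlapping deletion (the
#' known-disagreement case for the naive whole-genome oracle). One sample
#' is haploid. All genotypes are phased; the variant is carried on phase 0.
#'
#' @param transcript a [TranscriptModel-class] from the toy reference.
#' @param genome a named [Biostrings::DNAStringSet].
#' @return list with `vcf` (character(1) VCF text) and `scenarios`
#'   (data.frame: `sample`, `type`, `gt`, `regime` — "exonic", "intronic"
#'   or "splice").
#' @export
generateMutationSeries <- function(transcript, genome) {
  refCds <- splicedCds(transcript, genome)
  L <- nchar(refCds)
  nCod <- L %/% 3L
  stopifnot(nCod >= 12L)
  codon <- function(i) substr(refCds, 3L * i - 2L, 3L * i)
  map <- cdsGenomicMap(transcript)

  specs <- list()
  addCds <- function(type, cdsStart, cdsEnd, altCds, gt = "1|0",
                     regime = "exonic") {
    v <- .cdsEditToVcf(transcript, genome, cdsStart, cdsEnd, altCds)
    specs[[length(specs) + 1L]] <<- c(v, list(type = type, gt = gt,
                                              regime = regime))
  }

  # scenario codons are allocated from genomically contiguous CDS windows
  # (an anchor base, the codon(s) and a margin must not straddle an
  # intron), so the series is valid for any random exon structure
  contiguous <- function(a, b) {
    g <- sort(map[a:b])
    all(diff(g) == 1L)
  }
  curs <- 3L
  nextCodon <- function(span = 1L) {
    cc <- curs
    repeat {
      a <- 3L * (cc - 1L) - 1L
      b <- 3L * (cc + span - 1L)
      if (b > L - 3L) stop("transcript too fragmented for mutation series")
      if (a >= 1L && contiguous(a, b)) break
      cc <- cc + 1L
    }
    curs <<- cc + span + 1L
    cc
  }

  # exonic SNV, het: 2nd base of a codon
  c1 <- nextCodon()
  addCds("snv_het", 3L * c1 - 1L, 3L * c1 - 1L,
         .pickMissenseAlt(codon(c1)))
  # same class of change, homozygous alternate
  c2 <- nextCodon()
  addCds("snv_hom", 3L * c2 - 1L, 3L * c2 - 1L,
         .pickMissenseAlt(codon(c2)), gt = "1|1")
  # multi-nucleotide substitution: first two codon bases shifted (in frame)
  c3 <- nextCodon()
  mnvAlt <- chartr("ACGT", "CATG", substr(codon(c3), 1L, 2L))
  addCds("mnv", 3L * c3 - 2L, 3L * c3 - 1L, mnvAlt)
  # in-frame insertion of one codon at a codon boundary
  c4 <- nextCodon()
  addCds("inframe_ins", 3L * (c4 - 1L) + 1L, 3L * (c4 - 1L), "GCT")
  # in-frame deletion of one codon
  c5 <- nextCodon()
  addCds("inframe_del", 3L * c5 - 2L, 3L * c5, "")
  # frameshift insertion after the first base of a codon
  c6 <- nextCodon()
  addCds("frameshift_ins", 3L * c6 - 1L, 3L * c6 - 2L, "A")
  # frameshift deletion of the first base of a codon
  c7 <- nextCodon()
  addCds("frameshift_del", 3L * c7 - 2L, 3L * c7 - 2L, "")
  # stop gain: whole codon -> TAA
  c8 <- nextCodon()
  addCds("stop_gain", 3L * c8 - 2L, 3L * c8, "TAA")
  # stop loss: middle base of the terminal stop codon -> C (TAA->TCA,
  # TGA->TCA, TAG->TCG; single-base so it cannot straddle an intron)
  addCds("stop_loss", L - 1L, L - 1L, "C")
  # first CDS base (start codon A of ATG -> G)
  addCds("first_base", 1L, 1L, "G")
  # last CDS base (3rd base of the stop codon -> C; removes the stop)
  addCds("last_base", L, L, "C")
  # haploid sample carrying an exonic SNV
  c9 <- nextCodon()
  addCds("haploid_snv", 3L * c9 - 1L, 3L * c9 - 1L,
         .pickMissenseAlt(codon(c9)), gt = "1")

  chrom <- transcript@chrom
  cr <- cdsRanges(transcript)
  if (length(cr) > 1L) {
    # intronic SNV: 5 bases past the genomically-first CDS interval end
    gIn <- IRanges::end(cr)[1L] + 5L
    refIn <- genomeSubseq(genome, chrom, gIn, gIn)
    altIn <- setdiff(c("A", "C", "G", "T"), refIn)[1L]
    specs[[length(specs) + 1L]] <- list(pos = gIn, ref = refIn,
                                        alt = altIn, type = "intronic_snv",
                                        gt = "1|0", regime = "intronic")
    # deletion spanning the exon/intron boundary: last 2 CDS bases of the
    # first interval plus 3 intronic bases
    e1 <- IRanges::end(cr)[1L]
    gStart <- e1 - 2L
    refSp <- genomeSubseq(genome, chrom, gStart, e1 + 3L)
    specs[[length(specs) + 1L]] <- list(pos = gStart, ref = refSp,
                                        alt = substr(refSp, 1L, 1L),
                                        type = "splice_del", gt = "1|0",
                                        regime = "splice")
  }

  samples <- vapply(specs, function(s) paste0("S_", s$type), character(1))
  ord <- order(vapply(specs, function(s) s$pos, numeric(1)))
  chromLen <- Biostrings::width(genome)[match(chrom, names(genome))]
  lines <- .vcfHeader(chrom, chromLen, samples)
  for (i in ord) {
    s <- specs[[i]]
    gts <- ifelse(samples == paste0("S_", s$type), s$gt,
                  ifelse(samples == "S_haploid_snv", "0", "0|0"))
    id <- if (s$type == "mnv") "." else paste0("var_", s$type)
    lines <- c(lines, .vcfLine(chrom, s$pos, id, s$ref, s$alt, gts))
  }
  scen <- data.frame(sample = samples,
                     type = vapply(specs, `[[`, character(1), "type"),
                     gt = vapply(specs, `[[`, character(1), "gt"),
                     regime = vapply(specs, `[[`, character(1), "regime"),
                     stringsAsFactors = FALSE)
  list(vcf = paste(c(lines, ""), collapse = "\n"), scenarios = scen)
}

#' Generate a phased population VCF with known ground truth
#'
#' Draws haplotype classes i.i.d. from the configured per-population
#' frequency profiles and pairs them randomly into diploids
#' (Hardy-Weinberg), emitting phased GT fields. Haplotype class 1 is the
#' reference; class k carries the first k-1 of a nested series of missense
#' SNVs on the first configured transcript, so every class yields a
#' distinct protein. The expected per-sample, per-phase CDS and protein
#' sequences are derived by direct string substitution on the transcript
#' layout — not through the main pipeline.
#'
#' @param config a [simulationConfig()].
#' @return list with `fasta`, `gff`, `vcf`, `panel` (text blobs),
#'   `transcriptId`, `truth` (list: `classes` — nSamples x 2 matrix of
#'   class indices, NA second column for haploid samples; `trueFreq` —
#'   per-population frequency vectors; `classCds` / `classProtein` —
#'   expected sequences per class; `pop` — per-sample population) and
#'   `layout`.
#' @export
generatePopulationVcf <- function(config) {
  ref <- generateToyReference(config)
  set.seed(config$seed + 1L)
  layout <- ref$layout[[1L]]
  tid <- layout$transcriptId
  cds <- layout$cdsSeq
  nCod <- nchar(cds) %/% 3L
  K <- max(vapply(config$hapFrequencies, length, integer(1)))
  stopifnot(nCod >= 10L + 2L * K)

  # nested missense SNVs at 2nd base of codons 10, 12, 14, ...
  variants <- lapply(seq_len(K - 1L), function(j) {
    cod <- 10L + 2L * (j - 1L)
    cdsPos <- 3L * (cod - 1L) + 2L
    codon <- substr(cds, 3L * cod - 2L, 3L * cod)
    alt <- .pickMissenseAlt(codon)
    list(cdsPos = cdsPos, ref = substr(cds, cdsPos, cdsPos), alt = alt)
  })

  # expected sequences per class by direct substitution
  classCds <- vapply(seq_len(K), function(k) {
    s <- cds
    for (j in seq_len(k - 1L))
      substr(s, variants[[j]]$cdsPos, variants[[j]]$cdsPos) <-
        variants[[j]]$alt
    s
  }, character(1))
  classProtein <- vapply(classCds, function(s) {
    aa <- .translateCodons(s)
    paste(aa[-length(aa)], collapse = "")
  }, character(1), USE.NAMES = FALSE)

  pops <- names(config$hapFrequencies)
  n <- config$nSamples
  samples <- sprintf("SAMP%04d", seq_len(n))
  pop <- rep(pops, length.out = n)[order(rep(seq_along(pops),
                                             length.out = n))]
  pop <- rep(pops, times = diff(round(seq(0, n, length.out =
                                            length(pops) + 1L))))
  nHap <- max(0L, min(n, round(config$fractionHaploid * n)))
  haploid <- seq_len(n) <= nHap

  classes <- matrix(NA_integer_, nrow = n, ncol = 2L)
  for (i in seq_len(n)) {
    f <- config$hapFrequencies[[pop[i]]]
    draws <- sample.int(length(f), if (haploid[i]) 1L else 2L,
                        replace = TRUE, prob = f)
    classes[i, seq_along(draws)] <- draws
  }

  # VCF records: one per nested variant, in genomic order
  tx <- TranscriptModel(tid, layout$geneId, chrom = layout$chrom,
                        strand = layout$strand,
                        exons = IRanges::IRanges(layout$exons[, 1L],
                                                 layout$exons[, 2L]),
                        cds = IRanges::IRanges(layout$cds[, 1L],
                                               layout$cds[, 2L]))
  genome <- loadReferenceText(ref$fasta)
  recs <- lapply(seq_along(variants), function(j) {
    v <- variants[[j]]
    vc <- .cdsEditToVcf(tx, genome, v$cdsPos, v$cdsPos, v$alt)
    vc$id <- sprintf("rsSIM%04d", j)
    vc$j <- j
    vc
  })
  recs <- recs[order(vapply(recs, `[[`, numeric(1), "pos"))]

  chromLen <- Biostrings::width(genome)[1L]
  lines <- .vcfHeader(layout$chrom, chromLen, samples)
  for (r in recs) {
    carries <- function(cl) !is.na(cl) && cl - 1L >= r$j
    gts <- vapply(seq_len(n), function(i) {
      a0 <- as.integer(carries(classes[i, 1L]))
      if (haploid[i]) as.character(a0)
      else paste0(a0, "|", as.integer(carries(classes[i, 2L])))
    }, character(1))
    lines <- c(lines, .vcfLine(layout$chrom, r$pos, r$id, r$ref, r$alt,
                               gts))
  }

  panel <- paste(c("sample\tpop\tsuper_pop\tgender",
                   paste(samples, pop, sub("^POP", "SUP", pop),
                         ifelse(haploid, "male", "female"), sep = "\t"),
                   ""), collapse = "\n")
  list(fasta = ref$fasta, gff = ref$gff,
       vcf = paste(c(lines, ""), collapse = "\n"),
       panel = panel, transcriptId = tid,
       truth = list(classes = classes,
                    trueFreq = config$hapFrequencies,
                    classCds = unname(classCds),
                    classProtein = classProtein,
                    pop = pop, haploid = haploid, samples = samples),
       layout = ref$layout)
}

#' Load a reference genome from FASTA text
#'
#' Convenience wrapper around [loadReference()] for in-memory FASTA text,
#' as produced by the synthetic generators.
#'
#' @param fastaText character FASTA content.
#' @return A named [Biostrings::DNAStringSet].
#' @export
loadReferenceText <- function(fastaText) {
  tf <- tempfile(fileext = ".fa")
  on.exit(unlink(tf))
  writeLines(fastaText, tf)
  loadReference(tf)
}
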