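.revcomp <- function(x) {
  if (!nchar(x)) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

.codonTable <- function() {
  # standard genetic code (table 1), from Biostrings
  tab <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(tab), names(tab))
}

.translateCodons <- function(seq) {
  # character vector of amino acids, one per complete codon; "X" for codons
  # containing ambiguity characters
  n <- nchar(seq) %/% 3L
  if (n == 0L) return(character())
  starts <- seq.int(1L, by = 3L, length.out = n)
  codons <- substring(seq, starts, starts + 2L)
  aa <- .codonTable()[codons]
  aa[is.na(aa)] <- "X"
  unname(aa)
}

#' Project a VCF variant allele into spliced CDS coordinates
#'
#' Trims shared flanking bases between the VCF REF and ALT alleles (so the
#' anchored-indel VCF convention does not leak an exonic/intronic
#' misclassification), verifies the REF allele against the reference
#' genome, and maps the trimmed reference span into spliced CDS
#' coordinates. A variant is applied only if its trimmed reference span
#' lies wholly inside CDS exonic bases; anything touching intronic, splice
#' or UTR bases is skipped with a reason. On minus-strand transcripts the
#' alleles are reverse-complemented and the coordinates flipped into the
#' CDS frame.
#'
#' @param transcript a [TranscriptModel-class].
#' @param genome a named [Biostrings::DNAStringSet].
#' @param record a variant record (list with `chrom`, `pos`, `id`, `ref`,
#'   `alts`), as produced by [fetchGenotypes()].
#' @param altIndex which ALT allele (1-based) to project.
#' @return A `CdsEdit`: list with `cdsStart`, `cdsEnd` (1-based inclusive;
#'   `cdsEnd = cdsStart - 1` for a pure insertion before `cdsStart`),
#'   `ref`, `alt` (CDS-strand sequences), `variantId`, `pos` (genomic) and
#'   `skip = NA`. When skipped, a list with `skip` set to the reason
#'   ("intronic", "splice" or "outside").
#' @export
projectVariant <- function(transcript, genome, record, altIndex = 1L) {
  ref <- record$ref
  alt <- record$alts[[altIndex]]
  genomicRef <- genomeSubseq(genome, record$chrom, record$pos,
                             record$pos + nchar(ref) - 1L)
  if (!identical(genomicRef, toupper(ref)))
    stop("VCF REF allele '", ref, "' at ", record$chrom, ":", record$pos,
         " does not match the reference genome ('", genomicRef, "')")

  # trim shared prefix, then shared suffix
  p <- 0L
  while (p < nchar(ref) && p < nchar(alt) &&
         substr(ref, p + 1L, p + 1L) == substr(alt, p + 1L, p + 1L))
    p <- p + 1L
  r2 <- substr(ref, p + 1L, nchar(ref))
  a2 <- substr(alt, p + 1L, nchar(alt))
  s <- 0L
  while (s < nchar(r2) && s < nchar(a2) &&
         substr(r2, nchar(r2) - s, nchar(r2) - s) ==
         substr(a2, nchar(a2) - s, nchar(a2) - s))
    s <- s + 1L
  trimRef <- substr(r2, 1L, nchar(r2) - s)
  trimAlt <- substr(a2, 1L, nchar(a2) - s)
  gStart <- record$pos + p

  skipOut <- function(reason)
    list(skip = reason, variantId = record$id, pos = record$pos,
         ref = ref, alt = alt)

  minus <- txStrand(transcript) < 0L
  if (nchar(trimRef) > 0L) {
    gEnd <- gStart + nchar(trimRef) - 1L
    cc <- genomicToCds(transcript, gStart, gEnd)
    if (cc$status != "coding") return(skipOut(cc$status))
    cdsStart <- cc$start; cdsEnd <- cc$end
    # a multi-base span must also be contiguous in CDS space
    if (cdsEnd - cdsStart != gEnd - gStart) return(skipOut("splice"))
    edRef <- if (minus) .revcomp(trimRef) else trimRef
    edAlt <- if (minus) .revcomp(trimAlt) else trimAlt
  } else {
    # pure insertion after genomic position gStart - 1
    g0 <- gStart - 1L
    c0 <- genomicToCds(transcript, g0)
    c1 <- genomicToCds(transcript, g0 + 1L)
    if (c0$status != "coding" || c1$status != "coding")
      return(skipOut(if (c0$status == "intronic" ||
                         c1$status == "intronic") "intronic" else "splice"))
    if (abs(c1$start - c0$start) != 1L) return(skipOut("splice"))
    insAfter <- min(c0$start, c1$start)
    cdsStart <- insAfter + 1L
    cdsEnd <- insAfter
    edRef <- ""
    edAlt <- if (minus) .revcomp(trimAlt) else trimAlt
  }
  list(cdsStart = cdsStart, cdsEnd = cdsEnd, ref = edRef, alt = edAlt,
       variantId = record$id, pos = record$pos, skip = NA_character_)
}

#' Apply CDS edits in 3'-to-5' order
#'
#' Splices each edit's `alt` sequence over its reference-CDS interval.
#' Edits are sorted by descending `cdsStart` internally, so insertions and
#' deletions never shift the coordinates of edits still to be applied; the
#' result is independent of input order. Edits must be pairwise
#' non-overlapping (resolved upstream by [splitPhases()]).
#'
#' @param referenceCds character(1) reference spliced CDS.
#' @param edits list of `CdsEdit`s from [projectVariant()].
#' @return character(1) edited CDS sequence.
#' @export
applyEdits <- function(referenceCds, edits) {
  if (!length(edits)) return(referenceCds)
  starts <- vapply(edits, `[[`, numeric(1), "cdsStart")
  ends <- vapply(edits, `[[`, numeric(1), "cdsEnd")
  ord <- order(starts)
  if (any(starts[ord][-1L] <= ends[ord][-length(ord)]))
    stop("overlapping edits in CDS coordinates")
  seq <- referenceCds
  n0 <- nchar(referenceCds)
  for (e in rev(lapply(ord, function(i) edits[[i]]))) {
    if (e$cdsStart < 1L || e$cdsEnd > n0)
      stop("edit outside the reference CDS")
    obs <- substr(referenceCds, e$cdsStart, e$cdsEnd)
    if (e$cdsEnd >= e$cdsStart && !identical(obs, e$ref))
      stop("edit ref '", e$ref, "' does not match reference CDS ('",
           obs, "') at [", e$cdsStart, ",", e$cdsEnd, "]")
    seq <- paste0(substr(seq, 1L, e$cdsStart - 1L), e$alt,
                  substring(seq, e$cdsEnd + 1L))
  }
  seq
}

#' Translate a CDS haplotype in silico
#'
#' Standard genetic-code (table 1) translation from position 1, stopping at
#' the first stop codon. A stop that is not the final complete codon of the
#' sequence is premature and is retained as a final "*" residue (so a stop
#' gain renders as e.g. "577R>*"); a terminal stop — the reference's own,
#' or the natural terminus after an in-frame indel — is never included.
#' A trailing incomplete codon is ignored and flagged.
#'
#' @param sequence character(1) nucleotide sequence, length >= 3.
#' @param referenceProteinLength reference protein length in residues
#'   (excluding the terminal stop); used to flag stop changes. `NULL` for
#'   translating a reference CDS.
#' @return list with `protein` (character(1)) and `flags` (character
#'   vector; possibly "incomplete_cds", "contains_stop_change").
#' @export
translateCds <- function(sequence, referenceProteinLength = NULL) {
  if (nchar(sequence) < 3L)
    stop("sequence must be at least one codon long")
  flags <- character()
  if (nchar(sequence) %% 3L != 0L) flags <- c(flags, "incomplete_cds")
  aa <- .translateCodons(sequence)
  nCodon <- length(aa)
  stop1 <- match("*", aa)
  if (is.na(stop1)) {
    protein <- paste(aa, collapse = "")
    if (!is.null(referenceProteinLength))
      flags <- c(flags, "contains_stop_change")  # stop lost, none regained
  } else if (stop1 == nCodon) {
    protein <- paste(aa[-nCodon], collapse = "")
    if (!is.null(referenceProteinLength) &&
        stop1 > referenceProteinLength + 1L)
      flags <- c(flags, "contains_stop_change")  # stop-loss extension
  } else {
    protein <- paste(aa[seq_len(stop1)], collapse = "")  # keeps "*"
    if (!is.null(referenceProteinLength))
      flags <- c(flags, "contains_stop_change")  # premature stop
  }
  if (!nzchar(protein)) {
    # stop codon in first position: represent as bare "*"
    protein <- "*"
  }
  list(protein = protein, flags = unique(flags))
}

#' Build per-phase CDS and protein haplotypes for one sample
#'
#' Projects the sample's phased non-reference alleles into CDS space,
#' applies them 3'-to-5' to the reference CDS and translates. One
#' (CDS, protein) pair is produced per phase: two for diploid samples, one
#' for haploid (male X/Y) samples. Variants falling in introns, splice
#' regions or UTRs are skipped and recorded. When `name = TRUE` the
#' haplotypes are re-aligned to the reference and named (see
#' [callDiffs()]).
#'
#' @param transcript a [TranscriptModel-class].
#' @param genome a named [Biostrings::DNAStringSet].
#' @param sampleAlleles one element of the [splitPhases()] result.
#' @param name compute diffs and HGVS-like names (default TRUE).
#' @param scoring alignment scoring from [alignmentScoring()].
#' @return list with one element per phase, each a list with `cds` and
#'   `protein` ([SequenceHaplotype-class] objects), `edits` (applied
#'   `CdsEdit`s) and `skipped` (skip records).
#' @export
buildSampleHaplotypes <- function(transcript, genome, sampleAlleles,
                                  name = TRUE,
                                  scoring = alignmentScoring()) {
  refCds <- splicedCds(transcript, genome)
  refTrans <- translateCds(refCds)
  refProtLen <- nchar(refTrans$protein)
  lapply(seq_along(sampleAlleles$phases), function(ph) {
    entries <- sampleAlleles$phases[[ph]]
    edits <- list()
    skipped <- list()
    for (e in entries) {
      pr <- projectVariant(transcript, genome, e$record, e$altIndex)
      if (is.na(pr$skip)) edits <- c(edits, list(pr))
      else skipped <- c(skipped, list(pr))
    }
    cdsSeq <- applyEdits(refCds, edits)
    tr <- translateCds(cdsSeq, refProtLen)
    flags <- tr$flags
    if (any(vapply(edits, function(e)
      nchar(e$ref) != nchar(e$alt), logical(1))))
      flags <- union(flags, "contains_indel")
    protFlags <- flags
    if (identical(tr$protein, refTrans$protein))
      protFlags <- union(protFlags, "is_reference")
    cdsFlags <- flags
    if (identical(cdsSeq, refCds))
      cdsFlags <- union(cdsFlags, "is_reference")
    cdsHap <- .makeHaplotype(transcript, "cds", cdsSeq, refCds,
                             edits, cdsFlags,
                             sampleAlleles$sampleId, ph - 1L,
                             name = name, scoring = scoring)
    protHap <- .makeHaplotype(transcript, "protein", tr$protein,
                              refTrans$protein, edits, protFlags,
                              sampleAlleles$sampleId, ph - 1L,
                              name = name, scoring = scoring)
    list(cds = cdsHap, protein = protHap, edits = edits, skipped = skipped)
  })
}

.makeHaplotype <- function(transcript, type, sequence, refSequence, edits,
                           flags, sampleId, phase, name = TRUE,
                           scoring = alignmentScoring()) {
  display <- displayName(transcript)
  if (name) {
    if (identical(sequence, refSequence)) {
      diffs <- .emptyDiffs()
      hapName <- haplotypeName(display, diffs)
    } else {
      aln <- globalAlign(refSequence, sequence, scoring)
      diffs <- callDiffs(aln)
      diffs <- assignVariantIds(diffs, edits, type = type)
      hapName <- haplotypeName(display, diffs)
    }
  } else {
    diffs <- .emptyDiffs()
    hapName <- NA_character_
  }
  new("SequenceHaplotype", transcriptId = txId(transcript), type = type,
      sequence = sequence, diffs = diffs, name = hapName,
      flags = sort(unique(flags)), sampleId = sampleId,
      phase = as.integer(phase))
}
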