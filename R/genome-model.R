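#' @importFrom Biostrings readDNAStringSet DNAStringSet DNAString
#'   reverseComplement GENETIC_CODE
#' @importFrom rtracklayer import
NULL

#' Construct a transcript model
#'
#' @param transcriptId,geneId,displayName,chrom identifiers; `displayName`
#'   defaults to `transcriptId`.
#' @param strand +1 or -1 (also accepts "+"/"-").
#' @param exons,cds [IRanges::IRanges] of 1-based inclusive genomic
#'   intervals; stored sorted in ascending genomic order.
#' @param tags character vector of annotation tags ("CCDS", "merged", ...).
#' @param biotype transcript biotype, default "protein_coding".
#' @param flags QC flags; "incomplete_cds" is added automatically when the
#'   total CDS length is not a multiple of 3.
#' @return A [TranscriptModel-class] object.
#' @export
#' @examples
#' TranscriptModel("t1", "g1", chrom = "chr1", strand = 1L,
#'                 exons = IRanges::IRanges(1, 9),
#'                 cds = IRanges::IRanges(1, 9))
TranscriptModel <- function(transcriptId, geneId,
                            displayName = transcriptId,
                            chrom, strand, exons, cds,
                            tags = character(), biotype = "protein_coding",
                            flags = character()) {
  if (is.character(strand))
    strand <- ifelse(strand == "-", -1L, 1L)
  strand <- as.integer(strand)
  exons <- exons[order(IRanges::start(exons))]
  cds <- cds[order(IRanges::start(cds))]
  if (sum(IRanges::width(cds)) %% 3L != 0L)
    flags <- union(flags, "incomplete_cds")
  new("TranscriptModel", transcriptId = transcriptId, geneId = geneId,
      displayName = displayName, chrom = chrom, strand = strand,
      exons = exons, cds = cds, tags = tags, biotype = biotype,
      flags = flags)
}

#' Construct a gene model
#'
#' @param geneId gene identifier.
#' @param symbol gene symbol; defaults to `geneId`.
#' @param transcripts list of [TranscriptModel-class] objects.
#' @return A [GeneModel-class] object.
#' @export
GeneModel <- function(geneId, symbol = geneId, transcripts) {
  new("GeneModel", geneId = geneId, symbol = symbol,
      transcripts = transcripts)
}

#' Load a reference genome from FASTA
#'
#' Reads a (possibly line-wrapped, multi-record) FASTA file into a named
#' [Biostrings::DNAStringSet], upper-casing all sequence. Record names are
#' truncated at the first whitespace, the usual FASTA identifier convention.
#'
#' @param fastaPath path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet], one entry per chromosome.
#' @export
loadReference <- function(fastaPath) {
  if (!file.exists(fastaPath))
    stop("FASTA file not found: ", fastaPath)
  dna <- Biostrings::readDNAStringSet(fastaPath)
  names(dna) <- sub("\\s.*$", "", names(dna))
  if (anyDuplicated(names(dna)))
    stop("duplicate record names in FASTA: ",
         paste(unique(names(dna)[duplicated(names(dna))]), collapse = ", "))
  if (any(Biostrings::width(dna) == 0L))
    stop("empty sequence in FASTA")
  dna <- Biostrings::DNAStringSet(toupper(as.character(dna)))
  dna
}

#' Fetch a 1-based inclusive genomic subsequence
#'
#' @param genome a named [Biostrings::DNAStringSet] from [loadReference()].
#' @param chrom chromosome name.
#' @param start,end 1-based inclusive interval.
#' @return character(1) subsequence.
#' @export
genomeSubseq <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome))
    stop("chromosome not in genome: ", chrom)
  len <- Biostrings::width(genome)[match(chrom, names(genome))]
  if (start < 1L || end > len || start > end)
    stop("interval [", start, ",", end, "] out of bounds for ", chrom)
  as.character(Biostrings::subseq(genome[[chrom]], start, end))
}

#' Load gene and transcript models from GFF3 or GTF
#'
#' Reads Ensembl-style gene annotation (via [rtracklayer::import]) with
#' gene, mRNA/transcript, exon and CDS features linked by `Parent` (GFF3)
#' or `gene_id`/`transcript_id` (GTF) attributes; the dialect is detected
#' from the file extension with a content fallback. Exon and CDS intervals
#' are stored sorted in ascending genomic order; annotation tags
#' (`tag=CCDS`, `tag=merged`, or a `ccds_id` attribute) are captured for
#' canonical-transcript selection. Transcripts whose total CDS length is
#' not a multiple of 3 are flagged "incomplete_cds" (with a warning) rather
#' than rejected.
#'
#' @param gffPath path to a GFF3 or GTF file.
#' @return Named list of [GeneModel-class] objects, keyed by gene id.
#' @export
loadGeneModels <- function(gffPath) {
  if (!file.exists(gffPath))
    stop("annotation file not found: ", gffPath)
  fmt <- if (grepl("\\.gtf(\\.gz)?$", gffPath, ignore.case = TRUE)) "gtf"
         else if (grepl("\\.gff3?(\\.gz)?$", gffPath, ignore.case = TRUE))
           "gff3"
         else {
    head <- readLines(gffPath, n = 50L)
    if (any(grepl("\t[^\t]*=[^\t]*$", head))) "gff3" else "gtf"
  }
  gr <- rtracklayer::import(gffPath, format = fmt)
  mc <- S4Vectors::mcols(gr)
  getcol <- function(i, keys) {
    for (k in keys) {
      if (!k %in% colnames(mc)) next
      v <- mc[[k]][i]
      if (methods::is(v, "List") || is.list(v)) v <- unlist(v)
      if (length(v) && !all(is.na(v))) return(as.character(v))
    }
    NA_character_
  }
  stripPrefix <- function(x) sub("^(gene|transcript):", "", x)
  type <- as.character(mc$type)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  strand <- as.character(GenomicRanges::strand(gr))
  starts <- IRanges::start(gr)
  ends <- IRanges::end(gr)

  geneInfo <- list()
  for (i in which(type == "gene")) {
    gid <- stripPrefix(getcol(i, c("ID", "gene_id"))[1L])
    geneInfo[[gid]] <- list(symbol = getcol(i, c("Name", "gene_name"))[1L])
  }

  txMeta <- list()
  for (i in which(type %in% c("mRNA", "transcript"))) {
    tid <- stripPrefix(getcol(i, c("ID", "transcript_id"))[1L])
    if (is.na(tid)) stop("transcript feature without an identifier")
    gid <- stripPrefix(getcol(i, c("Parent", "gene_id"))[1L])
    tags <- getcol(i, "tag")
    tags <- if (all(is.na(tags))) character()
            else unlist(strsplit(tags, ",", fixed = TRUE))
    if (!is.na(getcol(i, "ccds_id")[1L])) tags <- union(tags, "CCDS")
    txMeta[[tid]] <- list(
      geneId = gid,
      displayName = getcol(i, c("Name", "transcript_name"))[1L],
      chrom = chrom[i], strand = strand[i],
      biotype = getcol(i, c("biotype", "transcript_biotype",
                            "transcript_type"))[1L],
      tags = tags)
  }

  collect <- function(rows, what) {
    out <- list()
    for (i in rows) {
      tid <- stripPrefix(getcol(i, c("Parent", "transcript_id"))[1L])
      if (is.na(tid) || is.null(txMeta[[tid]]))
        stop(what, " feature with no parent transcript at ",
             chrom[i], ":", starts[i])
      out[[tid]] <- rbind(out[[tid]], c(starts[i], ends[i]))
    }
    out
  }
  exonsBy <- collect(which(type == "exon"), "exon")
  cdsBy <- collect(which(type == "CDS"), "CDS")

  genes <- list()
  for (tid in names(txMeta)) {
    meta <- txMeta[[tid]]
    exm <- exonsBy[[tid]]
    cdm <- cdsBy[[tid]]
    if (is.null(cdm)) next  # non-coding transcript: not modelled
    if (is.null(exm)) exm <- cdm
    ord <- order(exm[, 1L]); exm <- exm[ord, , drop = FALSE]
    ord <- order(cdm[, 1L]); cdm <- cdm[ord, , drop = FALSE]
    if (nrow(cdm) > 1L && any(cdm[-1L, 1L] <= cdm[-nrow(cdm), 2L]))
      stop("overlapping CDS intervals in transcript ", tid)
    exons <- IRanges::IRanges(exm[, 1L], exm[, 2L])
    cds <- IRanges::IRanges(cdm[, 1L], cdm[, 2L])
    within <- IRanges::findOverlaps(cds, exons, type = "within")
    if (length(unique(S4Vectors::queryHits(within))) < length(cds))
      stop("CDS interval outside all exons in transcript ", tid)
    flags <- character()
    if (sum(IRanges::width(cds)) %% 3L != 0L) {
      warning("transcript ", tid, " CDS length not a multiple of 3; ",
              "flagged incomplete_cds")
      flags <- "incomplete_cds"
    }
    gid <- if (is.na(meta$geneId)) paste0(tid, "_gene") else meta$geneId
    tx <- TranscriptModel(
      transcriptId = tid, geneId = gid,
      displayName = if (is.na(meta$displayName)) tid else meta$displayName,
      chrom = meta$chrom, strand = meta$strand,
      exons = exons, cds = cds, tags = meta$tags,
      biotype = if (is.na(meta$biotype)) "protein_coding" else meta$biotype,
      flags = flags)
    genes[[gid]] <- c(genes[[gid]], list(tx))
  }
  if (!length(genes)) stop("no coding transcripts found in ", gffPath)
  out <- lapply(names(genes), function(gid) {
    sym <- geneInfo[[gid]]$symbol
    GeneModel(geneId = gid,
              symbol = if (is.null(sym) || is.na(sym)) gid else sym,
              transcripts = genes[[gid]])
  })
  stats::setNames(out, names(genes))
}

#' Genomic positions of CDS bases, in transcript (5'->3') order
#'
#' The per-base genomic -> CDS map: element `k` is the genomic position of
#' CDS base `k`. For minus-strand transcripts the vector descends.
#'
#' @param transcript a [TranscriptModel-class].
#' @return integer vector of genomic positions, length = CDS length.
#' @export
cdsGenomicMap <- function(transcript) {
  r <- cdsRanges(transcript)
  pos <- unlist(lapply(seq_along(r), function(i)
    seq.int(IRanges::start(r)[i], IRanges::end(r)[i])), use.names = FALSE)
  if (txStrand(transcript) < 0L) pos <- rev(pos)
  pos
}

#' Extract the spliced CDS of a transcript
#'
#' Concatenates the CDS interval subsequences in genomic order and
#' reverse-complements for minus-strand transcripts, so the result reads
#' 5'->3' in transcript orientation (begins with the start codon for a
#' complete CDS).
#'
#' @param transcript a [TranscriptModel-class].
#' @param genome a named [Biostrings::DNAStringSet].
#' @return character(1) nucleotide sequence.
#' @export
splicedCds <- function(transcript, genome) {
  r <- cdsRanges(transcript)
  pieces <- vapply(seq_along(r), function(i)
    genomeSubseq(genome, transcript@chrom,
                 IRanges::start(r)[i], IRanges::end(r)[i]), character(1))
  seq <- paste(pieces, collapse = "")
  if (txStrand(transcript) < 0L)
    seq <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  seq
}

#' Project a genomic interval into spliced CDS coordinates
#'
#' Returns the CDS-frame interval when the genomic interval lies entirely
#' within the transcript's CDS intervals, or a non-coding marker otherwise.
#' On the minus strand the mapping reverses orientation, so the genomic end
#' maps to the smaller CDS position.
#'
#' @param transcript a [TranscriptModel-class].
#' @param start,end 1-based inclusive genomic interval (on the transcript's
#'   chromosome).
#' @return A list with `status` ("coding", "intronic", "splice" or
#'   "outside") and, when coding, integer `start` and `end` in 1-based
#'   spliced CDS coordinates.
#' @export
genomicToCds <- function(transcript, start, end = start) {
  stopifnot(start <= end)
  map <- cdsGenomicMap(transcript)
  idx <- match(seq.int(start, end), map)
  if (!anyNA(idx))
    return(list(status = "coding",
                start = min(idx), end = max(idx)))
  nc <- list(start = NA_integer_, end = NA_integer_)
  if (any(!is.na(idx)))  # partially coding: touches a CDS/intron or
    return(c(list(status = "splice"), nc))  # CDS/UTR boundary
  ex <- exonRanges(transcript)
  spanStart <- min(IRanges::start(ex)); spanEnd <- max(IRanges::end(ex))
  if (end < spanStart || start > spanEnd)
    return(c(list(status = "outside"), nc))
  inExon <- IRanges::overlapsAny(IRanges::IRanges(start, end), ex)
  if (!inExon && start > spanStart && end < spanEnd)
    return(c(list(status = "intronic"), nc))
  # UTR-only, crosses the transcript boundary, or spans a UTR/intron edge
  c(list(status = "outside"), nc)
}

.translationLength <- function(transcript, genome) {
  # length of translation up to (excluding) first stop; Inf-penalised info
  seq <- splicedCds(transcript, genome)
  aa <- .translateCodons(seq)
  stop1 <- match("*", aa)
  list(len = if (is.na(stop1)) length(aa) else stop1 - 1L,
       internalStop = !is.na(stop1) && stop1 < length(aa))
}

#' Select the canonical transcript of a gene
#'
#' Applies a three-tier hierarchy: (1) the longest CCDS-tagged translation
#' with no internal stop codons; (2) the longest Ensembl/Havana-merged
#' translation with no internal stop codons; (3) the longest translation
#' with no internal stop codons. If no transcript qualifies under any tier
#' (every translation has an internal stop), the longest translation is
#' returned. Ties are broken by lexicographic transcript id.
#'
#' @param gene a [GeneModel-class].
#' @param genome a named [Biostrings::DNAStringSet].
#' @return The canonical [TranscriptModel-class].
#' @export
selectCanonical <- function(gene, genome) {
  txs <- gene@transcripts
  coding <- vapply(txs, function(t) t@biotype == "protein_coding",
                   logical(1))
  txs <- txs[coding]
  if (!length(txs))
    stop("gene ", gene@geneId, " has no protein-coding transcript")
  info <- lapply(txs, .translationLength, genome = genome)
  len <- vapply(info, `[[`, numeric(1), "len")
  clean <- !vapply(info, `[[`, logical(1), "internalStop")
  ids <- vapply(txs, txId, character(1))
  hasTag <- function(tag) vapply(txs, function(t) tag %in% t@tags,
                                 logical(1))
  pick <- function(cand) {
    if (!any(cand)) return(NA_integer_)
    best <- which(cand & len == max(len[cand]))
    best[order(ids[best])][1L]
  }
  sel <- pick(hasTag("CCDS") & clean)
  if (is.na(sel)) sel <- pick(hasTag("merged") & clean)
  if (is.na(sel)) sel <- pick(clean)
  if (is.na(sel)) sel <- pick(rep(TRUE, length(txs)))
  txs[[sel]]
}
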