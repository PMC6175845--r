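#' Independent whole-genome editing oracle
#'
#' Computes the protein haplotype of one sample and phase by a deliberately
#' different route from the main pipeline: the phase's VCF alleles are
#' applied directly to the whole genomic sequence, every downstream
#' annotation coordinate is shifted by the net indel length (naively, with
#' no regard for splice-site integrity — coordinates falling inside a
#' replaced span are clamped to it), the shifted CDS intervals are then
#' re-spliced from the edited chromosome, reverse-complemented for
#' minus-strand transcripts and translated. The function parses FASTA, GFF
#' and VCF with its own minimal readers and shares no computation with the
#' haplotype-construction code, so agreement between the two routes is an
#' end-to-end check of variant projection, 3'-to-5' editing and
#' translation.
#'
#' Because annotation coordinates are shifted without considering splice
#' sites, variants overlapping intron or splice-region bases are applied
#' naively here while the main pipeline skips them: those scenarios form a
#' known, expected disagreement set.
#'
#' @param fastaPath,gffPath,vcfPath input file paths.
#' @param transcriptId transcript to reconstruct.
#' @param sample sample identifier in the VCF.
#' @param phase 0-based phase index (0 for haploid samples).
#' @return character(1) protein sequence, with a premature stop retained as
#'   a final "*" (a terminal stop is dropped), as in the main pipeline's
#'   convention.
#' @export
oracleHaplotypes <- function(fastaPath, gffPath, vcfPath, transcriptId,
                             sample, phase = 0L) {
  # --- FASTA: minimal reader -------------------------------------------
  fl <- readLines(fastaPath)
  headers <- grep("^>", fl)
  stopifnot(length(headers) >= 1L)
  seqs <- list()
  bounds <- c(headers, length(fl) + 1L)
  for (i in seq_along(headers)) {
    nm <- sub("^>(\\S+).*$", "\\1", fl[headers[i]])
    body <- fl[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    seqs[[nm]] <- toupper(paste(body, collapse = ""))
  }

  # --- GFF: CDS rows of the transcript ---------------------------------
  gl <- readLines(gffPath)
  gl <- gl[!startsWith(gl, "#") & nzchar(gl)]
  parts <- strsplit(gl, "\t", fixed = TRUE)
  cdsRows <- Filter(function(p) {
    p[3L] == "CDS" && grepl(paste0("Parent=(transcript:)?", transcriptId,
                                   "(;|$)"), p[9L])
  }, parts)
  stopifnot(length(cdsRows) >= 1L)
  chrom <- cdsRows[[1L]][1L]
  strand <- cdsRows[[1L]][7L]
  ivs <- do.call(rbind, lapply(cdsRows, function(p)
    c(as.integer(p[4L]), as.integer(p[5L]))))
  ivs <- ivs[order(ivs[, 1L]), , drop = FALSE]

  # --- VCF: this sample's alleles on the requested phase ----------------
  vl <- readLines(vcfPath)
  hdr <- vl[startsWith(vl, "#CHROM")]
  stopifnot(length(hdr) == 1L)
  cols <- strsplit(hdr, "\t", fixed = TRUE)[[1L]]
  sampleCol <- match(sample, cols)
  if (is.na(sampleCol)) stop("sample not in VCF: ", sample)
  body <- vl[!startsWith(vl, "#") & nzchar(vl)]
  edits <- list()
  for (line in body) {
    p <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (p[1L] != chrom) next
    fmt <- strsplit(p[9L], ":", fixed = TRUE)[[1L]]
    gtIdx <- match("GT", fmt)
    gt <- strsplit(p[sampleCol], ":", fixed = TRUE)[[1L]][gtIdx]
    alleles <- strsplit(gt, "[|/]")[[1L]]
    if (phase + 1L > length(alleles)) next
    ai <- suppressWarnings(as.integer(alleles[phase + 1L]))
    if (is.na(ai) || ai == 0L) next
    alts <- strsplit(p[5L], ",", fixed = TRUE)[[1L]]
    edits[[length(edits) + 1L]] <- list(pos = as.integer(p[2L]),
                                        ref = p[4L], alt = alts[ai])
  }

  # --- apply edits to the chromosome, shifting annotation ---------------
  chromSeq <- seqs[[chrom]]
  if (is.null(chromSeq)) stop("chromosome not in FASTA: ", chrom)
  if (length(edits) > 1L) {
    pos <- vapply(edits, `[[`, numeric(1), "pos")
    endp <- pos + vapply(edits, function(e) nchar(e$ref), numeric(1)) - 1L
    ord <- order(pos)
    if (any(pos[ord][-1L] <= endp[ord][-length(ord)]))
      stop("overlapping edits on one phase")
    edits <- lapply(rev(ord), function(i) edits[[i]])
  }
  for (e in edits) {
    p <- e$pos
    r <- nchar(e$ref)
    a <- nchar(e$alt)
    stopifnot(substr(chromSeq, p, p + r - 1L) == toupper(e$ref))
    chromSeq <- paste0(substr(chromSeq, 1L, p - 1L), e$alt,
                       substring(chromSeq, p + r))
    delta <- a - r
    shift <- function(c) {
      if (c < p) c
      else if (c > p + r - 1L) c + delta
      else p + min(c - p, a - 1L)  # inside the replaced span: clamp
    }
    ivs <- t(apply(ivs, 1L, function(iv)
      c(shift(iv[1L]), shift(iv[2L]))))
  }

  # --- re-splice, orient, translate ------------------------------------
  pieces <- apply(ivs, 1L, function(iv)
    substr(chromSeq, iv[1L], iv[2L]))
  cdsSeq <- paste(pieces, collapse = "")
  if (strand == "-")
    cdsSeq <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(cdsSeq)))

  tab <- Biostrings::GENETIC_CODE
  nCodon <- nchar(cdsSeq) %/% 3L
  if (nCodon == 0L) stop("edited CDS shorter than one codon")
  aaStarts <- seq.int(1L, by = 3L, length.out = nCodon)
  aa <- unname(tab[substring(cdsSeq, aaStarts, aaStarts + 2L)])
  aa[is.na(aa)] <- "X"
  stop1 <- match("*", aa)
  if (is.na(stop1)) paste(aa, collapse = "")
  else if (stop1 == nCodon) paste(aa[-nCodon], collapse = "")
  else paste(aa[seq_len(stop1)], collapse = "")
}
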