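#' @importFrom VariantAnnotation readVcf alt ref geno
#' @importFrom GenomicRanges GRanges seqnames
#' @importFrom SummarizedExperiment rowRanges
NULL

#' Fetch genotypes overlapping a genomic region from a VCF
#'
#' Reads a VCF 4.x file (plain or bgzipped) and returns the records whose
#' reference span intersects the region spanned by a transcript's exons,
#' together with each sample's GT string. Sample order follows the VCF
#' header. Only the GT subfield is used.
#'
#' @param vcfPath path to a VCF file.
#' @param chrom chromosome name.
#' @param start,end 1-based inclusive region bounds.
#' @return A list with `records` (list of per-record lists: `chrom`, `pos`,
#'   `id`, `ref`, `alts` (character vector), `gt` (named character vector,
#'   one entry per sample)) and `samples` (character vector). Records are
#'   sorted by position. Returns zero records with a warning when the
#'   chromosome is absent from the VCF.
#' @export
fetchGenotypes <- function(vcfPath, chrom, start, end) {
  if (!file.exists(vcfPath)) stop("VCF file not found: ", vcfPath)
  vcf <- suppressWarnings(VariantAnnotation::readVcf(vcfPath))
  samples <- colnames(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  onChrom <- as.character(GenomicRanges::seqnames(rr)) == chrom
  if (!any(onChrom)) {
    warning("chromosome ", chrom, " absent from VCF ", vcfPath)
    return(list(records = list(), samples = samples))
  }
  pos <- GenomicRanges::start(rr)
  refs <- as.character(VariantAnnotation::ref(vcf))
  spanEnd <- pos + nchar(refs) - 1L
  keep <- which(onChrom & spanEnd >= start & pos <= end)
  keep <- keep[order(pos[keep])]
  gtmat <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gtmat)) stop("VCF has no GT genotype field: ", vcfPath)
  altList <- VariantAnnotation::alt(vcf)
  records <- lapply(keep, function(i) {
    id <- names(rr)[i]
    list(chrom = chrom, pos = pos[i],
         id = if (is.null(id) || is.na(id)) "." else id,
         ref = refs[i],
         alts = as.character(altList[[i]]),
         gt = stats::setNames(as.character(gtmat[i, ]), samples))
  })
  # readVcf synthesises names "chrom:pos_ref/alt" when ID is "."; recover "."
  for (j in seq_along(records)) {
    r <- records[[j]]
    if (grepl("^.+:[0-9]+_", r$id)) records[[j]]$id <- "."
  }
  # per-sample ploidy from the GT separator count (authoritative over panel
  # sex); needed because hom-ref genotypes are blanked downstream
  ploidy <- stats::setNames(rep(NA_integer_, length(samples)), samples)
  for (r in records) {
    known <- !is.na(ploidy)
    if (all(known)) break
    for (s in samples[!known]) {
      cls <- .gtClass(r$gt[[s]])
      if (!is.na(cls$ploidy)) ploidy[[s]] <- cls$ploidy
    }
  }
  list(records = records, samples = samples, ploidy = ploidy)
}

.gtClass <- function(gt) {
  # classify a GT string; returns list(type, alleles, phased, ploidy)
  if (is.na(gt) || gt %in% c(".", "./.", ".|."))
    return(list(type = "missing", alleles = integer(), phased = FALSE,
                ploidy = NA_integer_))
  phased <- grepl("|", gt, fixed = TRUE)
  parts <- strsplit(gt, "[|/]")[[1L]]
  if (any(parts == "."))
    return(list(type = "missing", alleles = integer(), phased = phased,
                ploidy = length(parts)))
  al <- suppressWarnings(as.integer(parts))
  if (anyNA(al)) stop("malformed GT field: ", gt)
  ploidy <- length(al)
  type <- if (ploidy == 1L) {
    if (al == 0L) "homref" else "alt"
  } else if (all(al == 0L)) "homref"
  else if (al[1L] == al[2L]) "homalt"
  else if (phased) "het_phased"
  else "het_unphased"
  list(type = type, alleles = al, phased = phased, ploidy = ploidy)
}

#' Drop genotypes homozygous for the reference allele
#'
#' Per-sample genotypes `0|0`, `0/0` and haploid `0` are blanked (set to
#' NA), and records left with no carrying sample are removed entirely.
#'
#' @param fetched result of [fetchGenotypes()].
#' @return The same structure with hom-ref genotypes removed.
#' @export
dropHomRef <- function(fetched) {
  recs <- lapply(fetched$records, function(r) {
    cls <- lapply(r$gt, .gtClass)
    homref <- vapply(cls, function(c) c$type == "homref", logical(1))
    r$gt[homref] <- NA_character_
    r
  })
  keep <- vapply(recs, function(r) any(!is.na(r$gt)), logical(1))
  list(records = recs[keep], samples = fetched$samples,
       ploidy = fetched$ploidy)
}

#' Split phased genotypes into per-sample, per-phase allele lists
#'
#' For each sample, builds one ordered list of (variant record, chosen
#' non-reference allele) pairs per phase. Homozygous-alternate genotypes
#' contribute their allele to both phases (no phase information needed);
#' haploid genotypes yield a single list. Samples carrying an unphased
#' heterozygous or missing genotype at any retained record are excluded
#' for this transcript, with a warning — the method presumes
#' chromosomally-phased input. When two non-reference alleles on the same
#' phase have overlapping reference spans, the later-starting one is
#' dropped with a warning.
#'
#' @param fetched result of [fetchGenotypes()] or [dropHomRef()].
#' @return A named list (by sample) of per-sample entries: `sampleId`,
#'   `ploidy` (1 or 2), `phases` — a list of 1 or 2 allele lists, each a
#'   list of `list(record, altIndex)` sorted by position. The character
#'   vector of excluded samples is attached as attribute
#'   `"excludedSamples"`.
#' @export
splitPhases <- function(fetched) {
  samples <- fetched$samples
  out <- list()
  excluded <- character()
  knownPloidy <- fetched$ploidy
  for (s in samples) {
    ploidy <- if (!is.null(knownPloidy)) knownPloidy[[s]] else NA_integer_
    phases <- list(list(), list())
    ok <- TRUE
    reason <- NULL
    for (r in fetched$records) {
      gt <- r$gt[[s]]
      if (is.na(gt)) next  # hom-ref blanked, or sample absent at record
      cls <- .gtClass(gt)
      if (cls$type == "missing") { ok <- FALSE; reason <- "missing"; break }
      if (cls$type == "het_unphased") {
        ok <- FALSE; reason <- "unphased"; break
      }
      if (is.na(ploidy)) ploidy <- cls$ploidy
      else if (ploidy != cls$ploidy) ploidy <- 2L  # mixed: treat as diploid
      if (cls$type == "homref") next
      for (ph in seq_len(cls$ploidy)) {
        ai <- cls$alleles[ph]
        if (ai > 0L) {
          if (ai > length(r$alts))
            stop("allele index ", ai, " out of range at ", r$chrom, ":",
                 r$pos)
          phases[[ph]] <- c(phases[[ph]],
                            list(list(record = r, altIndex = ai)))
        }
      }
    }
    if (!ok) {
      warning("sample ", s, " excluded (", reason, " genotype)")
      excluded <- c(excluded, s)
      next
    }
    if (is.na(ploidy)) ploidy <- 2L  # no non-ref genotypes seen
    phases <- phases[seq_len(ploidy)]
    phases <- lapply(phases, .resolvePhaseOverlaps, sample = s)
    out[[s]] <- list(sampleId = s, ploidy = ploidy, phases = phases)
  }
  attr(out, "excludedSamples") <- excluded
  out
}

.resolvePhaseOverlaps <- function(phase, sample) {
  if (length(phase) < 2L) return(phase)
  pos <- vapply(phase, function(e) e$record$pos, numeric(1))
  phase <- phase[order(pos)]
  keep <- list(phase[[1L]])
  lastEnd <- phase[[1L]]$record$pos + nchar(phase[[1L]]$record$ref) - 1L
  for (e in phase[-1L]) {
    if (e$record$pos <= lastEnd) {
      warning("sample ", sample, ": overlapping alleles on one phase at ",
              e$record$chrom, ":", e$record$pos,
              "; later-starting variant dropped")
      next
    }
    keep <- c(keep, list(e))
    lastEnd <- e$record$pos + nchar(e$record$ref) - 1L
  }
  keep
}

#' Load a population panel
#'
#' Reads a 1000 Genomes-style panel file: whitespace/tab-separated columns
#' sample, population, superpopulation, sex; a header row (first field
#' "sample") is skipped. Samples absent from the panel fall into the pooled
#' "ALL" population only.
#'
#' @param panelPath path to the panel file.
#' @return A data.frame with columns `sample`, `pop`, `superPop`, `sex`.
#' @export
loadPanel <- function(panelPath) {
  if (!file.exists(panelPath)) stop("panel file not found: ", panelPath)
  lines <- readLines(panelPath)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[ \t]+")
  if (length(fields) && tolower(fields[[1L]][1L]) == "sample")
    fields <- fields[-1L]
  if (!length(fields)) stop("empty panel file: ", panelPath)
  n <- vapply(fields, length, integer(1))
  if (any(n < 3L)) stop("panel rows must have at least 3 columns")
  df <- data.frame(
    sample = vapply(fields, `[`, character(1), 1L),
    pop = vapply(fields, `[`, character(1), 2L),
    superPop = vapply(fields, `[`, character(1), 3L),
    sex = vapply(fields, function(f)
      if (length(f) >= 4L) f[4L] else NA_character_, character(1)),
    stringsAsFactors = FALSE
  )
  dup <- duplicated(df$sample)
  if (any(dup)) {
    for (s in unique(df$sample[dup])) {
      rows <- df[df$sample == s, c("pop", "superPop")]
      if (nrow(unique(rows)) > 1L)
        stop("conflicting panel assignments for sample ", s)
    }
    df <- df[!dup, ]
  }
  rownames(df) <- NULL
  df
}
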