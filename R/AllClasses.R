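#' @import methods
#' @importFrom IRanges IRanges start end width
NULL

#' Transcript model
#'
#' A single transcript: its exon structure, coding (CDS) intervals, strand and
#' identifiers. All genomic intervals are 1-based inclusive and stored in
#' ascending genomic order regardless of strand; strand is +1 or -1.
#' The CDS intervals are the coordinate frame for every projection the
#' pipeline performs.
#'
#' @slot transcriptId character(1) stable transcript identifier.
#' @slot geneId character(1) parent gene identifier.
#' @slot displayName character(1) human-readable name (e.g. "TLR4-001");
#'   used as the prefix of haplotype names.
#' @slot chrom character(1) chromosome name.
#' @slot strand integer(1), +1 or -1.
#' @slot exons [IRanges::IRanges] of exon intervals, ascending, disjoint.
#' @slot cds [IRanges::IRanges] of CDS intervals, each contained in an exon.
#' @slot tags character vector of annotation tags (e.g. "CCDS", "merged").
#' @slot biotype character(1) transcript biotype.
#' @slot flags character vector of QC flags (e.g. "incomplete_cds" when the
#'   total CDS length is not a multiple of 3).
#'
#' @exportClass TranscriptModel
setClass("TranscriptModel",
  representation(
    transcriptId = "character",
    geneId = "character",
    displayName = "character",
    chrom = "character",
    strand = "integer",
    exons = "IRanges",
    cds = "IRanges",
    tags = "character",
    biotype = "character",
    flags = "character"
  )
)

setValidity("TranscriptModel", function(object) {
  msg <- character()
  if (length(object@transcriptId) != 1L || !nzchar(object@transcriptId))
    msg <- c(msg, "transcriptId must be a single non-empty string")
  if (!(length(object@strand) == 1L && object@strand %in% c(1L, -1L)))
    msg <- c(msg, "strand must be +1 or -1")
  for (nm in c("exons", "cds")) {
    r <- slot(object, nm)
    if (length(r) > 1L) {
      s <- IRanges::start(r); e <- IRanges::end(r)
      if (is.unsorted(s, strictly = TRUE))
        msg <- c(msg, paste(nm, "must be sorted by genomic start"))
      if (any(s[-1L] <= e[-length(e)]))
        msg <- c(msg, paste(nm, "intervals must be non-overlapping"))
    }
  }
  if (length(object@cds) > 0L) {
    hits <- IRanges::findOverlaps(object@cds, object@exons, type = "within")
    if (length(unique(S4Vectors::queryHits(hits))) < length(object@cds))
      msg <- c(msg, "every CDS interval must be contained in an exon")
    if (sum(IRanges::width(object@cds)) < 3L)
      msg <- c(msg, "total CDS length must be >= 3")
  }
  if (length(msg)) msg else TRUE
})

#' Gene model
#'
#' A gene and its transcripts; all transcripts share the gene's chromosome.
#'
#' @slot geneId character(1) gene identifier.
#' @slot symbol character(1) gene symbol.
#' @slot transcripts list of [TranscriptModel-class] objects.
#'
#' @exportClass GeneModel
setClass("GeneModel",
  representation(
    geneId = "character",
    symbol = "character",
    transcripts = "list"
  )
)

setValidity("GeneModel", function(object) {
  msg <- character()
  if (length(object@transcripts) < 1L)
    msg <- c(msg, "a gene must have at least one transcript")
  if (!all(vapply(object@transcripts, is, logical(1), "TranscriptModel")))
    msg <- c(msg, "transcripts must all be TranscriptModel objects")
  else {
    chroms <- unique(vapply(object@transcripts, slot, character(1), "chrom"))
    if (length(chroms) > 1L)
      msg <- c(msg, "all transcripts of a gene must share one chromosome")
  }
  if (length(msg)) msg else TRUE
})

#' Reconstructed haplotype sequence
#'
#' One reconstructed CDS or protein haplotype: the sequence, the contiguous
#' difference blocks relative to the reference sequence (from global
#' re-alignment), and the rendered HGVS-like name. A premature stop codon is
#' retained as a final "*" residue in protein haplotypes.
#'
#' @slot transcriptId character(1).
#' @slot type character(1), "cds" or "protein".
#' @slot sequence character(1) the haplotype sequence.
#' @slot diffs data.frame of difference blocks with columns `kind`
#'   ("substitution"/"insertion"/"deletion"), `refPos`, `ref`, `alt`,
#'   `name`, `variantId`.
#' @slot name character(1) full haplotype name, `"<display>:<diffs>"` or
#'   `"<display>:REF"`.
#' @slot flags character vector: any of "contains_indel",
#'   "contains_stop_change", "incomplete_cds", "is_reference".
#' @slot sampleId character, sample(s) of origin (may be empty for
#'   container-level unique haplotypes).
#' @slot phase integer, phase index (0-based) when sample-specific.
#'
#' @exportClass SequenceHaplotype
setClass("SequenceHaplotype",
  representation(
    transcriptId = "character",
    type = "character",
    sequence = "character",
    diffs = "data.frame",
    name = "character",
    flags = "character",
    sampleId = "character",
    phase = "integer"
  ),
  prototype(
    diffs = data.frame(kind = character(), refPos = integer(),
                       ref = character(), alt = character(),
                       name = character(), variantId = character(),
                       stringsAsFactors = FALSE),
    flags = character(), sampleId = character(), phase = integer()
  )
)

setValidity("SequenceHaplotype", function(object) {
  msg <- character()
  if (!(length(object@type) == 1L && object@type %in% c("cds", "protein")))
    msg <- c(msg, "type must be 'cds' or 'protein'")
  if (length(object@sequence) != 1L || !nzchar(object@sequence))
    msg <- c(msg, "sequence must be a single non-empty string")
  else if (object@type == "protein") {
    stars <- gregexpr("*", object@sequence, fixed = TRUE)[[1L]]
    if (stars[1L] != -1L &&
        (length(stars) > 1L || stars[1L] != nchar(object@sequence)))
      msg <- c(msg, "'*' may occur at most once and only as final character")
  }
  if (length(msg)) msg else TRUE
})

#' Transcript haplotype container
#'
#' Aggregation of the unique CDS and protein haplotypes observed across the
#' samples of a cohort for one transcript, with per-population observation
#' counts, carrier lists with zygosity, diplotype tallies and the population
#' denominators from which frequencies of occurrence (FoO) are computed.
#'
#' Populations always include the pooled "ALL" population; when a population
#' panel is supplied, superpopulation and population codes are added.
#' Denominators are haplotype-observation counts (2 per phased diploid
#' sample, 1 per haploid sample) for that transcript, so FoO is a proper
#' frequency even when samples were excluded for unphased or missing
#' genotypes.
#'
#' @slot transcriptId character(1).
#' @slot displayName character(1) used in haplotype names.
#' @slot refCds character(1) reference spliced CDS.
#' @slot refProtein character(1) reference translation (no terminal stop).
#' @slot proteinHaplotypes list of tally records; each a list with elements
#'   `haplotype` ([SequenceHaplotype-class]), `counts` (named integer per
#'   population) and `carriers` (named integer, sample -> copies).
#' @slot cdsHaplotypes list of tally records, same shape, CDS level.
#' @slot diplotypes list of records with `pair` (sorted character(2) of
#'   protein haplotype names) and `counts` (named integer per population).
#' @slot denominators named numeric: haplotype observations per population.
#' @slot diploidCounts named numeric: diploid individuals per population.
#' @slot samples character: sample ids aggregated.
#' @slot excludedSamples character: samples excluded (unphased/missing).
#'
#' @exportClass TranscriptHaplotypeContainer
setClass("TranscriptHaplotypeContainer",
  representation(
    transcriptId = "character",
    displayName = "character",
    refCds = "character",
    refProtein = "character",
    proteinHaplotypes = "list",
    cdsHaplotypes = "list",
    diplotypes = "list",
    denominators = "numeric",
    diploidCounts = "numeric",
    samples = "character",
    excludedSamples = "character"
  )
)

setValidity("TranscriptHaplotypeContainer", function(object) {
  msg <- character()
  if (!"ALL" %in% names(object@denominators))
    msg <- c(msg, "denominators must include the 'ALL' population")
  for (rec in object@proteinHaplotypes) {
    if (!is(rec$haplotype, "SequenceHaplotype")) {
      msg <- c(msg, "tally records must carry SequenceHaplotype objects")
      break
    }
    if (sum(rec$carriers) != rec$counts[["ALL"]]) {
      msg <- c(msg, "carrier copy counts must sum to the ALL count")
      break
    }
  }
  tot <- sum(vapply(object@proteinHaplotypes,
                    function(r) r$counts[["ALL"]], numeric(1)))
  if (length(object@proteinHaplotypes) &&
      abs(tot - object@denominators[["ALL"]]) > 1e-9)
    msg <- c(msg, "protein haplotype counts must sum to the ALL denominator")
  if (length(msg)) msg else TRUE
})
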