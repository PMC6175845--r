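#' @importClassesFrom IRanges IRanges
#' @importFrom S4Vectors queryHits
NULL

#' Accessors for transcript models, haplotypes and containers
#'
#' Small accessor generics in the Bioconductor style: `txId()`, `geneId()`,
#' `displayName()`, `txStrand()`, `exonRanges()`, `cdsRanges()`,
#' `haplotypeName()`, `haplotypeSequence()`, `haplotypeDiffs()`,
#' `haplotypeFlags()`, `populations()` and `denominators()`.
#'
#' @param x a [TranscriptModel-class], [SequenceHaplotype-class] or
#'   [TranscriptHaplotypeContainer-class] object, as appropriate.
#' @return The corresponding slot value: identifiers and names as character
#'   scalars, ranges as [IRanges::IRanges], diffs as a data.frame,
#'   denominators as a named numeric vector.
#' @name accessors
#' @aliases txId geneId displayName txStrand exonRanges cdsRanges
#'   haplotypeName haplotypeSequence haplotypeDiffs haplotypeFlags
#'   populations denominators
#' @examples
#' tx <- TranscriptModel("t1", "g1", chrom = "chr1", strand = 1L,
#'                       exons = IRanges::IRanges(1, 9),
#'                       cds = IRanges::IRanges(1, 9))
#' txId(tx)
#' cdsRanges(tx)
NULL

#' @rdname accessors
#' @export
setGeneric("txId", function(x) standardGeneric("txId"))
#' @rdname accessors
#' @export
setGeneric("geneId", function(x) standardGeneric("geneId"))
#' @rdname accessors
#' @export
setGeneric("displayName", function(x) standardGeneric("displayName"))
#' @rdname accessors
#' @export
setGeneric("txStrand", function(x) standardGeneric("txStrand"))
#' @rdname accessors
#' @export
setGeneric("exonRanges", function(x) standardGeneric("exonRanges"))
#' @rdname accessors
#' @export
setGeneric("cdsRanges", function(x) standardGeneric("cdsRanges"))
#' @rdname accessors
#' @export
setGeneric("haplotypeName", function(x, ...) standardGeneric("haplotypeName"))
#' @rdname accessors
#' @export
setGeneric("haplotypeSequence",
           function(x) standardGeneric("haplotypeSequence"))
#' @rdname accessors
#' @export
setGeneric("haplotypeDiffs", function(x) standardGeneric("haplotypeDiffs"))
#' @rdname accessors
#' @export
setGeneric("haplotypeFlags", function(x) standardGeneric("haplotypeFlags"))
#' @rdname accessors
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))
#' @rdname accessors
#' @export
setGeneric("denominators", function(x) standardGeneric("denominators"))

setMethod("txId", "TranscriptModel", function(x) x@transcriptId)
setMethod("geneId", "TranscriptModel", function(x) x@geneId)
setMethod("geneId", "GeneModel", function(x) x@geneId)
setMethod("displayName", "TranscriptModel", function(x) x@displayName)
setMethod("txStrand", "TranscriptModel", function(x) x@strand)
setMethod("exonRanges", "TranscriptModel", function(x) x@exons)
setMethod("cdsRanges", "TranscriptModel", function(x) x@cds)

setMethod("txId", "SequenceHaplotype", function(x) x@transcriptId)
setMethod("haplotypeName", "SequenceHaplotype", function(x, ...) x@name)
setMethod("haplotypeSequence", "SequenceHaplotype", function(x) x@sequence)
setMethod("haplotypeDiffs", "SequenceHaplotype", function(x) x@diffs)
setMethod("haplotypeFlags", "SequenceHaplotype", function(x) x@flags)

setMethod("txId", "TranscriptHaplotypeContainer", function(x) x@transcriptId)
setMethod("displayName", "TranscriptHaplotypeContainer",
          function(x) x@displayName)
setMethod("populations", "TranscriptHaplotypeContainer",
          function(x) names(x@denominators))
setMethod("denominators", "TranscriptHaplotypeContainer",
          function(x) x@denominators)

setMethod("show", "TranscriptModel", function(object) {
  cat("TranscriptModel", object@transcriptId,
      sprintf("(%s)", object@displayName), "\n")
  cat("  gene:", object@geneId, " chrom:", object@chrom,
      " strand:", ifelse(object@strand > 0, "+", "-"), "\n")
  cat("  exons:", length(object@exons),
      " CDS intervals:", length(object@cds),
      " CDS length:", sum(IRanges::width(object@cds)), "nt\n")
  if (length(object@tags)) cat("  tags:", paste(object@tags, collapse = ","),
                               "\n")
  if (length(object@flags)) cat("  flags:",
                                paste(object@flags, collapse = ","), "\n")
})

setMethod("show", "GeneModel", function(object) {
  cat("GeneModel", object@geneId,
      sprintf("(%s)", object@symbol), "with",
      length(object@transcripts), "transcript(s)\n")
})

setMethod("show", "SequenceHaplotype", function(object) {
  cat("SequenceHaplotype [", object@type, "] ", object@name, "\n", sep = "")
  seq <- object@sequence
  if (nchar(seq) > 60) seq <- paste0(substr(seq, 1, 57), "...")
  cat("  sequence (", nchar(object@sequence), "): ", seq, "\n", sep = "")
  if (nrow(object@diffs))
    cat("  diffs:", paste(object@diffs$name, collapse = ","), "\n")
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = ","), "\n")
})

setMethod("show", "TranscriptHaplotypeContainer", function(object) {
  cat("TranscriptHaplotypeContainer for", object@transcriptId, "\n")
  cat("  samples:", length(object@samples),
      " (excluded:", length(object@excludedSamples), ")\n")
  cat("  haplotype observations (ALL):", object@denominators[["ALL"]], "\n")
  cat("  unique protein haplotypes:", length(object@proteinHaplotypes),
      " | unique CDS haplotypes:", length(object@cdsHaplotypes),
      " | diplotypes:", length(object@diplotypes), "\n")
  cat("  populations:", paste(names(object@denominators), collapse = ", "),
      "\n")
})
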