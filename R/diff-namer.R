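#' Alignment scoring scheme
#'
#' Parameters of the affine-gap global alignment used to re-align each
#' haplotype to its reference. Haplotypes are near-identical to their
#' reference, so any sane scheme recovers the intended difference blocks;
#' the defaults (match +1, mismatch -1, gap open 2, gap extend 0.5, so a
#' gap of length L costs 2 + 0.5 L) are configurable.
#'
#' @param match,mismatch substitution scores; `match` must exceed
#'   `mismatch`.
#' @param gapOpen,gapExtend non-negative gap costs.
#' @return list of the four parameters, class "alignmentScoring".
#' @export
alignmentScoring <- function(match = 1, mismatch = -1,
                             gapOpen = 2, gapExtend = 0.5) {
  stopifnot(match > mismatch, gapOpen >= 0, gapExtend >= 0)
  structure(list(match = match, mismatch = mismatch,
                 gapOpen = gapOpen, gapExtend = gapExtend),
            class = "alignmentScoring")
}

#' Global alignment of a haplotype to its reference
#'
#' Affine-gap global (Needleman-Wunsch/Gotoh) alignment, computed in
#' compiled code with a deterministic traceback: among co-optimal
#' alignments, gap runs are placed at their 3'-most equivalent position
#' (the HGVS normalisation convention), so a premature stop renders as a
#' substitution followed by a tail deletion. Works for protein and
#' nucleotide sequences alike.
#'
#' @param reference,haplotype non-empty character(1) sequences.
#' @param scoring an [alignmentScoring()] scheme.
#' @return list with `score` and the two gapped strings `ref` and `alt`
#'   (equal length; "-" marks gaps).
#' @export
globalAlign <- function(reference, haplotype,
                        scoring = alignmentScoring()) {
  if (!nzchar(reference) || !nzchar(haplotype))
    stop("sequences must be non-empty")
  .gotohAlign(reference, haplotype, scoring$match, scoring$mismatch,
              scoring$gapOpen, scoring$gapExtend)
}

.emptyDiffs <- function() {
  data.frame(kind = character(), refPos = integer(), ref = character(),
             alt = character(), name = character(),
             variantId = character(), stringsAsFactors = FALSE)
}

#' Extract contiguous difference blocks from an alignment
#'
#' Scans the alignment columns and merges maximal runs of identical
#' non-match column type into blocks: mismatch columns become substitution
#' blocks, gap-in-haplotype runs become deletions, gap-in-reference runs
#' become insertions. A mismatch run directly adjacent to a gap run (as
#' produced by a premature stop: one substitution column, then unmatched
#' reference tail) therefore yields separate blocks, e.g. "577R>*" and
#' "578del(325)". Blocks are ordered by reference position.
#'
#' @param alignment result of [globalAlign()].
#' @return data.frame of diff blocks: `kind`, `refPos` (1-based position in
#'   the ungapped reference; for insertions, the position after which the
#'   insertion occurs), `ref`, `alt`, `name`, `variantId` (NA until
#'   [assignVariantIds()]).
#' @export
callDiffs <- function(alignment) {
  r <- strsplit(alignment$ref, "")[[1L]]
  q <- strsplit(alignment$alt, "")[[1L]]
  stopifnot(length(r) == length(q))
  colType <- ifelse(r == "-", "ins", ifelse(q == "-", "del",
                    ifelse(r == q, "match", "sub")))
  refIdx <- cumsum(r != "-")  # reference position of each column (0 before
                              # the first reference character)
  out <- .emptyDiffs()
  n <- length(colType)
  i <- 1L
  while (i <= n) {
    if (colType[i] == "match") { i <- i + 1L; next }
    j <- i
    while (j < n && colType[j + 1L] == colType[i]) j <- j + 1L
    refSeq <- paste(r[i:j][r[i:j] != "-"], collapse = "")
    altSeq <- paste(q[i:j][q[i:j] != "-"], collapse = "")
    kind <- switch(colType[i], sub = "substitution", del = "deletion",
                   ins = "insertion")
    # for sub/del the first block column holds a reference character, so
    # refIdx[i] is the block's first reference position; for an insertion
    # refIdx[i] is the reference position after which the insertion occurs
    refPos <- refIdx[i]
    block <- data.frame(kind = kind, refPos = as.integer(refPos),
                        ref = refSeq, alt = altSeq,
                        name = NA_character_,
                        variantId = NA_character_,
                        stringsAsFactors = FALSE)
    block$name <- nameDiff(block)
    out <- rbind(out, block)
    i <- j + 1L
  }
  out
}

#' Render one difference block in the compact HGVS-like notation
#'
#' Substitution: `"{pos}{ref}>{alt}"` (multi-residue blocks concatenate
#' the residues); deletion: `"{pos}del({length})"`; insertion:
#' `"{pos}ins({seq})"`. A premature stop appears as the alt residue "*".
#'
#' @param block one-row data.frame as produced by [callDiffs()].
#' @return character(1) name.
#' @export
nameDiff <- function(block) {
  switch(block$kind,
    substitution = paste0(block$refPos, block$ref, ">", block$alt),
    deletion = paste0(block$refPos, "del(", nchar(block$ref), ")"),
    insertion = paste0(block$refPos, "ins(", block$alt, ")"),
    stop("unknown diff kind: ", block$kind))
}

#' Compose the full haplotype name
#'
#' `"{displayId}:{diff1,diff2,...}"` with diffs ordered by reference
#' position; a haplotype with no diffs is named `"{displayId}:REF"`.
#' (Calling `haplotypeName()` on a [SequenceHaplotype-class] instead
#' returns its stored name.)
#'
#' @param x transcript or protein identifier used as prefix (character).
#' @param diffs data.frame from [callDiffs()].
#' @return character(1) haplotype name.
#' @rdname haplotypeName-compose
#' @export
setMethod("haplotypeName", "character", function(x, diffs) {
  if (!nrow(diffs)) return(paste0(x, ":REF"))
  paste0(x, ":", paste(diffs$name, collapse = ","))
})

#' Assign known-variant identifiers to difference blocks
#'
#' A diff attributable to exactly one applied variant inherits that
#' variant's VCF ID (when not "."). Blocks spanning several variants, and
#' downstream frameshift-composite blocks attributable to none, are left
#' unassigned.
#'
#' @param diffs data.frame from [callDiffs()].
#' @param edits list of applied `CdsEdit`s (from [projectVariant()]), each
#'   carrying `cdsStart`, `cdsEnd` and `variantId`.
#' @param type "protein" (diff positions are residues; edits are matched on
#'   their codon span) or "cds" (positions are nucleotides).
#' @return `diffs` with `variantId` populated where attribution is
#'   unambiguous.
#' @export
assignVariantIds <- function(diffs, edits, type = c("protein", "cds")) {
  type <- match.arg(type)
  if (!nrow(diffs) || !length(edits)) return(diffs)
  es <- vapply(edits, `[[`, numeric(1), "cdsStart")
  ee <- vapply(edits, `[[`, numeric(1), "cdsEnd")
  ids <- vapply(edits, `[[`, character(1), "variantId")
  if (type == "protein") {
    es2 <- (pmin(es, ee + 1L) - 1L) %/% 3L + 1L  # codon span of the edit
    ee2 <- (pmax(ee, es - 1L) - 1L) %/% 3L + 1L
  } else {
    es2 <- pmin(es, ee + 1L)
    ee2 <- pmax(ee, es - 1L)
  }
  for (k in seq_len(nrow(diffs))) {
    dStart <- diffs$refPos[k]
    dEnd <- if (diffs$kind[k] == "insertion") diffs$refPos[k] + 1L
            else diffs$refPos[k] + max(nchar(diffs$ref[k]), 1L) - 1L
    hit <- which(es2 <= dEnd & ee2 >= dStart)
    if (length(hit) == 1L && ids[hit] != ".")
      diffs$variantId[k] <- ids[hit]
  }
  diffs
}

#' Apply difference blocks back onto a reference sequence
#'
#' Reconstructs a haplotype from its diff blocks; the inverse of
#' [callDiffs()] and the basis of the round-trip invariant used in the
#' test-suite.
#'
#' @param reference character(1) ungapped reference sequence.
#' @param diffs data.frame from [callDiffs()].
#' @return character(1) reconstructed haplotype sequence.
#' @export
applyDiffs <- function(reference, diffs) {
  if (!nrow(diffs)) return(reference)
  # apply 3' to 5' so positions stay valid
  ord <- order(diffs$refPos, decreasing = TRUE)
  seq <- reference
  for (k in ord) {
    if (diffs$kind[k] == "insertion") {
      seq <- paste0(substr(seq, 1L, diffs$refPos[k]), diffs$alt[k],
                    substring(seq, diffs$refPos[k] + 1L))
    } else {
      seq <- paste0(substr(seq, 1L, diffs$refPos[k] - 1L), diffs$alt[k],
                    substring(seq, diffs$refPos[k] + nchar(diffs$ref[k])))
    }
  }
  seq
}
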