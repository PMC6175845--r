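.samplePops <- function(sampleId, panel) {
  # population scopes a sample contributes to: always ALL, plus its
  # superpopulation and population when the panel knows it
  if (is.null(panel)) return("ALL")
  row <- panel[panel$sample == sampleId, , drop = FALSE]
  if (!nrow(row)) return("ALL")
  c("ALL", row$superPop[1L], row$pop[1L])
}

.popOrder <- function(panel) {
  if (is.null(panel)) return("ALL")
  c("ALL", unique(panel$superPop), unique(panel$pop))
}

#' Aggregate per-sample haplotypes into a transcript container
#'
#' Collates the per-phase haplotypes of many samples into unique CDS and
#' protein haplotype tallies (keyed by exact sequence), carrier lists with
#' zygosity (1 copy = heterozygous, 2 = homozygous), per-population
#' observation counts and diplotype tallies. Diploid samples contribute two
#' haplotype observations and one diplotype; haploid samples one
#' observation and no diplotype. Denominators are per-transcript: samples
#' excluded upstream (unphased/missing genotypes) reduce them, keeping FoO
#' a proper frequency.
#'
#' Naming and diff extraction are performed once per unique sequence.
#'
#' @param sampleHaplotypes named list as produced by applying
#'   [buildSampleHaplotypes()] over the [splitPhases()] output (built with
#'   `name = FALSE` for speed; names are computed here), i.e. one element
#'   per sample.
#' @param transcript the [TranscriptModel-class] the haplotypes belong to.
#' @param genome a named [Biostrings::DNAStringSet].
#' @param panel optional data.frame from [loadPanel()].
#' @param excludedSamples samples dropped upstream, recorded in the
#'   container.
#' @param scoring an [alignmentScoring()] scheme for the re-alignment.
#' @return A [TranscriptHaplotypeContainer-class].
#' @export
aggregateHaplotypes <- function(sampleHaplotypes, transcript, genome,
                                panel = NULL,
                                excludedSamples = character(),
                                scoring = alignmentScoring()) {
  samples <- names(sampleHaplotypes)
  if (anyDuplicated(samples))
    stop("sample appearing twice in aggregation input")
  refCds <- splicedCds(transcript, genome)
  refProt <- translateCds(refCds)$protein
  display <- displayName(transcript)
  pops <- .popOrder(panel)

  zero <- stats::setNames(numeric(length(pops)), pops)
  denom <- zero
  diploid <- zero

  newTally <- function() list()
  protTally <- newTally(); cdsTally <- newTally(); dipTally <- list()
  protNameBySeq <- character()  # cache: sequence -> name

  addObs <- function(tally, seq, hap, sample, popScopes) {
    key <- seq
    rec <- tally[[key]]
    if (is.null(rec))
      rec <- list(haplotype = hap, counts = zero,
                  carriers = stats::setNames(integer(), character()))
    rec$counts[popScopes] <- rec$counts[popScopes] + 1
    prev <- rec$carriers[sample]
    rec$carriers[sample] <- if (is.na(prev)) 1L else prev + 1L
    tally[[key]] <- rec
    tally
  }

  for (s in samples) {
    phases <- sampleHaplotypes[[s]]
    popScopes <- intersect(pops, .samplePops(s, panel))
    denom[popScopes] <- denom[popScopes] + length(phases)
    protNames <- character(length(phases))
    for (ph in seq_along(phases)) {
      hp <- phases[[ph]]
      protSeq <- haplotypeSequence(hp$protein)
      cdsSeq <- haplotypeSequence(hp$cds)
      # name each unique sequence once, via the container-level cache
      if (is.null(protTally[[protSeq]])) {
        protHap <- .containerHaplotype(hp$protein, refProt, display,
                                       hp$edits, scoring)
        protTally <- addObs(protTally, protSeq, protHap, s, popScopes)
      } else protTally <- addObs(protTally, protSeq, NULL, s, popScopes)
      if (is.null(cdsTally[[cdsSeq]])) {
        cdsHap <- .containerHaplotype(hp$cds, refCds, display,
                                      hp$edits, scoring)
        cdsTally <- addObs(cdsTally, cdsSeq, cdsHap, s, popScopes)
      } else cdsTally <- addObs(cdsTally, cdsSeq, NULL, s, popScopes)
      protNames[ph] <- haplotypeName(protTally[[protSeq]]$haplotype)
    }
    if (length(phases) == 2L) {
      diploid[popScopes] <- diploid[popScopes] + 1
      pair <- sort(protNames)
      key <- paste(pair, collapse = " / ")
      rec <- dipTally[[key]]
      if (is.null(rec)) rec <- list(pair = pair, counts = zero)
      rec$counts[popScopes] <- rec$counts[popScopes] + 1
      dipTally[[key]] <- rec
    }
  }

  ord <- function(tally) {
    if (!length(tally)) return(tally)
    cnt <- vapply(tally, function(r) r$counts[["ALL"]], numeric(1))
    nms <- vapply(tally, function(r) haplotypeName(r$haplotype),
                  character(1))
    unname(tally[order(-cnt, nms)])
  }
  new("TranscriptHaplotypeContainer",
      transcriptId = txId(transcript), displayName = display,
      refCds = refCds, refProtein = refProt,
      proteinHaplotypes = ord(protTally), cdsHaplotypes = ord(cdsTally),
      diplotypes = unname(dipTally), denominators = denom,
      diploidCounts = diploid, samples = samples,
      excludedSamples = excludedSamples)
}

.containerHaplotype <- function(hap, refSeq, display, edits, scoring) {
  # (re)name a sample haplotype at container level, stripping sample identity
  seq <- haplotypeSequence(hap)
  if (identical(seq, refSeq)) {
    diffs <- .emptyDiffs()
  } else {
    aln <- globalAlign(refSeq, seq, scoring)
    diffs <- callDiffs(aln)
    diffs <- assignVariantIds(diffs, edits, type = hap@type)
  }
  new("SequenceHaplotype", transcriptId = hap@transcriptId,
      type = hap@type, sequence = seq, diffs = diffs,
      name = haplotypeName(display, diffs), flags = hap@flags,
      sampleId = character(), phase = integer())
}

#' End-to-end container construction for one transcript
#'
#' Convenience pipeline: fetch genotypes over the transcript's exon span,
#' drop hom-ref genotypes, split phases, build per-sample haplotypes and
#' aggregate.
#'
#' @param transcript a [TranscriptModel-class].
#' @param genome a named [Biostrings::DNAStringSet].
#' @param vcfPath path to a phased VCF.
#' @param panel optional data.frame from [loadPanel()].
#' @param scoring an [alignmentScoring()] scheme.
#' @return A [TranscriptHaplotypeContainer-class].
#' @export
transcriptHaplotypes <- function(transcript, genome, vcfPath,
                                 panel = NULL,
                                 scoring = alignmentScoring()) {
  ex <- exonRanges(transcript)
  fetched <- fetchGenotypes(vcfPath, transcript@chrom,
                            min(IRanges::start(ex)),
                            max(IRanges::end(ex)))
  fetched <- dropHomRef(fetched)
  phased <- splitPhases(fetched)
  perSample <- lapply(phased, function(sa)
    buildSampleHaplotypes(transcript, genome, sa, name = FALSE))
  aggregateHaplotypes(perSample, transcript, genome, panel = panel,
                      excludedSamples = attr(phased, "excludedSamples"),
                      scoring = scoring)
}

.tallyByName <- function(container, type = "protein") {
  recs <- if (type == "protein") container@proteinHaplotypes
          else container@cdsHaplotypes
  stats::setNames(recs, vapply(recs, function(r)
    haplotypeName(r$haplotype), character(1)))
}

#' Frequency of occurrence of a haplotype in a population
#'
#' FoO = count of the haplotype in the population divided by the
#' population's total haplotype-observation count (twice the number of
#' diploid individuals, haploid-adjusted).
#'
#' @param container a [TranscriptHaplotypeContainer-class].
#' @param name haplotype name (protein level).
#' @param population population code (default "ALL").
#' @param type "protein" or "cds".
#' @return numeric(1) frequency.
#' @export
frequencyOfOccurrence <- function(container, name, population = "ALL",
                                  type = "protein") {
  if (!population %in% names(container@denominators))
    stop("unknown population: ", population)
  d <- container@denominators[[population]]
  if (d == 0) stop("zero haplotype denominator for population ", population)
  recs <- .tallyByName(container, type)
  if (!name %in% names(recs)) return(0)
  recs[[name]]$counts[[population]] / d
}

#' FoO table for all unique haplotypes of a container
#'
#' @param container a [TranscriptHaplotypeContainer-class].
#' @param type "protein" or "cds".
#' @return data.frame with one row per unique haplotype: `name`, `count_*`
#'   and `FoO_*` columns per population, `n_het_carriers`,
#'   `n_hom_carriers`, `flags`, `variant_ids` and `sequence`.
#' @export
haplotypeTable <- function(container, type = "protein") {
  recs <- if (type == "protein") container@proteinHaplotypes
          else container@cdsHaplotypes
  pops <- names(container@denominators)
  rows <- lapply(recs, function(r) {
    counts <- as.list(r$counts)
    names(counts) <- paste0("count_", pops)
    foo <- as.list(ifelse(container@denominators > 0,
                          r$counts / container@denominators, 0))
    names(foo) <- paste0("FoO_", pops)
    ids <- unique(stats::na.omit(haplotypeDiffs(r$haplotype)$variantId))
    cbind(data.frame(transcript_id = container@transcriptId,
                     haplotype_name = haplotypeName(r$haplotype),
                     type = type, stringsAsFactors = FALSE),
          as.data.frame(counts), as.data.frame(foo),
          data.frame(n_het_carriers = sum(r$carriers == 1L),
                     n_hom_carriers = sum(r$carriers == 2L),
                     flags = paste(haplotypeFlags(r$haplotype),
                                   collapse = ";"),
                     variant_ids = paste(ids, collapse = ";"),
                     sequence = haplotypeSequence(r$haplotype),
                     stringsAsFactors = FALSE))
  })
  do.call(rbind, rows)
}

#' Common haplotypes at a FoO threshold
#'
#' Haplotypes whose FoO in the given population equals or exceeds the
#' threshold (1% by default), sorted by descending FoO then name.
#'
#' @param container a [TranscriptHaplotypeContainer-class].
#' @param threshold inclusive FoO threshold, default 0.01.
#' @param population population code, default "ALL".
#' @param type "protein" or "cds".
#' @return data.frame with columns `name` and `foo`.
#' @export
commonHaplotypes <- function(container, threshold = 0.01,
                             population = "ALL", type = "protein") {
  recs <- .tallyByName(container, type)
  d <- container@denominators[[population]]
  foo <- vapply(recs, function(r)
    if (d > 0) r$counts[[population]] / d else 0, numeric(1))
  keep <- foo >= threshold
  df <- data.frame(name = names(recs)[keep], foo = unname(foo[keep]),
                   stringsAsFactors = FALSE)
  df[order(-df$foo, df$name), , drop = FALSE]
}

#' Gene complexity classification
#'
#' Classifies a transcript by its number of common protein haplotypes:
#' "single" (0-1), "two_or_three" (2-3) or "four_plus" (>= 4). Also
#' reports the most common haplotype overall and per population (ties
#' broken by name) and whether it differs from the reference translation.
#'
#' @param container a [TranscriptHaplotypeContainer-class].
#' @param threshold inclusive FoO threshold for "common", default 0.01.
#' @return list with `nUnique`, `nCommon`, `category`, `mostCommon` (named
#'   character, one per population) and `mostCommonDiffersFromReference`.
#' @export
classifyGene <- function(container, threshold = 0.01) {
  recs <- .tallyByName(container, "protein")
  nUnique <- length(recs)
  nCommon <- nrow(commonHaplotypes(container, threshold))
  category <- if (nCommon <= 1L) "single"
              else if (nCommon <= 3L) "two_or_three" else "four_plus"
  pops <- names(container@denominators)
  mostCommon <- vapply(pops, function(p) {
    cnt <- vapply(recs, function(r) r$counts[[p]], numeric(1))
    if (!length(cnt) || max(cnt) == 0) return(NA_character_)
    cand <- names(recs)[cnt == max(cnt)]
    sort(cand)[1L]
  }, character(1))
  refName <- paste0(container@displayName, ":REF")
  list(nUnique = nUnique, nCommon = nCommon, category = category,
       mostCommon = mostCommon,
       mostCommonDiffersFromReference =
         !is.na(mostCommon[["ALL"]]) && mostCommon[["ALL"]] != refName)
}

.diffKey <- function(diffs) {
  if (!nrow(diffs)) return(character())
  paste0(diffs$refPos, ":", diffs$ref, ">", diffs$alt)
}

#' Variant-level FoO from containing haplotypes
#'
#' The FoO of each protein-level difference (identified by position,
#' reference and alternate sequence) is the sum of the FoO of every
#' haplotype containing it.
#'
#' @param container a [TranscriptHaplotypeContainer-class].
#' @param population population code, default "ALL".
#' @param type "protein" or "cds".
#' @return data.frame with `diff` (identity key), `name` (notation) and
#'   `foo`.
#' @export
variantFoo <- function(container, population = "ALL", type = "protein") {
  recs <- .tallyByName(container, type)
  d <- container@denominators[[population]]
  acc <- list()
  for (r in recs) {
    diffs <- haplotypeDiffs(r$haplotype)
    keys <- .diffKey(diffs)
    foo <- if (d > 0) r$counts[[population]] / d else 0
    for (k in seq_along(keys)) {
      key <- keys[k]
      if (is.null(acc[[key]]))
        acc[[key]] <- list(name = diffs$name[k], foo = 0)
      acc[[key]]$foo <- acc[[key]]$foo + foo
    }
  }
  data.frame(diff = names(acc),
             name = vapply(acc, `[[`, character(1), "name"),
             foo = vapply(acc, `[[`, numeric(1), "foo"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Variants-versus-haplotypes summary point
#'
#' For one transcript: `x` is the number of protein-level variants
#' (diffs) with FoO at or above the threshold; `y` counts the common
#' haplotypes plus the minimum number of additional highest-frequency
#' haplotypes needed so that every significant variant is contained in
#' some counted haplotype (the "diluted variant" top-up). The top-up is
#' greedy in descending FoO, ties broken by name.
#'
#' @param container a [TranscriptHaplotypeContainer-class].
#' @param threshold inclusive FoO threshold, default 0.01.
#' @param population population code, default "ALL".
#' @return list with `x`, `y`, `nCommon`, `topUp` (names of haplotypes
#'   added by the top-up).
#' @export
variantsVsHaplotypesPoint <- function(container, threshold = 0.01,
                                      population = "ALL") {
  vf <- variantFoo(container, population)
  sig <- vf$diff[vf$foo >= threshold]
  common <- commonHaplotypes(container, threshold, population)
  recs <- .tallyByName(container, "protein")
  covered <- unique(unlist(lapply(common$name, function(nm)
    .diffKey(haplotypeDiffs(recs[[nm]]$haplotype)))))
  remaining <- setdiff(sig, covered)
  topUp <- character()
  if (length(remaining)) {
    d <- container@denominators[[population]]
    others <- setdiff(names(recs), common$name)
    foo <- vapply(recs[others], function(r)
      r$counts[[population]] / d, numeric(1))
    others <- others[order(-foo, others)]
    for (nm in others) {
      if (!length(remaining)) break
      keys <- .diffKey(haplotypeDiffs(recs[[nm]]$haplotype))
      if (length(intersect(keys, remaining))) {
        topUp <- c(topUp, nm)
        remaining <- setdiff(remaining, keys)
      }
    }
    if (length(remaining))
      warning("significant variant(s) not contained in any haplotype: ",
              paste(remaining, collapse = ", "))
  }
  list(x = length(sig), y = nrow(common) + length(topUp),
       nCommon = nrow(common), topUp = topUp)
}

#' Guaranteed diplotype coverage from haplotype coverage
#'
#' Under random pairing, a drug effective against a fraction `c` of
#' haplotype observations covers at least `c^2` of diplotypes (both copies
#' covered); e.g. 99% haplotype coverage guarantees 98.01% of individuals.
#'
#' @param haplotypeCoverage numeric in 0..1.
#' @return numeric(1) `haplotypeCoverage^2`.
#' @export
diplotypeCoverageBound <- function(haplotypeCoverage) {
  if (any(haplotypeCoverage < 0 | haplotypeCoverage > 1))
    stop("coverage must be within [0, 1]")
  haplotypeCoverage^2
}

#' Enumerate hypothetical variant combinations
#'
#' All 2^n presence/absence combinations of n biallelic protein-altering
#' variants — the number of protein haplotypes that would need engineering
#' to test a drug against every combination (32 for 5 variants).
#'
#' @param variants character vector of variant labels.
#' @param cap guard against explosion; error when `length(variants) > cap`.
#' @return list of character vectors, each one combination (ordered as the
#'   input); the first element is the empty (reference) combination.
#' @export
enumerateVariantCombinations <- function(variants, cap = 16L) {
  n <- length(variants)
  if (n > cap)
    stop("refusing to enumerate 2^", n, " combinations (cap ", cap, ")")
  combos <- lapply(seq_len(2^n) - 1L, function(mask)
    variants[bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0])
  combos
}

#' Map haplotypes to an external protein set by exact sequence
#'
#' Exact full-length string matching of protein haplotypes (minus any
#' trailing stop residue) against an external protein FASTA (e.g. UniProt
#' or RefSeq). All external entries equal to a haplotype are reported.
#'
#' @param container a [TranscriptHaplotypeContainer-class].
#' @param proteinFasta path to a protein FASTA file.
#' @return list with `matches` (named list: haplotype name -> character
#'   vector of matching external ids) and `unmatchedExternal` (ids with no
#'   haplotype match).
#' @export
mapToExternalProteins <- function(container, proteinFasta) {
  aa <- Biostrings::readAAStringSet(proteinFasta)
  names(aa) <- sub("\\s.*$", "", names(aa))
  ext <- stats::setNames(as.character(aa), names(aa))
  ext <- sub("\\*$", "", ext)
  recs <- .tallyByName(container, "protein")
  matches <- list()
  matchedIds <- character()
  for (nm in names(recs)) {
    seq <- sub("\\*$", "", haplotypeSequence(recs[[nm]]$haplotype))
    hit <- names(ext)[ext == seq]
    if (length(hit)) {
      matches[[nm]] <- hit
      matchedIds <- c(matchedIds, hit)
    }
  }
  list(matches = matches,
       unmatchedExternal = setdiff(names(ext), matchedIds))
}

#' FoO-threshold sensitivity scan
#'
#' For a set of containers, counts significant haplotypes and genes per
#' complexity category at each threshold.
#'
#' @param containers list of [TranscriptHaplotypeContainer-class] objects.
#' @param thresholds numeric vector of FoO thresholds.
#' @param population population code, default "ALL".
#' @return data.frame with one row per threshold: `threshold`,
#'   `n_significant`, `genes_single`, `genes_two_or_three`,
#'   `genes_four_plus`.
#' @export
thresholdSensitivity <- function(containers, thresholds,
                                 population = "ALL") {
  stopifnot(length(containers) >= 1L)
  rows <- lapply(thresholds, function(th) {
    nSig <- sum(vapply(containers, function(ct)
      nrow(commonHaplotypes(ct, th, population)), numeric(1)))
    cats <- vapply(containers, function(ct)
      classifyGene(ct, th)$category, character(1))
    data.frame(threshold = th, n_significant = nSig,
               genes_single = sum(cats == "single"),
               genes_two_or_three = sum(cats == "two_or_three"),
               genes_four_plus = sum(cats == "four_plus"))
  })
  do.call(rbind, rows)
}
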