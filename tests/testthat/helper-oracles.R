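# Independent oracles used by the tests only.

# Quadratic dynamic-programming score oracle for affine-gap global
# alignment (row-wise; the in-row gap recurrence is closed into a running
# maximum). Deliberately a different formulation from the package's
# compiled aligner.
alignScoreOracle <- function(a, b, match = 1, mismatch = -1,
                             gapOpen = 2, gapExt = 0.5) {
  A <- strsplit(a, "")[[1L]]
  B <- strsplit(b, "")[[1L]]
  m <- length(A); n <- length(B)
  NEG <- -1e30
  open1 <- gapOpen + gapExt
  # rows indexed 0..n (position in b)
  Mp <- c(0, rep(NEG, n))
  Xp <- c(NEG, -(gapOpen + seq_len(n) * gapExt))  # gap consuming b
  Yp <- rep(NEG, n + 1L)
  for (i in seq_len(m)) {
    s <- ifelse(A[i] == B, match, mismatch)
    best_prev <- pmax(Mp, Xp, Yp)
    Mc <- c(NEG, best_prev[seq_len(n)] + s)
    Yc <- c(-(gapOpen + i * gapExt),
            pmax(Mp[-1L], Xp[-1L]) - open1)
    Yc[-1L] <- pmax(Yc[-1L], Yp[-1L] - gapExt)
    # X within-row recurrence: X[j] = max(max(Mc,Yc)[j-1] - open1,
    #   X[j-1] - gapExt); closed form via cumulative maximum
    W <- pmax(Mc, Yc)
    k <- 0:(n - 1L)
    carry <- cummax(W[seq_len(n)] + k * gapExt)
    Xc <- c(NEG, carry - gapOpen - seq_len(n) * gapExt)
    Mp <- Mc; Xp <- Xc; Yp <- Yc
  }
  max(Mp[n + 1L], Xp[n + 1L], Yp[n + 1L])
}

# brute-force minimal top-up for the variants-vs-haplotypes statistic:
# smallest set of non-common haplotypes covering all remaining significant
# variants (by subset enumeration)
bruteForceTopUp <- function(container, threshold = 0.01,
                            population = "ALL") {
  vf <- variantFoo(container, population)
  sig <- vf$diff[vf$foo >= threshold]
  common <- commonHaplotypes(container, threshold, population)$name
  recs <- ProteinHaplotypes:::.tallyByName(container, "protein")
  keyOf <- function(nm)
    ProteinHaplotypes:::.diffKey(haplotypeDiffs(recs[[nm]]$haplotype))
  covered <- unique(unlist(lapply(common, keyOf)))
  remaining <- setdiff(sig, covered)
  if (!length(remaining)) return(0L)
  others <- setdiff(names(recs), common)
  for (size in seq_along(others)) {
    combos <- utils::combn(others, size, simplify = FALSE)
    for (cmb in combos) {
      if (all(remaining %in% unlist(lapply(cmb, keyOf))))
        return(size)
    }
  }
  stop("no covering subset exists")
}

# random exonic variant cohort: n samples, each with 1-3 random
# non-overlapping wholly-exonic SNVs (plus occasional contiguous 1-3 nt
# in-frame/frameshift indels), all phased; returns VCF text
randomExonicCohort <- function(transcript, genome, n, seed) {
  set.seed(seed)
  map <- cdsGenomicMap(transcript)
  L <- length(map)
  refCds <- splicedCds(transcript, genome)
  chrom <- transcript@chrom
  samples <- sprintf("R%03d", seq_len(n))
  specs <- list()
  for (i in seq_len(n)) {
    k <- sample(1:3, 1L)
    used <- integer()
    for (v in seq_len(k)) {
      kind <- sample(c("snv", "snv", "snv", "ins", "del"), 1L)
      for (attempt in 1:50) {
        if (kind == "snv") {
          p <- sample(seq_len(L), 1L)
          win <- p
        } else {
          len <- sample(1:3, 1L)
          p <- sample(2:(L - len - 1L), 1L)
          win <- (p - 1L):(p + len)
          g <- sort(map[win])
          if (any(diff(g) != 1L)) next  # must not straddle an intron
        }
        if (any(win %in% used)) next
        used <- c(used, win)
        if (kind == "snv") {
          refb <- substr(refCds, p, p)
          altb <- sample(setdiff(c("A", "C", "G", "T"), refb), 1L)
          v2 <- ProteinHaplotypes:::.cdsEditToVcf(transcript, genome,
                                                  p, p, altb)
        } else if (kind == "ins") {
          ins <- paste(sample(c("A", "C", "G", "T"), len,
                              replace = TRUE), collapse = "")
          v2 <- ProteinHaplotypes:::.cdsEditToVcf(transcript, genome,
                                                  p + 1L, p, ins)
        } else {
          v2 <- ProteinHaplotypes:::.cdsEditToVcf(transcript, genome,
                                                  p, p + len - 1L, "")
        }
        specs[[length(specs) + 1L]] <-
          c(v2, list(sample = samples[i],
                     gt = sample(c("1|0", "0|1", "1|1"), 1L)))
        break
      }
    }
  }
  ord <- order(vapply(specs, `[[`, numeric(1), "pos"))
  chromLen <- Biostrings::width(genome)[match(chrom, names(genome))]
  lines <- ProteinHaplotypes:::.vcfHeader(chrom, chromLen, samples)
  for (s in specs[ord]) {
    gts <- ifelse(samples == s$sample, s$gt, "0|0")
    lines <- c(lines, ProteinHaplotypes:::.vcfLine(
      chrom, s$pos, ".", s$ref, s$alt, gts))
  }
  paste(c(lines, ""), collapse = "\n")
}
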