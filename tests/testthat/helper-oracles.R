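# Independent oracles, implemented without touching the package's alignment
# code paths: a quadratic affine-gap dynamic program for global alignment
# scores, and an exhaustive shifted-slice Hamming scan for genomic
# placement. Both deliberately re-derive what the implementation computes
# through Biostrings.

# Gotoh affine-gap global alignment score; a gap of length k costs
# open + k * extend (matching the package's scoring convention).
oracle_global_score <- function(a, b, match = 1, mismatch = -4,
                                open = 6, extend = 1) {
  av <- strsplit(a, "")[[1L]]
  bv <- strsplit(b, "")[[1L]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1L, m + 1L)   # ends in match/mismatch
  X <- matrix(NEG, n + 1L, m + 1L)   # ends in gap in b (a-base unmatched)
  Y <- matrix(NEG, n + 1L, m + 1L)   # ends in gap in a
  M[1L, 1L] <- 0
  for (i in seq_len(n) + 1L) X[i, 1L] <- -(open + extend * (i - 1L))
  for (j in seq_len(m) + 1L) Y[1L, j] <- -(open + extend * (j - 1L))
  for (i in seq_len(n) + 1L) {
    for (j in seq_len(m) + 1L) {
      s <- if (av[i - 1L] == bv[j - 1L] && av[i - 1L] != "N") match else
        mismatch
      M[i, j] <- max(M[i - 1L, j - 1L], X[i - 1L, j - 1L],
                     Y[i - 1L, j - 1L]) + s
      X[i, j] <- max(M[i - 1L, j] - open - extend, X[i - 1L, j] - extend)
      Y[i, j] <- max(M[i, j - 1L] - open - extend, Y[i, j - 1L] - extend)
    }
  }
  max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
}

# Exhaustive scan of every offset of every strand for placements of `query`
# with <= maxMismatch substitutions; mirrors the unique-best/margin rule so
# whole outcomes can be compared.
oracle_best_hit <- function(query, genome_chr, maxMismatch = 0L,
                            margin = 5, minLength = 25L) {
  if (nchar(query) < minLength) return(list(status = "too_short"))
  L <- nchar(query)
  gv <- utf8ToInt(genome_chr)
  n_off <- length(gv) - L + 1L
  scan <- function(q) {
    qv <- utf8ToInt(q)
    mm <- integer(n_off)
    for (j in seq_len(L))
      mm <- mm + (gv[seq.int(j, j + n_off - 1L)] != qv[j])
    mm
  }
  rc <- function(x) {
    chartr("ACGT", "TGCA",
           paste(rev(strsplit(x, "")[[1L]]), collapse = ""))
  }
  hits <- data.frame(start = integer(), strand = character(),
                     mm = integer())
  for (str in c("+", "-")) {
    mm <- scan(if (str == "+") query else rc(query))
    ok <- which(mm <= maxMismatch)
    if (length(ok))
      hits <- rbind(hits, data.frame(start = ok, strand = str, mm = mm[ok]))
  }
  if (nrow(hits) == 0L) return(list(status = "unmapped"))
  hits$score <- L - 5 * hits$mm
  ord <- order(hits$score, decreasing = TRUE)
  if (nrow(hits) > 1L && hits$score[ord[2L]] > hits$score[ord[1L]] - margin)
    return(list(status = "ambiguous"))
  b <- hits[ord[1L], ]
  list(status = "unique", start = b$start, end = b$start + L - 1L,
       strand = b$strand, mismatches = b$mm)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
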