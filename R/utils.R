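#' @import methods
#' @importFrom stats rbinom rgeom runif rmultinom setNames
#' @importFrom utils write.table read.delim head tail modifyList
NULL

# Coerce any sequence-like input to a single upper-case character string.
.seq_chr <- function(x) {
  if (is(x, "XString") || is(x, "XStringSet")) x <- as.character(x)
  toupper(as.character(x)[1L])
}

.dna <- function(x) Biostrings::DNAString(.seq_chr(x))

.revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Uniform random DNA of length n under the current RNG stream.
.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Substitute a base at 1-based position(s) with a base different from current.
.mutate_positions <- function(seq_chr, positions) {
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(seq_chr, "")[[1L]]
  for (p in positions) {
    chars[p] <- sample(setdiff(bases, chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

# Inject substitution errors at per-base rate; returns the mutated string.
.inject_substitutions <- function(seq_chr, error_rate) {
  if (error_rate <= 0) return(seq_chr)
  n <- nchar(seq_chr)
  k <- rbinom(1L, n, error_rate)
  if (k == 0L) return(seq_chr)
  .mutate_positions(seq_chr, sample.int(n, k))
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Hamming distance between equal-length strings; NA-safe, N never matches.
.hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  av <- utf8ToInt(a); bv <- utf8ToInt(b)
  n_code <- utf8ToInt("N")
  sum(av != bv | av == n_code | bv == n_code)
}

# 1-based positions where equal-length strings differ.
.mismatch_positions <- function(a, b) {
  av <- utf8ToInt(a); bv <- utf8ToInt(b)
  n_code <- utf8ToInt("N")
  which(av != bv | av == n_code | bv == n_code)
}
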