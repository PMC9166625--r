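#' @importFrom Biostrings pairwiseAlignment pattern subject score matchPattern
NULL

# Substitution matrix over A/C/G/T/N where N never matches anything
# (including itself).
.subst_matrix <- function(match, mismatch) {
  bases <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5L, 5L, dimnames = list(bases, bases))
  diag(m) <- match
  m["N", "N"] <- mismatch
  m
}

.default_scoring <- function() {
  list(match = 1, mismatch = -4, gapOpen = 6, gapExtend = 1)
}

# Decompose a gapped pattern/subject string pair into run-length operation
# list relative to the query (pattern): insertion = query base absent from
# the reference, deletion = reference base absent from the query.
.ops_from_gapped <- function(p, s) {
  pc <- strsplit(p, "")[[1L]]
  sc <- strsplit(s, "")[[1L]]
  op <- ifelse(pc == "-", "deletion",
        ifelse(sc == "-", "insertion",
        ifelse(pc == sc & pc != "N", "match", "mismatch")))
  r <- rle(op)
  data.frame(op = r$values, length = r$lengths, stringsAsFactors = FALSE)
}

.alignment_result <- function(aln, strand = "+") {
  p <- as.character(pattern(aln))
  s <- as.character(subject(aln))
  ops <- .ops_from_gapped(p, s)
  ncols <- nchar(p)
  matches <- sum(ops$length[ops$op == "match"])
  structure(list(
    score = score(aln),
    identity = if (ncols > 0) matches / ncols else 0,
    ops = ops,
    refInterval = c(start = BiocGenerics::start(subject(aln)),
                    end = BiocGenerics::end(subject(aln))),
    queryInterval = c(start = BiocGenerics::start(pattern(aln)),
                      end = BiocGenerics::end(pattern(aln))),
    strand = strand
  ), class = "AlignmentResult")
}

#' @export
print.AlignmentResult <- function(x, ...) {
  cat("AlignmentResult: score", x$score,
      "identity", sprintf("%.3f", x$identity),
      "cigar", opsToCigar(x$ops), "\n")
  invisible(x)
}

#' Serialize an operation list to a CIGAR-style string
#'
#' @param ops data.frame with columns `op`, `length` as produced by
#'   [globalAlign()] / [localAlign()].
#' @return character CIGAR string (`=`/`X`/`I`/`D`).
#' @export
opsToCigar <- function(ops) {
  code <- c(match = "=", mismatch = "X", insertion = "I", deletion = "D")
  paste0(ops$length, code[ops$op], collapse = "")
}

#' Global (end-to-end) pairwise alignment
#'
#' Needleman-Wunsch alignment with affine gaps via
#' [Biostrings::pairwiseAlignment]. Defaults penalize gaps heavily
#' (match +1, mismatch -4, gap open -6, gap extend -1 per base) so that
#' junction breakpoints stay crisp; a gap of length k costs 6 + k. N bases
#' count as mismatches. Tie-breaks among co-optimal alignments are
#' deterministic.
#'
#' @param a query DNA (character or DNAString).
#' @param b reference DNA.
#' @param scoring list with `match`, `mismatch`, `gapOpen`, `gapExtend`
#'   (penalties positive).
#' @return an `AlignmentResult`: `score`, `identity` (fraction of aligned
#'   columns matching), `ops` (run-length operation list), `refInterval`,
#'   `queryInterval`.
#' @export
globalAlign <- function(a, b, scoring = .default_scoring()) {
  a <- .seq_chr(a); b <- .seq_chr(b)
  if (nchar(a) == 0L || nchar(b) == 0L)
    .stopf("globalAlign: sequences must be non-empty")
  aln <- pairwiseAlignment(a, b, type = "global",
    substitutionMatrix = .subst_matrix(scoring$match, scoring$mismatch),
    gapOpening = scoring$gapOpen, gapExtension = scoring$gapExtend)
  .alignment_result(aln)
}

#' Local (Smith-Waterman) pairwise alignment
#'
#' Best local alignment of `query` against `target`; returns `NULL` when the
#' best score falls below `minScore`. With `bothStrands = TRUE` the reverse
#' complement of the query is also tried and the better strand returned.
#'
#' @inheritParams globalAlign
#' @param query,target DNA sequences.
#' @param minScore minimum alignment score to report a hit.
#' @param bothStrands also search the reverse complement of the query.
#' @return an `AlignmentResult` (with `strand`) or `NULL`.
#' @export
localAlign <- function(query, target, scoring = .default_scoring(),
                       minScore = 25, bothStrands = FALSE) {
  query <- .seq_chr(query); target <- .seq_chr(target)
  if (nchar(query) == 0L || nchar(target) == 0L)
    .stopf("localAlign: sequences must be non-empty")
  mat <- .subst_matrix(scoring$match, scoring$mismatch)
  aln_one <- function(q, strand) {
    a <- pairwiseAlignment(q, target, type = "local",
      substitutionMatrix = mat,
      gapOpening = scoring$gapOpen, gapExtension = scoring$gapExtend)
    .alignment_result(a, strand = strand)
  }
  best <- aln_one(query, "+")
  if (bothStrands) {
    rc <- aln_one(.revcomp_chr(query), "-")
    if (rc$score > best$score) best <- rc
  }
  if (best$score < minScore) return(NULL)
  best
}

#' Unique best genomic placement of a query
#'
#' Exhaustive substitution-only scan of every contig (both strands) for
#' placements of `query` with at most `maxMismatch` substitutions, the
#' default 0 implementing a "perfectly mapped" contract. A placement is
#' reported only when it is uniquely best: when a second placement scores
#' within `margin` score units of the best (match +1 / mismatch -4, so one
#' extra substitution costs 5), the query is ambiguous. Ambiguous and
#' unmapped queries are returned with a reason code, never dropped silently.
#'
#' @param query DNA sequence.
#' @param genome [MiniGenome-class] or named [Biostrings::DNAStringSet].
#' @param minLength minimum query length; shorter queries are rejected.
#' @param maxMismatch maximum substitutions per placement.
#' @param margin ambiguity margin in score units.
#' @param bothStrands search the minus strand too.
#' @return list with `status` (`"unique"`, `"ambiguous"`, `"unmapped"`,
#'   `"too_short"`) and, for unique hits, `contig`, `start`, `end`,
#'   `strand`, `mismatches`, `score`.
#' @export
bestGenomicHit <- function(query, genome, minLength = 25L, maxMismatch = 0L,
                           margin = 5, bothStrands = TRUE) {
  query <- .seq_chr(query)
  if (nchar(query) < minLength)
    return(list(status = "too_short"))
  ctg <- .contigs(genome)
  hits <- list()
  for (nm in names(ctg)) {
    for (str in if (bothStrands) c("+", "-") else "+") {
      q <- if (str == "+") query else .revcomp_chr(query)
      mp <- matchPattern(q, ctg[[nm]], max.mismatch = maxMismatch,
                         with.indels = FALSE, fixed = TRUE)
      if (length(mp) == 0L) next
      site <- as.character(mp)
      mm <- vapply(site, function(s) .hamming(s, q), integer(1L),
                   USE.NAMES = FALSE)
      for (i in seq_along(mp)) {
        hits[[length(hits) + 1L]] <- list(
          contig = nm, start = BiocGenerics::start(mp)[i],
          end = BiocGenerics::end(mp)[i], strand = str,
          mismatches = mm[i],
          score = nchar(query) - 5 * mm[i])
      }
    }
  }
  if (length(hits) == 0L) return(list(status = "unmapped"))
  scores <- vapply(hits, `[[`, numeric(1L), "score")
  ord <- order(scores, decreasing = TRUE)
  best <- hits[[ord[1L]]]
  if (length(hits) > 1L && scores[ord[2L]] > scores[ord[1L]] - margin)
    return(list(status = "ambiguous"))
  c(best, list(status = "unique"))
}

#' Annotate a genomic site against a protospacer+PAM
#'
#' Best substitution/bulge alignment of a candidate site to
#' protospacer+PAM: substitutions are counted per position and at most one
#' bulge (an unpaired stretch of 1-2 nt on either sequence, from a length
#' difference of up to 2) is allowed. Marks use `.` for a match, the site's
#' base for a mismatch, and record the bulge position.
#'
#' @param protospacerPam DNA, protospacer followed by PAM (typically 23 nt).
#' @param siteSeq candidate genomic site, within 2 nt of the same length.
#' @return list with `mismatchCount`, `bulgeCount`, `bulgePos` (position in
#'   the protospacer+PAM frame, NA when no bulge), `bulgeLen`, `marks`.
#' @export
guideMatchString <- function(protospacerPam, siteSeq) {
  q <- .seq_chr(protospacerPam)
  s <- .seq_chr(siteSeq)
  diff <- nchar(s) - nchar(q)
  if (abs(diff) > 2L)
    .stopf("site length differs from protospacer+PAM by more than 2 nt")
  marks_for <- function(site_aln) {
    pos <- .mismatch_positions(q, site_aln)
    marks <- strsplit(strrep(".", nchar(q)), "")[[1L]]
    if (length(pos))
      marks[pos] <- substring(site_aln, pos, pos)
    list(mm = length(pos), marks = paste(marks, collapse = ""))
  }
  if (diff == 0L) {
    r <- marks_for(s)
    return(list(mismatchCount = r$mm, bulgeCount = 0L, bulgePos = NA_integer_,
                bulgeLen = 0L, marks = r$marks))
  }
  k <- abs(diff)
  best <- NULL
  if (diff > 0L) {
    # site carries an insertion: drop k site bases at each position
    for (p in seq_len(nchar(s) - k + 1L)) {
      s2 <- paste0(substr(s, 1L, p - 1L), substr(s, p + k, nchar(s)))
      r <- marks_for(s2)
      if (is.null(best) || r$mm < best$mm) best <- c(r, pos = p)
    }
  } else {
    # site carries a deletion: drop k protospacer positions; mismatches are
    # counted over the remaining aligned columns
    for (p in seq_len(nchar(q) - k + 1L)) {
      q2 <- paste0(substr(q, 1L, p - 1L), substr(q, p + k, nchar(q)))
      pos <- .mismatch_positions(q2, s)
      # map marks back to the full protospacer frame
      full_pos <- ifelse(pos >= p, pos + k, pos)
      marks <- strsplit(strrep(".", nchar(q)), "")[[1L]]
      if (length(pos))
        marks[full_pos] <- substring(s, pos, pos)
      marks[p:(p + k - 1L)] <- "-"
      r <- list(mm = length(pos), marks = paste(marks, collapse = ""))
      if (is.null(best) || r$mm < best$mm) best <- c(r, pos = p)
    }
  }
  list(mismatchCount = best$mm, bulgeCount = 1L,
       bulgePos = as.integer(best$pos), bulgeLen = k, marks = best$marks)
}

#' In-silico restriction digest
#'
#' Splits a sequence at every occurrence of the recognition site, cutting
#' after `cutOffset` bases of the site (Sal I, GTCGAC, cuts G^TCGAC).
#' Fragment concatenation always reproduces the input.
#'
#' @param seq DNA sequence.
#' @param recognition recognition site (default Sal I).
#' @param cutOffset bases of the site 5' of the cut.
#' @return character vector of ordered fragments.
#' @export
inSilicoDigest <- function(seq, recognition = "GTCGAC", cutOffset = 1L) {
  seq <- .seq_chr(seq)
  recognition <- .seq_chr(recognition)
  if (nchar(recognition) == 0L) .stopf("recognition site must be non-empty")
  occ <- gregexpr(recognition, seq, fixed = TRUE)[[1L]]
  if (occ[1L] == -1L) return(seq)
  cuts <- as.integer(occ) + cutOffset - 1L   # last base of left fragment
  bounds <- c(0L, cuts, nchar(seq))
  vapply(seq_len(length(bounds) - 1L), function(i)
    substr(seq, bounds[i] + 1L, bounds[i + 1L]), character(1L))
}
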