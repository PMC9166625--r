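# Alignment profile machinery: per-reference base identity plus indel
# bookkeeping for a read aligned to a template. Fast paths avoid dynamic
# programming for exact containment and for equal-length, substitution-only
# reads (<= 2 substitutions, where a gapped alignment cannot score higher
# under the default +1/-4/-6-1 scheme); remaining reads are aligned in one
# vectorized pairwiseAlignment call.

# profile from a fast path, or NULL when DP is required
.fast_profile <- function(read, ref, type, scoring) {
  n_ref <- nchar(ref)
  hit <- if (type == "global" && nchar(read) == n_ref) {
    if (read == ref) 1L else -1L
  } else regexpr(read, ref, fixed = TRUE)[1L]
  if (hit > 0L) {
    read_at_ref <- rep(NA_character_, n_ref)
    idx <- hit:(hit + nchar(read) - 1L)
    read_at_ref[idx] <- strsplit(read, "")[[1L]]
    return(list(score = nchar(read) * scoring$match, identity = 1,
                read_at_ref = read_at_ref,
                insertions = data.frame(refPos = integer(), len = integer()),
                covered = c(hit, hit + nchar(read) - 1L)))
  }
  if (nchar(read) == n_ref) {
    mm <- .hamming(read, ref)
    if (mm <= 2L) {
      return(list(
        score = (n_ref - mm) * scoring$match + mm * scoring$mismatch,
        identity = (n_ref - mm) / n_ref,
        read_at_ref = strsplit(read, "")[[1L]],
        insertions = data.frame(refPos = integer(), len = integer()),
        covered = c(1L, n_ref)))
    }
  }
  NULL
}

# profile from one element of a (possibly vectorized) PairwiseAlignments
.profile_from_gapped <- function(p_str, s_str, ref_start, ref_end, scr,
                                 n_ref) {
  p <- strsplit(p_str, "")[[1L]]
  s <- strsplit(s_str, "")[[1L]]
  read_at_ref <- rep(NA_character_, n_ref)
  not_gap <- s != "-"
  ri <- ref_start - 1L + cumsum(not_gap)
  read_at_ref[ri[not_gap]] <- p[not_gap]
  insertions <- data.frame(refPos = integer(), len = integer())
  if (any(!not_gap)) {
    runs <- rle(!not_gap)
    run_start <- cumsum(c(1L, runs$lengths))[seq_along(runs$lengths)]
    ins_i <- which(runs$values)
    insertions <- data.frame(refPos = ri[run_start[ins_i]],
                             len = runs$lengths[ins_i])
  }
  matches <- sum(p == s & p != "-" & p != "N")
  list(score = scr, identity = matches / length(p),
       read_at_ref = read_at_ref, insertions = insertions,
       covered = c(ref_start, ref_end))
}

# profiles for a vector of reads against one reference; one batched DP call
.aln_profile_batch <- function(reads, ref, type = "global",
                               scoring = .default_scoring()) {
  n_ref <- nchar(ref)
  profs <- lapply(reads, .fast_profile, ref = ref, type = type,
                  scoring = scoring)
  need <- which(vapply(profs, is.null, logical(1L)))
  if (length(need)) {
    alns <- pairwiseAlignment(
      Biostrings::DNAStringSet(reads[need]), ref, type = type,
      substitutionMatrix = .subst_matrix(scoring$match, scoring$mismatch),
      gapOpening = scoring$gapOpen, gapExtension = scoring$gapExtend)
    p_str <- as.character(pattern(alns))
    s_str <- as.character(subject(alns))
    starts <- BiocGenerics::start(subject(alns))
    ends <- BiocGenerics::end(subject(alns))
    scrs <- score(alns)
    for (k in seq_along(need))
      profs[[need[k]]] <- .profile_from_gapped(p_str[k], s_str[k],
                                               starts[k], ends[k],
                                               scrs[k], n_ref)
  }
  profs
}

.aln_profile <- function(read, ref, type = "global",
                         scoring = .default_scoring()) {
  .aln_profile_batch(read, ref, type = type, scoring = scoring)[[1L]]
}

# TRUE when the profile has an insertion or deletion overlapping
# [lo, hi] (reference template coordinates); an insertion counts when its
# anchor position falls inside the window.
.window_indel <- function(prof, lo, hi) {
  lo <- max(1L, lo); hi <- min(length(prof$read_at_ref), hi)
  del <- any(prof$read_at_ref[lo:hi] == "-", na.rm = TRUE)
  ins <- nrow(prof$insertions) > 0L &&
    any(prof$insertions$refPos >= lo & prof$insertions$refPos <= hi)
  del || ins
}

.has_any_indel <- function(prof) {
  any(prof$read_at_ref == "-", na.rm = TRUE) || nrow(prof$insertions) > 0L
}

#' Classify one amplicon read into an editing outcome
#'
#' The read is aligned to the WT and HDR expected amplicons. It is called
#' `HDR` when every donor diagnostic variant is present and no indel
#' overlaps a quantification window, `HDR_IMPERFECT` when the diagnostic
#' variants are present but a window-overlapping indel remains, `INDEL`
#' (reported within NHEJ) when an insertion or deletion overlaps a
#' quantification window on the WT alignment, `WT` otherwise, and
#' `AMBIGUOUS` when identity to both amplicons falls below the threshold or
#' the read is shorter than the minimum length.
#'
#' @param read DNA sequence (character or DNAString).
#' @param amplicons expected-amplicon list from [buildExpectedAmplicons()]
#'   (region `"amplicon"`); `WT` required, `HDR` optional.
#' @param quantWindowHalf half-width of the per-nick quantification window.
#' @param identityMin minimum alignment identity for a classifiable read.
#' @param minLen minimum read length.
#' @return list: `category`, `detail`, `identity`.
#' @export
classifyAmpliconRead <- function(read, amplicons, quantWindowHalf = 10L,
                                 identityMin = 0.85, minLen = 50L) {
  read <- .seq_chr(read)
  if (nchar(read) < minLen)
    return(list(category = "AMBIGUOUS", detail = "too_short", identity = NA))
  wt_prof <- .aln_profile(read, as.character(amplicons$WT@sequence))
  hdr_prof <- if (!is.null(amplicons$HDR))
    .aln_profile(read, as.character(amplicons$HDR@sequence)) else NULL
  .classify_from_profiles(wt_prof, hdr_prof, amplicons, quantWindowHalf,
                          identityMin)
}

.classify_from_profiles <- function(wt_prof, hdr_prof, amplicons,
                                    quantWindowHalf, identityMin) {
  h <- quantWindowHalf
  diag_present <- FALSE
  if (!is.null(hdr_prof)) {
    anchors <- amplicons$HDR@anchors
    diag_off <- anchors[grepl("^diag", names(anchors))]
    if (length(diag_off)) {
      hdr_chars <- strsplit(as.character(amplicons$HDR@sequence), "")[[1L]]
      at <- hdr_prof$read_at_ref[diag_off]
      diag_present <- !anyNA(at) && all(at == hdr_chars[diag_off])
    }
  }
  best_id <- max(wt_prof$identity,
                 if (is.null(hdr_prof)) -Inf else hdr_prof$identity)
  if (best_id < identityMin)
    return(list(category = "AMBIGUOUS", detail = "low_identity",
                identity = best_id))
  if (diag_present) {
    jx <- amplicons$HDR@junctions
    bad <- .window_indel(hdr_prof, jx[["left"]] - h, jx[["left"]] + h) ||
      .window_indel(hdr_prof, jx[["right"]] - h, jx[["right"]] + h)
    if (!bad)
      return(list(category = "HDR", detail = "diagnostics_complete",
                  identity = hdr_prof$identity))
    return(list(category = "HDR_IMPERFECT", detail = "diagnostics+indel",
                identity = hdr_prof$identity))
  }
  nk <- amplicons$WT@anchors
  indel <- .window_indel(wt_prof, nk[["nickA"]] - h, nk[["nickA"]] + h) ||
    .window_indel(wt_prof, nk[["nickB"]] - h, nk[["nickB"]] + h)
  if (indel)
    return(list(category = "INDEL", detail = "window_indel",
                identity = wt_prof$identity))
  list(category = "WT", detail = "reference", identity = wt_prof$identity)
}

#' Classify a set of amplicon reads
#'
#' @param reads named [Biostrings::DNAStringSet], character vector, or a
#'   `SimulatedReads` object.
#' @inheritParams classifyAmpliconRead
#' @return data.frame of per-read calls: `read_id`, `category`, `detail`,
#'   `identity`.
#' @export
classifyAmpliconReads <- function(reads, amplicons, quantWindowHalf = 10L,
                                  identityMin = 0.85, minLen = 50L) {
  if (inherits(reads, "SimulatedReads")) reads <- reads$reads
  rs <- as.character(reads)
  ids <- if (!is.null(names(rs))) names(rs) else
    sprintf("read_%05d", seq_along(rs))
  ok <- nchar(rs) >= minLen
  wt_profs <- vector("list", length(rs))
  hdr_profs <- vector("list", length(rs))
  wt_profs[ok] <- .aln_profile_batch(rs[ok],
                                     as.character(amplicons$WT@sequence))
  if (!is.null(amplicons$HDR))
    hdr_profs[ok] <- .aln_profile_batch(
      rs[ok], as.character(amplicons$HDR@sequence))
  calls <- lapply(seq_along(rs), function(i) {
    if (!ok[i])
      return(list(category = "AMBIGUOUS", detail = "too_short",
                  identity = NA))
    .classify_from_profiles(wt_profs[[i]], hdr_profs[[i]], amplicons,
                            quantWindowHalf, identityMin)
  })
  data.frame(read_id = ids,
             category = vapply(calls, `[[`, character(1L), "category"),
             detail = vapply(calls, `[[`, character(1L), "detail"),
             identity = vapply(calls, function(x)
               as.numeric(x$identity), numeric(1L)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Aggregate per-read calls into an outcome profile
#'
#' Three-way reporting follows the field's convention: `NHEJ` pools
#' `INDEL`, `DELETION`, `INVERSION` and `HDR_IMPERFECT` (an indel-bearing
#' allele is not a precise repair, so imperfect HDR counts as NHEJ in the
#' three-way split while remaining visible as its own category). The
#' HDR:NHEJ ratio is flagged and computed with pseudocount 1 when no NHEJ
#' read exists; the WT:mutated ratio uses
#' `WT / (INDEL + DELETION + INVERSION + AAV_INTEGRATION + TRANSLOCATION)`.
#'
#' @param calls data.frame of per-read calls (column `category`), or a
#'   character vector of categories.
#' @return an `OutcomeProfile` list: `counts`, `total`, `fractions`,
#'   `threeWay` (WT/NHEJ/HDR fractions over classified reads),
#'   `hdrNhejRatio`, `hdrNhejUndefined`, `wtMutatedRatio`,
#'   `wtMutatedUndefined`, `nAmbiguous`.
#' @export
quantifyOutcomes <- function(calls) {
  cat <- if (is.data.frame(calls)) calls$category else as.character(calls)
  if (length(cat) == 0L) .stopf("no calls to quantify")
  levels <- c("WT", "HDR", "HDR_IMPERFECT", "INDEL", "DELETION", "INVERSION",
              "AAV_INTEGRATION", "TRANSLOCATION", "AMBIGUOUS")
  unknown <- setdiff(unique(cat), levels)
  if (length(unknown)) .stopf("unknown categories: %s",
                              paste(unknown, collapse = ", "))
  counts <- table(factor(cat, levels = levels))
  counts <- setNames(as.integer(counts), levels)
  total <- sum(counts)
  fractions <- counts / total
  nhej <- counts[["INDEL"]] + counts[["DELETION"]] + counts[["INVERSION"]] +
    counts[["HDR_IMPERFECT"]]
  classified <- total - counts[["AMBIGUOUS"]]
  three <- if (classified > 0)
    c(WT = counts[["WT"]] / classified, NHEJ = nhej / classified,
      HDR = counts[["HDR"]] / classified)
  else c(WT = NA_real_, NHEJ = NA_real_, HDR = NA_real_)
  hdr_undef <- nhej == 0L
  hdr_ratio <- counts[["HDR"]] / max(nhej, 1L)
  mutated <- counts[["INDEL"]] + counts[["DELETION"]] + counts[["INVERSION"]] +
    counts[["AAV_INTEGRATION"]] + counts[["TRANSLOCATION"]]
  wt_undef <- mutated == 0L
  wt_ratio <- counts[["WT"]] / max(mutated, 1L)
  structure(list(counts = counts, total = total, fractions = fractions,
                 threeWay = three,
                 hdrNhejRatio = hdr_ratio, hdrNhejUndefined = hdr_undef,
                 wtMutatedRatio = wt_ratio, wtMutatedUndefined = wt_undef,
                 nAmbiguous = counts[["AMBIGUOUS"]]),
            class = "OutcomeProfile")
}

#' @export
print.OutcomeProfile <- function(x, ...) {
  nz <- x$counts[x$counts > 0]
  cat("OutcomeProfile:", x$total, "reads;",
      paste(names(nz), nz, sep = "=", collapse = ", "), "\n")
  cat(sprintf("  WT/NHEJ/HDR = %.3f/%.3f/%.3f  HDR:NHEJ = %.3g%s  WT:mut = %.3g%s\n",
              x$threeWay[["WT"]], x$threeWay[["NHEJ"]], x$threeWay[["HDR"]],
              x$hdrNhejRatio, if (x$hdrNhejUndefined) "*" else "",
              x$wtMutatedRatio, if (x$wtMutatedUndefined) "*" else ""))
  invisible(x)
}

#' Fraction of reads with an indel in a quantification window
#'
#' Aligns every read to the WT amplicon and reports the fraction of
#' classifiable reads (identity above threshold) whose alignment carries an
#' insertion or deletion overlapping the window. Substitutions never count.
#'
#' @param reads reads (DNAStringSet, character, or `SimulatedReads`).
#' @param wtAmplicon WT [ExpectedAmplicon-class] or DNA sequence.
#' @param window integer(2): window `[lo, hi]` in amplicon coordinates;
#'   defaults to the WT amplicon's nick windows.
#' @param quantWindowHalf half-width used when `window` is derived from the
#'   amplicon anchors.
#' @param identityMin identity threshold for classifiable reads.
#' @return fraction in `[0, 1]`.
#' @export
indelRate <- function(reads, wtAmplicon, window = NULL,
                      quantWindowHalf = 10L, identityMin = 0.85) {
  if (inherits(reads, "SimulatedReads")) reads <- reads$reads
  rs <- as.character(reads)
  if (is(wtAmplicon, "ExpectedAmplicon")) {
    wt <- as.character(wtAmplicon@sequence)
    if (is.null(window)) {
      nk <- wtAmplicon@anchors
      window <- list(c(nk[["nickA"]] - quantWindowHalf,
                       nk[["nickA"]] + quantWindowHalf),
                     c(nk[["nickB"]] - quantWindowHalf,
                       nk[["nickB"]] + quantWindowHalf))
    }
  } else {
    wt <- .seq_chr(wtAmplicon)
    if (is.null(window)) .stopf("window required with a bare WT sequence")
  }
  if (!is.list(window)) window <- list(window)
  n_class <- 0L; n_indel <- 0L
  for (prof in .aln_profile_batch(rs, wt)) {
    if (prof$identity < identityMin) next
    n_class <- n_class + 1L
    if (any(vapply(window, function(w)
      .window_indel(prof, w[1L], w[2L]), logical(1L))))
      n_indel <- n_indel + 1L
  }
  if (n_class == 0L) .stopf("no classifiable reads")
  n_indel / n_class
}

#' Count reads carrying an embedded tag
#'
#' Reports the number of reads containing the tag (dsODN or ITR) in either
#' orientation: an exact or near-exact full-length hit, or a partial hit of
#' at least `minSpan` nt at high identity (tags split across read ends
#' still count).
#'
#' @param reads reads (DNAStringSet, character, or `SimulatedReads`).
#' @param tagSeq tag sequence (>= 20 nt).
#' @param minSpan minimum aligned tag span.
#' @param minIdentity minimum identity over the aligned span.
#' @return integer count.
#' @export
countTagIntegrations <- function(reads, tagSeq, minSpan = 20L,
                                 minIdentity = 0.9) {
  if (inherits(reads, "SimulatedReads")) reads <- reads$reads
  tag <- .resolve_tag(tagSeq)
  if (nchar(tag) < 20L) .stopf("tag must be at least 20 nt")
  rs <- as.character(reads)
  tag_rc <- .revcomp_chr(tag)
  n <- 0L
  for (r in rs) {
    # fast path: exact containment of either orientation
    if (grepl(tag, r, fixed = TRUE) || grepl(tag_rc, r, fixed = TRUE)) {
      n <- n + 1L
      next
    }
    hit <- localAlign(tag, r, minScore = minSpan - 5L, bothStrands = TRUE)
    if (!is.null(hit)) {
      span <- hit$refInterval[["end"]] - hit$refInterval[["start"]] + 1L
      if (span >= minSpan && hit$identity >= minIdentity) n <- n + 1L
    }
  }
  n
}

#' In-silico RFLP estimate of the HDR fraction
#'
#' Emulates the diagnostic restriction digest: the fraction of reads cut at
#' the donor-introduced recognition site, i.e. reads whose alignment to the
#' HDR amplicon reproduces the recognition sequence exactly at its expected
#' position. On error-free reads this equals the sequence-based
#' HDR + HDR_IMPERFECT fraction.
#'
#' @param reads reads (DNAStringSet, character, or `SimulatedReads`).
#' @param amplicons expected-amplicon list with an `HDR` entry.
#' @param recognition recognition site (default Sal I, GTCGAC).
#' @return fraction of reads cut at the expected position.
#' @export
rflpHdrEstimate <- function(reads, amplicons, recognition = "GTCGAC") {
  if (inherits(reads, "SimulatedReads")) reads <- reads$reads
  if (is.null(amplicons$HDR)) .stopf("design has no HDR amplicon")
  hdr <- as.character(amplicons$HDR@sequence)
  recognition <- .seq_chr(recognition)
  site <- regexpr(recognition, hdr, fixed = TRUE)[1L]
  if (site < 0L) .stopf("donor does not introduce the recognition site '%s'",
                        recognition)
  wt <- as.character(amplicons$WT@sequence)
  if (regexpr(recognition, wt, fixed = TRUE)[1L] > 0L)
    .warnf("recognition site also present in the WT amplicon; RFLP is not diagnostic")
  idx <- site:(site + nchar(recognition) - 1L)
  rec_chars <- strsplit(recognition, "")[[1L]]
  rs <- as.character(reads)
  profs <- .aln_profile_batch(rs, hdr)
  cut <- vapply(profs, function(prof) {
    at <- prof$read_at_ref[idx]
    !anyNA(at) && all(at == rec_chars) &&
      !any(prof$insertions$refPos >= idx[1L] &
           prof$insertions$refPos < idx[length(idx)])
  }, logical(1L), USE.NAMES = FALSE)
  mean(cut)
}
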