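#' Verify nested-primer priming and trim to the genome interface
#'
#' LAM-HTGTS reads must begin with the nested primer of their enrichment
#' side (at most `maxMismatch` substitutions); the primer is removed so the
#' remainder starts at the genome interface. Rejections are logged with a
#' reason, never raised.
#'
#' @param read DNA sequence.
#' @param primer nested primer sequence.
#' @param maxMismatch substitutions tolerated in the primer.
#' @param minRemainder minimum post-trim read length.
#' @return list with `trimmed`, or `reject` (`MISPRIMED` / `TOO_SHORT`).
#' @export
checkPrimingAndTrim <- function(read, primer, maxMismatch = 1L,
                                minRemainder = 25L) {
  read <- .seq_chr(read)
  primer <- .seq_chr(primer)
  plen <- nchar(primer)
  if (nchar(read) <= plen) return(list(reject = "TOO_SHORT"))
  if (.hamming(substr(read, 1L, plen), primer) > maxMismatch)
    return(list(reject = "MISPRIMED"))
  trimmed <- substr(read, plen + 1L, nchar(read))
  if (nchar(trimmed) < minRemainder) return(list(reject = "TOO_SHORT"))
  list(trimmed = trimmed)
}

#' Detect an AAV ITR junction within a read
#'
#' Local alignment of the ITR against the read (both orientations); an
#' AAV-integration call requires an aligned span of at least `minSpan` nt
#' at identity `minIdentity` or better. The call records where in the read
#' the genomic/ITR junction falls.
#'
#' @param read DNA sequence (post-trim).
#' @param itr ITR sequence.
#' @param minIdentity minimum identity over the aligned span.
#' @param minSpan minimum aligned span, nt.
#' @return list (`junctionInRead`, `span`, `identity`, `strand`) or `NULL`.
#' @export
detectItr <- function(read, itr = itrSequence(), minIdentity = 0.8,
                      minSpan = 20L) {
  read <- .seq_chr(read)
  hit <- localAlign(.seq_chr(itr), read, minScore = minSpan - 5L,
                    bothStrands = TRUE)
  if (is.null(hit)) return(NULL)
  span <- hit$refInterval[["end"]] - hit$refInterval[["start"]] + 1L
  if (span < minSpan || hit$identity < minIdentity) return(NULL)
  list(junctionInRead = unname(hit$refInterval[["start"]] - 1L),
       span = span, identity = hit$identity, strand = hit$strand)
}

# Perfect-prefix check: does `read` equal the first nchar(read) bases of
# `template`, allowing at most maxSubs substitutions (0 = the
# perfectly-mapped contract) and no indels?
.perfect_prefix <- function(read, template, maxSubs = 0L) {
  n <- nchar(read)
  if (n > nchar(template)) return(FALSE)
  if (maxSubs == 0L) return(substr(template, 1L, n) == read)
  .hamming(read, substr(template, 1L, n)) <= maxSubs
}

#' Classify one LAM-HTGTS read (post-priming)
#'
#' Strict priority cascade mirroring the processing order of the assay:
#' ITR detection first (AAV integration), then perfect assignment against
#' the expected-outcome templates (HDR requires the read to span a
#' diagnostic variant; ties among perfect matches resolve HDR > WT >
#' DELETION > INVERSION), then break-site indel/deletion analysis, then
#' translocation detection under the off-target window rule. Reads too
#' short to reach the proximal nick window are `UNINFORMATIVE`; reads
#' exhausting the cascade are `AMBIGUOUS` (logged, never counted as
#' translocations).
#'
#' @param trimmed post-priming read sequence.
#' @param tp template set from an internal per-side builder (see
#'   [classifyHtgtsReads()]).
#' @param genome genome object.
#' @param offTargets predicted off-target [GenomicRanges::GRanges].
#' @param window translocation overlap window, bp.
#' @param maxSubs substitutions tolerated in a "perfect" template match
#'   (default 0, the perfectly-mapped contract; relax for error-tolerant
#'   runs).
#' @param itrMinIdentity,itrMinSpan passed to [detectItr()].
#' @return list: `category`, `detail`, `partner` (translocation partner
#'   coordinate or NA).
#' @export
classifyHtgtsRead <- function(trimmed, tp, genome, offTargets,
                              window = 5000L, maxSubs = 0L,
                              itrMinIdentity = 0.8, itrMinSpan = 20L) {
  read <- .seq_chr(trimmed)
  h <- tp$quantHalf
  prox <- tp$nicks$WT[["proximal"]]
  if (nchar(read) < prox - h)
    return(list(category = "UNINFORMATIVE", detail = "short_of_breaksite",
                partner = NA_integer_))
  # stage 1: AAV ITR junction
  itr_hit <- detectItr(read, tp$itr, minIdentity = itrMinIdentity,
                       minSpan = itrMinSpan)
  if (!is.null(itr_hit))
    return(list(category = "AAV_INTEGRATION",
                detail = sprintf("itr@%d", itr_hit$junctionInRead),
                partner = NA_integer_))
  # stage 2: perfect match against the expected-outcome templates
  if (!is.null(tp$templates$HDR) &&
      .perfect_prefix(read, tp$templates$HDR, maxSubs) &&
      length(tp$diagOffsets) && nchar(read) >= min(tp$diagOffsets))
    return(list(category = "HDR", detail = "perfect_hdr",
                partner = NA_integer_))
  if (.perfect_prefix(read, tp$templates$WT, maxSubs) &&
      nchar(read) >= prox + h)
    return(list(category = "WT", detail = "perfect_wt",
                partner = NA_integer_))
  if (.perfect_prefix(read, tp$templates$DELETION, maxSubs) &&
      nchar(read) >= tp$nicks$DELETION[["proximal"]] + h)
    return(list(category = "DELETION", detail = "perfect_deletion",
                partner = NA_integer_))
  if (.perfect_prefix(read, tp$templates$INVERSION, maxSubs) &&
      nchar(read) >= prox + h)
    return(list(category = "INVERSION", detail = "perfect_inversion",
                partner = NA_integer_))
  # stage 3: break-site indel / deletion analysis against the WT template
  bs <- analyzeBreaksite(read, tp$templates$WT, tp$nicks$WT, quantHalf = h)
  if (!is.null(bs)) return(c(bs, list(partner = NA_integer_)))
  # stage 4: translocation under the off-target window rule
  detectTranslocation(read, genome, offTargets, tp, window = window)
}

#' Break-site indel and deletion analysis
#'
#' Aligns the read to the WT template (read-global within the template) and
#' inspects indels against the per-nick quantification windows: an indel
#' overlapping one nick window is `INDEL`; a deletion stretching from the
#' proximal nick window into the distal one is `DELETION`. Returns `NULL`
#' when the alignment does not support a break-site call (low identity —
#' e.g. a translocation read — or no window coverage).
#'
#' @param read post-priming read.
#' @param wtTemplate WT template sequence (interface coordinates).
#' @param nicks named vector with `proximal` and `distal` template offsets.
#' @param quantHalf window half-width.
#' @param minIdentity minimum alignment identity to accept a break-site
#'   call.
#' @return list (`category`, `detail`) or `NULL`.
#' @export
analyzeBreaksite <- function(read, wtTemplate, nicks, quantHalf = 10L,
                             minIdentity = 0.9) {
  read <- .seq_chr(read)
  h <- quantHalf
  prox <- nicks[["proximal"]]; dist <- nicks[["distal"]]
  # exact two-anchor path: a read that is a template prefix joined to a
  # downstream template segment is a pure deletion; this stays robust for
  # deletions far larger than what affine-gap alignment represents cleanly
  n <- min(nchar(read), nchar(wtTemplate))
  mm <- .mismatch_positions(substr(read, 1L, n), substr(wtTemplate, 1L, n))
  brk <- if (length(mm) == 0L) n else mm[1L] - 1L
  rest <- substr(read, brk + 1L, nchar(read))
  if (brk >= prox - h && nchar(rest) >= 20L) {
    t_rel <- regexpr(rest, substr(wtTemplate, brk + 2L, nchar(wtTemplate)),
                     fixed = TRUE)[1L]
    if (t_rel > 0L) {
      del_start <- brk + 1L
      del_end <- brk + t_rel - 1L + 1L   # last deleted template base
      size <- del_end - del_start + 1L
      if (size >= 1L) {
        if (dist > prox && del_start <= prox + h && del_end >= dist - h)
          return(list(category = "DELETION",
                      detail = sprintf("del_span:%d", size)))
        in_window <- (del_start <= prox + h && del_end >= prox - h) ||
          (del_start <= dist + h && del_end >= dist - h)
        if (in_window)
          return(list(category = "INDEL",
                      detail = sprintf("indel:%d@%d", size, del_start)))
      }
    }
  }
  prof <- .aln_profile(read, wtTemplate, type = "global-local")
  if (prof$identity < minIdentity) return(NULL)
  covered <- function(x) prof$covered[1L] <= x - h && prof$covered[2L] >= x - h
  if (!covered(prox) && !covered(dist)) return(NULL)
  # deletion spanning both nick windows
  del_pos <- which(prof$read_at_ref == "-")
  if (length(del_pos)) {
    spans <- any(del_pos <= prox + h) && any(del_pos >= dist - h)
    if (spans && dist > prox)
      return(list(category = "DELETION",
                  detail = sprintf("del_span:%d", length(del_pos))))
  }
  for (x in unique(c(prox, dist))) {
    if (.window_indel(prof, x - h, x + h)) {
      dp <- del_pos[del_pos >= x - h & del_pos <= x + h]
      sz <- if (length(dp)) length(del_pos) else
        sum(prof$insertions$len[prof$insertions$refPos >= x - h &
                                  prof$insertions$refPos <= x + h])
      return(list(category = "INDEL", detail = sprintf("indel:%d@%d", sz, x)))
    }
  }
  NULL
}

#' Detect a nuclease-driven translocation
#'
#' The read is trimmed at the proximal nick (the end of its best local
#' alignment to the WT template) and the distal segment is placed on the
#' genome by [bestGenomicHit()] under the perfectly-mapped contract. A
#' unique placement within `window` bp of a predicted off-target record is
#' a `TRANSLOCATION` with that partner; anything else — unplaced, ambiguous
#' or outside the window — is `AMBIGUOUS` and never counted as a
#' translocation.
#'
#' @param read post-priming read.
#' @param genome genome object.
#' @param offTargets predicted off-target [GenomicRanges::GRanges].
#' @param tp template set (see [classifyHtgtsReads()]).
#' @param window overlap window, bp.
#' @param minDistal minimum distal segment length to attempt placement.
#' @return list: `category` (`TRANSLOCATION`/`AMBIGUOUS`), `detail`,
#'   `partner`.
#' @export
detectTranslocation <- function(read, genome, offTargets, tp,
                                window = 5000L, minDistal = 25L) {
  read <- .seq_chr(read)
  amb <- function(reason) list(category = "AMBIGUOUS", detail = reason,
                               partner = NA_integer_)
  # locate the proximal breakpoint: longest exact prefix shared with the
  # WT template, refined by local alignment when substitutions intervene
  wt <- tp$templates$WT
  n <- min(nchar(read), nchar(wt))
  mm <- .mismatch_positions(substr(read, 1L, n), substr(wt, 1L, n))
  brk <- if (length(mm) == 0L) n else mm[1L] - 1L
  if (brk < 15L) {
    hit <- localAlign(read, wt, minScore = 20)
    if (is.null(hit)) return(amb("no_proximal_alignment"))
    brk <- hit$queryInterval[["end"]]
  }
  distal <- substr(read, brk + 1L, nchar(read))
  if (nchar(distal) < minDistal) return(amb("distal_too_short"))
  hit <- bestGenomicHit(distal, genome, minLength = minDistal,
                        maxMismatch = 0L)
  if (hit$status != "unique") return(amb(paste0("distal_", hit$status)))
  if (length(offTargets) == 0L) return(amb("no_predicted_records"))
  same <- as.character(seqnames(offTargets)) == hit$contig
  mid <- (hit$start + hit$end) / 2
  d <- ifelse(same, pmin(abs(start(offTargets) - mid),
                         abs(end(offTargets) - mid)), Inf)
  # overlap counts as distance 0
  d[same & start(offTargets) <= mid & end(offTargets) >= mid] <- 0
  j <- which.min(d)
  if (d[j] <= window) {
    pc <- mcols(offTargets)$nick[j]
    if (is.null(pc)) pc <- start(offTargets)[j]
    return(list(category = "TRANSLOCATION",
                detail = sprintf("partner=OT-%d", j),
                partner = as.integer(pc)))
  }
  amb("outside_window")
}

#' Classify a set of LAM-HTGTS reads
#'
#' Applies the full cascade — priming check, ITR detection, expected-
#' amplicon assignment, break-site analysis, translocation detection — to
#' every read of one enrichment side. Every read receives exactly one
#' terminal label; priming rejects are reported as `MISPRIMED` /
#' `TOO_SHORT` categories so label counts always sum to the input.
#'
#' @param reads reads (DNAStringSet, character, or `SimulatedReads`).
#' @param design a [LocusDesign-class].
#' @param genome genome object.
#' @param offTargets predicted off-target [GenomicRanges::GRanges].
#' @param side enrichment side, `"5p"` or `"3p"`.
#' @param itr ITR sequence.
#' @param window translocation window, bp.
#' @param maxSubs substitutions tolerated in perfect template matches and
#'   the priming check.
#' @return data.frame of per-read calls: `read_id`, `category`, `detail`,
#'   `partner`.
#' @export
classifyHtgtsReads <- function(reads, design, genome, offTargets = NULL,
                               side = c("5p", "3p"), itr = itrSequence(),
                               window = 5000L, maxSubs = 0L) {
  side <- match.arg(side)
  if (inherits(reads, "SimulatedReads")) reads <- reads$reads
  if (is.null(offTargets))
    offTargets <- if (is(genome, "MiniGenome")) genome@offTargets else
      GRanges()
  rs <- as.character(reads)
  ids <- if (!is.null(names(rs))) names(rs) else
    sprintf("read_%05d", seq_along(rs))
  tp <- .htgts_templates(design, genome, itr = itr, side = side)
  out <- vector("list", length(rs))
  for (i in seq_along(rs)) {
    pr <- checkPrimingAndTrim(rs[i], tp$primer, maxMismatch = max(1L, maxSubs))
    if (!is.null(pr$reject)) {
      out[[i]] <- list(category = pr$reject, detail = "priming",
                       partner = NA_integer_)
      next
    }
    out[[i]] <- classifyHtgtsRead(pr$trimmed, tp, genome, offTargets,
                                  window = window, maxSubs = maxSubs)
  }
  data.frame(read_id = ids,
             category = vapply(out, `[[`, character(1L), "category"),
             detail = vapply(out, `[[`, character(1L), "detail"),
             partner = vapply(out, function(x)
               as.integer(x$partner), integer(1L)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Summarize LAM-HTGTS calls into an outcome profile
#'
#' Per-class fractions over classified reads (heatmap-ready), HDR
#' efficiency = HDR / classified, and the WT:mutated ratio
#' `WT / (INDEL + DELETION + INVERSION + AAV_INTEGRATION + TRANSLOCATION)`
#' (HDR excluded from both terms; flagged with pseudocount 1 when the
#' denominator is zero). `AMBIGUOUS`, `UNINFORMATIVE` and priming rejects
#' are excluded from denominators but reported.
#'
#' @param calls data.frame from [classifyHtgtsReads()], or calls from two
#'   sides rbind-ed for a combined-enrichment summary.
#' @param side label recorded in the output (`"5p"`, `"3p"`, `"both"`).
#' @return list: `side`, `counts`, `classified`, `fractions` (per class
#'   over classified), `hdrEfficiency`, `wtMutatedRatio`,
#'   `wtMutatedUndefined`, `nAmbiguous`, `nUninformative`, `nRejected`.
#' @export
summarizeHtgts <- function(calls, side = "5p") {
  cat <- calls$category
  if (length(cat) == 0L) .stopf("no calls to summarize")
  classes <- c("WT", "HDR", "INDEL", "DELETION", "INVERSION",
               "AAV_INTEGRATION", "TRANSLOCATION")
  counts <- setNames(vapply(classes, function(cl) sum(cat == cl),
                            integer(1L)), classes)
  n_amb <- sum(cat == "AMBIGUOUS")
  n_uninf <- sum(cat == "UNINFORMATIVE")
  n_rej <- sum(cat %in% c("MISPRIMED", "TOO_SHORT"))
  classified <- sum(counts)
  fractions <- if (classified > 0) counts / classified else
    setNames(rep(NA_real_, length(classes)), classes)
  mutated <- counts[["INDEL"]] + counts[["DELETION"]] +
    counts[["INVERSION"]] + counts[["AAV_INTEGRATION"]] +
    counts[["TRANSLOCATION"]]
  list(side = side, counts = counts, classified = classified,
       fractions = fractions,
       hdrEfficiency = if (classified > 0) counts[["HDR"]] / classified
                       else NA_real_,
       wtMutatedRatio = counts[["WT"]] / max(mutated, 1L),
       wtMutatedUndefined = mutated == 0L,
       nAmbiguous = n_amb, nUninformative = n_uninf, nRejected = n_rej)
}
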