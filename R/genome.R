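#' Build a mini-genome with the locus embedded and off-target sites planted
#'
#' Constructs a desk-scale reference: one random contig carrying the given
#' locus window exactly once plus `nOffTargets` planted off-target sites for
#' the chosen guide, each differing from protospacer+PAM by a recorded
#' number of substitutions (drawn from `mismatchRange`, placed in the
#' PAM-distal protospacer region so the NGG PAM stays intact). Sites are
#' spaced at least 10 kb from each other and from the locus so that the
#' 5000-bp off-target aggregation window rule can be exercised without
#' collisions. Deterministic for a given seed.
#'
#' @param windowSeq DNA of the locus reference window.
#' @param guides list of guide placements within the window, each
#'   `list(id, start, strand)` with `start` the 1-based window offset of the
#'   23-nt protospacer+PAM interval.
#' @param nOffTargets number of off-target sites to plant (for the first
#'   guide unless `otGuide` selects another).
#' @param mismatchRange integer vector of allowed substitution counts.
#' @param contigLength contig length; must leave >= 20 kb slack per
#'   off-target beyond the window.
#' @param seed integer seed.
#' @param contig contig name.
#' @param windowStart 1-based position at which the window is embedded.
#' @param otGuide index of the guide receiving planted off-targets.
#' @return a [MiniGenome-class]; `plantedOffTargets()` carries mcols
#'   `guide_id`, `mismatch_count`, `bulge_count`, `match_string`, `nick`.
#' @export
buildMiniGenome <- function(windowSeq, guides, nOffTargets = 3L,
                            mismatchRange = 2:5, contigLength = NULL,
                            seed = 1L, contig = "chr1",
                            windowStart = 3001L, otGuide = 1L) {
  windowSeq <- .seq_chr(windowSeq)
  win_len <- nchar(windowSeq)
  need <- windowStart + win_len + 20000L * max(1L, nOffTargets)
  if (is.null(contigLength)) contigLength <- need + 5000L
  if (contigLength < need)
    .stopf("contig of %d bp too short: need >= %d bp (window + 20 kb slack per off-target)",
           contigLength, need)
  set.seed(seed)
  g <- .random_dna(contigLength)
  substr(g, windowStart, windowStart + win_len - 1L) <- windowSeq

  ot <- GRanges()
  if (nOffTargets > 0L) {
    gd <- guides[[otGuide]]
    gstart <- windowStart + gd$start - 1L
    site <- substr(g, gstart, gstart + 22L)   # genome plus-strand 23-mer
    # genome-strand offsets of the PAM-distal protospacer half, where the
    # planted substitutions go (PAM and seed region untouched)
    mut_ok <- if (gd$strand == "+") 1:14 else 10:23
    win_end <- windowStart + win_len - 1L
    starts <- integer(nOffTargets)
    mms <- integer(nOffTargets)
    seqs <- character(nOffTargets)
    for (i in seq_len(nOffTargets)) {
      base <- win_end + 12000L + (i - 1L) * 15000L
      starts[i] <- base + sample.int(3000L, 1L)
      k <- sample(rep(mismatchRange, 2L), 1L)
      mms[i] <- k
      seqs[i] <- .mutate_positions(site, sample(mut_ok, k))
      substr(g, starts[i], starts[i] + 22L) <- seqs[i]
    }
    nick_off <- if (gd$strand == "+") 16L else 5L
    proto_pam <- paste0(
      if (gd$strand == "+") site else .revcomp_chr(site))
    match_strings <- vapply(seqs, function(s) {
      s_guide <- if (gd$strand == "+") s else .revcomp_chr(s)
      guideMatchString(proto_pam, s_guide)$marks
    }, character(1L), USE.NAMES = FALSE)
    ot <- GRanges(contig, IRanges(starts, starts + 22L), strand = gd$strand,
                  guide_id = gd$id, mismatch_count = mms, bulge_count = 0L,
                  match_string = match_strings, nick = starts + nick_off)
  }
  contigs <- DNAStringSet(setNames(g, contig))
  new("MiniGenome", contigs = contigs, offTargets = ot,
      onTarget = GRanges(contig,
                         IRanges(windowStart, windowStart + win_len - 1L)))
}

# Remove every occurrence of a recognition site from a sequence by mutating
# its middle base (diagnostic enzymes are chosen absent from the WT locus).
.scrub_site <- function(seq, site = "GTCGAC") {
  repeat {
    p <- regexpr(site, seq, fixed = TRUE)[1L]
    if (p < 0L) return(seq)
    seq <- .mutate_positions(seq, p + as.integer(nchar(site) / 2L))
  }
}

# Generate a random locus window with two PAM-out guide sites stamped in.
# Guide A sits on the minus strand (PAM leftward), guide B on the plus
# strand (PAM rightward); nick-to-nick distance = spacerDistance.
.random_locus_window <- function(winLen, nickAOffset, spacerDistance) {
  w <- .scrub_site(.random_dna(winLen))
  # guide A (minus strand): interval start sA with PAM at sA..sA+2 (genome
  # CCN); nick at sA + 5  => sA = nickA - 5
  sA <- nickAOffset - 5L
  substr(w, sA, sA + 1L) <- "CC"
  # guide B (plus strand): nick at sB + 16 => sB = nickB - 16; PAM GG at
  # sB+21..sB+22
  nickB <- nickAOffset + spacerDistance
  sB <- nickB - 16L
  substr(w, sB + 21L, sB + 22L) <- "GG"
  list(seq = w,
       guides = list(list(id = "sgA", start = sA, strand = "-"),
                     list(id = "sgB", start = sB, strand = "+")))
}

# Build an HDR payload from the WT spacer segment: silent-mutation-style
# substitutions plus a diagnostic Sal I site (GTCGAC) stamped at its centre.
.demo_payload <- function(wt_spacer, nSilent = 5L, recognition = "GTCGAC") {
  p <- wt_spacer
  mid <- as.integer(nchar(p) / 2L)
  substr(p, mid, mid + nchar(recognition) - 1L) <- recognition
  # silent mutations away from the diagnostic site
  cand <- setdiff(seq(10L, nchar(p) - 10L),
                  seq(mid - 3L, mid + nchar(recognition) + 2L))
  p <- .mutate_positions(p, sample(cand, nSilent))
  # keep only positions that actually differ (stamping may be a no-op at
  # positions already matching)
  p
}

#' Generate the package's demo locus: genome, design and off-target list
#'
#' One call sets up everything the simulators and classifiers need: a
#' random locus window with a PAM-out nickase pair at the requested spacer
#' distance, an HDR donor (>= 800-bp homology arms outside each nick,
#' payload carrying silent mutations and a diagnostic Sal I site), a
#' mini-genome with the locus embedded and off-target sites planted, and
#' the predicted-off-target table. Deterministic per seed.
#'
#' @param seed integer seed.
#' @param spacer nick-to-nick distance, bp (spacer-nick designs use
#'   200-350).
#' @param haLength homology-arm length, bp.
#' @param nOffTargets planted off-target count.
#' @param mismatchRange substitutions per planted site.
#' @param name locus name.
#' @return list with `genome` ([MiniGenome-class]), `design`
#'   ([LocusDesign-class]), `offTargets` ([GenomicRanges::GRanges]).
#' @export
demoLocus <- function(seed = 1L, spacer = 250L, haLength = 800L,
                      nOffTargets = 3L, mismatchRange = 2:5,
                      name = "demo_locus") {
  set.seed(seed)
  win_len <- haLength * 2L + spacer + 400L
  nick_a_off <- haLength + 200L
  loc <- .random_locus_window(win_len, nick_a_off, spacer)
  genome <- buildMiniGenome(loc$seq, loc$guides, nOffTargets = nOffTargets,
                            mismatchRange = mismatchRange,
                            seed = seed + 1000L)
  win_start <- start(genome@onTarget)
  gA <- guideSite(genome, "chr1", win_start + loc$guides[[1L]]$start - 1L,
                  "-", id = "sgA")
  gB <- guideSite(genome, "chr1", win_start + loc$guides[[2L]]$start - 1L,
                  "+", id = "sgB")
  pair <- nickPair(gA, gB)
  set.seed(seed + 2000L)
  wt_spacer <- .genome_seq(genome, "chr1", gA@nick + 1L, gB@nick)
  donor <- donorTemplate(genome, pair, .demo_payload(wt_spacer),
                         haLength = haLength)
  design <- locusDesign(name, genome, pair, donor = donor)
  list(genome = genome, design = design, offTargets = genome@offTargets)
}

#' Write / read a predicted-off-target table as BED6
#'
#' BED6 columns: interval, name = guide id, score = mismatch count, strand.
#'
#' @param offTargets [GenomicRanges::GRanges] with mcols `guide_id` and
#'   `mismatch_count`.
#' @param path file path.
#' @return `readOffTargetBed` returns a [GenomicRanges::GRanges].
#' @export
writeOffTargetBed <- function(offTargets, path) {
  gr <- offTargets
  mcols(gr) <- DataFrame(name = mcols(offTargets)$guide_id,
                         score = mcols(offTargets)$mismatch_count)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname writeOffTargetBed
#' @export
readOffTargetBed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  mcols(gr)$guide_id <- mcols(gr)$name
  mcols(gr)$mismatch_count <- as.integer(mcols(gr)$score)
  gr
}

#' Write a genome to FASTA
#'
#' @param genome [MiniGenome-class] or [Biostrings::DNAStringSet].
#' @param path file path.
#' @export
writeGenomeFasta <- function(genome, path) {
  Biostrings::writeXStringSet(.contigs(genome), path)
  invisible(path)
}
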