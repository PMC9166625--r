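#' @importFrom Biostrings DNAString DNAStringSet reverseComplement subseq
NULL

# Pull the plain-character sequence of contig[start..end] (1-based, closed)
# from a MiniGenome or DNAStringSet.
.contigs <- function(genome) {
  if (is(genome, "MiniGenome")) genome@contigs else DNAStringSet(genome)
}

.genome_seq <- function(genome, contig, start, end) {
  ctg <- .contigs(genome)
  if (!contig %in% names(ctg))
    .stopf("contig '%s' not found in genome", contig)
  s <- ctg[[contig]]
  if (start < 1L || end > length(s) || start > end)
    .stopf("interval %d-%d outside contig '%s' (length %d)",
           start, end, contig, length(s))
  as.character(subseq(s, start, end))
}

.gr_seq <- function(genome, gr) {
  .genome_seq(genome, as.character(seqnames(gr)), start(gr), end(gr))
}

#' Construct a guide site from its genomic placement
#'
#' Extracts protospacer and PAM from the genome at the given interval start
#' and strand, validates the NGG PAM, and computes the nick coordinate
#' (between protospacer positions 17 and 18, 3 nt 5' of the PAM). When
#' `protospacer` is supplied it is checked against the genome; a mismatch is
#' a design error.
#'
#' @param genome [MiniGenome-class] or named [Biostrings::DNAStringSet].
#' @param contig contig name.
#' @param start 1-based leftmost genome coordinate of the 23-nt
#'   protospacer+PAM interval.
#' @param strand `"+"` or `"-"`.
#' @param id guide identifier.
#' @param protospacer optional 20-nt sequence to verify against the genome.
#' @return a [GuideSite-class].
#' @export
guideSite <- function(genome, contig, start, strand, id = "guide",
                      protospacer = NULL) {
  site <- .genome_seq(genome, contig, start, start + 22L)
  if (strand == "+") {
    proto <- substr(site, 1L, 20L)
    pam <- substr(site, 21L, 23L)
    nick <- start + 16L
  } else if (strand == "-") {
    rc <- .revcomp_chr(site)
    proto <- substr(rc, 1L, 20L)
    pam <- substr(rc, 21L, 23L)
    nick <- start + 5L
  } else .stopf("strand must be '+' or '-'")
  if (!is.null(protospacer) && !identical(.seq_chr(protospacer), proto))
    .stopf("guide '%s': protospacer does not match the genome at %s:%d(%s)",
           id, contig, start, strand)
  if (substr(pam, 2L, 3L) != "GG")
    .stopf("guide '%s': PAM '%s' does not match NGG", id, pam)
  new("GuideSite",
      id = id,
      protospacer = DNAString(proto),
      pam = DNAString(pam),
      interval = GRanges(contig, IRanges(start, start + 22L), strand = strand),
      nick = as.integer(nick))
}

#' Nick coordinate of a guide
#'
#' The plus-strand coordinate immediately 5' of the Cas9(n) cut; the cut
#' falls between `nickPosition(g)` and `nickPosition(g) + 1`, 3 nt 5' of the
#' PAM.
#'
#' @param guide a [GuideSite-class].
#' @return integer coordinate.
#' @export
nickPosition <- function(guide) guide@nick

#' Pair two nickase guides
#'
#' @param guideA,guideB [GuideSite-class] objects on one contig; order is
#'   irrelevant (the pair is stored upstream-first).
#' @return a [NickPair-class].
#' @export
nickPair <- function(guideA, guideB) {
  if (start(guideA@interval) > start(guideB@interval)) {
    tmp <- guideA; guideA <- guideB; guideB <- tmp
  }
  new("NickPair", guideA = guideA, guideB = guideB)
}

#' Distance between the two nick positions of a pair
#'
#' Symmetric in guide order; spacer-nick designs target 200-350 bp.
#'
#' @param pair a [NickPair-class].
#' @return non-negative integer (bp).
#' @export
spacerDistance <- function(pair) {
  abs(pair@guideB@nick - pair@guideA@nick)
}

#' PAM orientation of a guide pair
#'
#' `PAM_OUT` when both PAMs face away from the intervening spacer (upstream
#' guide on the minus strand, downstream guide on the plus strand), `PAM_IN`
#' when they face each other, `TANDEM` when both guides share a strand.
#'
#' @param pair a [NickPair-class].
#' @return one of `"PAM_OUT"`, `"PAM_IN"`, `"TANDEM"`.
#' @export
pamOrientation <- function(pair) {
  sa <- as.character(strand(pair@guideA@interval))
  sb <- as.character(strand(pair@guideB@interval))
  if (sa == sb) return("TANDEM")
  if (sa == "-" && sb == "+") return("PAM_OUT")
  "PAM_IN"
}

#' Validate a pair against the spacer-nick design rules
#'
#' Classifies the PAM orientation and warns when the spacer distance falls
#' outside the recommended window (200-350 bp for spacer-nick designs) or
#' the pair is not PAM-out.
#'
#' @param pair a [NickPair-class].
#' @param distanceRange recommended spacer-distance window, bp.
#' @return list with `orientation`, `spacerDistance`, `inRange`, `warnings`.
#' @export
validatePamOut <- function(pair, distanceRange = c(200L, 350L)) {
  ori <- pamOrientation(pair)
  d <- spacerDistance(pair)
  in_range <- d >= distanceRange[1L] && d <= distanceRange[2L]
  warnings <- character()
  if (ori != "PAM_OUT")
    warnings <- c(warnings, sprintf("pair orientation is %s, not PAM_OUT", ori))
  if (!in_range)
    warnings <- c(warnings, sprintf(
      "spacer distance %d bp outside the recommended %d-%d bp window",
      d, distanceRange[1L], distanceRange[2L]))
  for (w in warnings) .warnf("%s", w)
  list(orientation = ori, spacerDistance = d, inRange = in_range,
       warnings = warnings)
}

#' Construct an HDR donor template
#'
#' Homology arms are anchored to the reference immediately outside the
#' nick-to-nick interval: the left HA ends at the upstream nick, the right HA
#' starts one base after the downstream nick. The payload replaces the
#' nick-to-nick ("mini-homologous") segment. When the payload has the same
#' length as that segment, diagnostic variants are derived automatically as
#' the positions where the two differ.
#'
#' @param genome genome object.
#' @param pair [NickPair-class].
#' @param payload DNA replacing the nick-to-nick segment.
#' @param haLength homology-arm length, bp (donor designs use >= 800).
#' @param diagnosticVariants optional data.frame(`offset`, `ref`, `alt`);
#'   derived automatically for equal-length payloads.
#' @return a [DonorTemplate-class].
#' @export
donorTemplate <- function(genome, pair, payload, haLength = 800L,
                          diagnosticVariants = NULL) {
  contig <- as.character(seqnames(pair@guideA@interval))
  nick_a <- pair@guideA@nick
  nick_b <- pair@guideB@nick
  payload <- .seq_chr(payload)
  left <- GRanges(contig, IRanges(nick_a - haLength + 1L, nick_a))
  right <- GRanges(contig, IRanges(nick_b + 1L, nick_b + haLength))
  if (is.null(diagnosticVariants)) {
    wt_spacer <- .genome_seq(genome, contig, nick_a + 1L, nick_b)
    if (nchar(payload) == nchar(wt_spacer)) {
      pos <- .mismatch_positions(wt_spacer, payload)
      diagnosticVariants <- data.frame(
        offset = pos,
        ref = substring(wt_spacer, pos, pos),
        alt = substring(payload, pos, pos),
        stringsAsFactors = FALSE)
    } else {
      diagnosticVariants <- data.frame(offset = integer(), ref = character(),
                                       alt = character())
    }
  }
  new("DonorTemplate", leftArm = left, rightArm = right,
      payload = DNAString(payload), diagnosticVariants = diagnosticVariants)
}

#' Assemble a locus design
#'
#' @param name locus name.
#' @param genome genome object (used for validation only; not stored).
#' @param pair [NickPair-class].
#' @param donor optional [DonorTemplate-class].
#' @param referenceWindow [GenomicRanges::GRanges] locus window; defaults to
#'   the donor HAs plus margin.
#' @param ampliconRegion [GenomicRanges::GRanges] amplicon-seq region;
#'   defaults to the nick pair plus 100 bp on each side.
#' @param outerPrimerMargin distance of the outer (LAM) primers beyond the
#'   HA ends, bp.
#' @param htgtsOffset distance from each nick to the nested-primer genome
#'   interface (50-100 bp in LAM-HTGTS designs).
#' @param htgtsPrimerLength nested primer length, nt.
#' @param quantWindowHalf half-width of the per-nick indel quantification
#'   window, nt.
#' @param minHa minimum recommended HA length; shorter arms trigger a
#'   warning (or an error when `haError = TRUE`).
#' @param haError escalate a short HA from warning to error.
#' @return a [LocusDesign-class].
#' @export
locusDesign <- function(name, genome, pair, donor = NULL,
                        referenceWindow = NULL, ampliconRegion = NULL,
                        outerPrimerMargin = 60L, htgtsOffset = 60L,
                        htgtsPrimerLength = 20L, quantWindowHalf = 10L,
                        minHa = 800L, haError = FALSE) {
  contig <- as.character(seqnames(pair@guideA@interval))
  nick_a <- pair@guideA@nick
  nick_b <- pair@guideB@nick
  if (!is.null(donor)) {
    for (arm in list(donor@leftArm, donor@rightArm)) {
      if (width(arm) < minHa) {
        msg <- sprintf("homology arm of %d bp is shorter than the minimum %d bp",
                       width(arm), minHa)
        if (haError) .stopf("%s", msg) else .warnf("%s", msg)
      }
    }
    # HAs must match the reference at their anchors and stay outside the
    # nick-to-nick interval.
    if (end(donor@leftArm) > nick_a || start(donor@rightArm) <= nick_b)
      .stopf("homology arms must lie outside the nick-to-nick interval")
    ha_lo <- start(donor@leftArm)
    ha_hi <- end(donor@rightArm)
  } else {
    ha_lo <- nick_a - 800L
    ha_hi <- nick_b + 800L
  }
  if (is.null(referenceWindow))
    referenceWindow <- GRanges(contig, IRanges(
      max(1L, ha_lo - outerPrimerMargin - htgtsPrimerLength - 10L),
      ha_hi + outerPrimerMargin + htgtsPrimerLength + 10L))
  if (is.null(ampliconRegion))
    ampliconRegion <- GRanges(contig, IRanges(nick_a - 100L, nick_b + 100L))
  outer <- c(ha_lo - outerPrimerMargin, ha_hi + outerPrimerMargin)
  if (outer[1L] < start(referenceWindow) || outer[2L] > end(referenceWindow))
    .stopf("outer primers must lie inside the reference window")
  design <- new("LocusDesign",
    name = name,
    referenceWindow = referenceWindow,
    nickPair = pair,
    singleGuide = NULL,
    donor = donor,
    ampliconRegion = ampliconRegion,
    outerPrimers = as.integer(outer),
    htgtsPrimerLength = as.integer(htgtsPrimerLength),
    htgtsOffset = as.integer(htgtsOffset),
    quantWindowHalf = as.integer(quantWindowHalf))
  # fail fast on HA anchor mismatches
  if (!is.null(donor)) invisible(buildHdrSequence(design, genome, minHa = 0L))
  design
}

#' Write / read a locus design as YAML
#'
#' The on-disk schema holds one locus per file: `name`, `contig`, `guides`
#' (id, interval start, strand per guide), `donor` (payload sequence,
#' homology-arm length, optional diagnostic variants), the amplicon region
#' and the HTGTS geometry. Reading re-validates the design against the
#' genome, so a YAML whose guides or homology arms no longer match the
#' reference fails loudly.
#'
#' @param design a [LocusDesign-class].
#' @param path YAML file path.
#' @param genome genome object the design refers to.
#' @return `readLocusDesign` returns a validated [LocusDesign-class].
#' @export
writeLocusDesign <- function(design, path) {
  pair <- design@nickPair
  g <- function(gs) list(id = gs@id,
                         start = unname(start(gs@interval)),
                         strand = as.character(strand(gs@interval)))
  cfg <- list(
    name = design@name,
    contig = .design_contig(design),
    reference_window = list(start = unname(start(design@referenceWindow)),
                            end = unname(end(design@referenceWindow))),
    guides = list(g(pair@guideA), g(pair@guideB)),
    amplicon_region = list(start = unname(start(design@ampliconRegion)),
                           end = unname(end(design@ampliconRegion))),
    htgts = list(primer_length = design@htgtsPrimerLength,
                 offset = design@htgtsOffset),
    quant_window_half = design@quantWindowHalf)
  if (!is.null(design@donor)) {
    cfg$donor <- list(payload = as.character(design@donor@payload),
                      ha_length = unname(width(design@donor@leftArm)))
  }
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname writeLocusDesign
#' @export
readLocusDesign <- function(path, genome) {
  cfg <- yaml::read_yaml(path)
  for (req in c("name", "contig", "guides"))
    if (is.null(cfg[[req]])) .stopf("design YAML missing field '%s'", req)
  if (length(cfg$guides) != 2L)
    .stopf("design YAML must define exactly two guides")
  gs <- lapply(cfg$guides, function(x)
    guideSite(genome, cfg$contig, x$start, x$strand, id = x$id))
  pair <- nickPair(gs[[1L]], gs[[2L]])
  donor <- NULL
  if (!is.null(cfg$donor))
    donor <- donorTemplate(genome, pair, cfg$donor$payload,
                           haLength = cfg$donor$ha_length)
  rw <- if (!is.null(cfg$reference_window))
    GRanges(cfg$contig, IRanges(cfg$reference_window$start,
                                cfg$reference_window$end)) else NULL
  ar <- if (!is.null(cfg$amplicon_region))
    GRanges(cfg$contig, IRanges(cfg$amplicon_region$start,
                                cfg$amplicon_region$end)) else NULL
  locusDesign(cfg$name, genome, pair, donor = donor,
              referenceWindow = rw, ampliconRegion = ar,
              htgtsOffset = cfg$htgts$offset %||% 60L,
              htgtsPrimerLength = cfg$htgts$primer_length %||% 20L,
              quantWindowHalf = cfg$quant_window_half %||% 10L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.design_contig <- function(design) {
  as.character(seqnames(design@referenceWindow))
}

.design_nicks <- function(design) {
  c(a = design@nickPair@guideA@nick, b = design@nickPair@guideB@nick)
}

#' Per-nick indel quantification windows
#'
#' @param design a [LocusDesign-class].
#' @return [GenomicRanges::GRanges] of one window per nick
#'   (nick +/- `quantWindowHalf`).
#' @export
quantWindows <- function(design) {
  nk <- .design_nicks(design)
  h <- design@quantWindowHalf
  GRanges(.design_contig(design),
          IRanges(nk - h, nk + h), nick = unname(nk))
}

#' Build the HDR-edited reference window
#'
#' Returns the reference window with the donor payload substituted between
#' the nick positions. HA anchors are re-checked against the reference; a
#' mismatch is a design error.
#'
#' @param design a [LocusDesign-class] with a donor.
#' @param genome genome object.
#' @param minHa minimum HA length below which a warning is emitted.
#' @return character DNA sequence of the HDR allele over the reference
#'   window.
#' @export
buildHdrSequence <- function(design, genome, minHa = 800L) {
  donor <- design@donor
  if (is.null(donor)) .stopf("design '%s' has no donor", design@name)
  for (arm in list(donor@leftArm, donor@rightArm)) {
    if (width(arm) < minHa)
      .warnf("homology arm of %d bp is shorter than the minimum %d bp",
             width(arm), minHa)
  }
  contig <- .design_contig(design)
  nk <- .design_nicks(design)
  ws <- start(design@referenceWindow)
  we <- end(design@referenceWindow)
  # verify HA anchors against the reference (left arm abuts the upstream
  # nick, right arm the downstream nick; both are genome-matching by design)
  left_ref <- .gr_seq(genome, donor@leftArm)
  right_ref <- .gr_seq(genome, donor@rightArm)
  if (end(donor@leftArm) != nk["a"] || start(donor@rightArm) != nk["b"] + 1L)
    .stopf("donor homology arms are not anchored at the nick positions")
  stopifnot(nchar(left_ref) == width(donor@leftArm),
            nchar(right_ref) == width(donor@rightArm))
  paste0(.genome_seq(genome, contig, ws, nk["a"]),
         as.character(donor@payload),
         .genome_seq(genome, contig, nk["b"] + 1L, we))
}

.new_amplicon <- function(class, seq, junctions, anchors) {
  new("ExpectedAmplicon", outcomeClass = class, sequence = DNAString(seq),
      junctions = as.integer(junctions) |>
        setNames(names(junctions)),
      anchors = as.integer(anchors) |> setNames(names(anchors)))
}

#' Build the in-silico expected-outcome amplicons for a design
#'
#' Renders one sequence per expected editing-outcome class over a chosen
#' region of the design: WT (the reference), HDR (payload substituted
#' between the nicks; omitted with a warning when the design has no donor),
#' DELETION (precise nick-to-nick join), INVERSION (nick-to-nick segment
#' reverse-complemented in place), and AAV_INTEGRATION (the ITR joined at
#' each nick in both orientations). These sequences drive both the read
#' simulators and the classifiers.
#'
#' @param design a [LocusDesign-class].
#' @param genome genome object.
#' @param itr ITR sequence for the AAV-integration amplicons (DNA); use
#'   [itrSequence()] for the package default.
#' @param region `"reference"` (full reference window; HTGTS scale) or
#'   `"amplicon"` (the amplicon-seq region).
#' @return named list of [ExpectedAmplicon-class]: `WT`, `HDR`, `DELETION`,
#'   `INVERSION`, `AAV_A_FWD`, `AAV_A_REV`, `AAV_B_FWD`, `AAV_B_REV`.
#' @export
buildExpectedAmplicons <- function(design, genome, itr = itrSequence(),
                                   region = c("reference", "amplicon")) {
  region <- match.arg(region)
  gr <- if (region == "reference") design@referenceWindow else
    design@ampliconRegion
  contig <- .design_contig(design)
  rs <- start(gr)
  nk <- .design_nicks(design)
  a_off <- unname(nk["a"]) - rs + 1L   # last base before upstream cut, 1-based
  b_off <- unname(nk["b"]) - rs + 1L
  wt <- .gr_seq(genome, gr)
  itr <- .seq_chr(itr)
  stopifnot(a_off >= 1L, b_off <= nchar(wt))

  prefix <- substr(wt, 1L, a_off)
  spacer <- substr(wt, a_off + 1L, b_off)
  suffix <- substr(wt, b_off + 1L, nchar(wt))
  base_anchor <- c(nickA = a_off, nickB = b_off, regionStart = rs)

  out <- list(
    WT = .new_amplicon("WT", wt, c(), base_anchor),
    DELETION = .new_amplicon("DELETION", paste0(prefix, suffix),
                             c(join = a_off),
                             c(nickA = a_off, nickB = a_off, regionStart = rs)),
    INVERSION = .new_amplicon("INVERSION",
                              paste0(prefix, .revcomp_chr(spacer), suffix),
                              c(left = a_off, right = b_off), base_anchor))
  if (!is.null(design@donor)) {
    payload <- as.character(design@donor@payload)
    hdr <- paste0(prefix, payload, suffix)
    dv <- design@donor@diagnosticVariants
    anchors <- c(nickA = a_off,
                 nickB = a_off + nchar(payload),
                 regionStart = rs)
    if (nrow(dv)) {
      diag_off <- a_off + dv$offset
      names(diag_off) <- paste0("diag", seq_len(nrow(dv)))
      anchors <- c(anchors, diag_off)
    }
    out$HDR <- .new_amplicon("HDR", hdr,
                             c(left = a_off, right = a_off + nchar(payload)),
                             anchors)
  } else {
    .warnf("design '%s' has no donor; HDR amplicon omitted", design@name)
  }
  for (side in c("A", "B")) {
    off <- if (side == "A") a_off else b_off
    pre <- substr(wt, 1L, off)
    suf <- substr(wt, off + 1L, nchar(wt))
    for (ori in c("FWD", "REV")) {
      tag <- if (ori == "FWD") itr else .revcomp_chr(itr)
      nm <- paste0("AAV_", side, "_", ori)
      out[[nm]] <- .new_amplicon(
        "AAV_INTEGRATION", paste0(pre, tag, suf),
        c(left = off, right = off + nchar(tag)),
        c(nickA = a_off, nickB = b_off, regionStart = rs, itrLen = nchar(tag)))
    }
  }
  out
}
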