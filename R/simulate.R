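#' Simulation configuration
#'
#' Validates and normalizes the knobs shared by the three read simulators.
#' Outcome proportions must sum to 1; the per-base substitution error rate
#' is capped at 0.1; indel sizes follow a geometric distribution truncated
#' to 1-20 nt.
#'
#' @param assay `"AMPLICON"`, `"TAG_JUNCTION"` or `"HTGTS"`.
#' @param proportions named numeric vector of outcome-class fractions.
#' @param nReads read count.
#' @param readLength read length in nt; `NA` means read the full template
#'   (long-amplicon mode).
#' @param errorRate per-base substitution probability, in `[0, 0.1]`.
#' @param indelGeomP geometric parameter for simulated indel sizes.
#' @param tag `"dsodn"`, `"itr"`, or an explicit tag sequence.
#' @param tagSuffixLength length of the tag-derived read prefix (the part of
#'   the tag sequenced before the genomic junction).
#' @param backgroundReads tag-free background reads to emit (tag assays).
#' @param duplication mean extra PCR copies per molecule (tag assays).
#' @param side HTGTS enrichment side, `"5p"` or `"3p"`.
#' @param translocationPartner `"planted"` (junctions to planted off-target
#'   sites) or `"random"` (random loci, for testing the 5000-bp rejection
#'   rule).
#' @param seed integer seed.
#' @return a validated `SimulationConfig` list.
#' @export
simulationConfig <- function(assay = c("AMPLICON", "TAG_JUNCTION", "HTGTS"),
                             proportions = c(WT = 1),
                             nReads = 1000L, readLength = NA_integer_,
                             errorRate = 0, indelGeomP = 0.35,
                             tag = "dsodn", tagSuffixLength = 16L,
                             backgroundReads = 0L, duplication = 0,
                             side = c("5p", "3p"),
                             translocationPartner = c("planted", "random"),
                             seed = 1L) {
  assay <- match.arg(assay)
  side <- match.arg(side)
  translocationPartner <- match.arg(translocationPartner)
  if (length(proportions) && abs(sum(proportions) - 1) > 1e-9)
    .stopf("outcome proportions must sum to 1 (got %g)", sum(proportions))
  if (any(proportions < 0)) .stopf("proportions must be non-negative")
  if (errorRate < 0 || errorRate > 0.1)
    .stopf("errorRate must be in [0, 0.1]")
  if (nReads <= 0) .stopf("nReads must be positive")
  structure(list(assay = assay, proportions = proportions,
                 nReads = as.integer(nReads), readLength = readLength,
                 errorRate = errorRate, indelGeomP = indelGeomP,
                 tag = tag, tagSuffixLength = as.integer(tagSuffixLength),
                 backgroundReads = as.integer(backgroundReads),
                 duplication = duplication, side = side,
                 translocationPartner = translocationPartner,
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

.resolve_tag <- function(tag) {
  if (identical(tag, "dsodn")) return(dsodnTag())
  if (identical(tag, "itr")) return(itrSequence())
  .seq_chr(tag)
}

.trunc_read <- function(seq, readLength) {
  if (is.na(readLength) || nchar(seq) <= readLength) seq
  else substr(seq, 1L, readLength)
}

# geometric indel size truncated to 1..20 nt
.indel_size <- function(p) min(1L + rgeom(1L, p), 20L)

.sim_result <- function(reads, truth, config) {
  stopifnot(!anyDuplicated(truth$read_id))
  structure(list(reads = DNAStringSet(setNames(reads, truth$read_id)),
                 truth = truth, config = config),
            class = "SimulatedReads")
}

#' @export
print.SimulatedReads <- function(x, ...) {
  cat("SimulatedReads (", x$config$assay, "): ",
      length(x$reads), " reads; classes: ",
      paste(names(table(x$truth$class)), table(x$truth$class),
            sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

# draw per-read class labels for an exact multinomial draw, interleaved
.draw_classes <- function(n, proportions) {
  counts <- as.vector(rmultinom(1L, n, proportions))
  sample(rep(names(proportions), counts))
}

# apply one insertion or deletion at template position `pos` (indel placed
# immediately 3' of the cut); returns list(seq, detail)
.apply_indel <- function(seq, pos, geom_p) {
  size <- .indel_size(geom_p)
  if (runif(1L) < 0.5) {
    ins <- .random_dna(size)
    list(seq = paste0(substr(seq, 1L, pos), ins,
                      substr(seq, pos + 1L, nchar(seq))),
         detail = sprintf("ins:%d@%d", size, pos))
  } else {
    size <- min(size, nchar(seq) - pos)
    list(seq = paste0(substr(seq, 1L, pos),
                      substr(seq, pos + size + 1L, nchar(seq))),
         detail = sprintf("del:%d@%d", size, pos))
  }
}

#' Simulate amplicon-seq reads with ground truth
#'
#' Draws reads from the expected amplicons of a design per a multinomial
#' over outcome classes `WT`, `HDR`, `HDR_IMPERFECT`, `INDEL`. `INDEL`
#' reads carry one insertion or deletion (geometric size, 1-20 nt) at a
#' uniformly chosen nick; `HDR_IMPERFECT` reads are HDR reads with one such
#' indel at a payload junction. Substitution errors are injected per base at
#' `errorRate`. Deterministic per seed (byte-identical FASTQ on re-run).
#'
#' @param design a [LocusDesign-class].
#' @param genome genome object.
#' @param config a [simulationConfig()] with assay `"AMPLICON"`.
#' @return `SimulatedReads`: `reads` ([Biostrings::DNAStringSet] named by
#'   read id), `truth` (data.frame `read_id`, `class`, `detail`), `config`.
#' @export
simulateAmpliconReads <- function(design, genome, config) {
  stopifnot(config$assay == "AMPLICON")
  classes <- names(config$proportions)
  bad <- setdiff(classes, c("WT", "HDR", "HDR_IMPERFECT", "INDEL"))
  if (length(bad)) .stopf("unknown amplicon class(es): %s",
                          paste(bad, collapse = ", "))
  if (any(c("HDR", "HDR_IMPERFECT") %in% classes) && is.null(design@donor))
    .stopf("HDR classes requested but the design has no donor")
  amp <- suppressWarnings(
    buildExpectedAmplicons(design, genome, region = "amplicon"))
  wt <- as.character(amp$WT@sequence)
  hdr <- if (!is.null(amp$HDR)) as.character(amp$HDR@sequence) else NULL
  wt_nicks <- amp$WT@anchors[c("nickA", "nickB")]
  hdr_nicks <- if (!is.null(amp$HDR)) amp$HDR@junctions else NULL

  set.seed(config$seed)
  labels <- .draw_classes(config$nReads, config$proportions)
  reads <- character(config$nReads)
  detail <- character(config$nReads)
  for (i in seq_len(config$nReads)) {
    cls <- labels[i]
    if (cls == "WT") {
      r <- wt; d <- "wt"
    } else if (cls == "HDR") {
      r <- hdr; d <- "hdr"
    } else if (cls == "INDEL") {
      nick <- unname(sample(wt_nicks, 1L))
      x <- .apply_indel(wt, nick, config$indelGeomP)
      r <- x$seq; d <- x$detail
    } else {  # HDR_IMPERFECT
      nick <- unname(sample(hdr_nicks, 1L))
      x <- .apply_indel(hdr, nick, config$indelGeomP)
      r <- x$seq; d <- x$detail
    }
    r <- .inject_substitutions(r, config$errorRate)
    reads[i] <- .trunc_read(r, config$readLength)
    detail[i] <- d
  }
  truth <- data.frame(
    read_id = sprintf("amp_%05d", seq_len(config$nReads)),
    class = labels, detail = detail, stringsAsFactors = FALSE)
  .sim_result(reads, truth, config)
}

#' Simulate tag-junction (GUIDE-seq / AAV-seq) reads with ground truth
#'
#' Each integration event contributes `molecules` sequenced molecules; a
#' molecule's read is the tag-primer suffix followed by the genomic flank
#' from the integration point to a Tn5 shear point drawn uniformly 100-600
#' nt away. Both tag orientations are supported (`"+"` reads rightward from
#' the junction, `"-"` leftward on the reverse complement, `"both"` draws
#' per molecule). Tag-free background reads and PCR duplicates are emitted
#' at configurable rates. Truth records carry the integration coordinate,
#' orientation and shear coordinate.
#'
#' @param design a [LocusDesign-class] (unused beyond bookkeeping; events
#'   define the junctions).
#' @param genome genome object.
#' @param events data.frame with columns `coord` (integration boundary:
#'   junction falls between `coord` and `coord + 1`), `orientation`
#'   (`"+"`, `"-"`, `"both"`), `molecules`.
#' @param config a [simulationConfig()] with assay `"TAG_JUNCTION"`.
#' @return `SimulatedReads`; truth columns `read_id`, `class`
#'   (`INTEGRATION`/`BACKGROUND`), `coord`, `orientation`, `shear`,
#'   `molecule`.
#' @export
simulateTagReads <- function(design, genome, events, config) {
  stopifnot(config$assay == "TAG_JUNCTION")
  tag <- .resolve_tag(config$tag)
  sfx_len <- config$tagSuffixLength
  sfx_fwd <- substr(tag, nchar(tag) - sfx_len + 1L, nchar(tag))
  rc <- .revcomp_chr(tag)
  sfx_rev <- substr(rc, nchar(rc) - sfx_len + 1L, nchar(rc))
  ctg <- .contigs(genome)
  contig <- names(ctg)[1L]
  glen <- nchar(as.character(ctg[[contig]]))
  rl <- if (is.na(config$readLength)) 700L else config$readLength

  set.seed(config$seed)
  reads <- character(0L); rows <- list()
  mol_id <- 0L
  if (!is.null(events) && nrow(events)) {
    for (e in seq_len(nrow(events))) {
      coord <- events$coord[e]
      if (coord < 700L || coord > glen - 700L)
        .stopf("event coordinate %d outside the usable genome", coord)
      for (m in seq_len(events$molecules[e])) {
        mol_id <- mol_id + 1L
        ori <- events$orientation[e]
        if (ori == "both") ori <- sample(c("+", "-"), 1L)
        d <- as.integer(round(runif(1L, 100, 600)))
        if (ori == "+") {
          flank <- .genome_seq(genome, contig, coord + 1L, coord + d)
          shear <- coord + d
          r <- paste0(sfx_fwd, flank)
        } else {
          flank <- .revcomp_chr(
            .genome_seq(genome, contig, coord - d + 1L, coord))
          shear <- coord - d + 1L
          r <- paste0(sfx_rev, flank)
        }
        copies <- 1L + (if (config$duplication > 0)
          rgeom(1L, 1 / (1 + config$duplication)) else 0L)
        for (cp in seq_len(copies)) {
          r_err <- .trunc_read(.inject_substitutions(r, config$errorRate), rl)
          reads <- c(reads, r_err)
          rows[[length(rows) + 1L]] <- data.frame(
            class = "INTEGRATION", coord = coord, orientation = ori,
            shear = shear, molecule = mol_id, stringsAsFactors = FALSE)
        }
      }
    }
  }
  for (b in seq_len(config$backgroundReads)) {
    d <- as.integer(round(runif(1L, 100, 600)))
    p <- as.integer(round(runif(1L, 700, glen - 700)))
    frag <- .genome_seq(genome, contig, p, p + d - 1L)
    if (runif(1L) < 0.5) frag <- .revcomp_chr(frag)
    reads <- c(reads,
               .trunc_read(.inject_substitutions(frag, config$errorRate), rl))
    rows[[length(rows) + 1L]] <- data.frame(
      class = "BACKGROUND", coord = NA_integer_,
      orientation = NA_character_, shear = NA_integer_,
      molecule = NA_integer_, stringsAsFactors = FALSE)
  }
  truth <- if (length(rows)) do.call(rbind, rows) else
    data.frame(class = character(), coord = integer(),
               orientation = character(), shear = integer(),
               molecule = integer())
  truth <- cbind(read_id = sprintf("tag_%05d", seq_len(nrow(truth))), truth,
                 stringsAsFactors = FALSE)
  .sim_result(reads, truth, config)
}

# ---- HTGTS templates -------------------------------------------------------

# Per-side read templates derived from the expected amplicons. A template
# is the post-priming read sequence: for 5' enrichment the amplicon from
# the genome interface (nickA - offset) rightward; for 3' enrichment the
# reverse complement of the amplicon up to nickB + offset. Template
# coordinates start at 1 at the interface.
.htgts_templates <- function(design, genome, itr = itrSequence(),
                             side = "5p") {
  amp <- buildExpectedAmplicons(design, genome, itr = itr,
                                region = "reference")
  off <- design@htgtsOffset
  plen <- design@htgtsPrimerLength
  h <- design@quantWindowHalf
  a_off <- amp$WT@anchors[["nickA"]]
  b_off <- amp$WT@anchors[["nickB"]]
  wt <- as.character(amp$WT@sequence)
  # amplicon offset of the genome base at nickB for every class (the
  # position preceding the shared downstream suffix)
  suffix_anchor <- function(a) a@anchors[["nickB"]]
  tpl <- list(); nicks <- list()
  if (side == "5p") {
    primer <- substr(wt, a_off - off - plen + 1L, a_off - off)
    ifc <- a_off - off        # amplicon offset of the interface base
    for (nm in names(amp)) {
      s <- as.character(amp[[nm]]@sequence)
      tpl[[nm]] <- substr(s, ifc + 1L, nchar(s))
      nicks[[nm]] <- c(proximal = off,
                       distal = suffix_anchor(amp[[nm]]) - ifc)
    }
    interface_coord <- amp$WT@anchors[["regionStart"]] + ifc - 1L
  } else {
    for (nm in names(amp)) {
      s <- as.character(amp[[nm]]@sequence)
      end_off <- suffix_anchor(amp[[nm]]) + off
      tpl[[nm]] <- .revcomp_chr(substr(s, 1L, end_off))
      # template position of the proximal (nickB) cut boundary is `off`;
      # distal (nickA) lies `spacer`-like distance further in
      nicks[[nm]] <- c(proximal = off,
                       distal = end_off - amp[[nm]]@anchors[["nickA"]])
    }
    primer <- .revcomp_chr(
      .genome_seq(genome, .design_contig(design),
                  design@nickPair@guideB@nick + off + 1L,
                  design@nickPair@guideB@nick + off + plen))
    interface_coord <- design@nickPair@guideB@nick + off
  }
  # diagnostic-variant offsets in HDR template coordinates
  diag_tpl <- integer(0L)
  if (!is.null(amp$HDR)) {
    dg <- amp$HDR@anchors[grepl("^diag", names(amp$HDR@anchors))]
    if (side == "5p") {
      diag_tpl <- unname(dg - (a_off - off))
    } else {
      end_off <- suffix_anchor(amp$HDR) + off
      diag_tpl <- unname(end_off - dg + 1L)
    }
  }
  list(amplicons = amp, templates = tpl, nicks = nicks, primer = primer,
       side = side, interface = interface_coord, quantHalf = h,
       diagOffsets = sort(diag_tpl), itr = .seq_chr(itr),
       proximalNickCoord = if (side == "5p") design@nickPair@guideA@nick
                           else design@nickPair@guideB@nick)
}

#' Simulate LAM-HTGTS reads with ground truth
#'
#' Reads begin with the nested primer of the chosen enrichment side and
#' read across the proximal nick into the class-defining structure. Classes:
#' `WT`, `HDR`, `INDEL` (one 1-20-nt indel at a uniformly chosen nick),
#' `DELETION` (precise nick-to-nick join), `INVERSION`, `AAV_INTEGRATION`
#' (ITR joined at the proximal nick), `TRANSLOCATION` (proximal segment
#' joined to a planted off-target site, or to a random locus when
#' `translocationPartner = "random"`), and `FREE_AAV` (random fragments of
#' the AAV donor, emulating residual vector: these lack the nested-primer
#' anchoring and must be rejected at the priming check).
#'
#' @param design a [LocusDesign-class].
#' @param genome [MiniGenome-class] (planted off-targets provide
#'   translocation partners).
#' @param config a [simulationConfig()] with assay `"HTGTS"`.
#' @param itr ITR sequence.
#' @return `SimulatedReads`; truth columns `read_id`, `class`, `detail`,
#'   `partner` (translocation partner coordinate, NA otherwise).
#' @export
simulateHtgtsReads <- function(design, genome, config, itr = itrSequence()) {
  stopifnot(config$assay == "HTGTS")
  classes <- names(config$proportions)
  known <- c("WT", "HDR", "INDEL", "DELETION", "INVERSION",
             "AAV_INTEGRATION", "TRANSLOCATION", "FREE_AAV")
  bad <- setdiff(classes, known)
  if (length(bad)) .stopf("unknown HTGTS class(es): %s",
                          paste(bad, collapse = ", "))
  if ("HDR" %in% classes && is.null(design@donor))
    .stopf("HDR requested but the design has no donor")
  ot <- if (is(genome, "MiniGenome")) genome@offTargets else GRanges()
  if ("TRANSLOCATION" %in% classes && length(ot) == 0L &&
      config$translocationPartner == "planted")
    .stopf("TRANSLOCATION requested with no planted off-targets and random partners disabled")
  tp <- .htgts_templates(design, genome, itr = itr, side = config$side)
  rl <- if (is.na(config$readLength)) 450L else config$readLength
  body_len <- rl - nchar(tp$primer)
  contig <- .design_contig(design)
  glen <- nchar(as.character(.contigs(genome)[[contig]]))
  donor_seq <- if (!is.null(design@donor)) {
    paste0(.gr_seq(genome, design@donor@leftArm),
           as.character(design@donor@payload),
           .gr_seq(genome, design@donor@rightArm))
  } else NULL
  aav_name <- if (config$side == "5p") "AAV_A_FWD" else "AAV_B_FWD"

  set.seed(config$seed)
  labels <- .draw_classes(config$nReads, config$proportions)
  reads <- character(config$nReads)
  detail <- character(config$nReads)
  partner <- rep(NA_integer_, config$nReads)
  for (i in seq_len(config$nReads)) {
    cls <- labels[i]
    d <- tolower(cls)
    if (cls %in% c("WT", "HDR", "DELETION", "INVERSION")) {
      body <- substr(tp$templates[[cls]], 1L, body_len)
      r <- paste0(tp$primer, body)
    } else if (cls == "AAV_INTEGRATION") {
      body <- substr(tp$templates[[aav_name]], 1L, body_len)
      r <- paste0(tp$primer, body)
    } else if (cls == "INDEL") {
      nick <- unname(sample(tp$nicks$WT, 1L))
      x <- .apply_indel(tp$templates$WT, nick, config$indelGeomP)
      r <- paste0(tp$primer, substr(x$seq, 1L, body_len))
      d <- x$detail
    } else if (cls == "TRANSLOCATION") {
      prox <- substr(tp$templates$WT, 1L, tp$nicks$WT[["proximal"]])
      if (config$translocationPartner == "planted") {
        j <- sample.int(length(ot), 1L)
        pc <- mcols(ot)$nick[j]
      } else {
        repeat {
          pc <- as.integer(round(runif(1L, 2000, glen - 2000)))
          far <- all(abs(pc - start(ot)) > 6000) &&
            abs(pc - tp$proximalNickCoord) > 6000
          if (far) break
        }
      }
      dist_len <- body_len - nchar(prox)
      distal <- if (runif(1L) < 0.5)
        .genome_seq(genome, contig, pc + 1L, pc + dist_len)
      else
        .revcomp_chr(.genome_seq(genome, contig, pc - dist_len + 1L, pc))
      r <- paste0(tp$primer, prox, distal)
      partner[i] <- pc
      d <- sprintf("partner@%d", pc)
    } else {  # FREE_AAV
      pmax <- nchar(donor_seq) - rl
      repeat {
        p <- as.integer(round(runif(1L, 1, pmax)))
        # a random donor fragment must not begin exactly at the nested
        # primer (free AAV is never primer-anchored)
        frag <- substr(donor_seq, p, p + rl - 1L)
        if (substr(frag, 1L, nchar(tp$primer)) != tp$primer) break
      }
      r <- frag
    }
    reads[i] <- .inject_substitutions(r, config$errorRate)
    detail[i] <- d
  }
  truth <- data.frame(
    read_id = sprintf("htgts_%05d", seq_len(config$nReads)),
    class = labels, detail = detail, partner = partner,
    stringsAsFactors = FALSE)
  .sim_result(reads, truth, config)
}

#' Write a simulation to FASTQ + truth TSV
#'
#' FASTQ qualities are constant Q30 (the pipeline ignores qualities).
#'
#' @param sim a `SimulatedReads` object.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the paths written (`fastq`, `truth`).
#' @export
writeSimulation <- function(sim, dir, prefix = sim$config$assay) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fq <- file.path(dir, paste0(prefix, ".fastq"))
  quals <- Biostrings::BStringSet(strrep("?", Biostrings::width(sim$reads)))
  Biostrings::writeXStringSet(sim$reads, fq, format = "fastq",
                              qualities = quals)
  tr <- file.path(dir, paste0(prefix, "_truth.tsv"))
  writeTsv(sim$truth, tr, meta = c(assay = sim$config$assay,
                                   seed = sim$config$seed))
  invisible(list(fastq = fq, truth = tr))
}

#' Read simulated (or real) reads from FASTQ
#'
#' @param path FASTQ path (Phred+33).
#' @return named [Biostrings::DNAStringSet].
#' @export
readFastqReads <- function(path) {
  Biostrings::readDNAStringSet(path, format = "fastq")
}
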