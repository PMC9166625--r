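#' @importClassesFrom Biostrings DNAString DNAStringSet
#' @importClassesFrom GenomicRanges GRanges
#' @importFrom GenomicRanges GRanges seqnames start end strand width
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<- DataFrame
NULL

setClassUnion("DNAStringOrNULL", c("DNAString", "NULL"))

#' GuideSite: a validated SpCas9(n) guide placement
#'
#' Represents one sgRNA target site: the 20-nt protospacer, its NGG PAM, the
#' genomic interval covered by protospacer+PAM, and the nick coordinate.
#' Coordinates follow the Bioconductor convention (1-based, closed intervals,
#' as in [GenomicRanges::GRanges]); the nick coordinate is the plus-strand
#' position immediately 5' of the cut, i.e. Cas9(n) cuts between `nick` and
#' `nick + 1`, 3 nt 5' of the PAM (between protospacer positions 17 and 18).
#'
#' @slot id guide identifier.
#' @slot protospacer 20-nt [Biostrings::DNAString].
#' @slot pam 3-nt PAM matching NGG.
#' @slot interval [GenomicRanges::GRanges] of protospacer+PAM (width 23).
#' @slot nick integer nick coordinate (see above).
#' @export
setClass("GuideSite",
  slots = c(
    id = "character",
    protospacer = "DNAString",
    pam = "DNAString",
    interval = "GRanges",
    nick = "integer"
  )
)

setValidity("GuideSite", function(object) {
  msg <- character()
  if (length(object@protospacer) != 20L)
    msg <- c(msg, "protospacer must be 20 nt")
  pam <- as.character(object@pam)
  if (nchar(pam) != 3L || substr(pam, 2L, 3L) != "GG")
    msg <- c(msg, "PAM must be 3 nt matching NGG")
  if (length(object@interval) != 1L || width(object@interval) != 23L)
    msg <- c(msg, "interval must be a single range of width 23")
  if (length(msg)) msg else TRUE
})

#' NickPair: a pair of nickase guides
#'
#' Houses the paired-guide geometry of the spacer-nick design: two
#' [GuideSite-class] objects on one contig, the distance between their nick
#' positions, and the PAM orientation class (`PAM_OUT`, `PAM_IN`, `TANDEM`).
#' Spacer-nick designs use PAM-out pairs at a spacer distance of 200-350 bp.
#'
#' @slot guideA,guideB [GuideSite-class] objects (A upstream of B).
#' @export
setClass("NickPair", slots = c(guideA = "GuideSite", guideB = "GuideSite"))

setValidity("NickPair", function(object) {
  ca <- as.character(seqnames(object@guideA@interval))
  cb <- as.character(seqnames(object@guideB@interval))
  if (!identical(ca, cb)) return("guides must lie on the same contig")
  TRUE
})

#' DonorTemplate: an HDR donor with anchored homology arms
#'
#' The donor carries a left and right homology arm (HA) that match the
#' reference genome at their anchors, flanking a payload (modified
#' exon with silent mutations / diagnostic restriction site, or codon-modified
#' cDNA). Both HAs lie entirely outside the nick-to-nick interval; the
#' payload replaces the nick-to-nick ("mini-homologous") segment.
#'
#' @slot leftArm,rightArm [GenomicRanges::GRanges] anchors of the HAs on the
#'   reference; the left arm ends at the upstream nick, the right arm starts
#'   one base after the downstream nick.
#' @slot payload [Biostrings::DNAString] replacing the nick-to-nick segment.
#' @slot diagnosticVariants data.frame with columns `offset` (1-based within
#'   payload), `ref`, `alt` — the donor-encoded diagnostic substitutions.
#' @export
setClass("DonorTemplate",
  slots = c(
    leftArm = "GRanges",
    rightArm = "GRanges",
    payload = "DNAString",
    diagnosticVariants = "data.frame"
  )
)

setClassUnion("DonorTemplateOrNULL", c("DonorTemplate", "NULL"))
setClassUnion("NickPairOrNULL", c("NickPair", "NULL"))

#' LocusDesign: one targeted locus
#'
#' Bundles everything the simulators and classifiers need about a locus: the
#' reference window, the guide pair (or single guide), the donor, the
#' amplicon-seq region, outer (LAM) primer positions flanking the HAs,
#' nested HTGTS primers near the cleavage sites (~50-100 bp), and per-nick
#' quantification windows.
#'
#' @slot name locus name.
#' @slot referenceWindow [GenomicRanges::GRanges] locus window on the genome.
#' @slot nickPair [NickPair-class] (or NULL when a single guide is used).
#' @slot singleGuide [GuideSite-class] or NULL.
#' @slot donor [DonorTemplate-class] or NULL.
#' @slot ampliconRegion [GenomicRanges::GRanges] region amplified for
#'   amplicon-seq (covers both nicks with margin).
#' @slot outerPrimers integer(2): plus-strand start of the 5' LAM primer and
#'   minus-strand start (rightmost base) of the 3' LAM primer, outside the HAs.
#' @slot htgtsPrimerLength integer, nested primer length.
#' @slot htgtsOffset integer, distance from each nick to its nested primer's
#'   genome interface (50-100 bp).
#' @slot quantWindowHalf integer, half-width of the indel quantification
#'   window around each nick.
#' @export
setClass("LocusDesign",
  slots = c(
    name = "character",
    referenceWindow = "GRanges",
    nickPair = "NickPairOrNULL",
    singleGuide = "ANY",
    donor = "DonorTemplateOrNULL",
    ampliconRegion = "GRanges",
    outerPrimers = "integer",
    htgtsPrimerLength = "integer",
    htgtsOffset = "integer",
    quantWindowHalf = "integer"
  ),
  prototype = list(
    singleGuide = NULL,
    donor = NULL,
    htgtsPrimerLength = 20L,
    htgtsOffset = 60L,
    quantWindowHalf = 10L
  )
)

#' ExpectedAmplicon: an in-silico sequence for one editing outcome
#'
#' Each expected outcome class (WT, HDR, DELETION, INVERSION,
#' AAV_INTEGRATION) is rendered as the sequence a read of that class derives
#' from, with the positions of its class-defining junctions. The same
#' amplicons drive both read simulation and read classification.
#'
#' @slot outcomeClass one of WT, HDR, DELETION, INVERSION, AAV_INTEGRATION.
#' @slot sequence [Biostrings::DNAString].
#' @slot junctions named integer vector of class-defining positions within
#'   `sequence` (e.g. nick offsets, payload junctions, ITR junction).
#' @slot anchors named integer vector of bookkeeping offsets within
#'   `sequence`: nick offsets, diagnostic-variant offsets, region start.
#' @export
setClass("ExpectedAmplicon",
  slots = c(
    outcomeClass = "character",
    sequence = "DNAString",
    junctions = "integer",
    anchors = "integer"
  )
)

#' MiniGenome: a desk-scale reference with planted off-target sites
#'
#' A small stand-in for a genome-scale reference: one or more contigs with
#' the on-target locus embedded once and a configurable number of planted
#' off-target sites, each differing from protospacer+PAM by a recorded number
#' of substitutions. Lets the 5000-bp off-target window rule be exercised
#' without genome-scale mapping.
#'
#' @slot contigs [Biostrings::DNAStringSet].
#' @slot offTargets [GenomicRanges::GRanges] of planted sites with mcols
#'   `guide_id`, `mismatch_count`, `bulge_count`, `match_string`, `nick`.
#' @slot onTarget [GenomicRanges::GRanges] of the embedded reference window.
#' @export
setClass("MiniGenome",
  slots = c(
    contigs = "DNAStringSet",
    offTargets = "GRanges",
    onTarget = "GRanges"
  )
)

setMethod("show", "GuideSite", function(object) {
  cat("GuideSite", object@id, ":",
      as.character(object@protospacer), paste0("[", as.character(object@pam), "]"),
      "\n  ", as.character(seqnames(object@interval)), ":",
      start(object@interval), "-", end(object@interval),
      "(", as.character(strand(object@interval)), ") nick @", object@nick, "\n")
})

setMethod("show", "NickPair", function(object) {
  cat("NickPair:", object@guideA@id, "+", object@guideB@id,
      "| spacer", spacerDistance(object), "bp |",
      pamOrientation(object), "\n")
})

setMethod("show", "LocusDesign", function(object) {
  cat("LocusDesign", object@name, "\n")
  cat("  window: ", as.character(seqnames(object@referenceWindow)), ":",
      start(object@referenceWindow), "-", end(object@referenceWindow), "\n", sep = "")
  if (!is.null(object@nickPair)) show(object@nickPair)
  cat("  donor:", if (is.null(object@donor)) "none" else
      paste0(length(object@donor@payload), "-nt payload, HAs ",
             width(object@donor@leftArm), "/", width(object@donor@rightArm), " bp"),
      "\n")
})

setMethod("show", "MiniGenome", function(object) {
  cat("MiniGenome:", length(object@contigs), "contig(s),",
      sum(Biostrings::width(object@contigs)), "bp total,",
      length(object@offTargets), "planted off-target site(s)\n")
})

setMethod("show", "ExpectedAmplicon", function(object) {
  cat("ExpectedAmplicon", object@outcomeClass, ":",
      length(object@sequence), "nt; junctions:",
      paste(names(object@junctions), object@junctions, collapse = ", "), "\n")
})

# ---- accessors -------------------------------------------------------------

#' Accessors for design objects
#'
#' @param x a package object.
#' @return the corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
guideId <- function(x) x@id

#' @rdname accessors
#' @export
protospacer <- function(x) x@protospacer

#' @rdname accessors
#' @export
guideInterval <- function(x) x@interval

#' @rdname accessors
#' @export
ampliconClass <- function(x) x@outcomeClass

#' @rdname accessors
#' @export
ampliconSeq <- function(x) x@sequence

#' @rdname accessors
#' @export
ampliconJunctions <- function(x) x@junctions

#' @rdname accessors
#' @export
genomeContigs <- function(x) x@contigs

#' @rdname accessors
#' @export
plantedOffTargets <- function(x) x@offTargets

#' @rdname accessors
#' @export
onTargetWindow <- function(x) x@onTarget
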