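#' Trim the tag from a junction read
#'
#' Verifies correct priming — the read must begin with the expected
#' tag-primer suffix in either tag orientation (at most `maxMismatch`
#' substitutions) — strips it, and returns the genomic remainder.
#' Rejections are data, not exceptions: tag-free reads return reason
#' `NO_TAG`, remainders shorter than `minGenomic` return `TOO_SHORT`.
#'
#' @param read DNA sequence.
#' @param tag the full tag sequence (dsODN or ITR), or `"dsodn"`/`"itr"`.
#' @param tagSuffixLength length of the tag-derived read prefix.
#' @param minGenomic minimum genomic remainder length.
#' @param maxMismatch substitutions tolerated in the tag prefix.
#' @return list with either `genomic` and `orientation` (`"+"` forward tag,
#'   `"-"` reverse), or `reject` (reason code).
#' @export
extractJunction <- function(read, tag = "dsodn", tagSuffixLength = 16L,
                            minGenomic = 25L, maxMismatch = 1L) {
  read <- .seq_chr(read)
  tag <- .resolve_tag(tag)
  sfx_fwd <- substr(tag, nchar(tag) - tagSuffixLength + 1L, nchar(tag))
  rc <- .revcomp_chr(tag)
  sfx_rev <- substr(rc, nchar(rc) - tagSuffixLength + 1L, nchar(rc))
  if (nchar(read) <= tagSuffixLength)
    return(list(reject = "NO_TAG"))
  pre <- substr(read, 1L, tagSuffixLength)
  ori <- if (.hamming(pre, sfx_fwd) <= maxMismatch) "+"
         else if (.hamming(pre, sfx_rev) <= maxMismatch) "-"
         else return(list(reject = "NO_TAG"))
  genomic <- substr(read, tagSuffixLength + 1L, nchar(read))
  if (nchar(genomic) < minGenomic) return(list(reject = "TOO_SHORT"))
  list(genomic = genomic, orientation = ori)
}

#' Place junction sequences on the genome
#'
#' Each trimmed genomic remainder is placed by [bestGenomicHit()] under the
#' perfectly-mapped contract (0 mismatches by default, unique placement).
#' The junction coordinate is the tag-adjacent end of the placement: the
#' base preceding a plus-strand placement, the right edge of a minus-strand
#' placement — so both read orientations of one integration event yield the
#' same coordinate. The opposite (shear) end is retained for molecule
#' deduplication. Ambiguous and unplaced junctions are counted, never
#' dropped.
#'
#' @param junctions data.frame with columns `read_id`, `genomic`,
#'   `orientation` (tag orientation from [extractJunction()]).
#' @param genome genome object.
#' @param maxMismatch,margin passed to [bestGenomicHit()].
#' @param minLength minimum placement length.
#' @return data.frame: `read_id`, `status`, `contig`, `junction`, `shear`,
#'   `strand`, `orientation`.
#' @export
mapJunctions <- function(junctions, genome, maxMismatch = 0L, margin = 5,
                         minLength = 25L) {
  n <- nrow(junctions)
  if (n == 0L)
    return(data.frame(read_id = character(), status = character(),
                      contig = character(), junction = integer(),
                      shear = integer(), strand = character(),
                      orientation = character(), stringsAsFactors = FALSE))
  out <- data.frame(read_id = junctions$read_id,
                    status = character(n), contig = NA_character_,
                    junction = NA_integer_, shear = NA_integer_,
                    strand = NA_character_,
                    orientation = junctions$orientation,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    hit <- bestGenomicHit(junctions$genomic[i], genome,
                          minLength = minLength, maxMismatch = maxMismatch,
                          margin = margin)
    out$status[i] <- hit$status
    if (hit$status != "unique") next
    out$contig[i] <- hit$contig
    out$strand[i] <- hit$strand
    if (hit$strand == "+") {
      out$junction[i] <- hit$start - 1L
      out$shear[i] <- hit$end
    } else {
      out$junction[i] <- hit$end
      out$shear[i] <- hit$start - 1L
    }
  }
  out
}

#' Collapse placed reads to unique molecules
#'
#' The Tn5 protocol carries no UMI; a molecule is identified by its
#' (junction coordinate, tag orientation, shear coordinate) triple, the
#' standard proxy. PCR duplicates collapse; reads from distinct shear
#' points stay distinct.
#'
#' @param placed data.frame from [mapJunctions()] (only `status ==
#'   "unique"` rows are used).
#' @return data.frame of molecules: `contig`, `junction`, `orientation`,
#'   `shear`, `n_reads`.
#' @export
dedupeMolecules <- function(placed) {
  ok <- placed[placed$status == "unique", , drop = FALSE]
  if (nrow(ok) == 0L)
    return(data.frame(contig = character(), junction = integer(),
                      orientation = character(), shear = integer(),
                      n_reads = integer()))
  key <- paste(ok$contig, ok$junction, ok$orientation, ok$shear, sep = ":")
  agg <- as.data.frame(table(key), stringsAsFactors = FALSE)
  parts <- strsplit(agg$key, ":", fixed = TRUE)
  data.frame(
    contig = vapply(parts, `[[`, character(1L), 1L),
    junction = as.integer(vapply(parts, `[[`, character(1L), 2L)),
    orientation = vapply(parts, `[[`, character(1L), 3L),
    shear = as.integer(vapply(parts, `[[`, character(1L), 4L)),
    n_reads = agg$Freq, stringsAsFactors = FALSE)
}

#' Aggregate molecules into integration-site calls
#'
#' Single-linkage merge of junction coordinates within `mergeWindow` nt per
#' contig. Sites supported by fewer than `minMolecules` unique molecules
#' are suppressed from the call list but returned in the `"suppressed"`
#' attribute for inspection.
#'
#' @param molecules data.frame from [dedupeMolecules()].
#' @param mergeWindow merge distance, nt.
#' @param minMolecules minimum unique molecules per reported site.
#' @return data.frame of sites: `contig`, `start`, `end`, `junction`
#'   (median junction coordinate), `unique_molecule_count`, `read_count`,
#'   `fwd_molecules`, `rev_molecules`.
#' @export
aggregateSites <- function(molecules, mergeWindow = 25L, minMolecules = 2L) {
  empty <- data.frame(contig = character(), start = integer(),
                      end = integer(), junction = integer(),
                      unique_molecule_count = integer(),
                      read_count = integer(), fwd_molecules = integer(),
                      rev_molecules = integer())
  if (nrow(molecules) == 0L) {
    attr(empty, "suppressed") <- empty
    return(empty)
  }
  rows <- list()
  for (ctg in unique(molecules$contig)) {
    m <- molecules[molecules$contig == ctg, , drop = FALSE]
    m <- m[order(m$junction), , drop = FALSE]
    gap <- c(0L, diff(m$junction))
    cluster <- cumsum(gap > mergeWindow)
    for (cl in unique(cluster)) {
      mc <- m[cluster == cl, , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        contig = ctg,
        start = min(mc$junction), end = max(mc$junction),
        junction = as.integer(stats::median(mc$junction)),
        unique_molecule_count = nrow(mc),
        read_count = sum(mc$n_reads),
        fwd_molecules = sum(mc$orientation == "+"),
        rev_molecules = sum(mc$orientation == "-"),
        stringsAsFactors = FALSE)
    }
  }
  sites <- do.call(rbind, rows)
  keep <- sites$unique_molecule_count >= minMolecules
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "suppressed") <- sites[!keep, , drop = FALSE]
  out
}

#' Annotate integration sites against the design and predicted off-targets
#'
#' A site within `window` bp of the design's nick-to-nick interval is
#' `ON_TARGET`; otherwise, within `window` bp of a predicted off-target
#' record it is `KNOWN_OFF_TARGET` (the nearest record wins; ties broken by
#' smaller mismatch count, then leftmost coordinate); otherwise `NOVEL`.
#' Annotated sites carry the protospacer match string of their matched
#' record.
#'
#' @param sites data.frame from [aggregateSites()].
#' @param design a [LocusDesign-class].
#' @param offTargets predicted off-target [GenomicRanges::GRanges] (e.g.
#'   from [readOffTargetBed()] or `plantedOffTargets()`).
#' @param window overlap window, bp (the pipeline's off-target rule uses
#'   5000).
#' @return `sites` with added columns `annotation`, `matched_id`,
#'   `distance`, `match_string`.
#' @export
annotateSites <- function(sites, design, offTargets, window = 5000L) {
  nk <- sort(.design_nicks(design))
  contig <- .design_contig(design)
  n <- nrow(sites)
  annotation <- character(n)
  matched_id <- rep(NA_character_, n)
  distance <- rep(NA_integer_, n)
  match_string <- rep(NA_character_, n)
  ot_mid <- if (length(offTargets)) start(offTargets) + 11L else integer()
  ot_mm <- if (length(offTargets)) mcols(offTargets)$mismatch_count else
    integer()
  for (i in seq_len(n)) {
    x <- sites$junction[i]
    d_on <- if (sites$contig[i] == contig) {
      if (x >= nk[1L] && x <= nk[2L]) 0L else min(abs(x - nk))
    } else Inf
    if (d_on <= window) {
      annotation[i] <- "ON_TARGET"
      matched_id[i] <- design@name
      distance[i] <- as.integer(d_on)
      next
    }
    if (length(offTargets)) {
      same <- as.character(seqnames(offTargets)) == sites$contig[i]
      d <- ifelse(same, abs(ot_mid - x), Inf)
      inw <- which(d <= window)
      if (length(inw)) {
        ord <- inw[order(d[inw], ot_mm[inw], start(offTargets)[inw])]
        j <- ord[1L]
        annotation[i] <- "KNOWN_OFF_TARGET"
        matched_id[i] <- sprintf("OT-%d", j)
        distance[i] <- as.integer(d[j])
        match_string[i] <- mcols(offTargets)$match_string[j]
        next
      }
    }
    annotation[i] <- "NOVEL"
  }
  sites$annotation <- annotation
  sites$matched_id <- matched_id
  sites$distance <- distance
  sites$match_string <- match_string
  sites
}

#' End-to-end junction-site calling
#'
#' Runs tag trimming, genomic placement, molecule deduplication, site
#' aggregation and annotation in one pass — the GUIDE-seq path with
#' `tag = "dsodn"`, the AAV-seq path (processed identically) with
#' `tag = "itr"`.
#'
#' @param reads reads (DNAStringSet, character, or `SimulatedReads`).
#' @param design a [LocusDesign-class].
#' @param genome genome object.
#' @param offTargets predicted off-target [GenomicRanges::GRanges].
#' @param tag `"dsodn"`, `"itr"`, or an explicit tag sequence.
#' @param tagSuffixLength,minGenomic,maxMismatch passed to
#'   [extractJunction()].
#' @param mergeWindow,minMolecules passed to [aggregateSites()].
#' @param window annotation window, bp.
#' @return list: `sites` (annotated), `molecules`, `placed`, `rejected`
#'   (data.frame `read_id`, `reason` including mapping failures).
#' @export
callIntegrationSites <- function(reads, design, genome, offTargets,
                                 tag = "dsodn", tagSuffixLength = 16L,
                                 minGenomic = 25L, maxMismatch = 1L,
                                 mergeWindow = 25L, minMolecules = 2L,
                                 window = 5000L) {
  if (inherits(reads, "SimulatedReads")) reads <- reads$reads
  rs <- as.character(reads)
  ids <- if (!is.null(names(rs))) names(rs) else
    sprintf("read_%05d", seq_along(rs))
  ext <- lapply(rs, extractJunction, tag = tag,
                tagSuffixLength = tagSuffixLength, minGenomic = minGenomic,
                maxMismatch = maxMismatch)
  rejected <- data.frame(read_id = character(), reason = character(),
                         stringsAsFactors = FALSE)
  keep <- vapply(ext, function(x) is.null(x$reject), logical(1L))
  if (any(!keep))
    rejected <- data.frame(
      read_id = ids[!keep],
      reason = vapply(ext[!keep], `[[`, character(1L), "reject"),
      stringsAsFactors = FALSE)
  junctions <- data.frame(
    read_id = ids[keep],
    genomic = vapply(ext[keep], `[[`, character(1L), "genomic"),
    orientation = vapply(ext[keep], `[[`, character(1L), "orientation"),
    stringsAsFactors = FALSE)
  placed <- mapJunctions(junctions, genome)
  fail <- placed$status != "unique"
  if (any(fail))
    rejected <- rbind(rejected, data.frame(
      read_id = placed$read_id[fail],
      reason = toupper(placed$status[fail]), stringsAsFactors = FALSE))
  molecules <- dedupeMolecules(placed)
  sites <- aggregateSites(molecules, mergeWindow = mergeWindow,
                          minMolecules = minMolecules)
  sites <- annotateSites(sites, design, offTargets, window = window)
  list(sites = sites, molecules = molecules, placed = placed,
       rejected = rejected)
}

#' Compare integration-site tables between two conditions
#'
#' Sites are matched by annotation label (`ON_TARGET`, matched off-target
#' id, or novel locus); the fold change is `count_a / count_b` with
#' pseudocount 1 and a flag when the denominator is zero. Disjoint sites
#' appear zero-filled and flagged.
#'
#' @param sitesA,sitesB annotated site tables from [annotateSites()].
#' @param value column to compare (`"read_count"` or
#'   `"unique_molecule_count"`).
#' @return data.frame: `locus`, `annotation`, `count_a`, `count_b`,
#'   `fold_change`, `pseudocount`.
#' @export
compareConditions <- function(sitesA, sitesB, value = "read_count") {
  key <- function(s) ifelse(s$annotation == "ON_TARGET", "ON_TARGET",
                     ifelse(s$annotation == "KNOWN_OFF_TARGET", s$matched_id,
                            paste0("NOVEL:", s$contig, ":",
                                   round(s$junction / 1000))))
  ka <- key(sitesA); kb <- key(sitesB)
  loci <- union(ka, kb)
  get <- function(s, k, keys) {
    i <- match(k, keys)
    if (is.na(i)) 0L else s[[value]][i]
  }
  ann <- function(k) {
    i <- match(k, ka)
    if (!is.na(i)) return(sitesA$annotation[i])
    sitesB$annotation[match(k, kb)]
  }
  a <- vapply(loci, get, numeric(1L), s = sitesA, keys = ka)
  b <- vapply(loci, get, numeric(1L), s = sitesB, keys = kb)
  pseudo <- b == 0
  data.frame(locus = loci,
             annotation = vapply(loci, ann, character(1L)),
             count_a = a, count_b = b,
             fold_change = a / pmax(b, 1),
             pseudocount = pseudo,
             stringsAsFactors = FALSE, row.names = NULL)
}
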