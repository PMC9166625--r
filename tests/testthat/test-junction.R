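# GUIDE-seq / AAV-seq junction calling: tag trimming, placement,
# deduplication, aggregation, annotation and condition comparison.

test_that("junction extraction verifies priming and trims the tag", {
  tag <- dsodnTag()
  sfx <- substr(tag, nchar(tag) - 15, nchar(tag))
  set.seed(51)
  genomic <- random_dna(50)
  r <- extractJunction(paste0(sfx, genomic))
  expect_equal(r$genomic, genomic)
  expect_equal(r$orientation, "+")
  # reverse tag orientation
  rc_sfx <- substr(revcomp(tag), 19, 34)
  r2 <- extractJunction(paste0(rc_sfx, genomic))
  expect_equal(r2$orientation, "-")
  # tag-free and too-short remainders are rejected as data
  expect_equal(extractJunction(random_dna(60))$reject, "NO_TAG")
  expect_equal(extractJunction(paste0(sfx, random_dna(20)))$reject,
               "TOO_SHORT")
  # one substitution in the tag prefix is tolerated
  sfx1 <- paste0("A", substr(sfx, 2, 16))
  if (substr(sfx, 1, 1) == "A") sfx1 <- paste0("C", substr(sfx, 2, 16))
  expect_equal(extractJunction(paste0(sfx1, genomic))$orientation, "+")
})

test_that("junction placement reports the tag-adjacent coordinate on both strands", {
  loc <- fx_locus()
  g <- loc$genome
  coord <- 20000L
  plus_flank <- crisprAudit:::.genome_seq(g, "chr1", coord + 1, coord + 60)
  minus_flank <- revcomp(crisprAudit:::.genome_seq(g, "chr1", coord - 59,
                                                   coord))
  placed <- mapJunctions(
    data.frame(read_id = c("a", "b"),
               genomic = c(plus_flank, minus_flank),
               orientation = c("+", "-")), g)
  expect_equal(placed$status, c("unique", "unique"))
  expect_equal(placed$junction, c(coord, coord))
  expect_equal(placed$strand, c("+", "-"))
  # an unmappable junction is counted, not dropped
  set.seed(53)
  placed2 <- mapJunctions(
    data.frame(read_id = "x", genomic = random_dna(60), orientation = "+"),
    g)
  expect_equal(placed2$status, "unmapped")
})

test_that("molecule deduplication collapses identical triples only", {
  placed <- data.frame(
    read_id = sprintf("r%d", 1:6),
    status = "unique", contig = "chr1",
    junction = c(100, 100, 100, 100, 100, 300),
    shear = c(250, 250, 250, 260, 270, 500),
    strand = "+",
    orientation = c("+", "+", "+", "+", "-", "+"),
    stringsAsFactors = FALSE)
  mol <- dedupeMolecules(placed)
  expect_equal(nrow(mol), 4)   # 3 dup reads -> 1 molecule; others distinct
  expect_equal(sum(mol$n_reads), 6)
  expect_equal(nrow(dedupeMolecules(placed[0, ])), 0)
})

test_that("site aggregation merges within the window and suppresses singletons", {
  mol <- data.frame(
    contig = "chr1",
    junction = c(1000:1009, 6000, 6004, 9000),
    orientation = "+",
    shear = seq(2000, by = 7, length.out = 13),
    n_reads = 1L, stringsAsFactors = FALSE)
  sites <- aggregateSites(mol, mergeWindow = 25, minMolecules = 2)
  expect_equal(nrow(sites), 2)   # the singleton at 9000 is suppressed
  expect_equal(sites$unique_molecule_count, c(10, 2))
  suppressed <- attr(sites, "suppressed")
  expect_equal(suppressed$junction, 9000)
  # clusters far apart never merge
  expect_true(all(abs(sites$junction[1] - sites$junction[2]) > 4000))
})

test_that("annotation follows the 5000-bp window rule with nearest-record wins", {
  loc <- fx_locus()
  d <- loc$design
  ot <- plantedOffTargets(loc$genome)
  mk <- function(junction) data.frame(
    contig = "chr1", start = junction, end = junction, junction = junction,
    unique_molecule_count = 5L, read_count = 5L, fwd_molecules = 3L,
    rev_molecules = 2L, stringsAsFactors = FALSE)
  # inside the nick interval
  on <- annotateSites(mk(d@nickPair@guideA@nick + 50), d, ot)
  expect_equal(on$annotation, "ON_TARGET")
  # 4000 bp from a predicted record: KNOWN_OFF_TARGET
  near <- annotateSites(mk(start(ot)[1] + 4000), d, ot)
  expect_equal(near$annotation, "KNOWN_OFF_TARGET")
  expect_equal(near$matched_id, "OT-1")
  expect_match(near$match_string, "^[ACGT.]+$")
  # 6000 bp from every record: NOVEL
  far_coord <- start(ot)[1] - 6000
  far <- annotateSites(mk(far_coord), d, ot)
  expect_equal(far$annotation, "NOVEL")
  # annotation does not depend on site-list order
  both <- rbind(mk(start(ot)[1] + 4000), mk(far_coord))
  ann1 <- annotateSites(both, d, ot)
  ann2 <- annotateSites(both[2:1, ], d, ot)
  expect_setequal(ann1$annotation, ann2$annotation)
})

test_that("every planted event set with enough molecules is recovered", {
  loc <- fx_locus()
  ot <- plantedOffTargets(loc$genome)
  events <- data.frame(
    coord = c(loc$design@nickPair@guideA@nick, mcols(ot)$nick),
    orientation = "both",
    molecules = c(8, 6, 6, 6))
  sim <- simulateTagReads(loc$design, loc$genome, events,
    simulationConfig("TAG_JUNCTION", proportions = c(), nReads = 1,
                     errorRate = 0, backgroundReads = 40, seed = 55))
  called <- callIntegrationSites(sim, loc$design, loc$genome, ot)
  expect_equal(nrow(called$sites), 4)
  expect_equal(sum(called$sites$annotation == "ON_TARGET"), 1)
  expect_equal(sum(called$sites$annotation == "KNOWN_OFF_TARGET"), 3)
  expect_equal(sum(called$sites$annotation == "NOVEL"), 0)
  # each site window contains its true coordinate
  for (i in seq_len(nrow(called$sites))) {
    s <- called$sites[i, ]
    expect_true(any(events$coord >= s$start - 25 &
                      events$coord <= s$end + 25))
  }
  # per-stage accounting: rejects + placed = input
  expect_equal(nrow(called$rejected) + sum(called$placed$status == "unique"),
               length(sim$reads))
})

test_that("the AAV-seq mode reuses the same code path with the ITR tag", {
  loc <- fx_locus()
  ot <- plantedOffTargets(loc$genome)
  events <- data.frame(coord = loc$design@nickPair@guideB@nick,
                       orientation = "both", molecules = 10)
  sim <- simulateTagReads(loc$design, loc$genome, events,
    simulationConfig("TAG_JUNCTION", proportions = c(), nReads = 1,
                     errorRate = 0, tag = "itr", seed = 57))
  called <- callIntegrationSites(sim, loc$design, loc$genome, ot,
                                 tag = "itr")
  expect_equal(nrow(called$sites), 1)
  expect_equal(called$sites$annotation, "ON_TARGET")
  # the dsODN pipeline rejects ITR-tagged reads outright
  wrong <- callIntegrationSites(sim, loc$design, loc$genome, ot,
                                tag = "dsodn")
  expect_equal(nrow(wrong$sites), 0)
})

test_that("condition comparison computes folds with pseudocount flags", {
  a <- data.frame(contig = "chr1", start = 1, end = 1, junction = 4000,
                  unique_molecule_count = 10L, read_count = 260L,
                  fwd_molecules = 5L, rev_molecules = 5L,
                  annotation = "ON_TARGET", matched_id = "demo",
                  distance = 0L, match_string = NA, stringsAsFactors = FALSE)
  b <- a; b$read_count <- 1L
  cmp <- compareConditions(a, b)
  expect_equal(cmp$fold_change, 260)
  expect_false(cmp$pseudocount)
  # a site absent from b gets the pseudocount flag
  b0 <- b[0, ]
  cmp0 <- compareConditions(a, b0)
  expect_true(cmp0$pseudocount)
  expect_equal(cmp0$fold_change, 260)
  # identical tables give folds of 1
  cmp1 <- compareConditions(a, a)
  expect_true(all(cmp1$fold_change == 1))
})
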