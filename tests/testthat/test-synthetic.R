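# Mini-genome construction and the three read simulators, checked against
# their own ground truth and determinism guarantees.

test_that("mini-genome embeds the locus once and plants verifiable off-targets", {
  loc0 <- demoLocus(seed = 5, nOffTargets = 0)
  g0 <- loc0$genome; d0 <- loc0$design
  proto_pam <- paste0(as.character(d0@nickPair@guideB@protospacer),
                      as.character(d0@nickPair@guideB@pam))
  hits <- Biostrings::matchPattern(proto_pam,
                                   genomeContigs(g0)[["chr1"]])
  expect_length(hits, 1)   # guide matches the genome at exactly one position

  loc <- fx_locus()
  ot <- plantedOffTargets(loc$genome)
  expect_length(ot, 3)
  # verify each planted mismatch count with the matching operation,
  # independently of the planting code
  gA <- loc$design@nickPair@guideA
  proto <- paste0(as.character(gA@protospacer), as.character(gA@pam))
  for (i in seq_along(ot)) {
    site <- crisprAudit:::.gr_seq(loc$genome, ot[i])
    if (as.character(strand(ot[i])) == "-") site <- revcomp(site)
    r <- guideMatchString(proto, site)
    expect_equal(r$mismatchCount, mcols(ot)$mismatch_count[i])
    expect_identical(r$marks, mcols(ot)$match_string[i])
  }
})

test_that("the same seed reproduces the genome byte for byte", {
  a <- demoLocus(seed = 3)
  b <- demoLocus(seed = 3)
  expect_identical(as.character(genomeContigs(a$genome)[["chr1"]]),
                   as.character(genomeContigs(b$genome)[["chr1"]]))
  c <- demoLocus(seed = 4)
  expect_false(identical(as.character(genomeContigs(a$genome)[["chr1"]]),
                         as.character(genomeContigs(c$genome)[["chr1"]])))
})

test_that("amplicon simulation honours class templates and error model", {
  loc <- fx_locus()
  amp <- fx_amplicons(loc)
  # pure WT, no errors: every read is the WT amplicon
  sim <- simulateAmpliconReads(loc$design, loc$genome,
    simulationConfig("AMPLICON", proportions = c(WT = 1),
                     nReads = 50, errorRate = 0, seed = 2))
  expect_true(all(as.character(sim$reads) ==
                    as.character(ampliconSeq(amp$WT))))
  # substitution errors: mean per read ~ binomial expectation
  sim2 <- simulateAmpliconReads(loc$design, loc$genome,
    simulationConfig("AMPLICON", proportions = c(WT = 1), nReads = 5000,
                     errorRate = 0.01, readLength = 200, seed = 2))
  wt200 <- substr(as.character(ampliconSeq(amp$WT)), 1, 200)
  subs <- vapply(as.character(sim2$reads),
                 function(r) sum(strsplit(r, "")[[1]] !=
                                   strsplit(wt200, "")[[1]]),
                 numeric(1), USE.NAMES = FALSE)
  se <- sqrt(200 * 0.01 * 0.99 / 5000)
  expect_lt(abs(mean(subs) - 2), 3 * se)
  # HDR requested without a donor is a config error
  pair <- loc$design@nickPair
  no_donor <- locusDesign("nd", loc$genome, pair)
  expect_error(simulateAmpliconReads(no_donor, loc$genome,
    simulationConfig("AMPLICON", proportions = c(HDR = 1), nReads = 10)),
    "no donor")
  # byte-identical on the same seed
  again <- simulateAmpliconReads(loc$design, loc$genome,
    simulationConfig("AMPLICON", proportions = c(WT = 1),
                     nReads = 50, errorRate = 0, seed = 2))
  expect_identical(as.character(sim$reads), as.character(again$reads))
})

test_that("truth labels follow the requested multinomial", {
  loc <- fx_locus()
  p <- c(WT = 0.3, HDR = 0.4, INDEL = 0.3)
  sim <- simulateAmpliconReads(loc$design, loc$genome,
    simulationConfig("AMPLICON", proportions = p, nReads = 5000,
                     errorRate = 0, seed = 8))
  tab <- table(sim$truth$class)
  for (cls in names(p)) {
    bound <- 4 * sqrt(5000 * p[cls] * (1 - p[cls]))
    expect_lt(abs(tab[[cls]] - 5000 * p[cls]), bound)
  }
  expect_false(anyDuplicated(sim$truth$read_id) > 0)
  expect_setequal(names(sim$reads), sim$truth$read_id)
})

test_that("tag-junction reads carry the tag only when events exist", {
  loc <- fx_locus()
  cfg0 <- simulationConfig("TAG_JUNCTION", proportions = c(), nReads = 1,
                           errorRate = 0, backgroundReads = 80, seed = 6)
  sim0 <- simulateTagReads(loc$design, loc$genome, NULL, cfg0)
  tag <- dsodnTag()
  sfx <- substr(tag, nchar(tag) - 15, nchar(tag))
  expect_false(any(grepl(sfx, as.character(sim0$reads), fixed = TRUE)))
  # events only at one planted off-target: every tag junction is there
  ot <- plantedOffTargets(loc$genome)
  ev <- data.frame(coord = mcols(ot)$nick[2], orientation = "both",
                   molecules = 40)
  cfg <- simulationConfig("TAG_JUNCTION", proportions = c(), nReads = 1,
                          errorRate = 0, seed = 6)
  sim <- simulateTagReads(loc$design, loc$genome, ev, cfg)
  expect_true(all(sim$truth$coord == mcols(ot)$nick[2]))
  # orientations within 3 SE of 1:1
  n_fwd <- sum(sim$truth$orientation == "+")
  expect_lt(abs(n_fwd - 20), 3 * sqrt(40 * 0.25) + 1)
  # with error_rate 0 every read is tag suffix + genomic flank, exactly
  r1 <- as.character(sim$reads[[1]])
  expect_true(startsWith(r1, sfx) ||
                startsWith(r1, substr(revcomp(tag), nchar(tag) - 15,
                                      nchar(tag))))
})

test_that("HTGTS reads are primer-anchored prefixes of their class templates", {
  loc <- fx_locus()
  for (side in c("5p", "3p")) {
    sim <- simulateHtgtsReads(loc$design, loc$genome,
      simulationConfig("HTGTS", proportions = c(WT = 1), nReads = 20,
                       errorRate = 0, side = side, seed = 9))
    tp <- crisprAudit:::.htgts_templates(loc$design, loc$genome, side = side)
    full <- paste0(tp$primer, tp$templates$WT)
    for (r in as.character(sim$reads))
      expect_identical(r, substr(full, 1, nchar(r)))
  }
  # an inversion read contains the inversion junction sequence
  simi <- simulateHtgtsReads(loc$design, loc$genome,
    simulationConfig("HTGTS", proportions = c(INVERSION = 1), nReads = 1,
                     errorRate = 0, side = "5p", seed = 9))
  tp <- crisprAudit:::.htgts_templates(loc$design, loc$genome, side = "5p")
  junction <- substr(tp$templates$INVERSION,
                     tp$nicks$INVERSION[["proximal"]] - 10,
                     tp$nicks$INVERSION[["proximal"]] + 10)
  expect_true(grepl(junction, as.character(simi$reads[[1]]), fixed = TRUE))
  # determinism
  s1 <- simulateHtgtsReads(loc$design, loc$genome,
    simulationConfig("HTGTS", proportions = c(WT = .5, INDEL = .5),
                     nReads = 30, errorRate = 0.01, seed = 12))
  s2 <- simulateHtgtsReads(loc$design, loc$genome,
    simulationConfig("HTGTS", proportions = c(WT = .5, INDEL = .5),
                     nReads = 30, errorRate = 0.01, seed = 12))
  expect_identical(as.character(s1$reads), as.character(s2$reads))
})

test_that("error-free reads are exact substrings or junctions of their templates", {
  loc <- fx_locus()
  tp <- crisprAudit:::.htgts_templates(loc$design, loc$genome, side = "5p")
  sim <- simulateHtgtsReads(loc$design, loc$genome,
    simulationConfig("HTGTS",
                     proportions = c(WT = .3, HDR = .3, DELETION = .2,
                                     INVERSION = .2),
                     nReads = 40, errorRate = 0, side = "5p", seed = 14))
  for (i in seq_len(40)) {
    cls <- sim$truth$class[i]
    full <- paste0(tp$primer, tp$templates[[cls]])
    expect_identical(as.character(sim$reads[[i]]),
                     substr(full, 1, nchar(as.character(sim$reads[[i]]))))
  }
})

test_that("simulation config rejects invalid settings", {
  expect_error(simulationConfig("AMPLICON", proportions = c(WT = .5)),
               "sum to 1")
  expect_error(simulationConfig("AMPLICON", errorRate = 0.5), "errorRate")
  expect_error(simulationConfig("AMPLICON", nReads = 0), "positive")
  expect_error(simulateHtgtsReads(fx_locus()$design, fx_locus()$genome,
    simulationConfig("HTGTS", proportions = c(BOGUS = 1), nReads = 5)),
    "unknown HTGTS class")
})

test_that("FASTQ round-trips through write and read", {
  loc <- fx_locus()
  sim <- simulateAmpliconReads(loc$design, loc$genome,
    simulationConfig("AMPLICON", proportions = c(WT = 1), nReads = 10,
                     seed = 4))
  dir <- withr::local_tempdir()
  paths <- writeSimulation(sim, dir, prefix = "t")
  back <- readFastqReads(paths$fastq)
  expect_identical(as.character(back), as.character(sim$reads))
  truth <- readTsv(paths$truth)
  expect_equal(truth$read_id, sim$truth$read_id)
})
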