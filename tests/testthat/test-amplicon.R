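# Amplicon read classification, outcome profiles, indel rates, tag counts
# and the in-silico RFLP cross-check.

test_that("constructed reads classify into the expected categories", {
  loc <- fx_locus()
  amp <- fx_amplicons(loc)
  wt <- as.character(ampliconSeq(amp$WT))
  hdr <- as.character(ampliconSeq(amp$HDR))
  expect_equal(classifyAmpliconRead(wt, amp)$category, "WT")
  expect_equal(classifyAmpliconRead(hdr, amp)$category, "HDR")
  # a 5-nt deletion at a nick => INDEL
  a <- amp$WT@anchors[["nickA"]]
  del5 <- paste0(substr(wt, 1, a), substr(wt, a + 6, nchar(wt)))
  expect_equal(classifyAmpliconRead(del5, amp)$category, "INDEL")
  # an HDR read with a 4-nt insertion at the payload junction
  j <- amp$HDR@junctions[["left"]]
  ins <- paste0(substr(hdr, 1, j), "ACGT", substr(hdr, j + 1, nchar(hdr)))
  expect_equal(classifyAmpliconRead(ins, amp)$category, "HDR_IMPERFECT")
  # junk reads and short reads are AMBIGUOUS with reasons
  set.seed(3)
  junk <- classifyAmpliconRead(random_dna(nchar(wt)), amp)
  expect_equal(junk$category, "AMBIGUOUS")
  short <- classifyAmpliconRead("ACGTACGT", amp)
  expect_equal(short$detail, "too_short")
})

test_that("substitutions alone never produce an INDEL call", {
  loc <- fx_locus()
  amp <- fx_amplicons(loc)
  wt <- as.character(ampliconSeq(amp$WT))
  a <- amp$WT@anchors[["nickA"]]
  chars <- strsplit(wt, "")[[1]]
  chars[a] <- setdiff(c("A", "C", "G", "T"), chars[a])[1]
  expect_equal(classifyAmpliconRead(paste(chars, collapse = ""), amp)$category,
               "WT")
})

test_that("outcome profiles aggregate counts, ratios and edge policies", {
  calls <- c(rep("WT", 60), rep("INDEL", 20), rep("HDR", 20))
  p <- quantifyOutcomes(calls)
  expect_equal(unname(p$threeWay), c(0.6, 0.2, 0.2))
  expect_equal(p$hdrNhejRatio, 1.0)
  expect_false(p$hdrNhejUndefined)
  expect_equal(sum(p$fractions), 1)
  # zero NHEJ: flagged, pseudocount 1
  p0 <- quantifyOutcomes(c(rep("HDR", 40)))
  expect_true(p0$hdrNhejUndefined)
  expect_equal(p0$hdrNhejRatio, 40)
  expect_error(quantifyOutcomes(character(0)), "no calls")
  expect_error(quantifyOutcomes("NOT_A_CLASS"), "unknown")
  # HDR_IMPERFECT pools into NHEJ for three-way reporting
  p2 <- quantifyOutcomes(c(rep("HDR", 5), rep("HDR_IMPERFECT", 5)))
  expect_equal(unname(p2$threeWay[["NHEJ"]]), 0.5)
})

test_that("simulated proportions are recovered within sampling error", {
  loc <- fx_locus()
  amp <- fx_amplicons(loc)
  p <- c(WT = 0.4, HDR = 0.4, INDEL = 0.2)
  sim <- simulateAmpliconReads(loc$design, loc$genome,
    simulationConfig("AMPLICON", proportions = p, nReads = 2000,
                     errorRate = 0, seed = 21))
  prof <- quantifyOutcomes(classifyAmpliconReads(sim, amp))
  truth_frac <- table(sim$truth$class) / 2000
  for (cls in names(p))
    expect_equal(unname(prof$fractions[[cls]]),
                 unname(truth_frac[[cls]]))
})

test_that("indel rate counts only window-overlapping indels", {
  loc <- fx_locus()
  amp <- fx_amplicons(loc)
  wt <- as.character(ampliconSeq(amp$WT))
  # all error-free WT reads: 0
  expect_equal(indelRate(rep(wt, 20), amp$WT), 0)
  # 10 of 100 reads with a window-overlapping deletion: 0.10
  a <- amp$WT@anchors[["nickA"]]
  del <- paste0(substr(wt, 1, a - 2), substr(wt, a + 2, nchar(wt)))
  expect_equal(indelRate(c(rep(wt, 90), rep(del, 10)), amp$WT), 0.10)
  # substitution-only reads: 0
  set.seed(33)
  subs <- vapply(1:30, function(i) {
    chars <- strsplit(wt, "")[[1]]
    pos <- sample(nchar(wt), 3)
    chars[pos] <- sample(c("A", "C", "G", "T"), 3, replace = TRUE)
    paste(chars, collapse = "")
  }, character(1))
  expect_equal(indelRate(subs, amp$WT), 0)
  # an indel far outside the windows does not count
  far <- paste0(substr(wt, 1, 10), substr(wt, 14, nchar(wt)))
  expect_equal(indelRate(far, amp$WT), 0)
  expect_error(indelRate("ACGT", amp$WT, identityMin = 2), "classifiable")
})

test_that("indel rate is invariant to read order", {
  loc <- fx_locus()
  amp <- fx_amplicons(loc)
  wt <- as.character(ampliconSeq(amp$WT))
  a <- amp$WT@anchors[["nickA"]]
  del <- paste0(substr(wt, 1, a), substr(wt, a + 4, nchar(wt)))
  reads <- c(rep(wt, 7), rep(del, 3))
  set.seed(5)
  for (i in 1:3)
    expect_equal(indelRate(sample(reads), amp$WT), 0.3)
})

test_that("tag integration counting finds embedded tags in both orientations", {
  set.seed(37)
  tag <- dsodnTag()
  backbone <- function() random_dna(120)
  none <- replicate(5, backbone())
  expect_equal(countTagIntegrations(none, tag), 0)
  fwd <- replicate(7, paste0(random_dna(40), tag, random_dna(40)))
  rev <- replicate(3, paste0(random_dna(40), revcomp(tag), random_dna(40)))
  expect_equal(countTagIntegrations(c(fwd, rev, none), tag), 10)
  # a partial tag of >= 20 nt at the read end still counts
  part <- paste0(random_dna(100), substr(tag, 1, 22))
  expect_equal(countTagIntegrations(part, tag), 1)
  short_part <- paste0(random_dna(100), substr(tag, 1, 10))
  expect_equal(countTagIntegrations(short_part, tag), 0)
  expect_error(countTagIntegrations(none, "ACGTACGT"), "at least 20")
})

test_that("RFLP estimate matches direct site arithmetic and classification", {
  loc <- fx_locus()
  amp <- fx_amplicons(loc)
  wt <- as.character(ampliconSeq(amp$WT))
  hdr <- as.character(ampliconSeq(amp$HDR))
  expect_equal(rflpHdrEstimate(rep(hdr, 10), amp), 1.0)
  expect_equal(rflpHdrEstimate(c(rep(hdr, 5), rep(wt, 5)), amp), 0.5)
  # cross-method consistency on an error-free simulation
  sim <- simulateAmpliconReads(loc$design, loc$genome,
    simulationConfig("AMPLICON",
                     proportions = c(WT = .3, HDR = .4, HDR_IMPERFECT = .1,
                                     INDEL = .2),
                     nReads = 600, errorRate = 0, seed = 41))
  calls <- classifyAmpliconReads(sim, amp)
  expect_equal(rflpHdrEstimate(sim, amp),
               mean(calls$category %in% c("HDR", "HDR_IMPERFECT")))
  # a design whose donor lacks the site is a config error
  expect_error(rflpHdrEstimate(rep(hdr, 2), amp, recognition = "GAATTC"),
               "does not introduce")
})

test_that("adding reads never decreases any raw count", {
  loc <- fx_locus()
  amp <- fx_amplicons(loc)
  sim <- simulateAmpliconReads(loc$design, loc$genome,
    simulationConfig("AMPLICON", proportions = c(WT = .5, INDEL = .5),
                     nReads = 100, errorRate = 0, seed = 43))
  calls <- classifyAmpliconReads(sim, amp)
  p50 <- quantifyOutcomes(calls[1:50, ])
  p100 <- quantifyOutcomes(calls)
  expect_true(all(p100$counts >= p50$counts))
})
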