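# LAM-HTGTS classification: priming, ITR detection, the priority cascade,
# break-site analysis, translocation rules and summaries.

fx_templates <- function(side = "5p") {
  loc <- fx_locus()
  crisprAudit:::.htgts_templates(loc$design, loc$genome, side = side)
}

test_that("priming check trims correct reads and rejects the rest", {
  tp <- fx_templates()
  body <- substr(tp$templates$WT, 1, 100)
  ok <- checkPrimingAndTrim(paste0(tp$primer, body), tp$primer)
  expect_equal(ok$trimmed, body)
  # one substitution in the primer is tolerated
  p1 <- tp$primer
  substr(p1, 5, 5) <- setdiff(c("A", "C", "G", "T"), substr(p1, 5, 5))[1]
  expect_equal(checkPrimingAndTrim(paste0(p1, body), tp$primer)$trimmed,
               body)
  # the wrong primer is MISPRIMED
  set.seed(61)
  expect_equal(checkPrimingAndTrim(paste0(random_dna(20), body),
                                   tp$primer)$reject, "MISPRIMED")
  expect_equal(checkPrimingAndTrim(substr(tp$primer, 1, 10),
                                   tp$primer)$reject, "TOO_SHORT")
})

test_that("ITR detection requires span and identity", {
  set.seed(63)
  itr <- itrSequence()
  read <- paste0(random_dna(80), substr(itr, 1, 40))
  hit <- detectItr(read, itr)
  expect_false(is.null(hit))
  expect_equal(hit$junctionInRead, 80)
  expect_null(detectItr(random_dna(120), itr))
  # a 15-nt fragment falls below the span threshold
  expect_null(detectItr(paste0(random_dna(80), substr(itr, 1, 15)), itr))
  # reverse-complemented ITR is found too
  expect_false(is.null(detectItr(paste0(random_dna(80),
                                        revcomp(substr(itr, 1, 40))), itr)))
})

test_that("perfect template prefixes classify by the priority cascade", {
  loc <- fx_locus()
  tp <- fx_templates()
  g <- loc$genome; ot <- plantedOffTargets(g)
  cls <- function(read) classifyHtgtsRead(read, tp, g, ot)$category
  expect_equal(cls(substr(tp$templates$WT, 1, 420)), "WT")
  expect_equal(cls(substr(tp$templates$HDR, 1, 420)), "HDR")
  expect_equal(cls(substr(tp$templates$DELETION, 1, 420)), "DELETION")
  expect_equal(cls(substr(tp$templates$INVERSION, 1, 420)), "INVERSION")
  expect_equal(cls(substr(tp$templates$AAV_A_FWD, 1, 420)),
               "AAV_INTEGRATION")
  # a read stopping short of the break site is uninformative
  expect_equal(cls(substr(tp$templates$WT, 1, 40)), "UNINFORMATIVE")
})

test_that("break-site analysis distinguishes indels from nick-to-nick deletions", {
  tp <- fx_templates()
  wt <- tp$templates$WT
  prox <- tp$nicks$WT[["proximal"]]
  dist <- tp$nicks$WT[["distal"]]
  # 3-nt deletion at the proximal nick
  del3 <- paste0(substr(wt, 1, prox), substr(wt, prox + 4, prox + 400))
  r <- analyzeBreaksite(del3, wt, tp$nicks$WT)
  expect_equal(r$category, "INDEL")
  expect_match(r$detail, "indel:3")
  # deletion spanning nick A to nick B
  span <- paste0(substr(wt, 1, prox - 2), substr(wt, dist + 2, dist + 400))
  expect_equal(analyzeBreaksite(span, wt, tp$nicks$WT)$category, "DELETION")
  # insertion at the distal nick
  ins <- paste0(substr(wt, 1, dist), "ACGTAC",
                substr(wt, dist + 1, dist + 380))
  expect_equal(analyzeBreaksite(ins, wt, tp$nicks$WT)$category, "INDEL")
  # a read not reaching any window yields no break-site call
  expect_null(analyzeBreaksite(substr(wt, 1, 30), wt, tp$nicks$WT))
})

test_that("translocations are called only within the off-target window", {
  loc <- fx_locus()
  g <- loc$genome; d <- loc$design; ot <- plantedOffTargets(g)
  tp <- fx_templates()
  prox_seq <- substr(tp$templates$WT, 1, tp$nicks$WT[["proximal"]])
  # junction to a planted off-target: TRANSLOCATION with the right partner
  pc <- mcols(ot)$nick[2]
  distal <- crisprAudit:::.genome_seq(g, "chr1", pc + 1, pc + 150)
  r <- detectTranslocation(paste0(prox_seq, distal), g, ot, tp)
  expect_equal(r$category, "TRANSLOCATION")
  expect_equal(r$partner, pc)
  # junction to a locus > 5000 bp from every record: AMBIGUOUS
  far <- start(ot)[1] - 7000
  distal_far <- crisprAudit:::.genome_seq(g, "chr1", far, far + 149)
  rf <- detectTranslocation(paste0(prox_seq, distal_far), g, ot, tp)
  expect_equal(rf$category, "AMBIGUOUS")
  expect_equal(rf$detail, "outside_window")
  # unmappable distal segment: AMBIGUOUS
  set.seed(65)
  ru <- detectTranslocation(paste0(prox_seq, random_dna(150)), g, ot, tp)
  expect_equal(ru$category, "AMBIGUOUS")
})

test_that("the cascade labels every read exactly once and sums to input", {
  loc <- fx_locus()
  props <- c(WT = .2, HDR = .2, INDEL = .15, DELETION = .1, INVERSION = .1,
             AAV_INTEGRATION = .1, TRANSLOCATION = .1, FREE_AAV = .05)
  sim <- simulateHtgtsReads(loc$design, loc$genome,
    simulationConfig("HTGTS", proportions = props, nReads = 250,
                     errorRate = 0, side = "5p", seed = 67))
  calls <- classifyHtgtsReads(sim, loc$design, loc$genome, side = "5p")
  expect_equal(nrow(calls), 250)
  expect_false(anyNA(calls$category))
  # error-free: classification equals simulator truth; free AAV is
  # misprimed by construction
  informative <- sim$truth$class != "FREE_AAV"
  expect_equal(calls$category[informative], sim$truth$class[informative])
  expect_true(all(calls$category[!informative] == "MISPRIMED"))
  # translocation partners recovered
  tr <- sim$truth$class == "TRANSLOCATION"
  expect_equal(calls$partner[tr], sim$truth$partner[tr])
})

test_that("random-locus junctions are never counted as translocations", {
  loc <- fx_locus()
  sim <- simulateHtgtsReads(loc$design, loc$genome,
    simulationConfig("HTGTS", proportions = c(WT = .5, TRANSLOCATION = .5),
                     nReads = 60, errorRate = 0, side = "5p",
                     translocationPartner = "random", seed = 69))
  calls <- classifyHtgtsReads(sim, loc$design, loc$genome, side = "5p")
  tr <- sim$truth$class == "TRANSLOCATION"
  expect_equal(sum(calls$category[tr] == "TRANSLOCATION"), 0)
  expect_true(all(calls$category[tr] == "AMBIGUOUS"))
})

test_that("summaries compute HDR efficiency and WT:mutated ratios", {
  calls <- data.frame(
    read_id = sprintf("r%d", 1:40),
    category = c(rep("WT", 30), rep("INDEL", 10)),
    detail = "", partner = NA_integer_, stringsAsFactors = FALSE)
  s <- summarizeHtgts(calls)
  expect_equal(s$wtMutatedRatio, 3.0)
  expect_false(s$wtMutatedUndefined)
  calls2 <- data.frame(
    read_id = sprintf("r%d", 1:100),
    category = c(rep("HDR", 50), rep("WT", 40), rep("INDEL", 10)),
    detail = "", partner = NA_integer_, stringsAsFactors = FALSE)
  s2 <- summarizeHtgts(calls2)
  expect_equal(s2$hdrEfficiency, 0.5)
  expect_equal(unname(s2$counts[["TRANSLOCATION"]]), 0)
  # zero mutated reads: flagged with pseudocount
  s3 <- summarizeHtgts(data.frame(read_id = "r", category = "WT",
                                  detail = "", partner = NA_integer_))
  expect_true(s3$wtMutatedUndefined)
  expect_error(summarizeHtgts(data.frame(category = character())), "no calls")
  # ambiguous reads are excluded from denominators but reported
  calls4 <- rbind(calls2, data.frame(read_id = "x", category = "AMBIGUOUS",
                                     detail = "", partner = NA_integer_))
  s4 <- summarizeHtgts(calls4)
  expect_equal(s4$hdrEfficiency, 0.5)
  expect_equal(s4$nAmbiguous, 1)
})

test_that("both enrichment sides classify their own simulations", {
  loc <- fx_locus()
  for (side in c("5p", "3p")) {
    sim <- simulateHtgtsReads(loc$design, loc$genome,
      simulationConfig("HTGTS",
                       proportions = c(WT = .4, HDR = .3, DELETION = .3),
                       nReads = 60, errorRate = 0, side = side, seed = 71))
    calls <- classifyHtgtsReads(sim, loc$design, loc$genome, side = side)
    expect_equal(calls$category, sim$truth$class)
  }
})
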