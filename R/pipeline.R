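#' Write / read a TSV with `# key=value` provenance headers
#'
#' All pipeline tables are plain TSV with a commented provenance header so
#' they stay grep-able and spreadsheet-safe, and round-trip through the
#' package's own readers.
#'
#' @param df data.frame.
#' @param path file path.
#' @param meta named character/numeric vector written as `# key=value`.
#' @return `readTsv` returns the data.frame (header comments skipped).
#' @export
writeTsv <- function(df, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(meta))
    writeLines(sprintf("# %s=%s", names(meta), as.character(meta)), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTsv
#' @export
readTsv <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Serialize an outcome profile to a table
#'
#' @param profile an `OutcomeProfile` from [quantifyOutcomes()].
#' @return data.frame with one row per category plus summary rows.
#' @export
profileToTable <- function(profile) {
  data.frame(
    key = c(paste0("count_", names(profile$counts)),
            "total", "hdr_nhej_ratio", "hdr_nhej_undefined",
            "wt_mutated_ratio", "wt_mutated_undefined",
            "frac_wt_3way", "frac_nhej_3way", "frac_hdr_3way"),
    value = c(unname(profile$counts), profile$total,
              profile$hdrNhejRatio, as.integer(profile$hdrNhejUndefined),
              profile$wtMutatedRatio, as.integer(profile$wtMutatedUndefined),
              unname(profile$threeWay)),
    stringsAsFactors = FALSE)
}

.default_config <- function() {
  list(
    locus = list(spacer = 250L, haLength = 800L, nOffTargets = 3L,
                 mismatchRange = 2:5),
    amplicon = list(nReads = 2000L, errorRate = 0.001,
                    proportions = c(WT = 0.2, HDR = 0.4, INDEL = 0.4)),
    tagseq = list(tag = "dsodn", onMolecules = 30L, otMolecules = 10L,
                  backgroundReads = 50L, errorRate = 0.001,
                  mergeWindow = 25L, minMolecules = 2L, window = 5000L),
    htgts = list(nReads = 1400L, side = "5p", errorRate = 0,
                 proportions = c(WT = 0.35, HDR = 0.35, INDEL = 0.1,
                                 DELETION = 0.08, INVERSION = 0.05,
                                 AAV_INTEGRATION = 0.05,
                                 TRANSLOCATION = 0.02)),
    compare = list(nhej_a = 0.42, nhej_b = 0.016, hdr = 0.40)
  )
}

# Validate a user config against the default schema: unknown keys are
# reported with their path before any computation runs.
.check_config <- function(config, defaults = .default_config(),
                          path = "config") {
  if (is.null(config)) return(defaults)
  if (!is.list(config)) .stopf("%s must be a list", path)
  bad <- setdiff(names(config), names(defaults))
  if (length(bad))
    .stopf("unknown config key(s): %s",
           paste(paste0(path, "$", bad), collapse = ", "))
  for (nm in names(config)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      sub_bad <- setdiff(names(config[[nm]]),
                         c(names(defaults[[nm]]), "fastq"))
      if (length(sub_bad))
        .stopf("unknown config key(s): %s",
               paste(paste0(path, "$", nm, "$", sub_bad), collapse = ", "))
      defaults[[nm]] <- modifyList(defaults[[nm]], config[[nm]])
    } else {
      defaults[[nm]] <- config[[nm]]
    }
  }
  defaults
}

.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config, tmp)
  unname(tools::md5sum(tmp))
}

.write_manifest <- function(dir, task, config, seed, inputs = character()) {
  manifest <- list(
    task = task,
    seed = seed,
    package = as.character(utils::packageVersion("crisprAudit")),
    config_hash = .config_hash(config),
    input_checksums = if (length(inputs))
      as.list(tools::md5sum(inputs)) else list())
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

# default tag-junction events: one on-target event per nick plus one per
# planted off-target, scaled by condition
.default_events <- function(design, genome, onMolecules, otMolecules) {
  nk <- .design_nicks(design)
  ev <- data.frame(coord = unname(nk), orientation = "both",
                   molecules = as.integer(ceiling(onMolecules / 2)))
  ot <- genome@offTargets
  if (length(ot) && otMolecules > 0L)
    ev <- rbind(ev, data.frame(coord = mcols(ot)$nick, orientation = "both",
                               molecules = otMolecules))
  ev
}

#' Run one pipeline stage end-to-end
#'
#' A single entry point driving the whole audit from a config list (or
#' YAML file): `simulate` writes the mini-genome, off-target BED, FASTQs
#' and truth tables; `amplicon`, `tagseq` and `htgts` simulate (or read
#' `config$<stage>$fastq`) and analyze their assay, writing per-read calls
#' and profiles; `compare` runs a matched pair of conditions (Cas9-like
#' vs spacer-nick-like NHEJ levels) and writes side-by-side tables;
#' `report` re-reads a run directory and returns its tables. Every run
#' writes a `manifest.json` (config hash, seed, package version, input
#' checksums) and is byte-deterministic for a given config + seed.
#'
#' @param task one of `"simulate"`, `"amplicon"`, `"tagseq"`, `"htgts"`,
#'   `"compare"`, `"report"`.
#' @param out output directory.
#' @param config config list overriding the defaults, or a YAML file path.
#' @param seed integer seed for every stochastic step.
#' @return invisibly, a list of the main in-memory results.
#' @export
runPipeline <- function(task = c("simulate", "amplicon", "tagseq", "htgts",
                                 "compare", "report"),
                        out, config = list(), seed = 1L) {
  task <- match.arg(task)
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) .stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config)
    # YAML proportions arrive as named lists
    for (nm in intersect(names(config), c("amplicon", "htgts")))
      if (!is.null(config[[nm]]$proportions))
        config[[nm]]$proportions <- unlist(config[[nm]]$proportions)
  }
  cfg <- .check_config(config)
  if (task == "report") return(invisible(reportRun(out)))
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  loc <- demoLocus(seed = seed, spacer = cfg$locus$spacer,
                   haLength = cfg$locus$haLength,
                   nOffTargets = cfg$locus$nOffTargets,
                   mismatchRange = cfg$locus$mismatchRange)
  design <- loc$design; genome <- loc$genome
  res <- list(design = design, genome = genome)

  if (task == "simulate") {
    writeGenomeFasta(genome, file.path(out, "genome.fasta"))
    writeOffTargetBed(genome@offTargets, file.path(out, "off_targets.bed"))
    sims <- list(
      amplicon = .sim_amplicon(design, genome, cfg, seed),
      tagseq = .sim_tagseq(design, genome, cfg, seed),
      htgts = .sim_htgts(design, genome, cfg, seed))
    for (nm in names(sims)) writeSimulation(sims[[nm]], out, prefix = nm)
    .write_manifest(out, task, cfg, seed)
    return(invisible(c(res, sims)))
  }
  if (task == "amplicon") {
    sim <- if (!is.null(cfg$amplicon$fastq))
      list(reads = readFastqReads(cfg$amplicon$fastq)) else
      .sim_amplicon(design, genome, cfg, seed)
    amp <- suppressWarnings(
      buildExpectedAmplicons(design, genome, region = "amplicon"))
    calls <- classifyAmpliconReads(sim$reads, amp)
    profile <- quantifyOutcomes(calls)
    writeTsv(calls, file.path(out, "amplicon_calls.tsv"),
             meta = c(design = design@name, seed = seed))
    writeTsv(profileToTable(profile), file.path(out, "amplicon_profile.tsv"),
             meta = c(design = design@name, seed = seed))
    .write_manifest(out, task, cfg, seed)
    return(invisible(c(res, list(calls = calls, profile = profile))))
  }
  if (task == "tagseq") {
    sim <- .sim_tagseq(design, genome, cfg, seed)
    called <- callIntegrationSites(
      sim, design, genome, genome@offTargets, tag = cfg$tagseq$tag,
      mergeWindow = cfg$tagseq$mergeWindow,
      minMolecules = cfg$tagseq$minMolecules, window = cfg$tagseq$window)
    writeTsv(called$sites, file.path(out, "sites.tsv"),
             meta = c(design = design@name, seed = seed,
                      tag = cfg$tagseq$tag))
    writeTsv(called$rejected, file.path(out, "rejected_reads.tsv"),
             meta = c(design = design@name, seed = seed))
    .write_manifest(out, task, cfg, seed)
    return(invisible(c(res, called)))
  }
  if (task == "htgts") {
    sim <- .sim_htgts(design, genome, cfg, seed)
    calls <- classifyHtgtsReads(sim, design, genome, side = cfg$htgts$side)
    summary <- summarizeHtgts(calls, side = cfg$htgts$side)
    writeTsv(calls, file.path(out, "htgts_calls.tsv"),
             meta = c(design = design@name, seed = seed,
                      side = cfg$htgts$side))
    writeTsv(data.frame(class = names(summary$fractions),
                        count = unname(summary$counts),
                        fraction = unname(summary$fractions)),
             file.path(out, "htgts_outcomes.tsv"),
             meta = c(design = design@name, side = cfg$htgts$side,
                      hdr_efficiency = summary$hdrEfficiency,
                      wt_mutated_ratio = summary$wtMutatedRatio))
    .write_manifest(out, task, cfg, seed)
    return(invisible(c(res, list(calls = calls, summary = summary))))
  }
  # task == "compare": matched Cas9-like vs spacer-nick-like conditions
  p_hdr <- cfg$compare$hdr
  conds <- list(cas9 = cfg$compare$nhej_a, nick = cfg$compare$nhej_b)
  profiles <- list(); sites <- list()
  for (nm in names(conds)) {
    p_nhej <- conds[[nm]]
    props <- c(WT = 1 - p_hdr - p_nhej, HDR = p_hdr, INDEL = p_nhej)
    sc <- simulationConfig("AMPLICON", proportions = props,
                           nReads = cfg$amplicon$nReads,
                           errorRate = cfg$amplicon$errorRate, seed = seed)
    sim <- simulateAmpliconReads(design, genome, sc)
    amp <- suppressWarnings(
      buildExpectedAmplicons(design, genome, region = "amplicon"))
    profiles[[nm]] <- quantifyOutcomes(classifyAmpliconReads(sim$reads, amp))
    ot_mol <- if (nm == "cas9") cfg$tagseq$otMolecules else 0L
    on_mol <- if (nm == "cas9") cfg$tagseq$onMolecules else
      max(2L, as.integer(round(cfg$tagseq$onMolecules / 10)))
    ev <- .default_events(design, genome, on_mol, ot_mol)
    tc <- simulationConfig("TAG_JUNCTION", proportions = c(),
                           nReads = 1L, errorRate = cfg$tagseq$errorRate,
                           tag = cfg$tagseq$tag,
                           backgroundReads = cfg$tagseq$backgroundReads,
                           seed = seed)
    tsim <- simulateTagReads(design, genome, ev, tc)
    sites[[nm]] <- callIntegrationSites(
      tsim, design, genome, genome@offTargets, tag = cfg$tagseq$tag,
      mergeWindow = cfg$tagseq$mergeWindow,
      minMolecules = cfg$tagseq$minMolecules,
      window = cfg$tagseq$window)$sites
  }
  ratio_table <- data.frame(
    condition = names(conds),
    hdr_nhej_ratio = vapply(profiles, `[[`, numeric(1L), "hdrNhejRatio"),
    wt_mutated_ratio = vapply(profiles, `[[`, numeric(1L), "wtMutatedRatio"),
    stringsAsFactors = FALSE, row.names = NULL)
  folds <- compareConditions(sites$cas9, sites$nick)
  writeTsv(ratio_table, file.path(out, "compare_ratios.tsv"),
           meta = c(design = design@name, seed = seed))
  writeTsv(folds, file.path(out, "compare_site_folds.tsv"),
           meta = c(design = design@name, seed = seed))
  for (nm in names(profiles))
    writeTsv(profileToTable(profiles[[nm]]),
             file.path(out, paste0("profile_", nm, ".tsv")),
             meta = c(design = design@name, condition = nm, seed = seed))
  .write_manifest(out, task, cfg, seed)
  invisible(c(res, list(profiles = profiles, sites = sites,
                        ratios = ratio_table, folds = folds)))
}

.sim_amplicon <- function(design, genome, cfg, seed) {
  sc <- simulationConfig("AMPLICON", proportions = cfg$amplicon$proportions,
                         nReads = cfg$amplicon$nReads,
                         errorRate = cfg$amplicon$errorRate, seed = seed)
  simulateAmpliconReads(design, genome, sc)
}

.sim_tagseq <- function(design, genome, cfg, seed) {
  ev <- .default_events(design, genome, cfg$tagseq$onMolecules,
                        cfg$tagseq$otMolecules)
  tc <- simulationConfig("TAG_JUNCTION", proportions = c(), nReads = 1L,
                         errorRate = cfg$tagseq$errorRate,
                         tag = cfg$tagseq$tag,
                         backgroundReads = cfg$tagseq$backgroundReads,
                         seed = seed)
  simulateTagReads(design, genome, ev, tc)
}

.sim_htgts <- function(design, genome, cfg, seed) {
  hc <- simulationConfig("HTGTS", proportions = cfg$htgts$proportions,
                         nReads = cfg$htgts$nReads,
                         errorRate = cfg$htgts$errorRate,
                         side = cfg$htgts$side, seed = seed)
  simulateHtgtsReads(design, genome, hc)
}

#' Re-read the tables of a pipeline run
#'
#' @param dir run directory written by [runPipeline()].
#' @return list of the run's tables and its manifest.
#' @export
reportRun <- function(dir) {
  if (!dir.exists(dir)) .stopf("run directory not found: %s", dir)
  files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  tables <- lapply(files, readTsv)
  names(tables) <- sub("\\.tsv$", "", basename(files))
  manifest_path <- file.path(dir, "manifest.json")
  manifest <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path) else NULL
  list(tables = tables, manifest = manifest)
}

#' Compare two completed runs
#'
#' Reads the profile tables of two run directories produced on the same
#' design and lays them side by side, with HDR:NHEJ and WT:mutated ratio
#' columns and per-key fold changes.
#'
#' @param runA,runB run directories containing `amplicon_profile.tsv`.
#' @return data.frame: `key`, `value_a`, `value_b`, `fold_change`.
#' @export
compareReport <- function(runA, runB) {
  read_prof <- function(d) {
    p <- file.path(d, "amplicon_profile.tsv")
    if (!file.exists(p)) .stopf("no amplicon_profile.tsv in %s", d)
    meta <- grep("^# design=", readLines(p, n = 5L), value = TRUE)
    list(tab = readTsv(p), design = sub("^# design=", "", meta[1L]))
  }
  a <- read_prof(runA); b <- read_prof(runB)
  if (!identical(a$design, b$design))
    .stopf("runs were produced on different designs (%s vs %s)",
           a$design, b$design)
  m <- merge(a$tab, b$tab, by = "key", suffixes = c("_a", "_b"),
             all = TRUE)
  m$value_a[is.na(m$value_a)] <- 0
  m$value_b[is.na(m$value_b)] <- 0
  m$fold_change <- m$value_a / pmax(m$value_b, 1e-12)
  names(m) <- c("key", "value_a", "value_b", "fold_change")
  m
}
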