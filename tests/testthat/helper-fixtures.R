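# Shared fixtures, built once per test run. Everything is generated in code
# from fixed seeds; no data files.

.fixture_cache <- new.env(parent = emptyenv())

fx_locus <- function(seed = 1L) {
  key <- paste0("locus_", seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- demoLocus(seed = seed)
  .fixture_cache[[key]]
}

fx_amplicons <- function(loc, region = "amplicon") {
  key <- paste0("amp_", region, "_", loc$design@name, start(loc$genome@onTarget))
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- suppressWarnings(
      buildExpectedAmplicons(loc$design, loc$genome, region = region))
  .fixture_cache[[key]]
}
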