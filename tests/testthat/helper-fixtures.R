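# Shared fixtures, built lazily once per test run.

.fixture_env <- new.env(parent = emptyenv())

# standard two-barcode layout used across tests
test_layout <- function(flank = 2L) {
  read_layout(list(
    list(kind = "barcode", expected_length = 8, slot_id = "A"),
    list(kind = "linker", expected_length = 4, sequence = "ACGT"),
    list(kind = "barcode", expected_length = 8, slot_id = "B"),
    list(kind = "umi", expected_length = 6, slot_id = "U")),
    flank = flank)
}

# small simulated dataset + completed pipeline run, cached for the session
small_fixture <- function() {
  if (!is.null(.fixture_env$small)) return(.fixture_env$small)
  dir <- file.path(tempdir(), "spotrna_small_fixture")
  spec <- simulation_spec(seed = 42L, n_genes = 4L, n_mirnas = 2L,
                          n_spurious = 2L, n_barcodes_a = 8L,
                          n_barcodes_b = 8L, pixels_per_feature = 3L,
                          background_reads_per_spurious = 45L)
  d <- simulate_dataset(spec, dir)
  cfg <- read_config(d$config)
  run_pipeline(cfg)
  .fixture_env$small <- list(spec = spec, data = d, cfg = cfg)
  .fixture_env$small
}
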