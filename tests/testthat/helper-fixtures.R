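# Shared synthetic bundles, generated once per test run.

.fixture_env <- new.env(parent = emptyenv())

default_bundle <- function() {
  if (is.null(.fixture_env$bundle)) {
    .fixture_env$bundle <-
      generate_synthetic_bundle(synthetic_config(seed = 20140828))
  }
  .fixture_env$bundle
}

default_bundle_dir <- function() {
  if (is.null(.fixture_env$bundle_dir)) {
    d <- file.path(tempdir(), "clonability-fixture-bundle")
    generate_synthetic_bundle(synthetic_config(seed = 20140828), outdir = d)
    .fixture_env$bundle_dir <- d
  }
  .fixture_env$bundle_dir
}

# published library-level counts shipped with the package
published_counts <- function() {
  readr::read_tsv(system.file("extdata", "celegans_library_counts.tsv",
                              package = "clonability"),
                  comment = "#", col_types = "cddddddd", progress = FALSE)
}
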