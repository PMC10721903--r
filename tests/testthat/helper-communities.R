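# Shared synthetic communities, built once per test run.

.community_cache <- new.env(parent = emptyenv())

# small world: quick per-module tests
tiny_params <- function(seed = 101, ...) {
  synth_params(seed = seed, n_hosts = 4, n_viruses = 30, host_length = 30000,
               n_crispr_pairs = 3, n_trna_pairs = 3, n_amg_pairs = 3,
               n_binning_only = 2, reads_per_sample = 4000,
               n_junk_reads = 50, n_mid_reads = 50, ...)
}

get_tiny_com <- function() {
  if (is.null(.community_cache$tiny)) {
    withr::with_options(list(icevir.quiet = TRUE), {
      .community_cache$tiny <- simulate_community(tiny_params())
    })
  }
  .community_cache$tiny
}

# the default stated world: 20 hosts, 200 viruses, 60 strong-evidence pairs
get_default_com <- function() {
  if (is.null(.community_cache$default)) {
    withr::with_options(list(icevir.quiet = TRUE), {
      .community_cache$default <- simulate_community(synth_params(seed = 42),
                                                     recruitment = FALSE)
    })
  }
  .community_cache$default
}
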