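# Shared fixtures, computed once per test run.  Profiles are cached by
# the package itself; thresholds are cached here.

.fixture_cache <- new.env(parent = emptyenv())

test_profiles <- function() nstrat::default_marker_profiles()

test_thresholds <- function() {
  if (is.null(.fixture_cache$thr)) {
    .fixture_cache$thr <- nstrat::default_bit_thresholds(test_profiles(),
                                                         seed = 7)
  }
  .fixture_cache$thr
}

# hits data.frame from a list of marker ids, for rule-engine tests
hits_from_markers <- function(markers, genome_id = "G1") {
  data.frame(genome_id = rep(genome_id, length(markers)),
             protein_id = sprintf("p%d", seq_along(markers)),
             marker_id = markers,
             bit_score = rep(100, length(markers)),
             e_value = rep(1e-20, length(markers)),
             source = rep("native", length(markers)),
             stringsAsFactors = FALSE)
}
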