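# The reference minimal-model study (n = 5000 Latin hypercube points over
# [1e-3, 1e3]^8, stimulus 1e-6..1e1) shared by the acceptance tests. Computed
# once per test run and cached.

.study_cache <- new.env(parent = emptyenv())

reference_study <- function() {
  if (is.null(.study_cache$res)) {
    .study_cache$res <- run_sweep("MINIMAL", n_samples = 5000, seed = 101)
  }
  .study_cache$res
}

# per-(parameter, decade-bin) bistable fractions over the floor-passing
# population, as a long data.frame
study_fractions <- function(res) {
  an <- analyze_sweep(res, classes_per_decade = 1)
  an$fractions
}
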