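# Shared simulated-cohort pipeline runs, computed once per test session.
# Problem sizes: 300-bin chromosome (30 Mb at 100-kb bins), 10 cell types x 2
# replicates for the standard cohort; seeds fixed.

.cohort_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cohort_cache))
    assign(key, force(expr), envir = .cohort_cache)
  get(key, envir = .cohort_cache)
}

std_cohort_result <- function() {
  cached("std", run_full_pipeline(list(
    n_bins = 300, n_cell_types = 10, replicates = 2,
    boundary_perturb_rate = 0.3, seed = 7)))
}

null_cohort_result <- function() {
  cached("null", run_full_pipeline(list(
    n_bins = 300, n_cell_types = 10, replicates = 2,
    boundary_perturb_rate = 0, use_merged = FALSE, seed = 7)))
}

protocol_cohort_result <- function() {
  cached("protocol", {
    samples <- data.frame(
      sample_id = sprintf("S%02d", 1:18),
      cell_type = rep(sprintf("type%d", 1:6), each = 3),
      replicates = 1L,
      protocol = rep(c("in_situ", "in_situ", "dilution"), 6))
    run_full_pipeline(list(n_bins = 300, samples = samples,
                           boundary_perturb_rate = 0.3,
                           protocol_longrange_factor = 0.7, seed = 7))
  })
}
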