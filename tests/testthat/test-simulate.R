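test_that("planted partitions are reproducible, sorted and non-overlapping", {
  p <- sim_params(n_bins = 300)
  s1 <- sample_tad_partition(p, seed = 5)
  s2 <- sample_tad_partition(p, seed = 5)
  expect_identical(s1$tad_set$intervals, s2$tad_set$intervals)
  iv <- s1$tad_set$intervals
  expect_true(all(diff(iv$start_bin) > 0))
  expect_true(all(iv$start_bin[-1] >= iv$end_bin[-nrow(iv)]))
  expect_true(all(iv$end_bin - iv$start_bin >= 2))
  expect_error(sample_tad_partition(sim_params(n_bins = 10)), "too small")
})

test_that("planted median TAD length tracks the configured target", {
  p <- sim_params(n_bins = 5000)
  meds <- vapply(1:50, function(k)
    median_tad_length(sample_tad_partition(p, seed = k)$tad_set),
    numeric(1))
  target <- 880000
  expect_lt(abs(mean(meds) - target) / target, 0.15)
})

test_that("simulated counts follow the planted mean structure", {
  p <- sim_params(n_bins = 80, depth = 0.0)
  s <- sample_tad_partition(sim_params(n_bins = 80), seed = 2)
  expect_true(all(simulate_contact_matrix(s, p, seed = 3)$counts == 0))
  # background mean decreases with distance (averaged over seeds)
  p <- sim_params(n_bins = 80, depth = 200)
  s <- sample_tad_partition(p, seed = 4)
  acc <- vapply(1:20, function(k) {
    m <- simulate_contact_matrix(s, p, seed = 100 + k)$counts
    vapply(1:20, function(d) {
      i <- seq_len(80 - d)
      pairs <- cbind(i, i + d)
      same <- s$labels[pairs[, 1]] == s$labels[pairs[, 2]] &
        s$labels[pairs[, 1]] > 0
      mean(m[pairs[!same, , drop = FALSE]])
    }, numeric(1))
  }, numeric(20))
  bg_mean <- rowMeans(acc)
  expect_true(all(diff(bg_mean) < 0))
  # within-TAD enrichment approximately beta at matched distance
  p2 <- sim_params(n_bins = 200, depth = 2000, tad_enrichment = 2)
  s2 <- sample_tad_partition(p2, seed = 5)
  m <- simulate_contact_matrix(s2, p2, seed = 6)$counts
  d <- 2
  i <- seq_len(200 - d)
  pairs <- cbind(i, i + d)
  same <- s2$labels[pairs[, 1]] == s2$labels[pairs[, 2]] &
    s2$labels[pairs[, 1]] > 0
  ratio <- mean(m[pairs[same, ]]) / mean(m[pairs[!same, ]])
  expect_lt(abs(ratio - 2) / 2, 0.1)
})

test_that("protocol attenuation only affects long-range mean counts", {
  base <- sim_params(n_bins = 100, depth = 500)
  dil <- sim_params(n_bins = 100, depth = 500,
                    protocol_longrange_factor = 0.7)
  s <- sample_tad_partition(base, seed = 7)
  M1 <- tadvar:::expected_contact_matrix(s, base)
  M2 <- tadvar:::expected_contact_matrix(s, dil)
  d <- abs(outer(1:100, 1:100, `-`))
  expect_equal(M2[d <= 10], M1[d <= 10])
  expect_equal(M2[d > 10], 0.7 * M1[d > 10])
})

test_that("boundary perturbation preserves validity and scales with rate", {
  p <- sim_params(n_bins = 500)
  s <- sample_tad_partition(p, seed = 8)
  same <- perturb_partition(s, 0, seed = 9)
  expect_identical(boundaries_of(same$tad_set), boundaries_of(s$tad_set))
  # rate 1 destroys most of the boundary agreement
  jis <- vapply(1:20, function(k) {
    pert <- perturb_partition(s, 1, seed = 100 + k)
    jaccard_index(s$tad_set, pert$tad_set)
  }, numeric(1))
  expect_lt(mean(jis), 0.5)
  # structural validity over many runs and rates
  set.seed(10)
  for (k in 1:100) {
    pert <- perturb_partition(s, runif(1), seed = 200 + k)
    iv <- pert$tad_set$intervals
    expect_true(all(iv$end_bin - iv$start_bin >= 2))
    if (nrow(iv) > 1)
      expect_true(all(iv$start_bin[-1] >= iv$end_bin[-nrow(iv)]))
    expect_true(all(iv$start_bin >= 0 & iv$end_bin <= 500))
  }
  expect_error(perturb_partition(s, 1.5), "rate")
})

test_that("calibrated depth passes the coverage quality gate", {
  for (n in c(100, 300, 500)) {
    lam <- calibrate_depth(n)
    p <- sim_params(n_bins = n, depth = lam)
    s <- sample_tad_partition(p, seed = 11)
    m <- simulate_contact_matrix(s, p, seed = 12)
    expect_true(coverage_quality_check(m)$passed)
  }
})
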