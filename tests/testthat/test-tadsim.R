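test_that("identical tiling TAD sets give full coverage for any seed", {
  iv <- data.frame(start_bin = seq(0L, 90L, 10L), end_bin = seq(10L, 100L, 10L))
  t0 <- tad_set(iv, n_bins = 100)
  for (sd in c(1, 99, 12345))
    expect_equal(tadsim(t0, t0, 100, seed = sd)$coverage, 1.0)
})

test_that("an empty TAD set on either side gives zero coverage", {
  t1 <- tad_set(data.frame(start_bin = 0L, end_bin = 10L), n_bins = 50)
  e <- tad_set(data.frame(start_bin = integer(), end_bin = integer()))
  expect_warning(r <- tadsim(t1, e, 50, seed = 1), "empty")
  expect_equal(r$coverage, 0.0)
  expect_warning(r2 <- tadsim(e, e, 50, seed = 1), "empty")
  expect_equal(r2$coverage, 0.0)
})

test_that("parameter validation rejects bad inputs", {
  t1 <- tad_set(data.frame(start_bin = 0L, end_bin = 10L))
  expect_error(tadsim(t1, t1, 50, n_null = 50), "n_null")
  t2 <- tad_set(data.frame(start_bin = 0L, end_bin = 10L), bin_size = 40000)
  expect_error(tadsim(t1, t2, 50), "binning")
})

test_that("independent random TAD sets get low coverage", {
  p <- sim_params(n_bins = 500)
  cov <- vapply(1:20, function(k) {
    a <- sample_tad_partition(p, seed = 1000 + k)$tad_set
    b <- sample_tad_partition(p, seed = 2000 + k)$tad_set
    tadsim(a, b, 500, n_null = 300, seed = 3000 + k)$coverage
  }, numeric(1))
  expect_lte(mean(cov), 0.15)
})

test_that("coverage is seed-stable at the default null size", {
  p <- sim_params(n_bins = 400)
  s <- sample_tad_partition(p, seed = 51)
  a <- perturb_partition(s, 0.3, seed = 52)$tad_set
  b <- perturb_partition(s, 0.3, seed = 53)$tad_set
  c1 <- tadsim(a, b, 400, n_null = 1000, seed = 1)$coverage
  c2 <- tadsim(a, b, 400, n_null = 1000, seed = 2)$coverage
  expect_lte(abs(c1 - c2), 0.02)
  # and identical seeds reproduce exactly
  expect_equal(tadsim(a, b, 400, n_null = 1000, seed = 9)$coverage,
               tadsim(a, b, 400, n_null = 1000, seed = 9)$coverage)
})

test_that("perturbed pairs score between identical and independent pairs", {
  p <- sim_params(n_bins = 500)
  s <- sample_tad_partition(p, seed = 61)
  a <- perturb_partition(s, 0.3, seed = 62)$tad_set
  b <- perturb_partition(s, 0.3, seed = 63)$tad_set
  ind <- sample_tad_partition(p, seed = 64)$tad_set
  cov_same <- tadsim(s$tad_set, s$tad_set, 500, seed = 65)$coverage
  cov_pert <- tadsim(a, b, 500, seed = 66)$coverage
  cov_ind <- tadsim(s$tad_set, ind, 500, seed = 67)$coverage
  expect_equal(cov_same, 1.0)
  expect_gt(cov_pert, cov_ind)
  expect_lt(cov_pert, cov_same + 1e-12)
})

test_that("reported regions are disjoint, sorted and within the chromosome", {
  p <- sim_params(n_bins = 400)
  s <- sample_tad_partition(p, seed = 71)
  a <- perturb_partition(s, 0.4, seed = 72)$tad_set
  r <- tadsim(s$tad_set, a, 400, seed = 73)
  reg <- r$regions
  if (nrow(reg) > 1) {
    expect_true(all(diff(reg$start_bin) > 0))
    expect_true(all(reg$start_bin[-1] > reg$end_bin[-nrow(reg)]))
  }
  expect_true(all(reg$start_bin >= 0 & reg$end_bin <= 400))
  expect_true(all(r$windows$p_value >= 0 & r$windows$p_value <= 1,
                  na.rm = TRUE))
})
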