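test_that("scaled density matches hand evaluation", {
  m <- contact_matrix(matrix(c(0, 4, 4, 0), 2))
  expect_equal(scaled_density(m, 0, 1, gamma = 1), 2)   # 4 / 2^1
  expect_equal(scaled_density(m, 0, 1, gamma = 0), 4)   # 4 / 2^0
  z <- contact_matrix(matrix(0, 5, 5))
  expect_equal(scaled_density(z, 1, 4, gamma = 0.5), 0)
  expect_error(scaled_density(m, 1, 0, gamma = 1), "<=")
})

test_that("domain quality centres per length and ranks enriched blocks first", {
  # uniform off-diagonal matrix: all same-length intervals share q, so q' = 0
  x <- matrix(1, 5, 5); diag(x) <- 0
  q <- domain_quality(contact_matrix(x), gamma = 0.5, max_len = 4)
  for (len in 2:4) {
    vals <- q$q[len, !is.na(q$q[len, ])]
    expect_equal(vals, rep(0, length(vals)), tolerance = 1e-12)
  }
  # 4-bin matrix with one enriched 2-bin block
  x <- matrix(1, 4, 4); diag(x) <- 0
  x[1, 2] <- x[2, 1] <- 10
  q <- domain_quality(contact_matrix(x), gamma = 0.5, max_len = 4)
  len2 <- q$q[2, 1:3]
  expect_equal(which.max(len2), 1L)
  expect_true(len2[1] > max(len2[-1]))
  # centred values sum to zero within each length
  set.seed(8)
  q <- domain_quality(contact_matrix(rand_sym_counts(7)), gamma = 1)
  for (len in 2:7) {
    vals <- q$q[len, !is.na(q$q[len, ])]
    expect_equal(sum(vals), 0, tolerance = 1e-9)
  }
})

test_that("the quality table agrees with a direct per-interval computation", {
  set.seed(9)
  counts <- rand_sym_counts(8)
  for (gamma in c(0, 0.5, 1)) {
    q <- domain_quality(contact_matrix(counts), gamma = gamma)
    oq <- oracle_quality_table(counts, gamma, min_len = 2L, max_len = 8L)
    for (len in 2:8) {
      got <- q$q[len, seq_len(8 - len + 1)]
      expect_equal(unname(got), unname(oq[[as.character(len)]]),
                   tolerance = 1e-9)
    }
  }
})

test_that("the DP finds the exhaustive optimum on small matrices", {
  set.seed(10)
  for (k in 1:15) {
    n <- sample(4:8, 1)
    counts <- rand_sym_counts(n)
    for (gamma in c(0, 0.5, 1)) {
      t <- call_tads(contact_matrix(counts), gamma)
      expect_equal(t$total_quality,
                   oracle_best_partition(counts, gamma),
                   tolerance = 1e-9)
    }
  }
})

test_that("block-diagonal enrichment yields exactly the planted blocks", {
  x <- matrix(1, 6, 6); diag(x) <- 0
  x[1:3, 1:3] <- 8; x[4:6, 4:6] <- 8; diag(x) <- 0
  t <- call_tads(contact_matrix(x), gamma = 0.5)
  expect_equal(t$intervals$start_bin, c(0L, 3L))
  expect_equal(t$intervals$end_bin, c(3L, 6L))
  expect_true(all(t$intervals$score > 0))
})

test_that("an all-zero matrix yields an empty TAD set with zero quality", {
  t <- call_tads(contact_matrix(matrix(0, 6, 6)), gamma = 0.5)
  expect_equal(nrow(t$intervals), 0L)
  expect_equal(t$total_quality, 0)
  expect_equal(median_tad_length(t), 0)
})

test_that("gamma sweep runs the full default grid and matches single calls", {
  set.seed(12)
  m <- contact_matrix(rand_sym_counts(20))
  sw <- gamma_sweep(m)
  expect_length(sw$tad_sets, 11L)
  expect_equal(sw$gammas, seq(0, 1, by = 0.1))
  expect_true(all(is.finite(sw$medians_bases)) && all(sw$medians_bases >= 0))
  one <- gamma_sweep(m, gammas = 0.5)
  direct <- call_tads(m, 0.5)
  expect_equal(one$tad_sets[[1]]$intervals, direct$intervals)
  expect_error(gamma_sweep(m, gammas = numeric()), "empty")
})

test_that("gamma selection minimises distance to the target median", {
  mk <- function(med_kb, gamma) {
    len <- as.integer(med_kb / 100)
    tad_set(data.frame(start_bin = 0L, end_bin = len), gamma = gamma)
  }
  sweep <- structure(list(
    tad_sets = list(mk(500, 0), mk(880, 0.5), mk(1200, 1)),
    gammas = c(0, 0.5, 1),
    medians_bases = c(5e5, 8.8e5, 1.2e6)), class = "gamma_sweep")
  expect_equal(select_gamma_by_median(sweep)$gamma, 0.5)
  # equidistant tie breaks toward smaller gamma
  sweep2 <- structure(list(
    tad_sets = list(mk(800, 0.2), mk(960, 0.7)),
    gammas = c(0.2, 0.7),
    medians_bases = c(8e5, 9.6e5)), class = "gamma_sweep")
  expect_equal(select_gamma_by_median(sweep2)$gamma, 0.2)
  # robustness-sweep target picks the matching set
  sweep3 <- structure(list(
    tad_sets = list(mk(500, 0.1), mk(700, 0.3), mk(880, 0.5), mk(1000, 0.9)),
    gammas = c(0.1, 0.3, 0.5, 0.9),
    medians_bases = c(5e5, 7e5, 8.8e5, 1e6)), class = "gamma_sweep")
  expect_equal(select_gamma_by_median(sweep3, 500000)$gamma, 0.1)
  # empty sets are never selected; all-empty errors
  e <- tad_set(data.frame(start_bin = integer(), end_bin = integer()),
               gamma = 0)
  sweep4 <- structure(list(tad_sets = list(e, mk(500, 1)), gammas = c(0, 1),
                           medians_bases = c(0, 5e5)),
                      class = "gamma_sweep")
  expect_equal(select_gamma_by_median(sweep4, 100)$gamma, 1)
  sweep5 <- structure(list(tad_sets = list(e), gammas = 0,
                           medians_bases = 0), class = "gamma_sweep")
  expect_error(select_gamma_by_median(sweep5), "no TADs")
})

test_that("boundaries deduplicate shared positions", {
  t <- tad_set(data.frame(start_bin = c(0L, 5L), end_bin = c(5L, 10L)))
  expect_equal(boundaries_of(t), c(0L, 5L, 10L))
  t2 <- tad_set(data.frame(start_bin = c(2L, 7L), end_bin = c(4L, 9L)))
  expect_equal(boundaries_of(t2), c(2L, 4L, 7L, 9L))
  e <- tad_set(data.frame(start_bin = integer(), end_bin = integer()))
  expect_equal(boundaries_of(e), integer(0))
})

test_that("emitted domains always carry positive centred quality", {
  set.seed(13)
  for (k in 1:10) {
    m <- contact_matrix(rand_sym_counts(15))
    t <- call_tads(m, gamma = runif(1))
    if (nrow(t$intervals) > 0) expect_true(all(t$intervals$score > 0))
  }
})
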