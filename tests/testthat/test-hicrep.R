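test_that("mean-filter smoothing matches brute force and edge clipping", {
  set.seed(41)
  x <- rand_sym_counts(7)
  m <- contact_matrix(x)
  expect_equal(smooth_matrix(m, 0)$counts, x)
  cm <- contact_matrix(matrix(3, 5, 5))
  expect_equal(smooth_matrix(cm, 2)$counts, matrix(3, 5, 5))
  # 3x3, h = 1: centre is the mean of all nine entries
  y <- rand_sym_counts(3)
  expect_equal(smooth_matrix(contact_matrix(y), 1)$counts[2, 2], mean(y))
  # full brute force at h = 2
  sm <- smooth_matrix(m, 2)$counts
  for (i in 1:7) for (j in 1:7) {
    ri <- max(1, i - 2):min(7, i + 2)
    rj <- max(1, j - 2):min(7, j + 2)
    expect_equal(sm[i, j], mean(x[ri, rj]), tolerance = 1e-12)
  }
  expect_error(smooth_matrix(m, -1), "non-negative")
})

test_that("SCC of a matrix with itself is 1", {
  set.seed(42)
  m <- contact_matrix(rand_sym_counts(20))
  expect_equal(scc(m, m, h = 0), 1, tolerance = 1e-12)
  expect_equal(scc(m, m, h = 2), 1, tolerance = 1e-12)
})

test_that("SCC is invariant under per-stratum positive affine maps", {
  set.seed(43)
  x <- rand_sym_counts(15, 10)
  m1 <- contact_matrix(x)
  y <- 2 * x
  for (d in 1:14) {
    i <- seq_len(15 - d)
    idx <- cbind(i, i + d)
    y[idx] <- y[idx] + d          # per-stratum constant
    y[idx[, 2:1, drop = FALSE]] <- y[idx]
  }
  diag(y) <- 2 * diag(x)
  m2 <- contact_matrix(y)
  expect_equal(scc(m1, m2, h = 0), 1, tolerance = 1e-12)
})

test_that("SCC equals the hand-evaluated weighted formula on a 4x4 toy", {
  x <- matrix(c(0, 5, 2, 1,
                5, 0, 7, 3,
                2, 7, 0, 6,
                1, 3, 6, 0), 4, 4)
  y <- matrix(c(0, 4, 3, 2,
                4, 0, 6, 1,
                3, 6, 0, 8,
                2, 1, 8, 0), 4, 4)
  m1 <- contact_matrix(x); m2 <- contact_matrix(y)
  # direct evaluation over strata d = 1, 2 (d = 3 has a single entry)
  num <- 0; den <- 0
  for (d in 1:3) {
    i <- seq_len(4 - d)
    xv <- x[cbind(i, i + d)]; yv <- y[cbind(i, i + d)]
    if (length(xv) < 2 || sd(xv) == 0 || sd(yv) == 0) next
    w <- length(xv) * sd(xv) * sd(yv)
    num <- num + w * cor(xv, yv)
    den <- den + w
  }
  expect_equal(scc(m1, m2, h = 0, max_dist_bins = 3), num / den,
               tolerance = 1e-12)
})

test_that("SCC reduces to plain Pearson when all strata weights are equal", {
  # construct two matrices whose strata all share N, sd1 and sd2 by using
  # a single stratum
  set.seed(44)
  n <- 12
  x <- matrix(0, n, n); y <- matrix(0, n, n)
  i <- seq_len(n - 1)
  xv <- rpois(n - 1, 20); yv <- rpois(n - 1, 20)
  x[cbind(i, i + 1)] <- xv; x[cbind(i + 1, i)] <- xv
  y[cbind(i, i + 1)] <- yv; y[cbind(i + 1, i)] <- yv
  expect_equal(scc(contact_matrix(x), contact_matrix(y), h = 0,
                   max_dist_bins = 1),
               cor(xv, yv), tolerance = 1e-12)
})

test_that("degenerate strata are skipped, all-degenerate errors", {
  z <- contact_matrix(matrix(0, 5, 5))
  expect_error(scc(z, z, h = 0), "no usable strata")
  m <- contact_matrix(rand_sym_counts(5))
  expect_error(scc(m, contact_matrix(rand_sym_counts(4))), "shape")
})

test_that("h selection returns the first h at which SCC converges", {
  set.seed(45)
  p <- sim_params(n_bins = 60, depth = 50)
  s <- sample_tad_partition(p, seed = 1)
  m1 <- simulate_contact_matrix(s, p, seed = 2)
  m2 <- simulate_contact_matrix(s, p, seed = 3)
  sccs <- vapply(0:3, function(h) scc(m1, m2, h = h), numeric(1))
  diffs <- abs(diff(sccs))
  h <- suppressWarnings(select_h(m1, m2, delta = 0.01))
  conv <- which(diffs < 0.01)
  expected <- if (length(conv)) c(0:3)[conv[1]] else 3L
  expect_equal(h, expected)
  # delta so large every h converges: picks the smallest h
  expect_equal(select_h(m1, m2, delta = 2), 0L)
  # delta impossible to meet: warns and returns the range maximum
  expect_warning(hmax <- select_h(m1, m2, delta = 0), "did not converge")
  expect_equal(hmax, 3L)
  expect_error(select_h(m1, m2, h_range = integer(0)), "empty")
})

test_that("genome-wide HiCRep averages per-chromosome SCCs", {
  set.seed(46)
  p <- sim_params(n_bins = 40, depth = 50)
  mk_pair <- function(seed) {
    s <- sample_tad_partition(p, seed = seed)
    list(simulate_contact_matrix(s, p, seed = seed + 100),
         simulate_contact_matrix(s, p, seed = seed + 200))
  }
  pairs <- list(mk_pair(1), mk_pair(2))
  per_chrom <- vapply(pairs, function(pr) scc(pr[[1]], pr[[2]], h = 1),
                      numeric(1))
  expect_equal(hicrep_genomewide(pairs, h = 1), mean(per_chrom),
               tolerance = 1e-12)
  expect_equal(hicrep_genomewide(pairs[1], h = 1), per_chrom[1])
  same <- list(list(pairs[[1]][[1]], pairs[[1]][[1]]),
               list(pairs[[2]][[1]], pairs[[2]][[1]]))
  expect_equal(hicrep_genomewide(same, h = 0), 1, tolerance = 1e-12)
  expect_error(hicrep_genomewide(list()), "no chromosome")
})
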