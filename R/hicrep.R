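#' 2D mean-filter smoothing of a contact matrix
#'
#' Replaces each entry by the mean of the `(2h+1) x (2h+1)` square window
#' around it, clipped at the matrix edges (the mean is over in-bounds cells
#' only). `h = 0` returns the input unchanged. Smoothing before correlation
#' stabilises the stochastic single-bin counts while preserving domain-scale
#' structure.
#'
#' @param m a `ContactMatrix`.
#' @param h non-negative integer window half-width.
#' @return the smoothed `ContactMatrix` (symmetric).
#' @export
smooth_matrix <- function(m, h) {
  stopifnot_cm(m)
  h <- as.integer(h)
  if (is.na(h) || h < 0L) stop("'h' must be a non-negative integer")
  if (h == 0L) return(m)
  x <- m$counts
  n <- nrow(x)
  # summed-area table padded with a leading zero row/column
  P <- matrix(0, n + 1L, n + 1L)
  P[-1L, -1L] <- apply(apply(x, 2L, cumsum), 1L, cumsum)  # P[i+1,j+1]=sum x[1:i,1:j]
  P[-1L, -1L] <- t(P[-1L, -1L])
  i <- seq_len(n)
  lo <- pmax(i - h, 1L); hi <- pmin(i + h, n)
  # block sum over rows lo_i..hi_i and cols lo_j..hi_j for all (i, j)
  A <- P[cbind(rep(hi + 1L, n), rep(hi + 1L, each = n))]
  B <- P[cbind(rep(lo, n), rep(hi + 1L, each = n))]
  C <- P[cbind(rep(hi + 1L, n), rep(lo, each = n))]
  D <- P[cbind(rep(lo, n), rep(lo, each = n))]
  # cancellation in the summed-area differences can leave ~1e-12 negatives
  # where the true window sum is 0; clamp them
  sums <- matrix(pmax(A - B - C + D, 0), n, n)
  area <- outer(hi - lo + 1L, hi - lo + 1L)
  contact_matrix(sums / area, chrom = m$chrom, bin_size = m$bin_size,
                 sym_tol = 1e-8)
}

#' Stratum-adjusted correlation coefficient between two contact matrices
#'
#' Both matrices are smoothed with window half-width `h`, entries are
#' stratified by diagonal offset `d = 1..max_dist_bins`, a Pearson
#' correlation `rho_d` is computed per stratum, and the correlations are
#' combined as a weighted mean with weights `w_d = N_d * sd1_d * sd2_d`
#' (stratum size times the two per-sample standard deviations). Stratifying
#' by genomic distance prevents the strong distance decay shared by all Hi-C
#' matrices from inflating the correlation. Strata with zero variance in
#' either sample are skipped.
#'
#' @param m1,m2 `ContactMatrix` objects of identical shape and binning.
#' @param h smoothing half-width (see [smooth_matrix()]).
#' @param max_dist_bins largest diagonal offset used; default
#'   `min(n_bins - 1, 5e6 / bin_size)` (a 5 Mb cap).
#' @return the SCC, a real in `[-1, 1]`.
#' @export
scc <- function(m1, m2, h = 0L, max_dist_bins = NULL) {
  stopifnot_cm(m1); stopifnot_cm(m2)
  if (m1$n_bins != m2$n_bins || m1$bin_size != m2$bin_size)
    stop("matrices differ in shape or binning")
  n <- m1$n_bins
  if (is.null(max_dist_bins))
    max_dist_bins <- min(n - 1L, as.integer(5e6 / m1$bin_size))
  max_dist_bins <- min(max_dist_bins, n - 1L)
  if (max_dist_bins < 1L) stop("matrix too small for any stratum")
  x <- smooth_matrix(m1, h)$counts
  y <- smooth_matrix(m2, h)$counts
  num <- 0; den <- 0; used <- 0L
  for (d in seq_len(max_dist_bins)) {
    i <- seq_len(n - d)
    xv <- x[cbind(i, i + d)]
    yv <- y[cbind(i, i + d)]
    s1 <- stats::sd(xv); s2 <- stats::sd(yv)
    if (length(xv) < 2L || s1 == 0 || s2 == 0) next
    rho <- stats::cor(xv, yv)
    w <- length(xv) * s1 * s2
    num <- num + w * rho
    den <- den + w
    used <- used + 1L
  }
  if (used == 0L) stop("no usable strata (all degenerate)")
  num / den
}

#' Select the SCC smoothing parameter by convergence
#'
#' Returns the smallest `h` in the range at which the score begins to
#' converge, i.e. the first `h` with `|SCC(h+1) - SCC(h)| < delta`. If the
#' score never converges within the range, the maximum of the range is
#' returned with a warning.
#'
#' @param m1,m2 the matrix pair.
#' @param h_range candidate half-widths (default `0:3`).
#' @param delta convergence threshold on consecutive SCC values (default
#'   0.01).
#' @param max_dist_bins passed to [scc()].
#' @return the selected integer `h`.
#' @export
select_h <- function(m1, m2, h_range = 0:3, delta = 0.01,
                     max_dist_bins = NULL) {
  if (length(h_range) == 0L) stop("empty h range")
  h_range <- sort(unique(as.integer(h_range)))
  sccs <- vapply(h_range, function(h)
    scc(m1, m2, h = h, max_dist_bins = max_dist_bins), numeric(1))
  if (length(h_range) == 1L) return(h_range)
  diffs <- abs(diff(sccs))
  conv <- which(diffs < delta)
  if (length(conv) > 0L) return(h_range[conv[1L]])
  warning(sprintf("SCC did not converge within h range [%d, %d]; using %d",
                  min(h_range), max(h_range), max(h_range)))
  max(h_range)
}

#' Genome-wide HiCRep score
#'
#' The unweighted arithmetic mean of per-chromosome SCCs, giving a single
#' similarity value per sample pair.
#'
#' @param per_chrom_pairs list of `list(m1, m2)` matrix pairs, one per
#'   chromosome.
#' @param h a single half-width recycled over chromosomes, or one per pair.
#' @param max_dist_bins passed to [scc()].
#' @return mean SCC across chromosomes.
#' @export
hicrep_genomewide <- function(per_chrom_pairs, h = 0L, max_dist_bins = NULL) {
  if (length(per_chrom_pairs) == 0L) stop("no chromosome pairs")
  h <- rep_len(as.integer(h), length(per_chrom_pairs))
  vals <- vapply(seq_along(per_chrom_pairs), function(k) {
    pr <- per_chrom_pairs[[k]]
    scc(pr[[1L]], pr[[2L]], h = h[k], max_dist_bins = max_dist_bins)
  }, numeric(1))
  mean(vals)
}
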