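#' TAD set on one chromosome
#'
#' An ordered list of non-overlapping half-open bin intervals
#' `[start_bin, end_bin)` (0-based), typically produced by [armatus_dp()] at a
#' given resolution parameter `gamma`. Gaps between domains are allowed.
#'
#' @param intervals data.frame with integer columns `start_bin`, `end_bin`
#'   (and optionally `score`).
#' @param chrom chromosome label.
#' @param bin_size bin width in bases.
#' @param gamma resolution parameter that produced the set (`NA` if unknown).
#' @param total_quality dynamic-programming objective value, if applicable.
#' @param n_bins chromosome length in bins, when known (used for validation).
#' @return an object of class `TADSet`.
#' @export
tad_set <- function(intervals, chrom = "chr1", bin_size = 100000L,
                    gamma = NA_real_, total_quality = NA_real_,
                    n_bins = NULL) {
  stopifnot(is.data.frame(intervals),
            all(c("start_bin", "end_bin") %in% names(intervals)))
  iv <- intervals
  iv$start_bin <- as.integer(iv$start_bin)
  iv$end_bin <- as.integer(iv$end_bin)
  if (nrow(iv) > 0L) {
    if (any(iv$end_bin <= iv$start_bin))
      stop("intervals must satisfy start_bin < end_bin")
    if (is.unsorted(iv$start_bin, strictly = TRUE) && nrow(iv) > 1L)
      iv <- iv[order(iv$start_bin), , drop = FALSE]
    if (nrow(iv) > 1L && any(iv$start_bin[-1L] < iv$end_bin[-nrow(iv)]))
      stop("intervals overlap")
    if (any(iv$start_bin < 0L)) stop("negative bin positions")
    if (!is.null(n_bins) && any(iv$end_bin > n_bins))
      stop("interval extends beyond chromosome end")
  }
  rownames(iv) <- NULL
  structure(
    list(chrom = as.character(chrom), bin_size = as.integer(bin_size),
         intervals = iv, gamma = gamma, total_quality = total_quality),
    class = "TADSet"
  )
}

#' @export
print.TADSet <- function(x, ...) {
  n <- nrow(x$intervals)
  cat(sprintf("TADSet: %d domain(s) on %s (gamma = %s)\n", n, x$chrom,
              format(x$gamma)))
  if (n > 0L) {
    len <- (x$intervals$end_bin - x$intervals$start_bin) * x$bin_size
    cat(sprintf("  median length %.0f kb, range %.0f-%.0f kb\n",
                stats::median(len) / 1e3, min(len) / 1e3, max(len) / 1e3))
  }
  invisible(x)
}

#' Median TAD length of a set, in bases
#'
#' The median of an empty set is defined as 0 so that empty calls are never
#' preferred during gamma selection.
#' @param t a `TADSet`.
#' @return median domain length in bases.
#' @export
median_tad_length <- function(t) {
  stopifnot(inherits(t, "TADSet"))
  if (nrow(t$intervals) == 0L) return(0)
  stats::median((t$intervals$end_bin - t$intervals$start_bin) * t$bin_size)
}

#' TAD boundary positions
#'
#' All distinct start and end bin positions of the domains, sorted; a boundary
#' shared by two adjacent domains appears once.
#' @param t a `TADSet`.
#' @return sorted integer vector of boundary bin positions.
#' @examples
#' t <- tad_set(data.frame(start_bin = c(0, 5), end_bin = c(5, 10)))
#' boundaries_of(t)  # 0 5 10
#' @export
boundaries_of <- function(t) {
  stopifnot(inherits(t, "TADSet"))
  sort(unique(c(t$intervals$start_bin, t$intervals$end_bin)))
}

# Strict-upper-triangle block sums S(k,l) for all intervals up to max_len.
# Returns matrix S[len, k] = sum_{k <= i < j <= k+len-1} counts[i,j]
# (1-based starts k; NA where the interval would overrun the chromosome).
block_sums <- function(counts, max_len) {
  n <- nrow(counts)
  C <- apply(counts, 2L, cumsum)       # C[i,j] = sum counts[1..i, j]
  S <- matrix(NA_real_, max_len, n)
  S[1L, ] <- 0                         # single bin: no internal contacts
  if (max_len >= 2L) {
    for (len in 2:max_len) {
      ks <- seq_len(n - len + 1L)
      if (length(ks) == 0L) break
      ls <- ks + len - 1L
      add <- C[cbind(ls - 1L, ls)] -
        ifelse(ks > 1L, C[cbind(pmax(ks - 1L, 1L), ls)], 0)
      S[len, ks] <- S[len - 1L, ks] + add
    }
  }
  S
}

#' Scaled density of a candidate domain
#'
#' The quality of the interval of bins `[k, l]` (0-based, inclusive) is its
#' total internal contact count divided by its length raised to `gamma`:
#' `q_gamma(k, l) = S(k, l) / (l - k + 1)^gamma`, where `S` sums the strict
#' upper triangle of the block. `gamma` controls the preferred domain size:
#' larger values penalise long domains more.
#'
#' @param m a `ContactMatrix`.
#' @param k,l first and last bin of the interval (0-based, `k <= l`).
#' @param gamma resolution parameter.
#' @return the scaled density (a real number).
#' @examples
#' m <- contact_matrix(matrix(c(0, 4, 4, 0), 2))
#' scaled_density(m, 0, 1, gamma = 1)  # 4 / 2 = 2
#' @export
scaled_density <- function(m, k, l, gamma) {
  stopifnot_cm(m)
  if (k > l) stop("'k' must be <= 'l'")
  if (k < 0 || l >= m$n_bins) stop("interval out of range")
  i <- (k:l) + 1L
  s <- if (length(i) < 2L) 0 else sum(m$counts[i, i][upper.tri(diag(length(i)))])
  s / (l - k + 1)^gamma
}

#' Length-centered domain quality table
#'
#' Computes `q'(k, l) = q_gamma(k, l) - mu_gamma(len)` for every candidate
#' interval with length between `min_len` and `max_len` bins, where
#' `mu_gamma(len)` is the mean scaled density over all intervals of that
#' length in this matrix. Centering makes qualities comparable across lengths
#' and leaves enriched blocks positive.
#'
#' @param m a `ContactMatrix`.
#' @param gamma resolution parameter.
#' @param min_len minimum domain length in bins (default 2; a 1-bin domain has
#'   no internal contacts).
#' @param max_len maximum domain length in bins; default
#'   `min(n_bins, ceiling(3e6 / bin_size))`, i.e. a 3 Mb cap.
#' @return an object of class `tad_quality` holding the centered quality
#'   matrix `q` (`q[len, k1]` for 1-based start `k1`), and the matrix
#'   metadata.
#' @export
domain_quality <- function(m, gamma, min_len = 2L, max_len = NULL) {
  stopifnot_cm(m)
  n <- m$n_bins
  if (is.null(max_len)) max_len <- min(n, as.integer(ceiling(3e6 / m$bin_size)))
  max_len <- min(max_len, n)
  if (min_len < 1L || min_len > max_len)
    stop("need 1 <= min_len <= max_len <= n_bins")
  S <- block_sums(m$counts, max_len)
  lens <- seq_len(max_len)
  q <- S / lens^gamma
  for (len in lens) {
    row <- q[len, ]
    mu <- mean(row, na.rm = TRUE)
    q[len, ] <- row - mu
  }
  if (min_len > 1L) q[seq_len(min_len - 1L), ] <- NA_real_
  structure(
    list(q = q, n_bins = n, gamma = gamma, min_len = as.integer(min_len),
         max_len = as.integer(max_len), chrom = m$chrom,
         bin_size = m$bin_size),
    class = "tad_quality"
  )
}

#' Optimal TAD partition by dynamic programming
#'
#' Finds the set of non-overlapping candidate domains maximising the total
#' centered quality, allowing gaps, via
#' `OPT(l) = max(OPT(l-1), max_k {OPT(k-1) + q'(k,l) : q'(k,l) > 0})`.
#' Only strictly positive-quality domains are ever emitted; the objective of
#' the empty partition is 0.
#'
#' @param quality a `tad_quality` table from [domain_quality()].
#' @return a `TADSet` with per-domain `score` (its `q'`), the producing
#'   `gamma` and `total_quality = OPT(n_bins - 1)`.
#' @export
armatus_dp <- function(quality) {
  stopifnot(inherits(quality, "tad_quality"))
  q <- quality$q
  n <- quality$n_bins
  if (all(is.na(q))) stop("empty quality table")
  opt <- numeric(n + 1L)          # opt[l+1] = OPT over bins 1..l
  choice_len <- integer(n)        # 0 = skip bin l
  for (l in seq_len(n)) {
    best <- opt[l]
    best_len <- 0L
    len_cap <- min(quality$max_len, l)
    if (len_cap >= quality$min_len) {
      lens <- seq.int(quality$min_len, len_cap)
      ks <- l - lens + 1L
      vals <- q[cbind(lens, ks)]
      ok <- !is.na(vals) & vals > 0
      if (any(ok)) {
        cand <- opt[ks[ok]] + vals[ok]
        w <- which.max(cand)
        if (cand[w] > best) {
          best <- cand[w]
          best_len <- lens[ok][w]
        }
      }
    }
    opt[l + 1L] <- best
    choice_len[l] <- best_len
  }
  # backtrack
  starts <- integer(0); ends <- integer(0); scores <- numeric(0)
  l <- n
  while (l > 0L) {
    len <- choice_len[l]
    if (len == 0L) {
      l <- l - 1L
    } else {
      k <- l - len + 1L
      starts <- c(k - 1L, starts)       # to 0-based
      ends <- c(l, ends)                # half-open end = l (0-based l-1 + 1)
      scores <- c(q[len, k], scores)
      l <- k - 1L
    }
  }
  tad_set(data.frame(start_bin = starts, end_bin = ends, score = scores),
          chrom = quality$chrom, bin_size = quality$bin_size,
          gamma = quality$gamma, total_quality = opt[n + 1L],
          n_bins = n)
}

#' Call TADs at a single gamma
#'
#' Convenience wrapper: [domain_quality()] followed by [armatus_dp()].
#' @inheritParams domain_quality
#' @return a `TADSet`.
#' @export
call_tads <- function(m, gamma, min_len = 2L, max_len = NULL) {
  armatus_dp(domain_quality(m, gamma, min_len = min_len, max_len = max_len))
}

#' Sweep the resolution parameter over a gamma grid
#'
#' Calls TADs at each gamma of the grid (default 0 to 1 in steps of 0.1) and
#' records each call's median domain length in bases.
#'
#' @inheritParams domain_quality
#' @param gammas numeric vector of gamma values (default `seq(0, 1, 0.1)`).
#' @return an object of class `gamma_sweep`: list with `tad_sets` (one
#'   `TADSet` per gamma), `gammas`, `medians_bases`.
#' @export
gamma_sweep <- function(m, gammas = seq(0, 1, by = 0.1), min_len = 2L,
                        max_len = NULL) {
  stopifnot_cm(m)
  if (length(gammas) == 0L) stop("empty gamma grid")
  n <- m$n_bins
  if (is.null(max_len)) max_len <- min(n, as.integer(ceiling(3e6 / m$bin_size)))
  max_len <- min(max_len, n)
  S <- block_sums(m$counts, max_len)
  lens <- seq_len(max_len)
  sets <- vector("list", length(gammas))
  for (g in seq_along(gammas)) {
    q <- S / lens^gammas[g]
    mu <- rowMeans(q, na.rm = TRUE)
    q <- q - mu
    if (min_len > 1L) q[seq_len(min_len - 1L), ] <- NA_real_
    qual <- structure(
      list(q = q, n_bins = n, gamma = gammas[g], min_len = as.integer(min_len),
           max_len = as.integer(max_len), chrom = m$chrom,
           bin_size = m$bin_size),
      class = "tad_quality")
    sets[[g]] <- armatus_dp(qual)
  }
  structure(
    list(tad_sets = sets, gammas = gammas,
         medians_bases = vapply(sets, median_tad_length, numeric(1))),
    class = "gamma_sweep"
  )
}

#' @export
print.gamma_sweep <- function(x, ...) {
  cat("gamma sweep:\n")
  for (g in seq_along(x$gammas))
    cat(sprintf("  gamma %.2f: %3d TADs, median %.0f kb\n", x$gammas[g],
                nrow(x$tad_sets[[g]]$intervals), x$medians_bases[g] / 1e3))
  invisible(x)
}

#' Select the gamma whose calls match a target median TAD size
#'
#' Among the sweep's non-empty TAD sets, returns the one whose median domain
#' length is closest to `target_bases` (default 880 kb, the expected median
#' TAD size); ties are broken toward smaller gamma. Empty sets are never
#' selected; if every set is empty an error is raised.
#'
#' @param sweep a `gamma_sweep`.
#' @param target_bases target median TAD length in bases (default 880000).
#' @return the selected `TADSet`.
#' @export
select_gamma_by_median <- function(sweep, target_bases = 880000) {
  stopifnot(inherits(sweep, "gamma_sweep"))
  nonempty <- vapply(sweep$tad_sets,
                     function(t) nrow(t$intervals) > 0L, logical(1))
  if (!any(nonempty)) stop("no TADs callable at any gamma")
  dist <- abs(sweep$medians_bases - target_bases)
  dist[!nonempty] <- Inf
  sweep$tad_sets[[which.min(dist)]]    # which.min takes the first (smaller gamma)
}
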