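#' Simulation parameters for synthetic Hi-C samples
#'
#' Bundles the knobs of the generative model: a binned chromosome whose
#' background contact mean decays as a power law of genomic distance,
#' `lambda * (1 + d)^-decay_exponent`, with a multiplicative enrichment
#' `tad_enrichment` inside planted TADs, an optional long-range attenuation
#' emulating protocol (cross-linking) differences, and Poisson counting noise.
#'
#' @param n_bins chromosome length in bins.
#' @param bin_size bin width in bases (default 100000).
#' @param decay_exponent power-law decay exponent `alpha > 0` (default 1).
#' @param tad_enrichment within-TAD mean multiplier `beta > 1` (default 2).
#' @param depth Poisson mean scale `lambda` (expected diagonal count;
#'   default 300, deep enough for the coverage gate at a few hundred bins —
#'   see [calibrate_depth()]).
#' @param median_tad_bases target median planted TAD length (default 880000).
#' @param sigma_log log-scale spread of the log-normal TAD length law
#'   (default 0.5).
#' @param gap_prob probability of a background gap between consecutive TADs
#'   (default 0.1).
#' @param gap_mean_bins mean gap length in bins (geometric law, default 2).
#' @param boundary_perturb_rate per-boundary edit probability between "cell
#'   types" (default 0.3).
#' @param protocol_longrange_factor multiplier on mean counts beyond
#'   `longrange_cutoff_bins`, in `(0, 1]`; 1 = no protocol effect (the
#'   dilution protocol recovers fewer long-range contacts, default factor 0.7
#'   when applied).
#' @param longrange_cutoff_bins distance beyond which the protocol factor
#'   applies (default `1e6 / bin_size`, i.e. 1 Mb).
#' @return a list of class `sim_params`.
#' @export
sim_params <- function(n_bins, bin_size = 100000L, decay_exponent = 1.0,
                       tad_enrichment = 2.0, depth = 300,
                       median_tad_bases = 880000, sigma_log = 0.5,
                       gap_prob = 0.1, gap_mean_bins = 2,
                       boundary_perturb_rate = 0.3,
                       protocol_longrange_factor = 1.0,
                       longrange_cutoff_bins = NULL) {
  if (is.null(longrange_cutoff_bins))
    longrange_cutoff_bins <- as.integer(1e6 / bin_size)
  p <- list(n_bins = as.integer(n_bins), bin_size = as.integer(bin_size),
            decay_exponent = decay_exponent, tad_enrichment = tad_enrichment,
            depth = depth, median_tad_bases = median_tad_bases,
            sigma_log = sigma_log, gap_prob = gap_prob,
            gap_mean_bins = gap_mean_bins,
            boundary_perturb_rate = boundary_perturb_rate,
            protocol_longrange_factor = protocol_longrange_factor,
            longrange_cutoff_bins = as.integer(longrange_cutoff_bins))
  if (p$n_bins < 2L) stop("'n_bins' must be >= 2")
  if (p$decay_exponent <= 0) stop("'decay_exponent' must be > 0")
  if (p$tad_enrichment <= 1) stop("'tad_enrichment' must be > 1")
  if (p$depth < 0) stop("'depth' must be >= 0")
  if (p$boundary_perturb_rate < 0 || p$boundary_perturb_rate > 1)
    stop("'boundary_perturb_rate' must be in [0, 1]")
  if (p$protocol_longrange_factor <= 0 || p$protocol_longrange_factor > 1)
    stop("'protocol_longrange_factor' must be in (0, 1]")
  class(p) <- "sim_params"
  p
}

#' Minimum depth to pass the coverage quality gate
#'
#' Returns the `depth` (lambda) at which a simulated sample's expected
#' per-bin marginal equals `safety * min_contacts`, so generated cohorts
#' comfortably clear the "more than `min_contacts` in at least 80% of bins"
#' gate.
#'
#' @param n_bins chromosome length in bins.
#' @param decay_exponent background decay exponent.
#' @param min_contacts gate threshold (default 1000).
#' @param safety multiplier on the threshold (default 3).
#' @return suggested `depth` value.
#' @export
calibrate_depth <- function(n_bins, decay_exponent = 1.0,
                            min_contacts = 1000L, safety = 3) {
  g <- cumsum((1 + seq_len(n_bins))^-decay_exponent)  # g[k] = sum_{d=1..k}
  i <- seq_len(n_bins)
  marg <- 1 + ifelse(i > 1L, g[pmax(i - 1L, 1L)], 0) +
    ifelse(i < n_bins, g[pmax(n_bins - i, 1L)], 0)
  q20 <- unname(stats::quantile(marg, 0.2))  # the gate tolerates 20% failures
  safety * min_contacts / q20
}

#' Sample a planted TAD partition
#'
#' Domain lengths are i.i.d. log-normal in bins, parameterised so the
#' distribution median equals `median_tad_bases / bin_size` with log-scale
#' spread `sigma_log`, floored at 2 bins. Domains are laid left to right;
#' between consecutive domains a background gap is inserted with probability
#' `gap_prob` (geometric length, mean `gap_mean_bins`). The final domain is
#' truncated at the chromosome end.
#'
#' @param p a `sim_params`.
#' @param seed optional integer seed.
#' @return a list of class `planted_structure`: `tad_set` (ground-truth
#'   `TADSet`), `labels` (per-bin block labels, 0 = background).
#' @export
sample_tad_partition <- function(p, seed = NULL) {
  stopifnot(inherits(p, "sim_params"))
  med_bins <- p$median_tad_bases / p$bin_size
  if (p$n_bins < 2 * med_bins)
    stop("'n_bins' too small for the target median TAD size")
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  starts <- integer(0); ends <- integer(0)
  pos <- 0L
  while (pos < p$n_bins - 1L) {
    len <- max(2L, as.integer(round(stats::rlnorm(1, meanlog = log(med_bins),
                                                  sdlog = p$sigma_log))))
    end <- min(pos + len, p$n_bins)
    if (end - pos >= 2L) {
      starts <- c(starts, pos)
      ends <- c(ends, end)
    }
    pos <- end
    if (stats::runif(1) < p$gap_prob)
      pos <- pos + stats::rgeom(1, 1 / p$gap_mean_bins) + 1L
  }
  ts <- tad_set(data.frame(start_bin = starts, end_bin = ends),
                bin_size = p$bin_size, n_bins = p$n_bins)
  planted_structure(ts, p$n_bins)
}

planted_structure <- function(ts, n_bins) {
  labels <- integer(n_bins)
  iv <- ts$intervals
  for (r in seq_len(nrow(iv)))
    labels[(iv$start_bin[r] + 1L):iv$end_bin[r]] <- r
  structure(list(tad_set = ts, labels = labels, n_bins = n_bins),
            class = "planted_structure")
}

#' Simulate a Hi-C contact matrix over a planted structure
#'
#' The mean matrix is
#' `M[i,j] = depth * (1 + |i-j|)^-alpha * beta^[same TAD] * f^[|i-j| > cutoff]`
#' where `f` is the protocol long-range factor; counts are drawn entrywise
#' Poisson on the upper triangle and mirrored.
#'
#' @param s a `planted_structure`.
#' @param p a `sim_params`.
#' @param seed optional integer seed.
#' @return a raw-count `ContactMatrix`.
#' @export
simulate_contact_matrix <- function(s, p, seed = NULL) {
  stopifnot(inherits(s, "planted_structure"), inherits(p, "sim_params"))
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  M <- expected_contact_matrix(s, p)
  n <- p$n_bins
  up <- upper.tri(M, diag = TRUE)
  counts <- matrix(0, n, n)
  counts[up] <- stats::rpois(sum(up), M[up])
  counts <- counts + t(counts) - diag(diag(counts), n)
  contact_matrix(counts, bin_size = p$bin_size)
}

expected_contact_matrix <- function(s, p) {
  n <- p$n_bins
  idx <- seq_len(n)
  d <- abs(outer(idx, idx, `-`))
  M <- p$depth * (1 + d)^(-p$decay_exponent)
  same <- outer(s$labels, s$labels, `==`) & (s$labels > 0L)
  M[same] <- M[same] * p$tad_enrichment
  if (p$protocol_longrange_factor < 1) {
    far <- d > p$longrange_cutoff_bins
    M[far] <- M[far] * p$protocol_longrange_factor
  }
  M
}

#' Perturb a planted partition's boundaries
#'
#' Operationalises between-cell-type boundary divergence: each interior
#' boundary is edited independently with probability `rate`, choosing with
#' equal probability among a shift by 1-3 bins (either direction), a deletion
#' (merging the blocks it separates) or a split (a new boundary inside an
#' adjacent domain). Edits that would produce an invalid partition (domains
#' shorter than 2 bins, overlaps) are skipped. `rate = 0` returns an
#' identical structure.
#'
#' @param s a `planted_structure`.
#' @param rate per-boundary edit probability in `[0, 1]`.
#' @param seed optional integer seed.
#' @return a new `planted_structure`.
#' @export
perturb_partition <- function(s, rate, seed = NULL) {
  stopifnot(inherits(s, "planted_structure"))
  if (rate < 0 || rate > 1) stop("'rate' must be in [0, 1]")
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  iv <- s$tad_set$intervals[, c("start_bin", "end_bin")]
  n <- s$n_bins
  if (rate == 0 || nrow(iv) == 0L)
    return(planted_structure(tad_set(iv, chrom = s$tad_set$chrom,
                                     bin_size = s$tad_set$bin_size,
                                     n_bins = n), n))
  bounds <- sort(unique(c(iv$start_bin, iv$end_bin)))
  bounds <- bounds[bounds > 0L & bounds < n]
  for (b in bounds) {
    if (stats::runif(1) >= rate) next
    op <- sample(c("shift", "delete", "split"), 1L)
    iv <- switch(op,
                 shift = perturb_shift(iv, b, n),
                 delete = perturb_delete(iv, b, n),
                 split = perturb_split(iv, b))
  }
  iv <- iv[order(iv$start_bin), , drop = FALSE]
  planted_structure(tad_set(iv, chrom = s$tad_set$chrom,
                            bin_size = s$tad_set$bin_size, n_bins = n), n)
}

perturb_shift <- function(iv, b, n) {
  delta <- sample(c(-3:-1, 1:3), 1L)
  nb <- b + delta
  if (nb <= 0L || nb >= n) return(iv)
  cand <- iv
  cand$start_bin[cand$start_bin == b] <- nb
  cand$end_bin[cand$end_bin == b] <- nb
  if (valid_intervals(cand, n)) cand else iv
}

perturb_delete <- function(iv, b, n) {
  ei <- which(iv$end_bin == b)
  si <- which(iv$start_bin == b)
  cand <- iv
  if (length(ei) == 1L && length(si) == 1L) {
    # shared boundary of two adjacent domains: merge them
    cand$end_bin[ei] <- cand$end_bin[si]
    cand <- cand[-si, , drop = FALSE]
  } else if (length(ei) == 1L) {
    # domain end followed by a gap: absorb the gap
    nxt <- which(iv$start_bin > b)
    cand$end_bin[ei] <- if (length(nxt)) min(iv$start_bin[nxt]) else n
  } else if (length(si) == 1L) {
    # domain start preceded by a gap: absorb it backwards
    prv <- which(iv$end_bin < b)
    cand$start_bin[si] <- if (length(prv)) max(iv$end_bin[prv]) else 0L
  } else {
    return(iv)
  }
  if (valid_intervals(cand, n)) cand else iv
}

perturb_split <- function(iv, b) {
  adj <- which(iv$start_bin == b | iv$end_bin == b)
  if (length(adj) == 0L) return(iv)
  i <- if (length(adj) == 1L) adj else sample(adj, 1L)
  len <- iv$end_bin[i] - iv$start_bin[i]
  if (len < 4L) return(iv)
  cuts <- seq.int(2L, len - 2L)
  cut <- iv$start_bin[i] + cuts[sample.int(length(cuts), 1L)]
  cand <- rbind(iv,
                data.frame(start_bin = cut, end_bin = iv$end_bin[i]))
  cand$end_bin[i] <- cut
  cand[order(cand$start_bin), , drop = FALSE]
}

valid_intervals <- function(iv, n) {
  iv <- iv[order(iv$start_bin), , drop = FALSE]
  if (any(iv$end_bin - iv$start_bin < 2L)) return(FALSE)
  if (any(iv$start_bin < 0L) || any(iv$end_bin > n)) return(FALSE)
  if (nrow(iv) > 1L && any(iv$start_bin[-1L] < iv$end_bin[-nrow(iv)]))
    return(FALSE)
  TRUE
}
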