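#' Binned intra-chromosomal Hi-C contact matrix
#'
#' Constructs a `ContactMatrix`: a symmetric, non-negative `n x n` matrix of
#' contact counts between fixed-width genomic bins on one chromosome. Raw
#' matrices hold integer counts; balanced matrices (see [ice_normalize()])
#' hold reals.
#'
#' @param counts symmetric numeric matrix of non-negative, finite values.
#' @param chrom chromosome label.
#' @param bin_size bin width in bases (default 100000, i.e. 100 kb).
#' @param sym_tol tolerance for the symmetry check; inputs asymmetric beyond
#'   this are rejected, smaller asymmetries (floating-point noise) are
#'   symmetrised away.
#' @return an object of class `ContactMatrix` with fields `chrom`, `bin_size`,
#'   `counts` and `n_bins`.
#' @examples
#' m <- contact_matrix(matrix(c(0, 5, 5, 0), 2), chrom = "chr1")
#' m$n_bins
#' @export
contact_matrix <- function(counts, chrom = "chr1", bin_size = 100000L,
                           sym_tol = 1e-9) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("'counts' must be a numeric matrix")
  n <- nrow(counts)
  if (n < 1L || ncol(counts) != n)
    stop("'counts' must be a non-empty square matrix")
  if (anyNA(counts) || any(!is.finite(counts)))
    stop("'counts' contains NA or non-finite values")
  if (any(counts < 0))
    stop("'counts' contains negative values")
  asym <- max(abs(counts - t(counts)))
  if (asym > sym_tol)
    stop(sprintf("matrix asymmetric beyond tolerance (max |m - t(m)| = %g)", asym))
  if (asym > 0) counts <- (counts + t(counts)) / 2
  bin_size <- as.integer(bin_size)
  if (is.na(bin_size) || bin_size < 1L) stop("'bin_size' must be >= 1")
  structure(
    list(chrom = as.character(chrom), bin_size = bin_size,
         counts = unname(counts), n_bins = n),
    class = "ContactMatrix"
  )
}

#' @export
print.ContactMatrix <- function(x, ...) {
  cat(sprintf("ContactMatrix: %s, %d bins of %s bp (%.1f Mb)\n",
              x$chrom, x$n_bins, format(x$bin_size, big.mark = ","),
              x$n_bins * x$bin_size / 1e6))
  cat(sprintf("  total counts: %s; nonzero entries: %d/%d\n",
              format(sum(x$counts), big.mark = ","),
              sum(x$counts != 0), length(x$counts)))
  invisible(x)
}

is_contact_matrix <- function(x) inherits(x, "ContactMatrix")

stopifnot_cm <- function(m) {
  if (!is_contact_matrix(m)) stop("expected a ContactMatrix")
  invisible(m)
}

#' Merge sequencing replicates by summing counts
#'
#' Replicate raw contact matrices of one sample are combined into a single
#' deeper matrix by entrywise addition, the standard way replicate Hi-C
#' libraries are pooled before downstream analysis.
#'
#' @param ms list of `ContactMatrix` objects sharing chromosome, bin size and
#'   dimension, all holding raw counts.
#' @return a `ContactMatrix` with the entrywise sum.
#' @export
merge_replicates <- function(ms) {
  if (!is.list(ms) || length(ms) == 0L)
    stop("'ms' must be a non-empty list of ContactMatrix objects")
  lapply(ms, stopifnot_cm)
  ref <- ms[[1L]]
  for (m in ms[-1L]) {
    if (m$chrom != ref$chrom || m$bin_size != ref$bin_size ||
        m$n_bins != ref$n_bins)
      stop("replicates disagree in chrom, bin_size or n_bins")
  }
  total <- Reduce(`+`, lapply(ms, `[[`, "counts"))
  contact_matrix(total, chrom = ref$chrom, bin_size = ref$bin_size)
}

#' Per-sample coverage quality gate
#'
#' A sample is analyzable at a given resolution when enough bins are well
#' covered: by default at least 80% of all bins must contain more than 1000
#' contacts. A bin's contact count is its marginal (row sum of the raw count
#' matrix, diagonal counted once); the contact threshold is strict
#' ("more than").
#'
#' @param m raw-count `ContactMatrix`.
#' @param min_contacts contact threshold per bin (strict; default 1000).
#' @param min_fraction minimum passing-bin fraction (default 0.80).
#' @param include_diagonal whether the diagonal contributes to the per-bin
#'   marginal (default `TRUE`).
#' @return a `QualityReport` list: `n_bins`, `n_passing_bins`,
#'   `fraction_passing`, `passed`, `threshold_contacts`, `threshold_fraction`.
#' @examples
#' m <- contact_matrix(matrix(600, 5, 5))
#' coverage_quality_check(m)$passed
#' @export
coverage_quality_check <- function(m, min_contacts = 1000L,
                                   min_fraction = 0.80,
                                   include_diagonal = TRUE) {
  stopifnot_cm(m)
  if (m$n_bins == 0L) stop("empty matrix")
  marg <- rowSums(m$counts)
  if (!include_diagonal) marg <- marg - diag(m$counts)
  n_pass <- sum(marg > min_contacts)
  frac <- n_pass / m$n_bins
  structure(
    list(n_bins = m$n_bins, n_passing_bins = n_pass,
         fraction_passing = frac, passed = frac >= min_fraction,
         threshold_contacts = min_contacts, threshold_fraction = min_fraction),
    class = "QualityReport"
  )
}

#' @export
print.QualityReport <- function(x, ...) {
  cat(sprintf("QualityReport: %d/%d bins (%.1f%%) with > %d contacts -> %s\n",
              x$n_passing_bins, x$n_bins, 100 * x$fraction_passing,
              x$threshold_contacts,
              if (x$passed) "PASS" else "FAIL"))
  invisible(x)
}
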