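#' Jaccard index of two TAD boundary sets
#'
#' `JI(A, B) = |A intersect B| / |A union B|` over the two boundary position
#' sets. With `tolerance_bins > 0` the intersection is counted via a maximum
#' bipartite matching of boundaries at most that many bins apart, and the
#' union size becomes `|A| + |B| - |matched|`. Two empty sets agree vacuously
#' (JI 1 with a warning) so cohort pipelines do not fail on empty chromosomes.
#'
#' @param a,b sorted integer vectors of boundary bin positions (see
#'   [boundaries_of()]), or `TADSet` objects.
#' @param tolerance_bins matching tolerance in bins (default 0 = exact).
#' @return the Jaccard index in `[0, 1]`.
#' @examples
#' jaccard_index(c(5, 10, 15, 20), c(10, 20, 30))  # 2/5
#' @export
jaccard_index <- function(a, b, tolerance_bins = 0L) {
  if (inherits(a, "TADSet")) a <- boundaries_of(a)
  if (inherits(b, "TADSet")) b <- boundaries_of(b)
  a <- sort(unique(as.integer(a)))
  b <- sort(unique(as.integer(b)))
  if (length(a) == 0L && length(b) == 0L) {
    warning("both boundary sets empty; JI defined as 1")
    return(1.0)
  }
  if (tolerance_bins == 0L) {
    inter <- length(intersect(a, b))
    return(inter / (length(a) + length(b) - inter))
  }
  matched <- convex_max_matching(a, b, tolerance_bins)
  matched / (length(a) + length(b) - matched)
}

# Maximum matching between two sorted position vectors where a pair may be
# matched iff |a_i - b_j| <= tol. The adjacency is convex (each b sees a
# contiguous run of a), so the greedy rule "assign each b, in order, the
# smallest unused compatible a" attains the maximum matching size.
convex_max_matching <- function(a, b, tol) {
  matched <- 0L
  i <- 1L
  for (j in seq_along(b)) {
    while (i <= length(a) && a[i] < b[j] - tol) i <- i + 1L
    if (i <= length(a) && a[i] <= b[j] + tol) {
      matched <- matched + 1L
      i <- i + 1L
    }
  }
  matched
}
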