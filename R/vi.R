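#' Partition of a bin window induced by a TAD set
#'
#' Clips a TAD set to the half-open window `[w_start, w_end)` and labels every
#' bin: each (clipped) TAD is one block, and each maximal run of bins not
#' covered by any TAD is its own background block. The partition is
#' represented by its internal breakpoints, which is all the variation of
#' information needs.
#'
#' @param t a `TADSet` (or integer vector of breakpoint positions).
#' @param w_start,w_end window bounds in bins (0-based, half-open).
#' @return an object of class `bin_partition`: `w_start`, `w_end`,
#'   `breaks` (sorted positions strictly inside the window where the block
#'   label changes).
#' @export
bin_partition <- function(t, w_start, w_end) {
  if (w_end <= w_start) stop("window must satisfy w_start < w_end")
  pos <- if (inherits(t, "TADSet"))
    c(t$intervals$start_bin, t$intervals$end_bin) else as.integer(t)
  breaks <- sort(unique(pos[pos > w_start & pos < w_end]))
  structure(list(w_start = as.integer(w_start), w_end = as.integer(w_end),
                 breaks = as.integer(breaks)),
            class = "bin_partition")
}

partition_block_sizes <- function(p) {
  diff(c(p$w_start, p$breaks, p$w_end))
}

entropy_nats <- function(sizes) {
  pr <- sizes / sum(sizes)
  -sum(pr * log(pr))
}

#' Variation of information between two partitions of the same window
#'
#' The Meila distance `VI = H(P) + H(Q) - 2 I(P, Q)` in nats, computed over
#' block-size proportions. Because both partitions consist of contiguous
#' blocks, the joint partition is simply the one induced by the union of
#' their breakpoints, and `VI = 2 H(joint) - H(P) - H(Q)`. VI is 0 iff the
#' partitions are identical, and satisfies symmetry and the triangle
#' inequality.
#'
#' @param p,q `bin_partition` objects over identical windows.
#' @return VI in nats (>= 0).
#' @examples
#' p <- bin_partition(c(2L), 0, 4)   # blocks [0,2), [2,4)
#' q <- bin_partition(integer(), 0, 4)
#' variation_of_information(p, q)    # log(2)
#' @export
variation_of_information <- function(p, q) {
  stopifnot(inherits(p, "bin_partition"), inherits(q, "bin_partition"))
  if (p$w_start != q$w_start || p$w_end != q$w_end)
    stop("partitions cover different windows")
  hp <- entropy_nats(partition_block_sizes(p))
  hq <- entropy_nats(partition_block_sizes(q))
  joint <- p
  joint$breaks <- sort(unique(c(p$breaks, q$breaks)))
  hj <- entropy_nats(partition_block_sizes(joint))
  max(0, 2 * hj - hp - hq)
}
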