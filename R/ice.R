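#' Iterative correction (ICE) balancing of a contact matrix
#'
#' Removes multiplicative per-bin biases by iterative proportional fitting:
#' the raw counts are factorised as `counts[i,j] = bias[i] * bias[j] * W[i,j]`
#' with the balanced matrix `W` having equal marginals on all usable rows.
#' The target is unit mean row sum over nonzero rows. All-zero rows
#' (unmappable bins) are excluded from balancing: they keep bias 1, stay zero,
#' and are reported in `unusable_bins`.
#'
#' @param m raw-count `ContactMatrix` with at least one nonzero entry.
#' @param tol convergence tolerance: iteration stops when the maximum relative
#'   change of the bias vector drops below `tol` (default 1e-6).
#' @param max_iter maximum number of iterations (default 200); if reached
#'   without convergence a warning is raised and the partial result returned
#'   with `converged = FALSE`.
#' @return a list of class `ice_result`: `matrix` (balanced `ContactMatrix`),
#'   `bias` (length `n_bins`), `converged`, `n_iter`, `unusable_bins`
#'   (0-based indices of all-zero rows).
#' @examples
#' m <- contact_matrix(matrix(c(0, 4, 4, 0), 2))
#' ice_normalize(m)$bias
#' @export
ice_normalize <- function(m, tol = 1e-6, max_iter = 200L) {
  stopifnot_cm(m)
  if (tol <= 0) stop("'tol' must be > 0")
  if (max_iter < 1L) stop("'max_iter' must be >= 1")
  counts <- m$counts
  n <- m$n_bins
  usable <- rowSums(counts) > 0
  if (!any(usable)) stop("all-zero matrix cannot be balanced")
  W <- counts
  bias <- rep(1, n)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    s <- rowSums(W)
    db <- s / mean(s[usable])
    db[!usable | db == 0] <- 1
    W <- W / outer(db, db)
    bias <- bias * db
    if (max(abs(db - 1)) < tol) {
      converged <- TRUE
      break
    }
  }
  # rescale so usable rows have unit mean row sum, absorbing scale into bias
  sc <- mean(rowSums(W)[usable])
  W <- W / sc
  bias <- bias * sqrt(sc)
  bias[!usable] <- 1    # unmappable bins keep unit bias
  if (!converged)
    warning(sprintf("ICE did not converge in %d iterations (tol %g)",
                    max_iter, tol))
  out <- contact_matrix(W, chrom = m$chrom, bin_size = m$bin_size,
                        sym_tol = 1e-8)
  structure(
    list(matrix = out, bias = bias, converged = converged, n_iter = iter,
         unusable_bins = which(!usable) - 1L),
    class = "ice_result"
  )
}

#' @export
print.ice_result <- function(x, ...) {
  cat(sprintf("ICE balancing: %s after %d iterations; %d unusable bin(s)\n",
              if (x$converged) "converged" else "NOT converged",
              x$n_iter, length(x$unusable_bins)))
  invisible(x)
}
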