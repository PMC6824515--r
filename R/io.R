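#' Read a contact matrix from HiC-Pro sparse or dense TSV format
#'
#' HiC-Pro sparse format is a header-free, tab-separated triplet file
#' `bin_i  bin_j  value` (0-based bin ids, upper-triangular or symmetric)
#' with a companion BED bin table `chrom  start  end  bin_id`. Dense TSV is a
#' full `n x n` matrix, no header.
#'
#' @param matrix_path path to the matrix file.
#' @param bins_path path to the companion BED bin table (required for
#'   `format = "hicpro_sparse"`).
#' @param format `"hicpro_sparse"` or `"dense_tsv"`.
#' @param chrom,bin_size metadata used for `dense_tsv` input (for sparse input
#'   they are taken from the bin table).
#' @return a `ContactMatrix`. Missing sparse entries are zero; upper-triangular
#'   input is mirrored.
#' @export
read_contact_matrix <- function(matrix_path, bins_path = NULL,
                                format = c("hicpro_sparse", "dense_tsv"),
                                chrom = "chr1", bin_size = 100000L) {
  format <- match.arg(format)
  if (!file.exists(matrix_path)) stop("no such file: ", matrix_path)
  if (format == "dense_tsv") {
    d <- as.matrix(data.table::fread(matrix_path, header = FALSE, sep = "\t"))
    if (anyNA(d)) stop("malformed dense matrix: non-numeric or missing cells")
    return(contact_matrix(d, chrom = chrom, bin_size = bin_size))
  }
  if (is.null(bins_path)) stop("hicpro_sparse format requires 'bins_path'")
  bins <- read_bin_table(bins_path)
  n <- nrow(bins)
  trip <- read_triplets(matrix_path)
  counts <- matrix(0, n, n)
  if (nrow(trip) > 0L) {
    oob <- which(trip$i < 0L | trip$j < 0L | trip$i >= n | trip$j >= n)
    if (length(oob) > 0L)
      stop(sprintf("triplet bin id out of range for %d-bin table (line %d)",
                   n, oob[1L]))
    counts[cbind(trip$i + 1L, trip$j + 1L)] <- trip$v
    if (all(trip$i <= trip$j)) {
      # upper-triangular input: mirror below the diagonal
      counts <- counts + t(counts) - diag(diag(counts), n)
    }
    # symmetric input is validated (and fp noise symmetrised) by the ctor
  }
  contact_matrix(counts, chrom = bins$chrom[1L],
                 bin_size = as.integer(bins$end[1L] - bins$start[1L]))
}

read_bin_table <- function(bins_path) {
  if (!file.exists(bins_path)) stop("no such file: ", bins_path)
  bins <- tryCatch(
    data.table::fread(bins_path, header = FALSE, sep = "\t",
                      col.names = c("chrom", "start", "end", "bin_id")),
    error = function(e) stop("malformed bin table: ", conditionMessage(e)))
  bins <- as.data.frame(bins)
  if (nrow(bins) == 0L) stop("empty bin table")
  if (!identical(as.integer(bins$bin_id), seq_len(nrow(bins)) - 1L))
    stop("bin ids must be 0-based, contiguous and sorted")
  if (any(bins$end <= bins$start)) stop("bin intervals must have end > start")
  if (nrow(bins) > 1L && any(bins$start[-1L] != bins$end[-nrow(bins)]))
    stop("bin intervals must tile the chromosome without gaps")
  bins
}

read_triplets <- function(matrix_path) {
  lines <- readLines(matrix_path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(data.frame(i = integer(), j = integer(), v = numeric()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad) > 0L)
    stop(sprintf("malformed triplet at line %d: expected 3 tab-separated fields",
                 bad[1L]))
  i <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 1L)))
  j <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L)))
  v <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  bad <- which(is.na(i) | is.na(j) | is.na(v))
  if (length(bad) > 0L)
    stop(sprintf("malformed triplet at line %d: non-numeric field", bad[1L]))
  data.frame(i = i, j = j, v = v)
}

#' Write a contact matrix in HiC-Pro sparse or dense TSV format
#'
#' Sparse output lists the upper triangle only (`i <= j`), omitting zero
#' entries, alongside a BED bin table; reading back reproduces the matrix
#' exactly for integer counts.
#'
#' @param m a `ContactMatrix`.
#' @param matrix_path output path for the matrix file.
#' @param bins_path output path for the BED bin table (sparse format only).
#' @param format `"hicpro_sparse"` or `"dense_tsv"`.
#' @return invisibly, the paths written.
#' @export
write_contact_matrix <- function(m, matrix_path, bins_path = NULL,
                                 format = c("hicpro_sparse", "dense_tsv")) {
  stopifnot_cm(m)
  format <- match.arg(format)
  if (format == "dense_tsv") {
    data.table::fwrite(as.data.frame(m$counts), matrix_path, sep = "\t",
                       col.names = FALSE)
    return(invisible(matrix_path))
  }
  if (is.null(bins_path)) stop("hicpro_sparse format requires 'bins_path'")
  idx <- which(upper.tri(m$counts, diag = TRUE) & m$counts != 0,
               arr.ind = TRUE)
  trip <- data.frame(i = idx[, 1L] - 1L, j = idx[, 2L] - 1L,
                     v = m$counts[idx])
  trip <- trip[order(trip$i, trip$j), , drop = FALSE]
  data.table::fwrite(trip, matrix_path, sep = "\t", col.names = FALSE)
  starts <- (seq_len(m$n_bins) - 1L) * m$bin_size
  bed <- data.frame(chrom = m$chrom, start = starts,
                    end = starts + m$bin_size,
                    bin_id = seq_len(m$n_bins) - 1L)
  data.table::fwrite(bed, bins_path, sep = "\t", col.names = FALSE)
  invisible(c(matrix_path, bins_path))
}

#' Write a TAD set as a BED file
#'
#' One line per domain: chrom, start, end (bases, 0-based half-open), name
#' `TAD_k`, score (the domain's centered quality, 0 when absent), strand ".".
#'
#' @param t a `TADSet`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_tad_bed <- function(t, path) {
  stopifnot(inherits(t, "TADSet"))
  iv <- t$intervals
  bed <- data.frame(
    chrom = rep(t$chrom, nrow(iv)),
    start = iv$start_bin * t$bin_size,
    end = iv$end_bin * t$bin_size,
    name = if (nrow(iv)) paste0("TAD_", seq_len(nrow(iv))) else character(),
    score = if (is.null(iv$score)) rep(0, nrow(iv)) else iv$score,
    strand = rep(".", nrow(iv)))
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a TAD set from a BED file
#'
#' @param path BED file (at least chrom/start/end columns), coordinates in
#'   bases.
#' @param bin_size bin width used to convert coordinates to bin units.
#' @return a `TADSet` (with `gamma = NA`).
#' @export
read_tad_bed <- function(path, bin_size = 100000L) {
  if (!file.exists(path)) stop("no such file: ", path)
  info <- file.info(path)
  if (info$size == 0L) {
    return(tad_set(data.frame(start_bin = integer(), end_bin = integer()),
                   chrom = "chr1", bin_size = bin_size, gamma = NA_real_))
  }
  bed <- as.data.frame(data.table::fread(path, header = FALSE, sep = "\t"))
  iv <- data.frame(start_bin = as.integer(bed[[2L]] / bin_size),
                   end_bin = as.integer(bed[[3L]] / bin_size))
  if (ncol(bed) >= 5L) iv$score <- as.numeric(bed[[5L]])
  tad_set(iv[order(iv$start_bin), , drop = FALSE], chrom = bed[[1L]][1L],
          bin_size = bin_size, gamma = NA_real_)
}
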