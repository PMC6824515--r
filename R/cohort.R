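#' Specification of a synthetic Hi-C cohort
#'
#' Describes a cohort of simulated samples: each row of `samples` is one
#' biological sample with a cell type, a replicate count and technical
#' metadata. Samples of the same cell type share one planted TAD partition;
#' partitions of different cell types are independent perturbations of a
#' common root at `boundary_perturb_rate`. Replicates are independent Poisson
#' resamples of the same mean matrix. The dilution protocol applies the
#' long-range attenuation factor; restriction enzyme and lab are metadata-only
#' by default (no generative effect), so the pipeline can demonstrate
#' true-negative contrasts.
#'
#' @param samples data.frame with columns `sample_id`, `cell_type`,
#'   `replicates`, and optionally `protocol` (`"in_situ"`/`"dilution"`),
#'   `enzyme` (`"HindIII"`, `"MboI"`, `"NcoI"`, `"DpnII"`), `lab`,
#'   `donor_id`, `is_tissue`, `family_id`, `trio_relation`
#'   (`"parent1"`/`"parent2"`/`"child"`/`"none"`), `depth_factor`
#'   (per-sample library-size multiplier on `depth`). Missing optional
#'   columns get defaults (in situ, MboI, one lab, cell lines, no trios,
#'   factor 1).
#' @param params a [sim_params()] object (supplies `n_bins`, decay, depth,
#'   enrichment, perturb rate, protocol factor).
#' @param seed master integer seed; all randomness flows from it through
#'   named substreams.
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(samples, params, seed = 1L) {
  stopifnot(is.data.frame(samples), inherits(params, "sim_params"))
  req <- c("sample_id", "cell_type", "replicates")
  miss <- setdiff(req, names(samples))
  if (length(miss)) stop("samples table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id in cohort config")
  if (any(samples$replicates < 1L)) stop("each sample needs >= 1 replicate")
  defaults <- list(protocol = "in_situ", enzyme = "MboI", lab = "lab1",
                   is_tissue = FALSE, trio_relation = "none",
                   family_id = NA_character_, depth_factor = 1.0)
  for (nm in names(defaults))
    if (is.null(samples[[nm]])) samples[[nm]] <- defaults[[nm]]
  if (is.null(samples$donor_id))
    samples$donor_id <- paste0("donor_", seq_len(nrow(samples)))
  bad <- setdiff(samples$protocol, c("in_situ", "dilution"))
  if (length(bad)) stop("unknown protocol: ", paste(bad, collapse = ", "))
  bad <- setdiff(samples$enzyme, c("HindIII", "MboI", "NcoI", "DpnII"))
  if (length(bad)) stop("unknown enzyme: ", paste(bad, collapse = ", "))
  bad <- setdiff(samples$trio_relation, c("parent1", "parent2", "child", "none"))
  if (length(bad)) stop("unknown trio relation: ", paste(bad, collapse = ", "))
  structure(list(samples = samples, params = params, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Default cohort layout: k cell types with r replicates each
#'
#' @param n_cell_types number of cell types (one sample per type).
#' @param replicates replicates per sample.
#' @param params a [sim_params()].
#' @param seed master seed.
#' @return a `cohort_config`.
#' @export
default_cohort_config <- function(n_cell_types = 10L, replicates = 2L,
                                  params, seed = 1L) {
  samples <- data.frame(
    sample_id = sprintf("S%02d", seq_len(n_cell_types)),
    cell_type = sprintf("type%02d", seq_len(n_cell_types)),
    replicates = as.integer(replicates))
  cohort_config(samples, params, seed = seed)
}

#' Generate a synthetic Hi-C cohort
#'
#' Materialises a [cohort_config()]: plants one root TAD partition, derives a
#' per-cell-type partition by boundary perturbation, simulates each
#' replicate's raw contact matrix, and merges replicates per sample. Fully
#' deterministic given the config seed.
#'
#' @param config a `cohort_config`.
#' @return a list of class `tad_cohort`: `samples` (per sample: `meta`,
#'   `replicates` list of raw `ContactMatrix`, `merged`), `truth` (planted
#'   `planted_structure` per cell type), `metadata` (one row per replicate),
#'   `sample_table`, `config`.
#' @export
make_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  p <- config$params
  seed <- config$seed
  root <- sample_tad_partition(p, seed = substream_seed(seed, "root"))
  types <- unique(config$samples$cell_type)
  truth <- list()
  for (ct in types) {
    truth[[ct]] <- if (p$boundary_perturb_rate > 0)
      perturb_partition(root, p$boundary_perturb_rate,
                        seed = substream_seed(seed, paste0("type:", ct)))
    else root
  }
  samples <- list()
  meta_rows <- list()
  for (r in seq_len(nrow(config$samples))) {
    row <- config$samples[r, , drop = FALSE]
    sp <- p
    sp$protocol_longrange_factor <-
      if (row$protocol == "dilution") p$protocol_longrange_factor else 1.0
    sp$depth <- p$depth * row$depth_factor   # per-sample library size
    class(sp) <- "sim_params"
    struct <- truth[[row$cell_type]]
    reps <- lapply(seq_len(row$replicates), function(k)
      simulate_contact_matrix(struct, sp,
        seed = substream_seed(seed, paste0("sample:", row$sample_id,
                                           ":rep:", k))))
    merged <- if (length(reps) > 1L) merge_replicates(reps) else reps[[1L]]
    samples[[row$sample_id]] <- list(meta = row, replicates = reps,
                                     merged = merged)
    for (k in seq_len(row$replicates)) {
      mr <- row
      mr$replicate_index <- k
      meta_rows[[length(meta_rows) + 1L]] <- mr
    }
  }
  structure(list(samples = samples, truth = truth,
                 metadata = do.call(rbind, meta_rows),
                 sample_table = config$samples, config = config),
            class = "tad_cohort")
}

#' @export
print.tad_cohort <- function(x, ...) {
  cat(sprintf("tad_cohort: %d sample(s), %d replicate matrices, %d cell type(s), %d bins\n",
              length(x$samples), nrow(x$metadata),
              length(x$truth), x$config$params$n_bins))
  invisible(x)
}

#' Write a cohort to disk in standard formats
#'
#' Emits, per replicate, a HiC-Pro sparse matrix and BED bin table; per cell
#' type, the planted truth TADs as BED; plus a metadata TSV.
#'
#' @param cohort a `tad_cohort`.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "tad_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(cohort$samples)) {
    s <- cohort$samples[[id]]
    for (k in seq_along(s$replicates)) {
      base <- file.path(dir, sprintf("%s_rep%d", id, k))
      write_contact_matrix(s$replicates[[k]],
                           paste0(base, ".matrix"),
                           paste0(base, "_abs.bed"))
    }
  }
  for (ct in names(cohort$truth))
    write_tad_bed(cohort$truth[[ct]]$tad_set,
                  file.path(dir, paste0("truth_", ct, ".bed")))
  data.table::fwrite(cohort$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t")
  invisible(dir)
}
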