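#' Validate and normalise a pipeline configuration
#'
#' Fills defaults (100-kb bins, gamma grid 0-1 by 0.1, 880-kb median target,
#' h range 0-3, alpha 0.05, 1000 null draws), rejects unknown keys, and
#' aggregates all type/range violations into one error. The h range is
#' hard-capped at 3 unless `allow_h_extend = TRUE`.
#'
#' @param config named list of overrides (possibly empty).
#' @return the full normalised config list (class `tadvar_config`).
#' @export
validate_config <- function(config = list()) {
  defaults <- list(
    mode = "simulate",
    n_bins = 300L, bin_size = 100000L,
    n_cell_types = 10L, replicates = 2L, samples = NULL,
    ingest = NULL,
    decay_exponent = 1.0, tad_enrichment = 2.0, depth = 300,
    median_tad_bases = 880000, sigma_log = 0.5,
    gap_prob = 0.1, gap_mean_bins = 2,
    boundary_perturb_rate = 0.3,
    protocol_longrange_factor = 0.7, longrange_cutoff_bins = NULL,
    gamma_grid = seq(0, 1, by = 0.1), target_bases = 880000,
    min_tad_bins = 2L, max_tad_bins = NULL,
    h_range = 0:3, h_delta = 0.01, allow_h_extend = FALSE,
    max_dist_bins = NULL,
    alpha = 0.05, n_null = 1000L, min_window_bins = 3L,
    max_window_bins = NULL,
    jaccard_tolerance = 0L,
    quality_min_contacts = 1000L, quality_min_fraction = 0.80,
    ice_tol = 1e-6, ice_max_iter = 200L,
    use_merged = TRUE,
    seed = 1L)
  if (!is.list(config)) stop("config must be a list")
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config, keep.null = TRUE)
  probs <- character(0)
  chk <- function(ok, msg) if (!ok) probs <<- c(probs, msg)
  chk(cfg$mode %in% c("simulate", "ingest"),
      "mode must be 'simulate' or 'ingest'")
  chk(is.numeric(cfg$n_bins) && cfg$n_bins >= 2, "n_bins must be >= 2")
  chk(is.numeric(cfg$bin_size) && cfg$bin_size >= 1, "bin_size must be >= 1")
  chk(is.numeric(cfg$gamma_grid) && length(cfg$gamma_grid) >= 1 &&
        all(cfg$gamma_grid >= 0), "gamma_grid must be non-negative numbers")
  chk(is.numeric(cfg$target_bases) && cfg$target_bases > 0,
      "target_bases must be > 0")
  chk(all(cfg$h_range >= 0), "h_range must be non-negative")
  if (!cfg$allow_h_extend)
    chk(max(cfg$h_range) <= 3, "h_range above 3 requires allow_h_extend")
  chk(cfg$alpha > 0 && cfg$alpha < 1, "alpha must be in (0, 1)")
  chk(cfg$n_null >= 100, "n_null must be >= 100")
  chk(cfg$quality_min_fraction > 0 && cfg$quality_min_fraction <= 1,
      "quality_min_fraction must be in (0, 1]")
  chk(cfg$boundary_perturb_rate >= 0 && cfg$boundary_perturb_rate <= 1,
      "boundary_perturb_rate must be in [0, 1]")
  chk(cfg$protocol_longrange_factor > 0 && cfg$protocol_longrange_factor <= 1,
      "protocol_longrange_factor must be in (0, 1]")
  chk(cfg$ice_tol > 0, "ice_tol must be > 0")
  chk(cfg$ice_max_iter >= 1, "ice_max_iter must be >= 1")
  if (length(probs) > 0L)
    stop("invalid config:\n  - ", paste(probs, collapse = "\n  - "))
  cfg$n_bins <- as.integer(cfg$n_bins)
  cfg$gamma_grid <- as.numeric(cfg$gamma_grid)
  cfg$h_range <- as.integer(cfg$h_range)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- c("tadvar_config", "list")
  cfg
}

pipeline_params <- function(cfg) {
  sim_params(n_bins = cfg$n_bins, bin_size = cfg$bin_size,
             decay_exponent = cfg$decay_exponent,
             tad_enrichment = cfg$tad_enrichment, depth = cfg$depth,
             median_tad_bases = cfg$median_tad_bases,
             sigma_log = cfg$sigma_log, gap_prob = cfg$gap_prob,
             gap_mean_bins = cfg$gap_mean_bins,
             boundary_perturb_rate = cfg$boundary_perturb_rate,
             protocol_longrange_factor = cfg$protocol_longrange_factor,
             longrange_cutoff_bins = cfg$longrange_cutoff_bins)
}

#' Run the full analysis pipeline
#'
#' Orchestrates all stages on a simulated (or ingested) cohort: coverage
#' quality gate, ICE balancing, gamma-swept TAD calling with median-size
#' selection, pairwise scoring with all three similarity measures (replicate
#' pairs within samples, non-replicate pairs across merged samples), group
#' labelling, and Mann-Whitney contrasts. Samples whose merged matrix fails
#' the quality gate are excluded and logged, mirroring the exclusion of
#' unanalysable experiments in real cohorts.
#'
#' @param config named list of configuration overrides, see
#'   [validate_config()].
#' @param quiet suppress stage progress messages.
#' @return a list of class `tad_pipeline`: `config`, `cohort`, `pair_table`,
#'   `group_tests`, `tad_sets` (selected call per matrix id), `sweeps`
#'   (full gamma sweep per matrix id, for robustness re-selection),
#'   `pair_index`, `manifest`.
#' @export
run_full_pipeline <- function(config = list(), quiet = TRUE) {
  cfg <- validate_config(config)
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()

  say("stage 1/5: cohort")
  if (cfg$mode == "simulate") {
    params <- pipeline_params(cfg)
    cc <- if (is.null(cfg$samples))
      default_cohort_config(cfg$n_cell_types, cfg$replicates, params,
                            seed = cfg$seed)
    else cohort_config(cfg$samples, params, seed = cfg$seed)
    cohort <- make_cohort(cc)
  } else {
    cohort <- ingest_cohort(cfg)
  }

  say("stage 2/5: quality gate")
  excluded <- character(0)
  excluded_reps <- character(0)
  for (id in names(cohort$samples)) {
    s <- cohort$samples[[id]]
    qc <- coverage_quality_check(s$merged, cfg$quality_min_contacts,
                                 cfg$quality_min_fraction)
    if (!qc$passed) {
      excluded <- c(excluded, id)
      next
    }
    for (k in seq_along(s$replicates)) {
      qr <- coverage_quality_check(s$replicates[[k]],
                                   cfg$quality_min_contacts,
                                   cfg$quality_min_fraction)
      if (!qr$passed)
        excluded_reps <- c(excluded_reps, sprintf("%s.rep%d", id, k))
    }
  }
  included <- setdiff(names(cohort$samples), excluded)
  if (length(included) == 0L) stop("quality gate excluded every sample")

  say("stage 3/5: ICE + TAD calling")
  norm <- list()     # normalized ContactMatrix per matrix id
  sweeps <- list()   # gamma_sweep per matrix id
  tads <- list()     # selected TADSet per matrix id
  gamma_sel <- list()
  add_matrix <- function(mid, m) {
    nm <- ice_normalize(m, tol = cfg$ice_tol, max_iter = cfg$ice_max_iter)
    norm[[mid]] <<- nm$matrix
    sw <- gamma_sweep(nm$matrix, gammas = cfg$gamma_grid,
                      min_len = cfg$min_tad_bins, max_len = cfg$max_tad_bins)
    sweeps[[mid]] <<- sw
    tsel <- select_gamma_by_median(sw, cfg$target_bases)
    tads[[mid]] <<- tsel
    gamma_sel[[mid]] <<- tsel$gamma
  }
  for (id in included) {
    s <- cohort$samples[[id]]
    add_matrix(id, if (cfg$use_merged) s$merged else s$replicates[[1L]])
    for (k in seq_along(s$replicates)) {
      rid <- sprintf("%s.rep%d", id, k)
      if (rid %in% excluded_reps) next
      if (length(s$replicates) >= 2L) add_matrix(rid, s$replicates[[k]])
    }
  }

  say("stage 4/5: pairwise scoring")
  score_pair <- function(mid1, mid2, seed_label) {
    h <- suppressWarnings(
      select_h(norm[[mid1]], norm[[mid2]], h_range = cfg$h_range,
               delta = cfg$h_delta, max_dist_bins = cfg$max_dist_bins))
    sc <- scc(norm[[mid1]], norm[[mid2]], h = h,
              max_dist_bins = cfg$max_dist_bins)
    ji <- suppressWarnings(
      jaccard_index(tads[[mid1]], tads[[mid2]],
                    tolerance_bins = cfg$jaccard_tolerance))
    tsim <- suppressWarnings(
      tadsim(tads[[mid1]], tads[[mid2]], n_bins = cfg$n_bins,
             alpha = cfg$alpha, n_null = cfg$n_null,
             min_window_bins = cfg$min_window_bins,
             max_window_bins = cfg$max_window_bins,
             seed = substream_seed(cfg$seed, seed_label)))
    list(hicrep = sc, ji = ji, tadsim = tsim$coverage, h = h)
  }
  merged_rows <- list(); rep_rows <- list(); idx_rows <- list()
  h_sel <- list()
  if (length(included) >= 2L) {
    prs <- utils::combn(included, 2L)
    for (c_i in seq_len(ncol(prs))) {
      id1 <- prs[1L, c_i]; id2 <- prs[2L, c_i]
      sc <- score_pair(id1, id2, paste0("tadsim:", id1, ":", id2))
      merged_rows[[length(merged_rows) + 1L]] <-
        data.frame(id1 = id1, id2 = id2, hicrep = sc$hicrep, ji = sc$ji,
                   tadsim = sc$tadsim)
      h_sel[[paste(id1, id2, sep = "|")]] <- sc$h
      idx_rows[[length(idx_rows) + 1L]] <-
        data.frame(id1 = id1, id2 = id2, mid1 = id1, mid2 = id2,
                   is_replicate = FALSE,
                   seed_label = paste0("tadsim:", id1, ":", id2))
    }
  }
  for (id in included) {
    s <- cohort$samples[[id]]
    reps_ok <- setdiff(sprintf("%s.rep%d", id, seq_along(s$replicates)),
                       excluded_reps)
    if (length(reps_ok) < 2L) next
    rp <- utils::combn(reps_ok, 2L)
    for (c_i in seq_len(ncol(rp))) {
      rid1 <- rp[1L, c_i]; rid2 <- rp[2L, c_i]
      sc <- score_pair(rid1, rid2, paste0("tadsim:", rid1, ":", rid2))
      k1 <- as.integer(sub(".*rep", "", rid1))
      k2 <- as.integer(sub(".*rep", "", rid2))
      rep_rows[[length(rep_rows) + 1L]] <-
        data.frame(sample_id = id, rep1 = k1, rep2 = k2,
                   hicrep = sc$hicrep, ji = sc$ji, tadsim = sc$tadsim)
      h_sel[[paste(rid1, rid2, sep = "|")]] <- sc$h
      idx_rows[[length(idx_rows) + 1L]] <-
        data.frame(id1 = rid1, id2 = rid2, mid1 = rid1, mid2 = rid2,
                   is_replicate = TRUE,
                   seed_label = paste0("tadsim:", rid1, ":", rid2))
    }
  }
  merged_scores <- if (length(merged_rows)) do.call(rbind, merged_rows)
    else data.frame(id1 = character(), id2 = character(), hicrep = numeric(),
                    ji = numeric(), tadsim = numeric())
  rep_scores <- if (length(rep_rows)) do.call(rbind, rep_rows)
    else data.frame(sample_id = character(), rep1 = integer(),
                    rep2 = integer(), hicrep = numeric(), ji = numeric(),
                    tadsim = numeric())
  pair_table <- build_pair_table(
    cohort$sample_table[cohort$sample_table$sample_id %in% included, ,
                        drop = FALSE],
    rep_scores, merged_scores)

  say("stage 5/5: group statistics")
  group_tests <- run_comparison_suite(pair_table)

  cfg_strip <- cfg; cfg_strip$samples <- NULL
  tf <- tempfile()
  writeLines(paste(deparse(cfg_strip), collapse = ""), tf)
  hash <- unname(tools::md5sum(tf))
  unlink(tf)
  manifest <- list(
    config_hash = hash, seed = cfg$seed,
    tool_version = as.character(utils::packageVersion("tadvar")),
    excluded_samples = excluded, excluded_replicates = excluded_reps,
    gamma_selected = unlist(gamma_sel),
    h_selected = unlist(h_sel),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  structure(list(config = cfg, cohort = cohort, pair_table = pair_table,
                 group_tests = group_tests, tad_sets = tads, sweeps = sweeps,
                 pair_index = do.call(rbind, idx_rows), manifest = manifest),
            class = "tad_pipeline")
}

#' @export
print.tad_pipeline <- function(x, ...) {
  cat(sprintf("tad_pipeline: %d pair(s) scored (%d replicate), %d excluded sample(s)\n",
              nrow(x$pair_table), sum(x$pair_table$is_replicate),
              length(x$manifest$excluded_samples)))
  cat("group tests:\n")
  print(x$group_tests[, c("measure", "contrast", "n_a", "n_b", "median_a",
                          "median_b", "p_value")])
  invisible(x)
}

# Ingest mode: cfg$ingest is a data.frame with columns sample_id, replicate,
# matrix_path, bins_path (HiC-Pro sparse); sample metadata may be supplied
# via cfg$samples (sample_id, cell_type, ...).
ingest_cohort <- function(cfg) {
  ing <- cfg$ingest
  if (is.null(ing) || !is.data.frame(ing))
    stop("ingest mode requires an 'ingest' data.frame")
  req <- c("sample_id", "replicate", "matrix_path", "bins_path")
  miss <- setdiff(req, names(ing))
  if (length(miss)) stop("ingest table lacks columns: ",
                         paste(miss, collapse = ", "))
  ids <- unique(ing$sample_id)
  samples <- list()
  for (id in ids) {
    sub <- ing[ing$sample_id == id, , drop = FALSE]
    sub <- sub[order(sub$replicate), , drop = FALSE]
    reps <- lapply(seq_len(nrow(sub)), function(k)
      read_contact_matrix(sub$matrix_path[k], sub$bins_path[k],
                          format = "hicpro_sparse"))
    merged <- if (length(reps) > 1L) merge_replicates(reps) else reps[[1L]]
    meta <- if (!is.null(cfg$samples))
      cfg$samples[cfg$samples$sample_id == id, , drop = FALSE]
    else data.frame(sample_id = id, cell_type = id,
                    replicates = nrow(sub))
    samples[[id]] <- list(meta = meta, replicates = reps, merged = merged)
  }
  sample_table <- do.call(rbind, lapply(samples, `[[`, "meta"))
  rownames(sample_table) <- NULL
  structure(list(samples = samples, truth = NULL, metadata = sample_table,
                 sample_table = sample_table, config = cfg),
            class = "tad_cohort")
}

#' Robustness of group contrasts to the target TAD size
#'
#' Re-selects each sample's gamma for every target median TAD size,
#' recomputes the TAD-level similarity measures (JI and TADsim; the
#' matrix-level HiCRep does not depend on the TAD calls) over all scored
#' pairs, and reports per-target group medians along with whether the
#' replicate > non-replicate median ordering holds at each target.
#'
#' @param result a `tad_pipeline` result.
#' @param targets_bases target median TAD sizes (default 500 kb, 700 kb,
#'   880 kb, 1 Mb).
#' @param n_null null draws per TADsim call (defaults to the pipeline's).
#' @return a list of class `robustness_sweep`: `summary` (per target and
#'   measure: group medians and `ordering_holds`), `scores` (long per-pair
#'   table).
#' @export
robustness_sweep <- function(result,
                             targets_bases = c(500000, 700000, 880000,
                                               1000000),
                             n_null = NULL) {
  stopifnot(inherits(result, "tad_pipeline"))
  if (is.null(n_null)) n_null <- result$config$n_null
  cfg <- result$config
  idx <- result$pair_index
  rows <- list(); sums <- list()
  for (tg in targets_bases) {
    tsel <- lapply(result$sweeps, select_gamma_by_median,
                   target_bases = tg)
    for (r in seq_len(nrow(idx))) {
      t1 <- tsel[[idx$mid1[r]]]; t2 <- tsel[[idx$mid2[r]]]
      ji <- suppressWarnings(
        jaccard_index(t1, t2, tolerance_bins = cfg$jaccard_tolerance))
      ts <- suppressWarnings(
        tadsim(t1, t2, n_bins = cfg$n_bins, alpha = cfg$alpha,
               n_null = n_null, min_window_bins = cfg$min_window_bins,
               max_window_bins = cfg$max_window_bins,
               seed = substream_seed(cfg$seed,
                                     paste0(idx$seed_label[r], ":", tg))))
      rows[[length(rows) + 1L]] <-
        data.frame(target_bases = tg, id1 = idx$id1[r], id2 = idx$id2[r],
                   is_replicate = idx$is_replicate[r], ji = ji,
                   tadsim = ts$coverage)
    }
  }
  scores <- do.call(rbind, rows)
  for (tg in targets_bases) {
    sub <- scores[scores$target_bases == tg, , drop = FALSE]
    for (ms in c("ji", "tadsim")) {
      ma <- stats::median(sub[[ms]][sub$is_replicate])
      mb <- stats::median(sub[[ms]][!sub$is_replicate])
      sums[[length(sums) + 1L]] <-
        data.frame(target_bases = tg, measure = ms, median_replicate = ma,
                   median_nonreplicate = mb, ordering_holds = ma > mb)
    }
  }
  structure(list(summary = do.call(rbind, sums), scores = scores),
            class = "robustness_sweep")
}

#' @export
print.robustness_sweep <- function(x, ...) {
  print(x$summary)
  invisible(x)
}
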