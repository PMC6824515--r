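#' Build the pair-comparison table
#'
#' Assembles one record per unordered sample pair. Non-replicate pairs are
#' all pairs of (merged) samples; replicate pairs are all within-sample
#' replicate pairs. Group labels (replicate, same cell type, tissue/donor,
#' protocol, enzyme, lab, trio relation) are derived from the sample
#' metadata.
#'
#' @param samples data.frame of sample metadata: `sample_id`, `cell_type`,
#'   and optionally `protocol`, `enzyme`, `lab`, `donor_id`, `is_tissue`,
#'   `family_id`, `trio_relation`.
#' @param replicate_scores data.frame with columns `sample_id`, `rep1`,
#'   `rep2`, `hicrep`, `ji`, `tadsim` — one row per within-sample replicate
#'   pair.
#' @param merged_scores data.frame with columns `id1`, `id2`, `hicrep`,
#'   `ji`, `tadsim` — one row per unordered pair of samples; every pair of
#'   rows of `samples` must be present.
#' @return data.frame with one row per pair: ids, `is_replicate`, the group
#'   labels and the three scores.
#' @export
build_pair_table <- function(samples, replicate_scores, merged_scores) {
  stopifnot(is.data.frame(samples))
  opt_defaults <- list(protocol = "in_situ", enzyme = "MboI", lab = "lab1",
                       is_tissue = FALSE, trio_relation = "none",
                       family_id = NA_character_)
  for (nm in names(opt_defaults))
    if (is.null(samples[[nm]])) samples[[nm]] <- opt_defaults[[nm]]
  if (is.null(samples$donor_id))
    samples$donor_id <- paste0("donor_", seq_len(nrow(samples)))
  key <- function(x, y) paste(pmin(x, y), pmax(x, y), sep = "||")
  rows <- list()
  meta_of <- function(id) samples[samples$sample_id == id, , drop = FALSE]
  # non-replicate pairs over merged samples
  ids <- samples$sample_id
  if (length(ids) >= 2L) {
    want <- utils::combn(ids, 2L)
    have <- key(merged_scores$id1, merged_scores$id2)
    missing <- which(!(key(want[1L, ], want[2L, ]) %in% have))
    if (length(missing) > 0L)
      stop("missing scores for pair(s): ",
           paste(want[1L, missing], want[2L, missing],
                 sep = " vs ", collapse = "; "))
  }
  for (r in seq_len(nrow(merged_scores))) {
    sc <- merged_scores[r, , drop = FALSE]
    a <- meta_of(sc$id1); b <- meta_of(sc$id2)
    trio <- "none"
    if (!is.na(a$family_id) && !is.na(b$family_id) &&
        a$family_id == b$family_id) {
      rel <- sort(c(a$trio_relation, b$trio_relation))
      trio <- if (identical(rel, c("parent1", "parent2"))) "parent-parent"
              else if ("child" %in% rel) "parent-child" else "none"
    }
    rows[[length(rows) + 1L]] <- data.frame(
      id1 = sc$id1, id2 = sc$id2, is_replicate = FALSE,
      same_cell_type = a$cell_type == b$cell_type,
      both_tissue = a$is_tissue && b$is_tissue,
      same_tissue_diff_donor = a$is_tissue && b$is_tissue &&
        a$cell_type == b$cell_type && a$donor_id != b$donor_id,
      same_protocol = a$protocol == b$protocol,
      same_enzyme = a$enzyme == b$enzyme,
      same_lab = a$lab == b$lab,
      trio_relation = trio,
      hicrep = sc$hicrep, ji = sc$ji, tadsim = sc$tadsim)
  }
  # replicate pairs within samples
  for (r in seq_len(nrow(replicate_scores))) {
    sc <- replicate_scores[r, , drop = FALSE]
    rows[[length(rows) + 1L]] <- data.frame(
      id1 = paste0(sc$sample_id, ".rep", sc$rep1),
      id2 = paste0(sc$sample_id, ".rep", sc$rep2),
      is_replicate = TRUE, same_cell_type = TRUE, both_tissue = FALSE,
      same_tissue_diff_donor = FALSE, same_protocol = TRUE,
      same_enzyme = TRUE, same_lab = TRUE, trio_relation = "none",
      hicrep = sc$hicrep, ji = sc$ji, tadsim = sc$tadsim)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

default_contrasts <- function() {
  list(
    replicate_vs_nonreplicate = list(
      a = function(d) d$is_replicate,
      b = function(d) !d$is_replicate),
    same_tissue_diff_donor_vs_diff_tissue = list(
      a = function(d) !d$is_replicate & d$same_tissue_diff_donor,
      b = function(d) !d$is_replicate & d$both_tissue & !d$same_cell_type),
    trio_related_vs_unrelated_same_cell_type = list(
      a = function(d) d$trio_relation == "parent-child",
      b = function(d) !d$is_replicate & d$same_cell_type &
        d$trio_relation != "parent-child"),
    mixed_protocol_vs_same_protocol_same_type = list(
      a = function(d) !d$is_replicate & d$same_cell_type & !d$same_protocol,
      b = function(d) !d$is_replicate & d$same_cell_type & d$same_protocol),
    diff_enzyme_vs_same_enzyme_same_type = list(
      a = function(d) !d$is_replicate & d$same_cell_type & !d$same_enzyme,
      b = function(d) !d$is_replicate & d$same_cell_type & d$same_enzyme),
    diff_lab_vs_same_lab_same_type = list(
      a = function(d) !d$is_replicate & d$same_cell_type & !d$same_lab,
      b = function(d) !d$is_replicate & d$same_cell_type & d$same_lab))
}

#' Run Mann-Whitney contrasts over the pair table
#'
#' For each similarity measure and each contrast of the design, compares the
#' two pair groups with [mann_whitney_u()] and reports group sizes, medians,
#' U, p and direction. A contrast whose groups are empty on this cohort
#' yields an error record (the suite continues). Two-sided tests are the
#' default, with the direction reported; no multiple-testing correction is
#' applied by default (a Benjamini-Hochberg column can be requested).
#'
#' @param pairs pair table from [build_pair_table()].
#' @param contrasts named list of contrasts, each `list(a =, b =)` of
#'   predicate functions over the pair table; default [default_contrasts()]
#'   restricted to those with non-empty groups is NOT applied — empty groups
#'   are reported as error records.
#' @param measures which score columns to test.
#' @param alternative passed to [mann_whitney_u()].
#' @param adjust if `TRUE`, append Benjamini-Hochberg adjusted p-values.
#' @return data.frame: `measure`, `contrast`, `n_a`, `n_b`, `median_a`,
#'   `median_b`, `U`, `p_value`, `direction`, `error`.
#' @export
run_comparison_suite <- function(pairs, contrasts = default_contrasts(),
                                 measures = c("hicrep", "ji", "tadsim"),
                                 alternative = "two_sided",
                                 adjust = FALSE) {
  rows <- list()
  for (ms in measures) {
    for (cn in names(contrasts)) {
      ct <- contrasts[[cn]]
      ia <- which(ct$a(pairs)); ib <- which(ct$b(pairs))
      if (length(ia) == 0L || length(ib) == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          measure = ms, contrast = cn, n_a = length(ia), n_b = length(ib),
          median_a = NA_real_, median_b = NA_real_, U = NA_real_,
          p_value = NA_real_, direction = NA_character_,
          error = sprintf("empty group: %s",
                          paste(c("a", "b")[c(length(ia) == 0L,
                                              length(ib) == 0L)],
                                collapse = ",")))
        next
      }
      xs <- pairs[[ms]][ia]; ys <- pairs[[ms]][ib]
      tst <- mann_whitney_u(xs, ys, alternative = alternative)
      rows[[length(rows) + 1L]] <- data.frame(
        measure = ms, contrast = cn, n_a = tst$n_a, n_b = tst$n_b,
        median_a = stats::median(xs), median_b = stats::median(ys),
        U = tst$U, p_value = tst$p_value, direction = tst$direction,
        error = NA_character_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (adjust) out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out
}
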