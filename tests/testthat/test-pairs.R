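mk_merged_scores <- function(ids, value = 0.5) {
  prs <- utils::combn(ids, 2L)
  data.frame(id1 = prs[1, ], id2 = prs[2, ], hicrep = value, ji = value,
             tadsim = value)
}

test_that("pair table combinatorics match the cohort design", {
  # 3 samples x 2 replicates: 3 replicate pairs and 3 non-replicate pairs
  samples <- data.frame(sample_id = c("A", "B", "C"),
                        cell_type = c("t1", "t2", "t3"))
  reps <- data.frame(sample_id = c("A", "B", "C"), rep1 = 1L, rep2 = 2L,
                     hicrep = 0.9, ji = 0.9, tadsim = 0.9)
  pt <- build_pair_table(samples, reps, mk_merged_scores(samples$sample_id))
  expect_equal(sum(pt$is_replicate), 3L)
  expect_equal(sum(!pt$is_replicate), 3L)
  # 69 merged samples give 2346 non-replicate pairs
  ids69 <- sprintf("S%02d", 1:69)
  samples69 <- data.frame(sample_id = ids69, cell_type = ids69)
  pt69 <- build_pair_table(samples69,
                           reps[0, , drop = FALSE],
                           mk_merged_scores(ids69))
  expect_equal(nrow(pt69), 2346L)
  # a sample with a single replicate contributes no replicate pairs
  pt1 <- build_pair_table(samples, reps[0, , drop = FALSE],
                          mk_merged_scores(samples$sample_id))
  expect_equal(sum(pt1$is_replicate), 0L)
})

test_that("missing pair scores are reported with the offending pair", {
  samples <- data.frame(sample_id = c("A", "B", "C"),
                        cell_type = c("t1", "t2", "t3"))
  short <- mk_merged_scores(samples$sample_id)[-2, ]
  expect_error(build_pair_table(samples, data.frame(), short), "A vs C")
})

test_that("group labels derive from sample metadata", {
  samples <- data.frame(
    sample_id = c("A", "B", "C", "D"),
    cell_type = c("liver", "liver", "brain", "liver"),
    is_tissue = c(TRUE, TRUE, TRUE, FALSE),
    donor_id = c("d1", "d2", "d3", "d4"),
    protocol = c("in_situ", "dilution", "in_situ", "in_situ"),
    enzyme = c("MboI", "MboI", "HindIII", "MboI"),
    lab = c("lab1", "lab2", "lab1", "lab1"))
  pt <- build_pair_table(samples, data.frame(),
                         mk_merged_scores(samples$sample_id))
  ab <- pt[pt$id1 == "A" & pt$id2 == "B", ]
  expect_true(ab$same_cell_type)
  expect_true(ab$same_tissue_diff_donor)
  expect_false(ab$same_protocol)
  ac <- pt[pt$id1 == "A" & pt$id2 == "C", ]
  expect_false(ac$same_cell_type)
  expect_true(ac$both_tissue)
  expect_false(ac$same_enzyme)
  ad <- pt[pt$id1 == "A" & pt$id2 == "D", ]
  expect_false(ad$both_tissue)
  expect_false(ad$same_tissue_diff_donor)
})

test_that("trio relations classify parent-parent and parent-child pairs", {
  samples <- data.frame(
    sample_id = c("P1", "P2", "K", "X"),
    cell_type = "blood",
    family_id = c("f1", "f1", "f1", NA),
    trio_relation = c("parent1", "parent2", "child", "none"))
  pt <- build_pair_table(samples, data.frame(),
                         mk_merged_scores(samples$sample_id))
  expect_equal(pt$trio_relation[pt$id1 == "P1" & pt$id2 == "P2"],
               "parent-parent")
  expect_equal(pt$trio_relation[pt$id1 == "P1" & pt$id2 == "K"],
               "parent-child")
  expect_equal(pt$trio_relation[pt$id1 == "P1" & pt$id2 == "X"], "none")
})

test_that("the comparison suite separates duplicated replicates from noise", {
  # replicate scores are exact duplicates (similarity 1), non-replicates
  # perturbed: medians 1 vs lower, significant for every measure
  set.seed(61)
  ids <- sprintf("S%d", 1:10)
  samples <- data.frame(sample_id = ids, cell_type = ids)
  reps <- data.frame(sample_id = ids, rep1 = 1L, rep2 = 2L,
                     hicrep = 1, ji = 1, tadsim = 1)
  ms <- mk_merged_scores(ids)
  for (col in c("hicrep", "ji", "tadsim")) ms[[col]] <- runif(nrow(ms), 0.3, 0.8)
  pt <- build_pair_table(samples, reps, ms)
  out <- run_comparison_suite(pt)
  sub <- out[out$contrast == "replicate_vs_nonreplicate", ]
  expect_equal(nrow(sub), 3L)
  expect_true(all(sub$median_a == 1))
  expect_true(all(sub$p_value < 0.01))
  expect_true(all(sub$direction == "a"))
})

test_that("contrasts with empty groups produce error records, not failures", {
  ids <- c("A", "B")
  samples <- data.frame(sample_id = ids, cell_type = c("t1", "t2"))
  pt <- build_pair_table(samples, data.frame(), mk_merged_scores(ids))
  out <- run_comparison_suite(pt)
  # every measure x contrast combination is present exactly once
  expect_equal(nrow(out), 3 * 6)
  rep_rows <- out[out$contrast == "replicate_vs_nonreplicate", ]
  expect_true(all(grepl("empty group", rep_rows$error)))
  expect_true(all(is.na(rep_rows$p_value)))
})

test_that("suite output is deterministic given the scores", {
  ids <- sprintf("S%d", 1:6)
  samples <- data.frame(sample_id = ids, cell_type = ids)
  ms <- mk_merged_scores(ids)
  set.seed(62)
  for (col in c("hicrep", "ji", "tadsim")) ms[[col]] <- runif(nrow(ms))
  reps <- data.frame(sample_id = ids[1:3], rep1 = 1L, rep2 = 2L,
                     hicrep = 0.95, ji = 0.95, tadsim = 0.95)
  pt <- build_pair_table(samples, reps, ms)
  expect_identical(run_comparison_suite(pt), run_comparison_suite(pt))
})
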