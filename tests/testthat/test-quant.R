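make_meas <- function(confidence, h_to_l) {
  n <- length(confidence)
  tibble::tibble(
    sample_id = paste0("s", seq_len(n)), subject_id = paste0("s", seq_len(n)),
    group = "case", replicate = 1L, accession = "P1", peptide = "AACDEK",
    cys_positions = rep(list(3L), n), confidence = confidence, h_to_l = h_to_l,
    key = peptide_key(rep("P1", n), rep("AACDEK", n), rep(list(3L), n))
  )
}

test_that("filtering applies inclusive confidence and ratio floors", {
  meas <- make_meas(c(96, 94, 96, 95), c(0.5, 0.5, 0.005, 0.01))
  f <- filter_peptides(meas)
  expect_equal(which(meas$h_to_l %in% f$retained$h_to_l &
                       meas$confidence %in% f$retained$confidence), c(1, 4))
  expect_equal(nrow(f$retained), 2L)
  expect_equal(f$rejections$n_rejected, c(1L, 1L))

  allbad <- filter_peptides(make_meas(rep(80, 4), rep(0.5, 4)))
  expect_equal(nrow(allbad$retained), 0L)
  expect_equal(allbad$rejections$n_rejected[allbad$rejections$criterion == "confidence"], 4L)

  empty <- filter_peptides(make_meas(numeric(0), numeric(0)))
  expect_equal(nrow(empty$retained), 0L)
  expect_equal(sum(empty$rejections$n_rejected), 0L)

  strict <- filter_peptides(make_meas(c(95, 96), c(1, 1)),
                            quant_config(strict_confidence = TRUE))
  expect_equal(nrow(strict$retained), 1L)
})

test_that("technical replicates collapse to per-subject means", {
  meas <- make_meas(rep(99, 4), c(1, 3, 1.7, 2.5))
  meas$subject_id <- c("a", "a", "b", "c")
  meas$replicate <- c(1L, 2L, 1L, 1L)
  coll <- collapse_technical_replicates(meas)
  expect_equal(nrow(coll), 3L)
  expect_equal(coll$h_to_l[coll$subject_id == "a"], 2)
  expect_equal(coll$h_to_l[coll$subject_id == "b"], 1.7)
  expect_equal(coll$n_replicates[coll$subject_id == "a"], 2L)
})

test_that("group summaries honour the mean kind and the subject minimum", {
  s <- summarize_group(c(1, 2, 3), "case")
  expect_equal(s$group_mean, 2)
  expect_true(s$retained)

  g <- summarize_group(c(2, 8, 4), "case", quant_config(mean_kind = "geometric"))
  expect_equal(g$group_mean, 4)

  const <- summarize_group(rep(3, 5), "case")
  constg <- summarize_group(rep(3, 5), "case", quant_config(mean_kind = "geometric"))
  expect_equal(const$group_mean, constg$group_mean)

  few <- summarize_group(c(1, 2), "control")
  expect_false(few$retained)
  expect_equal(few$reason, "insufficient observations")
})

test_that("ratio-of-ratios divides group means and rejects bad controls", {
  expect_equal(ratio_of_ratios(3, 1.5), 2)
  expect_equal(ratio_of_ratios(2, 2), 1)
  expect_error(ratio_of_ratios(1, 0), "undefined ratio")
  expect_error(ratio_of_ratios(1, NA_real_), "undefined ratio")
})

test_that("differential calls use strict fold and alpha semantics", {
  cfg <- quant_config()
  exact_cut <- call_differential(1.5, 0.01, cfg)
  expect_false(exact_cut$passes_fold)      # "exceeded" read strictly
  expect_false(exact_cut$significant)

  weak_p <- call_differential(2.0, 0.2, cfg)
  expect_true(weak_p$passes_fold)
  expect_false(weak_p$significant)

  hit <- call_differential(2.0, 0.01, cfg)
  expect_true(hit$significant)

  down <- call_differential(0.5, 0.01, quant_config(two_sided_fold = TRUE))
  expect_true(down$passes_fold)

  bh <- call_differential(2.0, 0.01, quant_config(mtc = "BH"), q_value = 0.2)
  expect_false(bh$significant)             # alpha applies to q under BH
})

test_that("protein rollup applies the any-peptide rule and conserves counts", {
  calls <- tibble::tibble(
    accession = c("A", "A", "B", "C", "C", "C"),
    ratio_of_ratios = c(2, 1.1, 1.2, 3, 2.5, 1.9),
    p_value = c(0.01, 0.5, 0.6, 0.001, 0.01, 0.04),
    significant = c(TRUE, FALSE, FALSE, TRUE, TRUE, TRUE)
  )
  prot <- rollup_to_proteins(calls)
  expect_equal(prot$accession, c("A", "B", "C"))
  expect_equal(prot$significant, c(TRUE, FALSE, TRUE))
  expect_equal(prot$n_peptides_significant, c(1L, 0L, 3L))
  expect_equal(prot$best_ratio_of_ratios, c(2, 1.2, 3))
  expect_equal(prot$best_p_value, c(0.01, 0.6, 0.001))
  # conservation: peptide totals partition the call set
  expect_equal(sum(prot$n_peptides_total), nrow(calls))
  expect_warning(rollup_to_proteins(calls, toy_proteome()), "absent")
})

test_that("occupancy and ratio transforms are mutual inverses", {
  expect_equal(occupancy_from_ratio(1), 0.5)
  expect_equal(occupancy_from_ratio(0), 0)
  expect_equal(ratio_from_occupancy(0.8), 4)
  expect_error(ratio_from_occupancy(1), "unbounded")
  theta <- seq(0, 0.99, by = 0.0033)
  expect_equal(occupancy_from_ratio(ratio_from_occupancy(theta)), theta,
               tolerance = 1e-12)
  r <- c(0, 10^seq(-3, 2, by = 0.25))
  expect_equal(ratio_from_occupancy(occupancy_from_ratio(r)), r,
               tolerance = 1e-12)
})

test_that("pipeline is scale-equivariant and null on identical groups", {
  # scale an already-filtered table so the same rows survive in both runs:
  # the invariance claim is about the test statistics, not the H:L floor
  tbl <- filter_peptides(fixture_table_50())$retained
  cfg <- quant_config(min_subjects_per_group = 2L)
  res <- quantify_peptides(tbl, cfg)

  scaled <- tbl; scaled$h_to_l <- scaled$h_to_l * 37.5
  res2 <- quantify_peptides(scaled, cfg)
  expect_equal(res2$calls$ratio_of_ratios, res$calls$ratio_of_ratios,
               tolerance = 1e-12)
  expect_equal(res2$calls$p_value, res$calls$p_value, tolerance = 1e-12)

  # make the control arm an exact mirror of the case arm
  mirror <- tbl[tbl$group == "case", ]
  flip <- mirror
  flip$group <- "control"
  flip$subject_id <- paste0("m_", flip$subject_id)
  flip$sample_id <- paste0("m_", flip$sample_id)
  null_res <- quantify_peptides(dplyr::bind_rows(mirror, flip), cfg)
  expect_true(all(null_res$calls$ratio_of_ratios == 1))
  expect_false(any(null_res$calls$significant))
})

test_that("increasing case values never decreases the ratio-of-ratios", {
  tbl <- fixture_table_50()
  cfg <- quant_config(min_subjects_per_group = 2L)
  base <- quantify_peptides(tbl, cfg)
  boosted <- tbl
  boosted$h_to_l[boosted$group == "case"] <-
    boosted$h_to_l[boosted$group == "case"] * 1.8
  up <- quantify_peptides(boosted, cfg)
  shared <- intersect(base$calls$key, up$calls$key)
  b <- base$calls[match(shared, base$calls$key), ]
  u <- up$calls[match(shared, up$calls$key), ]
  expect_true(all(u$ratio_of_ratios >= b$ratio_of_ratios - 1e-12))
})

test_that("peptides short of the subject minimum are excluded with a reason", {
  tbl <- fixture_table_50()
  res <- quantify_peptides(tbl, quant_config(min_subjects_per_group = 3L))
  # only 2 control subjects exist in the fixture -> everything is excluded
  expect_equal(nrow(res$calls), 0L)
  expect_true(all(res$excluded$reason == "insufficient observations"))
})
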