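#' Run the two-arm differential study design
#'
#' Quantifies each arm (e.g. disease vs. control, and inhibitor-treated
#' vs. vehicle) independently with the same configuration, then overlaps
#' the two arms' significant protein sets. If `out_dir` is given, writes
#' per-arm peptide and protein call tables and a JSON run report; outputs
#' are byte-deterministic for identical inputs and configuration.
#'
#' @param arm1,arm2 Measurement tibbles, each containing both a case and a
#'   control group (see [read_peptide_table()]).
#' @param config A [quant_config()] applied to both arms.
#' @param proteome Optional protein tibble for site mapping.
#' @param arm_names Length-2 character vector of arm labels.
#' @param out_dir Optional output directory.
#' @return List of class `glutaquant_report`: `arms` (named list of
#'   `glutaquant_result`), `venn` (overlap of significant protein sets),
#'   `report` (plain-list run report: config echo, per-arm stage counts,
#'   Venn counts).
#' @export
run_two_arm <- function(arm1, arm2, config = quant_config(),
                        proteome = NULL,
                        arm_names = c("arm1", "arm2"),
                        out_dir = NULL) {
  stopifnot(length(arm_names) == 2L)
  arms <- stats::setNames(list(arm1, arm2), arm_names)
  results <- lapply(arm_names, function(nm) {
    res <- quantify_peptides(arms[[nm]], config, proteome)
    if (res$counts$peptides_tested == 0L) {
      stop("arm '", nm, "' has no testable peptides after filtering ",
           "(rows read ", res$counts$rows_read,
           ", retained ", res$counts$rows_retained,
           ", excluded ", res$counts$peptides_excluded, ")")
    }
    res
  })
  names(results) <- arm_names

  sig <- lapply(results, function(r) r$proteins$accession[r$proteins$significant])
  venn <- if (length(sig[[1]]) == 0L) {
    list(only_a = 0L, only_b = length(unique(sig[[2]])),
         shared = 0L, shared_ids = character(0),
         shared_fraction_a = NA_real_)
  } else {
    overlap_sets(sig[[1]], sig[[2]])
  }

  report <- list(
    config = unclass(config),
    arms = lapply(results, function(r) r$counts),
    venn = venn[c("only_a", "only_b", "shared", "shared_fraction_a")]
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in arm_names) {
      r <- results[[nm]]
      write_results_table(r$calls, file.path(out_dir, paste0(nm, "_peptides.tsv")))
      write_results_table(r$proteins, file.path(out_dir, paste0(nm, "_proteins.tsv")))
      if (!is.null(r$sites) && nrow(r$sites)) {
        write_results_table(r$sites, file.path(out_dir, paste0(nm, "_sites.tsv")))
      }
    }
    jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  structure(list(arms = results, venn = venn, report = report),
            class = "glutaquant_report")
}

#' @export
print.glutaquant_report <- function(x, ...) {
  cat("Two-arm differential glutathionylation report\n")
  for (nm in names(x$arms)) {
    c <- x$arms[[nm]]$counts
    cat(sprintf("  %s: %d peptides tested, %d significant; %d proteins significant\n",
                nm, c$peptides_tested, c$peptides_significant,
                c$proteins_significant))
  }
  v <- x$venn
  cat(sprintf("  venn: only_a %d | shared %d | only_b %d (shared fraction of A: %s)\n",
              v$only_a, v$shared, v$only_b,
              ifelse(is.na(v$shared_fraction_a), "NA",
                     sprintf("%.1f%%", 100 * v$shared_fraction_a))))
  invisible(x)
}

#' Simulate, quantify, and score recovery against ground truth
#'
#' Runs the full loop: simulates a synthetic experiment, quantifies it,
#' joins the peptide calls to the planted ground truth, and scores
#' recovery at the cysteine-site level. A planted site counts as a true
#' positive when its host peptide is called significant; planted sites
#' whose peptide never reached testing (filtered or insufficient
#' observations) count as missed. Sensitivity is TP / (TP + FN) over
#' planted sites; the empirical false-discovery proportion is
#' FP / (FP + TP) over called sites (0 when nothing is called).
#'
#' @param sim_config A [sim_config()].
#' @param config A [quant_config()].
#' @return List of class `glutaquant_benchmark`: `sensitivity`, `fdp`
#'   (numbers; sensitivity is NA when nothing was planted), `n_planted`,
#'   `n_called`, `n_true_positive`, `peptide_truth` (peptide-level join of
#'   truth and calls), `site_truth` (site-level join), `result` (the
#'   `glutaquant_result`), `sim` (the simulation), `breakdown`
#'   (sensitivity by expected ratio-of-ratios).
#' @export
run_recovery_benchmark <- function(sim_config, config = quant_config()) {
  sim <- simulate_experiment(sim_config)
  if (sim_config$fraction_differential > 0 &&
      !any(sim$truth$peptides$is_differential)) {
    stop("fraction_differential > 0 but no effects were planted")
  }
  res <- quantify_peptides(sim$table, config)

  call_cols <- sim$truth$peptides
  idx <- match(call_cols$key, res$calls$key)
  call_cols$tested <- !is.na(idx)
  call_cols$ratio_of_ratios <- res$calls$ratio_of_ratios[idx]
  call_cols$p_value <- res$calls$p_value[idx]
  call_cols$significant <- !is.na(idx) & res$calls$significant[idx]

  site_truth <- sim$truth$sites
  sidx <- match(site_truth$key, res$calls$key)
  site_truth$tested <- !is.na(sidx)
  site_truth$ratio_of_ratios <- res$calls$ratio_of_ratios[sidx]
  site_truth$p_value <- res$calls$p_value[sidx]
  site_truth$significant <- !is.na(sidx) & res$calls$significant[sidx]

  tp <- sum(site_truth$is_differential & site_truth$significant)
  fn <- sum(site_truth$is_differential & !site_truth$significant)
  fp <- sum(!site_truth$is_differential & site_truth$significant)
  sensitivity <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  fdp <- if (tp + fp > 0) fp / (tp + fp) else 0

  breakdown <- site_truth |>
    dplyr::filter(.data$is_differential) |>
    dplyr::group_by(.data$expected_ratio_of_ratios) |>
    dplyr::summarise(n_planted = dplyr::n(),
                     n_detected = sum(.data$significant),
                     sensitivity = mean(.data$significant),
                     .groups = "drop")

  structure(
    list(sensitivity = sensitivity, fdp = fdp,
         n_planted = tp + fn, n_called = tp + fp, n_true_positive = tp,
         peptide_truth = call_cols, site_truth = site_truth,
         result = res, sim = sim, breakdown = breakdown),
    class = "glutaquant_benchmark"
  )
}

#' @export
print.glutaquant_benchmark <- function(x, ...) {
  cat("Recovery benchmark\n")
  cat(sprintf("  planted sites %d | called %d | true positives %d\n",
              x$n_planted, x$n_called, x$n_true_positive))
  cat(sprintf("  sensitivity %s | empirical FDP %.4f\n",
              ifelse(is.na(x$sensitivity), "NA",
                     sprintf("%.4f", x$sensitivity)), x$fdp))
  invisible(x)
}
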