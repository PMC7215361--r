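#' Quantification configuration
#'
#' Thresholds and options for the differential glutathionylation pipeline.
#' Defaults follow standard practice for cleavable-ICAT redox datasets:
#' peptides are kept at >= 95% identification confidence and H:L >= 0.01,
#' a case/control ratio-of-ratios must strictly exceed 1.5-fold, and
#' Mann-Whitney significance uses alpha = 0.05 with no multiplicity
#' correction unless requested.
#'
#' @param min_confidence Minimum identification confidence, percent
#'   (inclusive unless `strict_confidence`).
#' @param min_h_to_l Minimum heavy:light ratio (inclusive).
#' @param fold_cutoff Ratio-of-ratios cutoff; a call must strictly exceed it.
#' @param alpha Significance level; p (or q) must be strictly below it.
#' @param min_subjects_per_group Minimum subjects with data in each group
#'   for a peptide to be testable.
#' @param mean_kind `"arithmetic"` (default) or `"geometric"` group mean of
#'   per-subject H:L values.
#' @param mtc Multiple-testing correction: `"none"` (default) or `"BH"`
#'   (Benjamini-Hochberg; alpha is then applied to q-values).
#' @param exact_test_max_n Use the exact Mann-Whitney null distribution
#'   when total sample size is at most this and the data are tie-free.
#' @param strict_confidence Use strict `>` instead of `>=` for the
#'   confidence floor.
#' @param two_sided_fold Also call decreases (ratio-of-ratios below
#'   `1/fold_cutoff`); by default only increased glutathionylation is
#'   called.
#' @return A list of class `quant_config`.
#' @export
quant_config <- function(min_confidence = 95,
                         min_h_to_l = 0.01,
                         fold_cutoff = 1.5,
                         alpha = 0.05,
                         min_subjects_per_group = 3L,
                         mean_kind = c("arithmetic", "geometric"),
                         mtc = c("none", "BH"),
                         exact_test_max_n = 12L,
                         strict_confidence = FALSE,
                         two_sided_fold = FALSE) {
  mean_kind <- match.arg(mean_kind)
  mtc <- match.arg(mtc)
  stopifnot(
    min_confidence >= 0, min_confidence <= 100,
    min_h_to_l > 0,
    fold_cutoff > 1,
    alpha > 0, alpha < 1,
    min_subjects_per_group >= 1,
    exact_test_max_n >= 2
  )
  structure(
    list(min_confidence = min_confidence, min_h_to_l = min_h_to_l,
         fold_cutoff = fold_cutoff, alpha = alpha,
         min_subjects_per_group = as.integer(min_subjects_per_group),
         mean_kind = mean_kind, mtc = mtc,
         exact_test_max_n = as.integer(exact_test_max_n),
         strict_confidence = strict_confidence,
         two_sided_fold = two_sided_fold),
    class = "quant_config"
  )
}

#' Filter peptide measurements on confidence and minimum H:L
#'
#' Keeps rows passing both the identification-confidence floor and the
#' minimum heavy:light ratio (both inclusive by default). The rejection
#' log counts failures per criterion; a row failing both is counted under
#' both criteria.
#'
#' @param measurements Measurement tibble.
#' @param config A [quant_config()].
#' @return List with `retained` (tibble) and `rejections` (tibble with
#'   `criterion`, `n_rejected`).
#' @export
filter_peptides <- function(measurements, config = quant_config()) {
  if (nrow(measurements) == 0L) {
    return(list(
      retained = measurements,
      rejections = tibble::tibble(criterion = c("confidence", "h_to_l"),
                                  n_rejected = c(0L, 0L))
    ))
  }
  ok_conf <- if (config$strict_confidence) {
    measurements$confidence > config$min_confidence
  } else {
    measurements$confidence >= config$min_confidence
  }
  ok_ratio <- measurements$h_to_l >= config$min_h_to_l
  list(
    retained = measurements[ok_conf & ok_ratio, , drop = FALSE],
    rejections = tibble::tibble(
      criterion = c("confidence", "h_to_l"),
      n_rejected = c(sum(!ok_conf), sum(!ok_ratio))
    )
  )
}

#' Collapse technical replicates to one value per subject
#'
#' Repeated injections of the same subject's sample are averaged
#' (arithmetic mean of H:L) before any group statistic, so that subjects -
#' not injections - are the units of the downstream test. Subjects with a
#' single observation pass through unchanged.
#'
#' @param measurements Measurement tibble (post-filtering).
#' @return Tibble with one row per (key, subject): `key`, `accession`,
#'   `peptide`, `cys_positions`, `subject_id`, `group`, `n_replicates`,
#'   `h_to_l`.
#' @export
collapse_technical_replicates <- function(measurements) {
  collapsed <- measurements |>
    dplyr::group_by(.data$key, .data$accession, .data$peptide,
                    .data$subject_id, .data$group) |>
    dplyr::summarise(n_replicates = dplyr::n(),
                     h_to_l = mean(.data$h_to_l), .groups = "drop")
  cys <- measurements[!duplicated(measurements$key), c("key", "cys_positions")]
  collapsed$cys_positions <- cys$cys_positions[match(collapsed$key, cys$key)]
  collapsed[, c("key", "accession", "peptide", "cys_positions", "subject_id",
                "group", "n_replicates", "h_to_l")]
}

#' Summarise one group's per-subject values
#'
#' @param values Numeric vector of per-subject H:L values for one peptide
#'   in one group.
#' @param group Group label (`"case"` or `"control"`).
#' @param config A [quant_config()].
#' @return List with `group`, `subject_values`, `n_subjects`, `group_mean`,
#'   `retained` (FALSE with `reason = "insufficient observations"` when
#'   fewer than `min_subjects_per_group` subjects contribute).
#' @export
summarize_group <- function(values, group, config = quant_config()) {
  n <- length(values)
  if (n < config$min_subjects_per_group) {
    return(list(group = group, subject_values = values, n_subjects = n,
                group_mean = NA_real_, retained = FALSE,
                reason = "insufficient observations"))
  }
  m <- group_mean(values, config$mean_kind)
  list(group = group, subject_values = values, n_subjects = n,
       group_mean = m, retained = TRUE, reason = NA_character_)
}

group_mean <- function(values, kind) {
  switch(kind,
         arithmetic = mean(values),
         geometric = exp(mean(log(values))))
}

#' Ratio of group-mean H:L ratios
#'
#' The differential statistic: mean case H:L divided by mean control H:L.
#' Being a ratio of ratios it is unitless and invariant to any common
#' rescaling of the raw intensities.
#'
#' @param case_mean,control_mean Group mean H:L values (vectorised).
#' @return `case_mean / control_mean`.
#' @export
ratio_of_ratios <- function(case_mean, control_mean) {
  if (any(!is.finite(control_mean)) || any(control_mean <= 0)) {
    stop("undefined ratio: control group mean is zero, negative or missing")
  }
  case_mean / control_mean
}

#' Two-sided Mann-Whitney p-value
#'
#' Uses the exact U null distribution when the pooled sample size is at
#' most `exact_max_n` and the data are tie-free (two-sided p as twice the
#' smaller tail probability, capped at 1 - identical to full enumeration
#' over group labelings); otherwise the midrank normal approximation with
#' tie and continuity corrections. A pooled sample with zero rank variance
#' (e.g. all values identical) carries no evidence and returns 1.
#'
#' @param values_a,values_b Numeric vectors, both nonempty.
#' @param exact_max_n Switch point between exact and approximate branches.
#' @return A p-value in (0, 1].
#' @export
mann_whitney_p <- function(values_a, values_b, exact_max_n = 12L) {
  if (length(values_a) == 0L || length(values_b) == 0L) {
    stop("both groups must be nonempty")
  }
  pooled <- c(values_a, values_b)
  if (length(unique(pooled)) == 1L) return(1)
  ties <- anyDuplicated(pooled) > 0L
  if (!ties && length(pooled) <= exact_max_n) {
    p <- stats::wilcox.test(values_a, values_b, exact = TRUE)$p.value
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(values_a, values_b, exact = FALSE, correct = TRUE)$p.value
    )
  }
  if (!is.finite(p)) p <- 1   # degenerate tie-corrected variance
  min(max(p, .Machine$double.xmin), 1)
}

#' Assemble a differential call from its components
#'
#' Threshold semantics: the fold cutoff is strict (`ratio_of_ratios >
#' fold_cutoff`, "exceeded"), and significance is strict (`p < alpha`).
#' When a multiple-testing correction is enabled the alpha is applied to
#' q-values. By default only increases are called; `two_sided_fold` in the
#' config also calls `ratio_of_ratios < 1/fold_cutoff`.
#'
#' @param ror Ratio-of-ratios value(s).
#' @param p_value Mann-Whitney p-value(s).
#' @param config A [quant_config()].
#' @param q_value Optional BH q-value(s) (required when `config$mtc != "none"`).
#' @return Tibble with `ratio_of_ratios`, `p_value`, `q_value`,
#'   `passes_fold`, `passes_p`, `significant`.
#' @export
call_differential <- function(ror, p_value, config = quant_config(),
                              q_value = NULL) {
  p_eff <- if (config$mtc != "none") {
    if (is.null(q_value)) stop("mtc enabled but no q_value supplied")
    q_value
  } else {
    p_value
  }
  passes_fold <- ror > config$fold_cutoff
  if (config$two_sided_fold) {
    passes_fold <- passes_fold | ror < 1 / config$fold_cutoff
  }
  passes_p <- p_eff < config$alpha
  tibble::tibble(
    ratio_of_ratios = ror,
    p_value = p_value,
    q_value = if (is.null(q_value)) NA_real_ else q_value,
    passes_fold = passes_fold,
    passes_p = passes_p,
    significant = passes_fold & passes_p
  )
}

#' Roll peptide-level calls up to proteins
#'
#' A protein is called significant if at least one of its peptides is.
#' `best_ratio_of_ratios` is the largest peptide ratio-of-ratios and
#' `best_p_value` the smallest peptide p-value.
#'
#' @param calls Peptide-level call tibble (see [quantify_peptides()]).
#' @param proteome Optional protein tibble; accessions absent from it
#'   trigger a warning (calls are retained).
#' @return Tibble sorted by accession with `accession`, `n_peptides_total`,
#'   `n_peptides_significant`, `significant`, `best_ratio_of_ratios`,
#'   `best_p_value`.
#' @export
rollup_to_proteins <- function(calls, proteome = NULL) {
  if (!is.null(proteome)) {
    unknown <- setdiff(unique(calls$accession), proteome$accession)
    if (length(unknown)) {
      warning("accession(s) absent from protein database: ",
              paste(head(unknown, 5L), collapse = ", "),
              if (length(unknown) > 5L) ", ..." else "")
    }
  }
  calls |>
    dplyr::group_by(.data$accession) |>
    dplyr::summarise(
      n_peptides_total = dplyr::n(),
      n_peptides_significant = sum(.data$significant),
      significant = any(.data$significant),
      best_ratio_of_ratios = max(.data$ratio_of_ratios),
      best_p_value = min(.data$p_value),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$accession)
}

#' Convert between H:L ratio and site occupancy
#'
#' With light ICAT marking reduced thiols and heavy ICAT marking
#' glutathionylated thiols, the heavy:light ratio r equals SG/SH, so the
#' glutathionylated fraction (occupancy) is theta = r / (1 + r) and
#' conversely r = theta / (1 - theta).
#'
#' @param r Heavy:light ratio(s), nonnegative.
#' @return `occupancy_from_ratio`: occupancy in \[0, 1).
#' @export
occupancy_from_ratio <- function(r) {
  if (any(r < 0)) stop("ratio must be nonnegative")
  r / (1 + r)
}

#' @rdname occupancy_from_ratio
#' @param theta Occupancy value(s) in \[0, 1).
#' @return `ratio_from_occupancy`: the corresponding H:L ratio.
#' @export
ratio_from_occupancy <- function(theta) {
  if (any(theta < 0) || any(theta >= 1)) {
    stop("occupancy must lie in [0, 1); the ratio is unbounded at 1")
  }
  theta / (1 - theta)
}

#' Run the full peptide-level differential pipeline
#'
#' Filters measurements, collapses technical replicates per subject,
#' summarises each group, computes the case/control ratio-of-ratios and a
#' Mann-Whitney p-value per peptide, and assembles differential calls and
#' a protein-level rollup. Peptides observed in fewer than
#' `min_subjects_per_group` subjects in either group are excluded and
#' logged.
#'
#' @param measurements Measurement tibble (see [read_peptide_table()]).
#' @param config A [quant_config()].
#' @param proteome Optional protein tibble for cysteine-site mapping.
#' @return An object of class `glutaquant_result`: a list with `calls`
#'   (peptide-level tibble), `proteins` (rollup), `sites` (site-level
#'   tibble or NULL), `subject_values`, `excluded`, `rejections`, `counts`,
#'   `config`.
#' @export
quantify_peptides <- function(measurements, config = quant_config(),
                              proteome = NULL) {
  filt <- filter_peptides(measurements, config)
  subj <- collapse_technical_replicates(filt$retained)

  nested <- subj |>
    dplyr::group_by(.data$key, .data$accession, .data$peptide, .data$group) |>
    dplyr::summarise(values = list(.data$h_to_l), n = dplyr::n(),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "group",
                       values_from = c("values", "n"),
                       values_fill = list(n = 0L))
  for (col in c("values_case", "values_control")) {
    if (!col %in% names(nested)) nested[[col]] <- list(numeric(0))
  }
  for (col in c("n_case", "n_control")) {
    if (!col %in% names(nested)) nested[[col]] <- 0L
  }
  nested$n_case[is.na(nested$n_case)] <- 0L
  nested$n_control[is.na(nested$n_control)] <- 0L

  testable <- nested$n_case >= config$min_subjects_per_group &
    nested$n_control >= config$min_subjects_per_group
  excluded <- tibble::tibble(
    key = nested$key[!testable],
    accession = nested$accession[!testable],
    peptide = nested$peptide[!testable],
    n_case = nested$n_case[!testable],
    n_control = nested$n_control[!testable],
    reason = "insufficient observations"
  )
  kept <- nested[testable, , drop = FALSE]

  if (nrow(kept) > 0L) {
    case_mean <- vapply(kept$values_case, group_mean, numeric(1),
                        kind = config$mean_kind)
    control_mean <- vapply(kept$values_control, group_mean, numeric(1),
                           kind = config$mean_kind)
    ror <- ratio_of_ratios(case_mean, control_mean)
    p <- purrr::map2_dbl(kept$values_case, kept$values_control,
                         mann_whitney_p, exact_max_n = config$exact_test_max_n)
    q <- if (config$mtc == "BH") stats::p.adjust(p, method = "BH") else NULL
    calls <- call_differential(ror, p, config, q)
    calls <- dplyr::bind_cols(
      kept[, c("key", "accession", "peptide", "n_case", "n_control")],
      tibble::tibble(case_mean = case_mean, control_mean = control_mean),
      calls
    )
  } else {
    calls <- tibble::tibble(
      key = character(), accession = character(), peptide = character(),
      n_case = integer(), n_control = integer(),
      case_mean = numeric(), control_mean = numeric(),
      ratio_of_ratios = numeric(), p_value = numeric(), q_value = numeric(),
      passes_fold = logical(), passes_p = logical(), significant = logical()
    )
  }
  cys <- filt$retained[!duplicated(filt$retained$key),
                       c("key", "cys_positions")]
  calls$cys_positions <- cys$cys_positions[match(calls$key, cys$key)]
  calls <- dplyr::arrange(calls, .data$accession, .data$peptide, .data$key)

  proteins <- if (nrow(calls)) rollup_to_proteins(calls, proteome) else
    tibble::tibble(accession = character(), n_peptides_total = integer(),
                   n_peptides_significant = integer(), significant = logical(),
                   best_ratio_of_ratios = numeric(), best_p_value = numeric())

  sites <- NULL
  if (!is.null(proteome) && nrow(calls)) {
    smap <- map_table_sites(calls, proteome)
    sites <- dplyr::inner_join(
      smap,
      calls[, c("key", "ratio_of_ratios", "p_value", "q_value", "significant")],
      by = "key"
    )
    sites <- dplyr::arrange(sites, .data$accession, .data$position, .data$peptide)
  }

  counts <- list(
    rows_read = nrow(measurements),
    rows_rejected_confidence = filt$rejections$n_rejected[1],
    rows_rejected_h_to_l = filt$rejections$n_rejected[2],
    rows_retained = nrow(filt$retained),
    peptides_observed = nrow(nested),
    peptides_excluded = nrow(excluded),
    peptides_tested = nrow(calls),
    peptides_significant = sum(calls$significant),
    proteins_quantified = nrow(proteins),
    proteins_significant = sum(proteins$significant)
  )

  structure(
    list(calls = calls, proteins = proteins, sites = sites,
         subject_values = subj, excluded = excluded,
         rejections = filt$rejections, counts = counts, config = config),
    class = "glutaquant_result"
  )
}

#' @export
print.glutaquant_result <- function(x, ...) {
  c <- x$counts
  cat("Differential S-glutathionylation result\n")
  cat(sprintf("  rows read %d | rejected conf %d, ratio %d | retained %d\n",
              c$rows_read, c$rows_rejected_confidence,
              c$rows_rejected_h_to_l, c$rows_retained))
  cat(sprintf("  peptides tested %d (excluded %d) | significant %d\n",
              c$peptides_tested, c$peptides_excluded, c$peptides_significant))
  cat(sprintf("  proteins quantified %d | significant %d\n",
              c$proteins_quantified, c$proteins_significant))
  invisible(x)
}
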