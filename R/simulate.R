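# Average amino-acid frequencies (UniProtKB-like, percent); C is replaced
# by the configured cysteine frequency at generation time.
AA_BACKGROUND <- c(
  A = 8.25, R = 5.53, N = 4.06, D = 5.45, C = 1.38, Q = 3.93, E = 6.75,
  G = 7.07, H = 2.27, I = 5.96, L = 9.66, K = 5.84, M = 2.42, F = 3.86,
  P = 4.70, S = 6.56, T = 5.34, W = 1.08, Y = 2.92, V = 6.87
)

#' Simulation configuration
#'
#' Parameters of the synthetic cleavable-ICAT experiment. The defaults
#' emulate a fibroblast case/control redox-proteomics study: 11 case and 7
#' control subjects measured in technical duplicate; a 300-protein random
#' proteome at human-like composition (2.3% cysteine), which after in
#' silico tryptic digestion yields roughly 2,100 observable cysteine
#' peptides; baseline site occupancies drawn from Beta(1.5, 10) (mean
#' ~12%, matching reported basal thiol-oxidation levels); 10% of peptides
#' carry a planted 2-fold increase in the case group; 20% multiplicative
#' lognormal noise per isotope channel; 5% missing observations.
#'
#' @param n_proteins Number of synthetic proteins.
#' @param protein_length_range Length range (inclusive) for each protein.
#' @param cys_frequency Per-residue probability of cysteine.
#' @param n_case_subjects,n_control_subjects Subjects per arm.
#' @param n_technical_replicates Technical replicates per subject.
#' @param occupancy_shape1,occupancy_shape2 Beta parameters of the
#'   baseline (control) occupancy distribution on (0, 1).
#' @param occupancy_floor Lower truncation of the baseline occupancy.
#'   Quantified ICAT data definitionally passed the H:L >= 0.01 floor, so
#'   the generator emulates that population: occupancies below ~1% (whose
#'   noise-free H:L falls under the floor) are not drawn.
#' @param fraction_differential Fraction of cysteine peptides (hence,
#'   approximately, of sites) with a planted case-group effect.
#' @param effect_ratio Target ratio-of-ratios at planted peptides (> 1, or
#'   exactly 1 for a pure null).
#' @param noise_cv Coefficient of variation of the multiplicative
#'   lognormal noise on each of the heavy and light channels.
#' @param missing_rate Per-observation dropout probability
#'   (missing-completely-at-random).
#' @param low_confidence_rate Fraction of rows drawn with identification
#'   confidence below the conventional 95% floor.
#' @param min_peptide_length,max_peptide_length Observable tryptic peptide
#'   length window (typical LC-MS/MS detectability).
#' @param missed_cleavages Missed tryptic cleavages to include (0-2).
#' @param seed Integer seed; mandatory, governs all randomness through
#'   deterministic per-stage substreams.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 300L,
                       protein_length_range = c(200L, 600L),
                       cys_frequency = 0.023,
                       n_case_subjects = 11L,
                       n_control_subjects = 7L,
                       n_technical_replicates = 2L,
                       occupancy_shape1 = 1.5,
                       occupancy_shape2 = 10,
                       occupancy_floor = 0.01,
                       fraction_differential = 0.10,
                       effect_ratio = 2,
                       noise_cv = 0.20,
                       missing_rate = 0.05,
                       low_confidence_rate = 0.05,
                       min_peptide_length = 6L,
                       max_peptide_length = 40L,
                       missed_cleavages = 0L,
                       seed) {
  if (missing(seed)) stop("sim_config requires an explicit integer seed")
  stopifnot(
    n_proteins >= 1,
    length(protein_length_range) == 2L,
    protein_length_range[1] >= 10, diff(protein_length_range) >= 0,
    cys_frequency >= 0, cys_frequency < 1,
    n_case_subjects >= 1, n_control_subjects >= 1,
    n_technical_replicates >= 1,
    occupancy_shape1 > 0, occupancy_shape2 > 0,
    occupancy_floor >= 0, occupancy_floor < 1,
    fraction_differential >= 0, fraction_differential <= 1,
    effect_ratio >= 1,
    noise_cv >= 0,
    missing_rate >= 0, missing_rate < 1,
    low_confidence_rate >= 0, low_confidence_rate <= 1,
    missed_cleavages >= 0, missed_cleavages <= 2
  )
  structure(
    list(n_proteins = as.integer(n_proteins),
         protein_length_range = as.integer(protein_length_range),
         cys_frequency = cys_frequency,
         n_case_subjects = as.integer(n_case_subjects),
         n_control_subjects = as.integer(n_control_subjects),
         n_technical_replicates = as.integer(n_technical_replicates),
         occupancy_shape1 = occupancy_shape1,
         occupancy_shape2 = occupancy_shape2,
         occupancy_floor = occupancy_floor,
         fraction_differential = fraction_differential,
         effect_ratio = effect_ratio,
         noise_cv = noise_cv,
         missing_rate = missing_rate,
         low_confidence_rate = low_confidence_rate,
         min_peptide_length = as.integer(min_peptide_length),
         max_peptide_length = as.integer(max_peptide_length),
         missed_cleavages = as.integer(missed_cleavages),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Generate a random synthetic proteome
#'
#' Sequences are drawn residue-by-residue from an average proteome
#' composition in which the cysteine frequency is replaced by
#' `cys_frequency` (other residues rescaled). Every protein is guaranteed
#' at least one K/R so that tryptic digestion is possible. Accessions are
#' `SYNP0001`, `SYNP0002`, ... marking the records as synthetic.
#'
#' @param config A [sim_config()].
#' @return Protein tibble (`accession`, `description`, `sequence`),
#'   FASTA-writable via [write_fasta()]. Reproducible per seed.
#' @export
generate_proteome <- function(config) {
  freqs <- AA_BACKGROUND / sum(AA_BACKGROUND)
  non_c <- setdiff(names(freqs), "C")
  freqs[non_c] <- freqs[non_c] / sum(freqs[non_c]) * (1 - config$cys_frequency)
  freqs["C"] <- config$cys_frequency
  lr <- config$protein_length_range
  withr::with_seed(config$seed + 101L, {
    seqs <- character(config$n_proteins)
    for (i in seq_len(config$n_proteins)) {
      repeat {
        len <- if (lr[1] == lr[2]) lr[1] else sample(lr[1]:lr[2], 1L)
        s <- paste(sample(names(freqs), len, replace = TRUE, prob = freqs),
                   collapse = "")
        if (grepl("[KR]", s)) break
      }
      seqs[i] <- s
    }
  })
  tibble::tibble(
    accession = sprintf("SYNP%04d", seq_len(config$n_proteins)),
    description = "synthetic protein",
    sequence = seqs
  )
}

#' In silico tryptic digestion
#'
#' Cleaves after K or R except when the next residue is P (standard
#' trypsin convention). With `missed_cleavages = 0` the returned peptides
#' concatenate back to the input sequence; with 1 or 2, concatenations of
#' up to that many adjacent fragments are appended.
#'
#' @param sequence Nonempty amino-acid string.
#' @param missed_cleavages Number of missed cleavages to include (0-2).
#' @return Character vector of peptides.
#' @examples
#' tryptic_digest("MKCRGWK")  # "MK" "CR" "GWK"
#' tryptic_digest("AKPGR")    # "AKPGR": K before P does not cleave
#' @export
tryptic_digest <- function(sequence, missed_cleavages = 0L) {
  if (!nzchar(sequence)) stop("cannot digest an empty sequence")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  cut_after <- which(chars %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & chars[cut_after + 1L] != "P"]
  starts <- c(1L, cut_after + 1L)
  ends <- c(cut_after, n)
  base <- substring(sequence, starts, ends)
  if (missed_cleavages == 0L || length(base) == 1L) return(base)
  out <- base
  for (k in seq_len(min(missed_cleavages, length(base) - 1L))) {
    idx <- seq_len(length(base) - k)
    out <- c(out, vapply(idx, function(i) paste(base[i:(i + k)], collapse = ""),
                         character(1)))
  }
  out
}

#' Enumerate observable cysteine peptides of a proteome
#'
#' Digests every protein, keeps peptides inside the detectable length
#' window that contain at least one cysteine, and records the protein
#' coordinates of their cysteines. A peptide occurring at several
#' positions in its protein keeps all site coordinates and is flagged
#' ambiguous.
#'
#' @param proteome Protein tibble.
#' @param config A [sim_config()] (length window and missed cleavages).
#' @return Tibble with one row per distinct (accession, peptide):
#'   `accession`, `peptide`, `cys_positions` (peptide-relative, list),
#'   `site_positions` (protein coordinates over all occurrences, list),
#'   `ambiguous`, `key`.
#' @export
digest_proteome <- function(proteome, config) {
  rows <- purrr::map2(proteome$accession, proteome$sequence, function(acc, seq) {
    peps <- tryptic_digest(seq, config$missed_cleavages)
    peps <- unique(peps[nchar(peps) >= config$min_peptide_length &
                          nchar(peps) <= config$max_peptide_length &
                          grepl("C", peps, fixed = TRUE)])
    if (length(peps) == 0L) return(NULL)
    cys <- lapply(peps, function(p) {
      as.integer(gregexpr("C", p, fixed = TRUE)[[1]])
    })
    sites <- vector("list", length(peps))
    ambiguous <- logical(length(peps))
    for (i in seq_along(peps)) {
      m <- Biostrings::matchPattern(peps[i], Biostrings::AAString(seq))
      starts <- Biostrings::start(m)
      sites[[i]] <- as.integer(outer(starts - 1L, cys[[i]], "+"))
      ambiguous[i] <- length(starts) > 1L
    }
    tibble::tibble(accession = acc, peptide = peps, cys_positions = cys,
                   site_positions = sites, ambiguous = ambiguous)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out)) {
    out$key <- peptide_key(out$accession, out$peptide, out$cys_positions)
  } else {
    out$key <- character(0)
  }
  out
}

#' Plant differential glutathionylation effects
#'
#' Draws a baseline (control) occupancy for every cysteine peptide from
#' the configured Beta distribution and plants a case-group effect on a
#' random `fraction_differential` of peptides by multiplying the odds:
#' `theta_case = e * rho / (1 + e * rho)` with `rho = theta / (1 - theta)`
#' and `e = effect_ratio`, so the expected ratio-of-ratios at a planted
#' peptide is exactly `effect_ratio`. Because one H:L value exists per
#' peptide, all cysteine sites of a peptide share its occupancy and
#' differential status; the per-site ground truth inherits them.
#'
#' @param peptides Cysteine-peptide tibble from [digest_proteome()].
#' @param config A [sim_config()].
#' @return List with `peptides` (peptide-level truth: adds
#'   `theta_control`, `theta_case`, `is_differential`,
#'   `expected_ratio_of_ratios`) and `sites` (per-site truth: `accession`,
#'   `position`, `key`, same truth columns).
#' @export
plant_effects <- function(peptides, config) {
  if (nrow(peptides) == 0L) {
    stop("no cysteine peptides available to plant effects on ",
         "(is cys_frequency zero?)")
  }
  n <- nrow(peptides)
  withr::with_seed(config$seed + 202L, {
    # baseline occupancy: Beta truncated below the quantification floor
    p_lo <- stats::pbeta(config$occupancy_floor, config$occupancy_shape1,
                         config$occupancy_shape2)
    theta_control <- stats::qbeta(runif(n, p_lo, 1), config$occupancy_shape1,
                                  config$occupancy_shape2)
    is_diff <- rep(FALSE, n)
    n_diff <- round(config$fraction_differential * n)
    if (config$effect_ratio > 1 && n_diff > 0L) {
      is_diff[sample.int(n, n_diff)] <- TRUE
    }
  })
  odds <- theta_control / (1 - theta_control)
  theta_case <- ifelse(is_diff,
                       config$effect_ratio * odds / (1 + config$effect_ratio * odds),
                       theta_control)
  truth <- peptides
  truth$theta_control <- theta_control
  truth$theta_case <- theta_case
  truth$is_differential <- is_diff
  truth$expected_ratio_of_ratios <- ifelse(is_diff, config$effect_ratio, 1)

  sites <- truth |>
    dplyr::select("accession", "peptide", "key", "site_positions",
                  "ambiguous", "theta_control", "theta_case",
                  "is_differential", "expected_ratio_of_ratios") |>
    tidyr::unnest_longer("site_positions", values_to = "position") |>
    dplyr::arrange(.data$accession, .data$position)
  list(peptides = truth, sites = sites)
}

#' Simulate a pipeline-ready peptide quantification table
#'
#' For each cysteine peptide, subject, and technical replicate the
#' noise-free ratio `r = theta / (1 - theta)` (occupancy of the subject's
#' group) is perturbed by multiplicative lognormal noise
#' `exp(eps_H - eps_L)`, with each channel's error sized to the configured
#' coefficient of variation. Observations drop out completely at random at
#' `missing_rate`; identification confidence is drawn high
#' (Uniform(95, 100)) except for a `low_confidence_rate` fraction drawn
#' from Uniform(70, 95).
#'
#' @param truth Peptide-level ground truth from [plant_effects()].
#' @param config A [sim_config()].
#' @return Measurement tibble in the package's internal form (same columns
#'   as [read_peptide_table()] output); serialise with
#'   [write_peptide_table()].
#' @export
simulate_peptide_table <- function(truth, config) {
  pep <- truth$peptides
  subjects <- tibble::tibble(
    subject_id = c(sprintf("case_%02d", seq_len(config$n_case_subjects)),
                   sprintf("control_%02d", seq_len(config$n_control_subjects))),
    group = rep(c("case", "control"),
                c(config$n_case_subjects, config$n_control_subjects))
  )
  grid <- tidyr::expand_grid(
    pep_idx = seq_len(nrow(pep)),
    subjects,
    replicate = seq_len(config$n_technical_replicates)
  )
  theta <- ifelse(grid$group == "case",
                  pep$theta_case[grid$pep_idx],
                  pep$theta_control[grid$pep_idx])
  r <- theta / (1 - theta)
  n <- nrow(grid)
  withr::with_seed(config$seed + 303L, {
    if (config$noise_cv > 0) {
      sigma <- sqrt(log1p(config$noise_cv^2))
      noise <- exp(rnorm(n, 0, sigma) - rnorm(n, 0, sigma))
    } else {
      noise <- rep(1, n)
    }
    low <- runif(n) < config$low_confidence_rate
    confidence <- ifelse(low, runif(n, 70, 95), runif(n, 95, 100))
    dropped <- runif(n) < config$missing_rate
  })
  out <- tibble::tibble(
    sample_id = paste0(grid$subject_id, "_r", grid$replicate),
    subject_id = grid$subject_id,
    group = grid$group,
    replicate = grid$replicate,
    accession = pep$accession[grid$pep_idx],
    peptide = pep$peptide[grid$pep_idx],
    cys_positions = pep$cys_positions[grid$pep_idx],
    confidence = confidence,
    h_to_l = r * noise,
    key = pep$key[grid$pep_idx]
  )
  out[!dropped & out$h_to_l > 0, , drop = FALSE]
}

#' Simulate a complete synthetic experiment
#'
#' Convenience wrapper: generates the proteome, digests it, plants
#' effects, and simulates the quantification table. If `out_dir` is given,
#' writes `proteome.fasta`, `peptide_table.tsv`, `ground_truth_sites.tsv`,
#' `ground_truth_peptides.tsv`, and `sim_config.json` there.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional output directory (created if needed).
#' @return List with `proteome`, `peptides` (digest), `truth` (list of
#'   peptide- and site-level ground truth), `table` (measurements),
#'   `config`.
#' @export
simulate_experiment <- function(config, out_dir = NULL) {
  proteome <- generate_proteome(config)
  peptides <- digest_proteome(proteome, config)
  truth <- plant_effects(peptides, config)
  table <- simulate_peptide_table(truth, config)
  res <- list(proteome = proteome, peptides = peptides, truth = truth,
              table = table, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(proteome, file.path(out_dir, "proteome.fasta"))
    write_peptide_table(table, file.path(out_dir, "peptide_table.tsv"))
    write_results_table(truth$sites,
                        file.path(out_dir, "ground_truth_sites.tsv"))
    write_results_table(truth$peptides,
                        file.path(out_dir, "ground_truth_peptides.tsv"))
    jsonlite::write_json(unclass(config),
                         file.path(out_dir, "sim_config.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  res
}
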