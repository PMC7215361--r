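# Independent brute-force oracles used to check the package's statistics.

# Two-sided Mann-Whitney p by full enumeration of all group labelings of
# the pooled sample (midranks; p = 2 * min tail probability, capped at 1).
enum_mw_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  na <- length(x)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - na * (na + 1) / 2
  u_obs <- u_of(seq_len(na))
  labelings <- utils::combn(n, na)
  u_all <- apply(labelings, 2L, u_of)
  eps <- 1e-9
  p <- 2 * min(mean(u_all <= u_obs + eps), mean(u_all >= u_obs - eps))
  min(p, 1)
}

# Hypergeometric upper tail P(X >= k) by exhaustive enumeration of all
# n-subsets of a universe of size N with K special elements.
enum_hyper_p <- function(N, K, n, k) {
  subsets <- utils::combn(N, n)
  hits_in <- apply(subsets, 2L, function(s) sum(s <= K))
  mean(hits_in >= k)
}

# A small deterministic proteome for mapping tests.
toy_proteome <- function() {
  tibble::tibble(
    accession = c("P1", "P2", "P3"),
    description = c("alpha", "beta", "gamma"),
    sequence = c("MACDEFCK", "CRXXCR", "MKTTCGYKAACDEK")
  )
}

# Handcrafted 50-row measurement table: 5 peptides on 3 proteins,
# case subjects s1..s3 and control subjects c1..c2 (some in duplicate),
# with a sprinkling of low-confidence and below-floor rows.
fixture_table_50 <- function() {
  peps <- tibble::tibble(
    accession = c("PA", "PA", "PB", "PB", "PC"),
    peptide   = c("AACDEK", "CCGTLR", "MMCPLK", "TTCGYK", "GGCVVR"),
    cys       = list(3L, c(1L, 2L), 3L, 3L, 3L)
  )
  subj <- tibble::tibble(
    subject_id = c("s1", "s1", "s2", "s3", "c1", "c1", "c2"),
    group      = c("case", "case", "case", "case", "control", "control", "control"),
    replicate  = c(1L, 2L, 1L, 1L, 1L, 2L, 1L)
  )
  grid <- tidyr::expand_grid(p = seq_len(nrow(peps)), s = seq_len(nrow(subj)))
  n <- nrow(grid)  # 35 rows so far; pad to 50 with extra replicates below
  base_ratio <- c(0.5, 1.2, 0.8, 0.02, 0.4)[grid$p]
  bump <- ifelse(subj$group[grid$s] == "case", c(2.0, 1.0, 1.6, 1.0, 1.0)[grid$p], 1)
  jitter <- 1 + 0.01 * (seq_len(n) %% 7)
  tab <- tibble::tibble(
    sample_id = paste0(subj$subject_id[grid$s], "_r", subj$replicate[grid$s]),
    subject_id = subj$subject_id[grid$s],
    group = subj$group[grid$s],
    replicate = subj$replicate[grid$s],
    accession = peps$accession[grid$p],
    peptide = peps$peptide[grid$p],
    cys_positions = peps$cys[grid$p],
    confidence = rep(c(99, 97, 96, 98, 95, 94, 99), length.out = n),
    h_to_l = base_ratio * bump * jitter
  )
  extra <- tab[1:15, ]
  extra$replicate <- extra$replicate + 2L
  extra$sample_id <- paste0(extra$subject_id, "_r", extra$replicate)
  extra$confidence <- rep(c(99, 80, 96), length.out = 15)
  extra$h_to_l <- extra$h_to_l * 1.05
  extra$h_to_l[12] <- 0.004   # below the H:L floor
  out <- dplyr::bind_rows(tab, extra)
  out$key <- peptide_key(out$accession, out$peptide, out$cys_positions)
  out
}

# Serialise a measurement tibble to a temp file in the default dialect.
write_temp_table <- function(tbl) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  write_peptide_table(tbl, path)
  path
}
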