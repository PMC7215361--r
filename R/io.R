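#' Read a protein sequence database from FASTA
#'
#' Parses a (possibly multi-line) amino-acid FASTA file into a protein
#' table. The accession is the first whitespace-delimited token after the
#' `>`; anything after it becomes the description. Sequences are uppercased
#' and line breaks removed.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `accession`, `description`, `sequence`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">P1 demo protein", "MACD"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) stop("no FASTA records found in ", path)
  headers <- names(seqs)
  accession <- sub("\\s.*$", "", headers)
  if (any(!nzchar(accession))) stop("FASTA record with empty accession")
  dup <- unique(accession[duplicated(accession)])
  if (length(dup)) {
    stop("duplicate accession(s) in FASTA: ", paste(dup, collapse = ", "))
  }
  description <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  tibble::tibble(
    accession = accession,
    description = description,
    sequence = unname(toupper(as.character(seqs)))
  )
}

#' Write a protein table to FASTA
#'
#' @param proteins Tibble with `accession`, `description`, `sequence`
#'   (as returned by [read_fasta()] or [generate_proteome()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  stopifnot(all(c("accession", "sequence") %in% names(proteins)))
  desc <- if ("description" %in% names(proteins)) proteins$description else ""
  hdr <- trimws(paste(proteins$accession, desc))
  set <- Biostrings::AAStringSet(stats::setNames(proteins$sequence, hdr))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Peptide-table dialect
#'
#' Describes how a delimited peptide quantification export maps onto the
#' logical columns the pipeline needs. The default matches the package's
#' own tab-separated format.
#'
#' @param delim Field delimiter.
#' @param cys_sep Separator between multiple labelled-cysteine positions
#'   within one field (positions are 1-based indices into the peptide).
#' @param case_label,control_label Values of the group column denoting the
#'   case (disease/treated) and control arms.
#' @param columns Named character vector mapping logical names
#'   (`sample_id`, `subject_id`, `group`, `replicate`, `accession`,
#'   `peptide`, `cys_positions`, `confidence`, `h_to_l`) to physical
#'   header names in the file.
#' @return A list of class `peptide_table_dialect`.
#' @export
peptide_table_dialect <- function(delim = "\t",
                                  cys_sep = ";",
                                  case_label = "case",
                                  control_label = "control",
                                  columns = c(
                                    sample_id = "sample_id",
                                    subject_id = "subject_id",
                                    group = "group",
                                    replicate = "replicate",
                                    accession = "accession",
                                    peptide = "peptide",
                                    cys_positions = "cys_positions",
                                    confidence = "confidence",
                                    h_to_l = "h_to_l"
                                  )) {
  required <- c("sample_id", "subject_id", "group", "replicate", "accession",
                "peptide", "cys_positions", "confidence", "h_to_l")
  missing <- setdiff(required, names(columns))
  if (length(missing)) {
    stop("dialect is missing logical column(s): ", paste(missing, collapse = ", "))
  }
  structure(
    list(delim = delim, cys_sep = cys_sep, case_label = case_label,
         control_label = control_label, columns = columns),
    class = "peptide_table_dialect"
  )
}

#' Build the canonical peptide identity key
#'
#' One quantified entity is a (protein accession, peptide sequence,
#' labelled-cysteine positions) triple; all grouping in the pipeline uses
#' this key.
#'
#' @param accession Protein accession(s).
#' @param peptide Peptide sequence(s).
#' @param cys_positions List of integer vectors (1-based, peptide-relative).
#' @return Character vector of keys.
#' @export
peptide_key <- function(accession, peptide, cys_positions) {
  cys <- vapply(cys_positions, function(p) paste(p, collapse = ";"), character(1))
  paste(accession, peptide, cys, sep = "|")
}

#' Read a peptide-level quantification table
#'
#' Reads a delimited export of per-sample peptide H:L measurements
#' (emulating a cleavable-ICAT search-engine export). Rows with unparsable
#' numeric fields, out-of-range confidence, non-positive H:L, unknown group
#' labels, or cysteine positions that do not point at a `C` are rejected;
#' the rejected rows (with 1-based data row numbers and reasons) are
#' attached as attribute `"rejected"` and reported in a warning.
#'
#' @param path Path to the delimited file (header row required).
#' @param dialect A [peptide_table_dialect()].
#' @return A tibble of measurements with columns `sample_id`, `subject_id`,
#'   `group` (`"case"`/`"control"`), `replicate`, `accession`, `peptide`,
#'   `cys_positions` (list of integer vectors), `confidence`, `h_to_l`,
#'   and `key`.
#' @export
read_peptide_table <- function(path, dialect = peptide_table_dialect()) {
  raw <- readr::read_delim(path, delim = dialect$delim,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  cols <- dialect$columns
  missing <- setdiff(unname(cols), names(raw))
  if (length(missing)) {
    stop("peptide table is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (nrow(raw) == 0L) stop("peptide table is empty: ", path)
  df <- tibble::tibble(
    sample_id = raw[[cols[["sample_id"]]]],
    subject_id = raw[[cols[["subject_id"]]]],
    group_raw = raw[[cols[["group"]]]],
    replicate_raw = raw[[cols[["replicate"]]]],
    accession = raw[[cols[["accession"]]]],
    peptide = toupper(raw[[cols[["peptide"]]]]),
    cys_raw = raw[[cols[["cys_positions"]]]],
    confidence_raw = raw[[cols[["confidence"]]]],
    h_to_l_raw = raw[[cols[["h_to_l"]]]]
  )

  suppress_nan_warn <- function(x) suppressWarnings(as.numeric(x))
  replicate <- suppressWarnings(as.integer(df$replicate_raw))
  confidence <- suppress_nan_warn(df$confidence_raw)
  h_to_l <- suppress_nan_warn(df$h_to_l_raw)
  cys_positions <- lapply(strsplit(df$cys_raw, dialect$cys_sep, fixed = TRUE),
                          function(x) suppressWarnings(as.integer(trimws(x))))

  reason <- rep(NA_character_, nrow(df))
  flag <- function(bad, why) {
    bad <- which(bad & is.na(reason))
    reason[bad] <<- why
  }
  flag(is.na(replicate) | replicate < 1L, "unparsable or non-positive replicate")
  flag(is.na(confidence), "unparsable confidence")
  flag(!is.na(confidence) & (confidence < 0 | confidence > 100),
       "confidence outside [0, 100]")
  flag(is.na(h_to_l), "unparsable h_to_l")
  flag(!is.na(h_to_l) & h_to_l <= 0, "non-positive h_to_l")
  flag(!(df$group_raw %in% c(dialect$case_label, dialect$control_label)),
       "unknown group label")
  cys_ok <- mapply(function(pos, pep) {
    length(pos) > 0L && !anyNA(pos) && all(pos >= 1L) &&
      all(pos <= nchar(pep)) &&
      all(substring(pep, pos, pos) == "C")
  }, cys_positions, df$peptide)
  flag(!cys_ok, "cys_positions do not index 'C' residues of peptide")

  rejected <- tibble::tibble(row = which(!is.na(reason)),
                             reason = reason[!is.na(reason)])
  keep <- is.na(reason)
  if (!any(keep)) stop("peptide table has no valid rows: ", path)

  out <- tibble::tibble(
    sample_id = df$sample_id[keep],
    subject_id = df$subject_id[keep],
    group = ifelse(df$group_raw[keep] == dialect$case_label, "case", "control"),
    replicate = replicate[keep],
    accession = df$accession[keep],
    peptide = df$peptide[keep],
    cys_positions = cys_positions[keep],
    confidence = confidence[keep],
    h_to_l = h_to_l[keep]
  )
  out$key <- peptide_key(out$accession, out$peptide, out$cys_positions)
  if (nrow(rejected)) {
    warning(nrow(rejected), " row(s) rejected while reading ", path,
            " (see attr(x, 'rejected'))")
  }
  attr(out, "rejected") <- rejected
  out
}

#' Write a measurement table in the package's dialect
#'
#' Inverse of [read_peptide_table()]; cysteine-position lists are collapsed
#' with the dialect separator.
#'
#' @param measurements Measurement tibble (see [read_peptide_table()]).
#' @param path Output path.
#' @param dialect A [peptide_table_dialect()].
#' @return `path`, invisibly.
#' @export
write_peptide_table <- function(measurements, path,
                                dialect = peptide_table_dialect()) {
  cols <- dialect$columns
  out <- tibble::tibble(
    measurements$sample_id,
    measurements$subject_id,
    ifelse(measurements$group == "case", dialect$case_label, dialect$control_label),
    measurements$replicate,
    measurements$accession,
    measurements$peptide,
    vapply(measurements$cys_positions, paste, character(1), collapse = dialect$cys_sep),
    measurements$confidence,
    measurements$h_to_l
  )
  names(out) <- unname(cols[c("sample_id", "subject_id", "group", "replicate",
                              "accession", "peptide", "cys_positions",
                              "confidence", "h_to_l")])
  readr::write_delim(out, path, delim = dialect$delim, progress = FALSE)
  invisible(path)
}

#' Map a peptide's labelled cysteines onto protein coordinates
#'
#' Finds every exact occurrence of the peptide in the protein sequence
#' (overlapping occurrences included) and converts each peptide-relative
#' cysteine index `i` to the 1-based protein position
#' `occurrence_start - 1 + i`. Peptides occurring more than once are
#' retained and flagged ambiguous rather than dropped.
#'
#' @param peptide_sequence Peptide amino-acid string.
#' @param peptide_cys_positions Integer vector of 1-based cysteine indices
#'   into the peptide.
#' @param protein A list or one-row data frame with `accession` and
#'   `sequence`.
#' @return Tibble with columns `accession`, `occurrence_start`,
#'   `peptide_cys_position`, `position` (protein coordinate), `ambiguous`.
#' @examples
#' map_peptide_to_protein("ACDEFCK", c(2, 6),
#'                        list(accession = "P1", sequence = "MACDEFCK"))
#' @export
map_peptide_to_protein <- function(peptide_sequence, peptide_cys_positions,
                                   protein) {
  if (!nzchar(peptide_sequence)) stop("empty peptide sequence")
  bad <- if (length(peptide_cys_positions)) {
    substring(peptide_sequence, peptide_cys_positions,
              peptide_cys_positions) != "C"
  } else {
    logical(0)
  }
  if (any(bad)) {
    stop("cysteine position(s) ", paste(peptide_cys_positions[bad], collapse = ", "),
         " do not point at 'C' in peptide ", peptide_sequence)
  }
  hits <- Biostrings::matchPattern(peptide_sequence,
                                   Biostrings::AAString(protein$sequence))
  starts <- Biostrings::start(hits)
  if (length(starts) == 0L) {
    stop("unmapped peptide: ", peptide_sequence, " not found in protein ",
         protein$accession)
  }
  out <- tidyr::expand_grid(occurrence_start = starts,
                            peptide_cys_position = as.integer(peptide_cys_positions))
  out$accession <- protein$accession
  out$position <- out$occurrence_start - 1L + out$peptide_cys_position
  out$ambiguous <- length(starts) > 1L
  out[, c("accession", "occurrence_start", "peptide_cys_position",
          "position", "ambiguous")]
}

#' Map all peptides of a table onto cysteine sites of a proteome
#'
#' @param x Measurement or call tibble with `accession`, `peptide`,
#'   `cys_positions` (list), `key` columns.
#' @param proteome Protein tibble as from [read_fasta()].
#' @return Site tibble: one row per (key, occurrence, cysteine) with
#'   protein `position` and `ambiguous` flag. Keys whose accession is
#'   absent from the proteome are dropped with a warning.
#' @export
map_table_sites <- function(x, proteome) {
  pep <- dplyr::distinct(
    tibble::tibble(key = x$key, accession = x$accession,
                   peptide = x$peptide, cys_positions = x$cys_positions),
    .data$key, .keep_all = TRUE
  )
  known <- pep$accession %in% proteome$accession
  if (any(!known)) {
    warning(sum(!known), " peptide key(s) reference accessions absent from ",
            "the protein database; retained without site coordinates")
  }
  pep <- pep[known, ]
  if (nrow(pep) == 0L) {
    return(tibble::tibble(key = character(), accession = character(),
                          peptide = character(), occurrence_start = integer(),
                          peptide_cys_position = integer(), position = integer(),
                          ambiguous = logical()))
  }
  idx <- match(pep$accession, proteome$accession)
  maps <- purrr::pmap(
    list(pep$peptide, pep$cys_positions, idx, pep$key),
    function(p, cys, i, k) {
      m <- map_peptide_to_protein(p, cys, proteome[i, ])
      m$key <- k
      m$peptide <- p
      m
    }
  )
  out <- dplyr::bind_rows(maps)
  out[, c("key", "accession", "peptide", "occurrence_start",
          "peptide_cys_position", "position", "ambiguous")]
}

#' Write a results table deterministically
#'
#' Writes tab-separated results with a fixed column order and rows sorted
#' by accession, then site position, then peptide (whichever of those
#' columns are present), so repeated runs produce byte-identical files.
#' Doubles are written in shortest round-trip representation and survive a
#' read back unchanged.
#'
#' @param results Nonempty data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(results, path) {
  if (is.null(results) || nrow(results) == 0L) {
    stop("refusing to write empty results table")
  }
  out <- results
  is_list <- vapply(out, is.list, logical(1))
  out[is_list] <- lapply(out[is_list],
                         function(col) vapply(col, paste, character(1), collapse = ";"))
  sort_cols <- intersect(c("accession", "position", "peptide", "set_id", "key"),
                         names(out))
  if (length(sort_cols)) {
    out <- out[do.call(order, out[sort_cols]), , drop = FALSE]
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read back a results table written by [write_results_table()]
#'
#' @param path Path to the TSV file.
#' @return A tibble.
#' @export
read_results_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
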