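#' Overlap (Venn) of two identifier sets
#'
#' Partitions two hit sets (e.g. significant proteins from two study arms)
#' into exclusive and shared counts and reports the shared fraction of the
#' first set.
#'
#' @param set_a,set_b Character vectors of identifiers (duplicates
#'   ignored). `set_a` must be nonempty.
#' @return List with `only_a`, `only_b`, `shared` (counts),
#'   `shared_ids`, and `shared_fraction_a` = shared / |A|.
#' @examples
#' overlap_sets(paste0("p", 1:79), paste0("p", 47:140))
#' @export
overlap_sets <- function(set_a, set_b) {
  a <- unique(set_a)
  b <- unique(set_b)
  if (length(a) == 0L) stop("set_a is empty; shared fraction undefined")
  shared <- intersect(a, b)
  list(
    only_a = length(setdiff(a, b)),
    only_b = length(setdiff(b, a)),
    shared = length(shared),
    shared_ids = sort(shared),
    shared_fraction_a = length(shared) / length(a)
  )
}

#' Read annotation sets from a GMT file
#'
#' GMT lines are `set_id <TAB> label <TAB> member1 <TAB> member2 ...`.
#'
#' @param path Path to a GMT file.
#' @return Tibble with `set_id`, `label`, `members` (list of character
#'   vectors).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad)) {
    stop("GMT line(s) without members: ", paste(bad, collapse = ", "))
  }
  tibble::tibble(
    set_id = vapply(parts, `[[`, character(1), 1L),
    label = vapply(parts, `[[`, character(1), 2L),
    members = lapply(parts, function(x) unique(x[-(1:2)]))
  )
}

#' Write annotation sets to a GMT file
#'
#' @param sets Tibble with `set_id`, `label`, `members` (list).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- mapply(function(id, lab, mem) {
    paste(c(id, lab, mem), collapse = "\t")
  }, sets$set_id, sets$label, sets$members)
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation analysis
#'
#' For each annotation set, tests whether the hit set over-represents the
#' set's members relative to the declared universe: the p-value is the
#' hypergeometric upper tail P(X >= k) with k the hit/set overlap, K the
#' set size (after intersection with the universe), n the number of hits,
#' and N the universe size. Benjamini-Hochberg q-values are computed
#' across the tested sets.
#'
#' @param hits Character vector of hit identifiers; must be a subset of
#'   `universe`.
#' @param annotation_sets Tibble as from [read_gmt()].
#' @param universe Character vector: the background (conventionally all
#'   quantified features, not all significant ones).
#' @return Tibble sorted by p then set_id: `set_id`, `label`, `k_overlap`,
#'   `n_hits`, `K_setsize`, `N_universe`, `p_value`, `q_value`.
#' @export
hypergeometric_enrichment <- function(hits, annotation_sets, universe) {
  hits <- unique(hits)
  universe <- unique(universe)
  stray <- setdiff(hits, universe)
  if (length(stray)) {
    stop("hit(s) outside the declared universe: ",
         paste(head(stray, 10L), collapse = ", "),
         if (length(stray) > 10L) ", ..." else "")
  }
  N <- length(universe)
  n <- length(hits)
  res <- purrr::map2(annotation_sets$set_id, annotation_sets$members,
                     function(id, mem) {
    mem <- intersect(unique(mem), universe)
    K <- length(mem)
    k <- length(intersect(hits, mem))
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    tibble::tibble(set_id = id, k_overlap = k, n_hits = n,
                   K_setsize = K, N_universe = N, p_value = min(p, 1))
  })
  out <- dplyr::bind_rows(res)
  out$label <- annotation_sets$label[match(out$set_id, annotation_sets$set_id)]
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[, c("set_id", "label", "k_overlap", "n_hits", "K_setsize",
                 "N_universe", "p_value", "q_value")]
  dplyr::arrange(out, .data$p_value, .data$set_id)
}

#' Joint protein + metabolite pathway over-representation
#'
#' Pools the protein and metabolite universes into one background (tagging
#' each identifier by kind so the two namespaces cannot collide) and runs
#' a single hypergeometric test per pathway on the pooled hit set, a
#' transparent stand-in for topology-weighted joint pathway tools.
#' Per-kind overlap counts are also reported.
#'
#' @param protein_hits,metabolite_hits Hit identifiers per kind.
#' @param pathway_sets Tibble as from [read_gmt()]; members may mix both
#'   kinds (untagged; kind is resolved by universe membership).
#' @param protein_universe,metabolite_universe Backgrounds per kind. An
#'   identifier present in both universes is an error (tag your inputs).
#' @return Tibble like [hypergeometric_enrichment()] output plus
#'   `k_protein`, `k_metabolite`.
#' @export
joint_pathway_enrichment <- function(protein_hits, metabolite_hits,
                                     pathway_sets,
                                     protein_universe, metabolite_universe) {
  clash <- intersect(unique(protein_universe), unique(metabolite_universe))
  if (length(clash)) {
    stop("identifier(s) present in both universes (tag by kind): ",
         paste(head(clash, 10L), collapse = ", "))
  }
  tag <- function(x, kind) {
    if (length(x) == 0L) return(character(0))  # paste0 would coerce to ""
    paste0(kind, ":", x)
  }
  uni <- c(tag(unique(protein_universe), "protein"),
           tag(unique(metabolite_universe), "metabolite"))
  hits <- c(tag(unique(protein_hits), "protein"),
            tag(unique(metabolite_hits), "metabolite"))
  tagged_sets <- pathway_sets
  tagged_sets$members <- lapply(pathway_sets$members, function(mem) {
    mem <- unique(mem)
    c(tag(intersect(mem, protein_universe), "protein"),
      tag(intersect(mem, metabolite_universe), "metabolite"))
  })
  out <- hypergeometric_enrichment(hits, tagged_sets, uni)
  counts <- purrr::map(tagged_sets$members, function(mem) {
    ov <- intersect(hits, mem)
    c(k_protein = sum(startsWith(ov, "protein:")),
      k_metabolite = sum(startsWith(ov, "metabolite:")))
  })
  cm <- do.call(rbind, counts)
  idx <- match(out$set_id, tagged_sets$set_id)
  out$k_protein <- as.integer(cm[idx, "k_protein"])
  out$k_metabolite <- as.integer(cm[idx, "k_metabolite"])
  out
}
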