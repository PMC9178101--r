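# Time-stamped re-audit of classified variants against a later database
# snapshot: which locally classified (previously unpublished) variants have
# since been submitted, how the submitted classifications compare, and
# whether the overlap is larger than chance under a hypergeometric model.

#' Hypergeometric enrichment probability
#'
#' Probability of observing at least (`tail = "upper"`, the default) or at
#' most (`tail = "lower"`) `n_overlap` of `n_query` drawn variants among the
#' `n_added` newly submitted ones, when draws come from a universe of
#' `n_universe` variants. The upper tail is the enrichment convention:
#' P(X >= n_overlap) for X ~ Hypergeometric(`n_universe`, `n_added`,
#' `n_query`).
#'
#' @param n_universe total variants in the union snapshot.
#' @param n_added newly submitted variants (successes in the population).
#' @param n_query locally classified variants (number of draws).
#' @param n_overlap query variants found among the additions.
#' @param tail `"upper"` (enrichment, default) or `"lower"` (depletion).
#' @return a probability in \[0, 1\].
#' @export
#' @examples
#' hypergeometric_enrichment(10, 5, 4, 4) # 5/210
hypergeometric_enrichment <- function(n_universe, n_added, n_query, n_overlap,
                                      tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  counts <- c(n_universe = n_universe, n_added = n_added,
              n_query = n_query, n_overlap = n_overlap)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (n_added > n_universe || n_query > n_universe ||
      n_overlap > n_query || n_overlap > n_added) {
    stop("inconsistent counts: need n_added, n_query <= n_universe and ",
         "n_overlap <= min(n_added, n_query)", call. = FALSE)
  }
  if (tail == "upper") {
    stats::phyper(n_overlap - 1, n_added, n_universe - n_added, n_query,
                  lower.tail = FALSE)
  } else {
    stats::phyper(n_overlap, n_added, n_universe - n_added, n_query,
                  lower.tail = TRUE)
  }
}

#' Compare locally classified variants against a later snapshot
#'
#' The classified variants were unpublished relative to the baseline extract;
#' this audit checks which of them appear in the updated extract, builds a
#' per-variant concordance table (local classification vs snapshot
#' classification and review stars), and computes the hypergeometric
#' enrichment probability of the overlap. A classified variant found in the
#' baseline contradicts its unpublished status and is a hard error.
#'
#' Concordance: both classifications in \{Pathogenic, Likely Pathogenic\}, or
#' both Uncertain (including "Conflicting Interpretations of Pathogenicity",
#' which ClinVar uses for unresolved submissions).
#'
#' @param classified tibble of classified variants with columns `key`,
#'   `category` (local classification), `gene`, `cdna_change`,
#'   `protein_change` (see [classified_variants()]). Matching against the
#'   snapshots uses the same representation-aware rules as the
#'   published/unpublished comparison, so a protein-only registry variant
#'   can be found in an update whose names are c.-anchored.
#' @param baseline converted baseline extract (see [convert_extract()]).
#' @param updated converted updated extract.
#' @param tail tail convention passed to [hypergeometric_enrichment()].
#' @return an object of class `snapshot_comparison`: a list with counts
#'   (`n_universe`, `n_added`, `n_query`, `n_overlap`), `p_value`, and
#'   `concordance` (one row per overlapping variant).
#' @export
compare_snapshots <- function(classified, baseline, updated, tail = "upper") {
  stopifnot(all(c("key", "category", "gene", "cdna_change", "protein_change")
                %in% names(classified)))
  base_keys <- unique(baseline$key)
  upd_keys <- unique(updated$key)
  base_hits <- match_in_extract(classified$gene, classified$cdna_change,
                                classified$protein_change, baseline)
  if (any(lengths(base_hits) > 0)) {
    clash <- classified$key[lengths(base_hits) > 0]
    stop("classified variant(s) present in the baseline extract ",
         "(contradicts unpublished status): ",
         paste(utils::head(clash, 5), collapse = ", "), call. = FALSE)
  }
  added <- updated[!(updated$key %in% base_keys), , drop = FALSE]
  universe_keys <- union(base_keys, upd_keys)

  upd_hits <- match_in_extract(classified$gene, classified$cdna_change,
                               classified$protein_change, added)
  found <- lengths(upd_hits) > 0
  idx <- vapply(upd_hits[found], `[`, integer(1), 1)
  concordance <- tibble::tibble(
    key = classified$key[found],
    name = added$name[idx],
    snapshot_classification = added$significance[idx],
    review_status = added$review_status[idx],
    local_classification = classified$category[found]
  )
  plp <- c("Pathogenic", "Likely Pathogenic")
  vus <- c("Uncertain Significance",
           "Conflicting Interpretations of Pathogenicity")
  concordance$concordant <-
    (concordance$snapshot_classification %in% plp &
       concordance$local_classification %in% plp) |
    (concordance$snapshot_classification %in% vus &
       concordance$local_classification %in% vus)
  concordance <- concordance[order(concordance$key), , drop = FALSE]

  n_universe <- length(universe_keys)
  n_added <- length(unique(added$key))
  n_query <- length(unique(classified$key))
  n_overlap <- nrow(concordance)
  structure(list(
    n_universe = n_universe,
    n_added = n_added,
    n_query = n_query,
    n_overlap = n_overlap,
    p_value = hypergeometric_enrichment(n_universe, n_added, n_query,
                                        n_overlap, tail = tail),
    concordance = concordance
  ), class = "snapshot_comparison")
}

#' @export
print.snapshot_comparison <- function(x, ...) {
  cat(sprintf(
    "Snapshot comparison: %d of %d classified variants found among %d additions\n",
    x$n_overlap, x$n_query, x$n_added))
  cat(sprintf("Universe: %d variants; enrichment p = %.3g\n",
              x$n_universe, x$p_value))
  if (nrow(x$concordance) > 0) {
    cat(sprintf("Concordant: %d / %d\n",
                sum(x$concordance$concordant), nrow(x$concordance)))
  }
  invisible(x)
}
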