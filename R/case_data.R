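# Stage 1: case-level review of the registry table — partition by disorder
# category and disease, count subjects, and harvest variant submissions.

#' Partition a registry table by disease
#'
#' Splits the subject table into disease-specific tables. Rows whose disease
#' code is missing, or absent from `diseases` when a disease list is given,
#' are quarantined (kept in a separate table and reported), never silently
#' dropped.
#'
#' @param subjects subject-level registry tibble with `disease` and
#'   `category` columns.
#' @param diseases optional character vector of known disease codes.
#' @return a list with `tables` (named list of per-disease tibbles), `counts`
#'   (tibble of disease, category, n_subjects), `category_counts` (diseases
#'   and subjects per disorder category) and `quarantined`.
#' @export
partition_by_disease <- function(subjects, diseases = NULL) {
  known <- if (is.null(diseases)) unique(stats::na.omit(subjects$disease))
           else diseases
  bad <- is.na(subjects$disease) | !(subjects$disease %in% known)
  quarantined <- subjects[bad, , drop = FALSE]
  if (nrow(quarantined) > 0) {
    message(nrow(quarantined), " row(s) with unknown disease code quarantined")
  }
  good <- subjects[!bad, , drop = FALSE]
  tables <- split(good, factor(good$disease, levels = sort(known)))
  counts <- dplyr::summarise(
    dplyr::group_by(good, .data$disease, .data$category),
    n_subjects = dplyr::n(), .groups = "drop")
  # carry diseases with zero subjects so totals stay auditable
  missing <- setdiff(known, counts$disease)
  if (length(missing) > 0) {
    counts <- dplyr::bind_rows(
      counts,
      tibble::tibble(disease = missing, category = NA_character_,
                     n_subjects = 0L))
  }
  counts <- dplyr::arrange(counts, .data$disease)
  category_counts <- dplyr::summarise(
    dplyr::group_by(counts[counts$n_subjects > 0, ], .data$category),
    n_diseases = dplyr::n_distinct(.data$disease),
    n_subjects = sum(.data$n_subjects), .groups = "drop")
  list(tables = tables, counts = counts, category_counts = category_counts,
       quarantined = quarantined)
}

#' Harvest variant observations from subject records
#'
#' Each subject contributes up to two raw variant strings (`variant1`,
#' `variant2`). Every non-empty, non-placeholder string becomes one
#' observation (subject x allele x normalized variant); placeholder tokens
#' are filtered and counted. A subject is genotyped when it has at least one
#' valid observation. Conservation holds: filtered tokens + observations +
#' empty fields = total raw variant fields.
#'
#' @param subjects subject tibble (whole cohort or one disease table) with
#'   columns `subject_id`, `disease`, `category`, `gene`, `variant1`,
#'   `variant2`.
#' @param references optional reference-sequence tibble; when given, stated
#'   reference residues are validated ([validate_reference()]).
#' @param invalid_tokens see [default_invalid_tokens()].
#' @return a list with `observations` (one row per harvested variant
#'   observation, carrying all parser columns plus `subject_id`,
#'   `allele_index`), `filtered` (invalid-token fields), `n_empty`,
#'   `genotyped_ids`, and `n_genotyped`.
#' @export
harvest_variants <- function(subjects, references = NULL,
                             invalid_tokens = default_invalid_tokens()) {
  stopifnot(all(c("subject_id", "disease", "gene", "variant1", "variant2")
                %in% names(subjects)))
  long <- tidyr::pivot_longer(
    subjects[, c("subject_id", "disease", "category", "gene",
                 "variant1", "variant2")],
    cols = c("variant1", "variant2"),
    names_to = "allele_index", values_to = "raw")
  long$allele_index <- ifelse(long$allele_index == "variant1", 1L, 2L)

  empty <- is.na(long$raw) | trimws(long$raw) == ""
  n_empty <- sum(empty)
  long <- long[!empty, , drop = FALSE]

  parsed <- parse_variant_string(long$raw, long$gene,
                                 invalid_tokens = invalid_tokens)
  parsed$subject_id <- long$subject_id
  parsed$disease <- long$disease
  parsed$category <- long$category
  parsed$allele_index <- long$allele_index

  filtered <- parsed[parsed$mapping_status == "invalid_token", , drop = FALSE]
  obs <- parsed[parsed$mapping_status != "invalid_token", , drop = FALSE]
  if (!is.null(references)) {
    obs <- validate_reference(obs, references)
  }
  # unparseable strings stay observations (they are counted, audited and
  # reported) but need a stable key so deduplication can group them
  nokey <- is.na(obs$key)
  obs$key[nokey] <- paste0(toupper(obs$gene[nokey]), "|raw:",
                           tolower(trimws(obs$raw[nokey])))
  genotyped_ids <- unique(obs$subject_id)
  list(observations = obs,
       filtered = filtered,
       n_empty = n_empty,
       genotyped_ids = genotyped_ids,
       n_genotyped = length(genotyped_ids))
}
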