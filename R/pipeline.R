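# End-to-end orchestration: case review -> parsing/validation -> extract
# matching and deduplication -> evidence assignment -> combining-rule
# classification -> summaries.

#' Run the full classification pipeline
#'
#' Stages: (1) partition the registry table by disease and harvest variant
#' observations, validating stated reference residues when reference
#' proteins are given; (2) convert the extract and match every distinct
#' variant (published vs unpublished); (3) assign ACMG/AMP evidence criteria
#' to the unpublished variants from the longitudinal clinical data,
#' predictor tables and secondary database; (4) combine criteria into
#' classifications; (5) attach a run summary.
#'
#' @param subjects subject-level registry tibble.
#' @param extract raw baseline extract tibble (`Name`, `Gene`, ... columns)
#'   or an already-converted extract.
#' @param references optional reference-protein tibble.
#' @param predictions optional predictor-score tibble.
#' @param secondary_db optional secondary-database tibble.
#' @param inheritance optional disease-inheritance tibble.
#' @param overrides optional manual-override tibble (`key`, `code`,
#'   `action`).
#' @param strict_lp3 see [acmg_rule_table()].
#' @param invalid_tokens see [default_invalid_tokens()].
#' @param metadata optional named list recorded in the summary (seed,
#'   config digest, snapshot dates).
#' @return an object of class `nbs_run`: a list with `subjects`,
#'   `partition`, `observations`, `filtered`, `n_genotyped`, `distinct`
#'   (published flags attached), `profiles` (criteria + classification per
#'   unpublished variant), `summary`, `metadata`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_subjects = 320, seed = 7))
#' run <- run_pipeline(cohort$subjects, cohort$extract,
#'                     references = cohort$references,
#'                     predictions = cohort$predictions,
#'                     secondary_db = cohort$secondary_db,
#'                     inheritance = cohort$inheritance)
#' run$summary
run_pipeline <- function(subjects, extract, references = NULL,
                         predictions = NULL, secondary_db = NULL,
                         inheritance = NULL, overrides = NULL,
                         strict_lp3 = FALSE,
                         invalid_tokens = default_invalid_tokens(),
                         metadata = list()) {
  partition <- partition_by_disease(subjects)
  harvest <- harvest_variants(subjects, references = references,
                              invalid_tokens = invalid_tokens)
  extract_conv <- if ("key" %in% names(extract)) extract else
    convert_extract(extract)

  distinct <- deduplicate(harvest$observations)
  distinct <- match_variants(distinct, extract_conv)

  unpub <- distinct[!distinct$published, , drop = FALSE]
  profiles <- assign_criteria(unpub, harvest$observations, subjects,
                              extract_conv, predictions = predictions,
                              secondary_db = secondary_db,
                              inheritance = inheritance,
                              overrides = overrides)
  profiles <- classify_profiles(profiles, strict_lp3 = strict_lp3)

  run <- structure(list(
    subjects = subjects,
    partition = partition,
    observations = harvest$observations,
    filtered = harvest$filtered,
    n_genotyped = harvest$n_genotyped,
    distinct = distinct,
    profiles = profiles,
    metadata = metadata
  ), class = "nbs_run")
  run$summary <- summarize_run(run)
  run
}

#' @export
print.nbs_run <- function(x, ...) {
  print(x$summary)
  invisible(x)
}

#' Classified variants for snapshot re-audit
#'
#' The subset of a run's profiles that received a classification (unmapped
#' variants are excluded: they were never classified), in the shape
#' [compare_snapshots()] expects.
#'
#' @param run an `nbs_run`.
#' @return tibble with `key`, `category`, `gene`, `cdna_change`,
#'   `protein_change`.
#' @export
classified_variants <- function(run) {
  p <- run$profiles[run$profiles$category != "Excluded-Unmapped", ,
                    drop = FALSE]
  idx <- match(p$key, run$distinct$key)
  tibble::tibble(key = p$key, category = p$category,
                 gene = run$distinct$gene[idx],
                 cdna_change = run$distinct$cdna_change[idx],
                 protein_change = run$distinct$protein_change[idx])
}
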