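# Stage 5: per-disease text reports and study-level summary tables
# (criterion counts and classification breakdown with percentages).

#' Round half-up
#'
#' Percentage rounding convention used throughout the reports: half-way
#' cases round away from zero (base R's `round()` rounds to even).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percentage with a division-by-zero guard
#'
#' `100 * count / denom`, rounded half-up to one decimal; `NA` (undefined,
#' not zero) when the denominator is zero.
#'
#' @param count numerator(s).
#' @param denom denominator.
#' @param digits decimal places.
#' @return numeric vector.
#' @export
pct <- function(count, denom, digits = 1) {
  if (length(denom) == 1 && (is.na(denom) || denom == 0)) {
    return(rep(NA_real_, length(count)))
  }
  round_half_up(100 * count / denom, digits)
}

#' Summarize a pipeline run
#'
#' Emits the study-level summary: per-disease subject/genotyping/variant
#' counts, the criterion-assignment table (counts and percentages over the
#' distinct unpublished variants), the classification breakdown by combining
#' rule, excluded-variant tallies, and run metadata. Percentages recompute
#' exactly from the counts under the half-up rounding rule; with zero
#' unpublished variants all percentages are reported as `NA` (undefined).
#'
#' @param run an `nbs_run` from [run_pipeline()].
#' @return an object of class `run_summary`.
#' @export
summarize_run <- function(run) {
  distinct <- run$distinct
  unpub <- distinct[!distinct$published, , drop = FALSE]
  n_unpub <- nrow(unpub)

  per_disease <- dplyr::left_join(
    run$partition$counts,
    dplyr::summarise(
      dplyr::group_by(run$observations, .data$disease),
      n_genotyped = dplyr::n_distinct(.data$subject_id), .groups = "drop"),
    by = "disease")
  per_disease$n_genotyped[is.na(per_disease$n_genotyped)] <- 0L
  by_dis <- tidyr::unnest(distinct[, c("key", "published", "diseases")],
                          cols = "diseases")
  dis_var <- dplyr::summarise(
    dplyr::group_by(by_dis, disease = .data$diseases),
    n_distinct_variants = dplyr::n(),
    n_published = sum(.data$published),
    n_unpublished = sum(!.data$published), .groups = "drop")
  per_disease <- dplyr::left_join(per_disease, dis_var, by = "disease")
  for (col in c("n_distinct_variants", "n_published", "n_unpublished")) {
    per_disease[[col]][is.na(per_disease[[col]])] <- 0L
  }

  codes <- sort(unique(unlist(run$profiles$criteria)))
  criteria_table <- tibble::tibble(
    code = codes,
    n = vapply(codes, function(cd) {
      sum(vapply(run$profiles$criteria, function(x) cd %in% x, logical(1)))
    }, integer(1)),
    pct = NA_real_)
  criteria_table$pct <- pct(criteria_table$n, n_unpub)

  cls <- run$profiles
  lab <- ifelse(cls$category %in% c("Pathogenic", "Likely Pathogenic"),
                cls$rule_label, cls$category)
  lab_levels <- c(acmg_rule_table()$label[acmg_rule_table()$axis == "pathogenic"],
                  "Benign", "Likely Benign",
                  "Uncertain Significance", "Excluded-Unmapped")
  tab <- table(factor(lab, levels = lab_levels))
  classification_table <- tibble::tibble(
    label = names(tab)[tab > 0 | names(tab) %in%
                         c("Uncertain Significance", "Excluded-Unmapped")],
    n = as.integer(tab[tab > 0 | names(tab) %in%
                         c("Uncertain Significance", "Excluded-Unmapped")]))
  classification_table$pct <- pct(classification_table$n, n_unpub)

  n_plp <- sum(cls$category %in% c("Pathogenic", "Likely Pathogenic"))

  structure(list(
    n_subjects = nrow(run$subjects),
    n_genotyped = run$n_genotyped,
    genotyped_pct = pct(run$n_genotyped, nrow(run$subjects)),
    n_distinct = nrow(distinct),
    n_published = sum(distinct$published),
    n_unpublished = n_unpub,
    unpublished_pct = pct(n_unpub, nrow(distinct)),
    n_unmapped = sum(unpub$mapping_status == "unmapped_reference_mismatch"),
    n_invalid_tokens = nrow(run$filtered),
    per_disease = per_disease,
    zero_genotype_diseases =
      per_disease$disease[per_disease$n_genotyped == 0],
    zero_unpublished_diseases =
      per_disease$disease[per_disease$n_genotyped > 0 &
                            per_disease$n_unpublished == 0],
    criteria_table = criteria_table,
    classification_table = classification_table,
    n_pathogenic_or_likely = n_plp,
    pathogenic_or_likely_pct = pct(n_plp, n_unpub),
    metadata = run$metadata
  ), class = "run_summary")
}

#' @export
print.run_summary <- function(x, ...) {
  cat(sprintf("Subjects: %d (%s%% genotyped: %d)\n", x$n_subjects,
              format(x$genotyped_pct), x$n_genotyped))
  cat(sprintf("Distinct variants: %d (published %d, unpublished %d = %s%%)\n",
              x$n_distinct, x$n_published, x$n_unpublished,
              format(x$unpublished_pct)))
  cat(sprintf("Unmapped (reference mismatch): %d; placeholder tokens: %d\n",
              x$n_unmapped, x$n_invalid_tokens))
  cat(sprintf("Classified Pathogenic / Likely Pathogenic: %d (%s%%)\n",
              x$n_pathogenic_or_likely, format(x$pathogenic_or_likely_pct)))
  cat("\nClassification breakdown:\n")
  print(as.data.frame(x$classification_table), row.names = FALSE)
  invisible(x)
}

#' Write per-disease plain-text reports
#'
#' One `.txt` file per disease with the subject total, the published and
#' unpublished variant lists, per-variant evidence provenance, and an
#' exclusions section (reference-mismatch variants with the reason,
#' placeholder-token tally). Ordering is stable, so regeneration from the
#' same inputs is byte-identical.
#'
#' @param run an `nbs_run` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return character vector of files written, invisibly.
#' @export
write_disease_report <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  prof_by_key <- run$profiles
  for (dis in sort(unique(run$subjects$disease))) {
    subs <- run$subjects[run$subjects$disease == dis, , drop = FALSE]
    obs <- run$observations[run$observations$disease == dis, , drop = FALSE]
    dis_keys <- sort(unique(obs$key))
    dd <- run$distinct[run$distinct$key %in% dis_keys, , drop = FALSE]
    pub <- dd[dd$published, , drop = FALSE]
    unpub <- dd[!dd$published &
                  dd$mapping_status == "mapped", , drop = FALSE]
    excl <- dd[dd$mapping_status == "unmapped_reference_mismatch", ,
               drop = FALSE]
    n_tok <- sum(run$filtered$disease == dis)

    lines <- c(
      sprintf("Disease report: %s", dis),
      sprintf("Total subjects: %d", nrow(subs)),
      sprintf("Genotyped subjects: %d",
              length(unique(obs$subject_id))),
      "",
      sprintf("Published variants (%d):", nrow(pub)))
    lines <- c(lines, if (nrow(pub) > 0) {
      sprintf("  %s (subjects: %d)", pub$key, pub$n_subjects)
    } else "  (none)")
    lines <- c(lines, "", sprintf("Unpublished variants (%d):", nrow(unpub)))
    if (nrow(unpub) > 0) {
      for (k in unpub$key) {
        p <- prof_by_key[prof_by_key$key == k, , drop = FALSE]
        crit <- if (nrow(p) > 0 && length(p$criteria[[1]]) > 0) {
          paste(sort(p$criteria[[1]]), collapse = ", ")
        } else "(no criteria)"
        cls_txt <- if (nrow(p) > 0) {
          sprintf("%s [%s]", p$category, p$rule_label)
        } else "(unclassified)"
        lines <- c(lines,
                   sprintf("  %s", k),
                   sprintf("    criteria: %s", crit),
                   sprintf("    classification: %s", cls_txt))
        if (nrow(p) > 0 && length(p$provenance[[1]]) > 0) {
          pv <- p$provenance[[1]]
          lines <- c(lines, sprintf("    evidence %s: %s", names(pv), pv))
        }
      }
    } else {
      lines <- c(lines, "  (none)")
    }
    lines <- c(lines, "", "Exclusions:",
               sprintf("  Placeholder variant fields filtered: %d", n_tok))
    if (nrow(excl) > 0) {
      notes <- vapply(excl$key, function(k) {
        o <- obs[obs$key == k, , drop = FALSE]
        nn <- stats::na.omit(o$mismatch_note)
        if (length(nn) > 0) nn[1] else "reference residue mismatch"
      }, character(1))
      lines <- c(lines, sprintf("  %s: unmapped (%s), no criteria assigned",
                                excl$key, notes))
    } else {
      lines <- c(lines, "  (no unmapped variants)")
    }
    path <- file.path(dir, paste0("report_", dis, ".txt"))
    writeLines(lines, path)
    files <- c(files, path)
  }
  invisible(files)
}
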