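#!/usr/bin/env Rscript
# Step 3 — time-stamped re-audit against the updated extract snapshot.
#
# The classified (previously unpublished) variants are checked for
# inclusion among the update's additions; overlapping variants get a
# concordance row (local vs snapshot classification, review stars) and the
# overlap is tested for enrichment with an upper-tail hypergeometric test.

suppressPackageStartupMessages({
  library(nbsvar)
  library(readr)
})

cohort_dir <- "results/cohort"
cls_dir <- "results/classification"
out_dir <- "results/timestamp"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

baseline <- convert_extract(read_csv(
  file.path(cohort_dir, "clinvar_extract.csv"), show_col_types = FALSE))
updated <- convert_extract(read_csv(
  file.path(cohort_dir, "clinvar_extract_updated.csv"),
  show_col_types = FALSE))
profiles <- read_csv(file.path(cls_dir, "criteria_profiles.csv"),
                     show_col_types = FALSE)
distinct <- read_csv(file.path(cls_dir, "distinct_variants.csv"),
                     show_col_types = FALSE)

cls <- profiles[profiles$category != "Excluded-Unmapped", ]
idx <- match(cls$key, distinct$key)
classified <- tibble::tibble(
  key = cls$key, category = cls$category,
  gene = distinct$gene[idx],
  cdna_change = distinct$cdna_change[idx],
  protein_change = distinct$protein_change[idx])

cmp <- compare_snapshots(classified, baseline, updated)
print(cmp)

write_csv(cmp$concordance, file.path(out_dir, "concordance.csv"))
jsonlite::write_json(
  list(n_universe = cmp$n_universe, n_added = cmp$n_added,
       n_query = cmp$n_query, n_overlap = cmp$n_overlap,
       p_value = cmp$p_value,
       n_concordant = sum(cmp$concordance$concordant)),
  file.path(out_dir, "snapshot_summary.json"),
  auto_unbox = TRUE, digits = NA)
cat("Concordance table and summary in", out_dir, "\n")
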