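# Shared fixtures, built in code at test time.

# A small cohort: 8 diseases x 20 subjects, fast to generate.
small_config <- function(seed = 42, ...) {
  cohort_config(
    n_diseases_per_category = c(amino_acid = 2, fatty_acid_oxidation = 2,
                                organic_acid = 2, other = 2),
    subjects_per_disease = 20,
    seed = seed,
    ...
  )
}

# Generate-once cache so several test files can share one small cohort.
.fixture_env <- new.env(parent = emptyenv())
small_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    .fixture_env$cohort <- generate_cohort(small_config())
  }
  .fixture_env$cohort
}
small_run <- function() {
  if (is.null(.fixture_env$run)) {
    co <- small_cohort()
    .fixture_env$run <- run_pipeline(
      co$subjects, co$extract, references = co$references,
      predictions = co$predictions, secondary_db = co$secondary_db,
      inheritance = co$inheritance,
      metadata = list(seed = co$config$seed))
  }
  .fixture_env$run
}

# A minimal converted-extract tibble built directly (bypasses CSV parsing).
mini_extract <- function(rows) {
  if (length(rows) == 0) {
    return(tibble::tibble(
      name = character(), gene = character(), transcript = character(),
      cdna_change = character(), protein_change = character(),
      protein_pos = integer(), protein_ref = character(),
      protein_alt = character(), consequence = character(),
      significance = character(), review_status = integer(),
      key = character(), snapshot_date = NA[0]))
  }
  # rows: list of lists with gene, cdna, protein (single letter), sig
  out <- lapply(rows, function(r) {
    p <- if (is.null(r$protein)) {
      list(change = NA_character_, pos = NA_integer_,
           ref = NA_character_, alt = NA_character_, cons = "unknown")
    } else {
      m <- regmatches(r$protein,
                      regexec("^([A-Z*])(\\d+)([A-Z*]|fs)$", r$protein))[[1]]
      cons <- if (m[4] == "*") "nonsense" else if (m[4] == "fs") "frameshift"
        else if (m[2] == m[4]) "synonymous" else "missense"
      list(change = r$protein, pos = as.integer(m[3]), ref = m[2],
           alt = m[4], cons = cons)
    }
    tibble::tibble(
      name = paste0("NM_000001.1(", r$gene, "):",
                    if (!is.null(r$cdna)) r$cdna else "c.1A>G"),
      gene = toupper(r$gene),
      transcript = "NM_000001.1",
      cdna_change = if (is.null(r$cdna)) NA_character_ else r$cdna,
      protein_change = p$change, protein_pos = p$pos,
      protein_ref = p$ref, protein_alt = p$alt, consequence = p$cons,
      significance = r$sig,
      review_status = 1L,
      key = variant_key(r$gene,
                        if (is.null(r$cdna)) NA_character_ else r$cdna,
                        p$change),
      snapshot_date = NA)
  })
  dplyr::bind_rows(out)
}

# Minimal subject rows with the clinical-evidence fields the evidence module
# consumes.
mini_subjects <- function(ids, confirmed = TRUE) {
  n <- length(ids)
  tibble::tibble(
    subject_id = ids,
    disease = "AA01", category = "amino_acid", gene = "GENEA",
    confirmed_dx = rep_len(confirmed, n),
    nbs_positive = TRUE,
    fh_affected_relative = FALSE,
    fh_affected_carrier_allele1 = FALSE,
    fh_affected_carrier_allele2 = FALSE,
    de_novo_allele1 = FALSE,
    de_novo_allele2 = FALSE,
    parentage_confirmed = FALSE,
    phase_tested = FALSE,
    alleles_in_trans = NA,
    variant1 = "", variant2 = "")
}

# Observations for given (subject, allele, raw) triples in one gene/disease.
mini_observations <- function(subject_id, allele_index, raw, gene = "GENEA",
                              disease = "AA01") {
  parsed <- parse_variant_string(raw, gene)
  parsed$subject_id <- subject_id
  parsed$disease <- disease
  parsed$category <- "amino_acid"
  parsed$allele_index <- allele_index
  parsed
}
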