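test_that("config validation rejects bad fields by name", {
  expect_error(cohort_config(genotyping_rate = 1.5), "genotyping_rate")
  expect_error(cohort_config(dialect_mix = c(hgvs_c = 0.9,
                                             hgvs_c_spaced = 0.9,
                                             hgvs_p3 = 0, single_letter = 0)),
               "dialect_mix")
  expect_error(cohort_config(n_diseases_per_category = c(1, 2, 3)),
               "n_diseases_per_category")
  expect_error(cohort_config(subjects_per_disease = 0),
               "subjects_per_disease")
  expect_error(cohort_config(consequence_mix = c(null = 0.5,
                                                 synonymous = 0.2,
                                                 missense = 0.2)),
               "consequence_mix")
})

test_that("a zero genotyping rate yields no variant observations at all", {
  co <- generate_cohort(small_config(genotyping_rate = 0))
  h <- harvest_variants(co$subjects, references = co$references)
  expect_equal(nrow(h$observations), 0L)
  expect_equal(h$n_genotyped, 0L)
  expect_equal(nrow(co$manifest$variants), 0L)
})

test_that("disease layout and subject counts follow the config", {
  cfg <- cohort_config(n_diseases_per_category = c(amino_acid = 8,
                                                   fatty_acid_oxidation = 8,
                                                   organic_acid = 8,
                                                   other = 8),
                       subjects_per_disease = 20, seed = 3)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co$subjects), 640L)
  expect_equal(length(unique(co$subjects$disease)), 32L)
  expect_equal(as.integer(table(co$subjects$disease)), rep(20L, 32L))
  # each subject sits in exactly one disease, each disease in one category
  expect_equal(anyDuplicated(co$subjects$subject_id), 0L)
  expect_equal(nrow(unique(co$diseases[, c("disease", "category")])), 32L)
})

test_that("identical config and seed give identical cohorts", {
  co1 <- generate_cohort(small_config(seed = 7))
  co2 <- generate_cohort(small_config(seed = 7))
  expect_identical(co1$subjects, co2$subjects)
  expect_identical(co1$extract, co2$extract, ignore_attr = FALSE)
  expect_identical(co1$extract_updated, co2$extract_updated)
  expect_identical(co1$manifest$variants, co2$manifest$variants)
  expect_identical(co1$predictions, co2$predictions)
})

test_that("extract rows carry consistent HGVS names and standard significance terms", {
  ex <- generate_clinvar_extract("GCDH", n_variants_per_gene = 5, seed = 5)
  expect_equal(nrow(ex), 5L)
  expect_true(all(ex$Gene == "GCDH"))
  conv <- convert_extract(ex)
  expect_true(all(conv$gene == "GCDH"))
  allowed <- c("Benign", "Likely Benign", "Uncertain Significance",
               "Likely Pathogenic", "Pathogenic",
               "Conflicting Interpretations of Pathogenicity")
  big <- generate_clinvar_extract(c("G1", "G2", "G3"), 30, seed = 8)
  expect_true(all(big$`Clinical significance` %in% allowed))
  # c. position falls inside the codon of the p. position
  bc <- convert_extract(big)
  has_p <- !is.na(bc$protein_pos)
  cpos <- as.integer(sub("^c\\.(\\d+).*$", "\\1", bc$cdna_change[has_p]))
  expect_true(all(cpos >= 3 * bc$protein_pos[has_p] - 2 &
                    cpos <= 3 * bc$protein_pos[has_p]))
  expect_error(generate_clinvar_extract(character(0)), "empty gene list")
})

test_that("a planted ClinVar-style entry round-trips through the extract reader", {
  row <- tibble::tibble(
    Name = "NM_000159.4(GCDH):c.776C>T (p.Ser259Leu)",
    Gene = "GCDH", `Protein change` = "S259L",
    `Clinical significance` = "Likely Pathogenic", `Review status` = 1L)
  conv <- convert_extract(row)
  expect_equal(conv$gene, "GCDH")
  expect_equal(conv$cdna_change, "c.776C>T")
  expect_equal(conv$protein_change, "S259L")
  expect_equal(conv$significance, "Likely Pathogenic")
  expect_equal(conv$key, "GCDH|c.776C>T")
})

test_that("updated extracts plant exactly the requested overlap", {
  base <- generate_clinvar_extract(c("G1", "G2", "G3", "G4", "G5"), 20,
                                   seed = 9)
  refs <- generate_reference_sequences(c("G1", "G2", "G3", "G4", "G5"),
                                       seed = 10)
  overlap <- tibble::tibble(
    gene = c("G1", "G2", "G3", "G4", "G5", "G1", "G2", "G3"),
    transcript = "NM_000001.1",
    cdna_change = NA_character_,
    protein_pos = 401:408,
    protein_ref = substring(refs$protein[c(1:5, 1:3)], 401:408, 401:408),
    protein_alt = rep("W", 8),
    significance = rep(c("Pathogenic", "Uncertain Significance"), 4),
    review_status = rep(1L, 8))
  upd <- generate_updated_extract(base, 50, planted_overlap = overlap,
                                  seed = 11, references = refs)
  expect_equal(nrow(upd), 150L)
  # direct enumeration: exactly 8 of the query set among the additions
  conv_base <- convert_extract(base)
  conv_upd <- convert_extract(upd)
  added <- conv_upd[!(conv_upd$key %in% conv_base$key), ]
  qkeys <- paste0(overlap$gene, "|p.", overlap$protein_ref,
                  overlap$protein_pos, overlap$protein_alt)
  found <- vapply(seq_len(nrow(overlap)), function(i) {
    any(added$gene == overlap$gene[i] &
          added$protein_change == paste0(overlap$protein_ref[i],
                                         overlap$protein_pos[i],
                                         overlap$protein_alt[i]))
  }, logical(1))
  expect_equal(sum(found), 8L)

  # identity when nothing is added
  upd0 <- generate_updated_extract(base, 0, seed = 12)
  expect_equal(nrow(upd0), nrow(base))
  expect_equal(upd0$Name, base$Name)

  # planting a variant already in the baseline is a hard error
  clash <- conv_base[1, ]
  bad <- tibble::tibble(gene = clash$gene, transcript = clash$transcript,
                        cdna_change = clash$cdna_change,
                        protein_pos = clash$protein_pos,
                        protein_ref = clash$protein_ref,
                        protein_alt = clash$protein_alt,
                        significance = "Pathogenic", review_status = 1L)
  expect_error(generate_updated_extract(base, 10, planted_overlap = bad,
                                        seed = 13),
               "already present")
})

test_that("predictor tables cover missense variants only, with planted call patterns", {
  vars <- tibble::tibble(
    gene = c("G1", "G1", "G1", "G1"),
    protein_change = c("F256L", "F256F", "R10Q", "K5T"),
    consequence = c("missense", "synonymous", "missense", "missense"))
  pred <- generate_predictions(vars, seed = 1,
                               planted_call = c("deleterious", "none",
                                                "discordant", "neutral"))
  expect_equal(nrow(pred), 6L)  # three missense x two predictors
  expect_false("F256F" %in% pred$protein_change)
  f <- pred[pred$protein_change == "F256L", ]
  expect_equal(f$call, c("deleterious", "deleterious"))
  r <- pred[pred$protein_change == "R10Q", ]
  expect_setequal(r$call, c("deleterious", "neutral"))
  # concordance = 1 with all-deleterious planting: two deleterious per variant
  allv <- vars[vars$consequence == "missense", ]
  pred2 <- generate_predictions(allv, seed = 2, concordance = 1,
                                p_deleterious = 1)
  expect_true(all(pred2$call == "deleterious"))
  expect_equal(nrow(pred2), 2L * nrow(allv))
})

test_that("every rendered variant string decodes to its manifest entry", {
  co <- small_cohort()
  mv <- co$manifest$variants
  parsed <- parse_variant_string(mv$rendered, mv$gene)
  expect_equal(parsed$key, mv$key)
  expect_equal(parsed$consequence, mv$notation_consequence)
  # planted reference mismatches are exactly the ones validation flags
  checked <- validate_reference(parsed, co$references)
  expect_equal(checked$mapping_status == "unmapped_reference_mismatch",
               mv$mismatch)
})

test_that("realized genotyping and unpublished rates track the config at large n", {
  cfg <- cohort_config(
    n_diseases_per_category = c(amino_acid = 1, fatty_acid_oxidation = 1,
                                organic_acid = 1, other = 1),
    subjects_per_disease = 500, seed = 77)
  co <- generate_cohort(cfg)
  h <- harvest_variants(co$subjects, references = co$references)
  p_g <- cfg$genotyping_rate
  se_g <- sqrt(p_g * (1 - p_g) / nrow(co$subjects))
  expect_lt(abs(h$n_genotyped / nrow(co$subjects) - p_g), 3 * se_g)
  mv <- co$manifest$variants
  p_u <- cfg$unpublished_rate
  se_u <- sqrt(p_u * (1 - p_u) / nrow(mv))
  expect_lt(abs(mean(!mv$published) - p_u), 3 * se_u)
})

test_that("cohort artifacts round-trip through plain-text files", {
  co <- small_cohort()
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  subj <- readr::read_csv(file.path(dir, "subjects.csv"),
                          show_col_types = FALSE)
  expect_equal(nrow(subj), nrow(co$subjects))
  refs <- read_reference_fasta(file.path(dir, "references.fasta"))
  expect_equal(refs$gene, co$references$gene)
  expect_equal(refs$protein, co$references$protein)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(length(man$variants), nrow(co$manifest$variants))
  expect_equal(length(man$subjects), nrow(co$subjects))
})
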