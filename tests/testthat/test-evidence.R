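# Hand-built fixtures: one gene GENEA, autosomal recessive disease AA01.

ar_inheritance <- tibble::tibble(disease = "AA01", gene = "GENEA",
                                 inheritance = "AR")

test_that("PS3 and PP4 go to every mapped variant with confirmed supporters", {
  subj <- mini_subjects(c("S1", "S2"))
  obs <- mini_observations(c("S1", "S2"), c(1L, 1L), c("F256L", "A9T"))
  refs <- tibble::tibble(gene = "GENEA", transcript = "NM_000001.1",
                         protein = paste0("MAAAAAAAT",
                                          strrep("Q", 246), "F",
                                          strrep("Q", 50)))
  obs <- validate_reference(obs, refs)  # A9T mismatches (protein has T at 9)
  d <- deduplicate(obs)
  flag <- assign_global_criteria(d, subj)
  expect_equal(flag, d$mapping_status == "mapped")
  # unmapped variant gets nothing anywhere
  prof <- assign_criteria(d, obs, subj, mini_extract(list()),
                          inheritance = ar_inheritance)
  unm <- prof[prof$mapping_status == "unmapped_reference_mismatch", ]
  expect_equal(length(unm$criteria[[1]]), 0L)
})

test_that("an unconfirmed supporter withholds PS3/PP4 with a warning", {
  subj <- mini_subjects(c("S1", "S2"), confirmed = c(TRUE, FALSE))
  obs <- mini_observations(c("S1", "S2"), c(1L, 1L), c("F256L", "F256L"))
  d <- deduplicate(obs)
  expect_warning(flag <- assign_global_criteria(d, subj), "withheld")
  expect_false(flag)
})

test_that("PVS1 tracks the predicted-null consequence", {
  obs <- mini_observations(c("S1", "S2", "S3"), rep(1L, 3),
                           c("W123X", "F256L", "c.244+1G>A"))
  d <- deduplicate(obs)
  got <- setNames(assess_pvs1(d), d$key)
  expect_true(got[["GENEA|p.W123*"]])
  expect_false(got[["GENEA|p.F256L"]])
  expect_true(got[["GENEA|c.244+1G>A"]])
})

test_that("PM3 requires recessive inheritance and a pathogenic published partner", {
  extract <- mini_extract(list(
    list(gene = "GENEA", cdna = "c.100A>T", protein = "K34T",
         sig = "Pathogenic"),
    list(gene = "GENEA", cdna = "c.200G>A", protein = "R67H",
         sig = "Uncertain Significance")))
  subj <- mini_subjects(c("S1", "S2", "S3", "S4"))
  obs <- dplyr::bind_rows(
    mini_observations(c("S1", "S1"), c(1L, 2L), c("F256L", "K34T")),
    mini_observations(c("S2", "S2"), c(1L, 2L), c("A10V", "R67H")),
    mini_observations(c("S3", "S3"), c(1L, 2L), c("G20D", "Q40P")),
    mini_observations("S4", 1L, "P30L"))
  d <- deduplicate(obs)
  got <- setNames(assess_pm3(d, obs, extract, ar_inheritance), d$key)
  expect_true(got[["GENEA|p.F256L"]])   # partner Pathogenic
  expect_false(got[["GENEA|p.A10V"]])   # partner VUS
  expect_false(got[["GENEA|p.G20D"]])   # partner itself unpublished
  expect_false(got[["GENEA|p.P30L"]])   # single reported allele
  # same pairs under non-recessive inheritance: nothing
  dom <- tibble::tibble(disease = "AA01", gene = "GENEA",
                        inheritance = "AD")
  expect_false(any(assess_pm3(d, obs, extract, dom)))
})

test_that("PM5 needs a published pathogenic missense at the same residue with a different alt", {
  extract <- mini_extract(list(
    list(gene = "GENEA", cdna = "c.880C>T", protein = "R294W",
         sig = "Pathogenic"),
    list(gene = "GENEA", cdna = "c.700C>T", protein = "P234S",
         sig = "Benign")))
  obs <- mini_observations(c("S1", "S2", "S3"), rep(1L, 3),
                           c("R294Q", "P234L", "A50V"))
  d <- deduplicate(obs)
  got <- setNames(assess_pm5(d, extract), d$key)
  expect_true(got[["GENEA|p.R294Q"]])   # neighbour R294W is Pathogenic
  expect_false(got[["GENEA|p.P234L"]])  # neighbour is Benign
  expect_false(got[["GENEA|p.A50V"]])   # no same-residue entry
})

test_that("family history yields PP1 for segregation and PM6 for assumed de novo", {
  subj <- mini_subjects(c("S1", "S2", "S3"))
  subj$fh_affected_carrier_allele1[1] <- TRUE
  subj$de_novo_allele2[2] <- TRUE
  obs <- dplyr::bind_rows(
    mini_observations("S1", 1L, "F256L"),
    mini_observations(c("S2", "S2"), c(1L, 2L), c("A10V", "G20D")),
    mini_observations("S3", 1L, "P30L"))
  d <- deduplicate(obs)
  fam <- assess_family(d, obs, subj)
  got_pp1 <- setNames(fam$pp1, d$key)
  got_pm6 <- setNames(fam$pm6, d$key)
  expect_true(got_pp1[["GENEA|p.F256L"]])
  expect_true(got_pm6[["GENEA|p.G20D"]])
  expect_false(got_pm6[["GENEA|p.A10V"]])  # de novo flag sits on allele 2
  expect_false(got_pp1[["GENEA|p.P30L"]])  # empty family history
  # confirmed parentage suppresses PM6
  subj$parentage_confirmed[2] <- TRUE
  expect_false(assess_family(d, obs, subj)$pm6[d$key == "GENEA|p.G20D"])
})

test_that("computational criteria follow the all-concordant rule, enumerated over call pairs", {
  obs <- mini_observations("S1", 1L, "F256L")
  d <- deduplicate(obs)
  mk <- function(calls) tibble::tibble(
    gene = "GENEA", protein_change = "F256L",
    predictor = c("FATHMM", "SNPS&GO")[seq_along(calls)], call = calls)
  cases <- list(
    list(calls = c("deleterious", "deleterious"), pp3 = TRUE, bp4 = FALSE),
    list(calls = c("neutral", "neutral"), pp3 = FALSE, bp4 = TRUE),
    list(calls = c("deleterious", "neutral"), pp3 = FALSE, bp4 = FALSE),
    list(calls = c("neutral", "deleterious"), pp3 = FALSE, bp4 = FALSE),
    list(calls = "deleterious", pp3 = TRUE, bp4 = FALSE),
    list(calls = character(0), pp3 = FALSE, bp4 = FALSE))
  for (cs in cases) {
    got <- assess_computational(d, mk(cs$calls))
    expect_equal(got$pp3, cs$pp3, label = paste(cs$calls, collapse = "/"))
    expect_equal(got$bp4, cs$bp4, label = paste(cs$calls, collapse = "/"))
  }
  # PP3 and BP4 can never co-occur for one variant
  set.seed(2)
  for (i in 1:50) {
    calls <- sample(c("deleterious", "neutral"), sample(0:2, 1),
                    replace = TRUE)
    got <- assess_computational(d, mk(calls))
    expect_false(got$pp3 && got$bp4)
  }
})

test_that("PP5 requires a pathogenic assertion in the secondary database", {
  sec <- tibble::tibble(
    gene = c("GENEA", "GENEA"),
    cdna_change = c(NA, NA),
    protein_change = c("F256L", "A10V"),
    significance = c("Pathogenic", "Uncertain Significance"))
  obs <- mini_observations(c("S1", "S2", "S3"), rep(1L, 3),
                           c("F256L", "A10V", "G20D"))
  d <- deduplicate(obs)
  got <- setNames(assess_pp5(d, sec), d$key)
  expect_true(got[["GENEA|p.F256L"]])
  expect_false(got[["GENEA|p.A10V"]])  # present but uncertain
  expect_false(got[["GENEA|p.G20D"]])  # absent
})

test_that("BP7 covers synonymous variants without deleterious predictions", {
  obs <- mini_observations(c("S1", "S2", "S3"), rep(1L, 3),
                           c("F256F", "p.Ala10=", "G20D"))
  d <- deduplicate(obs)
  got <- setNames(assess_bp7(d, NULL), d$key)
  expect_true(got[["GENEA|p.F256F"]])
  expect_true(got[["GENEA|p.A10A"]])
  expect_false(got[["GENEA|p.G20D"]])  # missense
  pred <- tibble::tibble(gene = "GENEA", protein_change = "F256F",
                         predictor = "FATHMM", call = "deleterious")
  got2 <- setNames(assess_bp7(d, pred), d$key)
  expect_false(got2[["GENEA|p.F256F"]])
})

test_that("profile assembly is order-independent and honours overrides", {
  co <- small_cohort()
  run <- small_run()
  unpub <- run$distinct[!run$distinct$published, ]
  shuffle <- function(x) x[sample(nrow(x)), ]
  set.seed(9)
  p1 <- assign_criteria(unpub, run$observations, co$subjects,
                        convert_extract(co$extract),
                        predictions = co$predictions,
                        secondary_db = co$secondary_db,
                        inheritance = co$inheritance)
  p2 <- assign_criteria(unpub, shuffle(run$observations), co$subjects,
                        convert_extract(co$extract),
                        predictions = co$predictions,
                        secondary_db = co$secondary_db,
                        inheritance = co$inheritance)
  expect_equal(lapply(p1$criteria, sort), lapply(p2$criteria, sort))

  # population criteria are never auto-assigned but can be injected
  expect_false(any(vapply(p1$criteria,
                          function(x) any(x %in% c("PM2", "BA1", "BS1")),
                          logical(1))))
  k <- p1$key[p1$mapping_status == "mapped"][1]
  ov <- tibble::tibble(key = k, code = "PM2", action = "add")
  p3 <- assign_criteria(unpub, run$observations, co$subjects,
                        convert_extract(co$extract),
                        predictions = co$predictions,
                        secondary_db = co$secondary_db,
                        inheritance = co$inheritance, overrides = ov)
  expect_true("PM2" %in% p3$criteria[[match(k, p3$key)]])
  expect_equal(unname(p3$provenance[[match(k, p3$key)]]["PM2"]),
               "manual override (add)")
  ov2 <- tibble::tibble(key = k, code = "PS3", action = "remove")
  p4 <- assign_criteria(unpub, run$observations, co$subjects,
                        convert_extract(co$extract),
                        predictions = co$predictions,
                        secondary_db = co$secondary_db,
                        inheritance = co$inheritance, overrides = ov2)
  expect_false("PS3" %in% p4$criteria[[match(k, p4$key)]])
})
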