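test_that("extract conversion turns HGVS names into single-letter form", {
  raw <- tibble::tibble(
    Name = c("NM_000155.4(GALT):c.601C>T (p.Arg201Cys)",
             "NM_000155.4(GALT):c.2T>C",
             "broken name"),
    Gene = "GALT",
    `Protein change` = c("R201C", NA, NA),
    `Clinical significance` = c("Pathogenic", "Uncertain Significance",
                                "Benign"),
    `Review status` = c(2L, 1L, 0L))
  expect_message(conv <- convert_extract(raw), "skipped")
  expect_equal(nrow(conv), 2L)
  expect_equal(conv$protein_change[1], "R201C")
  expect_equal(conv$cdna_change, c("c.601C>T", "c.2T>C"))
  expect_true(is.na(conv$protein_change[2]))
  expect_equal(attr(conv, "n_skipped"), 1L)
  # empty extract converts to an empty list
  expect_equal(nrow(suppressMessages(convert_extract(raw[0, ]))), 0L)
})

test_that("matching is representation-aware, case-insensitive and stop-synonym-blind", {
  extract <- mini_extract(list(
    list(gene = "GALT", cdna = "c.601C>T", protein = "R201C",
         sig = "Pathogenic"),
    list(gene = "GALT", cdna = "c.100A>T", protein = "W34*",
         sig = "Likely Pathogenic"),
    list(gene = "GALT", cdna = "c.900G>A", sig = "Benign")))

  q <- deduplicate(mini_observations(
    c("S1", "S2", "S3", "S4", "S5"), rep(1L, 5),
    c("R201C", "F256L", "p.Trp34Ter", "W34X", "c.900G>A"), gene = "GALT"))
  m <- match_variants(q, extract)
  res <- setNames(m$published, m$key)
  expect_true(res[["GALT|p.R201C"]])
  expect_false(res[["GALT|p.F256L"]])
  # Ter / X / * spellings all reach the same published entry
  expect_true(res[["GALT|p.W34*"]])
  expect_true(res[["GALT|c.900G>A"]])
  expect_equal(m$matched_significance[m$key == "GALT|p.R201C"], "Pathogenic")

  # exhaustive stop-synonym enumeration against the planted entry
  for (spelling in c("W34X", "W34*", "p.Trp34Ter", "p.W34X", "p.Trp34*")) {
    d <- deduplicate(mini_observations("S9", 1L, spelling, gene = "GALT"))
    expect_true(match_variants(d, extract)$published,
                label = paste("spelling", spelling))
  }
})

test_that("a protein-only query never matches a c.-only entry", {
  extract <- mini_extract(list(
    list(gene = "GALT", cdna = "c.601C>T", sig = "Pathogenic")))
  d <- deduplicate(mini_observations("S1", 1L, "R201C", gene = "GALT"))
  expect_false(match_variants(d, extract)$published)
})

test_that("transcript version differences do not affect matching", {
  raw <- tibble::tibble(
    Name = "NM_000159.3(GCDH):c.776C>T (p.Ser259Leu)",
    Gene = "GCDH", `Protein change` = "S259L",
    `Clinical significance` = "Pathogenic", `Review status` = 1L)
  extract <- convert_extract(raw)
  q <- parse_variant_string("NM_000159.4(GCDH):c.776C>T (p.Ser259Leu)", "X")
  q$subject_id <- "S1"; q$disease <- "D"; q$category <- "c"
  q$allele_index <- 1L
  d <- deduplicate(q)
  expect_true(match_variants(d, extract)$published)
})

test_that("deduplication accumulates supporters and allele counts", {
  obs <- mini_observations(
    c("S1", "S2", "S3", "S3"), c(1L, 1L, 1L, 2L),
    c("R201C", "p.Arg201Cys", "F256L", "F256L"), gene = "GALT")
  d <- deduplicate(obs)
  expect_equal(nrow(d), 2L)
  r <- d[d$key == "GALT|p.R201C", ]
  expect_equal(r$n_subjects, 2L)
  expect_equal(r$allele_count, 2L)
  expect_setequal(r$subjects[[1]], c("S1", "S2"))
  # homozygous subject: one supporter, two alleles
  h <- d[d$key == "GALT|p.F256L", ]
  expect_equal(h$n_subjects, 1L)
  expect_equal(h$allele_count, 2L)
})

test_that("deduplication output is independent of observation order", {
  co <- small_cohort()
  h <- harvest_variants(co$subjects, references = co$references)
  d1 <- deduplicate(h$observations)
  set.seed(4)
  shuffled <- h$observations[sample(nrow(h$observations)), ]
  d2 <- deduplicate(shuffled)
  expect_equal(d1, d2)
})

test_that("published and unpublished distinct counts partition the total", {
  run <- small_run()
  expect_equal(sum(run$distinct$published) + sum(!run$distinct$published),
               nrow(run$distinct))
  # and agree with the planted truth
  mv <- small_cohort()$manifest$variants
  expect_equal(sort(run$distinct$key[run$distinct$published]),
               sort(mv$key[mv$published]))
})
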