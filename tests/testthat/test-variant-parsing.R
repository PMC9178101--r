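test_that("registry dialects normalize to one canonical representation", {
  v <- parse_variant_string(
    c("F256L", "c.549A > C", "p. Phe256Leu", "p.Arg31His", "c.549A>C"),
    "PAH")
  expect_equal(v$protein_change[1], "F256L")
  expect_equal(v$consequence[1], "missense")
  expect_equal(v$cdna_change[2], "c.549A>C")
  expect_equal(v$protein_change[3], "F256L")
  expect_equal(v$protein_change[4], "R31H")
  # spaced and compact c. notation land on the same key
  expect_equal(v$key[2], v$key[5])
  # single-letter and three-letter protein notation land on the same key
  expect_equal(v$key[1], v$key[3])
})

test_that("placeholder tokens and undecodable text map to statuses, never errors", {
  v <- parse_variant_string(
    c("none", "NEGATIVE", "  none ", "", NA, "what?!", "12345", "p.Xyz9Abc"),
    "PAH")
  expect_equal(v$mapping_status[1:5], rep("invalid_token", 5))
  expect_equal(v$mapping_status[6:8], rep("unparseable", 3))
  # property: arbitrary junk always lands in exactly one status
  set.seed(1)
  junk <- vapply(1:200, function(i) {
    paste(sample(c(LETTERS, letters, 0:9, ".", ">", "+", "(", ")", " "),
                 sample(1:12, 1), replace = TRUE), collapse = "")
  }, character(1))
  vj <- parse_variant_string(junk, "PAH")
  expect_true(all(vj$mapping_status %in%
                    c("mapped", "invalid_token", "unparseable")))
})

test_that("stop synonyms Ter, X and * unify", {
  v <- parse_variant_string(c("W123X", "p.Trp123Ter", "p.W123*", "W123*"),
                            "GENEA")
  expect_true(all(v$protein_change == "W123*"))
  expect_true(all(v$consequence == "nonsense"))
  expect_equal(length(unique(v$key)), 1L)
  # X is stop only in the alt position; as a reference residue it fails
  expect_equal(parse_variant_string("X123W", "GENEA")$mapping_status,
               "unparseable")
})

test_that("ClinVar-style full names parse into gene, transcript, c. and p.", {
  v <- parse_variant_string("NM_000159.4(GCDH):c.776C > T (p.Ser259Leu)", "X")
  expect_equal(v$gene, "GCDH")
  expect_equal(v$transcript, "NM_000159.4")
  expect_equal(v$cdna_change, "c.776C>T")
  expect_equal(v$protein_change, "S259L")
  expect_equal(v$key, "GCDH|c.776C>T")
})

test_that("parsing a canonicalized string is idempotent", {
  raws <- c("F256L", "c.549A > C", "p. Phe256Leu", "K329fs", "W123X",
            "c.244+1G>A", "c.385delA")
  v1 <- parse_variant_string(raws, "PAH")
  canon <- ifelse(!is.na(v1$cdna_change), v1$cdna_change,
                  v1$protein_change)
  v2 <- parse_variant_string(canon, "PAH")
  cols <- c("gene", "cdna_change", "protein_change", "consequence",
            "mapping_status", "key")
  expect_equal(v1[, cols], v2[, cols])
})

test_that("three-letter/one-letter conversion is a bijection over 20 residues plus stop", {
  ones <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
            "M", "F", "P", "S", "T", "W", "Y", "V", "*")
  threes <- aa_one_to_three(ones)
  expect_equal(length(unique(threes)), 21L)
  expect_equal(aa_three_to_one(threes), ones)
  # independent cross-check against the Biostrings code table
  bs <- Biostrings::AMINO_ACID_CODE[ones[ones != "*"]]
  expect_equal(unname(threes[ones != "*"]), unname(bs))
  # case-insensitive input
  expect_equal(aa_three_to_one(c("phe", "TER", "aRg")), c("F", "*", "R"))
})

test_that("consequence classification covers the notation grammar", {
  cases <- tibble::tribble(
    ~raw,            ~consequence,
    "W123X",         "nonsense",
    "F256F",         "synonymous",
    "p.Phe256=",     "synonymous",
    "K329fs",        "frameshift",
    "p.Lys329Serfs", "frameshift",
    "M1L",           "start_loss",
    "F256L",         "missense",
    "c.385delA",     "frameshift",
    "c.384_386delTAG", "other",
    "c.120dupT",     "frameshift",
    "c.100_101insAT", "frameshift",
    "c.549A>C",      "unknown"
  )
  v <- parse_variant_string(cases$raw, "G1")
  expect_equal(v$consequence, cases$consequence)
  expect_equal(is_null_variant(v$consequence),
               cases$consequence %in%
                 c("nonsense", "frameshift", "canonical_splice", "start_loss"))
})

test_that("canonical splice detection agrees with a regex oracle over generated offsets", {
  set.seed(7)
  pos <- sample(50:900, 60, replace = TRUE)
  off <- sample(c(-6:-1, 1:6), 60, replace = TRUE)
  raw <- sprintf("c.%d%+dG>A", pos, off)
  v <- parse_variant_string(raw, "G1")
  oracle <- grepl("^c\\.\\d+[+-][12][ACGT]>[ACGT]$", raw)
  expect_equal(v$consequence == "canonical_splice", oracle)
  expect_true(all(v$consequence[!oracle] == "other"))
})

test_that("reference-residue validation flags mismatches and out-of-range positions", {
  refs <- tibble::tibble(gene = "GENEA", transcript = "NM_000001.1",
                         protein = "MFAW")
  v <- parse_variant_string(c("F2L", "A2L", "W999X", "c.9G>A"), "GENEA")
  v <- validate_reference(v, refs)
  expect_equal(v$mapping_status,
               c("mapped", "unmapped_reference_mismatch",
                 "unmapped_reference_mismatch", "mapped"))
  expect_match(v$mismatch_note[2], "protein has F")
  expect_match(v$mismatch_note[3], "out of range")
  # pure c. notation carries no residue to validate
  expect_true(is.na(v$mismatch_note[4]))
})
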