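# Synthetic registry cohorts with planted ground truth.
#
# The real follow-up registry behind this kind of analysis is
# access-controlled, so the generator emulates its structure: 32 diseases in
# four disorder categories, a genotyping rate near one half, mixed
# variant-string dialects (HGVS c., spaced HGVS c., three-letter HGVS p.,
# bare single-letter), placeholder tokens in variant fields, planted
# wrong-reference-residue submissions, and per-variant clinical-evidence
# availability mirroring the criterion frequencies reported for such
# cohorts. Every planted fact is recorded in a truth manifest so each
# downstream stage can be tested for exact recovery.

CLINVAR_DIALECTS <- c("hgvs_c", "hgvs_c_spaced", "hgvs_p3", "single_letter")

#' Default per-criterion evidence availability rates
#'
#' Probabilities that a planted unpublished variant carries the clinical or
#' computational evidence for each criterion, conditional on eligibility:
#' `pm3`, `pm6`, `pp1`, `pp5` apply to mapped non-synonymous variants;
#' `pm5`, `pp3`, `bp4` to variants reported as protein-level missense.
#' PVS1 and BP7 are not rates: they follow deterministically from the
#' planted consequence class.
#'
#' @return named numeric vector.
#' @export
default_evidence_rates <- function() {
  c(pm3 = 66 / 150, pm5 = 13 / 102, pm6 = 2 / 150, pp1 = 7 / 150,
    pp3 = 77 / 102, bp4 = 1 / 102, pp5 = 23 / 150)
}

#' Configuration for a synthetic registry cohort
#'
#' Defaults reproduce the structure of the study cohort this generator
#' emulates: 10 amino acid, 8 fatty acid oxidation, 11 organic acid and 3
#' other disorders (32 diseases), 1904 subjects, a 51.6% genotyping rate, a
#' 28.5% unpublished rate among distinct variants, and an 11/161 planted
#' wrong-reference-residue rate among unpublished variants.
#'
#' @param n_diseases_per_category named counts for the four disorder
#'   categories.
#' @param n_subjects total subjects, distributed as evenly as possible
#'   across diseases (ignored when `subjects_per_disease` is given).
#' @param subjects_per_disease scalar or per-disease vector of subject
#'   counts.
#' @param genotyping_rate probability a subject has a reported genotype.
#' @param unpublished_rate probability a distinct planted variant is absent
#'   from the baseline extract.
#' @param unmapped_rate probability an unpublished variant is planted with a
#'   wrong reference residue.
#' @param invalid_token_rate probability a non-genotyped subject's variant
#'   field holds a placeholder token ("none"/"negative").
#' @param dialect_mix distribution over the four variant-string dialects;
#'   must sum to 1.
#' @param evidence_rates see [default_evidence_rates()].
#' @param consequence_mix distribution of planted consequence classes among
#'   unpublished variants (`null`, `synonymous`, `missense`).
#' @param two_variant_prob probability a genotyped subject reports two
#'   alleles (biallelic recessive disorders dominate the screened panel).
#' @param homozygous_prob probability a two-allele subject repeats the same
#'   variant string.
#' @param variants_per_disease target distinct-variant pool size per disease.
#' @param n_extract_per_gene baseline extract rows per gene.
#' @param protein_length reference protein length (residues).
#' @param update_n_added new rows in the updated extract snapshot.
#' @param update_overlap classified variants planted into the update.
#' @param seed integer seed; identical configs give byte-identical output.
#' @return a validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_diseases_per_category = c(amino_acid = 10,
                                                      fatty_acid_oxidation = 8,
                                                      organic_acid = 11,
                                                      other = 3),
                          n_subjects = 1904,
                          subjects_per_disease = NULL,
                          genotyping_rate = 0.516,
                          unpublished_rate = 0.285,
                          unmapped_rate = 11 / 161,
                          invalid_token_rate = 0.05,
                          dialect_mix = c(hgvs_c = 0.35, hgvs_c_spaced = 0.10,
                                          hgvs_p3 = 0.15, single_letter = 0.40),
                          evidence_rates = default_evidence_rates(),
                          consequence_mix = c(null = 44 / 150,
                                              synonymous = 4 / 150,
                                              missense = 102 / 150),
                          two_variant_prob = 0.85,
                          homozygous_prob = 0.10,
                          variants_per_disease = 18,
                          n_extract_per_gene = 20,
                          protein_length = 500,
                          update_n_added = 250,
                          update_overlap = 8,
                          seed = 1) {
  cfg <- list(
    n_diseases_per_category = n_diseases_per_category,
    n_subjects = n_subjects,
    subjects_per_disease = subjects_per_disease,
    genotyping_rate = genotyping_rate,
    unpublished_rate = unpublished_rate,
    unmapped_rate = unmapped_rate,
    invalid_token_rate = invalid_token_rate,
    dialect_mix = dialect_mix,
    evidence_rates = evidence_rates,
    consequence_mix = consequence_mix,
    two_variant_prob = two_variant_prob,
    homozygous_prob = homozygous_prob,
    variants_per_disease = variants_per_disease,
    n_extract_per_gene = n_extract_per_gene,
    protein_length = protein_length,
    update_n_added = update_n_added,
    update_overlap = update_overlap,
    seed = seed
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  fail <- function(field, why) {
    stop("invalid cohort config: field '", field, "' ", why, call. = FALSE)
  }
  if (length(cfg$n_diseases_per_category) != 4 ||
      any(cfg$n_diseases_per_category < 1) ||
      any(cfg$n_diseases_per_category != floor(cfg$n_diseases_per_category))) {
    fail("n_diseases_per_category", "must be 4 positive integer counts")
  }
  for (field in c("genotyping_rate", "unpublished_rate", "unmapped_rate",
                  "invalid_token_rate", "two_variant_prob",
                  "homozygous_prob")) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      fail(field, "must be a probability in [0, 1]")
    }
  }
  if (any(cfg$dialect_mix < 0) ||
      !setequal(names(cfg$dialect_mix), CLINVAR_DIALECTS) ||
      abs(sum(cfg$dialect_mix) - 1) > 1e-8) {
    fail("dialect_mix", "must be a distribution over the four dialects summing to 1")
  }
  if (any(cfg$evidence_rates < 0) || any(cfg$evidence_rates > 1)) {
    fail("evidence_rates", "must be probabilities in [0, 1]")
  }
  if (any(cfg$consequence_mix < 0) ||
      abs(sum(cfg$consequence_mix) - 1) > 1e-8 ||
      !setequal(names(cfg$consequence_mix),
                c("null", "synonymous", "missense"))) {
    fail("consequence_mix", "must be a distribution over null/synonymous/missense summing to 1")
  }
  if (!is.null(cfg$subjects_per_disease) &&
      any(cfg$subjects_per_disease < 1)) {
    fail("subjects_per_disease", "must be positive")
  }
  for (field in c("n_subjects", "variants_per_disease", "n_extract_per_gene",
                  "protein_length", "update_n_added")) {
    if (cfg[[field]] < 1) fail(field, "must be a positive count")
  }
  if (cfg$update_overlap < 0) fail("update_overlap", "must be non-negative")
  if (cfg$seed != floor(cfg$seed)) fail("seed", "must be an integer")
  invisible(cfg)
}

#' Generate reference protein sequences
#'
#' One synthetic protein per gene (single-letter alphabet, initiator
#' methionine first), keyed by a synthetic transcript accession.
#'
#' @param genes character vector of gene symbols.
#' @param transcripts optional accessions (defaults to synthetic NM_9xxxxx.1).
#' @param protein_length residues per protein.
#' @param seed integer seed.
#' @return tibble with `gene`, `transcript`, `protein`.
#' @export
generate_reference_sequences <- function(genes, transcripts = NULL,
                                         protein_length = 500, seed = 1) {
  if (length(genes) == 0) stop("empty gene list", call. = FALSE)
  set.seed(seed)
  if (is.null(transcripts)) {
    transcripts <- sprintf("NM_9%05d.1", seq_along(genes))
  }
  aa <- setdiff(unname(AA_THREE_TO_ONE), "*")
  proteins <- vapply(seq_along(genes), function(i) {
    paste0("M", paste(sample(aa, protein_length - 1, replace = TRUE),
                      collapse = ""))
  }, character(1))
  tibble::tibble(gene = toupper(genes), transcript = transcripts,
                 protein = proteins)
}

#' Write / read reference proteins as FASTA
#'
#' Headers are `<transcript> gene=<SYMBOL>` so gene symbols survive the
#' round trip.
#'
#' @param references tibble from [generate_reference_sequences()].
#' @param path FASTA file path.
#' @return `write_reference_fasta` returns `path` invisibly;
#'   `read_reference_fasta` returns the references tibble.
#' @export
write_reference_fasta <- function(references, path) {
  seqs <- Biostrings::AAStringSet(references$protein)
  names(seqs) <- paste0(references$transcript, " gene=", references$gene)
  Biostrings::writeXStringSet(seqs, filepath = path)
  invisible(path)
}

#' @rdname write_reference_fasta
#' @export
read_reference_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  hdr <- names(seqs)
  transcript <- sub("\\s.*$", "", hdr)
  gene <- toupper(sub("^.*gene=([^ ]+).*$", "\\1", hdr))
  tibble::tibble(gene = gene, transcript = transcript,
                 protein = unname(as.character(seqs)))
}

# nucleotide helpers for plausible c. strings
random_substitution_nt <- function(n = 1) {
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                character(1))
  list(ref = ref, alt = unname(alt))
}

#' Generate a ClinVar-style gene extract
#'
#' One row per variant with an HGVS-style `Name`
#' (`NM_900001.1(GENE):c.602G>A (p.Arg201His)`), gene symbol, single-letter
#' protein change, clinical significance from the five standard terms plus
#' "Conflicting Interpretations of Pathogenicity", and a star-count review
#' status. The first three rows of every gene are Pathogenic so each gene is
#' guaranteed published pathogenic alleles. A small fraction of rows carries
#' no p. segment. c. and p. positions are mutually consistent (the c.
#' position falls inside the codon of the p. position) and the reference
#' residue matches the reference protein when one is supplied.
#'
#' @param genes character vector of gene symbols (nonempty).
#' @param n_variants_per_gene rows per gene.
#' @param seed integer seed.
#' @param references optional tibble from [generate_reference_sequences()].
#' @param snapshot_date date string recorded on the extract.
#' @param p_no_protein fraction of rows without a p. segment.
#' @param p_nonsense fraction of rows that are stop gains.
#' @return raw extract tibble (`Name`, `Gene`, `Protein change`,
#'   `Clinical significance`, `Review status`) with per-row protein
#'   positions attached as attribute `positions`.
#' @export
generate_clinvar_extract <- function(genes, n_variants_per_gene = 20,
                                     seed = 1, references = NULL,
                                     snapshot_date = "2018-11-28",
                                     p_no_protein = 0.08,
                                     p_nonsense = 0.08) {
  if (length(genes) == 0) stop("empty gene list", call. = FALSE)
  set.seed(seed)
  genes <- toupper(genes)
  if (is.null(references)) {
    references <- generate_reference_sequences(genes, seed = seed + 1)
  }
  sig_terms <- CLINVAR_SIGNIFICANCE
  sig_w <- c(0.25, 0.10, 0.30, 0.15, 0.05, 0.15)

  rows <- list()
  positions <- list()
  for (g in genes) {
    ref <- references[references$gene == g, , drop = FALSE]
    L <- nchar(ref$protein[1])
    pos <- sample(2:(L - 1), n_variants_per_gene)
    true_ref <- substr(rep(ref$protein[1], n_variants_per_gene), pos, pos)
    nonsense <- stats::runif(n_variants_per_gene) < p_nonsense
    alt <- vapply(seq_len(n_variants_per_gene), function(i) {
      if (nonsense[i]) return("*")
      sample(setdiff(setdiff(unname(AA_THREE_TO_ONE), "*"), true_ref[i]), 1)
    }, character(1))
    nts <- random_substitution_nt(n_variants_per_gene)
    cpos <- 3L * pos - 1L
    no_prot <- stats::runif(n_variants_per_gene) < p_no_protein
    sig <- c(rep("Pathogenic", min(3, n_variants_per_gene)),
             sample(sig_terms, max(0, n_variants_per_gene - 3),
                    replace = TRUE, prob = sig_w))
    p3 <- paste0(aa_one_to_three(true_ref), pos, aa_one_to_three(alt))
    name <- ifelse(
      no_prot,
      sprintf("%s(%s):c.%d%s>%s", ref$transcript[1], g, cpos,
              nts$ref, nts$alt),
      sprintf("%s(%s):c.%d%s>%s (p.%s)", ref$transcript[1], g, cpos,
              nts$ref, nts$alt, p3))
    rows[[g]] <- tibble::tibble(
      Name = name,
      Gene = g,
      `Protein change` = ifelse(no_prot, NA_character_,
                                paste0(true_ref, pos, alt)),
      `Clinical significance` = sig,
      `Review status` = sample(0:4, n_variants_per_gene, replace = TRUE,
                               prob = c(0.15, 0.45, 0.3, 0.08, 0.02))
    )
    positions[[g]] <- tibble::tibble(gene = g, protein_pos = pos)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "positions") <- dplyr::bind_rows(positions)
  attr(out, "snapshot_date") <- snapshot_date
  out
}

#' Generate an updated extract snapshot
#'
#' Returns the baseline extract plus `n_added` new rows, with
#' `planted_overlap` variants guaranteed among the additions (a
#' planted-overlap variant already present in the baseline is a hard
#' error). Novel additions avoid `avoid_positions` so they cannot
#' accidentally match cohort variants.
#'
#' @param baseline raw extract tibble (see [generate_clinvar_extract()]).
#' @param n_added number of new rows (must be >= the number of planted
#'   overlap variants).
#' @param planted_overlap optional tibble with `gene`, `transcript`,
#'   `cdna_change` (NA allowed), `protein_pos`, `protein_ref`,
#'   `protein_alt`, `significance`, `review_status`.
#' @param seed integer seed.
#' @param avoid_positions optional tibble (`gene`, `protein_pos`) of residue
#'   positions the novel additions must not touch.
#' @param references optional references tibble for consistent residues.
#' @param snapshot_date date string for the update.
#' @return raw extract tibble of `nrow(baseline) + n_added` rows.
#' @export
generate_updated_extract <- function(baseline, n_added,
                                     planted_overlap = NULL, seed = 1,
                                     avoid_positions = NULL,
                                     references = NULL,
                                     snapshot_date = "2021-10-01") {
  set.seed(seed)
  n_overlap <- if (is.null(planted_overlap)) 0L else nrow(planted_overlap)
  if (n_added < n_overlap) {
    stop("n_added must be at least the number of planted overlap variants",
         call. = FALSE)
  }
  base_conv <- suppressMessages(convert_extract(baseline))

  new_rows <- list()
  if (n_overlap > 0) {
    hits <- match_in_extract(
      planted_overlap$gene,
      planted_overlap$cdna_change,
      paste0(planted_overlap$protein_ref, planted_overlap$protein_pos,
             planted_overlap$protein_alt),
      base_conv)
    if (any(lengths(hits) > 0)) {
      stop("planted overlap variant already present in baseline extract",
           call. = FALSE)
    }
    for (i in seq_len(n_overlap)) {
      v <- planted_overlap[i, ]
      cpart <- if (!is.na(v$cdna_change)) v$cdna_change else {
        nt <- random_substitution_nt(1)
        sprintf("c.%d%s>%s", 3L * v$protein_pos - 1L, nt$ref, nt$alt)
      }
      ppart <- if (!is.na(v$protein_pos) && !is.na(v$protein_alt) &&
                   v$protein_alt != "fs") {
        sprintf(" (p.%s%d%s)", aa_one_to_three(v$protein_ref),
                v$protein_pos, aa_one_to_three(v$protein_alt))
      } else ""
      new_rows[[length(new_rows) + 1]] <- tibble::tibble(
        Name = sprintf("%s(%s):%s%s", v$transcript, toupper(v$gene),
                       cpart, ppart),
        Gene = toupper(v$gene),
        `Protein change` = if (nzchar(ppart)) {
          paste0(v$protein_ref, v$protein_pos, v$protein_alt)
        } else NA_character_,
        `Clinical significance` = v$significance,
        `Review status` = v$review_status
      )
    }
  }

  n_novel <- n_added - n_overlap
  if (n_novel > 0) {
    genes <- unique(base_conv$gene)
    if (is.null(references)) {
      references <- generate_reference_sequences(genes, seed = seed + 1)
    }
    taken <- dplyr::bind_rows(
      tibble::tibble(gene = base_conv$gene,
                     protein_pos = base_conv$protein_pos),
      avoid_positions)
    gene_cycle <- rep_len(genes, n_novel)
    tr_by_gene <- stats::setNames(references$transcript, references$gene)
    prot_by_gene <- stats::setNames(references$protein, references$gene)
    for (i in seq_len(n_novel)) {
      g <- gene_cycle[i]
      L <- nchar(prot_by_gene[[g]])
      used <- stats::na.omit(taken$protein_pos[taken$gene == g])
      free <- setdiff(2:(L - 1), used)
      pos <- if (length(free) > 0) sample(free, 1) else sample(2:(L - 1), 1)
      taken <- dplyr::bind_rows(taken,
                                tibble::tibble(gene = g, protein_pos = pos))
      pref <- substr(prot_by_gene[[g]], pos, pos)
      palt <- sample(setdiff(setdiff(unname(AA_THREE_TO_ONE), "*"), pref), 1)
      nt <- random_substitution_nt(1)
      new_rows[[length(new_rows) + 1]] <- tibble::tibble(
        Name = sprintf("%s(%s):c.%d%s>%s (p.%s%d%s)",
                       tr_by_gene[[g]], g, 3L * pos - 1L, nt$ref, nt$alt,
                       aa_one_to_three(pref), pos, aa_one_to_three(palt)),
        Gene = g,
        `Protein change` = paste0(pref, pos, palt),
        `Clinical significance` = sample(CLINVAR_SIGNIFICANCE, 1,
                                         prob = c(0.25, 0.1, 0.3, 0.15,
                                                  0.05, 0.15)),
        `Review status` = sample(0:4, 1, prob = c(0.15, 0.45, 0.3, 0.08, 0.02))
      )
    }
  }
  out <- dplyr::bind_rows(c(list(baseline[, c("Name", "Gene",
                                              "Protein change",
                                              "Clinical significance",
                                              "Review status")]),
                            new_rows))
  attr(out, "snapshot_date") <- snapshot_date
  out
}

#' Generate in-silico predictor score tables
#'
#' Two predictor calls (deleterious/neutral) per missense variant;
#' non-missense variants get no rows. The planted call pattern can be set
#' per variant (`"deleterious"`, `"neutral"`, `"discordant"`, `"none"`);
#' otherwise calls agree with probability `concordance` and an agreed call
#' is deleterious with probability `p_deleterious`.
#'
#' @param variants tibble with `gene`, `protein_change`, `consequence`.
#' @param seed integer seed.
#' @param concordance probability the two predictors agree (used when
#'   `planted_call` is NULL).
#' @param p_deleterious probability an agreed call is deleterious.
#' @param planted_call optional per-variant call pattern.
#' @param predictors names of the two predictors.
#' @return tibble with `gene`, `protein_change`, `predictor`, `call`,
#'   `score`.
#' @export
generate_predictions <- function(variants, seed = 1, concordance = 1,
                                 p_deleterious = 0.8, planted_call = NULL,
                                 predictors = c("FATHMM", "SNPS&GO")) {
  set.seed(seed)
  rows <- list()
  for (i in seq_len(nrow(variants))) {
    if (!identical(variants$consequence[i], "missense")) next
    pattern <- if (!is.null(planted_call)) planted_call[i] else {
      if (stats::runif(1) < concordance) {
        if (stats::runif(1) < p_deleterious) "deleterious" else "neutral"
      } else "discordant"
    }
    calls <- switch(pattern,
      deleterious = c("deleterious", "deleterious"),
      neutral = c("neutral", "neutral"),
      discordant = sample(c("deleterious", "neutral")),
      none = NULL,
      stop("unknown planted call pattern: ", pattern, call. = FALSE))
    if (is.null(calls)) next
    rows[[length(rows) + 1]] <- tibble::tibble(
      gene = toupper(variants$gene[i]),
      protein_change = variants$protein_change[i],
      predictor = predictors,
      call = calls,
      score = ifelse(calls == "deleterious",
                     round(stats::runif(2, -7, -1.5), 2),
                     round(stats::runif(2, -1.5, 3), 2))
    )
  }
  if (length(rows) == 0) {
    return(tibble::tibble(gene = character(), protein_change = character(),
                          predictor = character(), call = character(),
                          score = numeric()))
  }
  dplyr::bind_rows(rows)
}

# Render one planted variant in its dialect.
render_variant <- function(dialect, cdna_change, protein_pos, protein_ref,
                           protein_alt) {
  if (dialect %in% c("hgvs_c", "hgvs_c_spaced")) {
    out <- cdna_change
    if (dialect == "hgvs_c_spaced") out <- sub(">", " > ", out, fixed = TRUE)
    return(out)
  }
  if (dialect == "single_letter") {
    alt <- switch(protein_alt, "*" = "X", "fs" = "fs", protein_alt)
    return(paste0(protein_ref, protein_pos, alt))
  }
  # hgvs_p3, with the stray space after "p." seen in registry submissions
  alt3 <- switch(protein_alt,
                 "*" = "Ter",
                 "fs" = "fs",
                 if (protein_alt == protein_ref) "=" else
                   aa_one_to_three(protein_alt))
  paste0("p. ", aa_one_to_three(protein_ref), protein_pos, alt3)
}

# Draw a dialect restricted to `eligible`, renormalizing the configured mix.
draw_dialect <- function(mix, eligible) {
  w <- mix[eligible]
  if (sum(w) <= 0) w <- stats::setNames(rep(1, length(eligible)), eligible)
  sample(names(w), 1, prob = w)
}

#' Generate a synthetic registry cohort with planted ground truth
#'
#' Builds, from one config: reference proteins, a baseline ClinVar-style
#' extract, the subject-level registry table (with raw variant strings in
#' mixed dialects), predictor score tables, a secondary variant database, an
#' updated extract snapshot with a planted overlap, a disease-inheritance
#' table (all autosomal recessive), and a truth manifest recording every
#' planted fact. Identical configs (including seed) give identical output.
#'
#' @param config a [cohort_config()].
#' @return an object of class `nbs_cohort`: a list with elements `subjects`,
#'   `manifest`, `diseases`, `references`, `extract` (raw baseline),
#'   `extract_updated` (raw update), `predictions`, `secondary_db`,
#'   `inheritance`, `config`.
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  set.seed(config$seed)
  aa20 <- setdiff(unname(AA_THREE_TO_ONE), "*")

  # --- diseases, genes, subjects-per-disease -------------------------------
  cats <- names(config$n_diseases_per_category)
  abbrev <- c(amino_acid = "AA", fatty_acid_oxidation = "FAO",
              organic_acid = "OA", other = "OTH")
  diseases <- dplyr::bind_rows(lapply(cats, function(ct) {
    k <- config$n_diseases_per_category[[ct]]
    tibble::tibble(category = ct,
                   disease = sprintf("%s%02d", abbrev[[ct]], seq_len(k)))
  }))
  nd <- nrow(diseases)
  diseases$gene <- sprintf("SG%02d", seq_len(nd))
  diseases$transcript <- sprintf("NM_9%05d.1", seq_len(nd))
  if (is.null(config$subjects_per_disease)) {
    base <- config$n_subjects %/% nd
    extra <- config$n_subjects %% nd
    diseases$n_subjects <- base + (seq_len(nd) <= extra)
  } else {
    diseases$n_subjects <- rep_len(config$subjects_per_disease, nd)
  }

  references <- generate_reference_sequences(
    diseases$gene, diseases$transcript,
    protein_length = config$protein_length, seed = config$seed + 1)
  extract_raw <- generate_clinvar_extract(
    diseases$gene, config$n_extract_per_gene, seed = config$seed + 2,
    references = references)
  extract_conv <- suppressMessages(convert_extract(extract_raw))
  used_positions <- attr(extract_raw, "positions")

  set.seed(config$seed + 3)

  # --- per-disease variant pools and allele assignment ---------------------
  pool_rows <- list()
  subj_rows <- list()
  neighbor_rows <- list()
  subj_counter <- 0L
  rates <- config$evidence_rates

  for (d in seq_len(nd)) {
    dis <- diseases$disease[d]
    g <- diseases$gene[d]
    tr <- diseases$transcript[d]
    prot <- references$protein[references$gene == g]
    L <- nchar(prot)
    n_sub <- diseases$n_subjects[d]

    geno <- stats::runif(n_sub) < config$genotyping_rate
    n_alleles <- ifelse(geno,
                        1L + (stats::runif(n_sub) < config$two_variant_prob),
                        0L)
    slots <- sum(n_alleles)
    pool_size <- min(config$variants_per_disease, slots)

    gene_extract <- extract_conv[extract_conv$gene == g, , drop = FALSE]
    free_pos <- setdiff(2:(L - 1),
                        used_positions$protein_pos[used_positions$gene == g])

    pool <- list()
    if (pool_size > 0) {
      unpub <- stats::runif(pool_size) < config$unpublished_rate
      n_pub <- sum(!unpub)
      pub_rows <- integer(0)
      if (n_pub > 0) {
        # guarantee a pathogenic allele among published picks so planted
        # in-trans evidence is realizable
        path_idx <- which(sig_is_plp(gene_extract$significance))
        pick <- sample(path_idx, 1)
        rest <- sample(setdiff(seq_len(nrow(gene_extract)), pick),
                       min(n_pub - 1, nrow(gene_extract) - 1))
        pub_rows <- c(pick, rest)[seq_len(min(n_pub, nrow(gene_extract)))]
      }
      pub_i <- 0L
      for (v in seq_len(pool_size)) {
        if (!unpub[v] && pub_i < length(pub_rows)) {
          pub_i <- pub_i + 1L
          row <- gene_extract[pub_rows[pub_i], ]
          has_prot <- !is.na(row$protein_change)
          eligible <- if (has_prot) CLINVAR_DIALECTS else
            c("hgvs_c", "hgvs_c_spaced")
          dia <- draw_dialect(config$dialect_mix, eligible)
          protein_in_render <- dia %in% c("hgvs_p3", "single_letter")
          pool[[v]] <- tibble::tibble(
            disease = dis, gene = g, transcript = tr,
            published = TRUE, significance = row$significance,
            mismatch = FALSE, planted_class = "published",
            dialect = dia,
            cdna_change = if (protein_in_render) NA_character_ else
              row$cdna_change,
            protein_pos = if (protein_in_render) row$protein_pos else
              NA_integer_,
            protein_ref = if (protein_in_render) row$protein_ref else
              NA_character_,
            protein_alt = if (protein_in_render) row$protein_alt else
              NA_character_,
            pm3 = FALSE, pm5 = FALSE, pm6 = FALSE, pp1 = FALSE,
            pp3 = FALSE, bp4 = FALSE, pp5 = FALSE)
          next
        }
        # unpublished (or published overflow folded into unpublished):
        mismatch <- stats::runif(1) < config$unmapped_rate
        cls <- if (mismatch) "missense" else
          sample(names(config$consequence_mix), 1,
                 prob = config$consequence_mix)
        if (cls == "null") {
          cls <- sample(c("nonsense", "frameshift", "canonical_splice",
                          "start_loss"),
                        1, prob = c(0.45, 0.30, 0.20, 0.05))
        }
        pos <- if (cls == "start_loss") 1L else {
          p <- free_pos[1]
          free_pos <- free_pos[-1]
          p
        }
        true_ref <- substr(prot, pos, pos)
        stated_ref <- if (mismatch) sample(setdiff(aa20, true_ref), 1) else
          true_ref
        cdna <- NA_character_
        p_alt <- NA_character_
        dia <- NA_character_
        if (cls == "canonical_splice") {
          dia <- draw_dialect(config$dialect_mix,
                              c("hgvs_c", "hgvs_c_spaced"))
          nt <- random_substitution_nt(1)
          cdna <- sprintf("c.%d%+d%s>%s", 3L * pos,
                          sample(c(1L, 2L, -1L, -2L), 1), nt$ref, nt$alt)
          pos <- NA_integer_; stated_ref <- NA_character_
        } else if (cls == "frameshift") {
          dia <- draw_dialect(config$dialect_mix, CLINVAR_DIALECTS)
          if (dia %in% c("hgvs_c", "hgvs_c_spaced")) {
            cdna <- sprintf("c.%ddel%s", 3L * pos - 1L,
                            sample(c("A", "C", "G", "T"), 1))
            pos <- NA_integer_; stated_ref <- NA_character_
          } else {
            p_alt <- "fs"
          }
        } else if (cls == "nonsense") {
          dia <- draw_dialect(config$dialect_mix,
                              c("hgvs_p3", "single_letter"))
          p_alt <- "*"
        } else if (cls == "start_loss") {
          dia <- draw_dialect(config$dialect_mix,
                              c("hgvs_p3", "single_letter"))
          p_alt <- sample(setdiff(aa20, "M"), 1)
        } else if (cls == "synonymous") {
          dia <- draw_dialect(config$dialect_mix,
                              c("hgvs_p3", "single_letter"))
          p_alt <- stated_ref
        } else { # missense
          dia <- if (mismatch) {
            draw_dialect(config$dialect_mix, c("hgvs_p3", "single_letter"))
          } else draw_dialect(config$dialect_mix, CLINVAR_DIALECTS)
          if (dia %in% c("hgvs_c", "hgvs_c_spaced")) {
            nt <- random_substitution_nt(1)
            cdna <- sprintf("c.%d%s>%s", 3L * pos - 1L, nt$ref, nt$alt)
            pos <- NA_integer_; stated_ref <- NA_character_
          } else {
            p_alt <- sample(setdiff(aa20, stated_ref), 1)
          }
        }
        is_protein_missense <- cls == "missense" && !is.na(p_alt)
        evidence_ok <- !mismatch
        pool[[v]] <- tibble::tibble(
          disease = dis, gene = g, transcript = tr,
          published = FALSE, significance = NA_character_,
          mismatch = mismatch, planted_class = cls, dialect = dia,
          cdna_change = cdna, protein_pos = pos, protein_ref = stated_ref,
          protein_alt = p_alt,
          pm3 = evidence_ok && cls != "synonymous" &&
            stats::runif(1) < rates[["pm3"]],
          pm5 = evidence_ok && is_protein_missense &&
            stats::runif(1) < rates[["pm5"]],
          pm6 = evidence_ok && cls != "synonymous" &&
            stats::runif(1) < rates[["pm6"]],
          pp1 = evidence_ok && cls != "synonymous" &&
            stats::runif(1) < rates[["pp1"]],
          pp3 = evidence_ok && is_protein_missense &&
            stats::runif(1) < rates[["pp3"]],
          bp4 = FALSE, # set below, exclusive of pp3
          pp5 = evidence_ok && cls != "synonymous" &&
            stats::runif(1) < rates[["pp5"]])
        if (!pool[[v]]$pp3 && is_protein_missense && evidence_ok) {
          pool[[v]]$bp4 <- stats::runif(1) < rates[["bp4"]] /
            max(1e-9, 1 - rates[["pp3"]])
        }
      }
    }
    pool <- if (length(pool) > 0) dplyr::bind_rows(pool) else NULL

    if (!is.null(pool)) {
      # rendered string, canonical key
      pool$rendered <- vapply(seq_len(nrow(pool)), function(v) {
        render_variant(pool$dialect[v], pool$cdna_change[v],
                       pool$protein_pos[v], pool$protein_ref[v],
                       pool$protein_alt[v])
      }, character(1))
      pool$protein_change <- ifelse(
        is.na(pool$protein_alt), NA_character_,
        paste0(pool$protein_ref, pool$protein_pos, pool$protein_alt))
      pool$key <- variant_key(pool$gene, pool$cdna_change,
                              pool$protein_change)
      # drop in-pool duplicates (a published row drawn twice cannot happen;
      # unpublished positions are unique) — defensive only
      pool <- pool[!duplicated(pool$key), , drop = FALSE]

      # PM5 neighbours enter the extract as Pathogenic missense
      for (v in which(pool$pm5)) {
        nb_alt <- sample(setdiff(aa20, c(pool$protein_ref[v],
                                         pool$protein_alt[v])), 1)
        nt <- random_substitution_nt(1)
        neighbor_rows[[length(neighbor_rows) + 1]] <- tibble::tibble(
          Name = sprintf("%s(%s):c.%d%s>%s (p.%s%d%s)", tr, g,
                         3L * pool$protein_pos[v] - 1L, nt$ref, nt$alt,
                         aa_one_to_three(pool$protein_ref[v]),
                         pool$protein_pos[v], aa_one_to_three(nb_alt)),
          Gene = g,
          `Protein change` = paste0(pool$protein_ref[v],
                                    pool$protein_pos[v], nb_alt),
          `Clinical significance` = "Pathogenic",
          `Review status` = 1L)
      }
    }

    # --- assign alleles to genotyped subjects ------------------------------
    ids <- sprintf("S%05d", subj_counter + seq_len(n_sub))
    subj_counter <- subj_counter + n_sub
    allele1 <- rep(NA_integer_, n_sub)
    allele2 <- rep(NA_integer_, n_sub)

    if (!is.null(pool) && nrow(pool) > 0) {
      P <- nrow(pool)
      pub_plp <- pool$published & sig_is_plp(pool$significance)
      unpub_nonpm3 <- !pool$published & !pool$mismatch & !pool$pm3
      allowed <- function(a, b) {
        !((unpub_nonpm3[a] && pub_plp[b]) || (pub_plp[a] && unpub_nonpm3[b]))
      }
      sample_partner <- function(a) {
        ok <- which(vapply(seq_len(P), function(b) allowed(a, b), logical(1)))
        if (length(ok) == 0) a else ok[sample.int(length(ok), 1)]
      }
      pm3_idx <- which(pool$pm3)
      plp_idx <- which(pub_plp)
      if (length(plp_idx) == 0 && length(pm3_idx) > 0) {
        pool$pm3[pm3_idx] <- FALSE
        pm3_idx <- integer(0)
        unpub_nonpm3 <- !pool$published & !pool$mismatch & !pool$pm3
      }
      required <- lapply(pm3_idx, function(v) {
        c(v, plp_idx[sample.int(length(plp_idx), 1)])
      })
      queue <- sample.int(P)
      ord <- order(-n_alleles)
      for (s in ord) {
        if (n_alleles[s] == 0L) next
        if (n_alleles[s] == 2L && length(required) > 0) {
          pr <- required[[1]]
          required <- required[-1]
          allele1[s] <- pr[1]
          allele2[s] <- pr[2]
          queue <- setdiff(queue, pr)
          next
        }
        a1 <- if (length(queue) > 0) {
          q <- queue[1]; queue <- queue[-1]; q
        } else sample.int(P, 1)
        allele1[s] <- a1
        if (n_alleles[s] == 2L) {
          if (stats::runif(1) < config$homozygous_prob && allowed(a1, a1)) {
            allele2[s] <- a1
          } else {
            hit <- NA_integer_
            for (q in queue) if (allowed(a1, q)) { hit <- q; break }
            if (!is.na(hit)) {
              allele2[s] <- hit
              queue <- setdiff(queue, hit)
            } else {
              allele2[s] <- sample_partner(a1)
            }
          }
        }
      }
      # any pm3 pairs that found no two-allele subject: flag off
      if (length(required) > 0) {
        for (pr in required) pool$pm3[pr[1]] <- FALSE
      }
      carried <- sort(unique(stats::na.omit(c(allele1, allele2))))
      pool$carried <- seq_len(P) %in% carried
    }

    # --- clinical evidence fields and raw strings --------------------------
    fh1 <- rep(FALSE, n_sub); fh2 <- rep(FALSE, n_sub)
    dn1 <- rep(FALSE, n_sub); dn2 <- rep(FALSE, n_sub)
    if (!is.null(pool) && nrow(pool) > 0) {
      plant_on_carrier <- function(v) {
        s1 <- which(allele1 == v)
        s2 <- which(allele2 == v)
        if (length(s1) > 0) c(min(s1), 1L)
        else if (length(s2) > 0) c(min(s2), 2L)
        else NULL
      }
      for (v in which(pool$pp1 & pool$carried)) {
        at <- plant_on_carrier(v)
        if (is.null(at)) { pool$pp1[v] <- FALSE; next }
        if (at[2] == 1L) fh1[at[1]] <- TRUE else fh2[at[1]] <- TRUE
      }
      for (v in which(pool$pm6 & pool$carried)) {
        at <- plant_on_carrier(v)
        if (is.null(at)) { pool$pm6[v] <- FALSE; next }
        if (at[2] == 1L) dn1[at[1]] <- TRUE else dn2[at[1]] <- TRUE
      }
      pool$pp1 <- pool$pp1 & pool$carried
      pool$pm6 <- pool$pm6 & pool$carried
    }

    v1 <- rep("", n_sub); v2 <- rep("", n_sub)
    if (!is.null(pool) && nrow(pool) > 0) {
      v1[!is.na(allele1)] <- pool$rendered[allele1[!is.na(allele1)]]
      v2[!is.na(allele2)] <- pool$rendered[allele2[!is.na(allele2)]]
    }
    not_geno <- n_alleles == 0L
    tok1 <- not_geno & stats::runif(n_sub) < config$invalid_token_rate
    tok2 <- not_geno & stats::runif(n_sub) < config$invalid_token_rate
    v1[tok1] <- sample(c("none", "negative"), sum(tok1), replace = TRUE)
    v2[tok2] <- sample(c("none", "negative"), sum(tok2), replace = TRUE)

    subj_rows[[d]] <- tibble::tibble(
      subject_id = ids,
      disease = dis,
      category = diseases$category[d],
      gene = g,
      confirmed_dx = TRUE,
      nbs_positive = TRUE,
      fh_affected_relative = fh1 | fh2 |
        (stats::runif(n_sub) < 0.05),
      fh_affected_carrier_allele1 = fh1,
      fh_affected_carrier_allele2 = fh2,
      de_novo_allele1 = dn1,
      de_novo_allele2 = dn2,
      parentage_confirmed = FALSE,
      phase_tested = stats::runif(n_sub) < 0.10,
      alleles_in_trans = NA,
      variant1 = v1,
      variant2 = v2,
      genotyped = !not_geno,
      allele1_key = if (is.null(pool)) NA_character_ else
        pool$key[allele1],
      allele2_key = if (is.null(pool)) NA_character_ else
        pool$key[allele2]
    )
    subj_rows[[d]]$alleles_in_trans <- ifelse(
      subj_rows[[d]]$phase_tested & n_alleles == 2L, TRUE, NA)
    if (!is.null(pool)) {
      pool_rows[[d]] <- pool[pool$carried, , drop = FALSE]
    }
  }

  subjects_full <- dplyr::bind_rows(subj_rows)
  truth_cols <- c("genotyped", "allele1_key", "allele2_key")
  subjects <- subjects_full[, setdiff(names(subjects_full), truth_cols)]
  pool_all <- if (length(pool_rows) > 0) dplyr::bind_rows(pool_rows) else
    tibble::tibble()

  # extend the extract with PM5 neighbours of carried variants
  if (length(neighbor_rows) > 0 && nrow(pool_all) > 0) {
    nb <- dplyr::bind_rows(neighbor_rows)
    keep_pos <- paste(pool_all$gene[pool_all$pm5], pool_all$protein_pos[pool_all$pm5])
    nb_conv <- suppressMessages(convert_extract(nb))
    nb <- nb[paste(nb_conv$gene, nb_conv$protein_pos) %in% keep_pos, ,
             drop = FALSE]
    extract_raw <- dplyr::bind_rows(extract_raw, nb)
    used_positions <- dplyr::bind_rows(
      used_positions,
      tibble::tibble(gene = nb_conv$gene, protein_pos = nb_conv$protein_pos))
  }

  # --- predictions, secondary database -------------------------------------
  has_pool <- nrow(pool_all) > 0
  pred_input <- if (has_pool) {
    pool_all[pool_all$planted_class == "missense" &
               !is.na(pool_all$protein_alt) & !pool_all$published &
               !pool_all$mismatch, , drop = FALSE]
  } else tibble::tibble(gene = character(), protein_change = character(),
                        pp3 = logical(), bp4 = logical())
  predictions <- generate_predictions(
    tibble::tibble(gene = pred_input$gene,
                   protein_change = pred_input$protein_change,
                   consequence = rep("missense", nrow(pred_input))),
    seed = config$seed + 4,
    planted_call = ifelse(pred_input$pp3, "deleterious",
                          ifelse(pred_input$bp4, "neutral", "discordant")))

  sec_rows <- if (has_pool) pool_all[pool_all$pp5, , drop = FALSE] else
    tibble::tibble(gene = character(), cdna_change = character(),
                   protein_change = character())
  secondary_db <- tibble::tibble(
    gene = sec_rows$gene,
    cdna_change = sec_rows$cdna_change,
    protein_change = sec_rows$protein_change,
    significance = rep("Pathogenic", nrow(sec_rows)),
    source = rep("synthetic secondary database", nrow(sec_rows)))
  # a few uncertain entries exercise the significance filter
  vus_cand <- if (has_pool) {
    pool_all[!pool_all$published & !pool_all$pp5 & !pool_all$mismatch, ,
             drop = FALSE]
  } else tibble::tibble()
  if (nrow(vus_cand) > 0) {
    take <- utils::head(seq_len(nrow(vus_cand)), 3)
    secondary_db <- dplyr::bind_rows(secondary_db, tibble::tibble(
      gene = vus_cand$gene[take],
      cdna_change = vus_cand$cdna_change[take],
      protein_change = vus_cand$protein_change[take],
      significance = "Uncertain Significance",
      source = "synthetic secondary database"))
  }
  if (nrow(secondary_db) == 0) {
    secondary_db <- tibble::tibble(gene = character(),
                                   cdna_change = character(),
                                   protein_change = character(),
                                   significance = character(),
                                   source = character())
  }

  inheritance <- tibble::tibble(disease = diseases$disease,
                                gene = diseases$gene,
                                inheritance = "AR")

  # --- expected criteria and classification per planted variant ------------
  if (nrow(pool_all) > 0) {
    exp_criteria <- vector("list", nrow(pool_all))
    exp_cat <- character(nrow(pool_all))
    exp_rule <- character(nrow(pool_all))
    notation_cons <- ifelse(
      !is.na(pool_all$protein_alt),
      ifelse(pool_all$protein_alt == "*", "nonsense",
      ifelse(pool_all$protein_alt == "fs", "frameshift",
      ifelse(pool_all$protein_pos == 1L & pool_all$protein_ref == "M" &
               pool_all$protein_alt != "M", "start_loss",
      ifelse(pool_all$protein_ref == pool_all$protein_alt, "synonymous",
             "missense")))),
      ifelse(pool_all$planted_class == "canonical_splice", "canonical_splice",
      ifelse(pool_all$planted_class == "frameshift", "frameshift", "unknown")))
    for (v in seq_len(nrow(pool_all))) {
      if (pool_all$published[v]) {
        exp_criteria[[v]] <- character(0)
        exp_cat[v] <- NA_character_
        exp_rule[v] <- NA_character_
        next
      }
      if (pool_all$mismatch[v]) {
        exp_criteria[[v]] <- character(0)
        exp_cat[v] <- "Excluded-Unmapped"
        exp_rule[v] <- "excluded-unmapped"
        next
      }
      codes <- character(0)
      if (is_null_variant(notation_cons[v])) codes <- c(codes, "PVS1")
      codes <- c(codes, "PS3")
      if (pool_all$pm3[v]) codes <- c(codes, "PM3")
      if (pool_all$pm5[v]) codes <- c(codes, "PM5")
      if (pool_all$pm6[v]) codes <- c(codes, "PM6")
      if (pool_all$pp1[v]) codes <- c(codes, "PP1")
      if (pool_all$pp3[v]) codes <- c(codes, "PP3")
      codes <- c(codes, "PP4")
      if (pool_all$pp5[v]) codes <- c(codes, "PP5")
      if (pool_all$bp4[v]) codes <- c(codes, "BP4")
      if (notation_cons[v] == "synonymous") codes <- c(codes, "BP7")
      exp_criteria[[v]] <- codes
      res <- classify_variant(codes)
      exp_cat[v] <- res$category
      exp_rule[v] <- res$rule_label
    }
    pool_all$notation_consequence <- notation_cons
    pool_all$expected_criteria <- exp_criteria
    pool_all$expected_category <- exp_cat
    pool_all$expected_rule_label <- exp_rule
  }

  # --- updated extract with planted overlap --------------------------------
  # pm5-flagged protein-only variants are excluded: their update name would
  # need a synthesized c. part at the codon already occupied by their
  # planted extract neighbour
  overlap_cand <- if (nrow(pool_all) > 0) {
    pool_all[!pool_all$published & !pool_all$mismatch &
               !(pool_all$pm5 & is.na(pool_all$cdna_change)) &
               (!is.na(pool_all$cdna_change) |
                  pool_all$notation_consequence %in%
                    c("missense", "nonsense", "synonymous")), , drop = FALSE]
  } else tibble::tibble()
  n_overlap <- min(config$update_overlap, nrow(overlap_cand))
  planted_overlap <- NULL
  if (n_overlap > 0) {
    pick <- sort(sample.int(nrow(overlap_cand), n_overlap))
    oc <- overlap_cand[pick, ]
    upd_sig <- rep_len(c("Likely Pathogenic", "Pathogenic", "Pathogenic",
                         "Pathogenic", "Uncertain Significance",
                         "Uncertain Significance",
                         "Conflicting Interpretations of Pathogenicity",
                         "Uncertain Significance"), n_overlap)
    planted_overlap <- tibble::tibble(
      gene = oc$gene, transcript = oc$transcript,
      cdna_change = oc$cdna_change,
      protein_pos = oc$protein_pos, protein_ref = oc$protein_ref,
      protein_alt = oc$protein_alt,
      significance = upd_sig,
      review_status = rep_len(c(1L, 1L, 2L, 1L, 2L, 1L, 1L, 1L), n_overlap),
      key = oc$key)
  }
  pool_positions <- if (nrow(pool_all) > 0) {
    tibble::tibble(gene = pool_all$gene, protein_pos = pool_all$protein_pos)
  } else NULL
  extract_updated <- generate_updated_extract(
    extract_raw, config$update_n_added,
    planted_overlap = planted_overlap, seed = config$seed + 5,
    avoid_positions = dplyr::bind_rows(used_positions, pool_positions),
    references = references)

  if (nrow(pool_all) > 0) {
    pool_all$in_update <- pool_all$key %in%
      (if (is.null(planted_overlap)) character(0) else planted_overlap$key)
  }

  manifest <- list(
    seed = config$seed,
    config_digest = rlang::hash(unclass(config)),
    subjects = subjects_full[, c("subject_id", "disease", "genotyped",
                                 "allele1_key", "allele2_key")],
    variants = pool_all,
    planted_overlap_keys = if (is.null(planted_overlap)) character(0) else
      planted_overlap$key
  )

  structure(list(
    subjects = subjects,
    manifest = manifest,
    diseases = diseases,
    references = references,
    extract = extract_raw,
    extract_updated = extract_updated,
    predictions = predictions,
    secondary_db = secondary_db,
    inheritance = inheritance,
    config = config
  ), class = "nbs_cohort")
}

#' @export
print.nbs_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic registry cohort: %d subjects, %d diseases, seed %d\n",
    nrow(x$subjects), nrow(x$diseases), x$config$seed))
  cat(sprintf("Planted distinct variants: %d (%d unpublished, %d mismatched)\n",
              nrow(x$manifest$variants),
              sum(!x$manifest$variants$published),
              sum(x$manifest$variants$mismatch)))
  invisible(x)
}

#' Write cohort artifacts to disk as plain-text files
#'
#' Writes the subject table, baseline and updated extracts, predictor
#' scores, secondary database and inheritance table as CSV, the reference
#' proteins as FASTA, and the truth manifest plus config as JSON.
#'
#' @param cohort an `nbs_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(cohort$subjects, file.path(dir, "subjects.csv"))
  readr::write_csv(cohort$extract, file.path(dir, "clinvar_extract.csv"))
  readr::write_csv(cohort$extract_updated,
                   file.path(dir, "clinvar_extract_updated.csv"))
  readr::write_csv(cohort$predictions, file.path(dir, "predictions.csv"))
  readr::write_csv(cohort$secondary_db, file.path(dir, "secondary_db.csv"))
  readr::write_csv(cohort$inheritance, file.path(dir, "inheritance.csv"))
  readr::write_csv(cohort$diseases, file.path(dir, "diseases.csv"))
  write_reference_fasta(cohort$references, file.path(dir, "references.fasta"))
  manifest <- cohort$manifest
  if (nrow(manifest$variants) > 0) {
    manifest$variants$expected_criteria <- vapply(
      manifest$variants$expected_criteria, paste, character(1),
      collapse = ";")
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  jsonlite::write_json(unclass(cohort$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
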