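# Stages 2-3: convert ClinVar-style gene extracts into matchable form,
# compare harvested variants against them, and deduplicate into distinct
# variants with published/unpublished status.

CLINVAR_SIGNIFICANCE <- c(
  "Benign", "Likely Benign", "Uncertain Significance",
  "Likely Pathogenic", "Pathogenic",
  "Conflicting Interpretations of Pathogenicity"
)

#' Convert a raw ClinVar-style extract into matchable entries
#'
#' Parses each row's HGVS `Name` (transcript accession, gene, c. change,
#' optional parenthesized p. change), converting the protein segment to
#' single-letter codes. Malformed names are counted, reported and skipped.
#'
#' @param raw tibble read from an extract CSV with columns `Name`, `Gene`,
#'   `Clinical significance`, `Review status` (column names are normalized
#'   case-insensitively; `Protein change` is optional and ignored in favour
#'   of the Name's own p. segment).
#' @param snapshot_date optional date recorded on every entry.
#' @return a tibble of entries with columns `name`, `gene`, `transcript`,
#'   `cdna_change`, `protein_change`, `protein_pos`, `protein_ref`,
#'   `protein_alt`, `consequence`, `significance`, `review_status`, `key`,
#'   `snapshot_date`; the number of skipped rows is attached as attribute
#'   `n_skipped`.
#' @export
convert_extract <- function(raw, snapshot_date = NA) {
  nm <- tolower(names(raw))
  pick <- function(what) {
    i <- match(what, nm)
    if (is.na(i)) stop("extract is missing column: ", what, call. = FALSE)
    raw[[i]]
  }
  name <- as.character(pick("name"))
  gene <- toupper(as.character(pick("gene")))
  significance <- as.character(pick("clinical significance"))
  review <- pick("review status")

  parsed <- parse_variant_string(name, gene)
  # the Name's own gene symbol wins when present; otherwise fall back to the
  # Gene column
  parsed$gene[is.na(parsed$gene) | parsed$gene == ""] <-
    gene[is.na(parsed$gene) | parsed$gene == ""]
  ok <- parsed$mapping_status == "mapped"
  if (any(!ok)) {
    message(sum(!ok), " extract row(s) with malformed Name skipped")
  }
  out <- tibble::tibble(
    name = name[ok],
    gene = parsed$gene[ok],
    transcript = parsed$transcript[ok],
    cdna_change = parsed$cdna_change[ok],
    protein_change = parsed$protein_change[ok],
    protein_pos = parsed$protein_pos[ok],
    protein_ref = parsed$protein_ref[ok],
    protein_alt = parsed$protein_alt[ok],
    consequence = parsed$consequence[ok],
    significance = significance[ok],
    review_status = as.integer(review)[ok],
    key = parsed$key[ok],
    snapshot_date = snapshot_date
  )
  attr(out, "n_skipped") <- sum(!ok)
  out
}

# Indices of extract entries matching each variant. Matching is on
# gene + c. change when the variant carries c. notation, otherwise on
# gene + single-letter protein change (both canonicalized, so comparison is
# case- and stop-synonym-insensitive). A protein-only variant never matches a
# c.-only entry: cross-level inference would require transcript translation.
match_in_extract <- function(gene, cdna_change, protein_change, extract) {
  gene <- toupper(gene)
  n <- length(gene)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    g <- extract$gene == gene[i]
    if (!is.na(cdna_change[i])) {
      hit <- g & !is.na(extract$cdna_change) &
        extract$cdna_change == cdna_change[i]
    } else if (!is.na(protein_change[i])) {
      hit <- g & !is.na(extract$protein_change) &
        extract$protein_change == protein_change[i]
    } else {
      hit <- rep(FALSE, nrow(extract))
    }
    out[[i]] <- which(hit)
  }
  out
}

#' Match distinct variants against a converted extract
#'
#' Adds a `published` flag (any extract entry matches) and the matched
#' entry's clinical significance (`matched_significance`; when several
#' entries match, the first in extract order).
#'
#' @param distinct tibble of distinct variants (see [deduplicate()]), or any
#'   tibble with `gene`, `cdna_change`, `protein_change` columns.
#' @param extract converted extract from [convert_extract()].
#' @return `distinct` with `published` and `matched_significance` added.
#' @export
match_variants <- function(distinct, extract) {
  hits <- match_in_extract(distinct$gene, distinct$cdna_change,
                           distinct$protein_change, extract)
  distinct$published <- lengths(hits) > 0
  distinct$matched_significance <- vapply(hits, function(ix) {
    if (length(ix) == 0) NA_character_ else extract$significance[ix[1]]
  }, character(1))
  distinct
}

#' Deduplicate variant observations into distinct variants
#'
#' Observations sharing a canonical key (gene + canonical representation)
#' collapse into one distinct variant accumulating supporting subjects,
#' diseases and allele count. A homozygous subject (same string twice)
#' contributes one supporter but two alleles. Output order is by key, so the
#' result is independent of observation order.
#'
#' @param observations observation tibble from [harvest_variants()].
#' @return a tibble with one row per distinct variant: parser columns plus
#'   `n_subjects`, `allele_count`, `subjects` and `diseases` list-columns.
#' @export
deduplicate <- function(observations) {
  if (nrow(observations) == 0) {
    return(tibble::tibble(
      key = character(), gene = character(), transcript = character(),
      cdna_change = character(), protein_change = character(),
      protein_pos = integer(), protein_ref = character(),
      protein_alt = character(), consequence = character(),
      mapping_status = character(), n_subjects = integer(),
      allele_count = integer(), subjects = list(), diseases = list()))
  }
  grp <- dplyr::group_by(observations, .data$key)
  out <- dplyr::summarise(
    grp,
    gene = dplyr::first(.data$gene),
    transcript = dplyr::first(.data$transcript),
    cdna_change = dplyr::first(.data$cdna_change),
    protein_change = dplyr::first(.data$protein_change),
    protein_pos = dplyr::first(.data$protein_pos),
    protein_ref = dplyr::first(.data$protein_ref),
    protein_alt = dplyr::first(.data$protein_alt),
    consequence = dplyr::first(.data$consequence),
    mapping_status = dplyr::first(.data$mapping_status),
    n_subjects = dplyr::n_distinct(.data$subject_id),
    allele_count = dplyr::n(),
    subjects = list(sort(unique(.data$subject_id))),
    diseases = list(sort(unique(.data$disease))),
    .groups = "drop")
  dplyr::arrange(out, .data$key)
}
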