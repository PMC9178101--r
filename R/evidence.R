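# Stage 4: map longitudinal clinical and computational data to ACMG/AMP
# evidence criteria, one profile per distinct unpublished variant.
#
# Evidence-to-data mapping: functional data (confirmatory metabolite/enzyme
# testing of every enrollee) supports PS3; the well-characterized early-onset
# phenotype of each screened disorder supports PP4; family-history fields
# support PP1 (segregation) and PM6 (de novo); allelic data under the
# in-trans assumption for recessive disorders supports PM3; extract
# neighbours support PM5; in-silico predictor tables support PP3/BP4/BP7; a
# secondary variant database supports PP5. Population-data criteria (PM2,
# BA1, BS1, ...) are representable in the engine but never auto-assigned —
# no population data is generated by a follow-up registry; they can be
# injected through the manual-override table.

PATHOGENIC_SIG <- c("Pathogenic", "Likely Pathogenic")

sig_is_plp <- function(x) {
  !is.na(x) & tolower(x) %in% tolower(PATHOGENIC_SIG)
}

#' Assign the study-wide criteria PS3 and PP4
#'
#' Every enrollee has a positive newborn screen plus a functional
#' confirmatory test (metabolite or enzyme assay), supporting PS3, and each
#' screened disorder presents a well-characterized phenotype, supporting
#' PP4. Both apply to every mapped variant whose supporting subjects all
#' carry a confirmed diagnosis; unmapped variants receive nothing. A
#' supporter without confirmed diagnosis withholds both, with a warning.
#'
#' @param distinct distinct-variant tibble (with `subjects` list-column).
#' @param subjects subject tibble with `subject_id`, `confirmed_dx`.
#' @return logical vector: variant receives \{PS3, PP4\}.
#' @export
assign_global_criteria <- function(distinct, subjects) {
  confirmed <- stats::setNames(subjects$confirmed_dx, subjects$subject_id)
  out <- logical(nrow(distinct))
  for (i in seq_len(nrow(distinct))) {
    if (distinct$mapping_status[i] != "mapped") next
    supp <- distinct$subjects[[i]]
    ok <- confirmed[supp]
    if (any(is.na(ok)) || !all(ok)) {
      warning("variant ", distinct$key[i],
              " has supporter(s) without confirmed diagnosis; ",
              "PS3/PP4 withheld", call. = FALSE)
      next
    }
    out[i] <- TRUE
  }
  out
}

#' Assess PVS1 (predicted null variant)
#'
#' @param distinct distinct-variant tibble.
#' @return logical vector: PVS1 applies.
#' @export
assess_pvs1 <- function(distinct) {
  distinct$mapping_status == "mapped" & is_null_variant(distinct$consequence)
}

#' Assess PM3 (in trans with a pathogenic allele)
#'
#' For autosomal recessive disorders, reported variant pairs are assumed in
#' trans. PM3 applies when some supporting subject's other reported allele
#' matches an extract entry with significance Pathogenic or Likely
#' Pathogenic. A VUS partner does not qualify, nor does a partner that is
#' itself unpublished (no asserted significance to lean on).
#'
#' @param distinct distinct-variant tibble.
#' @param observations observation tibble (for allele pairing).
#' @param extract converted extract.
#' @param inheritance tibble with `disease`, `inheritance` columns
#'   (`"AR"` = autosomal recessive); diseases absent from the table are
#'   treated as non-recessive.
#' @return logical vector: PM3 applies.
#' @export
assess_pm3 <- function(distinct, observations, extract, inheritance) {
  inh <- stats::setNames(inheritance$inheritance, inheritance$disease)
  # significance of every observed key, via extract matching
  obs_once <- observations[!duplicated(observations$key), , drop = FALSE]
  hits <- match_in_extract(obs_once$gene, obs_once$cdna_change,
                           obs_once$protein_change, extract)
  key_sig <- stats::setNames(vapply(hits, function(ix) {
    if (length(ix) == 0) NA_character_ else extract$significance[ix[1]]
  }, character(1)), obs_once$key)

  out <- logical(nrow(distinct))
  for (i in seq_len(nrow(distinct))) {
    if (distinct$mapping_status[i] != "mapped") next
    v_obs <- observations[observations$key == distinct$key[i], , drop = FALSE]
    for (j in seq_len(nrow(v_obs))) {
      if (!identical(inh[[v_obs$disease[j]]], "AR")) next
      partner <- observations[
        observations$subject_id == v_obs$subject_id[j] &
          observations$allele_index != v_obs$allele_index[j], , drop = FALSE]
      if (nrow(partner) == 0) next
      if (any(sig_is_plp(key_sig[partner$key]))) {
        out[i] <- TRUE
        break
      }
    }
  }
  out
}

#' Assess PM5 (novel missense at a position with a published pathogenic
#' missense)
#'
#' @param distinct distinct-variant tibble.
#' @param extract converted extract.
#' @return logical vector: PM5 applies.
#' @export
assess_pm5 <- function(distinct, extract) {
  path_missense <- extract[extract$consequence == "missense" &
                             sig_is_plp(extract$significance), , drop = FALSE]
  out <- logical(nrow(distinct))
  for (i in seq_len(nrow(distinct))) {
    if (distinct$mapping_status[i] != "mapped" ||
        distinct$consequence[i] != "missense" ||
        is.na(distinct$protein_pos[i])) next
    same_pos <- path_missense$gene == toupper(distinct$gene[i]) &
      path_missense$protein_pos == distinct$protein_pos[i] &
      path_missense$protein_alt != distinct$protein_alt[i]
    out[i] <- any(same_pos, na.rm = TRUE)
  }
  out
}

#' Assess family-history criteria PP1 and PM6
#'
#' PP1 (segregation): at least one supporting subject reports an affected,
#' genotyped relative carrying the same allele. PM6 (assumed de novo): a
#' de-novo indication without confirmed parentage.
#'
#' @param distinct distinct-variant tibble.
#' @param observations observation tibble.
#' @param subjects subject tibble with columns `fh_affected_carrier_allele1`,
#'   `fh_affected_carrier_allele2`, `de_novo_allele1`, `de_novo_allele2`,
#'   `parentage_confirmed`.
#' @return tibble with logical columns `pp1`, `pm6` (one row per distinct
#'   variant).
#' @export
assess_family <- function(distinct, observations, subjects) {
  sub_idx <- match(observations$subject_id, subjects$subject_id)
  fh_carrier <- ifelse(observations$allele_index == 1L,
                       subjects$fh_affected_carrier_allele1[sub_idx],
                       subjects$fh_affected_carrier_allele2[sub_idx])
  de_novo <- ifelse(observations$allele_index == 1L,
                    subjects$de_novo_allele1[sub_idx],
                    subjects$de_novo_allele2[sub_idx]) &
    !subjects$parentage_confirmed[sub_idx]

  pp1 <- logical(nrow(distinct))
  pm6 <- logical(nrow(distinct))
  for (i in seq_len(nrow(distinct))) {
    if (distinct$mapping_status[i] != "mapped") next
    sel <- observations$key == distinct$key[i]
    pp1[i] <- any(fh_carrier[sel], na.rm = TRUE)
    pm6[i] <- any(de_novo[sel], na.rm = TRUE)
  }
  tibble::tibble(pp1 = pp1, pm6 = pm6)
}

#' Assess computational criteria PP3 and BP4
#'
#' PP3 when every available predictor call for the variant is deleterious
#' (at least one call required); BP4 when every call is neutral; neither
#' when calls are discordant or absent. The all-concordant rule is this
#' module's documented convention.
#'
#' @param distinct distinct-variant tibble.
#' @param predictions predictor-score tibble with `gene`, `protein_change`,
#'   `predictor`, `call` (`"deleterious"`/`"neutral"`).
#' @return tibble with logical columns `pp3`, `bp4`.
#' @export
assess_computational <- function(distinct, predictions) {
  pp3 <- logical(nrow(distinct))
  bp4 <- logical(nrow(distinct))
  if (is.null(predictions) || nrow(predictions) == 0) {
    return(tibble::tibble(pp3 = pp3, bp4 = bp4))
  }
  for (i in seq_len(nrow(distinct))) {
    if (distinct$mapping_status[i] != "mapped" ||
        is.na(distinct$protein_change[i])) next
    calls <- predictions$call[
      toupper(predictions$gene) == toupper(distinct$gene[i]) &
        predictions$protein_change == distinct$protein_change[i]]
    if (length(calls) == 0) next
    pp3[i] <- all(calls == "deleterious")
    bp4[i] <- all(calls == "neutral")
  }
  tibble::tibble(pp3 = pp3, bp4 = bp4)
}

#' Assess PP5 (reported pathogenic in a reputable secondary database)
#'
#' @param distinct distinct-variant tibble.
#' @param secondary_db converted secondary-database extract (same shape as a
#'   ClinVar extract; see [convert_extract()]).
#' @return logical vector: PP5 applies.
#' @export
assess_pp5 <- function(distinct, secondary_db) {
  if (is.null(secondary_db) || nrow(secondary_db) == 0) {
    return(logical(nrow(distinct)))
  }
  hits <- match_in_extract(distinct$gene, distinct$cdna_change,
                           distinct$protein_change, secondary_db)
  mapped <- distinct$mapping_status == "mapped"
  vapply(seq_along(hits), function(i) {
    mapped[i] && any(sig_is_plp(secondary_db$significance[hits[[i]]]))
  }, logical(1))
}

#' Assess BP7 (synonymous variant with no deleterious prediction)
#'
#' @param distinct distinct-variant tibble.
#' @param predictions predictor-score tibble (may be NULL).
#' @return logical vector: BP7 applies.
#' @export
assess_bp7 <- function(distinct, predictions) {
  out <- logical(nrow(distinct))
  for (i in seq_len(nrow(distinct))) {
    if (distinct$mapping_status[i] != "mapped" ||
        distinct$consequence[i] != "synonymous") next
    calls <- character(0)
    if (!is.null(predictions) && nrow(predictions) > 0 &&
        !is.na(distinct$protein_change[i])) {
      calls <- predictions$call[
        toupper(predictions$gene) == toupper(distinct$gene[i]) &
          predictions$protein_change == distinct$protein_change[i]]
    }
    out[i] <- !any(calls == "deleterious")
  }
  out
}

#' Assemble criteria profiles for distinct unpublished variants
#'
#' Runs every criterion assessor and collects, per variant, the set of
#' assigned criterion codes with a provenance note naming the data source
#' that justified each. Unmapped variants always get an empty profile.
#' Manual overrides (curator adjustments) are applied last and logged into
#' provenance.
#'
#' @param distinct distinct-variant tibble (normally the unpublished subset).
#' @param observations observation tibble from [harvest_variants()].
#' @param subjects subject tibble.
#' @param extract converted baseline extract.
#' @param predictions predictor-score tibble or NULL.
#' @param secondary_db converted secondary extract or NULL.
#' @param inheritance disease-inheritance tibble.
#' @param overrides optional tibble with columns `key`, `code`, `action`
#'   (`"add"`/`"remove"`).
#' @return tibble with `key`, `mapping_status`, `criteria` (list-column) and
#'   `provenance` (list-column of named notes).
#' @export
assign_criteria <- function(distinct, observations, subjects, extract,
                            predictions = NULL, secondary_db = NULL,
                            inheritance = NULL, overrides = NULL) {
  if (is.null(inheritance)) {
    inheritance <- tibble::tibble(disease = character(),
                                  inheritance = character())
  }
  global <- assign_global_criteria(distinct, subjects)
  pvs1 <- assess_pvs1(distinct)
  pm3 <- assess_pm3(distinct, observations, extract, inheritance)
  pm5 <- assess_pm5(distinct, extract)
  fam <- assess_family(distinct, observations, subjects)
  comp <- assess_computational(distinct, predictions)
  pp5 <- assess_pp5(distinct, secondary_db)
  bp7 <- assess_bp7(distinct, predictions)

  notes <- c(
    PVS1 = "predicted null variant (notation-level consequence)",
    PS3 = "functional confirmatory testing of all supporting subjects",
    PM3 = "in trans with pathogenic allele (recessive disorder)",
    PM5 = "published pathogenic missense at same residue",
    PM6 = "de novo indication without confirmed parentage",
    PP1 = "affected genotyped relative carries the variant",
    PP3 = "all in-silico predictor calls deleterious",
    PP4 = "well-characterized single-gene phenotype",
    PP5 = "pathogenic in reputable secondary database",
    BP4 = "all in-silico predictor calls neutral",
    BP7 = "synonymous with no deleterious prediction"
  )

  criteria <- vector("list", nrow(distinct))
  provenance <- vector("list", nrow(distinct))
  for (i in seq_len(nrow(distinct))) {
    codes <- character(0)
    if (pvs1[i]) codes <- c(codes, "PVS1")
    if (global[i]) codes <- c(codes, "PS3")
    if (pm3[i]) codes <- c(codes, "PM3")
    if (pm5[i]) codes <- c(codes, "PM5")
    if (fam$pm6[i]) codes <- c(codes, "PM6")
    if (fam$pp1[i]) codes <- c(codes, "PP1")
    if (comp$pp3[i]) codes <- c(codes, "PP3")
    if (global[i]) codes <- c(codes, "PP4")
    if (pp5[i]) codes <- c(codes, "PP5")
    if (comp$bp4[i]) codes <- c(codes, "BP4")
    if (bp7[i]) codes <- c(codes, "BP7")
    criteria[[i]] <- codes
    provenance[[i]] <- notes[codes]
  }

  out <- tibble::tibble(
    key = distinct$key,
    mapping_status = distinct$mapping_status,
    criteria = criteria,
    provenance = provenance
  )

  if (!is.null(overrides) && nrow(overrides) > 0) {
    stopifnot(all(c("key", "code", "action") %in% names(overrides)))
    bad <- setdiff(overrides$code, ACMG_CODES)
    if (length(bad) > 0) {
      stop("unknown criterion code in overrides: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    for (j in seq_len(nrow(overrides))) {
      i <- match(overrides$key[j], out$key)
      if (is.na(i)) next
      if (out$mapping_status[i] != "mapped") next  # unmapped stay empty
      code <- overrides$code[j]
      if (overrides$action[j] == "add") {
        out$criteria[[i]] <- union(out$criteria[[i]], code)
        out$provenance[[i]][code] <- "manual override (add)"
      } else if (overrides$action[j] == "remove") {
        out$criteria[[i]] <- setdiff(out$criteria[[i]], code)
        out$provenance[[i]] <-
          out$provenance[[i]][names(out$provenance[[i]]) != code]
      }
    }
  }
  out
}
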