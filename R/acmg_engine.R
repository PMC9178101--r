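# ACMG/AMP combining-rule engine.
#
# Evidence criteria carry fixed strengths (PVS1 very strong; PS1-PS4 strong;
# PM1-PM6 moderate; PP1-PP5 supporting on the pathogenic axis; BA1
# stand-alone; BS1-BS4 strong; BP1-BP7 supporting on the benign axis). The
# engine tallies strengths and applies the complete published combining-rule
# table. If rules on both axes fire the result is Uncertain Significance with
# a conflict flag; if none fires, Uncertain Significance by default.

ACMG_CODES <- c(
  "PVS1",
  paste0("PS", 1:4),
  paste0("PM", 1:6),
  paste0("PP", 1:5),
  "BA1",
  paste0("BS", 1:4),
  paste0("BP", 1:7)
)

#' Strength class of ACMG/AMP criterion codes
#'
#' @param code character vector of criterion codes.
#' @return character vector: `"very_strong"`, `"strong"`, `"moderate"`,
#'   `"supporting"` (pathogenic axis), `"stand_alone"`, `"benign_strong"`,
#'   `"benign_supporting"` (benign axis).
#' @export
criterion_strength <- function(code) {
  bad <- setdiff(code, ACMG_CODES)
  if (length(bad) > 0) {
    stop("unknown ACMG/AMP criterion code: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  dplyr::case_when(
    code == "PVS1" ~ "very_strong",
    grepl("^PS", code) ~ "strong",
    grepl("^PM", code) ~ "moderate",
    grepl("^PP", code) ~ "supporting",
    code == "BA1" ~ "stand_alone",
    grepl("^BS", code) ~ "benign_strong",
    grepl("^BP", code) ~ "benign_supporting"
  )
}

# Tally a criteria set into strength counts.
criteria_counts <- function(criteria) {
  criteria <- unique(criteria)
  s <- criterion_strength(criteria)
  list(
    very_strong = sum(s == "very_strong"),
    strong = sum(s == "strong"),
    moderate = sum(s == "moderate"),
    supporting = sum(s == "supporting"),
    stand_alone = sum(s == "stand_alone"),
    benign_strong = sum(s == "benign_strong"),
    benign_supporting = sum(s == "benign_supporting")
  )
}

#' The ACMG/AMP combining-rule table
#'
#' Returns every combining rule in canonical evaluation order (Pathogenic
#' rules before Likely Pathogenic; Benign before Likely Benign) with its
#' label, resulting category, and requirement pattern. The label of a
#' classification is the first satisfied rule in this order.
#'
#' @param strict_lp3 logical; when `TRUE` the "Likely Pathogenic 3" rule
#'   requires more than two supporting criteria (sensitivity-analysis mode)
#'   instead of the published at-least-two.
#' @return a tibble with columns `label`, `category`, `axis`, `requires`.
#' @export
acmg_rule_table <- function(strict_lp3 = FALSE) {
  lp3_req <- if (strict_lp3) ">=1 strong and >2 supporting"
             else ">=1 strong and >=2 supporting"
  tibble::tibble(
    label = c(
      "Pathogenic 1a", "Pathogenic 1b", "Pathogenic 1c", "Pathogenic 1d",
      "Pathogenic 2", "Pathogenic 3a", "Pathogenic 3b", "Pathogenic 3c",
      "Likely Pathogenic 1", "Likely Pathogenic 2", "Likely Pathogenic 3",
      "Likely Pathogenic 4", "Likely Pathogenic 5", "Likely Pathogenic 6",
      "Benign 1", "Benign 2", "Likely Benign 1", "Likely Benign 2"
    ),
    category = c(
      rep("Pathogenic", 8), rep("Likely Pathogenic", 6),
      rep("Benign", 2), rep("Likely Benign", 2)
    ),
    axis = c(rep("pathogenic", 14), rep("benign", 4)),
    requires = c(
      "PVS1 and >=1 strong",
      "PVS1 and >=2 moderate",
      "PVS1 and 1 moderate and >=1 supporting",
      "PVS1 and >=2 supporting",
      ">=2 strong",
      ">=1 strong and >=3 moderate",
      ">=1 strong and >=2 moderate and >=2 supporting",
      ">=1 strong and >=1 moderate and >=4 supporting",
      "PVS1 and >=1 moderate",
      ">=1 strong and 1-2 moderate",
      lp3_req,
      ">=3 moderate",
      ">=2 moderate and >=2 supporting",
      ">=1 moderate and >=4 supporting",
      "BA1",
      ">=2 benign strong",
      "1 benign strong and >=1 benign supporting",
      ">=2 benign supporting"
    )
  )
}

# Rule predicates over a strength tally, in canonical order. Kept separate
# from acmg_rule_table() so the table stays a plain description.
acmg_rule_predicates <- function(strict_lp3 = FALSE) {
  lp3_min_supporting <- if (strict_lp3) 3L else 2L
  list(
    "Pathogenic 1a" = function(k) k$very_strong >= 1 && k$strong >= 1,
    "Pathogenic 1b" = function(k) k$very_strong >= 1 && k$moderate >= 2,
    "Pathogenic 1c" = function(k) k$very_strong >= 1 && k$moderate == 1 && k$supporting >= 1,
    "Pathogenic 1d" = function(k) k$very_strong >= 1 && k$supporting >= 2,
    "Pathogenic 2"  = function(k) k$strong >= 2,
    "Pathogenic 3a" = function(k) k$strong >= 1 && k$moderate >= 3,
    "Pathogenic 3b" = function(k) k$strong >= 1 && k$moderate >= 2 && k$supporting >= 2,
    "Pathogenic 3c" = function(k) k$strong >= 1 && k$moderate >= 1 && k$supporting >= 4,
    "Likely Pathogenic 1" = function(k) k$very_strong >= 1 && k$moderate >= 1,
    "Likely Pathogenic 2" = function(k) k$strong >= 1 && k$moderate >= 1 && k$moderate <= 2,
    "Likely Pathogenic 3" = function(k) k$strong >= 1 && k$supporting >= lp3_min_supporting,
    "Likely Pathogenic 4" = function(k) k$moderate >= 3,
    "Likely Pathogenic 5" = function(k) k$moderate >= 2 && k$supporting >= 2,
    "Likely Pathogenic 6" = function(k) k$moderate >= 1 && k$supporting >= 4,
    "Benign 1" = function(k) k$stand_alone >= 1,
    "Benign 2" = function(k) k$benign_strong >= 2,
    "Likely Benign 1" = function(k) k$benign_strong >= 1 && k$benign_supporting >= 1,
    "Likely Benign 2" = function(k) k$benign_supporting >= 2
  )
}

#' Classify one set of evidence criteria
#'
#' Applies the full combining-rule table to a set of ACMG/AMP criterion
#' codes. The category is determined solely by the strength tally; the rule
#' label records the first satisfied rule in canonical order (Pathogenic
#' before Likely Pathogenic). When rules fire on both the pathogenic and the
#' benign axis, the result is Uncertain Significance with label
#' `"conflict-VUS"`; when no rule fires, label `"default-VUS"`.
#'
#' @param criteria character vector of criterion codes (duplicates ignored);
#'   an unknown code is a hard error.
#' @param strict_lp3 see [acmg_rule_table()].
#' @return a list with `category`, `rule_label` and `counts` (the strength
#'   tally).
#' @export
#' @examples
#' classify_variant(c("PVS1", "PS3", "PP4"))$rule_label
classify_variant <- function(criteria, strict_lp3 = FALSE) {
  k <- criteria_counts(criteria)
  preds <- acmg_rule_predicates(strict_lp3)
  rules <- acmg_rule_table(strict_lp3)
  fired <- vapply(preds, function(f) isTRUE(f(k)), logical(1))
  path_fired <- fired & rules$axis == "pathogenic"
  benign_fired <- fired & rules$axis == "benign"
  if (any(path_fired) && any(benign_fired)) {
    return(list(category = "Uncertain Significance",
                rule_label = "conflict-VUS", counts = k))
  }
  if (any(fired)) {
    first <- which(fired)[1]
    return(list(category = rules$category[first],
                rule_label = rules$label[first], counts = k))
  }
  list(category = "Uncertain Significance", rule_label = "default-VUS",
       counts = k)
}

#' Classify a table of criteria profiles
#'
#' Vectorized driver over [classify_variant()]. Rows whose `mapping_status`
#' is `"unmapped_reference_mismatch"` bypass the rule engine and are reported
#' as `"Excluded-Unmapped"` (such variants carry no criteria by construction).
#'
#' @param profiles tibble with a `key` column, a `criteria` list-column of
#'   criterion-code vectors, and optionally `mapping_status`.
#' @param strict_lp3 see [acmg_rule_table()].
#' @return `profiles` with `category` and `rule_label` columns added.
#' @export
classify_profiles <- function(profiles, strict_lp3 = FALSE) {
  n <- nrow(profiles)
  category <- character(n)
  rule_label <- character(n)
  has_status <- "mapping_status" %in% names(profiles)
  for (i in seq_len(n)) {
    if (has_status &&
        identical(profiles$mapping_status[i], "unmapped_reference_mismatch")) {
      category[i] <- "Excluded-Unmapped"
      rule_label[i] <- "excluded-unmapped"
      next
    }
    res <- classify_variant(profiles$criteria[[i]], strict_lp3 = strict_lp3)
    category[i] <- res$category
    rule_label[i] <- res$rule_label
  }
  profiles$category <- category
  profiles$rule_label <- rule_label
  profiles
}
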