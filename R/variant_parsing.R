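# Parsing and normalization of heterogeneous variant submissions.
#
# Registry records report variants in several dialects: HGVS coding notation
# ("c.549A>C", often with stray spaces around ">"), HGVS protein notation with
# three-letter residues ("p. Phe256Leu"), bare single-letter protein notation
# ("F256L"), and non-variant placeholder tokens ("none", "negative"). Every
# input string is normalized into one canonical representation with an explicit
# mapping status; no input raises an error.

# Three-letter <-> single-letter residue codes (20 standard residues + stop).
AA_THREE_TO_ONE <- c(
  Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
  Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
  Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
  Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V",
  Ter = "*"
)
AA_ONE_TO_THREE <- stats::setNames(names(AA_THREE_TO_ONE), AA_THREE_TO_ONE)

#' Convert three-letter residue codes to single-letter codes
#'
#' Case-insensitive on input; the stop synonyms `Ter`, `X` and `*` all map to
#' `"*"`. Unknown codes map to `NA`.
#'
#' @param x character vector of three-letter residue codes.
#' @return character vector of single-letter codes.
#' @export
#' @examples
#' aa_three_to_one(c("Phe", "Ter", "arg"))
aa_three_to_one <- function(x) {
  x <- paste0(toupper(substr(x, 1, 1)), tolower(substr(x, 2, nchar(x))))
  x[x %in% c("X", "*")] <- "Ter"
  unname(AA_THREE_TO_ONE[x])
}

#' Convert single-letter residue codes to three-letter codes
#'
#' @param x character vector of single-letter residue codes (`*` for stop).
#' @return character vector of three-letter codes.
#' @export
aa_one_to_three <- function(x) {
  unname(AA_ONE_TO_THREE[toupper(x)])
}

#' Default non-variant placeholder tokens
#'
#' Tokens that clinicians enter in a variant field to record that no variant
#' was reported. Matched case-insensitively after trimming.
#'
#' @return character vector.
#' @export
default_invalid_tokens <- function() c("none", "negative", "")

# --- internal: protein-change parsing ---------------------------------------

# Parse the payload of a protein change (after stripping "p.", spaces and
# enclosing parentheses). Returns list(ref, pos, alt) with single-letter
# ref/alt ("*" for stop, "fs" for frameshift) or NULL when the payload does
# not match the supported grammar. "X" is read as stop only in the alt
# position; elsewhere it is rejected (it would collide with unknown-residue
# usage).
parse_protein_payload <- function(txt) {
  # three-letter form, e.g. Phe256Leu, Trp123Ter, Lys329fs, Lys329Serfs*12
  m <- regmatches(txt, regexec(
    "^([A-Za-z]{3})(\\d+)([A-Za-z]{3}|\\*|=|(?:[A-Za-z]{3})?[Ff][Ss].*)$",
    txt))[[1]]
  if (length(m) == 4) {
    ref <- aa_three_to_one(m[2])
    pos <- as.integer(m[3])
    alt_raw <- m[4]
    if (is.na(ref) || ref == "*") return(NULL)
    if (grepl("^(?:[A-Za-z]{3})?[Ff][Ss]", alt_raw) &&
        !grepl("^([A-Za-z]{3}|\\*|=)$", alt_raw)) {
      return(list(ref = ref, pos = pos, alt = "fs"))
    }
    if (alt_raw == "=") return(list(ref = ref, pos = pos, alt = ref))
    if (alt_raw == "*") return(list(ref = ref, pos = pos, alt = "*"))
    alt <- aa_three_to_one(alt_raw)
    if (is.na(alt)) {
      # three-letter ref with a frameshift tail like Glufs handled above;
      # anything else is unparseable
      return(NULL)
    }
    return(list(ref = ref, pos = pos, alt = alt))
  }
  # single-letter form, e.g. F256L, W123X, K329fs
  m <- regmatches(txt, regexec(
    "^([A-Za-z])(\\d+)([A-Za-z]|\\*|=|[Ff][Ss].*)$", txt))[[1]]
  if (length(m) == 4) {
    ref <- toupper(m[2])
    pos <- as.integer(m[3])
    alt_raw <- m[4]
    if (!ref %in% AA_THREE_TO_ONE || ref == "*") return(NULL)
    if (toupper(ref) == "X") return(NULL)
    if (grepl("^[Ff][Ss]", alt_raw)) {
      return(list(ref = ref, pos = pos, alt = "fs"))
    }
    if (alt_raw == "=") return(list(ref = ref, pos = pos, alt = ref))
    alt <- toupper(alt_raw)
    if (alt %in% c("X", "*")) alt <- "*"
    if (!(alt %in% AA_THREE_TO_ONE)) return(NULL)
    return(list(ref = ref, pos = pos, alt = alt))
  }
  NULL
}

# Parse a canonicalized (whitespace-stripped) c. string. Returns
# list(pos, offset, kind, len) or NULL. kind in {sub, del, dup, ins, delins}.
parse_cdna_payload <- function(txt) {
  m <- regmatches(txt, regexec(
    "^c\\.(\\d+)([+-]\\d+)?([ACGTacgt])>([ACGTacgt])$", txt))[[1]]
  if (length(m) == 5) {
    return(list(
      pos = as.integer(m[2]),
      offset = if (m[3] == "") 0L else as.integer(m[3]),
      kind = "sub", len = 1L,
      canonical = sprintf("c.%s%s%s>%s", m[2], m[3], toupper(m[4]), toupper(m[5]))
    ))
  }
  m <- regmatches(txt, regexec(
    "^c\\.(\\d+)([+-]\\d+)?(?:_(\\d+)([+-]\\d+)?)?(del|dup|ins|delins)([ACGTacgt]*)$",
    txt))[[1]]
  if (length(m) == 7) {
    start <- as.integer(m[2])
    end <- if (m[4] == "") start else as.integer(m[4])
    kind <- m[6]
    seq <- toupper(m[7])
    len <- if (nzchar(seq)) nchar(seq) else end - start + 1L
    if (kind == "ins" && !nzchar(seq)) return(NULL)
    canonical <- paste0("c.", m[2], m[3],
                        if (m[4] != "") paste0("_", m[4], m[5]) else "",
                        kind, seq)
    return(list(pos = start,
                offset = if (m[3] == "") 0L else as.integer(m[3]),
                kind = kind, len = len, canonical = canonical))
  }
  NULL
}

# Consequence from parsed components. Protein-level information wins when
# present; a bare c. substitution without protein annotation is "unknown"
# (its protein effect cannot be read from the notation alone).
consequence_from_parts <- function(prot, cdna) {
  if (!is.null(prot)) {
    if (prot$alt == "fs") return("frameshift")
    if (prot$alt == "*") return("nonsense")
    if (prot$pos == 1L && prot$ref == "M" && prot$alt != "M") return("start_loss")
    if (prot$ref == prot$alt) return("synonymous")
    return("missense")
  }
  if (!is.null(cdna)) {
    if (cdna$kind == "sub") {
      if (cdna$offset != 0L && abs(cdna$offset) <= 2L) return("canonical_splice")
      if (cdna$offset != 0L) return("other")
      return("unknown")
    }
    if (cdna$kind %in% c("del", "dup", "ins", "delins")) {
      if (cdna$len %% 3L != 0L) return("frameshift")
      return("other")
    }
  }
  "unknown"
}

#' Parse and normalize raw variant strings
#'
#' Auto-detects the reporting dialect of each string: full ClinVar-style names
#' (`NM_000159.4(GCDH):c.776C>T (p.Ser259Leu)`), HGVS coding changes with or
#' without internal whitespace (`c.549A > C`), HGVS protein changes in
#' three-letter (`p. Phe256Leu`) or single-letter (`p.F256L`) form, bare
#' protein changes (`F256L`, `Phe256Leu`), frameshifts (`K329fs`), and stop
#' synonyms (`Ter`, `X`, `*`, unified to `*`). Strings in `invalid_tokens`
#' (case-insensitive, trimmed) get `mapping_status = "invalid_token"`; any
#' other undecodable text gets `"unparseable"`. No input raises an error.
#'
#' Protein positions are 1-based, per HGVS convention.
#'
#' @param raw character vector of raw variant strings (NA allowed).
#' @param gene character vector (length 1 or `length(raw)`) of gene symbols.
#' @param transcript optional transcript accession(s); overridden when the raw
#'   string itself carries an accession.
#' @param invalid_tokens tokens treated as "no variant reported".
#' @return a tibble with one row per input and columns `raw`, `gene`,
#'   `transcript`, `cdna_change`, `protein_change`, `protein_pos`,
#'   `protein_ref`, `protein_alt`, `consequence`, `mapping_status`, `key`.
#' @export
#' @examples
#' parse_variant_string(c("F256L", "c.549A > C", "p. Phe256Leu", "none"), "PAH")
parse_variant_string <- function(raw, gene,
                                 transcript = NA_character_,
                                 invalid_tokens = default_invalid_tokens()) {
  n <- length(raw)
  gene <- rep_len(toupper(as.character(gene)), n)
  transcript <- rep_len(as.character(transcript), n)
  invalid_tokens <- tolower(trimws(invalid_tokens))

  if (n == 0) {
    return(parse_one_variant("", "", NA_character_, character(0))[0, ])
  }
  out <- vector("list", n)
  for (i in seq_len(n)) {
    out[[i]] <- parse_one_variant(raw[i], gene[i], transcript[i], invalid_tokens)
  }
  dplyr::bind_rows(out)
}

parse_one_variant <- function(raw, gene, transcript, invalid_tokens) {
  res <- tibble::tibble(
    raw = if (is.na(raw)) NA_character_ else raw,
    gene = gene,
    transcript = transcript,
    cdna_change = NA_character_,
    protein_change = NA_character_,
    protein_pos = NA_integer_,
    protein_ref = NA_character_,
    protein_alt = NA_character_,
    consequence = "unknown",
    mapping_status = "unparseable",
    key = NA_character_
  )
  txt <- if (is.na(raw)) "" else trimws(raw)
  if (tolower(txt) %in% invalid_tokens) {
    res$mapping_status <- "invalid_token"
    return(res)
  }

  # ClinVar-style full name: accession(GENE):c.change (p.change)
  m <- regmatches(txt, regexec(
    "^([A-Z]{2}_\\d+(?:\\.\\d+)?)\\s*\\(([A-Za-z0-9_-]+)\\)\\s*:\\s*(.*)$", txt))[[1]]
  if (length(m) == 4) {
    res$transcript <- m[2]
    res$gene <- toupper(m[3])
    txt <- trimws(m[4])
  }

  prot <- NULL
  cdna <- NULL

  # optional trailing "(p....)" protein segment
  pm <- regmatches(txt, regexec("^(.*?)\\s*\\(\\s*p\\.\\s*([^)]*)\\)$", txt))[[1]]
  if (length(pm) == 3 && grepl("c\\.", pm[2])) {
    prot <- parse_protein_payload(gsub("\\s", "", pm[3]))
    txt <- trimws(pm[2])
  }

  compact <- gsub("\\s", "", txt)
  if (grepl("^c\\.", compact)) {
    cdna <- parse_cdna_payload(compact)
    if (is.null(cdna) && is.null(prot)) return(res)
  } else if (grepl("^p\\.", compact) || grepl("^\\(p\\.", compact)) {
    payload <- sub("^\\(?p\\.", "", sub("\\)$", "", compact))
    prot <- parse_protein_payload(payload)
    if (is.null(prot)) return(res)
  } else if (is.null(prot)) {
    prot <- parse_protein_payload(compact)
    if (is.null(prot)) return(res)
  }

  if (is.null(prot) && is.null(cdna)) return(res)

  if (!is.null(cdna)) res$cdna_change <- cdna$canonical
  if (!is.null(prot)) {
    res$protein_change <- paste0(prot$ref, prot$pos,
                                 if (prot$alt == "fs") "fs" else prot$alt)
    res$protein_pos <- prot$pos
    res$protein_ref <- prot$ref
    res$protein_alt <- prot$alt
  }
  res$consequence <- consequence_from_parts(prot, cdna)
  res$mapping_status <- "mapped"
  res$key <- variant_key(res$gene, res$cdna_change, res$protein_change)
  res
}

#' Canonical matching key for a normalized variant
#'
#' The coding-level (c.) representation anchors the key when present (ClinVar
#' names are c.-anchored); otherwise the single-letter protein change is used.
#' Gene symbols are upper-cased; transcript versions never enter the key.
#'
#' @param gene gene symbol(s).
#' @param cdna_change canonical c. string(s) or NA.
#' @param protein_change canonical single-letter protein change(s) or NA.
#' @return character vector of keys (NA where neither representation exists).
#' @export
variant_key <- function(gene, cdna_change, protein_change) {
  dplyr::if_else(
    !is.na(cdna_change),
    paste0(toupper(gene), "|", cdna_change),
    dplyr::if_else(!is.na(protein_change),
                   paste0(toupper(gene), "|p.", protein_change),
                   NA_character_)
  )
}

#' Validate the reported reference residue against a reference protein
#'
#' For each parsed variant that carries a protein change, the reference
#' protein of its gene is looked up and the residue at the stated (1-based)
#' position compared with the stated reference letter. Disagreement — or a
#' position beyond the end of the protein — sets
#' `mapping_status = "unmapped_reference_mismatch"`; such variants are
#' excluded from criteria assignment downstream. Variants without a protein
#' representation (e.g. pure c. notation) are left untouched.
#'
#' @param variants tibble from [parse_variant_string()].
#' @param references tibble with columns `gene`, `transcript`, `protein`
#'   (single-letter amino-acid strings), as produced by
#'   [generate_reference_sequences()] or [read_reference_fasta()].
#' @return `variants` with `mapping_status` updated and a `mismatch_note`
#'   column describing any failure.
#' @export
validate_reference <- function(variants, references) {
  stopifnot(all(c("gene", "protein") %in% names(references)))
  ref_by_gene <- stats::setNames(references$protein, toupper(references$gene))
  note <- rep(NA_character_, nrow(variants))
  status <- variants$mapping_status
  for (i in seq_len(nrow(variants))) {
    if (status[i] != "mapped" || is.na(variants$protein_pos[i])) next
    prot <- ref_by_gene[[toupper(variants$gene[i])]]
    if (is.null(prot) || is.na(prot)) next
    pos <- variants$protein_pos[i]
    if (pos > nchar(prot)) {
      status[i] <- "unmapped_reference_mismatch"
      note[i] <- sprintf("position %d out of range (protein length %d)",
                         pos, nchar(prot))
      next
    }
    actual <- substr(prot, pos, pos)
    if (!identical(actual, variants$protein_ref[i])) {
      status[i] <- "unmapped_reference_mismatch"
      note[i] <- sprintf("stated reference %s at position %d, protein has %s",
                         variants$protein_ref[i], pos, actual)
    }
  }
  variants$mapping_status <- status
  variants$mismatch_note <- note
  variants
}

#' Classify the molecular consequence of parsed variants
#'
#' Recomputes the consequence column from the canonical representations:
#' nonsense (alt is stop), frameshift (`fs` suffix, or a c. del/dup/ins whose
#' length is not divisible by 3), canonical splice (c. substitution at intron
#' offset +/-1 or +/-2), start loss (p.M1 substitution), synonymous
#' (ref == alt), missense, otherwise other/unknown.
#'
#' @param variants tibble from [parse_variant_string()].
#' @return `variants` with `consequence` recomputed.
#' @export
classify_consequence <- function(variants) {
  for (i in seq_len(nrow(variants))) {
    if (variants$mapping_status[i] %in% c("invalid_token", "unparseable")) next
    prot <- NULL
    cdna <- NULL
    if (!is.na(variants$protein_change[i])) {
      prot <- list(ref = variants$protein_ref[i],
                   pos = variants$protein_pos[i],
                   alt = variants$protein_alt[i])
    }
    if (!is.na(variants$cdna_change[i])) {
      cdna <- parse_cdna_payload(variants$cdna_change[i])
    }
    variants$consequence[i] <- consequence_from_parts(prot, cdna)
  }
  variants
}

#' Predicted-null predicate
#'
#' A variant is predicted null when its notation indicates loss of gene
#' product function: nonsense, frameshift, canonical +/-1/2 splice, or start
#' loss. This is the eligibility test for the PVS1 criterion.
#'
#' @param consequence character vector of consequence classes.
#' @return logical vector.
#' @export
is_null_variant <- function(consequence) {
  consequence %in% c("nonsense", "frameshift", "canonical_splice", "start_loss")
}
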