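#' Drug vocabulary
#'
#' The package classifies antitumor and concomitant drugs through a small
#' versioned vocabulary table shipped with the package. Each row is one drug:
#'
#' * `drug_id` — stable lookup key used in prescription records.
#' * `canonical_name` — human-readable name.
#' * `drug_class` — one of `fluoropyrimidine_oral`, `fluoropyrimidine_iv`,
#'   `oxaliplatin`, `irinotecan`, `ftd_tpi`, `antiangiogenic`, `anti_egfr`,
#'   `other_targeted`, `leucovorin`, `antihypertensive`, `anticholinergic`,
#'   `anticoagulant`, `other`.
#' * `is_biologic` — `TRUE` exactly for the five monoclonal antibodies
#'   (bevacizumab, ramucirumab, aflibercept beta, cetuximab, panitumumab);
#'   only these participate in the biologic-addition exception.
#' * `is_antitumor` — `TRUE` for drugs that start/extend therapy lines.
#'   Antitumor drugs of class `other` are outside the treatment-guideline
#'   list and trigger cohort exclusion.
#' * `default_cycle_days` — cycle length used for expected-final-dose dates
#'   when a prescription has no `days_supplied`: 14 for drugs given on
#'   biweekly schedules (infusional 5-FU, leucovorin, oxaliplatin,
#'   irinotecan, and the five antibodies), 21 for capecitabine, S-1 and
#'   FTD/TPI oral cycles, 28 as the generic oral fallback.
#'
#' @param path optional path to a user-supplied vocabulary CSV with the same
#'   columns, allowing extension of the shipped table.
#' @return a tibble, one row per drug.
#' @export
#' @examples
#' drug_vocabulary()
drug_vocabulary <- function(path = NULL) {
  path <- path %||% system.file("extdata", "drug_vocabulary.csv", package = "crclot")
  vocab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("drug_id", "canonical_name", "drug_class", "is_biologic",
                "is_antitumor", "default_cycle_days")
  missing <- setdiff(required, names(vocab))
  if (length(missing) > 0) {
    abort(paste0("vocabulary file lacks columns: ", paste(missing, collapse = ", ")))
  }
  mabs <- sort(vocab$drug_id[vocab$is_biologic])
  expected <- sort(c("bevacizumab", "ramucirumab", "aflibercept_beta",
                     "cetuximab", "panitumumab"))
  if (!identical(mabs, expected)) {
    abort("is_biologic must be TRUE exactly for the five monoclonal antibodies")
  }
  vocab
}

# Fixed biologic display order used for suffixes and tie-breaking:
# antiangiogenics first (BEV < RAM < AFL), then anti-EGFR (CET < PANI).
BIOLOGIC_ORDER <- c(bevacizumab = "BEV", ramucirumab = "RAM",
                    aflibercept_beta = "AFL", cetuximab = "CET",
                    panitumumab = "PANI")

ANTIANGIOGENIC_DRUGS <- c("bevacizumab", "ramucirumab", "aflibercept_beta")
ANTI_EGFR_DRUGS <- c("cetuximab", "panitumumab")
FIRST_LINE_MABS <- c("bevacizumab", "cetuximab", "panitumumab")
ADJUVANT_DRUGS <- c("capecitabine", "fluorouracil", "s1", "uft", "oxaliplatin")

# Exact-set backbone dictionary over the non-biologic antitumor drugs
# (+ leucovorin, which is a modulator and never defines a line by itself).
backbone_dictionary <- function() {
  list(
    FOLFOX    = c("fluorouracil", "leucovorin", "oxaliplatin"),
    FOLFIRI   = c("fluorouracil", "leucovorin", "irinotecan"),
    FOLFOXIRI = c("fluorouracil", "leucovorin", "oxaliplatin", "irinotecan"),
    CAPOX     = c("capecitabine", "oxaliplatin"),
    SOX       = c("s1", "oxaliplatin"),
    IRIS      = c("s1", "irinotecan"),
    CAPE      = "capecitabine",
    `S-1`     = "s1",
    `5-FU`    = "fluorouracil",
    `5-FU/LV` = c("fluorouracil", "leucovorin"),
    UFT       = "uft",
    `UFT/LV`  = c("uft", "leucovorin"),
    `FTD/TPI` = "ftd_tpi",
    IRI       = "irinotecan"
  )
}

#' Look up a drug in the vocabulary
#'
#' @param drug_id character vector of drug keys.
#' @param vocab vocabulary table from [drug_vocabulary()].
#' @return a tibble with one row per requested drug, in input order.
#' @export
#' @examples
#' classify_drug(c("bevacizumab", "capecitabine"))
classify_drug <- function(drug_id, vocab = drug_vocabulary()) {
  idx <- match(drug_id, vocab$drug_id)
  if (anyNA(idx)) {
    abort(paste0("unknown drug_id: ",
                 paste(unique(drug_id[is.na(idx)]), collapse = ", ")))
  }
  vocab[idx, ]
}

#' Name a regimen from a drug set
#'
#' The regimen backbone is determined solely by the set of non-biologic
#' antitumor drugs (plus leucovorin) by exact-set match against the backbone
#' dictionary (e.g. 5-FU + leucovorin + oxaliplatin -> FOLFOX; capecitabine +
#' oxaliplatin -> CAPOX). Sets matching no entry are labelled `OTHER` with the
#' raw set retained. Biologics are appended as an ordered suffix
#' (BEV < RAM < AFL < CET < PANI); multi-biologic sets are retained and
#' flagged as unusual rather than rejected.
#'
#' @param drug_ids non-empty character vector (a set; order is irrelevant).
#' @param vocab vocabulary table.
#' @return one-row tibble: `backbone`, `biologic_suffix` (list-column of
#'   display codes), `label` (display string), `base_drugs` (list-column of
#'   the non-biologic antitumor + leucovorin set), `raw_drug_set`
#'   (list-column), `multi_biologic` flag.
#' @export
#' @examples
#' name_regimen(c("fluorouracil", "leucovorin", "oxaliplatin", "bevacizumab"))
name_regimen <- function(drug_ids, vocab = drug_vocabulary()) {
  drug_ids <- unique(drug_ids)
  if (length(drug_ids) == 0) abort("empty drug set")
  entries <- classify_drug(drug_ids, vocab)
  biologics <- entries$drug_id[entries$is_biologic]
  base <- entries$drug_id[(entries$is_antitumor & !entries$is_biologic) |
                            entries$drug_class == "leucovorin"]
  backbone <- backbone_for_set(base)
  suffix <- BIOLOGIC_ORDER[intersect(names(BIOLOGIC_ORDER), biologics)]
  label <- if (length(base) == 0 && length(suffix) > 0) {
    paste(suffix, collapse = "+")
  } else {
    paste(c(backbone, suffix), collapse = "+")
  }
  tibble::tibble(
    backbone = backbone,
    biologic_suffix = list(unname(suffix)),
    label = label,
    base_drugs = list(sort(base)),
    raw_drug_set = list(sort(drug_ids)),
    multi_biologic = length(suffix) > 1
  )
}

backbone_for_set <- function(base_drugs) {
  key <- sort(base_drugs)
  for (bk in names(backbone_dictionary())) {
    if (identical(sort(backbone_dictionary()[[bk]]), key)) return(bk)
  }
  "OTHER"
}

#' Group a regimen label into major regimen classes
#'
#' Backbones containing oxaliplatin are `oxaliplatin_based`; irinotecan
#' without oxaliplatin is `irinotecan_based`; backbones containing both
#' (FOLFOXIRI) are reported under the combined group
#' `oxaliplatin_irinotecan_based`; a single fluoropyrimidine (with or
#' without leucovorin) is `fluoropyrimidine_monotherapy`; everything else is
#' `other`.
#'
#' @param regimen a tibble of regimen rows from [name_regimen()] (or a
#'   `base_drugs` list-column thereof).
#' @param vocab vocabulary table.
#' @return character vector of groups, one per regimen row.
#' @export
#' @examples
#' regimen_group(name_regimen(c("capecitabine", "oxaliplatin")))
regimen_group <- function(regimen, vocab = drug_vocabulary()) {
  base_sets <- if (is.data.frame(regimen)) regimen$base_drugs else regimen
  fp_classes <- c("fluoropyrimidine_oral", "fluoropyrimidine_iv")
  purrr::map_chr(base_sets, function(base) {
    if (length(base) == 0) return("other")
    cls <- classify_drug(base, vocab)$drug_class
    has_ox <- "oxaliplatin" %in% cls
    has_iri <- "irinotecan" %in% cls
    if (has_ox && has_iri) return("oxaliplatin_irinotecan_based")
    if (has_ox) return("oxaliplatin_based")
    if (has_iri) return("irinotecan_based")
    non_lv <- cls[cls != "leucovorin"]
    if (length(non_lv) == 1 && non_lv %in% fp_classes) {
      return("fluoropyrimidine_monotherapy")
    }
    "other"
  })
}
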