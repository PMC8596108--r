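#' The six microtubule-targeting drugs used for the response signature
#'
#' Taxanes, vinca alkaloids and the epothilone in the screening panel whose
#' joint sensitivity pattern defines the pan-sensitive / pan-resistant PDO
#' groups used for signature derivation.
#'
#' @format Character vector of six drug identifiers.
#' @export
MICROTUBULE_DRUGS <- c(
  "docetaxel", "paclitaxel", "vinorelbine",
  "ixabepilone", "vincristine", "vinblastine"
)

#' Construct one drug-panel entry
#'
#' A panel entry records the tested dose range of one compound: the top
#' concentration, the dilution fold, and the number of points of the series.
#' Concentrations are stored in molar units throughout the package.
#'
#' @param drug_id Short drug identifier (non-empty string).
#' @param target_label Free-text target / mechanism annotation.
#' @param top_conc Top tested concentration in molar; must be positive.
#' @param fold Dilution factor between adjacent points; must exceed 1.
#' @param n_points Number of points in the series; integer >= 1.
#' @param approved_for_breast Logical; is the drug approved for breast cancer?
#' @return A one-row data frame with the validated fields.
#' @export
drug_panel_entry <- function(drug_id, target_label = "",
                             top_conc = 20e-6, fold = 3, n_points = 7L,
                             approved_for_breast = FALSE) {
  if (!is.character(drug_id) || length(drug_id) != 1L || !nzchar(drug_id))
    stop("'drug_id' must be a non-empty string")
  if (!is.numeric(top_conc) || top_conc <= 0)
    stop("'top_conc' must be a positive molar concentration")
  if (!is.numeric(fold) || fold <= 1)
    stop("'fold' must be a dilution factor > 1")
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 1L)
    stop("'n_points' must be an integer >= 1")
  data.frame(
    drug_id = drug_id,
    target_label = as.character(target_label),
    top_conc = as.numeric(top_conc),
    fold = as.numeric(fold),
    n_points = n_points,
    approved_for_breast = isTRUE(approved_for_breast),
    stringsAsFactors = FALSE
  )
}

#' Default 49-drug screening panel
#'
#' Nineteen drugs approved for breast cancer and thirty drugs approved for
#' other cancer types, each with the default 7-point threefold series from a
#' 20 uM top dose. The panel is a synthetic stand-in assembled from the drug
#' names reported for the screen; per-drug range adjustments made during the
#' original screen are not reproduced.
#'
#' @return Data frame with one row per drug (see [drug_panel_entry()]).
#' @export
default_panel <- function() {
  breast <- list(
    c("docetaxel",    "microtubule stabilizer (taxane)"),
    c("paclitaxel",   "microtubule stabilizer (taxane)"),
    c("vinorelbine",  "microtubule destabilizer (vinca)"),
    c("ixabepilone",  "microtubule stabilizer (epothilone)"),
    c("vincristine",  "microtubule destabilizer (vinca)"),
    c("vinblastine",  "microtubule destabilizer (vinca)"),
    c("gemcitabine",  "nucleoside analogue"),
    c("fluorouracil", "antimetabolite"),
    c("methotrexate", "dihydrofolate reductase inhibitor"),
    c("epirubicin",   "anthracycline / topoisomerase II"),
    c("doxorubicin",  "anthracycline / topoisomerase II"),
    c("mitoxantrone", "anthracenedione / topoisomerase II"),
    c("carboplatin",  "platinum crosslinker"),
    c("cisplatin",    "platinum crosslinker"),
    c("eribulin",     "microtubule dynamics inhibitor"),
    c("formestane",   "aromatase inhibitor"),
    c("palbociclib",  "CDK4/6 inhibitor"),
    c("lapatinib",    "HER2/EGFR kinase inhibitor"),
    c("neratinib",    "HER2 kinase inhibitor")
  )
  other <- list(
    c("topotecan",    "topoisomerase I inhibitor"),
    c("irinotecan",   "topoisomerase I inhibitor"),
    c("bortezomib",   "proteasome inhibitor"),
    c("cantharidin",  "protein phosphatase inhibitor"),
    c("cepharanthine","NF-kB pathway inhibitor"),
    c("afatinib",     "EGFR kinase inhibitor"),
    c("gefitinib",    "EGFR kinase inhibitor"),
    c("erlotinib",    "EGFR kinase inhibitor"),
    c("dacomitinib",  "EGFR kinase inhibitor"),
    c("everolimus",   "mTOR inhibitor"),
    c("temsirolimus", "mTOR inhibitor"),
    c("cladribine",   "nucleoside analogue"),
    c("cytarabine",   "nucleoside analogue"),
    c("oxaliplatin",  "platinum crosslinker"),
    c("etoposide",    "topoisomerase II inhibitor"),
    c("sunitinib",    "multi-target kinase inhibitor"),
    c("sorafenib",    "multi-target kinase inhibitor"),
    c("imatinib",     "BCR-ABL/KIT kinase inhibitor"),
    c("dasatinib",    "SRC/ABL kinase inhibitor"),
    c("nilotinib",    "BCR-ABL kinase inhibitor"),
    c("ponatinib",    "BCR-ABL kinase inhibitor"),
    c("crizotinib",   "ALK/MET kinase inhibitor"),
    c("vemurafenib",  "BRAF kinase inhibitor"),
    c("trametinib",   "MEK inhibitor"),
    c("axitinib",     "VEGFR kinase inhibitor"),
    c("pemetrexed",   "antifolate"),
    c("hydroxyurea",  "ribonucleotide reductase inhibitor"),
    c("daunorubicin", "anthracycline / topoisomerase II"),
    c("idarubicin",   "anthracycline / topoisomerase II"),
    c("bleomycin",    "DNA strand-break inducer")
  )
  rows <- c(
    lapply(breast, function(x)
      drug_panel_entry(x[1], x[2], approved_for_breast = TRUE)),
    lapply(other, function(x)
      drug_panel_entry(x[1], x[2], approved_for_breast = FALSE))
  )
  do.call(rbind, rows)
}

#' Dilution series of tested concentrations
#'
#' Element `k` is `top_conc / fold^(k-1)`, so a 7-point threefold series
#' from 20 uM ends at 20e-6 / 3^6 = 27.4 nM.
#'
#' @param top_conc Top concentration in molar (> 0).
#' @param fold Dilution factor (> 1).
#' @param n_points Number of points (integer >= 1).
#' @return Numeric vector of length `n_points`, strictly decreasing.
#' @examples
#' dilution_series(20e-6, 3, 7)
#' @export
dilution_series <- function(top_conc, fold = 3, n_points = 7L) {
  if (!is.numeric(top_conc) || length(top_conc) != 1L || top_conc <= 0)
    stop("'top_conc' must be a single positive number")
  if (!is.numeric(fold) || length(fold) != 1L || fold <= 1)
    stop("'fold' must be a single number > 1")
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 1L)
    stop("'n_points' must be an integer >= 1")
  top_conc / fold^(seq_len(n_points) - 1L)
}

#' Format a molar concentration for display
#'
#' Chooses uM or nM by magnitude; values are stored in molar internally.
#'
#' @param conc_molar Numeric vector of molar concentrations.
#' @param digits Significant digits.
#' @return Character vector like "20 uM" or "27.4 nM".
#' @export
format_conc <- function(conc_molar, digits = 3) {
  vapply(conc_molar, function(x) {
    if (is.na(x)) return(NA_character_)
    if (x >= 1e-6) paste0(signif(x * 1e6, digits), " uM")
    else paste0(signif(x * 1e9, digits), " nM")
  }, character(1))
}
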