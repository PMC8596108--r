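#' @name pdoscreen-io
#' @title Table readers and writers
#' @description
#' All tables are long/tidy CSV or TSV files (delimiter chosen by file
#' extension). A plate table has columns `pdo_id`, `drug_id`, `conc_molar`,
#' `replicate`, `signal`, `role` with `role` one of `test`, `neg_control`,
#' `pos_control`; control rows may leave `drug_id` empty and `conc_molar`
#' missing. Writers emit deterministic, unquoted tab-separated text so that
#' fixed-seed pipeline runs are byte-identical.
NULL

WELL_ROLES <- c("test", "neg_control", "pos_control")
RECIST_LEVELS <- c("CR", "PR", "SD", "PD", "unknown")

delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

read_table_file <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  utils::read.table(path, header = TRUE, sep = delim_for(path),
                    stringsAsFactors = FALSE, na.strings = "NA",
                    check.names = FALSE)
}

#' Write a data frame as a deterministic TSV
#'
#' @param x Data frame.
#' @param path Output path (`.tsv` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_table_file <- function(x, path) {
  utils::write.table(x, path, sep = delim_for(path), quote = FALSE,
                     row.names = FALSE, na = "NA", eol = "\n")
  invisible(path)
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("%s is missing required column '%s'", what, missing[1]))
  invisible(df)
}

#' Read and validate a plate table of raw viability reads
#'
#' Wells are validated row by row: test wells must name a panel drug, carry a
#' positive concentration inside the drug's tested range, and an integer
#' replicate >= 1; all signals must be finite and non-negative. Control wells
#' (`neg_control`: vehicle, `pos_control`: a maximally cytotoxic reference)
#' may omit `drug_id` and `conc_molar`.
#'
#' @param path Path to a CSV/TSV plate table.
#' @param panel Drug panel data frame (see [default_panel()]); used to check
#'   drug identities and concentration ranges. `NULL` skips panel checks.
#' @param range_tol Relative tolerance when checking concentrations against
#'   the panel range.
#' @return Data frame of validated wells with class `pdo_plate`.
#' @export
read_plate_table <- function(path, panel = default_panel(),
                             range_tol = 1e-6) {
  df <- read_table_file(path)
  require_columns(df, c("pdo_id", "drug_id", "conc_molar", "replicate",
                        "signal", "role"), "plate table")
  validate_wells(df, panel = panel, range_tol = range_tol)
}

#' Validate an in-memory plate-well table
#'
#' @inheritParams read_plate_table
#' @param wells Data frame with the plate-table columns.
#' @return The validated data frame with class `pdo_plate`.
#' @export
validate_wells <- function(wells, panel = default_panel(),
                           range_tol = 1e-6) {
  df <- as.data.frame(wells, stringsAsFactors = FALSE)
  require_columns(df, c("pdo_id", "drug_id", "conc_molar", "replicate",
                        "signal", "role"), "plate table")
  bad_role <- which(!df$role %in% WELL_ROLES)
  if (length(bad_role))
    stop(sprintf("row %d: unknown well role '%s'",
                 bad_role[1], df$role[bad_role[1]]))
  bad_sig <- which(!is.finite(df$signal) | df$signal < 0)
  if (length(bad_sig))
    stop(sprintf("row %d: raw signal must be finite and non-negative",
                 bad_sig[1]))
  is_test <- df$role == "test"
  bad_drug <- which(is_test & (is.na(df$drug_id) | !nzchar(df$drug_id)))
  if (length(bad_drug))
    stop(sprintf("row %d: test well lacks a drug_id", bad_drug[1]))
  bad_conc <- which(is_test & (is.na(df$conc_molar) | df$conc_molar <= 0))
  if (length(bad_conc))
    stop(sprintf("row %d: test well needs a positive concentration",
                 bad_conc[1]))
  bad_rep <- which(is_test & (is.na(df$replicate) | df$replicate < 1))
  if (length(bad_rep))
    stop(sprintf("row %d: replicate must be an integer >= 1", bad_rep[1]))
  if (!is.null(panel)) {
    idx <- match(df$drug_id[is_test], panel$drug_id)
    unknown <- which(is.na(idx))
    if (length(unknown)) {
      row <- which(is_test)[unknown[1]]
      stop(sprintf("row %d: drug '%s' is not in the panel",
                   row, df$drug_id[row]))
    }
    top <- panel$top_conc[idx]
    bottom <- top / panel$fold[idx]^(panel$n_points[idx] - 1L)
    conc <- df$conc_molar[is_test]
    out <- which(conc > top * (1 + range_tol) |
                 conc < bottom * (1 - range_tol))
    if (length(out)) {
      row <- which(is_test)[out[1]]
      stop(sprintf(
        "row %d: concentration %s outside the tested range of '%s'",
        row, format_conc(df$conc_molar[row]), df$drug_id[row]))
    }
  }
  class(df) <- c("pdo_plate", "data.frame")
  df
}

#' Read clinical treatment records
#'
#' One row per regimen: `patient_id`, `pdo_id`, `round_index`, `drugs`
#' (drug ids joined by `;`), `outcome` (RECIST: CR/PR/SD/PD/unknown).
#'
#' @param path Path to a CSV/TSV file.
#' @return Data frame of validated treatment records.
#' @export
read_treatments <- function(path) {
  df <- read_table_file(path)
  require_columns(df, c("patient_id", "pdo_id", "round_index", "drugs",
                        "outcome"), "treatment table")
  validate_treatments(df)
}

#' @rdname read_treatments
#' @param treatments In-memory data frame with the treatment columns.
#' @export
validate_treatments <- function(treatments) {
  df <- as.data.frame(treatments, stringsAsFactors = FALSE)
  bad <- which(!df$outcome %in% RECIST_LEVELS)
  if (length(bad))
    stop(sprintf("row %d: outcome '%s' is not a RECIST category",
                 bad[1], df$outcome[bad[1]]))
  empty <- which(is.na(df$drugs) | !nzchar(df$drugs))
  if (length(empty))
    stop(sprintf("row %d: regimen drug list is empty", empty[1]))
  if (any(is.na(df$round_index) | df$round_index < 1))
    stop("round_index must be an integer >= 1")
  df
}

#' Split a `;`-joined regimen string into drug ids
#' @param drugs Character vector of joined regimens.
#' @return List of character vectors.
#' @export
split_regimen <- function(drugs) {
  strsplit(as.character(drugs), ";", fixed = TRUE)
}

#' Read survival records
#'
#' Columns: `subject_id`, `time` (>= 0), `event` (0/1 or logical),
#' `group` (`sensitive_signature` / `non_sensitive`).
#'
#' @param path Path to a CSV/TSV file.
#' @return Validated data frame.
#' @export
read_survival <- function(path) {
  df <- read_table_file(path)
  require_columns(df, c("subject_id", "time", "event", "group"),
                  "survival table")
  if (any(!is.finite(df$time) | df$time < 0))
    stop("survival times must be finite and >= 0")
  df$event <- as.logical(df$event)
  if (anyNA(df$event)) stop("event must be 0/1 or logical")
  df
}
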