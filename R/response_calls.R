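RESPONSE_LABELS <- c("sensitive", "moderate", "resistant")

# Rank-block labels for ascending IC50s: ranks 1..ceil(n/3) sensitive,
# up to ceil(2n/3) moderate, remainder resistant. Tied values take the
# label of their lowest (most sensitive) rank, so ties never straddle a
# cutoff with different labels.
tertile_labels <- function(ic50) {
  n <- length(ic50)
  cut1 <- ceiling(n / 3)
  cut2 <- ceiling(2 * n / 3)
  r <- rank(ic50, ties.method = "min")
  ifelse(r <= cut1, "sensitive", ifelse(r <= cut2, "moderate", "resistant"))
}

# Split the uncensored remainder into two equal-rank halves (lower block
# gets `lower_label`), again with ties sharing the lower block's label.
half_labels <- function(ic50, lower_label, upper_label) {
  n <- length(ic50)
  r <- rank(ic50, ties.method = "min")
  ifelse(r <= ceiling(n / 2), lower_label, upper_label)
}

#' Tertile response classification of one drug across PDOs
#'
#' Default rule: rank the IC50s ascending and call the lowest third
#' `sensitive`, the middle third `moderate` and the top third `resistant`
#' (cutoffs at ranks `ceiling(n/3)` and `ceiling(2n/3)`; ties share the
#' label of the lower rank block). Bound rule: when more than
#' `tertile_fraction` of the PDOs are censored at the top of the tested
#' range (`at_max`), all censored PDOs are `resistant` and the remainder is
#' split into two equal-rank halves (`sensitive` / `moderate`);
#' symmetrically, when more than `tertile_fraction` are censored `at_min`,
#' all censored PDOs are `sensitive` and the remainder splits into
#' `moderate` / `resistant`. If both censored fractions exceed the
#' threshold the classification is ambiguous and an error is raised.
#'
#' @param ic50_records Data frame with columns `pdo_id`, `ic50_molar` and
#'   `censor` (`interior` / `at_max` / `at_min`) for one drug.
#' @param tertile_fraction Tertile (and bound-rule) fraction, default 1/3.
#' @return Data frame `pdo_id`, `drug_id` (if present), `label`, `basis`
#'   (`tertile` or `bound_rule`).
#' @export
classify_drug <- function(ic50_records, tertile_fraction = 1 / 3) {
  df <- as.data.frame(ic50_records, stringsAsFactors = FALSE)
  if (!"censor" %in% names(df)) df$censor <- "interior"
  n <- nrow(df)
  if (n < 3L)
    stop("insufficient cohort: need >= 3 PDOs with an IC50, got ", n)
  if (anyNA(df$ic50_molar)) stop("IC50 values must not be missing")
  frac_max <- mean(df$censor == "at_max")
  frac_min <- mean(df$censor == "at_min")
  over_max <- frac_max > tertile_fraction
  over_min <- frac_min > tertile_fraction
  if (over_max && over_min)
    stop("ambiguous bound rule: censored fractions at both range bounds ",
         "exceed the tertile fraction")
  label <- character(n)
  if (over_max) {
    basis <- "bound_rule"
    hit <- df$censor == "at_max"
    label[hit] <- "resistant"
    label[!hit] <- half_labels(df$ic50_molar[!hit], "sensitive", "moderate")
  } else if (over_min) {
    basis <- "bound_rule"
    hit <- df$censor == "at_min"
    label[hit] <- "sensitive"
    label[!hit] <- half_labels(df$ic50_molar[!hit], "moderate", "resistant")
  } else {
    basis <- "tertile"
    label <- tertile_labels(df$ic50_molar)
  }
  out <- data.frame(pdo_id = df$pdo_id, label = label, basis = basis,
                    stringsAsFactors = FALSE)
  if ("drug_id" %in% names(df)) out <- cbind(drug_id = df$drug_id, out)
  out[, intersect(c("pdo_id", "drug_id", "label", "basis"), names(out))]
}

#' Per-drug response calls for a whole IC50 table
#'
#' Applies [classify_drug()] drug by drug. A drug whose classification fails
#' (too few PDOs, ambiguous bound rule) is skipped; its error message is
#' collected and the run continues.
#'
#' @param ic50 Data frame `pdo_id`, `drug_id`, `ic50_molar`, `censor`.
#' @param tertile_fraction Passed to [classify_drug()].
#' @return Data frame of calls (`pdo_id`, `drug_id`, `label`, `basis`) with
#'   attributes `errors` (named character vector per failed drug) and
#'   `marginals` (per-drug label counts).
#' @export
call_matrix <- function(ic50, tertile_fraction = 1 / 3) {
  if (!nrow(ic50)) {
    warning("empty IC50 table: no calls made")
    out <- data.frame(pdo_id = character(0), drug_id = character(0),
                      label = character(0), basis = character(0))
    attr(out, "errors") <- character(0)
    return(out)
  }
  errors <- character(0)
  rows <- lapply(split(ic50, ic50$drug_id), function(d) {
    res <- tryCatch(classify_drug(d, tertile_fraction),
                    error = function(e) e)
    if (inherits(res, "error")) {
      errors[[d$drug_id[1]]] <<- conditionMessage(res)
      return(NULL)
    }
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "errors") <- errors
  attr(out, "marginals") <- if (!is.null(out) && nrow(out))
    table(out$drug_id, factor(out$label, levels = RESPONSE_LABELS))
  out
}

#' Pivot long calls into a PDO x drug label matrix
#'
#' @param calls Long call table from [call_matrix()].
#' @return Character matrix, PDOs in rows, drugs in columns; `NA` where a
#'   PDO x drug pair has no call.
#' @export
calls_wide <- function(calls) {
  pdos <- sort(unique(calls$pdo_id))
  drugs <- sort(unique(calls$drug_id))
  m <- matrix(NA_character_, length(pdos), length(drugs),
              dimnames = list(pdos, drugs))
  m[cbind(match(calls$pdo_id, pdos), match(calls$drug_id, drugs))] <-
    calls$label
  m
}

#' Treatment-level prediction from per-drug calls
#'
#' The best label among the regimen's called drugs decides the prediction
#' (`sensitive` > `moderate` > `resistant`). By default a treatment is
#' predicted effective iff its best call is `sensitive`; with
#' `moderate_counts_good = TRUE` a best call of `moderate` also predicts a
#' good response. The continuous treatment score used for ranking (AUC) is
#' `(#sensitive + 0.5 * #moderate) / #called drugs`. Drugs without a call
#' for the treatment's PDO (e.g. prodrugs the platform cannot evaluate) are
#' ignored; a treatment with no called drug at all is flagged untestable
#' (`predicted_good = NA`).
#'
#' @param treatments Treatment data frame (`patient_id`, `pdo_id`,
#'   `round_index`, `drugs` as `;`-joined ids, `outcome`).
#' @param calls Long call table (`pdo_id`, `drug_id`, `label`).
#' @param moderate_counts_good Logical, see above.
#' @return `treatments` with added `best_call`, `predicted_good`, `score`,
#'   `n_called` columns.
#' @export
predict_treatment <- function(treatments, calls,
                              moderate_counts_good = FALSE) {
  regs <- split_regimen(treatments$drugs)
  best <- character(nrow(treatments))
  score <- numeric(nrow(treatments))
  n_called <- integer(nrow(treatments))
  for (i in seq_len(nrow(treatments))) {
    lab <- calls$label[calls$pdo_id == treatments$pdo_id[i] &
                       calls$drug_id %in% regs[[i]]]
    n_called[i] <- length(lab)
    if (!length(lab)) {
      best[i] <- NA_character_
      score[i] <- NA_real_
      next
    }
    best[i] <- RESPONSE_LABELS[min(match(lab, RESPONSE_LABELS))]
    score[i] <- (sum(lab == "sensitive") + 0.5 * sum(lab == "moderate")) /
      length(lab)
  }
  n_untestable <- sum(is.na(best))
  if (n_untestable)
    message(n_untestable,
            " treatment(s) untestable: no regimen drug has a call")
  good_labels <- if (moderate_counts_good) c("sensitive", "moderate")
                 else "sensitive"
  treatments$best_call <- best
  treatments$predicted_good <- ifelse(is.na(best), NA, best %in% good_labels)
  treatments$score <- score
  treatments$n_called <- n_called
  treatments
}
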