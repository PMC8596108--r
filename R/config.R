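#' Analysis run configuration
#'
#' One configuration object drives every threshold of the pipeline. Defaults
#' are the values of the published analysis: tertiles (1/3), differential
#' expression filters FDR <= 0.01 and fold change >= 2, Spearman |rho| > 0.3
#' for signature membership, 1000 bootstrap resamples at the 95% level, and a
#' fixed combination partner dosed at its IC30 (70% residual viability).
#'
#' @param seed Integer seed from which all randomness flows.
#' @param tertile_fraction Fraction per response tertile (default 1/3); also
#'   the censored-mass threshold that triggers the bound rule.
#' @param de_fdr_max FDR ceiling for differential expression (default 0.01).
#' @param de_fc_min Minimum fold change for differential expression
#'   (default 2; applied two-sided as |log2 FC| >= log2(de_fc_min)).
#' @param rho_min Minimum |Spearman rho| between expression and the IC50
#'   summary for signature membership (default 0.3).
#' @param bootstrap_reps Bootstrap resamples for confidence intervals
#'   (default 1000).
#' @param ci_level Confidence level (default 0.95).
#' @param fixed_partner_viability Residual viability fraction of the fixed
#'   combination partner (default 0.70, i.e. IC30).
#' @param noise_cv Coefficient of variation of multiplicative screen noise
#'   used by the simulator (default 0.10).
#' @param qc_cv_limit Median replicate CV above which a curve fails QC
#'   (default 0.20).
#' @param moderate_counts_good Logical; if TRUE a treatment whose best call
#'   is moderate is also predicted effective (default FALSE: sensitive only).
#' @param anchor Normalization anchoring: "two_point" uses both control
#'   means (negative = 100%, positive = 0%); "neg_only" divides by the
#'   negative-control mean alone.
#' @return A list of class `pdo_config`.
#' @export
pdo_config <- function(seed = 1L,
                       tertile_fraction = 1 / 3,
                       de_fdr_max = 0.01,
                       de_fc_min = 2,
                       rho_min = 0.3,
                       bootstrap_reps = 1000L,
                       ci_level = 0.95,
                       fixed_partner_viability = 0.70,
                       noise_cv = 0.10,
                       qc_cv_limit = 0.20,
                       moderate_counts_good = FALSE,
                       anchor = c("two_point", "neg_only")) {
  seed <- as.integer(seed)
  if (is.na(seed)) stop("'seed' must be an integer")
  stopifnot(
    tertile_fraction > 0, tertile_fraction < 0.5,
    de_fdr_max > 0, de_fdr_max <= 1,
    de_fc_min >= 1,
    rho_min >= 0, rho_min < 1,
    ci_level > 0, ci_level < 1,
    fixed_partner_viability > 0, fixed_partner_viability <= 1,
    noise_cv >= 0, qc_cv_limit >= 0
  )
  bootstrap_reps <- as.integer(bootstrap_reps)
  if (is.na(bootstrap_reps) || bootstrap_reps < 1L)
    stop("'bootstrap_reps' must be an integer >= 1")
  anchor <- match.arg(anchor)
  structure(
    list(
      seed = seed,
      tertile_fraction = tertile_fraction,
      de_fdr_max = de_fdr_max,
      de_fc_min = de_fc_min,
      rho_min = rho_min,
      bootstrap_reps = bootstrap_reps,
      ci_level = ci_level,
      fixed_partner_viability = fixed_partner_viability,
      noise_cv = noise_cv,
      qc_cv_limit = qc_cv_limit,
      moderate_counts_good = isTRUE(moderate_counts_good),
      anchor = anchor
    ),
    class = "pdo_config"
  )
}

#' @export
print.pdo_config <- function(x, ...) {
  cat("PDO screen run configuration\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# Derive a child seed for a pipeline stage; keeps results < 2^31 so the
# value stays a valid R integer seed.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% .Machine$integer.max)
}
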