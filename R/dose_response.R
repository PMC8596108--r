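#' Four-parameter logistic viability model
#'
#' `viability = bottom + (top - bottom) / (1 + (conc / ec50)^hill)`, with
#' `hill > 0` so viability decreases with concentration.
#'
#' @param conc Concentration(s), molar.
#' @param top,bottom Upper/lower viability asymptotes, percent.
#' @param hill Hill slope (> 0).
#' @param ec50 Inflection concentration, molar.
#' @return Viability percent, same length as `conc`.
#' @export
viability_4pl <- function(conc, top, bottom, hill, ec50) {
  bottom + (top - bottom) / (1 + (conc / ec50)^hill)
}

#' Normalize raw viability signals to plate controls
#'
#' Percent viability anchors the negative-control (vehicle) mean at 100% and
#' the positive-control (cytotoxic reference) mean at 0%:
#' `100 * (signal - mean_pos) / (mean_neg - mean_pos)`. Values outside
#' \[0, 100\] are possible and retained. With `anchor = "neg_only"` the
#' positive control is ignored and viability is `100 * signal / mean_neg`.
#'
#' Controls are matched per PDO: each PDO's wells are normalized against its
#' own control wells.
#'
#' @param wells Validated plate-well table (see [read_plate_table()]).
#' @param anchor `"two_point"` (default) or `"neg_only"`.
#' @return The test wells with an added `viability` column (percent).
#' @export
normalize_viability <- function(wells, anchor = c("two_point", "neg_only")) {
  anchor <- match.arg(anchor)
  out <- lapply(split(seq_len(nrow(wells)), wells$pdo_id), function(idx) {
    w <- wells[idx, , drop = FALSE]
    neg <- w$signal[w$role == "neg_control"]
    pos <- w$signal[w$role == "pos_control"]
    if (!length(neg))
      stop("PDO '", w$pdo_id[1], "': no negative-control wells")
    if (anchor == "two_point" && !length(pos))
      stop("PDO '", w$pdo_id[1], "': no positive-control wells")
    mean_neg <- mean(neg)
    mean_pos <- if (anchor == "two_point") mean(pos) else 0
    if (mean_neg <= mean_pos)
      stop("PDO '", w$pdo_id[1],
           "': degenerate plate, negative-control mean does not exceed ",
           "positive-control mean")
    t <- w[w$role == "test", , drop = FALSE]
    t$viability <- 100 * (t$signal - mean_pos) / (mean_neg - mean_pos)
    t
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Assemble one PDO x drug dose-response curve
#'
#' @param norm_wells Normalized test wells from [normalize_viability()].
#' @param pdo_id,drug_id Identifiers selecting one curve.
#' @return List of class `pdo_curve` with `conc` (strictly decreasing),
#'   per-replicate `points` (conc, replicate, viability) and
#'   `mean_viability` (arithmetic mean over replicates, aligned to `conc`).
#' @export
build_curve <- function(norm_wells, pdo_id, drug_id) {
  w <- norm_wells[norm_wells$pdo_id == pdo_id &
                  norm_wells$drug_id == drug_id, , drop = FALSE]
  if (!nrow(w)) stop("no wells for ", pdo_id, " x ", drug_id)
  conc <- sort(unique(w$conc_molar), decreasing = TRUE)
  mv <- vapply(conc, function(cc)
    mean(w$viability[w$conc_molar == cc]), numeric(1))
  structure(
    list(pdo_id = pdo_id, drug_id = drug_id, conc = conc,
         points = data.frame(conc = w$conc_molar, replicate = w$replicate,
                             viability = w$viability),
         mean_viability = mv),
    class = "pdo_curve"
  )
}

#' @export
print.pdo_curve <- function(x, ...) {
  cat(sprintf("Dose-response curve %s x %s (%d doses, %d wells)\n",
              x$pdo_id, x$drug_id, length(x$conc), nrow(x$points)))
  print(data.frame(conc = format_conc(x$conc),
                   mean_viability = round(x$mean_viability, 1)))
  invisible(x)
}

# Asymptote box: viability asymptotes are kept in a generous percent range
# so a nearly flat curve cannot drive an unidentifiable asymptote to
# absurd extrapolated values.
ASYM_MIN <- -100
ASYM_MAX <- 400

# Given the nonlinear shape f = 1/(1+(c/ec50)^hill), the model is linear in
# (bottom, top): y = bottom*(1-f) + top*f. Solve that 2-parameter least
# squares under top >= bottom and the asymptote box; when the unconstrained
# optimum is infeasible, the best boundary candidate (one coordinate fixed,
# the other re-solved conditionally) or the flat fit is taken.
solve_asymptotes <- function(f, y) {
  clamp <- function(x) min(max(x, ASYM_MIN), ASYM_MAX)
  rss_of <- function(b, t) sum((y - (b * (1 - f) + t * f))^2)
  m <- clamp(mean(y))
  best <- list(bottom = m, top = m, rss = rss_of(m, m))
  consider <- function(b, t) {
    if (t >= b) {
      r <- rss_of(b, t)
      if (r < best$rss) best <<- list(bottom = b, top = t, rss = r)
    }
  }
  X <- cbind(1 - f, f)
  fit <- tryCatch(stats::lm.fit(X, y), error = function(e) NULL)
  if (!is.null(fit) && !anyNA(fit$coefficients)) {
    b <- fit$coefficients[[1]]; t <- fit$coefficients[[2]]
    if (b >= ASYM_MIN && b <= ASYM_MAX && t >= ASYM_MIN && t <= ASYM_MAX) {
      consider(b, t)
    }
  }
  # boundary candidates: fix one asymptote, solve the other conditionally
  cond_t <- function(b) {
    s <- sum(f^2)
    if (s == 0) return(m)
    clamp(sum(f * (y - b * (1 - f))) / s)
  }
  cond_b <- function(t) {
    s <- sum((1 - f)^2)
    if (s == 0) return(m)
    clamp(sum((1 - f) * (y - t * f)) / s)
  }
  for (b in c(ASYM_MIN, ASYM_MAX)) consider(b, max(cond_t(b), b))
  for (t in c(ASYM_MIN, ASYM_MAX)) consider(min(cond_b(t), t), t)
  best
}

# Brute-force grid search over log10(ec50) x hill; used both as the fit
# initializer and (in tests) as the independent oracle.
grid_4pl <- function(conc, y, hill_grid = c(0.5, 0.75, 1, 1.5, 2, 3, 4),
                     n_ec50 = 40L, pad = 2) {
  lo <- log10(min(conc)) - pad
  hi <- log10(max(conc)) + pad
  ec_grid <- 10^seq(lo, hi, length.out = n_ec50)
  best <- NULL
  for (h in hill_grid) {
    for (e in ec_grid) {
      f <- 1 / (1 + (conc / e)^h)
      s <- solve_asymptotes(f, y)
      if (is.null(best) || s$rss < best$rss)
        best <- list(top = s$top, bottom = s$bottom, hill = h, ec50 = e,
                     rss = s$rss)
    }
  }
  best
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Replicates are pooled at the residual level: the least-squares objective
#' runs over every well, not over per-dose means. Initialization is a coarse
#' grid over log10(EC50) and Hill slope with a closed-form solve for the
#' asymptotes, followed by derivative-free (Nelder-Mead) refinement and a
#' Levenberg-Marquardt polish that is kept only if it lowers the residual
#' sum of squares. The constraint `top >= bottom` is enforced; a fit whose
#' dynamic range collapses (top - bottom < 1 viability point) or whose local
#' refinement fails to converge is returned flagged with the best available
#' parameters.
#'
#' @param curve A `pdo_curve` (see [build_curve()]), or any list with
#'   `points$conc` / `points$viability`.
#' @return List of class `pdo_4pl`: `top`, `bottom`, `hill`, `ec50`, `rss`,
#'   `flagged`, `degenerate`, `n_points`.
#' @export
fit_4pl <- function(curve) {
  conc <- curve$points$conc
  y <- curve$points$viability
  keep <- is.finite(conc) & is.finite(y) & conc > 0
  conc <- conc[keep]; y <- y[keep]
  if (length(unique(conc)) < 4L)
    stop("insufficient data: a 4PL fit needs >= 4 distinct concentrations")

  g <- grid_4pl(conc, y)
  obj <- function(par) {
    top <- par[1]; bottom <- par[2]
    ec50 <- 10^par[3]; hill <- exp(par[4])
    if (top < bottom || !is.finite(ec50) || hill < 0.05 || hill > 20 ||
        top > ASYM_MAX || bottom < ASYM_MIN)
      return(1e12)
    sum((y - viability_4pl(conc, top, bottom, hill, ec50))^2)
  }
  start <- c(g$top, g$bottom, log10(g$ec50), log(g$hill))
  opt <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  # restart once from the solution; Nelder-Mead benefits from a fresh simplex
  opt2 <- stats::optim(opt$par, obj, method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-12))
  if (opt2$value <= opt$value) opt <- opt2
  flagged <- opt$convergence != 0 || opt$value > g$rss + 1e-8
  if (opt$value > g$rss) { # fall back to the grid optimum
    par <- start; rss <- g$rss
  } else {
    par <- opt$par; rss <- opt$value
  }
  top <- par[1]; bottom <- par[2]; ec50 <- 10^par[3]; hill <- exp(par[4])

  # Levenberg-Marquardt polish on the same objective
  pol <- tryCatch({
    df <- data.frame(conc = conc, y = y)
    fit <- minpack.lm::nlsLM(
      y ~ bottom + (top - bottom) / (1 + (conc / 10^logec50)^hill),
      data = df,
      start = list(top = top, bottom = bottom,
                   logec50 = log10(ec50), hill = hill),
      lower = c(ASYM_MIN, ASYM_MIN, -Inf, 0.05),
      upper = c(ASYM_MAX, ASYM_MAX, Inf, 20),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- stats::coef(fit)
    list(top = cf[["top"]], bottom = cf[["bottom"]],
         ec50 = 10^cf[["logec50"]], hill = cf[["hill"]],
         rss = sum(stats::resid(fit)^2))
  }, error = function(e) NULL)
  if (!is.null(pol) && pol$rss < rss && pol$top >= pol$bottom) {
    top <- pol$top; bottom <- pol$bottom
    ec50 <- pol$ec50; hill <- pol$hill; rss <- pol$rss
    flagged <- FALSE
  }
  if (top < bottom) { tmp <- top; top <- bottom; bottom <- tmp }

  structure(
    list(top = unname(top), bottom = unname(bottom), hill = unname(hill),
         ec50 = unname(ec50), rss = unname(rss),
         flagged = flagged, degenerate = unname(top - bottom) < 1,
         n_points = length(y)),
    class = "pdo_4pl"
  )
}

#' @export
print.pdo_4pl <- function(x, ...) {
  cat(sprintf(
    "4PL fit: top %.1f%%, bottom %.1f%%, hill %.2f, EC50 %s, RSS %.2f%s\n",
    x$top, x$bottom, x$hill, format_conc(x$ec50), x$rss,
    if (x$degenerate) " [degenerate]" else if (x$flagged) " [flagged]" else ""))
  invisible(x)
}

#' Extract an IC50 with censoring at the tested range
#'
#' The IC50 is the concentration at which the fitted curve crosses 50%
#' absolute viability (not the relative-to-asymptote EC50). Curves that stay
#' at or above 50% across the tested range are censored to the highest
#' tested dose (`at_max`); curves at or below 50% everywhere are censored to
#' the lowest tested dose (`at_min`).
#'
#' @param fit A `pdo_4pl` fit.
#' @param curve The fitted `pdo_curve` (supplies the tested range).
#' @param tested_range Optional numeric length-2 (min, max) molar range.
#' @return List of class `pdo_ic50`: `pdo_id`, `drug_id`, `ic50` (molar),
#'   `censor` in `interior` / `at_max` / `at_min`.
#' @export
extract_ic50 <- function(fit, curve, tested_range = range(curve$conc)) {
  cmin <- min(tested_range); cmax <- max(tested_range)
  v <- function(cc) viability_4pl(cc, fit$top, fit$bottom, fit$hill, fit$ec50)
  if (v(cmax) >= 50) {
    ic50 <- cmax; censor <- "at_max"
  } else if (v(cmin) <= 50) {
    ic50 <- cmin; censor <- "at_min"
  } else {
    # invert: 50 = bottom + (top-bottom)/(1+(c/ec50)^h)
    ratio <- (fit$top - 50) / (50 - fit$bottom)
    ic50 <- fit$ec50 * ratio^(1 / fit$hill)
    ic50 <- min(max(ic50, cmin), cmax)
    censor <- "interior"
  }
  structure(
    list(pdo_id = curve$pdo_id, drug_id = curve$drug_id,
         ic50 = ic50, censor = censor),
    class = "pdo_ic50"
  )
}

#' Replicate quality control by coefficient of variation
#'
#' Computes the per-concentration CV (sample SD / mean) of normalized
#' replicate viabilities; a curve fails when the median CV exceeds the
#' limit. With a single replicate QC is skipped with a warning.
#'
#' @param curve A `pdo_curve`.
#' @param cv_limit Median-CV failure threshold (default 0.20).
#' @return List: `cv` (per concentration, aligned to `curve$conc`),
#'   `median_cv`, `pass` (logical, `NA` if skipped).
#' @export
replicate_qc <- function(curve, cv_limit = 0.20) {
  p <- curve$points
  cv <- vapply(curve$conc, function(cc) {
    y <- p$viability[p$conc == cc]
    if (length(y) < 2L) return(NA_real_)
    stats::sd(y) / abs(mean(y))
  }, numeric(1))
  if (all(is.na(cv))) {
    warning("single replicate: QC skipped for ",
            curve$pdo_id, " x ", curve$drug_id)
    return(list(cv = cv, median_cv = NA_real_, pass = NA))
  }
  med <- stats::median(cv, na.rm = TRUE)
  list(cv = cv, median_cv = med, pass = med <= cv_limit)
}

#' Predicted-additive combination curve
#'
#' Under Bliss-style independence, combining the gradient-diluted drug with a
#' partner fixed at its IC30 is expected to leave, at each dose, the product
#' of the single-agent viability and the partner's residual viability
#' fraction (default 0.70). Viabilities are percent; the prediction is on the
#' same concentration grid as the single-agent curve.
#'
#' @param curve Single-agent `pdo_curve` (normalized).
#' @param fixed_partner_viability Partner residual viability fraction in
#'   (0, 1\]; default 0.70.
#' @param partner_id Identifier of the fixed partner drug.
#' @return List of class `pdo_combo`: `conc`, `single_agent` (mean percent
#'   viability), `predicted_additive`, `observed` (NULL until supplied),
#'   `partner_id`, `fixed_partner_viability`.
#' @export
predicted_additive <- function(curve, fixed_partner_viability = 0.70,
                               partner_id = "partner") {
  if (!is.numeric(fixed_partner_viability) ||
      fixed_partner_viability <= 0 || fixed_partner_viability > 1)
    stop("'fixed_partner_viability' must be in (0, 1]")
  structure(
    list(pdo_id = curve$pdo_id, drug_id = curve$drug_id,
         partner_id = partner_id,
         fixed_partner_viability = fixed_partner_viability,
         conc = curve$conc,
         single_agent = curve$mean_viability,
         predicted_additive = curve$mean_viability * fixed_partner_viability,
         observed = NULL),
    class = "pdo_combo"
  )
}

#' Attach the observed combination curve
#'
#' @param combo A `pdo_combo` from [predicted_additive()].
#' @param observed_curve A `pdo_curve` of the combination measured on the
#'   same concentration grid.
#' @return The `pdo_combo` with `observed` filled.
#' @export
set_observed_combo <- function(combo, observed_curve) {
  if (length(observed_curve$conc) != length(combo$conc) ||
      any(abs(log(observed_curve$conc / combo$conc)) > 1e-9))
    stop("observed combination grid does not match the single-agent grid")
  combo$observed <- observed_curve$mean_viability
  combo
}

#' Excess over the predicted-additive curve
#'
#' Mean over concentrations of (predicted - observed) viability, percent.
#' Positive values indicate a stronger-than-additive combination.
#'
#' @param combo A `pdo_combo` with `observed` filled.
#' @return Scalar excess score.
#' @export
combo_excess <- function(combo) {
  if (is.null(combo$observed))
    stop("observed combination viability has not been supplied")
  mean(combo$predicted_additive - combo$observed)
}

#' Fit every PDO x drug curve in a normalized well table
#'
#' @param norm_wells Output of [normalize_viability()].
#' @param qc_cv_limit Replicate-QC threshold passed to [replicate_qc()].
#' @return List with `ic50` (data frame: pdo_id, drug_id, ic50_molar,
#'   censor), `fits` (data frame of 4PL parameters and QC flags) and
#'   `errors` (character vector of per-curve failures).
#' @export
fit_screen <- function(norm_wells, qc_cv_limit = 0.20) {
  keys <- unique(norm_wells[, c("pdo_id", "drug_id")])
  keys <- keys[order(keys$pdo_id, keys$drug_id), , drop = FALSE]
  ic_rows <- vector("list", nrow(keys))
  fit_rows <- vector("list", nrow(keys))
  errors <- character(0)
  for (i in seq_len(nrow(keys))) {
    res <- tryCatch({
      cu <- build_curve(norm_wells, keys$pdo_id[i], keys$drug_id[i])
      ft <- fit_4pl(cu)
      ic <- extract_ic50(ft, cu)
      qc <- suppressWarnings(replicate_qc(cu, qc_cv_limit))
      list(
        ic = data.frame(pdo_id = ic$pdo_id, drug_id = ic$drug_id,
                        ic50_molar = ic$ic50, censor = ic$censor,
                        stringsAsFactors = FALSE),
        fit = data.frame(pdo_id = cu$pdo_id, drug_id = cu$drug_id,
                         top = ft$top, bottom = ft$bottom, hill = ft$hill,
                         ec50_molar = ft$ec50, rss = ft$rss,
                         flagged = ft$flagged, degenerate = ft$degenerate,
                         qc_median_cv = qc$median_cv,
                         qc_pass = qc$pass, stringsAsFactors = FALSE))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors <- c(errors, sprintf("%s x %s: %s", keys$pdo_id[i],
                                  keys$drug_id[i], conditionMessage(res)))
    } else {
      ic_rows[[i]] <- res$ic
      fit_rows[[i]] <- res$fit
    }
  }
  list(ic50 = do.call(rbind, ic_rows),
       fits = do.call(rbind, fit_rows),
       errors = errors)
}
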