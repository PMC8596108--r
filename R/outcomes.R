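#' Kaplan-Meier product-limit estimate per group
#'
#' @param records Data frame with `time` (>= 0), `event` (logical/0-1) and
#'   optionally `group`.
#' @return Data frame `group`, `time`, `n_risk`, `n_event`, `n_censor`,
#'   `surv`; the underlying `survfit` object is attached as attribute
#'   `survfit`.
#' @export
km_fit <- function(records) {
  if (!nrow(records)) stop("empty survival record set")
  if (any(records$time < 0)) stop("survival times must be >= 0")
  records$event <- as.logical(records$event)
  has_group <- "group" %in% names(records) &&
    length(unique(records$group)) > 1L
  fit <- if (has_group) {
    survival::survfit(survival::Surv(time, event) ~ group, data = records)
  } else {
    survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  }
  s <- summary(fit, censored = TRUE)
  grp <- if (has_group) sub("^group=", "", as.character(s$strata))
         else rep("all", length(s$time))
  out <- data.frame(group = grp, time = s$time, n_risk = s$n.risk,
                    n_event = s$n.event, n_censor = s$n.censor,
                    surv = s$surv, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "survfit") <- fit
  out
}

#' Two-group log-rank test
#'
#' @param records Data frame with `time`, `event` and a two-level `group`.
#' @return List `chisq` (1 df statistic) and `p`.
#' @export
logrank_test <- function(records) {
  groups <- unique(records$group)
  if (length(groups) != 2L)
    stop("log-rank test needs exactly two groups, got ", length(groups))
  if (!any(as.logical(records$event))) stop("no events in either group")
  records$event <- as.logical(records$event)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group,
                           data = records)
  list(chisq = unname(sd$chisq),
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Pearson chi-square test of a 2x2 table
#'
#' Without continuity correction, 1 df. Requires positive row and column
#' margins.
#'
#' @param counts 2x2 numeric matrix of non-negative counts.
#' @return List `chisq`, `p`.
#' @export
chi2_test <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == 2L)) stop("need a 2x2 table")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero margin: chi-square statistic undefined")
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(chisq = unname(ct$statistic), p = unname(ct$p.value))
}

#' Percentile bootstrap confidence interval
#'
#' Resamples rows of `data` with replacement `reps` times, evaluates
#' `metric_fn` on each resample, and returns the percentile interval whose
#' endpoints are order statistics of the resampled metric. Deterministic
#' for a fixed seed. Resamples on which the metric is undefined (`NA`) are
#' dropped.
#'
#' @param metric_fn Function `data -> scalar`.
#' @param data Data frame of analysis units (here: treatments).
#' @param reps Number of resamples (>= 1).
#' @param level Confidence level in (0, 1).
#' @param seed Integer seed.
#' @return Numeric `c(ci_low, ci_high)`, with the resampled metric values
#'   as attribute `boot`.
#' @export
bootstrap_ci <- function(metric_fn, data, reps = 1000L, level = 0.95,
                         seed = 1L) {
  if (!nrow(data)) stop("empty data")
  if (reps < 1L) stop("'reps' must be >= 1")
  if (level <= 0 || level >= 1) stop("'level' must be in (0, 1)")
  n <- nrow(data)
  stats_v <- local({
    set.seed(as.integer(seed))
    vapply(seq_len(reps), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      as.numeric(metric_fn(data[idx, , drop = FALSE]))
    }, numeric(1))
  })
  stats_v <- stats_v[!is.na(stats_v)]
  if (!length(stats_v)) stop("metric undefined on every resample")
  s <- sort(stats_v)
  m <- length(s)
  alpha <- (1 - level) / 2
  lo <- s[max(1L, floor(alpha * m))]
  hi <- s[min(m, ceiling((1 - alpha) * m))]
  structure(c(ci_low = lo, ci_high = hi), boot = stats_v)
}

rank_auc <- function(score, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

confusion_counts <- function(pred, obs_good) {
  c(tp = sum(pred & obs_good), fn = sum(!pred & obs_good),
    fp = sum(pred & !obs_good), tn = sum(!pred & !obs_good))
}

#' Concordance of PDO predictions with clinical outcomes
#'
#' The unit of analysis is the treatment (one regimen). Observed positives
#' are good responses (CR, PR or SD under RECIST); PD is a poor response;
#' `unknown` outcomes and untestable treatments are excluded listwise with
#' a reported count. Predicted positives are treatments whose regimen
#' contains at least one PDO-sensitive drug (`predicted_good`). Reported:
#' the 2x2 counts, accuracy, sensitivity, specificity, a rank-based AUC on
#' the continuous treatment score, percentile bootstrap confidence
#' intervals for each metric, and the Pearson chi-square p-value of the
#' 2x2 table.
#'
#' @param predictions Treatment table from [predict_treatment()] (needs
#'   `predicted_good`, `score`, `outcome`).
#' @param reps Bootstrap resamples (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed for the bootstrap.
#' @return List of class `pdo_concordance` with counts, metrics (percent
#'   scale), CIs and `chi2_p`.
#' @export
evaluate_concordance <- function(predictions, reps = 1000L, level = 0.95,
                                 seed = 1L) {
  df <- predictions
  excluded <- sum(df$outcome == "unknown" | is.na(df$predicted_good))
  df <- df[df$outcome != "unknown" & !is.na(df$predicted_good), ,
           drop = FALSE]
  if (!nrow(df))
    stop("no treatment has both a prediction and an evaluable outcome")
  if (excluded)
    message(excluded, " treatment(s) excluded (unknown outcome or ",
            "untestable regimen)")
  df$obs_good <- df$outcome %in% c("CR", "PR", "SD")
  cnt <- confusion_counts(df$predicted_good, df$obs_good)

  acc_fn <- function(d) mean(d$predicted_good == d$obs_good)
  sens_fn <- function(d) {
    if (!any(d$obs_good)) return(NA_real_)
    mean(d$predicted_good[d$obs_good])
  }
  spec_fn <- function(d) {
    if (all(d$obs_good)) return(NA_real_)
    mean(!d$predicted_good[!d$obs_good])
  }
  auc_fn <- function(d) rank_auc(d$score, d$obs_good)

  point <- c(accuracy = acc_fn(df), sensitivity = sens_fn(df),
             specificity = spec_fn(df), auc = auc_fn(df))
  if (any(is.na(point)))
    warning("metric(s) undefined (a margin is empty): ",
            paste(names(point)[is.na(point)], collapse = ", "))
  cis <- lapply(
    stats::setNames(list(acc_fn, sens_fn, spec_fn, auc_fn), names(point)),
    function(f) {
      tryCatch(bootstrap_ci(f, df, reps = reps, level = level, seed = seed),
               error = function(e) c(ci_low = NA_real_, ci_high = NA_real_))
    })
  chi2 <- tryCatch(
    chi2_test(matrix(cnt[c("tp", "fn", "fp", "tn")], 2, byrow = TRUE)),
    error = function(e) list(chisq = NA_real_, p = NA_real_))
  structure(
    list(counts = cnt,
         n = nrow(df), n_excluded = excluded,
         metrics = 100 * point,
         ci = lapply(cis, function(x) 100 * as.numeric(x)[1:2]),
         chi2 = chi2$chisq, chi2_p = chi2$p),
    class = "pdo_concordance"
  )
}

#' @export
print.pdo_concordance <- function(x, ...) {
  cat(sprintf("Treatment-level concordance (n = %d, excluded %d)\n",
              x$n, x$n_excluded))
  cat(sprintf("  counts: tp=%d fn=%d fp=%d tn=%d\n",
              x$counts["tp"], x$counts["fn"], x$counts["fp"],
              x$counts["tn"]))
  for (m in names(x$metrics)) {
    ci <- x$ci[[m]]
    cat(sprintf("  %-12s %6.2f%%  (95%% CI %.2f-%.2f%%)\n", m,
                x$metrics[[m]], ci[1], ci[2]))
  }
  cat(sprintf("  Pearson chi-square p = %.3g\n", x$chi2_p))
  invisible(x)
}

#' Fraction of a parental gene set preserved in the organoid
#'
#' @param parent Character vector of genes altered in the parental tumor
#'   (non-empty).
#' @param organoid Character vector of genes altered in the organoid.
#' @return Percent `100 * |parent intersect organoid| / |parent|`.
#' @export
preservation_fraction <- function(parent, organoid) {
  parent <- unique(parent); organoid <- unique(organoid)
  if (!length(parent))
    stop("parental gene set is empty: preservation undefined")
  100 * length(intersect(parent, organoid)) / length(parent)
}

#' Cosine similarity of two mutational-signature contribution vectors
#'
#' @param a,b Equal-length non-negative vectors, each with at least one
#'   positive entry.
#' @return Similarity in \[0, 1\].
#' @export
signature_similarity <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  if (any(a < 0) || any(b < 0)) stop("contribution vectors must be >= 0")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("zero vector: similarity undefined")
  sum(a * b) / (na * nb)
}

#' Percent success rate from printed numerator/denominator
#'
#' Organoid derivation rates are reported as whole percentages, e.g.
#' 99/132 = 75%.
#'
#' @param n_success,n_total Counts (`n_total` > 0).
#' @param digits Decimal places of the reported percentage (default 0).
#' @return Rounded percent.
#' @export
derivation_rate <- function(n_success, n_total, digits = 0) {
  if (any(n_total <= 0)) stop("'n_total' must be positive")
  round(100 * n_success / n_total, digits)
}
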