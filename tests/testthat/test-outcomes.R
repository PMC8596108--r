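test_that("Kaplan-Meier matches a hand-computed product-limit table", {
  # 6 subjects, mixed censoring: events at 1, 3, 5; censored at 2, 4, 6
  rec <- data.frame(subject_id = letters[1:6],
                    time = c(1, 2, 3, 4, 5, 6),
                    event = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE),
                    group = "all")
  km <- km_fit(rec)
  ev <- km[km$n_event == 1, ]
  # S(1) = 5/6; S(3) = 5/6 * 3/4; S(5) = 5/6 * 3/4 * 1/2
  expect_equal(ev$surv, c(5 / 6, 5 / 6 * 3 / 4, 5 / 6 * 3 / 4 * 1 / 2))
  expect_equal(ev$n_risk, c(6, 4, 2))
  # survival curve properties
  expect_true(all(km$surv >= 0 & km$surv <= 1))
  expect_true(all(diff(km$surv) <= 1e-12))
})

test_that("KM degenerate cases follow the estimator", {
  none <- data.frame(time = c(2, 4), event = c(FALSE, FALSE))
  expect_true(all(km_fit(none)$surv == 1))
  two <- data.frame(time = c(1, 3), event = c(TRUE, FALSE))
  expect_equal(km_fit(two)$surv[1], 0.5)
  expect_error(km_fit(none[0, ]), "empty")
  # with no censoring KM equals the empirical survival function
  set.seed(1)
  t <- rexp(40)
  km <- km_fit(data.frame(time = t, event = TRUE))
  emp <- vapply(km$time, function(x) mean(t > x), numeric(1))
  expect_equal(km$surv, emp)
})

test_that("log-rank equals the observed-minus-expected oracle", {
  rec <- data.frame(
    time = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10),
    event = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
    group = rep(c("sensitive_signature", "non_sensitive"), 5))
  lr <- logrank_test(rec)
  # brute-force O-E computation over event times for group 1
  o <- e <- v <- 0
  for (t in sort(unique(rec$time[rec$event]))) {
    at_risk <- rec$time >= t
    d <- sum(rec$event & rec$time == t)
    n <- sum(at_risk)
    n1 <- sum(at_risk & rec$group == "non_sensitive")
    d1 <- sum(rec$event & rec$time == t & rec$group == "non_sensitive")
    o <- o + d1
    e <- e + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  expect_equal(lr$chisq, (o - e)^2 / v, tolerance = 1e-9)
  expect_equal(lr$p, pchisq((o - e)^2 / v, 1, lower.tail = FALSE),
               tolerance = 1e-9)
  # statistic is symmetric under group relabelling and non-negative
  rec2 <- rec
  rec2$group <- ifelse(rec$group == "non_sensitive",
                       "sensitive_signature", "non_sensitive")
  expect_equal(logrank_test(rec2)$chisq, lr$chisq)
  expect_gte(lr$chisq, 0)
})

test_that("identical groups give a null log-rank statistic", {
  base <- data.frame(time = c(1, 2, 3, 4), event = c(TRUE, TRUE, FALSE, TRUE))
  rec <- rbind(cbind(base, group = "sensitive_signature"),
               cbind(base, group = "non_sensitive"))
  lr <- logrank_test(rec)
  expect_equal(lr$chisq, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1)
  expect_error(logrank_test(cbind(base, group = "only")), "two groups")
})

test_that("chi-square matches the 2x2 closed form", {
  # n(ad - bc)^2 / (margin products): (10,0;0,10) -> 20
  expect_equal(chi2_test(matrix(c(10, 0, 0, 10), 2))$chisq, 20)
  # identical row proportions -> 0
  expect_equal(chi2_test(matrix(c(5, 10, 5, 10), 2))$chisq, 0)
  # homogeneity: scaling all counts by 10 scales the statistic by 10
  m <- matrix(c(12, 5, 7, 9), 2)
  expect_equal(chi2_test(m * 10)$chisq, 10 * chi2_test(m)$chisq)
  expect_error(chi2_test(matrix(c(0, 0, 3, 4), 2)), "zero margin")
})

test_that("concordance metrics reproduce the reconstructed 2x2 table", {
  # tp=14, fn=3, fp=4, tn=9 is the unique table consistent with the
  # printed 76.67% accuracy, 82.35% sensitivity, 69.23% specificity, n=30
  df <- data.frame(
    predicted_good = rep(c(TRUE, FALSE, TRUE, FALSE), c(14, 3, 4, 9)),
    obs = rep(c(TRUE, TRUE, FALSE, FALSE), c(14, 3, 4, 9)))
  df$outcome <- ifelse(df$obs, "PR", "PD")
  df$score <- ifelse(df$predicted_good, 1, 0)
  conc <- evaluate_concordance(df, reps = 200, seed = 3)
  expect_equal(unname(conc$counts), c(14, 3, 4, 9))
  expect_equal(round(unname(conc$metrics["accuracy"]), 2), 76.67)
  expect_equal(round(unname(conc$metrics["sensitivity"]), 2), 82.35)
  expect_equal(round(unname(conc$metrics["specificity"]), 2), 69.23)
  # CIs bracket the point estimates
  for (m in c("accuracy", "sensitivity", "specificity")) {
    expect_lte(conc$ci[[m]][1], conc$metrics[[m]])
    expect_gte(conc$ci[[m]][2], conc$metrics[[m]])
  }
  expect_lt(conc$chi2_p, 0.05)
  expect_output(print(conc), "accuracy")
})

test_that("degenerate concordance inputs are handled by contract", {
  ok <- data.frame(predicted_good = c(TRUE, FALSE),
                   outcome = c("PR", "PD"), score = c(1, 0))
  res <- evaluate_concordance(ok, reps = 20, seed = 1)
  expect_equal(unname(res$metrics[c("accuracy", "sensitivity",
                                    "specificity")]), c(100, 100, 100))
  # no observed positives: sensitivity undefined, reported missing
  neg <- data.frame(predicted_good = c(TRUE, FALSE),
                    outcome = c("PD", "PD"), score = c(1, 0))
  expect_warning(r2 <- evaluate_concordance(neg, reps = 20, seed = 1),
                 "sensitivity")
  expect_true(is.na(r2$metrics["sensitivity"]))
  allunk <- data.frame(predicted_good = TRUE, outcome = "unknown", score = 1)
  expect_error(evaluate_concordance(allunk), "no treatment")
  # unknown outcomes are excluded with a message
  mix <- rbind(ok, data.frame(predicted_good = TRUE, outcome = "unknown",
                              score = 1))
  expect_message(r3 <- evaluate_concordance(mix, reps = 20, seed = 1),
                 "excluded")
  expect_equal(r3$n, 2)
})

test_that("the rank AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(13)
  score <- runif(60)
  pos <- rbinom(60, 1, plogis(4 * (score - 0.5))) == 1
  ours <- pdoscreen:::rank_auc(score, pos)
  ref <- as.numeric(pROC::auc(pROC::roc(pos, score, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("bootstrap CIs are order statistics with deterministic seeds", {
  df <- data.frame(x = c(rep(1, 8), rep(0, 2)))
  f <- function(d) mean(d$x)
  ci <- bootstrap_ci(f, df, reps = 400, level = 0.95, seed = 9)
  ci_again <- bootstrap_ci(f, df, reps = 400, level = 0.95, seed = 9)
  expect_identical(ci, ci_again)
  expect_lte(ci["ci_low"], ci["ci_high"])
  boot <- attr(ci, "boot")
  expect_true(all(c(ci["ci_low"], ci["ci_high"]) %in% boot))
  # constant metric: zero-width interval
  cst <- bootstrap_ci(function(d) 1, df, reps = 50, seed = 1)
  expect_equal(unname(cst["ci_high"] - cst["ci_low"]), 0)
  expect_error(bootstrap_ci(f, df[0, , drop = FALSE], 10), "empty")
})

test_that("set-overlap and cosine similarities follow their formulas", {
  expect_equal(preservation_fraction(letters[1:10], letters[1:10]), 100)
  expect_equal(preservation_fraction(letters[1:10], LETTERS[1:10]), 0)
  expect_equal(preservation_fraction(letters[1:10], letters[5:10]), 60)
  expect_error(preservation_fraction(character(0), "a"), "empty")
  expect_equal(signature_similarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(signature_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(signature_similarity(c(1, 1, 0), c(1, 0, 1)), 0.5)
  expect_error(signature_similarity(c(0, 0), c(1, 1)), "zero vector")
  expect_error(signature_similarity(1:2, 1:3), "equal length")
})

test_that("derivation rates reproduce printed cohort percentages", {
  expect_equal(derivation_rate(99, 132), 75)
  expect_equal(derivation_rate(11, 17), 65)
  expect_equal(derivation_rate(14, 17), 82)
  expect_equal(derivation_rate(13, 17), 76)
  expect_equal(derivation_rate(52, 77), 68)
  expect_error(derivation_rate(1, 0), "positive")
})
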