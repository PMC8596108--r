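test_that("CPM normalization is library-size invariant", {
  m <- matrix(c(10, 20, 70, 10, 20, 70, 5, 10, 35), 3,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:3)))
  norm <- normalize_counts(m)
  expect_equal(norm[, 1], norm[, 2]) # identical samples
  expect_equal(norm[, 1], norm[, 3]) # doubling every count changes nothing
  # hand-computed CPM for a toy library of 100 reads
  expect_equal(unname(norm[, 1]),
               log2(c(10, 20, 70) / 100 * 1e6 + 1))
  m0 <- cbind(m, s4 = c(0, 0, 0))
  expect_error(normalize_counts(m0), "s4")
  expect_error(normalize_counts(m[, 1, drop = FALSE]), ">= 2 samples")
})

test_that("Welch DE finds planted fold changes and respects thresholds", {
  set.seed(8)
  n1 <- 10; n2 <- 10
  expr <- matrix(rnorm(200 * (n1 + n2), 6, 0.3), 200,
                 dimnames = list(sprintf("g%03d", 1:200), NULL))
  colnames(expr) <- sprintf("s%02d", 1:(n1 + n2))
  groups <- rep(c("pan_sensitive", "pan_resistant"), c(n1, n2))
  expr[1, groups == "pan_sensitive"] <- # planted 4-fold gene
    expr[1, groups == "pan_sensitive"] + 2
  expr[2, groups == "pan_sensitive"] <- # 1.5-fold: below the FC filter
    expr[2, groups == "pan_sensitive"] + log2(1.5)
  de <- differential_expression(expr, groups)
  expect_lte(de$q[1], 0.01)
  expect_gte(de$log2fc[1], 1)
  expect_lt(abs(de$log2fc[2]), 1) # excluded by FC >= 2 regardless of q
  # null genes: mean fold change near zero, q spread to 1
  expect_lt(mean(abs(de$log2fc[-(1:2)])), 0.2)
  expect_gt(max(de$q), 0.5)
  expect_error(differential_expression(expr, rep(c("pan_sensitive",
                                                   "pan_resistant",
                                                   "intermediate"),
                                                 c(2, 10, 8))),
               ">= 3 samples")
})

test_that("BH q-values are monotone in p-values", {
  set.seed(9)
  expr <- matrix(rnorm(500 * 12, 5, 1), 500)
  colnames(expr) <- sprintf("s%02d", 1:12)
  de <- differential_expression(expr, rep(c("pan_sensitive",
                                            "pan_resistant"), each = 6))
  o <- order(de$p)
  expect_true(all(diff(de$q[o]) >= -1e-12))
})

test_that("spearman filter matches a brute-force rank oracle with ties", {
  # oracle: Pearson correlation of average ranks
  rank_rho <- function(x, y) {
    rx <- rank(x); ry <- rank(y)
    sum((rx - mean(rx)) * (ry - mean(ry))) /
      sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  }
  set.seed(10)
  n <- 12
  u <- rnorm(n)
  pdos <- sprintf("PDO%03d", 1:n)
  ic50 <- do.call(rbind, lapply(MICROTUBULE_DRUGS, function(d)
    data.frame(pdo_id = pdos, drug_id = d,
               ic50_molar = 10^(-6.5 + u + rnorm(n, 0, 0.1)))))
  summ <- ic50_summary(ic50)
  expr <- rbind(
    anti = -u + rnorm(n, 0, 0.05),          # strongly anticorrelated
    tied = rep(c(1, 2), length.out = n),     # heavy ties
    weak = rnorm(n))
  colnames(expr) <- pdos
  de <- data.frame(gene_id = rownames(expr),
                   log2fc = c(2, 1.5, 1.2), q = c(1e-4, 1e-4, 1e-4))
  sig <- spearman_filter(de, expr, ic50, rho_min = 0.3)
  for (g in rownames(expr)) {
    oracle <- rank_rho(expr[g, pdos], summ[pdos])
    got <- suppressWarnings(
      cor(expr[g, pdos], summ[pdos], method = "spearman"))
    expect_equal(got, oracle, tolerance = 1e-12)
  }
  expect_true("anti" %in% sig$gene_id)
  expect_equal(sig$direction[sig$gene_id == "anti"], "up_in_sensitive")
  expect_lt(sig$rho[sig$gene_id == "anti"], -0.3)
})

test_that("weak or sign-inconsistent correlations are filtered out", {
  set.seed(11)
  n <- 20
  pdos <- sprintf("PDO%03d", 1:n)
  u <- rnorm(n)
  ic50 <- data.frame(pdo_id = pdos, drug_id = "docetaxel",
                     ic50_molar = 10^(u - 6))
  # "wrongsign": up in sensitive by DE but positively correlated with IC50
  expr <- rbind(wrongsign = u, weak = 0.1 * u + rnorm(n))
  colnames(expr) <- pdos
  de <- data.frame(gene_id = c("wrongsign", "weak"),
                   log2fc = c(2, 2), q = c(1e-5, 1e-5))
  sig <- spearman_filter(de, expr, ic50, drugs = "docetaxel")
  expect_false("wrongsign" %in% sig$gene_id)
  expect_error(spearman_filter(de, expr[, 1:4], ic50, drugs = "docetaxel"),
               ">= 5 samples")
})

test_that("every emitted signature gene satisfies all three thresholds", {
  ex <- simulate_expression(n_genes = 1500, n_pdos = 30, n_signature = 30,
                            effect_log2fc = 2, seed = 21, dispersion = 0.1)
  expr <- normalize_counts(ex$counts)
  groups <- setNames(ex$truth$pdos$group, ex$truth$pdos$pdo_id)
  de <- differential_expression(expr, groups[colnames(expr)])
  u <- setNames(ex$truth$pdos$mt_latent, ex$truth$pdos$pdo_id)
  set.seed(22)
  ic50 <- do.call(rbind, lapply(MICROTUBULE_DRUGS, function(d)
    data.frame(pdo_id = names(u), drug_id = d,
               ic50_molar = 10^(-6.5 + 0.9 * u + rnorm(length(u), 0, 0.2)))))
  sig <- spearman_filter(de, expr, ic50)
  expect_gt(nrow(sig), 0)
  expect_true(all(sig$fdr_q <= 0.01))
  expect_true(all(abs(sig$log2fc) >= 1))
  expect_true(all(abs(sig$rho) > 0.3))
  up <- sig$direction == "up_in_sensitive"
  expect_true(all(sig$rho[up] < 0) && all(sig$rho[!up] > 0))
})

test_that("signature clustering recovers planted blocks", {
  set.seed(30)
  n <- 12
  pdos <- sprintf("PDO%03d", 1:n)
  planted <- rep(c("sensitive_signature", "non_sensitive"), each = n / 2)
  sig <- data.frame(gene_id = sprintf("g%02d", 1:10),
                    direction = rep(c("up_in_sensitive",
                                      "down_in_sensitive"), 5))
  shift <- ifelse(sig$direction == "up_in_sensitive", 2, -2)
  expr <- matrix(rnorm(10 * n, 5, 0.3), 10,
                 dimnames = list(sig$gene_id, pdos))
  # both classes carry a coherent (opposite) profile over the signature
  expr[, planted == "sensitive_signature"] <-
    expr[, planted == "sensitive_signature"] + shift / 2
  expr[, planted == "non_sensitive"] <-
    expr[, planted == "non_sensitive"] - shift / 2
  cl <- cluster_pdos(expr, sig)
  expect_equal(cl$group, planted)
  # duplicated profiles land in the same cluster
  expr2 <- expr; expr2[, 2] <- expr2[, 1]
  cl2 <- cluster_pdos(expr2, sig)
  expect_equal(cl2$group[1], cl2$group[2])
  # constant profiles make the correlation distance degenerate
  expr3 <- expr; expr3[, 1] <- 1
  expect_error(cluster_pdos(expr3, sig), "degenerate")
})

test_that("the linear classifier separates, centers, and generalizes", {
  set.seed(31)
  sig_genes <- sprintf("g%02d", 1:8)
  make_expr <- function(n_per, shift) {
    lab <- rep(c("sensitive_signature", "non_sensitive"), each = n_per)
    x <- matrix(rnorm(8 * 2 * n_per, 0, 0.5), 8,
                dimnames = list(sig_genes,
                                sprintf("s%03d", 1:(2 * n_per))))
    x[, lab == "sensitive_signature"] <-
      x[, lab == "sensitive_signature"] + shift
    list(x = x, lab = lab)
  }
  tr <- make_expr(10, 2)
  model <- train_classifier(tr$x, tr$lab)
  expect_equal(as.character(apply_classifier(model, tr$x)), tr$lab)
  te <- make_expr(25, 2)
  acc <- mean(as.character(apply_classifier(model, te$x)) == te$lab)
  expect_gte(acc, 0.9)
  # symmetric two-point problem: the boundary sits at the midpoint
  x2 <- matrix(c(-1, 1), 1, 2, dimnames = list("g01", c("a", "b")))
  m2 <- train_classifier(x2, c("neg", "pos"))
  mid_lo <- matrix(-0.1, 1, 1, dimnames = list("g01", "m1"))
  mid_hi <- matrix(0.1, 1, 1, dimnames = list("g01", "m2"))
  expect_equal(as.character(apply_classifier(m2, mid_lo)), "neg")
  expect_equal(as.character(apply_classifier(m2, mid_hi)), "pos")
  # missing signature genes are imputed at the training mean
  te_missing <- te$x[-1, , drop = FALSE]
  expect_message(pred <- apply_classifier(model, te_missing), "imputed")
  expect_gte(mean(as.character(pred) == te$lab), 0.85)
  expect_error(train_classifier(tr$x, rep("one", 20)), "two classes")
})

test_that("classifier training is deterministic", {
  set.seed(32)
  x <- matrix(rnorm(60), 6, 10,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:10)))
  lab <- rep(c("a", "b"), 5)
  m1 <- train_classifier(x, lab)
  m2 <- train_classifier(x, lab)
  expect_identical(m1$model$coefs, m2$model$coefs)
  expect_identical(apply_classifier(m1, x), apply_classifier(m2, x))
})
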