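#' Library-size normalization of a count matrix
#'
#' Counts per million on total library size, then `log2(CPM + 1)`.
#'
#' @param counts Non-negative count matrix, genes in rows, samples in
#'   columns.
#' @return Matrix of log2(CPM + 1), same dimensions.
#' @export
normalize_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("need >= 2 samples")
  if (any(counts < 0)) stop("counts must be non-negative")
  libs <- colSums(counts)
  zero <- which(libs == 0)
  if (length(zero))
    stop("sample '", colnames(counts)[zero[1]] %||% zero[1],
         "' has an all-zero library")
  log2(t(t(counts) / libs) * 1e6 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-gene Welch differential expression between response groups
#'
#' Welch two-sample t statistic on log2 expression per gene, comparing the
#' pan-sensitive group against the pan-resistant group (PDOs sensitive /
#' resistant to all six microtubule-targeting drugs). `log2fc` is the mean
#' difference (sensitive minus resistant); q-values are Benjamini-Hochberg.
#'
#' @param expr Log-scale expression matrix, genes x samples (see
#'   [normalize_counts()]).
#' @param groups Character/factor per sample: `pan_sensitive`,
#'   `pan_resistant` (others are dropped).
#' @return Data frame `gene_id`, `log2fc`, `t`, `df`, `p`, `q`.
#' @export
differential_expression <- function(expr, groups) {
  groups <- as.character(groups)
  s <- which(groups == "pan_sensitive")
  r <- which(groups == "pan_resistant")
  if (length(s) < 3L || length(r) < 3L)
    stop("each group needs >= 3 samples (got ", length(s), " sensitive, ",
         length(r), " resistant)")
  xs <- expr[, s, drop = FALSE]
  xr <- expr[, r, drop = FALSE]
  n1 <- ncol(xs); n2 <- ncol(xr)
  m1 <- rowMeans(xs); m2 <- rowMeans(xr)
  v1 <- rowSums((xs - m1)^2) / (n1 - 1)
  v2 <- rowSums((xr - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  p[!is.finite(t)] <- 1 # zero-variance, zero-difference genes
  q <- stats::p.adjust(p, method = "BH")
  data.frame(
    gene_id = rownames(expr) %||% as.character(seq_len(nrow(expr))),
    log2fc = m1 - m2, t = t, df = df, p = p, q = q,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Median log10 IC50 across the six microtubule-targeting drugs
#'
#' @param ic50 Data frame `pdo_id`, `drug_id`, `ic50_molar`.
#' @param drugs Drug set to aggregate over (default [MICROTUBULE_DRUGS]).
#' @return Named numeric vector, one summary value per PDO.
#' @export
ic50_summary <- function(ic50, drugs = MICROTUBULE_DRUGS) {
  sub <- ic50[ic50$drug_id %in% drugs, , drop = FALSE]
  if (!nrow(sub)) stop("no IC50 records for the requested drugs")
  vapply(split(sub$ic50_molar, sub$pdo_id),
         function(x) stats::median(log10(x)), numeric(1))
}

#' Rank-correlation filter defining the response signature
#'
#' Starting from genes that pass the differential-expression thresholds
#' (`q <= de_fdr_max`, `|log2fc| >= log2(de_fc_min)`), keeps a gene iff the
#' tie-corrected Spearman correlation between its expression and the
#' per-PDO median log10 IC50 of the six microtubule-targeting drugs exceeds
#' `rho_min` in absolute value with a sign consistent with the
#' differential-expression direction: a gene up in sensitive PDOs must
#' anticorrelate with IC50 (high expression, low IC50), and vice versa.
#'
#' @param de Differential-expression table from
#'   [differential_expression()].
#' @param expr Log-scale expression matrix (genes x samples); column names
#'   must match the PDO ids of `ic50`.
#' @param ic50 IC50 table covering the six microtubule drugs for the
#'   expression samples.
#' @param de_fdr_max,de_fc_min,rho_min Thresholds, see [pdo_config()].
#' @param drugs Drug set for the IC50 summary.
#' @return Data frame `gene_id`, `direction` (`up_in_sensitive` /
#'   `down_in_sensitive`), `log2fc`, `fdr_q`, `rho`.
#' @export
spearman_filter <- function(de, expr, ic50,
                            de_fdr_max = 0.01, de_fc_min = 2,
                            rho_min = 0.3, drugs = MICROTUBULE_DRUGS) {
  summ <- ic50_summary(ic50, drugs)
  shared <- intersect(colnames(expr), names(summ))
  if (length(shared) < 5L)
    stop("need >= 5 samples with both expression and IC50 (got ",
         length(shared), ")")
  summ <- summ[shared]
  hits <- de[de$q <= de_fdr_max & abs(de$log2fc) >= log2(de_fc_min), ,
             drop = FALSE]
  if (!nrow(hits))
    return(data.frame(gene_id = character(0), direction = character(0),
                      log2fc = numeric(0), fdr_q = numeric(0),
                      rho = numeric(0), stringsAsFactors = FALSE))
  sub <- expr[hits$gene_id, shared, drop = FALSE]
  rho <- as.numeric(stats::cor(t(sub), summ, method = "spearman"))
  direction <- ifelse(hits$log2fc > 0, "up_in_sensitive", "down_in_sensitive")
  consistent <- (direction == "up_in_sensitive" & rho < 0) |
    (direction == "down_in_sensitive" & rho > 0)
  keep <- !is.na(rho) & abs(rho) > rho_min & consistent
  data.frame(gene_id = hits$gene_id[keep], direction = direction[keep],
             log2fc = hits$log2fc[keep], fdr_q = hits$q[keep],
             rho = rho[keep], row.names = NULL, stringsAsFactors = FALSE)
}

#' Cluster PDOs by their signature expression profiles
#'
#' Agglomerative clustering (average linkage) on the correlation distance
#' `1 - Pearson r` between signature profiles, cut at `k = 2`. The cluster
#' with the higher mean expression of `up_in_sensitive` genes is labelled
#' `sensitive_signature`; the other `non_sensitive`.
#'
#' @param expr Log-scale expression matrix (genes x samples).
#' @param signature Signature table from [spearman_filter()].
#' @param k Number of clusters (default 2).
#' @return Data frame `pdo_id`, `group`, plus the `hclust` tree as
#'   attribute `tree`.
#' @export
cluster_pdos <- function(expr, signature, k = 2L) {
  if (nrow(signature) < 2L) stop("need >= 2 signature genes")
  if (ncol(expr) < 4L) stop("need >= 4 PDOs to cluster")
  sub <- expr[signature$gene_id, , drop = FALSE]
  cc <- suppressWarnings(stats::cor(sub))
  if (anyNA(cc))
    stop("degenerate distance: constant signature profile(s)")
  d <- stats::as.dist(1 - cc)
  tree <- stats::hclust(d, method = "average")
  cl <- stats::cutree(tree, k = k)
  up <- signature$gene_id[signature$direction == "up_in_sensitive"]
  score <- if (length(up)) {
    colMeans(sub[up, , drop = FALSE])
  } else {
    -colMeans(sub) # only down-genes: sensitive class has the lower mean
  }
  means <- tapply(score, cl, mean)
  sens_cluster <- as.integer(names(means)[which.max(means)])
  out <- data.frame(
    pdo_id = colnames(expr),
    group = ifelse(cl == sens_cluster, "sensitive_signature",
                   "non_sensitive"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "tree") <- tree
  out
}

#' Train a linear support-vector classifier on the signature
#'
#' Features (genes) are standardized to zero mean / unit variance using the
#' training data only; the model is a linear-kernel SVM. Training is
#' deterministic for fixed inputs.
#'
#' @param expr Log-scale expression matrix restricted to signature genes
#'   (genes x samples).
#' @param labels Class label per sample (two classes required).
#' @param cost SVM cost parameter.
#' @return List of class `pdo_svm`: the fitted model plus the gene order
#'   and per-gene center/scale used for standardization.
#' @export
train_classifier <- function(expr, labels, cost = 1) {
  labels <- factor(labels)
  if (nlevels(labels) != 2L)
    stop("training needs exactly two classes, got ", nlevels(labels))
  x <- t(expr) # samples x genes
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  xs <- scale(x, center = center, scale = scale)
  model <- e1071::svm(xs, labels, kernel = "linear", cost = cost,
                      scale = FALSE)
  structure(
    list(model = model, genes = rownames(expr), center = center,
         scale = scale, levels = levels(labels)),
    class = "pdo_svm"
  )
}

#' Apply a trained signature classifier to new expression data
#'
#' Signature genes absent from the new matrix are imputed at the training
#' mean (zero after centering); the number of imputed genes is reported.
#'
#' @param object A `pdo_svm` from [train_classifier()].
#' @param new_expr Log-scale expression matrix (genes x samples).
#' @return Factor of predicted labels, one per sample.
#' @export
apply_classifier <- function(object, new_expr) {
  genes <- object$genes
  x <- matrix(0, ncol(new_expr), length(genes),
              dimnames = list(colnames(new_expr), genes))
  present <- intersect(genes, rownames(new_expr))
  missing <- setdiff(genes, present)
  if (length(missing))
    message(length(missing),
            " signature gene(s) missing; imputed at training mean")
  x[, present] <- t(new_expr[present, , drop = FALSE])
  if (length(missing))
    x[, missing] <- matrix(object$center[missing], nrow(x),
                           length(missing), byrow = TRUE)
  xs <- scale(x, center = object$center[genes],
              scale = object$scale[genes])
  stats::predict(object$model, xs)
}
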