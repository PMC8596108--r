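#' @name pdoscreen-pipeline
#' @title Stage dispatcher and end-to-end pipeline
#' @description
#' `pdo_run()` executes one named stage against a working directory,
#' reading the artifacts earlier stages wrote and failing with a
#' dependency error when they are absent. `pdo_pipeline()` chains every
#' stage. All randomness derives from the configuration seed, and all
#' outputs are plain deterministic text, so a fixed seed reproduces the
#' run byte for byte.
NULL

PIPELINE_STAGES <- c("simulate", "fit", "classify", "combo", "signature",
                     "survival", "concord", "report")

path_in <- function(dir, name) file.path(dir, name)

need_artifact <- function(dir, name, produced_by) {
  p <- path_in(dir, name)
  if (!file.exists(p))
    stop("missing artifact '", name, "': run the '", produced_by,
         "' stage first")
  p
}

log_line <- function(dir, ...) {
  cat(paste0(..., "\n"), file = path_in(dir, "log.txt"), append = TRUE)
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (synthetic screen, expression and clinic written as
#' tables), `fit` (normalize + 4PL + IC50), `classify` (tertile calls),
#' `combo` (predicted-additive example curve), `signature` (DE + rank
#' filter + clustering), `survival` (cohort simulation + KM + log-rank),
#' `concord` (treatment predictions vs outcomes), `report` (summary JSON).
#'
#' @param stage One of the stage names above.
#' @param dir Working directory for artifacts (created if needed).
#' @param config A [pdo_config()].
#' @param n_pdos,n_genes,n_signature,n_treatments Problem sizes for the
#'   `simulate` stage; defaults are the study scale.
#' @param panel Drug panel.
#' @return Invisibly, the paths written.
#' @export
pdo_run <- function(stage, dir, config = pdo_config(),
                    n_pdos = 76L, n_genes = 12000L, n_signature = 150L,
                    n_treatments = 100L, panel = default_panel()) {
  if (!stage %in% PIPELINE_STAGES)
    stop("unknown subcommand '", stage, "'; expected one of: ",
         paste(PIPELINE_STAGES, collapse = ", "))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  log_line(dir, "stage=", stage, " seed=", config$seed,
           " config=", jsonlite::toJSON(unclass(config), auto_unbox = TRUE))
  written <- switch(
    stage,
    simulate = {
      scr <- simulate_screen(panel = panel, n_pdos = n_pdos,
                             noise_cv = config$noise_cv,
                             seed = derive_seed(config$seed, 1))
      write_table_file(scr$wells, path_in(dir, "plates.tsv"))
      write_table_file(scr$truth$pdos, path_in(dir, "truth_pdos.tsv"))
      write_table_file(scr$truth$curves, path_in(dir, "truth_curves.tsv"))
      u <- stats::setNames(scr$truth$pdos$mt_latent, scr$truth$pdos$pdo_id)
      ex <- simulate_expression(n_genes = n_genes,
                                n_signature = n_signature,
                                seed = derive_seed(config$seed, 2),
                                mt_latent = u)
      cm <- data.frame(gene_id = rownames(ex$counts), ex$counts,
                       check.names = FALSE)
      write_table_file(cm, path_in(dir, "counts.tsv"))
      write_table_file(ex$truth$genes, path_in(dir, "truth_genes.tsv"))
      c("plates.tsv", "counts.tsv")
    },
    fit = {
      wells <- read_plate_table(
        need_artifact(dir, "plates.tsv", "simulate"), panel = panel)
      norm <- normalize_viability(wells, anchor = config$anchor)
      res <- fit_screen(norm, qc_cv_limit = config$qc_cv_limit)
      if (length(res$errors))
        log_line(dir, "fit errors: ", paste(res$errors, collapse = " | "))
      write_table_file(res$ic50, path_in(dir, "ic50.tsv"))
      write_table_file(res$fits, path_in(dir, "fits.tsv"))
      c("ic50.tsv", "fits.tsv")
    },
    classify = {
      ic50 <- read_table_file(need_artifact(dir, "ic50.tsv", "fit"))
      calls <- call_matrix(ic50, config$tertile_fraction)
      errs <- attr(calls, "errors")
      if (length(errs))
        log_line(dir, "classify errors: ",
                 paste(names(errs), errs, sep = ": ", collapse = " | "))
      write_table_file(calls, path_in(dir, "calls.tsv"))
      "calls.tsv"
    },
    combo = {
      wells <- read_plate_table(
        need_artifact(dir, "plates.tsv", "simulate"), panel = panel)
      norm <- normalize_viability(wells, anchor = config$anchor)
      cu <- build_curve(norm, norm$pdo_id[1], norm$drug_id[1])
      cb <- predicted_additive(cu, config$fixed_partner_viability)
      write_table_file(
        data.frame(pdo_id = cb$pdo_id, drug_id = cb$drug_id,
                   conc_molar = cb$conc, single_agent = cb$single_agent,
                   predicted_additive = cb$predicted_additive),
        path_in(dir, "combo.tsv"))
      "combo.tsv"
    },
    signature = {
      cm <- read_table_file(need_artifact(dir, "counts.tsv", "simulate"))
      counts <- as.matrix(cm[, -1, drop = FALSE])
      rownames(counts) <- cm$gene_id
      ic50 <- read_table_file(need_artifact(dir, "ic50.tsv", "fit"))
      calls <- read_table_file(need_artifact(dir, "calls.tsv", "classify"))
      expr <- normalize_counts(counts)
      groups <- pan_response_groups(calls)
      if (sum(groups == "pan_sensitive") < 3L ||
          sum(groups == "pan_resistant") < 3L) {
        # strict all-six grouping too sparse for this cohort: fall back to
        # tertiles of the six-drug median log10 IC50
        log_line(dir, "pan groups sparse; using IC50-summary tertiles")
        summ <- ic50_summary(ic50)
        qs <- stats::quantile(summ, c(1 / 3, 2 / 3), names = FALSE,
                              type = 1)
        groups <- stats::setNames(
          ifelse(summ <= qs[1], "pan_sensitive",
                 ifelse(summ > qs[2], "pan_resistant", "intermediate")),
          names(summ))
      }
      de <- differential_expression(expr,
                                    groups[match(colnames(expr),
                                                 names(groups))])
      sig <- spearman_filter(de, expr, ic50,
                             de_fdr_max = config$de_fdr_max,
                             de_fc_min = config$de_fc_min,
                             rho_min = config$rho_min)
      write_table_file(sig, path_in(dir, "signature.tsv"))
      if (nrow(sig) >= 2L) {
        cl <- cluster_pdos(expr, sig)
        write_table_file(cl, path_in(dir, "groups.tsv"))
      } else {
        log_line(dir, "signature too small to cluster (",
                 nrow(sig), " genes)")
      }
      "signature.tsv"
    },
    survival = {
      surv <- simulate_survival(seed = derive_seed(config$seed, 3))
      write_table_file(surv, path_in(dir, "survival.tsv"))
      km <- km_fit(surv)
      write_table_file(km, path_in(dir, "km.tsv"))
      lr <- logrank_test(surv)
      write_json_file(lr, path_in(dir, "logrank.json"))
      c("survival.tsv", "km.tsv", "logrank.json")
    },
    concord = {
      calls <- read_table_file(need_artifact(dir, "calls.tsv", "classify"))
      tr_path <- path_in(dir, "treatments.tsv")
      if (!file.exists(tr_path)) {
        cl <- simulate_clinic(calls, n_treatments = n_treatments,
                              seed = derive_seed(config$seed, 4))
        write_table_file(cl$treatments, tr_path)
      }
      treatments <- read_treatments(tr_path)
      pred <- predict_treatment(treatments, calls,
                                config$moderate_counts_good)
      write_table_file(pred, path_in(dir, "treatment_predictions.tsv"))
      conc <- evaluate_concordance(pred, reps = config$bootstrap_reps,
                                   level = config$ci_level,
                                   seed = derive_seed(config$seed, 5))
      write_json_file(
        list(counts = as.list(conc$counts), n = conc$n,
             n_excluded = conc$n_excluded,
             metrics = as.list(conc$metrics),
             ci = conc$ci, chi2 = conc$chi2, chi2_p = conc$chi2_p),
        path_in(dir, "concordance.json"))
      c("treatment_predictions.tsv", "concordance.json")
    },
    report = {
      conc <- path_in(dir, "concordance.json")
      lr <- path_in(dir, "logrank.json")
      summary <- list(
        seed = config$seed,
        concordance = if (file.exists(conc)) jsonlite::read_json(conc),
        logrank = if (file.exists(lr)) jsonlite::read_json(lr))
      write_json_file(summary, path_in(dir, "summary.json"))
      "summary.json"
    }
  )
  invisible(file.path(dir, written))
}

#' Pan-sensitive / pan-resistant groups from response calls
#'
#' A PDO is `pan_sensitive` when called sensitive for all six
#' microtubule-targeting drugs with calls, `pan_resistant` when called
#' resistant for all of them, `intermediate` otherwise.
#'
#' @param calls Long call table.
#' @param drugs Drug set (default [MICROTUBULE_DRUGS]).
#' @return Named character vector of groups per PDO.
#' @export
pan_response_groups <- function(calls, drugs = MICROTUBULE_DRUGS) {
  sub <- calls[calls$drug_id %in% drugs, , drop = FALSE]
  if (!nrow(sub)) stop("no calls for the microtubule drugs")
  vapply(split(sub$label, sub$pdo_id), function(lab) {
    if (all(lab == "sensitive")) "pan_sensitive"
    else if (all(lab == "resistant")) "pan_resistant"
    else "intermediate"
  }, character(1))
}

#' Run the full pipeline into a directory
#'
#' Chains `simulate`, `fit`, `classify`, `combo`, `signature`,
#' `survival`, `concord`, `report`. Deterministic for a fixed
#' configuration seed.
#'
#' @inheritParams pdo_run
#' @return Invisibly, the working directory.
#' @export
pdo_pipeline <- function(dir, config = pdo_config(), n_pdos = 76L,
                         n_genes = 12000L, n_signature = 150L,
                         n_treatments = 100L, panel = default_panel()) {
  for (stage in PIPELINE_STAGES)
    pdo_run(stage, dir, config, n_pdos = n_pdos, n_genes = n_genes,
            n_signature = n_signature, n_treatments = n_treatments,
            panel = panel)
  invisible(dir)
}
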