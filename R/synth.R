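#' @name pdoscreen-synth
#' @title Synthetic screen, expression, clinic and survival generators
#' @description
#' Seeded generators that emit data with the statistical structure the
#' analysis assumes, in the same formats the readers accept, each together
#' with a ground-truth object so recovery can be scored without peeking.
#' Defaults mirror the study conditions: 76 organoid lines screened against
#' a 49-drug panel as 7-point threefold series from 20 uM in triplicate,
#' with vehicle (0.2% DMSO) negative controls and a 1 uM proteasome-
#' inhibitor positive control; multiplicative lognormal viability noise at
#' CV 10%; correlated responses across the six microtubule-targeting
#' drugs; treatment outcomes drawn with P(good | >= 1 sensitive drug) =
#' 0.71 and P(progression | no sensitive drug) = 0.93.
NULL

# mean-one multiplicative lognormal noise at a given CV
lognormal_factor <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sigma <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -sigma^2 / 2, sigma))
}

# closed-form 50%-crossing of a 4PL curve, censored to the tested range
true_ic50 <- function(top, bottom, hill, ec50, cmin, cmax) {
  v <- function(cc) viability_4pl(cc, top, bottom, hill, ec50)
  if (v(cmax) >= 50) return(list(ic50 = cmax, censor = "at_max"))
  if (v(cmin) <= 50) return(list(ic50 = cmin, censor = "at_min"))
  ratio <- (top - 50) / (50 - bottom)
  list(ic50 = min(max(ec50 * ratio^(1 / hill), cmin), cmax),
       censor = "interior")
}

#' Simulate a full viability screen
#'
#' For every PDO x drug pair a true 4PL curve is drawn (top near 100%,
#' bottom near 0%, Hill slope 0.8-2.2, log10 EC50 uniform over a window
#' spanning and slightly exceeding the tested range so range censoring
#' occurs naturally). The six microtubule-targeting drugs share a per-PDO
#' latent sensitivity factor, producing the correlated response block the
#' signature analysis relies on. Raw luminescence wells are the 4PL
#' viability mapped between per-PDO control levels and multiplied by
#' mean-one lognormal noise; each PDO also gets six negative- and six
#' positive-control wells.
#'
#' @param panel Drug panel (default [default_panel()]).
#' @param n_pdos Number of organoid lines (default 76).
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (default 0.10).
#' @param seed Integer seed.
#' @param mt_loading Loading of the shared microtubule latent factor on
#'   log10 EC50 (default 0.9 decades).
#' @return List `wells` (validated plate table) and `truth` (list with
#'   `pdos`: pdo_id, mt_latent, planted group; `curves`: true 4PL
#'   parameters, IC50 and censor status per PDO x drug).
#' @export
simulate_screen <- function(panel = default_panel(), n_pdos = 76L,
                            noise_cv = 0.10, seed = 1L, mt_loading = 0.9) {
  if (n_pdos < 1L) stop("'n_pdos' must be >= 1")
  if (noise_cv < 0) stop("'noise_cv' must be >= 0")
  set.seed(as.integer(seed))
  pdo_ids <- sprintf("PDO%03d", seq_len(n_pdos))
  u <- stats::rnorm(n_pdos) # shared microtubule latent; low = sensitive
  grp_cut <- stats::quantile(u, c(1 / 3, 2 / 3), names = FALSE, type = 1)
  group <- ifelse(u <= grp_cut[1], "pan_sensitive",
                  ifelse(u > grp_cut[2], "pan_resistant", "intermediate"))

  curves <- vector("list", nrow(panel))
  well_blocks <- vector("list", nrow(panel))
  for (d in seq_len(nrow(panel))) {
    drug <- panel$drug_id[d]
    conc <- dilution_series(panel$top_conc[d], panel$fold[d],
                            panel$n_points[d])
    cmin <- min(conc); cmax <- max(conc)
    # drug-level median potency, allowed slightly beyond the tested range
    mu_d <- stats::runif(1, log10(cmin) - 0.5, log10(cmax) + 0.8)
    is_mt <- drug %in% MICROTUBULE_DRUGS
    eps <- stats::rnorm(n_pdos, 0, if (is_mt) 0.35 else 0.9)
    l_ec50 <- mu_d + (if (is_mt) mt_loading * u else 0) + eps
    top <- stats::rnorm(n_pdos, 100, 2)
    bottom <- stats::runif(n_pdos, 0, 8)
    hill <- stats::runif(n_pdos, 0.8, 2.2)
    ic <- t(vapply(seq_len(n_pdos), function(i) {
      r <- true_ic50(top[i], bottom[i], hill[i], 10^l_ec50[i], cmin, cmax)
      c(r$ic50, match(r$censor, c("interior", "at_max", "at_min")))
    }, numeric(2)))
    curves[[d]] <- data.frame(
      pdo_id = pdo_ids, drug_id = drug, top = top, bottom = bottom,
      hill = hill, ec50_molar = 10^l_ec50, ic50_true = ic[, 1],
      censor_true = c("interior", "at_max", "at_min")[ic[, 2]],
      stringsAsFactors = FALSE)
    # triplicate wells on the dilution grid
    nrep <- 3L
    grid <- expand.grid(rep_i = seq_len(nrep), conc = conc,
                        pdo = seq_len(n_pdos))
    via <- viability_4pl(grid$conc, top[grid$pdo], bottom[grid$pdo],
                         hill[grid$pdo], 10^l_ec50[grid$pdo])
    well_blocks[[d]] <- data.frame(
      pdo_id = pdo_ids[grid$pdo], drug_id = drug, conc_molar = grid$conc,
      replicate = grid$rep_i, viability_frac = via / 100, role = "test",
      stringsAsFactors = FALSE)
  }
  wells <- do.call(rbind, well_blocks)

  # per-PDO plate control levels; positive control sits near zero signal
  neg_level <- 5e5 * 2^stats::runif(n_pdos, -0.5, 0.5)
  pos_level <- 0.005 * neg_level
  names(neg_level) <- names(pos_level) <- pdo_ids
  wells$signal <- (pos_level[wells$pdo_id] +
                   wells$viability_frac *
                     (neg_level[wells$pdo_id] - pos_level[wells$pdo_id])) *
    lognormal_factor(nrow(wells), noise_cv)
  wells$signal <- pmax(wells$signal, 0)
  wells$viability_frac <- NULL

  ctrl <- do.call(rbind, lapply(pdo_ids, function(p) {
    data.frame(pdo_id = p, drug_id = "", conc_molar = NA_real_,
               replicate = rep(1:6, 2),
               signal = c(neg_level[p] * lognormal_factor(6, noise_cv),
                          pos_level[p] * lognormal_factor(6, noise_cv)),
               role = rep(c("neg_control", "pos_control"), each = 6),
               stringsAsFactors = FALSE)
  }))
  wells <- rbind(wells, ctrl)
  rownames(wells) <- NULL

  list(
    wells = validate_wells(wells, panel = panel),
    truth = list(
      pdos = data.frame(pdo_id = pdo_ids, mt_latent = u, group = group,
                        stringsAsFactors = FALSE),
      curves = do.call(rbind, curves)
    )
  )
}

#' Simulate an expression count matrix with a planted response signature
#'
#' Negative-binomial counts with library sizes spanning at least 2-fold.
#' The first `n_signature` genes are signature genes with alternating
#' direction: their log2 mean is shifted by `+/- effect_log2fc / 2`
#' between the planted pan-sensitive and pan-resistant PDO tertiles (a
#' full `effect_log2fc` difference between the outer groups), which also
#' induces the monotone association with the planted log-IC50 latent that
#' the rank-correlation filter requires.
#'
#' @param n_genes Total genes (default 12000).
#' @param n_pdos Number of PDOs / samples (default 57); ignored when
#'   `mt_latent` is given.
#' @param n_signature Number of planted signature genes (default 150).
#' @param effect_log2fc Planted log2 fold change between the sensitive and
#'   resistant groups (default 2, i.e. 4-fold).
#' @param seed Integer seed.
#' @param dispersion Negative-binomial dispersion (default 0.15).
#' @param mt_latent Optional named per-PDO latent vector from
#'   [simulate_screen()] truth, to tie expression to a simulated screen.
#' @return List `counts` (genes x samples), `truth` (`genes`: membership
#'   and direction; `pdos`: latent, planted group).
#' @export
simulate_expression <- function(n_genes = 12000L, n_pdos = 57L,
                                n_signature = 150L, effect_log2fc = 2,
                                seed = 1L, dispersion = 0.15,
                                mt_latent = NULL) {
  if (n_signature > n_genes) stop("'n_signature' must be <= 'n_genes'")
  set.seed(as.integer(seed))
  if (is.null(mt_latent)) {
    pdo_ids <- sprintf("PDO%03d", seq_len(n_pdos))
    u <- stats::rnorm(n_pdos)
    names(u) <- pdo_ids
  } else {
    u <- mt_latent
    pdo_ids <- names(u)
    n_pdos <- length(u)
  }
  grp_cut <- stats::quantile(u, c(1 / 3, 2 / 3), names = FALSE, type = 1)
  group <- ifelse(u <= grp_cut[1], "pan_sensitive",
                  ifelse(u > grp_cut[2], "pan_resistant", "intermediate"))
  gshift <- c(pan_sensitive = 0.5, intermediate = 0,
              pan_resistant = -0.5)[group]

  gene_ids <- sprintf("G%05d", seq_len(n_genes))
  is_sig <- seq_len(n_genes) <= n_signature
  dir_sign <- ifelse(is_sig & (seq_len(n_genes) %% 2L == 1L), 1,
                     ifelse(is_sig, -1, 0))
  base <- stats::runif(n_genes, 3, 9) # log2 baseline abundance

  # library sizes: a deterministic 2-fold span, shuffled
  sf <- 2^seq(-0.5, 0.5, length.out = n_pdos)[sample.int(n_pdos)]
  lib <- 4e5 * sf

  log2mu <- outer(base, rep(1, n_pdos)) +
    outer(dir_sign * effect_log2fc, gshift)
  prop <- 2^log2mu
  prop <- sweep(prop, 2, colSums(prop), "/")
  mu <- sweep(prop, 2, lib, "*")
  counts <- matrix(
    stats::rnbinom(length(mu), mu = as.numeric(mu), size = 1 / dispersion),
    n_genes, n_pdos, dimnames = list(gene_ids, pdo_ids))

  list(
    counts = counts,
    truth = list(
      genes = data.frame(
        gene_id = gene_ids, is_signature = is_sig,
        direction = ifelse(dir_sign > 0, "up_in_sensitive",
                           ifelse(dir_sign < 0, "down_in_sensitive", "none")),
        stringsAsFactors = FALSE),
      pdos = data.frame(pdo_id = pdo_ids, mt_latent = as.numeric(u),
                        group = group, stringsAsFactors = FALSE)
    )
  )
}

#' Simulate clinical treatment records conditioned on response calls
#'
#' Each treatment first receives a PDO call profile (a regimen of 1-3
#' drugs sampled from one PDO's called drugs), then an outcome is drawn
#' from the stratum-conditional law: regimens containing at least one
#' sensitive drug achieve a good response (PR or SD) with probability
#' `p_good_given_sensitive`; all other regimens progress (PD) with
#' probability `p_pd_given_none`. By default the moderate-best stratum
#' follows the same law as the all-resistant stratum
#' (`p_good_given_moderate = 1 - p_pd_given_none`); supply a value to
#' break that tie.
#'
#' @param calls Long call table (`pdo_id`, `drug_id`, `label`).
#' @param n_treatments Number of regimens to draw (default 100).
#' @param p_good_given_sensitive P(good | >= 1 sensitive), default 0.71.
#' @param p_pd_given_none P(PD | no sensitive drug), default 0.93.
#' @param p_good_given_moderate Optional P(good | best call moderate).
#' @param seed Integer seed.
#' @return List `treatments` (patient_id, pdo_id, round_index, drugs,
#'   outcome) and `truth` (per-treatment stratum and good-response
#'   probability).
#' @export
simulate_clinic <- function(calls, n_treatments = 100L,
                            p_good_given_sensitive = 0.71,
                            p_pd_given_none = 0.93,
                            p_good_given_moderate = NULL,
                            seed = 1L) {
  stopifnot(p_good_given_sensitive >= 0, p_good_given_sensitive <= 1,
            p_pd_given_none >= 0, p_pd_given_none <= 1)
  if (is.null(p_good_given_moderate))
    p_good_given_moderate <- 1 - p_pd_given_none
  set.seed(as.integer(seed))
  pdos <- unique(calls$pdo_id)
  rows <- vector("list", n_treatments)
  strata <- character(n_treatments)
  p_good <- numeric(n_treatments)
  round_counter <- stats::setNames(integer(length(pdos)), pdos)
  for (i in seq_len(n_treatments)) {
    p <- sample(pdos, 1L)
    avail <- calls[calls$pdo_id == p, , drop = FALSE]
    k <- sample(1:3, 1L)
    pick <- avail[sample.int(nrow(avail), min(k, nrow(avail))), ,
                  drop = FALSE]
    stratum <- if (any(pick$label == "sensitive")) "sensitive"
               else if (any(pick$label == "moderate")) "moderate"
               else "none"
    pg <- switch(stratum,
                 sensitive = p_good_given_sensitive,
                 moderate = p_good_given_moderate,
                 none = 1 - p_pd_given_none)
    good <- stats::runif(1) < pg
    outcome <- if (good) sample(c("PR", "SD"), 1L) else "PD"
    round_counter[p] <- round_counter[p] + 1L
    rows[[i]] <- data.frame(
      patient_id = sub("^PDO", "Pat", p), pdo_id = p,
      round_index = round_counter[[p]],
      drugs = paste(pick$drug_id, collapse = ";"),
      outcome = outcome, stringsAsFactors = FALSE)
    strata[i] <- stratum
    p_good[i] <- pg
  }
  treatments <- validate_treatments(do.call(rbind, rows))
  list(treatments = treatments,
       truth = data.frame(stratum = strata, p_good = p_good))
}

#' Simulate a two-group survival cohort
#'
#' Exponential event times with group-specific hazards: the
#' `sensitive_signature` group has the baseline hazard, the
#' `non_sensitive` group `hazard_ratio` times it. Censoring is an
#' independent exponential time whose rate is calibrated so the expected
#' censored fraction equals `censor_rate` in each group
#' (`rate_censor = hazard * censor_rate / (1 - censor_rate)`);
#' `censor_rate = 0` yields no censoring.
#'
#' @param n_per_group Subjects per group (default 200).
#' @param hazard_ratio Hazard of the non-sensitive group relative to the
#'   sensitive-signature group (> 0, default 3).
#' @param censor_rate Expected censored fraction in \[0, 1).
#' @param baseline_hazard Event hazard of the sensitive-signature group.
#' @param seed Integer seed.
#' @return Data frame `subject_id`, `time`, `event`, `group`.
#' @export
simulate_survival <- function(n_per_group = 200L, hazard_ratio = 3,
                              censor_rate = 0.2, baseline_hazard = 0.1,
                              seed = 1L) {
  if (hazard_ratio <= 0) stop("'hazard_ratio' must be > 0")
  if (censor_rate < 0 || censor_rate >= 1)
    stop("'censor_rate' must be in [0, 1)")
  set.seed(as.integer(seed))
  hz <- c(sensitive_signature = baseline_hazard,
          non_sensitive = baseline_hazard * hazard_ratio)
  rows <- lapply(names(hz), function(g) {
    t_event <- stats::rexp(n_per_group, hz[[g]])
    t_cens <- if (censor_rate == 0) rep(Inf, n_per_group)
              else stats::rexp(n_per_group,
                               hz[[g]] * censor_rate / (1 - censor_rate))
    data.frame(
      subject_id = paste0(substr(g, 1, 1), seq_len(n_per_group)),
      time = pmin(t_event, t_cens), event = t_event <= t_cens,
      group = g, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
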