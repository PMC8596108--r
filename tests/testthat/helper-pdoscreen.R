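# Shared fixtures built in code.

# A tiny 4-drug panel (two microtubule drugs) with the default 7-pt series.
toy_panel <- function() {
  rbind(
    drug_panel_entry("docetaxel", "taxane", approved_for_breast = TRUE),
    drug_panel_entry("paclitaxel", "taxane", approved_for_breast = TRUE),
    drug_panel_entry("cisplatin", "platinum", approved_for_breast = TRUE),
    drug_panel_entry("bortezomib", "proteasome")
  )
}

# Panel holding all six microtubule drugs plus a few others; used when the
# signature stages need the full six-drug block.
mt_panel <- function() {
  extra <- rbind(
    drug_panel_entry("cisplatin", "platinum", approved_for_breast = TRUE),
    drug_panel_entry("gemcitabine", "nucleoside", approved_for_breast = TRUE),
    drug_panel_entry("bortezomib", "proteasome"),
    drug_panel_entry("everolimus", "mTOR")
  )
  rbind(default_panel()[default_panel()$drug_id %in% MICROTUBULE_DRUGS, ],
        extra)
}

# Noise-free plate wells for one PDO x drug from known 4PL parameters.
# Control wells anchor viability exactly (neg = 1000, pos = 0 signal).
toy_wells <- function(pdo = "PDO001", drug = "docetaxel",
                      top = 100, bottom = 0, hill = 1, ec50 = 0.5e-6,
                      conc = dilution_series(20e-6, 3, 7), n_rep = 3) {
  via <- viability_4pl(rep(conc, each = n_rep), top, bottom, hill, ec50)
  test <- data.frame(
    pdo_id = pdo, drug_id = drug, conc_molar = rep(conc, each = n_rep),
    replicate = rep(seq_len(n_rep), length(conc)),
    signal = 1000 * via / 100, role = "test", stringsAsFactors = FALSE)
  ctrl <- data.frame(
    pdo_id = pdo, drug_id = "", conc_molar = NA_real_,
    replicate = rep(1:3, 2),
    signal = c(1000, 1000, 1000, 0, 0, 0),
    role = rep(c("neg_control", "pos_control"), each = 3),
    stringsAsFactors = FALSE)
  rbind(test, ctrl)
}

# Curve object straight from known 4PL parameters (already normalized).
toy_curve <- function(pdo = "PDO001", drug = "docetaxel",
                      top = 100, bottom = 0, hill = 1, ec50 = 0.5e-6,
                      conc = dilution_series(20e-6, 3, 7), n_rep = 3,
                      noise_cv = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cc <- rep(conc, each = n_rep)
  via <- viability_4pl(cc, top, bottom, hill, ec50)
  if (noise_cv > 0) {
    sigma <- sqrt(log(1 + noise_cv^2))
    via <- via * exp(rnorm(length(via), -sigma^2 / 2, sigma))
  }
  pts <- data.frame(conc = cc, replicate = rep(seq_len(n_rep), length(conc)),
                    viability = via)
  mv <- vapply(conc, function(x) mean(pts$viability[pts$conc == x]),
               numeric(1))
  structure(list(pdo_id = pdo, drug_id = drug, conc = conc, points = pts,
                 mean_viability = mv),
            class = "pdo_curve")
}

# Flat-viability curve at a constant level.
flat_curve <- function(level = 100, conc = dilution_series(20e-6, 3, 7)) {
  cc <- rep(conc, each = 3)
  pts <- data.frame(conc = cc, replicate = rep(1:3, length(conc)),
                    viability = level)
  structure(list(pdo_id = "PDOf", drug_id = "flat", conc = conc,
                 points = pts, mean_viability = rep(level, length(conc))),
            class = "pdo_curve")
}

# IC50 record table for classification tests.
ic50_table <- function(values, censor = "interior", drug = "drugA") {
  data.frame(pdo_id = sprintf("PDO%03d", seq_along(values)),
             drug_id = drug, ic50_molar = values,
             censor = rep(censor, length.out = length(values)),
             stringsAsFactors = FALSE)
}
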