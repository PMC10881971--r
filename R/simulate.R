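#' Simulation configuration for a synthetic reporter screen
#'
#' Bundles the plate-design and noise parameters of a simulated
#' high-content screen. The defaults reproduce the study design:
#' 96-well plates with six negative and six positive control wells each, a
#' five-point 4-fold serial dilution from 100 uM, three replicate wells per
#' compound x dose, and 10% multiplicative well-to-well noise.
#'
#' @param doses Numeric vector of treatment concentrations (uM), strictly
#'   decreasing by a constant dilution factor.
#' @param n_replicate_wells Replicate wells per compound x dose (>= 2 so
#'   induction can be tested).
#' @param n_control_wells_per_type Negative and positive control wells per
#'   plate (>= 2; the screen design uses 6 of each).
#' @param cells_per_well_mean Expected cells imaged per well.
#' @param noise_cv Coefficient of variation of the multiplicative
#'   log-normal well-level noise (0 disables noise).
#' @param baseline_gfp Mean per-cell GFP intensity of unstimulated cells
#'   (arbitrary 16-bit-scale units).
#' @param pos_induction_fold GFP fold induction of the positive-chemical
#'   control wells over baseline (the scoring reference level).
#' @param gfp_pos_baseline_frac Fraction of GFP-positive cells in
#'   unstimulated wells.
#' @param gfp_area_per_cell Mean GFP-positive area per positive cell (px^2).
#' @param plate_size Wells per plate (96).
#' @param field_size Side length (pixels) of rendered image fields.
#' @param rng_seed Master seed; each plate derives its own stream from it.
#'
#' @return An object of class `hepascreen_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(noise_cv = 0)
#' cfg$doses
sim_config <- function(doses = 100 / 4^(0:4),
                       n_replicate_wells = 3,
                       n_control_wells_per_type = 6,
                       cells_per_well_mean = 1500,
                       noise_cv = 0.1,
                       baseline_gfp = 500,
                       pos_induction_fold = 3,
                       gfp_pos_baseline_frac = 0.05,
                       gfp_area_per_cell = 120,
                       plate_size = 96,
                       field_size = 256,
                       rng_seed = 1L) {
  if (length(doses) < 1) stopf("empty dose list")
  if (length(doses) > 1) {
    if (any(diff(doses) >= 0)) stopf("doses must be strictly decreasing")
    ratios <- doses[-length(doses)] / doses[-1]
    if (max(ratios) / min(ratios) > 1 + 1e-6)
      stopf("doses must form a constant-factor serial dilution")
  }
  if (n_control_wells_per_type < 2) stopf("need >= 2 control wells per type")
  if (n_replicate_wells < 2) stopf("need >= 2 replicate wells")
  if (noise_cv < 0) stopf("noise_cv must be >= 0")
  if (pos_induction_fold <= 1) stopf("pos_induction_fold must exceed 1")
  structure(list(
    doses = as.numeric(doses),
    n_replicate_wells = as.integer(n_replicate_wells),
    n_control_wells_per_type = as.integer(n_control_wells_per_type),
    cells_per_well_mean = cells_per_well_mean,
    noise_cv = noise_cv,
    baseline_gfp = baseline_gfp,
    pos_induction_fold = pos_induction_fold,
    gfp_pos_baseline_frac = gfp_pos_baseline_frac,
    gfp_area_per_cell = gfp_area_per_cell,
    plate_size = as.integer(plate_size),
    field_size = as.integer(field_size),
    rng_seed = as.integer(rng_seed)
  ), class = "hepascreen_config")
}

#' Ground-truth description of one simulated compound
#'
#' Defines what a simulated compound does: its GFP induction fold per
#' (pathway, condition), its cytotoxicity (Hill EC50 per condition and a
#' shared Hill slope), and the S9-dependence class it is constructed to
#' belong to. [simulate_screen()] verifies the declared class against the
#' noise-free expectation of the scoring rules and refuses inconsistent
#' truths.
#'
#' @param compound_id Unique compound label.
#' @param pathway_effects 4 x 2 numeric matrix of GFP induction folds
#'   (>= 0), rows [pathways()], columns [conditions()]. Fold 1 means no
#'   effect.
#' @param tox_ec50 Named numeric vector `c(S9minus = , S9plus = )` of
#'   viability EC50s (uM), both > 0.
#' @param hill_slope Hill slope of the viability decline (> 0).
#' @param intended_class One of `"consistent"`, `"s9_minus_specific"`,
#'   `"s9_plus_specific"`, `"non_responsive"`.
#'
#' @return An object of class `hepascreen_truth`.
#' @export
#' @examples
#' fx <- matrix(1, 4, 2, dimnames = list(pathways(), conditions()))
#' fx["Nrf2", ] <- 4.5
#' compound_truth("oxidant01", fx, c(S9minus = 300, S9plus = 300),
#'                intended_class = "consistent")
compound_truth <- function(compound_id, pathway_effects, tox_ec50,
                           hill_slope = 2,
                           intended_class = c("consistent",
                                              "s9_minus_specific",
                                              "s9_plus_specific",
                                              "non_responsive")) {
  intended_class <- match.arg(intended_class)
  pathway_effects <- as.matrix(pathway_effects)
  if (!identical(dim(pathway_effects), c(4L, 2L)))
    stopf("pathway_effects must be a 4 x 2 matrix (pathway x condition)")
  dimnames(pathway_effects) <- list(pathways(), conditions())
  if (any(pathway_effects < 0)) stopf("induction folds must be >= 0")
  tox_ec50 <- tox_ec50[conditions()]
  if (any(is.na(tox_ec50)) || any(tox_ec50 <= 0))
    stopf("tox_ec50 must be positive for both conditions")
  if (hill_slope <= 0) stopf("hill_slope must be > 0")
  structure(list(
    compound_id = as.character(compound_id),
    pathway_effects = pathway_effects,
    tox_ec50 = tox_ec50,
    hill_slope = hill_slope,
    intended_class = intended_class
  ), class = "hepascreen_truth")
}

#' Default 24-compound truth set
#'
#' Builds the reference synthetic screen: `n_per_class` compounds per
#' S9-dependence class. Active compounds induce two of the four pathways
#' (pathway pairs cycled across compounds) at fold `fold_active`, above the
#' positive-chemical reference; their viability EC50s (cycled 250/300/400
#' uM, Hill slope 2) keep the top 100 uM dose in the high-viability band.
#' Non-responders are strongly cytotoxic (EC50 30 uM) but reporter-silent,
#' mirroring compounds whose toxicity runs through other pathways.
#'
#' @param n_per_class Compounds per class (default 6, i.e. 24 compounds).
#' @param fold_active GFP induction fold of active pathway/condition cells.
#' @return List of [compound_truth()] objects.
#' @export
#' @examples
#' length(default_truths(1))
default_truths <- function(n_per_class = 6, fold_active = 4.5) {
  pair_sets <- list(c(1, 4), c(2, 3), c(1, 2), c(3, 4), c(1, 3), c(2, 4))
  ec50_cycle <- c(250, 300, 400)
  classes <- c("consistent", "s9_minus_specific", "s9_plus_specific",
               "non_responsive")
  truths <- list()
  k <- 0
  for (cl in classes) {
    for (i in seq_len(n_per_class)) {
      k <- k + 1
      fx <- matrix(1, 4, 2, dimnames = list(pathways(), conditions()))
      active_paths <- pair_sets[[(i - 1) %% length(pair_sets) + 1]]
      if (cl == "consistent") fx[active_paths, ] <- fold_active
      if (cl == "s9_minus_specific") fx[active_paths, "S9minus"] <- fold_active
      if (cl == "s9_plus_specific") fx[active_paths, "S9plus"] <- fold_active
      ec50 <- if (cl == "non_responsive") c(S9minus = 30, S9plus = 30) else {
        e <- ec50_cycle[(i - 1) %% length(ec50_cycle) + 1]
        c(S9minus = e, S9plus = e)
      }
      truths[[k]] <- compound_truth(
        compound_id = sprintf("CPD%02d_%s", k, cl),
        pathway_effects = fx, tox_ec50 = ec50, intended_class = cl
      )
    }
  }
  truths
}

# Noise-free expected well metrics for one treated condition. GFP induction
# is attenuated by the viability fraction once viability drops below 50%,
# reflecting that reporter intensity is unreliable in dying cells.
expected_metrics <- function(truth, config, dose, pathway, condition) {
  viab <- hill_viability(dose, truth$tox_ec50[[condition]], truth$hill_slope)
  fold <- truth$pathway_effects[pathway, condition]
  atten <- ifelse(viab < 0.5, viab, 1)
  eff_fold <- fold * atten
  f0 <- config$gfp_pos_baseline_frac
  pos_frac <- f0 + (1 - f0) * (1 - exp(-pmax(eff_fold - 1, 0)))
  list(
    viability = viab,
    gfp_mean = config$baseline_gfp * eff_fold,
    gfp_pos_frac = pos_frac
  )
}

# Noise-free expected profile used to assert a truth's intended class.
expected_class <- function(truth, config) {
  sums <- setNames(numeric(2), conditions())
  for (cond in conditions()) {
    scores <- vapply(pathways(), function(pw) {
      per_dose <- vapply(config$doses, function(d) {
        m <- expected_metrics(truth, config, d, pw, cond)
        c(m$viability, m$gfp_mean)
      }, numeric(2))
      viab_pct <- 100 * per_dose[1, ]
      sel <- which(viab_pct >= 50)
      i <- if (length(sel)) sel[which.max(config$doses[sel])] else
        which.min(config$doses)
      rp <- per_dose[2, i] / (config$baseline_gfp * config$pos_induction_fold)
      rn <- per_dose[2, i] / config$baseline_gfp
      p <- if (rn > 1 + 1e-9) 0 else 1
      assign_score(viab_pct[i], rp, rn, p)
    }, numeric(1))
    sums[cond] <- sum(scores)
  }
  classify_s9_dependence(sums[["S9minus"]], sums[["S9plus"]])
}

# Map between truth-class labels and classifier output labels.
class_to_output <- c(consistent = "consistent",
                     s9_minus_specific = "s9_minus_more_active",
                     s9_plus_specific = "s9_plus_more_active",
                     non_responsive = "non_responsive")

#' Simulate a full reporter-cell screen
#'
#' Generates the well-level measurement table of a screen: for every
#' compound, pathway, condition, dose and replicate one treated well, plus
#' six negative and six positive control wells per plate (configurable).
#' Expected viability follows a Hill decline with the compound's EC50 and
#' slope; expected per-cell GFP equals baseline x induction fold,
#' attenuated by the viability fraction at cytotoxic doses (< 50%
#' viability); all well metrics then receive multiplicative log-normal
#' noise with CV `config$noise_cv`. Each plate draws from its own RNG
#' stream derived from the master seed, so output is reproducible and
#' plates can be regenerated independently.
#'
#' The declared `intended_class` of every truth is asserted against the
#' noise-free expectation of the scoring rules; inconsistent truths are an
#' error.
#'
#' @param config A [sim_config()].
#' @param truths List of [compound_truth()] objects, unique compound ids.
#' @return An object of class `hepascreen_sim`: a list with `wells` (the
#'   measurement table, one row per well), `truth_ledger` (per-well
#'   noise-free expectations), `config`, and `truths`.
#' @export
#' @examples
#' sim <- simulate_screen(sim_config(noise_cv = 0), default_truths(1))
#' head(sim$wells)
simulate_screen <- function(config, truths) {
  stopifnot(inherits(config, "hepascreen_config"))
  if (length(truths) == 0) stopf("no compound truths supplied")
  ids <- vapply(truths, `[[`, character(1), "compound_id")
  if (anyDuplicated(ids)) stopf("duplicate compound_id in truths")
  for (tr in truths) {
    expect_cl <- class_to_output[[tr$intended_class]]
    got <- expected_class(tr, config)
    if (!identical(got, expect_cl))
      stopf("truth '%s' declares class '%s' but constructs '%s'",
            tr$compound_id, tr$intended_class, got)
  }

  n_doses <- length(config$doses)
  wells_per_cpd <- n_doses * config$n_replicate_wells
  treated_capacity <- config$plate_size - 2L * config$n_control_wells_per_type
  cpds_per_plate <- max(1L, treated_capacity %/% wells_per_cpd)
  if (wells_per_cpd > treated_capacity)
    stopf("dose x replicate design does not fit on one plate")
  well_names <- sprintf("%s%02d", rep(LETTERS[1:8], each = 12), 1:12)

  rows <- list()
  ledger <- list()
  plate_counter <- 0L
  for (cond in conditions()) {
    for (pw in pathways()) {
      chunks <- split(truths, ceiling(seq_along(truths) / cpds_per_plate))
      for (ci in seq_along(chunks)) {
        plate_counter <- plate_counter + 1L
        chunk <- chunks[[ci]]
        plate_id <- sprintf("%s_%s_P%02d", pw, cond, ci)
        seed_i <- plate_seed(config$rng_seed, plate_counter)
        plate <- with_seed(seed_i,
          simulate_plate(plate_id, pw, cond, chunk, config, well_names))
        rows[[plate_counter]] <- plate$wells
        ledger[[plate_counter]] <- plate$ledger
      }
    }
  }
  wells <- do.call(rbind, rows)
  rownames(wells) <- NULL
  truth_ledger <- do.call(rbind, ledger)
  rownames(truth_ledger) <- NULL
  structure(list(wells = wells, truth_ledger = truth_ledger,
                 config = config, truths = truths),
            class = "hepascreen_sim")
}

# One plate: controls first, then compounds in chunk order, doses high to
# low, replicates within dose. Called inside the plate's RNG stream.
simulate_plate <- function(plate_id, pathway, condition, chunk, config,
                           well_names) {
  nctl <- config$n_control_wells_per_type
  design <- data.frame(
    role = c(rep("neg_ctrl", nctl), rep("pos_ctrl", nctl)),
    compound_id = c(rep("NEG_CTRL", nctl), rep("POS_CTRL", nctl)),
    dose_uM = NA_real_, fold = 1, viability = 1,
    stringsAsFactors = FALSE
  )
  design$fold[design$role == "pos_ctrl"] <- config$pos_induction_fold
  for (tr in chunk) {
    for (d in config$doses) {
      m <- expected_metrics(tr, config, d, pathway, condition)
      eff_fold <- m$gfp_mean / config$baseline_gfp
      design <- rbind(design, data.frame(
        role = rep("treated", config$n_replicate_wells),
        compound_id = rep(tr$compound_id, config$n_replicate_wells),
        dose_uM = rep(d, config$n_replicate_wells),
        fold = rep(eff_fold, config$n_replicate_wells),
        viability = rep(m$viability, config$n_replicate_wells),
        stringsAsFactors = FALSE
      ))
    }
  }
  n <- nrow(design)
  if (n > length(well_names)) stopf("plate %s overfull", plate_id)
  f0 <- config$gfp_pos_baseline_frac
  pos_frac <- f0 + (1 - f0) * (1 - exp(-pmax(design$fold - 1, 0)))
  exp_gfp <- config$baseline_gfp * design$fold

  cv <- config$noise_cv
  nuclei <- pmax(0, round(config$cells_per_well_mean * ln_noise(n, cv)))
  live_frac <- pmin(1, design$viability * ln_noise(n, cv))
  gfp_mean <- exp_gfp * ln_noise(n, cv)
  gfp_pos <- pmin(nuclei, round(nuclei * pos_frac * ln_noise(n, cv)))
  gfp_area <- gfp_pos * config$gfp_area_per_cell * ln_noise(n, cv)

  wells <- data.frame(
    plate_id = plate_id, well = well_names[seq_len(n)],
    compound_id = design$compound_id, dose_uM = design$dose_uM,
    pathway = pathway, condition = condition, role = design$role,
    nuclei_count = as.integer(nuclei), live_fraction = live_frac,
    gfp_pos_count = as.integer(gfp_pos), gfp_mean_intensity = gfp_mean,
    gfp_total_area = gfp_area, stringsAsFactors = FALSE
  )
  ledger <- data.frame(
    plate_id = plate_id, well = wells$well, compound_id = design$compound_id,
    dose_uM = design$dose_uM, pathway = pathway, condition = condition,
    role = design$role, expected_viability = design$viability,
    expected_fold = design$fold, expected_gfp_mean = exp_gfp,
    expected_gfp_pos_frac = pos_frac, stringsAsFactors = FALSE
  )
  list(wells = wells, ledger = ledger)
}

#' @export
print.hepascreen_sim <- function(x, ...) {
  cat(sprintf(
    "Simulated screen: %d compounds, %d wells on %d plates (%d x %d design)\n",
    length(x$truths), nrow(x$wells), length(unique(x$wells$plate_id)),
    length(pathways()), length(conditions())))
  cat(sprintf("  doses (uM): %s; %d replicate wells; noise CV %.2f\n",
              paste(signif(x$config$doses, 3), collapse = ", "),
              x$config$n_replicate_wells, x$config$noise_cv))
  invisible(x)
}
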