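#' Weibull mortality model for stationary-phase aging
#'
#' Ground truth for the simulator: viability of a chronologically aging
#' culture declines as a Weibull survivor function anchored at day 1 (the
#' 72-h growth time point, taken as fully viable):
#' \deqn{V(t) = \exp(-((t - 1)/\lambda)^k), \quad t \ge 1.}
#' Shape `k > 1` gives accelerating mortality, which reconciles the typical
#' control trajectory (about 50% at day 4 but under 20% at day 7 -- an
#' exponential through the day-4 point would predict 25%); scale `lam` is
#' in days and sets how quickly the decline unfolds.
#'
#' @param k Weibull shape (> 0; default 1.3).
#' @param lam Weibull scale in days (> 0).
#' @return An object of class `mortality_model`.
#' @export
mortality_model <- function(k = 1.3, lam = 4) {
  if (!is.finite(k) || k <= 0 || !is.finite(lam) || lam <= 0) {
    picls_abort("mortality model needs k > 0 and lam > 0",
                "picls_validation_error")
  }
  structure(list(k = k, lam = lam), class = "mortality_model")
}

#' True viability of a mortality model at an age day
#'
#' @param model A [mortality_model()].
#' @param day Age day(s), >= 1 (day 1 = 72 h growth; viability 1 by
#'   definition).
#' @return Viability fraction(s) in (0, 1].
#' @examples
#' viability(mortality_model(1.3, 4), c(1, 4, 7))
#' @export
viability <- function(model, day) {
  stopifnot(inherits(model, "mortality_model"))
  if (any(day < 1)) {
    picls_abort("viability is defined for age days >= 1",
                "picls_validation_error")
  }
  exp(-((day - 1) / model$lam)^model$k)
}

#' Plate-reader measurement model
#'
#' How true culture state maps to the two optical channels. PI fluorescence
#' is density-proportional: a well of true cuvette-scale density `true_od`
#' containing live fraction `V` emits `(f_bg * V + f_dead * (1 - V)) *
#' true_od`, where `f_bg` is the per-OD background of unstained/live cells
#' and `f_dead` the per-OD gain of PI-stained dead cells. The OD600 channel
#' saturates: readings track true density up to `od_knee` and are
#' compressed above it, `saturate(x) = od_knee + (x - od_knee)^sat_exponent`
#' for `x > od_knee`. Both channels carry independent multiplicative
#' Gaussian noise with coefficient of variation `cv`.
#'
#' @param f_bg Background fluorescence of unstained cells, a.u. per OD
#'   (default 50).
#' @param f_dead Fluorescence of fully PI-stained dead cells, a.u. per OD
#'   (default 1050).
#' @param od_knee Cuvette OD where the plate OD response saturates
#'   (default 12, the upper edge of the validated linear range).
#' @param sat_exponent Compression power above the knee (default 0.7).
#' @param cv Multiplicative noise CV per channel (default 0.05).
#' @return An object of class `measurement_model`.
#' @export
measurement_model <- function(f_bg = 50, f_dead = 1050, od_knee = 12,
                              sat_exponent = 0.7, cv = 0.05) {
  if (!(f_dead > f_bg) || f_bg <= 0) {
    picls_abort("measurement model needs f_dead > f_bg > 0",
                "picls_validation_error")
  }
  if (od_knee <= 0 || cv < 0) {
    picls_abort("measurement model needs od_knee > 0 and cv >= 0",
                "picls_validation_error")
  }
  structure(list(f_bg = f_bg, f_dead = f_dead, od_knee = od_knee,
                 sat_exponent = sat_exponent, cv = cv),
            class = "measurement_model")
}

#' Saturating OD response
#'
#' @param x True cuvette-scale OD600 (vectorized).
#' @param measurement A [measurement_model()].
#' @return Plate-scale OD600 after the saturation knee.
#' @export
saturate_od <- function(x, measurement = measurement_model()) {
  ifelse(x <= measurement$od_knee, x,
         measurement$od_knee + (x - measurement$od_knee)^measurement$sat_exponent)
}

#' Simulate optical readings for wells
#'
#' Draws PI-fluorescence and OD600 readings for `n` wells of a culture with
#' the given viability, through the measurement model. Roles:
#' `sample` uses the culture viability; `neg_control_unstained` is fully
#' live and unstained (background fluorescence only);
#' `pos_control_boiled` is fully dead and stained. Uses the current RNG
#' state; seed upstream for reproducibility.
#'
#' @param n Number of wells.
#' @param v Viability fraction of the culture in \[0, 1\].
#' @param measurement A [measurement_model()].
#' @param true_od True cuvette-scale OD600 of the well contents (default 2,
#'   a typical stationary-phase culture density at assay dilution).
#' @param role Well role (see above).
#' @return A tibble with columns `fluorescence`, `od600`.
#' @export
simulate_well <- function(n, v, measurement = measurement_model(),
                          true_od = 2, role = "sample") {
  stopifnot(inherits(measurement, "measurement_model"))
  v <- switch(role,
              neg_control_unstained = 1,
              pos_control_boiled = 0,
              v)
  if (v < 0 || v > 1) {
    picls_abort("viability must be in [0, 1]", "picls_validation_error")
  }
  per_od <- if (role == "neg_control_unstained") {
    measurement$f_bg  # unstained: background only, no PI gain
  } else {
    measurement$f_bg * v + measurement$f_dead * (1 - v)
  }
  eps_f <- stats::rnorm(n, 0, measurement$cv)
  eps_o <- stats::rnorm(n, 0, measurement$cv)
  tibble(
    fluorescence = pmax(0, per_od * true_od * (1 + eps_f)),
    od600 = pmax(0, saturate_od(true_od, measurement) * (1 + eps_o)))
}

#' Define a plate-screen design
#'
#' @param arms A data frame with one row per screen arm: columns `compound`,
#'   `concentration`, `conc_unit`, `k`, `lam` (Weibull mortality
#'   parameters). Must include an untreated arm with `compound ==
#'   "control"`.
#' @param age_days Age days sampled (default `c(1, 4, 7, 14, 21)`; day 1
#'   must be present).
#' @param n_replicates Sample wells per arm per day (default 6).
#' @param n_controls Unstained-negative and boiled-positive control wells
#'   per plate per day (default 8 each, one plate column per control role,
#'   the usual HTS layout; the control means are plate-level normalization
#'   anchors, so their standard error should stay small next to the
#'   replicate-well noise).
#' @param true_od True cuvette-scale OD of assay wells (default 2).
#' @param growth_hours Growth-curve time points in hours (default
#'   `c(24, 48, 72)`).
#' @return An object of class `screen_design`.
#' @export
screen_design <- function(arms, age_days = c(1, 4, 7, 14, 21),
                          n_replicates = 6, n_controls = 8, true_od = 2,
                          growth_hours = c(24, 48, 72)) {
  arms <- as_tibble(arms)
  required <- c("compound", "concentration", "k", "lam")
  if (length(setdiff(required, names(arms))) > 0) {
    picls_abort("arms need columns compound, concentration, k, lam",
                "picls_validation_error")
  }
  if (!"conc_unit" %in% names(arms)) arms$conc_unit <- NA_character_
  if (!any(arms$compound == "control")) {
    picls_abort("screen design must include an untreated 'control' arm",
                "picls_validation_error")
  }
  if (!1 %in% age_days) {
    picls_abort("age days must include the day-1 anchor",
                "picls_validation_error")
  }
  structure(list(arms = arms, age_days = sort(unique(age_days)),
                 n_replicates = n_replicates, n_controls = n_controls,
                 true_od = true_od, growth_hours = growth_hours),
            class = "screen_design")
}

#' The default simulated screen
#'
#' A five-arm screen whose mortality parameters emulate the canonical
#' survival trajectories of a chronological-lifespan experiment: an
#' untreated control declining to about 50% at day 4 and under 20% at day
#' 7; a rapamycin-like arm holding about 70% at day 7; a calorie-
#' restriction-like arm of intermediate longevity; a strongly long-lived
#' fructose-analog arm still near 65% at day 21; and an inert-sugar arm
#' indistinguishable from control. Shape k = 1.3 throughout; scales in
#' days.
#'
#' @param n_replicates Sample wells per arm per day (default 6).
#' @return A [screen_design()].
#' @export
default_screen <- function(n_replicates = 6) {
  arms <- tibble(
    compound = c("control", "rapamycin", "glucose_restriction",
                 "2,5-AM", "fructose"),
    concentration = c(0, 5, 0.5, 8, 8),
    conc_unit = c(NA, "nM", "% glucose", "mM", "mM"),
    k = 1.3,
    lam = c(4, 13, 9, 38, 4))
  screen_design(arms, n_replicates = n_replicates)
}

# 96-well coordinates in row-major order
well_ids_96 <- function() {
  paste0(rep(LETTERS[1:8], each = 12), rep(1:12, times = 8))
}

#' Simulate a full plate screen
#'
#' Generates the complete well-record table of a screen: for each age day,
#' one (or more) 96-well plates holding every arm's replicate sample wells
#' plus that plate's own unstained-negative and boiled-positive control
#' wells, read through the measurement model. The ground-truth viability of
#' every arm/day is returned alongside, so recovery can be checked exactly.
#' The same (design, measurement, seed) triple reproduces the records
#' bit-for-bit.
#'
#' @param design A [screen_design()].
#' @param measurement A [measurement_model()].
#' @param seed Integer seed.
#' @return A list of class `picls_simulation` with elements `records` (well
#'   records across all plates/days), `truth` (tibble `compound`,
#'   `concentration`, `age_day`, `viability`), `growth` (growth-curve OD
#'   table for [growth_check()]), `design`, `measurement`, `seed`.
#' @export
simulate_plate <- function(design, measurement = measurement_model(),
                           seed = NULL) {
  stopifnot(inherits(design, "screen_design"),
            inherits(measurement, "measurement_model"))
  if (!is.null(seed)) set.seed(seed)
  arms <- design$arms
  per_plate_samples <- 96 - 2 * design$n_controls
  records <- purrr::map_dfr(design$age_days, function(day) {
    sample_plan <- arms %>%
      tidyr::expand_grid(replicate = seq_len(design$n_replicates)) %>%
      mutate(role = "sample")
    n_s <- nrow(sample_plan)
    plate_no <- ceiling(seq_len(n_s) / per_plate_samples)
    purrr::map_dfr(unique(plate_no), function(p) {
      plan <- sample_plan[plate_no == p, ]
      v <- vapply(seq_len(nrow(plan)), function(i)
        viability(mortality_model(plan$k[i], plan$lam[i]), day), numeric(1))
      reads_s <- purrr::map_dfr(seq_len(nrow(plan)), function(i)
        simulate_well(1, v[i], measurement, true_od = design$true_od))
      reads_n <- simulate_well(design$n_controls, 1, measurement,
                               true_od = design$true_od,
                               role = "neg_control_unstained")
      reads_p <- simulate_well(design$n_controls, 0, measurement,
                               true_od = design$true_od,
                               role = "pos_control_boiled")
      n_all <- nrow(plan) + 2 * design$n_controls
      tibble(
        plate_id = sprintf("SIM-D%02d-P%d", day, p),
        well = well_ids_96()[seq_len(n_all)],
        role = c(plan$role,
                 rep("neg_control_unstained", design$n_controls),
                 rep("pos_control_boiled", design$n_controls)),
        compound = c(plan$compound, rep(NA_character_, 2 * design$n_controls)),
        concentration = c(plan$concentration,
                          rep(NA_real_, 2 * design$n_controls)),
        conc_unit = c(plan$conc_unit, rep(NA_character_, 2 * design$n_controls)),
        age_day = as.integer(day),
        replicate = c(plan$replicate, rep(seq_len(design$n_controls), 2)),
        fluorescence = c(reads_s$fluorescence, reads_n$fluorescence,
                         reads_p$fluorescence),
        od600 = c(reads_s$od600, reads_n$od600, reads_p$od600))
    })
  })
  truth <- arms %>%
    tidyr::expand_grid(age_day = design$age_days) %>%
    mutate(viability = viability_vec(.data$k, .data$lam, .data$age_day)) %>%
    select(all_of(c("compound", "concentration", "age_day", "viability")))
  growth_delay <- if ("growth_delay_h" %in% names(arms)) {
    arms$growth_delay_h
  } else {
    rep(24, nrow(arms))
  }
  growth <- arms %>%
    mutate(growth_delay_h = growth_delay) %>%
    tidyr::expand_grid(time_h = design$growth_hours) %>%
    tidyr::expand_grid(replicate = seq_len(min(3, design$n_replicates))) %>%
    mutate(od600 = pmax(0, design$true_od *
                          pmin(1, .data$time_h / .data$growth_delay_h) *
                          (1 + stats::rnorm(n(), 0, measurement$cv)))) %>%
    select(all_of(c("compound", "concentration", "time_h", "replicate",
                    "od600")))
  out <- list(records = validate_well_records(records), truth = truth,
              growth = growth, design = design, measurement = measurement,
              seed = seed)
  class(out) <- "picls_simulation"
  out
}

# vectorized closed-form viability over parallel parameter vectors
viability_vec <- function(k, lam, day) {
  exp(-((day - 1) / lam)^k)
}

#' @export
print.picls_simulation <- function(x, ...) {
  cat(sprintf(
    "<picls_simulation> %d well records, %d arms x %d days, seed %s\n",
    nrow(x$records), nrow(x$design$arms), length(x$design$age_days),
    x$seed %||% "none"))
  invisible(x)
}
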