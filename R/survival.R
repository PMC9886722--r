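#' PI survival statistic for a well
#'
#' The core viability statistic. Each well's PI fluorescence is normalized
#' by its OD600 (so culture-density differences cancel), the unstained-cell
#' background is subtracted, and the remainder is scaled by the dynamic
#' range set by the boiled-cell positive control:
#'
#' \deqn{Survival = \left(1 - \frac{I_{well}/OD_{well} - I_c/OD_c}
#'   {I_D/OD_D - I_c/OD_c}\right) \times 100\%}
#'
#' where subscript c denotes the unstained negative control (100% live) and
#' D the boiled positive control (0% survival). The raw value can fall
#' outside \[0, 100\] under measurement noise; a clamped copy is returned
#' alongside with a flag.
#'
#' @param fluorescence,od600 Numeric vectors of PI fluorescence (a.u.,
#'   535/617 nm) and OD600 readings for sample wells.
#' @param controls A `picls_controls` summary from [summarize_controls()],
#'   or any one-row data frame with columns `i_c`, `od_c`, `i_d`, `od_d`.
#' @param od_floor Minimum OD600 allowed for normalization (default 0.05,
#'   the lower edge of the validated calibration range). Wells below the
#'   floor raise a below-range error.
#' @return A tibble with columns `survival_raw`, `survival_pct` (clamped to
#'   \[0, 100\]) and `clamped`.
#' @examples
#' ctrl <- tibble::tibble(i_c = 50, od_c = 1, i_d = 1050, od_d = 1)
#' picls_survival(550, 1, ctrl)  # midway between the controls -> 50%
#' @export
picls_survival <- function(fluorescence, od600, controls, od_floor = 0.05) {
  stopifnot(length(fluorescence) == length(od600))
  ratio_c <- controls$i_c / controls$od_c
  ratio_d <- controls$i_d / controls$od_d
  if (!is.finite(ratio_c) || !is.finite(ratio_d) || ratio_d <= ratio_c) {
    picls_abort(
      "invalid controls: boiled positive must exceed unstained negative per OD",
      "picls_invalid_plate_error")
  }
  if (any(od600 < od_floor)) {
    picls_abort(
      paste0("well OD600 below the validated floor of ", od_floor,
             "; normalization unstable"),
      "picls_below_range_error")
  }
  raw <- (1 - (fluorescence / od600 - ratio_c) / (ratio_d - ratio_c)) * 100
  pct <- pmin(100, pmax(0, raw))
  tibble(survival_raw = raw, survival_pct = pct, clamped = raw != pct)
}

#' Outgrowth survival relative to the day-1 anchor
#'
#' The traditional comparator: aged culture is inoculated into rich medium,
#' regrown for 24 h, and the outgrowth OD600 is read. Survival at each age
#' point is the outgrowth OD relative to the day-1 outgrowth, which defines
#' 100% survival. Values above the anchor are clamped to 100% with a flag.
#'
#' @param od_day_t Outgrowth OD600 at the queried age day(s).
#' @param od_day1 Outgrowth OD600 of the day-1 reference (scalar).
#' @param blank Optional blank OD600 subtracted from both (default 0).
#' @return A tibble with `survival_raw`, `survival_pct`, `clamped`.
#' @export
outgrowth_survival <- function(od_day_t, od_day1, blank = 0) {
  od1 <- od_day1 - blank
  if (!is.finite(od1) || od1 <= 0) {
    picls_abort("day-1 outgrowth OD must be positive after blank correction",
                "picls_invalid_anchor_error")
  }
  raw <- 100 * (od_day_t - blank) / od1
  pct <- pmin(100, pmax(0, raw))
  tibble(survival_raw = raw, survival_pct = pct, clamped = raw != pct)
}

# Per-well survival for every sample well, normalizing against that
# plate/day's own controls. Below-floor wells are dropped (not zero-filled).
well_survival <- function(records, od_floor = 0.05, min_controls = 3,
                          center = "mean") {
  records <- validate_well_records(records)
  groups <- records %>%
    distinct(.data$plate_id, .data$age_day)
  purrr::pmap_dfr(groups, function(plate_id, age_day) {
    plate <- filter(records, .data$plate_id == !!plate_id,
                    .data$age_day == !!age_day)
    ctrl <- summarize_controls(plate, min_controls = min_controls,
                               center = center)
    wells <- filter(plate, .data$role == "sample",
                    .data$od600 >= od_floor)
    n_below <- sum(plate$role == "sample" & plate$od600 < od_floor)
    if (n_below > 0) {
      warn(paste0(plate_id, " day ", age_day, ": dropped ", n_below,
                  " sample well(s) below the OD floor"))
    }
    if (nrow(wells) == 0) return(tibble())
    s <- picls_survival(wells$fluorescence, wells$od600, ctrl,
                        od_floor = od_floor)
    dplyr::bind_cols(
      wells %>% select(all_of(c("plate_id", "well", "compound",
                                "concentration", "conc_unit", "age_day",
                                "replicate"))),
      s)
  })
}

#' Assemble per-condition survival curves
#'
#' Computes survival for every sample well, then aggregates to a survival
#' curve per condition (compound x concentration): mean and SD of survival
#' across replicate wells at each age day.
#'
#' For `method = "picls"` each well is scored with [picls_survival()]
#' against its own plate/day controls; the statistic is absolute, so the
#' day-1 anchor is reported but not required. For `method = "outgrowth"`
#' the `od600` column is interpreted as 24-h outgrowth OD and survival is
#' relative to the condition's day-1 mean, which must be present.
#'
#' @param records A well-record tibble (see [validate_well_records()]).
#' @param method `"picls"` (default) or `"outgrowth"`.
#' @param od_floor,min_controls,center Passed to the per-well scoring; see
#'   [picls_survival()] and [summarize_controls()].
#' @return A tibble of class `survival_curves`: one row per (compound,
#'   concentration, age_day) with `survival_pct` (mean), `sd_pct`,
#'   `n_wells`, `method`.
#' @export
build_survival_curve <- function(records, method = c("picls", "outgrowth"),
                                 od_floor = 0.05, min_controls = 3,
                                 center = "mean") {
  method <- match.arg(method)
  if (method == "picls") {
    per_well <- well_survival(records, od_floor = od_floor,
                              min_controls = min_controls, center = center)
    if (nrow(per_well) == 0) {
      picls_abort("no scorable sample wells", "picls_validation_error")
    }
  } else {
    records <- validate_well_records(records)
    samples <- filter(records, .data$role == "sample")
    blanks <- filter(records, .data$role == "blank")
    blank_od <- if (nrow(blanks) > 0) mean(blanks$od600) else 0
    anchors <- samples %>%
      filter(.data$age_day == 1) %>%
      group_by(.data$compound, .data$concentration) %>%
      summarise(od_day1 = mean(.data$od600), .groups = "drop")
    missing_anchor <- samples %>%
      distinct(.data$compound, .data$concentration) %>%
      anti_join(anchors, by = c("compound", "concentration"))
    if (nrow(missing_anchor) > 0) {
      picls_abort(
        "outgrowth curves need a day-1 anchor for every condition",
        "picls_invalid_anchor_error")
    }
    per_well <- samples %>%
      left_join(anchors, by = c("compound", "concentration")) %>%
      group_by(.data$compound, .data$concentration) %>%
      mutate(outgrowth_survival(.data$od600, .data$od_day1[1],
                                blank = blank_od)) %>%
      ungroup() %>%
      select(all_of(c("plate_id", "well", "compound", "concentration",
                      "conc_unit", "age_day", "replicate", "survival_raw",
                      "survival_pct", "clamped")))
  }
  curves <- per_well %>%
    group_by(.data$compound, .data$concentration, .data$age_day) %>%
    summarise(mean_pct = mean(.data$survival_pct),
              sd_pct = dplyr::coalesce(sd(.data$survival_pct), 0),
              n_wells = n(), .groups = "drop") %>%
    dplyr::rename(survival_pct = "mean_pct") %>%
    mutate(method = method) %>%
    arrange(.data$compound, .data$concentration, .data$age_day)
  class(curves) <- c("survival_curves", class(curves))
  attr(curves, "per_well") <- per_well
  curves
}

#' Per-well survival table
#'
#' The well-level companion of [build_survival_curve()]: one row per scored
#' sample well, used by the bootstrap hit caller.
#'
#' @inheritParams build_survival_curve
#' @return A tibble with one row per sample well: condition columns,
#'   `age_day`, `replicate`, `survival_raw`, `survival_pct`, `clamped`.
#' @export
survival_by_well <- function(records, od_floor = 0.05, min_controls = 3,
                             center = "mean") {
  well_survival(records, od_floor = od_floor, min_controls = min_controls,
                center = center)
}

#' Fit a Weibull mortality model to a survival curve
#'
#' Describes stationary-phase mortality with a Weibull survivor function
#' anchored at day 1 (the 72-h growth point, defined as fully viable):
#' \deqn{V(t) = \exp(-((t - 1)/\lambda)^k), \quad t \ge 1}
#' with shape `k` (> 1: accelerating mortality) and scale `lam` in days.
#' The fit minimizes the residual sum of squares between `V(t)` and
#' survival/100 over post-anchor days. Initial values come from the exact
#' log-log linearization of the interior points, refined by Nelder-Mead
#' with fixed settings, so the fit is deterministic given its input.
#'
#' @param curve A survival curve for a single condition: a data frame with
#'   columns `age_day` and `survival_pct`.
#' @return An object of class `mortality_fit` with `k`, `lam`, `rss`,
#'   `n_points` and the fitted data.
#' @export
fit_mortality_model <- function(curve) {
  curve <- as_tibble(curve)
  pts <- filter(curve, .data$age_day > 1)
  s <- pts$survival_pct / 100
  interior <- s > 0 & s < 1
  if (nrow(pts) < 3 || sum(interior) < 2) {
    picls_abort(
      "mortality fit needs >= 3 post-anchor days with survival strictly between 0 and 100%",
      "picls_unidentifiable_error")
  }
  t_i <- pts$age_day[interior]
  y <- log(-log(s[interior]))
  xi <- log(t_i - 1)
  k0 <- if (var(xi) > 0) sum((xi - mean(xi)) * (y - mean(y))) / sum((xi - mean(xi))^2)
        else 1
  if (!is.finite(k0) || k0 <= 0) k0 <- 1
  lam0 <- exp(mean(xi) - mean(y) / k0)
  if (!is.finite(lam0) || lam0 <= 0) lam0 <- mean(t_i)
  rss_fun <- function(par) {
    k <- exp(par[1]); lam <- exp(par[2])
    sum((exp(-((pts$age_day - 1) / lam)^k) - s)^2)
  }
  opt <- optim(log(c(k0, lam0)), rss_fun, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 2000))
  structure(
    list(k = exp(opt$par[1]), lam = exp(opt$par[2]), rss = opt$value,
         n_points = nrow(pts), data = pts),
    class = "mortality_fit")
}

#' @export
print.mortality_fit <- function(x, ...) {
  cat(sprintf("<mortality_fit> Weibull k = %.4g, lambda = %.4g days (RSS %.3g, %d days)\n",
              x$k, x$lam, x$rss, x$n_points))
  invisible(x)
}

#' @export
tidy.mortality_fit <- function(x, ...) {
  tibble(term = c("k", "lam"), estimate = c(x$k, x$lam))
}

#' @export
glance.mortality_fit <- function(x, ...) {
  tibble(k = x$k, lam = x$lam, rss = x$rss, n.points = x$n_points,
         median.day = 1 + x$lam * log(2)^(1 / x$k))
}

#' Predicted viability from a mortality fit
#'
#' @param object A `mortality_fit`.
#' @param age_day Days (>= 1) at which to predict.
#' @param ... Unused.
#' @return Predicted survival percentages.
#' @export
predict.mortality_fit <- function(object, age_day, ...) {
  100 * exp(-((age_day - 1) / object$lam)^object$k)
}

# summaries for one condition's (age_day, survival_pct) trace
curve_summary_one <- function(days, pct) {
  ord <- order(days)
  days <- days[ord]; pct <- pct[ord]
  if (length(days) < 2) {
    picls_abort("curve summaries need >= 2 age days",
                "picls_insufficient_data_error")
  }
  auc <- sum(diff(days) * (utils::head(pct, -1) + utils::tail(pct, -1)) / 2)
  t50 <- NA_real_
  censored <- TRUE
  if (pct[1] < 50) {
    t50 <- days[1]
    censored <- FALSE
  } else {
    for (i in seq_len(length(days) - 1)) {
      if (pct[i] >= 50 && pct[i + 1] < 50) {
        t50 <- days[i] + (pct[i] - 50) / (pct[i] - pct[i + 1]) *
          (days[i + 1] - days[i])
        censored <- FALSE
        break
      }
    }
  }
  if (censored) t50 <- days[length(days)]
  tibble(auc = auc, t50 = t50, t50_censored = censored)
}

#' Longevity effect sizes of survival curves
#'
#' Per condition: the trapezoidal area under the survival-vs-day curve
#' (%-days) and the median survival day `t50`, linearly interpolated at the
#' first 50% crossing. Curves that never drop below 50% are censored at the
#' last observed day (`t50_censored = TRUE`).
#'
#' @param curves A `survival_curves` tibble (or any data frame with columns
#'   `compound`, `concentration`, `age_day`, `survival_pct`).
#' @return A tibble with one row per condition: `auc`, `t50`,
#'   `t50_censored`.
#' @export
curve_summaries <- function(curves) {
  as_tibble(curves) %>%
    group_by(.data$compound, .data$concentration) %>%
    summarise(curve_summary_one(.data$age_day, .data$survival_pct),
              .groups = "drop")
}
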