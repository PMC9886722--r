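#' Growth-toxicity check for screened conditions
#'
#' Lifespan extension is confounded when a compound simply slows growth, so
#' each condition's culture growth (OD600 at the 24/48/72-h time points) is
#' compared with the untreated control before any longevity call. Per time
#' point the ratio of condition to control mean OD is computed; verdicts:
#' `normal` when all ratios are at or above `ratio_threshold`,
#' `slowed_growth` when the first time point lags but the last has
#' recovered (the pattern of high-dose rapamycin, which reaches saturation
#' only after 48 h), `inhibited` when the last time point is still below
#' threshold.
#'
#' @param growth A data frame with columns `compound`, `concentration`,
#'   `time_h`, `od600` (one row per replicate measurement).
#' @param control Compound label of the untreated control arm (default
#'   `"control"`).
#' @param ratio_threshold Minimum condition/control OD ratio (default 0.8).
#' @return A tibble with one row per condition: `compound`,
#'   `concentration`, one `ratio_<t>h` column per time point, `verdict`.
#' @export
growth_check <- function(growth, control = "control", ratio_threshold = 0.8) {
  growth <- as_tibble(growth)
  ctrl <- filter(growth, .data$compound == control)
  if (nrow(ctrl) == 0) {
    picls_abort("no growth measurements for the control arm",
                "picls_missing_data_error")
  }
  ctrl_mean <- ctrl %>%
    group_by(.data$time_h) %>%
    summarise(ctrl_od = mean(.data$od600), .groups = "drop")
  ratios <- growth %>%
    filter(.data$compound != control) %>%
    group_by(.data$compound, .data$concentration, .data$time_h) %>%
    summarise(od = mean(.data$od600), .groups = "drop") %>%
    dplyr::inner_join(ctrl_mean, by = "time_h") %>%
    mutate(ratio = .data$od / .data$ctrl_od)
  verdicts <- ratios %>%
    group_by(.data$compound, .data$concentration) %>%
    arrange(.data$time_h, .by_group = TRUE) %>%
    summarise(verdict = dplyr::case_when(
      dplyr::last(.data$ratio) < ratio_threshold ~ "inhibited",
      dplyr::first(.data$ratio) < ratio_threshold ~ "slowed_growth",
      TRUE ~ "normal"), .groups = "drop")
  ratios %>%
    select(all_of(c("compound", "concentration", "time_h", "ratio"))) %>%
    tidyr::pivot_wider(names_from = "time_h", values_from = "ratio",
                       names_glue = "ratio_{time_h}h") %>%
    left_join(verdicts, by = c("compound", "concentration"))
}

# day-wise bootstrap of mean(condition) - mean(control) over wells
boot_delta_days <- function(cond_by_day, ctrl_by_day, n_boot) {
  lapply(seq_along(cond_by_day), function(i) {
    x <- cond_by_day[[i]]; y <- ctrl_by_day[[i]]
    mx <- matrix(sample(x, length(x) * n_boot, replace = TRUE),
                 nrow = length(x))
    my <- matrix(sample(y, length(y) * n_boot, replace = TRUE),
                 nrow = length(y))
    colMeans(mx) - colMeans(my)
  })
}

# longest run length of TRUE values
longest_run <- function(flag) {
  if (!any(flag)) return(0L)
  r <- rle(flag)
  max(r$lengths[r$values])
}

#' Call lifespan-extension hits against the untreated control
#'
#' Decides, per screened condition, whether survival is genuinely extended
#' relative to the untreated control. For each shared age day the survival
#' difference `delta = mean(condition) - mean(control)` is computed across
#' wells, with a percentile bootstrap confidence interval obtained by
#' resampling wells within each arm and day (seeded for reproducibility).
#' A condition is a `hit` when, at `consecutive_days` or more consecutive
#' age days, the CI lower bound is positive and delta reaches
#' `delta_threshold`; `toxic` overrides the call when a supplied growth
#' check reports inhibition; otherwise `no_effect`. With `adjusted = TRUE`
#' the one-sided bootstrap p-value at the decision day (the qualifying day
#' with the largest delta) is Holm-corrected across conditions and a hit
#' must additionally stay below `1 - conf`.
#'
#' @param wells A per-well survival table from [survival_by_well()] (columns
#'   `compound`, `concentration`, `age_day`, `survival_pct`).
#' @param control Compound label of the control arm (default `"control"`).
#' @param delta_threshold Minimum survival gain in percentage points
#'   (default 15, a conservative codification of clear curve separation).
#' @param consecutive_days Number of consecutive qualifying age days
#'   required (default 2).
#' @param n_boot Bootstrap draws (default 1000).
#' @param conf Confidence level (default 0.95).
#' @param seed Optional integer seed recorded in the result.
#' @param adjusted Apply Holm family-wise correction across conditions
#'   (default `TRUE`).
#' @param growth Optional growth table for the toxicity gate (see
#'   [growth_check()]).
#' @param growth_threshold Ratio threshold passed to [growth_check()].
#' @return A tibble of class `hit_calls`, one row per condition:
#'   `decision` (`hit` / `no_effect` / `toxic`), `decision_day`, `delta`,
#'   `ci_low`, `ci_high`, `p_value`, `p_holm`, `effect_days` (list-column
#'   of age days with CI > 0 and delta above threshold), `adjusted`,
#'   `seed`.
#' @export
call_hits <- function(wells, control = "control", delta_threshold = 15,
                      consecutive_days = 2, n_boot = 1000, conf = 0.95,
                      seed = NULL, adjusted = TRUE, growth = NULL,
                      growth_threshold = 0.8) {
  wells <- as_tibble(wells)
  ctrl <- filter(wells, .data$compound == control)
  if (nrow(ctrl) == 0) {
    picls_abort("no wells for the control arm", "picls_missing_data_error")
  }
  conds <- wells %>%
    filter(.data$compound != control) %>%
    distinct(.data$compound, .data$concentration)
  if (nrow(conds) == 0) {
    picls_abort("no screened conditions besides the control",
                "picls_missing_data_error")
  }
  if (!is.null(seed)) set.seed(seed)
  tox <- NULL
  if (!is.null(growth)) {
    tox <- growth_check(growth, control = control,
                        ratio_threshold = growth_threshold)
  }
  alpha <- 1 - conf
  rows <- purrr::pmap_dfr(conds, function(compound, concentration) {
    cond_wells <- filter(wells, .data$compound == !!compound,
                         (.data$concentration == !!concentration) |
                           (is.na(!!concentration) & is.na(.data$concentration)))
    days <- sort(intersect(unique(cond_wells$age_day), unique(ctrl$age_day)))
    days <- setdiff(days, 1)  # day 1 is the anchor, both arms fully viable
    if (length(days) < 2) {
      picls_abort(
        paste0("condition ", compound, " shares fewer than 2 post-anchor age days with the control"),
        "picls_insufficient_data_error")
    }
    cond_by_day <- lapply(days, function(d)
      cond_wells$survival_pct[cond_wells$age_day == d])
    ctrl_by_day <- lapply(days, function(d)
      ctrl$survival_pct[ctrl$age_day == d])
    n_min <- min(vapply(c(cond_by_day, ctrl_by_day), length, integer(1)))
    if (n_min < 3) {
      picls_abort("hit calling needs >= 3 replicate wells per (condition, day)",
                  "picls_insufficient_replicates_error")
    }
    delta <- vapply(seq_along(days), function(i)
      mean(cond_by_day[[i]]) - mean(ctrl_by_day[[i]]), numeric(1))
    boots <- boot_delta_days(cond_by_day, ctrl_by_day, n_boot)
    ci <- vapply(boots, quantile, numeric(2),
                 probs = c(alpha / 2, 1 - alpha / 2))
    p_day <- vapply(boots, function(b) (1 + sum(b <= 0)) / (n_boot + 1),
                    numeric(1))
    qualifies <- ci[1, ] > 0 & delta >= delta_threshold
    eligible <- longest_run(qualifies) >= consecutive_days
    effect_days <- days[qualifies]
    decision_day <- if (any(qualifies)) {
      effect_days[which.max(delta[qualifies])]
    } else {
      days[which.max(delta)]
    }
    di <- match(decision_day, days)
    tibble(compound = compound, concentration = concentration,
           decision = if (eligible) "hit" else "no_effect",
           decision_day = decision_day,
           delta = delta[di], ci_low = ci[1, di], ci_high = ci[2, di],
           p_value = p_day[di],
           effect_days = list(effect_days))
  })
  rows$p_holm <- stats::p.adjust(rows$p_value, method = "holm")
  if (adjusted) {
    rows$decision[rows$decision == "hit" & rows$p_holm >= alpha] <- "no_effect"
  }
  if (!is.null(tox)) {
    rows <- rows %>%
      left_join(select(tox, all_of(c("compound", "concentration", "verdict"))),
                by = c("compound", "concentration")) %>%
      mutate(decision = dplyr::if_else(
        !is.na(.data$verdict) & .data$verdict == "inhibited",
        "toxic", .data$decision)) %>%
      select(-"verdict")
  }
  rows$adjusted <- adjusted
  rows$seed <- if (is.null(seed)) NA_integer_ else as.integer(seed)
  class(rows) <- c("hit_calls", class(rows))
  rows
}

#' Dose-response summary table
#'
#' Orders the survival curves of one or more compounds by concentration and
#' attaches per-concentration longevity summaries (AUC, t50) plus a
#' monotone-trend annotation: the Spearman rank correlation of curve AUC
#' with concentration (0 when all AUCs are identical). Hill/EC50 fitting is
#' deliberately out of scope for the short double-dilution series this
#' assay uses.
#'
#' @param curves A `survival_curves` tibble covering at least two
#'   concentrations per compound (including the zero/control
#'   concentration); a single concentration yields a degenerate table with
#'   a warning.
#' @return A tibble of class `dose_response_table`, one row per (compound,
#'   concentration) ordered by concentration, with `auc`, `t50`,
#'   `t50_censored`, `trend_rho` (per compound), and a nested `by_day`
#'   tibble of per-day survival.
#' @export
summarize_dose_response <- function(curves) {
  curves <- as_tibble(curves)
  summaries <- curve_summaries(curves)
  by_day <- curves %>%
    group_by(.data$compound, .data$concentration) %>%
    tidyr::nest(by_day = dplyr::any_of(c("age_day", "survival_pct", "sd_pct",
                                         "n_wells"))) %>%
    ungroup()
  out <- summaries %>%
    left_join(by_day, by = c("compound", "concentration")) %>%
    group_by(.data$compound) %>%
    arrange(.data$concentration, .by_group = TRUE) %>%
    mutate(trend_rho = {
      if (n() < 2) {
        warn(paste0("compound ", .data$compound[1],
                    ": single concentration, dose-response trend undefined"))
        NA_real_
      } else if (sd(.data$auc) == 0) {
        0
      } else {
        suppressWarnings(cor(.data$concentration, .data$auc,
                             method = "spearman"))
      }
    }) %>%
    ungroup()
  class(out) <- c("dose_response_table", class(out))
  out
}
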