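#' Z-factor screening-window statistic
#'
#' The standard plate-screening quality metric:
#' \deqn{Z = 1 - \frac{3(\sigma_p + \sigma_n)}{|\mu_p - \mu_n|}}
#' computed from the means and sample standard deviations of a positive
#' (intervention) and a negative (untreated) well population. `Z` is at
#' most 1; values in \[0.5, 1\] indicate an excellent high-throughput
#' assay.
#'
#' @param pos_values,neg_values Numeric vectors (>= 3 values each) of the
#'   screening signal for the two arms. For this assay the default signal
#'   is OD-normalized PI fluorescence (`I/OD`), the quantity the survival
#'   statistic is built on; per-well survival percentages work equally.
#' @param signal Label recorded in the result (default
#'   `"normalized_fluorescence"`).
#' @return A one-row tibble of class `zfactor_result`: `z`, `mu_p`,
#'   `sigma_p`, `mu_n`, `sigma_n`, `n_p`, `n_n`, `signal`.
#' @examples
#' z_factor(c(950, 1000, 1050), c(180, 200, 220))
#' @export
z_factor <- function(pos_values, neg_values,
                     signal = c("normalized_fluorescence", "survival_pct")) {
  signal <- match.arg(signal)
  if (length(pos_values) < 3 || length(neg_values) < 3) {
    picls_abort("Z-factor needs >= 3 replicate values per arm",
                "picls_insufficient_replicates_error")
  }
  mu_p <- mean(pos_values); mu_n <- mean(neg_values)
  if (mu_p == mu_n) {
    picls_abort("arm means are identical: Z-factor undefined",
                "picls_undefined_separation_error")
  }
  sigma_p <- sd(pos_values); sigma_n <- sd(neg_values)
  out <- tibble(z = 1 - 3 * (sigma_p + sigma_n) / abs(mu_p - mu_n),
                mu_p = mu_p, sigma_p = sigma_p,
                mu_n = mu_n, sigma_n = sigma_n,
                n_p = length(pos_values), n_n = length(neg_values),
                signal = signal)
  class(out) <- c("zfactor_result", class(out))
  out
}

#' Classify assay quality from a Z-factor
#'
#' `excellent` for Z in \[0.5, 1\] (the screening-grade band), `marginal`
#' for Z in \[0, 0.5), `unusable` below 0.
#'
#' @param z Numeric vector of Z-factors (each <= 1).
#' @return Character vector of verdicts.
#' @export
classify_assay_quality <- function(z) {
  if (any(!is.finite(z))) {
    picls_abort("Z-factor must be a finite number", "picls_validation_error")
  }
  dplyr::case_when(z >= 0.5 ~ "excellent",
                   z >= 0 ~ "marginal",
                   TRUE ~ "unusable")
}

#' Plate-level quality-control report
#'
#' Screens each plate/day read for assay-integrity problems: control
#' separation (boiled positive brighter per OD than unstained negative),
#' replicate coefficient of variation of OD-normalized fluorescence per
#' condition, and counts of wells below the OD floor or clamped outside
#' \[0, 100\]% survival. Verdicts: `fail` when controls are unusable,
#' `warn` when any condition CV exceeds `cv_warn` or wells were dropped or
#' clamped, else `pass`. A report is always produced, never an error.
#'
#' @param records A well-record tibble (possibly several plates/days).
#' @param min_controls,od_floor As in [summarize_controls()] and
#'   [picls_survival()].
#' @param cv_warn,cv_fail Replicate-CV thresholds (defaults 0.20 / 0.35).
#' @return A tibble with one row per (plate_id, age_day): `verdict`
#'   (`pass`/`warn`/`fail`), `max_cv`, `n_below_floor`, `n_clamped`, and a
#'   list-column `reasons` of human-readable flags.
#' @export
plate_qc <- function(records, min_controls = 3, od_floor = 0.05,
                     cv_warn = 0.20, cv_fail = 0.35) {
  records <- validate_well_records(records)
  groups <- distinct(records, .data$plate_id, .data$age_day)
  purrr::pmap_dfr(groups, function(plate_id, age_day) {
    plate <- filter(records, .data$plate_id == !!plate_id,
                    .data$age_day == !!age_day)
    reasons <- character()
    verdict <- "pass"
    ctrl <- tryCatch(summarize_controls(plate, min_controls = min_controls),
                     picls_error = function(e) {
                       reasons <<- c(reasons, conditionMessage(e))
                       NULL
                     })
    samples <- filter(plate, .data$role == "sample")
    n_below <- sum(samples$od600 < od_floor)
    if (n_below > 0) {
      reasons <- c(reasons, paste0(n_below, " sample well(s) below OD floor"))
    }
    cv_tbl <- samples %>%
      filter(.data$od600 >= od_floor) %>%
      mutate(norm_fl = .data$fluorescence / .data$od600) %>%
      group_by(.data$compound, .data$concentration) %>%
      summarise(cv = ifelse(mean(.data$norm_fl) > 0 & n() > 1,
                            sd(.data$norm_fl) / mean(.data$norm_fl), 0),
                .groups = "drop")
    max_cv <- if (nrow(cv_tbl) > 0) max(cv_tbl$cv) else 0
    high_cv <- filter(cv_tbl, .data$cv > cv_warn)
    if (nrow(high_cv) > 0) {
      reasons <- c(reasons, paste0(
        "replicate CV above ", round(100 * cv_warn), "% for: ",
        paste0(high_cv$compound, " (", round(100 * high_cv$cv), "%)",
               collapse = ", ")))
    }
    n_clamped <- 0L
    if (!is.null(ctrl) && nrow(samples) > 0) {
      ok <- samples$od600 >= od_floor
      if (any(ok)) {
        s <- picls_survival(samples$fluorescence[ok], samples$od600[ok],
                            ctrl, od_floor = od_floor)
        n_clamped <- sum(s$clamped)
        if (n_clamped > 0) {
          reasons <- c(reasons,
                       paste0(n_clamped, " well(s) clamped outside [0, 100]%"))
        }
      }
    }
    if (is.null(ctrl) || max_cv > cv_fail) {
      verdict <- "fail"
    } else if (length(reasons) > 0) {
      verdict <- "warn"
    }
    tibble(plate_id = plate_id, age_day = age_day, verdict = verdict,
           max_cv = max_cv, n_below_floor = n_below, n_clamped = n_clamped,
           reasons = list(reasons))
  })
}
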