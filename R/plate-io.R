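#' Well-record tables
#'
#' All readers and the simulator return a tibble of well records, the
#' package's canonical long format: one row per well per chronological age
#' day. Columns are `plate_id`, `well` (e.g. `"A1"`), `role` (one of
#' `sample`, `neg_control_unstained`, `pos_control_boiled`, `blank`),
#' `compound`, `concentration`, `conc_unit`, `age_day`, `replicate`,
#' `fluorescence` (PI channel, excitation 535 nm / emission 617 nm, arbitrary
#' units) and `od600`. Day 1 is the 72-h growth time point of the
#' stationary-phase culture.
#'
#' `validate_well_records()` checks the schema and the record invariants:
#' both channels finite and non-negative, roles from the allowed set, well
#' coordinates unique within `(plate_id, age_day)`, and blank wells carrying
#' no compound.
#'
#' @param records A data frame of well records.
#' @return The validated records as a tibble (invisibly unchanged).
#' @export
validate_well_records <- function(records) {
  required <- c("plate_id", "well", "role", "compound", "concentration",
                "age_day", "replicate", "fluorescence", "od600")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    picls_abort(
      paste0("well records are missing columns: ",
             paste(missing_cols, collapse = ", ")),
      "picls_validation_error")
  }
  records <- as_tibble(records)
  if (!"conc_unit" %in% names(records)) records$conc_unit <- NA_character_
  bad_role <- setdiff(unique(records$role), well_roles)
  if (length(bad_role) > 0) {
    picls_abort(paste0("unknown well role(s): ", paste(bad_role, collapse = ", ")),
                "picls_validation_error")
  }
  for (col in c("fluorescence", "od600")) {
    v <- records[[col]]
    if (!is.numeric(v) || any(!is.finite(v))) {
      picls_abort(paste0("column '", col, "' must be finite numeric"),
                  "picls_validation_error")
    }
    if (any(v < 0)) {
      picls_abort(paste0("column '", col, "' contains negative readings"),
                  "picls_validation_error")
    }
  }
  if (any(records$age_day < 1)) {
    picls_abort("age_day must be >= 1 (day 1 = 72 h growth time point)",
                "picls_validation_error")
  }
  dup <- records %>%
    dplyr::count(.data$plate_id, .data$well, .data$age_day) %>%
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    picls_abort(
      paste0("duplicate (plate_id, well, age_day) keys, e.g. ",
             dup$plate_id[1], "/", dup$well[1], "/day ", dup$age_day[1]),
      "picls_duplicate_key_error")
  }
  blank_bad <- records$role == "blank" & !is.na(records$compound)
  if (any(blank_bad)) {
    picls_abort("blank wells must not carry a compound", "picls_validation_error")
  }
  invisible(records)
}

#' Read a tidy long-table plate export
#'
#' Reads the canonical long CSV format (one row per well per age day) and
#' validates it: text columns are trimmed, numeric channels must be finite
#' and non-negative, and `(plate_id, well, age_day)` must be unique.
#'
#' @param path Path to a CSV file with columns `plate_id`, `well`, `role`,
#'   `compound`, `concentration`, `conc_unit` (optional), `age_day`,
#'   `replicate`, `fluorescence`, `od600`.
#' @return A tibble of well records (see [validate_well_records()]).
#' @export
read_long_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        na = c("", "NA"))
  required <- c("plate_id", "well", "role", "compound", "concentration",
                "age_day", "replicate", "fluorescence", "od600")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    picls_abort(
      paste0("long table is missing columns: ",
             paste(missing_cols, collapse = ", ")),
      "picls_parse_error")
  }
  df <- df %>%
    mutate(across(c("plate_id", "well", "role", "compound"),
                  ~ trimws(as.character(.x))),
           compound = dplyr::if_else(.data$compound == "", NA_character_,
                                     .data$compound),
           concentration = as.numeric(.data$concentration),
           age_day = as.integer(.data$age_day),
           replicate = as.integer(.data$replicate),
           fluorescence = as.numeric(.data$fluorescence),
           od600 = as.numeric(.data$od600))
  if ("conc_unit" %in% names(df)) {
    df$conc_unit <- trimws(as.character(df$conc_unit))
  }
  out <- validate_well_records(df)
  out
}

#' Write well records to the long-table CSV format
#'
#' The written file round-trips: [read_long_table()] on the output
#' reproduces the input records field for field.
#'
#' @param records A tibble of well records.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_long_table <- function(records, path) {
  if (is.null(records) || nrow(records) == 0) {
    picls_abort("refusing to write an empty well-record table",
                "picls_validation_error")
  }
  records <- validate_well_records(records)
  cols <- c("plate_id", "well", "role", "compound", "concentration",
            "conc_unit", "age_day", "replicate", "fluorescence", "od600")
  readr::write_csv(records[, cols], path, progress = FALSE)
  invisible(path)
}

#' Read a plate layout from YAML
#'
#' A layout maps wells of one plate to their roles and conditions and
#' carries the optical channel metadata. Expected YAML structure:
#' ```yaml
#' plate_id: P1
#' channel_meta: {excitation_nm: 535, emission_nm: 617, od_wavelength_nm: 600}
#' wells:
#'   A1: {role: sample, compound: rapamycin, concentration: 5,
#'        conc_unit: nM, replicate: 1}
#'   B1: {role: neg_control_unstained}
#' ```
#'
#' @param path Path to the YAML layout file.
#' @param min_controls Minimum number of wells required for each of the
#'   unstained-negative and boiled-positive control roles (default 3,
#'   matching triplicate control staining).
#' @return A list with `plate_id`, `channel_meta`, and `assignments`
#'   (a tibble with one row per assigned well).
#' @export
read_plate_layout <- function(path, min_controls = 3) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$plate_id) || is.null(raw$wells)) {
    picls_abort("layout must contain 'plate_id' and 'wells'",
                "picls_parse_error")
  }
  wells <- names(raw$wells)
  if (anyDuplicated(wells)) {
    picls_abort("layout assigns a well twice", "picls_validation_error")
  }
  assignments <- purrr::map2_dfr(raw$wells, wells, function(w, id) {
    tibble(well = id,
           role = w$role %||% "sample",
           compound = as.character(w$compound %||% NA_character_),
           concentration = as.numeric(w$concentration %||% NA_real_),
           conc_unit = as.character(w$conc_unit %||% NA_character_),
           replicate = as.integer(w$replicate %||% 1L))
  })
  bad_role <- setdiff(unique(assignments$role), well_roles)
  if (length(bad_role) > 0) {
    picls_abort(paste0("unknown role(s) in layout: ",
                       paste(bad_role, collapse = ", ")),
                "picls_validation_error")
  }
  bad_well <- !grepl("^[A-H](1[0-2]|[1-9])$", assignments$well)
  if (any(bad_well)) {
    picls_abort(paste0("invalid 96-well coordinate(s): ",
                       paste(assignments$well[bad_well], collapse = ", ")),
                "picls_validation_error")
  }
  n_neg <- sum(assignments$role == "neg_control_unstained")
  n_pos <- sum(assignments$role == "pos_control_boiled")
  if (n_neg < min_controls || n_pos < min_controls) {
    picls_abort(
      paste0("layout needs at least ", min_controls,
             " unstained-negative and boiled-positive control wells ",
             "(found ", n_neg, " / ", n_pos, ")"),
      "picls_assay_design_error")
  }
  list(plate_id = as.character(raw$plate_id),
       channel_meta = raw$channel_meta %||%
         list(excitation_nm = 535, emission_nm = 617, od_wavelength_nm = 600),
       assignments = assignments)
}

# Parse one 8x12 numeric block starting after a channel header line.
parse_grid_block <- function(lines, start, channel) {
  if (start + 7 > length(lines)) {
    picls_abort(paste0("grid block '", channel, "' is truncated"),
                "picls_parse_error")
  }
  block <- matrix(NA_real_, nrow = 8, ncol = 12,
                  dimnames = list(LETTERS[1:8], as.character(1:12)))
  for (i in 1:8) {
    line <- lines[start + i - 1]
    fields <- strsplit(line, ",", fixed = TRUE)[[1]]
    # strsplit drops trailing empty fields; restore them from the comma count
    n_fields <- nchar(gsub("[^,]", "", line)) + 1
    if (length(fields) < n_fields) {
      fields <- c(fields, rep("", n_fields - length(fields)))
    }
    # tolerate a leading row-letter label column
    if (length(fields) >= 1 && toupper(trimws(fields[1])) == LETTERS[i]) {
      fields <- fields[-1]
    }
    if (length(fields) != 12) {
      picls_abort(
        paste0("grid block '", channel, "' row ", LETTERS[i], " has ",
               length(fields), " fields (expected 12)"),
        "picls_parse_error")
    }
    fields <- trimws(fields)
    vals <- suppressWarnings(as.numeric(fields))
    bad <- !is.na(fields) & fields != "" & is.na(vals)
    if (any(bad)) {
      picls_abort(
        paste0("grid block '", channel, "' row ", LETTERS[i],
               " contains non-numeric value '", fields[bad][1], "'"),
        "picls_parse_error")
    }
    vals[fields == ""] <- NA_real_
    block[i, ] <- vals
  }
  block
}

#' Read a stacked-grid plate export
#'
#' Plate readers commonly export one 8 x 12 grid per channel. This reader
#' expects stacked CSV blocks, each preceded by a header line whose first
#' field is the channel name (`PI_535_617` for the propidium-iodide channel,
#' `OD600` for absorbance), followed by eight rows of twelve comma-separated
#' values (an optional leading row-letter column is tolerated). Wells not
#' assigned in the layout are skipped with a warning; wells assigned in the
#' layout but empty in the file raise a missing-data error.
#'
#' @param path Path to the grid CSV export.
#' @param layout A plate layout, as returned by [read_plate_layout()].
#' @param age_day Chronological age day of this read (integer, day 1 =
#'   72 h growth).
#' @return A tibble of well records.
#' @export
read_plate_grid <- function(path, layout, age_day) {
  age_day <- as.integer(age_day)
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[trimws(lines) != ""]
  first_field <- vapply(strsplit(lines, ",", fixed = TRUE),
                        function(f) trimws(f[1]), character(1))
  blocks <- list()
  for (ch in grid_channels) {
    idx <- which(first_field == ch)
    if (length(idx) == 0) {
      picls_abort(paste0("grid file has no '", ch, "' block"),
                  "picls_parse_error")
    }
    blocks[[ch]] <- parse_grid_block(lines, idx[1] + 1, ch)
  }
  asg <- layout$assignments
  row_idx <- match(substr(asg$well, 1, 1), LETTERS[1:8])
  col_idx <- as.integer(substring(asg$well, 2))
  fl <- blocks[["PI_535_617"]][cbind(row_idx, col_idx)]
  od <- blocks[["OD600"]][cbind(row_idx, col_idx)]
  absent <- is.na(fl) | is.na(od)
  if (any(absent)) {
    picls_abort(
      paste0("well(s) assigned in layout but missing in grid file: ",
             paste(asg$well[absent], collapse = ", ")),
      "picls_missing_data_error")
  }
  # warn about measured wells the layout does not cover
  present <- which(!is.na(blocks[["PI_535_617"]]) | !is.na(blocks[["OD600"]]),
                   arr.ind = TRUE)
  if (nrow(present) > 0) {
    measured <- paste0(LETTERS[present[, 1]], present[, 2])
    extra <- setdiff(measured, asg$well)
    if (length(extra) > 0) {
      warn(paste0("skipping ", length(extra),
                  " measured well(s) not assigned in layout: ",
                  paste(utils::head(extra, 5), collapse = ", ")))
    }
  }
  records <- tibble(plate_id = layout$plate_id,
                    well = asg$well,
                    role = asg$role,
                    compound = asg$compound,
                    concentration = asg$concentration,
                    conc_unit = asg$conc_unit,
                    age_day = age_day,
                    replicate = asg$replicate,
                    fluorescence = fl,
                    od600 = od)
  out <- validate_well_records(records)
  out
}

#' Summarize the control wells of one plate read
#'
#' Aggregates the unstained-negative and boiled-positive control wells of a
#' single plate at a single age day into the control summary the survival
#' statistic needs: mean fluorescence and mean OD600 per control role. The
#' unstained cells define the background (0% dead); the boiled cells define
#' the fully-dead signal (0% survival). The summary is only valid when the
#' boiled controls are brighter per unit OD than the unstained ones.
#'
#' @param records Well records from one plate and one age day.
#' @param min_controls Minimum wells per control role (default 3).
#' @param center `"mean"` (default, mirroring single-value normalization) or
#'   `"median"`.
#' @return A one-row tibble of class `picls_controls` with columns `i_c`,
#'   `od_c` (unstained negative), `i_d`, `od_d` (boiled positive), `n_neg`,
#'   `n_pos`.
#' @export
summarize_controls <- function(records, min_controls = 3,
                               center = c("mean", "median")) {
  center <- match.arg(center)
  records <- validate_well_records(records)
  if (dplyr::n_distinct(records$plate_id) > 1 ||
      dplyr::n_distinct(records$age_day) > 1) {
    picls_abort("control summaries are per plate per age day; pass one plate read",
                "picls_validation_error")
  }
  mid <- if (center == "mean") mean else median
  neg <- filter(records, .data$role == "neg_control_unstained")
  pos <- filter(records, .data$role == "pos_control_boiled")
  if (nrow(neg) < min_controls || nrow(pos) < min_controls) {
    picls_abort(
      paste0("need >= ", min_controls, " wells per control role (found ",
             nrow(neg), " unstained-negative, ", nrow(pos),
             " boiled-positive)"),
      "picls_assay_design_error")
  }
  out <- tibble(i_c = mid(neg$fluorescence), od_c = mid(neg$od600),
                i_d = mid(pos$fluorescence), od_d = mid(pos$od600),
                n_neg = nrow(neg), n_pos = nrow(pos))
  if (out$od_c <= 0 || out$od_d <= 0 ||
      out$i_d / out$od_d <= out$i_c / out$od_c) {
    picls_abort(
      "invalid plate: boiled positive controls are not brighter per OD than unstained negatives",
      "picls_invalid_plate_error")
  }
  class(out) <- c("picls_controls", class(out))
  out
}
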