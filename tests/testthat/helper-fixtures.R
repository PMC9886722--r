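# Fixtures are built in code: small plates with known channel values, plus
# grid/long-table files written to tempdir.

# a plate read with identical wells per role; controls at I/OD 50 and 1050
make_plate <- function(n_samples = 3, fl = 550, od = 1,
                       neg_fl = 50, pos_fl = 1050, ctrl_od = 1,
                       plate_id = "P1", age_day = 1L, compound = "drugA",
                       concentration = 5, n_controls = 3) {
  ids <- picls:::well_ids_96()
  n <- n_samples + 2 * n_controls
  tibble::tibble(
    plate_id = plate_id,
    well = ids[seq_len(n)],
    role = c(rep("sample", n_samples),
             rep("neg_control_unstained", n_controls),
             rep("pos_control_boiled", n_controls)),
    compound = c(rep(compound, n_samples), rep(NA_character_, 2 * n_controls)),
    concentration = c(rep(concentration, n_samples),
                      rep(NA_real_, 2 * n_controls)),
    conc_unit = NA_character_,
    age_day = age_day,
    replicate = c(seq_len(n_samples), seq_len(n_controls),
                  seq_len(n_controls)),
    fluorescence = c(rep_len(fl, n_samples), rep(neg_fl, n_controls),
                     rep(pos_fl, n_controls)),
    od600 = c(rep_len(od, n_samples), rep(ctrl_od, 2 * n_controls)))
}

# triplicate two-fold dilution series of boiled stained cells (cuvette OD
# 48 down to ~0.05) read through the measurement model
make_dilution_series <- function(measurement = measurement_model(cv = 0.03),
                                 n_rep = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ods <- 48 / 2^(0:10)
  purrr::map_dfr(ods, function(o) {
    r <- simulate_well(n_rep, 0, measurement, true_od = o,
                       role = "pos_control_boiled")
    tibble::tibble(cuvette_od = o, plate_od = r$od600,
                   fluorescence = r$fluorescence)
  })
}

# write a stacked-grid CSV for a full 96-well plate
write_grid_file <- function(path, fl_grid, od_grid) {
  fmt <- function(m) apply(m, 1, paste, collapse = ",")
  writeLines(c("PI_535_617", fmt(fl_grid), "OD600", fmt(od_grid)), path)
  path
}

# layout YAML covering all 96 wells: first 90 samples, 3 + 3 controls
write_full_layout <- function(path, plate_id = "P1", skip_wells = character()) {
  ids <- setdiff(picls:::well_ids_96(), skip_wells)
  roles <- c(rep("sample", length(ids) - 6),
             rep("neg_control_unstained", 3),
             rep("pos_control_boiled", 3))
  wells <- stats::setNames(lapply(seq_along(ids), function(i) {
    if (roles[i] == "sample") {
      list(role = "sample", compound = "drugA", concentration = 5,
           conc_unit = "nM", replicate = i)
    } else {
      list(role = roles[i], replicate = i)
    }
  }), ids)
  yaml::write_yaml(list(plate_id = plate_id,
                        channel_meta = list(excitation_nm = 535,
                                            emission_nm = 617,
                                            od_wavelength_nm = 600),
                        wells = wells), path)
  path
}
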