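test_that("long-table round trip preserves records field for field", {
  set.seed(11)
  sim <- simulate_plate(default_screen(n_replicates = 2), seed = 11)
  path <- withr::local_tempfile(fileext = ".csv")
  write_long_table(sim$records, path)
  back <- read_long_table(path)
  expect_equal(as.data.frame(back), as.data.frame(sim$records[names(back)]),
               tolerance = 1e-12)
})

test_that("long-table reader enforces schema, keys and finite channels", {
  path <- withr::local_tempfile(fileext = ".csv")
  plate <- make_plate()
  write_long_table(plate, path)
  expect_equal(nrow(read_long_table(path)), nrow(plate))

  dup <- dplyr::bind_rows(plate, plate[1, ])
  expect_error(validate_well_records(dup), class = "picls_duplicate_key_error")

  bad <- plate
  bad$fluorescence[1] <- NaN
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_long_table(path), class = "picls_validation_error")

  neg <- plate
  neg$od600[2] <- -0.2
  expect_error(validate_well_records(neg), class = "picls_validation_error")

  expect_error(write_long_table(plate[0, ], path),
               class = "picls_validation_error")
})

test_that("grid reader populates both channels for every assigned well", {
  fl <- matrix(seq(100, by = 10, length.out = 96), nrow = 8, byrow = TRUE)
  od <- matrix(rep(1.5, 96), nrow = 8)
  grid_path <- withr::local_tempfile(fileext = ".csv")
  layout_path <- withr::local_tempfile(fileext = ".yaml")
  write_grid_file(grid_path, fl, od)
  layout <- read_plate_layout(write_full_layout(layout_path))
  rec <- read_plate_grid(grid_path, layout, age_day = 1)
  expect_equal(nrow(rec), 96)
  expect_equal(rec$fluorescence[rec$well == "A1"], 100)
  expect_equal(rec$fluorescence[rec$well == "A12"], 210)
  expect_equal(rec$fluorescence[rec$well == "H12"], 100 + 95 * 10)
  expect_true(all(rec$od600 == 1.5))
})

test_that("grid reader handles omissions, extra wells, and malformed blocks", {
  fl <- matrix(seq(100, by = 10, length.out = 96), nrow = 8, byrow = TRUE)
  od <- matrix(rep(1.5, 96), nrow = 8)
  # H12 empty in file and omitted from layout: consistent, no error
  fl_gap <- fl; od_gap <- od
  fl_gap[8, 12] <- NA; od_gap[8, 12] <- NA
  grid_path <- withr::local_tempfile(fileext = ".csv")
  lines <- readLines(write_grid_file(withr::local_tempfile(), fl_gap, od_gap))
  writeLines(gsub("NA", "", lines), grid_path)
  layout_path <- withr::local_tempfile(fileext = ".yaml")
  layout <- read_plate_layout(
    write_full_layout(layout_path, skip_wells = "H12"))
  rec <- read_plate_grid(grid_path, layout, age_day = 1)
  expect_equal(nrow(rec), 95)
  expect_false("H12" %in% rec$well)

  # well assigned in layout but empty in file -> missing data
  layout_full <- read_plate_layout(write_full_layout(layout_path))
  expect_error(read_plate_grid(grid_path, layout_full, age_day = 1),
               class = "picls_missing_data_error")

  # 7-row block -> parse error naming the block
  trunc_path <- withr::local_tempfile(fileext = ".csv")
  full_lines <- readLines(write_grid_file(withr::local_tempfile(), fl, od))
  writeLines(full_lines[-2], trunc_path)  # drop first PI data row
  expect_error(read_plate_grid(trunc_path, layout, age_day = 1),
               regexp = "PI_535_617", class = "picls_parse_error")

  # measured wells not covered by layout are skipped with a warning
  expect_warning(
    read_plate_grid(write_grid_file(withr::local_tempfile(), fl, od),
                    layout, age_day = 1),
    regexp = "not assigned")
})

test_that("control summaries average per role and enforce separation", {
  plate <- make_plate(n_samples = 0)
  ctrl <- summarize_controls(plate)
  expect_equal(ctrl$i_c, 50)
  expect_equal(ctrl$od_c, 1)
  expect_equal(ctrl$i_d, 1050)
  expect_equal(ctrl$od_d, 1)
  expect_equal(c(ctrl$n_neg, ctrl$n_pos), c(3, 3))

  # unequal OD across positive wells -> arithmetic mean
  uneq <- plate
  uneq$od600[uneq$role == "pos_control_boiled"] <- c(1.0, 1.2, 0.8)
  expect_equal(summarize_controls(uneq)$od_d, 1.0)

  # inverted controls -> invalid plate
  inv <- plate
  inv$fluorescence[inv$role == "pos_control_boiled"] <- 10
  expect_error(summarize_controls(inv), class = "picls_invalid_plate_error")

  # missing a control role -> assay design error
  expect_error(
    summarize_controls(dplyr::filter(plate, role != "pos_control_boiled")),
    class = "picls_assay_design_error")

  # permutation invariance
  set.seed(3)
  shuffled <- plate[sample(nrow(plate)), ]
  expect_equal(summarize_controls(shuffled), ctrl)
})

test_that("layout reader validates coordinates, duplicates and control counts", {
  path <- withr::local_tempfile(fileext = ".yaml")
  lay <- list(plate_id = "P9",
              wells = list(A1 = list(role = "sample", compound = "x",
                                     concentration = 1),
                           B1 = list(role = "neg_control_unstained"),
                           B2 = list(role = "neg_control_unstained"),
                           B3 = list(role = "neg_control_unstained"),
                           C1 = list(role = "pos_control_boiled"),
                           C2 = list(role = "pos_control_boiled"),
                           C3 = list(role = "pos_control_boiled")))
  yaml::write_yaml(lay, path)
  out <- read_plate_layout(path)
  expect_equal(out$plate_id, "P9")
  expect_equal(nrow(out$assignments), 7)

  lay_bad <- lay
  names(lay_bad$wells)[1] <- "Z9"
  yaml::write_yaml(lay_bad, path)
  expect_error(read_plate_layout(path), class = "picls_validation_error")

  lay_few <- lay
  lay_few$wells$C3 <- NULL
  yaml::write_yaml(lay_few, path)
  expect_error(read_plate_layout(path), class = "picls_assay_design_error")
})
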