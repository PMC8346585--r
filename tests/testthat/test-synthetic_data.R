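test_that("scenario_config validates its stated world", {
  expect_s3_class(scenario_config(), "scenario_config")
  expect_error(scenario_config(cast_offset_m = 2))
  expect_error(scenario_config(true_n2_rates = c(30, 0.1, 0)))  # exceeds PON
  bad_shares <- data.frame(name = "a", share = 0.5, mean_rate_fmol_d = 1,
                           rate_cv = 0.3, width_um = 2, length_um = 3,
                           size_cv = 0.1, n_cells_imaged = 5L)
  expect_error(scenario_config(populations = bad_shares))
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- small_scenario(seed = 99L)
  expect_identical(make_casts(cfg)$downcast, make_casts(cfg)$downcast)
  expect_identical(make_incubations(cfg)$incubations,
                   make_incubations(cfg)$incubations)
  expect_identical(make_rois(cfg)$rois, make_rois(cfg)$rois)
  expect_identical(make_fish_counts(cfg)$fish, make_fish_counts(cfg)$fish)
  # different seeds give different draws
  expect_false(identical(make_rois(cfg)$rois,
                         make_rois(small_scenario(seed = 100L))$rois))
})

test_that("cast generator honours the offset and noise contracts", {
  cfg <- small_scenario(seed = 2L, cast_offset_m = 0)
  casts <- make_casts(cfg)
  expect_s3_class(casts$downcast, "depth_profile")
  expect_equal(casts$truth$true_corrected_depths, cfg$station_depths_m)
  # noiseless, zero-offset stations match their own row nearly exactly
  cfg0 <- small_scenario(seed = 2L, cast_offset_m = 0,
                         sensor_noise = c(conductivity = 0, temperature = 0,
                                          pressure = 0, turbidity = 0))
  casts0 <- make_casts(cfg0)
  # epsilon-scale clamping can fire when a noiseless station mean coincides
  # with a profile extreme; irrelevant to the contract under test
  al0 <- suppressWarnings(align_stations(casts0$stations, casts0$downcast))
  expect_true(all(al0$score < 1e-9))
  expect_equal(al0$corrected_depth_m, al0$nominal_depth_m)
})

test_that("incubation forward model inverts exactly when noiseless", {
  cfg <- small_scenario(seed = 4L, noise_cv = 0)
  inc <- make_incubations(cfg)
  bt <- bulk_rate_table(inc$incubations)
  truth <- inc$truth
  for (i in seq_len(nrow(truth))) {
    row <- bt[bt$depth_m == truth$depth_m[i] & bt$element == truth$element[i], ]
    rec <- if (row$below_detection) 0 else row$rate
    if (truth$true_rate[i] > 0) {
      expect_equal(rec, truth$true_rate[i], tolerance = 1e-9)
    } else {
      expect_equal(rec, 0)
    }
  }
  # zero rate -> endpoint equals natural abundance
  zero_rows <- inc$incubations[inc$incubations$depth_m == 15.5 &
                                 inc$incubations$element == "N", ]
  expect_equal(zero_rows$at_sample, rep(NAT_ABUNDANCE_15N, nrow(zero_rows)))
})

test_that("noisy incubations recover the truth within calibration bounds", {
  # CV 5%, 3 replicates: mean within +/-15% of truth in >=90% of repetitions
  reps <- 200
  hits <- 0
  for (s in seq_len(reps)) {
    cfg <- small_scenario(seed = 1000L + s)
    inc <- make_incubations(cfg)
    g <- inc$incubations[inc$incubations$depth_m == 13.7 &
                           inc$incubations$element == "N", ]
    rec <- mean(bulk_rate(g$at_sample, g$at_na, g$at_pool,
                          g$biomass_conc_umol_L, g$time_d))
    if (abs(rec - 0.27) / 0.27 <= 0.15) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.90)
})

test_that("ROI count scales calibrate the QC filter as intended", {
  cfg <- small_scenario(seed = 8L, include_inactive_cell = FALSE)
  pass_rate <- function(target) {
    rois <- make_rois(cfg, target_rel_error = target)
    ct <- cell_rate_table(rois$rois, rois$geometry,
                          at_excess_15N_medium = rois$truth$at_excess_15N_medium,
                          at_excess_13C_medium = rois$truth$at_excess_13C_medium,
                          time_d = cfg$time_d, cn_ratio = cfg$cn_ratio)
    mean(ct$passed_qc_N)
  }
  expect_gte(pass_rate(0.03), 0.95)   # well under the 5% threshold
  expect_lte(pass_rate(0.08), 0.05)   # well over it
  # consistency: more counts -> fraction converges to truth
  rois_hi <- make_rois(cfg, target_rel_error = 0.002)
  ct_hi <- cell_rate_table(rois_hi$rois, rois_hi$geometry,
                           at_excess_15N_medium = rois_hi$truth$at_excess_15N_medium,
                           at_excess_13C_medium = rois_hi$truth$at_excess_13C_medium,
                           time_d = cfg$time_d, cn_ratio = cfg$cn_ratio)
  m <- merge(ct_hi, rois_hi$truth$cells)
  expect_lt(median(abs(m$fraction_15N - m$true_fraction_15N) /
                     m$true_fraction_15N), 0.005)
})

test_that("FISH count generator round-trips through cells_per_liter", {
  cfg <- small_scenario(seed = 12L, fish_n_fields = 60L)
  fish <- make_fish_counts(cfg)
  for (p in unique(fish$fish$population)) {
    f <- fish$fish[fish$fish$population == p, ]
    ab <- cells_per_liter(f$count, f$field_area_um2[1], f$filter_area_um2[1],
                          f$volume_L[1])
    truth <- fish$truth$abundance_cells_L[fish$truth$name == p]
    expect_lt(abs(ab$abundance - truth), 4 * ab$se + 1e-9,
              label = paste("abundance recovery for", p))
  }
  # zero abundance -> all-zero fields
  cfg0 <- small_scenario(seed = 12L)
  cfg0$populations$share <- c(1e-12, 1e-12, 1 - 2e-12)
  fish0 <- make_fish_counts(cfg0)
  expect_true(all(fish0$fish$count[fish0$fish$population == "big"] == 0))
})

test_that("simulate_scenario writes byte-identical CSVs for a fixed config", {
  cfg <- small_scenario(seed = 77L)
  d1 <- tempfile(); d2 <- tempfile()
  simulate_scenario(cfg, d1)
  simulate_scenario(cfg, d2)
  files <- list.files(d1)
  expect_true(all(c("downcast.csv", "stations.csv", "incubations.csv",
                    "rois.csv", "geometry.csv", "fish_counts.csv",
                    "nutrient_profile.csv", "ground_truth.json") %in% files))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})
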