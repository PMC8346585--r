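test_that("plane accumulation sums per species and rejects empty ROIs", {
  planes <- data.frame(n15 = c(10, 12), n14 = c(1000, 1100))
  expect_equal(unname(accumulate_planes(planes)), c(22, 2100))
  one <- data.frame(n15 = 5, n14 = 500)
  expect_equal(unname(accumulate_planes(one)), c(5, 500))
  many <- data.frame(n15 = rep(2, 50), n14 = rep(200, 50))
  expect_equal(unname(accumulate_planes(many)), c(100, 10000))
  expect_error(accumulate_planes(planes[0, ]), "no recorded planes")
  expect_error(accumulate_planes(data.frame(n15 = -1, n14 = 10)), "non-negative")
})

test_that("isotope fraction equals the count-weighted mean over plane splits", {
  expect_equal(isotope_fraction(0, 1000), 0)
  expect_equal(isotope_fraction(1000, 0), 1)
  expect_equal(isotope_fraction(37, 10063), 0.0036633663, tolerance = 1e-7)
  expect_warning(f <- isotope_fraction(0, 0), "undefined")
  expect_true(is.na(f))

  # plane-partition invariance: arbitrary chunking never changes the
  # accumulated fraction
  set.seed(7)
  minor <- rpois(60, 40); major <- rpois(60, 8000)
  full <- isotope_fraction(sum(minor), sum(major))
  for (k in c(2, 5, 12)) {
    idx <- sort(sample(1:k, 60, replace = TRUE))
    chunk_minor <- tapply(minor, idx, sum); chunk_major <- tapply(major, idx, sum)
    expect_equal(isotope_fraction(sum(chunk_minor), sum(chunk_major)), full)
  }
})

test_that("Poisson ratio error and QC threshold follow counting statistics", {
  expect_equal(ratio_poisson_error(100, 10000), 0.10049876, tolerance = 1e-7)
  expect_false(passes_poisson_qc(100, 10000))
  expect_equal(ratio_poisson_error(1e6, 1e8), 0.0010049876, tolerance = 1e-6)
  expect_true(passes_poisson_qc(1e6, 1e8))
  # minor -> infinity asymptote: error -> sqrt(1/major)
  expect_equal(ratio_poisson_error(1e12, 400), sqrt(1 / 400), tolerance = 1e-4)
  expect_identical(ratio_poisson_error(0, 100), Inf)
  # strict inequality at the boundary
  n <- 800  # sqrt(2/800) = 0.05 exactly
  expect_equal(ratio_poisson_error(n, n), 0.05)
  expect_false(passes_poisson_qc(n, n))
})

test_that("biovolume and elemental contents follow the allometric forms", {
  expect_equal(biovolume(2, 2), pi / 6 * 8)          # sphere limit
  expect_equal(biovolume(2, 4), 8.3775804, tolerance = 1e-7)
  expect_equal(biovolume(4, 8), 8 * biovolume(2, 4)) # cubic scaling
  expect_error(biovolume(0, 1), "positive")
  expect_error(biovolume(3, 2), "exceed")

  expect_equal(carbon_content(0), 0)
  expect_equal(carbon_content(1), 36.0833333, tolerance = 1e-7)
  expect_equal(carbon_content(100), 1920.024, tolerance = 1e-6)
  # strictly increasing, concave power on the pg scale (exponent < 1)
  bv <- c(1, 2, 4, 8, 16)
  cc <- carbon_content(bv)
  expect_true(all(diff(cc) > 0))
  slopes <- diff(cc) / diff(bv)
  expect_true(all(diff(slopes) < 0))  # concave power law

  expect_equal(nitrogen_content(8.6, 8.6), 1)
  expect_equal(nitrogen_content(0, 8.6), 0)
  expect_equal(nitrogen_content(36.08, 8.6), 4.1953488, tolerance = 1e-7)
  expect_error(nitrogen_content(1, 0), "positive")
})

test_that("cell_rate scales excess enrichment to content turnover", {
  expect_equal(cell_rate(0, 29.6, 100, 1), 0)
  expect_equal(cell_rate(29.6, 29.6, 100, 1), 100)   # fully label-equilibrated
  expect_equal(cell_rate(1, 29.6, 100, 2), 1 / 29.6 * 100 / 2)
  expect_error(cell_rate(1, 0, 100, 1), "medium excess")
})

test_that("simulated cells are recovered without systematic bias", {
  # rate recovery against the Poisson forward model, scaled-down (200 cells)
  cfg <- small_scenario(seed = 21L, include_inactive_cell = FALSE)
  cfg$populations <- data.frame(
    name = "mix", share = 1, mean_rate_fmol_d = 1.0, rate_cv = 0.6,
    width_um = 3, length_um = 4, size_cv = 0.1, n_cells_imaged = 200L)
  rois <- make_rois(cfg, target_rel_error = 0.02)
  ct <- cell_rate_table(rois$rois, rois$geometry,
                        at_excess_15N_medium = rois$truth$at_excess_15N_medium,
                        at_excess_13C_medium = rois$truth$at_excess_13C_medium,
                        time_d = cfg$time_d, cn_ratio = cfg$cn_ratio)
  m <- merge(ct, rois$truth$cells)
  rel <- (m$rate_N_fmol_d - m$true_rate_N_fmol_d) / m$true_rate_N_fmol_d
  expect_lt(median(abs(rel)), 0.05)
  expect_lt(abs(mean(rel)), 0.02)
  expect_true(all(ct$passed_qc))
})

test_that("an inactive cell shows ~zero excess and rate but stays in the table", {
  cfg <- small_scenario(seed = 9L, include_inactive_cell = TRUE)
  rois <- make_rois(cfg)
  inactive_id <- rois$truth$cells$cell_id[rois$truth$cells$true_rate_N_fmol_d == 0]
  expect_length(inactive_id, 1)
  ct <- cell_rate_table(rois$rois, rois$geometry,
                        at_excess_15N_medium = rois$truth$at_excess_15N_medium,
                        at_excess_13C_medium = rois$truth$at_excess_13C_medium,
                        time_d = cfg$time_d, cn_ratio = cfg$cn_ratio)
  row <- ct[ct$cell_id == inactive_id, ]
  expect_false(row$enriched_15N)
  expect_lt(row$rate_N_fmol_d, 0.05)        # ~0 within counting noise
  expect_true(inactive_id %in% ct$cell_id)  # included for all calculations
})

test_that("convergence check reports the adequate sample size", {
  ident <- convergence_check(rep(0.004, 10))
  expect_equal(ident$adequate_n, 2)
  expect_true(ident$converged)

  set.seed(13)
  frac <- rlnorm(50, log(0.005), 0.3)       # CV ~30%
  cv <- convergence_check(frac, threshold = 0.05)
  expect_true(cv$converged)
  expect_lt(cv$adequate_n, 50)

  alt <- convergence_check(rep(c(0, 1), 5), threshold = 0.05)
  expect_false(alt$converged)
  expect_true(is.na(alt$adequate_n))

  expect_warning(short <- convergence_check(0.5), "fewer than 2")
  expect_false(short$converged)
})

test_that("FISH-effect comparison detects shifts and flags tiny groups", {
  set.seed(17)
  a <- rnorm(20, 0.005, 0.0005)
  same <- fish_effect_compare(a, a)
  expect_gt(same$p_value, 0.9)
  expect_equal(same$median_difference, 0)

  b <- rnorm(20, 0.005 + 5 * 0.0005, 0.0005)  # shift of 5 SD
  shifted <- fish_effect_compare(b, a)
  expect_lt(shifted$p_value, 0.01)
  expect_gt(shifted$median_difference, 0)

  expect_warning(flagged <- fish_effect_compare(a[1:2], a), "fewer than 3")
  expect_equal(flagged$flag, "insufficient_n")
})

test_that("roi_equivalent_ellipse recovers axis lengths of an ellipse", {
  # dense pixel grid of an axis-aligned ellipse with semi-axes 2 x 1 um
  g <- expand.grid(x = seq(-2.5, 2.5, by = 0.01), y = seq(-1.5, 1.5, by = 0.01))
  inside <- (g$x / 2)^2 + (g$y / 1)^2 <= 1
  ax <- roi_equivalent_ellipse(g$x[inside], g$y[inside])
  expect_equal(ax$length_um, 4, tolerance = 0.01)
  expect_equal(ax$width_um, 2, tolerance = 0.01)
})
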