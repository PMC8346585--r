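# small scenario for fast unit tests: fewer cells, coarser grid
small_scenario <- function(seed = 1L, ...) {
  defaults <- list(
    station_depths_m = seq(13.0, 15.0, by = 0.5),
    populations = data.frame(
      name = c("big", "mid", "small"),
      share = c(0.8, 0.15, 0.05),
      mean_rate_fmol_d = c(3.0, 0.9, 0.3),
      rate_cv = 0.30,
      width_um = c(4.5, 2.8, 2.0),
      length_um = c(7.0, 3.2, 2.3),
      size_cv = 0.10,
      n_cells_imaged = c(10L, 8L, 6L)),
    fish_n_fields = 20L)
  args <- utils::modifyList(defaults, list(...))
  do.call(scenario_config, c(list(seed = seed), args))
}

# two-pool mass-balance forward model for one incubation endpoint
# (independent of make_incubations: used as the oracle for bulk_rate)
forward_endpoint <- function(true_rate, pon, at_na, at_pool, time) {
  transferred <- true_rate * time
  (at_na * (pon - transferred) + at_pool * transferred) / pon
}
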