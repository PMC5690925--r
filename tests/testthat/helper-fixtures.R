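# Shared fixtures. Tests that exercise the full verification pipeline use a
# 0.5 cm fluence grid: at 63x63 pixels a whole plan verifies in well under a
# second while every threshold behaves identically to the default 1 mm grid.

fast_grid <- function() grid_spec(spacing = 0.5)

fast_config <- function(...) tolerance_config(grid = fast_grid(), ...)

# calibration day as treatment day: day rate == nominal, decay factor 1
CAL_DATE <- as.Date("2026-01-01")

small_plan <- function(seed = 1, ...) {
  generate_plan(seed, n_groups = 1L, beams_per_group = 2L,
                segments_per_beam = 2L, ...)
}

clean_delivery <- function(p, treatment_date = CAL_DATE, ...) {
  simulate_delivery(p, default_sources(CAL_DATE), treatment_date, ...)
}
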