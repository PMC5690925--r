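test_that("plan generation is deterministic per seed and valid", {
  p1 <- generate_plan(77)
  p2 <- generate_plan(77)
  expect_equal(p1, p2, tolerance = 0)
  expect_false(isTRUE(all.equal(generate_plan(78), p1)))
  # minimal shape
  pm <- generate_plan(1, 1, 1, 1)
  expect_length(plan_beams(pm), 1)
  expect_length(plan_beams(pm)[[1]]$segments, 1)
  # full shape: all group invariants hold by construction over seeds
  for (s in 1:15) {
    p <- generate_plan(s, n_groups = 2, beams_per_group = 3)
    expect_length(plan_beams(p), 6)
    for (g in p$beam_groups) {
      angles <- vapply(g$beams, `[[`, numeric(1), "gantry_angle")
      rel <- (angles - angles[1]) %% 360
      expect_true(all(vapply(rel, function(r)
        min(abs(r - c(0, 120, 240, 360))) < 1e-6, logical(1))))
    }
  }
})

test_that("segment times and apertures stay within the stated ranges", {
  for (s in 1:10) {
    p <- generate_plan(s)
    for (b in plan_beams(p)) for (sg in b$segments) {
      expect_gte(sg$beam_on_time, 1)
      expect_lte(sg$beam_on_time, 60)
      widths <- vapply(sg$leaf_pairs, function(lp) lp$right_x - lp$left_x,
                       numeric(1))
      expect_true(all(widths >= 0))
      expect_lte(max(widths), 10 + 0.011)
      expect_true(any(widths == 0))  # closed pairs always remain
      expect_lte(max(abs(vapply(sg$leaf_pairs, `[[`, numeric(1), "right_x"))),
                 15.75)
    }
  }
})

test_that("zero-noise simulation reproduces the plan exactly at calibration", {
  p <- small_plan(41)
  rec <- clean_delivery(p)  # day rate == nominal
  pb <- plan_beams(p)
  for (i in seq_along(pb)) {
    db <- rec$delivered_beams[[i]]
    expect_identical(db$gantry_angle, pb[[i]]$gantry_angle)
    for (k in seq_along(pb[[i]]$segments)) {
      expect_identical(db$segments[[k]]$beam_on_time,
                       pb[[i]]$segments[[k]]$beam_on_time)
      expect_equal(db$segments[[k]]$leaf_pairs,
                   pb[[i]]$segments[[k]]$leaf_pairs, tolerance = 0)
    }
  }
})

test_that("delivered times scale by the decay ratio", {
  p <- small_plan(42)
  late <- CAL_DATE + 700
  rec <- clean_delivery(p, treatment_date = late)
  day_rate <- rec$sources[[1]]$decayed_dose_rate
  pb <- plan_beams(p)
  for (i in seq_along(pb)) for (k in seq_along(pb[[i]]$segments)) {
    expect_equal(rec$delivered_beams[[i]]$segments[[k]]$beam_on_time,
                 expected_delivered_time(pb[[i]]$segments[[k]]$beam_on_time,
                                         p$nominal_dose_rate, day_rate),
                 tolerance = 1e-3)  # ms log resolution
  }
})

test_that("error injection touches exactly the intended field", {
  p <- small_plan(43)
  rec <- clean_delivery(p)
  flat <- function(r) unlist(r, recursive = TRUE, use.names = TRUE)
  a <- flat(rec)
  g <- flat(inject_error(rec, error_spec("gantry_offset", 0.6, beam_id = "B1")))
  changed <- names(a)[a != g]
  expect_true(all(grepl("gantry_angle", changed)))
  expect_identical(sum(a != g), 1L)
  l <- flat(inject_error(rec, error_spec("leaf_offset", 10, beam_id = "B2",
                                         segment_index = 2L, leaf_index = 8L)))
  expect_identical(sum(a != l), 1L)
  t <- flat(inject_error(rec, error_spec("segment_time_offset", 0.5,
                                         beam_id = "B1", segment_index = 1L)))
  expect_identical(sum(a != t), 1L)
  w <- flat(inject_error(rec, error_spec("wrong_patient")))
  expect_true(all(grepl("^patient\\.", names(a)[a != w])))
})

test_that("light machine noise never trips the checks", {
  # default 1 mm grid: on coarser grids a sub-resolution leaf wobble is
  # smeared over wide edge pixels and distorts the pass rate
  cfgn <- tolerance_config()
  noise <- list(gantry_deg = 0.05, mlc_mm = 0.2, time_s = 0.02)
  for (s in 1:8) {
    p <- small_plan(300 + s)
    rec <- simulate_delivery(p, default_sources(CAL_DATE), CAL_DATE + 60,
                             noise = noise, seed = 1000 + s)
    v <- verify_delivery(p, rec, cfgn)
    expect_identical(v$overall, "pass")
    expect_identical(unname(v$counts[["n_warn"]]), 0L)
  }
})
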