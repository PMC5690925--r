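cfg <- fast_config()

test_that("an error-free delivery passes every check", {
  p <- small_plan(21)
  v <- verify_delivery(p, clean_delivery(p), cfg)
  expect_identical(v$overall, "pass")
  expect_identical(unname(v$counts[["n_fail"]]), 0L)
  expect_identical(unname(v$counts[["n_warn"]]), 0L)
  expect_true(all(vapply(v$fluence, function(s) s$pass_rate, numeric(1)) == 100))
})

test_that("identity mismatches fail on the right item", {
  p <- small_plan(22)
  rec <- clean_delivery(p)
  wrong_pt <- inject_error(rec, error_spec("wrong_patient"))
  r <- check_identity(p, wrong_pt)
  expect_setequal(r$item[r$status == "fail"], c("Patient name", "Patient ID"))
  wrong_ver <- inject_error(rec, error_spec("wrong_plan_version"))
  r <- check_identity(p, wrong_ver)
  expect_identical(r$item[r$status == "fail"], "Plan name")
  expect_true(all(check_identity(p, rec)$status == "pass"))
})

test_that("prescription changes and fraction overruns are flagged", {
  p <- small_plan(23)
  rec <- clean_delivery(p)
  expect_true(all(check_prescription(p, rec, cfg)$status == "pass"))
  # the 2 Gy -> 1.8 Gy scenario
  rec18 <- rec
  rec18$prescription <- prescription(rec$prescription$prescription_name, 1.8,
                                     rec$prescription$n_fractions,
                                     rec$prescription$ptv_name)
  r <- check_prescription(p, rec18, cfg)
  expect_identical(r$status[r$item == "Prescription dose"], "fail")
  over <- clean_delivery(p)
  over$fraction_number <- p$prescription$n_fractions + 1L
  r <- check_prescription(p, over, cfg)
  expect_identical(r$status[r$item == "Fraction number"], "warn")
  expect_false(any(r$status == "fail"))
})

test_that("undecayed source data on a later date fails the source check", {
  p <- small_plan(24)
  late <- CAL_DATE + 293  # day rate ~0.90 x nominal
  rec <- clean_delivery(p, treatment_date = late)
  expect_true(all(check_source(rec$sources, cfg, late)$status == "pass"))
  stale <- inject_error(rec, error_spec("source_decay_wrong"))
  r <- check_source(stale$sources, cfg, late)
  expect_true(all(r$status[grepl("Decayed", r$item)] == "fail"))
  # serial mismatch
  s <- rec$sources
  s[[2]] <- source_info(2, "OTHER-999", s[[2]]$calibration_date,
                        s[[2]]$calibration_strength, s[[2]]$calibration_dose_rate,
                        s[[2]]$decayed_strength, s[[2]]$decayed_dose_rate,
                        s[[2]]$as_of_date)
  r <- check_source(s, cfg, late)
  expect_identical(r$status[r$item == "Source serial [head 2]"], "fail")
})

test_that("gantry deviations fail beyond and pass below tolerance", {
  p <- small_plan(25)
  rec <- clean_delivery(p)
  over <- inject_error(rec, error_spec("gantry_offset", 0.6, beam_id = "B1"))
  v <- verify_delivery(p, over, cfg)
  expect_identical(v$overall, "fail")
  expect_true(any_fail(v, "Gantry angle \\[beam B1\\]"))
  under <- inject_error(rec, error_spec("gantry_offset", 0.4, beam_id = "B1"))
  expect_identical(verify_delivery(p, under, cfg)$overall, "pass")
  # a deviation equal to the tolerance passes ("greater than" semantics)
  at <- inject_error(rec, error_spec("gantry_offset", 0.5, beam_id = "B1"))
  expect_identical(verify_delivery(p, at, cfg)$overall, "pass")
})

test_that("deviation status is symmetric in sign", {
  p <- small_plan(26)
  rec <- clean_delivery(p)
  for (mag in c(0.3, 0.6)) {
    up <- verify_delivery(p, inject_error(rec,
          error_spec("gantry_offset", mag, beam_id = "B2")), cfg)
    dn <- verify_delivery(p, inject_error(rec,
          error_spec("gantry_offset", -mag, beam_id = "B2")), cfg)
    expect_identical(up$overall, dn$overall)
  }
  for (mag in c(0.1, 0.4)) {
    up <- verify_delivery(p, inject_error(rec,
          error_spec("segment_time_offset", mag, beam_id = "B1",
                     segment_index = 1L)), cfg)
    dn <- verify_delivery(p, inject_error(rec,
          error_spec("segment_time_offset", -mag, beam_id = "B1",
                     segment_index = 1L)), cfg)
    expect_identical(any_fail(up, "Beam-on time \\[beam B1 seg 1\\]"),
                     any_fail(dn, "Beam-on time \\[beam B1 seg 1\\]"))
  }
})

test_that("single-leaf errors fail naming the leaf; small offsets pass", {
  p <- small_plan(27)
  rec <- clean_delivery(p)
  bad <- inject_error(rec, error_spec("leaf_offset", 10, beam_id = "B1",
                                      segment_index = 1L, leaf_index = 12L))
  v <- verify_delivery(p, bad, cfg)
  expect_identical(v$overall, "fail")
  r <- v$results
  hit <- r[r$status == "fail" & grepl("MLC leaf positions \\[beam B1 seg 1\\]", r$item), ]
  expect_identical(nrow(hit), 1L)
  expect_match(hit$item, "pair 12")
  # 1 mm on every leaf stays under the 2 mm tolerance
  shifted <- rec
  for (k in 1:2) {
    shifted <- inject_error(shifted, error_spec("leaf_offset", 1,
                  beam_id = "B1", segment_index = k, leaf_index = 5L))
  }
  expect_false(any(grepl("MLC", verify_delivery(p, shifted, cfg)$results$item) &
                   verify_delivery(p, shifted, cfg)$results$status == "fail"))
})

test_that("a closed pair at a shifted junction position fails", {
  p <- small_plan(28)
  rec <- clean_delivery(p)
  bad <- inject_error(rec, error_spec("junction_walk", 5, beam_id = "B1",
                                      segment_index = 1L))
  v <- verify_delivery(p, bad, cfg)
  expect_true(any_fail(v, "MLC leaf positions \\[beam B1 seg 1\\]"))
})

test_that("missing segments and missing beams fail the verification", {
  p <- small_plan(29)
  rec <- clean_delivery(p)
  noseg <- inject_error(rec, error_spec("skip_segment", beam_id = "B1",
                                        segment_index = 2L))
  v <- verify_delivery(p, noseg, cfg)
  expect_true(any_fail(v, "Number of segments \\[beam B1\\]"))
  nobeam <- inject_error(rec, error_spec("skip_beam", beam_id = "B2"))
  v <- verify_delivery(p, nobeam, cfg)
  expect_identical(v$overall, "fail")
  expect_true(any_fail(v, "Beam delivered \\[beam B2\\]"))
  expect_true(any_fail(v, "Number of beams"))
  # a beam the plan does not contain also fails
  extra <- rec
  eb <- rec$delivered_beams[[1]]
  extra$delivered_beams <- c(rec$delivered_beams,
    list(beam("B9", eb$head_id, normalize_angle(eb$gantry_angle + 35),
              eb$segments)))
  v <- verify_delivery(p, extra, cfg)
  expect_true(any_fail(v, "Unexpected beam \\[beam B9\\]"))
})

test_that("an interrupted then fully resumed delivery passes", {
  p <- small_plan(30)
  rec <- clean_delivery(p)
  resumed <- inject_error(rec, error_spec("interruption_split", 1,
                                          beam_id = "B2", segment_index = 2L))
  v <- verify_delivery(p, resumed, cfg)
  expect_identical(v$overall, "pass")
  # truncated (never resumed) delivery fails on time
  cut <- inject_error(rec, error_spec("interruption_split", 0.5,
                                      beam_id = "B2", segment_index = 2L))
  v <- verify_delivery(p, cut, cfg)
  expect_identical(v$overall, "fail")
  expect_true(any_fail(v, "Beam-on time \\[beam B2 seg 2\\]"))
})

test_that("beam matching falls back to head and gantry angle", {
  p <- small_plan(31)
  rec <- clean_delivery(p)
  renamed <- rec
  renamed$delivered_beams <- lapply(rec$delivered_beams, function(b)
    beam(paste0("X", b$beam_id), b$head_id, b$gantry_angle, b$segments))
  v <- verify_delivery(p, renamed, cfg)
  # matched by (head, gantry): parameter checks all pass
  expect_false(any_fail(v, "Gantry angle"))
  expect_false(any_fail(v, "Beam delivered"))
})

test_that("time checks normalize the delivered scale by source decay", {
  p <- small_plan(32)
  late <- CAL_DATE + 400
  rec <- clean_delivery(p, treatment_date = late)
  # delivered times differ from planned by the decay ratio, yet all pass
  expect_gt(rec$delivered_beams[[1]]$segments[[1]]$beam_on_time,
            plan_beams(p)[[1]]$segments[[1]]$beam_on_time)
  v <- verify_delivery(p, rec, cfg)
  expect_identical(v$overall, "pass")
})
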