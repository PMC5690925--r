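test_that("plan and log documents round-trip exactly", {
  for (s in 1:30) {
    p <- generate_plan(s, n_groups = 1 + s %% 2, beams_per_group = 1 + s %% 3,
                       segments_per_beam = 1 + s %% 3)
    rec <- simulate_delivery(p, default_sources(CAL_DATE),
                             CAL_DATE + (s * 13) %% 400)
    expect_equal(parse_plan_overview(write_plan_overview(p)), p,
                 tolerance = 0)
    expect_equal(parse_delivery_log(write_delivery_log(rec)), rec,
                 tolerance = 0)
  }
})

test_that("interruption records survive the round trip and sum correctly", {
  p <- small_plan(9)
  rec <- clean_delivery(p)
  rec <- inject_error(rec, error_spec("interruption_split", 1,
                                      beam_id = "B1", segment_index = 1L))
  txt <- write_delivery_log(rec)
  back <- parse_delivery_log(txt)
  expect_equal(back, rec, tolerance = 0)
  itr <- back$interruptions[[1]]
  expect_length(itr$partial_times, 2)
  expect_equal(sum(itr$partial_times),
               back$delivered_beams[[1]]$segments[[1]]$beam_on_time)
})

test_that("parse errors name the line, key and offending segment", {
  p <- small_plan(2)
  txt <- write_plan_overview(p)
  lines <- strsplit(txt, "\n")[[1]]
  # drop one LEAF line -> leaf-pair count error citing the segment
  leaf_idx <- grep("^LEAF 15", lines)[1]
  expect_error(parse_plan_overview(paste(lines[-leaf_idx], collapse = "\n")),
               "expected 30 LEAF lines.*found 29")
  # non-numeric value names the key
  bad <- sub("^GANTRY = .*", "GANTRY = north", lines)
  expect_error(parse_plan_overview(bad), "'GANTRY' is not numeric")
  # missing required key names section and key
  nokey <- lines[!grepl("^NOMINAL_DOSE_RATE", lines)]
  expect_error(parse_plan_overview(nokey),
               "\\[PLAN\\] missing required key 'NOMINAL_DOSE_RATE'")
  # malformed line reports its line number
  expect_error(parse_plan_overview(c(lines[1], "what is this", lines[-1])),
               "line 2: malformed line")
  # unknown format version is rejected
  expect_error(parse_plan_overview(sub("^FORMAT_VERSION = 1",
                                       "FORMAT_VERSION = 9", lines)),
               "unsupported FORMAT_VERSION")
})

test_that("a log without source sections is rejected", {
  rec <- clean_delivery(small_plan(3))
  lines <- strsplit(write_delivery_log(rec), "\n")[[1]]
  src_start <- grep("^\\[SOURCE\\]", lines)
  drop <- unlist(lapply(src_start, function(i) i:(i + 8)))
  expect_error(parse_delivery_log(paste(lines[-drop], collapse = "\n")),
               "source info absent")
})

test_that("the parser never silently defaults a required field", {
  p <- small_plan(4)
  lines <- strsplit(write_plan_overview(p), "\n")[[1]]
  for (key in c("NAME", "ID", "DOSE_GY", "FRACTIONS", "PTV", "DATE")) {
    mutated <- lines[-grep(sprintf("^%s = ", key), lines)[1]]
    expect_error(parse_plan_overview(mutated), "missing required key")
  }
})

test_that("screen captures load for embedding only", {
  expect_silent(expect_identical(load_screen_captures(character()), list()))
  tmp <- tempfile(fileext = ".png")
  png::writePNG(matrix(runif(64), 8, 8), tmp)
  caps <- load_screen_captures(tmp)
  expect_length(caps, 1)
  expect_equal(dim(caps[[1]]$image), c(8, 8))
  expect_warning(missing <- load_screen_captures(file.path(tempdir(), "nope.png")),
                 "screen capture missing")
  expect_length(missing, 0)
})
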