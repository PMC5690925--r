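cfg <- fast_config()

count_fail_rows <- function(html) {
  length(gregexpr("<tr class='fail'>", html, fixed = TRUE)[[1]]) -
    (gregexpr("<tr class='fail'>", html, fixed = TRUE)[[1]][1] == -1)
}

test_that("a clean run renders a report with zero highlighted rows", {
  p <- small_plan(61)
  rec <- clean_delivery(p)
  v <- verify_delivery(p, rec, cfg)
  html <- render_report(p, rec, v, config = cfg)
  expect_identical(count_fail_rows(html), 0L)
  expect_match(html, "Overall verdict: <b>PASS</b>")
  # every checked category appears
  for (needle in c("Patient name", "Patient ID", "Prescription dose",
                   "PTV target", "Number of fractions", "Source serial",
                   "Calibration date", "Decayed dose rate", "Plan name",
                   "Number of beams", "Gantry angle", "Number of segments",
                   "Total beam-on time", "MLC leaf positions", "Beam-on time",
                   "Fluence pass rate"))
    expect_match(html, needle, fixed = TRUE)
  expect_match(html, "Generated [0-9]{4}-")
})

test_that("highlighted rows equal the number of failures and name the beam", {
  p <- small_plan(62)
  rec <- clean_delivery(p)
  bad <- inject_error(rec, error_spec("gantry_offset", 0.8, beam_id = "B2"))
  v <- verify_delivery(p, bad, cfg)
  expect_identical(unname(v$counts[["n_fail"]]), 1L)
  html <- render_report(p, bad, v, config = cfg)
  expect_identical(count_fail_rows(html), 1L)
  expect_match(html, "<tr class='fail'><td>beam</td><td>Gantry angle \\[beam B2\\]")
})

test_that("reports embed captures and are self-contained", {
  p <- small_plan(63)
  rec <- clean_delivery(p)
  v <- verify_delivery(p, rec, cfg)
  cap_path <- tempfile(fileext = ".png")
  png::writePNG(matrix(runif(256), 16, 16), cap_path)
  caps <- load_screen_captures(cap_path)
  out <- tempfile(fileext = ".html")
  render_report(p, rec, v, captures = caps, config = cfg, out_html = out)
  html <- paste(readLines(out), collapse = "\n")
  # captures and fluence images are data URIs, not file references
  expect_match(html, "data:image/png;base64,")
  expect_false(grepl(cap_path, html, fixed = TRUE))
  expect_match(html, basename(cap_path), fixed = TRUE)
  # one planned + one delivered + one difference image per beam
  n_img <- length(gregexpr("<img class='fluence'", html, fixed = TRUE)[[1]])
  expect_identical(n_img, 3L * length(plan_beams(p)))
})

test_that("a zero-difference delivery renders an all-black difference map", {
  p <- generate_plan(64, 1, 1, 1)
  rec <- clean_delivery(p)
  v <- verify_delivery(p, rec, cfg)
  mp <- v$maps[[1]]
  uri <- diff_png_uri(mp$plan, mp$delivered)
  img <- png::readPNG(jsonlite::base64_dec(sub("^data:image/png;base64,", "", uri)))
  expect_identical(max(img), 0)
})

test_that("PDF export degrades gracefully without an engine", {
  p <- generate_plan(65, 1, 1, 1)
  rec <- clean_delivery(p)
  v <- verify_delivery(p, rec, cfg)
  out <- tempfile(fileext = ".html")
  render_report(p, rec, v, config = cfg, out_html = out)
  engines <- c("weasyprint", "wkhtmltopdf")
  if (any(nzchar(Sys.which(engines)))) {
    pdf <- export_pdf(out)
    expect_true(file.exists(pdf))
  } else {
    expect_warning(res <- export_pdf(out), "no HTML-to-PDF engine")
    expect_null(res)
  }
})
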