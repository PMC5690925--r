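# Daily treatment delivery report: one self-contained HTML document with
# plan/fraction info, IGRT setup captures, per-beam verification tables,
# fluence and difference images, source info and highlighted failures.
# Optionally converted to PDF when an HTML-to-PDF engine is available.

html_escape <- function(x) {
  x <- gsub("&", "&amp;", as.character(x), fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

matrix_png_uri <- function(m) {
  # rows are y ascending; flip so +y is up in the image
  img <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  raw_png <- png::writePNG(img)
  paste0("data:image/png;base64,", jsonlite::base64_enc(raw_png))
}

#' Render a fluence map as an embeddable grayscale image
#' @param fm a [fluence_map()]
#' @param scale white level in seconds; defaults to the map maximum
#' @return a PNG data URI string
#' @export
fluence_png_uri <- function(fm, scale = max(fm$values)) {
  v <- if (scale > 0) pmin(fm$values / scale, 1) else fm$values * 0
  matrix_png_uri(v)
}

#' Render a fluence difference as an embeddable grayscale image
#'
#' Symmetric in sign: brightness is |delivered - plan| relative to the
#' planned map maximum, so a perfect delivery renders all black.
#' @param plan_fm,delivered_fm [fluence_map()]s on the same grid
#' @return a PNG data URI string
#' @export
diff_png_uri <- function(plan_fm, delivered_fm) {
  scale <- max(plan_fm$values)
  d <- abs(delivered_fm$values - plan_fm$values)
  v <- if (scale > 0) pmin(d / scale, 1) else d * 0
  matrix_png_uri(v)
}

default_css_path <- function() {
  system.file("report", "style.css", package = "cobaltQA", mustWork = TRUE)
}

#' Render the daily treatment delivery report
#'
#' One self-contained HTML document: plan, patient and fraction
#' information, the IGRT setup screen captures (embedded, never analyzed),
#' every check result with failures highlighted, per-beam fluence and
#' difference images with their statistics, the cobalt-60 source block and
#' the overall verdict with a generation timestamp. Styling comes from an
#' external CSS file that is inlined so the document stays a single
#' archivable file.
#'
#' @param p the [plan()]
#' @param rec the [delivery_record()]
#' @param verification result of [verify_delivery()]
#' @param captures result of [load_screen_captures()] (paths are re-read
#'   and embedded)
#' @param config the [tolerance_config()] used
#' @param css_path stylesheet to inline; defaults to the packaged one
#' @param out_html optional path; when given the document is written there
#' @return the HTML document as a single string, invisibly when written
#' @export
render_report <- function(p, rec, verification, captures = list(),
                          config = tolerance_config(),
                          css_path = default_css_path(), out_html = NULL) {
  stopifnot(inherits(verification, "verification"))
  css <- paste(readLines(css_path, warn = FALSE), collapse = "\n")
  e <- html_escape
  rx <- p$prescription
  head_html <- c(
    "<!DOCTYPE html>", "<html><head><meta charset='utf-8'>",
    sprintf("<title>Daily delivery report: %s</title>", e(p$plan_name)),
    "<style>", css, "</style></head><body>",
    sprintf("<h1>Daily treatment delivery report</h1>"),
    sprintf("<p class='verdict %s'>Overall verdict: <b>%s</b> (%d pass / %d fail / %d warn)</p>",
            verification$overall, toupper(verification$overall),
            verification$counts[["n_pass"]], verification$counts[["n_fail"]],
            verification$counts[["n_warn"]]),
    "<h2>Plan and fraction</h2>", "<table class='info'>",
    sprintf("<tr><th>Patient</th><td>%s [%s]</td></tr>",
            e(p$patient$name), e(p$patient$patient_id)),
    sprintf("<tr><th>Plan</th><td>%s (approved %s)</td></tr>",
            e(p$plan_name), p$plan_date),
    sprintf("<tr><th>Prescription</th><td>%s: %.2f Gy &times; %d to %s</td></tr>",
            e(rx$prescription_name), rx$dose_per_fraction, rx$n_fractions,
            e(rx$ptv_name)),
    sprintf("<tr><th>Fraction</th><td>%d of %d, delivered %s</td></tr>",
            rec$fraction_number, rx$n_fractions, verification$treatment_date),
    sprintf("<tr><th>Nominal dose rate</th><td>%.2f Gy/min</td></tr>",
            p$nominal_dose_rate),
    "</table>")

  cap_html <- "<h2>IGRT setup screen captures</h2>"
  if (length(captures)) {
    for (cp in captures) {
      raw_png <- readBin(cp$path, "raw", n = file.size(cp$path))
      cap_html <- c(cap_html,
        sprintf("<div class='capture'><img src='data:image/png;base64,%s' alt='%s'/><br/><small>%s</small></div>",
                jsonlite::base64_enc(raw_png), e(basename(cp$path)),
                e(basename(cp$path))))
    }
  } else {
    cap_html <- c(cap_html, "<p class='note'>No screen captures provided.</p>")
  }

  res <- verification$results
  res_html <- c("<h2>Verification results</h2>",
                "<table class='results'>",
                "<tr><th>Category</th><th>Item</th><th>Planned</th><th>Delivered</th><th>Tolerance</th><th>Status</th></tr>")
  for (i in seq_len(nrow(res))) {
    cls <- if (res$status[i] == "fail") " class='fail'"
           else if (res$status[i] == "warn") " class='warn'" else ""
    res_html <- c(res_html,
      sprintf("<tr%s><td>%s</td><td>%s</td><td>%s</td><td>%s</td><td>%s</td><td>%s</td></tr>",
              cls, e(res$category[i]), e(res$item[i]), e(res$planned[i]),
              e(res$delivered[i]), e(res$tolerance[i]), e(res$status[i])))
  }
  res_html <- c(res_html, "</table>")

  fl_html <- "<h2>Per-beam fluence maps</h2>"
  for (id in names(verification$maps)) {
    mp <- verification$maps[[id]]
    s <- verification$fluence[[id]]
    fl_html <- c(fl_html,
      sprintf("<div class='beam-fluence'><h3>Beam %s</h3>", e(id)),
      sprintf("<img class='fluence' src='%s' alt='planned fluence'/>",
              fluence_png_uri(mp$plan)),
      sprintf("<img class='fluence' src='%s' alt='delivered fluence'/>",
              fluence_png_uri(mp$delivered, scale = max(mp$plan$values))),
      sprintf("<img class='fluence' src='%s' alt='difference'/>",
              diff_png_uri(mp$plan, mp$delivered)),
      sprintf("<p>pass rate %s%%, mean %.4f s, max %.4f s, SD %.4f s (n = %d px)</p></div>",
              ifelse(is.na(s$pass_rate), "n/a", sprintf("%.1f", s$pass_rate)),
              s$mean_diff, s$max_diff, s$sd_diff, s$n_evaluated))
  }

  src_html <- c("<h2>Cobalt-60 sources</h2>", "<table class='info'>",
                "<tr><th>Head</th><th>Serial</th><th>Calibrated</th><th>Cal. strength (Ci)</th><th>Cal. rate (Gy/min)</th><th>Day strength (Ci)</th><th>Day rate (Gy/min)</th></tr>")
  for (s in rec$sources)
    src_html <- c(src_html,
      sprintf("<tr><td>%d</td><td>%s</td><td>%s</td><td>%.2f</td><td>%.4f</td><td>%.2f</td><td>%.4f</td></tr>",
              s$head_id, e(s$serial), s$calibration_date,
              s$calibration_strength, s$calibration_dose_rate,
              s$decayed_strength, s$decayed_dose_rate))
  src_html <- c(src_html, "</table>")

  tail_html <- c(sprintf("<p class='footer'>Generated %s</p>",
                         format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
                 "</body></html>")
  doc <- paste(c(head_html, cap_html, res_html, fl_html, src_html, tail_html),
               collapse = "\n")
  if (!is.null(out_html)) {
    writeLines(doc, out_html)
    return(invisible(doc))
  }
  doc
}

#' Convert a rendered HTML report to PDF
#'
#' Uses the first HTML-to-PDF engine found on the PATH (`weasyprint` or
#' `wkhtmltopdf`). PDF conversion is optional: when no engine is present a
#' warning is recorded and NULL is returned; the HTML report is the
#' authoritative output either way.
#'
#' @param html_path path to the HTML report
#' @param pdf_path output PDF path
#' @return `pdf_path` invisibly, or NULL when no engine is available
#' @export
export_pdf <- function(html_path, pdf_path = sub("\\.html?$", ".pdf",
                                                 html_path)) {
  engines <- c("weasyprint", "wkhtmltopdf")
  found <- engines[nzchar(Sys.which(engines))]
  if (!length(found)) {
    warning("no HTML-to-PDF engine (weasyprint/wkhtmltopdf) on PATH; ",
            "PDF not produced", call. = FALSE)
    return(invisible(NULL))
  }
  status <- system2(found[[1]], shQuote(c(html_path, pdf_path)),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0 || !file.exists(pdf_path)) {
    warning(sprintf("%s failed (exit %d); PDF not produced", found[[1]], status),
            call. = FALSE)
    return(invisible(NULL))
  }
  invisible(pdf_path)
}
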