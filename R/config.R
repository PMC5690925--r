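# Tolerances, reference source data and global constants, backed by an XML
# configuration file so every threshold the checker applies is auditable.

#' Default reference sources for the three treatment heads
#'
#' Three cobalt-60 sources calibrated on the same day at the machine's
#' nominal 1.85 Gy/min per head; decayed values are as of the calibration
#' date (factor 1). Calibration strength defaults to 15,000 Ci per head, a
#' typical teletherapy loading.
#'
#' @param calibration_date calibration date for all three heads
#' @param calibration_strength activity per head at calibration, Ci
#' @param calibration_dose_rate dose rate per head at calibration, Gy/min
#' @return list of 3 [source_info()]
#' @export
default_sources <- function(calibration_date = as.Date("2026-01-01"),
                            calibration_strength = 15000,
                            calibration_dose_rate = 1.85) {
  lapply(1:3, function(h)
    source_info(h, sprintf("CO60-%04d", 1000L + h), calibration_date,
                calibration_strength, calibration_dose_rate,
                calibration_strength, calibration_dose_rate,
                calibration_date))
}

#' Verification tolerances and machine constants
#'
#' Defaults follow the machine commissioning choices: 0.5 degrees for
#' gantry, 2 mm for MLC leaf position, 0.2 s for beam-on time; fluence
#' pixels above 10% of the planned map maximum are evaluated, pass when the
#' difference is under 2% of that maximum, and a beam is acceptable at a
#' pass rate of 90% or higher.
#'
#' @param gantry_deg gantry tolerance, degrees
#' @param mlc_mm MLC leaf position tolerance, mm
#' @param time_s beam-on time tolerance, seconds (applied per segment and
#'   to the per-beam total)
#' @param fluence_low_cut evaluation cutoff as a fraction of the planned
#'   map maximum
#' @param fluence_pass_frac per-pixel pass threshold as a fraction of the
#'   planned map maximum
#' @param fluence_accept_rate minimum acceptable pass rate, percent
#' @param source_rel_tol relative tolerance for the recomputed decayed
#'   source strength and dose rate
#' @param reference_sources list of 3 [source_info()] the log's source
#'   block is checked against
#' @param nominal_dose_rate planning nominal dose rate, Gy/min
#' @param half_life_years Co-60 half-life used for decay arithmetic
#' @param grid [grid_spec()] used for fluence rasterization
#' @return a `tolerance_config` object
#' @export
tolerance_config <- function(gantry_deg = 0.5, mlc_mm = 2, time_s = 0.2,
                             fluence_low_cut = 0.10, fluence_pass_frac = 0.02,
                             fluence_accept_rate = 90, source_rel_tol = 1e-3,
                             reference_sources = default_sources(),
                             nominal_dose_rate = 1.85,
                             half_life_years = CO60_HALF_LIFE_YEARS,
                             grid = grid_spec()) {
  tol <- c(gantry_deg = gantry_deg, mlc_mm = mlc_mm, time_s = time_s,
           source_rel_tol = source_rel_tol)
  if (any(!is.finite(tol)) || any(tol <= 0))
    stop_invalid("all tolerances must be > 0")
  if (fluence_low_cut <= 0 || fluence_low_cut >= 1)
    stop_invalid("fluence_low_cut must be in (0, 1)")
  if (fluence_pass_frac <= 0 || fluence_pass_frac >= 1)
    stop_invalid("fluence_pass_frac must be in (0, 1)")
  if (fluence_accept_rate <= 0 || fluence_accept_rate > 100)
    stop_invalid("fluence_accept_rate must be in (0, 100]")
  if (length(reference_sources) != 3L ||
      !all(vapply(reference_sources, inherits, logical(1), "source_info")))
    stop_invalid("reference_sources must be 3 source_info objects")
  stopifnot(inherits(grid, "grid_spec"))
  structure(list(gantry_deg = gantry_deg, mlc_mm = mlc_mm, time_s = time_s,
                 fluence_low_cut = fluence_low_cut,
                 fluence_pass_frac = fluence_pass_frac,
                 fluence_accept_rate = fluence_accept_rate,
                 source_rel_tol = source_rel_tol,
                 reference_sources = reference_sources,
                 nominal_dose_rate = nominal_dose_rate,
                 half_life_years = half_life_years,
                 grid = grid),
            class = "tolerance_config")
}

#' @export
print.tolerance_config <- function(x, ...) {
  cat(sprintf(paste0("Verification tolerances: gantry %.2f deg, MLC %.1f mm, ",
                     "time %.2f s\n"), x$gantry_deg, x$mlc_mm, x$time_s))
  cat(sprintf("  fluence: evaluate > %.0f%% of max, pass < %.0f%%, accept >= %.0f%%\n",
              100 * x$fluence_low_cut, 100 * x$fluence_pass_frac,
              x$fluence_accept_rate))
  cat(sprintf("  nominal %.2f Gy/min, half-life %.4f y, grid %.2f cm\n",
              x$nominal_dose_rate, x$half_life_years, x$grid$spacing))
  invisible(x)
}

num_attr <- function(node, name) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) stop_invalid("config: missing attribute '%s' on <%s>",
                             name, xml2::xml_name(node))
  x <- suppressWarnings(as.numeric(v))
  if (is.na(x)) stop_invalid("config: attribute '%s' is not numeric: '%s'", name, v)
  x
}

chr_attr <- function(node, name) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) stop_invalid("config: missing attribute '%s' on <%s>",
                             name, xml2::xml_name(node))
  v
}

assert_known_attrs <- function(node, known) {
  have <- names(xml2::xml_attrs(node))
  extra <- setdiff(have, known)
  if (length(extra))
    stop_invalid("config: unknown attribute(s) %s on <%s>",
                 paste(sprintf("'%s'", extra), collapse = ", "),
                 xml2::xml_name(node))
}

#' Write a verification configuration to XML
#' @param config a [tolerance_config()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_config_xml <- function(config, path) {
  stopifnot(inherits(config, "tolerance_config"))
  doc <- xml2::xml_new_root("qa_config", version = "1")
  xml2::xml_add_child(doc, "tolerances",
                      gantry_deg = format(config$gantry_deg),
                      mlc_mm = format(config$mlc_mm),
                      time_s = format(config$time_s),
                      source_rel_tol = format(config$source_rel_tol))
  xml2::xml_add_child(doc, "fluence",
                      low_cut = format(config$fluence_low_cut),
                      pass_frac = format(config$fluence_pass_frac),
                      accept_rate = format(config$fluence_accept_rate))
  xml2::xml_add_child(doc, "machine",
                      nominal_dose_rate = format(config$nominal_dose_rate),
                      half_life_years = format(config$half_life_years))
  g <- config$grid
  xml2::xml_add_child(doc, "grid", spacing = format(g$spacing),
                      x_extent = format(g$x_extent),
                      y_extent = format(g$y_extent),
                      leaf_width = format(g$leaf_width))
  for (s in config$reference_sources)
    xml2::xml_add_child(doc, "source",
                        head = format(s$head_id), serial = s$serial,
                        calibration_date = format(s$calibration_date),
                        calibration_strength = format(s$calibration_strength),
                        calibration_dose_rate = format(s$calibration_dose_rate))
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a verification configuration from XML
#'
#' Strict: unknown elements or attributes are an error, so a misspelled
#' tolerance can never silently fall back to a default.
#'
#' @param path path to a configuration XML file
#' @return a [tolerance_config()]
#' @export
read_config_xml <- function(path) {
  if (!file.exists(path)) stop_invalid("config file not found: %s", path)
  doc <- xml2::read_xml(path)
  if (xml2::xml_name(doc) != "qa_config")
    stop_invalid("config: root element must be <qa_config>, got <%s>",
                 xml2::xml_name(doc))
  kids <- xml2::xml_children(doc)
  names_seen <- xml2::xml_name(kids)
  unknown <- setdiff(unique(names_seen),
                     c("tolerances", "fluence", "machine", "grid", "source"))
  if (length(unknown))
    stop_invalid("config: unknown element(s): %s", paste(unknown, collapse = ", "))
  need_one <- function(nm) {
    n <- kids[names_seen == nm]
    if (length(n) != 1L) stop_invalid("config: expected exactly one <%s>", nm)
    n[[1]]
  }
  tl <- need_one("tolerances")
  assert_known_attrs(tl, c("gantry_deg", "mlc_mm", "time_s", "source_rel_tol"))
  fl <- need_one("fluence")
  assert_known_attrs(fl, c("low_cut", "pass_frac", "accept_rate"))
  mc <- need_one("machine")
  assert_known_attrs(mc, c("nominal_dose_rate", "half_life_years"))
  gr <- need_one("grid")
  assert_known_attrs(gr, c("spacing", "x_extent", "y_extent", "leaf_width"))
  src_nodes <- kids[names_seen == "source"]
  if (length(src_nodes) != 3L)
    stop_invalid("config: expected 3 <source> elements, got %d", length(src_nodes))
  half_life <- num_attr(mc, "half_life_years")
  sources <- lapply(src_nodes, function(n) {
    assert_known_attrs(n, c("head", "serial", "calibration_date",
                            "calibration_strength", "calibration_dose_rate"))
    cal_date <- as.Date(chr_attr(n, "calibration_date"))
    strength <- num_attr(n, "calibration_strength")
    rate <- num_attr(n, "calibration_dose_rate")
    source_info(num_attr(n, "head"), chr_attr(n, "serial"), cal_date,
                strength, rate, strength, rate, cal_date)
  })
  ord <- order(vapply(sources, `[[`, integer(1), "head_id"))
  tolerance_config(
    gantry_deg = num_attr(tl, "gantry_deg"),
    mlc_mm = num_attr(tl, "mlc_mm"),
    time_s = num_attr(tl, "time_s"),
    source_rel_tol = num_attr(tl, "source_rel_tol"),
    fluence_low_cut = num_attr(fl, "low_cut"),
    fluence_pass_frac = num_attr(fl, "pass_frac"),
    fluence_accept_rate = num_attr(fl, "accept_rate"),
    reference_sources = sources[ord],
    nominal_dose_rate = num_attr(mc, "nominal_dose_rate"),
    half_life_years = half_life,
    grid = grid_spec(num_attr(gr, "spacing"), num_attr(gr, "x_extent"),
                     num_attr(gr, "y_extent"), num_attr(gr, "leaf_width")))
}
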