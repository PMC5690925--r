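#' @section Data model:
#' In-memory types shared by every stage of the verification pipeline.
#' All constructors validate their invariants and stop() on violation, so
#' downstream code can assume well-formed objects.
#'
#' Conventions: x is the leaf-travel direction, y the leaf-stacking
#' direction; pair 1 sits at the most-negative y; all positions are cm
#' projected to the isocenter plane. Gantry angles are stored normalized
#' to [0, 360) and compared on the circle.
#' @name cobaltQA-datamodel
#' @keywords internal
NULL

N_LEAF_PAIRS <- 30L

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

#' Normalize an angle to [0, 360)
#' @param deg angle in degrees
#' @return equivalent angle in [0, 360)
#' @export
normalize_angle <- function(deg) {
  deg %% 360
}

#' Circular difference between two gantry angles
#'
#' Smallest angular separation on the circle, so 359 vs 1 gives 2, never 358.
#' @param a,b angles in degrees
#' @return separation in degrees, in [0, 180]
#' @export
angle_diff <- function(a, b) {
  d <- abs(normalize_angle(a) - normalize_angle(b))
  pmin(d, 360 - d)
}

#' Patient identity
#' @param name patient name
#' @param patient_id non-empty patient identifier
#' @return a `patient_info` object
#' @export
patient_info <- function(name, patient_id) {
  name <- as.character(name); patient_id <- as.character(patient_id)
  if (length(patient_id) != 1L || is.na(patient_id) || !nzchar(patient_id))
    stop_invalid("patient_id must be a non-empty string")
  structure(list(name = name, patient_id = patient_id),
            class = "patient_info")
}

#' Prescription information
#' @param prescription_name label of the prescription
#' @param dose_per_fraction dose per fraction in Gy (> 0)
#' @param n_fractions number of treatment fractions (>= 1)
#' @param ptv_name name of the planning target volume
#' @return a `prescription` object
#' @export
prescription <- function(prescription_name, dose_per_fraction, n_fractions,
                         ptv_name) {
  dose_per_fraction <- as.numeric(dose_per_fraction)
  n_fractions <- as.integer(n_fractions)
  if (!is.finite(dose_per_fraction) || dose_per_fraction <= 0)
    stop_invalid("dose_per_fraction must be > 0 Gy (got %s)", dose_per_fraction)
  if (is.na(n_fractions) || n_fractions < 1L)
    stop_invalid("n_fractions must be >= 1")
  structure(list(prescription_name = as.character(prescription_name),
                 dose_per_fraction = dose_per_fraction,
                 n_fractions = n_fractions,
                 ptv_name = as.character(ptv_name)),
            class = "prescription")
}

#' Cobalt-60 source description
#'
#' Calibration values are fixed at source installation; decayed values are
#' the strength and dose rate on `as_of_date`. The decayed/calibration
#' ratios of strength and dose rate must agree (same decay factor).
#'
#' @param head_id treatment head, 1..3
#' @param serial source serial number
#' @param calibration_date calendar date of calibration
#' @param calibration_strength activity at calibration (Ci)
#' @param calibration_dose_rate dose rate at calibration (Gy/min)
#' @param decayed_strength activity on `as_of_date` (Ci)
#' @param decayed_dose_rate dose rate on `as_of_date` (Gy/min)
#' @param as_of_date date the decayed values refer to
#' @return a `source_info` object
#' @export
source_info <- function(head_id, serial, calibration_date,
                        calibration_strength, calibration_dose_rate,
                        decayed_strength, decayed_dose_rate, as_of_date) {
  head_id <- as.integer(head_id)
  calibration_date <- as.Date(calibration_date)
  as_of_date <- as.Date(as_of_date)
  if (is.na(head_id) || !head_id %in% 1:3)
    stop_invalid("head_id must be 1, 2 or 3")
  vals <- c(calibration_strength, calibration_dose_rate,
            decayed_strength, decayed_dose_rate)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop_invalid("source strengths and dose rates must be positive and finite")
  if (as_of_date >= calibration_date &&
      decayed_strength > calibration_strength * (1 + 1e-9))
    stop_invalid("decayed_strength exceeds calibration_strength after calibration")
  f_strength <- decayed_strength / calibration_strength
  f_rate <- decayed_dose_rate / calibration_dose_rate
  if (abs(f_strength - f_rate) > 1e-6 * max(f_strength, f_rate))
    stop_invalid("decayed strength and dose rate imply different decay factors (%g vs %g)",
                 f_strength, f_rate)
  structure(list(head_id = head_id, serial = as.character(serial),
                 calibration_date = calibration_date,
                 calibration_strength = as.numeric(calibration_strength),
                 calibration_dose_rate = as.numeric(calibration_dose_rate),
                 decayed_strength = as.numeric(decayed_strength),
                 decayed_dose_rate = as.numeric(decayed_dose_rate),
                 as_of_date = as_of_date),
            class = "source_info")
}

#' One MLC leaf pair
#' @param pair_index position in the stack, 1..30 (1 at most-negative y)
#' @param left_x,right_x leaf tip positions, cm at isocenter; left_x <= right_x.
#'   A closed pair has left_x == right_x.
#' @return a `leaf_pair` object
#' @export
leaf_pair <- function(pair_index, left_x, right_x) {
  pair_index <- as.integer(pair_index)
  left_x <- as.numeric(left_x); right_x <- as.numeric(right_x)
  if (is.na(pair_index) || pair_index < 1L || pair_index > N_LEAF_PAIRS)
    stop_invalid("pair_index must be in 1..%d", N_LEAF_PAIRS)
  if (!is.finite(left_x) || !is.finite(right_x))
    stop_invalid("leaf positions must be finite")
  if (left_x > right_x + 1e-12)
    stop_invalid("pair %d: left_x (%g) > right_x (%g)", pair_index, left_x, right_x)
  structure(list(pair_index = pair_index, left_x = left_x, right_x = right_x),
            class = "leaf_pair")
}

#' One step-and-shoot segment: a static MLC aperture plus a beam-on time
#' @param segment_index 1-based index within the beam
#' @param beam_on_time beam-on duration in seconds (>= 0)
#' @param leaf_pairs list of exactly 30 [leaf_pair()] objects, in stack order
#' @return a `segment` object
#' @export
segment <- function(segment_index, beam_on_time, leaf_pairs) {
  segment_index <- as.integer(segment_index)
  beam_on_time <- as.numeric(beam_on_time)
  if (is.na(segment_index) || segment_index < 1L)
    stop_invalid("segment_index must be >= 1")
  if (!is.finite(beam_on_time) || beam_on_time < 0)
    stop_invalid("segment %d: beam_on_time must be >= 0 s", segment_index)
  if (length(leaf_pairs) != N_LEAF_PAIRS)
    stop_invalid("segment %d: expected %d leaf pairs, got %d",
                 segment_index, N_LEAF_PAIRS, length(leaf_pairs))
  ok <- vapply(leaf_pairs, inherits, logical(1), what = "leaf_pair")
  if (!all(ok)) stop_invalid("segment %d: leaf_pairs must all be leaf_pair objects",
                             segment_index)
  idx <- vapply(leaf_pairs, `[[`, integer(1), "pair_index")
  if (!identical(idx, seq_len(N_LEAF_PAIRS)))
    stop_invalid("segment %d: leaf pair indices must be 1..%d in order",
                 segment_index, N_LEAF_PAIRS)
  structure(list(segment_index = segment_index, beam_on_time = beam_on_time,
                 leaf_pairs = leaf_pairs),
            class = "segment")
}

#' One treatment beam (a gantry position on one head)
#' @param beam_id unique beam label
#' @param head_id treatment head delivering the beam, 1..3
#' @param gantry_angle gantry angle in degrees (normalized to [0, 360))
#' @param segments ordered list of [segment()] objects, indices 1..N
#' @return a `beam` object
#' @export
beam <- function(beam_id, head_id, gantry_angle, segments) {
  head_id <- as.integer(head_id)
  if (is.na(head_id) || !head_id %in% 1:3) stop_invalid("head_id must be 1, 2 or 3")
  gantry_angle <- normalize_angle(as.numeric(gantry_angle))
  if (!is.finite(gantry_angle)) stop_invalid("gantry_angle must be finite")
  if (length(segments) < 1L) stop_invalid("beam %s: needs at least one segment", beam_id)
  ok <- vapply(segments, inherits, logical(1), what = "segment")
  if (!all(ok)) stop_invalid("beam %s: segments must be segment objects", beam_id)
  idx <- vapply(segments, `[[`, integer(1), "segment_index")
  if (!identical(idx, seq_along(segments)))
    stop_invalid("beam %s: segment indices must be 1..N without gaps", beam_id)
  structure(list(beam_id = as.character(beam_id), head_id = head_id,
                 gantry_angle = gantry_angle, segments = segments),
            class = "beam")
}

#' A group of 1-3 beams deliverable simultaneously
#'
#' The machine's three heads sit 120 degrees apart, so beams of one group
#' must have gantry angles separated by multiples of 120 degrees (mod 360).
#' @param group_index group label (integer)
#' @param beams list of 1-3 [beam()] objects
#' @return a `beam_group` object
#' @export
beam_group <- function(group_index, beams) {
  group_index <- as.integer(group_index)
  if (length(beams) < 1L || length(beams) > 3L)
    stop_invalid("group %d: must contain 1-3 beams", group_index)
  ok <- vapply(beams, inherits, logical(1), what = "beam")
  if (!all(ok)) stop_invalid("group %d: beams must be beam objects", group_index)
  angles <- vapply(beams, `[[`, numeric(1), "gantry_angle")
  if (length(angles) > 1L) {
    rel <- (angles - angles[1]) %% 360
    off <- vapply(rel, function(r) min(abs(r - c(0, 120, 240, 360))), numeric(1))
    if (any(off > 1e-6))
      stop_invalid("group %d: gantry angles must be 120 deg apart (got %s)",
                   group_index, paste(round(angles, 3), collapse = ", "))
  }
  structure(list(group_index = group_index, beams = beams),
            class = "beam_group")
}

#' The approved treatment plan
#' @param patient a [patient_info()]
#' @param prescription a [prescription()]
#' @param plan_name plan label (version-bearing)
#' @param plan_date plan approval date
#' @param beam_groups list of [beam_group()] objects (at least one)
#' @param nominal_dose_rate planning reference dose rate, Gy/min; segment
#'   beam-on times in the plan are defined at this rate
#' @return a `plan` object
#' @export
plan <- function(patient, prescription, plan_name, plan_date, beam_groups,
                 nominal_dose_rate = 1.85) {
  stopifnot(inherits(patient, "patient_info"), inherits(prescription, "prescription"))
  if (length(beam_groups) < 1L) stop_invalid("plan needs at least one beam group")
  ok <- vapply(beam_groups, inherits, logical(1), what = "beam_group")
  if (!all(ok)) stop_invalid("beam_groups must be beam_group objects")
  nominal_dose_rate <- as.numeric(nominal_dose_rate)
  if (!is.finite(nominal_dose_rate) || nominal_dose_rate <= 0)
    stop_invalid("nominal_dose_rate must be > 0 Gy/min")
  ids <- unlist(lapply(beam_groups, function(g)
    vapply(g$beams, `[[`, character(1), "beam_id")))
  if (anyDuplicated(ids))
    stop_invalid("beam ids must be unique (duplicated: %s)",
                 paste(unique(ids[duplicated(ids)]), collapse = ", "))
  structure(list(patient = patient, prescription = prescription,
                 plan_name = as.character(plan_name),
                 plan_date = as.Date(plan_date),
                 beam_groups = beam_groups,
                 nominal_dose_rate = nominal_dose_rate),
            class = "plan")
}

#' The as-delivered record parsed from a machine log
#'
#' Per-segment beam-on times are the as-delivered values at the day's
#' decayed dose rate of the delivering head (not the planning nominal rate).
#' @param patient a [patient_info()]
#' @param prescription the [prescription()] the machine delivered under,
#'   as recorded in the log
#' @param plan_name plan label recorded in the log
#' @param fraction_number which fraction this delivery was (>= 1)
#' @param delivered_beams list of [beam()] objects with as-delivered values
#' @param sources list of 3 [source_info()] objects (heads 1..3), with
#'   decayed values as of the treatment day
#' @param interruptions list of interruption records, each a list with
#'   `beam_id`, `segment_index` and `partial_times` (seconds); the partials
#'   of an interrupted segment must sum to its recorded beam-on time
#' @return a `delivery_record` object
#' @export
delivery_record <- function(patient, prescription, plan_name, fraction_number,
                            delivered_beams, sources,
                            interruptions = list()) {
  stopifnot(inherits(patient, "patient_info"),
            inherits(prescription, "prescription"))
  fraction_number <- as.integer(fraction_number)
  if (is.na(fraction_number) || fraction_number < 1L)
    stop_invalid("fraction_number must be >= 1")
  ok <- vapply(delivered_beams, inherits, logical(1), what = "beam")
  if (length(delivered_beams) && !all(ok))
    stop_invalid("delivered_beams must be beam objects")
  if (length(sources) != 3L ||
      !all(vapply(sources, inherits, logical(1), what = "source_info")))
    stop_invalid("sources must be exactly 3 source_info objects")
  heads <- sort(vapply(sources, `[[`, integer(1), "head_id"))
  if (!identical(heads, 1:3)) stop_invalid("sources must cover heads 1, 2 and 3")
  bid <- vapply(delivered_beams, `[[`, character(1), "beam_id")
  for (itr in interruptions) {
    b <- match(itr$beam_id, bid)
    if (is.na(b)) stop_invalid("interruption references unknown beam '%s'", itr$beam_id)
    segs <- delivered_beams[[b]]$segments
    if (itr$segment_index < 1L || itr$segment_index > length(segs))
      stop_invalid("interruption references missing segment %d of beam '%s'",
                   itr$segment_index, itr$beam_id)
    t_seg <- segs[[itr$segment_index]]$beam_on_time
    if (abs(sum(itr$partial_times) - t_seg) > 1e-6)
      stop_invalid("beam '%s' segment %d: interruption partials sum to %g, recorded time is %g",
                   itr$beam_id, itr$segment_index, sum(itr$partial_times), t_seg)
  }
  structure(list(patient = patient, prescription = prescription,
                 plan_name = as.character(plan_name),
                 fraction_number = fraction_number,
                 delivered_beams = delivered_beams, sources = sources,
                 interruptions = interruptions),
            class = "delivery_record")
}

#' Rasterization grid on the isocenter plane
#' @param spacing pixel size, cm
#' @param x_extent,y_extent grid extent, cm, centered on the isocenter axis
#' @param leaf_width projected leaf width at isocenter, cm; the grid must
#'   cover the full 30-pair leaf stack (y_extent >= 30 * leaf_width)
#' @return a `grid_spec` object
#' @export
grid_spec <- function(spacing = 0.1, x_extent = 31.5, y_extent = 31.5,
                      leaf_width = 1.05) {
  spacing <- as.numeric(spacing)
  if (!is.finite(spacing) || spacing <= 0) stop_invalid("spacing must be > 0 cm")
  if (y_extent < N_LEAF_PAIRS * leaf_width - 1e-9)
    stop_invalid("y_extent (%g cm) smaller than the %d x %g cm leaf stack",
                 y_extent, N_LEAF_PAIRS, leaf_width)
  structure(list(spacing = spacing, x_extent = as.numeric(x_extent),
                 y_extent = as.numeric(y_extent),
                 leaf_width = as.numeric(leaf_width)),
            class = "grid_spec")
}

#' Integrated primary fluence map (seconds of open beam time per pixel)
#' @param values numeric matrix, rows = y (stack direction), cols = x
#'   (travel direction); all values finite and >= 0
#' @param grid the [grid_spec()] the map was rasterized on
#' @return a `fluence_map` object
#' @export
fluence_map <- function(values, grid) {
  stopifnot(is.matrix(values), inherits(grid, "grid_spec"))
  if (any(!is.finite(values)) || any(values < 0))
    stop_invalid("fluence values must be finite and >= 0")
  structure(list(values = values, grid = grid), class = "fluence_map")
}

#' Total beam-on time of a beam
#'
#' Sum of the per-segment beam-on times, in whatever time scale the beam's
#' segments carry (nominal for a plan beam, delivered for a log beam).
#' @param b a [beam()]
#' @return total beam-on time, seconds
#' @export
total_beam_on_time <- function(b) {
  stopifnot(inherits(b, "beam"))
  sum(vapply(b$segments, `[[`, numeric(1), "beam_on_time"))
}

#' All beams of a plan, flattened in group order
#' @param p a [plan()]
#' @return list of [beam()] objects
#' @export
plan_beams <- function(p) {
  stopifnot(inherits(p, "plan"))
  unlist(lapply(p$beam_groups, `[[`, "beams"), recursive = FALSE)
}

#' @export
print.plan <- function(x, ...) {
  bs <- plan_beams(x)
  nseg <- sum(vapply(bs, function(b) length(b$segments), integer(1)))
  cat(sprintf("Treatment plan '%s' (%s)\n", x$plan_name, x$plan_date))
  cat(sprintf("  patient: %s [%s]\n", x$patient$name, x$patient$patient_id))
  cat(sprintf("  prescription: %s, %.2f Gy x %d to %s\n",
              x$prescription$prescription_name, x$prescription$dose_per_fraction,
              x$prescription$n_fractions, x$prescription$ptv_name))
  cat(sprintf("  %d beam group(s), %d beam(s), %d segment(s); nominal %.2f Gy/min\n",
              length(x$beam_groups), length(bs), nseg, x$nominal_dose_rate))
  invisible(x)
}

#' @export
print.delivery_record <- function(x, ...) {
  cat(sprintf("Delivery record: plan '%s', fraction %d\n",
              x$plan_name, x$fraction_number))
  cat(sprintf("  patient: %s [%s]\n", x$patient$name, x$patient$patient_id))
  cat(sprintf("  %d delivered beam(s), %d interruption record(s)\n",
              length(x$delivered_beams), length(x$interruptions)))
  for (s in x$sources)
    cat(sprintf("  head %d source %s: %.4f Gy/min on %s\n",
                s$head_id, s$serial, s$decayed_dose_rate, s$as_of_date))
  invisible(x)
}

#' @export
print.fluence_map <- function(x, ...) {
  cat(sprintf("Fluence map %dx%d px @ %.2f cm, max %.3f s\n",
              nrow(x$values), ncol(x$values), x$grid$spacing, max(x$values)))
  invisible(x)
}
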