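# Synthetic fixture generator: random valid plans, error-free simulated
# deliveries, and an injectable catalogue of the delivery-error scenarios
# the verification engine must detect.

ERROR_KINDS <- c("gantry_offset", "leaf_offset", "segment_time_offset",
                 "beam_time_scale", "skip_beam", "skip_segment",
                 "wrong_patient", "wrong_plan_version",
                 "decay_uncorrected_times", "interruption_split",
                 "source_decay_wrong", "junction_walk")

#' Specification of one injectable delivery error
#'
#' @param kind one of `gantry_offset` (degrees added to a beam's gantry),
#'   `leaf_offset` (mm added to one leaf of one segment),
#'   `segment_time_offset` (seconds added to one segment's delivered time),
#'   `beam_time_scale` (all of a beam's segment times multiplied by the
#'   magnitude, the "beam weighting" scenario), `skip_beam` (beam missing
#'   from the log), `skip_segment` (segment missing and the rest
#'   renumbered), `wrong_patient` (different patient name and ID),
#'   `wrong_plan_version` (plan name with a version suffix),
#'   `decay_uncorrected_times` (log times carry the nominal planning values
#'   instead of the decay-corrected ones), `interruption_split` (magnitude
#'   = fraction of the segment actually delivered; 1 means interrupted and
#'   fully resumed, < 1 means truncated), `source_decay_wrong` (log carries
#'   calibration-day source strength/dose rate on the treatment day) and
#'   `junction_walk` (a closed leaf pair recorded at a shifted junction
#'   position, magnitude in mm)
#' @param magnitude error size, units per kind (unused for the identity and
#'   skip kinds)
#' @param beam_id,segment_index,leaf_index target of the error, as
#'   applicable for the kind
#' @param side which leaf of the pair a `leaf_offset` moves ("left"/"right")
#' @return an `error_spec` object
#' @export
error_spec <- function(kind, magnitude = NA_real_, beam_id = NULL,
                       segment_index = NULL, leaf_index = NULL,
                       side = "right") {
  kind <- match.arg(kind, ERROR_KINDS)
  if (!is.na(magnitude) && !is.finite(magnitude))
    stop_invalid("error magnitude must be finite")
  side <- match.arg(side, c("left", "right"))
  structure(list(kind = kind, magnitude = magnitude, beam_id = beam_id,
                 segment_index = segment_index, leaf_index = leaf_index,
                 side = side),
            class = "error_spec")
}

random_aperture <- function(grid, width_range, staircase = FALSE) {
  # contiguous open span of 6..20 pairs so closed pairs always remain
  n_open <- sample(6:20, 1L)
  first <- sample(seq_len(N_LEAF_PAIRS - n_open + 1L), 1L)
  cx <- round_dec(stats::runif(1, -3, 3), 2)
  w <- stats::runif(1, width_range[1], width_range[2])
  step <- if (staircase) round_dec(stats::runif(1, -0.4, 0.4), 2) else 0
  lapply(seq_len(N_LEAF_PAIRS), function(i) {
    if (i >= first && i < first + n_open) {
      c_i <- round_dec(cx + step * (i - first), 2)
      half <- round_dec(w / 2, 2)
      leaf_pair(i, round_dec(c_i - half, 2), round_dec(c_i + half, 2))
    } else {
      # closed pairs park at the aperture's central junction
      leaf_pair(i, cx, cx)
    }
  })
}

#' Generate a random valid treatment plan
#'
#' Beam groups carry 120-degree-separated beams on distinct heads;
#' apertures are random rectangles or staircases 2-10 cm wide within the
#' leaf stack; segment beam-on times are uniform in the given range at the
#' nominal planning dose rate. Deterministic per seed.
#'
#' @param seed RNG seed
#' @param n_groups number of beam groups
#' @param beams_per_group beams per group (1-3)
#' @param segments_per_beam segments per beam
#' @param field_params list with `width_range` (cm, default c(2, 10)) and
#'   `time_range` (s, default c(1, 60))
#' @param nominal_dose_rate planning dose rate, Gy/min
#' @return a [plan()]
#' @export
generate_plan <- function(seed, n_groups = 2L, beams_per_group = 3L,
                          segments_per_beam = 3L,
                          field_params = list(),
                          nominal_dose_rate = 1.85) {
  set.seed(seed)
  width_range <- field_params$width_range %||% c(2, 10)
  time_range <- field_params$time_range %||% c(1, 60)
  patient <- patient_info(
    paste(sample(c("Avery", "Blake", "Casey", "Drew", "Ellis"), 1L),
          sample(c("Kim", "Lopez", "Nguyen", "Okafor", "Silva"), 1L)),
    sprintf("PT%06d", sample.int(999999L, 1L)))
  rx <- prescription(sprintf("RX-%03d", sample.int(999L, 1L)),
                     sample(c(1.8, 2, 2.5, 3), 1L),
                     sample(5:30, 1L),
                     sprintf("PTV_%d", sample.int(3L, 1L)))
  grid <- grid_spec()
  beam_counter <- 0L
  groups <- lapply(seq_len(n_groups), function(g) {
    base <- round_dec(stats::runif(1, 0, 360), 1)
    beams <- lapply(seq_len(beams_per_group), function(h) {
      beam_counter <<- beam_counter + 1L
      segs <- lapply(seq_len(segments_per_beam), function(k)
        segment(k, round_dec(stats::runif(1, time_range[1], time_range[2]), 3),
                random_aperture(grid, width_range,
                                staircase = stats::runif(1) < 0.5)))
      beam(sprintf("B%d", beam_counter), h,
           round_dec(normalize_angle(base + (h - 1L) * 120), 3), segs)
    })
    beam_group(g, beams)
  })
  plan(patient, rx, sprintf("PLAN-%03d_v1", sample.int(999L, 1L)),
       as.Date("2026-02-01") + sample.int(60L, 1L),
       groups, nominal_dose_rate)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate an error-free treatment delivery
#'
#' Decays each head's reference source to the treatment day, converts every
#' planned segment time to the as-delivered scale (planned x nominal /
#' day rate of the delivering head), and optionally adds Gaussian machine
#' noise. All values are rounded to the log dialect's resolution (ms for
#' times, 0.1 mm for positions), as a real machine log would record them.
#' With the default zero noise the record is exact.
#'
#' @param p a [plan()]
#' @param sources 3 reference [source_info()] (calibration data used)
#' @param treatment_date the delivery date
#' @param fraction_number fraction being delivered
#' @param noise list of per-quantity SDs: `gantry_deg`, `mlc_mm`, `time_s`
#'   (all default 0)
#' @param seed optional RNG seed for the noise draws
#' @param half_life_years half-life for the source decay
#' @return a [delivery_record()]
#' @export
simulate_delivery <- function(p, sources = default_sources(),
                              treatment_date = as.Date("2026-03-01"),
                              fraction_number = 1L,
                              noise = list(), seed = NULL,
                              half_life_years = CO60_HALF_LIFE_YEARS) {
  stopifnot(inherits(p, "plan"))
  if (!is.null(seed)) set.seed(seed)
  sd_gantry <- noise$gantry_deg %||% 0
  sd_mlc_cm <- (noise$mlc_mm %||% 0) / 10
  sd_time <- noise$time_s %||% 0
  day_sources <- lapply(sources, function(s) {
    d <- decay_source(s, treatment_date, half_life_years)
    source_info(d$head_id, d$serial, d$calibration_date,
                round_dec(d$calibration_strength, 6),
                round_dec(d$calibration_dose_rate, 6),
                round_dec(d$decayed_strength, 6),
                round_dec(d$decayed_dose_rate, 6),
                d$as_of_date)
  })
  delivered <- lapply(plan_beams(p), function(b) {
    day_rate <- head_day_rate(day_sources, b$head_id)
    segs <- lapply(b$segments, function(sg) {
      t_del <- expected_delivered_time(sg$beam_on_time, p$nominal_dose_rate,
                                       day_rate)
      if (sd_time > 0) t_del <- t_del + stats::rnorm(1, 0, sd_time)
      lps <- lapply(sg$leaf_pairs, function(lp) {
        l <- lp$left_x; r <- lp$right_x
        if (sd_mlc_cm > 0) {
          l <- l + stats::rnorm(1, 0, sd_mlc_cm)
          r <- r + stats::rnorm(1, 0, sd_mlc_cm)
          if (l > r) { m <- (l + r) / 2; l <- m; r <- m }
        }
        leaf_pair(lp$pair_index, round_dec(l, 2), round_dec(r, 2))
      })
      segment(sg$segment_index, round_dec(max(0, t_del), 3), lps)
    })
    g <- b$gantry_angle
    if (sd_gantry > 0) g <- g + stats::rnorm(1, 0, sd_gantry)
    beam(b$beam_id, b$head_id, round_dec(normalize_angle(g), 3), segs)
  })
  delivery_record(p$patient, p$prescription, p$plan_name, fraction_number,
                  delivered, day_sources)
}

modify_beam <- function(rec, beam_id, f) {
  ids <- vapply(rec$delivered_beams, `[[`, character(1), "beam_id")
  i <- match(beam_id, ids)
  if (is.na(i)) stop_invalid("error target beam '%s' not in record", beam_id)
  rec$delivered_beams[[i]] <- f(rec$delivered_beams[[i]])
  rec
}

rebuild_record <- function(rec, ...) {
  args <- list(...)
  fields <- list(patient = rec$patient, prescription = rec$prescription,
                 plan_name = rec$plan_name,
                 fraction_number = rec$fraction_number,
                 delivered_beams = rec$delivered_beams,
                 sources = rec$sources, interruptions = rec$interruptions)
  fields[names(args)] <- args
  do.call(delivery_record, fields)
}

#' Inject a single delivery error into a record
#'
#' Applies exactly the modification described by the [error_spec()] and
#' leaves every other field identical, so tests can assert locality.
#'
#' @param rec an error-free [delivery_record()]
#' @param spec an [error_spec()]
#' @param p the [plan()] the record was simulated from; required only for
#'   `decay_uncorrected_times` (the planned nominal times are copied into
#'   the log)
#' @return the modified [delivery_record()]
#' @export
inject_error <- function(rec, spec, p = NULL) {
  stopifnot(inherits(rec, "delivery_record"), inherits(spec, "error_spec"))
  need_seg <- function() {
    if (is.null(spec$beam_id) || is.null(spec$segment_index))
      stop_invalid("%s needs beam_id and segment_index", spec$kind)
  }
  switch(spec$kind,
    gantry_offset = modify_beam(rec, spec$beam_id, function(b)
      beam(b$beam_id, b$head_id,
           normalize_angle(b$gantry_angle + spec$magnitude), b$segments)),
    leaf_offset = {
      need_seg()
      if (is.null(spec$leaf_index)) stop_invalid("leaf_offset needs leaf_index")
      modify_beam(rec, spec$beam_id, function(b) {
        sg <- b$segments[[spec$segment_index]]
        lp <- sg$leaf_pairs[[spec$leaf_index]]
        d_cm <- spec$magnitude / 10
        lp2 <- if (spec$side == "left")
          leaf_pair(lp$pair_index, lp$left_x + d_cm, max(lp$right_x, lp$left_x + d_cm))
        else
          leaf_pair(lp$pair_index, min(lp$left_x, lp$right_x + d_cm), lp$right_x + d_cm)
        sg$leaf_pairs[[spec$leaf_index]] <- lp2
        b$segments[[spec$segment_index]] <-
          segment(sg$segment_index, sg$beam_on_time, sg$leaf_pairs)
        beam(b$beam_id, b$head_id, b$gantry_angle, b$segments)
      })
    },
    segment_time_offset = {
      need_seg()
      modify_beam(rec, spec$beam_id, function(b) {
        sg <- b$segments[[spec$segment_index]]
        b$segments[[spec$segment_index]] <-
          segment(sg$segment_index, max(0, sg$beam_on_time + spec$magnitude),
                  sg$leaf_pairs)
        beam(b$beam_id, b$head_id, b$gantry_angle, b$segments)
      })
    },
    beam_time_scale = modify_beam(rec, spec$beam_id, function(b) {
      b$segments <- lapply(b$segments, function(sg)
        segment(sg$segment_index, sg$beam_on_time * spec$magnitude,
                sg$leaf_pairs))
      beam(b$beam_id, b$head_id, b$gantry_angle, b$segments)
    }),
    skip_beam = {
      ids <- vapply(rec$delivered_beams, `[[`, character(1), "beam_id")
      i <- match(spec$beam_id, ids)
      if (is.na(i)) stop_invalid("error target beam '%s' not in record",
                                 spec$beam_id)
      rebuild_record(rec, delivered_beams = rec$delivered_beams[-i])
    },
    skip_segment = {
      need_seg()
      modify_beam(rec, spec$beam_id, function(b) {
        segs <- b$segments[-spec$segment_index]
        segs <- lapply(seq_along(segs), function(k)
          segment(k, segs[[k]]$beam_on_time, segs[[k]]$leaf_pairs))
        beam(b$beam_id, b$head_id, b$gantry_angle, segs)
      })
    },
    wrong_patient = rebuild_record(rec,
      patient = patient_info("Wrong Patient",
                             paste0(rec$patient$patient_id, "X"))),
    wrong_plan_version = rebuild_record(rec,
      plan_name = sub("_v[0-9]+$", "", rec$plan_name) |> paste0("_v2")),
    decay_uncorrected_times = {
      if (is.null(p))
        stop_invalid("decay_uncorrected_times needs the source plan")
      planned <- plan_beams(p)
      pids <- vapply(planned, `[[`, character(1), "beam_id")
      beams <- lapply(rec$delivered_beams, function(b) {
        i <- match(b$beam_id, pids)
        if (is.na(i)) return(b)
        segs <- lapply(seq_along(b$segments), function(k)
          segment(k, planned[[i]]$segments[[k]]$beam_on_time,
                  b$segments[[k]]$leaf_pairs))
        beam(b$beam_id, b$head_id, b$gantry_angle, segs)
      })
      rebuild_record(rec, delivered_beams = beams)
    },
    interruption_split = {
      need_seg()
      frac <- spec$magnitude
      if (!is.finite(frac) || frac <= 0 || frac > 1)
        stop_invalid("interruption_split magnitude must be in (0, 1]")
      ids <- vapply(rec$delivered_beams, `[[`, character(1), "beam_id")
      b <- rec$delivered_beams[[match(spec$beam_id, ids)]]
      t_full <- b$segments[[spec$segment_index]]$beam_on_time
      if (frac >= 1) {
        # interrupted then fully resumed: recorded total unchanged
        p1 <- round_dec(0.6 * t_full, 3)
        partials <- c(p1, round_dec(t_full - p1, 3))
        t_new <- t_full
      } else {
        t_new <- round_dec(frac * t_full, 3)
        partials <- t_new
      }
      rec <- modify_beam(rec, spec$beam_id, function(b) {
        sg <- b$segments[[spec$segment_index]]
        b$segments[[spec$segment_index]] <-
          segment(sg$segment_index, t_new, sg$leaf_pairs)
        beam(b$beam_id, b$head_id, b$gantry_angle, b$segments)
      })
      rebuild_record(rec, interruptions = c(rec$interruptions,
        list(list(beam_id = spec$beam_id,
                  segment_index = spec$segment_index,
                  partial_times = partials))))
    },
    source_decay_wrong = rebuild_record(rec, sources = lapply(rec$sources,
      function(s) source_info(s$head_id, s$serial, s$calibration_date,
                              s$calibration_strength, s$calibration_dose_rate,
                              s$calibration_strength, s$calibration_dose_rate,
                              s$as_of_date))),
    junction_walk = {
      need_seg()
      modify_beam(rec, spec$beam_id, function(b) {
        sg <- b$segments[[spec$segment_index]]
        i <- spec$leaf_index
        if (is.null(i)) {
          closed <- which(vapply(sg$leaf_pairs, function(lp)
            lp$right_x - lp$left_x <= 0, logical(1)))
          if (!length(closed))
            stop_invalid("junction_walk: no closed pair in beam %s segment %d",
                         spec$beam_id, spec$segment_index)
          i <- closed[[1]]
        }
        lp <- sg$leaf_pairs[[i]]
        d_cm <- spec$magnitude / 10
        sg$leaf_pairs[[i]] <- leaf_pair(lp$pair_index, lp$left_x + d_cm,
                                        lp$right_x + d_cm)
        b$segments[[spec$segment_index]] <-
          segment(sg$segment_index, sg$beam_on_time, sg$leaf_pairs)
        beam(b$beam_id, b$head_id, b$gantry_angle, b$segments)
      })
    })
}

#' Write a plan/log fixture pair (plus config and manifest) to disk
#'
#' Generates a plan, simulates its delivery, optionally injects errors, and
#' writes `<stem>.plan.txt`, `<stem>.log.txt`, `<stem>.config.xml` and a
#' JSON manifest of the injected errors.
#'
#' @param out_dir output directory (created if needed)
#' @param seed generator seed
#' @param stem file name stem
#' @param errors list of [error_spec()] to inject into the log
#' @param treatment_date delivery date
#' @param config a [tolerance_config()]
#' @param ... forwarded to [generate_plan()]
#' @return invisibly, a list with the paths and the in-memory objects
#' @export
write_fixture_pair <- function(out_dir, seed, stem = sprintf("case%d", seed),
                               errors = list(),
                               treatment_date = as.Date("2026-03-01"),
                               config = tolerance_config(), ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- generate_plan(seed, ...)
  rec <- simulate_delivery(p, config$reference_sources, treatment_date,
                           half_life_years = config$half_life_years)
  for (e in errors) rec <- inject_error(rec, e, p)
  paths <- list(plan = file.path(out_dir, paste0(stem, ".plan.txt")),
                log = file.path(out_dir, paste0(stem, ".log.txt")),
                config = file.path(out_dir, paste0(stem, ".config.xml")),
                manifest = file.path(out_dir, paste0(stem, ".manifest.json")))
  writeLines(write_plan_overview(p), paths$plan)
  writeLines(write_delivery_log(rec), paths$log)
  write_config_xml(config, paths$config)
  manifest <- lapply(errors, function(e)
    Filter(Negate(is.null), unclass(e)))
  jsonlite::write_json(list(seed = seed, errors = manifest), paths$manifest,
                       auto_unbox = TRUE, null = "null")
  invisible(list(paths = paths, plan = p, record = rec, config = config))
}
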