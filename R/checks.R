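# The comparison engine: identity, prescription, source, per-beam,
# per-segment and fluence checks with tolerance application.
#
# Status semantics: a numeric comparison fails iff the deviation is
# strictly greater than its tolerance (deviation == tolerance passes);
# warn is reserved for non-safety findings (fraction overrun, degenerate
# fluence denominator, missing captures).

check_row <- function(category, item, planned, delivered, tolerance, status) {
  data.frame(category = category, item = item,
             planned = as.character(planned),
             delivered = as.character(delivered),
             tolerance = as.character(tolerance),
             status = status,
             stringsAsFactors = FALSE)
}

bind_rows_df <- function(rows) {
  do.call(rbind, rows)
}

compare_exact <- function(category, item, planned, delivered) {
  status <- if (identical(as.character(planned), as.character(delivered)))
    "pass" else "fail"
  check_row(category, item, planned, delivered, "exact", status)
}

compare_num <- function(category, item, planned, delivered, tol, unit,
                        fmt = "%.4g") {
  dev <- abs(delivered - planned)
  status <- if (dev > tol) "fail" else "pass"
  check_row(category, item, sprintf(fmt, planned), sprintf(fmt, delivered),
            sprintf("%g %s", tol, unit), status)
}

#' Check patient and plan identity
#'
#' Exact string comparison of patient name, patient ID and plan name, so a
#' delivery under the wrong patient or the wrong plan version fails.
#'
#' @param p the approved [plan()]
#' @param rec the [delivery_record()]
#' @return data frame of check results
#' @export
check_identity <- function(p, rec) {
  bind_rows_df(list(
    compare_exact("patient", "Patient name", p$patient$name, rec$patient$name),
    compare_exact("patient", "Patient ID", p$patient$patient_id,
                  rec$patient$patient_id),
    compare_exact("plan", "Plan name", p$plan_name, rec$plan_name)))
}

#' Check the prescription block
#'
#' Dose per fraction, number of fractions and PTV name must match exactly;
#' a fraction number beyond the prescribed count is a warning (re-treatment
#' and plan extensions are clinical decisions, not delivery errors).
#'
#' @inheritParams check_identity
#' @param config a [tolerance_config()]
#' @return data frame of check results
#' @export
check_prescription <- function(p, rec, config) {
  rx_p <- p$prescription; rx_d <- rec$prescription
  over <- rec$fraction_number > rx_p$n_fractions
  bind_rows_df(list(
    compare_exact("prescription", "Prescription name",
                  rx_p$prescription_name, rx_d$prescription_name),
    compare_num("prescription", "Prescription dose",
                rx_p$dose_per_fraction, rx_d$dose_per_fraction,
                tol = 1e-6, unit = "Gy", fmt = "%.3f"),
    compare_exact("prescription", "Number of fractions",
                  rx_p$n_fractions, rx_d$n_fractions),
    compare_exact("prescription", "PTV target", rx_p$ptv_name, rx_d$ptv_name),
    check_row("prescription", "Fraction number",
              sprintf("<= %d", rx_p$n_fractions), rec$fraction_number,
              "within prescribed fractions", if (over) "warn" else "pass")))
}

#' Check the log's cobalt-60 source block against the configuration
#'
#' Serial and calibration data are compared exactly against the reference
#' sources in the configuration; the decayed strength and dose rate are
#' recomputed from the reference calibration via the decay law and compared
#' within the configured relative tolerance, so a log that carries an
#' undecayed (calibration-day) dose rate on a later treatment date fails.
#'
#' @param record_sources the 3 [source_info()] from the log
#' @param config a [tolerance_config()]
#' @param treatment_date the treatment day
#' @return data frame of check results
#' @export
check_source <- function(record_sources, config, treatment_date) {
  treatment_date <- as.Date(treatment_date)
  rows <- list()
  ref_heads <- vapply(config$reference_sources, `[[`, integer(1), "head_id")
  for (s in record_sources) {
    i <- match(s$head_id, ref_heads)
    lab <- sprintf("[head %d]", s$head_id)
    if (is.na(i)) {
      rows[[length(rows) + 1L]] <-
        check_row("source", paste("Source reference", lab), "present", "absent",
                  "exact", "fail")
      next
    }
    ref <- config$reference_sources[[i]]
    rows[[length(rows) + 1L]] <-
      compare_exact("source", paste("Source serial", lab), ref$serial, s$serial)
    rows[[length(rows) + 1L]] <-
      compare_exact("source", paste("Calibration date", lab),
                    format(ref$calibration_date), format(s$calibration_date))
    rows[[length(rows) + 1L]] <-
      compare_num("source", paste("Calibration strength", lab),
                  ref$calibration_strength, s$calibration_strength,
                  tol = config$source_rel_tol * ref$calibration_strength,
                  unit = "Ci (rel)", fmt = "%.4f")
    rows[[length(rows) + 1L]] <-
      compare_num("source", paste("Calibration dose rate", lab),
                  ref$calibration_dose_rate, s$calibration_dose_rate,
                  tol = config$source_rel_tol * ref$calibration_dose_rate,
                  unit = "Gy/min (rel)", fmt = "%.6f")
    f <- decay_factor(ref$calibration_date, treatment_date,
                      config$half_life_years)
    exp_strength <- ref$calibration_strength * f
    exp_rate <- ref$calibration_dose_rate * f
    rows[[length(rows) + 1L]] <-
      compare_num("source", paste("Decayed strength", lab),
                  exp_strength, s$decayed_strength,
                  tol = config$source_rel_tol * exp_strength,
                  unit = "Ci (rel)", fmt = "%.4f")
    rows[[length(rows) + 1L]] <-
      compare_num("source", paste("Decayed dose rate", lab),
                  exp_rate, s$decayed_dose_rate,
                  tol = config$source_rel_tol * exp_rate,
                  unit = "Gy/min (rel)", fmt = "%.6f")
  }
  bind_rows_df(rows)
}

#' Check one delivered beam's parameters against the plan
#'
#' Gantry angle (circular difference), segment count, and the total
#' beam-on time with the delivered total normalized to the nominal dose
#' rate scale before comparison.
#'
#' @param plan_beam,delivered_beam matched [beam()] objects
#' @param day_rate the delivering head's decayed dose rate, Gy/min
#' @param config a [tolerance_config()]
#' @return data frame of check results
#' @export
check_beam <- function(plan_beam, delivered_beam, day_rate, config) {
  lab <- sprintf("[beam %s]", plan_beam$beam_id)
  g_dev <- angle_diff(plan_beam$gantry_angle, delivered_beam$gantry_angle)
  t_plan <- total_beam_on_time(plan_beam)
  t_del <- normalize_delivered_time(total_beam_on_time(delivered_beam),
                                    config$nominal_dose_rate, day_rate)
  bind_rows_df(list(
    check_row("beam", paste("Gantry angle", lab),
              sprintf("%.3f", plan_beam$gantry_angle),
              sprintf("%.3f", delivered_beam$gantry_angle),
              sprintf("%g deg", config$gantry_deg),
              if (g_dev > config$gantry_deg) "fail" else "pass"),
    compare_exact("beam", paste("Number of segments", lab),
                  length(plan_beam$segments), length(delivered_beam$segments)),
    compare_num("beam", paste("Total beam-on time", lab), t_plan, t_del,
                tol = config$time_s, unit = "s", fmt = "%.3f")))
}

#' Check each segment's MLC leaf positions and beam-on time
#'
#' Per segment: every leaf position is compared within the MLC tolerance
#' (the result row reports the maximum deviation and, on failure, names the
#' worst leaf), and the decay-normalized segment beam-on time is compared
#' within the time tolerance. Only segment indices present in both beams
#' are compared; count mismatches are reported by [check_beam()].
#'
#' @inheritParams check_beam
#' @return data frame of check results
#' @export
check_segments <- function(plan_beam, delivered_beam, day_rate, config) {
  rows <- list()
  n <- min(length(plan_beam$segments), length(delivered_beam$segments))
  tol_cm <- config$mlc_mm / 10
  for (k in seq_len(n)) {
    sp <- plan_beam$segments[[k]]; sd_ <- delivered_beam$segments[[k]]
    lab <- sprintf("[beam %s seg %d]", plan_beam$beam_id, k)
    pos_p <- unlist(lapply(sp$leaf_pairs, function(lp) c(lp$left_x, lp$right_x)))
    pos_d <- unlist(lapply(sd_$leaf_pairs, function(lp) c(lp$left_x, lp$right_x)))
    dev <- abs(pos_d - pos_p)
    worst <- which.max(dev)
    pair_i <- (worst + 1L) %/% 2L
    side <- if (worst %% 2L == 1L) "left" else "right"
    item <- paste("MLC leaf positions", lab)
    if (max(dev) > tol_cm)
      item <- sprintf("%s (worst: pair %d %s)", item, pair_i, side)
    rows[[length(rows) + 1L]] <-
      check_row("segment", item,
                sprintf("%.2f", pos_p[worst]), sprintf("%.2f", pos_d[worst]),
                sprintf("%g mm", config$mlc_mm),
                if (max(dev) > tol_cm) "fail" else "pass")
    t_del <- normalize_delivered_time(sd_$beam_on_time,
                                      config$nominal_dose_rate, day_rate)
    rows[[length(rows) + 1L]] <-
      compare_num("segment", paste("Beam-on time", lab),
                  sp$beam_on_time, t_del,
                  tol = config$time_s, unit = "s", fmt = "%.3f")
  }
  bind_rows_df(rows)
}

#' Compose and compare a beam's integrated primary fluence map
#'
#' Both maps are composed on the same grid; the delivered segment times are
#' normalized to the nominal dose rate scale first, so source decay alone
#' never produces a fluence difference. The beam fails when the pixel pass
#' rate drops below the configured acceptance rate; a plan beam whose map
#' is zero everywhere is reported as warn.
#'
#' @inheritParams check_beam
#' @param grid a [grid_spec()]
#' @return list with `stats` (a [fluence_stats()]), `result` (one check
#'   row), `plan_map` and `delivered_map` (the composed [fluence_map()]s)
#' @export
check_beam_fluence <- function(plan_beam, delivered_beam, day_rate, grid,
                               config) {
  plan_map <- compose_fluence(plan_beam$segments, grid)
  norm_segs <- lapply(delivered_beam$segments, function(sg)
    segment(sg$segment_index,
            normalize_delivered_time(sg$beam_on_time,
                                     config$nominal_dose_rate, day_rate),
            sg$leaf_pairs))
  del_map <- compose_fluence(norm_segs, grid)
  stats <- fluence_compare(plan_map, del_map, config$fluence_low_cut,
                           config$fluence_pass_frac)
  lab <- sprintf("[beam %s]", plan_beam$beam_id)
  status <- if (is.na(stats$pass_rate)) "warn"
            else if (stats$pass_rate < config$fluence_accept_rate) "fail"
            else "pass"
  row <- check_row("fluence", paste("Fluence pass rate", lab),
                   sprintf(">= %.1f%%", config$fluence_accept_rate),
                   if (is.na(stats$pass_rate)) "n/a (empty field)"
                   else sprintf("%.1f%%", stats$pass_rate),
                   sprintf("%g%% of evaluated pixels", config$fluence_accept_rate),
                   status)
  list(stats = stats, result = row, plan_map = plan_map,
       delivered_map = del_map)
}

match_beams <- function(p, rec, config) {
  pb <- plan_beams(p)
  db <- rec$delivered_beams
  p_ids <- vapply(pb, `[[`, character(1), "beam_id")
  d_ids <- vapply(db, `[[`, character(1), "beam_id")
  d_used <- logical(length(db))
  pairs <- integer(length(pb))  # index into db, NA if unmatched
  for (i in seq_along(pb)) {
    j <- match(p_ids[i], d_ids)
    if (!is.na(j) && !d_used[j]) {
      pairs[i] <- j; d_used[j] <- TRUE
      next
    }
    # fall back to (head, gantry-within-tolerance)
    j <- which(!d_used &
               vapply(db, `[[`, integer(1), "head_id") == pb[[i]]$head_id &
               vapply(db, function(b)
                 angle_diff(b$gantry_angle, pb[[i]]$gantry_angle), numeric(1)) <=
                 config$gantry_deg)
    if (length(j)) {
      pairs[i] <- j[1]; d_used[j[1]] <- TRUE
    } else {
      pairs[i] <- NA_integer_
    }
  }
  list(plan_beams = pb, delivered = db, pairs = pairs, d_used = d_used)
}

#' Run the full delivery verification
#'
#' Executes the whole check sequence: identity, prescription, source block,
#' plan-level beam count, then per matched beam the gantry/segment-count/
#' time checks, per-segment MLC and time checks, and the fluence map
#' comparison. Plan beams missing from the log (incomplete or interrupted
#' delivery) and extra beams in the log each fail.
#'
#' @param p the approved [plan()]
#' @param rec the [delivery_record()]
#' @param config a [tolerance_config()]
#' @param grid a [grid_spec()]; defaults to the one in `config`
#' @return a `verification` object: `results` (data frame of all check
#'   rows), `fluence` (per-beam [fluence_stats()]), `maps` (per-beam
#'   plan/delivered [fluence_map()]s), `overall` ("pass"/"fail") and
#'   `counts`
#' @export
verify_delivery <- function(p, rec, config = tolerance_config(),
                            grid = config$grid) {
  treatment_date <- rec$sources[[1]]$as_of_date
  rows <- list(check_identity(p, rec),
               check_prescription(p, rec, config),
               check_source(rec$sources, config, treatment_date))
  m <- match_beams(p, rec, config)
  rows[[length(rows) + 1L]] <-
    compare_exact("plan", "Number of beams", length(m$plan_beams),
                  length(m$delivered))
  fl_stats <- list(); fl_maps <- list()
  for (i in seq_along(m$plan_beams)) {
    pb <- m$plan_beams[[i]]
    j <- m$pairs[i]
    if (is.na(j)) {
      rows[[length(rows) + 1L]] <-
        check_row("beam", sprintf("Beam delivered [beam %s]", pb$beam_id),
                  "delivered", "missing (interruption / incomplete delivery)",
                  "exact", "fail")
      next
    }
    db <- m$delivered[[j]]
    day_rate <- head_day_rate(rec$sources, db$head_id)
    rows[[length(rows) + 1L]] <- check_beam(pb, db, day_rate, config)
    rows[[length(rows) + 1L]] <- check_segments(pb, db, day_rate, config)
    fl <- check_beam_fluence(pb, db, day_rate, grid, config)
    rows[[length(rows) + 1L]] <- fl$result
    fl_stats[[pb$beam_id]] <- fl$stats
    fl_maps[[pb$beam_id]] <- list(plan = fl$plan_map,
                                  delivered = fl$delivered_map)
  }
  for (j in which(!m$d_used)) {
    rows[[length(rows) + 1L]] <-
      check_row("beam",
                sprintf("Unexpected beam [beam %s]", m$delivered[[j]]$beam_id),
                "absent", "delivered", "exact", "fail")
  }
  results <- bind_rows_df(rows)
  counts <- c(n_pass = sum(results$status == "pass"),
              n_fail = sum(results$status == "fail"),
              n_warn = sum(results$status == "warn"))
  structure(list(results = results, fluence = fl_stats, maps = fl_maps,
                 overall = if (counts[["n_fail"]] > 0) "fail" else "pass",
                 counts = counts, treatment_date = treatment_date),
            class = "verification")
}

#' @export
print.verification <- function(x, ...) {
  cat(sprintf("Delivery verification: %s (%d pass, %d fail, %d warn)\n",
              toupper(x$overall), x$counts[["n_pass"]], x$counts[["n_fail"]],
              x$counts[["n_warn"]]))
  bad <- x$results[x$results$status != "pass", , drop = FALSE]
  if (nrow(bad)) {
    cat("Findings:\n")
    for (i in seq_len(nrow(bad)))
      cat(sprintf("  [%s] %s: %s (planned %s, delivered %s, tol %s)\n",
                  bad$status[i], bad$category[i], bad$item[i],
                  bad$planned[i], bad$delivered[i], bad$tolerance[i]))
  }
  for (id in names(x$fluence)) {
    s <- x$fluence[[id]]
    cat(sprintf("  fluence %s: pass rate %s%%, mean %.4f s, max %.4f s, SD %.4f s\n",
                id, ifelse(is.na(s$pass_rate), "NA", sprintf("%.1f", s$pass_rate)),
                s$mean_diff, s$max_diff, s$sd_diff))
  }
  invisible(x)
}
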