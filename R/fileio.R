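# Plan-overview and delivery-log file dialect.
#
# Line-oriented `KEY = value` entries inside `[SECTION]` blocks, UTF-8,
# full-line `#` comments, and a mandatory `FORMAT_VERSION = 1` header
# before the first section. Leaf pairs are 30 lines `LEAF i = left right`
# (cm at isocenter). Times carry 3 decimals (ms), positions 2 (0.1 mm),
# angles 3, dose rates and strengths 6, so writing and re-parsing is exact.

FORMAT_VERSION <- 1L

#' Round a value to the file dialect's decimal resolution
#'
#' Returns the double that `sprintf("%.*f")` serialization will reproduce
#' exactly, so in-memory objects built at dialect resolution round-trip
#' through write/parse with no drift.
#' @param x numeric
#' @param digits decimal places
#' @return rounded numeric
#' @export
round_dec <- function(x, digits) {
  as.numeric(sprintf("%.*f", digits, x))
}

fmt_time <- function(x) sprintf("%.3f", x)
fmt_pos  <- function(x) sprintf("%.2f", x)
fmt_ang  <- function(x) sprintf("%.3f", x)
fmt_rate <- function(x) sprintf("%.6f", x)

parse_error <- function(line, fmt, ...) {
  stop(sprintf("parse error at line %d: %s", line, sprintf(fmt, ...)),
       call. = FALSE)
}

# --- tokenizer -------------------------------------------------------------

tokenize_doc <- function(text) {
  lines <- strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE)[[1]]
  sections <- list()
  header <- list()
  cur <- NULL
  flush <- function() if (!is.null(cur)) sections[[length(sections) + 1L]] <<- cur
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    if (grepl("^\\[[A-Z_]+\\]$", ln)) {
      flush()
      cur <- list(name = substr(ln, 2, nchar(ln) - 1L), line = i,
                  keys = character(), values = character(), klines = integer())
    } else if (grepl("=", ln, fixed = TRUE)) {
      pos <- regexpr("=", ln, fixed = TRUE)
      key <- trimws(substr(ln, 1L, pos - 1L))
      val <- trimws(substr(ln, pos + 1L, nchar(ln)))
      if (!nzchar(key)) parse_error(i, "empty key")
      if (is.null(cur)) {
        header[[key]] <- val
      } else {
        cur$keys <- c(cur$keys, key)
        cur$values <- c(cur$values, val)
        cur$klines <- c(cur$klines, i)
      }
    } else {
      parse_error(i, "malformed line: '%s'", ln)
    }
  }
  flush()
  v <- header[["FORMAT_VERSION"]]
  if (is.null(v)) parse_error(1L, "missing required key 'FORMAT_VERSION'")
  if (!identical(suppressWarnings(as.integer(v)), FORMAT_VERSION))
    parse_error(1L, "unsupported FORMAT_VERSION '%s' (expected %d)", v, FORMAT_VERSION)
  sections
}

sec_get <- function(sec, key, required = TRUE) {
  i <- match(key, sec$keys)
  if (is.na(i)) {
    if (required)
      parse_error(sec$line, "section [%s] missing required key '%s'", sec$name, key)
    return(NULL)
  }
  list(value = sec$values[[i]], line = sec$klines[[i]])
}

sec_chr <- function(sec, key) sec_get(sec, key)$value

sec_num <- function(sec, key) {
  e <- sec_get(sec, key)
  x <- suppressWarnings(as.numeric(e$value))
  if (is.na(x)) parse_error(e$line, "key '%s' is not numeric: '%s'", key, e$value)
  x
}

sec_int <- function(sec, key) {
  x <- sec_num(sec, key)
  if (x != round(x)) {
    e <- sec_get(sec, key)
    parse_error(e$line, "key '%s' is not an integer: '%s'", key, e$value)
  }
  as.integer(x)
}

sec_date <- function(sec, key) {
  e <- sec_get(sec, key)
  d <- tryCatch(as.Date(e$value), error = function(err) NA)
  if (is.na(d)) parse_error(e$line, "key '%s' is not a date: '%s'", key, e$value)
  d
}

only_section <- function(sections, name) {
  hits <- Filter(function(s) s$name == name, sections)
  if (length(hits) != 1L)
    parse_error(1L, "expected exactly one [%s] section, found %d", name, length(hits))
  hits[[1]]
}

sections_named <- function(sections, name) {
  Filter(function(s) s$name == name, sections)
}

parse_leaf_pairs <- function(sec, context) {
  is_leaf <- grepl("^LEAF [0-9]+$", sec$keys)
  n <- sum(is_leaf)
  if (n != N_LEAF_PAIRS)
    parse_error(sec$line, "%s: expected %d LEAF lines, found %d",
                context, N_LEAF_PAIRS, n)
  idx <- as.integer(sub("^LEAF ", "", sec$keys[is_leaf]))
  vals <- sec$values[is_leaf]
  klines <- sec$klines[is_leaf]
  if (!setequal(idx, seq_len(N_LEAF_PAIRS)))
    parse_error(sec$line, "%s: LEAF indices must be 1..%d", context, N_LEAF_PAIRS)
  out <- vector("list", N_LEAF_PAIRS)
  for (j in seq_along(idx)) {
    parts <- strsplit(trimws(vals[[j]]), "[[:space:]]+")[[1]]
    if (length(parts) != 2L)
      parse_error(klines[[j]], "%s: LEAF %d must be 'left right'", context, idx[[j]])
    lr <- suppressWarnings(as.numeric(parts))
    if (any(is.na(lr)))
      parse_error(klines[[j]], "%s: LEAF %d has non-numeric position", context, idx[[j]])
    out[[idx[[j]]]] <- leaf_pair(idx[[j]], lr[[1]], lr[[2]])
  }
  out
}

parse_beam_sections <- function(sections, with_group) {
  beam_secs <- sections_named(sections, "BEAM")
  seg_secs <- sections_named(sections, "SEGMENT")
  if (!length(beam_secs)) parse_error(1L, "no [BEAM] section found")
  segs_by_beam <- list()
  for (sec in seg_secs) {
    bid <- sec_chr(sec, "BEAM")
    k <- sec_int(sec, "INDEX")
    ctx <- sprintf("segment %d of beam '%s'", k, bid)
    sg <- segment(k, sec_num(sec, "TIME"), parse_leaf_pairs(sec, ctx))
    segs_by_beam[[bid]] <- c(segs_by_beam[[bid]], list(sg))
  }
  beams <- list()
  groups <- integer()
  for (sec in beam_secs) {
    bid <- sec_chr(sec, "ID")
    n_declared <- sec_int(sec, "SEGMENTS")
    segs <- segs_by_beam[[bid]]
    if (length(segs) != n_declared)
      parse_error(sec$line, "beam '%s' declares %d segments, found %d",
                  bid, n_declared, length(segs))
    segs <- segs[order(vapply(segs, `[[`, integer(1), "segment_index"))]
    beams[[length(beams) + 1L]] <-
      beam(bid, sec_int(sec, "HEAD"), sec_num(sec, "GANTRY"), segs)
    groups <- c(groups, if (with_group) sec_int(sec, "GROUP") else NA_integer_)
  }
  list(beams = beams, groups = groups)
}

# --- plan overview ---------------------------------------------------------

#' Parse a plan overview document
#'
#' @param text the document, either a single string or a character vector
#'   of lines
#' @return a [plan()]
#' @export
parse_plan_overview <- function(text) {
  sections <- tokenize_doc(text)
  pa <- only_section(sections, "PATIENT")
  pr <- only_section(sections, "PRESCRIPTION")
  pl <- only_section(sections, "PLAN")
  patient <- patient_info(sec_chr(pa, "NAME"), sec_chr(pa, "ID"))
  rx <- prescription(sec_chr(pr, "NAME"), sec_num(pr, "DOSE_GY"),
                     sec_int(pr, "FRACTIONS"), sec_chr(pr, "PTV"))
  pb <- parse_beam_sections(sections, with_group = TRUE)
  grp_ids <- unique(pb$groups)
  beam_groups <- lapply(grp_ids, function(g)
    beam_group(g, pb$beams[pb$groups == g]))
  plan(patient, rx, sec_chr(pl, "NAME"), sec_date(pl, "DATE"),
       beam_groups, sec_num(pl, "NOMINAL_DOSE_RATE"))
}

#' Serialize a plan to the plan-overview dialect
#' @param p a [plan()]
#' @return a single string (the document)
#' @export
write_plan_overview <- function(p) {
  stopifnot(inherits(p, "plan"))
  out <- c(sprintf("FORMAT_VERSION = %d", FORMAT_VERSION),
           "[PATIENT]",
           sprintf("NAME = %s", p$patient$name),
           sprintf("ID = %s", p$patient$patient_id),
           "[PRESCRIPTION]",
           sprintf("NAME = %s", p$prescription$prescription_name),
           sprintf("DOSE_GY = %s", fmt_time(p$prescription$dose_per_fraction)),
           sprintf("FRACTIONS = %d", p$prescription$n_fractions),
           sprintf("PTV = %s", p$prescription$ptv_name),
           "[PLAN]",
           sprintf("NAME = %s", p$plan_name),
           sprintf("DATE = %s", format(p$plan_date)),
           sprintf("NOMINAL_DOSE_RATE = %s", fmt_rate(p$nominal_dose_rate)))
  for (g in p$beam_groups) {
    for (b in g$beams) {
      out <- c(out, write_beam_lines(b, group = g$group_index))
    }
  }
  paste(out, collapse = "\n")
}

write_beam_lines <- function(b, group = NULL) {
  out <- c("[BEAM]",
           sprintf("ID = %s", b$beam_id),
           if (!is.null(group)) sprintf("GROUP = %d", group),
           sprintf("HEAD = %d", b$head_id),
           sprintf("GANTRY = %s", fmt_ang(b$gantry_angle)),
           sprintf("SEGMENTS = %d", length(b$segments)))
  for (sg in b$segments) {
    out <- c(out, "[SEGMENT]",
             sprintf("BEAM = %s", b$beam_id),
             sprintf("INDEX = %d", sg$segment_index),
             sprintf("TIME = %s", fmt_time(sg$beam_on_time)),
             vapply(sg$leaf_pairs, function(lp)
               sprintf("LEAF %d = %s %s", lp$pair_index,
                       fmt_pos(lp$left_x), fmt_pos(lp$right_x)),
               character(1)))
  }
  out
}

# --- delivery log ----------------------------------------------------------

#' Parse a delivery log document
#' @param text the document, a single string or character vector of lines
#' @return a [delivery_record()]
#' @export
parse_delivery_log <- function(text) {
  sections <- tokenize_doc(text)
  pa <- only_section(sections, "PATIENT")
  pr <- only_section(sections, "PRESCRIPTION")
  fr <- only_section(sections, "FRACTION")
  patient <- patient_info(sec_chr(pa, "NAME"), sec_chr(pa, "ID"))
  rx <- prescription(sec_chr(pr, "NAME"), sec_num(pr, "DOSE_GY"),
                     sec_int(pr, "FRACTIONS"), sec_chr(pr, "PTV"))
  src_secs <- sections_named(sections, "SOURCE")
  if (length(src_secs) != 3L)
    parse_error(1L, "source info absent or incomplete: expected 3 [SOURCE] sections, found %d",
                length(src_secs))
  sources <- lapply(src_secs, function(sec)
    source_info(sec_int(sec, "HEAD"), sec_chr(sec, "SERIAL"),
                sec_date(sec, "CALIBRATION_DATE"),
                sec_num(sec, "CALIBRATION_STRENGTH"),
                sec_num(sec, "CALIBRATION_DOSE_RATE"),
                sec_num(sec, "DECAYED_STRENGTH"),
                sec_num(sec, "DECAYED_DOSE_RATE"),
                sec_date(sec, "AS_OF_DATE")))
  ord <- order(vapply(sources, `[[`, integer(1), "head_id"))
  pb <- parse_beam_sections(sections, with_group = FALSE)
  interruptions <- lapply(sections_named(sections, "INTERRUPT"), function(sec) {
    e <- sec_get(sec, "TIMES")
    times <- suppressWarnings(as.numeric(strsplit(trimws(e$value),
                                                  "[[:space:]]+")[[1]]))
    if (!length(times) || any(is.na(times)))
      parse_error(e$line, "TIMES must be one or more numbers")
    list(beam_id = sec_chr(sec, "BEAM"),
         segment_index = sec_int(sec, "SEGMENT"),
         partial_times = times)
  })
  delivery_record(patient, rx, sec_chr(fr, "PLAN"), sec_int(fr, "NUMBER"),
                  pb$beams, sources[ord], interruptions)
}

#' Serialize a delivery record to the log dialect
#' @param rec a [delivery_record()]
#' @return a single string (the document)
#' @export
write_delivery_log <- function(rec) {
  stopifnot(inherits(rec, "delivery_record"))
  out <- c(sprintf("FORMAT_VERSION = %d", FORMAT_VERSION),
           "[PATIENT]",
           sprintf("NAME = %s", rec$patient$name),
           sprintf("ID = %s", rec$patient$patient_id),
           "[PRESCRIPTION]",
           sprintf("NAME = %s", rec$prescription$prescription_name),
           sprintf("DOSE_GY = %s", fmt_time(rec$prescription$dose_per_fraction)),
           sprintf("FRACTIONS = %d", rec$prescription$n_fractions),
           sprintf("PTV = %s", rec$prescription$ptv_name),
           "[FRACTION]",
           sprintf("PLAN = %s", rec$plan_name),
           sprintf("NUMBER = %d", rec$fraction_number))
  for (s in rec$sources) {
    out <- c(out, "[SOURCE]",
             sprintf("HEAD = %d", s$head_id),
             sprintf("SERIAL = %s", s$serial),
             sprintf("CALIBRATION_DATE = %s", format(s$calibration_date)),
             sprintf("CALIBRATION_STRENGTH = %s", fmt_rate(s$calibration_strength)),
             sprintf("CALIBRATION_DOSE_RATE = %s", fmt_rate(s$calibration_dose_rate)),
             sprintf("DECAYED_STRENGTH = %s", fmt_rate(s$decayed_strength)),
             sprintf("DECAYED_DOSE_RATE = %s", fmt_rate(s$decayed_dose_rate)),
             sprintf("AS_OF_DATE = %s", format(s$as_of_date)))
  }
  for (b in rec$delivered_beams)
    out <- c(out, write_beam_lines(b))
  for (itr in rec$interruptions)
    out <- c(out, "[INTERRUPT]",
             sprintf("BEAM = %s", itr$beam_id),
             sprintf("SEGMENT = %d", itr$segment_index),
             sprintf("TIMES = %s", paste(fmt_time(itr$partial_times), collapse = " ")))
  paste(out, collapse = "\n")
}

# --- screen captures -------------------------------------------------------

#' Load IGRT setup screen captures for report embedding
#'
#' Captures are embedded in the report verbatim; their content is never
#' analyzed. A missing file produces a warning and is skipped, so a lost
#' capture can never block delivery verification.
#'
#' @param paths character vector of PNG paths (possibly empty)
#' @return list of loaded captures, each `list(path, image)` with `image`
#'   the PNG array
#' @export
load_screen_captures <- function(paths) {
  out <- list()
  for (p in paths) {
    if (!file.exists(p)) {
      warning(sprintf("screen capture missing: %s", p), call. = FALSE)
      next
    }
    out[[length(out) + 1L]] <- list(path = p, image = png::readPNG(p))
  }
  out
}
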