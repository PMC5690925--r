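# Integrated primary fluence maps: F(x,y) = sum_k t_k * A_k(x,y), with
# A_k rasterized from the 30 MLC leaf pairs on the isocenter plane and
# F in seconds.

grid_axes <- function(grid) {
  nx <- as.integer(round(grid$x_extent / grid$spacing))
  ny <- as.integer(round(grid$y_extent / grid$spacing))
  list(nx = nx, ny = ny,
       x = -grid$x_extent / 2 + (seq_len(nx) - 0.5) * grid$spacing,
       y = -grid$y_extent / 2 + (seq_len(ny) - 0.5) * grid$spacing)
}

leaf_stack_bottom <- function(grid) -N_LEAF_PAIRS * grid$leaf_width / 2

same_grid <- function(a, b) {
  isTRUE(all.equal(unlist(a[c("spacing", "x_extent", "y_extent", "leaf_width")]),
                   unlist(b[c("spacing", "x_extent", "y_extent", "leaf_width")]),
                   tolerance = 1e-9))
}

#' Rasterize an MLC aperture onto the isocenter-plane grid
#'
#' Area-weighted (anti-aliased) rasterization: each pixel's value is the
#' fraction of its area inside the open aperture, so pixels straddling a
#' leaf tip or a leaf-row boundary get fractional coverage. This keeps the
#' integral of the map equal to the analytic open area and makes the
#' downstream pass rate insensitive to grid phase.
#'
#' @param leaf_pairs list of 30 [leaf_pair()] in stack order
#' @param grid a [grid_spec()]; must cover the full leaf stack
#' @return numeric matrix (rows = y, cols = x) of coverage in [0, 1]
#' @export
rasterize_aperture <- function(leaf_pairs, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  if (length(leaf_pairs) != N_LEAF_PAIRS)
    stop_invalid("expected %d leaf pairs, got %d", N_LEAF_PAIRS, length(leaf_pairs))
  ax <- grid_axes(grid)
  s <- grid$spacing
  xlo <- ax$x - s / 2; xhi <- ax$x + s / 2
  ylo <- ax$y - s / 2; yhi <- ax$y + s / 2
  y0 <- leaf_stack_bottom(grid)
  m <- matrix(0, nrow = ax$ny, ncol = ax$nx)
  for (lp in leaf_pairs) {
    if (lp$right_x - lp$left_x <= 0) next
    band_lo <- y0 + (lp$pair_index - 1L) * grid$leaf_width
    band_hi <- band_lo + grid$leaf_width
    cov_y <- pmax(0, pmin(yhi, band_hi) - pmax(ylo, band_lo)) / s
    cov_x <- pmax(0, pmin(xhi, lp$right_x) - pmax(xlo, lp$left_x)) / s
    nzy <- which(cov_y > 0)
    if (length(nzy))
      m[nzy, ] <- m[nzy, , drop = FALSE] + outer(cov_y[nzy], cov_x)
  }
  # leaf bands are disjoint, so coverage can only exceed 1 by rounding
  pmin(m, 1)
}

#' Analytic open area of an MLC aperture
#'
#' Sum over pairs of (right - left) * leaf width, optionally clipped to a
#' grid's x extent. Used as the conservation reference for the rasterizer.
#'
#' @param leaf_pairs list of 30 [leaf_pair()]
#' @param grid optional [grid_spec()]; when given, openings are clipped to
#'   the grid's x extent
#' @return open area, cm^2
#' @export
aperture_open_area <- function(leaf_pairs, grid = NULL) {
  lw <- if (is.null(grid)) 1.05 else grid$leaf_width
  half <- if (is.null(grid)) Inf else grid$x_extent / 2
  sum(vapply(leaf_pairs, function(lp) {
    w <- max(0, min(lp$right_x, half) - max(lp$left_x, -half))
    w * lw
  }, numeric(1)))
}

#' Compose the integrated primary fluence map of a beam
#'
#' F(x,y) = sum over segments k of t_k * A_k(x,y), where t_k is the
#' segment beam-on time in seconds and A_k the rasterized aperture
#' coverage. The map's units are seconds of open beam time.
#'
#' @param segments non-empty list of [segment()] objects
#' @param grid a [grid_spec()]
#' @return a [fluence_map()]
#' @export
compose_fluence <- function(segments, grid) {
  if (length(segments) < 1L)
    stop_invalid("compose_fluence needs at least one segment")
  ax <- grid_axes(grid)
  vals <- matrix(0, nrow = ax$ny, ncol = ax$nx)
  for (sg in segments)
    if (sg$beam_on_time > 0)
      vals <- vals + sg$beam_on_time * rasterize_aperture(sg$leaf_pairs, grid)
  fluence_map(vals, grid)
}

#' Per-beam fluence difference statistics
#' @param mean_diff mean of (delivered - plan) over evaluated pixels, s
#' @param max_diff maximum absolute difference over evaluated pixels, s
#' @param sd_diff standard deviation of (delivered - plan), s
#' @param pass_rate percent of evaluated pixels passing; NA when no pixel
#'   is evaluated
#' @param n_evaluated number of evaluated pixels
#' @return a `fluence_stats` object
#' @export
fluence_stats <- function(mean_diff, max_diff, sd_diff, pass_rate,
                          n_evaluated) {
  if (!is.na(pass_rate) && (pass_rate < 0 || pass_rate > 100))
    stop_invalid("pass_rate must be in [0, 100]")
  if (n_evaluated < 0) stop_invalid("n_evaluated must be >= 0")
  structure(list(mean_diff = mean_diff, max_diff = max_diff,
                 sd_diff = sd_diff, pass_rate = pass_rate,
                 n_evaluated = as.integer(n_evaluated)),
            class = "fluence_stats")
}

#' @export
print.fluence_stats <- function(x, ...) {
  cat(sprintf("Fluence diff: mean %.4f s, max %.4f s, SD %.4f s; pass %s%% (n=%d)\n",
              x$mean_diff, x$max_diff, x$sd_diff,
              ifelse(is.na(x$pass_rate), "NA", sprintf("%.1f", x$pass_rate)),
              x$n_evaluated))
  invisible(x)
}

#' Compare a delivered fluence map against the planned one
#'
#' Pixels with planned intensity strictly greater than `low_cut` times the
#' planned map maximum are evaluated; an evaluated pixel passes when the
#' absolute plan-vs-delivered difference is strictly less than `pass_frac`
#' times that maximum. The pass rate is the percentage of evaluated pixels
#' that pass. Mean, maximum (absolute) and SD of the difference are
#' computed over the evaluated set.
#'
#' A planned map that is zero everywhere (or has no pixel above the cutoff)
#' yields `pass_rate = NA` and `n_evaluated = 0`; callers report this as a
#' warning rather than a failure.
#'
#' @param plan_fm planned [fluence_map()]
#' @param delivered_fm delivered [fluence_map()] on the identical grid,
#'   with times on the nominal (plan) scale
#' @param low_cut evaluation cutoff, fraction of the planned maximum
#' @param pass_frac per-pixel pass threshold, fraction of the planned maximum
#' @return a [fluence_stats()]
#' @export
fluence_compare <- function(plan_fm, delivered_fm, low_cut = 0.10,
                            pass_frac = 0.02) {
  stopifnot(inherits(plan_fm, "fluence_map"), inherits(delivered_fm, "fluence_map"))
  if (!same_grid(plan_fm$grid, delivered_fm$grid) ||
      !identical(dim(plan_fm$values), dim(delivered_fm$values)))
    stop_invalid("fluence maps are on different grids")
  p <- plan_fm$values; d <- delivered_fm$values
  pmax_val <- max(p)
  eval_mask <- p > low_cut * pmax_val
  n_eval <- sum(eval_mask)
  if (pmax_val <= 0 || n_eval == 0L)
    return(fluence_stats(NA_real_, NA_real_, NA_real_, NA_real_, 0L))
  diff <- (d - p)[eval_mask]
  passes <- abs(diff) < pass_frac * pmax_val
  fluence_stats(mean_diff = mean(diff),
                max_diff = max(abs(diff)),
                sd_diff = stats::sd(diff),
                pass_rate = 100 * sum(passes) / n_eval,
                n_evaluated = n_eval)
}
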