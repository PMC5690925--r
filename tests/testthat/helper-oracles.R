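# Independent oracles used to verify the implementation. These deliberately
# avoid the package's rasterization / comparison code paths: coverage is
# estimated by brute-force supersampling of the aperture indicator, and
# pass-rate statistics by direct pixel counting.

# Fractional coverage of one pixel by supersampling the aperture indicator
# on a sub_step grid (default 0.01 mm = 0.001 cm sub-pixels).
oracle_pixel_coverage <- function(leaf_pairs, grid, row, col,
                                  sub_step = 0.001) {
  s <- grid$spacing
  xc <- -grid$x_extent / 2 + (col - 0.5) * s
  yc <- -grid$y_extent / 2 + (row - 0.5) * s
  n <- max(1L, round(s / sub_step))
  off <- -s / 2 + (seq_len(n) - 0.5) * s / n
  xs <- xc + off
  ys <- yc + off
  y0 <- -30 * grid$leaf_width / 2
  lefts <- vapply(leaf_pairs, `[[`, numeric(1), "left_x")
  rights <- vapply(leaf_pairs, `[[`, numeric(1), "right_x")
  inside <- 0
  for (y in ys) {
    ip <- floor((y - y0) / grid$leaf_width) + 1
    if (ip < 1 || ip > 30) next
    inside <- inside + sum(xs > lefts[ip] & xs < rights[ip])
  }
  inside / (n * n)
}

# Direct pixel-count pass-rate statistics (the printed criterion applied
# literally, written independently of fluence_compare()).
oracle_fluence_stats <- function(plan_vals, del_vals, low_cut, pass_frac) {
  m <- max(plan_vals)
  n_eval <- 0L; n_pass <- 0L; diffs <- numeric()
  for (i in seq_along(plan_vals)) {
    if (plan_vals[i] > low_cut * m) {
      n_eval <- n_eval + 1L
      d <- del_vals[i] - plan_vals[i]
      diffs <- c(diffs, d)
      if (abs(d) < pass_frac * m) n_pass <- n_pass + 1L
    }
  }
  list(n_evaluated = n_eval,
       pass_rate = if (n_eval) 100 * n_pass / n_eval else NA_real_,
       mean_diff = if (n_eval) mean(diffs) else NA_real_,
       max_diff = if (n_eval) max(abs(diffs)) else NA_real_)
}

# Full rectangular aperture: every pair open [left, right].
open_pairs <- function(left, right) {
  lapply(1:30, function(i) leaf_pair(i, left, right))
}

closed_pairs <- function(at = 0) {
  lapply(1:30, function(i) leaf_pair(i, at, at))
}
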