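test_that("rasterization covers open fields and ignores closed ones", {
  g <- grid_spec()
  m <- rasterize_aperture(open_pairs(-5, 5), g)
  # pixel at the isocenter is fully inside the aperture
  ctr <- round(dim(m) / 2)
  expect_equal(m[ctr[1], ctr[2]], 1.0)
  expect_true(all(m >= 0 & m <= 1))
  expect_equal(sum(rasterize_aperture(closed_pairs(), g)), 0)
})

test_that("a leaf tip on a pixel center yields half coverage", {
  g <- grid_spec()  # pixel centers at ..., 1.9, 2.0, 2.1, ... cm
  m <- rasterize_aperture(open_pairs(-5, 2.0), g)
  col <- which.min(abs(-g$x_extent / 2 + (seq_len(ncol(m)) - 0.5) * g$spacing - 2.0))
  row <- round(nrow(m) / 2)
  expect_equal(m[row, col], 0.5)
  # supersampling oracle agrees
  expect_equal(oracle_pixel_coverage(open_pairs(-5, 2.0), g, row, col), 0.5,
               tolerance = 1e-2)
})

test_that("rasterization agrees with the supersampling oracle", {
  set.seed(7)
  g <- grid_spec()
  for (rep in 1:4) {
    p <- generate_plan(rep, 1, 1, 1)
    lps <- plan_beams(p)[[1]]$segments[[1]]$leaf_pairs
    m <- rasterize_aperture(lps, g)
    rows <- sample(nrow(m), 12)
    cols <- sample(ncol(m), 12)
    for (i in seq_along(rows)) {
      expect_equal(m[rows[i], cols[i]],
                   oracle_pixel_coverage(lps, g, rows[i], cols[i]),
                   tolerance = 1e-2)
    }
  }
})

test_that("fluence composition is linear in segment times", {
  g <- fast_grid()
  ap <- open_pairs(-5, 5)
  two <- list(segment(1, 3, ap), segment(2, 7, ap))
  fm <- compose_fluence(two, g)
  ctr <- round(dim(fm$values) / 2)
  expect_equal(fm$values[ctr[1], ctr[2]], 10)
  doubled <- compose_fluence(list(segment(1, 6, ap), segment(2, 14, ap)), g)
  expect_equal(doubled$values, 2 * fm$values)
  expect_equal(max(compose_fluence(list(segment(1, 0, ap)), g)$values), 0)
  expect_error(compose_fluence(list(), g), "at least one segment")
})

test_that("map integral conserves time-weighted open area", {
  set.seed(11)
  g <- grid_spec()
  for (rep in 1:10) {
    p <- generate_plan(100 + rep, 1, 1, 2)
    segs <- plan_beams(p)[[1]]$segments
    fm <- compose_fluence(segs, g)
    analytic <- sum(vapply(segs, function(sg)
      sg$beam_on_time * aperture_open_area(sg$leaf_pairs, g), numeric(1)))
    expect_equal(sum(fm$values) * g$spacing^2, analytic,
                 tolerance = 1e-3)
  }
})

test_that("the pass criterion applies the printed thresholds strictly", {
  g <- fast_grid()
  ap <- open_pairs(-6, 6)
  plan_fm <- compose_fluence(list(segment(1, 10, ap)), g)
  # identity: everything passes with zero differences
  s <- fluence_compare(plan_fm, plan_fm)
  expect_equal(s$pass_rate, 100)
  expect_equal(s$mean_diff, 0)
  expect_equal(s$max_diff, 0)
  expect_equal(s$sd_diff, 0)
  # a uniform +3% of max offset fails every evaluated pixel
  shifted <- fluence_map(plan_fm$values + 0.03 * max(plan_fm$values), g)
  expect_equal(fluence_compare(plan_fm, shifted)$pass_rate, 0)
  # a +1.9% offset is under the 2% threshold everywhere
  under <- fluence_map(plan_fm$values + 0.019 * max(plan_fm$values), g)
  expect_equal(fluence_compare(plan_fm, under)$pass_rate, 100)
})

test_that("checkerboard half-shift yields a 50 percent pass rate", {
  g <- fast_grid()
  v <- matrix(10, 63, 63)
  plan_fm <- fluence_map(v, g)
  chk <- outer(1:63, 1:63, function(i, j) (i + j) %% 2 == 0)
  d <- v
  d[chk] <- d[chk] + 0.03 * max(v)
  del_fm <- fluence_map(d, g)
  s <- fluence_compare(plan_fm, del_fm)
  o <- oracle_fluence_stats(v, d, 0.10, 0.02)
  expect_equal(s$pass_rate, o$pass_rate)
  expect_equal(s$pass_rate, 100 * sum(!chk) / length(chk))
  expect_equal(s$n_evaluated, o$n_evaluated)
  expect_equal(s$mean_diff, o$mean_diff)
  expect_equal(s$max_diff, o$max_diff)
})

test_that("pass rate ignores sub-threshold uniform offsets", {
  set.seed(5)
  g <- fast_grid()
  p <- generate_plan(55, 1, 1, 2)
  fm <- compose_fluence(plan_beams(p)[[1]]$segments, g)
  for (frac in c(0.001, 0.01, 0.019)) {
    shifted <- fluence_map(fm$values + frac * max(fm$values), g)
    expect_equal(fluence_compare(fm, shifted)$pass_rate, 100)
  }
})

test_that("degenerate and mismatched inputs are handled", {
  g <- fast_grid()
  zero <- compose_fluence(list(segment(1, 5, closed_pairs())), g)
  s <- fluence_compare(zero, zero)
  expect_true(is.na(s$pass_rate))
  expect_identical(s$n_evaluated, 0L)
  other <- compose_fluence(list(segment(1, 5, open_pairs(-2, 2))), grid_spec())
  full <- compose_fluence(list(segment(1, 5, open_pairs(-2, 2))), g)
  expect_error(fluence_compare(full, other), "different grids")
})
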