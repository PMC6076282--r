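# Rasterization, the accuracy/precision regression and the residual
# correlogram.

test_that("rasterization reproduces a hand tally and conserves counts and marks", {
  w <- rect_window("c1", 30, 30)
  # 12 trees on a 3x3 grid of 10 m cells; cell (ix, iy) indexed from the
  # lower-left corner
  tr <- data.frame(
    tree_id = sprintf("t%02d", 1:12), concession_id = "c1",
    x = c(1, 2, 3, 15, 16, 25, 5, 15, 25, 5, 15, 25.5),
    y = c(1, 2, 3, 5, 6, 5, 15, 15, 15, 25, 25, 29),
    seed_kg = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12)
  )
  pat <- marked_pattern(tr, w)
  cells <- rasterize_pattern(pat, "seed", 10)
  expect_equal(nrow(cells), 9L)
  tally <- c("0,0" = 3L, "1,0" = 2L, "2,0" = 1L,
             "0,1" = 1L, "1,1" = 1L, "2,1" = 1L,
             "0,2" = 1L, "1,2" = 1L, "2,2" = 1L)
  key <- sprintf("%d,%d", floor(cells$cx / 10), floor(cells$cy / 10))
  expect_equal(cells$n_trees[match(names(tally), key)], unname(tally))
  expect_equal(sum(cells$n_trees), 12L)
  expect_equal(sum(cells$measured), sum(tr$seed_kg))
  # expected = count x grand mean, exactly
  expect_equal(cells$expected, cells$n_trees * mean(tr$seed_kg))
  expect_equal(attr(cells, "cell_area_ha"), 0.01)

  # one tree whose mark equals the grand mean: measured == expected
  pat1 <- make_pattern(x = 10, y = 10, seed_kg = 4,
                       window = rect_window("c1", 200, 200))
  c1 <- rasterize_pattern(pat1, "seed", 200)
  expect_equal(c1$measured[c1$n_trees == 1], c1$expected[c1$n_trees == 1])
})

test_that("partial boundary cells are excluded at full min_coverage", {
  # 25 m cells on a 30 m window: only the first 25 m column/row cells are
  # fully covered
  w <- rect_window("c1", 30, 30)
  pat <- marked_pattern(
    data.frame(tree_id = "a", concession_id = "c1", x = 1, y = 1, seed_kg = 1),
    w
  )
  cells <- rasterize_pattern(pat, "seed", 25, min_coverage = 1)
  expect_equal(nrow(cells), 1L)
  cells2 <- rasterize_pattern(pat, "seed", 25, min_coverage = 0.03)
  expect_equal(nrow(cells2), 4L)  # corner cell has coverage 25/625 = 0.04
  expect_warning(rasterize_pattern(pat, "seed", 100, min_coverage = 0.05),
                 "degenerate")
})

test_that("scaling regression recovers exact slopes and matches the OLS oracle", {
  w <- rect_window("c1", 400, 400)
  p <- runif_points(120, 400, 400, seed = 61)
  pat <- make_pattern(p$x, p$y, seed_kg = runif(120, 1, 9), window = w)
  cells <- rasterize_pattern(pat, "seed", 50)

  # measured == expected gives slope 1, R^2 = 1
  perfect <- cells
  perfect$measured_ha <- perfect$expected_ha
  reg <- suppressWarnings(scaling_regression(perfect))  # exact fit
  expect_equal(reg$slope, 1, tolerance = 1e-12)
  expect_equal(reg$r_squared, 1, tolerance = 1e-12)

  half <- cells
  half$measured_ha <- 0.5 * half$expected_ha
  reg2 <- suppressWarnings(scaling_regression(half))
  expect_equal(reg2$slope, 0.5, tolerance = 1e-12)
  expect_equal(reg2$r_squared, 1, tolerance = 1e-12)

  # noisy cells against the closed-form OLS oracle, both modes
  reg3 <- scaling_regression(cells, "through_origin")
  oracle <- bf_ols(cells$expected_ha, cells$measured_ha, intercept = FALSE)
  expect_equal(reg3$slope, oracle$slope, tolerance = 1e-10)
  expect_equal(reg3$r_squared, oracle$r2, tolerance = 1e-10)
  expect_equal(unname(reg3$ci), oracle$ci, tolerance = 1e-10)
  expect_true(reg3$ci[1] <= reg3$slope && reg3$slope <= reg3$ci[2])

  nz <- cells[cells$n_trees > 0, ]
  reg4 <- scaling_regression(cells, "with_intercept")
  oracle4 <- bf_ols(nz$expected_ha, nz$measured_ha, intercept = TRUE)
  expect_equal(reg4$slope, oracle4$slope, tolerance = 1e-10)
  expect_equal(reg4$r_squared, oracle4$r2, tolerance = 1e-10)

  same <- cells
  same$expected_ha <- 1
  expect_error(scaling_regression(same), "zero variance")
})

test_that("arc-second cells have the advertised metric size", {
  wh <- cell_size_m(3.33, lat_deg = -12)
  area_ha <- prod(wh) / 1e4
  expect_lt(abs(area_ha - 1), 0.05)  # ~1 ha within 5%
  # east-west width carries the cos(latitude) factor
  expect_equal(unname(wh[1] / wh[2]), cos(12 * pi / 180), tolerance = 1e-12)
  expect_equal(unname(cell_size_m(1)[2]), pi / 648000 * 6371000, tolerance = 1e-12)
})

test_that("location-independent marks give slopes compatible with 1 at every size", {
  pat <- simulate_scenario(scenario_presets()$null, seed = 71,
                           n_concessions = 3, area_range_ha = c(150, 350))
  sc <- scaling_curve(pat, "seed",
                      scaling_config(cell_sizes_m = c(50, 100, 200, 300)))
  expect_true(all(sc$ci_lo <= 1 & sc$ci_hi >= 1))
  expect_true(all(diff(sc$cell_area_ha) > 0))
})

test_that("negative density dependence pulls fine-scale slopes below 1", {
  pat <- simulate_scenario(scenario_presets()$ddd_full, seed = 72,
                           n_concessions = 3, area_range_ha = c(150, 350))
  sc <- scaling_curve(pat, "seed",
                      scaling_config(cell_sizes_m = c(50, 100, 200, 300)))
  expect_lt(sc$slope[1], 1)
  # coarser cells move the slope toward 1 in rank terms
  expect_gt(cor(sc$cell_area_ha, sc$slope, method = "spearman"), 0)
})

test_that("the residual correlogram matches direct computation on a 4-cell fixture", {
  cells <- data.frame(cx = c(0, 10, 0, 10), cy = c(0, 0, 10, 10))
  res <- c(1, 2, 3, 5)
  out <- residual_correlogram(cells, res, breaks = c(12, 20), n_sim = 19, seed = 3)
  # bin 1 (<= 12 m): the 4 side pairs; bin 2: the 2 diagonals
  side_a <- c(1, 3, 1, 2); side_b <- c(2, 5, 3, 5)
  expect_equal(out$correlation[1], cor(c(side_a, side_b), c(side_b, side_a)),
               tolerance = 1e-12)
  diag_a <- c(1, 2); diag_b <- c(5, 3)
  expect_equal(out$correlation[2], cor(c(diag_a, diag_b), c(diag_b, diag_a)),
               tolerance = 1e-12)
  expect_equal(out$n_pairs, c(4L, 2L))
})

test_that("a smooth residual gradient is flagged in the first distance bin", {
  g <- expand.grid(cx = seq(5, 95, 10), cy = seq(5, 95, 10))
  set.seed(8)
  res <- 0.05 * (g$cx + g$cy) + rnorm(nrow(g), 0, 0.3)
  out <- residual_correlogram(g, res, breaks = seq(15, 135, 30),
                              n_sim = 99, seed = 9)
  expect_gt(out$correlation[1], 0)
  expect_true(out$significant[1])

  # spatially independent residuals stay inside the envelope almost everywhere
  set.seed(10)
  out0 <- residual_correlogram(g, rnorm(nrow(g)), breaks = seq(15, 135, 30),
                               n_sim = 99, seed = 11)
  expect_gte(mean(!out0$significant), 0.75)
})
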