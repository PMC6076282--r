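# The four mark correlation functions, their edge corrections and the
# neighbourhood Clark-Evans index.

test_that("nearest-neighbour edge rule keeps trees with edge_dist >= nn_dist", {
  w <- rect_window("c1", 100, 100)
  tr <- data.frame(
    tree_id = c("keep", "nb1", "drop"),
    concession_id = "c1",
    # "keep": 5 m from edge, neighbour 3 m away; "drop": 5 m from edge,
    # nearest neighbour ~8 m away
    x = c(5, 8, 95), y = c(50, 50, 50),
    seed_kg = 1
  )
  pat <- marked_pattern(tr, w)
  nb <- neighbour_info(pat)
  ef <- edge_filter_nn(pat, nb)
  expect_true(ef$retained[1])
  expect_false(ef$retained[3])
  expect_equal(ef$fraction_dropped, 1 / 3)  # nb1's neighbour is 3 m, edge 8 m: kept

  # brute-force application of the rule on a dense random fixture
  p <- runif_points(150, 300, 300, seed = 5)
  pat2 <- make_pattern(p$x, p$y, window = rect_window("c1", 300, 300))
  nb2 <- neighbour_info(pat2)
  oracle <- bf_nearest(pat2$trees)$nn_dist <=
    bf_boundary(pat2$trees$x, pat2$trees$y, pat2$windows$c1$boundary, step = 1e-3)
  expect_equal(edge_filter_nn(pat2, nb2)$retained, oracle)
})

test_that("nn-mean function is 1 for constant marks and matches a group-by oracle", {
  p <- runif_points(250, 1500, 1500, seed = 11)
  pat <- make_pattern(p$x, p$y, window = rect_window("c1", 1500, 1500))
  mf <- mark_correlation(pat, "seed", "nnmean", bins = "near_5", envelope = NULL)
  expect_true(all(mf$stat[mf$n > 0] == 1))
  expect_true(all(mf$flag[mf$n == 0] == "empty"))

  # marks equal to each tree's nn distance: bin means equal a direct group-by
  nb <- neighbour_info(pat)
  marks <- nb$nn_dist
  mf2 <- mark_correlation(pat, "seed", "nnmean", bins = "near_5",
                          envelope = NULL, marks = marks)
  keep <- nb$edge_dist >= nb$nn_dist
  b <- make_bins("near_5")
  for (k in seq_along(b$centers)) {
    r <- b$centers[k]
    sel <- keep & nb$nn_dist >= r - 5 & nb$nn_dist <= r + 5 &
      !(k > 1 & nb$nn_dist == r - 5)  # shared boundary belongs to lower bin
    if (any(sel)) {
      expect_equal(mf2$stat[k], mean(marks[sel]), tolerance = 1e-12)
      expect_equal(mf2$n[k], sum(sel))
    } else {
      expect_identical(mf2$flag[k], "empty")
    }
  }
})

test_that("Schlather correlation matches a hand-computed fixture", {
  # three isolated 2-tree clusters; each tree's nn is its partner at 8 m,
  # all pairs in the bin centred at 5 (h = 5)
  x <- c(50, 58, 550, 558, 1000, 1008)
  y <- rep(500, 6)
  marks <- c(1, 2, 3, 5, 10, 4)
  pat <- make_pattern(x, y, window = rect_window("c1", 1100, 1000))
  mf <- mark_correlation(pat, "seed", "schlather", bins = "near_5",
                         envelope = NULL, marks = marks)
  # ordered pairs: (1,2),(2,1),(3,4),(4,3),(5,6),(6,5)
  xi <- marks[c(1, 2, 3, 4, 5, 6)]
  yi <- marks[c(2, 1, 4, 3, 6, 5)]
  expect_equal(mf$stat[1], cor(xi, yi), tolerance = 1e-12)
  expect_equal(mf$n[1], 6L)

  # unique-pair mode keeps one orientation of each mutual pair
  mfu <- mark_correlation(pat, "seed", "schlather", bins = "near_5",
                          envelope = NULL, marks = marks, pair_mode = "unique")
  expect_equal(mfu$n[1], 3L)
  expect_equal(mfu$stat[1], cor(marks[c(1, 3, 5)], marks[c(2, 4, 6)]),
               tolerance = 1e-12)
})

test_that("Schlather correlation approaches 1 when nn pairs share marks and 0 under shuffling", {
  p <- runif_points(300, 2000, 2000, seed = 13)
  pat <- make_pattern(p$x, p$y, window = rect_window("c1", 2000, 2000))
  nb <- neighbour_info(pat)

  # impose mark equality along mutual nn pairs where consistent
  set.seed(1)
  marks <- runif(300, 1, 5)
  nnrow <- match(nb$nn_id, pat$trees$tree_id)
  for (i in seq_len(300)) {
    j <- nnrow[i]
    if (!is.na(j) && nnrow[j] == i && i < j) marks[j] <- marks[i]
  }
  mf <- mark_correlation(pat, "seed", "schlather", bins = bin_spec(75, 75),
                         envelope = NULL, marks = marks)
  expect_gt(mf$stat[1], 0.5)

  set.seed(2)
  mfs <- mark_correlation(pat, "seed", "schlather", bins = bin_spec(75, 75),
                          envelope = NULL, marks = sample(marks))
  expect_lt(abs(mfs$stat[1]), 0.25)
})

test_that("zero-variance marks leave correlation functions undefined, never 0", {
  p <- runif_points(100, 800, 800, seed = 21)
  pat <- make_pattern(p$x, p$y, window = rect_window("c1", 800, 800))
  for (fn in c("schlather", "density", "aggregation")) {
    bins <- if (fn == "schlather") bin_spec(75, 75) else bin_spec(c(50, 100), NA_real_, "cumulative")
    mf <- mark_correlation(pat, "seed", fn, bins = bins, envelope = NULL,
                           marks = rep(2, 100))
    expect_true(all(is.na(mf$stat)))
    expect_true(all(mf$flag[mf$n > 0] == "undefined"))
  }
})

test_that("density correlation equals the brute-force correlation of the count table", {
  p <- runif_points(180, 700, 700, seed = 31)
  pat <- make_pattern(p$x, p$y, window = rect_window("c1", 700, 700))
  set.seed(4)
  marks <- rlnorm(180)
  radii <- c(25, 50, 100, 150)
  mf <- mark_correlation(pat, "seed", "density",
                         bins = bin_spec(radii, NA_real_, "cumulative"),
                         envelope = NULL, marks = marks)
  cnt <- bf_counts(pat$trees, radii)
  edge <- bf_boundary(pat$trees$x, pat$trees$y, pat$windows$c1$boundary,
                      step = 1e-3)
  for (k in seq_along(radii)) {
    sel <- edge >= radii[k]
    expect_equal(mf$stat[k], cor(marks[sel], cnt[sel, k]), tolerance = 1e-9)
    expect_equal(mf$n[k], sum(sel))
  }
})

test_that("density correlation detects an imposed negative density effect", {
  pat <- simulate_scenario(scenario_config(process = "thomas"), seed = 5,
                           n_concessions = 4, area_range_ha = c(300, 600))
  cnt <- as.numeric(neighbour_counts(pat, 50))
  set.seed(6)
  marks <- exp(-0.25 * cnt) * rlnorm(n_trees(pat), 0, 0.2)
  mf <- mark_correlation(pat, "seed", "density",
                         bins = bin_spec(c(50, 100), NA_real_, "cumulative"),
                         envelope = envelope_config(n_sim = 99, seed = 8),
                         marks = marks)
  expect_lt(mf$stat[1], 0)
  expect_true(mf$significant[1])

  # location-independent marks: small correlations at all radii
  set.seed(7)
  mf0 <- mark_correlation(pat, "seed", "density",
                          bins = bin_spec(c(50, 100), NA_real_, "cumulative"),
                          envelope = NULL, marks = rlnorm(n_trees(pat)))
  expect_true(all(abs(mf0$stat) < 0.15, na.rm = TRUE))
})

test_that("Clark-Evans neighbourhood index is 2 on a square lattice and ~0 for a clump", {
  s <- 10
  g <- expand.grid(x = s * (0:20), y = s * (0:20))
  # window area chosen so concession density is exactly 1/s^2
  w <- concession_window("c1", cbind(c(-5, 205, 205, -5), c(-5, -5, 205, 205)))
  pat <- marked_pattern(
    data.frame(tree_id = sprintf("t%03d", seq_len(nrow(g))), concession_id = "c1",
               x = g$x, y = g$y, seed_kg = 1),
    w
  )
  expect_equal(pat$windows$c1$density_m2, 1 / s^2)
  centre <- which(g$x == 100 & g$y == 100)
  ce <- clark_evans_neighbourhood(pat, centre, r = 50)
  expect_true(ce$defined)
  expect_equal(ce$mean_nn_dist, s)
  expect_equal(ce$ce_index, 2)

  # tight clump: mean nearest-member distance near 0
  set.seed(9)
  cl <- data.frame(
    tree_id = c("f", paste0("m", 1:8)), concession_id = "c1",
    x = c(500, 500 + runif(8, -0.5, 0.5)),
    y = c(500, 500 + runif(8, -0.5, 0.5)),
    seed_kg = 1
  )
  patc <- marked_pattern(cl, rect_window("c1", 1000, 1000))
  cec <- clark_evans_neighbourhood(patc, "f", r = 100)
  expect_lt(cec$ce_index, 0.05)

  # eligibility: focal must be at least r from the boundary
  expect_error(clark_evans_neighbourhood(pat, centre, r = 150), "boundary")
})

test_that("Clark-Evans index is rigid-motion invariant and scale-consistent", {
  p <- runif_points(120, 400, 400, seed = 41)
  pat <- make_pattern(p$x, p$y, window = rect_window("c1", 400, 400))
  edge <- boundary_distances(pat)
  ce0 <- markddd:::ce_indices_all(pat, 60, edge)

  # rotate by 33 degrees about the window centre, same window re-centred
  th <- 33 * pi / 180
  cx <- p$x - 200; cy <- p$y - 200
  rx <- cos(th) * cx - sin(th) * cy
  ry <- sin(th) * cx + cos(th) * cy
  patr <- make_pattern(rx, ry, window = rect_window(
    "c1", 600, 600, origin = c(-300, -300)
  ))
  # window changes, so compare only focals eligible in both
  cer <- markddd:::ce_indices_all(patr, 60, boundary_distances(patr))
  both <- !is.na(ce0) & !is.na(cer)
  # density term differs (bigger window): rescale to the same rho
  ratio <- sqrt(patr$windows$c1$density_m2 / pat$windows$c1$density_m2)
  expect_equal(cer[both] / ratio, ce0[both], tolerance = 1e-10)

  # coordinate rescaling x -> 3x with r -> 3r: index unchanged
  pats <- make_pattern(3 * p$x, 3 * p$y, window = rect_window("c1", 1200, 1200))
  ces <- markddd:::ce_indices_all(pats, 180, boundary_distances(pats))
  expect_equal(ces, ce0, tolerance = 1e-10)
})

test_that("aggregation correlation equals direct Pearson on precomputed indices", {
  p <- runif_points(150, 500, 500, seed = 51)
  pat <- make_pattern(p$x, p$y, window = rect_window("c1", 500, 500))
  set.seed(10)
  marks <- rlnorm(150)
  r <- 80
  mf <- mark_correlation(pat, "seed", "aggregation",
                         bins = bin_spec(r, NA_real_, "cumulative"),
                         envelope = NULL, marks = marks)
  edge <- bf_boundary(pat$trees$x, pat$trees$y, pat$windows$c1$boundary,
                      step = 1e-3)
  ce <- vapply(seq_len(150), function(i) {
    if (edge[i] < r) return(NA_real_)
    out <- clark_evans_neighbourhood(pat, i, r)
    if (out$defined) out$ce_index else NA_real_
  }, 0)
  sel <- !is.na(ce)
  expect_equal(mf$stat[1], cor(marks[sel], ce[sel]), tolerance = 1e-10)
  expect_equal(mf$n[1], sum(sel))
})

test_that("aggregation correlation recovers the sign of an imposed index effect", {
  pat <- simulate_scenario(scenario_config(process = "thomas"), seed = 12,
                           n_concessions = 3, area_range_ha = c(250, 450))
  edge <- boundary_distances(pat)
  ce <- markddd:::ce_indices_all(pat, 100, edge)
  set.seed(13)
  marks <- 2 + 1.5 * ifelse(is.na(ce), 1, ce) + rnorm(n_trees(pat), 0, 0.3)
  mf <- mark_correlation(pat, "seed", "aggregation",
                         bins = bin_spec(100, NA_real_, "cumulative"),
                         envelope = envelope_config(n_sim = 99, seed = 14),
                         marks = marks)
  expect_gt(mf$stat[1], 0)
  expect_true(mf$significant[1])
})

test_that("all four functions agree with brute force on a multi-concession pattern", {
  pat <- simulate_scenario(scenario_config(process = "poisson", density_ha = 2),
                           seed = 15, n_concessions = 2,
                           area_range_ha = c(60, 100))
  n <- n_trees(pat)
  expect_lte(n, 500)
  marks <- as.numeric(normalize_marks(pat, "seed"))
  trees <- pat$trees
  nnor <- bf_nearest(trees)
  edge <- numeric(n)
  for (cid in names(pat$windows)) {
    idx <- which(trees$concession_id == cid)
    edge[idx] <- bf_boundary(trees$x[idx], trees$y[idx],
                             pat$windows[[cid]]$boundary, step = 1e-3)
  }
  keep <- !is.na(nnor$nn_dist) & edge >= nnor$nn_dist

  b <- make_bins("near_10")
  f1 <- mark_correlation(pat, "seed", "nnmean", bins = b, envelope = NULL,
                         marks = marks)
  f2 <- mark_correlation(pat, "seed", "schlather", bins = b, envelope = NULL,
                         marks = marks)
  nnrow <- match(nnor$nn_id, trees$tree_id)
  lower <- c(-Inf, b$centers[-length(b$centers)] + b$halfwidth)
  for (k in seq_along(b$centers)) {
    insel <- keep & nnor$nn_dist > lower[k] &
      nnor$nn_dist >= b$centers[k] - b$halfwidth &
      nnor$nn_dist <= b$centers[k] + b$halfwidth
    if (sum(insel) > 0) {
      expect_equal(f1$stat[k], mean(marks[insel]), tolerance = 1e-10)
    }
    if (sum(insel) >= 2 && sd(marks[insel]) > 0 &&
        sd(marks[nnrow[insel]]) > 0) {
      expect_equal(f2$stat[k], cor(marks[insel], marks[nnrow[insel]]),
                   tolerance = 1e-10)
    }
  }

  radii <- c(40, 80, 120)
  f3 <- mark_correlation(pat, "seed", "density",
                         bins = bin_spec(radii, NA_real_, "cumulative"),
                         envelope = NULL, marks = marks)
  cnt <- bf_counts(trees, radii)
  for (k in seq_along(radii)) {
    sel <- edge >= radii[k]
    if (sum(sel) >= 3) {
      expect_equal(f3$stat[k], cor(marks[sel], cnt[sel, k]), tolerance = 1e-10)
    }
  }
})
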