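# Plot-size scaling experiment: rasterize the pattern at several grid-cell
# sizes, compare expected (tree count x grand mean) against measured
# (summed marks) per-hectare values by linear regression, and check the
# regression residuals for spatial autocorrelation.
#
# The regression slope is the accuracy proxy and R^2 the precision proxy of
# plots of that size for estimating area-based seed production or AGB.

#' Convert an arc-second cell size to metres at a reference latitude
#'
#' East-west width shrinks with `cos(latitude)`; north-south width does
#' not.  Uses a spherical Earth radius of 6,371,000 m.
#'
#' @param arcsec Cell size in arc-seconds.
#' @param lat_deg Reference latitude in degrees (negative south); default
#'   -12, the latitude of the Madre de Dios region.
#' @return Numeric length-2 `c(width_x, width_y)` in metres.
#' @examples
#' cell_size_m(3.33)  # roughly 1 ha per cell at 12 degrees south
#' @export
cell_size_m <- function(arcsec, lat_deg = -12) {
  check_number(arcsec, "arcsec", 0, strict = TRUE)
  r_earth <- 6371000
  rad <- pi / 648000  # one arc-second in radians
  c(width_x = arcsec * rad * r_earth * cos(lat_deg * pi / 180),
    width_y = arcsec * rad * r_earth)
}

#' Scaling-experiment configuration
#'
#' @param cell_sizes_arcsec Grid-cell size ladder in arc-seconds (default
#'   the standard ladder 1, 2.5, 3.33, 5, 7.5, 10, 15, 20, 30, 40).
#' @param cell_sizes_m Alternative ladder directly in metres (square
#'   cells); overrides `cell_sizes_arcsec` when non-NULL.
#' @param lat_deg Reference latitude for the arc-second conversion.
#' @param min_coverage Minimum fraction of a cell that must lie inside the
#'   concession window for the cell to be kept (default 1: only fully
#'   interior cells).
#' @param regression_mode `"through_origin"` (default: a cell with zero
#'   expected value structurally has zero measured value) or
#'   `"with_intercept"`.
#' @return An object of class `scaling_config`.
#' @export
scaling_config <- function(cell_sizes_arcsec = c(1, 2.5, 3.33, 5, 7.5, 10, 15, 20, 30, 40),
                           cell_sizes_m = NULL, lat_deg = -12,
                           min_coverage = 1,
                           regression_mode = c("through_origin", "with_intercept")) {
  if (min_coverage <= 0 || min_coverage > 1) stop_ddd("`min_coverage` must be in (0, 1]")
  structure(
    list(cell_sizes_arcsec = cell_sizes_arcsec, cell_sizes_m = cell_sizes_m,
         lat_deg = lat_deg, min_coverage = min_coverage,
         regression_mode = match.arg(regression_mode)),
    class = "scaling_config"
  )
}

#' Rasterize a marked pattern at one cell size
#'
#' Each concession window gets its own grid aligned to the window bounding
#' box (origin at the minimum corner, half-open cells `[x0, x0 + w)`).
#' Cells covered by the window below `min_coverage` are dropped.  Per cell:
#' the tree count, the measured mark total (sum of per-tree marks), the
#' expected total (count times the grand mean mark over all trees in the
#' pattern), and both totals per hectare.
#'
#' @param pattern A [marked_pattern()].
#' @param mark `"seed"` or `"agb"`.
#' @param cell_size Cell width in metres (scalar for square cells, or
#'   length-2 `c(wx, wy)` e.g. from [cell_size_m()]).
#' @param min_coverage Fraction of the cell that must be inside the window.
#' @return Data frame with one row per retained cell: `concession_id`,
#'   `cx`, `cy` (cell centroid), `coverage`, `n_trees`, `measured`,
#'   `expected`, `measured_ha`, `expected_ha`; attributes `cell_area_ha`
#'   and `grand_mean`.
#' @export
rasterize_pattern <- function(pattern, mark = c("seed", "agb"), cell_size,
                              min_coverage = 1) {
  mark <- match.arg(mark)
  if (length(cell_size) == 1L) cell_size <- c(cell_size, cell_size)
  wx <- cell_size[1L]; wy <- cell_size[2L]
  check_number(wx, "cell width", 0, strict = TRUE)
  check_number(wy, "cell height", 0, strict = TRUE)
  m <- pattern_marks(pattern, mark)
  usable <- !is.na(m)
  grand_mean <- mean(m[usable])
  cell_area_m2 <- wx * wy
  rows <- list()
  for (cid in names(pattern$windows)) {
    w <- pattern$windows[[cid]]
    bb <- apply(w$boundary, 2L, range)
    x0 <- bb[1L, 1L]; y0 <- bb[1L, 2L]
    nx <- max(1L, ceiling((bb[2L, 1L] - x0) / wx))
    ny <- max(1L, ceiling((bb[2L, 2L] - y0) / wy))
    if (nx == 1L && ny == 1L && cell_area_m2 > w$area_m2) {
      warning("cell size exceeds window extent for concession '", cid,
              "'; degenerate single-cell grid", call. = FALSE)
    }
    idx <- which(pattern$trees$concession_id == cid & usable)
    ix <- pmin(nx - 1L, floor((pattern$trees$x[idx] - x0) / wx))
    iy <- pmin(ny - 1L, floor((pattern$trees$y[idx] - y0) / wy))
    cell_of_tree <- ix + nx * iy
    # coverage of every cell in the bounding box
    gx <- rep(seq_len(nx) - 1L, times = ny)
    gy <- rep(seq_len(ny) - 1L, each = nx)
    cover <- vapply(seq_along(gx), function(k) {
      ring_rect_overlap_area(
        w$boundary,
        x0 + gx[k] * wx, x0 + (gx[k] + 1L) * wx,
        y0 + gy[k] * wy, y0 + (gy[k] + 1L) * wy
      ) / cell_area_m2
    }, 0)
    keep <- which(cover >= min_coverage - 1e-9)
    if (!length(keep)) next
    cellid <- gx[keep] + nx * gy[keep]
    counts <- as.integer(table(factor(cell_of_tree, levels = cellid)))
    match_cell <- match(cell_of_tree, cellid)  # NA: tree in a dropped cell
    sums <- numeric(length(cellid))
    if (any(!is.na(match_cell))) {
      tb <- tapply(m[idx][!is.na(match_cell)], match_cell[!is.na(match_cell)], sum)
      sums[as.integer(names(tb))] <- as.numeric(tb)
    }
    rows[[cid]] <- data.frame(
      concession_id = cid,
      cx = x0 + (gx[keep] + 0.5) * wx,
      cy = y0 + (gy[keep] + 0.5) * wy,
      coverage = cover[keep],
      n_trees = counts,
      measured = sums,
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) stop_ddd("no cells retained at this cell size / coverage")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$expected <- out$n_trees * grand_mean
  area_ha <- cell_area_m2 / M2_PER_HA
  out$measured_ha <- out$measured / area_ha
  out$expected_ha <- out$expected / area_ha
  structure(out, cell_area_ha = area_ha, grand_mean = grand_mean, mark = mark)
}

#' Accuracy/precision regression for one cell table
#'
#' Least-squares regression of measured on expected per-hectare values.
#' The slope is the accuracy proxy (1 = unbiased), R^2 the precision
#' proxy.  In `"through_origin"` mode empty cells (zero count) are kept;
#' in `"with_intercept"` mode they are excluded so zero-inflation does not
#' dominate the fit.
#'
#' @param cells Output of [rasterize_pattern()].
#' @param mode `"through_origin"` or `"with_intercept"`.
#' @return List with `slope`, `ci` (95% confidence interval), `r_squared`,
#'   `n_cells`, `mode` and the fitted `lm` object.
#' @export
scaling_regression <- function(cells, mode = c("through_origin", "with_intercept")) {
  mode <- match.arg(mode)
  dat <- as.data.frame(cells)
  if (mode == "with_intercept") dat <- dat[dat$n_trees > 0L, , drop = FALSE]
  if (nrow(dat) < 3L) stop_ddd("need at least 3 cells for the scaling regression")
  if (stats::sd(dat$expected_ha) == 0) {
    stop_ddd("zero variance in expected values; regression undefined")
  }
  fit <- if (mode == "through_origin") {
    stats::lm(measured_ha ~ 0 + expected_ha, data = dat)
  } else {
    stats::lm(measured_ha ~ expected_ha, data = dat)
  }
  co <- stats::coef(fit)
  slope <- unname(co[["expected_ha"]])
  ci <- stats::confint(fit, "expected_ha", level = 0.95)
  list(
    slope = slope, ci = c(ci[1L], ci[2L]),
    r_squared = summary(fit)$r.squared,
    n_cells = nrow(dat), mode = mode, fit = fit
  )
}

#' Scaling curve across a ladder of cell sizes
#'
#' Runs [rasterize_pattern()] and [scaling_regression()] at every
#' configured cell size and assembles the accuracy (slope) and precision
#' (R^2) profiles by cell area.
#'
#' @param pattern A [marked_pattern()].
#' @param mark `"seed"` or `"agb"`.
#' @param config A [scaling_config()].
#' @return An object of class `scaling_result`: data frame ordered by cell
#'   area with columns `cell_label`, `cell_area_ha`, `n_cells`, `slope`,
#'   `ci_lo`, `ci_hi`, `r_squared`; the per-size cell tables are attached
#'   as attribute `cells`.
#' @export
scaling_curve <- function(pattern, mark = c("seed", "agb"),
                          config = scaling_config()) {
  mark <- match.arg(mark)
  stopifnot(inherits(config, "scaling_config"))
  if (!is.null(config$cell_sizes_m)) {
    sizes <- lapply(config$cell_sizes_m, function(s) c(s, s))
    labels <- paste0(config$cell_sizes_m, " m")
  } else {
    sizes <- lapply(config$cell_sizes_arcsec, cell_size_m, lat_deg = config$lat_deg)
    labels <- paste0(config$cell_sizes_arcsec, "\"")
  }
  if (length(sizes) < 2L) stop_ddd("need at least 2 cell sizes")
  rows <- vector("list", length(sizes))
  tables <- vector("list", length(sizes))
  for (k in seq_along(sizes)) {
    cells <- rasterize_pattern(pattern, mark, sizes[[k]], config$min_coverage)
    reg <- scaling_regression(cells, config$regression_mode)
    rows[[k]] <- data.frame(
      cell_label = labels[k],
      cell_area_ha = attr(cells, "cell_area_ha"),
      n_cells = reg$n_cells,
      slope = reg$slope, ci_lo = reg$ci[1L], ci_hi = reg$ci[2L],
      r_squared = reg$r_squared,
      stringsAsFactors = FALSE
    )
    tables[[k]] <- cells
  }
  out <- do.call(rbind, rows)
  ord <- order(out$cell_area_ha)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
    class = c("scaling_result", "data.frame"),
    cells = tables[ord], mark = mark, mode = config$regression_mode
  )
}

#' @export
print.scaling_result <- function(x, ...) {
  cat(sprintf(
    "Plot-size scaling (%s marks, %s regression): %d cell sizes\n",
    attr(x, "mark"),
    sub("_", "-", attr(x, "mode")), nrow(x)
  ))
  print.data.frame(as.data.frame(x), digits = 4)
  invisible(x)
}

#' Plot slope and R-squared against cell area
#'
#' Accuracy (slope with 95% CI) and precision (R^2) versus cell area on a
#' square-root axis.
#'
#' @param x A `scaling_result`.
#' @param ... Passed on to [graphics::plot()].
#' @export
plot.scaling_result <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  sa <- sqrt(x$cell_area_ha)
  graphics::plot(sa, x$slope, ylim = range(c(x$ci_lo, x$ci_hi, 1)),
                 xlab = "sqrt(cell area, ha)", ylab = "slope (accuracy)",
                 pch = 16, ...)
  graphics::arrows(sa, x$ci_lo, sa, x$ci_hi, angle = 90, code = 3, length = 0.03)
  graphics::abline(h = 1, lty = 2, col = "grey40")
  graphics::plot(sa, x$r_squared, ylim = c(0, 1), pch = 16,
                 xlab = "sqrt(cell area, ha)", ylab = expression(R^2 ~ "(precision)"))
  invisible(x)
}

#' Distance-binned correlogram of regression residuals
#'
#' Moran-type check for residual spatial autocorrelation: for every pair
#' of cells whose centroid distance falls in a bin, the Pearson
#' correlation between the residuals at the two ends is computed, with a
#' pointwise permutation envelope obtained by shuffling residuals across
#' cells.
#'
#' @param cells Cell table from [rasterize_pattern()] (needs `cx`, `cy`).
#' @param residuals Numeric residual vector aligned with `cells` rows.
#' @param breaks Distance-bin break points in metres; defaults to 10 bins
#'   spanning the observed centroid distances.
#' @param n_sim Number of residual permutations for the envelope (default
#'   99).
#' @param rank Envelope rank (default 3: pointwise two-sided level 0.06).
#' @param seed RNG seed.
#' @return Data frame with `r` (bin midpoint), `correlation`, `n_pairs`,
#'   `lo`, `hi`, `significant`.
#' @export
residual_correlogram <- function(cells, residuals, breaks = NULL,
                                 n_sim = 99L, rank = 3L, seed = NULL) {
  cells <- as.data.frame(cells)
  if (length(residuals) != nrow(cells)) {
    stop_ddd("`residuals` must align with `cells` rows")
  }
  n <- nrow(cells)
  if (n < 2L) stop_ddd("need at least 2 cells")
  d <- as.matrix(stats::dist(cbind(cells$cx, cells$cy)))
  pair <- which(upper.tri(d), arr.ind = TRUE)
  pd <- d[upper.tri(d)]
  if (is.null(breaks)) breaks <- seq(0, max(pd), length.out = 11L)[-1L]
  breaks <- sort(breaks)
  binidx <- findInterval(pd, c(0, breaks), left.open = TRUE)
  binidx[binidx > length(breaks)] <- NA_integer_
  corr_by_bin <- function(res) {
    vapply(seq_along(breaks), function(b) {
      sel <- which(!is.na(binidx) & binidx == b)
      if (length(sel) < 2L) return(NA_real_)
      x <- res[pair[sel, 1L]]; y <- res[pair[sel, 2L]]
      # symmetrized pair correlation (each pair used in both orientations)
      xx <- c(x, y); yy <- c(y, x)
      if (stats::sd(xx) == 0) return(NA_real_)
      stats::cor(xx, yy)
    }, 0)
  }
  obs <- corr_by_bin(residuals)
  if (all(is.na(obs))) stop_ddd("fewer than 2 pairs in every distance bin")
  cfg <- envelope_config(n_sim = n_sim, rank = rank, seed = seed)
  env <- build_envelopes(corr_by_bin, residuals, cfg)
  mids <- c(0, breaks[-length(breaks)]) + diff(c(0, breaks)) / 2
  npairs <- vapply(seq_along(breaks), function(b) sum(!is.na(binidx) & binidx == b), 0L)
  data.frame(
    r = mids, correlation = obs, n_pairs = npairs,
    lo = env$lo, hi = env$hi,
    significant = !is.na(obs) & !is.na(env$lo) & (obs < env$lo | obs > env$hi)
  )
}
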