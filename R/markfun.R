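# The four mark correlation functions with their edge corrections.
#
# f "nnmean":      mean normalized mark of trees whose nearest conspecific
#                  neighbour lies in distance bin [r - h, r + h].
# f "schlather":   Pearson correlation between the normalized marks of the
#                  ordered pairs (tree, its nearest neighbour) in a bin;
#                  the mark analogue of Moran's I.
# f "density":     Pearson correlation between a focal tree's normalized
#                  mark and its cumulative conspecific neighbour count
#                  within radius r.
# f "aggregation": Pearson correlation between a focal tree's normalized
#                  mark and the Clark-Evans aggregation index of its
#                  r-neighbourhood (1 = random, < 1 = aggregated,
#                  > 1 = regular).
#
# Edge corrections: the first two functions drop trees closer to the
# concession boundary than to their nearest neighbour; the last two restrict
# focal trees to those at least r from the boundary, and the aggregation
# index additionally drops neighbourhood members closer to the circular
# boundary than to their nearest member.

MARKFUN_CHOICES <- c("nnmean", "schlather", "density", "aggregation")

#' Nearest-neighbour edge correction
#'
#' Retains trees whose distance to the concession boundary is at least
#' their nearest-neighbour distance; trees failing the rule would have a
#' censored neighbour relation and bias the nearest-neighbour statistics.
#' Trees without a neighbour (single-tree concessions) are dropped and
#' counted separately.
#'
#' @param pattern A [marked_pattern()].
#' @param nb Output of [neighbour_info()]; recomputed when omitted.
#' @return List with `retained` (logical vector over trees), `n_dropped`,
#'   `n_no_neighbour` and `fraction_dropped` (share of neighbour-bearing
#'   trees dropped by the edge rule).
#' @export
edge_filter_nn <- function(pattern, nb = neighbour_info(pattern)) {
  has_nn <- !is.na(nb$nn_dist)
  retained <- has_nn & nb$edge_dist >= nb$nn_dist
  n_drop <- sum(has_nn & !retained)
  list(
    retained = retained,
    n_dropped = n_drop,
    n_no_neighbour = sum(!has_nn),
    fraction_dropped = if (any(has_nn)) n_drop / sum(has_nn) else 0
  )
}

#' Clark-Evans aggregation index of one circular neighbourhood
#'
#' Members are the conspecific trees (excluding the focal tree) within
#' distance `r` of the focal tree, in the same concession.  For each member
#' the nearest-neighbour distance among members is found; members closer to
#' the circumference of the neighbourhood than to their nearest member are
#' excluded from the mean (the second-level edge rule), because their true
#' nearest neighbour might lie outside the disc.  The index is
#' `2 * dbar * sqrt(rho)` with `dbar` the mean retained nearest-member
#' distance (m) and `rho` the concession density in trees per square metre
#' — equivalently `dbar / E(d)` with `E(d) = 1 / (2 sqrt(rho))`, the
#' expected nearest-neighbour distance under complete spatial randomness.
#' It is 1 for random patterns, below 1 for aggregated and above 1 for
#' regular ones.
#'
#' @param pattern A [marked_pattern()].
#' @param focal A `tree_id` (character) or row index into `pattern$trees`.
#' @param r Neighbourhood radius in metres; the focal tree must be at least
#'   `r` from its concession boundary.
#' @return List with `n_members`, `n_used`, `mean_nn_dist`,
#'   `expected_nn_dist`, `ce_index` (NA with `defined = FALSE` when fewer
#'   than 2 members survive the exclusions).
#' @export
clark_evans_neighbourhood <- function(pattern, focal, r) {
  check_number(r, "r", 0, strict = TRUE)
  trees <- pattern$trees
  i <- if (is.character(focal)) match(focal, trees$tree_id) else as.integer(focal)
  if (is.na(i) || i < 1L || i > nrow(trees)) stop_ddd("unknown focal tree")
  edge <- dist_to_ring(trees$x[i], trees$y[i],
                       pattern$windows[[trees$concession_id[i]]]$boundary)
  if (edge < r) {
    stop_ddd("focal tree '", trees$tree_id[i],
             "' is closer to the concession boundary than r = ", r)
  }
  cid <- trees$concession_id[i]
  idx <- which(trees$concession_id == cid)
  dx <- trees$x[idx] - trees$x[i]
  dy <- trees$y[idx] - trees$y[i]
  dfoc <- sqrt(dx^2 + dy^2)
  members <- idx[idx != i & dfoc <= r]
  dfoc <- dfoc[idx != i & dfoc <= r]
  rho <- pattern$windows[[cid]]$density_m2
  res <- ce_index_members(trees$x[members], trees$y[members], dfoc, r, rho)
  c(list(focal_id = trees$tree_id[i], r = r), res)
}

#' Index computation given member coordinates and focal distances
#' @noRd
ce_index_members <- function(mx, my, dist_focal, r, rho_m2) {
  n <- length(mx)
  out <- list(n_members = n, n_used = 0L, mean_nn_dist = NA_real_,
              expected_nn_dist = 1 / (2 * sqrt(rho_m2)),
              ce_index = NA_real_, defined = FALSE)
  if (n < 2L) return(out)
  d <- as.matrix(stats::dist(cbind(mx, my)))
  diag(d) <- Inf
  nnd <- apply(d, 1L, min)
  circ <- r - dist_focal          # distance to the neighbourhood circumference
  keep <- circ >= nnd
  if (sum(keep) < 2L) {
    out$n_used <- sum(keep)
    return(out)
  }
  dbar <- mean(nnd[keep])
  out$n_used <- sum(keep)
  out$mean_nn_dist <- dbar
  out$ce_index <- 2 * dbar * sqrt(rho_m2)
  out$defined <- TRUE
  out
}

#' Clark-Evans indices for all eligible focal trees at one radius
#'
#' @return numeric vector over all trees; NA where ineligible/undefined.
#' @noRd
ce_indices_all <- function(pattern, r, edge_dist) {
  trees <- pattern$trees
  out <- rep(NA_real_, nrow(trees))
  for (cid in names(pattern$windows)) {
    cd <- concession_dist(pattern, cid)
    n <- length(cd$idx)
    if (n < 3L) next
    rho <- pattern$windows[[cid]]$density_m2
    d <- cd$d
    for (jj in seq_len(n)) {
      gi <- cd$idx[jj]
      if (edge_dist[gi] < r) next
      sel <- which(d[jj, ] <= r & seq_len(n) != jj)
      if (length(sel) < 2L) next
      sub <- d[sel, sel, drop = FALSE]
      diag(sub) <- Inf
      nnd <- apply(sub, 1L, min)
      keep <- (r - d[jj, sel]) >= nnd
      if (sum(keep) < 2L) next
      out[gi] <- 2 * mean(nnd[keep]) * sqrt(rho)
    }
  }
  out
}

# ---------------------------------------------------------------------------
# Preparation: everything that depends on geometry only, so that the
# permutation null (which moves marks, not trees) can re-evaluate the
# statistic cheaply.

#' @noRd
mcf_prepare <- function(pattern, fun, bins, nb) {
  if (fun %in% c("nnmean", "schlather")) {
    if (bins$regime == "cumulative") {
      stop_ddd("'", fun, "' needs an interval bin scheme (near/far), not cumulative")
    }
    ef <- edge_filter_nn(pattern, nb)
    keep <- which(ef$retained)
    binidx <- assign_bins(nb$nn_dist[keep], bins)
    nn_row <- match(nb$nn_id[keep], pattern$trees$tree_id)
    list(
      r = bins$centers, fraction_dropped = ef$fraction_dropped,
      focal = keep, partner = nn_row, binidx = binidx, n_bins = length(bins$centers)
    )
  } else {
    radii <- bins$centers
    edge <- nb$edge_dist
    if (fun == "density") {
      counts <- neighbour_counts(pattern, radii)
      list(r = radii, edge = edge, covariate = counts, n_bins = length(radii),
           fraction_dropped = NA_real_)
    } else {
      ce <- vapply(radii, function(r) ce_indices_all(pattern, r, edge),
                   numeric(nrow(pattern$trees)))
      list(r = radii, edge = edge, covariate = ce, n_bins = length(radii),
           fraction_dropped = NA_real_)
    }
  }
}

#' Evaluate one mark function for a mark vector, given prepared geometry
#'
#' Returns list(stat, n): per-bin statistic and contributing count.
#' @noRd
mcf_eval <- function(prep, fun, marks) {
  B <- prep$n_bins
  stat <- rep(NA_real_, B)
  n <- integer(B)
  if (fun == "nnmean") {
    m <- marks[prep$focal]
    ok <- !is.na(m) & !is.na(prep$binidx)
    if (any(ok)) {
      sums <- rowsum(m[ok], prep$binidx[ok])
      cnts <- rowsum(rep(1, sum(ok)), prep$binidx[ok])
      at <- as.integer(rownames(sums))
      stat[at] <- sums[, 1L] / cnts[, 1L]
      n[at] <- as.integer(cnts[, 1L])
    }
  } else if (fun == "schlather") {
    mi <- marks[prep$focal]
    mj <- marks[prep$partner]
    ok <- !is.na(mi) & !is.na(mj) & !is.na(prep$binidx)
    for (b in seq_len(B)) {
      sel <- ok & prep$binidx == b
      n[b] <- sum(sel)
      if (n[b] >= 2L) {
        x <- mi[sel]; y <- mj[sel]
        if (stats::sd(x) > 0 && stats::sd(y) > 0) stat[b] <- stats::cor(x, y)
      }
    }
  } else { # density / aggregation: covariate matrix, focal filter edge >= r
    for (b in seq_len(B)) {
      r <- prep$r[b]
      cov <- prep$covariate[, b]
      sel <- which(prep$edge >= r & !is.na(marks) & !is.na(cov))
      n[b] <- length(sel)
      if (n[b] >= 3L) {
        x <- marks[sel]; y <- cov[sel]
        if (stats::sd(x) > 0 && stats::sd(y) > 0) stat[b] <- stats::cor(x, y)
      }
    }
  }
  list(stat = stat, n = n)
}

# ---------------------------------------------------------------------------

#' Mark correlation functions with permutation envelopes
#'
#' Computes one of the four mark correlation functions for a marked tree
#' pattern, after per-concession mark normalization and the matching edge
#' correction, and (optionally) pointwise simulation envelopes from a
#' mark-shuffling null model.
#'
#' @param pattern A [marked_pattern()].
#' @param mark `"seed"` or `"agb"`.
#' @param fun `"nnmean"`, `"schlather"`, `"density"` or `"aggregation"`.
#' @param bins A [bin_spec()] or a scheme name accepted by [make_bins()].
#'   Interval schemes (near/far) apply to `"nnmean"`/`"schlather"`; the
#'   cumulative ladder applies to `"density"`/`"aggregation"`.
#' @param normalize Divide marks by concession means first (default TRUE;
#'   set FALSE for raw-mark sensitivity analyses).
#' @param pair_mode For `"schlather"`: `"ordered"` counts the pair (i,
#'   nn(i)) for every retained tree, so mutual nearest neighbours
#'   contribute twice; `"unique"` collapses mutual pairs to one.
#' @param envelope An [envelope_config()], or `NULL` to skip envelopes.
#' @param marks Optional explicit mark vector aligned with
#'   `pattern$trees`, overriding `mark`/`normalize` (used by the null-model
#'   machinery and sensitivity analyses).
#' @return An object of class `markfun`: data frame with one row per
#'   distance bin and columns `r`, `stat`, `n`, `lo`, `hi`, `n_sim_eff`,
#'   `significant`, `flag`, plus attributes describing the call.
#' @examples
#' pat <- simulate_scenario(scenario_presets()$null, n_concessions = 2,
#'                          area_range_ha = c(50, 60), seed = 1)
#' mark_correlation(pat, "seed", "nnmean", bins = "near_5",
#'                  envelope = envelope_config(n_sim = 39, seed = 1))
#' @export
mark_correlation <- function(pattern, mark = c("seed", "agb"),
                             fun = MARKFUN_CHOICES, bins = NULL,
                             normalize = TRUE,
                             pair_mode = c("ordered", "unique"),
                             envelope = envelope_config(), marks = NULL) {
  mark <- match.arg(mark)
  fun <- match.arg(fun)
  pair_mode <- match.arg(pair_mode)
  if (is.null(bins)) {
    bins <- if (fun %in% c("nnmean", "schlather")) "near_5" else "cumulative"
  }
  if (is.character(bins)) bins <- make_bins(bins)
  if (!inherits(bins, "bin_spec")) stop_ddd("`bins` must be a bin_spec or scheme name")
  if (fun %in% c("density", "aggregation") && bins$regime != "cumulative") {
    stop_ddd("'", fun, "' uses cumulative radii; pass bins = \"cumulative\"")
  }

  if (is.null(marks)) {
    marks <- if (normalize) as.numeric(normalize_marks(pattern, mark)) else pattern_marks(pattern, mark)
  }
  if (length(marks) != n_trees(pattern)) {
    stop_ddd("`marks` must align with pattern$trees")
  }

  nb <- neighbour_info(pattern)
  prep <- mcf_prepare(pattern, fun, bins, nb)
  if (fun == "schlather" && pair_mode == "unique") {
    ids <- pattern$trees$tree_id
    mutual <- !is.na(prep$partner) &
      prep$partner %in% prep$focal &
      vapply(seq_along(prep$focal), function(k) {
        j <- prep$partner[k]
        pos <- match(j, prep$focal)
        !is.na(pos) && prep$partner[pos] == prep$focal[k]
      }, TRUE)
    drop <- mutual & ids[prep$focal] > ids[prep$partner]
    prep$focal <- prep$focal[!drop]
    prep$partner <- prep$partner[!drop]
    prep$binidx <- prep$binidx[!drop]
  }

  obs <- mcf_eval(prep, fun, marks)

  lo <- hi <- rep(NA_real_, prep$n_bins)
  n_sim_eff <- rep(NA_integer_, prep$n_bins)
  significant <- rep(NA, prep$n_bins)
  if (!is.null(envelope)) {
    env <- build_envelopes(
      function(m) mcf_eval(prep, fun, m)$stat,
      marks, envelope, concession_id = pattern$trees$concession_id
    )
    lo <- env$lo
    hi <- env$hi
    n_sim_eff <- env$n_sim_eff
    significant <- !is.na(obs$stat) & !is.na(lo) & !is.na(hi) &
      (obs$stat < lo | obs$stat > hi)
  }

  flag <- rep("", prep$n_bins)
  flag[obs$n == 0L] <- "empty"
  flag[obs$n > 0L & is.na(obs$stat)] <- "undefined"
  if (fun %in% c("schlather", "density", "aggregation")) {
    flag[obs$n > 0L & obs$n < 3L & flag == ""] <- "unstable"
  }

  out <- data.frame(
    r = prep$r, stat = obs$stat, n = obs$n,
    lo = lo, hi = hi, n_sim_eff = n_sim_eff,
    significant = significant, flag = flag,
    stringsAsFactors = FALSE
  )
  structure(out,
    class = c("markfun", "data.frame"),
    fun = fun, mark = mark, normalize = normalize,
    regime = bins$regime, halfwidth = bins$halfwidth,
    pair_mode = if (fun == "schlather") pair_mode else NA_character_,
    fraction_dropped = prep$fraction_dropped,
    n_sim = if (is.null(envelope)) 0L else envelope$n_sim,
    rank = if (is.null(envelope)) NA_integer_ else envelope$rank
  )
}

#' @export
print.markfun <- function(x, ...) {
  labels <- c(
    nnmean = "nearest-neighbour mark mean",
    schlather = "Schlather mark correlation",
    density = "density correlation",
    aggregation = "aggregation correlation"
  )
  cat(sprintf(
    "Mark correlation function: %s (%s marks%s)\n",
    labels[[attr(x, "fun")]], attr(x, "mark"),
    if (isTRUE(attr(x, "normalize"))) ", normalized" else ", raw"
  ))
  if (!is.na(attr(x, "fraction_dropped"))) {
    cat(sprintf("  edge correction dropped %.1f%% of trees\n",
                100 * attr(x, "fraction_dropped")))
  }
  if (attr(x, "n_sim") > 0L) {
    cat(sprintf(
      "  envelopes: %d randomizations, rank %d (pointwise two-sided level %.3f)\n",
      attr(x, "n_sim"), attr(x, "rank"),
      2 * attr(x, "rank") / (attr(x, "n_sim") + 1)
    ))
    cat(sprintf("  significant bins: %d of %d evaluated\n",
                sum(x$significant, na.rm = TRUE), sum(!is.na(x$stat))))
  }
  print.data.frame(utils::head(as.data.frame(x), 12), digits = 4)
  if (nrow(x) > 12L) cat("  ... ", nrow(x) - 12L, " more bins\n", sep = "")
  invisible(x)
}

#' @export
summary.markfun <- function(object, ...) {
  cat(sprintf(
    "%s / %s: %d bins, %d populated, %d significant\n",
    attr(object, "fun"), attr(object, "mark"), nrow(object),
    sum(object$n > 0), sum(object$significant, na.rm = TRUE)
  ))
  invisible(object)
}

#' Plot a mark correlation function with its envelopes
#'
#' Observed statistics are drawn as points (filled when inside the
#' envelope, open when significantly outside), the null envelopes as grey
#' lines, and the null expectation as a dashed line.
#'
#' @param x A `markfun` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.markfun <- function(x, ...) {
  ref <- if (attr(x, "fun") == "nnmean") 1 else 0
  ylim <- range(c(x$stat, x$lo, x$hi, ref), na.rm = TRUE)
  graphics::plot(x$r, x$stat, type = "n", ylim = ylim,
                 xlab = "distance r (m)",
                 ylab = paste0(attr(x, "fun"), " statistic"), ...)
  if (any(!is.na(x$lo))) {
    graphics::lines(x$r, x$lo, col = "grey55")
    graphics::lines(x$r, x$hi, col = "grey55")
  }
  graphics::abline(h = ref, lty = 2, col = "grey40")
  sig <- !is.na(x$significant) & x$significant
  graphics::points(x$r[!sig], x$stat[!sig], pch = 16)
  graphics::points(x$r[sig], x$stat[sig], pch = 21, bg = "white")
  invisible(x)
}
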