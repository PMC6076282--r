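# Spatial queries on marked patterns.  All neighbour relations are
# conspecific and confined within a concession: statistics are computed
# per-concession and pooled, and the boundary edge corrections are only
# meaningful within a window, so neighbours never cross concession
# boundaries.

#' Per-concession pairwise distance matrices (cached on the pattern)
#' @noRd
concession_dist <- function(pattern, cid) {
  idx <- which(pattern$trees$concession_id == cid)
  d <- as.matrix(stats::dist(cbind(pattern$trees$x[idx], pattern$trees$y[idx])))
  list(idx = idx, d = d)
}

#' Nearest conspecific neighbours
#'
#' For every tree, the strictly nearest other tree within the same
#' concession, with exact Euclidean distances.  Ties are broken by the
#' smallest `tree_id` (lexicographic) for reproducibility.  Trees in
#' single-tree concessions have no neighbour and are returned with `NA`
#' distance.
#'
#' @param pattern A [marked_pattern()].
#' @return Data frame with one row per tree (same order as
#'   `pattern$trees`): `tree_id`, `concession_id`, `nn_id`, `nn_dist`.
#' @examples
#' w <- rect_window("c1", 100, 100)
#' tr <- data.frame(tree_id = 1:3, concession_id = "c1",
#'                  x = c(0, 10, 25), y = 0, seed_kg = 1)
#' nearest_neighbours(marked_pattern(tr, w))
#' @export
nearest_neighbours <- function(pattern) {
  trees <- pattern$trees
  out <- data.frame(
    tree_id = trees$tree_id,
    concession_id = trees$concession_id,
    nn_id = NA_character_,
    nn_dist = NA_real_,
    stringsAsFactors = FALSE
  )
  for (cid in names(pattern$windows)) {
    cd <- concession_dist(pattern, cid)
    n <- length(cd$idx)
    if (n < 2L) next
    d <- cd$d
    diag(d) <- Inf
    if (any(d == 0)) {
      pair <- which(d == 0, arr.ind = TRUE)[1L, ]
      stop_ddd(
        "duplicate coordinates within concession '", cid, "': trees ",
        trees$tree_id[cd$idx[pair[1L]]], " and ", trees$tree_id[cd$idx[pair[2L]]]
      )
    }
    ids <- trees$tree_id[cd$idx]
    # order columns so that on ties which.min picks the smallest tree_id
    ord <- order(ids)
    nn_local <- ord[apply(d[, ord, drop = FALSE], 1L, which.min)]
    out$nn_id[cd$idx] <- ids[nn_local]
    out$nn_dist[cd$idx] <- d[cbind(seq_len(n), nn_local)]
  }
  out
}

#' Cumulative conspecific neighbour counts
#'
#' Number of same-concession trees within distance `r` of each tree
#' (interval from 0 to r, closed at r), excluding the focal tree itself.
#'
#' @param pattern A [marked_pattern()].
#' @param radii Strictly increasing positive radii in metres.
#' @return Integer matrix, one row per tree, one column per radius.
#' @export
neighbour_counts <- function(pattern, radii) {
  if (!length(radii)) stop_ddd("`radii` must be a non-empty numeric vector")
  if (any(radii <= 0) || any(diff(radii) <= 0)) {
    stop_ddd("`radii` must be strictly increasing and positive")
  }
  trees <- pattern$trees
  counts <- matrix(0L, nrow = nrow(trees), ncol = length(radii),
                   dimnames = list(NULL, paste0("r", radii)))
  for (cid in names(pattern$windows)) {
    cd <- concession_dist(pattern, cid)
    n <- length(cd$idx)
    if (n < 2L) next
    d <- cd$d
    diag(d) <- Inf
    for (k in seq_along(radii)) {
      counts[cd$idx, k] <- as.integer(rowSums(d <= radii[k]))
    }
  }
  counts
}

#' Distance from each tree to its concession boundary
#'
#' @param pattern A [marked_pattern()].
#' @return Numeric vector of boundary distances in metres, aligned with
#'   `pattern$trees`.
#' @export
boundary_distances <- function(pattern) {
  trees <- pattern$trees
  out <- numeric(nrow(trees))
  for (cid in names(pattern$windows)) {
    idx <- which(trees$concession_id == cid)
    if (!length(idx)) next
    out[idx] <- dist_to_ring(trees$x[idx], trees$y[idx],
                             pattern$windows[[cid]]$boundary)
  }
  out
}

#' Combined nearest-neighbour and boundary-distance table
#'
#' Convenience wrapper joining [nearest_neighbours()] and
#' [boundary_distances()]; this is the table the edge corrections consume.
#'
#' @param pattern A [marked_pattern()].
#' @return Data frame with `tree_id`, `concession_id`, `nn_id`, `nn_dist`,
#'   `edge_dist`.
#' @export
neighbour_info <- function(pattern) {
  nb <- nearest_neighbours(pattern)
  nb$edge_dist <- boundary_distances(pattern)
  nb
}

#' Normalize marks by concession means
#'
#' Divides each tree's mark by the mean mark of all trees in the same
#' concession, so that within each concession normalized marks average
#' exactly 1.  This removes between-concession differences in mean seed
#' production or AGB (environmental conditions, estimator effects) before
#' any mark correlation function is computed.
#'
#' For `mark = "agb"`, trees without DBH have no AGB and receive `NA`; the
#' number of such exclusions is attached as attribute `n_excluded`.
#'
#' @param pattern A [marked_pattern()].
#' @param mark `"seed"` or `"agb"`.
#' @return Numeric vector of normalized marks aligned with `pattern$trees`,
#'   with attribute `n_excluded`.
#' @examples
#' w <- rect_window("c1", 100, 100)
#' tr <- data.frame(tree_id = 1:3, concession_id = "c1",
#'                  x = c(1, 50, 99), y = 50, seed_kg = c(2, 4, 6))
#' normalize_marks(marked_pattern(tr, w), "seed")
#' @export
normalize_marks <- function(pattern, mark = c("seed", "agb")) {
  mark <- match.arg(mark)
  m <- pattern_marks(pattern, mark)
  cid <- pattern$trees$concession_id
  out <- rep(NA_real_, length(m))
  for (cc in unique(cid)) {
    idx <- which(cid == cc)
    vals <- m[idx]
    usable <- !is.na(vals)
    if (!any(usable)) next
    mu <- mean(vals[usable])
    if (mu <= 0) {
      stop_ddd("concession '", cc, "' has non-positive mean ", mark,
               " mark; normalization undefined")
    }
    out[idx[usable]] <- vals[usable] / mu
  }
  structure(out, n_excluded = sum(is.na(out)))
}
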