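# Brute-force oracles and small fixture builders.  Oracles use direct loops
# and never share code with the package internals they check.

# O(n^2) nearest neighbour per concession, ties by smallest tree_id
bf_nearest <- function(trees) {
  n <- nrow(trees)
  nn_id <- rep(NA_character_, n)
  nn_dist <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    best <- Inf
    best_id <- NA_character_
    for (j in seq_len(n)) {
      if (i == j || trees$concession_id[i] != trees$concession_id[j]) next
      d <- sqrt((trees$x[i] - trees$x[j])^2 + (trees$y[i] - trees$y[j])^2)
      if (d < best || (d == best && trees$tree_id[j] < best_id)) {
        best <- d
        best_id <- trees$tree_id[j]
      }
    }
    if (is.finite(best)) {
      nn_dist[i] <- best
      nn_id[i] <- best_id
    }
  }
  data.frame(nn_id = nn_id, nn_dist = nn_dist, stringsAsFactors = FALSE)
}

# O(n^2) cumulative neighbour counts
bf_counts <- function(trees, radii) {
  n <- nrow(trees)
  out <- matrix(0L, n, length(radii))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || trees$concession_id[i] != trees$concession_id[j]) next
      d <- sqrt((trees$x[i] - trees$x[j])^2 + (trees$y[i] - trees$y[j])^2)
      out[i, ] <- out[i, ] + as.integer(d <= radii)
    }
  }
  out
}

# boundary distance by dense sampling of the polygon edges
bf_boundary <- function(x, y, ring, step = 5e-4) {
  ring <- rbind(ring, ring[1, ])
  pts <- NULL
  for (k in seq_len(nrow(ring) - 1)) {
    a <- ring[k, ]; b <- ring[k + 1, ]
    len <- sqrt(sum((b - a)^2))
    t <- seq(0, 1, length.out = max(2L, ceiling(len / step)))
    pts <- rbind(pts, cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2])))
  }
  vapply(seq_along(x), function(i) {
    sqrt(min((pts[, 1] - x[i])^2 + (pts[, 2] - y[i])^2))
  }, 0)
}

# single-concession pattern on a big window, constant seed marks by default
make_pattern <- function(x, y, seed_kg = 1, window = NULL, cid = "c1",
                         ids = NULL) {
  if (is.null(window)) {
    pad <- 50
    window <- concession_window(cid, cbind(
      c(min(x) - pad, max(x) + pad, max(x) + pad, min(x) - pad),
      c(min(y) - pad, min(y) - pad, max(y) + pad, max(y) + pad)
    ))
  }
  if (is.null(ids)) ids <- sprintf("t%04d", seq_along(x))
  marked_pattern(
    data.frame(tree_id = ids, concession_id = cid, x = x, y = y,
               seed_kg = seed_kg, stringsAsFactors = FALSE),
    window
  )
}

# uniform points in a rectangle
runif_points <- function(n, width, height, seed) {
  set.seed(seed)
  list(x = runif(n, 0, width), y = runif(n, 0, height))
}

# closed-form OLS oracle (through origin and with intercept)
bf_ols <- function(x, y, intercept = FALSE) {
  if (!intercept) {
    slope <- sum(x * y) / sum(x^2)
    res <- y - slope * x
    r2 <- 1 - sum(res^2) / sum(y^2)
    se <- sqrt(sum(res^2) / (length(x) - 1) / sum(x^2))
    df <- length(x) - 1
  } else {
    xb <- mean(x); yb <- mean(y)
    slope <- sum((x - xb) * (y - yb)) / sum((x - xb)^2)
    a <- yb - slope * xb
    res <- y - a - slope * x
    r2 <- 1 - sum(res^2) / sum((y - yb)^2)
    se <- sqrt(sum(res^2) / (length(x) - 2) / sum((x - xb)^2))
    df <- length(x) - 2
  }
  ci <- slope + c(-1, 1) * qt(0.975, df) * se
  list(slope = slope, r2 = r2, ci = ci)
}
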