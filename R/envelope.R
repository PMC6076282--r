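# Mark-shuffling null model and pointwise simulation envelopes.
#
# The null model destroys any mark-location association by randomly
# permuting marks over trees while keeping all locations fixed.  Envelopes
# are the rank-th lowest and highest values per bin across n_sim
# randomizations; with the defaults (199 randomizations, rank 5) the bounds
# sit at the pointwise 2.5th and 97.5th percentiles.

#' Envelope configuration
#'
#' @param n_sim Number of mark-shuffling randomizations (default 199).
#' @param rank Order statistic used for the bounds: the `rank`-th lowest
#'   and highest null values (default 5; with 199 randomizations this is
#'   the 2.5th/97.5th percentile pair).  The implied pointwise two-sided
#'   level is `2 * rank / (n_sim + 1)`.
#' @param seed Master RNG seed; one child seed per replicate is spawned up
#'   front so results do not depend on evaluation order.
#' @param scope `"global"` permutes marks across all trees (the null model
#'   of record); `"within_concession"` permutes within each concession, a
#'   stricter conditional null.
#' @return An object of class `envelope_config`.
#' @export
envelope_config <- function(n_sim = 199L, rank = 5L, seed = NULL,
                            scope = c("global", "within_concession")) {
  n_sim <- as.integer(n_sim)
  rank <- as.integer(rank)
  if (n_sim < 2L) stop_ddd("`n_sim` must be at least 2")
  if (rank < 1L || n_sim < 2L * rank) {
    stop_ddd("`rank` must satisfy 1 <= rank <= n_sim / 2")
  }
  structure(
    list(n_sim = n_sim, rank = rank, seed = seed, scope = match.arg(scope)),
    class = "envelope_config"
  )
}

#' @export
print.envelope_config <- function(x, ...) {
  cat(sprintf(
    "Envelope config: %d randomizations, rank %d (level %.3f), scope %s\n",
    x$n_sim, x$rank, 2 * x$rank / (x$n_sim + 1), x$scope
  ))
  invisible(x)
}

#' Randomly permute marks over trees
#'
#' Locations are untouched and the multiset of marks is preserved exactly;
#' with `scope = "within_concession"` each concession's multiset is
#' preserved separately.
#'
#' @param marks Numeric mark vector.
#' @param scope `"global"` or `"within_concession"`.
#' @param seed RNG seed for reproducibility (optional).
#' @param concession_id Concession of each tree; required for
#'   within-concession scope.
#' @return Permuted mark vector of the same length.
#' @export
shuffle_marks <- function(marks, scope = c("global", "within_concession"),
                          seed = NULL, concession_id = NULL) {
  scope <- match.arg(scope)
  with_seed(seed, {
    if (scope == "global") {
      sample(marks)
    } else {
      if (is.null(concession_id) || length(concession_id) != length(marks)) {
        stop_ddd("within-concession shuffling needs `concession_id` aligned with marks")
      }
      out <- marks
      for (cc in unique(concession_id)) {
        idx <- which(concession_id == cc)
        out[idx] <- marks[sample(idx)]
      }
      out
    }
  })
}

#' Build pointwise simulation envelopes for a mark statistic
#'
#' Applies `stat_fn` to `n_sim` independent mark shuffles and returns, per
#' bin, the rank-th lowest and highest null values.  Bins where some null
#' replicates are undefined (e.g. zero-variance or empty bins) use the
#' available replicates and report the reduced effective count.
#'
#' @param stat_fn Function mapping a mark vector to a numeric vector of
#'   per-bin statistics (fixed bins).
#' @param marks Observed mark vector (already normalized if the statistic
#'   expects normalized marks; marks are shuffled as-is, without
#'   re-normalization).
#' @param config An [envelope_config()].
#' @param concession_id Concession ids aligned with marks (needed for
#'   within-concession scope).
#' @return List with `lo`, `hi` (numeric per bin), `n_sim_eff` (integer per
#'   bin) and `null_stats` (the n_sim x n_bins matrix of null statistics).
#' @export
build_envelopes <- function(stat_fn, marks, config = envelope_config(),
                            concession_id = NULL) {
  stopifnot(inherits(config, "envelope_config"))
  seeds <- if (is.null(config$seed)) {
    # unseeded: draw replicate seeds from the session RNG
    sample.int(.Machine$integer.max, config$n_sim)
  } else {
    spawn_seeds(config$seed, config$n_sim)
  }
  sims <- vapply(
    seq_len(config$n_sim),
    function(k) {
      m <- shuffle_marks(marks, config$scope, seed = seeds[k],
                         concession_id = concession_id)
      stat_fn(m)
    },
    FUN.VALUE = numeric(length(stat_fn(marks)))
  )
  sims <- if (is.matrix(sims)) t(sims) else matrix(sims, ncol = 1L)  # n_sim x n_bins
  B <- ncol(sims)
  lo <- hi <- rep(NA_real_, B)
  n_eff <- integer(B)
  for (b in seq_len(B)) {
    v <- sims[, b]
    v <- v[!is.na(v)]
    n_eff[b] <- length(v)
    if (length(v) >= 2L * config$rank) {
      s <- sort(v)
      lo[b] <- s[config$rank]
      hi[b] <- s[length(s) + 1L - config$rank]
    }
  }
  list(lo = lo, hi = hi, n_sim_eff = n_eff, null_stats = sims)
}
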