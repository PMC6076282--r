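# Distance binning schemes for the mark correlation functions.
#
# Nearest-neighbour distances up to 150 m are binned into contiguous
# intervals [r - h, r + h] of width 2h for bandwidths h = 1.5, 5 and 10 m;
# beyond 150 m (up to 350 m) the interval width doubles relative to the
# matching near scheme to keep bins populated.  The cumulative scheme used
# by the density and aggregation correlation functions is the radius ladder
# 10, 20, ..., 350 m.

#' Construct a distance-bin specification
#'
#' @param centers Strictly increasing bin centres `r` in metres.
#' @param halfwidth Bandwidth `h` in metres; each bin covers the closed
#'   interval `[r - h, r + h]`.  `NA` for cumulative radii.
#' @param regime One of `"near"`, `"far"`, `"cumulative"`.
#' @return An object of class `bin_spec`.
#' @export
bin_spec <- function(centers, halfwidth, regime = "near") {
  if (!is.numeric(centers) || !length(centers) || any(diff(centers) <= 0)) {
    stop_ddd("`centers` must be strictly increasing")
  }
  if (!is.na(halfwidth)) check_number(halfwidth, "halfwidth", 0, strict = TRUE)
  regime <- match.arg(regime, c("near", "far", "cumulative"))
  structure(
    list(centers = as.numeric(centers), halfwidth = as.numeric(halfwidth),
         regime = regime),
    class = "bin_spec"
  )
}

#' @export
print.bin_spec <- function(x, ...) {
  cat(sprintf(
    "Bin spec (%s): %d centres from %g to %g m, h = %g m\n",
    x$regime, length(x$centers), min(x$centers), max(x$centers), x$halfwidth
  ))
  invisible(x)
}

#' Standard binning schemes
#'
#' `near_*` schemes cover 0-150 m with bandwidths 1.5, 5 and 10 m
#' (contiguous bins of width 2h, centres h, 3h, 5h, ...); `far_*` schemes
#' cover 150-350 m with the same bandwidths but doubled interval widths
#' (6, 20 and 40 m); `cumulative` is the radius ladder 10, 20, ..., 350 m.
#'
#' @param scheme One of `"near_1.5"`, `"near_5"`, `"near_10"`, `"far_3"`,
#'   `"far_10"`, `"far_20"`, `"cumulative"`.
#' @return A [bin_spec()].
#' @examples
#' make_bins("near_5")      # centres 5, 15, ..., 145
#' make_bins("cumulative")  # radii 10, 20, ..., 350
#' @export
make_bins <- function(scheme) {
  switch(scheme,
    near_1.5 = bin_spec(seq(1.5, 148.5, by = 3), 1.5, "near"),
    near_5 = bin_spec(seq(5, 145, by = 10), 5, "near"),
    near_10 = bin_spec(seq(10, 130, by = 20), 10, "near"),
    far_3 = bin_spec(seq(153, 347, by = 6), 3, "far"),
    far_10 = bin_spec(seq(160, 340, by = 20), 10, "far"),
    far_20 = bin_spec(seq(170, 330, by = 40), 20, "far"),
    cumulative = bin_spec(seq(10, 350, by = 10), NA_real_, "cumulative"),
    stop_ddd("unknown binning scheme: '", scheme, "'")
  )
}

#' Assign distances to bins
#'
#' Closed intervals `[r - h, r + h]`; a distance lying on a shared boundary
#' is assigned to the lower bin (deterministic tie-break).  Distances in no
#' bin get `NA`.
#' @noRd
assign_bins <- function(d, bins) {
  if (bins$regime == "cumulative") {
    stop_ddd("cumulative bin specs have no interval membership")
  }
  h <- bins$halfwidth
  idx <- rep(NA_integer_, length(d))
  for (k in seq_along(bins$centers)) {
    r <- bins$centers[k]
    hit <- is.na(idx) & d >= (r - h) & d <= (r + h)
    idx[hit] <- k
  }
  idx
}
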