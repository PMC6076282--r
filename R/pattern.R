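# Marked-pattern data model: trees with ecosystem-service marks inside
# polygonal concession windows.

#' Create a concession window
#'
#' A concession is the polygonal tenure unit within which tree density and
#' mark means are defined.  Windows carry the boundary polygon (planar
#' metres) and the derived area; tree density is attached when the window is
#' combined with trees in [marked_pattern()].
#'
#' @param concession_id Identifier (coerced to character).
#' @param boundary Two-column numeric matrix of polygon vertices in metres;
#'   the ring may be open or closed.
#' @return An object of class `concession_window` with fields
#'   `concession_id`, `boundary`, `area_m2`, `area_ha`.
#' @examples
#' w <- concession_window("c1", cbind(c(0, 1000, 1000, 0), c(0, 0, 1000, 1000)))
#' w$area_ha
#' @export
concession_window <- function(concession_id, boundary) {
  ring <- as_ring(boundary)
  area <- abs(ring_area_signed(ring))
  if (area <= 0) stop_ddd("window polygon has zero area")
  structure(
    list(
      concession_id = as.character(concession_id)[1L],
      boundary = ring,
      area_m2 = area,
      area_ha = area / M2_PER_HA
    ),
    class = "concession_window"
  )
}

#' Rectangular window helper
#'
#' @param concession_id Identifier.
#' @param width,height Side lengths in metres.
#' @param origin Numeric length-2, lower-left corner (metres).
#' @return A `concession_window`.
#' @export
rect_window <- function(concession_id, width, height, origin = c(0, 0)) {
  check_number(width, "width", 0, strict = TRUE)
  check_number(height, "height", 0, strict = TRUE)
  concession_window(concession_id, cbind(
    origin[1L] + c(0, width, width, 0),
    origin[2L] + c(0, 0, height, height)
  ))
}

#' @export
print.concession_window <- function(x, ...) {
  cat(sprintf(
    "Concession window '%s': %d vertices, area %.2f ha\n",
    x$concession_id, nrow(x$boundary), x$area_ha
  ))
  invisible(x)
}

#' Assemble a marked point pattern
#'
#' Binds a tree table to its concession windows, validates the geometry and
#' derives per-concession densities and mark means.  Marks are per-tree
#' seed production (kg per year) and above-ground biomass (kg); AGB is
#' derived from DBH via [agb_from_dbh()] when not supplied.  Trees with
#' missing DBH carry the seed mark only and are excluded from AGB analyses.
#'
#' @param trees Data frame with columns `tree_id`, `concession_id`, `x`,
#'   `y` (metres), and optionally `dbh_cm`, `seed_kg`, `agb_kg`.
#' @param windows A `concession_window`, or a list of them, covering every
#'   `concession_id` in `trees`.
#' @param allometry [allometry_params()] used to derive `agb_kg` from
#'   `dbh_cm` when the column is absent.
#' @param tol Containment tolerance in metres: trees within `tol` of the
#'   boundary count as inside.
#' @return An object of class `marked_pattern`: list with `trees` (validated
#'   data frame, one row per tree) and `windows` (named list of
#'   `concession_window`s with `n_trees`, `density_ha`, `density_m2`,
#'   `mean_seed_kg`, `mean_agb_kg` attached).
#' @examples
#' w <- rect_window("c1", 200, 200)
#' tr <- data.frame(
#'   tree_id = 1:3, concession_id = "c1",
#'   x = c(10, 50, 120), y = c(20, 60, 100),
#'   dbh_cm = c(40, 80, 120), seed_kg = c(10, 30, 50)
#' )
#' p <- marked_pattern(tr, w)
#' p
#' @export
marked_pattern <- function(trees, windows, allometry = allometry_params(),
                           tol = 1e-6) {
  trees <- as.data.frame(trees)
  required <- c("tree_id", "concession_id", "x", "y")
  missing_cols <- setdiff(required, names(trees))
  if (length(missing_cols)) {
    stop_ddd("trees table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (inherits(windows, "concession_window")) windows <- list(windows)
  if (!length(windows) || !all(vapply(windows, inherits, TRUE, "concession_window"))) {
    stop_ddd("`windows` must be one or more concession_window objects")
  }
  names(windows) <- vapply(windows, `[[`, "", "concession_id")
  if (anyDuplicated(names(windows))) stop_ddd("duplicate concession_id among windows")

  trees$tree_id <- as.character(trees$tree_id)
  trees$concession_id <- as.character(trees$concession_id)
  if (anyDuplicated(trees$tree_id)) {
    stop_ddd("duplicate tree_id: ", paste(unique(trees$tree_id[duplicated(trees$tree_id)])[1:5], collapse = ", "))
  }
  if (!is.numeric(trees$x) || !is.numeric(trees$y) ||
      anyNA(trees$x) || anyNA(trees$y) ||
      any(!is.finite(trees$x)) || any(!is.finite(trees$y))) {
    stop_ddd("tree coordinates must be finite numbers")
  }
  unknown <- setdiff(unique(trees$concession_id), names(windows))
  if (length(unknown)) {
    stop_ddd("trees reference concessions without windows: ", paste(unknown, collapse = ", "))
  }

  if (!"dbh_cm" %in% names(trees)) trees$dbh_cm <- NA_real_
  trees$dbh_cm <- as.numeric(trees$dbh_cm)
  bad_dbh <- which(!is.na(trees$dbh_cm) & trees$dbh_cm < 10)
  if (length(bad_dbh)) {
    stop_ddd(
      "DBH below the 10 cm inventory threshold for tree(s): ",
      paste(trees$tree_id[bad_dbh][seq_len(min(5, length(bad_dbh)))], collapse = ", ")
    )
  }
  if (!"seed_kg" %in% names(trees)) trees$seed_kg <- NA_real_
  trees$seed_kg <- as.numeric(trees$seed_kg)
  if (any(trees$seed_kg < 0, na.rm = TRUE)) stop_ddd("seed_kg must be >= 0")
  if (!"agb_kg" %in% names(trees)) {
    trees$agb_kg <- NA_real_
    has_dbh <- !is.na(trees$dbh_cm)
    if (any(has_dbh)) trees$agb_kg[has_dbh] <- agb_from_dbh(trees$dbh_cm[has_dbh], allometry)
  }
  trees$agb_kg <- as.numeric(trees$agb_kg)
  if (any(trees$agb_kg <= 0, na.rm = TRUE)) stop_ddd("agb_kg must be > 0")

  # containment and per-concession derived quantities
  for (cid in names(windows)) {
    w <- windows[[cid]]
    idx <- which(trees$concession_id == cid)
    if (length(idx)) {
      ok <- points_in_ring(trees$x[idx], trees$y[idx], w$boundary, tol = tol)
      if (!all(ok)) {
        stop_ddd(
          "tree(s) outside their concession window '", cid, "': ",
          paste(trees$tree_id[idx[!ok]][seq_len(min(5, sum(!ok)))], collapse = ", ")
        )
      }
    }
    w$n_trees <- length(idx)
    w$density_ha <- w$n_trees / w$area_ha
    w$density_m2 <- w$n_trees / w$area_m2
    w$mean_seed_kg <- if (length(idx)) mean(trees$seed_kg[idx]) else NA_real_
    w$mean_agb_kg <- if (any(!is.na(trees$agb_kg[idx]))) {
      mean(trees$agb_kg[idx], na.rm = TRUE)
    } else {
      NA_real_
    }
    windows[[cid]] <- w
  }

  rownames(trees) <- NULL
  structure(
    list(trees = trees, windows = windows),
    class = "marked_pattern"
  )
}

#' Number of trees in a pattern
#' @param x A `marked_pattern`.
#' @export
n_trees <- function(x) nrow(x$trees)

#' @export
print.marked_pattern <- function(x, ...) {
  nw <- length(x$windows)
  area <- sum(vapply(x$windows, `[[`, 0, "area_ha"))
  cat(sprintf(
    "Marked point pattern: %d trees in %d concession%s (%.1f ha total)\n",
    n_trees(x), nw, if (nw == 1L) "" else "s", area
  ))
  cat(sprintf(
    "  overall density %.3f trees/ha; DBH present for %d trees\n",
    n_trees(x) / area, sum(!is.na(x$trees$dbh_cm))
  ))
  invisible(x)
}

#' @export
summary.marked_pattern <- function(object, ...) {
  w <- object$windows
  tab <- data.frame(
    concession_id = names(w),
    area_ha = vapply(w, `[[`, 0, "area_ha"),
    n_trees = vapply(w, `[[`, 0, "n_trees"),
    density_ha = vapply(w, `[[`, 0, "density_ha"),
    mean_seed_kg = vapply(w, `[[`, 0, "mean_seed_kg"),
    mean_agb_kg = vapply(w, `[[`, 0, "mean_agb_kg"),
    row.names = NULL
  )
  structure(list(pattern = object, concessions = tab), class = "summary.marked_pattern")
}

#' @export
print.summary.marked_pattern <- function(x, ...) {
  print(x$pattern)
  cat("\nPer-concession summary:\n")
  print(x$concessions, digits = 4)
  invisible(x)
}

#' Extract the mark vector of a pattern
#'
#' @param pattern A `marked_pattern`.
#' @param mark `"seed"` (seed production, kg) or `"agb"` (above-ground
#'   biomass, kg).  AGB is `NA` for trees without DBH.
#' @return Numeric vector aligned with `pattern$trees`.
#' @export
pattern_marks <- function(pattern, mark = c("seed", "agb")) {
  mark <- match.arg(mark)
  if (mark == "seed") pattern$trees$seed_kg else pattern$trees$agb_kg
}
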