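# Readers, writers and the end-to-end pipeline.
#
# Tree tables are CSV with header tree_id, concession_id, x, y, dbh_cm and
# either seed_kg or seed_latas (lata counts are converted on read).
# Concession windows are GeoJSON FeatureCollections of Polygons with a
# `concession_id` property; coordinates are planar metres unless
# `coords = "lonlat"`, in which case they are projected to UTM first.

#' Read a tree table
#'
#' Validates every row (finite coordinates, DBH >= 10 cm where present,
#' non-negative seed production, unique tree ids) and reports offending
#' rows by line number.  A `seed_latas` column is converted to `seed_kg`
#' via [latas_to_kg()].
#'
#' @param path CSV file path.
#' @param params [allometry_params()] for the lata conversion.
#' @param coords `"planar"` (metres, default) or `"lonlat"` (projected via
#'   [project_lonlat()]).
#' @param zone,south UTM zone settings used when `coords = "lonlat"`.
#' @return Data frame ready for [marked_pattern()].
#' @export
read_trees <- function(path, params = allometry_params(),
                       coords = c("planar", "lonlat"), zone = 19L, south = TRUE) {
  coords <- match.arg(coords)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("tree_id", "concession_id", "x", "y")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop_ddd("tree table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!("seed_kg" %in% names(tab)) && !("seed_latas" %in% names(tab))) {
    stop_ddd("tree table needs a seed_kg or seed_latas column")
  }
  line <- seq_len(nrow(tab)) + 1L  # header is line 1
  problems <- character(0)
  flag <- function(bad, what) {
    if (any(bad)) {
      problems <<- c(problems, sprintf(
        "%s (lines %s)", what,
        paste(line[bad][seq_len(min(5, sum(bad)))], collapse = ", ")
      ))
    }
  }
  tab$x <- suppressWarnings(as.numeric(tab$x))
  tab$y <- suppressWarnings(as.numeric(tab$y))
  flag(!is.finite(tab$x) | !is.finite(tab$y), "non-numeric coordinates")
  flag(duplicated(tab$tree_id), "duplicate tree_id")
  if ("dbh_cm" %in% names(tab)) {
    tab$dbh_cm <- suppressWarnings(as.numeric(tab$dbh_cm))
    flag(!is.na(tab$dbh_cm) & tab$dbh_cm < 10,
         "DBH below the 10 cm inventory threshold")
  }
  if ("seed_latas" %in% names(tab)) {
    tab$seed_latas <- suppressWarnings(as.numeric(tab$seed_latas))
    flag(is.na(tab$seed_latas) | tab$seed_latas < 0, "invalid seed_latas")
  } else {
    tab$seed_kg <- suppressWarnings(as.numeric(tab$seed_kg))
    flag(is.na(tab$seed_kg) | tab$seed_kg < 0, "invalid seed_kg")
  }
  if (length(problems)) {
    stop_ddd("invalid rows in '", path, "': ", paste(problems, collapse = "; "))
  }
  if ("seed_latas" %in% names(tab)) {
    tab$seed_kg <- latas_to_kg(tab$seed_latas, params)
    tab$seed_latas <- NULL
  }
  if (coords == "lonlat") {
    xy <- project_lonlat(tab$x, tab$y, zone = zone, south = south)
    tab$x <- xy[, 1L]
    tab$y <- xy[, 2L]
  }
  tab
}

#' Write a tree table
#'
#' @param pattern A [marked_pattern()] (or a plain tree data frame).
#' @param path CSV file path.
#' @export
write_trees <- function(pattern, path) {
  trees <- if (inherits(pattern, "marked_pattern")) pattern$trees else as.data.frame(pattern)
  # 17 significant digits so doubles survive the text round trip exactly
  for (col in names(trees)) {
    if (is.double(trees[[col]])) {
      v <- sprintf("%.17g", trees[[col]])
      v[is.na(trees[[col]])] <- NA_character_
      trees[[col]] <- v
    }
  }
  utils::write.csv(trees, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read concession windows from GeoJSON
#'
#' Expects a FeatureCollection of Polygon features, each with a
#' `concession_id` property; only the outer ring is used.
#'
#' @param path GeoJSON file path.
#' @param coords `"planar"` or `"lonlat"` (projected via [project_lonlat()]).
#' @param zone,south UTM settings for `coords = "lonlat"`.
#' @return Named list of [concession_window()]s.
#' @export
read_windows_geojson <- function(path, coords = c("planar", "lonlat"),
                                 zone = 19L, south = TRUE) {
  coords <- match.arg(coords)
  gj <- jsonlite::read_json(path)
  if (is.null(gj$type) || gj$type != "FeatureCollection") {
    stop_ddd("'", path, "' is not a GeoJSON FeatureCollection")
  }
  wins <- lapply(gj$features, function(f) {
    if (is.null(f$geometry) || f$geometry$type != "Polygon") {
      stop_ddd("every feature must be a Polygon")
    }
    cid <- f$properties$concession_id
    if (is.null(cid)) stop_ddd("feature without concession_id property")
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1L]], function(p) {
      c(as.numeric(p[[1L]]), as.numeric(p[[2L]]))
    }))
    if (coords == "lonlat") ring <- project_lonlat(ring[, 1L], ring[, 2L], zone, south)
    concession_window(cid, ring)
  })
  names(wins) <- vapply(wins, `[[`, "", "concession_id")
  wins
}

#' Write concession windows to GeoJSON
#'
#' @param windows A list of [concession_window()]s or a `marked_pattern`.
#' @param path Output file path.
#' @export
write_windows_geojson <- function(windows, path) {
  if (inherits(windows, "marked_pattern")) windows <- windows$windows
  features <- lapply(windows, function(w) {
    ring <- rbind(w$boundary, w$boundary[1L, ])  # close the ring
    list(
      type = "Feature",
      properties = list(concession_id = w$concession_id),
      geometry = list(
        type = "Polygon",
        coordinates = list(lapply(seq_len(nrow(ring)), function(i) {
          as.numeric(ring[i, ])
        }))
      )
    )
  })
  gj <- list(type = "FeatureCollection", features = unname(features))
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a mark-function result as CSV
#'
#' One row per distance bin with the statistic, contributing count,
#' envelope bounds and significance flag.
#'
#' @param result A `markfun` object.
#' @param path Output CSV path.
#' @export
write_markfun_csv <- function(result, path) {
  stopifnot(inherits(result, "markfun"))
  out <- as.data.frame(result)
  out$fun <- attr(result, "fun")
  out$mark <- attr(result, "mark")
  out <- out[, c("fun", "mark", setdiff(names(out), c("fun", "mark")))]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) a marked pattern, then for each requested mark
#' computes the four mark correlation functions with permutation
#' envelopes and the plot-size scaling curve, writing result CSVs, the
#' input data and a plain-text run manifest to `out_dir`.  Reruns with the
#' same seeds reproduce identical outputs.
#'
#' @param out_dir Output directory (created if absent).
#' @param pattern A [marked_pattern()]; alternatively give `scenario` to
#'   simulate one.
#' @param scenario A [scenario_config()] used when `pattern` is NULL.
#' @param marks Character subset of `c("seed", "agb")`.
#' @param scheme Interval bin scheme for the nearest-neighbour functions.
#' @param radii Cumulative radii for the density/aggregation functions
#'   (kept short by default; the full ladder is `seq(10, 350, 10)`).
#' @param envelope An [envelope_config()]; its seed is derived from `seed`
#'   when unset.
#' @param scaling A [scaling_config()] or NULL to skip the scaling stage.
#' @param seed Master seed for simulation and envelopes.
#' @param n_concessions,area_range_ha Overrides passed to
#'   [simulate_scenario()].
#' @return Invisibly, a list with the pattern, results and manifest.
#' @export
run_pipeline <- function(out_dir, pattern = NULL, scenario = scenario_config(),
                         marks = c("seed", "agb"), scheme = "near_5",
                         radii = seq(25, 150, by = 25),
                         envelope = envelope_config(),
                         scaling = scaling_config(cell_sizes_m = c(50, 100, 150, 200)),
                         seed = 1L, n_concessions = NULL, area_range_ha = NULL) {
  marks <- match.arg(marks, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- spawn_seeds(seed, 2L)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_ddd("pipeline stage '", name, "' failed: ", conditionMessage(e))
    })
  }
  if (is.null(pattern)) {
    pattern <- stage("simulate", simulate_scenario(
      scenario, seed = seeds[1L],
      n_concessions = n_concessions, area_range_ha = area_range_ha
    ))
  }
  write_trees(pattern, file.path(out_dir, "trees.csv"))
  write_windows_geojson(pattern, file.path(out_dir, "windows.geojson"))

  if (is.null(envelope$seed)) envelope$seed <- seeds[2L]
  ef <- edge_filter_nn(pattern)
  results <- list()
  counts <- list(
    trees_total = n_trees(pattern),
    trees_retained_nn_filter = sum(ef$retained),
    trees_dropped_nn_filter = ef$n_dropped,
    trees_without_neighbour = ef$n_no_neighbour,
    fraction_dropped_nn_filter = ef$fraction_dropped
  )
  for (mk in marks) {
    for (fn in MARKFUN_CHOICES) {
      bins <- if (fn %in% c("nnmean", "schlather")) make_bins(scheme) else
        bin_spec(radii, NA_real_, "cumulative")
      res <- stage(paste(fn, mk), mark_correlation(
        pattern, mark = mk, fun = fn, bins = bins, envelope = envelope
      ))
      key <- paste(fn, mk, sep = "_")
      results[[key]] <- res
      write_markfun_csv(res, file.path(out_dir, paste0(key, ".csv")))
    }
    if (!is.null(scaling)) {
      sc <- stage(paste("scaling", mk), scaling_curve(pattern, mk, scaling))
      results[[paste0("scaling_", mk)]] <- sc
      utils::write.csv(as.data.frame(sc),
                       file.path(out_dir, paste0("scaling_", mk, ".csv")),
                       row.names = FALSE)
    }
  }

  manifest <- c(
    sprintf("markddd pipeline manifest"),
    sprintf("package_version: %s", as.character(utils::packageVersion("markddd"))),
    sprintf("date: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("master_seed: %d", as.integer(seed)),
    sprintf("envelope_seed: %d", as.integer(envelope$seed)),
    sprintf("n_sim: %d  rank: %d  scope: %s", envelope$n_sim, envelope$rank,
            envelope$scope),
    sprintf("scheme: %s  radii: %s", scheme, paste(radii, collapse = ",")),
    vapply(names(counts), function(k) sprintf("%s: %s", k, format(counts[[k]])), ""),
    sprintf("input_digest_trees: %s",
            unname(tools::md5sum(file.path(out_dir, "trees.csv")))),
    sprintf("input_digest_windows: %s",
            unname(tools::md5sum(file.path(out_dir, "windows.geojson")))),
    vapply(names(results), function(k) {
      sprintf("result_rows_%s: %d", k, nrow(results[[k]]))
    }, "")
  )
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  invisible(list(pattern = pattern, results = results, manifest = manifest,
                 counts = counts))
}
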