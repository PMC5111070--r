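# End-to-end orchestration: configuration, input validation, and the
# run-all pipeline producing a machine-readable report.

#' Pipeline configuration
#'
#' Gathers every module threshold with its field default: 144 km^2
#' thinning cells, the 0.364-style decision threshold (selected from the
#' data when `NULL`), 0.5/0.75 class bounds, 1.7 km occupancy radius
#' (recomputed as the median outside distance when `NULL`), 15 km grouping
#' radius, 50-adult population threshold, 230 km^2 good-area threshold,
#' reference density 1 / 100 km^2, and `r_max` 100.
#'
#' @param suitability_asc path to the suitability ASCII grid.
#' @param roads_geojson path to road polylines (optional).
#' @param records_csv path to presence records (optional).
#' @param units_csv unit-evidence table enabling prioritization-only mode.
#' @param out_dir artifact directory (created).
#' @param threshold,class_bounds,thin_cell_area_km2 suitability settings.
#' @param occupancy_radius_km,grouping_radius_km occupancy/grouping radii.
#' @param pop_threshold,good_area_threshold_km2 unit classification bars.
#' @param reference_density_per100km2,r_max capacity-rule density and
#'   maximum movement resistance.
#' @param n_background,n_replicates evaluation settings.
#' @param secr a [secr_config()].
#' @param seed integer seed.
#' @export
pipeline_config <- function(suitability_asc = NULL, roads_geojson = NULL,
                            records_csv = NULL, units_csv = NULL,
                            out_dir = tempfile("onca_out_"),
                            threshold = NULL, class_bounds = c(0.5, 0.75),
                            thin_cell_area_km2 = 144,
                            occupancy_radius_km = NULL,
                            grouping_radius_km = 15, pop_threshold = 50,
                            good_area_threshold_km2 = 230,
                            reference_density_per100km2 = 1.0,
                            r_max = 100, n_background = 10000,
                            n_replicates = 10, secr = secr_config(),
                            seed = 1) {
  cfg <- as.list(environment())
  for (nm in c("thin_cell_area_km2", "grouping_radius_km", "pop_threshold",
               "good_area_threshold_km2", "reference_density_per100km2")) {
    if (cfg[[nm]] <= 0) stop(nm, " must be positive", call. = FALSE)
  }
  if (r_max < 1) stop("r_max must be >= 1", call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

#' Validate pipeline inputs
#'
#' Checks raster value range and header, GeoJSON parseability, CSV schemas
#' and detection/trap referential integrity. Failures are reported, not
#' raised.
#'
#' @param paths named list with any of `suitability_asc`, `roads_geojson`,
#'   `records_csv`, `traps_csv`, `detections_csv`, `units_csv`.
#' @return data.frame `input`, `ok`, `message` (one row per check).
#' @export
validate_inputs <- function(paths) {
  rows <- list()
  note <- function(input, ok, message = "") {
    rows[[length(rows) + 1L]] <<- data.frame(input = input, ok = ok,
                                             message = message)
  }
  check <- function(input, expr) {
    res <- tryCatch({ expr; NULL }, error = function(e) conditionMessage(e))
    note(input, is.null(res), res %||% "")
  }
  if (!is.null(paths$suitability_asc)) {
    check("suitability_asc", read_ascii_grid(paths$suitability_asc))
  }
  if (!is.null(paths$roads_geojson)) {
    check("roads_geojson", read_lines_geojson(paths$roads_geojson))
  }
  if (!is.null(paths$records_csv)) {
    check("records_csv", {
      df <- read.csv(paths$records_csv)
      miss <- setdiff(c("x_km", "y_km"), names(df))
      if (length(miss)) stop("missing columns: ",
                             paste(miss, collapse = ", "))
    })
  }
  if (!is.null(paths$traps_csv) && !is.null(paths$detections_csv)) {
    check("detections_csv", {
      traps <- read.csv(paths$traps_csv)
      det <- read.csv(paths$detections_csv)
      bad <- setdiff(det$trap_id, traps$trap_id)
      if (length(bad)) stop("detections reference unknown trap_id: ",
                            paste(unique(bad), collapse = ", "))
    })
  }
  if (!is.null(paths$units_csv)) {
    check("units_csv", read_unit_table(paths$units_csv))
  }
  do.call(rbind, rows) %||%
    data.frame(input = character(0), ok = logical(0),
               message = character(0))
}

#' Run the full pipeline
#'
#' Executes suitability evaluation, occupancy, prioritization and
#' connectivity on the configured inputs, writes artifacts plus a JSON
#' report to `config$out_dir`, and returns the report. With only
#' `units_csv` set, runs in prioritization-only mode (classification and
#' population aggregation from the evidence table; no rasters required).
#' Identical `(config, seed)` produce identical reports.
#'
#' @param config a [pipeline_config()].
#' @return the report list, invisibly; also written to
#'   `file.path(config$out_dir, "report.json")`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = config$seed)

  units <- NULL
  if (!is.null(config$units_csv)) {
    units <- read_unit_table(config$units_csv)
  }

  if (!is.null(config$suitability_asc)) {
    r <- read_ascii_grid(config$suitability_asc)
    roads <- if (!is.null(config$roads_geojson)) {
      read_lines_geojson(config$roads_geojson)
    } else list()
    records <- if (!is.null(config$records_csv)) {
      read.csv(config$records_csv, stringsAsFactors = FALSE)
    } else stop("records_csv is required with a suitability raster",
                call. = FALSE)

    sr <- suitability_report(r, records, threshold = config$threshold,
                             n_background = config$n_background,
                             n_replicates = config$n_replicates,
                             thin_cell_area_km2 = config$thin_cell_area_km2,
                             seed = config$seed)
    report$suitability <- sr
    cm <- reclassify(r, sr$threshold,
                     adapt_class_bounds(sr$threshold, config$class_bounds))
    report$class_areas_km2 <- as.list(class_areas(cm))

    frags <- extract_fragments(cm, roads)
    radius <- config$occupancy_radius_km %||%
      tryCatch(median_outside_distance(records, frags),
               error = function(e) 1.7)
    labels <- classify_occupancy(frags, records, radius)
    report$occupancy <- list(
      radius_km = radius,
      summary = occupancy_summary(frags, labels),
      ratios = occupancy_ratios(
        class_areas(cm),
        sum(vapply(frags, `[[`, 0, "area_km2")[labels$label == "AJO"]),
        sum(vapply(frags, `[[`, 0, "area_km2")[labels$label == "APJO"]))
    )
    write_fragments_geojson(frags, r,
                            file.path(config$out_dir, "fragments.geojson"),
                            labels)

    # both-sexes evidence per fragment from the records' sex column
    bs_ids <- integer(0)
    if ("sex" %in% names(records)) {
      for (fr in frags) {
        d <- point_fragment_distance(fr, records$x_km, records$y_km)
        sexes <- records$sex[d < radius | d == 0]
        if (any(sexes == "F") && any(sexes == "M")) {
          bs_ids <- c(bs_ids, fr$id)
        }
      }
    }
    sunits <- group_fragments(frags, labels, config$grouping_radius_km,
                              both_sexes_ids = bs_ids)
    cls <- lapply(sunits, classify_unit,
                  pop_threshold = config$pop_threshold,
                  good_area_threshold_km2 = config$good_area_threshold_km2,
                  reference_density_per100km2 =
                    config$reference_density_per100km2)
    empty <- frags[vapply(frags, `[[`, 0L, "id") %in%
                     labels$fragment_id[labels$label == "empty"]]
    report$prioritization <- list(
      units = lapply(seq_along(sunits), function(i) {
        u <- sunits[[i]]
        list(unit_id = u$unit_id, fragment_ids = u$fragment_ids,
             total_area_km2 = u$total_area_km2, ajo_km2 = u$ajo_km2,
             apjo_km2 = u$apjo_km2, good_area_km2 = u$good_area_km2,
             both_sexes = u$both_sexes_confirmed,
             label = cls[[i]]$label,
             recommendation = recommend_action(cls[[i]]$label))
      }),
      empty_areas = classify_empty_areas(
        empty, sunits, cls, config$grouping_radius_km,
        config$good_area_threshold_km2)
    )

    if (length(sunits) >= 2L) {
      surf <- resistance_from_suitability(r, config$r_max)
      cells <- lapply(sunits, function(u) {
        do.call(rbind, lapply(u$members, `[[`, "cells"))
      })
      names(cells) <- paste0("U", vapply(sunits, `[[`, 0L, "unit_id"))
      link <- least_cost_linkages(surf, cells)
      report$connectivity <- list(cost = link$cost)
      if (length(link$paths)) {
        write_lines_geojson(unname(link$paths),
                            file.path(config$out_dir, "linkages.geojson"),
                            data.frame(pair = names(link$paths)))
      }
    }
  }

  if (!is.null(units)) {
    cls <- lapply(units, classify_unit,
                  pop_threshold = config$pop_threshold,
                  good_area_threshold_km2 = config$good_area_threshold_km2,
                  reference_density_per100km2 =
                    config$reference_density_per100km2)
    labs <- vapply(cls, `[[`, "", "label")
    report$unit_table <- data.frame(
      name = vapply(units, `[[`, "", "name"),
      label = labs,
      total_area_km2 = vapply(units, `[[`, 0, "total_area_km2"),
      stringsAsFactors = FALSE)
    report$unit_counts <- list(
      JCU = sum(labs %in% c("JCU_I", "JCU_II")),
      JCU_I = sum(labs == "JCU_I"), JCU_II = sum(labs == "JCU_II"),
      PJCU = sum(labs == "PJCU"),
      small_fragment = sum(labs == "small_fragment"))
    report$aggregate_population <-
      as.list(aggregate_population(units))
  }

  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE, force = TRUE)
  invisible(report)
}
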