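# Rule-based classification of conservation units: occupied fragments are
# grouped into candidate units, classified as JCU Type I / Type II / PJCU /
# small fragment, record-free habitat is classified as potential expansion
# or future core area, and per-unit population estimates are aggregated.

#' Evidence describing a candidate conservation unit
#'
#' @param unit_id identifier.
#' @param fragment_ids member fragment ids.
#' @param ajo_km2,apjo_km2 occupied / potentially occupied member areas.
#' @param good_area_km2 medium + high suitability area (km^2).
#' @param both_sexes_confirmed were both a male and a female detected.
#' @param population_estimate optional `c(point, low, high)` from
#'   [population_from_fit()], or `NULL` when the unit was not surveyed.
#' @param total_area_km2 defaults to `ajo_km2 + apjo_km2`.
#' @param name optional display name.
#' @export
unit_evidence <- function(unit_id, fragment_ids = integer(0),
                          ajo_km2 = 0, apjo_km2 = 0, good_area_km2 = 0,
                          both_sexes_confirmed = FALSE,
                          population_estimate = NULL,
                          total_area_km2 = ajo_km2 + apjo_km2,
                          name = as.character(unit_id)) {
  if (!is.null(population_estimate)) {
    population_estimate <- as.numeric(population_estimate)
    if (length(population_estimate) != 3L || anyNA(population_estimate)) {
      stop("population_estimate must be c(point, low, high)",
           call. = FALSE)
    }
  }
  structure(list(unit_id = unit_id, name = name,
                 fragment_ids = fragment_ids,
                 total_area_km2 = total_area_km2, ajo_km2 = ajo_km2,
                 apjo_km2 = apjo_km2, good_area_km2 = good_area_km2,
                 both_sexes_confirmed = isTRUE(both_sexes_confirmed),
                 population_estimate = population_estimate),
            class = "unit_evidence")
}

#' Group labelled fragments into candidate units
#'
#' Single-linkage clustering of AJO/APJO fragments: two fragments join the
#' same unit when their boundary-to-boundary distance is strictly less
#' than `grouping_radius_km` (default 15 km, the radius of the largest
#' home range), or when the pair is listed in `forced_merges` (units joined
#' by decree regardless of distance, e.g. for shared management).
#'
#' @param fragments list from [extract_fragments()].
#' @param labels data.frame from [classify_occupancy()].
#' @param grouping_radius_km linkage distance (km), >= 0.
#' @param forced_merges list of length-2 vectors of fragment ids.
#' @param both_sexes_ids fragment ids with both sexes detected; a unit is
#'   flagged `both_sexes_confirmed` when it contains one.
#' @return list of [unit_evidence()] objects; each also carries `members`
#'   (the member fragment objects) for downstream geometry work.
#' @export
group_fragments <- function(fragments, labels, grouping_radius_km = 15,
                            forced_merges = list(),
                            both_sexes_ids = integer(0)) {
  if (grouping_radius_km < 0) stop("grouping_radius_km must be >= 0",
                                   call. = FALSE)
  ids <- vapply(fragments, `[[`, 0L, "id")
  lab <- labels$label[match(ids, labels$fragment_id)]
  keep <- which(lab %in% c("AJO", "APJO"))
  if (!length(keep)) return(list())
  sub <- fragments[keep]
  m <- length(sub)
  edges <- integer(0)
  if (m > 1L) {
    for (i in seq_len(m - 1L)) {
      for (j in seq.int(i + 1L, m)) {
        if (fragment_distance(sub[[i]], sub[[j]]) < grouping_radius_km) {
          edges <- c(edges, i, j)
        }
      }
    }
  }
  sub_ids <- ids[keep]
  for (fm in forced_merges) {
    a <- match(fm[1L], sub_ids); b <- match(fm[2L], sub_ids)
    if (!is.na(a) && !is.na(b)) edges <- c(edges, a, b)
  }
  g <- igraph::make_graph(edges, n = m, directed = FALSE)
  comp <- igraph::components(g)$membership
  lapply(seq_len(max(comp)), function(u) {
    members <- sub[comp == u]
    mem_ids <- sub_ids[comp == u]
    mem_lab <- lab[keep][comp == u]
    areas <- vapply(members, `[[`, 0, "area_km2")
    ev <- unit_evidence(
      unit_id = u, fragment_ids = mem_ids,
      ajo_km2 = sum(areas[mem_lab == "AJO"]),
      apjo_km2 = sum(areas[mem_lab == "APJO"]),
      good_area_km2 = sum(vapply(members, `[[`, 0, "good_area_km2")),
      both_sexes_confirmed = any(mem_ids %in% both_sexes_ids)
    )
    ev$members <- members
    ev
  })
}

#' Classify a candidate unit
#'
#' Units with both sexes confirmed are JCUs: Type I when the population
#' point estimate is `>= pop_threshold` (default 50 adults) *or* when the
#' occupied area could hold that many at the reference density
#' (capacity rule: `ajo_km2 * reference_density / 100 >= pop_threshold`);
#' otherwise Type II. Units without both sexes are PJCU when their
#' good-condition habitat reaches `good_area_threshold_km2` (default
#' 230 km^2, the good habitat of the smallest JCU), else small fragments.
#'
#' @param ev a [unit_evidence()].
#' @param pop_threshold adults needed for Type I.
#' @param good_area_threshold_km2 good habitat needed for PJCU.
#' @param reference_density_per100km2 density used by the capacity rule.
#' @return list `unit_id`, `label` in
#'   `{JCU_I, JCU_II, PJCU, small_fragment}`, `rationale` codes.
#' @export
classify_unit <- function(ev, pop_threshold = 50,
                          good_area_threshold_km2 = 230,
                          reference_density_per100km2 = 1.0) {
  stopifnot(inherits(ev, "unit_evidence"))
  rationale <- character(0)
  if (ev$both_sexes_confirmed) {
    capacity <- ev$ajo_km2 * reference_density_per100km2 / 100
    pt <- if (!is.null(ev$population_estimate)) {
      ev$population_estimate[1L]
    } else {
      rationale <- c(rationale, "no_estimate_capacity_only")
      NA_real_
    }
    if (!is.na(pt) && pt >= pop_threshold) {
      label <- "JCU_I"; rationale <- c(rationale, "estimate_ge_threshold")
    } else if (capacity >= pop_threshold) {
      label <- "JCU_I"; rationale <- c(rationale, "capacity_ge_threshold")
    } else {
      label <- "JCU_II"; rationale <- c(rationale, "below_threshold")
    }
  } else if (ev$good_area_km2 >= good_area_threshold_km2) {
    label <- "PJCU"; rationale <- c(rationale, "good_area_ge_threshold")
  } else {
    label <- "small_fragment"; rationale <- c(rationale, "good_area_below_threshold")
  }
  list(unit_id = ev$unit_id, name = ev$name, label = label,
       rationale = rationale)
}

#' Classify record-free habitat fragments
#'
#' A record-free fragment within `radius_km` of a JCU or PJCU is a
#' potential `expansion` area of that unit; an isolated fragment whose
#' contiguous good-condition habitat reaches `core_area_threshold_km2` is a
#' potential future `core` area; anything else is `other`.
#'
#' @param empty_fragments fragments labelled `empty`.
#' @param units list from [group_fragments()] (with `members`).
#' @param unit_labels classifications from [classify_unit()]; only units
#'   labelled JCU or PJCU attract expansion areas.
#' @param radius_km proximity distance (km).
#' @param core_area_threshold_km2 good-habitat bar for core areas.
#' @return data.frame `fragment_id`, `label`.
#' @export
classify_empty_areas <- function(empty_fragments, units, unit_labels,
                                 radius_km = 15,
                                 core_area_threshold_km2 = 230) {
  lab_by_unit <- vapply(unit_labels, `[[`, "", "label")
  attract <- which(lab_by_unit %in% c("JCU_I", "JCU_II", "PJCU"))
  out <- vapply(empty_fragments, function(fr) {
    near <- FALSE
    for (u in attract) {
      dd <- vapply(units[[u]]$members, function(mf) {
        fragment_distance(fr, mf)
      }, 0)
      if (any(dd < radius_km)) { near <- TRUE; break }
    }
    if (near) "expansion"
    else if (fr$good_area_km2 >= core_area_threshold_km2) "core"
    else "other"
  }, "")
  data.frame(fragment_id = vapply(empty_fragments, `[[`, 0L, "id"),
             label = out, stringsAsFactors = FALSE)
}

#' Aggregate population estimates across units
#'
#' Component-wise sums of `(point, low, high)` over the units that carry an
#' estimate.
#'
#' @param units list of [unit_evidence()].
#' @return numeric `c(point, low, high)`.
#' @export
aggregate_population <- function(units) {
  ests <- Filter(Negate(is.null),
                 lapply(units, `[[`, "population_estimate"))
  if (!length(ests)) stop("no unit carries a population estimate",
                          call. = FALSE)
  out <- Reduce(`+`, ests)
  names(out) <- c("point", "low", "high")
  out
}

RECOMMENDATIONS <- list(
  JCU_I = paste("Reduce all sources of mortality and poaching of prey.",
                "Maintain connectivity among the unit's habitat blocks.",
                "Monitor the population."),
  JCU_II = paste("Reduce all sources of mortality.",
                 "Evaluate connectivity with neighbouring units.",
                 "Monitor the population including genetic diversity."),
  JCU_II_isolated = paste("Reduce all sources of mortality.",
                          "Evaluate the supplementation of individuals.",
                          "Monitor the population including genetic",
                          "diversity."),
  PJCU = paste("Evaluate the status of the population. If a population",
               "exists, reduce all sources of mortality and evaluate its",
               "main threats and habitat connectivity with neighbouring",
               "units."),
  small_fragment = paste("Area too small to maintain a population. Reduce",
                         "mortality threats. Evaluate connectivity with a",
                         "conservation unit. Studies of movements in the",
                         "human-dominated matrix are recommended."),
  expansion = paste("Potential expansion area: manage to enlarge the",
                    "neighbouring conservation unit."),
  core = paste("Potential future core area: candidate for natural",
               "recolonization or reintroduction programs.")
)

#' Management recommendation for a classified unit
#'
#' Static lookup from the unit label (plus an isolation flag) to the
#' standard recommendation template.
#'
#' @param label one of `JCU_I`, `JCU_II`, `PJCU`, `small_fragment`,
#'   `expansion`, `core`.
#' @param isolated is the unit isolated from other units.
#' @return recommendation text.
#' @export
recommend_action <- function(label, isolated = FALSE) {
  key <- if (label == "JCU_II" && isolated) "JCU_II_isolated" else label
  if (is.null(RECOMMENDATIONS[[key]])) {
    stop("unknown unit label: ", label, call. = FALSE)
  }
  RECOMMENDATIONS[[key]]
}

#' Read a unit-evidence table
#'
#' CSV with one row per unit: `name`, `both_sexes` (0/1),
#' `total_area_km2`, `ajo_km2`, `apjo_km2`, `good_area_km2`, and the
#' estimate triple `pop_point`, `pop_low`, `pop_high` (empty when not
#' surveyed). Enables the prioritization stage without rasters.
#'
#' @param path CSV path.
#' @return list of [unit_evidence()].
#' @export
read_unit_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("name", "both_sexes", "total_area_km2", "ajo_km2", "apjo_km2",
            "good_area_km2", "pop_point", "pop_low", "pop_high")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("unit table missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    est <- if (is.na(df$pop_point[i])) NULL else {
      c(df$pop_point[i], df$pop_low[i], df$pop_high[i])
    }
    unit_evidence(unit_id = i, name = df$name[i],
                  ajo_km2 = df$ajo_km2[i], apjo_km2 = df$apjo_km2[i],
                  good_area_km2 = df$good_area_km2[i],
                  both_sexes_confirmed = df$both_sexes[i] == 1,
                  population_estimate = est,
                  total_area_km2 = df$total_area_km2[i])
  })
}
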