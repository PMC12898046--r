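# Experiment drivers behind the command-line front end: solve an instance,
# compare manual selection schemes against the optimized front, run the
# parameter sensitivity sweeps, and benchmark indicator scores over seeds.

#' Solve an instance and write run artifacts
#'
#' Runs the NSGA-II engine and, when `out_dir` is given, writes the front as
#' JSON (plans + objectives + resolved configuration and seed), a summary
#' CSV (one row per solution: count of selected hospitals, patient cost,
#' hospital cost), and the per-generation convergence log CSV.
#'
#' @param inst A `problem_instance` or a path accepted by
#'   [load_instance()].
#' @param config Engine settings from [engine_config()].
#' @param out_dir Optional artifact directory (created if needed).
#' @return The `pareto_set`, invisibly when writing artifacts.
#' @export
run_solve <- function(inst, config = engine_config(), out_dir = NULL) {
  if (is.character(inst)) inst <- load_instance(inst)
  res <- evolve(inst, config)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    summary <- as.data.frame(res)
    utils::write.csv(summary, file.path(out_dir, "front.csv"),
                     row.names = FALSE)
    utils::write.csv(res$convergence, file.path(out_dir, "convergence.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(seed = config$seed,
           config = config[setdiff(names(config), "operator")],
           operator = config$operator,
           solutions = lapply(res$plans, function(p) {
             list(x = as.list(p$x), y = as.list(p$y), z = as.list(p$z),
                  w = as.list(p$w), f1 = p$objectives[["f1"]],
                  f2 = p$objectives[["f2"]])
           })),
      file.path(out_dir, "front.json"), auto_unbox = TRUE, digits = NA)
    return(invisible(res))
  }
  res
}

#' Evaluate manual selection schemes against the optimized front
#'
#' Each scheme (a character vector of facility ids) is evaluated through the
#' same plan construction as the optimizer, except that selected facilities
#' serving no demand point are kept as given — they still force contracts —
#' and reported in a warning rather than silently repaired. Each scheme is
#' then flagged dominated or non-dominated relative to the optimized front.
#'
#' @param inst A `problem_instance` or instance path.
#' @param schemes Named list of character vectors of facility ids.
#' @param front A `pareto_set` from [evolve()]/[run_solve()]; computed with
#'   `config` when missing.
#' @param config Engine settings used when `front` is missing.
#' @return Data frame: one row per scheme with `scheme`, `n_selected`,
#'   `patient_cost`, `hospital_cost`, `dominated`, `unused` (ids of
#'   selected-but-unused facilities, comma-separated).
#' @export
run_compare <- function(inst, schemes, front = NULL,
                        config = engine_config()) {
  if (is.character(inst)) inst <- load_instance(inst)
  if (!length(schemes)) stop("no manual scheme supplied", call. = FALSE)
  if (is.null(names(schemes)) || any(names(schemes) == "")) {
    names(schemes) <- paste0("scheme_", seq_along(schemes))
  }
  fac_ids <- inst$facilities$id
  for (nm in names(schemes)) {
    bad <- setdiff(schemes[[nm]], fac_ids)
    if (length(bad)) {
      stop("scheme '", nm, "' names unknown facility id(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  if (is.null(front)) front <- evolve(inst, config)
  rows <- lapply(names(schemes), function(nm) {
    selected <- fac_ids %in% schemes[[nm]]
    plan <- construct_plan(inst, selected, repair_unused = FALSE)
    if (length(plan$unused)) {
      warning("scheme '", nm, "' selects facilities serving no demand point: ",
              paste(plan$unused, collapse = ", "), call. = FALSE)
    }
    o <- plan$objectives
    dominated <- any(front$objectives[, 1L] <= o[["f1"]] &
                       front$objectives[, 2L] <= o[["f2"]] &
                       (front$objectives[, 1L] < o[["f1"]] |
                          front$objectives[, 2L] < o[["f2"]]))
    data.frame(scheme = nm, n_selected = sum(plan$x),
               patient_cost = o[["f1"]], hospital_cost = o[["f2"]],
               dominated = dominated,
               unused = paste(plan$unused, collapse = ","))
  })
  out <- do.call(rbind, rows)
  attr(out, "front") <- front
  out
}

#' Parameter sensitivity sweep
#'
#' Re-solves the instance at each level of one parameter (`C1`, `C2`, `F1`
#' or `F2` — frequencies apply to every patient type), reusing the same seed
#' list at every level so hypervolume differences reflect the parameter, not
#' sampling noise. Per level, the fronts of all seeds are pooled into a
#' union front; hypervolumes are computed in raw objective units against a
#' single reference point shared across the whole sweep (component-wise
#' maximum of the pooled scenarios, see [sensitivity_hv()]).
#'
#' @param inst A `problem_instance` or instance path.
#' @param parameter One of `"C1"`, `"C2"`, `"F1"`, `"F2"`.
#' @param levels Numeric vector of positive parameter levels.
#' @param config Engine settings (the seed field is overridden per run).
#' @param seeds Integer vector of seeds used at every level.
#' @return Data frame with one row per level: `level`, `n_solutions`
#'   (union-front size), `hypervolume`; the per-level union fronts and the
#'   shared reference point are attached as attributes `"fronts"` and
#'   `"reference"`.
#' @export
run_sensitivity <- function(inst, parameter, levels,
                            config = engine_config(), seeds = 1:3) {
  if (is.character(inst)) inst <- load_instance(inst)
  if (!parameter %in% c("C1", "C2", "F1", "F2")) {
    stop("parameter must be one of C1, C2, F1, F2", call. = FALSE)
  }
  if (any(levels <= 0)) stop("levels must be positive", call. = FALSE)
  fronts <- lapply(levels, function(lv) {
    mod <- set_parameter(inst, parameter, lv)
    runs <- lapply(seeds, function(s) {
      cfg <- config; cfg$seed <- as.integer(s)
      evolve(mod, cfg)$objectives
    })
    union_reference_front(runs)
  })
  names(fronts) <- as.character(levels)
  hv <- sensitivity_hv(fronts)
  out <- data.frame(level = levels,
                    n_solutions = vapply(fronts, nrow, integer(1L)),
                    hypervolume = as.numeric(hv))
  attr(out, "fronts") <- fronts
  attr(out, "reference") <- attr(hv, "reference")
  out
}

# Rebuild an instance with one scalar parameter replaced.
set_parameter <- function(inst, parameter, level) {
  if (parameter %in% c("C1", "C2")) {
    inst$costs[[parameter]] <- level
  } else {
    inst$patient_types[[parameter]] <- rep(level,
                                           nrow(inst$patient_types))
  }
  validate_instance(inst)
  inst
}

#' Multi-seed indicator benchmarking
#'
#' Runs the engine once per seed, pools all resulting fronts (plus any
#' externally supplied algorithm fronts) into a union reference front, and
#' scores each group of runs with the normalized HV/IGD/spacing protocol.
#' External fronts make it possible to score third-party solver output with
#' the same protocol.
#'
#' @param inst A `problem_instance` or instance path.
#' @param config Engine settings (seed overridden per run).
#' @param seeds Integer vector of seeds.
#' @param external_fronts Optional named list of lists of objective
#'   matrices: `external_fronts$algo[[run]]`.
#' @param ref_point Normalized-space reference point (default
#'   `c(1.2, 1.2)`).
#' @return Named list of `indicator_report`s, one per algorithm (the
#'   package's engine is reported as `"nsga2"`).
#' @export
run_benchmark <- function(inst, config = engine_config(), seeds = 1:5,
                          external_fronts = list(),
                          ref_point = c(1.2, 1.2)) {
  if (is.character(inst)) inst <- load_instance(inst)
  own <- lapply(seeds, function(s) {
    cfg <- config; cfg$seed <- as.integer(s)
    evolve(inst, cfg)$objectives
  })
  groups <- c(list(nsga2 = own), external_fronts)
  all_fronts <- do.call(c, unname(groups))
  ref_front <- union_reference_front(all_fronts)
  lapply(groups, indicator_report, ref_point = ref_point,
         reference_front = ref_front)
}

#' Objective vectors reported for the motivating case study
#'
#' The published results table of the motivating real-world district
#' application: ten model solutions plus three manually designed schemes
#' (A: two distal regions, B: densest region, C: central region), each with
#' its count of selected hospitals, patient cost and hospital cost. The
#' underlying instance data are unpublished, so these vectors serve as a
#' worked non-dominated-sorting example, not a reproduction target.
#'
#' @return Data frame with columns `solution`, `n_selected`,
#'   `patient_cost`, `hospital_cost`.
#' @export
case_study_front <- function() {
  utils::read.csv(system.file("extdata", "case_front.csv",
                              package = "coopselect"),
                  stringsAsFactors = FALSE)
}
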