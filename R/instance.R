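# Problem-instance data model: two-tier facility hierarchy (RMCs and their
# subordinate PHCs), community demand points with patient-type mixes, scalar
# cost/frequency parameters, and a facility-by-demand distance matrix.

#' Default cost and follow-up parameters
#'
#' Baseline single-patient-type parameterization used throughout the package:
#' each discharged patient receives `F1 = 6` facility visits and `F2 = 10`
#' home visits per year; a facility visit consumes `e1 = 2` capacity units
#' and a home visit `e2 = 3`; contracting an RMC costs `C1 = 10000` currency
#' per year; one capacity unit costs `C2 = 50`; a facility visit costs the
#' hospital `c1_base = 80` currency while a home visit costs
#' `c2_per_dist = 60` currency per distance unit travelled; patients pay
#' `h1_per_dist = 30` currency per distance unit to reach the facility and
#' `h2_base = 50` currency per home visit received.
#'
#' @return A list with components `patient_types` (one-row data frame with
#'   columns `F1`, `F2`, `e1`, `e2`) and `costs` (list with `C1`, `C2`,
#'   `c1_base`, `c2_per_dist`, `h1_per_dist`, `h2_base`).
#' @export
#' @examples
#' p <- default_parameters()
#' p$costs$C1                       # 10000
#' with(p$patient_types, F1 * e1 + F2 * e2)  # 42 capacity units/patient-year
default_parameters <- function() {
  list(
    patient_types = data.frame(F1 = 6, F2 = 10, e1 = 2, e2 = 3),
    costs = list(C1 = 10000, C2 = 50, c1_base = 80, c2_per_dist = 60,
                 h1_per_dist = 30, h2_base = 50)
  )
}

#' Construct and validate a problem instance
#'
#' @param facilities Data frame with columns `id` (character, unique),
#'   `tier` (`"RMC"` or `"PHC"`), `parent_id` (the supervising RMC; an RMC is
#'   its own parent), and optionally `x`, `y` planar coordinates.
#' @param demand_points Data frame with columns `id`, `n` (non-negative
#'   patient count per year) and optionally `x`, `y`.
#' @param type_mix Numeric matrix, one row per demand point and one column
#'   per patient type; rows must sum to 1. Defaults to a single type.
#' @param patient_types Data frame with one row per patient type and columns
#'   `F1`, `F2`, `e1`, `e2` (follow-up frequencies and per-visit capacity
#'   loads). Defaults to `default_parameters()$patient_types`.
#' @param costs List of scalar cost parameters (see [default_parameters()]).
#'   May additionally carry 3-d override arrays `c1_table`, `c2_table`,
#'   `h1_table`, `h2_table` of dimension facilities x demand points x types,
#'   replacing the affine distance-based defaults.
#' @param distances Optional facility-by-demand-point distance matrix. When
#'   absent, Euclidean distances are computed from coordinates; when present
#'   it takes precedence over coordinates.
#' @param capacity_cap Optional per-facility upper bound on annual capacity
#'   units (scalar recycled, or vector of length `nrow(facilities)`).
#'   `NULL` means uncapped.
#' @return An object of class `problem_instance`.
#' @export
problem_instance <- function(facilities, demand_points, type_mix = NULL,
                             patient_types = NULL, costs = NULL,
                             distances = NULL, capacity_cap = NULL) {
  defaults <- default_parameters()
  if (is.null(patient_types)) patient_types <- defaults$patient_types
  if (is.null(costs)) costs <- defaults$costs
  facilities <- as.data.frame(facilities, stringsAsFactors = FALSE)
  demand_points <- as.data.frame(demand_points, stringsAsFactors = FALSE)
  if (is.null(type_mix)) {
    type_mix <- matrix(1, nrow(demand_points), nrow(patient_types))
  }
  type_mix <- as.matrix(type_mix)
  if (!is.null(distances)) {
    distances <- as.matrix(distances)
  } else {
    distances <- euclidean_distances(facilities, demand_points)
  }
  dimnames(distances) <- list(as.character(facilities$id),
                              as.character(demand_points$id))
  if (!is.null(capacity_cap)) {
    capacity_cap <- rep_len(as.numeric(capacity_cap), nrow(facilities))
  }
  inst <- structure(
    list(facilities = facilities, demand_points = demand_points,
         type_mix = type_mix, patient_types = patient_types, costs = costs,
         distances = distances, capacity_cap = capacity_cap),
    class = "problem_instance")
  validate_instance(inst)
}

euclidean_distances <- function(facilities, demand_points) {
  if (is.null(facilities$x) || is.null(demand_points$x) ||
      anyNA(facilities$x) || anyNA(demand_points$x)) {
    stop("no distance matrix supplied and coordinates are incomplete",
         call. = FALSE)
  }
  dx <- outer(facilities$x, demand_points$x, "-")
  dy <- outer(facilities$y, demand_points$y, "-")
  sqrt(dx^2 + dy^2)
}

#' Validate a problem instance
#'
#' Checks the structural invariants: unique ids, RMC-rooted hierarchy
#' (a PHC's parent is an existing RMC, an RMC is its own parent), type-mix
#' rows summing to one, non-negative demand and distances, and conforming
#' matrix dimensions. Errors name the offending record.
#'
#' @param inst A `problem_instance`.
#' @return The instance, invisibly unchanged, if valid.
#' @export
validate_instance <- function(inst) {
  fac <- inst$facilities
  dem <- inst$demand_points
  if (nrow(fac) < 1L) stop("instance needs at least one facility", call. = FALSE)
  if (nrow(dem) < 1L) stop("instance needs at least one demand point", call. = FALSE)
  for (col in c("id", "tier", "parent_id")) {
    if (is.null(fac[[col]])) stop("facilities lack column '", col, "'", call. = FALSE)
  }
  if (anyDuplicated(fac$id)) {
    stop("duplicate facility id: ", fac$id[duplicated(fac$id)][1L], call. = FALSE)
  }
  if (anyDuplicated(dem$id)) {
    stop("duplicate demand point id: ", dem$id[duplicated(dem$id)][1L], call. = FALSE)
  }
  if (!all(fac$tier %in% c("RMC", "PHC"))) {
    bad <- fac$id[!fac$tier %in% c("RMC", "PHC")][1L]
    stop("facility '", bad, "' has unknown tier (must be RMC or PHC)", call. = FALSE)
  }
  rmc_ids <- fac$id[fac$tier == "RMC"]
  parent_pos <- match(fac$parent_id, fac$id)
  if (anyNA(parent_pos)) {
    bad <- fac$id[is.na(parent_pos)][1L]
    stop("facility '", bad, "' has dangling parent_id '",
         fac$parent_id[is.na(parent_pos)][1L], "'", call. = FALSE)
  }
  not_rmc_parent <- !fac$parent_id %in% rmc_ids
  if (any(not_rmc_parent)) {
    bad <- fac$id[not_rmc_parent][1L]
    stop("facility '", bad, "' has parent '", fac$parent_id[not_rmc_parent][1L],
         "' which is not an RMC (hierarchy must be RMC-rooted)", call. = FALSE)
  }
  self <- fac$tier == "RMC" & fac$parent_id != fac$id
  if (any(self)) {
    stop("RMC '", fac$id[self][1L], "' must be its own parent", call. = FALSE)
  }
  if (any(dem$n < 0)) {
    stop("demand point '", dem$id[dem$n < 0][1L], "' has negative n", call. = FALSE)
  }
  pt <- inst$patient_types
  for (col in c("F1", "F2", "e1", "e2")) {
    if (is.null(pt[[col]])) stop("patient_types lack column '", col, "'", call. = FALSE)
    if (any(pt[[col]] < 0)) stop("patient_types: '", col, "' must be non-negative", call. = FALSE)
  }
  mix <- inst$type_mix
  if (nrow(mix) != nrow(dem) || ncol(mix) != nrow(pt)) {
    stop("type_mix must be ", nrow(dem), " x ", nrow(pt), call. = FALSE)
  }
  if (any(mix < 0 | mix > 1)) {
    bad <- which(apply(mix < 0 | mix > 1, 1L, any))[1L]
    stop("demand point '", dem$id[bad], "' has type_mix entries outside [0,1]",
         call. = FALSE)
  }
  bad_sum <- abs(rowSums(mix) - 1) > 1e-9
  if (any(bad_sum)) {
    stop("demand point '", dem$id[bad_sum][1L],
         "' has type_mix not summing to 1", call. = FALSE)
  }
  d <- inst$distances
  if (nrow(d) != nrow(fac) || ncol(d) != nrow(dem)) {
    stop("distance matrix must be ", nrow(fac), " x ", nrow(dem), call. = FALSE)
  }
  if (anyNA(d) || any(d < 0)) {
    stop("distance matrix has missing or negative entries", call. = FALSE)
  }
  cs <- inst$costs
  for (nm in c("C1", "C2", "c1_base", "c2_per_dist", "h1_per_dist", "h2_base")) {
    if (is.null(cs[[nm]])) stop("costs lack parameter '", nm, "'", call. = FALSE)
    if (cs[[nm]] < 0) stop("cost parameter '", nm, "' must be non-negative", call. = FALSE)
  }
  for (nm in c("c1_table", "c2_table", "h1_table", "h2_table")) {
    if (!is.null(cs[[nm]]) &&
        !identical(dim(cs[[nm]]), c(nrow(fac), nrow(dem), nrow(pt)))) {
      stop("cost override '", nm, "' must have dim facilities x demand x types",
           call. = FALSE)
    }
  }
  if (!is.null(inst$capacity_cap)) {
    if (length(inst$capacity_cap) != nrow(fac) || any(inst$capacity_cap < 0)) {
      stop("capacity_cap must be a non-negative vector over facilities",
           call. = FALSE)
    }
  }
  invisible(inst)
}

#' @export
print.problem_instance <- function(x, ...) {
  fac <- x$facilities
  cat("Problem instance:", nrow(fac), "facilities (",
      sum(fac$tier == "RMC"), "RMCs,", sum(fac$tier == "PHC"), "PHCs ),",
      nrow(x$demand_points), "demand points,",
      sum(x$demand_points$n), "patients/year,",
      nrow(x$patient_types), "patient type(s),",
      if (is.null(x$capacity_cap)) "uncapped" else "capacity-capped", "\n")
  invisible(x)
}

#' Read a problem instance from disk
#'
#' Accepts either a single JSON document or a directory holding a CSV bundle
#' (`facilities.csv`, `demand.csv`, `params.csv` and optionally
#' `distances.csv`). When locations are given but no distance matrix,
#' Euclidean distances are computed; an explicit matrix always wins.
#'
#' @param path Path to a JSON file or a CSV bundle directory.
#' @return A validated `problem_instance`.
#' @seealso [write_instance()]
#' @export
load_instance <- function(path) {
  if (dir.exists(path)) return(load_instance_csv(path))
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = TRUE, simplifyMatrix = TRUE)
  fac <- as.data.frame(doc$facilities, stringsAsFactors = FALSE)
  if (!is.null(fac$location)) {
    loc <- do.call(rbind, fac$location)
    fac$x <- loc[, 1L]; fac$y <- loc[, 2L]; fac$location <- NULL
  }
  dem <- as.data.frame(doc$demand_points, stringsAsFactors = FALSE)
  if (!is.null(dem$location)) {
    loc <- do.call(rbind, dem$location)
    dem$x <- loc[, 1L]; dem$y <- loc[, 2L]; dem$location <- NULL
  }
  mix <- NULL
  if (!is.null(dem$type_mix)) {
    mix <- do.call(rbind, lapply(dem$type_mix, as.numeric))
    dem$type_mix <- NULL
  }
  pt <- as.data.frame(doc$patient_types, stringsAsFactors = FALSE)
  costs <- doc$costs
  for (nm in c("c1_table", "c2_table", "h1_table", "h2_table")) {
    if (!is.null(costs[[nm]])) {
      costs[[nm]] <- array(as.numeric(unlist(costs[[nm]])),
                           dim = c(nrow(fac), nrow(dem), nrow(pt)))
    }
  }
  distances <- if (!is.null(doc$distances)) as.matrix(doc$distances)
  cap <- doc$capacity_cap
  problem_instance(fac, dem, type_mix = mix, patient_types = pt,
                   costs = costs, distances = distances, capacity_cap = cap)
}

load_instance_csv <- function(dir) {
  fac <- utils::read.csv(file.path(dir, "facilities.csv"),
                         stringsAsFactors = FALSE)
  dem <- utils::read.csv(file.path(dir, "demand.csv"),
                         stringsAsFactors = FALSE)
  mix_cols <- grep("^mix_", names(dem), value = TRUE)
  mix <- NULL
  if (length(mix_cols)) {
    mix <- as.matrix(dem[mix_cols])
    dem <- dem[setdiff(names(dem), mix_cols)]
  }
  par <- utils::read.csv(file.path(dir, "params.csv"),
                         stringsAsFactors = FALSE)
  costs <- as.list(stats::setNames(par$value[is.na(par$type)],
                                   par$param[is.na(par$type)]))
  ptr <- par[!is.na(par$type), , drop = FALSE]
  pt <- NULL
  if (nrow(ptr)) {
    pt <- stats::reshape(ptr, idvar = "type", timevar = "param",
                         direction = "wide")
    names(pt) <- sub("^value\\.", "", names(pt))
    pt <- pt[order(pt$type), c("F1", "F2", "e1", "e2"), drop = FALSE]
    rownames(pt) <- NULL
  }
  dpath <- file.path(dir, "distances.csv")
  distances <- NULL
  if (file.exists(dpath)) {
    distances <- as.matrix(utils::read.csv(dpath, row.names = 1L,
                                           check.names = FALSE))
  }
  cap <- fac$capacity_cap
  fac$capacity_cap <- NULL
  if (!is.null(cap) && all(is.na(cap))) cap <- NULL
  problem_instance(fac, dem, type_mix = mix, patient_types = pt,
                   costs = costs, distances = distances, capacity_cap = cap)
}

#' Write a problem instance to disk
#'
#' @param inst A `problem_instance`.
#' @param path Output path: a `.json` file, or a directory for the CSV
#'   bundle format.
#' @param format `"json"` or `"csv"`; guessed from `path` by default.
#' @return `path`, invisibly.
#' @export
write_instance <- function(inst, path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "json") {
    fac <- inst$facilities
    dem <- inst$demand_points
    doc <- list(
      facilities = lapply(seq_len(nrow(fac)), function(i) {
        rec <- list(id = fac$id[i], tier = fac$tier[i],
                    parent_id = fac$parent_id[i])
        if (!is.null(fac$x) && !is.na(fac$x[i])) {
          rec$location <- c(fac$x[i], fac$y[i])
        }
        rec
      }),
      demand_points = lapply(seq_len(nrow(dem)), function(j) {
        rec <- list(id = dem$id[j])
        if (!is.null(dem$x) && !is.na(dem$x[j])) {
          rec$location <- c(dem$x[j], dem$y[j])
        }
        rec$n <- dem$n[j]
        rec$type_mix <- as.numeric(inst$type_mix[j, ])
        rec
      }),
      patient_types = inst$patient_types,
      costs = inst$costs[!vapply(inst$costs, is.null, logical(1L))],
      distances = unname(inst$distances)
    )
    if (!is.null(inst$capacity_cap)) doc$capacity_cap <- inst$capacity_cap
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    fac <- inst$facilities
    if (!is.null(inst$capacity_cap)) fac$capacity_cap <- inst$capacity_cap
    utils::write.csv(fac, file.path(path, "facilities.csv"), row.names = FALSE)
    dem <- inst$demand_points
    mix <- inst$type_mix
    colnames(mix) <- paste0("mix_", seq_len(ncol(mix)))
    utils::write.csv(cbind(dem, mix), file.path(path, "demand.csv"),
                     row.names = FALSE)
    pt <- inst$patient_types
    par <- rbind(
      data.frame(param = names(Filter(is.numeric, inst$costs)),
                 type = NA_integer_,
                 value = unlist(Filter(is.numeric, inst$costs))),
      do.call(rbind, lapply(seq_len(nrow(pt)), function(k) {
        data.frame(param = c("F1", "F2", "e1", "e2"), type = k,
                   value = as.numeric(pt[k, c("F1", "F2", "e1", "e2")]))
      })))
    utils::write.csv(par, file.path(path, "params.csv"), row.names = FALSE)
    utils::write.csv(inst$distances, file.path(path, "distances.csv"))
  }
  invisible(path)
}
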