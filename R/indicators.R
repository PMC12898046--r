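# Pareto-front quality indicators (minimization throughout) and the two
# evaluation protocols: normalized HV/IGD/spacing against a pooled union
# reference front, and raw-scale HV against a single global reference point
# shared across sensitivity scenarios.

#' Min-max normalization bounds
#'
#' @param points Numeric matrix of objective vectors (rows = points).
#' @return List with `min` and `max` per objective, class
#'   `normalization_bounds`.
#' @export
normalization_bounds <- function(points) {
  points <- as.matrix(points)
  structure(list(min = apply(points, 2L, min), max = apply(points, 2L, max)),
            class = "normalization_bounds")
}

#' Min-max normalize objective vectors
#'
#' Maps each coordinate by `(v - min) / (max - min)`. Points outside the
#' bounds source map outside `[0,1]`, which is permitted; a degenerate
#' objective (`max == min`) is an error.
#'
#' @param points Numeric matrix of objective vectors.
#' @param bounds A `normalization_bounds` object.
#' @return Matrix of normalized points.
#' @export
normalize_points <- function(points, bounds) {
  points <- as.matrix(points)
  rng <- bounds$max - bounds$min
  if (any(rng <= 0)) {
    stop("degenerate normalization bounds in objective ",
         which(rng <= 0)[1L], call. = FALSE)
  }
  sweep(sweep(points, 2L, bounds$min, "-"), 2L, rng, "/")
}

#' Exact 2-D hypervolume (minimization)
#'
#' Lebesgue measure of the union of rectangles `[z, r]` over the
#' non-dominated subset of `points`, computed by a sort-and-sweep. Points
#' with any coordinate at or beyond the reference contribute nothing;
#' dominated points never change the value.
#'
#' @param points Numeric matrix of objective vectors.
#' @param reference Reference point `c(r1, r2)`; larger is worse.
#' @return Non-negative hypervolume.
#' @export
#' @examples
#' hypervolume_2d(rbind(c(0.2, 0.2)), c(1.2, 1.2))  # 1.0
hypervolume_2d <- function(points, reference) {
  points <- as.matrix(points)
  if (anyNA(points) || anyNA(reference)) stop("NaN/NA input", call. = FALSE)
  keep <- points[, 1L] < reference[1L] & points[, 2L] < reference[2L]
  points <- points[keep, , drop = FALSE]
  if (!nrow(points)) return(0)
  ord <- order(points[, 1L], points[, 2L])
  points <- points[ord, , drop = FALSE]
  # sweep in increasing f1; each non-dominated point adds a strip up to the
  # next point's f1 (or the reference)
  best_f2 <- Inf
  nd_f1 <- numeric(0); nd_f2 <- numeric(0)
  for (i in seq_len(nrow(points))) {
    if (points[i, 2L] < best_f2) {
      best_f2 <- points[i, 2L]
      nd_f1 <- c(nd_f1, points[i, 1L])
      nd_f2 <- c(nd_f2, points[i, 2L])
    }
  }
  right <- c(nd_f1[-1L], reference[1L])
  sum((right - nd_f1) * (reference[2L] - nd_f2))
}

#' Inverted generational distance
#'
#' Mean over reference-front points of the Euclidean distance to the nearest
#' candidate point; smaller is better, 0 means every reference point is
#' attained.
#'
#' @param candidate,reference Numeric matrices of objective vectors.
#' @return Non-negative IGD value.
#' @export
igd <- function(candidate, reference) {
  candidate <- as.matrix(candidate)
  reference <- as.matrix(reference)
  if (!nrow(reference)) stop("empty reference front", call. = FALSE)
  if (!nrow(candidate)) stop("empty candidate set", call. = FALSE)
  d2 <- outer(reference[, 1L], candidate[, 1L], "-")^2 +
    outer(reference[, 2L], candidate[, 2L], "-")^2
  mean(sqrt(apply(d2, 1L, min)))
}

#' Spacing of a solution set
#'
#' Sample standard deviation of each point's nearest-neighbor distance
#' (Euclidean by default, Manhattan optionally); 0 means perfectly even
#' spacing.
#'
#' @param points Numeric matrix with at least two rows.
#' @param metric `"euclidean"` (default) or `"manhattan"`.
#' @return Non-negative spacing value.
#' @export
spacing <- function(points, metric = c("euclidean", "manhattan")) {
  metric <- match.arg(metric)
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 2L) stop("spacing needs at least 2 points", call. = FALSE)
  d <- if (metric == "euclidean") {
    as.matrix(stats::dist(points))
  } else {
    as.matrix(stats::dist(points, method = "manhattan"))
  }
  diag(d) <- Inf
  stats::sd(apply(d, 1L, min))
}

#' Pooled union reference front
#'
#' Merges the final non-dominated sets of several runs/algorithms,
#' deduplicates, and filters the pool to its non-dominated subset.
#'
#' @param fronts List of numeric objective matrices (each possibly empty).
#' @return Matrix: the pooled non-dominated reference front, sorted by the
#'   first objective.
#' @export
union_reference_front <- function(fronts) {
  fronts <- Filter(function(f) !is.null(f) && nrow(as.matrix(f)) > 0, fronts)
  if (!length(fronts)) stop("all fronts empty", call. = FALSE)
  pool <- unique(do.call(rbind, lapply(fronts, as.matrix)))
  nd <- nondominated_sort(pool)$rank == 1L
  pool <- pool[nd, , drop = FALSE]
  pool[order(pool[, 1L], pool[, 2L]), , drop = FALSE]
}

#' Raw-scale hypervolume for sensitivity scenarios
#'
#' All scenario fronts share a single global reference point: the
#' component-wise maximum over the pooled points, inflated by `margin`.
#' Hypervolumes are computed in raw objective units, so values are directly
#' comparable across scenarios of one sweep.
#'
#' @param scenario_fronts Named list of numeric objective matrices.
#' @param margin Relative inflation of the global reference point
#'   (default 0: the exact component-wise maximum).
#' @return Named numeric vector of per-scenario hypervolumes, with the
#'   shared reference point as attribute `"reference"`.
#' @export
sensitivity_hv <- function(scenario_fronts, margin = 0) {
  fronts <- lapply(scenario_fronts, as.matrix)
  if (!length(fronts) || !sum(vapply(fronts, nrow, integer(1L)))) {
    stop("empty scenario pool", call. = FALSE)
  }
  pool <- do.call(rbind, fronts)
  ref <- apply(pool, 2L, max) * (1 + margin)
  hv <- vapply(fronts, hypervolume_2d, numeric(1L), reference = ref)
  attr(hv, "reference") <- ref
  hv
}

#' Indicator report for multi-run comparison
#'
#' Implements the normalized benchmarking protocol: pool every run's front
#' into a union reference front, normalize all points by that pool's min-max
#' bounds (the reference front then spans `[0,1]`), and score each run with
#' hypervolume against `ref_point`, IGD against the normalized reference
#' front, and spacing. Reported as per-run values plus mean and standard
#' deviation.
#'
#' @param run_fronts List of numeric objective matrices, one per run (seed).
#' @param ref_point Reference point in normalized space (default
#'   `c(1.2, 1.2)`).
#' @param reference_front Optional externally supplied raw-scale reference
#'   front; by default the pooled union front of `run_fronts`.
#' @return An `indicator_report`: list with `per_run` (data frame with `hv`,
#'   `igd`, `spacing`), `mean`, `sd`, `ref_point`, `bounds`,
#'   `reference_front`, `runs`.
#' @export
indicator_report <- function(run_fronts, ref_point = c(1.2, 1.2),
                             reference_front = NULL) {
  if (is.null(reference_front)) {
    reference_front <- union_reference_front(run_fronts)
  }
  bounds <- normalization_bounds(reference_front)
  ref_norm <- normalize_points(reference_front, bounds)
  per_run <- do.call(rbind, lapply(run_fronts, function(f) {
    fn <- normalize_points(as.matrix(f), bounds)
    data.frame(hv = hypervolume_2d(fn, ref_point),
               igd = igd(fn, ref_norm),
               spacing = if (nrow(fn) >= 2L) spacing(fn) else NA_real_)
  }))
  structure(list(per_run = per_run,
                 mean = colMeans(per_run, na.rm = TRUE),
                 sd = apply(per_run, 2L, stats::sd, na.rm = TRUE),
                 ref_point = ref_point, bounds = bounds,
                 reference_front = reference_front,
                 runs = length(run_fronts)),
            class = "indicator_report")
}

#' @export
print.indicator_report <- function(x, ...) {
  cat("Indicator report over", x$runs, "run(s):\n")
  for (nm in c("hv", "igd", "spacing")) {
    cat(sprintf("  %-8s %.4f +/- %.4f\n", toupper(nm), x$mean[[nm]],
                x$sd[[nm]]))
  }
  invisible(x)
}
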