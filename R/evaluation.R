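# Plan construction and evaluation: proximity-based allocation with optional
# capacity overflow, minimal hierarchical contracts, the two cost objectives,
# and the feasibility checks.
#
# Model recap (minimization of both):
#   f1 = sum_k sum_{i,j} (F_k1 h_ijk1 + F_k2 h_ijk2) n_j p_jk z_ij
#   f2 = C1 sum_{i in RMCs} y_i
#        + sum_k sum_{i,j} (F_k1 c_ijk1 + F_k2 c_ijk2) n_j p_jk z_ij
#        + C2 sum_k sum_{i,j} (F_k1 e_k1 + F_k2 e_k2) n_j p_jk z_ij
# subject to: unique assignment (3), assignment only to selected facilities
# (4), a selected facility's supervising RMC must hold a contract (5), and
# facility workload bounded by its provisioned capacity w_i (6).

# Per-(facility, demand point) cost matrices, summed over patient types:
# P1[i,j] = patient-side cost of assigning j to i, P2[i,j] = hospital-side
# service + capacity cost (contracting excluded). Also the per-point annual
# capacity workload u[j] and each facility's parent-RMC index.
instance_tables <- function(inst) {
  d <- inst$distances
  pt <- inst$patient_types
  mix <- inst$type_mix
  cs <- inst$costs
  n_fac <- nrow(d); n_dem <- ncol(d); n_k <- nrow(pt)
  nj <- inst$demand_points$n
  P1 <- matrix(0, n_fac, n_dem)
  P2 <- matrix(0, n_fac, n_dem)
  u <- numeric(n_dem)
  for (k in seq_len(n_k)) {
    npk <- nj * mix[, k]                    # n_j p_jk, length n_dem
    h1 <- if (!is.null(cs$h1_table)) cs$h1_table[, , k] else cs$h1_per_dist * d
    h2 <- if (!is.null(cs$h2_table)) cs$h2_table[, , k] else
      matrix(cs$h2_base, n_fac, n_dem)
    c1 <- if (!is.null(cs$c1_table)) cs$c1_table[, , k] else
      matrix(cs$c1_base, n_fac, n_dem)
    c2 <- if (!is.null(cs$c2_table)) cs$c2_table[, , k] else cs$c2_per_dist * d
    load_k <- pt$F1[k] * pt$e1[k] + pt$F2[k] * pt$e2[k]
    P1 <- P1 + sweep(pt$F1[k] * h1 + pt$F2[k] * h2, 2L, npk, "*")
    P2 <- P2 + sweep(pt$F1[k] * c1 + pt$F2[k] * c2, 2L, npk, "*") +
      matrix(cs$C2 * load_k * npk, n_fac, n_dem, byrow = TRUE)
    u <- u + load_k * npk
  }
  rmc_ids <- inst$facilities$id[inst$facilities$tier == "RMC"]
  parent <- match(inst$facilities$parent_id, rmc_ids)
  list(P1 = P1, P2 = P2, workload_per_point = u, parent = parent,
       rmc_ids = rmc_ids)
}

#' Proximity-based allocation of demand points to selected facilities
#'
#' Each demand point is assigned to the nearest selected facility; distance
#' ties break toward the facility appearing first in file order. When the
#' instance carries a `capacity_cap`, demand points are processed in
#' decreasing order of their annual workload and each takes the nearest
#' selected facility whose remaining capacity can absorb its full workload
#' (points are never split); exhaustion of all candidates is an error naming
#' the shortfall.
#'
#' @param inst A `problem_instance`.
#' @param selected Logical or 0/1 vector over facilities.
#' @return Integer vector: for each demand point, the index of its assigned
#'   facility.
#' @export
induce_allocation <- function(inst, selected) {
  allocate_points(inst, selected, tab = NULL)
}

# Same contract as induce_allocation, with optionally precomputed
# instance_tables() (the GA hot path passes them in).
allocate_points <- function(inst, selected, tab = NULL) {
  selected <- as.logical(selected)
  if (!any(selected)) stop("no facility selected", call. = FALSE)
  sel_idx <- which(selected)
  d_sel <- inst$distances[sel_idx, , drop = FALSE]
  if (is.null(inst$capacity_cap)) {
    local <- max.col(-t(d_sel), ties.method = "first")
    return(sel_idx[local])
  }
  if (is.null(tab)) tab <- instance_tables(inst)
  u <- tab$workload_per_point
  residual <- inst$capacity_cap[sel_idx]
  if (sum(residual) < sum(u) - 1e-9) {
    stop(sprintf(
      "infeasible: total selected capacity %.6g short of total workload %.6g by %.6g",
      sum(residual), sum(u), sum(u) - sum(residual)), call. = FALSE)
  }
  assign <- integer(ncol(d_sel))
  for (j in order(-u, seq_along(u))) {
    ord <- order(d_sel[, j], seq_along(sel_idx))   # nearest first, tie: file order
    pick <- ord[match(TRUE, residual[ord] >= u[j] - 1e-9)]
    if (is.na(pick)) {
      stop(sprintf(
        "infeasible: demand point '%s' (workload %.6g) exceeds every facility's remaining capacity",
        inst$demand_points$id[j], u[j]), call. = FALSE)
    }
    residual[pick] <- residual[pick] - u[j]
    assign[j] <- sel_idx[pick]
  }
  assign
}

#' Minimal feasible contracts implied by a facility selection
#'
#' An RMC holds a contract exactly when it is selected itself or supervises a
#' selected PHC; this is the cheapest contract vector satisfying the
#' hierarchical-contracting constraint.
#'
#' @param inst A `problem_instance`.
#' @param selected Logical or 0/1 vector over facilities.
#' @return Named 0/1 integer vector over RMCs.
#' @export
contracts_from_selection <- function(inst, selected) {
  selected <- as.logical(selected)
  tab <- instance_tables(inst)
  y <- integer(length(tab$rmc_ids))
  if (any(selected)) y[unique(tab$parent[selected])] <- 1L
  stats::setNames(y, tab$rmc_ids)
}

#' Annual capacity workload of a facility under an assignment
#'
#' Sums `(e_k1 F_k1 + e_k2 F_k2) n_j p_jk` over all patient types and all
#' demand points assigned to the facility.
#'
#' @param inst A `problem_instance`.
#' @param assignment Integer vector of assigned facility indices (one per
#'   demand point), as returned by [induce_allocation()].
#' @param facility Facility id (character) or index; when missing, the full
#'   per-facility workload vector is returned.
#' @return Workload in capacity units.
#' @export
workload <- function(inst, assignment, facility) {
  u <- instance_tables(inst)$workload_per_point
  all_w <- as.numeric(tapply(u, factor(assignment,
                                       levels = seq_len(nrow(inst$facilities))),
                             sum, default = 0))
  names(all_w) <- inst$facilities$id
  if (missing(facility)) return(all_w)
  if (is.character(facility)) {
    if (!facility %in% inst$facilities$id) {
      stop("unknown facility id '", facility, "'", call. = FALSE)
    }
    return(unname(all_w[facility]))
  }
  unname(all_w[[facility]])
}

#' Construct a full plan from a facility selection
#'
#' Runs proximity allocation, optionally repairs away selected facilities
#' that serve no demand point, derives the minimal contracts, and provisions
#' capacity at exactly the induced workload (`w_i` equals the workload, the
#' cheapest feasible choice).
#'
#' @param inst A `problem_instance`.
#' @param selected Logical or 0/1 vector over facilities.
#' @param repair_unused Drop selected-but-unused facilities (default); when
#'   `FALSE` they stay selected (and still force contracts) and their ids are
#'   recorded in the plan's `unused` field.
#' @return A `selection_plan`: list with `x`, `y`, `assignment`, `z`
#'   (demand id -> facility id), `w`, `objectives` (`f1`, `f2`) and `unused`.
#' @export
construct_plan <- function(inst, selected, repair_unused = TRUE) {
  selected <- as.logical(selected)
  assignment <- induce_allocation(inst, selected)
  counts <- tabulate(assignment, nbins = nrow(inst$facilities))
  unused <- selected & counts == 0L
  if (repair_unused) {
    selected[unused] <- FALSE
    unused_ids <- character(0)
  } else {
    unused_ids <- inst$facilities$id[unused]
  }
  y <- contracts_from_selection(inst, selected)
  w <- workload(inst, assignment)
  plan <- structure(
    list(x = stats::setNames(as.integer(selected), inst$facilities$id),
         y = y, assignment = assignment,
         z = stats::setNames(inst$facilities$id[assignment],
                             inst$demand_points$id),
         w = w, objectives = NULL, unused = unused_ids),
    class = "selection_plan")
  plan$objectives <- evaluate_objectives(inst, plan)
  plan
}

#' Evaluate the two cost objectives of a plan
#'
#' @param inst A `problem_instance`.
#' @param plan A `selection_plan` satisfying the assignment/selection/
#'   contract constraints (violations raise an error naming them).
#' @return Named numeric vector `c(f1 = patient cost, f2 = hospital cost)`.
#' @export
evaluate_objectives <- function(inst, plan) {
  viol <- check_constraints(inst, plan, check_capacity = FALSE)
  if (nrow(viol)) {
    stop("plan violates constraint(s) ",
         paste(unique(viol$constraint), collapse = ", "), call. = FALSE)
  }
  tab <- instance_tables(inst)
  ij <- cbind(plan$assignment, seq_along(plan$assignment))
  f1 <- sum(tab$P1[ij])
  f2 <- inst$costs$C1 * sum(plan$y) + sum(tab$P2[ij])
  c(f1 = f1, f2 = f2)
}

#' Itemized constraint-violation report
#'
#' Checks the four model constraints: unique assignment, assignment only to
#' selected facilities, hierarchical contracting, and workload within the
#' provisioned capacity `w_i`. An empty report means the plan is feasible.
#'
#' @param inst A `problem_instance`.
#' @param plan A `selection_plan`.
#' @param check_capacity Include the workload-vs-`w` check (default `TRUE`).
#' @return Data frame with columns `constraint` (`"assignment"`,
#'   `"selection_linkage"`, `"contracting"`, `"capacity"`), `facility`,
#'   `demand_point`, `detail`.
#' @export
check_constraints <- function(inst, plan, check_capacity = TRUE) {
  out <- list()
  n_dem <- nrow(inst$demand_points)
  a <- plan$assignment
  bad_j <- which(is.na(a) | a < 1L | a > nrow(inst$facilities))
  if (length(a) != n_dem) bad_j <- union(bad_j, seq_len(n_dem))
  for (j in bad_j) {
    out[[length(out) + 1L]] <- data.frame(
      constraint = "assignment", facility = NA_character_,
      demand_point = inst$demand_points$id[j],
      detail = "not assigned to exactly one facility")
  }
  ok_j <- setdiff(seq_len(min(length(a), n_dem)), bad_j)
  for (j in ok_j[plan$x[a[ok_j]] != 1L]) {
    out[[length(out) + 1L]] <- data.frame(
      constraint = "selection_linkage", facility = inst$facilities$id[a[j]],
      demand_point = inst$demand_points$id[j],
      detail = "assigned to an unselected facility")
  }
  tab <- instance_tables(inst)
  need_contract <- unique(tab$parent[plan$x == 1L])
  for (i in need_contract[plan$y[need_contract] != 1L]) {
    out[[length(out) + 1L]] <- data.frame(
      constraint = "contracting", facility = tab$rmc_ids[i],
      demand_point = NA_character_,
      detail = "selected facility's supervising RMC holds no contract")
  }
  if (check_capacity) {
    wl <- workload(inst, a)
    over <- which(wl > plan$w + 1e-9)
    for (i in over) {
      out[[length(out) + 1L]] <- data.frame(
        constraint = "capacity", facility = inst$facilities$id[i],
        demand_point = NA_character_,
        detail = sprintf("workload %.6g exceeds provisioned capacity %.6g",
                         wl[i], plan$w[i]))
    }
  }
  if (!length(out)) {
    return(data.frame(constraint = character(), facility = character(),
                      demand_point = character(), detail = character()))
  }
  do.call(rbind, out)
}

#' @export
print.selection_plan <- function(x, ...) {
  cat("Selection plan:", sum(x$x), "facilities selected,", sum(x$y),
      "RMC contract(s); f1 =", format(x$objectives[["f1"]], big.mark = ","),
      " f2 =", format(x$objectives[["f2"]], big.mark = ","), "\n")
  invisible(x)
}

#' Serialize a plan to JSON
#'
#' @param plan A `selection_plan`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plan <- function(plan, path) {
  jsonlite::write_json(
    list(x = as.list(plan$x), y = as.list(plan$y), z = as.list(plan$z),
         w = as.list(plan$w), f1 = plan$objectives[["f1"]],
         f2 = plan$objectives[["f2"]]),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
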