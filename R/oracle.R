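# Exact ground truth on small instances: exhaustive enumeration of all
# non-empty facility selections, with the same plan construction as the
# evolutionary engine (proximity allocation, repair of unused facilities,
# minimal contracts, capacity provisioned at workload).

#' Enumerate the exact Pareto front of a small instance
#'
#' Iterates every non-empty selection in `{0,1}^n`, constructs the induced
#' plan, deduplicates by repaired selection (cosmetically distinct raw
#' selections that repair to the same operating plan are counted once), and
#' filters to the non-dominated set. Intended as a validation oracle; the
#' `max_facilities` guard refuses instances whose `2^n` enumeration would be
#' accidental.
#'
#' @param inst A `problem_instance`.
#' @param max_facilities Enumeration guard (default 16).
#' @return An `exact_front`: list with `plans`, `objectives` matrix,
#'   `selections` (0/1 matrix, one row per front member) and `n_enumerated`.
#' @export
enumerate_front <- function(inst, max_facilities = 16L) {
  n <- nrow(inst$facilities)
  if (n > max_facilities) {
    stop("instance has ", n, " facilities; enumeration guard is ",
         max_facilities, " (2^n selections)", call. = FALSE)
  }
  tab <- instance_tables(inst)
  seen <- new.env(parent = emptyenv())
  sels <- list(); objs <- list()
  bits <- 2^(seq_len(n) - 1L)
  for (s in seq_len(2^n - 1L)) {
    selection <- as.logical(s %/% bits %% 2)
    assignment <- try_allocate(inst, selection, tab)
    if (is.null(assignment)) next   # infeasible under a capacity cap
    counts <- tabulate(assignment, nbins = n)
    selection[selection & counts == 0L] <- FALSE
    key <- rawToChar(as.raw(selection + 48L))
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    ij <- cbind(assignment, seq_along(assignment))
    n_contracts <- length(unique(tab$parent[selection]))
    sels[[length(sels) + 1L]] <- as.integer(selection)
    objs[[length(objs) + 1L]] <-
      c(f1 = sum(tab$P1[ij]),
        f2 = inst$costs$C1 * n_contracts + sum(tab$P2[ij]))
  }
  if (!length(objs)) stop("no feasible selection exists", call. = FALSE)
  obj <- do.call(rbind, objs)
  sel <- do.call(rbind, sels)
  nd <- nondominated_sort(obj)$rank == 1L
  obj <- obj[nd, , drop = FALSE]
  sel <- sel[nd, , drop = FALSE]
  ord <- order(obj[, 1L], obj[, 2L])
  obj <- obj[ord, , drop = FALSE]
  sel <- sel[ord, , drop = FALSE]
  plans <- lapply(seq_len(nrow(sel)), function(i) {
    construct_plan(inst, as.logical(sel[i, ]))
  })
  structure(list(plans = plans, objectives = obj, selections = sel,
                 n_enumerated = 2^n - 1L),
            class = "exact_front")
}

# NULL instead of an error when a capped selection is infeasible.
try_allocate <- function(inst, selection, tab) {
  if (is.null(inst$capacity_cap)) return(allocate_points(inst, selection, tab))
  tryCatch(allocate_points(inst, selection, tab), error = function(e) NULL)
}

#' @export
print.exact_front <- function(x, ...) {
  cat("Exact Pareto front:", nrow(x$objectives), "solution(s) from",
      x$n_enumerated, "enumerated selections\n")
  invisible(x)
}

#' Export an exact front as a CSV table
#'
#' One row per front member: the selection bitstring plus both objectives.
#'
#' @param x An `exact_front`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_exact_front <- function(x, path) {
  utils::write.csv(
    data.frame(selection = apply(x$selections, 1L, paste0, collapse = ""),
               f1 = x$objectives[, 1L], f2 = x$objectives[, 2L]),
    path, row.names = FALSE)
  invisible(path)
}
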