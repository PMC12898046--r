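# Constraint-aware NSGA-II over random-key chromosomes.
#
# A chromosome is a vector of n real keys in [0,1], one per candidate
# facility; key >= 0.5 decodes to "selected". Decoding is followed by the
# consistency repair: proximity allocation is induced, and every selected
# facility that ends up serving no demand point is deselected (its key is
# pushed below threshold). An all-zero decoded selection is repaired by
# force-selecting the facility with the largest key. The real-key encoding
# lets the printed SBX/polynomial-mutation distribution indices apply
# literally; a pure-binary operator mode (uniform crossover + per-gene
# bit flip) is available for comparison.

#' NSGA-II engine settings
#'
#' Defaults follow the study configuration: population 100, 500 generations,
#' 100 probabilistic binary tournaments per generation with win probability
#' 0.9, SBX distribution index 2 and polynomial-mutation index 5.
#' `crossover_prob` defaults to 0.9 and `mutation_prob` to `1/n` per gene
#' (resolved against the instance when left `NULL`).
#'
#' @param population_size,generations Positive integers.
#' @param tournament_rounds Number of binary tournaments (mating-pool size)
#'   per generation.
#' @param tournament_win_prob Probability that the better individual wins a
#'   tournament.
#' @param crossover_index,mutation_index SBX / polynomial-mutation
#'   distribution indices.
#' @param crossover_prob Per-pair crossover probability.
#' @param mutation_prob Per-gene mutation probability; `NULL` means `1/n`.
#' @param operator `"sbx"` (real keys, default) or `"binary"` (uniform
#'   crossover and bit-flip on the decoded bits).
#' @param seed Integer RNG seed.
#' @return A list of engine settings.
#' @export
engine_config <- function(population_size = 100L, generations = 500L,
                          tournament_rounds = 100L,
                          tournament_win_prob = 0.9,
                          crossover_index = 2, mutation_index = 5,
                          crossover_prob = 0.9, mutation_prob = NULL,
                          operator = c("sbx", "binary"), seed = 1L) {
  operator <- match.arg(operator)
  stopifnot(population_size >= 2, generations >= 1, tournament_rounds >= 2,
            tournament_win_prob >= 0, tournament_win_prob <= 1,
            crossover_prob >= 0, crossover_prob <= 1,
            is.null(mutation_prob) ||
              (mutation_prob >= 0 && mutation_prob <= 1))
  list(population_size = as.integer(population_size),
       generations = as.integer(generations),
       tournament_rounds = as.integer(tournament_rounds),
       tournament_win_prob = tournament_win_prob,
       crossover_index = crossover_index, mutation_index = mutation_index,
       crossover_prob = crossover_prob, mutation_prob = mutation_prob,
       operator = operator, seed = as.integer(seed))
}

#' Decode keys, repair the selection, and evaluate
#'
#' @param inst A `problem_instance`.
#' @param keys Numeric vector in `[0,1]`, one key per facility.
#' @return A `chromosome`: list with `keys` (after repair), `selection`
#'   (0/1), `allocation_counts`, `objectives` (`f1`, `f2`), `rank`,
#'   `crowding`.
#' @export
decode_and_repair <- function(inst, keys) {
  tab <- instance_tables(inst)
  chr <- decode_eval(inst, tab, keys, cache = NULL)
  chr
}

# Internal decode/repair/evaluate with precomputed tables and an optional
# memo cache keyed by the decoded (pre-repair) selection. The map from
# decoded selection to (repaired selection, allocation, objectives) is
# deterministic, so caching is a pure speedup.
decode_eval <- function(inst, tab, keys, cache = NULL) {
  selection <- keys >= 0.5
  if (!any(selection)) {
    i_star <- which.max(keys)
    selection[i_star] <- TRUE
    keys[i_star] <- 0.5 + keys[i_star] / 2
  }
  key_str <- NULL
  if (!is.null(cache)) {
    key_str <- rawToChar(as.raw(selection + 48L))
    hit <- cache[[key_str]]
    if (!is.null(hit)) {
      keys[hit$dropped] <- keys[hit$dropped] - 0.5
      return(list(keys = keys, selection = hit$selection,
                  allocation_counts = hit$counts, objectives = hit$obj,
                  rank = NA_integer_, crowding = NA_real_))
    }
  }
  assignment <- allocate_points(inst, selection, tab)
  counts <- tabulate(assignment, nbins = length(selection))
  dropped <- which(selection & counts == 0L)
  selection[dropped] <- FALSE
  keys[dropped] <- keys[dropped] - 0.5
  ij <- cbind(assignment, seq_along(assignment))
  n_contracts <- length(unique(tab$parent[selection]))
  obj <- c(f1 = sum(tab$P1[ij]),
           f2 = inst$costs$C1 * n_contracts + sum(tab$P2[ij]))
  sel_int <- as.integer(selection)
  if (!is.null(cache)) {
    cache[[key_str]] <- list(selection = sel_int, counts = counts,
                             obj = obj, dropped = dropped)
  }
  list(keys = keys, selection = sel_int, allocation_counts = counts,
       objectives = obj, rank = NA_integer_, crowding = NA_real_)
}

#' Initialize and evaluate a random population
#'
#' Keys are drawn independently uniform on `[0,1]`; every chromosome is
#' decoded, repaired, allocated and evaluated. Deterministic per seed.
#'
#' @param inst A `problem_instance`.
#' @param config Settings from [engine_config()].
#' @return List of `population_size` chromosomes.
#' @export
initialize_population <- function(inst, config = engine_config()) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(config$seed)
  tab <- instance_tables(inst)
  n <- nrow(inst$facilities)
  lapply(seq_len(config$population_size), function(i) {
    decode_eval(inst, tab, stats::runif(n))
  })
}

#' Fast non-dominated sorting (minimization, weak dominance)
#'
#' `a` dominates `b` iff `a <= b` in both objectives with at least one
#' strict inequality; duplicated points share a front. Fronts are numbered
#' from 1.
#'
#' @param objectives Numeric matrix (or 2-column data frame), one row per
#'   point, columns `f1`, `f2`.
#' @return List with `rank` (integer vector, 1 = first front) and `fronts`
#'   (list of index vectors).
#' @export
nondominated_sort <- function(objectives) {
  obj <- as.matrix(objectives)
  if (anyNA(obj) || any(is.nan(obj))) {
    stop("objectives contain NA/NaN", call. = FALSE)
  }
  n <- nrow(obj)
  f1 <- obj[, 1L]; f2 <- obj[, 2L]
  # dom[a, b]: a dominates b. With le[a, b] = (a <= b componentwise),
  # le[a, b] & le[b, a] holds iff a == b, so dom = le & !t(le).
  le <- outer(f1, f1, "<=") & outer(f2, f2, "<=")
  dom <- le & !t(le)
  n_dominators <- .colSums(dom, n, n)
  rank <- integer(n)
  current <- which(n_dominators == 0)
  r <- 0L
  fronts <- list()
  while (length(current)) {
    r <- r + 1L
    rank[current] <- r
    fronts[[r]] <- current
    if (length(current) == n) break
    n_dominators <- n_dominators -
      .colSums(dom[current, , drop = FALSE], length(current), n)
    n_dominators[rank > 0L] <- NA_integer_
    current <- which(!is.na(n_dominators) & n_dominators == 0)
  }
  list(rank = rank, fronts = fronts)
}

#' Crowding distance within one front
#'
#' Boundary points receive `Inf`; interior points the sum over objectives of
#' the normalized gap between their neighbors in the objective's sorted
#' order. An objective with zero range contributes 0.
#'
#' @param objectives Numeric matrix of one front's objective vectors.
#' @return Numeric vector of crowding distances.
#' @export
crowding_distance <- function(objectives) {
  obj <- as.matrix(objectives)
  n <- nrow(obj)
  if (n <= 2L) return(rep(Inf, n))
  cd <- numeric(n)
  for (m in seq_len(ncol(obj))) {
    ord <- order(obj[, m])
    rng <- obj[ord[n], m] - obj[ord[1L], m]
    cd[ord[c(1L, n)]] <- Inf
    if (rng > 0) {
      cd[ord[2:(n - 1L)]] <- cd[ord[2:(n - 1L)]] +
        (obj[ord[3:n], m] - obj[ord[1:(n - 2L)], m]) / rng
    }
  }
  cd
}

# Assign rank and crowding to a population in place (returns the list).
rank_population <- function(pop) {
  obj <- do.call(rbind, lapply(pop, `[[`, "objectives"))
  nds <- nondominated_sort(obj)
  for (f in nds$fronts) {
    cd <- crowding_distance(obj[f, , drop = FALSE])
    for (t in seq_along(f)) {
      pop[[f[t]]]$rank <- nds$rank[f[t]]
      pop[[f[t]]]$crowding <- cd[t]
    }
  }
  pop
}

# Probabilistic binary tournaments: `rounds` winners by (rank, -crowding),
# the better individual winning with probability win_prob.
tournament_select <- function(rank, crowding, rounds, win_prob) {
  n <- length(rank)
  a <- sample.int(n, rounds, replace = TRUE)
  b <- sample.int(n, rounds, replace = TRUE)
  a_better <- rank[a] < rank[b] |
    (rank[a] == rank[b] & crowding[a] > crowding[b]) |
    (rank[a] == rank[b] & crowding[a] == crowding[b])
  better <- ifelse(a_better, a, b)
  worse <- ifelse(a_better, b, a)
  ifelse(stats::runif(rounds) < win_prob, better, worse)
}

# Simulated binary crossover on [0,1]-bounded key matrices (rows = pairs).
sbx_crossover <- function(P1, P2, eta, p_cross) {
  C1 <- P1; C2 <- P2
  cross_pair <- stats::runif(nrow(P1)) < p_cross
  if (!any(cross_pair)) return(list(C1, C2))
  do_gene <- matrix(stats::runif(length(P1)) < 0.5, nrow(P1)) & cross_pair &
    abs(P1 - P2) > 1e-14
  if (any(do_gene)) {
    u <- stats::runif(sum(do_gene))
    beta <- ifelse(u <= 0.5, (2 * u)^(1 / (eta + 1)),
                   (1 / (2 * (1 - u)))^(1 / (eta + 1)))
    x1 <- P1[do_gene]; x2 <- P2[do_gene]
    c1 <- 0.5 * ((1 + beta) * x1 + (1 - beta) * x2)
    c2 <- 0.5 * ((1 - beta) * x1 + (1 + beta) * x2)
    C1[do_gene] <- pmin(pmax(c1, 0), 1)
    C2[do_gene] <- pmin(pmax(c2, 0), 1)
  }
  list(C1, C2)
}

# Polynomial mutation on a [0,1]-bounded key matrix.
poly_mutation <- function(K, eta, p_mut) {
  do_gene <- matrix(stats::runif(length(K)) < p_mut, nrow(K))
  if (any(do_gene)) {
    x <- K[do_gene]
    u <- stats::runif(length(x))
    delta <- ifelse(
      u < 0.5,
      (2 * u + (1 - 2 * u) * (1 - x)^(eta + 1))^(1 / (eta + 1)) - 1,
      1 - (2 * (1 - u) + (2 * u - 1) * x^(eta + 1))^(1 / (eta + 1)))
    K[do_gene] <- pmin(pmax(x + delta, 0), 1)
  }
  K
}

# Binary-mode variation: uniform crossover + per-gene bit flip on decoded
# bits; children keys are written as 0/1.
binary_variation <- function(P1, P2, p_cross, p_mut) {
  B1 <- (P1 >= 0.5) + 0; B2 <- (P2 >= 0.5) + 0
  cross_pair <- stats::runif(nrow(P1)) < p_cross
  swap <- matrix(stats::runif(length(B1)) < 0.5, nrow(B1)) & cross_pair
  tmp <- B1[swap]; B1[swap] <- B2[swap]; B2[swap] <- tmp
  flip1 <- matrix(stats::runif(length(B1)) < p_mut, nrow(B1))
  flip2 <- matrix(stats::runif(length(B2)) < p_mut, nrow(B2))
  B1[flip1] <- 1 - B1[flip1]
  B2[flip2] <- 1 - B2[flip2]
  list(B1, B2)
}

#' Run the NSGA-II evolutionary loop
#'
#' A (mu+lambda) generational loop: probabilistic binary tournaments on
#' (rank, crowding) fill the mating pool, SBX crossover and polynomial
#' mutation (or the binary operators) produce offspring keys, each offspring
#' is decoded/repaired/evaluated, and environmental selection keeps the best
#' `population_size` individuals by rank then crowding. Deterministic per
#' seed.
#'
#' @param inst A `problem_instance`.
#' @param config Settings from [engine_config()].
#' @return A `pareto_set`: the final population's first front, deduplicated
#'   by selection vector, with full plans, an objective matrix, the
#'   per-generation convergence log, and the seed/config used.
#' @export
evolve <- function(inst, config = engine_config()) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(config$seed)
  tab <- instance_tables(inst)
  n <- nrow(inst$facilities)
  p_mut <- if (is.null(config$mutation_prob)) 1 / n else config$mutation_prob
  mu <- config$population_size
  cache <- new.env(parent = emptyenv())

  pop <- lapply(seq_len(mu), function(i) {
    decode_eval(inst, tab, stats::runif(n), cache)
  })
  pop <- rank_population(pop)

  # fixed reference point for the convergence log, from the initial
  # population's objective spread
  obj0 <- do.call(rbind, lapply(pop, `[[`, "objectives"))
  log_ref <- apply(obj0, 2L, max) * 1.1 + 1e-9
  log <- vector("list", config$generations)

  for (gen in seq_len(config$generations)) {
    rank <- vapply(pop, `[[`, integer(1L), "rank")
    crowd <- vapply(pop, `[[`, numeric(1L), "crowding")
    pool <- tournament_select(rank, crowd, config$tournament_rounds,
                              config$tournament_win_prob)
    if (length(pool) %% 2L == 1L) pool <- c(pool, pool[1L])
    half <- length(pool) / 2L
    K <- do.call(rbind, lapply(pop, `[[`, "keys"))
    P1 <- K[pool[seq_len(half)], , drop = FALSE]
    P2 <- K[pool[half + seq_len(half)], , drop = FALSE]
    kids <- if (config$operator == "sbx") {
      ch <- sbx_crossover(P1, P2, config$crossover_index,
                          config$crossover_prob)
      lapply(ch, poly_mutation, eta = config$mutation_index, p_mut = p_mut)
    } else {
      binary_variation(P1, P2, config$crossover_prob, p_mut)
    }
    kid_keys <- rbind(kids[[1L]], kids[[2L]])
    offspring <- lapply(seq_len(nrow(kid_keys)), function(i) {
      decode_eval(inst, tab, kid_keys[i, ], cache)
    })
    combined <- c(pop, offspring)
    obj <- do.call(rbind, lapply(combined, `[[`, "objectives"))
    nds <- nondominated_sort(obj)
    keep <- integer(0)
    for (f in nds$fronts) {
      cd <- crowding_distance(obj[f, , drop = FALSE])
      for (t in seq_along(f)) {
        combined[[f[t]]]$rank <- nds$rank[f[t]]
        combined[[f[t]]]$crowding <- cd[t]
      }
      if (length(keep) + length(f) <= mu) {
        keep <- c(keep, f)
      } else {
        room <- mu - length(keep)
        if (room > 0) keep <- c(keep, f[order(-cd, seq_along(f))][seq_len(room)])
        break
      }
    }
    pop <- combined[keep]
    front0 <- which(vapply(pop, `[[`, integer(1L), "rank") == 1L)
    fobj <- do.call(rbind, lapply(pop[front0], `[[`, "objectives"))
    log[[gen]] <- data.frame(
      generation = gen, front_size = length(front0),
      best_f1 = min(fobj[, 1L]), best_f2 = min(fobj[, 2L]),
      hypervolume = hypervolume_2d(fobj, log_ref))
  }

  pop <- rank_population(pop)
  front_idx <- which(vapply(pop, `[[`, integer(1L), "rank") == 1L)
  sel_strings <- vapply(pop[front_idx], function(ch) {
    paste0(ch$selection, collapse = "")
  }, character(1L))
  front_idx <- front_idx[!duplicated(sel_strings)]
  ord <- order(vapply(pop[front_idx], function(ch) ch$objectives[["f1"]],
                      numeric(1L)))
  front_idx <- front_idx[ord]
  plans <- lapply(pop[front_idx], function(ch) {
    construct_plan(inst, as.logical(ch$selection))
  })
  pareto_set(plans, seed = config$seed, config = config,
             convergence = do.call(rbind, log))
}

#' Bundle plans into a Pareto set
#'
#' @param plans List of `selection_plan` objects (mutually non-dominated).
#' @param seed,config,convergence Run metadata (optional).
#' @return A `pareto_set`: list with `plans`, `objectives` matrix, `seed`,
#'   `config`, `convergence`.
#' @export
pareto_set <- function(plans, seed = NULL, config = NULL,
                       convergence = NULL) {
  obj <- do.call(rbind, lapply(plans, `[[`, "objectives"))
  structure(list(plans = plans, objectives = obj, seed = seed,
                 config = config, convergence = convergence),
            class = "pareto_set")
}

#' @export
print.pareto_set <- function(x, ...) {
  cat("Pareto set:", length(x$plans), "non-dominated plan(s)\n")
  print(as.data.frame(x))
  invisible(x)
}

#' Summarize a Pareto set as one row per solution
#'
#' @param x A `pareto_set`.
#' @param ... Unused.
#' @return Data frame with columns `solution`, `n_selected` (count of
#'   selected hospitals), `patient_cost` (`f1`), `hospital_cost` (`f2`).
#' @export
as.data.frame.pareto_set <- function(x, ...) {
  data.frame(
    solution = seq_along(x$plans),
    n_selected = vapply(x$plans, function(p) sum(p$x), integer(1L)),
    patient_cost = x$objectives[, 1L],
    hospital_cost = x$objectives[, 2L])
}

#' Scatter plot of a Pareto front
#'
#' @param x A `pareto_set`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.pareto_set <- function(x, ...) {
  graphics::plot(x$objectives[, 1L], x$objectives[, 2L],
                 xlab = "patient cost (f1)", ylab = "hospital cost (f2)",
                 pch = 19, ...)
  invisible(x)
}
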