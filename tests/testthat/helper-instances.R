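# Fixtures built in code, plus independent oracles used by the tests.

# One RMC at the origin, one demand point at distance 2, one patient,
# default parameters: the hand-computable worked example.
unit_example_instance <- function() {
  problem_instance(
    facilities = data.frame(id = "R1", tier = "RMC", parent_id = "R1",
                            x = 0, y = 0),
    demand_points = data.frame(id = "D1", x = 0, y = 2, n = 1))
}

# Two RMCs three distance units apart, one community next to each: close
# enough that saving the second contract can beat the extra travel, so the
# instance carries a real contracting-vs-travel trade-off.
two_facility_instance <- function() {
  problem_instance(
    facilities = data.frame(id = c("R1", "R2"), tier = "RMC",
                            parent_id = c("R1", "R2"),
                            x = c(0, 3), y = c(0, 0)),
    demand_points = data.frame(id = c("D1", "D2"), x = c(0, 3),
                               y = c(1, 1), n = c(5, 4)))
}

# Small seeded random instance (<= 10 facilities by construction).
small_random_instance <- function(seed, n_demand = 6, capacity_cap = NULL) {
  cfg <- generator_config(n_rmc = 2 + seed %% 2, phc_per_rmc = c(1, 2),
                          n_demand = n_demand,
                          total_patients = 40 + 5 * (seed %% 5),
                          capacity_cap = capacity_cap)
  generate_instance(cfg, seed = seed)
}

# Independent scalar objective oracle for a single-type instance: given the
# assigned distance and patient count per demand point plus the number of
# contracts, applies the cost formulas term by term (never calls the
# package's evaluation path).
scalar_objectives <- function(d_assigned, n, n_contracts,
                              p = default_parameters()) {
  pt <- p$patient_types; cs <- p$costs
  f1 <- sum(n * (pt$F1 * cs$h1_per_dist * d_assigned + pt$F2 * cs$h2_base))
  f2 <- cs$C1 * n_contracts +
    sum(n * (pt$F1 * cs$c1_base + pt$F2 * cs$c2_per_dist * d_assigned)) +
    cs$C2 * sum(n * (pt$F1 * pt$e1 + pt$F2 * pt$e2))
  c(f1 = f1, f2 = f2)
}

# O(n^2) brute-force non-dominated ranking (weak dominance, minimization),
# by repeated peeling with explicit pairwise loops.
brute_force_ranks <- function(obj) {
  n <- nrow(obj)
  rank <- rep(NA_integer_, n)
  r <- 0L
  while (anyNA(rank)) {
    r <- r + 1L
    alive <- which(is.na(rank))
    for (a in alive) {
      dominated <- FALSE
      for (b in alive) {
        if (b != a &&
            obj[b, 1L] <= obj[a, 1L] && obj[b, 2L] <= obj[a, 2L] &&
            (obj[b, 1L] < obj[a, 1L] || obj[b, 2L] < obj[a, 2L])) {
          dominated <- TRUE
          break
        }
      }
      if (!dominated) rank[a] <- r
    }
  }
  rank
}

# Monte-Carlo hypervolume oracle: fraction of uniform samples in
# [0, ref1] x [0, ref2] dominated by some point, scaled by the box area.
# Returns the estimate and its standard error.
mc_hypervolume <- function(points, reference, n_samples) {
  sx <- runif(n_samples, 0, reference[1L])
  sy <- runif(n_samples, 0, reference[2L])
  dominated <- rep(FALSE, n_samples)
  for (i in seq_len(nrow(points))) {
    dominated <- dominated | (points[i, 1L] <= sx & points[i, 2L] <= sy)
  }
  p_hat <- mean(dominated)
  area <- reference[1L] * reference[2L]
  list(estimate = p_hat * area,
       se = sqrt(p_hat * (1 - p_hat) / n_samples) * area)
}

# Objective matrix helper.
obj_matrix <- function(...) {
  m <- rbind(...)
  colnames(m) <- c("f1", "f2")
  m
}
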