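# Seeded synthetic-instance generator emulating a dense-core/sparse-periphery
# urban district: a two-tier RMC/PHC hierarchy with PHCs clustered around
# their supervising RMC, a few high-density communities and many sparse ones.

#' Generator settings
#'
#' @param n_rmc Number of candidate RMCs.
#' @param phc_per_rmc Integer range `c(min, max)` of subordinate PHCs drawn
#'   uniformly per RMC (use `c(0, 0)` for an RMC-only instance).
#' @param n_demand Number of community demand points.
#' @param total_patients Total discharged patients per year, split across
#'   demand points.
#' @param extent Side length of the square planning region (distance units).
#' @param cluster_fraction Expected share of patients concentrated in the
#'   `n_dense` high-density communities; must lie in `[0, 1]`.
#' @param n_dense Number of dense communities, placed in the eastern core of
#'   the region; the remaining communities are scattered uniformly.
#' @param n_types Number of patient types (type mixes drawn from a flat
#'   Dirichlet when greater than 1).
#' @param patient_types,costs Parameter overrides; defaults from
#'   [default_parameters()].
#' @param capacity_cap Optional per-facility capacity bound passed through to
#'   the instance.
#' @return A list of generator settings for [generate_instance()].
#' @export
generator_config <- function(n_rmc = 5, phc_per_rmc = c(1, 3), n_demand = 8,
                             total_patients = 200, extent = 10,
                             cluster_fraction = 0.6, n_dense = 2,
                             n_types = 1, patient_types = NULL, costs = NULL,
                             capacity_cap = NULL) {
  stopifnot(n_rmc >= 1, n_demand >= 1, total_patients >= 0,
            length(phc_per_rmc) == 2L, phc_per_rmc[1L] >= 0,
            phc_per_rmc[2L] >= phc_per_rmc[1L], extent > 0, n_types >= 1)
  if (cluster_fraction < 0 || cluster_fraction > 1) {
    stop("cluster_fraction must be in [0, 1]", call. = FALSE)
  }
  n_dense <- min(n_dense, n_demand)
  defaults <- default_parameters()
  list(n_rmc = n_rmc, phc_per_rmc = phc_per_rmc, n_demand = n_demand,
       total_patients = total_patients, extent = extent,
       cluster_fraction = cluster_fraction, n_dense = n_dense,
       n_types = n_types,
       patient_types = if (is.null(patient_types)) defaults$patient_types else patient_types,
       costs = if (is.null(costs)) defaults$costs else costs,
       capacity_cap = capacity_cap)
}

#' District-scale generator preset
#'
#' Settings emulating the structure of the motivating case study district:
#' 29 candidate RMCs with subordinate PHCs, 28 communities totalling 726
#' discharged patients per year, most of them concentrated in four dense
#' communities on one side of the district, a single patient type, and the
#' default cost parameters.
#'
#' @return A generator configuration (see [generator_config()]).
#' @export
wuhou_like_config <- function() {
  generator_config(n_rmc = 29, phc_per_rmc = c(1, 3), n_demand = 28,
                   total_patients = 726, extent = 10,
                   cluster_fraction = 0.6, n_dense = 4, n_types = 1)
}

#' Generate a seeded synthetic problem instance
#'
#' Deterministic for a fixed `(config, seed)` pair. RMCs are placed uniformly
#' in the square region; each RMC supervises a uniform number of PHCs
#' scattered around it. Dense communities live in the eastern core
#' (x in the top 30% of the extent, central band in y) and carry an expected
#' `cluster_fraction` share of the patients; patient counts are split by a
#' Dirichlet-multinomial so they sum exactly to `total_patients`.
#'
#' @param config Settings from [generator_config()] or [wuhou_like_config()].
#' @param seed Integer RNG seed.
#' @return A validated `problem_instance`.
#' @export
#' @examples
#' inst <- generate_instance(wuhou_like_config(), seed = 1)
#' sum(inst$demand_points$n)  # 726
generate_instance <- function(config = generator_config(), seed = 1L) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  ext <- config$extent
  n_rmc <- config$n_rmc
  rmc <- data.frame(
    id = sprintf("R%02d", seq_len(n_rmc)), tier = "RMC",
    parent_id = sprintf("R%02d", seq_len(n_rmc)),
    x = stats::runif(n_rmc, 0, ext), y = stats::runif(n_rmc, 0, ext),
    stringsAsFactors = FALSE)
  n_phc <- if (config$phc_per_rmc[2L] == 0) integer(n_rmc) else
    sample(seq(config$phc_per_rmc[1L], config$phc_per_rmc[2L]), n_rmc,
           replace = TRUE)
  phc <- NULL
  if (sum(n_phc) > 0) {
    parent <- rep(seq_len(n_rmc), n_phc)
    # PHCs sit near their supervising RMC (community clinics of the same
    # sub-district); clamp to the region
    px <- pmin(pmax(rmc$x[parent] + stats::rnorm(length(parent), 0, ext / 15),
                    0), ext)
    py <- pmin(pmax(rmc$y[parent] + stats::rnorm(length(parent), 0, ext / 15),
                    0), ext)
    phc <- data.frame(
      id = sprintf("P%03d", seq_along(parent)), tier = "PHC",
      parent_id = rmc$id[parent], x = px, y = py, stringsAsFactors = FALSE)
  }
  facilities <- rbind(rmc, phc)

  nd <- config$n_demand
  k_dense <- config$n_dense
  dense_x <- stats::runif(k_dense, 0.7 * ext, ext)
  dense_y <- stats::runif(k_dense, 0.25 * ext, 0.75 * ext)
  k_sparse <- nd - k_dense
  sparse_x <- stats::runif(k_sparse, 0, ext)
  sparse_y <- stats::runif(k_sparse, 0, ext)
  dem <- data.frame(
    id = sprintf("D%02d", seq_len(nd)),
    x = c(dense_x, sparse_x), y = c(dense_y, sparse_y),
    n = 0L, stringsAsFactors = FALSE)
  # Dirichlet-multinomial split of the patient total between the dense core
  # and the sparse background
  w <- stats::rgamma(nd, shape = 1)
  p <- numeric(nd)
  if (k_dense > 0 && k_dense < nd) {
    p[seq_len(k_dense)] <-
      config$cluster_fraction * w[seq_len(k_dense)] / sum(w[seq_len(k_dense)])
    p[-seq_len(k_dense)] <-
      (1 - config$cluster_fraction) * w[-seq_len(k_dense)] /
      sum(w[-seq_len(k_dense)])
  } else {
    p <- w / sum(w)
  }
  dem$n <- as.integer(stats::rmultinom(1L, config$total_patients, p))

  mix <- if (config$n_types == 1L) {
    matrix(1, nd, 1L)
  } else {
    g <- matrix(stats::rgamma(nd * config$n_types, shape = 1), nd)
    g / rowSums(g)
  }
  pt <- config$patient_types
  if (nrow(pt) != config$n_types) {
    pt <- pt[rep_len(seq_len(nrow(pt)), config$n_types), , drop = FALSE]
    rownames(pt) <- NULL
  }
  problem_instance(facilities, dem, type_mix = mix, patient_types = pt,
                   costs = config$costs, capacity_cap = config$capacity_cap)
}
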