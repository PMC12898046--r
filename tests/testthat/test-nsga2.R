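test_that("decode-and-repair removes unused facilities and fixes empty selections", {
  inst <- two_facility_instance()
  # both keys clear the threshold and each facility serves its nearest point
  chr <- decode_and_repair(inst, c(0.9, 0.6))
  expect_equal(chr$selection, c(1L, 1L))
  expect_equal(chr$allocation_counts, c(1L, 1L))

  # a selected facility allocated zero demand points is deselected
  cluster <- problem_instance(
    data.frame(id = c("R1", "R2"), tier = "RMC", parent_id = c("R1", "R2"),
               x = c(0, 9), y = 0),
    data.frame(id = c("D1", "D2"), x = c(0, 1), y = 0, n = c(3, 3)))
  chr2 <- decode_and_repair(cluster, c(0.8, 0.7))
  expect_equal(chr2$selection, c(1L, 0L))         # R2 served nothing
  expect_lt(chr2$keys[2L], 0.5)                   # key pushed below threshold
  expect_equal(chr2$allocation_counts, c(2L, 0L))

  # all keys below threshold: force-select the argmax key
  chr3 <- decode_and_repair(cluster, c(0.2, 0.4))
  expect_equal(chr3$selection, c(0L, 1L))
  expect_gte(chr3$keys[2L], 0.5)
  expect_equal(sum(chr3$allocation_counts), 2L)

  # a repair fixed point is left unchanged
  chr4 <- decode_and_repair(two_facility_instance(), c(0.7, 0.7))
  expect_equal(chr4$selection, c(1L, 1L))
  expect_equal(chr4$keys, c(0.7, 0.7))
})

test_that("repaired chromosomes stay consistent with their induced plan", {
  inst <- small_random_instance(2)
  set.seed(7)
  for (r in 1:25) {
    chr <- decode_and_repair(inst, runif(nrow(inst$facilities)))
    expect_true(all(chr$allocation_counts[chr$selection == 1L] >= 1L))
    expect_equal(sum(chr$allocation_counts), nrow(inst$demand_points))
    plan <- construct_plan(inst, chr$selection == 1L)
    expect_equal(plan$objectives, chr$objectives)
  }
})

test_that("population initialization is seeded and fully evaluated", {
  inst <- small_random_instance(1)
  cfg <- engine_config(population_size = 30L, generations = 1L, seed = 42L)
  pop1 <- initialize_population(inst, cfg)
  pop2 <- initialize_population(inst, cfg)
  expect_equal(length(pop1), 30L)
  expect_identical(pop1, pop2)
  for (chr in pop1) {
    expect_equal(sum(chr$allocation_counts), nrow(inst$demand_points))
    expect_false(anyNA(chr$objectives))
  }
  # a 1-facility instance always repairs to the forced selection
  single <- generate_instance(generator_config(n_rmc = 1,
                                               phc_per_rmc = c(0, 0),
                                               n_demand = 2,
                                               total_patients = 10), 1)
  for (chr in initialize_population(single, cfg)) {
    expect_equal(chr$selection, 1L)
  }
})

test_that("non-dominated sorting matches a brute-force pairwise oracle", {
  for (s in 1:6) {
    set.seed(500 + s)
    obj <- cbind(sample(1:8, 20, replace = TRUE),
                 sample(1:8, 20, replace = TRUE))  # ties and duplicates
    expect_equal(nondominated_sort(obj)$rank, brute_force_ranks(obj))
  }
  expect_equal(nondominated_sort(rbind(c(1, 2)))$rank, 1L)
  # duplicates share a front
  expect_equal(nondominated_sort(rbind(c(1, 1), c(1, 1)))$rank, c(1L, 1L))
  expect_error(nondominated_sort(rbind(c(NaN, 1))), "NA/NaN")
})

test_that("crowding distance follows the standard normalized-gap formula", {
  expect_equal(crowding_distance(rbind(c(0, 1), c(1, 0))), c(Inf, Inf))
  # three collinear equally spaced points: interior gets 1 per objective
  cd <- crowding_distance(rbind(c(0, 2), c(1, 1), c(2, 0)))
  expect_equal(cd, c(Inf, 2, Inf))
  # duplicated interior points: the duplicate side contributes a zero gap
  cd2 <- crowding_distance(rbind(c(0, 0), c(1, 1), c(1, 1), c(3, 3)))
  expect_equal(cd2, c(Inf, 2 * 1 / 3, 2 * 2 / 3, Inf))
  # zero range in one objective contributes 0
  cd3 <- crowding_distance(rbind(c(0, 5), c(1, 5), c(2, 5)))
  expect_equal(cd3, c(Inf, 1, Inf))
})

test_that("evolve is seed-deterministic and returns a feasible single front", {
  inst <- small_random_instance(3)
  cfg <- engine_config(population_size = 40L, generations = 30L, seed = 9L)
  r1 <- evolve(inst, cfg)
  r2 <- evolve(inst, cfg)
  expect_identical(r1$objectives, r2$objectives)
  expect_identical(as.data.frame(r1), as.data.frame(r2))

  # self-consistency: the returned set is one non-dominated front
  expect_true(all(nondominated_sort(r1$objectives)$rank == 1L))
  for (p in r1$plans) {
    expect_equal(nrow(check_constraints(inst, p)), 0L)
    served <- tabulate(p$assignment, nbins = nrow(inst$facilities))
    expect_true(all(served[p$x == 1L] >= 1L))  # repair invariant
  }
})

test_that("evolve on a 1-facility instance returns the single forced plan", {
  single <- generate_instance(generator_config(n_rmc = 1,
                                               phc_per_rmc = c(0, 0),
                                               n_demand = 3,
                                               total_patients = 12), 2)
  res <- evolve(single, engine_config(population_size = 10L,
                                      generations = 5L, seed = 1L))
  expect_equal(length(res$plans), 1L)
  expect_equal(unname(res$plans[[1L]]$x), 1L)
})

test_that("rank-0 hypervolume against a fixed reference is non-decreasing", {
  inst <- small_random_instance(5)
  res <- evolve(inst, engine_config(population_size = 40L,
                                    generations = 40L, seed = 11L))
  hv <- res$convergence$hypervolume
  expect_true(all(diff(hv) >= -1e-9))
})

test_that("the binary operator mode also yields a valid front", {
  inst <- small_random_instance(6)
  res <- evolve(inst, engine_config(population_size = 30L,
                                    generations = 25L, seed = 4L,
                                    operator = "binary"))
  expect_true(all(nondominated_sort(res$objectives)$rank == 1L))
  for (p in res$plans) {
    expect_equal(nrow(check_constraints(inst, p)), 0L)
  }
})

test_that("the reported front never contains a vector dominated by the exact front", {
  inst <- small_random_instance(7)
  exact <- enumerate_front(inst)
  res <- evolve(inst, engine_config(population_size = 60L,
                                    generations = 60L, seed = 2L))
  for (i in seq_len(nrow(res$objectives))) {
    o <- res$objectives[i, ]
    dominated <- any(exact$objectives[, 1L] <= o[1L] &
                       exact$objectives[, 2L] <= o[2L] &
                       (exact$objectives[, 1L] < o[1L] |
                          exact$objectives[, 2L] < o[2L]))
    expect_false(dominated)
  }
})
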