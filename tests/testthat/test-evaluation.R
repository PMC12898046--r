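test_that("proximity allocation picks nearest selected facility, ties to file order", {
  inst <- two_facility_instance()
  # one selected facility takes everything
  expect_equal(induce_allocation(inst, c(TRUE, FALSE)), c(1L, 1L))
  # both selected: each point to its nearest
  expect_equal(induce_allocation(inst, c(TRUE, TRUE)), c(1L, 2L))
  expect_error(induce_allocation(inst, c(FALSE, FALSE)), "no facility")

  # equidistant tie breaks toward the lower file-order index
  tie <- problem_instance(
    data.frame(id = c("R1", "R2"), tier = "RMC", parent_id = c("R1", "R2"),
               x = c(-1, 1), y = 0),
    data.frame(id = "D1", x = 0, y = 0, n = 1))
  expect_equal(induce_allocation(tie, c(TRUE, TRUE)), 1L)
})

test_that("uncapped allocation achieves the per-point minimum distance", {
  for (s in 1:8) {
    inst <- small_random_instance(s)
    n_fac <- nrow(inst$facilities)
    set.seed(100 + s)
    sel <- runif(n_fac) < 0.5
    if (!any(sel)) sel[1L] <- TRUE
    a <- induce_allocation(inst, sel)
    for (j in seq_len(nrow(inst$demand_points))) {
      # brute-force nearest-neighbor scan over the selected facilities
      expect_equal(inst$distances[a[j], j],
                   min(inst$distances[which(sel), j]))
    }
  }
})

test_that("capacity caps reroute overflow to the next-nearest facility", {
  # D1 (heavy) and D2 both nearest to R1; R1 can hold only one of them
  inst <- problem_instance(
    data.frame(id = c("R1", "R2"), tier = "RMC", parent_id = c("R1", "R2"),
               x = c(0, 5), y = 0),
    data.frame(id = c("D1", "D2"), x = c(0, 1), y = 0, n = c(10, 4)),
    capacity_cap = c(430, 1000))  # workloads: 420 and 168 units
  a <- induce_allocation(inst, c(TRUE, TRUE))
  # heavier point processed first and kept at its nearest facility
  expect_equal(a, c(1L, 2L))

  # without the cap both points stay at R1
  uncapped <- problem_instance(
    inst$facilities, inst$demand_points, distances = inst$distances)
  expect_equal(induce_allocation(uncapped, c(TRUE, TRUE)), c(1L, 1L))

  # aggregate shortfall is an explicit infeasibility error
  tight <- problem_instance(
    inst$facilities, inst$demand_points, distances = inst$distances,
    capacity_cap = c(430, 100))
  expect_error(induce_allocation(tight, c(TRUE, TRUE)), "infeasible")
})

test_that("contracts are the minimal feasible RMC set", {
  fac <- data.frame(id = c("R1", "R2", "P1", "P2"),
                    tier = c("RMC", "RMC", "PHC", "PHC"),
                    parent_id = c("R1", "R2", "R1", "R1"),
                    x = c(0, 5, 1, 2), y = 0)
  dem <- data.frame(id = "D1", x = 0, y = 0, n = 1)
  inst <- problem_instance(fac, dem)
  # empty selection: no contract
  expect_equal(sum(contracts_from_selection(inst, rep(FALSE, 4L))), 0L)
  # two PHCs under the same RMC: C1 is charged once
  y <- contracts_from_selection(inst, c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(unname(y), c(1L, 0L))
  # an RMC contracts itself (self-subordination)
  y2 <- contracts_from_selection(inst, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(unname(y2), c(0L, 1L))
  # exhaustive 0/1 check of the contracting constraint over all selections
  for (s in 0:15) {
    sel <- as.logical(s %/% 2^(0:3) %% 2)
    y <- contracts_from_selection(inst, sel)
    parent <- match(fac$parent_id, c("R1", "R2"))
    for (i in which(sel)) expect_equal(unname(y[parent[i]]), 1L)
    expect_equal(sum(y), length(unique(parent[sel])))
  }
})

test_that("workload matches the capacity arithmetic and is linear in n", {
  inst <- unit_example_instance()
  a <- induce_allocation(inst, TRUE)
  expect_equal(workload(inst, a, "R1"), 42)   # (2*6 + 3*10) * 1 patient
  expect_error(workload(inst, a, "nope"), "unknown facility")

  inst10 <- problem_instance(inst$facilities,
                             transform(inst$demand_points, n = 10))
  expect_equal(workload(inst10, a, "R1"), 420)

  two <- two_facility_instance()
  a2 <- induce_allocation(two, c(TRUE, FALSE))
  expect_equal(unname(workload(two, a2)["R2"]), 0)  # serving nothing
})

test_that("objectives reproduce the hand-computed worked example", {
  inst <- unit_example_instance()
  plan <- construct_plan(inst, TRUE)
  # f1 = F1 * (30*d) + F2 * 50 = 6*60 + 500 at d = 2
  expect_equal(plan$objectives[["f1"]], 860)
  # f2 = C1 + (6*80 + 10*60*2) + 50*42
  expect_equal(plan$objectives[["f2"]], 13780)
})

test_that("objectives agree with an independent scalar oracle on random instances", {
  for (s in 1:6) {
    inst <- small_random_instance(s)
    n_fac <- nrow(inst$facilities)
    set.seed(300 + s)
    sel <- runif(n_fac) < 0.6
    if (!any(sel)) sel[1L] <- TRUE
    plan <- construct_plan(inst, sel)
    d_assigned <- inst$distances[cbind(plan$assignment,
                                       seq_along(plan$assignment))]
    expected <- scalar_objectives(d_assigned, inst$demand_points$n,
                                  n_contracts = sum(plan$y))
    expect_equal(plan$objectives, expected, tolerance = 1e-12)
  }
})

test_that("empty demand collapses f1 to 0 and f2 to the contracting bill", {
  inst <- problem_instance(
    data.frame(id = c("R1", "R2"), tier = "RMC", parent_id = c("R1", "R2"),
               x = c(0, 5), y = 0),
    data.frame(id = c("D1", "D2"), x = c(0, 5), y = 1, n = c(0, 0)))
  plan <- construct_plan(inst, c(TRUE, TRUE), repair_unused = FALSE)
  expect_equal(plan$objectives[["f1"]], 0)
  expect_equal(plan$objectives[["f2"]], inst$costs$C1 * sum(plan$y))
})

test_that("constraint reports itemize violations and clear feasible plans", {
  fac <- data.frame(id = c("R1", "P1"), tier = c("RMC", "PHC"),
                    parent_id = c("R1", "R1"), x = c(0, 3), y = 0)
  dem <- data.frame(id = c("D1", "D2"), x = c(0, 3), y = 1, n = c(2, 3))
  inst <- problem_instance(fac, dem)
  plan <- construct_plan(inst, c(TRUE, TRUE))
  expect_equal(nrow(check_constraints(inst, plan)), 0L)

  # assignment to an unselected facility cites the linkage constraint
  broken <- plan
  broken$x[2L] <- 0L
  rep4 <- check_constraints(inst, broken)
  expect_true("selection_linkage" %in% rep4$constraint)
  expect_equal(rep4$facility[rep4$constraint == "selection_linkage"], "P1")

  # selected PHC with an uncontracted parent RMC cites contracting
  broken2 <- plan
  broken2$y[1L] <- 0L
  rep5 <- check_constraints(inst, broken2)
  expect_true("contracting" %in% rep5$constraint)
  expect_equal(rep5$facility[rep5$constraint == "contracting"], "R1")

  # under-provisioned capacity cites the capacity constraint
  broken3 <- plan
  broken3$w[] <- 0
  rep6 <- check_constraints(inst, broken3)
  expect_true("capacity" %in% rep6$constraint)

  expect_error(evaluate_objectives(inst, broken), "selection_linkage")
})

test_that("constructed plans are always feasible", {
  for (s in 1:8) {
    inst <- small_random_instance(s)
    set.seed(400 + s)
    sel <- runif(nrow(inst$facilities)) < 0.5
    if (!any(sel)) sel[2L] <- TRUE
    plan <- construct_plan(inst, sel)
    expect_equal(nrow(check_constraints(inst, plan)), 0L)
  }
})

test_that("f2 responds to C1 exactly through the contract count", {
  inst <- small_random_instance(3)
  sel <- rep(TRUE, nrow(inst$facilities))
  plan <- construct_plan(inst, sel)
  delta <- 1234.5
  inst2 <- inst
  inst2$costs$C1 <- inst$costs$C1 + delta
  plan2 <- construct_plan(inst2, plan$x == 1L)
  expect_equal(plan2$objectives[["f2"]] - plan$objectives[["f2"]],
               delta * sum(plan$y))
  expect_equal(plan2$objectives[["f1"]], plan$objectives[["f1"]])
})

test_that("scaling demand scales the non-contracting cost terms exactly", {
  inst <- small_random_instance(4)
  sel <- rep(TRUE, nrow(inst$facilities))
  plan <- construct_plan(inst, sel)
  alpha <- 3
  inst2 <- problem_instance(
    inst$facilities,
    transform(inst$demand_points, n = n * alpha),
    type_mix = inst$type_mix, patient_types = inst$patient_types,
    costs = inst$costs, distances = inst$distances)
  plan2 <- construct_plan(inst2, plan$x == 1L)
  c1_term <- inst$costs$C1 * sum(plan$y)
  expect_equal(sum(plan2$y), sum(plan$y))
  expect_equal(plan2$objectives[["f1"]], alpha * plan$objectives[["f1"]])
  expect_equal(plan2$objectives[["f2"]] - c1_term,
               alpha * (plan$objectives[["f2"]] - c1_term))
})

test_that("per-(i,j,k) cost override tables replace the affine defaults", {
  inst <- unit_example_instance()
  n_k <- 1L
  ov <- inst
  ov$costs$h1_table <- array(100, c(1L, 1L, n_k))   # flat patient travel cost
  ov <- validate_instance(ov)
  plan <- construct_plan(ov, TRUE)
  # f1 = F1 * 100 + F2 * 50 = 600 + 500
  expect_equal(plan$objectives[["f1"]], 1100)
})
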