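test_that("feasible moves at the root respect state and constraints", {
  st <- rb_state(extend_matrix(sigma_matrix()))
  expect_setequal(feasible_moves(st), c("c1+", "c2+"))
  stF <- rb_state(extend_matrix(sigma_matrix(),
                                cppp_constraints("c1", "s3")))
  expect_setequal(feasible_moves(stF), "c2+")
  # all characters free: nothing to do
  res <- apply_c_reduction(sigma_matrix(),
                           reduction = c("c1+", "c2+", "c1-"))
  expect_length(feasible_moves(res$state), 0L)
})

test_that("search solves, refuses and verifies the hand instances", {
  fit <- cppp(sigma_matrix())
  expect_s3_class(fit, "cppp")
  expect_equal(fit$status, "solution")
  expect_true(verify_ppp(fit$tree, sigma_matrix())$pass)
  expect_true(admits_directed_pp(fit$completed))
  # a genuinely conflicted instance (no all-zero rows, so the conflict
  # survives isolated-vertex pruning) forces at least one branching step
  Mc <- cppp_matrix(cbind(c1 = c(1, 1, 0, 0), c2 = c(0, 1, 1, 0),
                          c3 = c(1, 0, 1, 1)))
  expect_false(is_edgeless(conflict_graph(Mc)))
  fitc <- cppp(Mc)
  expect_identical(fitc$status == "solution", oracle_decide(Mc)$decision)
  expect_gt(fitc$stats$nodes, 1L)
  if (fitc$status == "solution")
    expect_true(verify_ppp(fitc$tree, Mc)$pass)
  # unsat constrained instance
  fit2 <- cppp(sigma_matrix(),
               cppp_constraints(c("c1", "c2"), c("s3", "s1")))
  expect_equal(fit2$status, "no-solution")
  # perfect-phylogeny input is trivially a persistent phylogeny
  Mpp <- cppp_matrix(cbind(c(1, 1, 0, 0), c(1, 0, 0, 0), c(0, 0, 1, 0)))
  fit3 <- cppp(Mpp)
  expect_equal(fit3$status, "solution")
  expect_true(verify_ppp(fit3$tree, Mpp)$pass)
})

test_that("returned reductions are valid and successful", {
  set.seed(303)
  for (i in 1:30) {
    M <- random_binary_matrix(sample(2:5, 1), sample(2:5, 1))
    fit <- cppp(M)
    if (fit$status != "solution") next
    expect_silent(ppphylo:::validate_reduction(fit$reduction, colnames(M)))
    expect_true(apply_c_reduction(M, reduction = fit$reduction)$success)
  }
})

test_that("adding constraints never enlarges the root move set", {
  set.seed(304)
  for (i in 1:20) {
    M <- random_binary_matrix(4, 4)
    if (sum(M == 0L) < 2) next
    Fk <- sim_constraints(M, 2)
    base <- feasible_moves(rb_state(extend_matrix(M)))
    constrained <- feasible_moves(rb_state(extend_matrix(M, Fk)))
    expect_true(all(constrained %in% base))
  }
})

test_that("memoized search reaches the same decisions", {
  set.seed(305)
  for (i in 1:40) {
    M <- random_binary_matrix(sample(3:5, 1), sample(3:5, 1))
    expect_identical(cppp(M, memoize = TRUE)$status, cppp(M)$status)
  }
})

test_that("the node budget is honored and reported", {
  M <- cppp_matrix(matrix(c(0, 1, 1, 0, 1, 1, 0, 0, 1, 0, 1, 1,
                            1, 1, 0, 0, 0, 0, 1, 1), 4, 5))
  fit <- cppp(M, max_nodes = 3)
  expect_equal(fit$status, "budget-exceeded")
  expect_lte(fit$stats$nodes, 4)
})
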