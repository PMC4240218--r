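test_that("conflict graph edges are exactly the four-configuration pairs", {
  M <- cppp_matrix(cbind(a = c(0, 1, 1, 0), b = c(1, 1, 0, 0)))
  g <- conflict_graph(M)
  expect_equal(nrow(g$edges), 1L)
  expect_setequal(as.vector(g$edges), c("a", "b"))
  # identical columns: no (1,0) configuration
  expect_true(is_edgeless(conflict_graph(cbind(c(1, 0), c(1, 0)))))
  # nested columns
  expect_true(is_edgeless(conflict_graph(cbind(c(1, 1, 0), c(1, 0, 0)))))
  # the sigma instance is conflict-free yet has no perfect phylogeny
  expect_true(is_edgeless(conflict_graph(sigma_matrix())))
})

test_that("red-black graph of a fresh instance has the right black edges", {
  g <- red_black_graph(extend_matrix(sigma_matrix()))
  expect_equal(nrow(g$edges), 4L)
  expect_true(all(g$edges$color == "black"))
  expect_setequal(paste(g$edges$species, g$edges$character),
                  c("s1 c1", "s2 c1", "s2 c2", "s3 c2"))
  st <- rb_state(extend_matrix(sigma_matrix()))
  expect_length(ppphylo:::rb_components(st), 1L)
  # all-zero matrix fully constrained: no edges at all
  M0 <- cppp_matrix(matrix(0L, 2, 2))
  F0 <- cppp_constraints(rep(colnames(M0), each = 2), rep(rownames(M0), 2))
  expect_equal(nrow(red_black_graph(extend_matrix(M0, F0))$edges), 0L)
  # a single 1-entry: a single black edge
  M1 <- cppp_matrix(matrix(c(1L, 0L), 1, 2))
  expect_equal(nrow(red_black_graph(extend_matrix(M1))$edges), 1L)
})

test_that("gain realization follows the component completion steps", {
  st <- rb_state(extend_matrix(sigma_matrix()))
  r <- realize(st, "c1+")
  expect_equal(r$status, "ok")
  st1 <- r$state
  # s3 is in C(c1) and not black-adjacent: persistent completion + red edge
  expect_equal(unname(st1$ext$cells["s3", c("c1+", "c1-")]), c(1L, 1L))
  g <- red_black_graph(st1)
  expect_true(any(g$edges$species == "s3" & g$edges$character == "c1" &
                    g$edges$color == "red"))
  # black edges of c1 gone, c1 active
  expect_false(any(g$edges$character == "c1" & g$edges$color == "black"))
  expect_equal(unname(st1$status["c1"]), "active")
  # s1 is now isolated (pruned from all components)
  comps <- ppphylo:::rb_components(st1)
  expect_false(any(vapply(comps, function(cc) 1L %in% cc$species,
                          logical(1))))
})

test_that("a constrained species in the component blocks the gain", {
  st <- rb_state(extend_matrix(sigma_matrix(), cppp_constraints("c1", "s3")))
  r <- realize(st, "c1+")
  expect_equal(r$status, "impossible")
  expect_equal(r$reason, "constraint-violation")
  # atomic: state unchanged
  expect_identical(r$state$ext$cells, st$ext$cells)
})

test_that("losses require an active covering character", {
  st <- rb_state(extend_matrix(sigma_matrix()))
  expect_equal(realize(st, "c1-")$status, "impossible")
  st1 <- realize(st, "c1+")$state
  # c1 active but s2 in its component lacks a red edge
  r <- realize(st1, "c1-")
  expect_equal(r$status, "impossible")
  expect_equal(r$reason, "active-not-covering")
  # repeated gain of an active character is impossible
  expect_equal(realize(st1, "c1+")$status, "impossible")
  expect_error(realize(st, "cX+"), "unknown character")
})

test_that("red-sigma detection matches its definition", {
  M <- cppp_matrix(matrix(0L, 3, 2, dimnames = list(paste0("s", 1:3),
                                                    c("a", "b"))))
  # red path s1-a-s2-b-s3 with Me[s3,a+]=0, Me[s1,b+]=0
  st <- state_with_reds(M, data.frame(
    species = c("s1", "s2", "s2", "s3"),
    character = c("a", "a", "b", "b"), stringsAsFactors = FALSE))
  w <- detect_red_sigma(st)
  expect_false(is.null(w))
  expect_setequal(w$characters, c("a", "b"))
  expect_length(w$species, 3L)
  # a 3-edge red path is not a sigma
  st2 <- state_with_reds(M, data.frame(
    species = c("s1", "s2", "s2"),
    character = c("a", "a", "b"), stringsAsFactors = FALSE))
  expect_null(detect_red_sigma(st2))
  # black-only graphs never contain one
  expect_null(detect_red_sigma(rb_state(extend_matrix(sigma_matrix()))))
})

test_that("c-reductions realize left to right and report failures", {
  M <- sigma_matrix()
  res <- apply_c_reduction(M, reduction = c("c1+", "c2+", "c1-"))
  expect_true(res$success)
  expect_true(res$edgeless)
  expect_false(anyNA(res$state$ext$cells))
  expect_true(admits_directed_pp(res$state$ext))
  expect_equal(unname(res$state$ext$cells["s3", c("c1+", "c1-")]),
               c(1L, 1L)) # c1 persistent for s3
  # empty sequence on a nonempty graph: not successful, graph unchanged
  res0 <- apply_c_reduction(M, reduction = character(0))
  expect_false(res0$success)
  # loss before gain violates the c-reduction invariant
  expect_error(apply_c_reduction(M, reduction = c("c1-", "c1+")),
               "precedes")
  # failure step index is reported (c1+ is blocked at the fresh state)
  resF <- apply_c_reduction(M, constraints = cppp_constraints("c1", "s3"),
                            reduction = c("c1+", "c2+"))
  expect_false(resF$success)
  expect_equal(resF$failed_step, 1L)
  expect_equal(resF$reason, "constraint-violation")
})

test_that("derived graph invariants hold along random realizations", {
  set.seed(101)
  for (rep in 1:40) {
    M <- random_binary_matrix(sample(2:5, 1), sample(2:5, 1))
    st <- rb_state(extend_matrix(M))
    for (step in 1:6) {
      mv <- feasible_moves(st)
      if (!length(mv)) break
      r <- realize(st, sample(mv, 1))
      expect_equal(r$status, "ok")
      st <- r$state
      expect_length(check_state_invariants(st), 0L)
    }
  }
})
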