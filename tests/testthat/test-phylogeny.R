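test_that("the completed sigma matrix yields the expected chain tree", {
  res <- apply_c_reduction(sigma_matrix(),
                           reduction = c("c1+", "c2+", "c1-"))
  tree <- build_tree(res$state$ext, sigma_matrix())
  expect_equal(length(tree$parent), 4L)
  expect_equal(tree$parent, c(0L, 1L, 2L, 3L)) # a root-to-leaf chain
  expect_equal(unname(tree$species_node[c("s1", "s2", "s3")]), c(2L, 3L, 4L))
  expect_equal(unname(tree$labels), rbind(c(0L, 0L), c(1L, 0L),
                                          c(1L, 1L), c(0L, 1L)))
  expect_equal(tree$edge_gains[[2L]], "c1")
  expect_equal(tree$edge_gains[[3L]], "c2")
  expect_equal(tree$edge_losses[[4L]], "c1")
  expect_true(verify_ppp(tree, sigma_matrix())$pass)
})

test_that("identity and degenerate matrices build star / single-node trees", {
  M2 <- cppp_matrix(diag(2))
  fit <- cppp(M2)
  tree <- fit$tree
  expect_equal(sort(tree$parent), c(0L, 1L, 1L)) # root with two children
  expect_true(verify_ppp(tree, M2)$pass)
  M0 <- cppp_matrix(matrix(0L, 1, 1))
  t0 <- cppp(M0)$tree
  expect_equal(length(t0$parent), 1L)
  expect_equal(unname(t0$species_node["s1"]), 1L)
  expect_true(verify_ppp(t0, M0)$pass)
  # duplicated rows share one node
  Md <- cppp_matrix(rbind(a = c(1, 0), b = c(1, 0)))
  td <- cppp(Md)$tree
  expect_equal(unname(td$species_node["a"]), unname(td$species_node["b"]))
})

test_that("the verifier reports each class of violation", {
  M <- sigma_matrix()
  tree <- cppp(M)$tree
  # two gain edges for one character
  bad <- tree
  bad$edge_gains[[4L]] <- c(bad$edge_gains[[4L]], "c1")
  v <- verify_ppp(bad, M)
  expect_false(v$pass)
  expect_true(any(grepl("gained on 2 edges", v$violations)))
  # root label corruption
  bad2 <- tree
  bad2$labels[1L, 1L] <- 1L
  expect_true(any(grepl("root", verify_ppp(bad2, M)$violations)))
  # unlabeled edge
  bad3 <- tree
  bad3$edge_gains[[2L]] <- character(0)
  expect_true(any(grepl("no character label", verify_ppp(bad3, M)$violations)))
  # constraint violation: s3 sits below the c1+ edge
  vc <- verify_ppp(tree, M, cppp_constraints("c1", "s3"))
  expect_false(vc$pass)
  expect_true(any(grepl("constraint \\(c1, s3\\)", vc$violations)))
})

test_that("persistence in the matrix equals gain-then-loss on the path", {
  set.seed(404)
  for (i in 1:25) {
    M <- random_binary_matrix(sample(3:5, 1), sample(2:4, 1))
    fit <- cppp(M)
    if (fit$status != "solution") next
    tree <- fit$tree
    cells <- fit$completed$cells
    anc <- function(x) {
      path <- x
      while (tree$parent[x] != 0L) { x <- tree$parent[x]; path <- c(x, path) }
      path
    }
    for (s in rownames(M)) for (ch in colnames(M)) {
      persistent <- cells[s, paste0(ch, "+")] == 1L &&
        cells[s, paste0(ch, "-")] == 1L
      path <- anc(tree$species_node[[s]])
      gain_at <- which(vapply(path, function(x)
        ch %in% tree$edge_gains[[x]], logical(1)))
      loss_at <- which(vapply(path, function(x)
        ch %in% tree$edge_losses[[x]], logical(1)))
      crosses_both <- length(gain_at) == 1L && length(loss_at) == 1L &&
        gain_at < loss_at
      expect_identical(persistent, crosses_both)
      # loss-implies-gain, directly
      if (length(loss_at)) expect_length(gain_at, 1L)
    }
  }
})

test_that("solved duplicate-free instances satisfy the size bound", {
  set.seed(405)
  checked <- 0L
  for (i in 1:60) {
    n <- sample(2:5, 1); m <- sample(2:5, 1)
    M <- random_binary_matrix(n, m)
    dd <- dedup_matrix(M)
    if (!identical(dim(dd$matrix), dim(M))) next # duplicates present: skip
    if (cppp(M)$status != "solution") next
    checked <- checked + 1L
    expect_gte(m, n / 2)
    expect_lte(m, 2 * n)
  }
  expect_gt(checked, 10L)
})

test_that("annotated Newick round trip preserves the verified tree", {
  M <- sigma_matrix()
  tree <- cppp(M)$tree
  nwk <- write_cppp_newick(tree)
  expect_equal(nwk, "(((s3[&losses=c1])s2[&gains=c2])s1[&gains=c1]);")
  back <- read_cppp_newick(nwk)
  expect_true(verify_ppp(back, M)$pass)
  # file round trip, branching tree with a multi-species node
  M2 <- cppp_matrix(rbind(a = c(1, 0), b = c(1, 0), c = c(0, 1)))
  t2 <- cppp(M2)$tree
  f <- tempfile(fileext = ".nwk")
  write_cppp_newick(t2, f)
  expect_true(verify_ppp(read_cppp_newick(f), M2)$pass)
  unlink(f)
})

test_that("conversion to ape phylo keeps tips and labels", {
  M2 <- cppp_matrix(diag(3))
  tree <- cppp(M2)$tree
  phy <- ape::as.phylo(tree)
  expect_s3_class(phy, "phylo")
  expect_equal(ape::Ntip(phy), 3L)
  expect_true(all(grepl("\\[\\+c", phy$tip.label)))
})
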