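test_that("the hand-computed 3-taxon VCV is reproduced exactly", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  V <- vcv_from_tree(tr)
  expect_equal(V[c("A", "B", "C"), c("A", "B", "C")],
               matrix(c(2, 1, 0, 1, 2, 0, 0, 0, 2), 3,
                      dimnames = list(c("A", "B", "C"), c("A", "B", "C"))))
})

test_that("a star tree has no shared history: VCV is h times identity", {
  tr <- ape::read.tree(text = "(A:1.5,B:1.5,C:1.5,D:1.5);")
  expect_equal(unname(vcv_from_tree(tr)), 1.5 * diag(4))
})

test_that("VCVs agree with an independent path-depth oracle on random trees", {
  set.seed(14)
  for (i in 1:100) {
    M <- sample(3:10, 1)
    tr <- if (i %% 2 == 0) ape::rcoal(M) else ape::rtree(M)
    expect_lt(max(abs(vcv_from_tree(tr) - brute_vcv(tr))), 1e-8)
  }
})

test_that("VCVs agree with the reference implementation and ultrametric trees have constant diagonal", {
  set.seed(15)
  for (i in 1:20) {
    tr <- ape::rcoal(sample(3:12, 1))
    V <- vcv_from_tree(tr)
    ref <- ape::vcv.phylo(tr)
    expect_lt(max(abs(V - ref[rownames(V), colnames(V)])), 1e-8)
    expect_lt(diff(range(diag(V))), 1e-8)
  }
})

test_that("invalid trees are rejected", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  un <- ape::unroot(ape::rtree(5))
  expect_error(vcv_from_tree(un), "rooted")
  bad <- tr
  bad$edge.length[2] <- -0.5
  expect_error(vcv_from_tree(bad), "negative")
})

test_that("scaling gives unit diagonal and the inverse reconstructs the identity", {
  si <- scale_and_invert(3 * diag(4))
  expect_equal(si$scaled, diag(4))
  expect_equal(si$inverse, diag(4))
  expect_equal(si$height, 3)

  V <- matrix(c(2, 1, 0, 1, 2, 0, 0, 0, 2), 3)
  si <- scale_and_invert(V)
  expect_equal(si$scaled, matrix(c(1, .5, 0, .5, 1, 0, 0, 0, 1), 3))
  expect_lt(max(abs(si$scaled %*% si$inverse - diag(3))), 1e-10)
})

test_that("degenerate matrices produce an error or a condition warning", {
  expect_error(scale_and_invert(matrix(c(1, 2, 2, 1), 2)), "not positive definite")
  # two tips whose MRCA sits at essentially the tree height
  tr <- ape::read.tree(text = "((A:0.00000000001,B:0.00000000001):1,C:1.00000000001);")
  V <- vcv_from_tree(tr)
  expect_warning(try(scale_and_invert(V), silent = TRUE), "near-singular")
})

test_that("simulated tree sets are ultrametric, labelled and deterministic", {
  cfg <- comparative_sim_config(n_taxa = 3, n_trees = 1, seed = 9)
  trees <- simulate_tree_set(cfg)
  expect_length(trees, 1)
  expect_identical(length(trees[[1]]$tip.label), 3L)
  d <- diag(vcv_from_tree(trees[[1]]))
  expect_lt(diff(range(d)), 1e-8)

  cfg2 <- comparative_sim_config(n_taxa = 8, n_trees = 5, seed = 10)
  t1 <- simulate_tree_set(cfg2)
  t2 <- simulate_tree_set(cfg2)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  # every tree yields a positive-definite scaled VCV (Cholesky succeeds)
  for (tr in t1) expect_no_error(scale_and_invert(vcv_from_tree(tr)))
  expect_error(simulate_tree_set(comparative_sim_config(n_taxa = 2)), "n_taxa")
})

test_that("Newick files round-trip and inconsistent tip sets are caught", {
  cfg <- comparative_sim_config(n_taxa = 6, n_trees = 4, seed = 12)
  trees <- simulate_tree_set(cfg)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_trees(trees, path)
  expect_identical(length(readLines(path)), 4L)
  back <- read_trees(path)
  for (q in seq_along(trees)) {
    V1 <- vcv_from_tree(trees[[q]])
    V2 <- vcv_from_tree(back[[q]])
    expect_lt(max(abs(V1 - V2[rownames(V1), colnames(V1)])), 1e-9)
  }
  writeLines(c("((A:1,B:1):1,C:2);", "((A:1,D:1):1,C:2);"), path)
  expect_error(read_trees(path), "different tip set")
  # non-ultrametric input warns by default, errors on request
  writeLines("((A:1,B:2):1,C:4);", path)
  expect_warning(read_trees(path), "ultrametric")
  expect_error(read_trees(path, ultrametric = "error"), "ultrametric")
})

test_that("the inverse-VCV array is exact per slice and order-checked", {
  cfg <- comparative_sim_config(n_taxa = 7, n_trees = 6, seed = 13)
  trees <- simulate_tree_set(cfg)
  om <- build_vcv_array(trees)
  for (q in 1:6) {
    expect_lt(max(abs(om$scaled[, , q] %*% om$omega[, , q] - diag(7))), 1e-8)
    expect_equal(unname(diag(om$scaled[, , q])), rep(1, 7), tolerance = 1e-9)
  }
  expect_error(build_vcv_array(trees, taxa = c(om$taxa[-1], "nonexistent")),
               "does not match")
})
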