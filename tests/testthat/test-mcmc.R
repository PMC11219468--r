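# small reference topologies for split-frequency tests
.tAB <- function() nwk("((a:1,b:1):1,c:2);")
.tAC <- function() nwk("((a:1,c:1):1,b:2);")
.tstar <- function() nwk("(a:1,b:1,c:1);")

test_that("ASDSF is zero for identical chains", {
  chain <- tree_chain(list(.tAB(), .tAC()), 20)
  expect_equal(asdsf(chain, chain), 0)
})

test_that("ASDSF of disjoint topology pairs is 1/sqrt(2)", {
  c0 <- tree_chain(nwk("((a:1,b:1):1,(c:1,d:1):1);"), 10)
  c1 <- tree_chain(nwk("((a:1,c:1):1,(b:1,d:1):1);"), 10)
  expect_equal(asdsf(c0, c1), 1 / sqrt(2))
})

test_that("ASDSF matches the two-chain standard deviation formula", {
  # single qualifying split {a,b} at frequencies 0.6 vs 0.4
  c0 <- tree_chain(c(rep(list(.tAB()), 6), rep(list(.tstar()), 4)), 10)
  c1 <- tree_chain(c(rep(list(.tAB()), 4), rep(list(.tstar()), 6)), 10)
  expect_equal(asdsf(c0, c1), 0.2 / sqrt(2), tolerance = 1e-12)
  # star trees carry no nontrivial split at all
  stars <- tree_chain(.tstar(), 10)
  expect_error(asdsf(stars, stars), "no splits")
  expect_error(asdsf(c0, tree_chain(nwk("((a:1,b:1):1,d:2);"), 10)),
               "leaf sets")
})

test_that("chain AUC is near 1/2 for identically distributed chains", {
  set.seed(301)
  X0 <- rtroplap(100, e = 3, sigma = 1)
  X1 <- rtroplap(100, e = 3, sigma = 1)
  r <- chain_auc(X0, X1, keep_fraction = 1, seed = 302)
  expect_gt(r$auc, 0.35); expect_lt(r$auc, 0.65)
})

test_that("chain AUC detects well separated chains", {
  set.seed(303)
  X0 <- rtroplap(80, center = c(0, 0, 0), sigma = 0.5)
  X1 <- rtroplap(80, center = c(3, 2, 0), sigma = 0.5)   # separation 6 sigma
  r <- chain_auc(X0, X1, keep_fraction = 1, seed = 304)
  expect_gt(r$auc, 0.95)
  expect_s3_class(r$model, "tlr")
})

test_that("only the retained suffix window influences the AUC", {
  set.seed(305)
  X0 <- rtroplap(100, e = 3, sigma = 1)
  X1 <- rtroplap(100, e = 3, sigma = 1)
  r1 <- chain_auc(X0, X1, keep_fraction = 0.3, seed = 306)
  X0b <- X0; X0b[1:70, ] <- X0b[1:70, ] + matrix(rnorm(210, 0, 50), 70, 3)
  r2 <- chain_auc(trop_canonical(X0b), X1, keep_fraction = 0.3, seed = 306)
  expect_identical(r1$auc, r2$auc)
})

test_that("branch-length discordance is invisible to ASDSF but not to AUC", {
  sp <- sim_yule_tree(8, species_depth = 1, seed = 307)
  genes <- sim_msc_gene_trees(sp, pop_size = 0.2, n_genes = 60, seed = 308)
  c0 <- genes
  c1 <- scale_chain(genes, 1.5)   # same topologies, rescaled branch lengths
  expect_lt(asdsf(c0, c1, keep_fraction = 0.3), 0.01)
  r <- chain_auc(c0, c1, keep_fraction = 0.3, folds = 3, seed = 309)
  expect_gt(r$auc, 0.8)
})

test_that("convergence trace walks checkpoints and reaches a verdict", {
  sp <- sim_yule_tree(6, species_depth = 1, seed = 310)
  set.seed(311)
  g0 <- sim_msc_gene_trees(sp, pop_size = 0.3, n_genes = 80)
  g1 <- sim_msc_gene_trees(sp, pop_size = 0.3, n_genes = 80)
  tr <- convergence_trace(g0, g1, diagnfreq = 40, folds = 3, seed = 312)
  expect_equal(nrow(tr$trace), 2)
  expect_equal(tr$trace$checkpoint, c(40, 80))
  expect_true(all(tr$trace$auc >= 0 & tr$trace$auc <= 1))
  expect_true(all(tr$trace$asdsf >= 0))

  # unequal chains are truncated with a warning
  expect_warning(
    convergence_trace(g0, g1[1:60], diagnfreq = 30, folds = 3, seed = 313),
    "truncating")
})
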