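test_that("simulate_tree draws seeded unit-depth Yule trees", {
  tr <- simulate_tree(3, seed = 1)
  expect_true(ape::is.binary(tr))
  expect_equal(ape::Ntip(tr), 3)
  depths <- resorb:::node_depths(tr)[1:3]
  expect_equal(max(depths), 1.0)

  tr36 <- simulate_tree(36, seed = 7)
  expect_equal(ape::Ntip(tr36), 36)
  expect_equal(tr36$Nnode, 35)  # 2n - 1 nodes for a binary tree

  expect_identical(write_newick(simulate_tree(36, seed = 7)),
                   write_newick(tr36))
  expect_error(simulate_tree(2, seed = 1), "at least 3")
})

test_that("simulate_bm_traits follows the Brownian model", {
  tr <- tree3()
  # near-zero rate: tips collapse to the root value
  x <- simulate_bm_traits(tr, sigma2 = 1e-18, root_value = 5, seed = 1)
  expect_equal(unname(x[, 1]), rep(5, 3), tolerance = 1e-6)

  # star tree: tips i.i.d. Normal(root, branch length); law of large
  # numbers over 1000 tips
  star <- ape::stree(1000, type = "star")
  star$edge.length <- rep(2, nrow(star$edge))
  y <- simulate_bm_traits(star, sigma2 = 1, root_value = 0, seed = 42)
  expect_lt(abs(stats::var(y[, 1]) - 2) / 2, 0.10)
  expect_lt(abs(mean(y[, 1])), 0.15)

  expect_error(
    simulate_bm_traits(tr, n_traits = 2,
                       correlation = matrix(c(1, 2, 2, 1), 2)),
    "positive-definite")
  expect_identical(simulate_bm_traits(tr, seed = 9),
                   simulate_bm_traits(tr, seed = 9))
})

test_that("correlated BM traits show the requested PIC correlation", {
  # generator-level check of the trait-correlation machinery
  rs <- vapply(1:40, function(s) {
    tr <- simulate_tree(100, seed = 3000 + s)
    xy <- simulate_bm_traits(tr, n_traits = 2, seed = 4000 + s,
                             correlation = matrix(c(1, .7, .7, 1), 2))
    pic_correlation(tr, xy[, 1], xy[, 2])$r
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.7), 0.1)
})

test_that("assign_groups produces clustered or random labels", {
  tr <- simulate_tree(4, seed = 2)
  g <- assign_groups(tr, clustered = TRUE)
  expect_equal(sort(unname(g)), sort(resorb_groups()))  # one tip each

  tr36 <- simulate_tree(36, seed = 3)
  g36 <- assign_groups(tr36, clustered = TRUE)
  expect_equal(as.integer(table(factor(g36, resorb_groups()))),
               c(10, 5, 11, 10))
  # clustered labels form few clades: integer-coded trait has low K? no -
  # strong signal means small PIC variance; checked via the power test below
  gr <- assign_groups(tr36, clustered = FALSE, seed = 5)
  expect_true(all(resorb_groups() %in% gr))
  expect_error(assign_groups(simulate_tree(3, seed = 1)), "at least")
})

test_that("clustered groups carry detectable phylogenetic signal at n = 36", {
  hits <- vapply(1:100, function(s) {
    tr <- simulate_tree(36, seed = 5000 + s)
    g <- encode_group_trait(assign_groups(tr, clustered = TRUE))
    signal_test(tr, g, n_perm = 199, seed = 6000 + s)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.80)
})

test_that("random group labels give a calibrated (null) signal test", {
  ps <- vapply(1:100, function(s) {
    tr <- simulate_tree(36, seed = 7000 + s)
    g <- encode_group_trait(assign_groups(tr, clustered = FALSE,
                                          seed = 7100 + s))
    signal_test(tr, g, n_perm = 99, seed = 7200 + s)$p_value
  }, numeric(1))
  # p approximately uniform: rejection near nominal, mean near 0.5
  expect_lt(abs(mean(ps < 0.25) - 0.25), 0.12)
  expect_lt(abs(mean(ps) - 0.5), 0.1)
})

test_that("generate_leaf_dataset inverts the RE formula exactly at zero noise", {
  truth <- synthetic_truth(seed = 5, noise_sd = 0)
  truth$true_RE[, ] <- 0.5
  ds <- generate_leaf_dataset(truth)
  rt <- resorption_table(ds$samples, level = "species")
  expect_equal(rt$RE_percent, rep(50, nrow(rt)), tolerance = 1e-12)
  # species MLCF recovered exactly
  expect_equal(unname(ds$species$MLCF),
               unname(truth$MLCF_of[ds$species$species]), tolerance = 1e-12)
})

test_that("group Na means match the reference design at seed 42", {
  ds <- generate_leaf_dataset(synthetic_truth(seed = 42))
  eu <- ds$species$green_Na[ds$species$group == "Eu"]
  se2 <- 2 * stats::sd(eu) / sqrt(length(eu))
  expect_lt(abs(mean(eu) - 53.5), se2)
})

test_that("a 3-4 individual layout reproduces the 252-sample design", {
  n <- vapply(1:20, function(s) {
    truth <- synthetic_truth(seed = 800 + s)
    nrow(generate_leaf_dataset(truth, individuals_per_species = 3:4)$samples)
  }, numeric(1))
  expect_true(all(n >= 2 * 36 * 3 & n <= 2 * 36 * 4))
  expect_lt(abs(mean(n) - 252), 10)  # 36 species x 3.5 pairs x 2 leaves
})

test_that("species-mean RE is unbiased under individual noise", {
  res <- vapply(1:200, function(s) {
    truth <- synthetic_truth(n_species = 12, seed = 9000 + s,
                             noise_sd = 0.2)
    ds <- generate_leaf_dataset(truth, individuals_per_species = 5:8)
    rt <- resorption_table(ds$samples, level = "species")
    idx <- cbind(match(rt$species, rownames(truth$true_RE)),
                 match(rt$element, colnames(truth$true_RE)))
    mean(rt$RE_percent - 100 * truth$true_RE[idx])
  }, numeric(1))
  expect_lt(abs(mean(res)), 2)  # mean bias within +/- 2 RE points
})

test_that("generated data always satisfies the leaf-sample invariants", {
  withr::with_seed(123, {
    for (i in 1:8) {
      truth <- synthetic_truth(
        n_species = sample(6:20, 1), seed = sample.int(1e6, 1),
        noise_sd = runif(1, 0, 0.4), tau = runif(1, 0.05, 0.4),
        site_sd = runif(1, 0, 0.15),
        clustered = sample(c(TRUE, FALSE), 1))
      ds <- generate_leaf_dataset(truth)
      checked <- suppressWarnings(
        resorb:::validate_leaf_samples(ds$samples))
      expect_equal(attr(checked, "n_rejected"), 0)
    }
  })
})

test_that("the generator is deterministic under a fixed seed", {
  t1 <- synthetic_truth(seed = 77)
  t2 <- synthetic_truth(seed = 77)
  expect_identical(t1$green_mean, t2$green_mean)
  expect_identical(write_newick(t1$tree), write_newick(t2$tree))
  expect_identical(generate_leaf_dataset(t1)$samples,
                   generate_leaf_dataset(t2)$samples)
})

test_that("true RE at or above 1 is rejected", {
  truth <- synthetic_truth(seed = 3)
  truth$true_RE[1, 1] <- 1
  expect_error(generate_leaf_dataset(truth), "negative senesced")
})
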