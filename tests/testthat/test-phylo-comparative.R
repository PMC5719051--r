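test_that("vcv_matrix gives shared root-to-tip path lengths", {
  C <- vcv_matrix(tree3())
  expect_equal(unname(C[c("A", "B", "C"), c("A", "B", "C")]),
               matrix(c(2, 1, 0, 1, 2, 0, 0, 0, 2), 3))

  star <- ape::stree(5, type = "star")
  star$edge.length <- rep(3, 5)
  expect_equal(unname(vcv_matrix(star)), 3 * diag(5))

  # ultrametric trees have a constant diagonal; matches ape on random trees
  for (seed in 1:5) {
    tr <- random_tree(15, seed)
    C <- vcv_matrix(tr)
    expect_equal(unname(diag(C)), rep(1, 15), tolerance = 1e-9)
    expect_equal(C, ape::vcv.phylo(tr)[rownames(C), colnames(C)],
                 tolerance = 1e-12)
  }
})

test_that("blomberg_k matches the hand-computed 3-tip value", {
  expect_equal(blomberg_k(tree3(), c(A = 1, B = 3, C = 2)), 7 / 12,
               tolerance = 1e-12)
  expect_error(blomberg_k(tree3(), c(A = 2, B = 2, C = 2)), "constant")
})

test_that("K equals 1 on star trees and matches a dense oracle elsewhere", {
  withr::with_seed(7, {
    for (i in 1:20) {
      n <- sample(5:50, 1)
      star <- ape::stree(n, type = "star")
      star$edge.length <- rep(runif(1, 0.5, 3), n)
      x <- stats::setNames(rnorm(n), star$tip.label)
      expect_equal(blomberg_k(star, x), 1, tolerance = 1e-10)
    }
    # dense-matrix oracle (built on ape::vcv.phylo) on random 6-tip trees
    for (i in 1:20) {
      tr <- simulate_tree(6, seed = sample.int(1e6, 1))
      x <- stats::setNames(rnorm(6), tr$tip.label)
      expect_equal(blomberg_k(tr, x), brute_force_k(tr, x),
                   tolerance = 1e-10)
    }
  })
})

test_that("K is invariant to affine transformations of the trait", {
  withr::with_seed(11, {
    for (i in 1:10) {
      tr <- simulate_tree(12, seed = sample.int(1e6, 1))
      x <- stats::setNames(rnorm(12), tr$tip.label)
      a <- runif(1, -5, 5); if (a == 0) a <- 1
      b <- runif(1, -10, 10)
      expect_equal(blomberg_k(tr, a * x + b), blomberg_k(tr, x),
                   tolerance = 1e-9)
    }
  })
})

test_that("pic_contrasts reproduces Felsenstein's worked example", {
  cs <- pic_contrasts(tree3(), c(A = 1, B = 3, C = 2))
  expect_equal(unname(cs[1:2]), c(-sqrt(2), 0), tolerance = 1e-12)
  expect_equal(attr(cs, "root_value"), 2)

  # identical trait: all contrasts zero
  expect_equal(as.numeric(pic_contrasts(tree3(), c(A = 4, B = 4, C = 4))),
               c(0, 0))

  # agrees with ape::pic up to contrast order and sign
  for (seed in 1:5) {
    tr <- random_tree(25, seed)
    x <- stats::setNames(rnorm(25), tr$tip.label)
    mine <- sort(abs(pic_contrasts(tr, x)))
    apes <- sort(abs(ape::pic(x[tr$tip.label], tr)))
    expect_equal(mine, unname(apes), tolerance = 1e-10)
  }
})

test_that("pic_contrasts errors on an all-zero-length cherry", {
  tr <- ape::read.tree(text = "((A:0,B:0):1,C:2);")
  expect_error(pic_contrasts(tr, c(A = 1, B = 2, C = 3)),
               "zero-length contrast denominator")
})

test_that("BM contrasts look standard normal on a large tree", {
  tr <- simulate_tree(500, seed = 13)
  x <- simulate_bm_traits(tr, seed = 14)[, 1]
  cs <- pic_contrasts(tr, x)
  skew <- mean((cs - mean(cs))^3) / stats::sd(cs)^3
  expect_lt(abs(skew), 0.3)
})

test_that("signal_test is deterministic, bounded and detects strong signal", {
  tr <- simulate_tree(36, seed = 17)
  x <- stats::setNames(rnorm(36), tr$tip.label)
  s1 <- signal_test(tr, x, n_perm = 999, seed = 4)
  s2 <- signal_test(tr, x, n_perm = 999, seed = 4)
  expect_identical(s1$p_value, s2$p_value)
  expect_gte(s1$p_value, 1 / 1000)

  # two clades at 10 vs 0: extreme signal
  t20 <- ape::read.tree(text = paste0(
    "((", paste0("a", 1:10, ":1", collapse = ","), "):1,(",
    paste0("b", 1:10, ":1", collapse = ","), "):1);"))
  t20 <- read_newick(ape::write.tree(t20))
  trait <- stats::setNames(rep(c(10, 0), each = 10), t20$tip.label)
  expect_lte(signal_test(t20, trait, n_perm = 999, seed = 1)$p_value, 0.01)
})

test_that("pic_correlation is exact for proportional traits and counts n-1", {
  tr <- simulate_tree(36, seed = 19)
  x <- stats::setNames(rnorm(36), tr$tip.label)
  pc <- pic_correlation(tr, x, 2 * x)
  expect_equal(pc$r, 1, tolerance = 1e-12)
  expect_equal(pc$n_contrasts, 35)

  expect_warning(
    pc0 <- pic_correlation(tr, stats::setNames(rep(1, 36), tr$tip.label), x),
    "undefined")
  expect_true(is.na(pc0$r))
})

test_that("PIC correlation of independent BM traits centres on zero", {
  rs <- vapply(1:100, function(s) {
    tr <- simulate_tree(100, seed = 20000 + s)
    xy <- simulate_bm_traits(tr, n_traits = 2, seed = 21000 + s)
    pic_correlation(tr, xy[, 1], xy[, 2])$r
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("encode_group_trait codes groups as documented", {
  expect_equal(encode_group_trait(c(A = "Eu", B = "Gl")),
               c(A = 1, B = 4))
  ind <- encode_group_trait(
    c(s1 = "Eu", s2 = "Se", s3 = "Ps", s4 = "Gl"), mode = "indicator")
  expect_equal(dim(ind), c(4, 4))
  expect_equal(unname(colSums(ind)), rep(1, 4))
  expect_error(encode_group_trait(c(A = "Zz")), "unknown plant group")
})
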