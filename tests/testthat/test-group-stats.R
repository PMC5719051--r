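test_that("one_way_anova reproduces the classical decomposition", {
  av <- one_way_anova(c(1, 2, 3, 4, 5, 6), rep(c("g1", "g2"), each = 3))
  expect_equal(av$ss_between, 13.5)
  expect_equal(av$ss_within, 4)
  expect_equal(av$F, 13.5)
  expect_equal(c(av$df_between, av$df_within), c(1, 4))

  # identical group means: F = 0
  expect_equal(one_way_anova(c(1, 3, 1, 3), c("a", "a", "b", "b"))$F, 0)
  expect_error(one_way_anova(1:5, rep("a", 5)), "2 groups")
})

test_that("ANOVA agrees with lm and with the t-squared identity", {
  withr::with_seed(5, {
    for (i in 1:10) {
      y <- rnorm(24)
      g <- sample(letters[1:3], 24, replace = TRUE)
      if (length(unique(g)) < 3) next
      av <- one_way_anova(y, g)
      ref <- stats::anova(stats::lm(y ~ factor(g)))
      expect_equal(av$F, ref$`F value`[1], tolerance = 1e-8)
      expect_equal(av$p_value, ref$`Pr(>F)`[1], tolerance = 1e-8)
      expect_equal(av$ss_between + av$ss_within, av$ss_total,
                   tolerance = 1e-9)

      # two groups: F equals the square of the pooled-variance t
      y2 <- rnorm(20); g2 <- rep(c("a", "b"), each = 10)
      tt <- stats::t.test(y2 ~ g2, var.equal = TRUE)
      expect_equal(one_way_anova(y2, g2)$F, unname(tt$statistic)^2,
                   tolerance = 1e-8)
    }
  })
})

test_that("letter display separates and joins groups correctly", {
  y <- c(rnorm(10, 0, .1), rnorm(10, 50, .1))
  g <- rep(c("lo", "hi"), each = 10)
  lt <- letter_groups(y, g)
  expect_equal(unname(lt[c("hi", "lo")]), c("a", "b"))

  y2 <- c(rnorm(10, 5, 1), rnorm(10, 5, 1))
  lt2 <- letter_groups(y2, g)
  expect_equal(unname(lt2), c("a", "a"), ignore_attr = TRUE)
  expect_error(letter_groups(y, rep("x", 20)), "2 groups")
})

test_that("groups share a letter exactly when Tukey finds no difference", {
  withr::with_seed(9, {
    for (i in 1:10) {
      g <- rep(letters[1:4], each = 7)
      y <- rnorm(28, mean = sample(0:3, 4, replace = TRUE)[as.integer(
        factor(g))])
      lt <- letter_groups(y, g, alpha = 0.05)
      tk <- attr(lt, "tukey_p")
      for (pair in strsplit(names(tk), "-")) {
        share <- any(strsplit(lt[pair[1]], "")[[1]] %in%
                       strsplit(lt[pair[2]], "")[[1]])
        expect_equal(share, tk[paste(pair, collapse = "-")] >= 0.05,
                     ignore_attr = TRUE)
      }
    }
  })
})

test_that("t tests handle symmetric, degenerate and reference cases", {
  t0 <- one_sample_t(c(-1, 0, 1), mu0 = 0)
  expect_equal(t0$t, 0)
  expect_equal(t0$p_value, 1)
  expect_error(one_sample_t(c(5, 5, 5), mu0 = 0), "zero-variance")
  expect_message(tz <- one_sample_t(c(5, 5, 5), mu0 = 5), "t = 0")
  expect_equal(tz$p_value, 1)

  # Welch from summary statistics equals Welch from the sample
  withr::with_seed(3, {
    x <- rnorm(15, 1); y <- rnorm(40, 0, 2)
    a <- two_sample_t(x, y)
    b <- two_sample_t(x, ref_mean = mean(y), ref_sd = sd(y),
                      ref_n = length(y))
    expect_equal(a$t, b$t, tolerance = 1e-10)
    expect_equal(a$p_value, b$p_value, tolerance = 1e-10)
  })
  expect_message(two_sample_t(c(1, 2, 3), ref_mean = 2), "one-sample")
})

test_that("one-sample power: strong resorption is detected at n = 36", {
  truth <- synthetic_truth(seed = 55)
  truth$true_RE[, "N"] <- 0.6
  ds <- generate_leaf_dataset(truth)
  rt <- resorption_table(ds$samples)
  re_n <- rt$RE_percent[rt$element == "N"]
  expect_lt(one_sample_t(re_n, 0)$p_value, 0.001)
})

test_that("pca_elements standardises, orthonormalises and conserves variance", {
  withr::with_seed(21, {
    x <- rnorm(30)
    two <- cbind(a = x, b = 2 * x + 3)  # perfectly correlated
    expect_equal(pca_elements(two)$variance_explained[1], 100)

    m <- matrix(rnorm(30 * 2), 30)
    colnames(m) <- c("a", "b")
    r <- abs(cor(m)[1, 2])
    pc <- pca_elements(m)
    # closed form for 2 standardized variables: eigenvalues 1 +/- r
    expect_equal(pc$variance_explained[1], 100 * (1 + r) / 2,
                 tolerance = 1e-9)

    m6 <- matrix(rnorm(40 * 6), 40)
    colnames(m6) <- resorb_elements()
    pc6 <- pca_elements(m6)
    expect_equal(crossprod(pc6$loadings), diag(6), ignore_attr = TRUE,
                 tolerance = 1e-9)
    expect_equal(sum(pc6$eigenvalues), 6, tolerance = 1e-9)
    expect_equal(pc6$eigenvalues, prcomp(m6, scale. = TRUE)$sdev^2,
                 tolerance = 1e-9)

    m6[, 2] <- 7
    expect_error(pca_elements(m6), "constant column.*P")
  })
})

test_that("sma_fit matches the closed form and its identities", {
  exact <- sma_fit(1:4, 2 * (1:4))
  expect_equal(exact$slope, 2)
  expect_equal(exact$intercept, 0)
  expect_equal(exact$r, 1)

  fit <- sma_fit(c(1, 2, 3, 4), c(1, 3, 2, 5))
  expect_equal(fit$slope, 1.3229, tolerance = 1e-4)
  expect_equal(fit$intercept, -0.5572, tolerance = 1e-4)
  expect_equal(fit$r, 0.8315, tolerance = 1e-4)

  withr::with_seed(31, {
    for (i in 1:20) {
      x <- rnorm(15); y <- 0.5 * x + rnorm(15)
      f <- sma_fit(x, y)
      expect_equal(f$slope, sign(f$r) * sd(y) / sd(x), tolerance = 1e-12)
      expect_equal(f$slope * sma_fit(y, x)$slope, 1, tolerance = 1e-8)
      # SMA slope = OLS slope / |r|
      ols <- unname(coef(lm(y ~ x))[2])
      expect_equal(f$slope, ols / abs(f$r), tolerance = 1e-8)
    }
  })
  expect_error(sma_fit(rep(1, 5), rnorm(5)), "constant")
})

test_that("variance partition sums to one and honours factor order", {
  # suppressWarnings: stats::anova warns on the (intended) perfect fit
  vp <- suppressWarnings(
    variance_partition(c(1, 1, 2, 2),
                       list(site = c("s1", "s1", "s2", "s2"),
                            group = c("g1", "g2", "g1", "g2"))))
  expect_equal(vp$proportion[vp$term == "site"], 1)
  expect_equal(vp$proportion[vp$term == "group"], 0)
  expect_equal(sum(vp$proportion), 1, tolerance = 1e-9)

  withr::with_seed(41, {
    y <- rnorm(40)
    f <- list(site = sample(c("s1", "s2", "s3"), 40, TRUE),
              group = sample(c("a", "b"), 40, TRUE))
    v1 <- variance_partition(y, f)
    expect_equal(sum(v1$proportion), 1, tolerance = 1e-9)
    # invariant under response rescaling
    v2 <- variance_partition(100 * y + 3, f)
    expect_equal(v1$proportion, v2$proportion, tolerance = 1e-9)
  })

  # response fully determined by one factor (perfect fit warns in anova)
  v3 <- suppressWarnings(
    variance_partition(rep(c(0, 5, 9), each = 4),
                       list(g = rep(c("a", "b", "c"), each = 4))))
  expect_equal(v3$proportion[v3$term == "g"], 1, tolerance = 1e-12)

  # perfectly confounded factors are refused by default
  expect_error(
    variance_partition(rnorm(8),
                       list(site = rep(c("s1", "s2"), each = 4),
                            group = rep(c("g1", "g2"), each = 4))),
    "aliased.*group")
})

test_that("correlation_table reports all three analysis levels", {
  truth <- synthetic_truth(seed = 61)
  ds <- generate_leaf_dataset(truth, individuals_per_species = 3:4)
  sp <- ds$species
  sp$negSLA <- -sp$SLA
  ind <- data.frame(SLA = rnorm(50))
  ind$negSLA <- -ind$SLA
  ct <- correlation_table(cbind("SLA", "negSLA"), sp, ind,
                          tree = truth$tree)
  expect_equal(ct$r, rep(-1, 3), tolerance = 1e-12)
  expect_equal(ct$n[ct$level == "species"], 36)
  expect_equal(ct$n[ct$level == "species_PIC"], 35)
  expect_equal(ct$n[ct$level == "individual"], 50)

  expect_warning(
    ct2 <- correlation_table(cbind("SLA", "LDMC"), sp[1:2, ],
                             levels = "species"),
    "fewer than 3")
  expect_true(is.na(ct2$r))
})
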