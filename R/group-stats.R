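#' One-way analysis of variance
#'
#' Classical decomposition of the total sum of squares into between- and
#' within-group parts: `F = MS_between / MS_within` with the p-value
#' from the F distribution on (k - 1, n - k) degrees of freedom.
#'
#' @param values Numeric response.
#' @param group_labels Group label per observation (>= 2 groups).
#' @return List of class `"anova_result"`: `F`, `p_value`,
#'   `df_between`, `df_within`, `ss_between`, `ss_within`, `ss_total`,
#'   `group_means`, `group_se`, `group_n`.
#' @export
#' @examples
#' one_way_anova(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
one_way_anova <- function(values, group_labels) {
  keep <- is.finite(values) & !is.na(group_labels)
  values <- values[keep]
  group_labels <- as.character(group_labels)[keep]
  k <- length(unique(group_labels))
  if (k < 2) stop("need at least 2 groups")
  n <- length(values)
  if (n - k < 1) stop("no residual degrees of freedom (need >= 2 ",
                      "observations in some group)")
  gm <- tapply(values, group_labels, mean)
  gn <- tapply(values, group_labels, length)
  gsd <- tapply(values, group_labels, stats::sd)
  grand <- mean(values)
  ss_between <- sum(gn * (gm - grand)^2)
  ss_total <- sum((values - grand)^2)
  ss_within <- ss_total - ss_between
  f <- (ss_between / (k - 1)) / (ss_within / (n - k))
  structure(list(
    F = f,
    p_value = stats::pf(f, k - 1, n - k, lower.tail = FALSE),
    df_between = k - 1L, df_within = n - k,
    ss_between = ss_between, ss_within = ss_within, ss_total = ss_total,
    group_means = gm, group_se = gsd / sqrt(gn), group_n = gn
  ), class = "anova_result")
}

#' Compact letter display from Tukey's HSD
#'
#' Runs pairwise Tukey honestly-significant-difference comparisons at
#' `alpha` after a one-way ANOVA and assigns letters by the
#' insert-and-absorb algorithm: groups that are not significantly
#' different share a letter.  Letters are assigned `a`, `b`, `c`, ... in
#' descending order of group mean, so the highest-mean group always
#' carries `a`.
#'
#' @inheritParams one_way_anova
#' @param alpha Significance level for the pairwise comparisons (0.05).
#' @return Named character vector of letter strings, one per group,
#'   with the Tukey pairwise p-values as attribute `tukey_p`.
#' @export
letter_groups <- function(values, group_labels, alpha = 0.05) {
  group_labels <- as.character(group_labels)
  if (length(unique(group_labels)) < 2) stop("need at least 2 groups")
  fit <- stats::aov(values ~ g, data = data.frame(values = values,
                                                  g = factor(group_labels)))
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
  pair_names <- strsplit(rownames(tk), "-", fixed = TRUE)
  means <- sort(tapply(values, group_labels, mean), decreasing = TRUE)
  grp <- names(means)
  k <- length(grp)
  # insert-and-absorb: columns of `m` are letter classes
  m <- matrix(TRUE, nrow = k, ncol = 1, dimnames = list(grp, NULL))
  sig <- which(tk[, "p adj"] < alpha)
  for (s in sig) {
    gi <- pair_names[[s]][1]; gj <- pair_names[[s]][2]
    both <- which(m[gi, ] & m[gj, ])
    for (col in both) {
      dup <- m[, col]
      m[gi, col] <- FALSE
      dup[gj] <- FALSE
      m <- cbind(m, dup)
    }
    # absorb columns that are subsets of another column
    keep <- rep(TRUE, ncol(m))
    for (a in seq_len(ncol(m))) {
      for (b in seq_len(ncol(m))) {
        if (a != b && keep[b] && all(m[, a] <= m[, b]) &&
            (any(m[, a] < m[, b]) || a > b)) {
          keep[a] <- FALSE
          break
        }
      }
    }
    m <- m[, keep, drop = FALSE]
  }
  # order letter classes by the best (highest-mean) member
  first_member <- apply(m, 2, function(col) which(col)[1])
  m <- m[, order(first_member), drop = FALSE]
  letters_used <- letters[seq_len(ncol(m))]
  out <- vapply(grp, function(g)
    paste(letters_used[m[g, ]], collapse = ""), character(1))
  attr(out, "tukey_p") <- tk[, "p adj"]
  out
}

#' One-sample t test (e.g. resorption efficiency against 0%)
#'
#' Two-sided one-sample t test of `values` against `mu0`.  A
#' zero-variance sample equal to `mu0` returns `t = 0, p = 1` by
#' convention (with a message); a zero-variance sample different from
#' `mu0` is an error.
#'
#' @param values Numeric sample, `n >= 2`.
#' @param mu0 Null mean (default 0).
#' @return List `t`, `p_value`, `df`, `mean`, `n`.
#' @export
one_sample_t <- function(values, mu0 = 0) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2) stop("need at least 2 observations")
  if (stats::sd(values) == 0) {
    if (mean(values) == mu0) {
      message("zero-variance sample equal to mu0: returning t = 0, p = 1")
      return(list(t = 0, p_value = 1, df = n - 1L, mean = mean(values), n = n))
    }
    stop("zero-variance sample differs from mu0: t statistic undefined")
  }
  ht <- stats::t.test(values, mu = mu0)
  list(t = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter), mean = mean(values), n = n)
}

#' Welch two-sample t test, against a sample or summary statistics
#'
#' Compares `x` with either a reference sample `y` or reference summary
#' statistics `(ref_mean, ref_sd, ref_n)` (Welch's unequal-variance
#' form in both cases).  When only a reference mean is available the
#' test degrades to a one-sample t test of `x` against that mean, with
#' a message - the appropriate fallback when a published global average
#' is reported without dispersion.
#'
#' @param x Numeric sample.
#' @param y Optional reference sample.
#' @param ref_mean,ref_sd,ref_n Alternatively, reference summary
#'   statistics.
#' @return List `t`, `p_value`, `df`, `mean_x`, `mean_ref`, `n`.
#' @export
two_sample_t <- function(x, y = NULL, ref_mean = NULL, ref_sd = NULL,
                         ref_n = NULL) {
  x <- x[is.finite(x)]
  if (length(x) < 2) stop("need at least 2 observations in x")
  if (!is.null(y)) {
    ht <- stats::t.test(x, y)
    return(list(t = unname(ht$statistic), p_value = ht$p.value,
                df = unname(ht$parameter), mean_x = mean(x),
                mean_ref = mean(y), n = length(x)))
  }
  if (is.null(ref_mean)) stop("supply y or ref_mean")
  if (is.null(ref_sd) || is.null(ref_n)) {
    message("reference given as a bare mean: falling back to a ",
            "one-sample t test against it")
    ht <- one_sample_t(x, mu0 = ref_mean)
    return(list(t = ht$t, p_value = ht$p_value, df = ht$df,
                mean_x = mean(x), mean_ref = ref_mean, n = length(x)))
  }
  v1 <- stats::var(x) / length(x)
  v2 <- ref_sd^2 / ref_n
  t <- (mean(x) - ref_mean) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(x) - 1) + v2^2 / (ref_n - 1))
  list(t = t, p_value = 2 * stats::pt(-abs(t), df), df = df,
       mean_x = mean(x), mean_ref = ref_mean, n = length(x))
}

#' PCA of the element concentration matrix
#'
#' Principal component analysis on the correlation matrix: columns are
#' standardised to zero mean and unit variance before the
#' eigendecomposition, so elements spanning different concentration
#' ranges (e.g. P around 2-3 vs Na up to 50+ mg g^-1) contribute
#' equally.  Loadings are the orthonormal eigenvectors; the sign of
#' each component is fixed so its largest-magnitude loading is
#' positive (determinism).
#'
#' @param mat Species x element numeric matrix, >= 3 rows, no missing
#'   values, no constant column.
#' @return List `loadings` (orthonormal, elements x components),
#'   `variance_explained` (percent, sums to 100), `eigenvalues`,
#'   `scores` (species x components, from standardised data).
#' @export
pca_elements <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 3) stop("need at least 3 rows (species)")
  if (any(!is.finite(mat))) stop("missing values not allowed in PCA input")
  sds <- apply(mat, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant column(s): ", paste(colnames(mat)[sds == 0],
                                       collapse = ", "))
  }
  z <- scale(mat)
  eig <- eigen(stats::cor(mat), symmetric = TRUE)
  load <- eig$vectors
  for (j in seq_len(ncol(load))) {
    if (load[which.max(abs(load[, j])), j] < 0) load[, j] <- -load[, j]
  }
  dimnames(load) <- list(colnames(mat), paste0("PC", seq_len(ncol(load))))
  list(loadings = load,
       variance_explained = 100 * eig$values / sum(eig$values),
       eigenvalues = eig$values,
       scores = z %*% load)
}

#' Standardized major axis (SMA) line fit
#'
#' Symmetric line fitting for bivariate relations where neither
#' variable is the predictor and both carry error:
#' `slope = sign(r) * sd(y)/sd(x)`, intercept through the means.  The
#' p-value is that of the Pearson correlation.  SMA is reciprocal:
#' `slope(y ~ x) * slope(x ~ y) = 1`.
#'
#' @param x,y Numeric vectors, `n >= 3`, both non-constant.
#' @return List of class `"sma_fit"`: `slope`, `intercept`, `r`,
#'   `p_value`, `n`.
#' @export
#' @examples
#' sma_fit(c(1, 2, 3, 4), c(1, 3, 2, 5))
sma_fit <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0) stop("x is constant: SMA slope undefined")
  if (stats::sd(y) == 0) stop("y is constant: SMA slope undefined")
  r <- stats::cor(x, y)
  slope <- (if (r < 0) -1 else 1) * stats::sd(y) / stats::sd(x)
  p <- stats::cor.test(x, y)$p.value
  structure(list(slope = slope,
                 intercept = mean(y) - slope * mean(x),
                 r = r, p_value = p, n = n),
            class = "sma_fit")
}

#' @export
print.sma_fit <- function(x, ...) {
  cat(sprintf("SMA fit (n = %d): slope %.4f, intercept %.4f, r = %.3f, P = %.4g\n",
              x$n, x$slope, x$intercept, x$r, x$p_value))
  invisible(x)
}

#' Sequential (Type I) variance partitioning across categorical factors
#'
#' Fits a linear model with the factors in the given order and reports
#' each factor's sequential sum of squares as a proportion of the total,
#' plus the residual proportion; proportions are non-negative and sum
#' to 1.  Entering site before plant group (or family) attributes
#' shared variance to site, mirroring a "soil first" reading of the
#' partition.
#'
#' @param response Numeric response.
#' @param factors Named list (or data.frame) of categorical factors, in
#'   the order they should enter the model.
#' @param allow_aliased With the default `FALSE`, a rank-deficient
#'   design is an error naming the aliased factor(s).  Set `TRUE` to
#'   proceed the way [stats::lm()] does - aliased level combinations
#'   are credited to the factor entered earlier and the later factor
#'   loses the corresponding degrees of freedom.  Useful when factors
#'   are ecologically confounded (e.g. plant groups restricted to soil
#'   types, so some group contrasts are collinear with site).
#' @return Data.frame of class `"variance_partition"`: `term`, `df`,
#'   `ss`, `proportion` (residual row last).
#' @export
variance_partition <- function(response, factors, allow_aliased = FALSE) {
  factors <- as.data.frame(factors, stringsAsFactors = FALSE)
  stopifnot(ncol(factors) >= 1, !is.null(names(factors)))
  keep <- is.finite(response) & stats::complete.cases(factors)
  d <- data.frame(.y = response[keep], lapply(factors[keep, , drop = FALSE],
                                              factor))
  n_par <- 1L + sum(vapply(d[-1], nlevels, integer(1)) - 1L)
  if (nrow(d) <= n_par) {
    stop("need more observations than model parameters (",
         n_par, " for these factor levels)")
  }
  fml <- stats::as.formula(paste(".y ~", paste(names(factors),
                                               collapse = " + ")))
  fit <- stats::lm(fml, data = d)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    terms_bad <- unique(unlist(lapply(names(factors), function(f)
      if (any(startsWith(bad, f))) f)))
    if (!allow_aliased) {
      stop("rank-deficient design; aliased factor(s): ",
           paste(terms_bad, collapse = ", "))
    }
    message("aliased level(s) in factor(s) ",
            paste(terms_bad, collapse = ", "),
            "; shared variance credited to earlier factor(s)")
  }
  a <- stats::anova(fit)
  ss <- a[["Sum Sq"]]
  out <- data.frame(term = rownames(a), df = a[["Df"]], ss = ss,
                    proportion = ss / sum(ss))
  out$term[out$term == "Residuals"] <- "residual"
  rownames(out) <- NULL
  class(out) <- c("variance_partition", "data.frame")
  out
}

#' Trait-pair correlations at three analysis levels
#'
#' Pearson correlations between trait pairs at the individual level
#' (all leaf observations), species level (species means) and
#' species-PIC level (through-origin correlation of phylogenetically
#' independent contrasts, n - 1 contrasts for n species).
#'
#' @param pairs Two-column character matrix/data.frame of trait names.
#' @param species_traits Data.frame of species-level traits with a
#'   `species` column (used for levels `"species"` and `"species_PIC"`).
#' @param individual_traits Optional data.frame of individual-level
#'   traits for level `"individual"`.
#' @param tree Tree for the PIC level.
#' @param levels Subset of `c("individual", "species", "species_PIC")`.
#' @return Long data.frame: `trait_x`, `trait_y`, `level`, `r`,
#'   `p_value`, `n`.  Entries with fewer than 3 complete pairs are `NA`
#'   with a warning.
#' @export
correlation_table <- function(pairs, species_traits,
                              individual_traits = NULL, tree = NULL,
                              levels = c("individual", "species",
                                         "species_PIC")) {
  pairs <- as.matrix(pairs)
  stopifnot(ncol(pairs) == 2)
  levels <- match.arg(levels, several.ok = TRUE)
  rows <- list()
  add <- function(tx, ty, lev, r, p, n) {
    rows[[length(rows) + 1L]] <<- data.frame(
      trait_x = tx, trait_y = ty, level = lev, r = r, p_value = p, n = n)
  }
  plain_cor <- function(df, tx, ty, lev) {
    if (is.null(df) || !all(c(tx, ty) %in% names(df))) {
      warning("traits ", tx, "/", ty, " unavailable at level ", lev)
      return(add(tx, ty, lev, NA_real_, NA_real_, NA_integer_))
    }
    ok <- is.finite(df[[tx]]) & is.finite(df[[ty]])
    if (sum(ok) < 3) {
      warning("fewer than 3 complete pairs for ", tx, "-", ty,
              " at level ", lev)
      return(add(tx, ty, lev, NA_real_, NA_real_, sum(ok)))
    }
    ct <- stats::cor.test(df[[tx]][ok], df[[ty]][ok])
    add(tx, ty, lev, unname(ct$estimate), ct$p.value, sum(ok))
  }
  for (i in seq_len(nrow(pairs))) {
    tx <- pairs[i, 1]; ty <- pairs[i, 2]
    if ("individual" %in% levels) {
      plain_cor(individual_traits, tx, ty, "individual")
    }
    if ("species" %in% levels) plain_cor(species_traits, tx, ty, "species")
    if ("species_PIC" %in% levels) {
      if (is.null(tree)) stop("species_PIC level requires a tree")
      sx <- stats::setNames(species_traits[[tx]], species_traits$species)
      sy <- stats::setNames(species_traits[[ty]], species_traits$species)
      ok <- is.finite(sx) & is.finite(sy)
      if (sum(ok) < 3) {
        warning("fewer than 3 species for ", tx, "-", ty, " at PIC level")
        add(tx, ty, "species_PIC", NA_real_, NA_real_, sum(ok))
      } else {
        sub <- ape::keep.tip(tree, names(sx)[ok])
        pc <- pic_correlation(sub, sx[ok], sy[ok])
        add(tx, ty, "species_PIC", pc$r, pc$p_value, pc$n_contrasts)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
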