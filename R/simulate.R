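#' Simulate a pure-birth (Yule) phylogeny
#'
#' Draws a Yule tree with unit birth rate and no extinction, labels the
#' tips `sp001...spNNN`, and rescales the root-to-tip depth to 1.0 so
#' downstream rates are in units of tree depth.  Identical
#' `n_tips`/`seed` give identical trees.
#'
#' @param n_tips Number of tips, >= 3.
#' @param seed Integer seed.
#' @return An ultrametric binary `"phylo"` tree of depth 1.
#' @export
#' @examples
#' tr <- simulate_tree(36, seed = 7)
#' ape::Ntip(tr)
simulate_tree <- function(n_tips, seed) {
  if (n_tips < 3) stop("n_tips must be at least 3")
  tree <- with_seed_or_not(seed, ape::rphylo(n_tips, birth = 1, death = 0))
  tree$tip.label <- sprintf("sp%03d", seq_len(n_tips))
  depth <- max(node_depths(tree)[seq_len(n_tips)])
  tree$edge.length <- tree$edge.length / depth
  tree
}

# Root-to-node path lengths for every node (root = 0).
node_depths <- function(tree) {
  tree <- ape::reorder.phylo(tree)  # cladewise: parents precede children
  nn <- ape::Ntip(tree) + tree$Nnode
  depth <- numeric(nn)
  for (i in seq_len(nrow(tree$edge))) {
    depth[tree$edge[i, 2L]] <- depth[tree$edge[i, 1L]] + tree$edge.length[i]
  }
  depth
}

#' Simulate Brownian-motion traits on a phylogeny
#'
#' Evolves `n_traits` traits from `root_value` along the tree: the
#' increment on each branch is Normal with variance `sigma2` times the
#' branch length, independent across branches; across traits the
#' increments are multivariate Normal with the given correlation
#' matrix.  This is the null model under which Blomberg's K is
#' calibrated (K = 1 in expectation).
#'
#' @param tree A rooted `"phylo"` tree with branch lengths.
#' @param sigma2 Brownian rate (variance per unit branch length), > 0.
#' @param root_value Trait value at the root.
#' @param seed Optional integer seed.
#' @param n_traits Number of traits.
#' @param correlation Optional `n_traits` x `n_traits` positive-definite
#'   correlation matrix for the increments.
#' @return Tips x traits numeric matrix, rownames = tip labels.
#' @export
simulate_bm_traits <- function(tree, sigma2 = 1, root_value = 0, seed = NULL,
                               n_traits = 1, correlation = NULL) {
  stopifnot(inherits(tree, "phylo"), sigma2 > 0, n_traits >= 1)
  L <- NULL
  if (!is.null(correlation)) {
    stopifnot(nrow(correlation) == n_traits, ncol(correlation) == n_traits)
    L <- tryCatch(chol(correlation), error = function(e) {
      stop("correlation matrix is not positive-definite", call. = FALSE)
    })
  }
  tree <- ape::reorder.phylo(tree)  # cladewise: parents precede children
  n <- ape::Ntip(tree)
  nn <- n + tree$Nnode
  with_seed_or_not(seed, {
    z <- matrix(stats::rnorm(nrow(tree$edge) * n_traits),
                nrow(tree$edge), n_traits)
    if (!is.null(L)) z <- z %*% L
    val <- matrix(0, nn, n_traits)
    val[n + 1L, ] <- root_value
    for (i in seq_len(nrow(tree$edge))) {
      val[tree$edge[i, 2L], ] <- val[tree$edge[i, 1L], ] +
        sqrt(sigma2 * tree$edge.length[i]) * z[i, ]
    }
    out <- val[seq_len(n), , drop = FALSE]
    rownames(out) <- tree$tip.label
    colnames(out) <- paste0("trait", seq_len(n_traits))
    out
  })
}

#' Assign species to plant groups, optionally phylogenetically clustered
#'
#' With `clustered = TRUE`, tips are taken in their cladewise order
#' along the tree and split into four contiguous blocks (sizes
#' proportional to the emulated study design Eu 10 / Se 5 / Ps 11 /
#' Gl 10), so each group occupies one or a few clades and the group
#' label carries phylogenetic signal.  With `clustered = FALSE` labels
#' are assigned uniformly at random (all four groups non-empty), which
#' destroys the signal.
#'
#' @param tree A `"phylo"` tree with >= 4 tips.
#' @param clustered Logical (default `TRUE`).
#' @param seed Optional seed (used only when `clustered = FALSE`).
#' @return Character vector of group labels named by species.
#' @export
assign_groups <- function(tree, clustered = TRUE, seed = NULL) {
  n <- ape::Ntip(tree)
  groups <- resorb_groups()
  if (n < length(groups)) stop("need at least as many tips as groups")
  # block sizes proportional to the study design, each >= 1
  sizes <- pmax(1L, round(.group_n_species / sum(.group_n_species) * n))
  while (sum(sizes) > n) sizes[which.max(sizes)] <- sizes[which.max(sizes)] - 1L
  while (sum(sizes) < n) sizes[which.min(sizes)] <- sizes[which.min(sizes)] + 1L
  if (clustered) {
    ord <- cladewise_tip_order(tree)
    lab <- rep(groups, times = sizes)
    out <- stats::setNames(character(n), tree$tip.label)
    out[ord] <- lab
    return(out)
  }
  with_seed_or_not(seed, {
    stats::setNames(sample(rep(groups, times = sizes)), tree$tip.label)
  })
}

# Tip labels in the order they appear along a cladewise traversal, so
# contiguous runs correspond to clades.
cladewise_tip_order <- function(tree) {
  tree <- ape::reorder.phylo(tree)
  e2 <- tree$edge[, 2L]
  tree$tip.label[e2[e2 <= ape::Ntip(tree)]]
}

# Partition tips into monophyletic "families" by slicing the tree at
# the epoch where n_families lineages exist (ultrametric trees).
assign_families <- function(tree, n_families) {
  n <- ape::Ntip(tree)
  if (n_families >= n) {
    return(stats::setNames(sprintf("fam%02d", seq_len(n)), tree$tip.label))
  }
  depth <- node_depths(tree)
  total <- max(depth[seq_len(n)])
  node_depth_internal <- sort(depth[(n + 1L):(n + tree$Nnode)])
  # after the k-th branching (by depth) there are k+1 lineages
  cut <- mean(node_depth_internal[c(n_families - 1L, n_families)])
  parent <- integer(n + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  fam_node <- vapply(seq_len(n), function(tip) {
    node <- tip
    while (parent[node] != 0L && depth[parent[node]] >= cut) {
      node <- parent[node]
    }
    node
  }, integer(1))
  ids <- match(fam_node, unique(fam_node))
  stats::setNames(sprintf("fam%02d", ids), tree$tip.label)
}

#' Scale factor for a target group share of log-concentration variance
#'
#' The generator's group effect enters the log green-leaf concentration
#' as `overall + scale * (log group mean - overall)`.  This helper
#' solves analytically for the `scale` at which the group term accounts
#' for a target fraction of the individual-level log-concentration
#' variance, given the generator's own variance components
#' (species-level spread `tau`, site effect `site_sd`, individual noise
#' `noise_sd`):
#' `scale^2 * V_group / (scale^2 * V_group + tau^2 + site_sd^2 +
#' noise_sd^2) = target`.
#'
#' @param target_fraction Desired group share of variance, in (0, 1).
#' @param element Element whose reference group means set `V_group`.
#' @param tau,noise_sd,site_sd Generator dispersion parameters (log
#'   scale); defaults match [synthetic_truth()].
#' @param group_weights Species counts per group used to weight the
#'   group means.
#' @return The `group_effect_scale` to pass to [synthetic_truth()].
#' @export
tune_group_effect <- function(target_fraction, element = "Na",
                              tau = 0.25, noise_sd = 0.2, site_sd = 0.05,
                              group_weights = .group_n_species) {
  stopifnot(target_fraction > 0, target_fraction < 1)
  lg <- log(.group_mean_green[names(group_weights), element])
  w <- group_weights / sum(group_weights)
  v_group <- sum(w * (lg - sum(w * lg))^2)
  v_within <- tau^2 + noise_sd^2 + site_sd^2
  sqrt(target_fraction / (1 - target_fraction) * v_within / v_group)
}

#' Ground truth for a synthetic leaf-resorption dataset
#'
#' Builds the hidden parameters the generator draws data from: a Yule
#' tree, phylogenetically clustered (or random) plant-group labels,
#' family clades, per-species green-leaf mean concentrations (group
#' reference means from [group_mean_concentrations()], a Brownian-motion
#' component mixing phylogenetic structure into the species-level
#' deviations, all on the log scale), per-species true resorption
#' efficiencies derived from the green/senesced reference means at the
#' nominal MLCF, per-species MLCF, SLA and LDMC, and a site layout
#' (13 saline sites for halophytes, 5 gravel sites for glycophytes).
#'
#' @param n_species Number of species (default 36).
#' @param seed Integer seed (mandatory; drives every random draw).
#' @param n_families Number of family clades (default 15).
#' @param clustered Cluster groups on the tree? (default `TRUE`).
#' @param phylo_weight Fraction of the species-level log-concentration
#'   variance `tau^2` attributable to Brownian motion on the tree,
#'   in `[0, 1]` (default 0.7).
#' @param tau Species-level log-concentration SD within group (0.25).
#' @param noise_sd Lognormal SD of individual-level deviation (0.2).
#' @param site_sd Lognormal SD of the per-site fertility effect (0.05).
#' @param group_effect_scale Scaling of log group-mean differences
#'   (1 = reference means as printed; see [tune_group_effect()]).
#' @param re_jitter_sd SD of species-level jitter on true RE (0.05).
#' @param mlcf_range Range of the per-species uniform MLCF (0.6-1.0).
#' @param tree,group_of Optional: supply a tree and/or group labels
#'   instead of simulating them.
#' @return Object of class `"synthetic_truth"`; fields include `tree`,
#'   `group_of`, `family_of`, `green_mean` (species x element),
#'   `true_RE` (species x element, fractions), `MLCF_of`, `SLA_of`,
#'   `LDMC_of`, `leaf_area_of`, `site_of` (per-species site pool),
#'   `site_effect`, and the scalar parameters.
#' @export
synthetic_truth <- function(n_species = 36, seed, n_families = 15,
                            clustered = TRUE, phylo_weight = 0.7,
                            tau = 0.25, noise_sd = 0.2, site_sd = 0.05,
                            group_effect_scale = 1, re_jitter_sd = 0.05,
                            mlcf_range = c(0.6, 1.0),
                            tree = NULL, group_of = NULL) {
  if (missing(seed)) stop("seed is mandatory for the generator")
  stopifnot(phylo_weight >= 0, phylo_weight <= 1, tau >= 0, noise_sd >= 0,
            site_sd >= 0, length(mlcf_range) == 2, all(mlcf_range > 0))
  if (is.null(tree)) tree <- simulate_tree(n_species, derive_seed(seed, 1))
  n_species <- ape::Ntip(tree)
  sp <- tree$tip.label
  if (is.null(group_of)) {
    group_of <- assign_groups(tree, clustered, derive_seed(seed, 2))
  }
  group_of <- group_of[sp]
  family_of <- assign_families(tree, min(n_families, n_species))
  els <- resorb_elements()
  nominal_mlcf <- mean(mlcf_range)

  # species-level log deviations: BM component (standardised to unit
  # variance across tips) mixed with an i.i.d. component
  bm <- simulate_bm_traits(tree, sigma2 = 1, seed = derive_seed(seed, 3),
                           n_traits = length(els))
  bm <- scale(bm)  # unit variance across tips, per element
  dev <- with_seed_or_not(derive_seed(seed, 4), {
    iid <- matrix(stats::rnorm(n_species * length(els)), n_species)
    tau * (sqrt(phylo_weight) * bm + sqrt(1 - phylo_weight) * iid)
  })
  dimnames(dev) <- list(sp, els)

  w <- .group_n_species / sum(.group_n_species)
  green_mean <- matrix(NA_real_, n_species, length(els),
                       dimnames = list(sp, els))
  for (e in els) {
    lg <- log(.group_mean_green[, e])
    overall <- sum(w * lg)
    scaled <- overall + group_effect_scale * (lg - overall)
    # -tau^2/2 keeps E[concentration] at the reference mean
    green_mean[, e] <- exp(scaled[group_of] + dev[, e] - tau^2 / 2)
  }

  base_re <- 1 - .group_mean_senesced / .group_mean_green * nominal_mlcf
  true_RE <- with_seed_or_not(derive_seed(seed, 5), {
    jit <- matrix(stats::rnorm(n_species * length(els), sd = re_jitter_sd),
                  n_species)
    pmin(pmax(base_re[group_of, , drop = FALSE] + jit, -0.49), 0.95)
  })
  dimnames(true_RE) <- list(sp, els)

  sla_range <- list(Eu = c(20, 40), Se = c(40, 80),
                    Ps = c(50, 100), Gl = c(40, 120))
  ldmc_range <- list(Eu = c(0.10, 0.20), Se = c(0.20, 0.35),
                     Ps = c(0.25, 0.40), Gl = c(0.25, 0.45))
  saline_sites <- sprintf("S%02d", 1:13)
  gravel_sites <- sprintf("G%02d", 1:5)
  per_species <- with_seed_or_not(derive_seed(seed, 6), {
    mlcf_of <- stats::runif(n_species, mlcf_range[1], mlcf_range[2])
    sla_of <- vapply(group_of, function(g)
      stats::runif(1, sla_range[[g]][1], sla_range[[g]][2]), numeric(1))
    ldmc_of <- vapply(group_of, function(g)
      stats::runif(1, ldmc_range[[g]][1], ldmc_range[[g]][2]), numeric(1))
    area_of <- stats::rlnorm(n_species, log(8), 0.3)
    site_of <- lapply(group_of, function(g) {
      pool <- if (g == "Gl") gravel_sites else saline_sites
      sample(pool, size = min(3L, length(pool)))
    })
    list(mlcf_of = mlcf_of, sla_of = sla_of, ldmc_of = ldmc_of,
         area_of = area_of, site_of = site_of)
  })
  site_effect <- with_seed_or_not(derive_seed(seed, 7), {
    s <- c(saline_sites, gravel_sites)
    stats::setNames(stats::rnorm(length(s), -site_sd^2 / 2, site_sd), s)
  })

  structure(list(
    tree = tree,
    group_of = group_of,
    family_of = family_of,
    green_mean = green_mean,
    true_RE = true_RE,
    MLCF_of = stats::setNames(per_species$mlcf_of, sp),
    SLA_of = stats::setNames(per_species$sla_of, sp),
    LDMC_of = stats::setNames(per_species$ldmc_of, sp),
    leaf_area_of = stats::setNames(per_species$area_of, sp),
    site_of = stats::setNames(per_species$site_of, sp),
    site_effect = site_effect,
    phylo_weight = phylo_weight, tau = tau, noise_sd = noise_sd,
    site_sd = site_sd, group_effect_scale = group_effect_scale,
    re_jitter_sd = re_jitter_sd, mlcf_range = mlcf_range,
    nominal_mlcf = nominal_mlcf, seed = as.integer(seed)
  ), class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "Synthetic ground truth: %d species, %d families, seed %d\n",
    ape::Ntip(x$tree), length(unique(x$family_of)), x$seed))
  cat("  groups:", paste(names(table(x$group_of)), table(x$group_of),
                         sep = "=", collapse = ", "), "\n")
  cat(sprintf("  phylo_weight %.2f, tau %.2f, noise_sd %.2f, site_sd %.2f\n",
              x$phylo_weight, x$tau, x$noise_sd, x$site_sd))
  invisible(x)
}

#' Generate a paired green/senesced leaf dataset with known truth
#'
#' Draws, for every species, a number of individuals from
#' `individuals_per_species` and emits one green and one senesced leaf
#' sample per individual (the emulated protocol tags individuals in
#' summer and resamples them at the end of the growing season).  Green
#' concentrations are the species mean times a mean-one lognormal
#' individual deviate and the site's fertility multiplier; senesced
#' concentrations are `green_mean * (1 - true_RE) / MLCF` times their
#' own lognormal deviate and the same site multiplier, i.e. the exact
#' inversion of the corrected-RE formula, so the estimated RE recovers
#' the true RE (exactly at `noise_sd = 0`, in expectation otherwise).
#' Masses and area are drawn so that SLA, LDMC and the species MLCF are
#' recovered exactly at zero noise.
#'
#' @param truth A [synthetic_truth()] object.
#' @param individuals_per_species Integer range to draw the per-species
#'   number of tagged individuals from, within `[1, 20]`.  The default
#'   `5:8` follows the emulated field protocol; `3:4` reproduces a
#'   252-row layout at 36 species.
#' @param seed Integer seed (defaults to the truth's seed).
#' @return List of class `"leaf_dataset"`: `samples` (leaf-sample
#'   data.frame, 2 rows per individual), `species` (per-species
#'   summaries via [species_summaries()]), and `truth`.
#' @export
generate_leaf_dataset <- function(truth, individuals_per_species = 5:8,
                                  seed = truth$seed) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (any(individuals_per_species < 1) || any(individuals_per_species > 20)) {
    stop("individuals_per_species must lie within [1, 20]")
  }
  if (any(truth$true_RE >= 1)) {
    stop("true_RE >= 1 would force a negative senesced concentration")
  }
  els <- resorb_elements()
  sp <- truth$tree$tip.label
  nsd <- truth$noise_sd
  ln_noise <- function(k) exp(stats::rnorm(k, -nsd^2 / 2, nsd))
  ln_half <- function(k) exp(stats::rnorm(k, -(nsd / 2)^2 / 2, nsd / 2))
  rows <- with_seed_or_not(derive_seed(seed, 8), lapply(sp, function(s) {
    n_ind <- if (length(individuals_per_species) == 1L) {
      individuals_per_species
    } else sample(individuals_per_species, 1L)
    sites <- sample(truth$site_of[[s]], n_ind, replace = TRUE)
    site_mult <- exp(truth$site_effect[sites])
    green_base <- truth$green_mean[s, els]
    sen_base <- green_base * (1 - truth$true_RE[s, els]) / truth$MLCF_of[[s]]
    out <- vector("list", n_ind)
    for (i in seq_len(n_ind)) {
      gc <- green_base * site_mult[i] * ln_noise(length(els))
      sc <- sen_base * site_mult[i] * ln_noise(length(els))
      area_g <- truth$leaf_area_of[[s]] * ln_half(1)
      area_s <- truth$leaf_area_of[[s]] * ln_half(1)
      dry_g <- truth$leaf_area_of[[s]] / truth$SLA_of[[s]] * ln_half(1)
      dry_s <- truth$leaf_area_of[[s]] / truth$SLA_of[[s]] *
        truth$MLCF_of[[s]] * ln_half(1)
      ldmc_g <- min(truth$LDMC_of[[s]] * ln_half(1), 0.95)
      ldmc_s <- min(truth$LDMC_of[[s]] * ln_half(1), 0.95)
      base <- data.frame(
        species = s, family = truth$family_of[[s]],
        group = truth$group_of[[s]], site = sites[i],
        individual = sprintf("i%02d", i),
        status = c("green", "senesced"))
      conc <- rbind(gc, sc)
      for (e in seq_along(els)) base[[els[e]]] <- conc[, e]
      base$leaf_area <- c(area_g, area_s)
      base$dry_mass <- c(dry_g, dry_s)
      base$saturated_mass <- c(dry_g / ldmc_g, dry_s / ldmc_s)
      out[[i]] <- base
    }
    do.call(rbind, out)
  }))
  samples <- do.call(rbind, rows)
  rownames(samples) <- NULL
  structure(list(samples = samples,
                 species = species_summaries(samples),
                 truth = truth),
            class = "leaf_dataset")
}

#' @export
print.leaf_dataset <- function(x, ...) {
  cat(sprintf(
    "Synthetic leaf dataset: %d samples, %d species (seed %d)\n",
    nrow(x$samples), length(unique(x$samples$species)), x$truth$seed))
  invisible(x)
}
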