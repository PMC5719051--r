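#' Build a pipeline run configuration
#'
#' Collects every knob of the end-to-end analysis.  Either supply paths
#' to a trait CSV and Newick tree (`traits_path`, `tree_path`) or let
#' the pipeline simulate a dataset with the synthetic generator
#' (the default; see [synthetic_truth()]).  A YAML or JSON file can
#' override the defaults via `config_file`.
#'
#' @param seed Integer seed; mandatory, drives every stochastic step.
#' @param traits_path,tree_path Optional input files; when `NULL` the
#'   generator is used.
#' @param n_species,individuals_per_species,clustered,group_effect_scale
#'   Generator settings (ignored when inputs are supplied).
#' @param alpha Significance level for letters and bold-facing (0.05).
#' @param n_permutations Tip shuffles for the signal test (999).
#' @param reference_re Named vector (or named list of
#'   `c(mean, sd, n)` triples) of global mass-loss-corrected RE
#'   reference values in percent; default `c(N = 62.1, P = 64.9)`, the
#'   two published global averages.
#' @param partition_order Factor order for the sequential variance
#'   partition; `"site"` first by default.
#' @param outdir Optional output directory; when given, all tables and
#'   run metadata are written there via [write_results()].
#' @param config_file Optional YAML/JSON file whose entries override
#'   the arguments above.
#' @return List of class `"run_config"`.
#' @export
run_config <- function(seed,
                       traits_path = NULL, tree_path = NULL,
                       n_species = 36, individuals_per_species = 5:8,
                       clustered = TRUE, group_effect_scale = 1,
                       alpha = 0.05, n_permutations = 999,
                       reference_re = c(N = 62.1, P = 64.9),
                       partition_order = c("site", "group"),
                       outdir = NULL, config_file = NULL) {
  cfg <- list(seed = seed, traits_path = traits_path,
              tree_path = tree_path, n_species = n_species,
              individuals_per_species = individuals_per_species,
              clustered = clustered,
              group_effect_scale = group_effect_scale, alpha = alpha,
              n_permutations = n_permutations,
              reference_re = reference_re,
              partition_order = partition_order, outdir = outdir)
  if (!is.null(config_file)) {
    over <- if (grepl("\\.ya?ml$", config_file)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop("yaml package required to read a YAML config")
      }
      yaml::read_yaml(config_file)
    } else {
      jsonlite::read_json(config_file, simplifyVector = TRUE)
    }
    cfg[names(over)] <- over
  }
  if (is.null(cfg$seed)) stop("seed is mandatory")
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

#' Cross-check a trait table against a phylogeny
#'
#' Report-only validation: species present in the traits but absent
#' from the tree (and vice versa), species missing element values,
#' species without both green and senesced samples, and the per-group
#' species counts.
#'
#' @param samples Leaf-sample data.frame.
#' @param tree A `"phylo"` tree.
#' @return List of class `"input_report"`: `trait_only`, `tree_only`,
#'   `shared`, `missing_elements`, `unpaired_species`, `group_sizes`.
#' @export
validate_inputs <- function(samples, tree) {
  sp_traits <- unique(samples$species)
  sp_tree <- tree$tip.label
  els <- resorb_elements()
  missing_el <- lapply(stats::setNames(sp_traits, sp_traits), function(s) {
    d <- samples[samples$species == s, els, drop = FALSE]
    els[vapply(d, function(x) any(!is.finite(x)), logical(1))]
  })
  missing_el <- missing_el[lengths(missing_el) > 0]
  has_status <- function(s, st) any(samples$species == s & samples$status == st)
  unpaired <- sp_traits[!vapply(sp_traits, has_status, logical(1), "green") |
                        !vapply(sp_traits, has_status, logical(1), "senesced")]
  sp_grp <- samples$group[match(sp_traits, samples$species)]
  gs <- table(factor(sp_grp, levels = resorb_groups()))
  structure(list(
    trait_only = setdiff(sp_traits, sp_tree),
    tree_only = setdiff(sp_tree, sp_traits),
    shared = intersect(sp_traits, sp_tree),
    missing_elements = missing_el,
    unpaired_species = unpaired,
    group_sizes = gs
  ), class = "input_report")
}

#' @export
print.input_report <- function(x, ...) {
  cat("Input validation report\n")
  cat("  species shared with tree:", length(x$shared), "\n")
  cat("  trait-only species:", length(x$trait_only),
      if (length(x$trait_only)) paste0("(", paste(x$trait_only,
                                                  collapse = ", "), ")"),
      "\n")
  cat("  tree-only species:", length(x$tree_only),
      if (length(x$tree_only)) paste0("(", paste(x$tree_only,
                                                 collapse = ", "), ")"), "\n")
  cat("  species without a green/senesced pair:",
      length(x$unpaired_species), "\n")
  cat("  species per group:", paste(names(x$group_sizes), x$group_sizes,
                                    sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# Group-level summary of one variable across species, with ANOVA letters.
group_summary_row <- function(values, groups, alpha) {
  av <- one_way_anova(values, groups)
  lt <- letter_groups(values, groups, alpha)
  gl <- resorb_groups()
  out <- data.frame(F = av$F, p_value = av$p_value)
  for (g in gl) {
    out[[paste0("mean_", g)]] <- unname(av$group_means[g])
    out[[paste0("se_", g)]] <- unname(av$group_se[g])
    out[[paste0("letter_", g)]] <- unname(lt[g])
  }
  out
}

#' Run the full resorption/phylogeny analysis pipeline
#'
#' Orchestrates the end-to-end analysis: simulate (or read) the
#' paired-leaf dataset and tree; compute per-species summaries,
#' resorption records at species and individual level; group-mean
#' tables with ANOVA compact letters for every element in green and
#' senesced leaves; RE summaries per group with one-sample t tests
#' against 0% and tests against the configured global reference values;
#' the phylogenetic-signal matrix (Blomberg's K + permutation p) for
#' green/senesced concentrations, N/P and K/Na ratios, SLA, LDMC,
#' corrected RE per element and the integer-coded plant group; the
#' trait-pair correlation table at individual, species and PIC levels;
#' and sequential variance partitions of each element run once with
#' plant group and once with family.  All stochastic steps derive their
#' seeds from `config$seed`, so a given configuration is exactly
#' reproducible.
#'
#' @param config A [run_config()] object (or a bare seed, for
#'   defaults).
#' @return List of class `"pipeline_result"`: `tables` (named list of
#'   data.frames: `species_summary`, `resorption`, `group_means`,
#'   `re_summary`, `signal`, `correlations`, `variance_partition`),
#'   `report` (input validation), `truth` (when simulated), `tree`,
#'   `samples`, `config`, `excluded_species`.  When `config$outdir` is
#'   set the tables are also written as CSVs with run metadata.
#' @export
#' @examples
#' \donttest{
#' res <- run_pipeline(run_config(seed = 42, n_permutations = 99))
#' names(res$tables)
#' }
run_pipeline <- function(config) {
  if (is.numeric(config)) config <- run_config(seed = config)
  stopifnot(inherits(config, "run_config"))
  els <- resorb_elements()
  truth <- NULL
  if (is.null(config$traits_path)) {
    truth <- synthetic_truth(n_species = config$n_species,
                             seed = config$seed,
                             clustered = config$clustered,
                             group_effect_scale = config$group_effect_scale)
    ds <- generate_leaf_dataset(
      truth, individuals_per_species = config$individuals_per_species)
    samples <- ds$samples
    tree <- truth$tree
  } else {
    samples <- read_trait_table(config$traits_path)
    if (is.null(config$tree_path)) stop("tree_path required with traits_path")
    tree <- read_newick(config$tree_path)
  }

  report <- validate_inputs(samples, tree)
  if (length(report$shared) == 0) {
    stop("no species shared between trait table and tree")
  }
  if (length(report$trait_only) || length(report$tree_only)) {
    warning("species mismatch between traits and tree: ",
            length(report$trait_only), " trait-only (excluded from ",
            "phylogenetic steps), ", length(report$tree_only),
            " tree-only (pruned)", call. = FALSE)
  }
  phylo_tree <- if (length(report$tree_only)) {
    ape::keep.tip(tree, report$shared)
  } else tree

  summ <- species_summaries(samples)
  res_sp <- resorption_table(samples, level = "species")
  res_ind <- resorption_table(samples, level = "individual")
  res_sp$level <- "species"
  res_ind$level <- "individual"
  resorption <- rbind(res_sp, res_ind)

  ## group means with letters (per element x leaf status), species level
  gm_rows <- list()
  for (st in c("green", "senesced")) {
    for (e in els) {
      v <- summ[[paste0(st, "_", e)]]
      ok <- is.finite(v)
      row <- group_summary_row(v[ok], summ$group[ok], config$alpha)
      gm_rows[[length(gm_rows) + 1L]] <-
        cbind(data.frame(status = st, element = e), row)
    }
  }
  group_means <- do.call(rbind, gm_rows)

  ## RE summaries per group with tests vs 0% and vs global references
  re_rows <- list()
  ref <- config$reference_re
  for (e in els) {
    d <- res_sp[res_sp$element == e & is.finite(res_sp$RE_percent), ]
    for (g in resorb_groups()) {
      v <- d$RE_percent[d$group == g]
      if (length(v) < 2) next
      t0 <- one_sample_t(v, mu0 = 0)
      re_row <- data.frame(element = e, group = g, n = length(v),
                           mean_RE = mean(v),
                           se_RE = stats::sd(v) / sqrt(length(v)),
                           t_vs_zero = t0$t, p_vs_zero = t0$p_value,
                           reference = NA_real_,
                           p_vs_reference = NA_real_)
      re_ref <- if (is.list(ref)) ref[[e]] else
        if (e %in% names(ref)) ref[[e]] else NULL
      if (!is.null(re_ref) && length(re_ref) >= 1 && is.finite(re_ref[1])) {
        tr <- if (length(re_ref) >= 3) {
          two_sample_t(v, ref_mean = re_ref[1], ref_sd = re_ref[2],
                       ref_n = re_ref[3])
        } else {
          suppressMessages(two_sample_t(v, ref_mean = re_ref[1]))
        }
        re_row$reference <- re_ref[1]
        re_row$p_vs_reference <- tr$p_value
      }
      re_rows[[length(re_rows) + 1L]] <- re_row
    }
  }
  re_summary <- do.call(rbind, re_rows)

  ## phylogenetic signal table
  summ_phylo <- summ[summ$species %in% report$shared, , drop = FALSE]
  sig_traits <- list()
  for (st in c("green", "senesced")) {
    for (e in els) {
      sig_traits[[paste0(st, "_", e)]] <-
        stats::setNames(summ_phylo[[paste0(st, "_", e)]],
                        summ_phylo$species)
    }
  }
  sig_traits$NP_ratio <- stats::setNames(summ_phylo$NP_ratio,
                                         summ_phylo$species)
  sig_traits$K_Na_ratio <- stats::setNames(summ_phylo$K_Na_ratio,
                                           summ_phylo$species)
  sig_traits$SLA <- stats::setNames(summ_phylo$SLA, summ_phylo$species)
  sig_traits$LDMC <- stats::setNames(summ_phylo$LDMC, summ_phylo$species)
  for (e in els) {
    d <- res_sp[res_sp$element == e, ]
    sig_traits[[paste0("RE_", e)]] <-
      stats::setNames(d$RE_percent, d$species)[summ_phylo$species]
  }
  sig_traits$plant_group <- encode_group_trait(
    stats::setNames(summ_phylo$group, summ_phylo$species))
  # pure-noise control: no phylogenetic structure by construction, so a
  # calibrated test should leave it non-significant
  sig_traits$noise_control <- with_seed_or_not(
    derive_seed(config$seed, 99),
    stats::setNames(stats::rnorm(nrow(summ_phylo)), summ_phylo$species))
  sig_rows <- list()
  for (k in seq_along(sig_traits)) {
    tr_name <- names(sig_traits)[k]
    v <- sig_traits[[k]]
    v <- v[is.finite(v)]
    if (length(v) < 3 || stats::var(v) == 0) next
    sub <- if (length(v) < ape::Ntip(phylo_tree)) {
      ape::keep.tip(phylo_tree, names(v))
    } else phylo_tree
    st <- signal_test(sub, v, n_perm = config$n_permutations,
                      seed = derive_seed(config$seed, 100 + k),
                      trait_name = tr_name)
    sig_rows[[length(sig_rows) + 1L]] <- data.frame(
      trait = tr_name, K = st$K, p_value = st$p_value,
      n_species = st$n_species, n_permutations = st$n_permutations)
  }
  signal <- do.call(rbind, sig_rows)

  ## trait-pair correlations at the three levels (SLA/LDMC vs RE/RP)
  sp_traits <- summ_phylo[, c("species", "SLA", "LDMC"), drop = FALSE]
  for (e in els) {
    d <- res_sp[res_sp$element == e, ]
    sp_traits[[paste0("RE_", e)]] <-
      stats::setNames(d$RE_percent, d$species)[sp_traits$species]
    sp_traits[[paste0("RP_", e)]] <-
      stats::setNames(d$RP, d$species)[sp_traits$species]
  }
  ind_rows <- res_ind
  ind_traits <- NULL
  if (nrow(ind_rows)) {
    green <- samples[samples$status == "green", , drop = FALSE]
    key <- paste(green$species, green$individual)
    ft <- functional_traits(green$leaf_area, green$dry_mass,
                            green$saturated_mass)
    ind_sla <- stats::setNames(ft$SLA, key)
    ind_ldmc <- stats::setNames(ft$LDMC, key)
    units <- unique(ind_rows[, c("unit", "species")])
    ind_traits <- data.frame(unit = units$unit)
    ukey <- sub("/", " ", units$unit)
    ind_traits$SLA <- ind_sla[ukey]
    ind_traits$LDMC <- ind_ldmc[ukey]
    for (e in els) {
      d <- ind_rows[ind_rows$element == e, ]
      ind_traits[[paste0("RE_", e)]] <-
        stats::setNames(d$RE_percent, d$unit)[units$unit]
      ind_traits[[paste0("RP_", e)]] <-
        stats::setNames(d$RP, d$unit)[units$unit]
    }
  }
  pairs <- expand.grid(x = c("SLA", "LDMC"),
                       y = c(paste0("RE_", els), paste0("RP_", els)),
                       stringsAsFactors = FALSE)
  correlations <- correlation_table(pairs, sp_traits, ind_traits,
                                    tree = phylo_tree)

  ## variance partition per element (individual green leaves),
  ## once with plant group and once with family
  vp_rows <- list()
  green <- samples[samples$status == "green", , drop = FALSE]
  for (e in els) {
    for (alt in c("group", "family")) {
      fac <- lapply(stats::setNames(config$partition_order,
                                    config$partition_order), function(f) {
        green[[if (f == "group") alt else f]]
      })
      names(fac)[config$partition_order == "group"] <- alt
      vp <- suppressMessages(
        variance_partition(green[[e]], fac, allow_aliased = TRUE))
      vp_rows[[length(vp_rows) + 1L]] <- cbind(
        data.frame(element = e, grouping = alt), as.data.frame(vp))
    }
  }
  vpart <- do.call(rbind, vp_rows)

  tables <- list(species_summary = summ, resorption = resorption,
                 group_means = group_means, re_summary = re_summary,
                 signal = signal, correlations = correlations,
                 variance_partition = vpart)
  out <- structure(list(tables = tables, report = report, truth = truth,
                        tree = tree, samples = samples, config = config,
                        excluded_species = report$trait_only),
                   class = "pipeline_result")
  if (!is.null(config$outdir)) {
    write_results(tables, config$outdir, seed = config$seed,
                  config = unclass(config))
  }
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Resorption pipeline result\n")
  cat("  samples:", nrow(x$samples), " species:",
      length(unique(x$samples$species)), " seed:", x$config$seed, "\n")
  cat("  tables:", paste(names(x$tables), collapse = ", "), "\n")
  invisible(x)
}
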