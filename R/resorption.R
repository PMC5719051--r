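#' Mass loss correction factor (MLCF)
#'
#' Leaves lose dry mass during senescence, which inflates apparent
#' nutrient concentrations in senesced leaves and so biases resorption
#' efficiency downward.  The MLCF compensates: it is the ratio of
#' senesced to green leaf dry mass, typically <= 1.
#'
#' @param green_dry_mass,senesced_dry_mass Dry masses in g; both > 0.
#' @return senesced/green, a dimensionless ratio.
#' @export
#' @examples
#' mlcf(1.0, 0.8) # 0.8
mlcf <- function(green_dry_mass, senesced_dry_mass) {
  if (any(!is.finite(green_dry_mass)) || any(green_dry_mass <= 0) ||
      any(!is.finite(senesced_dry_mass)) || any(senesced_dry_mass <= 0)) {
    stop("leaf dry masses must be positive")
  }
  senesced_dry_mass / green_dry_mass
}

#' Mass-loss-corrected resorption efficiency (RE)
#'
#' Proportional withdrawal of a nutrient during leaf senescence,
#' corrected for dry-mass loss:
#' \deqn{RE = (1 - \frac{Nu_{senesced}}{Nu_{green}} \times MLCF) \times 100\%}
#' Negative values signal net accumulation during senescence (common for
#' Ca, Mg, and for Na in euhalophytes) and are not capped.  The
#' "uncorrected" RE is this formula with `mlcf = 1`.
#'
#' @param green_conc Green-leaf concentration, mg g^-1, > 0.
#' @param senesced_conc Senesced-leaf concentration, mg g^-1, >= 0.
#' @param mlcf Mass loss correction factor, > 0 (1 = uncorrected).
#' @return RE in percent (<= 100, unbounded below).
#' @export
#' @examples
#' resorption_efficiency(20, 10, 1)      # 50
#' resorption_efficiency(53.5, 70.2, 1)  # negative: Na accumulation
resorption_efficiency <- function(green_conc, senesced_conc, mlcf = 1) {
  if (any(!is.finite(green_conc)) || any(green_conc <= 0)) {
    stop("green concentration must be positive (RE undefined at 0)")
  }
  if (any(!is.finite(senesced_conc)) || any(senesced_conc < 0)) {
    stop("senesced concentration must be non-negative")
  }
  if (any(!is.finite(mlcf)) || any(mlcf <= 0)) stop("mlcf must be positive")
  (1 - senesced_conc / green_conc * mlcf) * 100
}

#' Resorption proficiency (RP)
#'
#' The terminal nutrient concentration in senesced leaves.  By
#' convention a LOWER senesced concentration means HIGHER proficiency
#' (the plant drew the pool down further); RP is reported on the
#' concentration scale, so comparisons must remember the inversion.
#'
#' @param senesced_conc Senesced-leaf concentration, mg g^-1, >= 0.
#' @return The senesced concentration (identity), mg g^-1.
#' @export
resorption_proficiency <- function(senesced_conc) {
  if (any(!is.finite(senesced_conc)) || any(senesced_conc < 0)) {
    stop("senesced concentration must be non-negative")
  }
  senesced_conc
}

#' Leaf functional traits from morphology and chemistry
#'
#' Computes, for a green leaf (or species-level means):
#' * SLA, specific leaf area = area / dry mass (cm^2 g^-1);
#' * LDMC, leaf dry matter content = dry mass / saturated mass
#'   (dimensionless, in (0, 1]);
#' * succulence = water mass / leaf area expressed in g m^-2; values
#'   above 500 g m^-2 flag a significantly succulent leaf;
#' * K/Na ratio of green-leaf concentrations (K/Na < 1 marks plants
#'   using Na as the major osmoticum; `NA` with a warning when Na = 0).
#'
#' @param leaf_area Leaf area, cm^2, > 0.
#' @param dry_mass,saturated_mass Leaf masses, g; 0 < dry <= saturated.
#' @param green_K,green_Na Green-leaf K and Na concentrations, mg g^-1.
#' @return List of class `"functional_traits"`: `SLA`, `LDMC`,
#'   `succulence`, `succulent` (logical), `K_Na_ratio`.
#' @export
#' @examples
#' functional_traits(100, 0.5, 1.0, green_K = 22.2, green_Na = 53.5)
functional_traits <- function(leaf_area, dry_mass, saturated_mass,
                              green_K = NA_real_, green_Na = NA_real_) {
  if (any(!is.finite(leaf_area)) || any(leaf_area <= 0)) {
    stop("leaf_area must be positive")
  }
  if (any(!is.finite(dry_mass)) || any(dry_mass <= 0) ||
      any(!is.finite(saturated_mass)) || any(dry_mass > saturated_mass)) {
    stop("need 0 < dry_mass <= saturated_mass")
  }
  succulence <- (saturated_mass - dry_mass) / (leaf_area * 1e-4) # g m^-2
  k_na <- rep(NA_real_, length(green_K))
  ok <- is.finite(green_K) & is.finite(green_Na) & green_Na > 0
  k_na[ok] <- green_K[ok] / green_Na[ok]
  if (any(is.finite(green_Na) & green_Na == 0)) {
    warning("green Na = 0: K/Na ratio undefined, returned as NA")
  }
  structure(list(
    SLA = leaf_area / dry_mass,
    LDMC = dry_mass / saturated_mass,
    succulence = succulence,
    succulent = succulence > 500,
    K_Na_ratio = k_na
  ), class = "functional_traits")
}

#' Per-species trait summaries from a leaf-sample table
#'
#' Aggregates a long-format leaf-sample table to one row per species:
#' mean green and senesced concentration per element, MLCF (ratio of
#' mean senesced to mean green dry mass), and the functional traits
#' SLA, LDMC, succulence and K/Na computed from green-leaf means.
#' Species means average all individuals of the species.
#'
#' @param samples Leaf-sample data.frame (see [trait_table_columns()]).
#' @return Data.frame, one row per species: `species`, `family`,
#'   `group`, `n_green`, `n_senesced`, `green_<El>`/`senesced_<El>`
#'   per element, `MLCF`, `SLA`, `LDMC`, `succulence`, `succulent`,
#'   `K_Na_ratio`, `NP_ratio`.
#' @export
species_summaries <- function(samples) {
  stopifnot(all(trait_table_columns() %in% names(samples)))
  els <- resorb_elements()
  sp <- sort(unique(samples$species))
  rows <- lapply(sp, function(s) {
    d <- samples[samples$species == s, , drop = FALSE]
    g <- d[d$status == "green", , drop = FALSE]
    sn <- d[d$status == "senesced", , drop = FALSE]
    gm <- colMeans(g[, els, drop = FALSE])
    sm <- if (nrow(sn)) colMeans(sn[, els, drop = FALSE])
          else stats::setNames(rep(NA_real_, length(els)), els)
    m <- if (nrow(g) && nrow(sn)) mlcf(mean(g$dry_mass), mean(sn$dry_mass))
         else NA_real_
    ft <- if (nrow(g)) {
      functional_traits(mean(g$leaf_area), mean(g$dry_mass),
                        mean(g$saturated_mass),
                        green_K = gm[["K"]], green_Na = gm[["Na"]])
    } else list(SLA = NA_real_, LDMC = NA_real_, succulence = NA_real_,
                succulent = NA, K_Na_ratio = NA_real_)
    out <- data.frame(species = s, family = d$family[1L],
                      group = d$group[1L],
                      n_green = nrow(g), n_senesced = nrow(sn))
    for (e in els) out[[paste0("green_", e)]] <- unname(gm[e])
    for (e in els) out[[paste0("senesced_", e)]] <- unname(sm[e])
    out$MLCF <- m
    out$SLA <- ft$SLA
    out$LDMC <- ft$LDMC
    out$succulence <- ft$succulence
    out$succulent <- ft$succulent
    out$K_Na_ratio <- ft$K_Na_ratio
    out$NP_ratio <- unname(gm["N"] / gm["P"])
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Resorption efficiency and proficiency table
#'
#' Computes RE (mass-loss corrected, and uncorrected with MLCF = 1) and
#' RP per element, either at the species level (from species-mean green
#' and senesced concentrations and the per-species MLCF; the default,
#' matching group summaries averaged over species means) or at the
#' individual level (per paired green/senesced individual, using the
#' species-level MLCF).
#'
#' The RE arithmetic does not distinguish resorption from secretion:
#' in salt-secreting species (Se) a drop in leaf Na may reflect
#' secretion through salt glands, so the (Se, Na) rows carry
#' `caveat = TRUE`.
#'
#' @param samples Leaf-sample data.frame.
#' @param level `"species"` (default) or `"individual"`.
#' @return Data.frame with columns `unit` (species or
#'   species/individual id), `species`, `group`, `element`,
#'   `RE_percent`, `RE_uncorrected`, `RP`, `MLCF`, `caveat`.
#' @export
resorption_table <- function(samples, level = c("species", "individual")) {
  level <- match.arg(level)
  els <- resorb_elements()
  summ <- species_summaries(samples)
  summ <- summ[summ$n_green > 0 & summ$n_senesced > 0, , drop = FALSE]
  rows <- list()
  if (level == "species") {
    for (i in seq_len(nrow(summ))) {
      for (e in els) {
        g <- summ[[paste0("green_", e)]][i]
        s <- summ[[paste0("senesced_", e)]][i]
        if (!is.finite(g) || g <= 0) next
        rows[[length(rows) + 1L]] <- data.frame(
          unit = summ$species[i], species = summ$species[i],
          group = summ$group[i], element = e,
          RE_percent = resorption_efficiency(g, s, summ$MLCF[i]),
          RE_uncorrected = resorption_efficiency(g, s, 1),
          RP = resorption_proficiency(s), MLCF = summ$MLCF[i])
      }
    }
  } else {
    ml <- stats::setNames(summ$MLCF, summ$species)
    for (s in summ$species) {
      d <- samples[samples$species == s, , drop = FALSE]
      ids <- intersect(unique(d$individual[d$status == "green"]),
                       unique(d$individual[d$status == "senesced"]))
      for (id in ids) {
        g <- d[d$status == "green" & d$individual == id, , drop = FALSE]
        sn <- d[d$status == "senesced" & d$individual == id, , drop = FALSE]
        gm <- colMeans(g[, els, drop = FALSE])
        sm <- colMeans(sn[, els, drop = FALSE])
        for (e in els) {
          if (!is.finite(gm[[e]]) || gm[[e]] <= 0) next
          rows[[length(rows) + 1L]] <- data.frame(
            unit = paste(s, id, sep = "/"), species = s,
            group = d$group[1L], element = e,
            RE_percent = resorption_efficiency(gm[[e]], sm[[e]], ml[[s]]),
            RE_uncorrected = resorption_efficiency(gm[[e]], sm[[e]], 1),
            RP = resorption_proficiency(sm[[e]]), MLCF = ml[[s]])
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$caveat <- out$group == "Se" & out$element == "Na"
  out
}
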