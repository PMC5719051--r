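# Shared fixtures and independent oracles.

# 3-tip worked tree used across the comparative-method tests
tree3 <- function() read_newick("((A:1,B:1):1,C:2);")

# Independent dense-matrix evaluation of Blomberg's K built on
# ape::vcv.phylo (not the package's own C construction).
brute_force_k <- function(tree, x) {
  x <- x[tree$tip.label]
  C <- ape::vcv.phylo(tree)
  n <- length(x)
  Ci <- solve(C)
  a <- sum(Ci %*% x) / sum(Ci)
  mse0 <- sum((x - a)^2) / (n - 1)
  mse <- drop(t(x - a) %*% Ci %*% (x - a)) / (n - 1)
  (mse0 / mse) / ((sum(diag(C)) - n / sum(Ci)) / (n - 1))
}

# A minimal valid leaf-sample data.frame (one green + one senesced row
# per species), for reader tests.
tiny_trait_df <- function() {
  df <- expand.grid(species = c("spA", "spB", "spC"),
                    status = c("green", "senesced"),
                    stringsAsFactors = FALSE)
  df$family <- "famX"
  df$group <- c("Eu", "Se", "Gl")[match(df$species, c("spA", "spB", "spC"))]
  df$site <- "S01"
  df$individual <- "i01"
  for (e in resorb_elements()) df[[e]] <- seq_len(nrow(df)) + 1
  df$leaf_area <- 10
  df$dry_mass <- 0.1
  df$saturated_mass <- 0.4
  df[, trait_table_columns()]
}

# Random non-degenerate tree for property tests.
random_tree <- function(n, seed) simulate_tree(n, seed)
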