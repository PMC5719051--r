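#' Phylogenetic variance-covariance matrix
#'
#' Under Brownian motion the expected covariance of a trait between two
#' tips is the branch length they share on the path from the root, so
#' `C[i, j]` is the depth of the most recent common ancestor of tips
#' `i` and `j`, and the diagonal holds the root-to-tip depths.
#'
#' @param tree A rooted `"phylo"` tree with branch lengths.
#' @return A symmetric positive semi-definite tips x tips matrix with
#'   tip labels as dimnames.
#' @export
#' @examples
#' vcv_matrix(read_newick("((A:1,B:1):1,C:2);"))
vcv_matrix <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  tree <- ape::reorder.phylo(tree, "postorder")
  n <- ape::Ntip(tree)
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  # accumulate each edge's length over the tip pairs that share it
  desc <- vector("list", n + tree$Nnode)
  desc[seq_len(n)] <- as.list(seq_len(n))
  e1 <- tree$edge[, 1L]; e2 <- tree$edge[, 2L]
  for (i in seq_along(e1)) {
    tips <- desc[[e2[i]]]
    C[tips, tips] <- C[tips, tips] + tree$edge.length[i]
    desc[[e1[i]]] <- c(desc[[e1[i]]], tips)
  }
  if (any(diag(C) <= 0)) {
    stop("tip(s) at zero depth: ",
         paste(tree$tip.label[diag(C) <= 0], collapse = ", "))
  }
  C
}

# Match a named trait vector to the tree's tips, erroring on gaps.
match_trait <- function(tree, trait, what = "trait") {
  if (is.null(names(trait))) {
    if (length(trait) != ape::Ntip(tree)) {
      stop(what, " must be named by species or have one value per tip")
    }
    names(trait) <- tree$tip.label
  }
  missing <- setdiff(tree$tip.label, names(trait))
  if (length(missing)) {
    stop(what, " missing for tip(s): ", paste(missing, collapse = ", "))
  }
  out <- as.numeric(trait[tree$tip.label])
  if (any(!is.finite(out))) stop(what, " contains non-finite values")
  names(out) <- tree$tip.label
  out
}

#' Blomberg's K statistic of phylogenetic signal
#'
#' K compares the observed ratio of trait variance (around the
#' GLS phylogenetic mean) to the GLS mean squared error with the ratio
#' expected under Brownian motion on the given tree:
#' \deqn{K = \frac{(MSE_0/MSE)_{obs}}{(MSE_0/MSE)_{exp}}}
#' with phylogenetic mean \eqn{\hat a = (1'C^{-1}x)/(1'C^{-1}1)},
#' \eqn{MSE_0 = \sum_i (x_i-\hat a)^2/(n-1)},
#' \eqn{MSE = (x-\hat a)'C^{-1}(x-\hat a)/(n-1)} and expected ratio
#' \eqn{[\mathrm{tr}(C) - n/(1'C^{-1}1)]/(n-1)}.  K = 1 is the
#' Brownian-motion expectation; K < 1 means less resemblance among
#' relatives than Brownian motion predicts, K > 1 more.
#'
#' @param tree A rooted `"phylo"` tree with branch lengths.
#' @param trait Numeric vector named by species (or ordered as the
#'   tips); must not be constant.
#' @return The K statistic (non-negative scalar).
#' @export
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' blomberg_k(tr, c(A = 1, B = 3, C = 2)) # 7/12
blomberg_k <- function(tree, trait) {
  x <- match_trait(tree, trait)
  n <- length(x)
  if (n < 3L) stop("need at least 3 tips to compute K")
  if (stats::var(x) == 0) stop("signal undefined for constant trait")
  C <- vcv_matrix(tree)
  Cinv <- tryCatch(solve(C), error = function(e) {
    stop("singular phylogenetic covariance matrix (identical tips or ",
         "zero-length structure): ", conditionMessage(e), call. = FALSE)
  })
  one_Cinv_one <- sum(Cinv)
  a_hat <- sum(Cinv %*% x) / one_Cinv_one
  d <- x - a_hat
  mse0 <- sum(d^2) / (n - 1)
  mse <- drop(crossprod(d, Cinv %*% d)) / (n - 1)
  expected <- (sum(diag(C)) - n / one_Cinv_one) / (n - 1)
  (mse0 / mse) / expected
}

# Precompute the traversal used by the contrast engine so the numeric
# pass (run once per permutation) is a single O(n) loop.
pic_prep <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (!ape::is.binary(tree)) {
    stop("contrasts require a binary tree; resolve polytomies first ",
         "(read_newick() does this)")
  }
  tree <- ape::reorder.phylo(tree, "postorder")
  n <- ape::Ntip(tree)
  e1 <- tree$edge[, 1L]
  node_order <- unique(e1)           # children always precede parents
  first <- match(node_order, e1)     # each internal node has exactly two
  second <- nrow(tree$edge) + 1L - match(node_order, rev(e1)) # child edges
  len_by_node <- numeric(n + tree$Nnode)  # branch above each node; root 0
  len_by_node[tree$edge[, 2L]] <- tree$edge.length
  list(tree = tree, n_tip = n, n_node = tree$Nnode,
       node_order = node_order,
       child1 = tree$edge[first, 2L], child2 = tree$edge[second, 2L],
       len_by_node = len_by_node,
       tip_labels = tree$tip.label)
}

# Felsenstein pruning: returns the n-1 standardized contrasts in
# post-order, plus the root's GLS value.  `x` ordered as tip labels.
pic_engine <- function(prep, x) {
  n <- prep$n_tip
  val <- c(x, numeric(prep$n_node))
  bl <- prep$len_by_node
  contrasts <- numeric(prep$n_node)
  node_order <- prep$node_order
  c1 <- prep$child1; c2 <- prep$child2
  for (k in seq_along(node_order)) {
    node <- node_order[k]
    i <- c1[k]; j <- c2[k]
    b1 <- bl[i]; b2 <- bl[j]
    bsum <- b1 + b2
    if (bsum == 0) stop("zero-length contrast denominator at node ", node)
    contrasts[k] <- (val[i] - val[j]) / sqrt(bsum)
    val[node] <- if (b1 == 0) val[i]
                 else if (b2 == 0) val[j]
                 else (val[i] / b1 + val[j] / b2) / (1 / b1 + 1 / b2)
    bl[node] <- bl[node] + b1 * b2 / bsum
  }
  list(contrasts = contrasts, root_value = val[n + 1L])
}

#' Phylogenetically independent contrasts
#'
#' Felsenstein's pruning algorithm: at each internal node with child
#' values v1, v2 on (adjusted) branches b1, b2 the standardized contrast
#' is (v1 - v2)/sqrt(b1 + b2), the node is assigned the weighted value
#' (v1/b1 + v2/b2)/(1/b1 + 1/b2), and its parent branch is lengthened by
#' b1 b2/(b1 + b2).  A tree with n tips yields n - 1 contrasts, returned
#' in post-order.
#'
#' @inheritParams blomberg_k
#' @return Numeric vector of n - 1 standardized contrasts (post-order),
#'   with the root's GLS value as attribute `root_value`.
#' @export
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' pic_contrasts(tr, c(A = 1, B = 3, C = 2)) # -sqrt(2), 0
pic_contrasts <- function(tree, trait) {
  prep <- pic_prep(tree)
  x <- match_trait(prep$tree, trait)
  out <- pic_engine(prep, as.numeric(x))
  structure(out$contrasts, root_value = out$root_value)
}

#' Permutation test of phylogenetic signal
#'
#' Tests whether a trait carries phylogenetic signal by comparing the
#' variance of its standardized independent contrasts (mean squared
#' contrast; low variance = related species resemble each other) to the
#' null distribution obtained by shuffling trait values across the tips.
#' The one-tailed p-value is `(1 + #[null variance <= observed]) /
#' (n_perm + 1)`, so it can never fall below `1/(n_perm + 1)`.
#' Blomberg's K is reported alongside.
#'
#' @inheritParams blomberg_k
#' @param n_perm Number of tip shuffles (default 999).
#' @param seed Optional integer seed for the shuffles; the caller's RNG
#'   state is left untouched.
#' @param trait_name Label carried into the result.
#' @return An object of class `"signal_result"`: list with `trait_name`,
#'   `K`, `p_value`, `obs_pic_variance`, `n_permutations`, `seed`,
#'   `n_species`.
#' @export
signal_test <- function(tree, trait, n_perm = 999, seed = NULL,
                        trait_name = deparse(substitute(trait))) {
  stopifnot(n_perm >= 1)
  prep <- pic_prep(tree)
  x <- match_trait(prep$tree, trait)[prep$tip_labels]
  if (stats::var(x) == 0) stop("signal undefined for constant trait")
  obs <- mean(pic_engine(prep, as.numeric(x))$contrasts^2)
  null_le <- with_seed_or_not(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      mean(pic_engine(prep, sample(as.numeric(x)))$contrasts^2)
    }, numeric(1)) <= obs)
  })
  structure(list(
    trait_name = trait_name,
    K = blomberg_k(tree, trait),
    p_value = (1 + null_le) / (n_perm + 1),
    obs_pic_variance = obs,
    n_permutations = as.integer(n_perm),
    seed = seed,
    n_species = prep$n_tip
  ), class = "signal_result")
}

#' @export
print.signal_result <- function(x, ...) {
  cat(sprintf(
    "Phylogenetic signal of '%s' (%d species): K = %.3f, P = %.4g (%d permutations)\n",
    x$trait_name, x$n_species, x$K, x$p_value, x$n_permutations))
  invisible(x)
}

#' Correlation of two traits through phylogenetically independent contrasts
#'
#' Computes contrasts for both traits on the same tree and correlates
#' them through the origin, r = sum(cx cy)/sqrt(sum(cx^2) sum(cy^2)),
#' as contrasts have arbitrary sign.  The p-value comes from
#' t = r sqrt((n-2)/(1-r^2)) on n - 2 degrees of freedom, with n the
#' number of contrasts (n_tips - 1).
#'
#' @inheritParams blomberg_k
#' @param x,y Numeric trait vectors named by species.
#' @return List with `r`, `p_value`, `n_contrasts`.  `r` is `NA` (with a
#'   warning) when either contrast set is all zero.
#' @export
pic_correlation <- function(tree, x, y) {
  prep <- pic_prep(tree)
  cx <- pic_engine(prep, as.numeric(match_trait(prep$tree, x, "x")[prep$tip_labels]))$contrasts
  cy <- pic_engine(prep, as.numeric(match_trait(prep$tree, y, "y")[prep$tip_labels]))$contrasts
  n <- length(cx)
  sxx <- sum(cx^2); syy <- sum(cy^2)
  if (sxx == 0 || syy == 0) {
    warning("all contrasts zero in one trait; PIC correlation undefined")
    return(list(r = NA_real_, p_value = NA_real_, n_contrasts = n))
  }
  r <- sum(cx * cy) / sqrt(sxx * syy)
  p <- if (abs(r) >= 1) 0 else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(r = r, p_value = p, n_contrasts = n)
}

#' Encode plant-group labels as a numeric trait
#'
#' Blomberg's K needs a numeric trait; group membership is coded either
#' as a single integer vector in the fixed order Eu=1, Se=2, Ps=3, Gl=4,
#' or as four 0/1 indicator traits (one per group).  The true coding
#' behind published group-level K values is rarely stated, so both modes
#' are provided.
#'
#' @param group_of Character vector of group labels named by species.
#' @param mode `"integer"` (default) or `"indicator"`.
#' @return Named numeric vector (`"integer"`), or a species x 4 matrix
#'   of 0/1 indicators (`"indicator"`).
#' @export
#' @examples
#' encode_group_trait(c(A = "Eu", B = "Gl")) # A = 1, B = 4
encode_group_trait <- function(group_of, mode = c("integer", "indicator")) {
  mode <- match.arg(mode)
  groups <- resorb_groups()
  bad <- setdiff(unique(group_of), groups)
  if (length(bad)) stop("unknown plant group label(s): ",
                        paste(bad, collapse = ", "))
  if (mode == "integer") {
    out <- as.numeric(match(group_of, groups))
    names(out) <- names(group_of)
    return(out)
  }
  m <- vapply(groups, function(g) as.numeric(group_of == g),
              numeric(length(group_of)))
  rownames(m) <- names(group_of)
  m
}
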