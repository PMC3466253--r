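# Fritz-Purvis D statistic: phylogenetic signal in a binary trait, scaled
# between a tip-shuffle null (D = 1) and a Brownian-threshold null (D = 0).

# Sum of sister-clade differences for one or many tip-state vectors.
# S: n_tips x m matrix (each column one dataset). Internal node values are
# unweighted means of child values, computed tips -> root; each internal
# node contributes sum_children |v(child) - v(node)|, which at a binary
# node equals |v(left) - v(right)|.
.sumd_engine <- function(tree, S) {
  n <- .ntip(tree)
  m <- ncol(S)
  V <- matrix(0, n + tree$Nnode, m)
  V[seq_len(n), ] <- S
  kids <- .children_list(tree)
  acc <- numeric(m)
  for (v in .postorder_internal(tree)) {
    ch <- kids[[v]]
    Vc <- V[ch, , drop = FALSE]
    nv <- colMeans(Vc)
    V[v, ] <- nv
    acc <- acc + colSums(abs(Vc - rep(nv, each = length(ch))))
  }
  acc
}

#' Sum of sister-clade differences for a binary trait
#'
#' The raw conservatism score underlying the D statistic: ancestral node
#' values are unweighted means of child values (tips to root), and the
#' score sums, over internal nodes, the absolute differences between each
#' child's value and the node's value. Identical sister states contribute
#' nothing; a clumped trait yields a small score, a dispersed trait a
#' large one.
#'
#' @param tree a `"phylo"` (polytomies allowed).
#' @param states named or tree-ordered vector of 0/1 tip states.
#' @return the score (a single non-negative number).
#' @examples
#' tr <- read_newick(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' sum_sister_differences(tr, c(A = 1, B = 1, C = 0, D = 0))  # 1
#' sum_sister_differences(tr, c(A = 1, B = 0, C = 1, D = 0))  # 2
#' @export
sum_sister_differences <- function(tree, states) {
  s <- .match_states(tree, states)
  .sumd_engine(tree, matrix(s, ncol = 1L))
}

.match_states <- function(tree, states) {
  if (!is.null(names(states))) {
    miss <- setdiff(tree$tip.label, names(states))
    if (length(miss)) stop("missing state for tips: ",
                           paste(utils::head(miss, 5L), collapse = ", "))
    states <- states[tree$tip.label]
  } else if (length(states) != .ntip(tree)) {
    stop("states must be named or have one entry per tip")
  }
  s <- as.numeric(states)
  if (any(is.na(s)) || !all(s %in% c(0, 1)))
    stop("states must be binary (0/1) with no missing values")
  s
}

# Brownian tip values: n_tips x m matrix of independent BM simulations
# (rate 1 on the given branch lengths).
.bm_tips <- function(tree, m) {
  n <- .ntip(tree)
  X <- matrix(0, n + tree$Nnode, m)
  par <- .parent_vec(tree)
  lens <- .edge_above(tree)
  root <- .root_node(tree)
  for (v in .preorder_nodes(tree)) if (v != root)   # parent value already set
    X[v, ] <- X[par[v], ] + stats::rnorm(m, sd = sqrt(lens[v]))
  X[seq_len(n), , drop = FALSE]
}

# threshold each column so exactly `k1` top-ranked values become state 1
.threshold_by_rank <- function(X, k1) {
  out <- matrix(0, nrow(X), ncol(X))
  idx <- apply(X, 2L, function(v) order(v, decreasing = TRUE)[seq_len(k1)])
  for (j in seq_len(ncol(X))) out[idx[, j], j] <- 1
  out
}

#' Phylogenetic signal in a binary trait (Fritz-Purvis D)
#'
#' Scales the observed sum of sister-clade differences between two nulls
#' conditioned on the observed prevalence: random shuffles of tip states
#' (expected D = 1) and a Brownian threshold model, i.e. Brownian motion
#' tip values cut by rank so the same number of tips carry state 1
#' (expected D = 0). D below 0 indicates strong conservatism, above 1
#' overdispersion.
#'
#' @param tree `"phylo"` with branch lengths (branch lengths enter only
#'   through the Brownian null).
#' @param states binary 0/1 tip states (named, or in tip order).
#' @param n_perm permutations/simulations per null (default 1000).
#' @param seed integer seed; given a seed the full result is reproducible.
#' @return a `signal_result` list: `sum_d_obs`, `mean_sum_d_random`,
#'   `mean_sum_d_brownian`, `D`, `p_random` (probability that the trait is
#'   no more clumped than a random shuffle: small means significant
#'   clumping), `p_brownian` (probability of a Brownian score at least as
#'   dispersed as observed), `n_permutations`, `prevalence` (count of
#'   state-1 tips), `n_tips`.
#' @export
d_statistic <- function(tree, states, n_perm = 1000L, seed = NULL) {
  s <- .match_states(tree, states)
  n <- .ntip(tree)
  k1 <- sum(s)
  if (k1 == 0L || k1 == n)
    stop("signal is undefined when all tips share one state")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  .with_seed(seed, {
    d_obs <- .sumd_engine(tree, matrix(s, ncol = 1L))
    Sr <- vapply(seq_len(n_perm), function(i) sample(s), numeric(n))
    d_rand <- .sumd_engine(tree, Sr)
    Sb <- .threshold_by_rank(.bm_tips(tree, n_perm), k1)
    d_brow <- .sumd_engine(tree, Sb)
    mr <- mean(d_rand)
    mb <- mean(d_brow)
    out <- list(
      sum_d_obs = d_obs,
      mean_sum_d_random = mr,
      mean_sum_d_brownian = mb,
      D = (d_obs - mb) / (mr - mb),
      p_random = (1 + sum(d_rand <= d_obs)) / (n_perm + 1),
      p_brownian = (1 + sum(d_brow >= d_obs)) / (n_perm + 1),
      n_permutations = as.integer(n_perm),
      prevalence = as.integer(k1),
      n_tips = as.integer(n)
    )
    class(out) <- "signal_result"
    out
  })
}

#' @export
print.signal_result <- function(x, ...) {
  cat(sprintf("Phylogenetic signal (binary trait), %d tips, prevalence %d\n",
              x$n_tips, x$prevalence))
  cat(sprintf("  D = %.4f  (sum d obs = %.3f; null means: shuffle %.3f, Brownian %.3f)\n",
              x$D, x$sum_d_obs, x$mean_sum_d_random, x$mean_sum_d_brownian))
  cat(sprintf("  P(no more clumped than random)   = %.4f\n", x$p_random))
  cat(sprintf("  P(Brownian at least as dispersed) = %.4f\n", x$p_brownian))
  invisible(x)
}

#' Calibration study of the D statistic on simulated trees
#'
#' Generates `n_datasets` independent pure-birth trees, simulates a binary
#' trait on each by the requested mechanism at the given prevalence, and
#' computes D. Under `mode = "random"` the expected mean D is 1; under
#' `mode = "brownian_threshold"` it is 0 — the two anchor points of the
#' D scale.
#'
#' @param n_datasets number of replicate tree+trait datasets (default 100).
#' @param n_tips tips per tree (default 200).
#' @param prevalence fraction of tips in state 1 (default 0.3).
#' @param mode trait-generating mechanism (see [sim_threat()]).
#' @param birth pure-birth rate for the simulated trees.
#' @param n_perm permutations per null within each D computation.
#' @param seed master seed; replicate i uses seeds derived as
#'   `seed + 3i`, `seed + 3i + 1`, `seed + 3i + 2`.
#' @return numeric vector of `n_datasets` D values.
#' @export
d_calibration <- function(n_datasets = 100L, n_tips = 200L,
                          prevalence = 0.3,
                          mode = c("random", "brownian_threshold"),
                          birth = 0.045, n_perm = 1000L, seed = 1L) {
  mode <- match.arg(mode)
  vapply(seq_len(n_datasets), function(i) {
    tr <- sim_yule_tree(n_tips, birth = birth, seed = seed + 3L * i)
    th <- sim_threat(tr, prevalence, mode, seed = seed + 3L * i + 1L)
    s <- stats::setNames(as.integer(th$status == "threatened"), th$species)
    d_statistic(tr, s, n_perm = n_perm, seed = seed + 3L * i + 2L)$D
  }, numeric(1))
}

#' D statistic across thinned-tree replicates
#'
#' Computes [d_statistic()] on each replicate tree (restricting states to
#' each replicate's tips) and reports the range of D, mirroring the use of
#' thinned trees to check robustness of signal to phylogenetic resolution.
#'
#' @param trees list of `"phylo"` (e.g. from [thin_replicates()]).
#' @param states named binary states covering all tips.
#' @param n_perm,seed as in [d_statistic()]; replicate r uses
#'   `seed + r - 1`.
#' @return data.frame with one row per replicate (`D`, `p_random`,
#'   `p_brownian`, `n_tips`, `prevalence`) and attribute `D_range`
#'   (`c(min, max)`).
#' @export
d_statistic_range <- function(trees, states, n_perm = 1000L, seed = 1L) {
  if (is.null(names(states))) stop("states must be named for replicate trees")
  rows <- lapply(seq_along(trees), function(r) {
    tr <- trees[[r]]
    res <- d_statistic(tr, states[tr$tip.label], n_perm = n_perm,
                       seed = seed + r - 1L)
    data.frame(replicate = r, D = res$D, p_random = res$p_random,
               p_brownian = res$p_brownian, n_tips = res$n_tips,
               prevalence = res$prevalence)
  })
  out <- do.call(rbind, rows)
  attr(out, "D_range") <- range(out$D)
  out
}
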