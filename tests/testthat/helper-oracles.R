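# Independent oracles and small fixtures used across tests. The oracles
# deliberately share no code with the package implementation.

# hand-built chain trees (ape's reader collapses unary nodes, so these are
# constructed directly): root -> ... -> single tip
chain_tree <- function(labels, lengths = rep(1, length(labels))) {
  # labels: root-to-deepest internal labels; one tip "t" below the last
  nn <- length(labels)
  edge <- cbind(1L + seq_len(nn), c(1L + seq_len(nn)[-1L], 1L))
  structure(list(edge = edge, tip.label = "t", Nnode = nn,
                 node.label = labels, edge.length = lengths),
            class = "phylo")
}

# brute-force Mk2 log-likelihood: sum over all internal-state assignments
mk2_brute <- function(tree, states, q) {
  par <- tree$edge[, 1]; chd <- tree$edge[, 2]; len <- tree$edge.length
  nn <- tree$Nnode
  P <- function(same, t) if (same) 0.5 + 0.5 * exp(-2 * q * t)
       else 0.5 - 0.5 * exp(-2 * q * t)
  tot <- 0
  for (code in 0:(2^nn - 1)) {
    val <- c(states, as.integer(intToBits(code))[seq_len(nn)])
    pr <- 0.5
    for (k in seq_along(par))
      pr <- pr * P(val[par[k]] == val[chd[k]], len[k])
    tot <- tot + pr
  }
  log(tot)
}

# O(n^2) patristic-distance oracles from the cophenetic matrix of ape
mpd_brute <- function(tree, tips) {
  D <- ape::cophenetic.phylo(tree)[tips, tips]
  s <- 0; k <- 0
  for (i in seq_along(tips)) for (j in seq_along(tips)) if (i < j) {
    s <- s + D[i, j]; k <- k + 1
  }
  s / k
}

mntd_brute <- function(tree, tips) {
  D <- ape::cophenetic.phylo(tree)[tips, tips]
  mean(vapply(seq_along(tips),
              function(i) min(D[i, -i]), numeric(1)))
}

# normal-equation OLS oracle
ols_brute <- function(X, y) solve(t(X) %*% X, t(X) %*% y)

# binary threat states named by tip, from a sim_threat table
states_of <- function(threat) {
  stats::setNames(as.integer(threat$status == "threatened"), threat$species)
}

# forward simulation of the symmetric 2-state Markov chain down a tree,
# independent of the pruning likelihood implementation
sim_mk2_states <- function(tree, q, seed) {
  phylorisk:::.with_seed(seed, {
    n <- ape::Ntip(tree)
    par <- phylorisk:::.parent_vec(tree)
    lens <- phylorisk:::.edge_above(tree)
    val <- integer(n + tree$Nnode)
    root <- phylorisk:::.root_node(tree)
    val[root] <- stats::rbinom(1, 1, 0.5)
    for (v in phylorisk:::.preorder_nodes(tree)) if (v != root) {
      pch <- 0.5 - 0.5 * exp(-2 * q * lens[v])
      val[v] <- if (stats::runif(1) < pch) 1L - val[par[v]] else val[par[v]]
    }
    val[seq_len(n)]
  })
}

# records table with given per-category counts (unique species names)
records_from_tallies <- function(tallies) {
  cats <- rep(names(tallies), tallies)
  n <- length(cats)
  species_records(sprintf("sp_%04d", seq_len(n)),
                  sprintf("gen%03d", seq_len(n)),
                  sprintf("fam%03d", (seq_len(n) - 1L) %% 50L + 1L),
                  cats)
}
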