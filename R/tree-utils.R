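# Internal helpers shared across modules. All trees are ape "phylo" objects;
# node indexing follows ape: tips 1..Ntip, root Ntip+1.

.ntip <- function(tree) length(tree$tip.label)

.root_node <- function(tree) .ntip(tree) + 1L

# children[[i]] = integer vector of child node ids (empty for tips)
.children_list <- function(tree) {
  n_all <- .ntip(tree) + tree$Nnode
  ch <- vector("list", n_all)
  for (i in seq_len(n_all)) ch[[i]] <- integer(0)
  e <- tree$edge
  for (k in seq_len(nrow(e))) ch[[e[k, 1L]]] <- c(ch[[e[k, 1L]]], e[k, 2L])
  ch
}

.parent_vec <- function(tree) {
  n_all <- .ntip(tree) + tree$Nnode
  p <- integer(n_all)
  p[tree$edge[, 2L]] <- tree$edge[, 1L]
  p
}

# all nodes in preorder (parents before children); handles singleton
# nodes, which ape's reorder machinery does not
.preorder_nodes <- function(tree, kids = .children_list(tree)) {
  out <- integer(length(kids))
  stack <- .root_node(tree)
  k <- 0L
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    k <- k + 1L
    out[k] <- v
    ch <- kids[[v]]
    if (length(ch)) stack <- c(stack, rev(ch))
  }
  out[seq_len(k)]
}

# length of the edge above each node (NA at the root)
.edge_above <- function(tree) {
  lens <- rep(NA_real_, .ntip(tree) + tree$Nnode)
  if (!is.null(tree$edge.length)) lens[tree$edge[, 2L]] <- tree$edge.length
  lens
}

# depth from root of every node, in branch-length units
.node_depths <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  lens <- .edge_above(tree)
  par <- .parent_vec(tree)
  d <- numeric(length(lens))
  for (v in .preorder_nodes(tree)) if (v != .root_node(tree))
    d[v] <- d[par[v]] + lens[v]
  d
}

# internal nodes in postorder (every child's subtree before its parent)
.postorder_internal <- function(tree, kids = .children_list(tree)) {
  pre <- .preorder_nodes(tree, kids)
  rev(pre[lengths(kids[pre]) > 0L])
}

.tree_depth <- function(tree) {
  d <- .node_depths(tree)
  max(d[seq_len(.ntip(tree))])
}

.is_ultrametric <- function(tree, rel_tol = 1e-6) {
  d <- .node_depths(tree)[seq_len(.ntip(tree))]
  (max(d) - min(d)) <= rel_tol * max(d)
}

.assert_ultrametric <- function(tree, rel_tol = 1e-6) {
  if (!.is_ultrametric(tree, rel_tol))
    stop("tree is not ultrametric (root-to-tip depths differ)")
  invisible(tree)
}

# node ages for an ultrametric tree: age = tree depth - depth
.node_ages <- function(tree) {
  d <- .node_depths(tree)
  max(d[seq_len(.ntip(tree))]) - d
}

# Run code with a temporarily seeded RNG, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Rebuild branch lengths from a vector of node ages (parent age - child age).
.lengths_from_ages <- function(tree, ages) {
  tree$edge.length <- ages[tree$edge[, 1L]] - ages[tree$edge[, 2L]]
  tree
}

# Underscore form used as canonical species key (Newick convention)
.canon_name <- function(x) gsub("[ \t]+", "_", trimws(x))
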