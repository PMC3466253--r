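# Taxonomy-based supertree assembly: graft unplaced species onto a
# labelled backbone, date nodes by even interpolation between anchors of
# known age, and extract maximally resolved "thinned" subtrees.

# -- internal mutable-tree representation -------------------------------
# kids: list of integer child vectors; labels: character per node id;
# lens: branch length above each node (NA at root). Built from a phylo,
# manipulated, and converted back.

.unpack_tree <- function(tree) {
  n <- .ntip(tree)
  nn <- tree$Nnode
  labels <- c(tree$tip.label,
              if (is.null(tree$node.label)) rep("", nn) else tree$node.label)
  kids <- .children_list(tree)
  lens <- rep(NA_real_, n + nn)
  if (!is.null(tree$edge.length)) lens[tree$edge[, 2L]] <- tree$edge.length
  list(kids = kids, labels = labels, lens = lens, root = .root_node(tree),
       has_lengths = !is.null(tree$edge.length))
}

.pack_tree <- function(st) {
  # iterative preorder from root
  ord <- integer(0)
  stack <- st$root
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    ord <- c(ord, v)
    ch <- st$kids[[v]]
    if (length(ch)) stack <- c(stack, rev(ch))
  }
  deg <- lengths(st$kids[ord])
  tips <- ord[deg == 0L]
  ints <- ord[deg > 0L]
  ntip <- length(tips)
  newid <- integer(length(st$kids))
  newid[tips] <- seq_len(ntip)
  newid[ints] <- ntip + seq_along(ints)
  nedge <- length(ord) - 1L
  edge <- matrix(0L, nedge, 2L)
  el <- numeric(nedge)
  k <- 0L
  for (v in ints) for (c in st$kids[[v]]) {
    k <- k + 1L
    edge[k, ] <- c(newid[v], newid[c])
    el[k] <- st$lens[c]
  }
  tr <- list(edge = edge, tip.label = st$labels[tips],
             Nnode = length(ints), node.label = st$labels[ints])
  if (st$has_lengths) tr$edge.length <- el
  class(tr) <- "phylo"
  tr
}

# prune to tip set `keep` (logical per node id), collapsing unary nodes
.prune_st <- function(st, keep) {
  rec <- function(v) {
    ch <- st$kids[[v]]
    if (!length(ch)) {
      if (keep[v]) return(v) else return(NA_integer_)
    }
    surv <- integer(0)
    for (c in ch) {
      r <- rec(c)
      if (!is.na(r)) surv <- c(surv, r)
    }
    if (length(surv) == 0L) return(NA_integer_)
    if (length(surv) == 1L) {
      # merge the unary node into its surviving child
      st$lens[surv] <<- st$lens[surv] + st$lens[v]
      if (!nzchar(st$labels[surv])) st$labels[surv] <<- st$labels[v]
      return(surv)
    }
    st$kids[[v]] <<- surv
    v
  }
  new_root <- rec(st$root)
  if (is.na(new_root)) stop("pruning removed every tip")
  st$lens[new_root] <- NA_real_
  st$root <- new_root
  st
}

#' Graft species onto a taxonomy-labelled backbone tree
#'
#' Phylomatic-style supertree assembly: each species already present as a
#' backbone tip is kept; any other species is attached as a new tip at the
#' minimally inclusive taxonomic node — a child of the node labelled with
#' its genus if one exists, else of the node labelled with its family.
#' Attachment extends (or creates) a polytomy; backbone structure below the
#' attachment point is untouched. Backbone tips not in the species list are
#' pruned, so the returned tree contains exactly the placed species.
#' Genus/family anchors may be internal node labels or backbone tips (a tip
#' anchor becomes an internal node when species attach to it). New edges
#' get length 0; lengths are meaningful only after dating with [bladj()].
#'
#' @param backbone a `"phylo"` with genus/family labels on internal nodes
#'   (or tips).
#' @param records species table from [species_records()] (columns `species`,
#'   `genus`, `family`).
#' @return list with `tree` (the grafted `"phylo"`) and `unplaced`
#'   (character vector of species with no matching genus or family anchor,
#'   reported rather than silently dropped).
#' @export
graft <- function(backbone, records) {
  st <- .unpack_tree(backbone)
  n0 <- length(st$kids)
  # anchor lookup: first labelled node wins; internal labels take precedence
  deg <- lengths(st$kids)
  anchor <- new.env(parent = emptyenv())
  for (v in c(which(deg > 0L), which(deg == 0L))) {
    lb <- st$labels[v]
    if (nzchar(lb) && !exists(lb, envir = anchor, inherits = FALSE))
      assign(lb, v, envir = anchor)
  }
  tip_set <- st$labels[deg == 0L]
  species <- .canon_name(records$species)
  unplaced <- character(0)
  for (i in seq_along(species)) {
    sp <- species[i]
    if (sp %in% tip_set) next
    at <- NULL
    for (key in c(records$genus[i], records$family[i])) {
      if (exists(key, envir = anchor, inherits = FALSE)) {
        at <- get(key, envir = anchor)
        break
      }
    }
    if (is.null(at)) {
      unplaced <- c(unplaced, sp)
      next
    }
    id <- length(st$kids) + 1L
    st$kids[[id]] <- integer(0)
    st$kids[[at]] <- c(st$kids[[at]], id)
    st$labels[id] <- sp
    st$lens[id] <- 0
  }
  placed <- setdiff(species, unplaced)
  keep <- lengths(st$kids) == 0L & st$labels %in% placed
  st <- .prune_st(st, keep)
  list(tree = .pack_tree(st), unplaced = unplaced)
}

#' Date a tree by even interpolation between nodes of known age (BLADJ)
#'
#' Assigns an age to every node: tips get age 0, labelled internal nodes
#' found in `ages` keep their ages exactly, and each undated node is placed
#' evenly on the path between its nearest dated ancestor and its nearest
#' dated descendant (fewest intervening edges; ties broken by the older
#' age). Nodes are processed root-to-tip so earlier interpolations anchor
#' later ones, which spaces runs of undated nodes evenly, and a lower-bound
#' guard re-anchors on the oldest dated descendant whenever the step-nearest
#' anchor would date a node below a deeper, older calibration. Branch
#' lengths are rebuilt as parent age minus child age, so the result is
#' ultrametric in millions of years.
#'
#' @param tree a rooted `"phylo"`; its root's label must appear in `ages`.
#' @param ages named numeric vector (label -> age in My), e.g. from
#'   [read_node_ages()].
#' @return dated ultrametric `"phylo"`; node ages retrievable via
#'   [tree_node_ages()].
#' @export
bladj <- function(tree, ages) {
  n <- .ntip(tree)
  nn <- tree$Nnode
  if (is.null(tree$node.label)) tree$node.label <- rep("", nn)
  kids <- .children_list(tree)
  par <- .parent_vec(tree)
  root <- .root_node(tree)
  lab <- c(rep("", n), tree$node.label)
  age <- rep(NA_real_, n + nn)
  age[seq_len(n)] <- 0
  dated <- logical(n + nn)
  dated[seq_len(n)] <- TRUE    # tips are anchors at age 0
  for (v in (n + 1L):(n + nn)) {
    if (nzchar(lab[v]) && lab[v] %in% names(ages)) {
      age[v] <- unname(ages[[lab[v]]])
      dated[v] <- TRUE
    }
  }
  if (!dated[root]) stop("root must be dated (label it and list it in ages)")
  # consistency: each dated node younger than its nearest dated ancestor
  for (v in which(dated & seq_len(n + nn) != root)) {
    u <- par[v]
    while (!dated[u] && u != root) u <- par[u]
    if (!dated[u]) u <- root
    if (dated[u] && age[u] <= age[v])
      stop("inconsistent node ages: '", if (v <= n) lab[v] else lab[v],
           "' (", age[v], " My) is not younger than its dated ancestor (",
           age[u], " My)")
  }
  # preorder over internal nodes (parents before children)
  pre <- rev(.postorder_internal(tree))
  for (v in pre) {
    if (dated[v]) next
    a1 <- age[par[v]]           # parent already aged (preorder)
    # BFS down for the nearest dated descendant (tie -> older age), and
    # track the oldest dated descendant overall for the monotonicity guard
    best_s <- NA_integer_; best_a <- NA_real_
    max_a <- -Inf; max_s <- NA_integer_
    frontier <- kids[[v]]; s <- 1L
    while (length(frontier)) {
      nxt <- integer(0)
      for (w in frontier) {
        if (dated[w]) {
          if (is.na(best_s)) { best_s <- s; best_a <- age[w] }
          else if (s == best_s && age[w] > best_a) best_a <- age[w]
          if (age[w] > max_a) { max_a <- age[w]; max_s <- s }
        } else nxt <- c(nxt, kids[[w]])
      }
      if (!is.na(best_s) && length(nxt) == 0L) break
      frontier <- nxt; s <- s + 1L
    }
    cand <- a1 - (a1 - best_a) / (best_s + 1)
    if (cand <= max_a)          # deeper but older anchor: re-anchor on it
      cand <- a1 - (a1 - max_a) / (max_s + 1)
    age[v] <- cand
    dated[v] <- TRUE
  }
  out <- .lengths_from_ages(tree, age)
  if (any(out$edge.length <= 0))
    stop("age interpolation produced a non-positive branch length")
  out
}

#' Node ages of an ultrametric tree
#'
#' @param tree ultrametric `"phylo"`.
#' @return numeric vector of ages (My) indexed by node id
#'   (tips `1..Ntip`, then internal nodes).
#' @export
tree_node_ages <- function(tree) {
  .assert_ultrametric(tree)
  .node_ages(tree)
}

# tip labels under node v
.tips_under <- function(kids, labels, v) {
  out <- character(0)
  stack <- v
  while (length(stack)) {
    w <- stack[length(stack)]
    stack <- stack[-length(stack)]
    ch <- kids[[w]]
    if (length(ch)) stack <- c(stack, ch) else out <- c(out, labels[w])
  }
  out
}

#' Extract a maximally resolved subtree by random polytomy pruning
#'
#' Produces a strictly bifurcating "thinned" tree: at every polytomy, two
#' child subtrees are retained uniformly at random and the others are
#' deleted outright (with their tips); the sweep repeats until no polytomy
#' remains. Unary nodes left by deletion are suppressed and their branch
#' lengths merged, so the thinned tree is a topological restriction of the
#' input. An already bifurcating tree is returned unchanged.
#'
#' @param tree a `"phylo"` with at least 2 tips.
#' @param seed integer seed for reproducible pruning (optional).
#' @return bifurcating `"phylo"`.
#' @export
thin <- function(tree, seed = NULL) .with_seed(seed, {
  if (.ntip(tree) < 2L) stop("tree needs at least 2 tips")
  repeat {
    kids <- .children_list(tree)
    labels <- c(tree$tip.label, rep("", tree$Nnode))
    poly <- which(lengths(kids) > 2L)
    if (!length(poly)) break
    drop <- character(0)
    for (v in poly) {
      ch <- kids[[v]]
      keep <- sample(ch, 2L)
      for (d in setdiff(ch, keep))
        drop <- c(drop, .tips_under(kids, labels, d))
    }
    tree <- ape::drop.tip(tree, unique(drop), trim.internal = TRUE,
                          collapse.singles = TRUE)
  }
  tree
})

#' Thinned-tree replicates
#'
#' Generates `n` independent thinned trees (see [thin()]) from one master
#' seed; replicate r uses seed `seed + r - 1`.
#'
#' @param tree a `"phylo"`.
#' @param n number of replicates (default 100).
#' @param seed integer master seed.
#' @return list of bifurcating `"phylo"` objects.
#' @export
thin_replicates <- function(tree, n = 100L, seed = 1L) {
  lapply(seq_len(n), function(r) thin(tree, seed = seed + r - 1L))
}
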