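test_that("species attach at genus nodes, extending polytomies", {
  bb <- read_newick(text = "((x1:1,x2:1)GenA:1,(x3:1,x4:1)GenB:1)Fam;")
  rec <- species_records(c("s1", "s2", "s3", "x3"),
                         c("GenA", "GenA", "GenA", "GenB"),
                         rep("Fam", 4), rep("VU", 4))
  g <- graft(bb, rec)
  expect_setequal(g$tree$tip.label, rec$species)
  expect_length(g$unplaced, 0)
  # the three new GenA species plus no retained backbone tip = 3-polytomy
  kids <- phylorisk:::.children_list(g$tree)
  lab <- c(g$tree$tip.label, g$tree$node.label)
  gen_a <- which(lab == "GenA")
  expect_length(kids[[gen_a]], 3)
})

test_that("genus-absent species fall back to the family node", {
  bb <- read_newick(text = "((x1:1,x2:1)GenA:1,(x3:1,x4:1)GenB:1)FamZ;")
  rec <- species_records(c("a1", "b1"), c("GenA", "GenQ"),
                         c("FamZ", "FamZ"), c("VU", "LC"))
  g <- graft(bb, rec)
  expect_setequal(g$tree$tip.label, c("a1", "b1"))
  # b1 hangs directly off the family root
  root_kids <- phylorisk:::.children_list(g$tree)[[
    phylorisk:::.root_node(g$tree)]]
  lab <- c(g$tree$tip.label, g$tree$node.label)
  expect_true("b1" %in% lab[root_kids])
})

test_that("species with no anchor are reported unplaced, not dropped", {
  bb <- read_newick(text = "((x1:1,x2:1)GenA:1,(x3:1,x4:1)GenB:1)FamZ;")
  rec <- species_records(c("a1", "lost1"), c("GenA", "GenNo"),
                         c("FamZ", "FamNo"), c("VU", "LC"))
  g <- graft(bb, rec)
  expect_equal(g$unplaced, "lost1")
  expect_setequal(g$tree$tip.label, "a1")
})

test_that("grafted tip set equals the placed species set exactly", {
  # 100 species over 10 genera / 4 families on a labelled backbone
  bb <- read_newick(text = paste0(
    "(((g01:1,g02:1,g03:1)famA:1,(g04:1,g05:1)famB:1):1,",
    "((g06:1,g07:1,g08:1)famC:1,(g09:1,g10:1)famD:1):1)root;"))
  set.seed(11)
  gen <- sprintf("g%02d", sample(1:10, 100, replace = TRUE))
  fam <- c(g01 = "famA", g02 = "famA", g03 = "famA", g04 = "famB",
           g05 = "famB", g06 = "famC", g07 = "famC", g08 = "famC",
           g09 = "famD", g10 = "famD")[gen]
  rec <- species_records(sprintf("sp%03d", 1:100), gen, unname(fam),
                         rep("LC", 100))
  g <- graft(bb, rec)
  expect_length(g$unplaced, 0)
  expect_setequal(g$tree$tip.label, rec$species)
  # attachment never rearranges backbone structure: family clades stay
  # monophyletic
  for (f in unique(fam)) {
    tips <- rec$species[fam == f]
    expect_true(ape::is.monophyletic(g$tree, tips))
  }
})

test_that("age interpolation spaces undated nodes evenly", {
  # root(10) -> X -> tip : X at 5
  expect_equal(tree_node_ages(bladj(chain_tree(c("R", "X")), c(R = 10))),
               c(0, 10, 5))
  # root(12) -> A -> B -> tip : A = 8, B = 4
  expect_equal(tree_node_ages(bladj(chain_tree(c("R", "A", "B")),
                                    c(R = 12))),
               c(0, 12, 8, 4))
})

test_that("fully dated trees pass through bladj unchanged", {
  tr <- read_newick(text = "((A:1,B:1)X:1,C:2)R;")
  out <- bladj(tr, c(R = 2, X = 1))
  expect_equal(out$edge.length, tr$edge.length, tolerance = 1e-12)
})

test_that("bladj output is ultrametric with strictly decreasing ages and
           exact anchor ages", {
  bb <- read_newick(text = paste0(
    "(((g01:1,g02:1,g03:1)famA:1,(g04:1,g05:1)famB:1)cladeAB:1,",
    "((g06:1,g07:1)famC:1,(g09:1,g10:1)famD:1)cladeCD:1)root;"))
  ages <- c(root = 140, cladeAB = 100, famA = 61.25, cladeCD = 90)
  out <- bladj(bb, ages)
  expect_true(ape::is.ultrametric(out, tol = 1e-8))
  a <- tree_node_ages(out)
  lab <- c(out$tip.label, out$node.label)
  for (nm in names(ages)) expect_identical(a[match(nm, lab)],
                                           unname(ages[[nm]]))
  par <- phylorisk:::.parent_vec(out)
  for (v in seq_along(par)) if (par[v] != 0)
    expect_gt(a[par[v]], a[v])
})

test_that("bladj rejects an undated root and inconsistent anchors", {
  expect_error(bladj(chain_tree(c("R", "X")), c(X = 5)), "root")
  bb <- read_newick(text = "((A:1,B:1)young:1,C:2)old;")
  expect_error(bladj(bb, c(old = 10, young = 20)), "inconsistent")
})

test_that("thinning forces strict bifurcation and restricts the topology", {
  star <- read_newick(text = "(A:1,B:1,C:1,D:1,E:1);")
  th <- thin(star, seed = 1)
  expect_equal(ape::Ntip(th), 2)

  bin <- sim_yule_tree(16, birth = 0.1, seed = 5)
  expect_equal(write_newick(thin(bin, seed = 3)), write_newick(bin))

  # grafted tree with many polytomies: binary output, induced subtree
  bb <- read_newick(text = paste0(
    "(((g01:1,g02:1,g03:1)famA:1,(g04:1,g05:1)famB:1):1,",
    "((g06:1,g07:1,g08:1)famC:1,(g09:1,g10:1)famD:1):1)root;"))
  set.seed(21)
  gen <- sprintf("g%02d", sample(1:10, 200, replace = TRUE))
  fam <- c(g01 = "famA", g02 = "famA", g03 = "famA", g04 = "famB",
           g05 = "famB", g06 = "famC", g07 = "famC", g08 = "famC",
           g09 = "famD", g10 = "famD")[gen]
  rec <- species_records(sprintf("sp%03d", 1:200), gen, unname(fam),
                         rep("LC", 200))
  big <- bladj(graft(bb, rec)$tree,
               c(root = 100, famA = 50, famB = 40, famC = 60, famD = 30))
  th2 <- thin(big, seed = 9)
  expect_true(ape::is.binary(th2))
  expect_true(all(th2$tip.label %in% big$tip.label))
  induced <- ape::keep.tip(big, th2$tip.label)
  expect_true(ape::all.equal.phylo(ape::multi2di(induced, random = FALSE),
                                   ape::multi2di(th2, random = FALSE),
                                   use.edge.length = FALSE) ||
              ape::all.equal.phylo(induced, th2, use.edge.length = FALSE))
})

test_that("tips retained at a polytomy are uniform over seeds", {
  star <- read_newick(text = "(A:1,B:1,C:1,D:1,E:1);")
  kept <- table(unlist(lapply(1:1000, function(s)
    thin(star, seed = s)$tip.label)))
  expect_length(kept, 5)
  expect_gt(stats::chisq.test(kept)$p.value, 0.01)
})
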