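test_that("Newick reading preserves structure and round-trips", {
  tr <- read_newick(text = "((A:1,B:1):1,C:2);")
  expect_s3_class(tr, "phylo")
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  d <- ape::node.depth.edgelength(tr)
  expect_equal(d[match("A", tr$tip.label)], 2)

  # lengths flagged missing on a bare topology
  tr2 <- read_newick(text = "(A,B);")
  expect_true(isTRUE(attr(tr2, "lengths_missing")))

  # round-trip on a simulated 50-tip tree: same bipartitions, same lengths
  sim <- sim_yule_tree(50, birth = 0.1, seed = 42)
  back <- read_newick(text = write_newick(sim))
  expect_true(ape::all.equal.phylo(sim, back, use.edge.length = FALSE))
  expect_equal(sort(back$edge.length), sort(sim$edge.length),
               tolerance = 1e-9)
  expect_identical(write_newick(back), write_newick(read_newick(
    text = write_newick(back))))
})

test_that("malformed or duplicated Newick input errors", {
  expect_error(read_newick(text = "((A,B);"))
  expect_error(read_newick(text = "((A:1,A:1):1,C:2);"), "duplicate")
})

test_that("IUCN categories normalize across spellings", {
  expect_equal(normalize_iucn(c("lc", "LR/cd", "LC-CD", "LR-CD", "vu", "Ex")),
               c("LC", "LR/CD", "LR/CD", "LR/CD", "VU", "EX"))
  expect_error(normalize_iucn("CRITICAL"), "unknown IUCN category")
})

test_that("binarization partitions EX+CR+EN+VU vs LR/CD+NT+LC vs DD", {
  # mixed 10-species toy list, hand tally: 4 threatened, 5 lower, 1 DD
  rec <- species_records(paste0("s", 1:10), paste0("g", 1:10),
                         rep(c("F1", "F2"), 5),
                         c("EX", "CR", "EN", "VU", "LC", "LC", "NT",
                           "LR/CD", "LC", "DD"))
  rt <- binarize_risk(rec)
  cnt <- attr(rt, "counts")
  expect_equal(unname(cnt[c("threatened", "not_threatened", "excluded")]),
               c(4, 5, 1))
  expect_equal(sum(cnt[c("threatened", "not_threatened", "excluded")]),
               nrow(rec))

  # all-LC input
  lc <- species_records(paste0("s", 1:5), paste0("g", 1:5), rep("F", 5),
                        rep("LC", 5))
  expect_equal(unname(attr(binarize_risk(lc), "counts")["threatened"]), 0)
})

test_that("partition sizes always sum to the input size", {
  set.seed(9)
  for (i in 1:20) {
    n <- sample(5:60, 1)
    rec <- species_records(sprintf("x%03d", 1:n), sprintf("g%03d", 1:n),
                           rep("F", n),
                           sample(iucn_categories, n, replace = TRUE))
    cnt <- attr(binarize_risk(rec), "counts")
    expect_equal(sum(cnt[c("threatened", "not_threatened", "excluded")]), n)
  }
})

test_that("species names join across underscore/whitespace forms", {
  rec <- species_records(c("Genus species", "Other_sp"), c("Genus", "Other"),
                         c("F", "F"), c("VU", "LC"))
  expect_equal(rec$species, c("Genus_species", "Other_sp"))
})

test_that("tables round-trip through their readers", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species,genus,family,category",
               "A_a,Aa,Fam1,VU", "B b,Bb,Fam2,lc"), tmp)
  rec <- read_species_table(tmp)
  expect_equal(rec$species, c("A_a", "B_b"))
  expect_equal(rec$category, c("VU", "LC"))

  tmp2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("label,age", "rosids,117", "asterids,107"), tmp2)
  ages <- read_node_ages(tmp2)
  expect_equal(ages[["rosids"]], 117)

  blocks <- sim_blocks(seed = 4)
  tmp3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(blocks, tmp3, row.names = FALSE)
  back <- read_block_table(tmp3)
  expect_equal(back$sr_threat, blocks$sr_threat)
  expect_equal(back$elev_range, back$elev_max - back$elev_min)
})

test_that("block-table invariants are enforced", {
  b <- as.data.frame(sim_blocks(seed = 4))
  b$elev_max[1] <- b$elev_min[1] - 10
  expect_error(read_block_table(b), "elev_max")
  b2 <- as.data.frame(sim_blocks(seed = 4))
  b2$sr_threat[2] <- -1
  expect_error(read_block_table(b2), "sr_threat")
})
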