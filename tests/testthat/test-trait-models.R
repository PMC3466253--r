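test_that("identity parameters reproduce input branch lengths exactly", {
  tr <- sim_yule_tree(40, birth = 0.1, seed = 201)
  T0 <- max(ape::node.depth.edgelength(tr))
  expect_equal(transform_delta(tr, 1)$edge.length, tr$edge.length,
               tolerance = 1e-9)
  expect_equal(transform_linear(tr, 1)$edge.length, tr$edge.length,
               tolerance = 1e-9)
  expect_equal(transform_two_rate(tr, 0.37 * T0, 1)$edge.length,
               tr$edge.length, tolerance = 1e-9)
})

test_that("transforms preserve total depth and match closed forms", {
  # delta = 2 on root -> X(depth 5) -> tip(depth 10): X moves to 2.5
  tr <- read_newick(text = "((A:5,B:5)X:5,C:10)R;")
  d2 <- ape::node.depth.edgelength(transform_delta(tr, 2))
  expect_equal(d2[5], 10 * 0.5^2)
  expect_equal(max(d2), 10)

  # linearChange end_rate 3: depth map d(1 + (e-1)d/2T); midpoint 5 -> 7.5
  # then rescaled by T/f(T) = 10/20, landing at 3.75
  dl <- ape::node.depth.edgelength(transform_linear(tr, 3))
  expect_equal(dl[5], (5 * (1 + 2 * 5 / 20)) * (10 / 20))
  expect_equal(max(dl), 10)

  # twoRate breakpoint T/2, end_rate 4: f(T) = 5 + 4*5 = 25 (mean rate 2.5
  # pre-rescale); node at the breakpoint maps to 5 * 10/25 = 2
  dt <- ape::node.depth.edgelength(transform_two_rate(tr, 5, 4))
  expect_equal(dt[5], 2)
  expect_equal(max(dt), 10)

  # large delta crushes internal depths toward the root (star-like)
  dbig <- ape::node.depth.edgelength(transform_delta(tr, 50))
  expect_lt(dbig[5], 1e-10)
})

test_that("transforms validate their inputs", {
  tr <- sim_yule_tree(10, birth = 0.1, seed = 211)
  T0 <- max(ape::node.depth.edgelength(tr))
  expect_error(transform_delta(tr, -1), "positive")
  expect_error(transform_two_rate(tr, 2 * T0, 1), "breakpoint")
  nonultra <- tr
  nonultra$edge.length[1] <- nonultra$edge.length[1] * 3
  expect_error(transform_delta(nonultra, 2), "ultrametric")
})

test_that("pruning likelihood equals exhaustive enumeration (<= 10 tips)", {
  set.seed(221)
  for (nt in c(4, 6, 8, 10)) {
    tr <- sim_yule_tree(nt, birth = 0.5, seed = 220 + nt)
    s <- sample(0:1, nt, replace = TRUE)
    q <- runif(1, 0.05, 1.5)
    expect_equal(mk2_loglik(tr, s, q), mk2_brute(tr, s, q),
                 tolerance = 1e-8)
  }
  # 2-tip closed case: (A:1,B:1), A=0,B=1
  tr2 <- read_newick(text = "(A:1,B:1);")
  q <- 0.5
  ps <- 0.5 + 0.5 * exp(-2 * q); pd <- 0.5 - 0.5 * exp(-2 * q)
  expect_equal(mk2_loglik(tr2, c(A = 0, B = 1), q),
               log(0.5 * ps * pd + 0.5 * pd * ps), tolerance = 1e-10)
})

test_that("pruning likelihood agrees with an independent Mk implementation", {
  tr <- sim_yule_tree(60, birth = 0.1, seed = 231)
  s <- states_of(sim_threat(tr, 0.4, "brownian_threshold", seed = 232))
  for (q in c(0.01, 0.1, 0.6)) {
    fm <- phytools::fitMk(tr, factor(s[tr$tip.label]), model = "ER",
                          fixedQ = matrix(c(-q, q, q, -q), 2),
                          pi = c(0.5, 0.5))
    expect_equal(mk2_loglik(tr, s, q), unname(fm$logLik), tolerance = 1e-6)
  }
})

test_that("likelihood limits behave: q -> 0 with identical tips gives ln 1/2", {
  tr <- sim_yule_tree(12, birth = 0.2, seed = 241)
  s <- rep(0, 12)
  expect_equal(mk2_loglik(tr, s, 1e-9), log(0.5), tolerance = 1e-6)
  # discordant states across zero-length branches: large negative, not NaN
  tr0 <- read_newick(text = "(A:0,B:0);")
  expect_true(is.finite(mk2_loglik(tr0, c(A = 0, B = 1), 0.5)))
  expect_lt(mk2_loglik(tr0, c(A = 0, B = 1), 0.5), -1e6)
})

test_that("nested models never beat their generalization in likelihood", {
  tr <- sim_yule_tree(80, birth = 0.045, seed = 251)
  s <- states_of(sim_threat(tr, 0.4, "brownian_threshold", seed = 252))
  fits <- fit_trait_models(tr, s)
  lnl <- stats::setNames(fits$lnl, fits$model)
  expect_lte(lnl["null"], lnl["delta"] + 1e-6)
  expect_lte(lnl["null"], lnl["linearChange"] + 1e-6)
  expect_lte(lnl["null"], lnl["twoRate"] + 1e-6)
  expect_equal(fits$AIC, -2 * fits$lnl + 2 * fits$k)
  expect_equal(sort(unique(fits$k)), 1:3)
})

test_that("constant-rate data is recovered as the null model", {
  # small parameter-recovery study; q = 0.02 on 120-tip trees
  ok <- 0; qhat <- numeric(0)
  for (i in 1:6) {
    tr <- sim_yule_tree(120, birth = 0.045, seed = 260 + i)
    s <- sim_mk2_states(tr, 0.02, seed = 270 + i)
    if (sum(s) %in% c(0, length(s))) next
    f <- suppressWarnings(fit_trait_models(tr, s))
    if (f$dAIC[f$model == "null"] <= 2) ok <- ok + 1
    qhat <- c(qhat, f$q[f$model == "null"])
  }
  expect_gte(ok, 4)
  expect_lt(abs(stats::median(qhat) - 0.02) / 0.02, 0.5)
})

test_that("tipward-concentrated change is recovered as delta > 1", {
  # few expected changes (qT ~ 0.6) so change depths remain informative
  hits <- 0
  for (i in 1:4) {
    tr <- sim_yule_tree(250, birth = 0.045, seed = 280 + i)
    warped <- transform_delta(tr, 5)
    s <- sim_mk2_states(warped, 0.005, seed = 290 + i)
    if (sum(s) %in% c(0, length(s))) next
    f <- suppressWarnings(fit_trait_models(tr, s))
    if (f$delta[f$model == "delta"] > 1) hits <- hits + 1
  }
  expect_gte(hits, 3)
})
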