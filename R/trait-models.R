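# Time-varying models of binary-trait evolution, encoded as branch-length
# transformations of an ultrametric tree, fitted with a symmetric 2-state
# Markov (Mk2) likelihood and compared by AIC.

# apply a monotone depth map f(d) to all node depths, rebuild edge lengths,
# and rescale so total depth is preserved
.transform_depths <- function(tree, f) {
  .assert_ultrametric(tree)
  d <- .node_depths(tree)
  T0 <- max(d[seq_len(.ntip(tree))])
  nd <- f(d)
  nd <- nd * (T0 / f(T0))
  tree$edge.length <- nd[tree$edge[, 2L]] - nd[tree$edge[, 1L]]
  tree
}

#' Delta transform: raise node depths to a power
#'
#' Replaces every node depth `d` (measured from the root of an ultrametric
#' tree of depth `T`) by `T * (d/T)^delta`. `delta = 1` is the identity
#' (Brownian-rate) tree; `delta > 1` concentrates change towards the tips,
#' `delta < 1` towards the root. Total depth is preserved.
#'
#' @param tree ultrametric `"phylo"`.
#' @param delta positive exponent.
#' @return transformed `"phylo"`.
#' @export
transform_delta <- function(tree, delta) {
  if (delta <= 0) stop("delta must be positive")
  T0 <- .tree_depth(tree)
  .transform_depths(tree, function(d) T0 * (d / T0)^delta)
}

#' Linear-change transform: evolutionary rate changes linearly in time
#'
#' The instantaneous rate at time `t` from the root is
#' `r(t) = 1 + (end_rate - 1) * t / T`; each branch gets the integral of
#' `r` over its time span, and the tree is rescaled to its original depth.
#' `end_rate = 1` is the identity; `end_rate > 1` accelerates evolution
#' towards the present.
#'
#' @param tree ultrametric `"phylo"`.
#' @param end_rate positive rate at the present relative to the root.
#' @return transformed `"phylo"`.
#' @export
transform_linear <- function(tree, end_rate) {
  if (end_rate <= 0) stop("end_rate must be positive")
  T0 <- .tree_depth(tree)
  .transform_depths(tree, function(d) d * (1 + (end_rate - 1) * d / (2 * T0)))
}

#' Two-rate transform: an abrupt rate shift at a breakpoint
#'
#' Rate 1 before time `breakpoint` (from the root), `end_rate` after;
#' branch lengths are the piecewise integral, rescaled to the original
#' depth. `end_rate = 1` is the identity for any breakpoint.
#'
#' @param tree ultrametric `"phylo"`.
#' @param breakpoint shift time, strictly inside `(0, tree depth)`.
#' @param end_rate positive post-shift rate.
#' @return transformed `"phylo"`.
#' @export
transform_two_rate <- function(tree, breakpoint, end_rate) {
  if (end_rate <= 0) stop("end_rate must be positive")
  T0 <- .tree_depth(tree)
  if (breakpoint <= 0 || breakpoint >= T0)
    stop("breakpoint must lie strictly within (0, tree depth)")
  .transform_depths(tree, function(d)
    ifelse(d < breakpoint, d, breakpoint + end_rate * (d - breakpoint)))
}

#' Mk2 log-likelihood of binary tip states
#'
#' Felsenstein pruning under the symmetric two-state Markov model with
#' transition rate `q` (per My): along a branch of length `t`,
#' `P(same) = 1/2 + exp(-2qt)/2` and `P(change) = 1/2 - exp(-2qt)/2`.
#' The root is weighted by equal state frequencies (1/2, 1/2). Partial
#' likelihoods are rescaled at each node, so the computation is stable on
#' large trees; an impossible configuration (e.g. discordant sister tips
#' on zero-length branches) yields a very large negative number rather
#' than `NaN`.
#'
#' @param tree `"phylo"` with branch lengths.
#' @param states binary 0/1 tip states (named, or in tip order).
#' @param q positive transition rate.
#' @return log-likelihood (scalar).
#' @export
mk2_loglik <- function(tree, states, q) {
  if (q <= 0) stop("q must be positive")
  s <- .match_states(tree, states)
  n <- .ntip(tree)
  kids <- .children_list(tree)
  lens <- rep(NA_real_, n + tree$Nnode)
  lens[tree$edge[, 2L]] <- tree$edge.length
  L <- matrix(0, n + tree$Nnode, 2L)
  L[cbind(seq_len(n), s + 1L)] <- 1
  logscale <- 0
  for (v in .postorder_internal(tree)) {
    l0 <- 1; l1 <- 1
    for (c in kids[[v]]) {
      e <- exp(-2 * q * lens[c])
      ps <- 0.5 + 0.5 * e
      pd <- 0.5 - 0.5 * e
      l0 <- l0 * (ps * L[c, 1L] + pd * L[c, 2L])
      l1 <- l1 * (pd * L[c, 1L] + ps * L[c, 2L])
    }
    m <- max(l0, l1)
    if (m <= 0) return(-1e10)
    L[v, ] <- c(l0, l1) / m
    logscale <- logscale + log(m)
  }
  root <- .root_node(tree)
  logscale + log(0.5 * L[root, 1L] + 0.5 * L[root, 2L])
}

#' Fit and compare four evolutionary models of a binary trait
#'
#' Maximizes the Mk2 likelihood over the transition rate `q` jointly with
#' the parameters of each branch-length transform: `null` (no transform,
#' k = 1 free parameter), `delta` (power on node depths, k = 2),
#' `linearChange` (linearly changing rate, k = 2) and `twoRate`
#' (rate shift at a breakpoint, k = 3). Optimization is bounded on log
#' scale with multiple starts; the breakpoint is searched on
#' (0.02 T, 0.98 T). Models are ranked by `AIC = -2 lnl + 2k`.
#'
#' @param tree ultrametric `"phylo"`.
#' @param states binary 0/1 tip states.
#' @param n_starts multi-start count per model (default 5).
#' @return a `trait_model_fits` data.frame sorted by AIC with columns
#'   `model`, `lnl`, `q`, `delta`, `end_rate`, `breakpoint`, `k`, `AIC`,
#'   `dAIC`, `converged`.
#' @export
fit_trait_models <- function(tree, states, n_starts = 5L) {
  s <- .match_states(tree, states)
  T0 <- .tree_depth(tree)
  lq_box <- log(c(1e-4, 1e4) / T0)      # expected changes per tree depth
  lt_box <- c(log(1e-3), log(1e3))                        # delta / end_rate
  bp_box <- c(0.02 * T0, 0.98 * T0)

  nll <- function(model, par) {
    tr <- switch(model,
      null = tree,
      delta = transform_delta(tree, exp(par[2L])),
      linearChange = transform_linear(tree, exp(par[2L])),
      twoRate = transform_two_rate(tree, .unlogit(par[3L], bp_box),
                                   exp(par[2L])))
    -mk2_loglik(tr, s, exp(par[1L]))
  }

  starts <- function(model) {
    lq0 <- seq(lq_box[1L] + 1, lq_box[2L] - 1, length.out = n_starts)
    switch(model,
      null = lapply(lq0, function(q) q),
      delta = ,
      linearChange = mapply(function(q, t) c(q, t), lq0,
                            seq(-2, 2, length.out = n_starts),
                            SIMPLIFY = FALSE),
      twoRate = mapply(function(q, t, b) c(q, t, b), lq0,
                       seq(-2, 2, length.out = n_starts),
                       seq(-1.5, 1.5, length.out = n_starts),
                       SIMPLIFY = FALSE))
  }

  fit_one <- function(model) {
    k_trans <- c(null = 0L, delta = 1L, linearChange = 1L, twoRate = 2L)[model]
    best <- NULL
    for (p0 in starts(model)) {
      res <- if (length(p0) == 1L) {
        o <- stats::optimize(function(x) nll(model, x), interval = lq_box,
                             tol = 1e-10)
        list(par = o$minimum, value = o$objective, convergence = 0L)
      } else {
        lower <- c(lq_box[1L], rep(lt_box[1L], k_trans))
        upper <- c(lq_box[2L], rep(lt_box[2L], k_trans))
        if (model == "twoRate") { lower[3L] <- -12; upper[3L] <- 12 }
        tryCatch(
          stats::optim(p0, function(x) nll(model, x), method = "L-BFGS-B",
                       lower = lower, upper = upper,
                       control = list(factr = 1e4, maxit = 500)),
          error = function(e) NULL)
      }
      if (is.null(res)) next
      if (is.null(best) || res$value < best$value - 1e-9) best <- res
    }
    if (is.null(best)) stop("optimizer failed for model ", model)
    par <- best$par
    data.frame(
      model = model, lnl = -best$value, q = exp(par[1L]),
      delta = if (model == "delta") exp(par[2L]) else NA_real_,
      end_rate = if (model %in% c("linearChange", "twoRate"))
        exp(par[2L]) else NA_real_,
      breakpoint = if (model == "twoRate") .unlogit(par[3L], bp_box)
        else NA_real_,
      k = 1L + k_trans, converged = best$convergence == 0L,
      stringsAsFactors = FALSE)
  }

  out <- do.call(rbind, lapply(c("null", "delta", "linearChange", "twoRate"),
                               fit_one))
  out$AIC <- -2 * out$lnl + 2 * out$k
  out <- out[order(out$AIC), ]
  out$dAIC <- out$AIC - min(out$AIC)
  rownames(out) <- NULL
  if (any(!out$converged))
    warning("optimizer did not report convergence for: ",
            paste(out$model[!out$converged], collapse = ", "))
  class(out) <- c("trait_model_fits", "data.frame")
  out
}

.unlogit <- function(x, box) box[1L] + (box[2L] - box[1L]) / (1 + exp(-x))

#' @export
print.trait_model_fits <- function(x, ...) {
  cat("Evolutionary models of binary threat status (ranked by AIC):\n")
  print.data.frame(x, row.names = FALSE, digits = 5)
  invisible(x)
}
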