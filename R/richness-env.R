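# Log-log regressions of threatened-species richness on elevation and
# climate across forest blocks, ranked by small-sample-corrected AIC.

#' Small-sample corrected AIC for an OLS fit
#'
#' `AICc = n log(RSS/n) + 2k + 2k(k+1)/(n - k - 1)` with `k` counting the
#' intercept, the slopes and the error variance. The additive constant
#' convention drops the `n log(2*pi) + n` term; only AICc differences
#' between models fitted to the same response are interpreted.
#'
#' @param fit an `lm` object.
#' @return AICc (scalar).
#' @export
aicc <- function(fit) {
  n <- length(stats::residuals(fit))
  k <- length(stats::coef(fit)) + 1L
  if (n <= k + 1L) stop("too few observations for finite AICc")
  rss <- sum(stats::residuals(fit)^2)
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Regress threatened-species richness on block environment
#'
#' Fits, by ordinary least squares on log-transformed variables, six
#' univariate models of `sr_threat` (on minimum, maximum and mean
#' elevation, temperature, rainfall, and elevation range) and six
#' bivariate models adding log block area as a covariate, and ranks all
#' twelve by [aicc()].
#'
#' @param blocks a block table from [read_block_table()].
#' @param log_base base for all log transforms (default natural log).
#' @param zero_response how to treat blocks with `sr_threat = 0`:
#'   `"error"` (default) or `"add1"` (uses `log(sr_threat + 1)`).
#' @return a `block_regressions` data.frame in long form (one row per
#'   coefficient): `model`, `type`, `predictor`, `slope`, `p_value`,
#'   `intercept`, `adj_r2`, `AICc`, `rank` (shared within a model, 1 =
#'   lowest AICc); attribute `fits` holds the underlying `lm` objects.
#' @export
fit_block_models <- function(blocks, log_base = exp(1),
                             zero_response = c("error", "add1")) {
  blocks <- read_block_table(blocks)
  zero_response <- match.arg(zero_response)
  if (nrow(blocks) < 6L) stop("need at least 6 blocks")
  y <- blocks$sr_threat
  if (any(y <= 0)) {
    if (zero_response == "error")
      stop("sr_threat has zeros; use zero_response = \"add1\" or drop blocks")
    y <- y + 1
  }
  vars <- c(elev_min = "Min elevation", elev_max = "Max elevation",
            elev_mean = "Mean elevation", mat = "Temperature",
            map = "Precipitation", elev_range = "Elevation range")
  for (v in c(names(vars), "area_km2")) {
    if (any(blocks[[v]] <= 0))
      stop("non-positive value in '", v, "' cannot be log-transformed")
  }
  lg <- function(x) log(x, base = log_base)
  dat <- data.frame(lsr = lg(y), larea = lg(blocks$area_km2))
  for (v in names(vars)) dat[[paste0("l_", v)]] <- lg(blocks[[v]])

  fits <- list()
  rows <- list()
  add_model <- function(id, type, terms, labels) {
    fml <- stats::reformulate(terms, response = "lsr")
    fit <- stats::lm(fml, data = dat)
    if (any(is.na(stats::coef(fit))))
      stop("collinear predictors in model '", id, "' (rank deficient)")
    sm <- summary(fit)
    co <- sm$coefficients
    fits[[id]] <<- fit
    rows[[id]] <<- data.frame(
      model = id, type = type, predictor = labels,
      slope = co[labels_idx(terms), 1L],
      p_value = co[labels_idx(terms), 4L],
      intercept = co[1L, 1L], adj_r2 = sm$adj.r.squared,
      AICc = aicc(fit), stringsAsFactors = FALSE)
  }
  labels_idx <- function(terms) seq_along(terms) + 1L
  for (v in names(vars))
    add_model(vars[[v]], "univariate", paste0("l_", v), vars[[v]])
  for (v in names(vars))
    add_model(paste("Area +", vars[[v]]), "bivariate",
              c("larea", paste0("l_", v)), c("Area", vars[[v]]))
  out <- do.call(rbind, rows)
  model_aicc <- vapply(split(out$AICc, out$model), `[`, numeric(1), 1L)
  rk <- rank(model_aicc, ties.method = "first")
  out$rank <- rk[out$model]
  out <- out[order(out$rank), ]
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  attr(out, "log_base") <- log_base
  class(out) <- c("block_regressions", "data.frame")
  out
}

#' @export
print.block_regressions <- function(x, ...) {
  cat("Threatened-richness regressions (log-log OLS, ranked by AICc):\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
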