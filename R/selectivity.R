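#' Family-level randomization test for taxonomic selectivity of threat
#'
#' For each family, the observed proportion of threatened species among its
#' assessed (non-DD) members is compared against a null in which the binary
#' threat labels are permuted across all species, keeping family sizes and
#' the total number of threatened species fixed. One-sided Monte-Carlo
#' p-values are reported in both directions with the add-one correction:
#' `p_high = (1 + #[null >= observed]) / (n_rand + 1)` (enrichment) and
#' `p_low` analogously (depletion), so no p-value is ever exactly 0.
#'
#' @param records species table (columns `species`, `family`, `category`),
#'   e.g. from [read_species_table()].
#' @param n_rand number of randomizations (default 1000).
#' @param seed integer seed for reproducible permutations.
#' @param alpha significance level for flagging (default 0.05, each tail).
#' @return a `family_selectivity` data.frame with one row per family:
#'   `family`, `n_assessed`, `n_threatened`, `proportion`, `p_high`,
#'   `p_low`, `enriched`, `depleted`; attributes `n_rand`,
#'   `n_families_no_risk` (families with no threatened species) and
#'   `mean_proportion`.
#' @export
family_selectivity <- function(records, n_rand = 1000L, seed = NULL,
                               alpha = 0.05) {
  if (n_rand < 1L) stop("n_rand must be at least 1")
  risk <- binarize_risk(records)
  keep <- risk$status != "excluded"
  fam <- factor(records$family[keep])
  y <- as.integer(risk$status[keep] == "threatened")
  if (any(tabulate(fam, nbins = nlevels(fam)) == 0L))
    stop("family with 0 assessed species")
  n <- length(y)
  n1 <- sum(y)
  nf <- nlevels(fam)
  fam_i <- as.integer(fam)
  size <- tabulate(fam_i, nbins = nf)
  obs <- vapply(seq_len(nf), function(f) sum(y[fam_i == f]), integer(1))
  ge <- integer(nf)   # null count >= observed, per family
  le <- integer(nf)
  .with_seed(seed, {
    for (r in seq_len(n_rand)) {
      idx <- sample.int(n, n1)
      cnt <- tabulate(fam_i[idx], nbins = nf)
      ge <- ge + (cnt >= obs)
      le <- le + (cnt <= obs)
    }
  })
  p_high <- (1 + ge) / (n_rand + 1)
  p_low <- (1 + le) / (n_rand + 1)
  out <- data.frame(family = levels(fam), n_assessed = size,
                    n_threatened = obs, proportion = obs / size,
                    p_high = p_high, p_low = p_low,
                    enriched = p_high < alpha, depleted = p_low < alpha,
                    stringsAsFactors = FALSE)
  attr(out, "n_rand") <- as.integer(n_rand)
  attr(out, "n_families_no_risk") <- sum(obs == 0L)
  attr(out, "mean_proportion") <- mean(obs / size)
  class(out) <- c("family_selectivity", "data.frame")
  out
}

#' @export
print.family_selectivity <- function(x, ...) {
  cat(sprintf(
    "Taxonomic selectivity: %d families, %d randomizations\n",
    nrow(x), attr(x, "n_rand")))
  cat(sprintf("  enriched (p_high < 0.05): %d; depleted (p_low < 0.05): %d; no at-risk species: %d\n",
              sum(x$enriched), sum(x$depleted),
              attr(x, "n_families_no_risk")))
  print.data.frame(utils::head(x[order(x$p_high), ], 10L), row.names = FALSE)
  invisible(x)
}
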