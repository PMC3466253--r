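# Community phylogenetic structure of species sets (IUCN categories):
# mean pairwise distance, mean nearest-taxon distance, and their
# standardized effect sizes NRI/NTI under a phylogeny-pool null.

.mpd_from_mat <- function(D, idx) {
  m <- D[idx, idx]
  mean(m[upper.tri(m)])
}

.mntd_from_mat <- function(D, idx) {
  m <- D[idx, idx]
  diag(m) <- Inf
  mean(apply(m, 1L, min))
}

#' Mean pairwise phylogenetic distance of a tip set
#'
#' Average patristic (branch-length) distance over all unordered pairs of
#' distinct tips in the set. Undefined for sets of fewer than two tips
#' (returns `NA`), matching the convention of leaving singleton categories
#' blank.
#'
#' @param tree `"phylo"` with branch lengths (in My on a dated tree).
#' @param tip_set character vector of tip labels.
#' @param dist optional precomputed cophenetic distance matrix.
#' @return mean pairwise distance, or `NA_real_` if `|tip_set| < 2`.
#' @export
mpd <- function(tree, tip_set, dist = NULL) {
  idx <- .check_tipset(tree, tip_set)
  if (length(idx) < 2L) return(NA_real_)
  if (is.null(dist)) dist <- ape::cophenetic.phylo(tree)
  .mpd_from_mat(dist, tip_set)
}

#' Mean nearest-taxon distance of a tip set
#'
#' Average, over set members, of the patristic distance to the nearest
#' other member; more sensitive than [mpd()] to structure near the tips.
#' Equals [mpd()] for two-tip sets; `NA` for singletons.
#'
#' @inheritParams mpd
#' @return mean nearest-taxon distance, or `NA_real_` if `|tip_set| < 2`.
#' @export
mntd <- function(tree, tip_set, dist = NULL) {
  idx <- .check_tipset(tree, tip_set)
  if (length(idx) < 2L) return(NA_real_)
  if (is.null(dist)) dist <- ape::cophenetic.phylo(tree)
  .mntd_from_mat(dist, tip_set)
}

.check_tipset <- function(tree, tip_set) {
  idx <- match(tip_set, tree$tip.label)
  if (anyNA(idx)) stop("tips not in tree: ",
                       paste(tip_set[is.na(idx)], collapse = ", "))
  if (anyDuplicated(tip_set)) stop("duplicate tips in set")
  idx
}

#' Net relatedness and nearest taxon indices under a phylogeny-pool null
#'
#' Standardized effect sizes of [mpd()] and [mntd()] for a tip set, against
#' null sets of the same size drawn uniformly without replacement from all
#' tips of the phylogeny ("phylogeny pool"). Sign convention:
#' `NRI = -(MPD_obs - mean_null) / sd_null` (and NTI likewise from MNTD),
#' so phylogenetically clustered sets score positive. The p-value is
#' one-tailed toward clustering, `(1 + #[null <= observed]) / (n_null + 1)`;
#' the overdispersion tail is `1 - p + 1/(n_null + 1)`.
#'
#' @param tree dated `"phylo"`.
#' @param tip_set character vector of tip labels (>= 2 for defined indices).
#' @param n_null number of null draws (default 1000).
#' @param seed integer seed.
#' @param dist optional precomputed cophenetic matrix (reused across calls).
#' @param label optional category label carried into the result.
#' @return a `community_result` one-row data.frame: `category`, `SR`,
#'   `mpd_obs`, `mntd_obs`, `NRI`, `NTI`, `p_NRI`, `p_NTI`, `n_null`.
#'   For `SR < 2` the metric columns are `NA`.
#' @export
nri_nti <- function(tree, tip_set, n_null = 1000L, seed = NULL, dist = NULL,
                    label = NA_character_) {
  if (n_null < 2L) stop("n_null must be at least 2")
  sr <- length(tip_set)
  if (sr < 2L)
    return(.comm_row(label, sr, NA, NA, NA, NA, NA, NA, n_null))
  .check_tipset(tree, tip_set)
  if (is.null(dist)) dist <- ape::cophenetic.phylo(tree)
  mpd_obs <- .mpd_from_mat(dist, tip_set)
  mntd_obs <- .mntd_from_mat(dist, tip_set)
  n <- .ntip(tree)
  .with_seed(seed, {
    null_mpd <- numeric(n_null)
    null_mntd <- numeric(n_null)
    for (r in seq_len(n_null)) {
      idx <- sample.int(n, sr)
      null_mpd[r] <- .mpd_from_mat(dist, idx)
      null_mntd[r] <- .mntd_from_mat(dist, idx)
    }
    nri <- -(mpd_obs - mean(null_mpd)) / stats::sd(null_mpd)
    nti <- -(mntd_obs - mean(null_mntd)) / stats::sd(null_mntd)
    p_nri <- (1 + sum(null_mpd <= mpd_obs)) / (n_null + 1)
    p_nti <- (1 + sum(null_mntd <= mntd_obs)) / (n_null + 1)
    .comm_row(label, sr, mpd_obs, mntd_obs, nri, nti, p_nri, p_nti, n_null)
  })
}

.comm_row <- function(label, sr, mpd_obs, mntd_obs, nri, nti, p_nri, p_nti,
                      n_null) {
  out <- data.frame(category = label, SR = as.integer(sr),
                    mpd_obs = as.numeric(mpd_obs),
                    mntd_obs = as.numeric(mntd_obs),
                    NRI = as.numeric(nri), NTI = as.numeric(nti),
                    p_NRI = as.numeric(p_nri), p_NTI = as.numeric(p_nti),
                    n_null = as.integer(n_null), stringsAsFactors = FALSE)
  class(out) <- c("community_result", "data.frame")
  out
}

#' Per-category community phylogenetic structure
#'
#' Runs [nri_nti()] for the species set of each IUCN category present in
#' the records (categories with fewer than two species get an `NA` row,
#' mirroring tables that leave singleton categories blank).
#'
#' @param tree dated `"phylo"` whose tips are species.
#' @param records species table with `species` and `category` columns.
#' @param categories categories to test (default: the higher threat
#'   classes VU, EN, CR).
#' @param n_null,seed as in [nri_nti()]; category i uses `seed + i - 1`.
#' @return `community_result` data.frame, one row per category.
#' @export
community_structure <- function(tree, records,
                                categories = c("VU", "EN", "CR"),
                                n_null = 1000L, seed = NULL) {
  cat_norm <- normalize_iucn(records$category)
  sp <- .canon_name(records$species)
  dist <- ape::cophenetic.phylo(tree)
  rows <- lapply(seq_along(categories), function(i) {
    cc <- categories[i]
    set <- intersect(sp[cat_norm == cc], tree$tip.label)
    nri_nti(tree, set, n_null = n_null,
            seed = if (is.null(seed)) NULL else seed + i - 1L,
            dist = dist, label = cc)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("community_result", "data.frame")
  out
}
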