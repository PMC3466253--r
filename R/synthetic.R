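# Seeded generators emulating the structure of the study inputs: a dated
# species tree, an IUCN-annotated species list with family structure and
# tunable phylogenetic clustering of threat, and a forest-block table with
# a known log-log elevation-range effect on threatened richness.

#' Default simulation settings
#'
#' Bundles the knobs shared by the generators. Defaults emulate a
#' red-listed national flora: 581 species, prevalence 298/581 threatened
#' among all listed species, 78 families, and category proportions
#' matching the national tallies (238 LC, 2 LR/CD, 31 NT among the lower
#' risk classes; 209 VU, 70 EN, 18 CR, 1 EX among the threatened). The
#' pure-birth rate 0.045 per My gives ~140 My root ages at this richness,
#' an angiosperm-scale timescale. Block-model coefficients
#' (`intercept = -8`, `slope = 1.6`, `noise_sd = 0.4` on the natural-log
#' scale) encode a strong elevation-range effect on threatened richness.
#'
#' @param n_tips number of species.
#' @param birth pure-birth speciation rate (per My).
#' @param prevalence fraction of species threatened.
#' @param signal_mode one of `"random"`, `"brownian_threshold"`,
#'   `"clade_conserved"`.
#' @param n_families number of (monophyletic) families.
#' @param enrichment threat odds multiplier for enriched families.
#' @param block_intercept,block_slope,block_noise_sd log-scale
#'   coefficients of the threatened-richness block model.
#' @param seed integer seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_tips = 581L, birth = 0.045,
                       prevalence = 298 / 581,
                       signal_mode = c("random", "brownian_threshold",
                                       "clade_conserved"),
                       n_families = 78L, enrichment = 1,
                       block_intercept = -8, block_slope = 1.6,
                       block_noise_sd = 0.4, seed = 1L) {
  stopifnot(n_tips >= 4L, prevalence > 0, prevalence < 1, enrichment >= 1)
  structure(list(n_tips = as.integer(n_tips), birth = birth,
                 prevalence = prevalence,
                 signal_mode = match.arg(signal_mode),
                 n_families = as.integer(n_families),
                 enrichment = enrichment,
                 block_intercept = block_intercept,
                 block_slope = block_slope,
                 block_noise_sd = block_noise_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate an ultrametric pure-birth (Yule) tree
#'
#' Starts from two lineages, waits exponential times with total rate
#' `birth * k` (k = current lineage count), splits a uniformly chosen
#' lineage, and stops when `n_tips` lineages exist, extending all tips by
#' one further exponential waiting time so the final interval is not
#' truncated. Deterministic given the seed.
#'
#' @param n_tips number of tips (>= 2).
#' @param birth speciation rate (per My).
#' @param seed integer seed.
#' @return ultrametric `"phylo"` with tips `sp0001`, `sp0002`, ...
#' @export
sim_yule_tree <- function(n_tips = 200L, birth = 0.045, seed = NULL) {
  if (n_tips < 2L) stop("n_tips must be at least 2")
  .with_seed(seed, {
    # node records: parent id, birth time; id 1 is the root
    max_nodes <- 2L * n_tips
    parent <- integer(max_nodes)
    t_start <- numeric(max_nodes)
    t_end <- numeric(max_nodes)
    parent[2:3] <- 1L
    n_nodes <- 3L
    active <- c(2L, 3L)
    t <- 0
    while (length(active) < n_tips) {
      t <- t + stats::rexp(1L, rate = birth * length(active))
      i <- active[sample.int(length(active), 1L)]
      t_end[i] <- t
      c1 <- n_nodes + 1L; c2 <- n_nodes + 2L
      parent[c(c1, c2)] <- i
      t_start[c(c1, c2)] <- t
      n_nodes <- n_nodes + 2L
      active <- c(setdiff(active, i), c1, c2)
    }
    t <- t + stats::rexp(1L, rate = birth * n_tips)
    t_end[active] <- t
    # assemble the phylo object: tips first, root next, internals after
    ids <- seq_len(n_nodes)
    is_tip <- ids %in% active
    newid <- integer(n_nodes)
    newid[is_tip] <- seq_len(n_tips)
    newid[!is_tip] <- n_tips + seq_len(sum(!is_tip))  # id 1 (root) first
    edge <- cbind(newid[parent[ids[-1L]]], newid[ids[-1L]])
    len <- t_end[ids[-1L]] - t_start[ids[-1L]]
    tr <- list(edge = edge, edge.length = len,
               tip.label = sprintf("sp%04d", seq_len(n_tips)),
               Nnode = n_tips - 1L)
    class(tr) <- "phylo"
    ape::reorder.phylo(tr, "cladewise")
  })
}

# national category tallies used as default subdivision weights
.cat_weights_threatened <- c(VU = 209, EN = 70, CR = 18, EX = 1)
.cat_weights_lower <- c(LC = 238, NT = 31, `LR/CD` = 2)

#' Simulate binary threat status (and full IUCN categories) on a tree
#'
#' Assigns `round(prevalence * n_tips)` tips state "threatened" by one of
#' three mechanisms: `random` (a uniform random tip subset, no signal),
#' `brownian_threshold` (tips with the top-ranked values of a Brownian
#' motion character, Brownian-level signal) or `clade_conserved` (all tips
#' of the clade whose size is closest to the target, extreme signal; ties
#' broken by preorder). Threatened tips are then subdivided into
#' VU/EN/CR/EX and the rest into LC/NT/LR-CD, by default in the national
#' tally proportions.
#'
#' @param tree `"phylo"` (needs branch lengths for `brownian_threshold`).
#' @param prevalence fraction of tips threatened.
#' @param mode signal mechanism (see above).
#' @param seed integer seed.
#' @param dd_n number of additional tips relabelled Data Deficient,
#'   drawn from either class (default 0).
#' @return data.frame with `species`, `category`, `status`
#'   (`"threatened"`/`"not_threatened"`/`"excluded"`).
#' @export
sim_threat <- function(tree, prevalence = 0.3,
                       mode = c("random", "brownian_threshold",
                                "clade_conserved"),
                       seed = NULL, dd_n = 0L) {
  mode <- match.arg(mode)
  n <- .ntip(tree)
  n1 <- round(prevalence * n)
  if (n1 < 1L || n1 >= n)
    stop("prevalence rounds to 0 or all tips at n_tips = ", n)
  .with_seed(seed, {
    threat_idx <- switch(mode,
      random = sample.int(n, n1),
      brownian_threshold = order(.bm_tips(tree, 1L)[, 1L],
                                 decreasing = TRUE)[seq_len(n1)],
      clade_conserved = .closest_clade(tree, n1))
    status <- rep("not_threatened", n)
    status[threat_idx] <- "threatened"
    category <- character(n)
    thr <- which(status == "threatened")
    low <- which(status == "not_threatened")
    category[thr] <- sample(names(.cat_weights_threatened), length(thr),
                            replace = TRUE,
                            prob = .cat_weights_threatened)
    category[low] <- sample(names(.cat_weights_lower), length(low),
                            replace = TRUE, prob = .cat_weights_lower)
    if (dd_n > 0L) {
      dd <- sample.int(n, dd_n)
      category[dd] <- "DD"
      status[dd] <- "excluded"
    }
    data.frame(species = tree$tip.label, category = category,
               status = status, stringsAsFactors = FALSE)
  })
}

# tips of the clade whose size is closest to k (ties: first in preorder)
.closest_clade <- function(tree, k) {
  kids <- .children_list(tree)
  labels <- c(tree$tip.label, rep("", tree$Nnode))
  n <- .ntip(tree)
  sizes <- integer(n + tree$Nnode)
  sizes[seq_len(n)] <- 1L
  for (v in .postorder_internal(tree)) sizes[v] <- sum(sizes[kids[[v]]])
  pre <- c(rev(.postorder_internal(tree)), seq_len(n))  # internals, then tips
  best <- pre[which.min(abs(sizes[pre] - k))]
  match(.tips_under(kids, labels, best), tree$tip.label)
}

#' Assign a monophyletic taxonomy (families, nested genera) to a tree
#'
#' Splits the tree into `n_families` monophyletic groups by repeatedly
#' replacing the largest current clade with its child clades (exact on
#' bifurcating trees), then nests genera within each family the same way,
#' targeting a mean genus size of `genus_size`. Family f is named
#' `famF01...`; genera `genF01g1...`.
#'
#' @param tree bifurcating `"phylo"`.
#' @param n_families number of families (at most `n_tips / 2`).
#' @param genus_size target mean number of species per genus (default 3).
#' @return data.frame `species`, `genus`, `family` in tip order.
#' @export
sim_taxonomy <- function(tree, n_families = 10L, genus_size = 3) {
  n <- .ntip(tree)
  if (n_families > n %/% 2L) stop("n_families must be at most n_tips / 2")
  kids <- .children_list(tree)
  labels <- c(tree$tip.label, rep("", tree$Nnode))
  sizes <- integer(n + tree$Nnode)
  sizes[seq_len(n)] <- 1L
  for (v in .postorder_internal(tree)) sizes[v] <- sum(sizes[kids[[v]]])
  split_into <- function(root_ids, target) {
    groups <- root_ids
    while (length(groups) < target) {
      big <- groups[which.max(sizes[groups])]
      if (!length(kids[[big]])) break      # largest group is a single tip
      groups <- c(setdiff(groups, big), kids[[big]])
    }
    groups
  }
  fams <- split_into(.root_node(tree), n_families)
  out <- data.frame(species = tree$tip.label,
                    genus = NA_character_, family = NA_character_,
                    stringsAsFactors = FALSE)
  for (f in seq_along(fams)) {
    fam_name <- sprintf("fam%02d", f)
    n_gen <- max(1L, round(sizes[fams[f]] / genus_size))
    gens <- split_into(fams[f], n_gen)
    for (g in seq_along(gens)) {
      tips <- .tips_under(kids, labels, gens[g])
      i <- match(tips, out$species)
      out$family[i] <- fam_name
      out$genus[i] <- sprintf("%sg%02d", fam_name, g)
    }
  }
  out
}

#' Simulate label-based threat with family enrichment
#'
#' Draws binary threat labels independently of the phylogeny, with the
#' odds of being threatened multiplied by `enrichment` in the selected
#' families — the generating model for taxonomic-selectivity power and
#' calibration checks (`enrichment = 1` gives family-independent labels).
#'
#' @param taxonomy data.frame with `species` and `family` (e.g. from
#'   [sim_taxonomy()]).
#' @param prevalence baseline probability of being threatened.
#' @param enrichment odds multiplier (>= 1).
#' @param enriched_families family names to enrich (default: none).
#' @param seed integer seed.
#' @return data.frame `species`, `genus` (if present), `family`,
#'   `category` (`"VU"` for threatened, `"LC"` otherwise).
#' @export
sim_enriched_risk <- function(taxonomy, prevalence = 0.3, enrichment = 1,
                              enriched_families = character(0),
                              seed = NULL) {
  odds <- prevalence / (1 - prevalence)
  odds <- ifelse(taxonomy$family %in% enriched_families,
                 odds * enrichment, odds)
  p <- odds / (1 + odds)
  .with_seed(seed, {
    y <- stats::rbinom(nrow(taxonomy), 1L, p)
    taxonomy$category <- ifelse(y == 1L, "VU", "LC")
    taxonomy
  })
}

#' Simulate a forest-block environment table
#'
#' Generates `n_blocks` blocks with log-normal areas, uniform minimum
#' elevations and elevation ranges, temperature decreasing with mean
#' elevation at a 6.5 degC/km lapse rate, random rainfall, and threatened
#' richness generated from the log-log model
#' `SR_threat = round(exp(intercept + slope * log(elev_range) + noise))`,
#' truncated at 0.
#'
#' @param n_blocks number of blocks (default 13).
#' @param intercept,slope,noise_sd coefficients of the richness model
#'   (natural-log scale).
#' @param seed integer seed.
#' @return a `block_table` (see [read_block_table()]).
#' @export
sim_blocks <- function(n_blocks = 13L, intercept = -8, slope = 1.6,
                       noise_sd = 0.4, seed = NULL) {
  .with_seed(seed, {
    area <- stats::rlnorm(n_blocks, meanlog = log(300), sdlog = 1)
    elev_min <- stats::runif(n_blocks, 100, 800)
    rng <- stats::runif(n_blocks, 300, 2000)
    elev_max <- elev_min + rng
    elev_mean <- (elev_min + elev_max) / 2
    mat <- 28 - 6.5 * elev_mean / 1000 + stats::rnorm(n_blocks, sd = 0.5)
    map <- stats::runif(n_blocks, 800, 3000)
    sr <- pmax(0, round(exp(intercept + slope * log(rng) +
                              stats::rnorm(n_blocks, sd = noise_sd))))
    read_block_table(data.frame(
      block = sprintf("block%02d", seq_len(n_blocks)),
      area_km2 = area, elev_min = elev_min, elev_max = elev_max,
      elev_mean = elev_mean, elev_range = rng,
      mat = mat, map = map, sr_threat = as.integer(sr),
      stringsAsFactors = FALSE))
  })
}
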