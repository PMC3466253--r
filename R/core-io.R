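#' IUCN Red List categories recognised by phylorisk
#'
#' The eight categories used when red-listing a flora, from Data Deficient to
#' Extinct. `LR/CD` (Lower Risk/Conservation Dependent) also appears in older
#' assessments as "LR/cd" or "LC-CD"; [normalize_iucn()] maps all spellings
#' here.
#'
#' @format Character vector of length 8.
#' @export
iucn_categories <- c("DD", "LC", "LR/CD", "NT", "VU", "EN", "CR", "EX")

#' Normalize IUCN category strings
#'
#' Case-insensitive normalization of category labels to the canonical eight
#' in [iucn_categories]. The Lower Risk/Conservation Dependent class is
#' spelled several ways in the literature ("LR/CD", "LR/cd", "LC-CD",
#' "LR-CD"); all map to `"LR/CD"`.
#'
#' @param x character vector of category labels.
#' @return character vector of canonical categories.
#' @examples
#' normalize_iucn(c("lc", "LR/cd", "LC-CD", "vu"))
#' @export
normalize_iucn <- function(x) {
  y <- toupper(trimws(as.character(x)))
  y[y %in% c("LR/CD", "LR-CD", "LC-CD", "LC/CD", "LRCD")] <- "LR/CD"
  bad <- !is.na(y) & !(y %in% iucn_categories)
  if (any(bad))
    stop("unknown IUCN category: ", paste(unique(y[bad]), collapse = ", "))
  y
}

#' Read a rooted phylogeny from a Newick file
#'
#' Thin wrapper around [ape::read.tree()] that validates the result for use
#' in downstream risk analyses: a single rooted tree, unique tip labels,
#' non-negative branch lengths. Internal node labels (used as family/genus
#' anchors by [graft()] and as dated anchors by [bladj()]) are preserved.
#'
#' @param path path to a Newick file (or a Newick string via `text`).
#' @param text optional Newick string instead of a file.
#' @return an object of class `"phylo"`. If the file carries no branch
#'   lengths the returned tree has no `edge.length` and the attribute
#'   `lengths_missing` is set to `TRUE`.
#' @examples
#' tr <- read_newick(text = "((A:1,B:1):1,C:2);")
#' @export
read_newick <- function(path, text = NULL) {
  tr <- if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text)
  if (is.null(tr)) stop("malformed Newick input")
  if (inherits(tr, "multiPhylo")) stop("file contains more than one tree")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  if (is.null(tr$edge.length)) {
    attr(tr, "lengths_missing") <- TRUE
  } else if (any(tr$edge.length < 0)) {
    stop("negative branch lengths")
  }
  tr
}

#' Write a phylogeny to a Newick file
#'
#' @param tree a `"phylo"` object.
#' @param path output path; if `NULL` the Newick string is returned instead.
#' @return invisibly, the Newick string.
#' @export
write_newick <- function(tree, path = NULL) {
  s <- ape::write.tree(tree)
  if (!is.null(path)) writeLines(s, path)
  invisible(s)
}

#' Read a species table (species, genus, family, IUCN category)
#'
#' Reads a delimited text file with columns `species`, `genus`, `family`
#' and `category` (header required; comma or tab separated). Species names
#' are canonicalized to underscore form so they join against Newick tip
#' labels; categories are normalized with [normalize_iucn()].
#'
#' @param path path to the table.
#' @param sep field separator; guessed from the header line when `NULL`.
#' @return data.frame with columns `species`, `genus`, `family`, `category`.
#' @export
read_species_table <- function(path, sep = NULL) {
  if (is.null(sep)) {
    hdr <- readLines(path, n = 1L)
    sep <- if (grepl("\t", hdr)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  names(df) <- tolower(names(df))
  need <- c("species", "genus", "family", "category")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("species table lacks columns: ",
                         paste(miss, collapse = ", "))
  species_records(df$species, df$genus, df$family, df$category)
}

#' Construct a validated species-record table
#'
#' @param species,genus,family character vectors of equal length.
#' @param category IUCN category labels (normalized via [normalize_iucn()]).
#' @return data.frame with canonical `species` keys.
#' @export
species_records <- function(species, genus, family, category) {
  species <- .canon_name(species)
  genus <- trimws(as.character(genus))
  family <- trimws(as.character(family))
  if (anyDuplicated(species))
    stop("duplicate species names: ",
         paste(unique(species[duplicated(species)]), collapse = ", "))
  if (any(!nzchar(genus)) || any(!nzchar(family)))
    stop("every species needs a non-empty genus and family")
  data.frame(species = species, genus = genus, family = family,
             category = normalize_iucn(category),
             stringsAsFactors = FALSE)
}

#' Binarize IUCN categories into threatened / not threatened
#'
#' Partitions species into the binary threat status analysed throughout the
#' package: threatened = EX + CR + EN + VU; not threatened = LR/CD + NT + LC;
#' Data Deficient species are excluded from analysis (but reported).
#'
#' @param records data.frame from [species_records()] or
#'   [read_species_table()], or any data.frame with `species` and `category`
#'   columns.
#' @return a `risk_table`: data.frame with columns `species`, `category`,
#'   `status` (factor: `threatened`, `not_threatened`, `excluded`) and an
#'   attribute `counts` with the three tallies plus `assessed` (the full
#'   red-listed count, DD included).
#' @examples
#' rec <- species_records(c("A_a", "B_b", "C_c"), c("A", "B", "C"),
#'                        c("F1", "F1", "F2"), c("VU", "LC", "DD"))
#' rt <- binarize_risk(rec)
#' attr(rt, "counts")
#' @export
binarize_risk <- function(records) {
  cat <- normalize_iucn(records$category)
  status <- ifelse(cat %in% c("EX", "CR", "EN", "VU"), "threatened",
            ifelse(cat %in% c("LR/CD", "NT", "LC"), "not_threatened",
                   "excluded"))
  out <- data.frame(species = .canon_name(records$species), category = cat,
                    status = factor(status, levels = c("threatened",
                                                       "not_threatened",
                                                       "excluded")),
                    stringsAsFactors = FALSE)
  cnt <- table(out$status)
  counts <- c(threatened = unname(cnt["threatened"]),
              not_threatened = unname(cnt["not_threatened"]),
              excluded = unname(cnt["excluded"]))
  counts["assessed"] <- nrow(out)   # all red-listed species, DD included
  attr(out, "counts") <- counts
  class(out) <- c("risk_table", "data.frame")
  out
}

#' @export
print.risk_table <- function(x, ...) {
  cnt <- attr(x, "counts")
  cat("Risk table:", nrow(x), "species\n")
  cat(sprintf("  threatened (EX+CR+EN+VU):      %d (%.2f%%)\n",
              cnt["threatened"], 100 * cnt["threatened"] / nrow(x)))
  cat(sprintf("  not threatened (LR/CD+NT+LC):  %d (%.2f%%)\n",
              cnt["not_threatened"], 100 * cnt["not_threatened"] / nrow(x)))
  cat(sprintf("  excluded (DD):                 %d\n", cnt["excluded"]))
  invisible(x)
}

#' Read a node-age table (label, age)
#'
#' Ages are in million years (My) and anchor internal nodes for [bladj()].
#'
#' @param path delimited text with header columns `label` and `age`.
#' @param sep separator, guessed when `NULL`.
#' @return named numeric vector of ages.
#' @export
read_node_ages <- function(path, sep = NULL) {
  if (is.null(sep)) {
    hdr <- readLines(path, n = 1L)
    sep <- if (grepl("\t", hdr)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  if (!all(c("label", "age") %in% names(df)))
    stop("age table needs columns label, age")
  ages <- as.numeric(df$age)
  if (any(!is.finite(ages)) || any(ages <= 0)) stop("ages must be positive")
  names(ages) <- trimws(df$label)
  if (anyDuplicated(names(ages))) stop("duplicate node labels in age table")
  ages
}

#' Read and validate a forest-block table
#'
#' Expects one row per forest block with columns `block`, `area_km2`,
#' `elev_min`, `elev_max`, `mat` (mean annual temperature), `map` (mean
#' annual rainfall) and `sr_threat` (threatened-species richness).
#' `elev_mean` and `elev_range` are derived as (min+max)/2 and max-min if
#' absent, and validated against those definitions if present.
#'
#' @param path delimited text file, or a data.frame to validate in place.
#' @param sep separator, guessed when `NULL`.
#' @return validated data.frame (a `block_table`).
#' @export
read_block_table <- function(path, sep = NULL) {
  if (is.data.frame(path)) {
    df <- path
  } else {
    if (is.null(sep)) {
      hdr <- readLines(path, n = 1L)
      sep <- if (grepl("\t", hdr)) "\t" else ","
    }
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE)
  }
  names(df) <- tolower(names(df))
  need <- c("block", "area_km2", "elev_min", "elev_max", "mat", "map",
            "sr_threat")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("block table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (any(df$elev_max < df$elev_min)) stop("elev_max < elev_min")
  if (is.null(df$elev_mean)) df$elev_mean <- (df$elev_min + df$elev_max) / 2
  if (is.null(df$elev_range)) df$elev_range <- df$elev_max - df$elev_min
  if (any(abs(df$elev_mean - (df$elev_min + df$elev_max) / 2) > 1e-8))
    stop("elev_mean must equal (elev_min + elev_max)/2")
  if (any(abs(df$elev_range - (df$elev_max - df$elev_min)) > 1e-8))
    stop("elev_range must equal elev_max - elev_min")
  if (any(df$sr_threat < 0) || any(df$sr_threat != round(df$sr_threat)))
    stop("sr_threat must be a non-negative integer count")
  class(df) <- c("block_table", "data.frame")
  df
}
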