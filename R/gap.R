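# Barcoding-gap analysis: the global gap (intra vs inter distance
# distributions), the per-species local gap criterion, and the resulting
# per-individual discrimination rate.

#' Barcoding-gap histogram
#'
#' Bins intraspecific and interspecific distances on one shared grid from 0
#' to the largest observed distance (half-open bins, the last bin closed).
#'
#' @param part a `pair_partition` (see [partition_distances()]).
#' @param bin_width bin width in distance units (default 0.005).
#' @return object of class `gap_histogram`: data frame-like list with
#'   `bin_start`, `bin_end`, `intra_n`, `inter_n`.
#' @export
gap_histogram <- function(part, bin_width = 0.005) {
  if (!is.numeric(bin_width) || bin_width <= 0) stop("bin_width must be > 0")
  intra <- part$intra$d
  inter <- part$inter$d
  if (length(intra) + length(inter) == 0L) stop("empty partition")
  top <- max(c(intra, inter, bin_width))
  edges <- seq(0, bin_width * ceiling(top / bin_width + 1e-9), by = bin_width)
  if (length(edges) < 2L) edges <- c(0, bin_width)
  binof <- function(x) pmin(findInterval(x, edges, left.open = FALSE),
                            length(edges) - 1L)
  count <- function(x) tabulate(binof(x), nbins = length(edges) - 1L)
  structure(list(bin_start = edges[-length(edges)], bin_end = edges[-1L],
                 intra_n = count(intra), inter_n = count(inter)),
            class = "gap_histogram")
}

#' @export
print.gap_histogram <- function(x, ...) {
  df <- as.data.frame(unclass(x))
  print(df[df$intra_n + df$inter_n > 0L, ])
  invisible(x)
}

#' @export
#' @param x a `gap_histogram`.
#' @param ... passed to [graphics::barplot()].
#' @rdname gap_histogram
plot.gap_histogram <- function(x, ...) {
  h <- rbind(intra = x$intra_n, inter = x$inter_n)
  graphics::barplot(h, beside = TRUE, names.arg = sprintf("%.3f", x$bin_start),
                    col = c("steelblue", "firebrick"), border = NA,
                    legend.text = c("intraspecific", "interspecific"),
                    xlab = "K2P distance (bin start)", ylab = "pairs", ...)
  invisible(x)
}

#' Test for a global barcoding gap
#'
#' A global gap exists when the largest intraspecific distance lies strictly
#' below the smallest interspecific one.
#'
#' @param part a `pair_partition`.
#' @return list with `gap` (logical; `NA` when there are no intraspecific
#'   pairs) and `margin` = min(inter) - max(intra).
#' @export
global_gap_exists <- function(part) {
  if (nrow(part$inter) == 0L) stop("no interspecific pairs")
  if (nrow(part$intra) == 0L)
    return(list(gap = NA, margin = NA_real_))
  margin <- min(part$inter$d) - max(part$intra$d)
  list(gap = margin > 0, margin = margin)
}

# distances from members of `ids` to everything else / within `ids`,
# NA entries dropped
.species_dist_split <- function(species, mat, map) {
  sp <- species_of(map)
  ids <- map$samples[[species]]
  if (is.null(ids)) stop("species not in map: ", species)
  others <- setdiff(rownames(mat), ids)
  others <- intersect(others, names(sp))    # ingroup only
  within <- mat[ids, ids, drop = FALSE]
  within <- within[upper.tri(within)]
  between <- as.vector(mat[ids, others, drop = FALSE])
  list(intra = within[!is.na(within)], inter = between[!is.na(between)])
}

#' Local barcoding-gap success for one species
#'
#' A species with two or more sampled individuals is successfully
#' discriminated when its smallest interspecific distance (any member to any
#' non-member) strictly exceeds its largest intraspecific distance; ties
#' count as failure.
#'
#' @param species species name.
#' @param mat a `k2p_dist` matrix.
#' @param map a `species_map`; defaults to the matrix's own labels.
#' @return logical.
#' @export
local_gap_success <- function(species, mat, map = NULL) {
  mat <- ingroup_matrix(mat)
  if (is.null(map)) map <- .map_from_matrix(mat)
  map <- .restrict_map(map, rownames(mat))
  ids <- map$samples[[species]]
  if (is.null(ids)) stop("species not in map: ", species)
  if (length(ids) < 2L) stop("species '", species,
                             "' is a singleton: not eligible")
  d <- .species_dist_split(species, mat, map)
  if (!length(d$intra) || !length(d$inter)) return(NA)
  min(d$inter) > max(d$intra)
}

# restrict a species_map to the samples actually analysed (e.g. after
# per-combination dropping); species left with 0 samples disappear and
# singleton flags are recomputed
.restrict_map <- function(map, ids) {
  samples <- lapply(map$samples, intersect, y = ids)
  samples <- samples[lengths(samples) > 0L]
  structure(list(samples = samples, singleton = lengths(samples) == 1L,
                 n_species = length(samples),
                 n_samples = sum(lengths(samples)),
                 n_singletons = sum(lengths(samples) == 1L)),
            class = "species_map")
}

.map_from_matrix <- function(mat) {
  sp <- attr(mat, "species")
  if (is.null(sp)) stop("no species labels on matrix; supply 'map'")
  samples <- split(names(sp), factor(sp, levels = unique(sp)))
  structure(list(samples = samples, singleton = lengths(samples) == 1L,
                 n_species = length(samples), n_samples = length(sp),
                 n_singletons = sum(lengths(samples) == 1L)),
            class = "species_map")
}

# shared per-individual accounting for local-gap and tree discrimination
.discrimination_report <- function(method, success_by_species, map) {
  eligible_sp <- names(map$samples)[!map$singleton]
  succ <- success_by_species[eligible_sp]
  n_by_sp <- lengths(map$samples)[eligible_sp]
  n_eligible <- sum(n_by_sp)
  if (n_eligible == 0L) stop("no eligible individuals (all singletons)")
  n_success <- sum(n_by_sp[which(succ %in% TRUE)])
  structure(list(method = method,
                 species_success = succ,
                 n_success_individuals = as.integer(n_success),
                 n_eligible_individuals = as.integer(n_eligible),
                 rate = 100 * n_success / n_eligible),
            class = "discrimination_report")
}

#' @export
print.discrimination_report <- function(x, ...) {
  cat("Discrimination [", x$method, "]: ", x$n_success_individuals, "/",
      x$n_eligible_individuals, " individuals = ",
      sprintf("%.2f%%", x$rate), "\n", sep = "")
  invisible(x)
}

#' Local barcoding-gap (pairwise-distance) discrimination rate
#'
#' Applies the local-gap criterion to every non-singleton species and
#' reports a per-individual success rate: every individual of a successful
#' species counts as a success; singleton individuals are excluded from both
#' numerator and denominator but remain in the matrix as potential nearest
#' neighbours.
#'
#' @param mat a `k2p_dist` matrix.
#' @param map a `species_map`; defaults to the matrix's own labels.
#' @return object of class `discrimination_report` with `species_success`
#'   (named logical over non-singleton species), `n_success_individuals`,
#'   `n_eligible_individuals` and `rate` (percent).
#' @export
pwg_discrimination <- function(mat, map = NULL) {
  mat <- ingroup_matrix(mat)
  if (is.null(map)) map <- .map_from_matrix(mat)
  map <- .restrict_map(map, rownames(mat))
  eligible <- names(map$samples)[!map$singleton]
  if (!length(eligible)) stop("no eligible (non-singleton) species")
  succ <- vapply(eligible, function(s) isTRUE(local_gap_success(s, mat, map)),
                 TRUE)
  .discrimination_report("PWG local gap", succ, map)
}
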