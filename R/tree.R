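# Neighbor-joining on K2P distances, nonparametric bootstrap over alignment
# columns, and monophyly-based species discrimination. Tree agglomeration is
# delegated to ape's NJ (Saitou & Nei, Studier & Keppler); this module owns
# the bootstrap accounting, bipartition bookkeeping and the discrimination
# criterion (a species counts when its samples form an exclusive cluster
# with bootstrap support strictly above the threshold).

#' Neighbor-joining tree from a K2P distance matrix
#'
#' Builds the NJ tree and clamps negative branch lengths to zero, moving the
#' negative excess onto the sibling edge so path lengths change as little as
#' possible.
#'
#' @param mat a `k2p_dist` (or plain symmetric) distance matrix with no
#'   undefined entries.
#' @return an unrooted `phylo` tree (ape) over the matrix's samples.
#' @export
nj_tree <- function(mat) {
  if (nrow(mat) < 3L) stop("need at least 3 samples for a tree")
  na_idx <- which(is.na(mat) & upper.tri(mat), arr.ind = TRUE)
  if (nrow(na_idx))
    stop("undefined distances for pairs: ",
         paste(rownames(mat)[na_idx[, 1L]], colnames(mat)[na_idx[, 2L]],
               sep = "-", collapse = ", "))
  # canonical input order: agglomeration ties then break identically for
  # any row permutation of the same matrix
  ord <- order(rownames(mat))
  mat <- unclass(mat)[ord, ord]
  tr <- ape::nj(stats::as.dist(mat))
  .clamp_negative_edges(tr)
}

# set negative edge lengths to 0, adding the excess to a sibling edge
.clamp_negative_edges <- function(tr) {
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    parent <- tr$edge[e, 1L]
    sibs <- setdiff(which(tr$edge[, 1L] == parent), e)
    if (length(sibs))
      tr$edge.length[sibs[1L]] <- tr$edge.length[sibs[1L]] +
        tr$edge.length[e]
    tr$edge.length[e] <- 0
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

# canonical keys for the non-trivial bipartitions of an unrooted tree:
# each internal edge splits the leaves in two; the side NOT containing the
# alphabetically first leaf is sorted and collapsed to one string
.bipartition_keys <- function(tr) {
  # an internal edge of (numerically) zero length is an arbitrary
  # resolution of a polytomy, not a real cluster: collapse it first
  if (!is.null(tr$edge.length))
    tr <- ape::di2multi(tr, tol = 1e-12)
  pp <- ape::prop.part(tr)
  labs <- attr(pp, "labels")
  ref <- sort(labs)[1L]
  keys <- vapply(pp, function(idx) {
    side <- labs[idx]
    if (ref %in% side) side <- setdiff(labs, side)
    paste(sort(side), collapse = "\x01")
  }, "")
  # the root "clade" (all tips) canonicalizes to an empty complement: drop it
  unique(keys[nzchar(keys)])
}

.leafset_key <- function(leaves, all_leaves) {
  ref <- sort(all_leaves)[1L]
  if (ref %in% leaves) leaves <- setdiff(all_leaves, leaves)
  paste(sort(leaves), collapse = "\x01")
}

#' Robinson-Foulds style topology identity
#'
#' TRUE when two unrooted trees over the same leaves induce identical sets
#' of non-trivial bipartitions.
#'
#' @param a,b `phylo` trees with identical leaf sets.
#' @export
same_topology <- function(a, b) {
  if (!setequal(a$tip.label, b$tip.label)) stop("different leaf sets")
  setequal(.bipartition_keys(a), .bipartition_keys(b))
}

#' NJ tree with nonparametric bootstrap support
#'
#' Resamples alignment columns with replacement, recomputes the K2P matrix
#' and NJ tree per replicate, and scores every internal bipartition of the
#' original tree by the percentage of (non-skipped) replicates containing
#' it. Replicates whose resampled matrix contains undefined distances are
#' skipped and counted; more than 20% skipped is an error.
#'
#' @param aln a `locus_alignment` (outgroups included: they are part of the
#'   tree; discrimination accounting excludes them later).
#' @param n_replicates number of bootstrap replicates (>= 1).
#' @param seed integer seed; the run is reproducible given the seed.
#' @return object of class `nj_boot`: `tree` (`phylo` with `node.label`
#'   holding supports), `keys` (bipartition keys), `support` (named percent
#'   values in [0, 100]), `n_replicates`, `n_skipped`.
#' @export
bootstrap_nj <- function(aln, n_replicates = 1000L, seed = NULL) {
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  code <- .aln_int(aln)
  rownames(code) <- aln$sample_id
  d0 <- .k2p_matrix_code(code)
  dimnames(d0) <- list(aln$sample_id, aln$sample_id)
  tr <- nj_tree(d0)
  keys <- .bipartition_keys(tr)
  counts <- setNames(numeric(length(keys)), keys)
  if (!is.null(seed)) set.seed(seed)
  L <- ncol(code)
  skipped <- 0L
  for (r in seq_len(n_replicates)) {
    idx <- sample.int(L, L, replace = TRUE)
    d <- .k2p_matrix_code(code[, idx, drop = FALSE])
    if (anyNA(d)) { skipped <- skipped + 1L; next }
    dimnames(d) <- dimnames(d0)
    rk <- .bipartition_keys(.clamp_negative_edges(ape::nj(stats::as.dist(d))))
    hit <- keys %in% rk
    counts[hit] <- counts[hit] + 1
  }
  if (skipped > 0.2 * n_replicates)
    stop("more than 20% of bootstrap replicates skipped (", skipped, "/",
         n_replicates, ")")
  eff <- n_replicates - skipped
  support <- if (eff > 0L) 100 * counts / eff else counts * NA_real_
  tr <- .attach_support(tr, support)
  structure(list(tree = tr, keys = keys, support = support,
                 n_replicates = n_replicates, n_skipped = skipped),
            class = "nj_boot")
}

# write supports into node.label, matching prop.part's node order
.attach_support <- function(tr, support) {
  pp <- ape::prop.part(tr)
  labs <- attr(pp, "labels")
  lab <- vapply(pp, function(idx) {
    key <- .leafset_key(labs[idx], labs)
    if (key %in% names(support)) sprintf("%.0f", support[[key]]) else ""
  }, "")
  tr$node.label <- lab
  tr
}

#' @export
print.nj_boot <- function(x, ...) {
  cat("NJ tree with bootstrap support: ", length(x$tree$tip.label),
      " leaves, ", x$n_replicates, " replicates (", x$n_skipped,
      " skipped)\n", sep = "")
  invisible(x)
}

#' Write an NJ tree (with supports) to Newick
#'
#' @param x an `nj_boot` or `phylo` object.
#' @param path output path.
#' @export
write_nj_tree <- function(x, path) {
  tr <- if (inherits(x, "nj_boot")) x$tree else x
  ape::write.tree(tr, file = path)
  invisible(path)
}

#' Species monophyly verdicts on a tree
#'
#' A non-singleton species is monophyletic when some edge of the unrooted
#' tree separates exactly its samples from everything else (either side of
#' the edge). `counted_success` additionally requires bootstrap support
#' strictly above `support_threshold`; trees without support values count on
#' topology alone.
#'
#' @param x an `nj_boot` (preferred: carries supports) or `phylo` tree.
#' @param map a `species_map`; singleton species are skipped. Every species
#'   sample must be a tree leaf.
#' @param support_threshold support percentage that must be strictly
#'   exceeded (default 50).
#' @return data frame with columns `species`, `n_samples`,
#'   `is_monophyletic`, `support`, `counted_success`.
#' @export
species_monophyly <- function(x, map, support_threshold = 50) {
  tr <- if (inherits(x, "nj_boot")) x$tree else x
  support <- if (inherits(x, "nj_boot")) x$support else NULL
  leaves <- tr$tip.label
  keys <- .bipartition_keys(tr)
  eligible <- names(map$samples)[!map$singleton]
  rows <- lapply(eligible, function(s) {
    ids <- map$samples[[s]]
    if (!all(ids %in% leaves))
      stop("samples of species '", s, "' missing from tree: ",
           paste(setdiff(ids, leaves), collapse = ", "))
    n <- length(ids)
    if (n >= length(leaves) - 1L) {
      # isolated by a terminal edge (or the whole tree): trivially exclusive
      mono <- TRUE
      supp <- 100
    } else {
      key <- .leafset_key(ids, leaves)
      mono <- key %in% keys
      supp <- if (!mono) NA_real_
      else if (is.null(support)) NA_real_
      else unname(support[[key]])
    }
    counted <- mono && (is.na(supp) || supp > support_threshold)
    data.frame(species = s, n_samples = n, is_monophyletic = mono,
               support = supp, counted_success = counted)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Tree-based (NJ monophyly) discrimination rate
#'
#' Per-individual discrimination rate under the monophyly criterion: every
#' individual of a species whose samples form an exclusive cluster with
#' support strictly above the threshold counts as a success; singletons are
#' excluded from numerator and denominator.
#'
#' @inheritParams species_monophyly
#' @return a `discrimination_report` (see [pwg_discrimination()]).
#' @export
tree_discrimination <- function(x, map, support_threshold = 50) {
  tr <- if (inherits(x, "nj_boot")) x$tree else x
  map <- .restrict_map(map, tr$tip.label)
  verdicts <- species_monophyly(x, map, support_threshold)
  succ <- setNames(verdicts$counted_success, verdicts$species)
  .discrimination_report("NJ monophyly", succ, map)
}
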