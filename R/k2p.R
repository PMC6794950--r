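# Kimura two-parameter (K2P/K80) distances with pairwise deletion.
#
# For one sequence pair, let P and Q be the proportions of compared sites
# showing a transition (A<->G, C<->T) and a transversion respectively; then
#   d = -1/2 * ln[(1 - 2P - Q) * sqrt(1 - 2Q)].
# Sites where either sequence carries a gap, '?' or an IUPAC ambiguity code
# are excluded for that pair only (pairwise deletion, the MEGA default).
# The distance is undefined (NA, with a reason) when no sites remain or the
# log argument is non-positive (saturation).

.base_int <- function(chars) {
  # A=1 C=2 G=3 T=4 (U coded as T), everything else 0 (excluded pairwise)
  i <- match(chars, c("A", "C", "G", "T", "U"))
  i[is.na(i)] <- 0L
  i[i == 5L] <- 4L
  i
}

# integer-coded matrix (rows = samples) cached on the alignment
.aln_int <- function(aln) {
  m <- matrix(.base_int(aln$seq), nrow = nrow(aln$seq),
              dimnames = dimnames(aln$seq))
  m
}

.k2p_from_counts <- function(n_sites, n_ts, n_tv) {
  P <- if (n_sites > 0L) n_ts / n_sites else NA_real_
  Q <- if (n_sites > 0L) n_tv / n_sites else NA_real_
  reason <- NULL
  d <- NA_real_
  if (n_sites == 0L) {
    reason <- "no comparable sites"
  } else {
    w1 <- 1 - 2 * P - Q
    w2 <- 1 - 2 * Q
    if (w1 <= 0 || w2 <= 0) reason <- "saturated (log-domain failure)"
    else d <- -0.5 * log(w1 * sqrt(w2)) + 0   # + 0 normalizes IEEE -0
  }
  structure(list(n_sites = n_sites, n_transitions = n_ts,
                 n_transversions = n_tv, P = P, Q = Q, d = d,
                 undefined = is.na(d), reason = reason),
            class = "k2p_pair")
}

#' K2P distance between two aligned sequences
#'
#' @param seq_a,seq_b aligned sequences of equal length, as single strings
#'   or character vectors of single characters.
#' @return object of class `k2p_pair`: `n_sites` (compared columns after
#'   pairwise deletion), `n_transitions`, `n_transversions`, `P`, `Q`, `d`
#'   (substitutions/site; `NA` with `undefined = TRUE` and a `reason` when
#'   the estimate does not exist).
#' @examples
#' k2p_pair("AAAAAAAAAA", "GAAAAAAAAA")$d  # -0.5 * log(0.8)
#' @export
k2p_pair <- function(seq_a, seq_b) {
  a <- .base_int(.as_chars(seq_a))
  b <- .base_int(.as_chars(seq_b))
  if (length(a) != length(b)) stop("sequences differ in length")
  keep <- a > 0L & b > 0L
  a <- a[keep]; b <- b[keep]
  diff <- a != b
  # transition: A(1)<->G(3) or C(2)<->T(4), i.e. same parity of (a+b)
  ts <- diff & ((a + b) %% 2L == 0L)
  .k2p_from_counts(sum(keep), sum(ts), sum(diff & !ts))
}

.as_chars <- function(x) {
  if (length(x) == 1L && nchar(x) > 1L)
    x <- strsplit(x, "", fixed = TRUE)[[1L]]
  toupper(x)
}

#' @export
print.k2p_pair <- function(x, ...) {
  cat("K2P pair: n =", x$n_sites, " P =", signif(x$P, 4L),
      " Q =", signif(x$Q, 4L), " d =",
      if (x$undefined) paste0("undefined (", x$reason, ")")
      else signif(x$d, 6L), "\n")
  invisible(x)
}

# full K2P matrix from an integer-coded alignment (A=1..T=4, 0 = excluded),
# via indicator cross-products; NA where undefined
.k2p_matrix_code <- function(code) {
  ind <- lapply(1:4, function(b) (code == b) * 1)
  valid <- Reduce(`+`, ind)
  n_sites <- tcrossprod(valid)
  # transitions: (A,G)+(G,A)+(C,T)+(T,C)
  ag <- tcrossprod(ind[[1L]], ind[[3L]])
  ct <- tcrossprod(ind[[2L]], ind[[4L]])
  ts <- ag + t(ag) + ct + t(ct)
  same <- Reduce(`+`, lapply(ind, tcrossprod))
  tv <- n_sites - same - ts
  P <- ifelse(n_sites > 0, ts / n_sites, NA_real_)
  Q <- ifelse(n_sites > 0, tv / n_sites, NA_real_)
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  ok <- !is.na(w1) & w1 > 0 & w2 > 0
  d <- array(NA_real_, dim = dim(w1))
  d[ok] <- -0.5 * log(w1[ok] * sqrt(w2[ok])) + 0   # + 0 normalizes IEEE -0
  diag(d) <- 0
  d
}

#' All pairwise K2P distances for an alignment
#'
#' Computes the full symmetric distance matrix via indicator cross-products
#' (one pass over sixteen base-pair count matrices), equivalent to calling
#' [k2p_pair()] on every pair. Undefined entries are `NA` and are excluded,
#' with a warning, from any downstream summary.
#'
#' @param aln a `locus_alignment` with at least 2 records.
#' @param warn warn when undefined (NA) entries are produced.
#' @return symmetric numeric matrix (class `k2p_dist`), dimnames = sample
#'   ids, zero diagonal, `NA` for undefined pairs; the species labels travel
#'   along as attributes `species` and `outgroup`.
#' @export
distance_matrix <- function(aln, warn = TRUE) {
  if (nrow(aln$seq) < 2L) stop("need at least 2 records")
  d <- .k2p_matrix_code(.aln_int(aln))
  dimnames(d) <- list(aln$sample_id, aln$sample_id)
  und <- sum(is.na(d[upper.tri(d)]))
  if (und > 0L && warn)
    warning(und, " undefined pairwise distance(s) (no sites or saturation);",
            " excluded from summaries", call. = FALSE)
  structure(d, species = setNames(aln$species, aln$sample_id),
            outgroup = setNames(aln$outgroup, aln$sample_id),
            class = c("k2p_dist", "matrix", "array"))
}

#' @export
print.k2p_dist <- function(x, ...) {
  cat("K2P distance matrix: ", nrow(x), " samples, ",
      sum(is.na(x[upper.tri(x)])), " undefined pairs\n", sep = "")
  invisible(x)
}

# strip outgroup rows/columns from a k2p_dist
ingroup_matrix <- function(mat) {
  og <- attr(mat, "outgroup")
  if (is.null(og) || !any(og)) return(mat)
  keep <- names(og)[!og]
  out <- mat[keep, keep, drop = FALSE]
  structure(out, species = attr(mat, "species")[keep],
            outgroup = og[keep], class = class(mat))
}

#' Split pairwise distances into intra- and interspecific classes
#'
#' @param mat a `k2p_dist` matrix (see [distance_matrix()]).
#' @param map a `species_map` covering every ingroup sample of `mat`;
#'   defaults to the map carried by the matrix. Outgroup samples are
#'   excluded.
#' @return object of class `pair_partition`: two data frames `intra` and
#'   `inter` with columns `sample_a`, `sample_b`, `d` (defined pairs only),
#'   plus `n_undefined`.
#' @export
partition_distances <- function(mat, map = NULL) {
  mat <- ingroup_matrix(mat)
  ids <- rownames(mat)
  if (is.null(map)) {
    sp <- attr(mat, "species")
    if (is.null(sp)) stop("no species map available")
  } else {
    sp <- species_of(map)
    if (!all(ids %in% names(sp)))
      stop("samples not in species map: ",
           paste(setdiff(ids, names(sp)), collapse = ", "))
    sp <- sp[ids]
  }
  n <- length(ids)
  iu <- which(upper.tri(mat), arr.ind = TRUE)
  d <- mat[iu]
  same <- sp[iu[, 1L]] == sp[iu[, 2L]]
  def <- !is.na(d)
  mk <- function(keep) data.frame(sample_a = ids[iu[keep, 1L]],
                                  sample_b = ids[iu[keep, 2L]],
                                  d = d[keep], row.names = NULL)
  structure(list(intra = mk(def & same), inter = mk(def & !same),
                 n_undefined = sum(!def)),
            class = "pair_partition")
}

#' @export
print.pair_partition <- function(x, ...) {
  cat("pair_partition: ", nrow(x$intra), " intraspecific, ", nrow(x$inter),
      " interspecific pairs (", x$n_undefined, " undefined)\n", sep = "")
  invisible(x)
}

#' Five-parameter distance summary
#'
#' The standard barcoding distance descriptors: overall mean, mean and range
#' of interspecific distances, and mean and range of intraspecific
#' distances. An empty intraspecific class (all species singletons) yields
#' mean 0 with `intra_empty = TRUE`.
#'
#' @param part a `pair_partition` from [partition_distances()].
#' @return object of class `distance_summary`.
#' @export
summarize_distances <- function(part) {
  if (nrow(part$inter) == 0L) stop("no interspecific pairs")
  intra <- part$intra$d
  inter <- part$inter$d
  empty <- length(intra) == 0L
  structure(list(
    mean_all = mean(c(intra, inter)),
    mean_inter = mean(inter),
    mean_intra = if (empty) 0 else mean(intra),
    min_inter = min(inter),
    max_intra = if (empty) NA_real_ else max(intra),
    range_inter = range(inter),
    range_intra = if (empty) c(NA_real_, NA_real_) else range(intra),
    n_intra = length(intra), n_inter = length(inter),
    intra_empty = empty),
    class = "distance_summary")
}

#' @export
print.distance_summary <- function(x, ...) {
  f <- function(v) sprintf("%.4f", v)
  cat("Distance summary (K2P):\n")
  cat("  mean (all pairs):        ", f(x$mean_all), "\n")
  cat("  mean interspecific:      ", f(x$mean_inter),
      sprintf("  [%s-%s]\n", f(x$range_inter[1L]), f(x$range_inter[2L])))
  if (x$intra_empty) cat("  mean intraspecific:       0 (no intraspecific pairs)\n")
  else cat("  mean intraspecific:      ", f(x$mean_intra),
           sprintf("  [%s-%s]\n", f(x$range_intra[1L]), f(x$range_intra[2L])))
  cat("  smallest interspecific:  ", f(x$min_inter), "\n")
  if (!x$intra_empty)
    cat("  largest intraspecific:   ", f(x$max_intra), "\n")
  invisible(x)
}

#' Write a distance matrix in PHYLIP or long format
#'
#' @param mat a `k2p_dist` matrix.
#' @param path output path.
#' @param format `"phylip"` (square) or `"long"` (tab-separated
#'   `sample_a`, `sample_b`, `class`, `d`).
#' @export
write_distance_matrix <- function(mat, path, format = c("phylip", "long")) {
  format <- match.arg(format)
  if (format == "phylip") {
    lines <- c(sprintf("%5d", nrow(mat)),
               vapply(seq_len(nrow(mat)), function(i)
                 paste(formatC(rownames(mat)[i], width = -10),
                       paste(sprintf("%.6f", mat[i, ]), collapse = " ")),
                 ""))
    writeLines(lines, path)
  } else {
    part <- partition_distances(mat)
    long <- rbind(cbind(part$intra, class = "intraspecific"),
                  cbind(part$inter, class = "interspecific"))
    utils::write.table(long[, c("sample_a", "sample_b", "class", "d")],
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
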