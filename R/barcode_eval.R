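# One front door for the whole evaluation: takes the per-locus alignments,
# builds the requested single-locus and multi-locus units, and runs every
# analysis (characteristics, K2P distance summaries, barcoding gap, local
# gap discrimination, Best Match / Best Close Match, NJ monophyly) on each.

#' Evaluate single- and multi-locus DNA barcodes
#'
#' The main entry point. For each analysis unit — every locus and every
#' requested combination of loci — the function computes alignment
#' characteristics, the K2P distance summary, the global barcoding gap, the
#' local-gap (per-species) discrimination rate, Best Match and Best Close
#' Match identification summaries, and (optionally) the NJ-monophyly
#' discrimination rate with bootstrap support.
#'
#' @param loci named list of [locus_alignment()] objects (names are locus
#'   names).
#' @param combos `"all"` (every subset of size >= 2, the classic eleven for
#'   four loci), `"none"`, or a list of character vectors of locus names.
#' @param methods subset of `c("pwg", "bm", "bcm", "nj")`.
#' @param nboot bootstrap replicates for the NJ supports.
#' @param seed integer seed for the bootstrap resampling.
#' @param threshold_percentile percentile of intraspecific distances used as
#'   the Best Close Match threshold (default 95).
#' @param support_threshold bootstrap support that must be strictly exceeded
#'   for a monophyletic species to count (default 50).
#' @param gap_bin_width histogram bin width for the barcoding gap.
#' @return object of class `barcode_eval` with one entry per unit under
#'   `$units` (each holding `alignment`, `matrix`, `map`, `stats`,
#'   `distance_summary`, `gap`, `pwg`, `bm`, `bcm`, `nj`, `tree`), plus
#'   `$methods` and the call.
#' @examples
#' sim <- generate_dataset(pulsatilla_profile(seed = 1))
#' fit <- barcode_eval(sim$loci["ITS"], combos = "none", methods = "pwg")
#' summary(fit)
#' @export
barcode_eval <- function(loci, combos = "all",
                         methods = c("pwg", "bm", "bcm", "nj"),
                         nboot = 1000L, seed = NULL,
                         threshold_percentile = 95,
                         support_threshold = 50,
                         gap_bin_width = 0.005) {
  if (!length(loci)) stop("no loci given")
  if (is.null(names(loci)) || any(!nzchar(names(loci))))
    names(loci) <- vapply(loci, `[[`, "", "locus")
  methods <- match.arg(methods, several.ok = TRUE)
  units <- lapply(names(loci), function(nm) loci[[nm]])
  names(units) <- names(loci)
  if (identical(combos, "all") && length(loci) >= 2L)
    combos <- enumerate_combinations(names(loci))
  else if (identical(combos, "none") || identical(combos, "all"))
    combos <- list()
  for (cb in combos) {
    aln <- concatenate_loci(loci, cb)
    units[[aln$locus]] <- aln
  }
  res <- lapply(units, .eval_unit, methods = methods, nboot = nboot,
                seed = seed, threshold_percentile = threshold_percentile,
                support_threshold = support_threshold,
                gap_bin_width = gap_bin_width)
  structure(list(units = res, methods = methods,
                 support_threshold = support_threshold,
                 threshold_percentile = threshold_percentile,
                 call = match.call()),
            class = "barcode_eval")
}

.eval_unit <- function(aln, methods, nboot, seed, threshold_percentile,
                       support_threshold, gap_bin_width) {
  mat <- distance_matrix(aln, warn = FALSE)
  ing <- ingroup_matrix(mat)
  map <- .map_from_matrix(ing)
  part <- partition_distances(mat, map)
  out <- list(alignment = aln, matrix = mat, map = map,
              stats = alignment_stats(aln),
              distance_summary = summarize_distances(part),
              gap = global_gap_exists(part),
              histogram = gap_histogram(part, gap_bin_width))
  if ("pwg" %in% methods) out$pwg <- pwg_discrimination(mat, map)
  if ("bm" %in% methods)
    out$bm <- summarize_identification(identify_all(mat, map, "bm"))
  if ("bcm" %in% methods) {
    thr <- intraspecific_threshold(part, threshold_percentile)
    out$bcm_threshold <- thr
    out$bcm <- summarize_identification(
      identify_all(mat, map, "bcm", threshold = thr))
  }
  if ("nj" %in% methods) {
    boot <- bootstrap_nj(aln, n_replicates = nboot, seed = seed)
    out$tree <- boot
    out$nj <- tree_discrimination(boot, map, support_threshold)
  }
  out
}

#' @export
print.barcode_eval <- function(x, ...) {
  cat("barcode_eval: ", length(x$units), " analysis units (",
      paste(x$methods, collapse = ", "), ")\n", sep = "")
  print(summary(x))
  invisible(x)
}

#' Summarise a barcode evaluation
#'
#' @param object a `barcode_eval`.
#' @param ... unused.
#' @return data frame, one row per analysis unit: mean intra/interspecific
#'   distance, global-gap flag, and the per-individual success rates of the
#'   methods that were run (percent).
#' @export
summary.barcode_eval <- function(object, ...) {
  rows <- lapply(names(object$units), function(nm) {
    u <- object$units[[nm]]
    df <- data.frame(unit = nm,
                     n_individuals = u$map$n_samples,
                     n_species = u$map$n_species,
                     mean_intra = round(u$distance_summary$mean_intra, 4L),
                     mean_inter = round(u$distance_summary$mean_inter, 4L),
                     global_gap = u$gap$gap)
    df$pwg <- if (!is.null(u$pwg)) round(u$pwg$rate, 2L) else NA_real_
    df$bm_correct <- if (!is.null(u$bm)) u$bm$pct[["correct"]] else NA_real_
    df$bcm_correct <- if (!is.null(u$bcm)) u$bcm$pct[["correct"]]
    else NA_real_
    df$nj <- if (!is.null(u$nj)) round(u$nj$rate, 2L) else NA_real_
    df
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Plot the barcoding gap of one analysis unit
#'
#' @param x a `barcode_eval`.
#' @param unit unit name (default: first unit).
#' @param ... passed to [plot.gap_histogram()].
#' @export
plot.barcode_eval <- function(x, unit = names(x$units)[1L], ...) {
  u <- x$units[[unit]]
  if (is.null(u)) stop("no such unit: ", unit)
  plot(u$histogram, main = unit, ...)
  invisible(x)
}

#' Identify query sequences against an evaluated reference
#'
#' Classifies new aligned sequences by nearest-neighbour K2P distance
#' against the reference records of one analysis unit, using Best Match or
#' Best Close Match (with the unit's stored threshold).
#'
#' @param object a `barcode_eval`.
#' @param queries a `locus_alignment` of query sequences aligned to the same
#'   columns as the unit's alignment (species labels of queries are only
#'   used for reporting, not for matching).
#' @param unit unit name (default: first unit).
#' @param method `"bm"` or `"bcm"`.
#' @param ... unused.
#' @return data frame of per-query verdicts (see [verdict_table()]); the
#'   `category` compares the assigned species to the query's own label.
#' @export
predict.barcode_eval <- function(object, queries, unit = names(object$units)[1L],
                                 method = c("bcm", "bm"), ...) {
  method <- match.arg(method)
  u <- object$units[[unit]]
  if (is.null(u)) stop("no such unit: ", unit)
  ref <- u$alignment
  if (queries$aligned_length != ref$aligned_length)
    stop("queries must be aligned to the unit's ", ref$aligned_length,
         " columns")
  qid <- paste0("query:", queries$sample_id)
  comb <- locus_alignment(
    c(apply(ref$seq, 1L, paste, collapse = ""),
      apply(queries$seq, 1L, paste, collapse = "")),
    species = c(ref$species, queries$species),
    sample_id = c(ref$sample_id, qid),
    locus = ref$locus,
    outgroup = c(ref$outgroup, rep(FALSE, length(qid))))
  mat <- distance_matrix(comb, warn = FALSE)
  # queries must not match each other or themselves: keep reference columns
  keep <- c(ref$sample_id[!ref$outgroup])
  thr <- if (method == "bcm") u$bcm_threshold else Inf
  if (is.null(thr)) thr <- Inf
  verdicts <- lapply(qid, function(q) {
    sub <- mat[c(q, keep), c(q, keep)]
    class(sub) <- class(mat)
    attr(sub, "species") <- attr(mat, "species")[c(q, keep)]
    attr(sub, "outgroup") <- attr(mat, "outgroup")[c(q, keep)]
    if (method == "bcm") best_close_match(q, sub, threshold = thr)
    else best_match(q, sub)
  })
  verdict_table(verdicts)
}
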