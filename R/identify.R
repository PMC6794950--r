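# Sequence-similarity identification in the TAXONDNA style: each eligible
# individual is queried in turn against all other sequences. "Best Match"
# assigns the query to the species of its nearest neighbour(s) regardless of
# how distant they are; "Best Close Match" additionally requires the nearest
# distance to fall within a threshold derived from the intraspecific
# distance distribution, else the query is scored "no match".

.TIE_RTOL <- 1e-9   # relative tolerance for distance ties

#' Best Match verdict for one query
#'
#' The query's distance row is scanned for its minimum over all non-self
#' samples (undefined pairs skipped); all samples tying that minimum within
#' a relative tolerance form the match set. The verdict is `correct` when
#' every tied match is conspecific with the query, `incorrect` when none
#' are, and `ambiguous` otherwise.
#'
#' @param query sample id of the query.
#' @param mat a `k2p_dist` matrix containing the query.
#' @param map a `species_map`; defaults to the matrix's own labels.
#' @return object of class `query_verdict`: `query`, `best_distance`,
#'   `matched_species` (character), `category`.
#' @export
best_match <- function(query, mat, map = NULL) {
  .match_verdict(query, mat, map, threshold = Inf)
}

#' Best Close Match verdict for one query
#'
#' As [best_match()], but when the minimal distance strictly exceeds
#' `threshold` the verdict is `no_match`.
#'
#' @inheritParams best_match
#' @param threshold non-negative distance threshold, typically from
#'   [intraspecific_threshold()].
#' @export
best_close_match <- function(query, mat, map = NULL, threshold) {
  if (!is.numeric(threshold) || threshold < 0)
    stop("threshold must be a non-negative number")
  .match_verdict(query, mat, map, threshold = threshold)
}

.match_verdict <- function(query, mat, map, threshold) {
  mat <- ingroup_matrix(mat)
  if (!query %in% rownames(mat)) stop("query not in matrix: ", query)
  sp <- if (is.null(map)) attr(mat, "species") else species_of(map)
  if (is.null(sp) || !all(rownames(mat) %in% names(sp)))
    stop("species labels missing for some samples")
  sp <- sp[rownames(mat)]
  d <- mat[query, ]
  d <- d[names(d) != query]
  d <- d[!is.na(d)]
  if (!length(d)) stop("no defined distances for query ", query)
  dmin <- min(d)
  tied <- names(d)[d <= dmin + .TIE_RTOL * max(dmin, 1)]
  matched <- unique(sp[tied])
  qsp <- sp[query]
  category <- if (dmin > threshold) "no_match"
  else if (all(matched == qsp)) "correct"
  else if (!qsp %in% matched) "incorrect"
  else "ambiguous"
  structure(list(query = query, best_distance = dmin,
                 matched_species = unname(matched), category = category),
            class = "query_verdict")
}

#' @export
print.query_verdict <- function(x, ...) {
  cat(x$query, ": ", x$category, " (d = ", signif(x$best_distance, 6L),
      "; ", paste(x$matched_species, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Intraspecific distance threshold
#'
#' The given percentile (default 95, with linear interpolation) of all
#' intraspecific pairwise distances — the usual Best Close Match threshold.
#'
#' @param part a `pair_partition`.
#' @param percentile percentile in (0, 100].
#' @return distance threshold (numeric).
#' @export
intraspecific_threshold <- function(part, percentile = 95) {
  if (nrow(part$intra) == 0L) stop("no intraspecific pairs")
  unname(quantile(part$intra$d, percentile / 100, type = 7L))
}

#' Run Best Match / Best Close Match over all eligible queries
#'
#' Every individual of a non-singleton species is queried in turn against
#' the full reference matrix (singletons and everything else stay in the
#' reference as potential wrong matches).
#'
#' @param mat a `k2p_dist` matrix.
#' @param map a `species_map`; defaults to the matrix's own labels.
#' @param method `"bm"` (Best Match) or `"bcm"` (Best Close Match).
#' @param threshold distance threshold for `"bcm"`; by default the 95th
#'   percentile of intraspecific distances via [intraspecific_threshold()].
#' @return list of `query_verdict`, one per eligible query.
#' @export
identify_all <- function(mat, map = NULL, method = c("bm", "bcm"),
                         threshold = NULL) {
  method <- match.arg(method)
  mat <- ingroup_matrix(mat)
  if (is.null(map)) map <- .map_from_matrix(mat)
  map <- .restrict_map(map, rownames(mat))
  queries <- unlist(map$samples[!map$singleton], use.names = FALSE)
  if (!length(queries)) stop("no eligible queries (all species singletons)")
  if (method == "bcm" && is.null(threshold))
    threshold <- intraspecific_threshold(partition_distances(mat, map))
  lapply(queries, function(q)
    if (method == "bm") best_match(q, mat, map)
    else best_close_match(q, mat, map, threshold))
}

#' Summarise identification verdicts
#'
#' @param verdicts list of `query_verdict` (from [identify_all()]).
#' @return object of class `identification_summary`: per-category counts and
#'   percentages over the eligible queries.
#' @export
summarize_identification <- function(verdicts) {
  if (!length(verdicts)) stop("no verdicts to summarise")
  cats <- c("correct", "ambiguous", "incorrect", "no_match")
  got <- factor(vapply(verdicts, `[[`, "", "category"), levels = cats)
  counts <- table(got)
  n <- length(verdicts)
  structure(list(n_queries = n, counts = setNames(as.integer(counts), cats),
                 pct = setNames(round(100 * as.integer(counts) / n, 2L),
                                cats)),
            class = "identification_summary")
}

#' @export
print.identification_summary <- function(x, ...) {
  cat("Identification over", x$n_queries, "queries:\n")
  for (k in names(x$counts))
    cat(sprintf("  %-10s %3d  (%.2f%%)\n", k, x$counts[[k]], x$pct[[k]]))
  invisible(x)
}

#' Per-query verdict table
#'
#' @param verdicts list of `query_verdict`.
#' @return data frame with columns `query`, `best_distance`,
#'   `matched_species` (comma-joined), `category`.
#' @export
verdict_table <- function(verdicts) {
  data.frame(
    query = vapply(verdicts, `[[`, "", "query"),
    best_distance = vapply(verdicts, `[[`, 0, "best_distance"),
    matched_species = vapply(verdicts, function(v)
      paste(v$matched_species, collapse = ","), ""),
    category = vapply(verdicts, `[[`, "", "category"),
    row.names = NULL)
}
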