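# Alignment characteristics: variable sites, parsimony-informative sites,
# indel (DIP-style) events, and the summary block a barcode study tabulates.
# Site classification follows the MEGA/DnaSP convention: gaps, '?' and IUPAC
# ambiguity codes are treated as missing and never create variability.

#' Count variable sites
#'
#' A column is variable when at least two distinct unambiguous bases
#' (A/C/G/T) occur among its non-gap, non-ambiguous characters; gaps and
#' ambiguity codes never create variability.
#'
#' @param aln a `locus_alignment`.
#' @param include_outgroup include outgroup records (default FALSE: alignment
#'   characteristics are reported for the ingroup).
#' @return integer count of variable columns.
#' @export
count_variable_sites <- function(aln, include_outgroup = FALSE) {
  m <- .scope_matrix(aln, include_outgroup)
  sum(.col_base_counts(m) >= 2L)
}

#' Count parsimony-informative sites
#'
#' A column is parsimony-informative when at least two distinct unambiguous
#' bases each occur in at least two sequences.
#'
#' @inheritParams count_variable_sites
#' @return integer count.
#' @export
count_parsimony_informative <- function(aln, include_outgroup = FALSE) {
  m <- .scope_matrix(aln, include_outgroup)
  sum(.col_base_counts(m, min_per_base = 2L) >= 2L)
}

# per-column number of distinct A/C/G/T present in >= min_per_base rows
.col_base_counts <- function(m, min_per_base = 1L) {
  counts <- matrix(0L, nrow = 4L, ncol = ncol(m))
  for (i in seq_along(.BC_BASES))
    counts[i, ] <- colSums(m == .BC_BASES[i])
  colSums(counts >= min_per_base)
}

.scope_matrix <- function(aln, include_outgroup) {
  a <- if (include_outgroup) aln else ingroup_alignment(aln)
  a$seq
}

#' Count indel events
#'
#' An indel event is a maximal run of consecutive columns whose set of
#' gapped sequences is identical and non-empty; runs differing in their
#' gapped-sequence set or column interval are distinct events. This mirrors
#' deletion/insertion polymorphism (DIP) event counting on an alignment.
#'
#' @inheritParams count_variable_sites
#' @return list with `n_events`, and (when `n_events > 0`) `min_length` and
#'   `max_length` in columns, else `NA` lengths.
#' @export
count_indel_events <- function(aln, include_outgroup = FALSE) {
  m <- .scope_matrix(aln, include_outgroup)
  gap <- m == "-"
  # key per column: which rows are gapped (empty key = no gap)
  keys <- apply(gap, 2L, function(col) paste(which(col), collapse = ","))
  runs <- rle(keys)
  ev <- runs$lengths[nzchar(runs$values)]
  if (!length(ev))
    return(list(n_events = 0L, min_length = NA_integer_,
                max_length = NA_integer_))
  list(n_events = length(ev), min_length = min(ev), max_length = max(ev))
}

#' Alignment characteristics summary
#'
#' Aggregates the per-locus descriptors a barcode study tabulates: aligned
#' length, ungapped sequence-length range, variable and
#' parsimony-informative site counts with percentages, and indel events
#' with their column-length range.
#'
#' @inheritParams count_variable_sites
#' @return object of class `alignment_stats` (a list; see fields in source).
#' @export
alignment_stats <- function(aln, include_outgroup = FALSE) {
  a <- if (include_outgroup) aln else ingroup_alignment(aln)
  m <- a$seq
  L <- ncol(m)
  ungapped <- rowSums(m != "-" & m != "?")
  nv <- count_variable_sites(a, include_outgroup = TRUE)
  npi <- count_parsimony_informative(a, include_outgroup = TRUE)
  ind <- count_indel_events(a, include_outgroup = TRUE)
  structure(list(
    locus = a$locus,
    n_species = length(unique(a$species)),
    n_individuals = nrow(m),
    aligned_length = L,
    seq_length_range = c(min(ungapped), max(ungapped)),
    n_variable_sites = nv,
    pct_variable = round(100 * nv / L, 2L),
    n_parsimony_informative = npi,
    pct_pi = round(100 * npi / L, 2L),
    n_indel_events = ind$n_events,
    indel_length_range = c(ind$min_length, ind$max_length)),
    class = "alignment_stats")
}

#' @export
print.alignment_stats <- function(x, ...) {
  cat("Alignment characteristics [", x$locus, "]\n", sep = "")
  cat("  species (individuals):     ", x$n_species, " (", x$n_individuals,
      ")\n", sep = "")
  cat("  aligned length (bp):       ", x$aligned_length, "\n", sep = "")
  cat("  sequence length (bp):      ", x$seq_length_range[1L], "-",
      x$seq_length_range[2L], "\n", sep = "")
  cat("  variable sites (%):        ", x$n_variable_sites, " (",
      sprintf("%.2f", x$pct_variable), ")\n", sep = "")
  cat("  parsimony-informative (%): ", x$n_parsimony_informative, " (",
      sprintf("%.2f", x$pct_pi), ")\n", sep = "")
  if (x$n_indel_events > 0L)
    cat("  indels (length range):     ", x$n_indel_events, " (",
        x$indel_length_range[1L], "-", x$indel_length_range[2L], ")\n",
        sep = "")
  else cat("  indels (length range):     0\n")
  invisible(x)
}

#' Tabulate alignment characteristics for several loci
#'
#' @param loci named list of `locus_alignment` objects (single loci and/or
#'   concatenations).
#' @param include_outgroup passed to [alignment_stats()].
#' @return data frame, one row per alignment, mirroring the usual
#'   sequence-characteristics table of a barcoding study.
#' @export
stats_table <- function(loci, include_outgroup = FALSE) {
  rows <- lapply(loci, function(a) {
    s <- alignment_stats(a, include_outgroup)
    data.frame(locus = s$locus, n_species = s$n_species,
               n_individuals = s$n_individuals,
               aligned_length = s$aligned_length,
               min_length = s$seq_length_range[1L],
               max_length = s$seq_length_range[2L],
               variable_sites = s$n_variable_sites,
               pct_variable = s$pct_variable,
               parsimony_informative = s$n_parsimony_informative,
               pct_pi = s$pct_pi,
               indel_events = s$n_indel_events,
               indel_min = s$indel_length_range[1L],
               indel_max = s$indel_length_range[2L])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
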