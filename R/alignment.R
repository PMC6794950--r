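#' @importFrom stats quantile rexp rpois runif setNames
#' @importFrom utils combn
NULL

# IUPAC nucleotide codes plus alignment gap '-' and missing '?'
.BC_ALPHABET <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                  "B", "D", "H", "V", "N", "-", "?")
.BC_BASES <- c("A", "C", "G", "T")

#' Construct a locus alignment
#'
#' A `locus_alignment` is a rectangular set of aligned sequences for one
#' barcode locus (or a concatenation of loci), each sequence labelled with a
#' species name and a sample identifier. It is the basic container consumed
#' by all distance, characteristic and discrimination analyses.
#'
#' @param seqs character vector of aligned sequences (equal lengths; IUPAC
#'   nucleotide codes plus `-` for alignment gaps and `?` for missing data,
#'   case-insensitive).
#' @param species character vector of species names (binomials, infraspecific
#'   ranks allowed), one per sequence.
#' @param sample_id character vector of sample identifiers; the pair
#'   (`sample_id`, locus) must be unique.
#' @param locus single string naming the locus.
#' @param outgroup logical vector (or character vector of sample ids) marking
#'   outgroup records; outgroups are kept for tree building but excluded from
#'   all discrimination statistics.
#' @return An object of class `locus_alignment`: a list with elements
#'   `locus`, `sample_id`, `species`, `outgroup`, and `seq` (an upper-case
#'   character matrix with one row per record).
#' @examples
#' aln <- locus_alignment(c("ACGT", "ACGA"), c("Genus_a", "Genus_b"),
#'                        c("s1", "s2"), locus = "demo")
#' aln$aligned_length
#' @export
locus_alignment <- function(seqs, species, sample_id, locus = "locus",
                            outgroup = FALSE) {
  if (length(seqs) == 0L) stop("alignment must contain at least one record")
  if (length(species) != length(seqs) || length(sample_id) != length(seqs))
    stop("'seqs', 'species' and 'sample_id' must have equal lengths")
  if (any(!nzchar(species)) || any(is.na(species)))
    stop("empty or missing species label")
  if (any(!nzchar(sample_id)) || any(is.na(sample_id)))
    stop("empty or missing sample_id")
  if (anyDuplicated(sample_id))
    stop("duplicated sample_id within locus '", locus, "': ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  if (any(lens == 0L)) stop("empty sequence for sample ",
                            sample_id[which(lens == 0L)[1L]])
  if (length(unique(lens)) != 1L) {
    bad <- sample_id[lens != lens[1L]][1L]
    stop("ragged alignment for locus '", locus, "': record '", bad,
         "' has length ", nchar(seqs[sample_id == bad]),
         " but the first record has length ", lens[1L])
  }
  m <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
              nrow = length(seqs), byrow = TRUE,
              dimnames = list(sample_id, NULL))
  bad <- setdiff(unique(as.vector(m)), .BC_ALPHABET)
  if (length(bad))
    stop("invalid characters in alignment: ", paste(bad, collapse = ", "))
  if (is.character(outgroup)) outgroup <- sample_id %in% outgroup
  outgroup <- rep_len(as.logical(outgroup), length(seqs))
  structure(list(locus = locus, sample_id = sample_id, species = species,
                 outgroup = outgroup, seq = m,
                 aligned_length = ncol(m)),
            class = "locus_alignment")
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat("locus_alignment '", x$locus, "': ", nrow(x$seq), " records x ",
      x$aligned_length, " columns, ", length(unique(x$species[!x$outgroup])),
      " ingroup species", if (any(x$outgroup))
        paste0(" (+", sum(x$outgroup), " outgroup records)"), "\n", sep = "")
  invisible(x)
}

#' Number of records in a locus alignment
#' @param x a `locus_alignment`.
#' @export
n_records <- function(x) nrow(x$seq)

#' Subset a locus alignment by sample
#'
#' @param aln a `locus_alignment`.
#' @param samples character vector of sample ids to keep (order preserved as
#'   given).
#' @return a `locus_alignment` restricted to `samples`.
#' @export
subset_alignment <- function(aln, samples) {
  idx <- match(samples, aln$sample_id)
  if (anyNA(idx))
    stop("samples not present in alignment: ",
         paste(samples[is.na(idx)], collapse = ", "))
  locus_alignment(apply(aln$seq[idx, , drop = FALSE], 1L, paste, collapse = ""),
                  aln$species[idx], aln$sample_id[idx], aln$locus,
                  aln$outgroup[idx])
}

# drop outgroup records; errors if nothing remains
ingroup_alignment <- function(aln) {
  if (!any(!aln$outgroup)) stop("no ingroup records in alignment")
  if (!any(aln$outgroup)) return(aln)
  subset_alignment(aln, aln$sample_id[!aln$outgroup])
}

#' Read a species-labelled aligned FASTA file
#'
#' Headers are parsed as `"Genus_species<sep>sample_id"` (default separator
#' `"|"`). Sequences are upper-cased; record order is preserved.
#'
#' @param path path to an aligned FASTA file.
#' @param locus locus name to record; defaults to the file name without
#'   extension.
#' @param label_sep single character separating species from sample id in the
#'   headers.
#' @param outgroup character vector of sample ids to tag as outgroups.
#' @return a [locus_alignment()].
#' @export
read_locus_fasta <- function(path, locus = NULL, label_sep = "|",
                             outgroup = character()) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) stop("empty FASTA file: ", path)
  if (is.null(locus)) locus <- sub("\\.[^.]*$", "", basename(path))
  x <- ape::read.FASTA(path)
  if (length(x) == 0L) stop("no sequences in FASTA file: ", path)
  headers <- names(x)
  parts <- strsplit(headers, label_sep, fixed = TRUE)
  ok <- lengths(parts) == 2L & vapply(parts, function(p) all(nzchar(p)), TRUE)
  if (any(!ok))
    stop("header does not parse as 'species", label_sep, "sample_id': '",
         headers[which(!ok)[1L]], "'")
  seqs <- vapply(as.character(x), paste, "", collapse = "")
  locus_alignment(toupper(seqs),
                  species = vapply(parts, `[[`, "", 1L),
                  sample_id = vapply(parts, `[[`, "", 2L),
                  locus = locus, outgroup = outgroup)
}

#' Write a locus alignment to FASTA
#'
#' The inverse of [read_locus_fasta()]: headers are
#' `species<sep>sample_id`, sequences on one line, record order preserved.
#'
#' @param aln a `locus_alignment`.
#' @param path output file path.
#' @param label_sep header separator, as in [read_locus_fasta()].
#' @export
write_locus_fasta <- function(aln, path, label_sep = "|") {
  seqs <- apply(aln$seq, 1L, paste, collapse = "")
  writeLines(paste0(">", aln$species, label_sep, aln$sample_id, "\n", seqs),
             path)
  invisible(path)
}

#' Species-to-sample map with singleton flags
#'
#' Partitions the (ingroup) samples of an alignment by species and flags
#' singleton species (exactly one sampled individual). Singletons never enter
#' the numerator or denominator of an identification success rate, but remain
#' in distance matrices as potential nearest neighbours.
#'
#' @param aln a `locus_alignment`.
#' @param include_outgroup keep outgroup records in the map (default FALSE).
#' @return An object of class `species_map`: a list with `samples` (named
#'   list species -> character vector of sample ids), `singleton` (named
#'   logical), `n_species`, `n_samples`, `n_singletons`.
#' @export
build_species_map <- function(aln, include_outgroup = FALSE) {
  keep <- if (include_outgroup) rep(TRUE, length(aln$species)) else !aln$outgroup
  if (!any(keep)) stop("no records to map")
  sp <- aln$species[keep]
  ids <- aln$sample_id[keep]
  if (any(!nzchar(sp))) stop("empty species label")
  samples <- split(ids, factor(sp, levels = unique(sp)))
  singleton <- lengths(samples) == 1L
  structure(list(samples = samples, singleton = singleton,
                 n_species = length(samples), n_samples = length(ids),
                 n_singletons = sum(singleton)),
            class = "species_map")
}

#' @export
print.species_map <- function(x, ...) {
  cat("species_map: ", x$n_species, " species, ", x$n_samples, " samples, ",
      x$n_singletons, " singletons\n", sep = "")
  invisible(x)
}

# species label for each sample id, as a named character vector
species_of <- function(map) {
  setNames(rep(names(map$samples), lengths(map$samples)),
           unlist(map$samples, use.names = FALSE))
}

#' Enumerate multi-locus barcode combinations
#'
#' All subsets of size >= 2 of the given loci, ordered by subset size then
#' lexicographically; four loci yield the classic eleven combinations
#' (6 pairs + 4 triples + 1 quadruple).
#'
#' @param locus_names character vector of 2 to 8 locus names.
#' @return list of character vectors, each a combination.
#' @examples
#' length(enumerate_combinations(c("rbcL", "matK", "trnH-psbA", "ITS")))  # 11
#' @export
enumerate_combinations <- function(locus_names) {
  locus_names <- unique(locus_names)
  n <- length(locus_names)
  if (n < 2L || n > 8L) stop("need between 2 and 8 loci, got ", n)
  out <- list()
  sorted <- sort(locus_names)
  for (k in 2:n) {
    sets <- combn(sorted, k, simplify = FALSE)
    ord <- order(vapply(sets, paste, "", collapse = "\r"))
    out <- c(out, sets[ord])
  }
  out
}

#' Concatenate loci into a multi-locus alignment
#'
#' Joins per-locus alignments sample-wise in the order the loci are named.
#' Samples missing from any member locus are dropped (and reported via the
#' `dropped` attribute) rather than padded: padding with missing data would
#' silently deflate pairwise-deletion distances.
#'
#' @param loci named list of `locus_alignment` objects.
#' @param combo character vector (length >= 2) of locus names to join, in
#'   concatenation order.
#' @return a `locus_alignment` whose `locus` is the combo names joined with
#'   `"+"`, with attributes `partition` (data frame of 0-based half-open
#'   column intervals per locus) and `dropped` (sample ids dropped).
#' @export
concatenate_loci <- function(loci, combo = names(loci)) {
  if (length(combo) < 2L) stop("a combination needs at least 2 loci")
  missing_loci <- setdiff(combo, names(loci))
  if (length(missing_loci))
    stop("loci not provided: ", paste(missing_loci, collapse = ", "))
  member <- loci[combo]
  common <- Reduce(intersect, lapply(member, `[[`, "sample_id"))
  all_ids <- unique(unlist(lapply(member, `[[`, "sample_id")))
  if (length(common) == 0L)
    stop("no sample has data for every locus in the combination")
  # keep the sample order of the first member locus
  common <- member[[1L]]$sample_id[member[[1L]]$sample_id %in% common]
  dropped <- setdiff(all_ids, common)
  sub <- lapply(member, subset_alignment, samples = common)
  lens <- vapply(sub, `[[`, 0L, "aligned_length")
  ends <- cumsum(lens)
  part <- data.frame(locus = combo, start = c(0L, ends[-length(ends)]),
                     end = ends, row.names = NULL)
  sp <- sub[[1L]]$species
  for (a in sub[-1L]) {
    conflict <- a$species != sp
    if (any(conflict))
      stop("conflicting species labels for sample ",
           common[which(conflict)[1L]])
  }
  out <- locus_alignment(
    apply(do.call(cbind, lapply(sub, `[[`, "seq")), 1L, paste, collapse = ""),
    species = sp, sample_id = common,
    locus = paste(combo, collapse = "+"),
    outgroup = sub[[1L]]$outgroup)
  attr(out, "partition") <- part
  attr(out, "dropped") <- dropped
  out
}

#' Write a partition table for a concatenated alignment
#'
#' @param aln a concatenated `locus_alignment` (from [concatenate_loci()]).
#' @param path output path for a tab-separated table with columns
#'   `locus`, `start`, `end` (0-based, half-open).
#' @export
write_partition <- function(aln, path) {
  part <- attr(aln, "partition")
  if (is.null(part)) stop("alignment has no partition record")
  utils::write.table(part, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sampling table (voucher-style) and summarise its structure
#'
#' Reads a tab-separated table with one row per sampled individual and one
#' presence column per locus (any non-empty value other than `-` or `NA`
#' counts as present), such as a transcribed voucher/accession table.
#' Returns, per locus, the sampling structure a barcode study reports:
#' numbers of species, individuals and singleton species.
#'
#' @param path path to a TSV with columns `species`, `sample_id`, `group`
#'   (`ingroup`/`outgroup`) and one column per locus.
#' @param loci character vector naming the locus columns; defaults to all
#'   columns after the first three.
#' @return list with `table` (the parsed data frame), `loci`, and
#'   `structure`, a data frame with one row per locus: `n_samples`,
#'   `n_species`, `n_singletons`, `n_eligible` (individuals of non-singleton
#'   species, i.e. the denominator of an identification success rate).
#'   Outgroup rows are excluded from all counts.
#' @export
read_sample_table <- function(path, loci = NULL) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  need <- c("species", "sample_id", "group")
  if (!all(need %in% names(tab)))
    stop("sample table must have columns: ", paste(need, collapse = ", "))
  if (is.null(loci)) loci <- setdiff(names(tab), need)
  if (!length(loci)) stop("no locus columns found")
  ing <- tab[tab$group != "outgroup", , drop = FALSE]
  rows <- lapply(loci, function(lc) {
    present <- !is.na(ing[[lc]]) & nzchar(ing[[lc]]) & ing[[lc]] != "-"
    sp <- ing$species[present]
    counts <- table(sp)
    data.frame(locus = lc, n_samples = sum(present),
               n_species = length(counts),
               n_singletons = sum(counts == 1L),
               n_eligible = sum(counts[counts >= 2L]))
  })
  list(table = tab, loci = loci, structure = do.call(rbind, rows))
}
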