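# Shared fixtures and independent brute-force oracles. The oracles are
# deliberately written as plain loops over characters/pairs/edges so they
# share no code with the implementation they check.

make_aln <- function(seqs, species, ids = NULL, locus = "toy",
                     outgroup = FALSE) {
  if (is.null(ids)) ids <- paste0("s", seq_along(seqs))
  locus_alignment(seqs, species, ids, locus, outgroup)
}

# random alignment at moderate divergence (mutations from one ancestral
# sequence, so K2P stays well inside its domain)
random_aln <- function(n, L, species = NULL, gap_prob = 0, div = 0.08) {
  anc <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  m <- matrix(rep(anc, each = n), n, L)
  hit <- which(matrix(runif(n * L) < div, n, L))
  m[hit] <- sample(c("A", "C", "G", "T"), length(hit), replace = TRUE)
  if (gap_prob > 0)
    m[runif(n * L) < gap_prob] <- "-"
  if (is.null(species)) species <- paste0("sp", seq_len(n))
  make_aln(apply(m, 1, paste, collapse = ""), species)
}

# two well-separated species, two individuals each (10% transition
# divergence between species, none within)
two_clade_aln <- function(L = 60) {
  base <- rep(c("A", "C", "G", "T"), length.out = L)
  other <- base
  other[seq(1, L, by = 10)] <- chartr("ACGT", "GTAC", base[seq(1, L, by = 10)])
  a <- paste(base, collapse = "")
  b <- paste(other, collapse = "")
  make_aln(c(a, a, b, b), c("sp1", "sp1", "sp2", "sp2"),
           c("a1", "a2", "b1", "b2"))
}

# build a k2p_dist-classed matrix directly from numbers (for constructed
# discrimination cases)
dist_fixture <- function(m, species, outgroup = NULL) {
  ids <- rownames(m)
  if (is.null(ids)) {
    ids <- paste0("s", seq_len(nrow(m)))
    dimnames(m) <- list(ids, ids)
  }
  if (is.null(outgroup)) outgroup <- rep(FALSE, nrow(m))
  structure(m, species = stats::setNames(species, ids),
            outgroup = stats::setNames(outgroup, ids),
            class = c("k2p_dist", "matrix", "array"))
}

# ---- oracles ----------------------------------------------------------

# K2P for one pair: explicit per-character loop with a lookup table
oracle_k2p <- function(sa, sb) {
  a <- strsplit(toupper(sa), "")[[1]]
  b <- strsplit(toupper(sb), "")[[1]]
  ti_pairs <- c("AG", "GA", "CT", "TC")
  n <- 0L; ts <- 0L; tv <- 0L
  for (i in seq_along(a)) {
    if (!(a[i] %in% c("A", "C", "G", "T")) ||
        !(b[i] %in% c("A", "C", "G", "T"))) next
    n <- n + 1L
    if (a[i] != b[i]) {
      if (paste0(a[i], b[i]) %in% ti_pairs) ts <- ts + 1L else tv <- tv + 1L
    }
  }
  if (n == 0L) return(NA_real_)
  P <- ts / n; Q <- tv / n
  if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0) return(NA_real_)
  -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q))
}

# column classification by direct enumeration
oracle_col_class <- function(col) {
  bases <- col[col %in% c("A", "C", "G", "T")]
  tab <- table(bases)
  list(variable = sum(tab >= 1) >= 2, informative = sum(tab >= 2) >= 2)
}

oracle_variable_count <- function(m) {
  sum(apply(m, 2, function(col) oracle_col_class(col)$variable))
}

oracle_pi_count <- function(m) {
  sum(apply(m, 2, function(col) oracle_col_class(col)$informative))
}

# indel events by direct scan of column gap-sets
oracle_indels <- function(m) {
  sets <- apply(m == "-", 2, function(col) paste(which(col), collapse = ","))
  events <- integer(0)
  cur <- ""
  len <- 0L
  for (s in c(sets, "")) {
    if (s == cur && nzchar(s)) { len <- len + 1L; next }
    if (nzchar(cur)) events <- c(events, len)
    cur <- s
    len <- 1L
  }
  events
}

# nearest-neighbour verdict by direct loop
oracle_best_match <- function(query, m, species, threshold = Inf) {
  ids <- rownames(m)
  best <- Inf; matches <- character(0)
  for (j in seq_along(ids)) {
    if (ids[j] == query || is.na(m[query, j])) next
    if (m[query, j] < best - 1e-15) { best <- m[query, j]; matches <- ids[j] }
    else if (abs(m[query, j] - best) <= 1e-9 * max(best, 1))
      matches <- c(matches, ids[j])
  }
  msp <- unique(species[matches])
  qsp <- species[query]
  if (best > threshold) return("no_match")
  if (all(msp == qsp)) "correct"
  else if (!(qsp %in% msp)) "incorrect"
  else "ambiguous"
}

# local-gap success by direct loops over sample pairs
oracle_local_gap <- function(sp, m, species) {
  ids <- names(species)[species == sp]
  others <- setdiff(names(species), ids)
  intra <- c(); inter <- c()
  for (i in ids) for (j in ids) if (i < j && !is.na(m[i, j]))
    intra <- c(intra, m[i, j])
  for (i in ids) for (j in others) if (!is.na(m[i, j]))
    inter <- c(inter, m[i, j])
  min(inter) > max(intra)
}

# monophyly through an independent route: root the tree at a leaf outside
# the set, then ask ape whether the set is a clade
oracle_monophyletic <- function(tree, tips) {
  out <- setdiff(tree$tip.label, tips)
  rooted <- ape::root(tree, outgroup = out[1], resolve.root = TRUE)
  ape::is.monophyletic(rooted, tips)
}
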