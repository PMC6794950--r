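test_that("K2P pair distance matches the closed form on canonical cases", {
  p <- k2p_pair("AAAAAAAAAA", "AAAAAAAAAA")
  expect_identical(p$P, 0)
  expect_identical(p$Q, 0)
  expect_identical(p$d, 0)
  p2 <- k2p_pair("AAAAAAAAAA", "GAAAAAAAAA")
  expect_equal(p2$P, 0.1)
  expect_equal(p2$Q, 0)
  expect_equal(p2$d, -0.5 * log(0.8), tolerance = 1e-15)
  # all-transversion pair: log-domain boundary
  p3 <- k2p_pair("AAAA", "TTTT")
  expect_identical(p3$Q, 1)
  expect_true(p3$undefined)
  expect_match(p3$reason, "saturated")
  # no comparable sites
  p4 <- k2p_pair("--NN", "AC??")
  expect_true(p4$undefined)
  expect_match(p4$reason, "no comparable")
})

test_that("pairwise deletion removes exactly gap/missing/ambiguous columns", {
  p <- k2p_pair("ACGT-RA?", "ACGAAAAA")
  # columns 5 (gap), 6 (R), 8 (?) excluded -> 5 sites, 1 transition (T/A? no:
  # column 4 T vs A is a transversion)
  expect_identical(p$n_sites, 5L)
  expect_identical(p$n_transversions, 1L)
  expect_identical(p$n_transitions, 0L)
  # appending identical gap columns changes nothing
  q <- k2p_pair("ACGT-RA?--", "ACGAAAAA--")
  expect_identical(q[c("n_sites", "P", "Q", "d")],
                   p[c("n_sites", "P", "Q", "d")])
})

test_that("K2P is symmetric and equals an independent per-character oracle", {
  set.seed(17)
  for (rep in 1:50) {
    L <- sample(30:120, 1)
    a <- paste(sample(c("A", "C", "G", "T", "-", "N"), L, replace = TRUE,
                      prob = c(rep(0.23, 4), 0.04, 0.04)), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T", "-", "N"), L, replace = TRUE,
                      prob = c(rep(0.23, 4), 0.04, 0.04)), collapse = "")
    got <- k2p_pair(a, b)$d
    want <- oracle_k2p(a, b)
    if (is.na(want)) expect_true(is.na(got))
    else expect_equal(got, want, tolerance = 1e-12)
    expect_equal(k2p_pair(b, a)$d, got, tolerance = 0)
  }
})

test_that("distance matrix equals the per-pair route and ape's K80", {
  set.seed(23)
  aln <- random_aln(7, 200, gap_prob = 0.03)
  mat <- distance_matrix(aln, warn = FALSE)
  expect_true(isSymmetric(unclass(mat)))
  expect_identical(unname(diag(mat)), rep(0, 7))
  for (i in 1:6) for (j in (i + 1):7)
    expect_equal(mat[i, j],
                 k2p_pair(paste(aln$seq[i, ], collapse = ""),
                          paste(aln$seq[j, ], collapse = ""))$d,
                 tolerance = 1e-14)
  # gap-free case cross-checked against an established implementation
  aln2 <- random_aln(6, 300)
  mat2 <- distance_matrix(aln2, warn = FALSE)
  bin <- ape::as.DNAbin(strsplit(apply(aln2$seq, 1, paste, collapse = ""), ""))
  names(bin) <- aln2$sample_id
  ref <- as.matrix(ape::dist.dna(bin, model = "K80",
                                 pairwise.deletion = TRUE))
  expect_equal(unclass(mat2), ref[rownames(mat2), colnames(mat2)],
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("matrix entries are permutation-equivariant in sample order", {
  set.seed(29)
  aln <- random_aln(6, 80)
  mat <- distance_matrix(aln, warn = FALSE)
  perm <- sample(aln$sample_id)
  matp <- distance_matrix(subset_alignment(aln, perm), warn = FALSE)
  expect_equal(unclass(matp), unclass(mat)[perm, perm],
               tolerance = 1e-15, ignore_attr = TRUE)
})

test_that("undefined entries are flagged, warned about, and excluded", {
  # first pair shares no comparable site; the others are defined
  aln <- make_aln(c("AAA---", "---AAA", "AAAAAA"), c("a", "a", "b"))
  expect_warning(mat <- distance_matrix(aln), "undefined")
  expect_true(is.na(mat["s1", "s2"]))
  part <- partition_distances(mat)
  expect_identical(part$n_undefined, 1L)
  expect_identical(nrow(part$intra) + nrow(part$inter), 2L)
})

test_that("partition splits pairs by species with combinatorial counts", {
  aln <- make_aln(c("AAAAAA", "AAAAAT", "AAGGAA"), c("A", "A", "B"),
                  c("a1", "a2", "b1"))
  part <- partition_distances(distance_matrix(aln, warn = FALSE))
  expect_identical(nrow(part$intra), 1L)
  expect_identical(nrow(part$inter), 2L)
  # random labelled matrices: class sizes match the combinatorial count
  set.seed(37)
  for (rep in 1:10) {
    n <- sample(4:10, 1)
    sp <- sample(letters[1:3], n, replace = TRUE)
    aln <- random_aln(n, 40, species = sp)
    part <- partition_distances(distance_matrix(aln, warn = FALSE))
    tab <- table(sp)
    expect_identical(nrow(part$intra), as.integer(sum(choose(tab, 2))))
    expect_identical(nrow(part$inter),
                     as.integer(choose(n, 2) - sum(choose(tab, 2))))
  }
  # all singletons -> empty intraspecific class
  aln2 <- random_aln(4, 20)
  expect_identical(nrow(partition_distances(
    distance_matrix(aln2, warn = FALSE))$intra), 0L)
})

test_that("distance summary equals a direct recomputation from pair lists", {
  set.seed(41)
  aln <- random_aln(8, 100, species = c("A", "A", "A", "B", "B", "C", "C", "D"))
  part <- partition_distances(distance_matrix(aln, warn = FALSE))
  s <- summarize_distances(part)
  expect_equal(s$mean_inter, mean(part$inter$d))
  expect_equal(s$mean_intra, mean(part$intra$d))
  expect_equal(s$mean_all, mean(c(part$intra$d, part$inter$d)))
  expect_equal(s$min_inter, min(part$inter$d))
  expect_equal(s$max_intra, max(part$intra$d))
  expect_lte(s$min_inter, s$mean_inter)
  # empty intraspecific class: mean 0 with a flag
  s0 <- summarize_distances(partition_distances(
    distance_matrix(random_aln(3, 30), warn = FALSE)))
  expect_identical(s0$mean_intra, 0)
  expect_true(s0$intra_empty)
})

test_that("distance matrix writes PHYLIP and long formats", {
  aln <- make_aln(c("AAAAAA", "AAAAAT", "AAGGAA"), c("A", "A", "B"),
                  c("a1", "a2", "b1"))
  mat <- distance_matrix(aln, warn = FALSE)
  p1 <- withr::local_tempfile(fileext = ".phy")
  write_distance_matrix(mat, p1, "phylip")
  expect_identical(trimws(readLines(p1)[1]), "3")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_distance_matrix(mat, p2, "long")
  tab <- read.delim(p2)
  expect_identical(nrow(tab), 3L)
  expect_setequal(unique(tab$class), c("intraspecific", "interspecific"))
})
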