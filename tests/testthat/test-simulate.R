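test_that("the species tree is ultrametric, seeded and correctly sized", {
  tr <- simulate_species_tree(2, seed = 1)
  expect_identical(ape::Ntip(tr), 2L)
  t1 <- ape::write.tree(simulate_species_tree(8, seed = 4))
  t2 <- ape::write.tree(simulate_species_tree(8, seed = 4))
  expect_identical(t1, t2)
  t3 <- ape::write.tree(simulate_species_tree(8, seed = 5))
  expect_false(identical(t1, t3))
  tr8 <- simulate_species_tree(8, seed = 4)
  depths <- ape::node.depth.edgelength(tr8)[seq_len(8)]
  expect_lt(diff(range(depths)), 1e-9)
})

test_that("mean Yule root height matches its closed-form expectation", {
  lambda <- 2
  n <- 10
  set.seed(5)
  heights <- replicate(500, {
    tr <- simulate_species_tree(n, birth_rate = lambda)
    max(ape::node.depth.edgelength(tr))
  })
  expected <- sum(1 / (2:n)) / lambda
  expect_lt(abs(mean(heights) - expected) / expected, 0.1)
})

test_that("generation is fully deterministic under a fixed seed", {
  cfg <- pulsatilla_profile(seed = 33)
  s1 <- generate_dataset(cfg)
  s2 <- generate_dataset(cfg)
  for (nm in names(s1$loci))
    expect_identical(s1$loci[[nm]]$seq, s2$loci[[nm]]$seq)
  expect_identical(s1$truth$species_tree, s2$truth$species_tree)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_dataset(s1, d1); write_dataset(s2, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("the preset reproduces the intended sampling structure", {
  sim <- generate_dataset(pulsatilla_profile(seed = 2))
  map <- build_species_map(sim$loci$ITS)
  expect_identical(map$n_species, 19L)
  expect_identical(map$n_samples, 52L)
  expect_identical(map$n_singletons, 9L)
  expect_identical(nrow(sim$loci$rbcL$seq), 50L)
  expect_identical(nrow(sim$loci$matK$seq), 50L)
  expect_identical(sim$loci$ITS$aligned_length, 589L)
  expect_identical(sim$loci$rbcL$aligned_length, 1207L)
})

test_that("zero within-species depth makes every species monophyletic in
           every gene tree", {
  sim <- generate_dataset(sim_config(
    n_individuals = c(3L, 2L, 2L, 1L, 2L),
    loci = list(locus_config("p", 300L, inheritance = "plastid"),
                locus_config("n", 300L, inheritance = "nuclear")),
    mean_divergence = 0.05, intra_depth = 0, seed = 41))
  truth <- sim$truth$table
  for (gt in sim$truth$gene_trees) {
    tr <- ape::read.tree(text = gt)
    for (s in unique(truth$species)) {
      ids <- truth$sample_id[truth$species == s]
      if (length(ids) < 2 || length(ids) > ape::Ntip(tr) - 2) next
      expect_true(oracle_monophyletic(tr, ids))
    }
  }
})

test_that("forced chloroplast capture interleaves exactly the chosen pair", {
  base_cfg <- sim_config(
    n_individuals = c(2L, 2L, 2L, 2L, 2L),
    loci = list(locus_config("p", 300L, inheritance = "plastid"),
                locus_config("n", 300L, inheritance = "nuclear")),
    mean_divergence = 0.05, intra_depth = 0, seed = 47)
  base <- generate_dataset(base_cfg)
  # pick a sister pair straight from the generated species tree
  sp_tr <- ape::read.tree(text = base$truth$species_tree)
  pair <- NULL
  for (node in (ape::Ntip(sp_tr) + 1):(ape::Ntip(sp_tr) + sp_tr$Nnode)) {
    kids <- sp_tr$edge[sp_tr$edge[, 1] == node, 2]
    if (all(kids <= ape::Ntip(sp_tr))) { pair <- sp_tr$tip.label[kids]; break }
  }
  # every binary tree has a cherry, so `pair` is always found
  cfg <- base_cfg
  cfg$introgression_pairs <- list(pair)
  sim <- generate_dataset(cfg)
  expect_identical(sim$truth$introgression$recipient, pair[1])
  truth <- sim$truth$table
  ptr <- ape::read.tree(text = sim$truth$gene_trees$plastid)
  ntr <- ape::read.tree(text = sim$truth$gene_trees$nuclear)
  rec_ids <- truth$sample_id[truth$species == pair[1]]
  donor_ids <- truth$sample_id[truth$species == pair[2]]
  # plastid: recipient + donor form one cluster, recipient alone does not
  expect_true(oracle_monophyletic(ptr, c(rec_ids, donor_ids)))
  expect_false(oracle_monophyletic(ptr, rec_ids))
  # nuclear genealogy is untouched
  expect_true(oracle_monophyletic(ntr, rec_ids))
  expect_true(oracle_monophyletic(ntr, donor_ids))
  # and the event is recorded against the right samples
  expect_identical(
    sort(truth$sample_id[!is.na(truth$introgression_donor)]),
    sort(rec_ids))
})

test_that("sequence evolution respects branch lengths and kappa", {
  # zero-length tree: identical sequences
  tr <- ape::read.tree(text = "(a:0,b:0);")
  aln <- evolve_sequences(tr, locus_config("z", 200L),
                          c(a = "A", b = "B"), seed = 51)
  expect_identical(aln$seq["a", ], aln$seq["b", ])
  # transition:transversion counts consistent with kappa at long length
  kappa <- 4
  tr2 <- ape::read.tree(text = "(a:0.025,b:0.025);")
  ts_all <- 0; tv_all <- 0
  for (s in 1:20) {
    aln2 <- evolve_sequences(tr2, locus_config("z", 5000L, kappa = kappa),
                             c(a = "A", b = "B"), seed = 600 + s)
    p <- k2p_pair(paste(aln2$seq["a", ], collapse = ""),
                  paste(aln2$seq["b", ], collapse = ""))
    ts_all <- ts_all + p$n_transitions
    tv_all <- tv_all + p$n_transversions
  }
  # expected P/Q ratio for K80 at distance t (standard closed form)
  t <- 0.05; beta <- 1 / (kappa + 2); alpha <- kappa * beta
  P_exp <- 0.25 + 0.25 * exp(-4 * beta * t) - 0.5 * exp(-2 * (alpha + beta) * t)
  Q_exp <- 0.5 - 0.5 * exp(-4 * beta * t)
  expect_lt(abs((ts_all / tv_all) / (P_exp / Q_exp) - 1), 0.15)
})

test_that("indel events are shared by descendants and keep the alignment
           rectangular", {
  set.seed(57)
  sim <- generate_dataset(sim_config(
    n_individuals = c(3L, 3L, 2L),
    loci = list(locus_config("g", 400L, indel_mean = 6,
                             indel_len = c(2L, 10L))),
    mean_divergence = 0.05, intra_depth = 0.002, seed = 61))
  aln <- sim$loci$g
  expect_identical(unique(nchar(apply(aln$seq, 1, paste, collapse = ""))),
                   400L)
  ind <- count_indel_events(aln)
  expect_gte(ind$n_events, 1L)
  expect_gte(ind$min_length, 1L)
})

test_that("variable-site percentages follow the configured rate ordering", {
  set.seed(63)
  rates <- c(slow = 0.1, mid = 0.3, fast = 1)
  wins <- 0L
  for (rep in 1:10) {
    sim <- generate_dataset(sim_config(
      n_individuals = rep(2L, 8),
      loci = list(locus_config("slow", 600L, rate = rates["slow"]),
                  locus_config("mid", 600L, rate = rates["mid"]),
                  locus_config("fast", 600L, rate = rates["fast"])),
      mean_divergence = 0.04, intra_depth = 0.001, seed = 700 + rep))
    pv <- vapply(sim$loci, function(a) alignment_stats(a)$pct_variable, 0)
    if (all(order(pv) == order(rates))) wins <- wins + 1L
  }
  expect_gte(wins, 8L)
})
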