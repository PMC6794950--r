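test_that("best match categorises by the tied nearest-neighbour set", {
  m <- matrix(c(0,     0.001, 0.01,  0.01,
                0.001, 0,     0.01,  0.01,
                0.01,  0.01,  0,     0.002,
                0.01,  0.01,  0.002, 0), 4, 4)
  mat <- dist_fixture(m, c("A", "A", "B", "B"))
  expect_identical(best_match("s1", mat)$category, "correct")
  # tie between conspecific and allospecific -> ambiguous
  m2 <- m
  m2[1, 3] <- m2[3, 1] <- 0.001
  v <- best_match("s1", dist_fixture(m2, c("A", "A", "B", "B")))
  expect_identical(v$category, "ambiguous")
  expect_setequal(v$matched_species, c("A", "B"))
  # nearest is purely allospecific -> incorrect
  m3 <- m
  m3[1, 2] <- m3[2, 1] <- 0.05
  expect_identical(best_match("s1",
                              dist_fixture(m3, c("A", "A", "B", "B")))$category,
                   "incorrect")
})

test_that("the intraspecific threshold is the interpolated percentile", {
  part <- structure(list(intra = data.frame(sample_a = letters[1:4],
                                            sample_b = LETTERS[1:4],
                                            d = c(0, 0, 0, 0.01)),
                         inter = data.frame(), n_undefined = 0L),
                    class = "pair_partition")
  expect_equal(intraspecific_threshold(part, 95), 0.0085)
  expect_equal(intraspecific_threshold(part, 100), 0.01)
  # monotone in the percentile
  ps <- c(50, 75, 90, 95, 99)
  ths <- vapply(ps, function(p) intraspecific_threshold(part, p), 0)
  expect_true(all(diff(ths) >= 0))
  # all-zero intraspecific distances -> 0
  part0 <- part
  part0$intra$d <- rep(0, 4)
  expect_identical(intraspecific_threshold(part0, 95), 0)
})

test_that("best close match adds only the no_match reclassification", {
  m <- matrix(c(0, 0.2, 0.2, 0), 2, 2)
  mat <- dist_fixture(m, c("A", "B"))
  expect_identical(best_close_match("s1", mat, threshold = 0.01)$category,
                   "no_match")
  # an infinite threshold reduces exactly to best match
  set.seed(61)
  for (rep in 1:20) {
    n <- sample(4:9, 1)
    sp <- sample(c("A", "A", "B", "B", sample(c("A", "B", "C"), n - 4,
                                              replace = TRUE)))
    d <- matrix(runif(n * n, 0, 0.1), n, n)
    d <- (d + t(d)) / 2; diag(d) <- 0
    mat <- dist_fixture(d, sp)
    for (q in rownames(mat)) {
      bm <- best_match(q, mat)
      bcm <- best_close_match(q, mat, threshold = Inf)
      expect_identical(bcm$category, bm$category)
      expect_identical(bcm$matched_species, bm$matched_species)
    }
  }
})

test_that("verdicts equal a brute-force nearest-neighbour classifier", {
  set.seed(67)
  for (rep in 1:200) {
    n <- sample(4:10, 1)
    sp <- sample(letters[1:3], n, replace = TRUE)
    d <- matrix(runif(n * n, 0, 0.1), n, n)
    d <- (d + t(d)) / 2; diag(d) <- 0
    mat <- dist_fixture(d, sp)
    species <- attr(mat, "species")
    thr <- runif(1, 0, 0.08)
    q <- sample(rownames(mat), 1)
    expect_identical(best_match(q, mat)$category,
                     oracle_best_match(q, mat, species))
    expect_identical(best_close_match(q, mat, threshold = thr)$category,
                     oracle_best_match(q, mat, species, threshold = thr))
  }
})

test_that("BCM never upgrades a BM verdict, only reclassifies to no_match", {
  set.seed(71)
  for (rep in 1:30) {
    n <- sample(5:9, 1)
    sp <- sample(c("A", "A", "B", "B", "C")[1:min(5, n)], n, replace = TRUE)
    d <- matrix(runif(n * n, 0, 0.1), n, n)
    d <- (d + t(d)) / 2; diag(d) <- 0
    mat <- dist_fixture(d, sp)
    thr <- runif(1, 0, 0.05)
    for (q in rownames(mat)) {
      bm <- best_match(q, mat)$category
      bcm <- best_close_match(q, mat, threshold = thr)$category
      expect_true(bcm == bm || bcm == "no_match")
    }
  }
})

test_that("identification runs over eligible queries only and summarises", {
  aln <- two_clade_aln()
  # add a singleton: reference but never query
  far <- paste(rep(c("G", "T"), 30), collapse = "")
  aln2 <- make_aln(c(apply(aln$seq, 1, paste, collapse = ""), far),
                   c(aln$species, "solo"), c(aln$sample_id, "z1"))
  mat <- distance_matrix(aln2, warn = FALSE)
  verdicts <- identify_all(mat, method = "bm")
  expect_length(verdicts, 4L)
  expect_false("z1" %in% vapply(verdicts, `[[`, "", "query"))
  s <- summarize_identification(verdicts)
  expect_identical(s$counts[["correct"]], 4L)
  expect_equal(sum(s$pct), 100, tolerance = 0.05)
})

test_that("summary percentages follow the category counts", {
  mk_v <- function(cat) structure(list(query = "q", best_distance = 0.01,
                                       matched_species = "A",
                                       category = cat),
                                  class = "query_verdict")
  s <- summarize_identification(lapply(c("correct", "correct", "correct",
                                         "incorrect"), mk_v))
  expect_equal(unname(s$pct[c("correct", "ambiguous", "incorrect")]),
               c(75, 0, 25))
  # counts conserved under permutation
  s2 <- summarize_identification(lapply(c("incorrect", "correct", "correct",
                                          "correct"), mk_v))
  expect_identical(s$counts, s2$counts)
  # 34 correct of 43 queries reproduces the familiar 79.07%
  s3 <- summarize_identification(lapply(rep(c("correct", "ambiguous"),
                                            c(34, 9)), mk_v))
  expect_equal(unname(s3$pct[["correct"]]), 79.07)
})

test_that("removing a singleton from the reference only affects queries
           that matched it", {
  set.seed(73)
  aln <- random_aln(7, 80, species = c("A", "A", "B", "B", "C", "C", "solo"))
  mat <- distance_matrix(aln, warn = FALSE)
  before <- identify_all(mat, method = "bm")
  aln2 <- subset_alignment(aln, setdiff(aln$sample_id, "s7"))
  after <- identify_all(distance_matrix(aln2, warn = FALSE), method = "bm")
  vb <- verdict_table(before); va <- verdict_table(after)
  touched <- vb$query[grepl("solo", vb$matched_species)]
  same <- setdiff(vb$query, touched)
  expect_identical(va$category[match(same, va$query)],
                   vb$category[match(same, vb$query)])
})
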