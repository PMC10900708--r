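test_that("gap_penalties enforces open <= extend <= 0", {
  g <- gap_penalties()
  expect_equal(c(g$open, g$extend), c(-11, -1))
  expect_error(gap_penalties(-1, -11), "open <= extend")
  expect_error(gap_penalties(-5, 1), "open <= extend")
})

test_that("local alignment floors at zero and finds perfect diagonals", {
  neg <- matrix(-c(1, 5, 3, 8), 2, 2)
  aln <- smith_waterman(neg)
  expect_equal(aln$score, 0)
  expect_identical(nrow(aln$pairs), 0L)
  expect_identical(aln$qry_span, c(0L, 0L))

  S <- matrix(-10, 3, 3); diag(S) <- 10
  aln2 <- smith_waterman(S)
  expect_equal(aln2$score, 30)
  expect_identical(unname(aln2$pairs[, 1L]), 0:2)
  expect_identical(unname(aln2$pairs[, 2L]), 0:2)
})

test_that("global alignment consumes both sequences and penalizes end gaps", {
  aln <- needleman_wunsch(matrix(7, 1, 1))
  expect_equal(aln$score, 7)
  expect_identical(unname(aln$pairs), matrix(c(0L, 0L), 1))

  S <- matrix(c(9, -9, -9, 9), 2, 2)
  aln2 <- needleman_wunsch(S)
  expect_equal(aln2$score, 18)
  expect_identical(aln2$moves, "DD")

  # 2x1: one end gap is unavoidable and charged as a fresh open
  S3 <- matrix(c(5, 5), 2, 1)
  aln3 <- needleman_wunsch(S3, gap_penalties(-3, -1))
  expect_equal(aln3$score, 5 - 3)
})

test_that("DP matches the exhaustive oracle on random matrices", {
  set.seed(101)
  for (t in 1:200) {
    S <- random_score_matrix(max_dim = 5L)
    g <- gap_penalties()
    expect_same_alignment(smith_waterman(S, g),
                          brute_force_align(S, g, "local"))
    expect_same_alignment(needleman_wunsch(S, g),
                          brute_force_align(S, g, "global"))
  }
})

test_that("DP matches the oracle under exact score ties", {
  set.seed(202)
  for (t in 1:150) {
    m <- sample(1:4, 1L); n <- sample(1:4, 1L)
    S <- matrix(sample(c(-11, 0, 10), m * n, replace = TRUE), m, n)
    g <- gap_penalties()
    expect_same_alignment(smith_waterman(S, g),
                          brute_force_align(S, g, "local"))
    expect_same_alignment(needleman_wunsch(S, g),
                          brute_force_align(S, g, "global"))
  }
})

test_that("oracle equivalence holds under equal open/extend penalties", {
  set.seed(77)
  g <- gap_penalties(-2, -2)
  for (t in 1:40) {
    S <- matrix(sample(-4:6, 12, replace = TRUE), 3, 4)
    expect_same_alignment(smith_waterman(S, g),
                          brute_force_align(S, g, "local"))
    expect_same_alignment(needleman_wunsch(S, g),
                          brute_force_align(S, g, "global"))
  }
})

test_that("score audit reproduces every DP score", {
  set.seed(303)
  g <- gap_penalties()
  for (t in 1:100) {
    S <- random_score_matrix(max_dim = 8L)
    for (aln in list(smith_waterman(S, g), needleman_wunsch(S, g))) {
      expect_equal(score_audit(aln, S, g), aln$score, tolerance = 1e-9)
    }
  }
})

test_that("score audit applies the stated gap convention", {
  # one pair then a 3-long interior gap then another pair
  S <- matrix(-20, 5, 2)
  S[1, 1] <- 30; S[5, 2] <- 30
  aln <- smith_waterman(S)
  expect_identical(aln$moves, "DUUUD")
  expect_equal(aln$score, 30 + 30 + (-11 - 2 * 1))
  expect_equal(score_audit(aln, S, gap_penalties()), aln$score)
  # single pair
  S1 <- matrix(c(-1, 4), 1, 2)
  a1 <- smith_waterman(S1)
  expect_equal(score_audit(a1, S1, gap_penalties()), 4)
  # inconsistent pairs are rejected
  bad <- a1
  bad$pairs <- cbind(i = 5L, j = 0L)
  expect_error(score_audit(bad, S1), "out of matrix bounds")
})

test_that("adding a positive constant never decreases the local score", {
  set.seed(404)
  for (t in 1:30) {
    S <- random_score_matrix(max_dim = 6L)
    base <- smith_waterman(S)$score
    up <- smith_waterman(S + 2.5)$score
    expect_gte(up, base)
  }
})

test_that("transposing the matrix mirrors pairs and preserves scores", {
  set.seed(505)
  for (t in 1:30) {
    S <- random_score_matrix(max_dim = 6L)
    for (fn in list(smith_waterman, needleman_wunsch)) {
      a <- fn(S)
      b <- fn(t(S))
      expect_equal(a$score, b$score, tolerance = 1e-9)
      expect_identical(unname(a$pairs[, c(2L, 1L), drop = FALSE]),
                       unname(b$pairs))
    }
  }
})

test_that("global alignment of noise-free planted twins is the full diagonal", {
  spec <- synthetic_pair_spec(cbind(0:19, 0:19), 20L, 20L, dim = 64L,
                              noise_sigma = 0, seed = 6L)
  syn <- generate_synthetic_pair(spec)
  S <- embedding_score_matrix(syn$emb_a, syn$emb_b)
  aln <- needleman_wunsch(S)
  expect_identical(aln$moves, strrep("D", 20L))
  expect_equal(aln$score, 200, tolerance = 1e-6)
})

test_that("alignment_strings renders gapped rows consistent with the pairs", {
  sa <- protein_seq("a", "MKLVW")
  sb <- protein_seq("b", "MKW")
  S <- matrix(-5, 5, 3)
  S[1, 1] <- 10; S[2, 2] <- 10; S[5, 3] <- 30
  aln <- alignment_strings(smith_waterman(S), sa, sb)
  expect_identical(aln$gapped_a, "MKLVW")
  expect_identical(aln$gapped_b, "MK--W")
  expect_identical(degap(aln$gapped_a),
                   substr(sa$residues, aln$qry_span[1L] + 1L,
                          aln$qry_span[2L]))
})

test_that("brute force guards against oversized instances", {
  expect_error(brute_force_align(matrix(0, 7, 6)), "too large")
})
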