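test_that("column_pairs walks gapped rows to ungapped indices", {
  # columns (A,A),(C,-),(D,E) -> {(0,0),(2,1)}
  ref <- pairwise_reference("a", "b", "ACD", "A-E")
  expect_identical(unname(column_pairs(ref)$pairs),
                   matrix(c(0L, 2L, 0L, 1L), 2))
  # gapless identity alignment of length L -> L pairs
  ref2 <- pairwise_reference("a", "b", "WYFH", "WYFH")
  expect_identical(nrow(column_pairs(ref2)$pairs), 4L)
  # empty local alignment -> empty set
  empty <- smith_waterman(matrix(-1, 2, 2))
  expect_identical(nrow(column_pairs(empty)$pairs), 0L)
})

test_that("sp_score is the recovered fraction of reference pairs", {
  ref <- pairwise_reference("a", "b", "ACDE", "ACDE")
  rp <- column_pairs(ref)
  expect_equal(sp_score(rp, rp), 1)
  disjoint <- structure(list(pairs = cbind(i = 7L, j = 7L)),
                        class = "column_pair_set")
  expect_equal(sp_score(disjoint, rp), 0)
  ref4 <- structure(list(pairs = cbind(i = c(0L, 1L, 2L, 3L),
                                       j = c(0L, 1L, 2L, 3L))),
                    class = "column_pair_set")
  test3 <- structure(list(pairs = cbind(i = c(0L, 1L, 9L),
                                        j = c(0L, 1L, 9L))),
                     class = "column_pair_set")
  expect_equal(sp_score(test3, ref4), 0.5)
  emptyset <- structure(list(pairs = cbind(i = integer(0), j = integer(0))),
                        class = "column_pair_set")
  expect_error(sp_score(rp, emptyset), "empty")
})

test_that("f1_score is the harmonic mean of recall and precision", {
  ref4 <- structure(list(pairs = cbind(i = 0:3, j = 0:3)),
                    class = "column_pair_set")
  expect_equal(f1_score(ref4, ref4), 1)
  empty <- structure(list(pairs = cbind(i = integer(0), j = integer(0))),
                     class = "column_pair_set")
  expect_equal(f1_score(empty, ref4), 0)
  # |ref|=4, |test|=2, both correct: recall .5, precision 1, F1 = 2/3
  test2 <- structure(list(pairs = cbind(i = 0:1, j = 0:1)),
                     class = "column_pair_set")
  expect_equal(f1_score(test2, ref4), 2 / 3)
  expect_error(f1_score(ref4, empty), "empty")
})

test_that("SP and F1 are 1 on self and bounded on random sets", {
  set.seed(42)
  for (t in 1:100) {
    n <- sample.int(20L, 1L)
    i <- sort(sample.int(50L, n)) - 1L
    j <- sort(sample.int(50L, n)) - 1L
    x <- structure(list(pairs = cbind(i = i, j = j)),
                   class = "column_pair_set")
    expect_equal(sp_score(x, x), 1)
    expect_equal(f1_score(x, x), 1)
    m <- sample.int(20L, 1L)
    y <- structure(list(pairs = cbind(i = sort(sample.int(50L, m)) - 1L,
                                      j = sort(sample.int(50L, m)) - 1L)),
                   class = "column_pair_set")
    sp <- sp_score(y, x); f1 <- f1_score(y, x)
    expect_true(sp >= 0 && sp <= 1 && f1 >= 0 && f1 <= 1)
    if (f1 == 1) expect_setequal(embalign:::pair_keys(y),
                                 embalign:::pair_keys(x))
  }
})

test_that("SP is anchored to the reference: extra test pairs can't change it", {
  ref <- structure(list(pairs = cbind(i = 0:4, j = 0:4)),
                   class = "column_pair_set")
  base <- structure(list(pairs = cbind(i = 0:2, j = 0:2)),
                    class = "column_pair_set")
  with_extra <- structure(list(pairs = cbind(i = c(0:2, 30L, 40L),
                                             j = c(0:2, 31L, 41L))),
                          class = "column_pair_set")
  expect_equal(sp_score(base, ref), sp_score(with_extra, ref))
})

test_that("bin_results bins half-open, suppresses small bins, clamps overflow", {
  res <- data.frame(sp = rep(0.5, 10), f1 = rep(0.5, 10),
                    identity_pct = c(9.99, rep(10, 9)),
                    alignment_length = rep(100L, 10))
  b <- bin_results(res, "identity")
  expect_equal(b$count[1L], 1)  # 9.99 in [0,10)
  expect_equal(b$count[2L], 9)  # 10.0 in [10,20)
  expect_true(all(b$suppressed[1:2]))
  expect_true(all(is.na(b$mean_sp[1:2])))

  res10 <- data.frame(sp = rep(0.5, 10), f1 = rep(0.25, 10),
                      identity_pct = rep(15, 10),
                      alignment_length = rep(100L, 10))
  b10 <- bin_results(res10, "identity")
  expect_false(b10$suppressed[2L])
  expect_equal(b10$mean_sp[2L], 0.5)
  expect_equal(b10$mean_f1[2L], 0.25)
  expect_equal(b10$n_zero_sp[2L], 0)

  over <- data.frame(sp = 0, f1 = 0, identity_pct = 5,
                     alignment_length = 9000L)
  expect_warning(bo <- bin_results(over, "length"), "clamped")
  expect_equal(bo$count[nrow(bo)], 1)
  expect_equal(bo$n_zero_sp[nrow(bo)], 1)
  expect_error(bin_results(res, "identity", edges = c(0, 0, 10)),
               "increasing")
})

test_that("score distribution sampling separates aligned from random pairs", {
  make_group <- function(seed, noise) {
    spec <- random_pair_spec(len_a = 60L, len_b = 60L, n_pairs = 50L,
                             dim = 128L, noise_sigma = noise, seed = seed)
    syn <- generate_synthetic_pair(spec)
    list(refs = list(syn$reference),
         embeddings = setNames(list(syn$emb_a, syn$emb_b),
                               c(syn$emb_a$seq_id, syn$emb_b$seq_id)),
         seqs = setNames(list(syn$seq_a, syn$seq_b),
                         c(syn$seq_a$id, syn$seq_b$id)))
  }
  # noise-free planting: every aligned sample scores exactly the full scale
  g0 <- list(make_group(1L, 0))
  d0 <- sample_score_distributions(g0, "embedding", n_pairs = 30L,
                                   first_k = 1L, n_random_seqs = 2L,
                                   seed = 3L)
  expect_equal(d0$aligned, rep(10, 30), tolerance = 1e-9)

  # determinism
  d0b <- sample_score_distributions(g0, "embedding", n_pairs = 30L,
                                    first_k = 1L, n_random_seqs = 2L,
                                    seed = 3L)
  expect_identical(d0, d0b)

  # aligned mean exceeds random mean across seeds
  for (s in 1:20) {
    g <- list(make_group(s, 0.5))
    d <- sample_score_distributions(g, "embedding", n_pairs = 40L,
                                    first_k = 1L, n_random_seqs = 2L,
                                    seed = s)
    expect_gt(mean(d$aligned), mean(d$random))
  }

  # substitution scorer path runs on the same groups
  tab <- load_substitution_table("BLOSUM62")
  db <- sample_score_distributions(g0, tab, n_pairs = 10L, first_k = 1L,
                                   n_random_seqs = 2L, seed = 5L)
  expect_true(length(db$aligned) == 10L && length(db$random) > 0L)
})
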