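test_that("local search returns a locally optimal centre unchanged", {
  for (seed in 1:3) {
    fx <- tiny_fixture(seed)
    init <- top_labelling(fx$hmm, fx$y)
    converged <- local_search(fx$hmm, fx$y, init, r = 1)
    again <- local_search(fx$hmm, fx$y, converged$labelling, r = 1)
    expect_identical(again$labelling, converged$labelling)
    expect_identical(again$iterations, 0L)
  }
  # a single-feature labelling has no borders to move
  h2 <- two_state_hmm()
  res <- local_search(h2, c("a", "a", "b"), rep("A", 3), r = 2)
  expect_identical(res$labelling, rep("A", 3))
  expect_identical(res$iterations, 0L)
  # max_iters <= 0 returns the start unchanged
  res0 <- local_search(h2, c("a", "b", "a"), c("A", "B", "B"), r = 1,
                       max_iters = 0)
  expect_identical(res0$labelling, c("A", "B", "B"))
})

test_that("incremental neighbour evaluation matches full recomputation", {
  for (seed in 1:4) {
    fx <- tiny_fixture(seed + 20)
    set.seed(seed)
    init <- path_labelling(fx$hmm,
                           sample_path_posterior(fx$hmm, fx$y, seed = seed))
    res <- local_search(fx$hmm, fx$y, init, r = 1, audit = TRUE)
    f <- footprint_of(init)
    n <- length(fx$y)
    for (it in res$trace) {
      for (i in seq_len(nrow(it$moves))) {
        nb <- it$borders
        nb[it$moves$border[i]] <- nb[it$moves$border[i]] + it$moves$delta[i]
        lab <- labelling_from_borders(f, nb, n)
        full <- ball_prob_border_shift(fx$hmm, fx$y, lab, 1, log = TRUE)
        inc <- it$moves$log_prob[i]
        if (is.finite(full) || is.finite(inc)) {
          expect_lt(abs(inc - full), 1e-9 * max(1, abs(full)))
        }
      }
    }
  }
})

test_that("accepted local-search moves strictly increase the ball probability", {
  for (seed in 1:4) {
    fx <- tiny_fixture(seed + 40)
    init <- path_labelling(fx$hmm,
                           sample_path_posterior(fx$hmm, fx$y, seed = seed))
    res <- local_search(fx$hmm, fx$y, init, r = 1)
    if (length(res$history) > 1)
      expect_true(all(diff(res$history) > 0))
    # the result never falls below the start
    expect_gte(res$log_prob, res$history[1])
    # and no single-border move improves on the final centre
    b <- borders_of(res$labelling)
    f <- footprint_of(res$labelling)
    n <- length(fx$y)
    k <- length(f)
    if (k > 1) {
      for (t in seq_len(k - 1)) {
        for (delta in c(-1L, 1L)) {
          nb <- b
          nb[t] <- nb[t] + delta
          lower <- if (t > 1) b[t - 1] + 1L else 2L
          upper <- if (t < k - 1) b[t + 1] - 1L else n
          if (nb[t] < lower || nb[t] > upper) next
          lab <- labelling_from_borders(f, nb, n)
          expect_lte(ball_prob_border_shift(fx$hmm, fx$y, lab, 1, log = TRUE),
                     res$log_prob + 1e-9)
        }
      }
    }
  }
})

test_that("multi-start decoding is deterministic and dominated by more starts", {
  fx <- tiny_fixture(7)
  # one start from a given centre is plain local search
  init <- top_labelling(fx$hmm, fx$y)
  one <- decode_with_restarts(fx$hmm, fx$y, r = 1, n_starts = 1, init = init)
  direct <- local_search(fx$hmm, fx$y, init, r = 1)
  expect_identical(one$labelling, direct$labelling)
  expect_equal(one$log_prob, direct$log_prob)

  best1 <- decode_with_restarts(fx$hmm, fx$y, r = 1, n_starts = 1, seed = 5)
  best10 <- decode_with_restarts(fx$hmm, fx$y, r = 1, n_starts = 10, seed = 5)
  expect_gte(best10$log_prob, best1$log_prob)

  a <- decode_with_restarts(fx$hmm, fx$y, r = 1, n_starts = 5, seed = 123)
  b <- decode_with_restarts(fx$hmm, fx$y, r = 1, n_starts = 5, seed = 123)
  expect_identical(a$labelling, b$labelling)
  expect_identical(a$log_prob, b$log_prob)
})

test_that("regular-ball DP collapses to Viterbi at r = 0", {
  for (seed in 1:6) {
    fx <- tiny_fixture(seed + 60)
    d <- regular_ball_dp(fx$hmm, fx$y, 0)
    v <- viterbi(fx$hmm, fx$y)
    expect_identical(d$path, v$path)
    expect_equal(d$log_prob, v$log_prob, tolerance = 1e-12)
  }
})

test_that("regular-ball DP matches exhaustive maximization at r = 1", {
  set.seed(77)
  for (seed in 1:6) {
    h <- random_hmm(m = 2L + seed %% 2L, alphabet_size = 2L,
                    num_labels = 2L, seed = seed + 80)
    n <- sample(7:9, 1)
    y <- sample(h$alphabet, n, replace = TRUE)
    d <- regular_ball_dp(h, y, 1)
    o <- brute_best_regular_ball(h, y, 1)
    expect_lt(abs(d$log_prob - o$log_prob), 1e-9 * max(1, abs(o$log_prob)))
    # the reported probability is the ball probability of the centre
    expect_lt(abs(d$log_prob -
                    path_ball_probability(h, y, d$path, 1, log = TRUE)),
              1e-9 * max(1, abs(d$log_prob)))
    # every centre run is (2r+1)-regular
    expect_true(all(rle(d$path[-1])$lengths >= 3))
  }
})

test_that("regular-ball DP handles degenerate shapes", {
  h1 <- one_state_hmm()
  y <- rep("a", 5)
  d <- regular_ball_dp(h1, y, 1)
  expect_identical(d$path, rep(1L, 6))
  expect_equal(d$prob, forward(h1, y)$prob)
  # sequences shorter than 2r + 1 are rejected
  h2 <- two_state_hmm()
  expect_error(regular_ball_dp(h2, c("a", "b"), 1), "2r \\+ 1")
})
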