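test_that("joint probability is the product of transition and emission factors", {
  h1 <- one_state_hmm()
  expect_equal(joint_probability(h1, "aaa", c(1, 1, 1, 1)), 1.0)

  h2 <- two_state_hmm()
  # hand expansion: a_12 e_2(a) * a_21 e_1(b) = .3 * .2 * .4 * .1
  expect_equal(joint_probability(h2, "ab", c(1, 2, 1)), 0.0024)
  # term-by-term oracle on a longer path
  path <- c(1, 2, 2, 1, 1)
  y <- c("a", "b", "b", "a")
  manual <- h2$A[1, 2] * h2$E[2, 1] * h2$A[2, 2] * h2$E[2, 2] *
    h2$A[2, 1] * h2$E[1, 2] * h2$A[1, 1] * h2$E[1, 1]
  expect_equal(joint_probability(h2, y, path), manual)

  # a forbidden transition zeroes the product
  hc <- chain_hmm()
  expect_identical(joint_probability(hc, "xy", c(1, 1, 2)), 0)
  # malformed path length is rejected
  expect_error(joint_probability(h2, "ab", c(1, 2)), "length")
  expect_error(joint_probability(h2, "ab", c(2, 1, 2)), "start state")
})

test_that("forward total equals the exhaustive sum over paths", {
  h1 <- one_state_hmm()
  expect_equal(forward(h1, "aaaa")$prob, 1.0)

  h2 <- two_state_hmm()
  for (n in c(3, 6)) {
    set.seed(n)
    y <- sample(h2$alphabet, n, replace = TRUE)
    en <- enumerate_path_probabilities(h2, y)
    fw <- forward(h2, y)
    expect_lt(rel_err(fw$prob, sum(en$prob)), 1e-9)
    expect_equal(fw$log_prob, log(sum(en$prob)), tolerance = 1e-9)
  }

  # a symbol unreachable from the start gives probability 0, not an error
  hu <- unreachable_hmm()
  expect_identical(forward(hu, c("a", "b"))$prob, 0)
  expect_identical(forward(hu, c("a", "b"))$log_prob, -Inf)
  # unknown symbols are rejected
  expect_error(forward(h2, "az"), "alphabet")
})

test_that("backward vectors satisfy the forward-backward dot identity", {
  for (seed in 1:5) {
    fx <- tiny_fixture(seed)
    fw <- forward(fx$hmm, fx$y)
    bw <- backward(fx$hmm, fx$y)
    n <- length(fx$y)
    prefC <- c(0, cumsum(fw$logc))
    sufD <- c(rev(cumsum(rev(bw$logd))), 0)
    for (i in c(1L, n %/% 2L, n)) {
      if (i < 1L) next
      lp <- prefC[i + 1] + log(sum(fw$phi[, i] * bw$beta[, i + 1])) +
        sufD[i + 1]
      expect_lt(rel_err(lp, fw$log_prob), 1e-9)
    }
    # i = 0: start-state indicator against beta_1
    lp0 <- log(bw$beta[fx$hmm$start, 1]) + sufD[1]
    expect_lt(rel_err(lp0, fw$log_prob), 1e-9)
  }

  h1 <- one_state_hmm()
  expect_true(all(backward(h1, "aaa")$beta == 1))

  hu <- unreachable_hmm()
  bw <- backward(hu, c("a", "a"))
  fw <- forward(hu, c("a", "a"))
  expect_true(all(is.finite(bw$beta)))       # beta defined everywhere
  expect_identical(fw$phi[2, 2], 0)          # but no forward mass at state 2
})

test_that("viterbi matches exhaustive argmax and is self-consistent", {
  hc <- chain_hmm()
  v <- viterbi(hc, c("y", "z", "z"))
  expect_identical(v$path, c(1L, 2L, 3L, 3L))

  for (seed in 1:5) {
    fx <- tiny_fixture(seed)
    en <- enumerate_path_probabilities(fx$hmm, fx$y)
    v <- viterbi(fx$hmm, fx$y)
    expect_lt(rel_err(v$prob, max(en$prob)), 1e-9)
    expect_equal(v$prob, joint_probability(fx$hmm, fx$y, v$path),
                 tolerance = 1e-12)
    # never exceeds the total probability
    expect_lte(v$log_prob, forward(fx$hmm, fx$y)$log_prob + 1e-12)
  }
})

test_that("posterior state probabilities match enumeration marginals", {
  h1 <- one_state_hmm()
  expect_true(all(posterior_state_probs(h1, "aaa") == 1))

  for (seed in 1:4) {
    fx <- tiny_fixture(seed)
    P <- posterior_state_probs(fx$hmm, fx$y)
    expect_equal(colSums(P), rep(1, length(fx$y)), tolerance = 1e-12)
    en <- enumerate_path_probabilities(fx$hmm, fx$y)
    for (i in seq_along(fx$y)) {
      marg <- vapply(seq_len(nrow(fx$hmm$A)), function(k)
        sum(en$prob[en$paths[, i + 1] == k]), 1)
      expect_equal(P[, i], marg / sum(en$prob), tolerance = 1e-9,
                   ignore_attr = TRUE)
    }
  }
})

test_that("posterior path sampling reproduces conditional path frequencies", {
  hc <- chain_hmm()
  expect_identical(sample_path_posterior(hc, c("y", "z", "z"), seed = 1),
                   c(1L, 2L, 3L, 3L))

  h2 <- two_state_hmm()
  y <- c("a", "b", "a")
  en <- enumerate_path_probabilities(h2, y)
  cond <- en$prob / sum(en$prob)
  ndraw <- 8000L
  X <- sample_path_posterior(h2, y, n_draws = ndraw, seed = 99)
  key <- apply(X, 1, paste, collapse = ",")
  ref <- apply(en$paths, 1, paste, collapse = ",")
  freq <- as.numeric(table(factor(key, levels = ref))) / ndraw
  se <- sqrt(cond * (1 - cond) / ndraw)
  expect_true(all(abs(freq - cond) <= 3 * se + 1e-12))

  # same seed, same draw
  expect_identical(sample_path_posterior(h2, y, seed = 7),
                   sample_path_posterior(h2, y, seed = 7))
  expect_error(sample_path_posterior(unreachable_hmm(), c("a", "b")),
               "probability 0")
})
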