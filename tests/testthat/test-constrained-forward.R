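test_that("labelling probability equals the path sum with matching labels", {
  # one state per label: the labelling pins a unique path
  hc <- chain_hmm()
  y <- c("y", "z", "z")
  expect_equal(labelling_probability(hc, y, c("B", "C", "C")),
               joint_probability(hc, y, c(1, 2, 3, 3)))
  # a label with no states is infeasible
  expect_identical(labelling_probability(hc, y, c("B", "D", "C")), 0)

  for (seed in 1:6) {
    fx <- tiny_fixture(seed)
    tab <- enumerate_labelling_probabilities(fx$hmm, fx$y)
    total <- 0
    for (i in seq_len(nrow(tab))) {
      lab <- strsplit(tab$labelling[i], ";", fixed = TRUE)[[1]]
      lp <- labelling_probability(fx$hmm, fx$y, lab)
      expect_lt(rel_err(lp, tab$prob[i]), 1e-9)
      total <- total + lp
    }
    expect_lt(rel_err(total, forward(fx$hmm, fx$y)$prob), 1e-9)
  }
})

test_that("footprint probability sums labelling probabilities over the footprint", {
  h2 <- two_state_hmm()
  y <- c("a", "b", "a", "b")
  # k = 1: all positions share one label
  expect_equal(footprint_probability(h2, y, "A"),
               labelling_probability(h2, y, rep("A", 4)))

  for (seed in 1:6) {
    fx <- tiny_fixture(seed)
    tab <- enumerate_labelling_probabilities(fx$hmm, fx$y)
    labs <- lapply(tab$labelling, function(k)
      strsplit(k, ";", fixed = TRUE)[[1]])
    fps <- vapply(labs, function(l) paste(footprint_of(l), collapse = ";"), "")
    for (f in unique(fps)) {
      want <- sum(tab$prob[fps == f])
      got <- footprint_probability(fx$hmm, fx$y,
                                   strsplit(f, ";", fixed = TRUE)[[1]])
      expect_lt(rel_err(got, want), 1e-9)
    }
  }
  # footprint longer than the sequence is infeasible
  expect_identical(
    footprint_probability(h2, c("a", "b"), c("A", "B", "A")), 0)
})

test_that("ball probabilities match enumeration for every metric and radius", {
  for (seed in 1:8) {
    fx <- tiny_fixture(seed)
    ctr <- top_labelling(fx$hmm, fx$y)
    H <- hamming_matrix(sort(unique(fx$hmm$labels)))
    for (r in 0:2) {
      for (metric in c("border_shift", "border_shift_sum",
                       "generalized_hamming")) {
        spec <- ball_spec(ctr, r, metric,
                          H = if (metric == "generalized_hamming") H)
        got <- ball_probability(fx$hmm, fx$y, spec)
        want <- brute_ball_probability(fx$hmm, fx$y, spec)
        expect_lt(rel_err(got, want), 1e-9)
      }
    }
  }
})

test_that("radius-limit identities hold exactly", {
  for (seed in 1:6) {
    fx <- tiny_fixture(seed)
    n <- length(fx$y)
    ctr <- top_labelling(fx$hmm, fx$y)
    H01 <- hamming_matrix(sort(unique(fx$hmm$labels)))
    lp <- labelling_probability(fx$hmm, fx$y, ctr)
    # r = 0 collapses every metric to the labelling probability
    expect_lt(rel_err(ball_prob_border_shift(fx$hmm, fx$y, ctr, 0), lp), 1e-12)
    expect_lt(rel_err(ball_prob_border_shift_sum(fx$hmm, fx$y, ctr, 0), lp),
              1e-12)
    expect_lt(
      rel_err(ball_prob_generalized_hamming(fx$hmm, fx$y, ctr, 0, H01), lp),
      1e-12)
    # r = n unconstrains the windows: the footprint probability
    expect_lt(rel_err(ball_prob_border_shift(fx$hmm, fx$y, ctr, n),
                      footprint_probability(fx$hmm, fx$y, footprint_of(ctr))),
              1e-12)
    # a zero penalty matrix puts every labelling at distance 0
    H0 <- H01 * 0
    expect_lt(rel_err(ball_prob_generalized_hamming(fx$hmm, fx$y, ctr, 0, H0),
                      forward(fx$hmm, fx$y)$prob), 1e-12)
    # 0/1 penalties with radius n admit every labelling too
    expect_lt(rel_err(ball_prob_generalized_hamming(fx$hmm, fx$y, ctr, n, H01),
                      forward(fx$hmm, fx$y)$prob), 1e-12)
  }
})

test_that("ball probabilities are monotone in r and properly nested", {
  for (seed in 1:6) {
    fx <- tiny_fixture(seed)
    ctr <- top_labelling(fx$hmm, fx$y)
    py <- forward(fx$hmm, fx$y)$prob
    fp <- footprint_probability(fx$hmm, fx$y, footprint_of(ctr))
    lp <- labelling_probability(fx$hmm, fx$y, ctr)
    prev_shift <- prev_sum <- 0
    for (r in 0:4) {
      bs <- ball_prob_border_shift(fx$hmm, fx$y, ctr, r)
      bss <- ball_prob_border_shift_sum(fx$hmm, fx$y, ctr, r)
      expect_gte(bs, prev_shift * (1 - 1e-12))
      expect_gte(bss, prev_sum * (1 - 1e-12))
      # the sum-distance ball sits inside the max-distance ball
      expect_lte(bss, bs * (1 + 1e-12))
      expect_gte(bs, lp * (1 - 1e-12))
      expect_lte(bs, fp * (1 + 1e-12))
      expect_lte(fp, py * (1 + 1e-12))
      prev_shift <- bs
      prev_sum <- bss
    }
  }
})

test_that("infeasible centres give probability zero, not errors", {
  hc <- chain_hmm()
  y <- c("y", "z", "z")
  expect_identical(ball_prob_border_shift(hc, y, c("C", "B", "B"), 1), 0)
  expect_identical(ball_prob_border_shift(hc, y, c("B", "D", "C"), 2), 0)
  expect_identical(
    ball_prob_border_shift_sum(hc, y, c("B", "D", "C"), 2), 0)
})
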