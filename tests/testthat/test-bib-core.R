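test_that("windowed frequency reproduces the worked examples", {
  # a five-symbol history with capacity 4: only the last four count
  expect_equal(windowed_frequency(c(0L, 1L, 1L, 2L, 3L), n = 4, M = 4),
               c(0.0, 0.5, 0.25, 0.25))
  expect_equal(windowed_frequency(c(0L, 1L, 1L, 2L), n = 4, M = 4),
               c(0.25, 0.5, 0.25, 0.0))
  expect_equal(windowed_frequency(c(0L, 0L, 1L, 0L), n = 4, M = 4),
               c(0.75, 0.25, 0, 0))
})

test_that("windowed frequency handles short, empty and corrupt windows", {
  expect_equal(windowed_frequency(c(2L, 2L), n = 4), c(0, 0, 1, 0))
  expect_equal(windowed_frequency(integer(0), n = 4), c(0, 0, 0, 0))
  expect_error(windowed_frequency(c(0L, 7L), n = 4), "corrupt window")
  # nonempty windows always normalize
  set.seed(5)
  for (i in 1:20) {
    w <- sample(0:3, sample(1:10, 1), replace = TRUE)
    expect_equal(sum(windowed_frequency(w, 4)), 1)
  }
})

test_that("bayes_update matches hand-evaluated posteriors", {
  L <- rbind(c(0.8, 0.2), c(0.4, 0.6))
  expect_equal(bayes_update(c(0.5, 0.5), L, 0), c(2 / 3, 1 / 3))
  # identical rows cancel: uniform belief is a fixed point
  Lu <- rbind(c(0.3, 0.7), c(0.3, 0.7))
  expect_equal(bayes_update(c(0.5, 0.5), Lu, 1), c(0.5, 0.5))
  # a degenerate prior is a fixed point
  expect_equal(bayes_update(c(1, 0), L, 1), c(1, 0))
  # impossible observation errors
  Lz <- rbind(c(1, 0), c(1, 0))
  expect_error(bayes_update(c(0.5, 0.5), Lz, 1), "inconsistent observation")
})

test_that("iterated bayes_update equals brute-force enumeration", {
  L <- oracle_likelihood()
  prior <- c(0.3, 0.3, 0.4)
  worst <- 0
  for (len in 1:6) {
    for (s in all_sequences(len, 3)) {
      b <- prior
      for (d in s) b <- bayes_update(b, L, d)
      worst <- max(worst, max(abs(b - posterior_enumeration(prior, L, s))))
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("select_hs targets the minimum with probability 1 - P(h_s)", {
  set.seed(1)
  draws <- replicate(1e5, select_hs(c(0.5, 0.3, 0.2)))
  expect_true(all(draws == 3L | is.na(draws)))
  expect_equal(mean(!is.na(draws)), 0.8, tolerance = 0.02)
  # a zero-probability hypothesis is always replaced
  expect_true(all(replicate(100, select_hs(c(1, 0))) == 2L))
  # uniform belief: minimum ties split evenly, replacement rate 1 - 1/4
  draws <- replicate(1e5, select_hs(rep(0.25, 4)))
  expect_equal(mean(!is.na(draws)), 0.75, tolerance = 0.02)
  tab <- tabulate(draws[!is.na(draws)], 4)
  expect_true(all(abs(tab / sum(tab) - 0.25) < 0.02))
})

test_that("argmax_hypothesis picks maxima and splits ties evenly", {
  expect_equal(argmax_hypothesis(c(0.1, 0.7, 0.2)), 2L)
  expect_equal(argmax_hypothesis(c(1, 0, 0)), 1L)
  set.seed(2)
  draws <- replicate(1e5, argmax_hypothesis(c(0.5, 0.5)))
  expect_equal(mean(draws == 1L), 0.5, tolerance = 0.02)
})

test_that("ib_update substitutes exactly one row and preserves normalization", {
  L <- initial_likelihood(0.7, 4)
  f <- c(0, 0.5, 0.25, 0.25)
  L2 <- ib_update(L, 3, f)
  expect_equal(unname(L2[3, ]), f)
  expect_equal(L2[-3, ], L[-3, ])
  # substituting a row by itself is a no-op
  expect_equal(ib_update(L2, 3, f), L2)
  # all-zero frequency sentinel leaves the matrix untouched
  expect_equal(ib_update(L, 2, rep(0, 4)), L)
  # row sums stay 1 under random replacements
  set.seed(3)
  for (i in 1:25) {
    f <- stats::runif(4)
    f <- f / sum(f)
    L <- ib_update(L, sample(4, 1), f)
    expect_true(max(abs(rowSums(L) - 1)) < 1e-9)
  }
})

test_that("initial_likelihood builds the peaked family and rejects flat p", {
  L <- initial_likelihood(0.7, 4)
  expect_equal(unname(L[1, ]), c(0.7, 0.1, 0.1, 0.1))
  expect_equal(unname(diag(L)), rep(0.7, 4))
  expect_equal(unname(initial_likelihood(1, 2)), diag(2))
  expect_true(all(abs(rowSums(initial_likelihood(0.31, 5)) - 1) < 1e-12))
  expect_error(initial_likelihood(0.25, 4), "p must lie")
  expect_error(initial_likelihood(0.1, 4), "p must lie")
})

test_that("predict_prob reads the requested likelihood entry", {
  expect_equal(predict_prob(diag(4), 3, 2), 1)
  L <- initial_likelihood(0.7, 4)
  expect_equal(predict_prob(L, 1, 1), 0.1)
  expect_equal(sum(sapply(0:3, function(d) predict_prob(L, 2, d))), 1)
})

test_that("validators accept valid objects and flag violations", {
  expect_silent(validate_likelihood(initial_likelihood(0.7, 4)))
  expect_error(validate_likelihood(matrix(c(0.5, 0.4, 0.2, 0.8), 2)), "sum to 1")
  expect_error(validate_likelihood(matrix(c(-0.1, 1.1, 0.5, 0.5), 2,
                                          byrow = TRUE)), "probabilities")
  expect_silent(validate_belief(c(0.2, 0.8)))
  expect_error(validate_belief(c(0.2, 0.7)), "sum to 1")
})
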