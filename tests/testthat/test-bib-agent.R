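test_that("bib_step appends to the window and respects its capacity", {
  a <- bib_agent(n = 4, p = 0.7, M = 3)
  a <- bib_step(a, 2, "b")
  expect_equal(a$window, 2L)
  for (d in c(0L, 1L, 3L)) a <- bib_step(a, d, "b")
  expect_equal(a$window, c(0L, 1L, 3L)) # oldest evicted first
})

test_that("Bayes-only mode never modifies the likelihood", {
  set.seed(11)
  a <- bib_agent(n = 4, p = 0.7, M = 50)
  L0 <- a$likelihood
  out <- run_bib(a, sample(0:3, 1000, replace = TRUE), mode = "b")
  expect_identical(out$agent$likelihood, L0)
})

test_that("run_bib is step-for-step equivalent to bib_step plus argmax", {
  obs <- c(0L, 1L, 1L, 2L, 3L, 0L, 0L, 2L, 1L, 3L, 0L, 0L)
  for (mode in c("bib", "b")) {
    set.seed(21)
    fast <- run_bib(bib_agent(4, 0.7, M = 5), obs, mode)
    set.seed(21)
    a <- bib_agent(4, 0.7, M = 5)
    hm <- integer(length(obs))
    for (t in seq_along(obs)) {
      a <- bib_step(a, obs[t], mode)
      hm[t] <- argmax_hypothesis(a$belief)
    }
    expect_equal(fast$agent$belief, a$belief)
    expect_equal(unname(fast$agent$likelihood), unname(a$likelihood))
    expect_equal(fast$agent$window, a$window)
    expect_equal(fast$h_max, hm)
  }
})

test_that("belief and likelihood stay normalized along a long BIB run", {
  set.seed(31)
  a <- bib_agent(4, 0.7, M = 20)
  for (t in 1:300) {
    a <- bib_step(a, sample(0:3, 1, prob = c(0.6, 0.2, 0.1, 0.1)), "bib")
    expect_lt(abs(sum(a$belief) - 1), 1e-9)
    expect_lt(max(abs(rowSums(a$likelihood) - 1)), 1e-9)
  }
})

test_that("on stationary data the last-replaced row approaches the source", {
  q <- c(0.5, 0.2, 0.2, 0.1)
  set.seed(41)
  a <- bib_agent(4, 0.7, M = 100)
  last_replaced <- NULL
  for (t in 1:300) {
    before <- a$likelihood
    a <- bib_step(a, sample(0:3, 1, prob = q), "bib")
    changed <- which(rowSums(before != a$likelihood) > 0)
    if (length(changed) == 1L) last_replaced <- a$likelihood[changed, ]
  }
  expect_false(is.null(last_replaced))
  expect_lt(tv_dist(last_replaced, q), 0.2)
})

test_that("Bayes-only belief concentrates on the generating hypothesis", {
  # i.i.d. data from row k of the peaked likelihood: belief[k] > 0.99
  # within 100 steps in at least 19 of 20 seeded runs
  ok <- 0
  for (s in 1:20) {
    set.seed(s)
    k <- 2L
    obs <- sample(0:3, 100, replace = TRUE,
                  prob = initial_likelihood(0.7, 4)[k, ])
    out <- run_bib(bib_agent(4, 0.7, M = 100), obs, "b")
    if (out$agent$belief[k] > 0.99) ok <- ok + 1
  }
  expect_gte(ok, 19)
})

test_that("after a regime switch BIB predictions recover and Bayes-only do not", {
  # regime A matches hypothesis 0; regime B (0.05, 0.45, 0.45, 0.05) matches
  # no fixed hypothesis, so only a rewritten likelihood can fit it
  M <- 100
  qA <- c(0.7, 0.1, 0.1, 0.1)
  qB <- c(0.05, 0.45, 0.45, 0.05)
  recovered <- c(bib = 0L, b = 0L)
  for (s in 1:5) {
    set.seed(s)
    obs <- c(sample(0:3, 500, replace = TRUE, prob = qA),
             sample(0:3, 3 * M, replace = TRUE, prob = qB))
    for (mode in c("bib", "b")) {
      set.seed(s + 100)
      out <- run_bib(bib_agent(4, 0.7, M = M), obs, mode)
      # prediction error for the (first) modal symbol of regime B at the
      # end of the 3M-step recovery window
      tail_err <- abs(out$prediction[length(obs), 2] - qB[2])
      if (tail_err < 0.1) recovered[mode] <- recovered[mode] + 1L
    }
  }
  expect_gte(recovered[["bib"]], 4L)
  expect_lte(recovered[["b"]], 1L)
})

test_that("a hypothesis killed by a zero likelihood entry can be revived", {
  # row 2 assigns probability zero to symbol 0; observing symbol 0 floors
  # its belief instead of freezing it at an absorbing zero
  L <- rbind(c(0.5, 0.5, 0, 0), c(0, 0.5, 0.25, 0.25),
             c(0.25, 0.25, 0.25, 0.25), c(0.1, 0.2, 0.3, 0.4))
  a <- bib_agent(4, likelihood = L, M = 10)
  a <- bib_step(a, 0L, "b")
  expect_gt(a$belief[2], 0)
  expect_lt(abs(sum(a$belief) - 1), 1e-12)
  # a stream only row 2 fits well then lifts it back to dominance
  for (t in 1:200) a <- bib_step(a, c(1L, 2L)[t %% 2 + 1], "b")
  expect_gt(a$belief[2], 0.5)
})
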