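test_that("forward likelihood matches base case and path enumeration", {
  set.seed(31)
  p <- random_hmm(3)
  # length-1 base case: sum over states of pi * B
  s1 <- p$alphabet[2]
  expect_equal(hmm_forward(p, s1)$likelihood,
               sum(p$init * p$emis[, s1]), tolerance = 1e-12)

  for (i in 1:20) {
    q <- random_hmm(sample(2:5, 1))
    obs <- sample(q$alphabet, sample(2:5, 1), replace = TRUE)
    o <- oracle_hmm(q, obs)
    expect_equal(hmm_forward(q, obs)$likelihood, o$likelihood,
                 tolerance = 1e-12)
    expect_equal(hmm_forward(q, obs, method = "linear")$likelihood,
                 o$likelihood, tolerance = 1e-12)
  }

  # deterministic model forces a single sequence
  det <- hmm_params(rbind(c(1, 0), c(0, 1)),
                    rbind(c(1, 0), c(0, 1)), c(1, 0),
                    alphabet = c("x", "y"))
  expect_equal(hmm_forward(det, c("x", "x", "x"))$likelihood, 1)
  expect_equal(hmm_forward(det, c("x", "y", "x"))$likelihood, 0)

  expect_error(hmm_forward(det, c("x", "zz")), "zz")
})

test_that("log-space and linear forward agree on day-length sequences", {
  set.seed(32)
  for (i in 1:10) {
    q <- random_hmm(6)
    obs <- sample(q$alphabet, 24, replace = TRUE)
    a <- hmm_forward(q, obs)$loglik
    b <- hmm_forward(q, obs, method = "linear")$loglik
    expect_equal(a, b, tolerance = 1e-9)
  }
})

test_that("posteriors match enumeration and handle degenerate cases", {
  # fully symmetric model: posterior 1/2 everywhere
  sym <- hmm_params(matrix(0.5, 2, 2), matrix(0.5, 2, 2), c(0.5, 0.5),
                    alphabet = c("x", "y"))
  g <- hmm_posterior(sym, c("x", "y", "x", "y"))
  expect_true(all(abs(g - 0.5) < 1e-12))

  set.seed(33)
  for (i in 1:20) {
    q <- random_hmm(sample(2:5, 1))
    obs <- sample(q$alphabet, sample(2:5, 1), replace = TRUE)
    g <- hmm_posterior(q, obs)
    expect_equal(unname(g), unname(oracle_hmm(q, obs)$posterior),
                 tolerance = 1e-12)
    expect_equal(unname(rowSums(g)), rep(1, length(obs)), tolerance = 1e-12)
  }

  # zero emission for the AIA state excludes it at that position
  p <- hmm_params(matrix(0.5, 2, 2),
                  rbind(c(1, 0), c(0.5, 0.5)), c(0.5, 0.5),
                  alphabet = c("x", "y"))
  g <- hmm_posterior(p, c("x", "y", "x"))
  expect_equal(unname(g[2, "AIA"]), 0)
})

test_that("viterbi returns the maximum-probability path", {
  det <- hmm_params(rbind(c(0, 1), c(1, 0)),
                    rbind(c(1, 0), c(0, 1)), c(1, 0),
                    alphabet = c("x", "y"))
  v <- hmm_viterbi(det, c("x", "y", "x"))
  expect_equal(v$path, c("AIA", "normal", "AIA"))

  set.seed(34)
  for (i in 1:20) {
    q <- random_hmm(sample(2:5, 1))
    obs <- sample(q$alphabet, sample(2:6, 1), replace = TRUE)
    v <- hmm_viterbi(q, obs)
    expect_equal(exp(v$logprob), oracle_hmm(q, obs)$best_prob,
                 tolerance = 1e-12)
    # best single path never beats the total likelihood
    expect_lte(v$logprob, hmm_forward(q, obs)$loglik + 1e-12)
  }
})

test_that("supervised estimation recovers counts and generating parameters", {
  # pure-prior rows when a state is unobserved
  fit <- hmm_fit_supervised(list(c("x", "x")), list(c("normal", "normal")),
                            alphabet = c("x", "y"), smoothing = 1)
  expect_equal(unname(fit$emis["AIA", ]), c(0.5, 0.5))

  # raw count normalisation at zero smoothing
  obs <- list(rep("x", 11))
  hid <- list(c(rep("normal", 10), "AIA"))
  # transitions: normal->normal 9, normal->AIA 1
  fit0 <- hmm_fit_supervised(obs, hid, alphabet = c("x", "y"), smoothing = 0)
  expect_equal(unname(fit0$trans["normal", ]), c(0.1, 0.9))

  # parameter recovery from a long labelled corpus
  tr <- rbind(c(0.85, 0.15), c(0.05, 0.95))
  em <- rbind(c(0.7, 0.2, 0.1), c(0.1, 0.3, 0.6))
  states <- c("AIA", "normal")
  alphabet <- c("p", "q", "r")
  set.seed(35)
  hidden <- character(1e4)
  hidden[1] <- "normal"
  for (t in 2:1e4)
    hidden[t] <- sample(states, 1,
                        prob = tr[match(hidden[t - 1], states), ])
  symbols <- vapply(hidden, function(h)
    sample(alphabet, 1, prob = em[match(h, states), ]), character(1))
  fit <- hmm_fit_supervised(list(unname(symbols)), list(hidden), alphabet,
                            states = states)
  expect_lt(max(abs(fit$trans - tr)), 0.05)
  expect_lt(max(abs(fit$emis - em)), 0.05)

  expect_error(hmm_fit_supervised(list(), list(), alphabet), "empty")
})

test_that("group scores separate simulated agitation days from normal days", {
  res <- reference_micro_scenario(seed = 11)
  s <- res$scores
  aia <- s$P_G2[s$truth == "AIA"]
  normal <- s$P_G2[s$truth == "normal"]
  w <- wilcox.test(aia, normal, alternative = "greater", exact = FALSE)
  expect_lt(w$p.value, 0.01)

  # representation independence: permuting the alphabet consistently
  set.seed(36)
  q <- random_hmm(4)
  obs <- sample(q$alphabet, 10, replace = TRUE)
  perm <- sample(4)
  q2 <- hmm_params(q$trans, q$emis[, perm], q$init,
                   alphabet = q$alphabet[perm])
  expect_equal(score_group(q, obs), score_group(q2, obs), tolerance = 1e-12)

  # degenerate AIA-forcing model scores 1
  force_aia <- hmm_params(rbind(c(1, 0), c(1, 0)),
                          rbind(c(1, 0), c(0, 1)), c(1, 0),
                          alphabet = c("x", "y"))
  expect_equal(unname(score_group(force_aia, c("x", "x"))["AIA"]), 1)
})
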