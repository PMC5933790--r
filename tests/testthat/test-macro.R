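# helper: wrap a day x slot x sensor array as an activity grid
as_grid <- function(values, sensors = paste0("s", seq_len(dim(values)[3]))) {
  structure(list(values = values, sensor_index = sensors,
                 origin = as.Date("2024-01-01"), interval_minutes = 10,
                 scaling = NULL),
            class = "activity_grid")
}

test_that("day clustering separates templates and freezes centroids", {
  set.seed(3)
  away <- array(abs(rnorm(20 * 144 * 2, 0, 0.05)), c(20, 144, 2))
  busy <- array(abs(rnorm(20 * 144 * 2, 6, 0.5)), c(20, 144, 2))
  grid <- as_grid(array(c(aperm(away, c(1, 2, 3)), busy), c(40, 144, 2)))
  grid$values[1:20, , ] <- away
  grid$values[21:40, , ] <- busy
  cats <- cluster_days(grid, seed = 1)
  expect_equal(cats$assignment, rep(c("D1", "D2"), each = 20))

  # a day equal to a centroid is assigned to that category
  probe <- as_grid(array(cats$centroids[2, ], c(1, 144, 2)))
  expect_equal(assign_day_categories(cats, probe), "D2")

  # all-identical days: one category with a warning
  same <- as_grid(array(1, c(5, 144, 2)))
  expect_warning(c2 <- cluster_days(same, seed = 1), "distinct")
  expect_true(all(c2$assignment == "D1"))
})

test_that("state codebook maps windows to nearest frozen centroid", {
  v1 <- c(0, 0); v2 <- c(8, 8)
  vals <- array(0, c(2, 144, 2))
  vals[2, , ] <- 8
  grid <- as_grid(vals)
  cb <- map_states(grid, n_states = 2, seed = 1)
  seqs <- apply_codebook(cb, grid)
  expect_equal(length(unique(seqs[1, ])), 1)
  expect_equal(length(unique(seqs[2, ])), 1)
  expect_false(seqs[1, 1] == seqs[2, 1])
  # the zero window maps to the zero centroid
  zero_state <- seqs[1, 1]
  expect_equal(unname(rowSums(cb$centroids)[zero_state]), 0, tolerance = 1e-9)

  # perturbations below half the min inter-centroid distance never flip states
  d <- sqrt(sum((cb$centroids[1, ] - cb$centroids[2, ])^2))
  set.seed(7)
  for (i in 1:25) {
    eps <- rnorm(2)
    eps <- eps / sqrt(sum(eps^2)) * runif(1, 0, 0.49 * d)
    probe <- grid
    probe$values[1, 10, ] <- pmax(grid$values[1, 10, ] + eps, -Inf)
    expect_equal(apply_codebook(cb, probe)[1, 10], zero_state)
  }

  expect_error(map_states(as_grid(array(1, c(1, 144, 2))), n_states = 3),
               "distinct")
})

test_that("markov fitting reproduces the worked six-step chain", {
  m <- fit_markov(list(c("a", "b", "a", "a", "c", "b")))
  expect_equal(m$state_probs, c(1 / 2, 1 / 3, 1 / 6), tolerance = 1e-12)
  expect_equal(unname(m$trans["a", ]), rep(1 / 3, 3), tolerance = 1e-12)
  expect_equal(unname(m$trans["b", ]), c(1, 0, 0))
  expect_equal(unname(m$trans["c", ]), c(0, 1, 0))
  # entropy rate equals the term-by-term expansion: (1/2) log 3
  expect_equal(entropy_rate(m), log(3) / 2, tolerance = 1e-12)

  # alternating chain
  ab <- fit_markov(list(c("a", "b", "a", "b")))
  expect_equal(unname(ab$trans["a", "b"]), 1)
  expect_equal(unname(ab$trans["b", "a"]), 1)
  expect_equal(ab$state_probs, c(0.5, 0.5))

  # duplicating the corpus changes nothing
  twice <- fit_markov(list(c("a", "b", "a", "a", "c", "b"),
                           c("a", "b", "a", "a", "c", "b")))
  expect_equal(twice$trans, m$trans)
  expect_equal(twice$state_probs, m$state_probs)

  expect_error(fit_markov(list()), "length >= 2")
})

test_that("entropy and entropy rate match closed forms and oracles", {
  # deterministic cycle: zero entropy
  cyc <- markov_model(rbind(c(0, 1, 0), c(0, 0, 1), c(1, 0, 0)),
                      rep(1 / 3, 3))
  expect_equal(chain_entropy(cyc), 0)
  expect_equal(entropy_rate(cyc), 0)

  # uniform chain over k states: xi = log k
  for (k in c(2, 4, 6)) {
    u <- markov_model(matrix(1 / k, k, k), rep(1 / k, k))
    expect_equal(entropy_rate(u), log(k), tolerance = 1e-12)
    expect_equal(chain_entropy(u), k * log(k), tolerance = 1e-12)
  }

  # random models vs direct-summation oracles
  set.seed(42)
  for (i in 1:50) {
    k <- sample(2:6, 1)
    tr <- random_stochastic(k)
    p <- random_prob(k)
    m <- markov_model(tr, p)
    expect_equal(chain_entropy(m), oracle_entropy(tr), tolerance = 1e-12)
    expect_equal(entropy_rate(m), oracle_entropy_rate(p, tr),
                 tolerance = 1e-12)
    expect_lte(entropy_rate(m), chain_entropy(m) + 1e-12)
    expect_lte(entropy_rate(m), log(k) + 1e-12)
  }

  # symmetric transitions, asymmetric occupancy: xi discriminates, epsilon not
  tr <- rbind(c(0.6, 0.2, 0.2), c(0.2, 0.8, 0.0), c(0.3, 0.1, 0.6))
  m1 <- markov_model(tr, c(0.7, 0.2, 0.1))
  m2 <- markov_model(tr, c(0.2, 0.7, 0.1))
  expect_equal(chain_entropy(m1), chain_entropy(m2))
  expect_false(isTRUE(all.equal(entropy_rate(m1), entropy_rate(m2))))
})

test_that("deviation boundaries follow the confidence-coefficient formula", {
  p <- deviation_bounds(1.0, c(0.8, 1.2), mu = 2)
  expect_equal(p$sigma, 0.2, tolerance = 1e-12)
  expect_equal(unname(p$delta), c(0.6, 1.4), tolerance = 1e-12)

  # all verification days equal to xi_T: the band collapses to a point
  p0 <- deviation_bounds(1.0, rep(1.0, 5))
  expect_equal(p0$sigma, 0)
  expect_equal(unname(diff(p0$delta)), 0)

  # doubling mu doubles the half-width
  p4 <- deviation_bounds(1.0, c(0.8, 1.2), mu = 4)
  expect_equal(unname(diff(p4$delta)), 2 * unname(diff(p$delta)))

  expect_error(deviation_bounds(1, numeric(0)), "non-empty")
})

test_that("transition matrices are recovered from a long simulated chain", {
  tr <- rbind(c(0.70, 0.10, 0.10, 0.10),
              c(0.05, 0.80, 0.10, 0.05),
              c(0.25, 0.25, 0.25, 0.25),
              c(0.10, 0.20, 0.30, 0.40))
  path <- simulate_markov_chain(tr, len = 1e4, seed = 99)
  fit <- fit_markov(list(as.character(path)), states = as.character(1:4))
  expect_lt(max(abs(fit$trans - tr)), 0.05)
})

test_that("weekly sensitivity counts validated labelled weeks", {
  # weeks 1-4 labelled (2+ flags each), weeks 1-3 truly anomalous
  flags <- rep(c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE), 4)
  truth <- rep("normal", 28)
  truth[c(3, 10, 17)] <- "visitor"
  expect_equal(weekly_sensitivity(flags, truth), 0.75)
  truth[24] <- "away"
  expect_equal(weekly_sensitivity(flags, truth), 1)

  # permuting flags within a week leaves rho unchanged
  set.seed(2)
  perm <- unlist(lapply(0:3, function(w) 7 * w + sample(7)))
  expect_equal(weekly_sensitivity(flags[perm], truth), 1)

  expect_warning(r <- weekly_sensitivity(rep(FALSE, 14), rep("normal", 14)),
                 "undefined")
  expect_true(is.na(r))
})

test_that("anomaly/notification correlation is Pearson on normalised counts", {
  n_a <- c(1, 4, 2, 8, 5)
  expect_equal(anomaly_notification_correlation(n_a, 2 * n_a), 1)
  expect_equal(anomaly_notification_correlation(n_a, 10 - n_a), -1)
  set.seed(8)
  for (i in 1:20) {
    a <- runif(10); b <- runif(10)
    manual <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(anomaly_notification_correlation(a, b), manual,
                 tolerance = 1e-12)
  }
  expect_warning(r <- anomaly_notification_correlation(c(1, 1), c(1, 2)),
                 "constant")
  expect_true(is.na(r))
})

test_that("the macro pipeline flags injected days and is deterministic", {
  res1 <- reference_macro_scenario(seed = 5, n_train = 30, n_verify = 10,
                                   n_test = 21, n_visitor = 1, n_away = 2,
                                   n_aia = 0)
  res2 <- reference_macro_scenario(seed = 5, n_train = 30, n_verify = 10,
                                   n_test = 21, n_visitor = 1, n_away = 2,
                                   n_aia = 0)
  expect_identical(res1$flags, res2$flags)
  # away days (no away days in training) are always flagged
  away <- res1$truth_labels == "away"
  expect_true(all(res1$flags$flagged[away]))
})
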