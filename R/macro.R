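#' Macro assessment: routine modelling via Markov-chain entropy rates
#'
#' The macro track discretises each day into a sequence of activity states,
#' models the within-day state transitions as a first-order Markov chain and
#' quantifies the regularity of a day with its entropy rate. Deviation
#' boundaries learned from a verification period turn the entropy rate into
#' a day-level anomaly detector.
#'
#' @name macro
NULL

#' Cluster days into low-active and high-active categories
#'
#' First K-means stage: each training day (flattened slots x sensors vector)
#' is clustered into `k` categories, relabelled by total activity so that D1
#' is the least active category. Centroids are frozen after training; new
#' days are assigned by nearest centroid.
#'
#' @param grid training [normalise_grid()] output.
#' @param k number of categories. Default 2.
#' @param seed integer seed for the (seeded, multi-restart) K-means.
#' @return object of class `day_categories`: `centroids` (k x p),
#'   `assignment` (character vector, "D1".."Dk"), `totals`.
#' @export
cluster_days <- function(grid, k = 2, seed = 1) {
  stopifnot(inherits(grid, "activity_grid"))
  x <- matrix(grid$values, nrow = dim(grid$values)[1])
  if (nrow(x) < k) validation_error("need at least k = ", k, " training days")
  if (nrow(unique(x)) < k) {
    warning("fewer than ", k, " distinct day patterns; all days assigned to D1")
    centroids <- matrix(rep(x[1, ], k), nrow = k, byrow = TRUE)
    cl <- rep(1L, nrow(x))
  } else {
    km <- with_seed(derive_seed(seed, 11L),
                    stats::kmeans(x, centers = k, nstart = 10, iter.max = 100))
    centroids <- km$centers
    cl <- km$cluster
  }
  totals <- rowSums(centroids)
  ord <- order(totals)  # D1 = least total activity
  relabel <- match(seq_len(k), ord)
  structure(list(centroids = centroids[ord, , drop = FALSE],
                 assignment = paste0("D", relabel[cl]),
                 totals = totals[ord]),
            class = "day_categories")
}

#' Assign days of a grid to frozen day categories
#'
#' @param categories a [cluster_days()] result.
#' @param grid an `activity_grid`.
#' @return character vector ("D1", "D2", ...) per day, nearest centroid.
#' @export
assign_day_categories <- function(categories, grid) {
  x <- matrix(grid$values, nrow = dim(grid$values)[1])
  paste0("D", nearest_centroid(x, categories$centroids))
}

#' Learn the state codebook and discretise days into state sequences
#'
#' Second K-means stage: every time slot of a normalised grid is an
#' n-dimensional activity vector (n = number of sensors); K-means with
#' `n_states` centroids maps each slot vector to a single discrete state.
#' The codebook is learned on training slots only and frozen; apply it to
#' verification/test grids with [apply_codebook()].
#'
#' @param grid training `activity_grid`.
#' @param n_states number of states; defaults to the number of sensors.
#' @param seed integer seed.
#' @return object of class `state_codebook`: `centroids` (n_states x n).
#' @export
map_states <- function(grid, n_states = NULL, seed = 1) {
  stopifnot(inherits(grid, "activity_grid"))
  n_states <- n_states %||% length(grid$sensor_index)
  if (n_states < 2) validation_error("n_states must be >= 2")
  x <- matrix(grid$values, ncol = dim(grid$values)[3])
  if (nrow(unique(x)) < n_states)
    validation_error("fewer distinct slot vectors than n_states")
  km <- with_seed(derive_seed(seed, 12L),
                  stats::kmeans(x, centers = n_states, nstart = 10, iter.max = 100))
  structure(list(centroids = km$centers, n_states = n_states),
            class = "state_codebook")
}

#' Discretise a grid with a frozen state codebook
#'
#' @param codebook a [map_states()] result.
#' @param grid an `activity_grid`.
#' @return integer matrix, days x slots, of state indices (nearest
#'   centroid, ties toward the lowest index).
#' @export
apply_codebook <- function(codebook, grid) {
  d <- dim(grid$values)
  x <- matrix(grid$values, ncol = d[3])
  matrix(nearest_centroid(x, codebook$centroids), nrow = d[1])
}

#' Construct a Markov model from explicit matrices
#'
#' Low-level constructor used when the transition matrix and state
#' probabilities are known rather than fitted.
#'
#' @param trans row-stochastic transition matrix (rows with no observed
#'   transitions may be all zero).
#' @param state_probs state occupancy distribution (sums to 1).
#' @param states state labels; default from `trans` dimnames or indices.
#' @param category optional day-category tag ("D1"/"D2").
#' @return object of class `markov_model`.
#' @export
markov_model <- function(trans, state_probs, states = NULL, category = NULL) {
  trans <- as.matrix(trans)
  k <- nrow(trans)
  stopifnot(ncol(trans) == k, length(state_probs) == k)
  if (any(trans < 0) || any(state_probs < 0))
    validation_error("probabilities must be non-negative")
  rs <- rowSums(trans)
  if (any(abs(rs[rs > 0] - 1) > 1e-9))
    validation_error("each observed row of the transition matrix must sum to 1")
  if (abs(sum(state_probs) - 1) > 1e-9)
    validation_error("state probabilities must sum to 1")
  states <- states %||% rownames(trans) %||% as.character(seq_len(k))
  dimnames(trans) <- list(states, states)
  names(state_probs) <- states
  structure(list(states = states, trans = trans,
                 state_probs = as.numeric(state_probs),
                 empty_rows = which(rs == 0), category = category),
            class = "markov_model")
}

#' @export
print.markov_model <- function(x, ...) {
  cat("<markov_model> ", length(x$states), " states",
      if (!is.null(x$category)) paste0(" (category ", x$category, ")"),
      "; entropy rate ", signif(entropy_rate(x), 4), " nats\n", sep = "")
  invisible(x)
}

#' Fit a Markov model from state sequences
#'
#' Transition probabilities are within-day count ratios
#' `T[a, b] = count(a -> b) / count(a -> .)` over consecutive pairs; chains
#' never cross the midnight boundary between sequences. State probabilities
#' are the occupancy frequencies over all positions of all sequences.
#'
#' @param sequences a single vector, a matrix (rows = days), or a list of
#'   state vectors (integer or character), each of length >= 2.
#' @param states the full state set; defaults to the sorted distinct states
#'   observed. Supply it explicitly when fitting on data that may not visit
#'   every codebook state.
#' @param category optional category tag.
#' @return a [markov_model()].
#' @export
fit_markov <- function(sequences, states = NULL, category = NULL) {
  if (is.matrix(sequences)) sequences <- split(sequences, row(sequences))
  if (!is.list(sequences)) sequences <- list(sequences)
  sequences <- lapply(sequences, as.character)
  if (!length(sequences) || !any(lengths(sequences) >= 2))
    validation_error("need at least one sequence of length >= 2")
  states <- as.character(states %||% sort(unique(unlist(sequences))))
  k <- length(states)
  counts <- matrix(0, k, k, dimnames = list(states, states))
  occ <- stats::setNames(numeric(k), states)
  for (s in sequences) {
    idx <- match(s, states)
    if (anyNA(idx)) validation_error("sequence contains a state outside the state set")
    occ_tab <- tabulate(idx, k)
    occ <- occ + occ_tab
    if (length(idx) >= 2) {
      from <- idx[-length(idx)]
      to <- idx[-1]
      counts <- counts + matrix(tabulate((to - 1L) * k + from, k * k), k, k)
    }
  }
  rs <- rowSums(counts)
  trans <- counts
  trans[rs > 0, ] <- counts[rs > 0, , drop = FALSE] / rs[rs > 0]
  markov_model(trans, occ / sum(occ), states = states, category = category)
}

#' Entropy of a Markov model's transition probabilities
#'
#' `epsilon = -sum_ab P_ab log P_ab` in nats, with `0 log 0 := 0`. Depends
#' only on the transition probabilities; see [entropy_rate()] for the
#' occupancy-weighted variant.
#'
#' @param model a `markov_model`.
#' @return non-negative entropy in nats.
#' @export
chain_entropy <- function(model) {
  p <- model$trans[model$trans > 0]
  -sum(p * log(p))
}

#' Entropy rate of a Markov model
#'
#' `xi = -sum_ab P_a P_ab log P_ab` in nats, with `0 log 0 := 0`: each
#' state's transition entropy weighted by the empirical state occupancy
#' `P_a`. Unlike [chain_entropy()], the entropy rate distinguishes
#' transition patterns a -> b from b -> a whenever the two states are
#' occupied unequally.
#'
#' @param model a `markov_model`.
#' @return non-negative entropy rate in nats.
#' @export
entropy_rate <- function(model) {
  t <- model$trans
  w <- t * log(ifelse(t > 0, t, 1))
  -sum(model$state_probs * rowSums(w))
}

#' Deviation boundaries from verification-day entropy rates
#'
#' `sigma = sqrt(sum_i (xi_i - xi_T)^2 / v)` over the `v` verification days
#' and `Delta = xi_T +/- mu * sigma`, where `mu` is the confidence
#' coefficient (default 2, roughly 95% coverage under normality).
#'
#' @param xi_t training entropy rate.
#' @param xi_v numeric vector of per-verification-day entropy rates.
#' @param mu confidence coefficient. Default 2.
#' @return object of class `entropy_profile`: `xi_t`, `xi_v`, `v`, `sigma`,
#'   `mu`, `delta = c(lower, upper)`.
#' @export
deviation_bounds <- function(xi_t, xi_v, mu = 2.0) {
  if (!length(xi_v)) validation_error("verification set must be non-empty")
  v <- length(xi_v)
  sigma <- sqrt(sum((xi_v - xi_t)^2) / v)
  structure(list(xi_t = xi_t, xi_v = xi_v, v = v, sigma = sigma, mu = mu,
                 delta = c(lower = xi_t - mu * sigma, upper = xi_t + mu * sigma)),
            class = "entropy_profile")
}

#' @export
print.entropy_profile <- function(x, ...) {
  cat("<entropy_profile> xi_T = ", signif(x$xi_t, 4), ", sigma = ",
      signif(x$sigma, 4), " (v = ", x$v, "), Delta = [",
      signif(x$delta[1], 4), ", ", signif(x$delta[2], 4), "]\n", sep = "")
  invisible(x)
}

#' Entropy rate of a single day's state sequence
#'
#' `method = "cross"` (the default) scores the day's empirical occupancy
#' and transitions under the trained model's transition matrix, directly
#' measuring how far the day's sequence distribution deviates from the
#' trained chain; the trained matrix is mixed with a small uniform
#' component (`smooth`) so that transitions never observed in training
#' carry a large but finite penalty. `method = "own"` is the entropy rate
#' of the day's own fitted chain, a pure internal-regularity measure.
#'
#' @param states the day's state sequence (character).
#' @param codebook_states the full state set.
#' @param method `"cross"` or `"own"`.
#' @param trained the category's trained [markov_model()] (cross only).
#' @param smooth uniform mixture weight applied to the trained matrix.
#'   Default 0.01.
#' @return the day's entropy rate in nats.
#' @export
day_entropy_rate <- function(states, codebook_states, method = c("cross", "own"),
                             trained = NULL, smooth = 0.01) {
  method <- match.arg(method)
  day_model <- fit_markov(list(states), states = codebook_states)
  if (method == "own") return(entropy_rate(day_model))
  stopifnot(!is.null(trained))
  t_day <- day_model$trans
  t_ref <- (1 - smooth) * trained$trans + smooth / length(codebook_states)
  -sum(day_model$state_probs * rowSums(t_day * log(t_ref) * (t_day > 0)))
}

#' Flag anomalous days by entropy-rate deviation
#'
#' Each test day is assigned to a frozen day category, discretised with the
#' frozen state codebook, and its entropy rate compared against that
#' category's deviation boundaries. The default flags two-sided departures
#' (`|xi - xi_T| > mu * sigma`), catching both excess randomness (visitors,
#' agitation) and collapsed activity (away days); `mode = "upper"` applies
#' the literal one-sided rule `xi > Delta_upper`.
#'
#' @param test_grid `activity_grid` of test days (normalised with the
#'   training scaling).
#' @param categories frozen [cluster_days()] result.
#' @param codebook frozen [map_states()] result.
#' @param models named list ("D1", "D2", ...) of fitted [markov_model()]s.
#' @param profiles named list of [deviation_bounds()] profiles per category.
#' @param mode `"two_sided"` (default) or `"upper"`.
#' @param method per-day entropy rate: `"cross"` (the day's transitions
#'   scored under the trained matrix; default) or `"own"` (the day's own
#'   chain). See [day_entropy_rate()].
#' @return data.frame `day`, `category`, `xi`, `delta_lower`,
#'   `delta_upper`, `flagged`.
#' @export
detect_anomalous_days <- function(test_grid, categories, codebook, models,
                                  profiles, mode = c("two_sided", "upper"),
                                  method = c("cross", "own")) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  cats <- assign_day_categories(categories, test_grid)
  seqs <- apply_codebook(codebook, test_grid)
  state_set <- as.character(seq_len(codebook$n_states))
  out <- lapply(seq_len(nrow(seqs)), function(d) {
    cat_d <- cats[d]
    prof <- profiles[[cat_d]]
    if (is.null(prof)) validation_error("no entropy profile for category ", cat_d)
    if (ncol(seqs) < 2) {
      warning("day ", d, " has fewer than 2 slots; skipped")
      return(NULL)
    }
    xi <- day_entropy_rate(as.character(seqs[d, ]), state_set,
                           method = method, trained = models[[cat_d]])
    flagged <- if (mode == "two_sided")
      xi < prof$delta[1] || xi > prof$delta[2]
    else xi > prof$delta[2]
    data.frame(day = d, category = cat_d, xi = xi,
               delta_lower = unname(prof$delta[1]),
               delta_upper = unname(prof$delta[2]),
               flagged = flagged)
  })
  do.call(rbind, out)
}

#' Weekly sensitivity of the macro detector
#'
#' Days are grouped into consecutive weeks; a week is labelled anomalous
#' when at least `min_days_anomalous` of its days are flagged, and such a
#' labelled week is validated when the ground truth marks at least one of
#' its days anomalous. Sensitivity is
#' `rho = validated labelled weeks / total labelled weeks`.
#'
#' @param flagged logical vector of per-day flags.
#' @param truth_labels character vector of per-day ground-truth labels
#'   (anything other than `"normal"` counts as a true anomaly).
#' @param days_per_week week length. Default 7; a trailing partial week is
#'   ignored.
#' @param min_days_anomalous flagged days needed to label a week. Default 2.
#' @return `rho` in \[0, 1\], or NA (with a warning) when no week is
#'   labelled.
#' @export
weekly_sensitivity <- function(flagged, truth_labels, days_per_week = 7,
                               min_days_anomalous = 2) {
  stopifnot(length(flagged) == length(truth_labels))
  n_weeks <- length(flagged) %/% days_per_week
  if (n_weeks == 0) validation_error("need at least one full week")
  idx <- rep(seq_len(n_weeks), each = days_per_week)
  f <- flagged[seq_len(n_weeks * days_per_week)]
  t <- truth_labels[seq_len(n_weeks * days_per_week)] != "normal"
  labelled <- tapply(f, idx, sum) >= min_days_anomalous
  validated <- tapply(t, idx, any)
  w_tot <- sum(labelled)
  if (w_tot == 0) {
    warning("no weeks labelled anomalous; sensitivity undefined")
    return(NA_real_)
  }
  sum(labelled & validated) / w_tot
}

#' Correlation between anomaly counts and validated notifications
#'
#' Pearson correlation between per-participant anomaly counts and validated
#' notification counts, after min-max normalising each series to \[0, 1\]
#' (the two counts originate from different information sources and scales).
#'
#' @param n_a,n_n equal-length numeric vectors (one entry per participant,
#'   >= 2 participants, neither constant).
#' @return Pearson correlation in \[-1, 1\], or NA with a warning when a
#'   vector is constant.
#' @export
anomaly_notification_correlation <- function(n_a, n_n) {
  stopifnot(length(n_a) == length(n_n))
  if (length(n_a) < 2) validation_error("need at least 2 participants")
  if (stats::var(n_a) == 0 || stats::var(n_n) == 0) {
    warning("constant count vector; correlation undefined")
    return(NA_real_)
  }
  stats::cor(minmax01(n_a), minmax01(n_n))
}
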