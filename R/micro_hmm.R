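#' Micro decision layer II: hidden Markov models over label sequences
#'
#' Two-state (AIA/normal) discrete-emission HMMs score the hourly composite
#' label sequences of the participant-proximal (G2) and multi-occupancy (G3)
#' sensor groups. The model is `lambda = {T, B, pi}`: hidden-state
#' transition matrix, emission matrix over the composite-symbol alphabet,
#' and initial state distribution.
#'
#' @name micro_hmm
NULL

#' Construct HMM parameters
#'
#' @param trans 2 x 2 row-stochastic hidden-state transition matrix.
#' @param emis 2 x |alphabet| row-stochastic emission matrix.
#' @param init initial state distribution (length 2, sums to 1).
#' @param alphabet ordered character vector of emission symbols; defaults
#'   to `colnames(emis)`.
#' @param states hidden state labels. Default `c("AIA", "normal")`.
#' @return object of class `hmm_params`.
#' @export
hmm_params <- function(trans, emis, init, alphabet = colnames(emis),
                       states = c("AIA", "normal")) {
  trans <- as.matrix(trans); emis <- as.matrix(emis)
  k <- length(states)
  stopifnot(nrow(trans) == k, ncol(trans) == k, nrow(emis) == k,
            length(init) == k, !is.null(alphabet),
            ncol(emis) == length(alphabet))
  if (any(trans < 0) || any(emis < 0) || any(init < 0))
    validation_error("probabilities must be non-negative")
  if (any(abs(rowSums(trans) - 1) > 1e-9) ||
      any(abs(rowSums(emis) - 1) > 1e-9) ||
      abs(sum(init) - 1) > 1e-9)
    validation_error("rows of T and B and pi must each sum to 1")
  dimnames(trans) <- list(states, states)
  dimnames(emis) <- list(states, alphabet)
  names(init) <- states
  structure(list(states = states, trans = trans, emis = emis,
                 init = as.numeric(init), alphabet = as.character(alphabet)),
            class = "hmm_params")
}

#' @export
print.hmm_params <- function(x, ...) {
  cat("<hmm_params> states {", paste(x$states, collapse = ", "), "}, ",
      length(x$alphabet), "-symbol alphabet\n", sep = "")
  invisible(x)
}

symbol_index <- function(params, symbols) {
  idx <- match(symbols, params$alphabet)
  if (anyNA(idx))
    validation_error("symbol not in the model alphabet: ",
                     symbols[which(is.na(idx))[1]])
  idx
}

log_sum_exp <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(v - m)))
}

#' Forward algorithm: sequence likelihood under an HMM
#'
#' Computes `P(S | lambda)` by the forward recursion. The log-space path is
#' the default (and is required for day-long or longer sequences); the
#' linear path exists as an independent numerical route for short
#' sequences.
#'
#' @param params an [hmm_params()].
#' @param symbols character vector of observed symbols (all must be in the
#'   alphabet).
#' @param method `"log"` (default) or `"linear"`.
#' @return list with `loglik` and `likelihood`.
#' @export
hmm_forward <- function(params, symbols, method = c("log", "linear")) {
  method <- match.arg(method)
  obs <- symbol_index(params, symbols)
  l <- length(obs)
  stopifnot(l >= 1)
  k <- length(params$states)
  if (method == "linear") {
    alpha <- params$init * params$emis[, obs[1]]
    if (l > 1) for (t in 2:l)
      alpha <- as.numeric(alpha %*% params$trans) * params$emis[, obs[t]]
    lik <- sum(alpha)
    return(list(loglik = log(lik), likelihood = lik))
  }
  la <- log(params$init) + log(params$emis[, obs[1]])
  lt <- log(params$trans)
  if (l > 1) for (t in 2:l) {
    la <- vapply(seq_len(k), function(j) log_sum_exp(la + lt[, j]), numeric(1)) +
      log(params$emis[, obs[t]])
  }
  ll <- log_sum_exp(la)
  list(loglik = ll, likelihood = exp(ll))
}

#' Forward-backward smoothing: per-position hidden-state posteriors
#'
#' @inheritParams hmm_forward
#' @return numeric matrix, length(S) x 2, columns named by hidden state;
#'   each row sums to 1.
#' @export
hmm_posterior <- function(params, symbols) {
  obs <- symbol_index(params, symbols)
  l <- length(obs)
  k <- length(params$states)
  lt <- log(params$trans)
  le <- log(params$emis)
  la <- matrix(-Inf, l, k)
  la[1, ] <- log(params$init) + le[, obs[1]]
  if (l > 1) for (t in 2:l) for (j in seq_len(k))
    la[t, j] <- log_sum_exp(la[t - 1, ] + lt[, j]) + le[j, obs[t]]
  lb <- matrix(0, l, k)
  if (l > 1) for (t in (l - 1):1) for (i in seq_len(k))
    lb[t, i] <- log_sum_exp(lt[i, ] + le[, obs[t + 1]] + lb[t + 1, ])
  ll <- log_sum_exp(la[l, ])
  if (!is.finite(ll))
    validation_error("sequence has zero probability under the model")
  gamma <- exp(la + lb - ll)
  gamma <- gamma / rowSums(gamma)
  colnames(gamma) <- params$states
  gamma
}

#' Viterbi algorithm: most probable hidden path
#'
#' Ties are broken toward the "normal" state to bias against false alarms.
#'
#' @inheritParams hmm_forward
#' @return list with `path` (character vector of hidden states) and
#'   `logprob` (log probability of that path).
#' @export
hmm_viterbi <- function(params, symbols) {
  obs <- symbol_index(params, symbols)
  l <- length(obs)
  k <- length(params$states)
  lt <- log(params$trans)
  le <- log(params$emis)
  # preference order for ties: "normal" first, then model order
  pref <- order(params$states != "normal")
  pick <- function(v) pref[which.max(v[pref])]
  delta <- matrix(-Inf, l, k)
  back <- matrix(0L, l, k)
  delta[1, ] <- log(params$init) + le[, obs[1]]
  if (l > 1) for (t in 2:l) for (j in seq_len(k)) {
    cand <- delta[t - 1, ] + lt[, j]
    back[t, j] <- pick(cand)
    delta[t, j] <- cand[back[t, j]] + le[j, obs[t]]
  }
  path <- integer(l)
  path[l] <- pick(delta[l, ])
  if (l > 1) for (t in (l - 1):1) path[t] <- back[t + 1, path[t + 1]]
  list(path = params$states[path], logprob = delta[l, path[l]])
}

#' Supervised HMM estimation from labelled sequences
#'
#' Estimates `lambda = {T, B, pi}` by additive-smoothed counting of hidden
#' transitions, emissions and initial states from sequences whose hidden
#' labels are known (e.g. simulator ground truth, or clinician-annotated
#' seed data).
#'
#' @param obs_seqs list of observed symbol sequences.
#' @param state_seqs list of equal-length hidden-state label sequences.
#' @param alphabet full emission alphabet.
#' @param states hidden state labels. Default `c("AIA", "normal")`.
#' @param smoothing additive (Laplace) pseudo-count. Default 1.
#' @return an [hmm_params()].
#' @export
hmm_fit_supervised <- function(obs_seqs, state_seqs, alphabet,
                               states = c("AIA", "normal"), smoothing = 1.0) {
  if (!length(obs_seqs)) validation_error("empty training corpus")
  stopifnot(length(obs_seqs) == length(state_seqs),
            all(lengths(obs_seqs) == lengths(state_seqs)))
  k <- length(states)
  a <- length(alphabet)
  t_counts <- matrix(smoothing, k, k, dimnames = list(states, states))
  e_counts <- matrix(smoothing, k, a, dimnames = list(states, alphabet))
  i_counts <- stats::setNames(rep(smoothing, k), states)
  for (s in seq_along(obs_seqs)) {
    st <- match(state_seqs[[s]], states)
    ob <- match(obs_seqs[[s]], alphabet)
    if (anyNA(st)) validation_error("hidden label outside the state set")
    if (anyNA(ob)) validation_error("observed symbol outside the alphabet")
    i_counts[st[1]] <- i_counts[st[1]] + 1
    for (t in seq_along(st)) e_counts[st[t], ob[t]] <- e_counts[st[t], ob[t]] + 1
    if (length(st) > 1) for (t in 2:length(st))
      t_counts[st[t - 1], st[t]] <- t_counts[st[t - 1], st[t]] + 1
  }
  if (smoothing == 0) {
    # guard fully unobserved rows: fall back to uniform
    fix <- function(m) {
      rs <- rowSums(m)
      m[rs == 0, ] <- 1
      m
    }
    t_counts <- fix(t_counts); e_counts <- fix(e_counts)
    if (sum(i_counts) == 0) i_counts[] <- 1
  }
  hmm_params(t_counts / rowSums(t_counts), e_counts / rowSums(e_counts),
             i_counts / sum(i_counts), alphabet = alphabet, states = states)
}

#' Score a group's label sequence
#'
#' The group decision score (D_pf for G2, D_mo for G3) summarises the
#' smoothed per-hour posterior probability of the AIA state over the
#' scoring window (by convention one day of hourly symbols). The default
#' statistic is the maximum: agitation episodes occupy a few hours, so a
#' window containing any confidently-AIA hour is an AIA window, whereas a
#' mean over the window dilutes an episode by the episode-to-window length
#' ratio and can never cross 1/2 for short episodes. The mean remains
#' available for windows matched to episode length.
#'
#' @param params fitted [hmm_params()].
#' @param symbols the window's observed symbols (non-empty).
#' @param statistic `"max"` (default) or `"mean"` over the per-hour
#'   posteriors.
#' @return named numeric `c(AIA =, normal =)` summing to 1.
#' @export
score_group <- function(params, symbols, statistic = c("max", "mean")) {
  statistic <- match.arg(statistic)
  if (!length(symbols)) validation_error("empty scoring window")
  gamma <- hmm_posterior(params, symbols)
  p_aia <- if (statistic == "max") max(gamma[, "AIA"]) else mean(gamma[, "AIA"])
  c(AIA = p_aia, normal = 1 - p_aia)
}
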