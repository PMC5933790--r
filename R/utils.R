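# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child seed from a master seed
#'
#' Deterministically maps a master seed and a stage offset to a new seed,
#' kept below 2^31 so it is always a valid R integer seed. Used so that one
#' run-level seed controls every stochastic stage without the stages sharing
#' a stream.
#'
#' @param seed master integer seed.
#' @param offset integer stage offset (>= 0).
#' @return an integer seed.
#' @export
derive_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(offset))
  as.integer((as.double(seed) %% 2147483629 + 104729 * (as.double(offset) %% 20011)) %% 2147483629)
}

# Evaluate `code` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Min-max rescale to [0, 1]; errors on constant input (callers decide the
# degenerate behaviour themselves).
minmax01 <- function(x) {
  r <- range(x)
  if (r[2] == r[1]) stop("cannot min-max normalise a constant vector", call. = FALSE)
  (x - r[1]) / (r[2] - r[1])
}

# Nearest-centroid assignment (squared Euclidean), ties broken toward the
# lowest centroid index.
nearest_centroid <- function(x, centroids) {
  x <- matrix(as.numeric(x), ncol = ncol(centroids))
  d2 <- outer(rowSums(x^2), rep(1, nrow(centroids))) -
    2 * x %*% t(centroids) +
    outer(rep(1, nrow(x)), rowSums(centroids^2))
  max.col(-d2, ties.method = "first")
}

#' Simulate a path from a first-order Markov chain
#'
#' @param trans row-stochastic transition matrix.
#' @param init initial state distribution (defaults to uniform).
#' @param len path length (>= 1).
#' @param seed integer seed.
#' @return integer vector of state indices of length `len`.
#' @export
simulate_markov_chain <- function(trans, init = NULL, len, seed) {
  trans <- as.matrix(trans)
  k <- nrow(trans)
  stopifnot(ncol(trans) == k, len >= 1)
  init <- init %||% rep(1 / k, k)
  with_seed(seed, {
    path <- integer(len)
    path[1] <- sample.int(k, 1L, prob = init)
    if (len > 1) {
      for (i in 2:len) path[i] <- sample.int(k, 1L, prob = trans[path[i - 1], ])
    }
    path
  })
}

# Parse character timestamps trying ISO-8601 and common variants; elements
# no format can parse become NA (base as.POSIXlt would error instead).
parse_timestamps <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  x <- as.character(x)
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  for (f in c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
              "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
    miss <- is.na(out)
    if (!any(miss)) break
    out[miss] <- as.POSIXct(x[miss], tz = "UTC", format = f)
  }
  out
}

validation_error <- function(...) {
  cnd <- structure(
    class = c("homewatch_validation_error", "error", "condition"),
    list(message = paste0(...), call = NULL)
  )
  stop(cnd)
}
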