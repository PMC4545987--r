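#' Category response probabilities under the partial credit / rating scale
#' model
#'
#' For an item with difficulty `delta` and step thresholds `tau` (length
#' `m - 1`, constrained to sum to zero within a rating-scale group), the step
#' difficulty of step `j` is `delta + tau[j]` and the probability of category
#' `k` at ability `theta` is
#' \deqn{P(k) = \exp\!\big(\sum_{j \le k} (\theta - \delta - \tau_j)\big) /
#'   \sum_h \exp\!\big(\sum_{j \le h} (\theta - \delta - \tau_j)\big),}
#' with the empty sum for `k = 0` equal to zero. A dichotomous item has a
#' single threshold fixed at 0, reducing to the simple logistic Rasch model.
#'
#' @param theta person ability (logits), scalar or vector.
#' @param delta item difficulty (logits).
#' @param tau step thresholds (length `m - 1`); default `0` (dichotomous).
#' @return matrix `length(theta)` x `m` of probabilities; rows sum to 1.
#' @examples
#' category_probabilities(0, 0)                 # c(0.5, 0.5)
#' category_probabilities(0, 0, tau = c(-1, 1)) # symmetric three-category case
#' @export
category_probabilities <- function(theta, delta, tau = 0) {
  stopifnot(is.finite(delta), all(is.finite(tau)))
  m <- length(tau) + 1L
  cum <- c(0, cumsum(delta + tau))          # sum_{j<=k} step difficulties
  k <- 0:(m - 1L)
  eta <- outer(theta, k) - matrix(cum, length(theta), m, byrow = TRUE)
  eta <- eta - apply(eta, 1L, max)          # log-sum-exp stabilisation
  w <- exp(eta)
  w / rowSums(w)
}

#' Expected score and variance of a polytomous Rasch item
#'
#' Mean `E = sum k P(k)` and variance `Var = sum (k - E)^2 P(k)` of the
#' category distribution at `theta`; `E` is strictly increasing in `theta`.
#'
#' @inheritParams category_probabilities
#' @return `data.frame` with columns `expected` and `variance`, one row per
#'   `theta`.
#' @export
expected_score <- function(theta, delta, tau = 0) {
  p <- category_probabilities(theta, delta, tau)
  k <- 0:(length(tau))
  e <- drop(p %*% k)
  v <- drop(p %*% k^2) - e^2
  data.frame(expected = e, variance = pmax(v, 0))
}

# Moment matrices for a whole calibration problem.
# theta: length N; delta: named length I; tau_list: per item id, threshold
# vector. Returns list(E, V, P = list of N x m matrices) over all cells
# (missingness is applied by callers).
model_moments <- function(theta, delta, tau_list, want_p = FALSE) {
  n <- length(theta)
  ids <- names(delta)
  E <- V <- matrix(NA_real_, n, length(ids), dimnames = list(NULL, ids))
  P <- if (want_p) vector("list", length(ids)) else NULL
  for (j in seq_along(ids)) {
    id <- ids[j]
    p <- category_probabilities(theta, delta[[id]], tau_list[[id]])
    k <- 0:(ncol(p) - 1L)
    e <- drop(p %*% k)
    E[, j] <- e
    V[, j] <- pmax(drop(p %*% k^2) - e^2, 0)
    if (want_p) P[[j]] <- p
  }
  if (want_p) names(P) <- ids
  list(E = E, V = V, P = P)
}

# Joint log-likelihood over observed cells. X: N x I integer matrix with NA.
joint_loglik_cells <- function(X, theta, delta, tau_list) {
  ids <- colnames(X)
  ll <- matrix(0, nrow(X), ncol(X), dimnames = dimnames(X))
  for (id in ids) {
    p <- category_probabilities(theta, delta[[id]], tau_list[[id]])
    x <- X[, id]
    obs <- which(!is.na(x))
    ll[obs, id] <- log(p[cbind(obs, x[obs] + 1L)])
  }
  ll[is.na(X)] <- 0
  ll
}
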