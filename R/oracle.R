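#' Brute-force grid maximizer of the joint Rasch likelihood
#'
#' Reference implementation for validating the Newton-based calibrator on
#' small problems: every person measure and item difficulty is in turn
#' maximized over a fixed logit grid, cycling until a full sweep moves no
#' parameter, after which difficulties are mean-centered (and measures shifted
#' accordingly, using the model's translation invariance). No derivatives, no
#' shared code with [fit_jmle()] beyond the data layout, which makes it an
#' independent check: agreement is expected within the grid resolution.
#'
#' Dichotomous items only; intended for matrices of at most a few dozen
#' cells.
#'
#' @param X integer 0/1 matrix, persons x items, no extreme rows/columns.
#' @param grid_step grid resolution in logits (default 0.01).
#' @param grid_range symmetric search range in logits.
#' @param max_sweeps safety cap on coordinate sweeps.
#' @return list with `theta`, `delta` (mean-centered), `loglik`, `sweeps`.
#' @export
grid_search_jmle <- function(X, grid_step = 0.01, grid_range = c(-8, 8),
                             max_sweeps = 200L) {
  stopifnot(all(X %in% c(0L, 1L)))
  n <- nrow(X); k <- ncol(X)
  grid <- seq(grid_range[1], grid_range[2], by = grid_step)
  theta <- rep(0, n); delta <- rep(0, k)

  # log-likelihood of one 0/1 response at each grid value of (theta - delta)
  ll_bernoulli <- function(eta, x) x * eta - log1p(exp(eta))

  for (sweep in seq_len(max_sweeps)) {
    moved <- FALSE
    for (p in seq_len(n)) {
      ll <- rowSums(vapply(seq_len(k), function(i)
        ll_bernoulli(grid - delta[i], X[p, i]), numeric(length(grid))))
      best <- grid[which.max(ll)]
      if (abs(best - theta[p]) > grid_step / 2) { theta[p] <- best; moved <- TRUE }
    }
    for (i in seq_len(k)) {
      ll <- rowSums(vapply(seq_len(n), function(p)
        ll_bernoulli(theta[p] - grid, X[p, i]), numeric(length(grid))))
      best <- grid[which.max(ll)]
      if (abs(best - delta[i]) > grid_step / 2) { delta[i] <- best; moved <- TRUE }
    }
    if (!moved) break
  }
  shift <- mean(delta)
  theta <- theta - shift; delta <- delta - shift
  eta <- outer(theta, delta, `-`)
  list(theta = theta, delta = delta,
       loglik = sum(X * eta - log1p(exp(eta))), sweeps = sweep)
}
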