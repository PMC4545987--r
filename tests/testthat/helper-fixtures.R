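`%||%` <- function(a, b) if (is.null(a)) b else a

# k dichotomous items in one domain sharing a rating-scale group
dich_spec <- function(k, domain = "D", group = "bin") {
  instrument_spec(do.call(rbind, lapply(seq_len(k), function(i)
    item_spec(sprintf("it%02d", i), domain, 2, group))))
}

# evenly spaced difficulties over [lo, hi], named by the spec's items
spaced_delta <- function(spec, lo = -3, hi = 3) {
  ids <- spec$items$id
  stats::setNames(seq(lo, hi, length.out = length(ids)), ids)
}

# fixed 8-person x 5-item dichotomous matrix with mixed scores, no extremes
oracle_matrix <- function() {
  X <- rbind(c(1, 0, 0, 0, 0), c(1, 1, 0, 0, 0), c(1, 1, 0, 1, 0),
             c(0, 1, 1, 0, 1), c(1, 0, 1, 1, 0), c(1, 1, 1, 0, 1),
             c(1, 1, 0, 1, 1), c(0, 1, 1, 1, 1))
  colnames(X) <- paste0("i", 1:5)
  X
}

# hand-assembled calibration result for unit tests of downstream summaries
mock_result <- function(theta, delta, tau_list = NULL, theta_se = NULL,
                        delta_se = NULL, X = NULL,
                        extreme_theta = numeric(0)) {
  ids <- names(delta)
  if (is.null(names(theta))) names(theta) <- paste0("P", seq_along(theta))
  if (is.null(tau_list)) {
    tau_list <- stats::setNames(lapply(ids, function(i) 0), ids)
  }
  n_cat <- vapply(tau_list, length, 1L) + 1L
  items <- data.frame(id = ids, domain = "D", n_categories = n_cat[ids],
                      scale_group = ids, reversed = FALSE, excluded = FALSE,
                      row.names = ids, stringsAsFactors = FALSE)
  ext <- data.frame(person = character(0), raw = numeric(0),
                    max = numeric(0), theta = numeric(0))
  if (length(extreme_theta))
    ext <- data.frame(person = paste0("X", seq_along(extreme_theta)),
                      raw = 0, max = 1, theta = extreme_theta)
  structure(list(theta = theta,
                 theta_se = theta_se %||% rep(0.3, length(theta)),
                 delta = delta,
                 delta_se = delta_se %||% rep(0.1, length(delta)),
                 steps = NULL, items = items, tau_list = tau_list,
                 extremes = list(persons = ext, items = character(0)),
                 convergence = list(converged = TRUE, iterations = 0,
                                    max_change = 0, failed = FALSE,
                                    trace = numeric(0)),
                 data = list(X = X), control = rasch_control()),
            class = "calibration_result")
}
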