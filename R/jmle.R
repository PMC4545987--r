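#' Estimation settings for the joint maximum likelihood calibrator
#'
#' @param tol convergence tolerance: iteration stops when the largest absolute
#'   parameter change in a sweep falls below `tol` logits.
#' @param max_iter maximum number of alternating sweeps.
#' @param extreme_adjustment score-point adjustment used to extrapolate finite
#'   measures for zero/perfect raw scores (see [measure_extreme()]).
#' @param bias_correction logical; apply the multiplicative `(L-1)/L`
#'   correction to item difficulties (L = number of calibrated items). Off by
#'   default for comparability with joint-likelihood software conventions.
#' @param center identification constraint; only `"items"` (item difficulties
#'   mean-centered, persons free) is supported.
#' @param max_step cap on a single Newton step (logits).
#' @param divergence_bound absolute parameter bound beyond which estimation
#'   aborts with an error.
#' @return list of class `rasch_control`.
#' @export
rasch_control <- function(tol = 0.005, max_iter = 200L,
                          extreme_adjustment = 0.3, bias_correction = FALSE,
                          center = "items", max_step = 1,
                          divergence_bound = 30) {
  stopifnot(tol > 0, max_iter >= 1, extreme_adjustment > 0,
            extreme_adjustment < 0.5)
  center <- match.arg(center, "items")
  structure(list(tol = tol, max_iter = as.integer(max_iter),
                 extreme_adjustment = extreme_adjustment,
                 bias_correction = isTRUE(bias_correction), center = center,
                 max_step = max_step, divergence_bound = divergence_bound),
            class = "rasch_control")
}

# raw score and maximum attainable over observed items
raw_scores <- function(X, max_cat) {
  obs <- !is.na(X)
  list(raw = rowSums(X, na.rm = TRUE),
       max = as.numeric(obs %*% max_cat),
       n_obs = rowSums(obs))
}

# Iteratively drop persons/items with minimum or maximum possible raw scores
# (or nothing observed); returns index sets and a log of what was dropped.
find_extremes <- function(X, max_cat) {
  keep_p <- rep(TRUE, nrow(X)); keep_i <- rep(TRUE, ncol(X))
  repeat {
    sub <- X[keep_p, keep_i, drop = FALSE]
    mc <- max_cat[keep_i]
    rs <- raw_scores(sub, mc)
    p_ext <- rs$n_obs == 0 | rs$raw == 0 | rs$raw == rs$max
    obs <- !is.na(sub)
    cs <- colSums(sub, na.rm = TRUE)
    cmax <- colSums(obs) * mc
    i_ext <- colSums(obs) == 0 | cs == 0 | cs == cmax
    if (!any(p_ext) && !any(i_ext)) break
    keep_p[keep_p] <- !p_ext
    keep_i[keep_i] <- !i_ext
    if (sum(keep_p) < 2L || sum(keep_i) < 2L)
      stop("fewer than 2 non-extreme persons or items remain")
  }
  list(persons = keep_p, items = keep_i)
}

#' Normal-approximation (PROX-style) starting values
#'
#' Log-odds of each person's score proportion and each item's difficulty
#' proportion, with a mild variance expansion, used to warm-start the Newton
#' iterations. Persons with equal raw scores on identical observed item sets
#' receive equal starting values.
#'
#' @param matrix a [response_matrix()] (or bare integer matrix with item id
#'   column names).
#' @param spec an [instrument_spec()] covering the matrix columns.
#' @return list with components `theta` and `delta` (named numeric vectors,
#'   `delta` mean-centered).
#' @export
prox_initialize <- function(matrix, spec) {
  X <- if (inherits(matrix, "response_matrix")) matrix$responses else matrix
  X <- X[, intersect(colnames(X), spec$items$id), drop = FALSE]
  max_cat <- spec$items[colnames(X), "n_categories"] - 1L
  rs <- raw_scores(X, max_cat)
  p <- (rs$raw + 0.5) / (rs$max + 1)
  theta <- log(p / (1 - p))
  obs <- !is.na(X)
  cs <- colSums(X, na.rm = TRUE)
  cmax <- colSums(obs) * max_cat
  q <- (cs + 0.5) / (cmax + 1)
  delta <- log((1 - q) / q)
  delta <- delta - mean(delta)
  names(theta) <- rownames(X); names(delta) <- colnames(X)
  list(theta = theta, delta = delta)
}

# expand per-group thresholds into a per-item list
tau_by_item <- function(items, group_tau) {
  out <- lapply(items$scale_group, function(g) group_tau[[g]])
  names(out) <- items$id
  out
}

#' Calibrate a mixed rating-scale / partial-credit Rasch model by JMLE
#'
#' Alternating damped Newton--Raphson updates of person measures `theta`,
#' item difficulties `delta`, and rating-scale-group step thresholds `tau`,
#' maximizing the joint log-likelihood over observed cells. Item difficulties
#' are recentered to mean zero each sweep (identification); group thresholds
#' are kept sum-zero. Iteration stops when the largest absolute parameter
#' change drops below `control$tol` or after `control$max_iter` sweeps.
#' Persons and items with minimum or maximum possible raw scores are removed
#' before iteration and reported; extreme persons additionally receive
#' extrapolated measures (see [measure_extreme()]).
#'
#' Standard errors are the inverse square roots of the observed information
#' accumulated over observed cells.
#'
#' Domains are intended to be calibrated separately (pass a domain-subset
#' spec, e.g. via [subset_spec()]); all items in `spec` are calibrated
#' together on one logit metric.
#'
#' @param matrix a [response_matrix()].
#' @param spec an [instrument_spec()]; only its non-excluded items present in
#'   the matrix are calibrated (>= 2 required).
#' @param control a [rasch_control()].
#' @return object of class `calibration_result` with person measures and SEs,
#'   item difficulties and SEs, group step thresholds, extreme-score tables,
#'   and a convergence trace.
#' @export
fit_jmle <- function(matrix, spec, control = rasch_control()) {
  stopifnot(inherits(matrix, "response_matrix"))
  items <- spec_items(spec, analyzed_only = TRUE)
  items <- items[items$id %in% colnames(matrix$responses), , drop = FALSE]
  if (nrow(items) < 2L) stop("need at least 2 calibratable items")
  X_full <- matrix$responses[, items$id, drop = FALSE]
  max_cat <- items$n_categories - 1L

  keep <- find_extremes(X_full, max_cat)
  X <- X_full[keep$persons, keep$items, drop = FALSE]
  items_used <- items[keep$items, , drop = FALSE]
  mc <- max_cat[keep$items]

  init <- prox_initialize(X, instrument_spec(items_used))
  theta <- init$theta
  delta <- init$delta
  groups <- unique(items_used$scale_group)
  group_tau <- lapply(groups, function(g) {
    m <- items_used$n_categories[items_used$scale_group == g][1]
    rep(0, m - 1L)
  })
  names(group_tau) <- groups
  free_tau <- groups[vapply(group_tau, length, 1L) > 1L]

  bound <- control$divergence_bound
  loglik_total <- function(th, de, tl) sum(joint_loglik_cells(X, th, de, tl))
  trace <- numeric(0)
  converged <- FALSE

  for (iter in seq_len(control$max_iter)) {
    theta0 <- theta; delta0 <- delta; tau0 <- group_tau
    tl <- tau_by_item(items_used, group_tau)

    ## --- person update (damped Newton, per person) ---
    mom <- model_moments(theta, delta, tl)
    obs <- !is.na(X)
    score <- rowSums((X - mom$E) * obs, na.rm = TRUE)
    info <- rowSums(mom$V * obs)
    step <- score / pmax(info, 1e-10)
    step <- pmin(pmax(step, -control$max_step), control$max_step)
    ll_old <- rowSums(joint_loglik_cells(X, theta, delta, tl))
    for (h in 1:8) {
      cand <- theta + step
      ll_new <- rowSums(joint_loglik_cells(X, cand, delta, tl))
      worse <- ll_new < ll_old - 1e-12
      if (!any(worse)) break
      step[worse] <- step[worse] / 2
    }
    theta <- theta + step

    ## --- item update ---
    mom <- model_moments(theta, delta, tl)
    score_i <- colSums((mom$E - X) * obs, na.rm = TRUE)
    info_i <- colSums(mom$V * obs)
    step_i <- score_i / pmax(info_i, 1e-10)
    step_i <- pmin(pmax(step_i, -control$max_step), control$max_step)
    ll_old_i <- colSums(joint_loglik_cells(X, theta, delta, tl))
    for (h in 1:8) {
      cand <- delta + step_i
      tl_c <- tl
      ll_new_i <- colSums(joint_loglik_cells(X, theta, cand, tl_c))
      worse <- ll_new_i < ll_old_i - 1e-12
      if (!any(worse)) break
      step_i[worse] <- step_i[worse] / 2
    }
    delta <- delta + step_i

    ## --- threshold update per multi-category group (diagonal Newton) ---
    for (g in free_tau) {
      ids <- items_used$id[items_used$scale_group == g]
      tau_g <- group_tau[[g]]
      mm <- length(tau_g) + 1L
      grad <- hess <- numeric(mm - 1L)
      tl <- tau_by_item(items_used, group_tau)
      for (id in ids) {
        p <- category_probabilities(theta, delta[[id]], tl[[id]])
        x <- X[, id]
        o <- which(!is.na(x))
        if (!length(o)) next
        # survivor probabilities P(X >= j), j = 1..m-1
        surv <- 1 - t(apply(p[o, , drop = FALSE], 1L, cumsum))
        S <- surv[, 1:(mm - 1L), drop = FALSE]  # P(X >= j)
        Ind <- outer(x[o], 1:(mm - 1L), ">=") * 1
        grad <- grad + colSums(S - Ind)
        hess <- hess + colSums(S * (1 - S))
      }
      step_t <- grad / pmax(hess, 1e-10)
      step_t <- pmin(pmax(step_t, -control$max_step), control$max_step)
      ll_before <- loglik_total(theta, delta, tl)
      for (h in 1:8) {
        cand_tau <- group_tau
        cand_tau[[g]] <- tau_g + step_t
        tl_c <- tau_by_item(items_used, cand_tau)
        if (loglik_total(theta, delta, tl_c) >= ll_before - 1e-12) break
        step_t <- step_t / 2
      }
      group_tau[[g]] <- tau_g + step_t
      # keep the group sum-zero; absorb the shift into member difficulties
      m_shift <- mean(group_tau[[g]])
      group_tau[[g]] <- group_tau[[g]] - m_shift
      delta[ids] <- delta[ids] + m_shift
    }

    ## --- recenter items; slide persons along the invariance ridge ---
    c_shift <- mean(delta)
    delta <- delta - c_shift
    theta <- theta - c_shift

    if (max(abs(c(theta, delta, unlist(group_tau)))) > bound)
      stop("JMLE diverged: a parameter exceeded ", bound, " logits")

    max_change <- max(abs(theta - theta0), abs(delta - delta0),
                      abs(unlist(group_tau) - unlist(tau0)))
    trace <- c(trace, max_change)
    if (max_change < control$tol) { converged <- TRUE; break }
  }

  if (control$bias_correction) {
    L <- length(delta)
    delta <- delta * (L - 1) / L
  }

  tl <- tau_by_item(items_used, group_tau)
  mom <- model_moments(theta, delta, tl)
  obs <- !is.na(X)
  theta_se <- 1 / sqrt(pmax(rowSums(mom$V * obs), 1e-10))
  delta_se <- 1 / sqrt(pmax(colSums(mom$V * obs), 1e-10))

  result <- structure(list(
    theta = theta, theta_se = theta_se,
    delta = delta, delta_se = delta_se,
    steps = group_tau,
    items = items_used,
    tau_list = tl,
    extremes = NULL,
    convergence = list(converged = converged, iterations = length(trace),
                       max_change = if (length(trace)) trace[length(trace)]
                                    else NA_real_,
                       failed = !converged, trace = trace),
    data = list(X = X, X_full = X_full, items_full = items,
                kept_persons = keep$persons, kept_items = keep$items),
    control = control), class = "calibration_result")

  ## extrapolated measures for extreme persons; extreme item bookkeeping
  ext_p_idx <- which(!keep$persons)
  ext_persons <- data.frame(person = character(0), raw = numeric(0),
                            max = numeric(0), theta = numeric(0))
  for (i in ext_p_idx) {
    x <- X_full[i, keep$items]
    ids <- names(x)[!is.na(x)]
    ids <- intersect(ids, items_used$id)
    if (!length(ids)) next
    r <- sum(x[ids]); mx <- sum(items_used[ids, "n_categories"] - 1L)
    th <- if (r == 0 || r == mx)
      measure_extreme(r, result, item_ids = ids,
                      adjustment = control$extreme_adjustment)
    else NA_real_  # person became non-extreme only via dropped items
    ext_persons <- rbind(ext_persons,
                         data.frame(person = rownames(X_full)[i], raw = r,
                                    max = mx, theta = th))
  }
  ext_items <- items$id[!keep$items]
  result$extremes <- list(persons = ext_persons, items = ext_items)
  result
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result> ", length(x$theta), " persons, ",
      length(x$delta), " items",
      if (nrow(x$extremes$persons)) paste0(" (+", nrow(x$extremes$persons),
                                           " extreme persons)"), "\n",
      sep = "")
  cat("  converged: ", x$convergence$converged, " after ",
      x$convergence$iterations, " sweeps (max change ",
      signif(x$convergence$max_change, 3), ")\n", sep = "")
  cat("  item difficulty range: [",
      sprintf("%.2f", min(x$delta)), ", ", sprintf("%.2f", max(x$delta)),
      "] logits\n", sep = "")
  invisible(x)
}

#' Extrapolated measure for an extreme raw score
#'
#' Zero and perfect raw scores have no finite maximum-likelihood measure; a
#' finite value is extrapolated by solving for the ability whose expected
#' total score on the calibrated items equals the pseudo-score
#' `0 + adjustment` (floor) or `max - adjustment` (ceiling).
#'
#' @param raw_score observed raw score; must equal 0 or the maximum attainable
#'   on `item_ids`.
#' @param result a [fit_jmle()] calibration.
#' @param item_ids items the person answered (default: all calibrated items).
#' @param adjustment score-point adjustment, default 0.3.
#' @return extrapolated ability in logits.
#' @export
measure_extreme <- function(raw_score, result, item_ids = NULL,
                            adjustment = result$control$extreme_adjustment) {
  if (is.null(item_ids)) item_ids <- names(result$delta)
  item_ids <- intersect(item_ids, names(result$delta))
  mx <- sum(result$items[item_ids, "n_categories"] - 1L)
  if (!(raw_score == 0 || raw_score == mx))
    stop("raw score ", raw_score, " is not extreme (0 or ", mx,
         "); use the calibrated measure")
  target <- if (raw_score == 0) adjustment else mx - adjustment
  f <- function(th) {
    sum(vapply(item_ids, function(id)
      expected_score(th, result$delta[[id]], result$tau_list[[id]])$expected,
      numeric(1))) - target
  }
  stats::uniroot(f, c(-40, 40), tol = 1e-8)$root
}

#' Person measures from a calibration
#'
#' @param result a [fit_jmle()] calibration.
#' @param include_extreme include extreme-score persons with their
#'   extrapolated measures (`SE = NA`).
#' @return `data.frame` with columns `person`, `theta`, `se`, `extreme`.
#' @export
person_measures <- function(result, include_extreme = TRUE) {
  out <- data.frame(person = names(result$theta), theta = unname(result$theta),
                    se = unname(result$theta_se), extreme = FALSE,
                    stringsAsFactors = FALSE)
  ep <- result$extremes$persons
  if (include_extreme && nrow(ep))
    out <- rbind(out, data.frame(person = ep$person, theta = ep$theta,
                                 se = NA_real_, extreme = TRUE))
  out
}

#' Item difficulties from a calibration
#'
#' The item difficulty is the mean of the item's step locations (equal to its
#' `delta` under the sum-zero threshold constraint).
#'
#' @param result a [fit_jmle()] calibration.
#' @return `data.frame` with `item`, `domain`, `difficulty`, `se`.
#' @export
item_difficulties <- function(result) {
  data.frame(item = names(result$delta),
             domain = result$items[names(result$delta), "domain"],
             difficulty = unname(result$delta),
             se = unname(result$delta_se), stringsAsFactors = FALSE)
}

#' Step (threshold) locations of all calibrated items
#'
#' Step `j` of item `i` sits at `delta_i + tau_gj`; a dichotomous item
#' contributes its difficulty as its single threshold. These locations define
#' the instrument's operational range for coverage and ceiling/floor work.
#'
#' @param result a [fit_jmle()] calibration.
#' @return `data.frame` with `item`, `step` (1-based), `location`.
#' @export
step_locations <- function(result) {
  rows <- lapply(names(result$delta), function(id) {
    tau <- result$tau_list[[id]]
    data.frame(item = id, step = seq_along(tau),
               location = result$delta[[id]] + tau,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Export a calibration as a tabular item report
#'
#' One row per calibrated item ordered by difficulty (ties broken by item
#' id), with difficulty, standard error, and infit mean square, mirroring the
#' usual published layout.
#'
#' @param result a [fit_jmle()] calibration.
#' @param path optional CSV path; when given the table is also written there.
#' @return the table, invisibly if `path` is given.
#' @export
calibration_table <- function(result, path = NULL) {
  tab <- item_difficulties(result)
  fit <- infit_outfit(result)$items
  tab$infit <- fit$infit[match(tab$item, fit$item)]
  tab$outfit <- fit$outfit[match(tab$item, fit$item)]
  tab <- tab[order(tab$difficulty, tab$item), ]
  rownames(tab) <- NULL
  if (!is.null(path)) {
    utils::write.csv(tab, path, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}
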