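# internal: expected values and variances for the cells used in calibration
fitted_moments <- function(result) {
  mom <- model_moments(result$theta, result$delta, result$tau_list)
  mom$X <- result$data$X
  mom
}

#' Standardized response residuals
#'
#' For each observed cell, `z = (x - E) / sqrt(Var)` with `E` and `Var` the
#' model-implied mean and variance at the calibrated parameters. Degenerate
#' cells (zero variance) and extreme persons/items are `NA`.
#'
#' @param result a [fit_jmle()] calibration.
#' @return numeric matrix (non-extreme persons x items) of residual z values.
#' @export
standardized_residuals <- function(result) {
  mom <- fitted_moments(result)
  z <- (mom$X - mom$E) / sqrt(mom$V)
  z[!is.finite(z)] <- NA_real_
  rownames(z) <- names(result$theta)
  z
}

#' Infit and outfit mean squares
#'
#' Infit (information-weighted) for unit `i` is
#' `sum (x - E)^2 / sum Var`; outfit is the unweighted mean of squared
#' standardized residuals. Infit gives relatively more weight to persons
#' located close to the item. Items (or persons) with fewer than 2 observed
#' cells get `NA`. Classification against the configured band: below the low
#' bound overfit, above the high bound misfit.
#'
#' @param result a [fit_jmle()] calibration.
#' @param criteria a [rasch_criteria()].
#' @return list of two `data.frame`s, `items` (`item`, `infit`, `outfit`,
#'   `n_obs`, `classification`) and `persons`.
#' @export
infit_outfit <- function(result, criteria = rasch_criteria()) {
  mom <- fitted_moments(result)
  X <- mom$X; E <- mom$E; V <- mom$V
  obs <- !is.na(X)
  sq <- (X - E)^2
  z2 <- sq / V
  z2[!is.finite(z2)] <- NA

  stat_over <- function(margin) {
    f <- if (margin == 2) colSums else rowSums
    cnt <- if (margin == 2) colSums(obs) else rowSums(obs)
    infit <- f(sq, na.rm = TRUE) / f(V * obs, na.rm = TRUE)
    outfit <- f(z2, na.rm = TRUE) / cnt
    infit[cnt < 2] <- NA; outfit[cnt < 2] <- NA
    list(infit = infit, outfit = outfit, n = cnt)
  }
  si <- stat_over(2)
  sp <- stat_over(1)
  list(items = data.frame(item = colnames(X), infit = unname(si$infit),
                          outfit = unname(si$outfit), n_obs = unname(si$n),
                          classification = classify_fit(unname(si$infit),
                                                        criteria),
                          stringsAsFactors = FALSE),
       persons = data.frame(person = names(result$theta),
                            infit = unname(sp$infit),
                            outfit = unname(sp$outfit), n_obs = unname(sp$n),
                            classification = classify_fit(unname(sp$infit),
                                                          criteria),
                            stringsAsFactors = FALSE))
}

#' Reliability and separation from measures and their standard errors
#'
#' The observed measure variance is decomposed into true and error parts:
#' `adjusted = max(var(measures) - mean(se^2), 0)`, reliability
#' `R = adjusted / observed`, and separation `G = sqrt(R / (1 - R))`.
#' A reliability above 0.7 indicates good internal consistency; separation
#' between 1.5 and 2.0 is acceptable and above 3.0 excellent.
#'
#' @param measures measures in logits (>= 2 required).
#' @param ses matching standard errors.
#' @param criteria a [rasch_criteria()].
#' @return list with `reliability`, `separation`, `degenerate` flag, and
#'   qualitative `band`.
#' @export
separation_reliability <- function(measures, ses,
                                   criteria = rasch_criteria()) {
  stopifnot(length(measures) >= 2, length(measures) == length(ses))
  ov <- stats::var(measures)
  if (ov <= 0)
    return(list(reliability = 0, separation = 0, degenerate = TRUE,
                band = "degenerate"))
  adj <- max(ov - mean(ses^2), 0)
  r <- adj / ov
  g <- sqrt(r / (1 - r))
  list(reliability = r, separation = g, degenerate = FALSE,
       band = classify_separation(g, criteria))
}

#' Separation index implied by a reliability coefficient
#'
#' Closed form `G = sqrt(R / (1 - R))`; useful for checking that a published
#' reliability/separation pair is internally consistent.
#'
#' @param reliability reliability in `[0, 1)`.
#' @return separation index.
#' @export
separation_from_reliability <- function(reliability) {
  stopifnot(all(reliability >= 0), all(reliability < 1))
  sqrt(reliability / (1 - reliability))
}

#' Principal component analysis of standardized residuals
#'
#' Eigen-decomposition of the inter-item correlation matrix of standardized
#' residuals (pairwise-complete observations). Eigenvalues are in item units
#' (they sum to the number of retained items); the first eigenvalue is the
#' "first contrast" used to screen for a secondary dimension. Items with
#' constant residuals are dropped with a warning.
#'
#' @param z residual matrix from [standardized_residuals()].
#' @param criteria a [rasch_criteria()]; supplies the eigenvalue cut below
#'   which the scale is flagged unidimensional.
#' @return list with `eigenvalues` (descending), `first_contrast`,
#'   `unidimensional` flag, and `dropped` item ids.
#' @export
pca_residuals <- function(z, criteria = rasch_criteria()) {
  if (ncol(z) < 3) stop("residual PCA needs at least 3 items")
  sds <- apply(z, 2, stats::sd, na.rm = TRUE)
  dropped <- colnames(z)[is.na(sds) | sds == 0]
  if (length(dropped)) {
    warning("dropping constant-residual item(s): ",
            paste(dropped, collapse = ", "))
    z <- z[, !(colnames(z) %in% dropped), drop = FALSE]
  }
  cm <- stats::cor(z, use = "pairwise.complete.obs")
  cm[is.na(cm)] <- 0; diag(cm) <- 1
  ev <- sort(eigen(cm, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  list(eigenvalues = ev, first_contrast = ev[1],
       unidimensional = ev[1] < criteria$unidim_eigen_cut,
       dropped = dropped)
}

#' Screen item pairs for local dependence
#'
#' Item pairs whose standardized-residual correlation exceeds the threshold
#' in absolute value violate the local-independence assumption (typically
#' item pairs with overlapping content).
#'
#' @param z residual matrix from [standardized_residuals()].
#' @param threshold absolute correlation cut (default 0.3).
#' @return `data.frame` of flagged pairs (`item_a`, `item_b`, `r`), sorted by
#'   `|r|` descending; zero rows when nothing is flagged.
#' @export
local_independence <- function(z, threshold = 0.3) {
  if (ncol(z) < 2) stop("local independence screening needs >= 2 items")
  cm <- stats::cor(z, use = "pairwise.complete.obs")
  idx <- which(upper.tri(cm) & !is.na(cm) & abs(cm) > threshold,
               arr.ind = TRUE)
  out <- data.frame(item_a = colnames(cm)[idx[, 1]],
                    item_b = colnames(cm)[idx[, 2]],
                    r = cm[idx], stringsAsFactors = FALSE)
  out[order(-abs(out$r)), , drop = FALSE]
}

#' Kuder-Richardson formula 20 (KR-20)
#'
#' Internal-consistency coefficient for dichotomous items:
#' `(k / (k - 1)) (1 - sum p_i q_i / var_total)`, computed on complete rows
#' (listwise deletion) with population (n-divisor) variances, which makes it
#' identical to Cronbach's alpha computed generically on 0/1 data.
#'
#' @param X integer 0/1 matrix (persons x items); or a [response_matrix()]
#'   together with `spec`, in which case the dichotomous items are selected.
#' @param spec optional [instrument_spec()] used to pick dichotomous items.
#' @return KR-20 coefficient.
#' @export
kr20 <- function(X, spec = NULL) {
  if (inherits(X, "response_matrix")) {
    stopifnot(!is.null(spec))
    ids <- spec$items$id[spec$items$n_categories == 2L]
    X <- X$responses[, intersect(colnames(X$responses), ids), drop = FALSE]
  }
  if (!all(X %in% c(0L, 1L, NA)))
    stop("KR-20 requires dichotomous (0/1) items")
  X <- X[stats::complete.cases(X), , drop = FALSE]
  k <- ncol(X)
  if (k < 2) stop("KR-20 requires at least 2 items")
  if (nrow(X) < 2) stop("KR-20 requires at least 2 complete response rows")
  n <- nrow(X)
  p <- colMeans(X)
  tot <- rowSums(X)
  var_tot <- mean((tot - mean(tot))^2)   # population variance
  if (var_tot == 0) stop("KR-20 undefined: zero total-score variance")
  (k / (k - 1)) * (1 - sum(p * (1 - p)) / var_tot)
}

#' Full residual-based diagnostics for a calibrated domain
#'
#' Convenience wrapper bundling item/person fit, person and item
#' reliability/separation, residual PCA, local-independence screening, and
#' (when the domain is all-dichotomous) KR-20.
#'
#' @param result a [fit_jmle()] calibration.
#' @param criteria a [rasch_criteria()].
#' @return list of class `diagnostics_report`.
#' @export
diagnose <- function(result, criteria = rasch_criteria()) {
  z <- standardized_residuals(result)
  fit <- infit_outfit(result, criteria)
  pers <- separation_reliability(result$theta, result$theta_se, criteria)
  item <- separation_reliability(result$delta, result$delta_se, criteria)
  pca <- if (ncol(z) >= 3) pca_residuals(z, criteria) else NULL
  li <- local_independence(z, criteria$residual_r_threshold)
  dich <- result$items$id[result$items$n_categories == 2L]
  alpha <- if (length(dich) >= 2)
    tryCatch(kr20(result$data$X[, dich, drop = FALSE]),
             error = function(e) NA_real_)
  else NA_real_
  structure(list(fit = fit, person = pers, item = item, pca = pca,
                 dependent_pairs = li, kr20 = alpha, criteria = criteria),
            class = "diagnostics_report")
}

#' @export
print.diagnostics_report <- function(x, ...) {
  cat("<diagnostics_report>\n")
  cat(sprintf("  person reliability %.2f (separation %.2f, %s)\n",
              x$person$reliability, x$person$separation, x$person$band))
  mis <- x$fit$items$item[x$fit$items$classification %in% "misfit"]
  cat("  misfitting items: ",
      if (length(mis)) paste(mis, collapse = ", ") else "none", "\n", sep = "")
  if (!is.null(x$pca))
    cat(sprintf("  first-contrast eigenvalue %.2f (%s)\n",
                x$pca$first_contrast,
                if (x$pca$unidimensional) "unidimensional" else "check"))
  if (!is.na(x$kr20)) cat(sprintf("  KR-20 (dichotomous items) %.2f\n", x$kr20))
  cat("  locally dependent pairs: ", nrow(x$dependent_pairs), "\n", sep = "")
  invisible(x)
}
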