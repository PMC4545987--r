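# subset a response_matrix by person index, keeping covariates aligned
subset_persons <- function(matrix, idx) {
  structure(list(responses = matrix$responses[idx, , drop = FALSE],
                 covariates = if (is.null(matrix$covariates)) NULL
                              else matrix$covariates[idx, , drop = FALSE],
                 reversal_applied = matrix$reversal_applied),
            class = "response_matrix")
}

#' Split persons into two subgroups for DIF analysis
#'
#' Built-in rules: `"age_75"` splits at age 75 (group A `< 75`, group B
#' `>= 75`); `"stage"` splits disease severity into stages 0-II (group A)
#' versus III-IV (group B). A custom rule is a function of the covariate
#' `data.frame` returning `TRUE` for group A membership (`NA` excludes the
#' person with a warning).
#'
#' @param matrix a [response_matrix()] with covariates.
#' @param rule `"age_75"`, `"stage"`, or a predicate function.
#' @param stage012 severity labels assigned to group A under the `"stage"`
#'   rule (stage II is grouped with the milder stages by default; the split
#'   is configurable because severity tabulations often combine stages).
#' @return list with `A`, `B` ([response_matrix()] views), `labels`, `rule`.
#' @export
split_groups <- function(matrix, rule = "age_75",
                         stage012 = c("0", "I", "II", "0-I")) {
  cov <- matrix$covariates
  if (is.null(cov)) stop("response matrix has no covariates to split on")
  if (is.function(rule)) {
    in_a <- rule(cov)
    labels <- c(A = "group A", B = "group B")
    rule_name <- "custom"
  } else if (identical(rule, "age_75")) {
    if (is.null(cov$age_years)) stop("covariate 'age_years' not present")
    in_a <- cov$age_years < 75
    labels <- c(A = "age < 75", B = "age >= 75")
    rule_name <- "age_75"
  } else if (identical(rule, "stage")) {
    if (is.null(cov$stage)) stop("covariate 'stage' not present")
    in_a <- as.character(cov$stage) %in% stage012
    labels <- c(A = "stage 0-II", B = "stage III-IV")
    rule_name <- "severity_stage"
  } else stop("unknown split rule: ", rule)
  if (anyNA(in_a)) {
    warning(sum(is.na(in_a)), " person(s) with missing covariate excluded")
  }
  a_idx <- which(!is.na(in_a) & in_a)
  b_idx <- which(!is.na(in_a) & !in_a)
  if (!length(a_idx) || !length(b_idx))
    stop("split rule '", rule_name, "' leaves a group empty")
  list(A = subset_persons(matrix, a_idx), B = subset_persons(matrix, b_idx),
       labels = labels, rule = rule_name)
}

# re-estimate item difficulties with person measures and thresholds fixed
anchored_item_estimates <- function(X, theta, tau_list, max_cat,
                                    bound = 30) {
  ids <- colnames(X)
  delta <- se <- stats::setNames(rep(NA_real_, length(ids)), ids)
  for (id in ids) {
    x <- X[, id]
    o <- which(!is.na(x))
    if (length(o) < 2) next
    s <- sum(x[o])
    if (s == 0 || s == length(o) * max_cat[[id]]) next  # extreme in group
    d <- 0
    for (it in 1:100) {
      es <- expected_score(theta[o], d, tau_list[[id]])
      grad <- sum(es$expected - x[o])
      info <- sum(es$variance)
      step <- grad / max(info, 1e-10)
      step <- min(max(step, -2), 2)
      d <- d + step
      if (abs(d) > bound) { d <- NA_real_; break }
      if (abs(step) < 1e-8) break
    }
    if (!is.na(d)) {
      es <- expected_score(theta[o], d, tau_list[[id]])
      delta[[id]] <- d
      se[[id]] <- 1 / sqrt(max(sum(es$variance), 1e-10))
    }
  }
  list(delta = delta, se = se)
}

#' Differential item functioning by anchored group calibrations
#'
#' Item difficulties are re-estimated separately within each subgroup and
#' compared; an item whose difficulty contrast `delta_A - delta_B` exceeds
#' the criterion in absolute value (default 0.5 logits) is flagged as showing
#' DIF. Two estimation methods:
#'
#' * `"anchored"` (default): person measures are fixed at the pooled
#'   calibration's values (extrapolated for extreme scores) and group
#'   thresholds at the pooled values; only each item's difficulty is
#'   re-estimated per group. Better identified at modest group sizes.
#' * `"separate"`: a full calibration per group, linked by mean-item
#'   equating (both solutions are item-mean-centered), matching the
#'   two-calibration scatter construction.
#'
#' Items that are extreme within a group (all minimum or all maximum) get a
#' missing contrast and are reported as untestable.
#'
#' @param matrix a [response_matrix()].
#' @param spec an [instrument_spec()] (typically one domain).
#' @param groups a [split_groups()] result.
#' @param criterion DIF flag threshold in logits.
#' @param method `"anchored"` or `"separate"`.
#' @param control a [rasch_control()] for the underlying calibrations.
#' @param pooled optional precomputed pooled [fit_jmle()] result.
#' @return `data.frame` of class `dif_table`: `item`, `domain`, `delta_a`,
#'   `se_a`, `delta_b`, `se_b`, `contrast`, `flagged`; attributes `grouping`,
#'   `labels`, `criterion`, `method`.
#' @export
dif_contrast <- function(matrix, spec, groups, criterion = 0.5,
                         method = c("anchored", "separate"),
                         control = rasch_control(), pooled = NULL) {
  method <- match.arg(method)
  items <- spec_items(spec, analyzed_only = TRUE)
  items <- items[items$id %in% colnames(matrix$responses), , drop = FALSE]

  if (method == "anchored") {
    if (is.null(pooled)) pooled <- fit_jmle(matrix, spec, control)
    pm <- person_measures(pooled, include_extreme = TRUE)
    theta_all <- stats::setNames(pm$theta, pm$person)
    max_cat <- stats::setNames(as.list(pooled$items$n_categories - 1L),
                               pooled$items$id)
    est <- lapply(list(A = groups$A, B = groups$B), function(g) {
      ids <- intersect(rownames(g$responses), names(theta_all))
      ids <- ids[!is.na(theta_all[ids])]
      X <- g$responses[ids, names(pooled$delta), drop = FALSE]
      anchored_item_estimates(X, theta_all[ids], pooled$tau_list, max_cat,
                              bound = control$divergence_bound)
    })
    da <- est$A$delta; sa <- est$A$se
    db <- est$B$delta; sb <- est$B$se
  } else {
    fa <- fit_jmle(groups$A, spec, control)
    fb <- fit_jmle(groups$B, spec, control)
    ids <- items$id
    da <- sa <- db <- sb <- stats::setNames(rep(NA_real_, length(ids)), ids)
    da[names(fa$delta)] <- fa$delta; sa[names(fa$delta)] <- fa$delta_se
    db[names(fb$delta)] <- fb$delta; sb[names(fb$delta)] <- fb$delta_se
  }

  ids <- intersect(items$id, names(da))
  out <- data.frame(item = ids, domain = items[ids, "domain"],
                    delta_a = unname(da[ids]), se_a = unname(sa[ids]),
                    delta_b = unname(db[ids]), se_b = unname(sb[ids]),
                    stringsAsFactors = FALSE)
  out$contrast <- out$delta_a - out$delta_b
  out$flagged <- !is.na(out$contrast) & abs(out$contrast) > criterion
  rownames(out) <- NULL
  structure(out, grouping = groups$rule, labels = groups$labels,
            criterion = criterion, method = method,
            class = c("dif_table", "data.frame"))
}

#' Summarise DIF flags per domain
#'
#' @param table a [dif_contrast()] result.
#' @return `data.frame` per domain: `n_flagged`, `n_testable`, and a
#'   formatted `label` like `"4 (57 %)"` (percentage rounded to whole).
#' @export
dif_summary <- function(table) {
  sp <- split(as.data.frame(table), table$domain)
  rows <- lapply(names(sp), function(d) {
    t <- sp[[d]]
    testable <- sum(!is.na(t$contrast))
    flagged <- sum(t$flagged, na.rm = TRUE)
    pct <- if (testable) round(100 * flagged / testable) else 0
    data.frame(domain = d, n_flagged = flagged, n_testable = testable,
               label = sprintf("%d (%d %%)", flagged, pct),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Plot-ready coordinates for a DIF scatter
#'
#' The conventional display scatters group-A against group-B difficulties
#' with the identity line and parallel bands at plus/minus the criterion;
#' points outside the bands show DIF.
#'
#' @param table a [dif_contrast()] result.
#' @return list with `points` (the table), `identity` (two endpoints) and
#'   `bands` (offsets `+criterion`, `-criterion`).
#' @export
dif_plot_data <- function(table) {
  crit <- attr(table, "criterion")
  vals <- c(table$delta_a, table$delta_b)
  lim <- range(vals, na.rm = TRUE) + c(-0.5, 0.5)
  list(points = as.data.frame(table),
       identity = data.frame(x = lim, y = lim),
       bands = data.frame(offset = c(crit, -crit)),
       labels = attr(table, "labels"))
}

#' @export
plot.dif_table <- function(x, ...) {
  pd <- dif_plot_data(x)
  crit <- attr(x, "criterion")
  lim <- range(c(x$delta_a, x$delta_b), na.rm = TRUE) + c(-0.5, 0.5)
  plot(x$delta_a, x$delta_b, xlim = lim, ylim = lim,
       xlab = paste("Item difficulty,", pd$labels[["A"]], "(logits)"),
       ylab = paste("Item difficulty,", pd$labels[["B"]], "(logits)"),
       pch = ifelse(x$flagged, 19, 1), ...)
  graphics::abline(0, 1)
  graphics::abline(crit, 1, lty = 2)
  graphics::abline(-crit, 1, lty = 2)
  invisible(x)
}
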