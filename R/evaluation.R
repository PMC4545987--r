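#' Item-person targeting index
#'
#' Difference between the mean person measure (extreme persons included via
#' their extrapolated measures) and the mean item difficulty. With items
#' mean-centered the index is simply the mean person measure. Zero is perfect
#' targeting; an absolute value between the slight and substantial bounds is
#' slight mis-targeting, beyond the substantial bound substantial
#' mis-targeting. A positive index means the items sit below the persons
#' (the instrument is "easy" for the sample).
#'
#' @param result a [fit_jmle()] calibration.
#' @param criteria a [rasch_criteria()].
#' @return list with `index` (logits) and `band`.
#' @export
targeting <- function(result, criteria = rasch_criteria()) {
  th <- person_measures(result, include_extreme = TRUE)$theta
  th <- th[!is.na(th)]
  idx <- mean(th) - mean(result$delta)
  list(index = idx, band = classify_targeting(idx, criteria))
}

#' Threshold range, person range, and coverage
#'
#' The operational range of the instrument is the span of all item step
#' locations `delta_i + tau_gj`. Coverage is the percentage of persons
#' (extrapolated extremes included) whose measure falls inside that range,
#' boundary values counting as inside. Also reported: the person-measure
#' range and the 2.5th-97.5th percentile limits.
#'
#' @param result a [fit_jmle()] calibration.
#' @param criteria a [rasch_criteria()]; supplies the coverage target.
#' @return list with `threshold_range`, `person_range`, `person_limits`
#'   (2.5/97.5 percentiles), `coverage` (percent), and `good_coverage` flag.
#' @export
threshold_range_coverage <- function(result, criteria = rasch_criteria()) {
  loc <- step_locations(result)$location
  rng <- range(loc)
  th <- person_measures(result, include_extreme = TRUE)$theta
  th <- th[!is.na(th)]
  coverage <- 100 * mean(th >= rng[1] & th <= rng[2])
  list(threshold_range = rng,
       person_range = range(th),
       person_limits = unname(stats::quantile(th, c(0.025, 0.975))),
       coverage = coverage,
       good_coverage = coverage >= criteria$coverage_good)
}

#' Gaps between adjacent item difficulties
#'
#' Items are sorted by difficulty (the mean of each item's step locations)
#' and consecutive differences at or above `min_gap` logits are flagged: such
#' gaps mean the construct continuum is not evenly covered.
#'
#' @param result a [fit_jmle()] calibration.
#' @param min_gap flag threshold in logits (default from `criteria`).
#' @param criteria a [rasch_criteria()].
#' @return `data.frame` of consecutive pairs (`item_low`, `item_high`,
#'   `gap`, `flagged`) in difficulty order.
#' @export
gaps <- function(result, min_gap = criteria$min_gap,
                 criteria = rasch_criteria()) {
  d <- sort(result$delta)
  if (length(d) < 2) stop("gap detection needs >= 2 items")
  data.frame(item_low = names(d)[-length(d)], item_high = names(d)[-1],
             gap = unname(diff(d)), flagged = unname(diff(d)) >= min_gap,
             stringsAsFactors = FALSE)
}

#' Ceiling and floor effects
#'
#' Percentage of persons strictly above the highest item threshold (ceiling)
#' and strictly below the lowest (floor); persons exactly on a boundary count
#' as in range, so floor + ceiling + coverage partition to 100. Extrapolated
#' extreme measures are included — ceiling effects are precisely about
#' extremes. Flagged at or above the configured limit.
#'
#' @param result a [fit_jmle()] calibration.
#' @param criteria a [rasch_criteria()].
#' @return list with `ceiling`, `floor` (percent), and flags.
#' @export
ceiling_floor <- function(result, criteria = rasch_criteria()) {
  loc <- step_locations(result)$location
  th <- person_measures(result, include_extreme = TRUE)$theta
  th <- th[!is.na(th)]
  ceiling_pct <- 100 * mean(th > max(loc))
  floor_pct <- 100 * mean(th < min(loc))
  list(ceiling = ceiling_pct, floor = floor_pct,
       ceiling_flagged = ceiling_pct >= criteria$ceiling_floor_limit,
       floor_flagged = floor_pct >= criteria$ceiling_floor_limit)
}

#' Detect disordered step thresholds
#'
#' A polytomous item functions as intended only when its step thresholds
#' ascend strictly with category; any adjacent pair with
#' `tau_j >= tau_(j+1)` marks the item's category structure as disordered
#' (usually a rarely-used middle category). Dichotomous items are skipped.
#'
#' @param result a [fit_jmle()] calibration.
#' @return `data.frame` (`item`, `disordered`) over polytomous items; zero
#'   rows when none are polytomous.
#' @export
threshold_order <- function(result) {
  poly <- result$items$id[result$items$n_categories >= 3L]
  rows <- lapply(poly, function(id) {
    tau <- result$tau_list[[id]]
    data.frame(item = id, disordered = any(diff(tau) <= 0),
               stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(item = character(0), disordered = logical(0)))
  do.call(rbind, rows)
}

#' Scale-level evaluation bundle
#'
#' Targeting, threshold range/coverage, gap list, ceiling/floor effects and
#' threshold ordering for one calibrated domain.
#'
#' @param result a [fit_jmle()] calibration.
#' @param criteria a [rasch_criteria()].
#' @return list of class `scale_evaluation`.
#' @export
evaluate_scale <- function(result, criteria = rasch_criteria()) {
  structure(list(targeting = targeting(result, criteria),
                 range = threshold_range_coverage(result, criteria),
                 gaps = gaps(result, criteria = criteria),
                 ceiling_floor = ceiling_floor(result, criteria),
                 threshold_order = threshold_order(result),
                 criteria = criteria),
            class = "scale_evaluation")
}

#' @export
print.scale_evaluation <- function(x, ...) {
  cat("<scale_evaluation>\n")
  cat(sprintf("  targeting %.2f (%s)\n", x$targeting$index, x$targeting$band))
  cat(sprintf("  threshold range [%.2f, %.2f]; coverage %.2f%%%s\n",
              x$range$threshold_range[1], x$range$threshold_range[2],
              x$range$coverage,
              if (x$range$good_coverage) "" else " (below target)"))
  cat(sprintf("  floor %.2f%%, ceiling %.2f%%%s\n",
              x$ceiling_floor$floor, x$ceiling_floor$ceiling,
              if (x$ceiling_floor$ceiling_flagged ||
                  x$ceiling_floor$floor_flagged) " (flagged)" else ""))
  fg <- x$gaps[x$gaps$flagged, ]
  cat("  gaps >= ", x$criteria$min_gap, " logit: ", nrow(fg), "\n", sep = "")
  if (nrow(x$threshold_order))
    cat("  disordered-threshold items: ",
        sum(x$threshold_order$disordered), "\n", sep = "")
  invisible(x)
}
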