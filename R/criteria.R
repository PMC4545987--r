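#' Evaluation criteria configuration
#'
#' All decision thresholds used by the diagnostic and reporting layers live
#' here, never hard-coded at the point of use: infit bounds, reliability and
#' separation bands, targeting bands, gap size, coverage target, ceiling/floor
#' limit, the DIF logit-contrast criterion, the residual-correlation screen,
#' and the first-contrast eigenvalue cut.
#'
#' @param infit_low,infit_high mean-square band outside which an item is
#'   classified overfitting (< low) or misfitting (> high).
#' @param reliability_good person/item reliability above which internal
#'   consistency is called good.
#' @param separation_acceptable,separation_excellent separation index bands:
#'   `[acceptable[1], acceptable[2]]` acceptable, `> excellent` excellent.
#' @param targeting_slight,targeting_substantial absolute targeting-index
#'   bounds: below `slight` good, between `slight` and `substantial` slight
#'   mis-targeting, above `substantial` substantial mis-targeting.
#' @param min_gap logit gap between adjacent item difficulties flagged as a
#'   content gap.
#' @param coverage_good minimum percentage of persons inside the threshold
#'   range for good coverage.
#' @param ceiling_floor_limit percentage at or above which a ceiling or floor
#'   effect is flagged.
#' @param dif_criterion absolute logit contrast above which an item shows DIF.
#' @param residual_r_threshold absolute standardized-residual correlation
#'   above which an item pair violates local independence.
#' @param unidim_eigen_cut first-contrast eigenvalue (item units) below which
#'   a scale is called unidimensional.
#' @return list of class `rasch_criteria`.
#' @export
rasch_criteria <- function(infit_low = 0.6, infit_high = 1.4,
                           reliability_good = 0.7,
                           separation_acceptable = c(1.5, 2.0),
                           separation_excellent = 3.0,
                           targeting_slight = 0.5, targeting_substantial = 1.0,
                           min_gap = 1.0, coverage_good = 95,
                           ceiling_floor_limit = 15, dif_criterion = 0.5,
                           residual_r_threshold = 0.3, unidim_eigen_cut = 3.0) {
  structure(list(infit_low = infit_low, infit_high = infit_high,
                 reliability_good = reliability_good,
                 separation_acceptable = separation_acceptable,
                 separation_excellent = separation_excellent,
                 targeting_slight = targeting_slight,
                 targeting_substantial = targeting_substantial,
                 min_gap = min_gap, coverage_good = coverage_good,
                 ceiling_floor_limit = ceiling_floor_limit,
                 dif_criterion = dif_criterion,
                 residual_r_threshold = residual_r_threshold,
                 unidim_eigen_cut = unidim_eigen_cut),
            class = "rasch_criteria")
}

#' Classify a mean-square fit value
#'
#' @param msq infit or outfit mean square(s).
#' @param criteria a [rasch_criteria()].
#' @return character vector in `{"overfit", "fit", "misfit"}` (`NA` in, `NA`
#'   out).
#' @export
classify_fit <- function(msq, criteria = rasch_criteria()) {
  ifelse(is.na(msq), NA_character_,
         ifelse(msq < criteria$infit_low, "overfit",
                ifelse(msq > criteria$infit_high, "misfit", "fit")))
}

#' Classify a targeting index
#'
#' @param index targeting index (mean person measure minus mean item
#'   difficulty, logits).
#' @param criteria a [rasch_criteria()].
#' @return `"good"`, `"slight mis-targeting"`, or
#'   `"substantial mis-targeting"`.
#' @export
classify_targeting <- function(index, criteria = rasch_criteria()) {
  a <- abs(index)
  ifelse(a < criteria$targeting_slight, "good",
         ifelse(a <= criteria$targeting_substantial, "slight mis-targeting",
                "substantial mis-targeting"))
}

#' Classify a separation index
#'
#' @param g separation index.
#' @param criteria a [rasch_criteria()].
#' @return `"excellent"`, `"acceptable"`, or `"poor"`.
#' @export
classify_separation <- function(g, criteria = rasch_criteria()) {
  ifelse(g > criteria$separation_excellent, "excellent",
         ifelse(g >= criteria$separation_acceptable[1] &
                  g <= criteria$separation_acceptable[2], "acceptable",
                ifelse(g > criteria$separation_acceptable[2], "good", "poor")))
}
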