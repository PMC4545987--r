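#' Text Wright (item-person) map
#'
#' Two aligned panels on a shared logit axis: the left panel is a histogram
#' of person measures (one `#` per `persons_per_symbol` persons, extrapolated
#' extremes included), the right panel places item threshold labels on the
#' axis row nearest their location. Polytomous items are labelled
#' `item.<category>` per threshold (a 5-category item renders four labels,
#' `.2` through `.5`); dichotomous items render their plain id, no suffix.
#'
#' @param result a [fit_jmle()] calibration.
#' @param bin_width axis resolution in logits.
#' @param persons_per_symbol how many persons one `#` represents.
#' @return character vector of map lines, class `wright_map` (printed with
#'   `cat`).
#' @export
wright_map <- function(result, bin_width = 0.2, persons_per_symbol = 1) {
  th <- person_measures(result, include_extreme = TRUE)$theta
  th <- th[!is.na(th)]
  loc <- step_locations(result)
  m_of <- stats::setNames(result$items$n_categories, result$items$id)
  loc$label <- ifelse(m_of[loc$item] == 2L, loc$item,
                      paste0(loc$item, ".", loc$step + 1L))

  lo <- floor(min(c(th, loc$location)) / bin_width) * bin_width
  hi <- ceiling(max(c(th, loc$location)) / bin_width) * bin_width
  centers <- seq(hi, lo, by = -bin_width)
  nearest <- function(v) which.min(abs(centers - v))

  p_rows <- vapply(th, nearest, 1L)
  i_rows <- vapply(loc$location, nearest, 1L)

  left <- vapply(seq_along(centers), function(r) {
    k <- sum(p_rows == r)
    paste(rep("#", ceiling(k / persons_per_symbol)), collapse = "")
  }, character(1))
  right <- vapply(seq_along(centers), function(r) {
    paste(sort(loc$label[i_rows == r]), collapse = " ")
  }, character(1))

  width_l <- max(nchar(left), 8L)
  lines <- sprintf("%*s %6.2f | %s", width_l, left, centers, right)
  header <- sprintf("%*s %6s | %s", width_l, "persons", "logit", "items")
  structure(c(header, lines), class = "wright_map")
}

#' @export
print.wright_map <- function(x, ...) {
  cat(unclass(x), sep = "\n")
  invisible(x)
}

#' Pipeline configuration
#'
#' @param control a [rasch_control()] for all calibrations.
#' @param criteria a [rasch_criteria()] supplying every decision threshold.
#' @param dif_groupings DIF split rules to run (subset of
#'   `c("age_75", "stage")`); empty vector disables DIF.
#' @param bin_width Wright-map resolution (logits).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(control = rasch_control(),
                            criteria = rasch_criteria(),
                            dif_groupings = c("age_75", "stage"),
                            bin_width = 0.2) {
  structure(list(control = control, criteria = criteria,
                 dif_groupings = dif_groupings, bin_width = bin_width),
            class = "pipeline_config")
}

#' Run the full evaluation pipeline
#'
#' Per domain (>= 2 calibratable items; smaller domains are skipped with a
#' warning): calibrate by JMLE, compute residual diagnostics, scale
#' evaluation, a Wright map, and (when covariates are present) DIF tables for
#' each configured grouping. Psychometric "failures" (misfit, DIF, low
#' coverage) are findings, not errors.
#'
#' @param responses a [response_matrix()] or path to a response CSV.
#' @param spec an [instrument_spec()] or path to an instrument YAML file.
#' @param config a [pipeline_config()].
#' @return list of class `analysis_report`: one entry per analyzed domain
#'   (`calibration`, `table`, `diagnostics`, `evaluation`, `wright`, `dif`)
#'   plus `domain_scores` and the `config`.
#' @export
run_pipeline <- function(responses, spec, config = pipeline_config()) {
  if (is.character(spec)) spec <- read_instrument(spec)
  if (is.character(responses)) responses <- read_responses(responses, spec)
  report <- list(domains = list(),
                 domain_scores = domain_scores(responses, spec),
                 config = config)
  for (d in names(spec$domains)) {
    dspec <- tryCatch(subset_spec(spec, d), error = function(e) NULL)
    if (is.null(dspec) || nrow(dspec$items) < 2L) {
      warning("domain '", d, "' has fewer than 2 calibratable items; skipped")
      next
    }
    fit <- fit_jmle(responses, dspec, config$control)
    entry <- list(
      calibration = fit,
      table = calibration_table(fit),
      diagnostics = diagnose(fit, config$criteria),
      evaluation = evaluate_scale(fit, config$criteria),
      wright = wright_map(fit, bin_width = config$bin_width),
      dif = list())
    if (!is.null(responses$covariates)) {
      for (g in config$dif_groupings) {
        entry$dif[[g]] <- tryCatch({
          grp <- split_groups(responses, g)
          dif_contrast(responses, dspec, grp,
                       criterion = config$criteria$dif_criterion,
                       control = config$control, pooled = fit)
        }, error = function(e) {
          warning("DIF grouping '", g, "' skipped for domain '", d, "': ",
                  conditionMessage(e))
          NULL
        })
      }
    }
    report$domains[[d]] <- entry
  }
  structure(report, class = "analysis_report")
}

# fixed-format number: 2 decimals, "NA" for missing
fmt2 <- function(x) ifelse(is.na(x), "NA", sprintf("%.2f", x))

#' Render an analysis report as text lines
#'
#' Deterministic formatting (fixed ordering, 2-decimal logits and mean
#' squares, 2-decimal percentages): the same report always renders to the
#' same bytes. Every criterion value shown is taken from the report's
#' configuration.
#'
#' @param report an [run_pipeline()] result.
#' @return character vector of lines.
#' @export
format_report <- function(report) {
  cr <- report$config$criteria
  out <- character(0)
  push <- function(...) out <<- c(out, paste0(...))
  push("== Rasch evaluation report ==")
  push("criteria: infit [", fmt2(cr$infit_low), ", ", fmt2(cr$infit_high),
       "]; reliability > ", fmt2(cr$reliability_good),
       "; separation acceptable [", fmt2(cr$separation_acceptable[1]), ", ",
       fmt2(cr$separation_acceptable[2]), "], excellent > ",
       fmt2(cr$separation_excellent),
       "; targeting bands ", fmt2(cr$targeting_slight), "/",
       fmt2(cr$targeting_substantial),
       "; gap >= ", fmt2(cr$min_gap), " logit; coverage >= ",
       fmt2(cr$coverage_good), "%; ceiling/floor < ",
       fmt2(cr$ceiling_floor_limit), "%; DIF contrast > ",
       fmt2(cr$dif_criterion), " logits")
  for (d in names(report$domains)) {
    e <- report$domains[[d]]
    push("")
    push("-- Domain: ", d, " --")
    dg <- e$diagnostics
    push(sprintf("person reliability %s (separation %s, %s)",
                 fmt2(dg$person$reliability), fmt2(dg$person$separation),
                 dg$person$band))
    if (!is.na(dg$kr20)) push("KR-20 (dichotomous items): ", fmt2(dg$kr20))
    if (!is.null(dg$pca))
      push("first-contrast eigenvalue: ", fmt2(dg$pca$first_contrast),
           if (dg$pca$unidimensional) " (unidimensional)" else " (check)")
    push("locally dependent pairs (|r| > ", fmt2(cr$residual_r_threshold),
         "): ", nrow(dg$dependent_pairs))
    push("")
    push("item table (by difficulty):")
    push(sprintf("  %-8s %10s %6s %6s %s", "item", "difficulty", "SE",
                 "infit", "fit"))
    tab <- e$table
    for (i in seq_len(nrow(tab)))
      push(sprintf("  %-8s %10s %6s %6s %s", tab$item[i],
                   fmt2(tab$difficulty[i]), fmt2(tab$se[i]),
                   fmt2(tab$infit[i]),
                   classify_fit(tab$infit[i], cr)))
    ev <- e$evaluation
    push("")
    push(sprintf("targeting: %s (%s)", fmt2(ev$targeting$index),
                 ev$targeting$band))
    push(sprintf("threshold range: [%s, %s]",
                 fmt2(ev$range$threshold_range[1]),
                 fmt2(ev$range$threshold_range[2])))
    push(sprintf("person range: [%s, %s]; 95%% limits [%s, %s]",
                 fmt2(ev$range$person_range[1]),
                 fmt2(ev$range$person_range[2]),
                 fmt2(ev$range$person_limits[1]),
                 fmt2(ev$range$person_limits[2])))
    push(sprintf("coverage: %s%%; floor %s%%; ceiling %s%%",
                 fmt2(ev$range$coverage), fmt2(ev$ceiling_floor$floor),
                 fmt2(ev$ceiling_floor$ceiling)))
    fg <- ev$gaps[ev$gaps$flagged, ]
    push("flagged gaps: ",
         if (nrow(fg)) paste(sprintf("%s-%s (%s)", fg$item_low, fg$item_high,
                                     fmt2(fg$gap)), collapse = ", ")
         else "none")
    if (nrow(ev$threshold_order)) {
      dis <- ev$threshold_order$item[ev$threshold_order$disordered]
      push("disordered thresholds: ",
           if (length(dis)) paste(dis, collapse = ", ") else "none")
    }
    for (g in names(e$dif)) {
      t <- e$dif[[g]]
      if (is.null(t)) next
      push("")
      push("DIF (", attr(t, "grouping"), "; |contrast| > ",
           fmt2(attr(t, "criterion")), "):")
      s <- dif_summary(t)
      for (i in seq_len(nrow(s)))
        push("  ", s$domain[i], ": ", s$label[i], " of testable items flagged")
      fl <- t[which(t$flagged), ]
      push("  flagged: ",
           if (nrow(fl)) paste(sprintf("%s (%s)", fl$item, fmt2(fl$contrast)),
                               collapse = ", ") else "none")
    }
    push("")
    push("Wright map:")
    out <- c(out, unclass(e$wright))
  }
  out
}

#' Write an analysis report to disk
#'
#' Produces `report.txt` (see [format_report()]) plus per-domain calibration
#' CSVs and per-grouping DIF CSVs. Regeneration from the same inputs is
#' byte-identical.
#'
#' @param report an [run_pipeline()] result.
#' @param dir output directory (created if needed).
#' @return invisible character vector of files written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- file.path(dir, "report.txt")
  writeLines(format_report(report), files[1])
  for (d in names(report$domains)) {
    e <- report$domains[[d]]
    f <- file.path(dir, paste0("calibration_", d, ".csv"))
    tab <- e$table
    tab$difficulty <- sprintf("%.4f", tab$difficulty)
    tab$se <- sprintf("%.4f", tab$se)
    tab$infit <- fmt2(tab$infit); tab$outfit <- fmt2(tab$outfit)
    utils::write.csv(tab, f, row.names = FALSE)
    files <- c(files, f)
    for (g in names(e$dif)) {
      t <- e$dif[[g]]
      if (is.null(t)) next
      f <- file.path(dir, paste0("dif_", d, "_", g, ".csv"))
      td <- as.data.frame(t)
      for (col in c("delta_a", "se_a", "delta_b", "se_b", "contrast"))
        td[[col]] <- ifelse(is.na(td[[col]]), "",
                            sprintf("%.4f", td[[col]]))
      utils::write.csv(td, f, row.names = FALSE)
      files <- c(files, f)
    }
  }
  invisible(files)
}
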