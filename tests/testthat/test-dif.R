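test_that("group splitting follows the built-in rules", {
  spec <- dich_spec(3)
  X <- matrix(rbinom(12, 1, 0.5), 4, 3, dimnames = list(NULL, spec$items$id))
  rm <- response_matrix(X, spec,
                        covariates = data.frame(
                          age_years = c(70, 74, 75, 80),
                          stage = c("I", "II", "III", "IV")))
  by_age <- split_groups(rm, "age_75")
  expect_equal(nrow(by_age$A$responses), 2L)
  expect_equal(nrow(by_age$B$responses), 2L)
  by_stage <- split_groups(rm, "stage")
  expect_equal(nrow(by_stage$A$responses), 2L)  # stages I, II
  expect_equal(nrow(by_stage$B$responses), 2L)  # stages III, IV
  # everyone in one group is an error
  rm_young <- response_matrix(X, spec,
                              covariates = data.frame(age_years = 60:63,
                                                      stage = rep("II", 4)))
  expect_error(split_groups(rm_young, "age_75"), "empty")
  # missing covariate excludes the person with a warning
  rm_na <- response_matrix(X, spec,
                           covariates = data.frame(
                             age_years = c(70, NA, 75, 80),
                             stage = c("I", "II", "III", "IV")))
  expect_warning(g <- split_groups(rm_na, "age_75"), "missing covariate")
  expect_equal(nrow(g$A$responses) + nrow(g$B$responses), 3L)
})

test_that("identical groups yield zero contrasts and no flags", {
  spec <- dich_spec(6)
  cfg <- sim_config(spec = spec, n = 80, covariates = FALSE,
                    delta = spaced_delta(spec, -1.5, 1.5))
  g <- generate_responses(cfg, seed = 31)
  rm <- g$matrix
  grp <- list(A = rm, B = rm, labels = c(A = "copy A", B = "copy B"),
              rule = "copies")
  dt <- dif_contrast(rm, spec, grp)
  expect_true(all(abs(dt$contrast) < 1e-6))
  expect_false(any(dt$flagged))
})

test_that("swapping groups negates contrasts and preserves flags", {
  spec <- dich_spec(8)
  cfg <- sim_config(spec = spec, n = 200, covariates = TRUE,
                    delta = spaced_delta(spec, -2, 2), stage34_effect = 0)
  g <- generate_responses(cfg, seed = 32)
  pooled <- fit_jmle(g$matrix, spec)
  grp <- split_groups(g$matrix, "stage")
  swapped <- list(A = grp$B, B = grp$A,
                  labels = grp$labels[c(2, 1)], rule = grp$rule)
  d1 <- dif_contrast(g$matrix, spec, grp, pooled = pooled)
  d2 <- dif_contrast(g$matrix, spec, swapped, pooled = pooled)
  expect_equal(d2$contrast, -d1$contrast, tolerance = 1e-6)
  expect_equal(d2$flagged, d1$flagged)
})

test_that("anchoring absorbs a constant shift in person measures", {
  spec <- dich_spec(5)
  cfg <- sim_config(spec = spec, n = 100, covariates = FALSE,
                    delta = spaced_delta(spec, -1, 1))
  g <- generate_responses(cfg, seed = 33)
  X <- g$matrix$responses
  th <- g$truth$theta
  tl <- stats::setNames(lapply(1:5, function(i) 0), spec$items$id)
  mc <- stats::setNames(as.list(rep(1L, 5)), spec$items$id)
  a <- raschpro:::anchored_item_estimates(X, th, tl, mc)
  b <- raschpro:::anchored_item_estimates(X, th + 2.4, tl, mc)
  expect_equal(b$delta - a$delta, stats::setNames(rep(2.4, 5), spec$items$id),
               tolerance = 1e-5)
})

test_that("an injected difficulty shift is detected in one replicate", {
  spec <- dich_spec(12)
  cfg <- sim_config(spec = spec, n = 300, covariates = TRUE,
                    delta = spaced_delta(spec, -1.5, 1.5), stage34_effect = 0)
  cfg <- inject_dif(cfg, "it06", where = "age_ge75", shift = 1.2)
  g <- generate_responses(cfg, seed = 34)
  dt <- dif_contrast(g$matrix, spec, split_groups(g$matrix, "age_75"))
  row <- dt[dt$item == "it06", ]
  expect_true(row$flagged)
  # group A (young) finds the item easier: contrast negative
  expect_lt(row$contrast, -0.5)
})

test_that("DIF summary formats counts like published reports", {
  mk <- function(domain, flags) {
    structure(data.frame(item = paste0(domain, seq_along(flags)),
                         domain = domain, delta_a = 0, se_a = 0.1,
                         delta_b = 0, se_b = 0.1, contrast = 0,
                         flagged = flags),
              class = c("dif_table", "data.frame"),
              criterion = 0.5, grouping = "x",
              labels = c(A = "a", B = "b"))
  }
  s <- dif_summary(mk("Ac", c(rep(TRUE, 4), rep(FALSE, 3))))
  expect_equal(s$label, "4 (57 %)")
  expect_equal(dif_summary(mk("Sy", rep(FALSE, 6)))$label, "0 (0 %)")
  expect_equal(dif_summary(mk("Im", c(rep(TRUE, 13), rep(FALSE, 13))))$label,
               "13 (50 %)")
})

test_that("separate-calibration method agrees with anchoring on null data", {
  spec <- dich_spec(8)
  cfg <- sim_config(spec = spec, n = 400, covariates = TRUE,
                    delta = spaced_delta(spec, -1.5, 1.5), stage34_effect = 0)
  g <- generate_responses(cfg, seed = 35)
  grp <- split_groups(g$matrix, "age_75")
  d_anchor <- dif_contrast(g$matrix, spec, grp, method = "anchored")
  d_sep <- dif_contrast(g$matrix, spec, grp, method = "separate")
  expect_equal(d_anchor$contrast, d_sep$contrast, tolerance = 0.35)
})
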