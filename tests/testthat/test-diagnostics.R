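test_that("standardized residuals follow their definition", {
  # two persons at theta 0, two dichotomous items at delta 0: E = 0.5,
  # Var = 0.25, so z = (x - 0.5) / 0.5 = +/- 1
  X <- rbind(c(1L, 0L), c(0L, 1L))
  colnames(X) <- c("a", "b")
  res <- mock_result(theta = c(0, 0), delta = c(a = 0, b = 0), X = X)
  z <- standardized_residuals(res)
  expect_equal(unname(z), rbind(c(1, -1), c(-1, 1)))
})

test_that("residuals on model-true data are centered with unit spread", {
  spec <- dich_spec(10)
  cfg <- sim_config(spec = spec, n = 500, covariates = FALSE,
                    delta = spaced_delta(spec, -2, 2))
  # average the per-item moments over seeds: a single 500-person draw can
  # put one item's sample variance a little outside the band by chance
  moments <- lapply(8:10, function(s) {
    fit <- fit_jmle(generate_responses(cfg, seed = s)$matrix, spec)
    z <- standardized_residuals(fit)
    list(m = colMeans(z, na.rm = TRUE),
         v = apply(z, 2, stats::var, na.rm = TRUE))
  })
  mean_z <- rowMeans(vapply(moments, `[[`, numeric(10), "m"))
  var_z <- rowMeans(vapply(moments, `[[`, numeric(10), "v"))
  expect_true(all(abs(mean_z) < 0.15))
  expect_true(all(abs(var_z - 1) < 0.15))
})

test_that("mean-square classification uses the configured band", {
  cr <- rasch_criteria()
  expect_equal(classify_fit(1.46, cr), "misfit")
  expect_equal(classify_fit(1.00, cr), "fit")
  expect_equal(classify_fit(0.55, cr), "overfit")
  expect_equal(classify_fit(c(1.42, 0.69), rasch_criteria(infit_high = 1.5)),
               c("fit", "fit"))
})

test_that("outfit equals infit when all cell variances are equal", {
  # all persons and items at 0: every dichotomous cell has variance 0.25
  X <- matrix(c(1L, 0L, 0L, 1L, 1L, 1L, 0L, 0L), 4, 2,
              dimnames = list(NULL, c("a", "b")))
  res <- mock_result(theta = rep(0, 4), delta = c(a = 0, b = 0), X = X)
  f <- infit_outfit(res)
  expect_equal(f$items$infit, f$items$outfit)
  expect_equal(f$persons$infit, f$persons$outfit)
})

test_that("reliability and separation follow the closed form", {
  expect_equal(separation_from_reliability(0.8), 2.0)
  expect_equal(separation_from_reliability(0.5), 1.0)
  set.seed(2)
  m <- rnorm(50, 0, 2); s <- runif(50, 0.3, 0.5)
  sr <- separation_reliability(m, s)
  expect_equal(sr$separation,
               separation_from_reliability(sr$reliability))
  # invariant to adding a constant to all measures
  sr2 <- separation_reliability(m + 3.7, s)
  expect_equal(sr2$reliability, sr$reliability)
  expect_equal(sr2$separation, sr$separation)
  # degenerate: no observed variance
  d <- separation_reliability(rep(1, 5), rep(0.2, 5))
  expect_true(d$degenerate)
  expect_equal(c(d$reliability, d$separation), c(0, 0))
})

test_that("residual PCA flags rank structure and drops constant items", {
  set.seed(6)
  z <- matrix(rnorm(200 * 5), 200, 5,
              dimnames = list(NULL, paste0("i", 1:5)))
  z[, 2] <- z[, 1]  # perfectly correlated residual pair
  ev <- pca_residuals(z)
  expect_gte(ev$first_contrast, 2)
  expect_equal(sum(ev$eigenvalues), 5, tolerance = 1e-8)
  expect_true(all(diff(ev$eigenvalues) <= 1e-12))

  z[, 3] <- 0
  expect_warning(ev2 <- pca_residuals(z), "constant")
  expect_equal(ev2$dropped, "i3")
  expect_error(pca_residuals(z[, 1:2]), "at least 3")
})

test_that("local independence screening flags duplicated items", {
  spec <- dich_spec(6)
  set.seed(14)
  X <- matrix(rbinom(6 * 80, 1, 0.5), 80, 6,
              dimnames = list(NULL, spec$items$id))
  X[, 2] <- X[, 1]
  fit <- fit_jmle(response_matrix(X, spec), spec)
  z <- standardized_residuals(fit)
  flagged <- local_independence(z, threshold = 0.3)
  pair <- flagged[flagged$item_a == "it01" & flagged$item_b == "it02", ]
  expect_equal(nrow(pair), 1L)
  expect_gt(pair$r, 0.3)
  expect_equal(nrow(local_independence(z, threshold = 1.0)), 0L)
})

test_that("KR-20 has the right limits and equals generic alpha", {
  X <- matrix(rep(c(1L, 0L, 1L, 1L, 0L), 4), 5, 4)  # identical columns
  expect_equal(kr20(X), 1.0)
  expect_error(kr20(X[, 1, drop = FALSE]), "at least 2")
  expect_error(kr20(matrix(1L, 5, 3)), "variance")

  set.seed(15)
  Y <- matrix(rbinom(300 * 8, 1, runif(8, 0.2, 0.8)), 300, 8, byrow = TRUE)
  # generic Cronbach alpha on the same 0/1 data (population variances)
  popvar <- function(v) mean((v - mean(v))^2)
  k <- ncol(Y)
  alpha <- (k / (k - 1)) * (1 - sum(apply(Y, 2, popvar)) / popvar(rowSums(Y)))
  expect_equal(kr20(Y), alpha)

  # independent fair coins carry no internal consistency
  set.seed(16)
  Z <- matrix(rbinom(1000 * 6, 1, 0.5), 1000, 6)
  expect_lt(abs(kr20(Z)), 0.1)
})

test_that("diagnose bundles domain diagnostics", {
  spec <- dich_spec(8)
  cfg <- sim_config(spec = spec, n = 150, covariates = FALSE,
                    delta = spaced_delta(spec, -2, 2))
  g <- generate_responses(cfg, seed = 19)
  fit <- fit_jmle(g$matrix, spec)
  d <- diagnose(fit)
  expect_s3_class(d, "diagnostics_report")
  expect_true(d$person$reliability >= 0 && d$person$reliability < 1)
  expect_equal(nrow(d$fit$items), length(fit$delta))
  expect_false(is.na(d$kr20))
  expect_true(is.numeric(d$pca$first_contrast))
})
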