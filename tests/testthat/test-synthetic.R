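test_that("generation is deterministic in seed and config", {
  cfg <- sim_config(n = 60)
  g1 <- generate_responses(cfg, seed = 5)
  g2 <- generate_responses(cfg, seed = 5)
  expect_identical(g1$matrix$responses, g2$matrix$responses)
  expect_identical(g1$truth$theta, g2$truth$theta)
  g3 <- generate_responses(cfg, seed = 6)
  expect_false(identical(g1$matrix$responses, g3$matrix$responses))
})

test_that("observed proportions match model probabilities", {
  # dichotomous item at the persons' (near-degenerate) ability: half max
  spec <- dich_spec(2)
  cfg <- sim_config(spec = spec, n = 1000, covariates = FALSE,
                    theta_mean = 0, theta_sd = 1e-6,
                    delta = c(it01 = 0, it02 = 1))
  g <- generate_responses(cfg, seed = 41)
  expect_lt(abs(mean(g$matrix$responses[, "it01"]) - 0.5), 0.03)

  # category frequencies converge to the model distribution (chi-square GOF)
  spec5 <- instrument_spec(item_spec("q", "D", 5, "g5") |> rbind(
    item_spec("q2", "D", 5, "g5")))
  rejections <- 0L
  for (s in 1:10) {
    cfg5 <- sim_config(spec = spec5, n = 2000, covariates = FALSE,
                       delta = c(q = 0.3, q2 = -0.3),
                       tau = list(g5 = c(-1.5, -0.5, 0.5, 1.5)))
    g5 <- generate_responses(cfg5, seed = 200 + s)
    P <- category_probabilities(g5$truth$theta, 0.3,
                                c(-1.5, -0.5, 0.5, 1.5))
    expected <- colSums(P)
    observed <- tabulate(g5$matrix$responses[, "q"] + 1L, 5L)
    x2 <- sum((observed - expected)^2 / expected)
    rejections <- rejections + (stats::pchisq(x2, df = 4,
                                              lower.tail = FALSE) < 0.05)
  }
  expect_lte(rejections, 1L)
})

test_that("DIF injection lowers endorsement for the shifted group", {
  spec <- dich_spec(2)
  cfg <- sim_config(spec = spec, n = 2000, covariates = TRUE,
                    theta_sd = 1e-6, delta = c(it01 = 0, it02 = 0),
                    stage34_effect = 0, age75_effect = 0)
  cfg <- inject_dif(cfg, "it01", where = "age_ge75", shift = 1.0)
  g <- generate_responses(cfg, seed = 43)
  old <- g$truth$covariates$age_years >= 75
  p_old <- mean(g$matrix$responses[old, "it01"])
  p_young <- mean(g$matrix$responses[!old, "it01"])
  # matched ability, item one logit harder: 0.27 vs 0.50 endorsement
  expect_lt(p_old, p_young - 0.1)
  expect_equal(g$truth$dif[[1]]$shift, 1.0)
})

test_that("second-dimension injection validates its inputs", {
  cfg <- sim_config(n = 50)
  expect_error(inject_second_dimension(cfg, character(0)), "non-empty")
  expect_error(inject_second_dimension(cfg, "S_a1", correlation = 1),
               "correlation")
  expect_error(inject_second_dimension(cfg, cfg$spec$items$id), "all items")
  cfg2 <- inject_second_dimension(cfg, c("S_a1", "S_a2"), 0.3)
  g <- generate_responses(cfg2, seed = 44)
  expect_equal(unname(g$truth$dimension[c("S_a1", "S_a2", "S_a3")]),
               c(2L, 2L, 1L))
  expect_length(g$truth$theta2, 50L)
})

test_that("covariates follow the configured population", {
  g <- generate_responses(sim_config(n = 2000), seed = 45)
  cov <- g$truth$covariates
  expect_true(all(cov$age_years >= 46 & cov$age_years <= 88))
  expect_lt(abs(mean(cov$age_years) - 70.4), 1)
  expect_lt(abs(mean(cov$stage %in% c("III", "IV")) - 0.4791), 0.05)
  # severe-stage persons sit higher on the trait by construction
  expect_gt(mean(g$truth$theta[cov$stage %in% c("III", "IV")]),
            mean(g$truth$theta[!cov$stage %in% c("III", "IV")]))
})

test_that("truth records round-trip through structured text", {
  cfg <- inject_dif(sim_config(n = 25), "A_c3", "stage34", 0.7)
  g <- generate_responses(cfg, seed = 46)
  f <- withr::local_tempfile(fileext = ".json")
  write_truth(g$truth, f)
  back <- read_truth(f)
  expect_identical(back$theta, g$truth$theta)
  expect_identical(back$delta, g$truth$delta)
  expect_equal(back$tau, g$truth$tau)
  expect_identical(back$dimension, g$truth$dimension)
  expect_equal(back$covariates$age_years, g$truth$covariates$age_years)
  expect_equal(back$dif[[1]]$item, "A_c3")
  expect_identical(back$seed, g$truth$seed)
})

test_that("full loop: generated data recover the generating difficulties", {
  spec <- dich_spec(20)
  cfg <- sim_config(spec = spec, n = 300, covariates = FALSE,
                    delta = spaced_delta(spec, -3, 3))
  g <- generate_responses(cfg, seed = 47)
  fit <- fit_jmle(g$matrix, spec)
  tr <- g$truth$delta[names(fit$delta)]
  expect_gt(cor(fit$delta, tr), 0.98)
})
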