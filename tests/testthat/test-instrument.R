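test_that("instrument invariants are enforced", {
  expect_error(instrument_spec(rbind(item_spec("a", "D", 2),
                                     item_spec("a", "D", 2))),
               "duplicate")
  expect_error(instrument_spec(rbind(item_spec("a", "D", 3, "g"),
                                     item_spec("b", "D", 4, "g"))),
               "mixes category counts")
  expect_error(item_spec("a", "D", 1), "n_categories")
  expect_error(instrument_spec(item_spec("a", "D", 6)), "max_categories")
})

test_that("response CSV parses, bound-checks, and recodes reversals", {
  spec <- instrument_spec(rbind(item_spec("a", "D", 2),
                                item_spec("b", "D", 2),
                                item_spec("r", "D", 5, reversed = TRUE)))
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("person,a,b,r", "p1,0,1,4", "p2,1,1,0", "p3,1,0,2"), f)
  rm <- read_responses(f, spec)
  expect_equal(dim(rm), c(3L, 3L))
  expect_equal(sum(is.na(rm$responses)), 0L)
  # reversed 5-category item: source 4 stored as 0, source 0 as 4
  expect_equal(unname(rm$responses[, "r"]), c(0L, 4L, 2L))

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("person,a,b,r", "p1,0,4,1"), bad)
  expect_error(read_responses(bad, spec), "item 'b', person 'p1'.*4")
  unk <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("person,a,zz", "p1,0,1"), unk)
  expect_error(read_responses(unk, spec), "unknown item")
})

test_that("write/read round trip preserves cells, missing mask, covariates", {
  spec <- instrument_spec(rbind(item_spec("a", "D", 2),
                                item_spec("r", "D", 4, reversed = TRUE)))
  X <- rbind(c(1L, 3L), c(0L, NA), c(1L, 0L))
  colnames(X) <- c("a", "r"); rownames(X) <- paste0("p", 1:3)
  rm <- response_matrix(X, spec,
                        covariates = data.frame(age_years = c(70, 80, 65),
                                                stage = c("II", "III", "IV")),
                        reversal_applied = "r")
  f <- withr::local_tempfile(fileext = ".csv")
  write_responses(rm, spec, f)
  back <- read_responses(f, spec)
  expect_identical(back$responses, rm$responses)
  expect_equal(back$covariates$age_years, c(70, 80, 65))
  expect_equal(back$covariates$stage, c("II", "III", "IV"))
})

test_that("domain scores hit bounds, handle missing, and are monotone", {
  spec <- instrument_spec(rbind(item_spec("a", "D1", 2), item_spec("b", "D1", 2),
                                item_spec("c", "D2", 5), item_spec("d", "D2", 5)))
  X <- rbind(c(1L, 1L, 4L, 4L),      # everything at maximum
             c(0L, 0L, 0L, 0L),      # everything at zero
             c(1L, 0L, 2L, NA),      # partial
             c(NA, NA, 1L, 1L))      # D1 all missing
  colnames(X) <- spec$items$id
  s <- domain_scores(response_matrix(X, spec), spec)
  expect_equal(s$D1, c(100, 0, 50, NA))
  expect_equal(s$D2[1:2], c(100, 0))
  expect_equal(s$D2[3], 100 * 2 / 4)  # only observed items in the denominator

  # column-order invariance
  s2 <- domain_scores(response_matrix(X[, c(3, 1, 4, 2)], spec), spec)
  expect_equal(s2, s)

  # monotone non-decreasing in every single response value
  set.seed(11)
  for (rep in 1:20) {
    Y <- matrix(sample(0:1, 8, TRUE), 2, 4,
                dimnames = list(NULL, spec$items$id))
    Y[, 3:4] <- sample(0:4, 4, TRUE)
    base <- domain_scores(response_matrix(Y, spec), spec)
    i <- sample(2, 1); j <- sample(4, 1)
    if (Y[i, j] < spec$items$n_categories[j] - 1L) {
      Y2 <- Y; Y2[i, j] <- Y2[i, j] + 1L
      bumped <- domain_scores(response_matrix(Y2, spec), spec)
      expect_true(all(as.matrix(bumped) >= as.matrix(base), na.rm = TRUE))
    }
  }
})

test_that("category recoding collapses, validates, and re-derives groups", {
  spec <- instrument_spec(rbind(item_spec("a", "D", 5, "g"),
                                item_spec("b", "D", 5, "g")))
  X <- rbind(c(0L, 4L), c(2L, 1L), c(3L, 3L), c(4L, 2L))
  colnames(X) <- c("a", "b")
  rm <- response_matrix(X, spec)

  # the published Symptom collapse: merge categories 1 and 2 -> 4 options
  out <- recode_categories(rm, spec, list(a = c(0, 1, 1, 2, 3)))
  expect_equal(out$spec$items["a", "n_categories"], 4L)
  expect_equal(unname(out$matrix$responses[, "a"]), c(0L, 1L, 2L, 3L))
  # group split so 'b' (still 5 categories) no longer shares with 'a'
  expect_false(out$spec$items["a", "scale_group"] ==
                 out$spec$items["b", "scale_group"])

  # identity mapping changes nothing
  idm <- recode_categories(rm, spec, list(a = 0:4))
  expect_identical(idm$matrix$responses, rm$responses)
  expect_equal(idm$spec$items$n_categories, spec$items$n_categories)

  expect_error(recode_categories(rm, spec, list(a = c(0, 2, 2, 3, 4))),
               "contiguous")
  expect_error(recode_categories(rm, spec, list(a = c(1, 0, 1, 2, 3))),
               "order")

  # recoding never increases the number of distinct observed categories
  n_distinct <- function(m) length(unique(m$responses[, "a"]))
  expect_lte(n_distinct(out$matrix), n_distinct(rm))
})

test_that("instrument YAML round-trips", {
  spec <- sgrq_like_spec(include_excluded = TRUE)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_instrument(spec, f)
  back <- read_instrument(f)
  expect_equal(back$items[spec$items$id, ], spec$items[spec$items$id, ])
})

test_that("SGRQ-like instrument matches the analyzed structure", {
  spec <- sgrq_like_spec()
  expect_equal(nrow(spec$items), 48L)
  expect_equal(lengths(spec$domains)[c("Symptom", "Activity", "Impact")],
               c(Symptom = 6L, Activity = 16L, Impact = 26L))
  act <- spec$items[spec$domains$Activity, ]
  expect_true(all(act$n_categories == 2L))
  imp <- spec$items[spec$domains$Impact, ]
  expect_equal(sum(imp$n_categories > 2L), 3L)
  # group invariant holds by construction
  for (g in unique(spec$items$scale_group))
    expect_length(unique(spec$items$n_categories[spec$items$scale_group == g]),
                  1L)
  with_excl <- sgrq_like_spec(include_excluded = TRUE)
  expect_equal(nrow(with_excl$items), 50L)
  expect_equal(sum(with_excl$items$excluded), 2L)
})
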