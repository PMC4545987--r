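#' SGRQ-like instrument structure
#'
#' Instrument specification mirroring the analyzed structure of the
#' St. George's Respiratory Questionnaire: a Symptom domain of 6 polytomous
#' items (four 5-category items sharing one option set, one 5-category and
#' one 4-category item with their own sets), an Activity domain of 16
#' dichotomous items, and an Impact domain of 26 items of which 3 are
#' polytomous (4-category) and 23 dichotomous. Which Symptom items carry 4
#' versus 5 options is illustrative — the source instrument's option sets
#' vary from 2- to 5-point and the exact pre-revision assignment is not
#' published. Items `S_a5` and `I_i` are reverse-worded.
#'
#' @param include_excluded also carry the two Symptom items conventionally
#'   excluded from Rasch calibration (`S_a6`, `S_a8`) with their `excluded`
#'   flag set; they then take part in classical domain scoring only.
#' @return an [instrument_spec()] (48 analyzed items).
#' @export
sgrq_like_spec <- function(include_excluded = FALSE) {
  sym <- rbind(
    item_spec("S_a1", "Symptom", 5, "sym_freq5"),
    item_spec("S_a2", "Symptom", 5, "sym_freq5"),
    item_spec("S_a3", "Symptom", 5, "sym_freq5"),
    item_spec("S_a4", "Symptom", 5, "sym_freq5"),
    item_spec("S_a5", "Symptom", 5, "sym_attack5", reversed = TRUE),
    item_spec("S_a7", "Symptom", 4, "sym_days4"))
  if (include_excluded)
    sym <- rbind(sym,
                 item_spec("S_a6", "Symptom", 4, "sym_dur4", excluded = TRUE),
                 item_spec("S_a8", "Symptom", 2, "sym_bin", excluded = TRUE))
  act <- do.call(rbind, lapply(
    c(paste0("A_c", 1:7), paste0("A_g", 1:9)),
    function(id) item_spec(id, "Activity", 2, "act_bin")))
  imp_poly <- rbind(item_spec("I_b1", "Impact", 4, "imp_b4"),
                    item_spec("I_b2", "Impact", 4, "imp_b4"),
                    item_spec("I_i", "Impact", 4, "imp_i4", reversed = TRUE))
  imp_dich <- do.call(rbind, lapply(
    c("I_h5", "I_f2", "I_f1", "I_e5", "I_d3", "I_d4", "I_h3", "I_f3",
      "I_f4", "I_h4", "I_d1", "I_e2", "I_e3", "I_e4", "I_h2", "I_e1",
      "I_d2", "I_d5", "I_h1", "I_d6", "I_e6", "I_e8", "I_e7"),
    function(id) item_spec(id, "Impact", 2, "imp_bin")))
  instrument_spec(rbind(sym, act, imp_poly, imp_dich))
}

#' Published item-difficulty layout for the SGRQ-like generator
#'
#' Named vector of per-item difficulties (logits) matching the calibrated
#' values reported for a 240-patient COPD sample, used as the generator's
#' default difficulty layout so that simulated data reproduce a realistic
#' spread (Activity spanning roughly -6.4 to 4.5 logits, the other domains
#' much narrower).
#'
#' @return named numeric vector over the 48 analyzed items.
#' @export
sgrq_reference_difficulties <- function() {
  c(S_a5 = -1.09, S_a4 = -0.18, S_a3 = 0.09, S_a7 = 0.23, S_a1 = 0.47,
    S_a2 = 0.47,
    A_c1 = -6.42, A_c2 = -3.53, A_g1 = -3.14, A_g2 = -2.84, A_c3 = -2.56,
    A_c4 = -1.39, A_g3 = -0.67, A_g4 = 0.04, A_c5 = 0.38, A_g5 = 0.61,
    A_c7 = 2.54, A_g7 = 2.71, A_c6 = 2.77, A_g6 = 2.96, A_g8 = 4.07,
    A_g9 = 4.46,
    I_h5 = -1.87, I_f2 = -1.30, I_f1 = -1.30, I_e5 = -0.91, I_d3 = -0.72,
    I_d4 = -0.62, I_h3 = -0.54, I_f3 = -0.54, I_f4 = -0.51, I_h4 = -0.50,
    I_d1 = -0.45, I_e2 = -0.35, I_b2 = -0.20, I_e3 = -0.17, I_i = -0.13,
    I_e4 = -0.11, I_h2 = 0.15, I_e1 = 0.24, I_d2 = 0.88, I_d5 = 0.93,
    I_h1 = 1.11, I_b1 = 1.15, I_d6 = 1.19, I_e6 = 1.21, I_e8 = 1.62,
    I_e7 = 1.75)
}

# default ordered thresholds by category count
default_tau <- function(m) {
  switch(as.character(m),
         "2" = 0,
         "3" = c(-1, 1),
         "4" = c(-1, 0, 1),
         "5" = c(-1.5, -0.5, 0.5, 1.5),
         stop("no default thresholds for ", m, " categories"))
}

#' Configure a synthetic-response simulation
#'
#' Holds everything [generate_responses()] needs: the instrument, sample
#' size, the latent-trait distribution, item difficulty and threshold
#' layouts, covariate generation (age and disease stage, jointly linked to
#' the trait through additive shifts so severity-related DIF studies can
#' separate true trait differences from item-level DIF), DIF injections and
#' an optional second latent dimension.
#'
#' Defaults emulate a 240-person COPD sample: age normal with mean 70.4 and
#' SD 7.9 clamped to 46-88 years, stage frequencies 16.25 / 35.83 / 39.58 /
#' 8.33 percent for 0-I / II / III / IV, trait standard deviation 1.5 logits,
#' and severe disease (stage III-IV) shifted +0.8 logits toward worse status.
#'
#' @param spec an [instrument_spec()]; default [sgrq_like_spec()].
#' @param n number of persons.
#' @param theta_mean,theta_sd latent trait distribution (logits); higher
#'   trait = worse status.
#' @param delta named difficulty vector (defaults to
#'   [sgrq_reference_difficulties()] for the SGRQ-like spec, otherwise evenly
#'   spaced on `[-2, 2]` per domain); must lie within `[-7, 5]`.
#' @param tau named list of per-scale-group threshold vectors (defaults to
#'   ordered, evenly spaced thresholds).
#' @param covariates generate age/stage covariates?
#' @param age_mean,age_sd,age_range age distribution (years).
#' @param stage_probs named stage probabilities.
#' @param stage34_effect,age75_effect additive trait shifts (logits) for
#'   stage III-IV persons and persons aged 75+.
#' @param missing_rate completely-at-random missingness proportion.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(spec = sgrq_like_spec(), n = 240,
                       theta_mean = 0, theta_sd = 1.5,
                       delta = NULL, tau = NULL, covariates = TRUE,
                       age_mean = 70.4, age_sd = 7.9, age_range = c(46, 88),
                       stage_probs = c("0-I" = 0.1625, "II" = 0.3583,
                                       "III" = 0.3958, "IV" = 0.0833),
                       stage34_effect = 0.8, age75_effect = 0,
                       missing_rate = 0) {
  stopifnot(n >= 2, theta_sd > 0, age_sd > 0,
            missing_rate >= 0, missing_rate < 1)
  if (abs(sum(stage_probs) - 1) > 1e-3)
    stop("stage_probs must sum to 1")
  stage_probs <- stage_probs / sum(stage_probs)
  it <- spec$items
  if (is.null(delta)) {
    ref <- sgrq_reference_difficulties()
    if (all(it$id[!it$excluded] %in% names(ref))) {
      delta <- ref[it$id[!it$excluded]]
      if (any(it$excluded)) {
        extra <- stats::setNames(rep(0, sum(it$excluded)), it$id[it$excluded])
        delta <- c(delta, extra)
      }
    } else {
      delta <- stats::setNames(numeric(nrow(it)), it$id)
      for (d in names(spec$domains)) {
        ids <- spec$domains[[d]]
        delta[ids] <- if (length(ids) > 1)
          seq(-2, 2, length.out = length(ids)) else 0
      }
    }
  }
  if (!all(it$id %in% names(delta)))
    stop("delta must name every item in the spec")
  if (any(delta < -7 | delta > 5))
    stop("difficulty layout must lie within [-7, 5] logits")
  if (is.null(tau)) {
    tau <- lapply(unique(it$scale_group), function(g)
      default_tau(it$n_categories[it$scale_group == g][1]))
    names(tau) <- unique(it$scale_group)
  }
  structure(list(spec = spec, n = as.integer(n), theta_mean = theta_mean,
                 theta_sd = theta_sd, delta = delta[it$id], tau = tau,
                 covariates = isTRUE(covariates), age_mean = age_mean,
                 age_sd = age_sd, age_range = age_range,
                 stage_probs = stage_probs, stage34_effect = stage34_effect,
                 age75_effect = age75_effect, missing_rate = missing_rate,
                 dif = list(), second_dim = NULL),
            class = "sim_config")
}

#' Inject differential item functioning into a simulation
#'
#' Adds a group-specific difficulty shift applied at generation time: members
#' of the target group respond to `item` at difficulty `delta + shift`
#' (positive shift = harder for that group). The injected truth is recorded
#' exactly in the generated [truth record][generate_responses()].
#'
#' @param config a [sim_config()].
#' @param item item id.
#' @param where group predicate: `"age_ge75"`, `"stage34"`, or a function of
#'   the covariate `data.frame` returning a logical vector.
#' @param shift difficulty shift in logits.
#' @return the updated config.
#' @export
inject_dif <- function(config, item, where = "stage34", shift = 1.0) {
  stopifnot(inherits(config, "sim_config"),
            item %in% config$spec$items$id)
  config$dif <- c(config$dif, list(list(item = item, where = where,
                                        shift = shift)))
  config
}

#' Inject a second latent dimension into a simulation
#'
#' The listed items respond to a second latent trait correlated with the
#' first at the stated level (0 = orthogonal contamination), enabling power
#' studies of the residual-PCA dimensionality screen. The subset must leave
#' at least one item on the first dimension, otherwise there is no contrast
#' to detect.
#'
#' @param config a [sim_config()].
#' @param items item ids assigned to the second dimension (non-empty, proper
#'   subset of the spec's items).
#' @param correlation correlation between the two traits, in `[0, 1)`.
#' @return the updated config.
#' @export
inject_second_dimension <- function(config, items, correlation = 0) {
  stopifnot(inherits(config, "sim_config"))
  if (!length(items)) stop("second-dimension item subset must be non-empty")
  unknown <- setdiff(items, config$spec$items$id)
  if (length(unknown))
    stop("unknown item(s): ", paste(unknown, collapse = ", "))
  if (length(items) >= nrow(config$spec$items))
    stop("second dimension cannot cover all items (no contrast possible)")
  if (correlation < 0 || correlation >= 1)
    stop("correlation must lie in [0, 1)")
  config$second_dim <- list(items = items, correlation = correlation)
  config
}

# draw one category per row of a probability matrix, given uniforms
sample_categories <- function(P, u) {
  cp <- t(apply(P, 1L, cumsum))
  as.integer(rowSums(u > cp))
}

#' Generate synthetic questionnaire responses with known truth
#'
#' Draws responses cell by cell from the category probabilities at the true
#' parameters. The same seed and config always yield an identical matrix; the
#' random stream is split into per-component substreams (covariates/trait,
#' second dimension, responses) so switching an analysis option on or off
#' never perturbs the parts it does not touch.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list with `matrix` (a [response_matrix()], covariates attached)
#'   and `truth` (class `truth_record`): true `theta` (after covariate
#'   shifts), `theta2` when a second dimension is present, `delta`, `tau`,
#'   covariates, normalized DIF injections, per-item dimension assignment,
#'   and the seed.
#' @export
generate_responses <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  seed <- as.integer(seed)
  set.seed(seed)
  sub <- sample.int(.Machine$integer.max - 1L, 3L)

  it <- config$spec$items
  n <- config$n

  ## substream 1: covariates and base trait
  set.seed(sub[1])
  if (config$covariates) {
    age <- round(stats::rnorm(n, config$age_mean, config$age_sd))
    age <- pmin(pmax(age, config$age_range[1]), config$age_range[2])
    stage <- sample(names(config$stage_probs), n, replace = TRUE,
                    prob = config$stage_probs)
    cov <- data.frame(age_years = age, stage = stage,
                      stringsAsFactors = FALSE)
  } else cov <- NULL
  theta <- stats::rnorm(n, config$theta_mean, config$theta_sd)
  if (!is.null(cov)) {
    theta <- theta + config$stage34_effect * (cov$stage %in% c("III", "IV"))
    theta <- theta + config$age75_effect * (cov$age_years >= 75)
  }

  ## substream 2: second dimension
  theta2 <- NULL
  dim_of <- stats::setNames(rep(1L, nrow(it)), it$id)
  if (!is.null(config$second_dim)) {
    set.seed(sub[2])
    rho <- config$second_dim$correlation
    base <- (theta - mean(theta)) / stats::sd(theta)
    theta2 <- config$theta_mean + config$theta_sd *
      (rho * base + sqrt(1 - rho^2) * stats::rnorm(n))
    dim_of[config$second_dim$items] <- 2L
  }

  ## normalize DIF membership against the generated covariates
  dif_members <- lapply(config$dif, function(d) {
    w <- d$where
    memb <- if (is.function(w)) w(cov)
    else if (identical(w, "age_ge75")) {
      if (is.null(cov)) stop("DIF rule 'age_ge75' needs covariates")
      cov$age_years >= 75
    } else if (identical(w, "stage34")) {
      if (is.null(cov)) stop("DIF rule 'stage34' needs covariates")
      cov$stage %in% c("III", "IV")
    } else stop("unknown DIF group rule: ", w)
    list(item = d$item, shift = d$shift, members = which(memb))
  })

  ## substream 3: responses
  set.seed(sub[3])
  X <- matrix(NA_integer_, n, nrow(it), dimnames = list(
    sprintf("P%03d", seq_len(n)), it$id))
  for (j in seq_len(nrow(it))) {
    id <- it$id[j]
    tau <- config$tau[[it$scale_group[j]]]
    th <- if (dim_of[[id]] == 2L) theta2 else theta
    d_person <- rep(config$delta[[id]], n)
    for (dm in dif_members)
      if (dm$item == id) d_person[dm$members] <- d_person[dm$members] + dm$shift
    u <- stats::runif(n)
    for (dv in unique(d_person)) {
      rows <- which(d_person == dv)
      P <- category_probabilities(th[rows], dv, tau)
      X[rows, j] <- sample_categories(P, u[rows])
    }
  }
  if (config$missing_rate > 0) {
    drop <- stats::runif(length(X)) < config$missing_rate
    X[drop] <- NA_integer_
  }

  truth <- structure(list(
    theta = stats::setNames(theta, rownames(X)),
    theta2 = if (is.null(theta2)) NULL else stats::setNames(theta2,
                                                            rownames(X)),
    delta = config$delta, tau = config$tau,
    covariates = cov,
    dif = lapply(config$dif, function(d)
      list(item = d$item,
           where = if (is.function(d$where)) "custom" else d$where,
           shift = d$shift)),
    dimension = dim_of, seed = seed, n = n), class = "truth_record")

  list(matrix = response_matrix(X, config$spec, covariates = cov),
       truth = truth)
}

#' Save / load a truth record as structured text (JSON)
#'
#' Full-precision round trip of a `truth_record` from
#' [generate_responses()].
#'
#' @param truth a `truth_record`.
#' @param path file path.
#' @return `read_truth` returns the `truth_record`; `write_truth` returns
#'   `path` invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "truth_record"))
  payload <- unclass(truth)
  # named vectors as JSON objects; 17 significant digits round-trip doubles
  for (f in c("theta", "theta2", "delta", "dimension"))
    if (!is.null(payload[[f]])) payload[[f]] <- as.list(payload[[f]])
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  truth <- list(
    theta = unlist(raw$theta),
    theta2 = if (is.null(raw$theta2)) NULL else unlist(raw$theta2),
    delta = unlist(raw$delta),
    tau = lapply(raw$tau, as.numeric),
    covariates = if (is.null(raw$covariates)) NULL
                 else as.data.frame(raw$covariates),
    dif = if (length(raw$dif)) lapply(seq_len(nrow(as.data.frame(raw$dif))),
      function(i) as.list(as.data.frame(raw$dif)[i, ])) else list(),
    dimension = vapply(raw$dimension, as.integer, 1L),
    seed = as.integer(raw$seed), n = as.integer(raw$n))
  structure(truth, class = "truth_record")
}
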