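#' Default food-group layout for synthetic cohorts
#'
#' Thirty food groups covering 143 FFQ items: 14 groups with a positive
#' latent-HPF effect (the groups a development run should select), 11 healthy
#' groups whose consumption falls with the latent propensity, and 5 neutral
#' groups. Per-item baseline rates (times/day) and portion sizes (g) are
#' plausible synthetic defaults -- the source FFQ's portion list is not
#' public, so these are invented and labelled as such.
#'
#' @return Data frame with columns \code{group_id}, \code{n_items},
#'   \code{direction} (\code{hpf_positive}, \code{healthy_negative},
#'   \code{neutral}), \code{effect_size}, \code{base_rate} (times/day per
#'   item) and \code{portion_g}.
#' @export
default_group_spec <- function() {
  g <- function(id, n, dir, eff, rate, portion) {
    data.frame(group_id = id, n_items = n, direction = dir,
               effect_size = eff, base_rate = rate, portion_g = portion,
               stringsAsFactors = FALSE)
  }
  e <- 0.35
  rbind(
    g("fatty_dairy",        4L, "hpf_positive", e, 0.35,  40),
    g("sugary_dairy",       5L, "hpf_positive", e, 0.12, 125),
    g("cured_meat",         6L, "hpf_positive", e, 0.50,  50),
    g("fats",               3L, "hpf_positive", e, 0.08,  12),
    g("fermented_alcohol",  7L, "hpf_positive", e, 0.40, 150),
    g("distilled_alcohol",  4L, "hpf_positive", e, 0.05,  50),
    g("sugary_drinks",      4L, "hpf_positive", e, 0.20, 200),
    g("sweets",            18L, "hpf_positive", e, 0.18,  50),
    g("snacks",             2L, "hpf_positive", e, 0.12,  30),
    g("ready_to_eat",       3L, "hpf_positive", e, 0.15, 150),
    g("refined_cereals",    6L, "hpf_positive", e, 0.90,  60),
    g("sauces",             4L, "hpf_positive", e, 0.15,  15),
    g("additives",          2L, "hpf_positive", e, 1.50,   5),
    g("fried_foods",        1L, "hpf_positive", e, 0.30,  NA),
    g("vegetables",        12L, "healthy_negative", e, 0.80, 100),
    g("fruits",            14L, "healthy_negative", e, 0.70, 125),
    g("legumes",            4L, "healthy_negative", e, 0.25,  60),
    g("nuts",               3L, "healthy_negative", e, 0.30,  25),
    g("white_fish",         5L, "healthy_negative", e, 0.20, 110),
    g("blue_fish",          5L, "healthy_negative", e, 0.20, 110),
    g("white_meat",         3L, "healthy_negative", e, 0.35, 110),
    g("potatoes",           3L, "healthy_negative", e, 0.30, 150),
    g("oils",               4L, "healthy_negative", e, 0.80,  10),
    g("wholegrain_cereals", 3L, "healthy_negative", e, 0.30,  60),
    g("semi_skimmed_dairy", 3L, "healthy_negative", e, 0.50, 200),
    g("whole_dairy",        5L, "neutral", 0, 0.30, 200),
    g("eggs",               2L, "neutral", 0, 0.40,  60),
    g("red_meat",           4L, "neutral", 0, 0.30, 120),
    g("non_sugary_drinks",  3L, "neutral", 0, 0.60, 200),
    g("vitamin_supplements", 1L, "neutral", 0, 0.10,   2)
  )
}

#' Configuration for the synthetic-cohort generator
#'
#' The generator emulates the statistical structure the development pipeline
#' assumes: each participant has a latent HPF-propensity \eqn{\theta \sim
#' N(0, \sigma^2)} that raises consumption of the 14 planted HPF groups,
#' lowers consumption of the healthy groups, and is correlated with the
#' covariates in the directions seen in large Mediterranean cohorts (male
#' sex, younger age, higher energy intake and active working status go with
#' higher propensity). Items of planted groups are labelled HPF under each
#' classification system independently with probability \code{label_overlap},
#' producing partial cross-system disagreement.
#'
#' @param n_participants number of participants (at least 30; default 4400).
#' @param seed integer RNG seed.
#' @param group_spec food-group layout, see [default_group_spec()].
#' @param latent_sd standard deviation of the latent propensity.
#' @param noise_cv per-item noise standard deviation, as a multiple of the
#'   item's baseline rate.
#' @param label_overlap probability, per classification system, that a
#'   planted-HPF item is labelled HPF under that system.
#' @param covariate_effects named vector of latent-propensity effects on the
#'   covariates: \code{sex} (log-odds of male per SD), \code{age} (years
#'   lost per SD), \code{energy} (kcal/day gained per SD), \code{working}
#'   (log-odds per SD).
#' @param calibration_truth named vector \code{intercept}, \code{slope},
#'   \code{noise_sd}: the linear truth used when emulating the score-to-HPF%%
#'   calibration (defaults to the published screening equation so that
#'   calibration recovery can be verified against it).
#' @return A list of class \code{sqhpf_synth_config}.
#' @export
synthetic_config <- function(n_participants = 4400L,
                             seed = 1L,
                             group_spec = default_group_spec(),
                             latent_sd = 1,
                             noise_cv = 0.8,
                             label_overlap = 0.9,
                             covariate_effects = c(sex = 0.6, age = 1.2,
                                                   energy = 180, working = 0.45),
                             calibration_truth = c(intercept = 7.6,
                                                   slope = 3.7,
                                                   noise_sd = 5)) {
  if (!is.numeric(n_participants) || length(n_participants) != 1L ||
      n_participants < 30) {
    stop("invalid configuration field 'n_participants': need a count >= 30")
  }
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("invalid configuration field 'seed'")
  }
  if (!is.numeric(label_overlap) || label_overlap < 0 || label_overlap > 1) {
    stop("invalid configuration field 'label_overlap': need a probability in [0,1]")
  }
  if (!is.numeric(latent_sd) || latent_sd < 0) {
    stop("invalid configuration field 'latent_sd'")
  }
  if (!is.numeric(noise_cv) || noise_cv < 0) {
    stop("invalid configuration field 'noise_cv'")
  }
  need <- c("intercept", "slope", "noise_sd")
  if (!all(need %in% names(calibration_truth))) {
    stop("invalid configuration field 'calibration_truth': need ",
         paste(need, collapse = ", "))
  }
  gs_cols <- c("group_id", "n_items", "direction", "effect_size",
               "base_rate", "portion_g")
  if (!all(gs_cols %in% names(group_spec))) {
    stop("invalid configuration field 'group_spec': need columns ",
         paste(gs_cols, collapse = ", "))
  }
  if (anyDuplicated(group_spec$group_id)) {
    stop("invalid configuration field 'group_spec': duplicated group_id")
  }
  structure(list(
    n_participants = as.integer(n_participants),
    seed = as.integer(seed),
    group_spec = group_spec,
    latent_sd = latent_sd,
    noise_cv = noise_cv,
    label_overlap = label_overlap,
    covariate_effects = covariate_effects,
    calibration_truth = calibration_truth
  ), class = "sqhpf_synth_config")
}

# categories of each system that do NOT mark HPF, used for non-planted items
non_hpf_pool <- function() {
  list(nova_cat = c("1", "2", "3"),
       iarc_cat = c("1", "2"),
       ific_cat = c("1", "2", "3"),
       unc_cat  = c("1", "2", "3"))
}

hpf_pool <- function() {
  list(nova_cat = "4",
       iarc_cat = "3",
       ific_cat = c("4", "5"),
       unc_cat  = c("4.1", "4.2"))
}

# build the per-item classification config implied by a group spec
synth_classification <- function(group_spec, label_overlap) {
  n_items <- sum(group_spec$n_items)
  gid <- rep(group_spec$group_id, group_spec$n_items)
  item_no <- sequence(group_spec$n_items)
  id <- sprintf("it_%s_%d", gid, item_no)
  planted <- rep(group_spec$direction == "hpf_positive", group_spec$n_items)
  portion <- rep(group_spec$portion_g, group_spec$n_items)
  # portion jitter so items within a group differ, deterministic given RNG state
  jitter <- ifelse(is.na(portion), NA,
                   round(portion * stats::runif(n_items, 0.7, 1.3)))
  config <- data.frame(
    item_id = id,
    name = paste("synthetic item", seq_len(n_items)),
    portion_g = jitter,
    group_id = gid,
    stringsAsFactors = FALSE
  )
  np <- non_hpf_pool(); hp <- hpf_pool()
  for (sys in names(np)) {
    lab <- sample(np[[sys]], n_items, replace = TRUE)
    is_hpf <- planted & stats::runif(n_items) < label_overlap
    if (any(is_hpf)) {
      lab[is_hpf] <- sample(hp[[sys]], sum(is_hpf), replace = TRUE)
    }
    config[[sys]] <- lab
  }
  config
}

# discretize continuous times/day to the nearest grid category
rate_to_category <- function(rate, grid = ffq_frequency_grid()) {
  t <- grid$times_per_day
  mids <- (t[-1] + t[-length(t)]) / 2
  findInterval(rate, mids)
}

#' Generate a synthetic FFQ cohort
#'
#' Draws a cohort of participants with ordinal FFQ responses, covariates and
#' eating-habit fields from the latent-propensity model described in
#' [synthetic_config()]. Each item's continuous consumption rate is
#' \code{base * (1 + dir * effect * theta) + noise}, truncated at zero and
#' discretized to the nearest of the nine FFQ frequency categories.
#' Deterministic given the config's seed.
#'
#' @param config a [synthetic_config()] object.
#' @return A list with elements \code{cohort} (wide data frame),
#'   \code{config} (classification config data frame), \code{groups} (the
#'   group spec used) and \code{theta} (the latent propensities, for
#'   diagnostics).
#' @export
generate_cohort <- function(config = synthetic_config()) {
  if (!inherits(config, "sqhpf_synth_config")) {
    stop("'config' must come from synthetic_config()")
  }
  set.seed(config$seed)
  n <- config$n_participants
  gs <- config$group_spec
  ce <- config$covariate_effects

  theta <- stats::rnorm(n, 0, config$latent_sd)

  male <- stats::rbinom(n, 1L, stats::plogis(0.08 + ce[["sex"]] * theta))
  sex <- ifelse(male == 1L, "male", "female")
  age <- pmin(75, pmax(55, 65 - ce[["age"]] * theta + stats::rnorm(n, 0, 4.6)))
  energy <- ifelse(male == 1L, 2450, 2150) +
    ce[["energy"]] * theta + stats::rnorm(n, 0, 380)
  working <- stats::rbinom(n, 1L, stats::plogis(-1.35 + ce[["working"]] * theta))
  covars <- data.frame(
    participant_id = sprintf("P%05d", seq_len(n)),
    age = round(age, 1),
    sex = sex,
    center = sprintf("C%02d", sample.int(23L, n, replace = TRUE)),
    energy_kcal = round(energy, 1),
    pa_level = sample(c("low", "medium", "high"), n, replace = TRUE,
                      prob = c(0.55, 0.39, 0.06)),
    bp_med = stats::rbinom(n, 1L, 0.77),
    dm_med = stats::rbinom(n, 1L, 0.27),
    working = working,
    education = sample(c("primary", "secondary", "college"), n,
                       replace = TRUE, prob = c(0.50, 0.28, 0.22)),
    civil = sample(c("single", "married", "widowed_divorced"), n,
                   replace = TRUE, prob = c(0.05, 0.77, 0.18)),
    timepoint = "baseline",
    binge_eating = stats::rbinom(n, 1L, 0.07),
    snacking = stats::rbinom(n, 1L, 0.28),
    stringsAsFactors = FALSE
  )
  covars$n_binges_week <- covars$binge_eating * (1L + stats::rpois(n, 1.5))

  cls <- synth_classification(gs, config$label_overlap)

  dir_num <- c(hpf_positive = 1, healthy_negative = -1, neutral = 0)
  g_dir <- dir_num[rep(gs$direction, gs$n_items)]
  g_eff <- rep(gs$effect_size, gs$n_items)
  g_base <- rep(gs$base_rate, gs$n_items)
  n_items <- nrow(cls)

  resp <- matrix(0L, n, n_items, dimnames = list(NULL, cls$item_id))
  grid <- ffq_frequency_grid()
  for (j in seq_len(n_items)) {
    mu <- g_base[j] * (1 + g_dir[j] * g_eff[j] * theta)
    sdj <- config$noise_cv * g_base[j] + 0.02
    rate <- pmax(0, mu + stats::rnorm(n, 0, sdj))
    resp[, j] <- rate_to_category(rate, grid)
  }

  cohort <- cbind(covars, as.data.frame(resp))
  rownames(cohort) <- NULL
  list(cohort = cohort, config = cls, groups = gs, theta = theta)
}

#' Small deterministic fixture cohort
#'
#' Sixty participants, 12 items in 6 food groups (3 planted HPF, 2 healthy,
#' 1 neutral), with energies clamped into the plausibility windows so that
#' the energy and missingness filters exclude nobody. Intended for unit
#' tests and examples.
#'
#' @return Same structure as [generate_cohort()].
#' @export
generate_fixture_small <- function() {
  gs <- default_group_spec()
  small <- gs[gs$group_id %in% c("sugary_drinks", "sweets", "cured_meat",
                                 "vegetables", "fruits", "eggs"), ]
  small$n_items <- 2L
  cfg <- synthetic_config(n_participants = 60L, seed = 101L,
                          group_spec = small)
  out <- generate_cohort(cfg)
  # keep energies well inside both sexes' plausibility windows
  out$cohort$energy_kcal <- pmin(3400, pmax(900, out$cohort$energy_kcal))
  out
}

#' Simulate score/percentage pairs for calibration recovery
#'
#' Emulates the final calibration stage in isolation: questionnaire scores
#' 0--14 are drawn and the questionnaire-estimated HPF percentage is
#' generated from a linear truth plus Gaussian noise. Used to verify that
#' [fit_calibration()] recovers a known equation at cohort scale.
#'
#' @param n number of participants.
#' @param model linear truth, a [published_calibration()]-style model (or any
#'   list with \code{intercept} and \code{slope}).
#' @param noise_sd residual standard deviation, in percentage points.
#' @param seed integer RNG seed.
#' @return Data frame with columns \code{score} and \code{hpf_pct}.
#' @export
generate_calibration_data <- function(n = 4400L,
                                      model = published_calibration(),
                                      noise_sd = 5,
                                      seed = 1L) {
  set.seed(seed)
  score <- stats::rbinom(n, 14L, 0.33)
  hpf_pct <- model$intercept + model$slope * score +
    stats::rnorm(n, 0, noise_sd)
  data.frame(score = score, hpf_pct = hpf_pct)
}
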