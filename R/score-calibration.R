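#' Group-level answer category for scoring
#'
#' The scoring criteria are thresholds on a food group's frequency of
#' consumption, so a participant's group-level answer is the summed
#' times/day of the member items, re-binned to the nearest of the nine FFQ
#' categories. Single-item groups reduce to the item's own answered
#' category.
#'
#' @inheritParams group_frequency
#' @return Integer vector of category indices 0--8, one per cohort row.
#' @export
group_response_category <- function(cohort, config, group_id,
                                    grid = ffq_frequency_grid()) {
  rate_to_category(group_frequency(cohort, config, group_id, grid), grid)
}

#' Compute the screening-questionnaire score
#'
#' One point per scored food group whose group-level answer category meets
#' that group's criterion; the total score runs from 0 to the number of
#' criteria (14 for the standard instrument).
#'
#' @inheritParams group_frequency
#' @param criteria a list of \code{sqhpf_criterion} objects (one per scored
#'   group), as produced by [map_to_ffq_criterion()].
#' @return List with \code{score} (integer vector) and \code{indicators}
#'   (participants x groups 0/1 matrix).
#' @export
sqhpf_score <- function(cohort, config, criteria,
                        grid = ffq_frequency_grid()) {
  gids <- vapply(criteria, function(cr) cr$group_id, character(1))
  missing <- setdiff(gids, unique(config$group_id))
  if (length(missing)) {
    stop("no responses available for scored group(s): ",
         paste(missing, collapse = ", "))
  }
  ind <- matrix(0L, nrow(cohort), length(criteria),
                dimnames = list(NULL, gids))
  for (j in seq_along(criteria)) {
    cat_j <- group_response_category(cohort, config, gids[j], grid)
    ind[, j] <- item_indicator(cat_j, criteria[[j]])
  }
  list(score = as.integer(rowSums(ind)), indicators = ind)
}

#' FFQ-derived HPF percentage restricted to the questionnaire's groups
#'
#' The share (in % of total grams/day) contributed by the items of the
#' selected food groups. Groups without portion sizes (fried foods)
#' contribute no mass and are effectively excluded from the numerator.
#'
#' @inheritParams group_frequency
#' @param selected_groups character vector of scored food-group ids.
#' @return Numeric vector of percentages.
#' @export
questionnaire_hpf_percent <- function(cohort, config, selected_groups,
                                      grid = ffq_frequency_grid()) {
  check_config(config)
  g <- grams_matrix(cohort, config, grid)
  den <- rowSums(g)
  if (any(!is.na(den) & den == 0)) {
    stop("HPF share undefined: total grams per day is zero for ",
         sum(den == 0, na.rm = TRUE), " participant(s)")
  }
  in_sel <- config$group_id %in% selected_groups
  100 * rowSums(g[, in_sel, drop = FALSE]) / den
}

#' Calibrate the score against the FFQ-derived HPF percentage
#'
#' Ordinary least squares of the questionnaire HPF percentage on the score.
#' The fitted line converts a score into an estimated HPF share of daily
#' intake in grams.
#'
#' @param scores integer questionnaire scores.
#' @param pct FFQ-derived HPF percentages.
#' @return An object of class \code{sqhpf_calibration}: \code{intercept},
#'   \code{slope}, \code{r_squared}, \code{n}, \code{label}, and the
#'   residuals of the fit.
#' @export
fit_calibration <- function(scores, pct) {
  if (length(scores) != length(pct)) stop("scores and pct differ in length")
  if (length(scores) < 3L) stop("need at least 3 points to calibrate")
  if (stats::var(scores) == 0) stop("scores are constant; calibration undefined")
  fit <- stats::lm(pct ~ scores)
  ss_tot <- sum((pct - mean(pct))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else NA_real_
  structure(list(intercept = unname(stats::coef(fit)[1L]),
                 slope = unname(stats::coef(fit)[2L]),
                 r_squared = r2,
                 n = length(scores),
                 label = "fitted",
                 residuals = unname(stats::residuals(fit))),
            class = "sqhpf_calibration")
}

#' The published score-to-percentage calibration
#'
#' The screening instrument's published conversion, HPF consumption
#' (% g/day) = 3.7 x score + 7.6, shipped as a named model distinct from any
#' freshly fitted calibration.
#'
#' @return An \code{sqhpf_calibration} labelled \code{"published-2022"}.
#' @export
published_calibration <- function() {
  structure(list(intercept = 7.6, slope = 3.7, r_squared = NA_real_,
                 n = NA_integer_, label = "published-2022",
                 residuals = NULL),
            class = "sqhpf_calibration")
}

#' Estimate HPF consumption from a score
#'
#' @param score integer score(s) in 0..14.
#' @param model an \code{sqhpf_calibration}.
#' @return Estimated HPF percentage(s) of total grams/day.
#' @export
estimate_hpf <- function(score, model = published_calibration()) {
  if (anyNA(score) || any(score < 0) || any(score > 14) ||
      any(score != floor(score))) {
    stop("score must be an integer in 0..14")
  }
  model$intercept + model$slope * score
}

#' Score-to-percentage equivalency table
#'
#' @param model an \code{sqhpf_calibration}.
#' @return Named numeric vector: estimated HPF percentage for scores 1..14,
#'   rounded to one decimal.
#' @export
equivalency_table <- function(model = published_calibration()) {
  s <- 1:14
  out <- round(estimate_hpf(s, model), 1)
  names(out) <- s
  out
}

# "15" rather than "15.0", as equivalency rows are printed
format_pct <- function(x) {
  sub("\\.0$", "", formatC(round(x, 1), format = "f", digits = 1))
}

#' Render the questionnaire as plain text
#'
#' Produces the fieldable questionnaire: one line per scored group with its
#' criterion, followed by the score-to-percentage equivalency row. For the
#' self-reported version the criteria column is suppressed, since it is
#' meant for the assessor only.
#'
#' @param criteria list of \code{sqhpf_criterion} objects.
#' @param model calibration used for the equivalency row.
#' @param include_criteria show the "criteria for 1 point" column.
#' @return Character vector of text lines, invisibly also printed.
#' @export
format_questionnaire <- function(criteria, model = published_calibration(),
                                 include_criteria = TRUE) {
  lines <- c("What was your average frequency of consumption over the past year of...",
             "")
  for (i in seq_along(criteria)) {
    cr <- criteria[[i]]
    lab <- sprintf("Q%d. %s?", i, gsub("_", " ", cr$group_id))
    if (include_criteria) lab <- sprintf("%-40s [1 point if %s]", lab, cr$display)
    lines <- c(lines, lab)
  }
  eq <- equivalency_table(model)
  lines <- c(lines, "", "TOTAL SCORE: sum of item points",
             "Estimated HPF consumption (% of g/day) by score:",
             paste(sprintf("%s=%s", names(eq), format_pct(eq)),
                   collapse = "  "))
  lines
}
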