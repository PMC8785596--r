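#' Develop a highly-processed-food screening questionnaire from an FFQ cohort
#'
#' Runs the full instrument-development pipeline on a cohort of FFQ
#' responses: eligibility filters (energy plausibility, missingness),
#' per-system HPF consumption shares and tertiles, the tertile-agreement
#' outcome, covariate-adjusted logistic screening of every candidate food
#' group with Bonferroni correction, Youden-index cutpoints for the selected
#' groups mapped onto the nine FFQ answer categories, psychometric
#' validation of the resulting binary items (principal-axis factor analysis,
#' KMO, Bartlett, Cronbach's alpha), scoring of every participant, an OLS
#' calibration of the score against the FFQ-derived HPF percentage, and
#' weighted-kappa agreement between score tertiles and each classification
#' system's tertiles.
#'
#' @param cohort wide-format cohort data frame (see [read_cohort()]).
#' @param config classification config data frame.
#' @param alpha significance level of the selection rule.
#' @param m Bonferroni multiplier (\code{"auto"}: the number of candidates).
#' @param kappa_scheme weighting scheme for the agreement kappas.
#' @param efa_input run the factor analysis on the \code{"binary"} scored
#'   indicators (default) or on the continuous group \code{"frequency"}
#'   values of the selected groups.
#' @param grid frequency grid.
#' @return An object of class \code{sqhpf}; see the methods
#'   [print.sqhpf()], [summary.sqhpf()], [coef.sqhpf()], [predict.sqhpf()],
#'   [plot.sqhpf()], [residuals.sqhpf()].
#' @examples
#' synth <- generate_fixture_small()
#' fit <- sqhpf_develop(synth$cohort, synth$config, m = 6)
#' fit
#' coef(fit)
#' @export
sqhpf_develop <- function(cohort, config, alpha = 0.05, m = "auto",
                          kappa_scheme = c("linear", "quadratic", "unweighted"),
                          efa_input = c("binary", "frequency"),
                          grid = ffq_frequency_grid()) {
  kappa_scheme <- match.arg(kappa_scheme)
  efa_input <- match.arg(efa_input)
  cl <- match.call()

  filt <- apply_cohort_filters(cohort, config, grid)
  dev <- filt$cohort
  if (nrow(dev) < 30L) {
    stop("pipeline stage 'filters': fewer than 30 participants remain")
  }

  assoc <- association_table(dev, config, m = m, alpha = alpha, grid = grid)
  selected <- select_items(assoc, alpha)
  if (length(selected) < 2L) {
    stop("pipeline stage 'item_selection': fewer than 2 groups selected")
  }

  sel_groups <- intersect(selected, unique(config$group_id))
  cutpoints <- list()
  criteria <- list()
  for (gid in sel_groups) {
    x <- group_frequency(dev, config, gid, grid)
    cp <- youden_cutpoint(x, dev$tertile_agreement)
    cutpoints[[gid]] <- cp
    criteria[[gid]] <- map_to_ffq_criterion(cp, gid, grid)
  }

  scored <- sqhpf_score(dev, config, criteria, grid)

  efa_data <- if (efa_input == "binary") {
    scored$indicators
  } else {
    sapply(sel_groups, function(g) group_frequency(dev, config, g, grid))
  }
  R <- correlation_matrix(efa_data)
  kmo <- kmo_msa(R)
  bart <- bartlett_sphericity(R, nrow(efa_data))
  n_ret <- max(1L, kaiser_retention(eigen(R, symmetric = TRUE,
                                          only.values = TRUE)$values))
  efa <- principal_axis_efa(R, n_factors = n_ret)
  alpha_std <- cronbach_alpha(efa_data, standardized = TRUE)

  pct <- questionnaire_hpf_percent(dev, config, sel_groups, grid)
  calibration <- fit_calibration(scored$score, pct)

  score_tert <- assign_tertiles(scored$score)
  kappas <- list()
  for (nm in names(hpf_schemes())) {
    sys_tert <- dev[[paste0("tertile_", tolower(nm))]]
    kappas[[nm]] <- weighted_kappa(score_tert, sys_tert,
                                   scheme = kappa_scheme,
                                   levels = c("T1", "T2", "T3"))
  }

  structure(list(
    call = cl,
    n = nrow(dev),
    exclusions = filt$log,
    associations = assoc,
    selected = selected,
    cutpoints = cutpoints,
    criteria = criteria,
    scores = data.frame(participant_id = dev$participant_id,
                        score = scored$score,
                        quest_hpf_pct = pct,
                        stringsAsFactors = FALSE),
    indicators = scored$indicators,
    efa = c(efa, list(n_retained = kaiser_retention(efa$eigenvalues),
                      msa_overall = kmo$msa_overall,
                      msa_per_item = kmo$msa_per_item,
                      bartlett = bart,
                      cronbach_alpha_std = alpha_std,
                      input = efa_input)),
    kappa = kappas,
    calibration = calibration,
    config = config,
    grid = grid,
    alpha = alpha,
    m = attr(assoc, "m")
  ), class = "sqhpf")
}

#' @export
print.sqhpf <- function(x, ...) {
  cat("Screening questionnaire for highly processed food consumption\n")
  cat(sprintf("  development cohort: %d participants (after exclusions)\n", x$n))
  cat(sprintf("  items selected: %d of %d candidates (Bonferroni m = %d, alpha = %g)\n",
              length(x$selected), nrow(x$associations), x$m, x$alpha))
  cat(sprintf("  factor analysis: %d factor(s) retained, MSA = %.2f, alpha = %.2f\n",
              x$efa$n_retained, x$efa$msa_overall, x$efa$cronbach_alpha_std))
  cat(sprintf("  calibration: HPF%% = %.1f + %.1f x score (R^2 = %.2f)\n",
              x$calibration$intercept, x$calibration$slope,
              x$calibration$r_squared))
  invisible(x)
}

#' Summarize a developed screening questionnaire
#'
#' @param object an \code{sqhpf} fit.
#' @param ... unused.
#' @return An object of class \code{summary.sqhpf} (printed with the full
#'   association, criteria, loading, kappa and equivalency tables).
#' @export
summary.sqhpf <- function(object, ...) {
  crit <- data.frame(
    group_id = names(object$criteria),
    min_category = vapply(object$criteria, `[[`, integer(1), "min_category"),
    display = vapply(object$criteria, `[[`, character(1), "display"),
    threshold = vapply(object$cutpoints, `[[`, numeric(1), "threshold"),
    youden_j = vapply(object$cutpoints, `[[`, numeric(1), "youden_j"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  kap <- data.frame(
    scheme = names(object$kappa),
    kappa = vapply(object$kappa, `[[`, numeric(1), "kappa"),
    se = vapply(object$kappa, `[[`, numeric(1), "se"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(fit = object, criteria_table = crit, kappa_table = kap,
                 equivalency = equivalency_table(object$calibration)),
            class = "summary.sqhpf")
}

#' @export
print.summary.sqhpf <- function(x, ...) {
  print(x$fit)
  cat("\nExclusion log:\n")
  print(x$fit$exclusions, row.names = FALSE)
  cat("\nCandidate associations (tertile agreement ~ frequency):\n")
  a <- x$fit$associations
  a$beta <- round(a$beta, 2)
  a$se <- round(a$se, 2)
  a$p_bonf <- signif(a$p_bonf, 2)
  print(as.data.frame(a)[, c("predictor", "beta", "se", "p_bonf", "selected")],
        row.names = FALSE)
  cat("\nScoring criteria:\n")
  print(x$criteria_table, row.names = FALSE)
  cat("\nFactor loadings (unrotated, principal axis):\n")
  print(round(x$fit$efa$loadings, 2))
  cat(sprintf("\nBartlett chi^2 = %.1f (df %d, p %.3g); MSA = %.2f; Cronbach alpha = %.2f\n",
              x$fit$efa$bartlett$chi2, x$fit$efa$bartlett$df,
              x$fit$efa$bartlett$p, x$fit$efa$msa_overall,
              x$fit$efa$cronbach_alpha_std))
  cat("\nWeighted kappa, score tertiles vs classification-system tertiles:\n")
  print(transform(x$kappa_table, kappa = round(kappa, 2), se = round(se, 3)),
        row.names = FALSE)
  cat("\nScore-to-HPF% equivalency:\n")
  print(x$equivalency)
  invisible(x)
}

#' @export
coef.sqhpf <- function(object, ...) {
  c(intercept = object$calibration$intercept,
    slope = object$calibration$slope)
}

#' Score new participants with a developed questionnaire
#'
#' @param object an \code{sqhpf} fit.
#' @param newdata cohort data frame; defaults to re-scoring the development
#'   cohort is not possible (scores are stored in \code{object$scores}).
#' @param config classification config for \code{newdata} (defaults to the
#'   one used in development).
#' @param type \code{"score"}, \code{"hpf_percent"} (estimated from the
#'   calibration), or \code{"both"}.
#' @param model calibration to use for estimates: \code{"fitted"} (the
#'   development fit) or \code{"published"}.
#' @param ... unused.
#' @return Vector or data frame of predictions.
#' @export
predict.sqhpf <- function(object, newdata, config = object$config,
                          type = c("both", "score", "hpf_percent"),
                          model = c("fitted", "published"), ...) {
  type <- match.arg(type)
  model <- match.arg(model)
  cal <- if (model == "fitted") object$calibration else published_calibration()
  sc <- sqhpf_score(newdata, config, object$criteria, object$grid)$score
  if (type == "score") return(sc)
  est <- cal$intercept + cal$slope * sc
  if (type == "hpf_percent") return(est)
  data.frame(score = sc, est_hpf_pct = est)
}

#' @export
residuals.sqhpf <- function(object, ...) {
  object$calibration$residuals
}

#' @export
fitted.sqhpf <- function(object, ...) {
  object$calibration$intercept +
    object$calibration$slope * object$scores$score
}

#' Plot the score calibration of a developed questionnaire
#'
#' Scatter of the FFQ-derived HPF percentage against the questionnaire
#' score, with the fitted calibration line.
#'
#' @param x an \code{sqhpf} fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.sqhpf <- function(x, ...) {
  s <- jitter(x$scores$score, amount = 0.15)
  graphics::plot(s, x$scores$quest_hpf_pct,
                 xlab = "sQ-HPF score", ylab = "FFQ-derived HPF (% of g/day)",
                 pch = 16, cex = 0.4, col = grDevices::grey(0.4, 0.4), ...)
  graphics::abline(x$calibration$intercept, x$calibration$slope, lwd = 2)
  invisible(x)
}

#' Write the development artifacts of a fit to disk
#'
#' Emits the stage outputs as plain-text files: the exclusion log, the
#' candidate-association table, the scoring-criteria table, a JSON
#' validation block (loadings, Bartlett, MSA, alpha, kappas), per-participant
#' scores, and the rendered questionnaire.
#'
#' @param fit an \code{sqhpf} object.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_sqhpf_report <- function(fit, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(fit$exclusions, file.path(dir, "exclusions.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(fit$associations),
                   file.path(dir, "associations.csv"), row.names = FALSE)
  s <- summary(fit)
  utils::write.csv(s$criteria_table, file.path(dir, "criteria.csv"),
                   row.names = FALSE)
  utils::write.csv(fit$scores, file.path(dir, "scores.csv"), row.names = FALSE)
  validation <- list(
    loadings = as.data.frame(fit$efa$loadings),
    n_retained = fit$efa$n_retained,
    msa_overall = fit$efa$msa_overall,
    bartlett = fit$efa$bartlett,
    cronbach_alpha_std = fit$efa$cronbach_alpha_std,
    kappa = s$kappa_table,
    calibration = c(intercept = fit$calibration$intercept,
                    slope = fit$calibration$slope,
                    r_squared = fit$calibration$r_squared)
  )
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(validation, file.path(dir, "validation.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    utils::capture.output(utils::str(validation),
                          file = file.path(dir, "validation.txt"))
  }
  writeLines(format_questionnaire(fit$criteria, fit$calibration),
             file.path(dir, "questionnaire.txt"))
  invisible(dir)
}
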