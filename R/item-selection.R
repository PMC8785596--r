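#' Build the design matrix for one candidate predictor
#'
#' One logistic regression is fitted per candidate item: the tertile-agreement
#' outcome on the candidate's frequency of consumption, adjusted for the
#' fixed covariate set (age, sex, recruitment center, energy intake,
#' physical-activity level, blood-pressure and diabetes medication, working
#' status, education level, civil status). Categorical covariates are
#' dummy-coded against the alphabetically first level.
#'
#' @param cohort filtered development cohort: must carry a 0/1
#'   \code{tertile_agreement} column and complete covariates.
#' @param config classification config (used to compute group frequencies).
#' @param predictor either a food-group id, the name of a numeric cohort
#'   column (an eating-habit variable), or a numeric vector of predictor
#'   values.
#' @param grid frequency grid.
#' @return An object of class \code{sqhpf_design}: list with the model matrix
#'   \code{X} (intercept, predictor, covariate encodings), outcome \code{y}
#'   and \code{predictor} label.
#' @export
build_design_matrix <- function(cohort, config, predictor,
                                grid = ffq_frequency_grid()) {
  if (!"tertile_agreement" %in% names(cohort) ||
      anyNA(cohort$tertile_agreement) ||
      !all(cohort$tertile_agreement %in% 0:1)) {
    stop("cohort must carry a 0/1 'tertile_agreement' outcome; ",
         "run apply_cohort_filters() first")
  }
  if (is.character(predictor) && length(predictor) == 1L) {
    label <- predictor
    if (predictor %in% config$group_id) {
      x <- group_frequency(cohort, config, predictor, grid)
    } else if (predictor %in% names(cohort)) {
      x <- as.numeric(cohort[[predictor]])
    } else {
      stop("unknown predictor: ", predictor)
    }
  } else {
    label <- "predictor"
    x <- as.numeric(predictor)
    if (length(x) != nrow(cohort)) stop("predictor length does not match cohort")
  }

  cv <- cohort[, covariate_columns(), drop = FALSE]
  for (cl in c("sex", "center", "pa_level", "education", "civil")) {
    cv[[cl]] <- factor(cv[[cl]])  # reference = first level alphabetically
  }
  df <- cbind(data.frame(.pred = x), cv)
  X <- stats::model.matrix(~ ., data = df)
  colnames(X)[colnames(X) == ".pred"] <- label

  sds <- apply(X[, -1, drop = FALSE], 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant column in design matrix: ",
         paste(names(sds)[sds == 0], collapse = ", "))
  }
  if (qr(X)$rank < ncol(X)) {
    stop("design matrix is rank deficient (collinear covariates)")
  }
  structure(list(X = X, y = as.integer(cohort$tertile_agreement),
                 predictor = label),
            class = "sqhpf_design")
}

#' Binomial logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic fit with Wald z-tests. Starts from zero
#' coefficients and iterates weighted least squares until the largest
#' coefficient change falls below \code{tol}; complete separation is flagged
#' when any slope exceeds 15 on its standardized-predictor scale.
#'
#' @param design an \code{sqhpf_design} from [build_design_matrix()], or a
#'   numeric model matrix (then supply \code{y}).
#' @param y 0/1 outcome vector when \code{design} is a bare matrix.
#' @param tol convergence tolerance on the coefficient step.
#' @param max_iter maximum IRLS iterations.
#' @return List with \code{beta}, \code{se}, \code{z}, \code{p_raw} (named by
#'   column), \code{iterations} and \code{converged}.
#' @export
fit_logistic <- function(design, y = NULL, tol = 1e-8, max_iter = 50L) {
  if (inherits(design, "sqhpf_design")) {
    X <- design$X
    y <- design$y
  } else {
    X <- as.matrix(design)
    if (is.null(y)) stop("supply the outcome 'y' with a bare model matrix")
  }
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("outcome must be 0/1")
  if (length(unique(y)) < 2L) stop("both outcome classes must be present")
  if (qr(X)$rank < ncol(X)) stop("model matrix is rank deficient")

  p <- ncol(X)
  beta <- rep(0, p)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    beta_new <- drop(solve(XtW %*% X, XtW %*% z))
    step <- max(abs(beta_new - beta))
    beta <- beta_new
    # separation check: slope magnitude on the standardized scale
    if (p > 1L) {
      sds <- apply(X[, -1, drop = FALSE], 2, stats::sd)
      if (any(abs(beta[-1] * sds) > 15)) {
        stop("complete separation detected (diverging coefficients)")
      }
    }
    if (step < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    stop("IRLS did not converge within ", max_iter, " iterations")
  }

  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  info <- t(X * w) %*% X
  se <- sqrt(diag(solve(info)))
  zstat <- beta / se
  p_raw <- 2 * stats::pnorm(-abs(zstat))
  names(beta) <- names(se) <- names(zstat) <- names(p_raw) <- colnames(X)
  list(beta = beta, se = se, z = zstat, p_raw = p_raw,
       iterations = iter, converged = converged)
}

#' Bonferroni adjustment
#'
#' @param p_raw vector of raw p-values.
#' @param m number of tests (at least \code{length(p_raw)}).
#' @return Adjusted p-values, \code{min(1, m * p)}.
#' @export
bonferroni_adjust <- function(p_raw, m = length(p_raw)) {
  if (m < length(p_raw)) stop("'m' must be at least the number of p-values")
  stats::p.adjust(p_raw, method = "bonferroni", n = m)
}

#' Screen all candidate predictors against the tertile-agreement outcome
#'
#' Fits one covariate-adjusted logistic regression per candidate (every food
#' group in the config, plus any eating-habit columns present in the cohort)
#' and applies the Bonferroni correction across the full candidate set.
#'
#' @inheritParams build_design_matrix
#' @param m Bonferroni multiplier; default \code{"auto"} uses the number of
#'   candidates tested.
#' @param alpha significance level for selection.
#' @return Data frame of class \code{sqhpf_associations}: one row per
#'   candidate with \code{predictor}, \code{beta}, \code{se}, \code{p_raw},
#'   \code{p_bonf} and \code{selected}.
#' @export
association_table <- function(cohort, config, m = "auto", alpha = 0.05,
                              grid = ffq_frequency_grid()) {
  groups <- unique(as.character(config$group_id))
  habits <- intersect(habit_columns(), names(cohort))
  candidates <- c(groups, habits)
  if (identical(m, "auto")) m <- length(candidates)

  rows <- lapply(candidates, function(cand) {
    design <- build_design_matrix(cohort, config, cand, grid)
    fit <- fit_logistic(design)
    data.frame(predictor = cand,
               beta = unname(fit$beta[2L]),
               se = unname(fit$se[2L]),
               p_raw = unname(fit$p_raw[2L]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonf <- bonferroni_adjust(out$p_raw, m)
  out$selected <- out$beta > 0 & out$p_bonf < alpha
  attr(out, "m") <- m
  attr(out, "alpha") <- alpha
  class(out) <- c("sqhpf_associations", "data.frame")
  out
}

#' Selection rule: positive and Bonferroni-significant
#'
#' @param results an association table (or any data frame with columns
#'   \code{predictor}, \code{beta}, \code{p_bonf}).
#' @param alpha significance level.
#' @return Character vector of selected predictor ids, in input order.
#' @export
select_items <- function(results, alpha = 0.05) {
  results$predictor[results$beta > 0 & results$p_bonf < alpha]
}
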