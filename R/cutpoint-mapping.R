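#' ROC operating points over observed thresholds
#'
#' One operating point per unique observed predictor value, with the
#' convention that a participant is called positive when the predictor is at
#' or above the threshold (higher consumption predicts the high-HPF class).
#'
#' @param scores numeric predictor values.
#' @param labels 0/1 outcome vector.
#' @return Data frame with columns \code{threshold}, \code{sensitivity},
#'   \code{specificity}, sorted by threshold.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  if (length(unique(labels)) < 2L) {
    stop("both outcome classes must be present for ROC analysis")
  }
  thr <- sort(unique(scores))
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  sens <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(neg < t), numeric(1))
  data.frame(threshold = thr, sensitivity = sens, specificity = spec)
}

#' Youden-index optimal cutpoint
#'
#' Maximizes J = sensitivity + specificity - 1 over the observed operating
#' points; ties are broken toward the smallest threshold so the result is
#' deterministic.
#'
#' @inheritParams roc_points
#' @return List of class \code{sqhpf_cutpoint}: \code{threshold},
#'   \code{sensitivity}, \code{specificity}, \code{youden_j} and
#'   \code{degenerate} (TRUE when the predictor carries no information,
#'   i.e. a single unique value).
#' @export
youden_cutpoint <- function(scores, labels) {
  pts <- roc_points(scores, labels)
  j <- pts$sensitivity + pts$specificity - 1
  best <- which.max(j)  # first maximum = smallest threshold
  structure(list(threshold = pts$threshold[best],
                 sensitivity = pts$sensitivity[best],
                 specificity = pts$specificity[best],
                 youden_j = j[best],
                 degenerate = length(unique(scores)) == 1L),
            class = "sqhpf_cutpoint")
}

# per-category ">= this category" display strings, phrased in the category's
# natural period as questionnaire criteria are written
criterion_displays <- function() {
  c(">= 1 t/month",  # 1-3 times/month
    "> 3 t/month",   # once a week
    ">= 2 t/week",   # 2-4 times/week
    ">= 5 t/week",   # 5-6 times/week
    ">= 1 t/day",    # once a day
    "> 1 t/day",     # 2-3 times/day
    "> 3 t/day",     # 4-6 times/day
    "> 6 t/day")     # more than 6 times/day
}

#' Adapt a continuous cutpoint to the FFQ answer grid
#'
#' The scoring criterion must be answerable on the nine FFQ categories, so
#' the continuous optimal threshold is rounded up to the first attainable
#' category boundary: the smallest consuming category (index 1--8) whose
#' rate is at least the threshold. The resulting criterion is therefore at
#' least as strict as the continuous optimum. A threshold beyond the top
#' category's rate is clamped to category 8 with a warning.
#'
#' @param cutpoint an \code{sqhpf_cutpoint} (or a bare numeric threshold in
#'   times/day).
#' @param group_id identifier carried into the criterion.
#' @param grid frequency grid.
#' @return List of class \code{sqhpf_criterion}: \code{group_id},
#'   \code{min_category} (1--8) and \code{display}.
#' @export
map_to_ffq_criterion <- function(cutpoint, group_id = NA_character_,
                                 grid = ffq_frequency_grid()) {
  thr <- if (inherits(cutpoint, "sqhpf_cutpoint")) cutpoint$threshold
         else as.numeric(cutpoint)
  rates <- grid$times_per_day
  cand <- which(rates >= thr & grid$index >= 1L)
  if (length(cand) == 0L) {
    warning("threshold ", signif(thr, 4),
            " exceeds the top FFQ category; clamping to category 8")
    min_cat <- 8L
  } else {
    min_cat <- grid$index[min(cand)]
  }
  structure(list(group_id = as.character(group_id),
                 min_category = min_cat,
                 display = criterion_displays()[min_cat]),
            class = "sqhpf_criterion")
}

#' Score one answer category against a criterion
#'
#' @param response_category ordinal answer index 0--8 (vectorized).
#' @param criterion an \code{sqhpf_criterion}.
#' @return Integer 0/1: 1 when the answered category is at or above the
#'   criterion's minimum category.
#' @export
item_indicator <- function(response_category, criterion) {
  if (anyNA(response_category) || any(response_category < 0) ||
      any(response_category > 8)) {
    stop("response category must lie in 0..8")
  }
  as.integer(response_category >= criterion$min_category)
}
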