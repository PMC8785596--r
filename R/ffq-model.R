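#' The nine-category FFQ frequency grid
#'
#' A semi-quantitative FFQ records, for each food or beverage item, one of
#' nine ordinal frequency-of-consumption categories ranging from "never or
#' hardly ever" to "more than 6 times a day". Quantitative work needs each
#' category converted to a daily rate; the conversion used here is the usual
#' Willett-style category midpoint (months taken as 30.44 days).
#'
#' @param times_per_day optional numeric vector of length 9 overriding the
#'   default category-to-rate conversion. Must start at 0 and be strictly
#'   increasing.
#' @return A data frame with columns \code{index} (0--8), \code{label} and
#'   \code{times_per_day}.
#' @examples
#' ffq_frequency_grid()
#' @export
ffq_frequency_grid <- function(times_per_day = NULL) {
  labels <- c(
    "never or hardly ever", "1-3 times/month", "once a week",
    "2-4 times/week", "5-6 times/week", "once a day",
    "2-3 times/day", "4-6 times/day", "more than 6 times/day"
  )
  rates <- c(0, 2 / 30.44, 1 / 7, 3 / 7, 5.5 / 7, 1, 2.5, 5, 7)
  if (!is.null(times_per_day)) {
    if (length(times_per_day) != 9L || times_per_day[1L] != 0 ||
        any(diff(times_per_day) <= 0)) {
      stop("'times_per_day' must be 9 values, starting at 0, strictly increasing")
    }
    rates <- as.numeric(times_per_day)
  }
  data.frame(index = 0:8, label = labels, times_per_day = rates,
             stringsAsFactors = FALSE)
}

#' Convert an FFQ answer category to a consumption rate
#'
#' @param index integer vector of category indices (0--8).
#' @param grid frequency grid, see [ffq_frequency_grid()].
#' @return Numeric vector of rates in times/day.
#' @examples
#' freq_to_times_per_day(c(0, 5, 3))
#' @export
freq_to_times_per_day <- function(index, grid = ffq_frequency_grid()) {
  if (length(index) == 0L) return(numeric(0))
  if (anyNA(index) || any(index != floor(index)) ||
      any(index < 0) || any(index > 8)) {
    stop("FFQ category index must be an integer in 0..8")
  }
  grid$times_per_day[index + 1L]
}

# --- internal helpers shared across modules ---------------------------------

covariate_columns <- function() {
  c("age", "sex", "center", "energy_kcal", "pa_level", "bp_med", "dm_med",
    "working", "education", "civil")
}

habit_columns <- function() {
  c("binge_eating", "n_binges_week", "snacking")
}

item_ids <- function(config) as.character(config$item_id)

check_config <- function(config) {
  needed <- c("item_id", "name", "portion_g", "group_id",
              "nova_cat", "iarc_cat", "ific_cat", "unc_cat")
  miss <- setdiff(needed, names(config))
  if (length(miss)) {
    stop("classification config lacks column(s): ", paste(miss, collapse = ", "))
  }
  bad <- !is.na(config$portion_g) & config$portion_g <= 0
  if (any(bad)) {
    stop("non-positive portion size for item(s): ",
         paste(config$item_id[bad], collapse = ", "))
  }
  invisible(config)
}

check_cohort <- function(cohort, config) {
  ids <- item_ids(config)
  miss <- setdiff(ids, names(cohort))
  if (length(miss)) {
    stop("cohort lacks response column(s) for item(s): ",
         paste(utils::head(miss, 5L), collapse = ", "),
         if (length(miss) > 5L) ", ..." else "")
  }
  invisible(cohort)
}

# matrix of responses (participants x items), integer 0..8; NAs allowed
response_matrix <- function(cohort, config) {
  check_cohort(cohort, config)
  m <- as.matrix(cohort[, item_ids(config), drop = FALSE])
  storage.mode(m) <- "integer"
  m
}

# participants x items matrix of times/day
times_matrix <- function(cohort, config, grid = ffq_frequency_grid()) {
  r <- response_matrix(cohort, config)
  ok <- !is.na(r)
  if (any(r[ok] < 0L | r[ok] > 8L)) stop("FFQ responses must lie in 0..8")
  t <- matrix(NA_real_, nrow(r), ncol(r), dimnames = dimnames(r))
  t[ok] <- grid$times_per_day[r[ok] + 1L]
  t
}

# participants x items matrix of grams/day; items without portion contribute 0
grams_matrix <- function(cohort, config, grid = ffq_frequency_grid()) {
  t <- times_matrix(cohort, config, grid)
  portion <- ifelse(is.na(config$portion_g), 0, config$portion_g)
  sweep(t, 2L, portion, `*`)
}

#' Grams per day consumed of one FFQ item
#'
#' Daily intake of an item is its standard portion size multiplied by the
#' daily rate implied by the answered frequency category. Items whose portion
#' size is unknown (the fried-foods item of the source FFQ) carry frequency
#' information only and cannot be expressed in grams.
#'
#' @param cohort cohort data frame in wide format (one ordinal response column
#'   per item; see [read_cohort()]).
#' @param config classification config data frame (see
#'   [read_classification_config()]).
#' @param item_id item identifier.
#' @param grid frequency grid.
#' @return Numeric vector (one value per cohort row) of grams/day.
#' @export
item_grams_per_day <- function(cohort, config, item_id,
                               grid = ffq_frequency_grid()) {
  check_config(config)
  i <- match(as.character(item_id), item_ids(config))
  if (is.na(i)) stop("unknown item: ", item_id)
  if (is.na(config$portion_g[i])) {
    stop("item '", item_id, "' has no portion size; use its frequency only")
  }
  config$portion_g[i] *
    freq_to_times_per_day(cohort[[as.character(item_id)]], grid)
}

#' Frequency of consumption of a food group
#'
#' The frequency of a food group is the sum of its member items' daily rates.
#' This is the predictor scale on which candidate questionnaire items are
#' screened and on which the scoring criteria are expressed.
#'
#' @inheritParams item_grams_per_day
#' @param group_id food-group identifier.
#' @return Numeric vector of times/day, one value per cohort row.
#' @export
group_frequency <- function(cohort, config, group_id,
                            grid = ffq_frequency_grid()) {
  check_config(config)
  members <- config$group_id == as.character(group_id)
  if (!any(members)) stop("unknown food group: ", group_id)
  t <- times_matrix(cohort, config[members, , drop = FALSE], grid)
  rowSums(t)
}

#' Total grams of food consumed per day
#'
#' Sums grams/day over every item with a known portion size; items without a
#' portion (fried foods) are excluded, matching how the total is defined for
#' HPF percentage shares.
#'
#' @inheritParams item_grams_per_day
#' @return Numeric vector of g/day, one value per cohort row.
#' @export
total_grams <- function(cohort, config, grid = ffq_frequency_grid()) {
  check_config(config)
  rowSums(grams_matrix(cohort, config, grid))
}

#' List the food groups of a classification config
#'
#' @inheritParams item_grams_per_day
#' @return Data frame with one row per food group: \code{group_id},
#'   \code{n_items}, and \code{has_mass} (whether any member item carries a
#'   portion size).
#' @export
food_groups <- function(config) {
  check_config(config)
  ids <- unique(as.character(config$group_id))
  data.frame(
    group_id = ids,
    n_items = as.integer(table(factor(config$group_id, levels = ids))),
    has_mass = vapply(ids, function(g) {
      any(!is.na(config$portion_g[config$group_id == g]))
    }, logical(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

# --- file interfaces --------------------------------------------------------

#' Read or write a cohort table
#'
#' Cohorts are exchanged as delimited text in wide format: one row per
#' participant (per timepoint), columns \code{participant_id}, the covariates
#' (age, sex, center, energy_kcal, pa_level, bp_med, dm_med, working,
#' education, civil), \code{timepoint}, optional eating-habit fields
#' (binge_eating, n_binges_week, snacking), then one ordinal 0--8 column per
#' FFQ item.
#'
#' @param path file path.
#' @param sep field separator (default comma).
#' @return \code{read_cohort} returns a data frame; \code{write_cohort}
#'   returns \code{path} invisibly.
#' @export
read_cohort <- function(path, sep = ",") {
  x <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, check.names = FALSE,
                         fileEncoding = "UTF-8")
  if (!"participant_id" %in% names(x)) {
    stop("cohort file lacks a 'participant_id' column")
  }
  x
}

#' @rdname read_cohort
#' @param cohort cohort data frame.
#' @export
write_cohort <- function(cohort, path, sep = ",") {
  utils::write.table(cohort, path, sep = sep, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read or write a classification config
#'
#' The classification config maps every FFQ item to its standard portion size
#' in grams (empty for the fried-foods item), its food group, and its category
#' under each of the four food-processing classification systems (NOVA, IARC,
#' IFIC, UNC). Categories are stored as text because UNC uses subdivided
#' labels ("4.1", "4.2").
#'
#' @inheritParams read_cohort
#' @return \code{read_classification_config} returns a data frame.
#' @export
read_classification_config <- function(path, sep = ",") {
  x <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, check.names = FALSE,
                         fileEncoding = "UTF-8",
                         colClasses = c(unc_cat = "character"))
  for (cl in c("nova_cat", "iarc_cat", "ific_cat", "unc_cat")) {
    x[[cl]] <- as.character(x[[cl]])
  }
  check_config(x)
}

#' @rdname read_classification_config
#' @param config classification config data frame.
#' @export
write_classification_config <- function(config, path, sep = ",") {
  check_config(config)
  utils::write.table(config, path, sep = sep, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
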