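#' The four food-processing classification schemes
#'
#' Each scheme marks a subset of its processing categories as highly
#' processed food (HPF): NOVA group 4, IARC group 3, IFIC groups 4 and 5,
#' and UNC groups 4.1 and 4.2.
#'
#' @param name optionally, one of \code{"NOVA"}, \code{"IARC"},
#'   \code{"IFIC"}, \code{"UNC"} to return a single scheme.
#' @return A list of schemes (or one scheme), each a list with \code{name},
#'   \code{column} (the classification-config column holding the item's
#'   category) and \code{hpf_categories}.
#' @export
hpf_schemes <- function(name = NULL) {
  schemes <- list(
    NOVA = list(name = "NOVA", column = "nova_cat", hpf_categories = "4"),
    IARC = list(name = "IARC", column = "iarc_cat", hpf_categories = "3"),
    IFIC = list(name = "IFIC", column = "ific_cat", hpf_categories = c("4", "5")),
    UNC  = list(name = "UNC",  column = "unc_cat",  hpf_categories = c("4.1", "4.2"))
  )
  if (is.null(name)) return(schemes)
  nm <- toupper(name)
  if (!nm %in% names(schemes)) stop("unknown classification scheme: ", name)
  schemes[[nm]]
}

#' HPF consumption share under one classification scheme
#'
#' For each participant, the grams per day consumed from items labelled HPF
#' under the scheme, divided by the total grams consumed per day, times 100.
#' Items without a portion size (fried foods) contribute mass to neither the
#' numerator nor the denominator.
#'
#' @inheritParams item_grams_per_day
#' @param scheme a scheme from [hpf_schemes()], or a scheme name.
#' @return Numeric vector of percentages in [0, 100].
#' @export
hpf_percent <- function(cohort, config, scheme,
                        grid = ffq_frequency_grid()) {
  check_config(config)
  if (is.character(scheme)) scheme <- hpf_schemes(scheme)
  g <- grams_matrix(cohort, config, grid)
  is_hpf <- as.character(config[[scheme$column]]) %in% scheme$hpf_categories
  num <- rowSums(g[, is_hpf, drop = FALSE])
  den <- rowSums(g)
  if (any(!is.na(den) & den == 0)) {
    stop("HPF share undefined: total grams per day is zero for ",
         sum(den == 0, na.rm = TRUE), " participant(s)")
  }
  100 * num / den
}

#' Assign tertiles of a consumption distribution
#'
#' Cuts a vector at its empirical 1/3 and 2/3 quantiles (type 7, linear
#' interpolation). Values tied with a cutpoint go to the lower tertile, so
#' the assignment is deterministic; a degenerate constant vector is all T1.
#'
#' @param values numeric vector, length at least 3.
#' @return Factor with levels \code{T1 < T2 < T3}.
#' @export
assign_tertiles <- function(values) {
  if (length(values) < 3L) stop("need at least 3 values to form tertiles")
  q <- stats::quantile(values, c(1 / 3, 2 / 3), names = FALSE, type = 7)
  out <- ifelse(values <= q[1], "T1", ifelse(values <= q[2], "T2", "T3"))
  factor(out, levels = c("T1", "T2", "T3"), ordered = TRUE)
}

#' Tertile-agreement outcome across the four schemes
#'
#' A participant scores 1 (high-HPF consumer) if classified in the top
#' tertile of HPF consumption by at least two schemes and not in the bottom
#' tertile by two or more; 0 (low-HPF) in the mirror case; participants with
#' no two-scheme agreement in an extreme tertile, or with a 2-vs-2 split
#' between T1 and T3, are excluded from development.
#'
#' @param tertiles either a named character/factor vector of length 4 (one
#'   tertile per scheme) for a single participant, or a data frame / matrix
#'   with one column per scheme and one row per participant.
#' @return Data frame with columns \code{value} (\code{"0"}, \code{"1"} or
#'   \code{"EXCLUDED"}), \code{t3_count} and \code{t1_count}.
#' @export
tertile_agreement <- function(tertiles) {
  if (is.data.frame(tertiles)) {
    tertiles <- as.matrix(as.data.frame(lapply(tertiles, as.character),
                                        stringsAsFactors = FALSE))
  }
  if (!is.matrix(tertiles)) tertiles <- matrix(as.character(tertiles), nrow = 1)
  if (ncol(tertiles) != 4L) {
    stop("tertile agreement needs all four classification schemes")
  }
  if (anyNA(tertiles) || !all(tertiles %in% c("T1", "T2", "T3"))) {
    stop("tertiles must be T1, T2 or T3 for every scheme")
  }
  t3 <- rowSums(tertiles == "T3")
  t1 <- rowSums(tertiles == "T1")
  value <- ifelse(t3 >= 2 & t1 < 2, "1",
                  ifelse(t1 >= 2 & t3 < 2, "0", "EXCLUDED"))
  data.frame(value = value, t3_count = t3, t1_count = t1,
             stringsAsFactors = FALSE)
}

#' Apply the cohort eligibility filters
#'
#' Reproduces the development flowchart: (1) drop implausible energy intakes
#' (below 500 or above 3500 kcal/day for women, below 800 or above 4000 for
#' men); (2) drop records with missing covariate or dietary values; (3)
#' compute per-scheme HPF shares and tertiles on the remaining cohort and
#' drop participants whose tertile-agreement outcome is EXCLUDED. Kept
#' participants gain columns \code{hpf_pct_*} and \code{tertile_*} per
#' scheme plus \code{tertile_agreement} (0/1).
#'
#' @inheritParams item_grams_per_day
#' @param stages which filter stages to run, in order.
#' @return List with \code{cohort} (the kept rows, augmented) and \code{log}
#'   (data frame \code{reason}, \code{n_excluded}, \code{n_remaining}).
#' @export
apply_cohort_filters <- function(cohort, config,
                                 grid = ffq_frequency_grid(),
                                 stages = c("energy", "missing",
                                            "tertile_agreement")) {
  check_config(config)
  check_cohort(cohort, config)
  stages <- match.arg(stages, several.ok = TRUE)
  log <- data.frame(reason = character(0), n_excluded = integer(0),
                    n_remaining = integer(0), stringsAsFactors = FALSE)
  note <- function(reason, n_excluded, n_remaining) {
    rbind(log, data.frame(reason = reason, n_excluded = n_excluded,
                          n_remaining = n_remaining, stringsAsFactors = FALSE))
  }

  if ("energy" %in% stages) {
    e <- cohort$energy_kcal
    female <- cohort$sex == "female"
    bad <- ifelse(female, e < 500 | e > 3500, e < 800 | e > 4000)
    bad[is.na(bad)] <- FALSE  # missing energy handled by the missingness stage
    cohort <- cohort[!bad, , drop = FALSE]
    log <- note("implausible_energy", sum(bad), nrow(cohort))
  }

  if ("missing" %in% stages) {
    keep_cols <- intersect(c(covariate_columns(), habit_columns(),
                             item_ids(config)), names(cohort))
    ok <- stats::complete.cases(cohort[, keep_cols, drop = FALSE])
    cohort <- cohort[ok, , drop = FALSE]
    log <- note("missing_values", sum(!ok), nrow(cohort))
  }

  if ("tertile_agreement" %in% stages) {
    schemes <- hpf_schemes()
    tert <- matrix(NA_character_, nrow(cohort), length(schemes),
                   dimnames = list(NULL, names(schemes)))
    for (nm in names(schemes)) {
      pct <- hpf_percent(cohort, config, schemes[[nm]], grid)
      cohort[[paste0("hpf_pct_", tolower(nm))]] <- pct
      tl <- assign_tertiles(pct)
      cohort[[paste0("tertile_", tolower(nm))]] <- as.character(tl)
      tert[, nm] <- as.character(tl)
    }
    agr <- tertile_agreement(tert)
    drop <- agr$value == "EXCLUDED"
    cohort$tertile_agreement <- suppressWarnings(as.integer(agr$value))
    cohort <- cohort[!drop, , drop = FALSE]
    log <- note("no_tertile_agreement", sum(drop), nrow(cohort))
  }

  rownames(cohort) <- NULL
  list(cohort = cohort, log = log)
}
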