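#' Pearson correlation matrix of item data
#'
#' @param item_data numeric matrix or data frame, observations in rows and
#'   items in columns; at least 3 observations of at least 2 non-constant
#'   items.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(item_data) {
  x <- as.matrix(item_data)
  if (ncol(x) < 2L) stop("need at least 2 items")
  if (nrow(x) < 3L) stop("need at least 3 observations")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(x)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("constant item(s): ", paste(bad, collapse = ", "))
  }
  stats::cor(x)
}

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' MSA compares the observed pairwise correlations with the anti-image
#' partial correlations q (each pair partialled on all other items):
#' \deqn{MSA = \sum r_{ij}^2 / (\sum r_{ij}^2 + \sum q_{ij}^2), i \ne j.}
#' Values near 1 indicate data suited to factor analysis; below 0.5,
#' factoring is inadvisable.
#'
#' @param R correlation matrix (invertible).
#' @param ridge small diagonal inflation to apply when \code{R} is
#'   numerically singular (0 disables).
#' @return List with \code{msa_overall} and \code{msa_per_item}.
#' @export
kmo_msa <- function(R, ridge = 0) {
  R <- as.matrix(R)
  if (ridge > 0) R <- (R + diag(ridge, nrow(R))) / (1 + ridge)
  Rinv <- tryCatch(solve(R), error = function(e) {
    stop("correlation matrix is singular; consider the 'ridge' option")
  })
  d <- 1 / sqrt(diag(Rinv))
  Q <- -Rinv * outer(d, d)   # anti-image partial correlations off-diagonal
  diag(Q) <- 0
  R0 <- R
  diag(R0) <- 0
  r2 <- R0^2
  q2 <- Q^2
  msa_item <- rowSums(r2) / (rowSums(r2) + rowSums(q2))
  names(msa_item) <- colnames(R)
  list(msa_overall = sum(r2) / (sum(r2) + sum(q2)),
       msa_per_item = msa_item)
}

#' Bartlett's test of sphericity
#'
#' Tests whether a correlation matrix differs from the identity (i.e.
#' whether the items are correlated at all), using
#' \deqn{\chi^2 = -(n - 1 - (2p + 5)/6)\,\ln|R|}
#' on \eqn{p(p-1)/2} degrees of freedom.
#'
#' @param R correlation matrix (positive definite).
#' @param n number of observations behind \code{R}.
#' @return List with \code{chi2}, \code{df}, \code{p}.
#' @export
bartlett_sphericity <- function(R, n) {
  R <- as.matrix(R)
  p <- ncol(R)
  detR <- det(R)
  if (detR <= 0) stop("correlation matrix is not positive definite")
  chi2 <- -(n - 1 - (2 * p + 5) / 6) * log(detR)
  df <- p * (p - 1) / 2
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Principal-axis exploratory factor analysis, unrotated
#'
#' Classic iterated principal-axis factoring: communalities start at the
#' squared multiple correlations, the reduced correlation matrix (observed
#' correlations with communalities on the diagonal) is eigen-decomposed,
#' loadings of the leading factors are extracted, and the communalities are
#' updated from the loadings until they stabilize. No rotation is applied;
#' factor signs are fixed so each loading column sums positive.
#'
#' @param R correlation matrix.
#' @param n_factors number of factors to extract (1 to p-1).
#' @param tol convergence tolerance on the communalities.
#' @param max_iter maximum iterations.
#' @return List with \code{loadings} (items x factors), \code{communalities},
#'   \code{eigenvalues} (of the unreduced R, sorted descending),
#'   \code{iterations} and \code{heywood} (TRUE if any communality had to be
#'   clipped at 1).
#' @export
principal_axis_efa <- function(R, n_factors = 1L, tol = 1e-6,
                               max_iter = 100L) {
  R <- as.matrix(R)
  p <- ncol(R)
  if (n_factors < 1L || n_factors >= p) {
    stop("'n_factors' must lie between 1 and p-1")
  }
  eig_full <- eigen(R, symmetric = TRUE, only.values = TRUE)$values

  Rinv <- solve(R)
  h <- 1 - 1 / diag(Rinv)  # squared multiple correlations
  heywood <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    Rr <- R
    diag(Rr) <- h
    e <- eigen(Rr, symmetric = TRUE)
    k <- seq_len(n_factors)
    lam <- e$vectors[, k, drop = FALSE] %*%
      diag(sqrt(pmax(e$values[k], 0)), n_factors)
    h_new <- rowSums(lam^2)
    if (any(h_new > 1)) {
      heywood <- TRUE
      h_new <- pmin(h_new, 1)
    }
    delta <- max(abs(h_new - h))
    h <- h_new
    if (delta < tol) break
    if (iter == max_iter) {
      stop("principal-axis factoring did not converge within ",
           max_iter, " iterations")
    }
  }
  if (heywood) {
    warning("Heywood case: communality exceeded 1 and was clipped")
  }
  # deterministic sign: each factor's loadings sum positive
  flip <- ifelse(colSums(lam) < 0, -1, 1)
  lam <- sweep(lam, 2, flip, `*`)
  rownames(lam) <- colnames(R)
  colnames(lam) <- paste0("F", seq_len(n_factors))
  names(h) <- colnames(R)
  list(loadings = lam, communalities = h, eigenvalues = eig_full,
       iterations = iter, heywood = heywood)
}

#' Kaiser retention criterion
#'
#' @param eigenvalues eigenvalues of the unreduced correlation matrix.
#' @return Number of factors with eigenvalue strictly greater than 1.
#' @export
kaiser_retention <- function(eigenvalues) {
  sum(eigenvalues > 1)
}

#' Cronbach's alpha
#'
#' Internal-consistency reliability. The standardized form is
#' \eqn{k \bar r / (1 + (k - 1)\bar r)} with \eqn{\bar r} the mean inter-item
#' correlation; the raw form is \eqn{(k/(k-1))(1 - \sum s_i^2 / s_T^2)}.
#'
#' @param item_data observations x items matrix.
#' @param standardized use the standardized (correlation-based) form.
#' @return Scalar alpha.
#' @export
cronbach_alpha <- function(item_data, standardized = TRUE) {
  x <- as.matrix(item_data)
  k <- ncol(x)
  if (k < 2L) stop("need at least 2 items")
  if (standardized) {
    R <- correlation_matrix(x)
    rbar <- mean(R[lower.tri(R)])
    k * rbar / (1 + (k - 1) * rbar)
  } else {
    vt <- stats::var(rowSums(x))
    if (vt == 0) stop("total score has zero variance")
    (k / (k - 1)) * (1 - sum(apply(x, 2, stats::var)) / vt)
  }
}

#' Weighted Cohen's kappa for ordinal agreement
#'
#' Chance-corrected agreement between two ordinal ratings with
#' distance-dependent disagreement weights \eqn{w_{ij} = |i-j|/(k-1)}
#' (linear), its square (quadratic), or 0/1 (unweighted):
#' \deqn{\kappa_w = 1 - \sum w_{ij} p_{ij} / \sum w_{ij} e_{ij}},
#' where p is the observed joint distribution and e the product of the
#' marginals. The standard error is the large-sample (delta-method) form.
#'
#' @param ratings_a,ratings_b equal-length vectors of ordinal ratings
#'   sharing a category set (e.g. tertiles T1/T2/T3).
#' @param scheme weighting scheme.
#' @param levels optional explicit ordered category levels; by default the
#'   sorted union of observed values.
#' @return List of class \code{sqhpf_kappa}: \code{kappa}, \code{se},
#'   \code{weight_scheme}, \code{table} (the observed contingency table).
#' @export
weighted_kappa <- function(ratings_a, ratings_b,
                           scheme = c("linear", "quadratic", "unweighted"),
                           levels = NULL) {
  scheme <- match.arg(scheme)
  if (length(ratings_a) != length(ratings_b)) {
    stop("ratings must have equal length")
  }
  a <- as.character(ratings_a)
  b <- as.character(ratings_b)
  if (is.null(levels)) levels <- sort(unique(c(a, b)))
  if (length(levels) < 2L) {
    stop("kappa undefined: a single category present in both raters")
  }
  tab <- table(factor(a, levels = levels), factor(b, levels = levels))
  n <- sum(tab)
  p <- tab / n
  k <- length(levels)
  idx <- seq_len(k)
  dist <- abs(outer(idx, idx, "-")) / (k - 1)
  w <- switch(scheme,
              linear = dist,
              quadratic = dist^2,
              unweighted = (dist > 0) * 1)
  pr <- rowSums(p)
  pc <- colSums(p)
  e <- outer(pr, pc)
  kap <- 1 - sum(w * p) / sum(w * e)

  # large-sample SE (Fleiss, Cohen & Everitt), in the agreement-weight form
  v <- 1 - w
  po <- sum(v * p)
  pe <- sum(v * e)
  vi <- rowSums(sweep(v, 2, pc, `*`))   # row-wise expected agreement weight
  vj <- colSums(sweep(v, 1, pr, `*`))
  term <- (v * (1 - pe) - outer(vi, vj, `+`) * (1 - po))^2
  var_k <- (sum(p * term) - (po * pe - 2 * pe + po)^2) / (n * (1 - pe)^4)
  structure(list(kappa = kap, se = sqrt(max(var_k, 0)),
                 weight_scheme = scheme, table = tab),
            class = "sqhpf_kappa")
}
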