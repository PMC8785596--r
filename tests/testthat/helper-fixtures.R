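# Shared fixtures and independent oracles, built in code at test time.

# three-item config: itA is HPF under NOVA+IARC, itB under IFIC+UNC, itC never
tiny_config <- function() {
  data.frame(
    item_id = c("itA", "itB", "itC"),
    name = c("synthetic A", "synthetic B", "synthetic C"),
    portion_g = c(100, 100, 100),
    group_id = c("gA", "gB", "gC"),
    nova_cat = c("4", "1", "1"),
    iarc_cat = c("3", "1", "1"),
    ific_cat = c("1", "4", "1"),
    unc_cat = c("1", "4.1", "1"),
    stringsAsFactors = FALSE
  )
}

base_covariates <- function(n) {
  data.frame(
    age = rep(65, n),
    sex = rep("female", n),
    center = rep("C01", n),
    energy_kcal = rep(2000, n),
    pa_level = rep("low", n),
    bp_med = rep(1L, n),
    dm_med = rep(0L, n),
    working = rep(0L, n),
    education = rep("primary", n),
    civil = rep("married", n),
    timepoint = rep("baseline", n),
    stringsAsFactors = FALSE
  )
}

# 12-participant cohort with hand-derived expected exclusions:
# p01-p03 fail the energy windows; of the remaining nine, p04 is the 2-vs-2
# extreme-tertile split, p07 its mirror, and p10/p12 have no extreme
# agreement; p05, p06, p08, p09, p11 are kept, all as low-HPF (label 0).
filter_fixture <- function() {
  cov <- base_covariates(12)
  cov$sex <- c("female", "male", "female", "male", rep("female", 8))
  cov$energy_kcal <- c(450, 4200, 3600, 3800, rep(2000, 8))
  resp <- rbind(
    c(5, 5, 5),  # p01 (energy-excluded)
    c(5, 5, 5),  # p02 (energy-excluded)
    c(5, 5, 5),  # p03 (energy-excluded)
    c(7, 0, 6),  # p04  A=5.0  B=0    C=2.5
    c(6, 0, 6),  # p05  A=2.5  B=0    C=2.5
    c(5, 0, 6),  # p06  A=1.0  B=0    C=2.5
    c(0, 7, 6),  # p07  A=0    B=5.0  C=2.5
    c(0, 6, 6),  # p08  A=0    B=2.5  C=2.5
    c(0, 5, 6),  # p09  A=0    B=1.0  C=2.5
    c(5, 5, 0),  # p10  A=1.0  B=1.0  C=0
    c(0, 0, 5),  # p11  A=0    B=0    C=1.0
    c(7, 7, 0)   # p12  A=5.0  B=5.0  C=0
  )
  colnames(resp) <- c("itA", "itB", "itC")
  cohort <- cbind(data.frame(participant_id = sprintf("p%02d", 1:12),
                             stringsAsFactors = FALSE),
                  cov, as.data.frame(resp))
  cohort
}

# brute-force logistic maximum likelihood by nested grid refinement over
# (intercept, slope); independent of the IRLS path
gridsearch_logit <- function(x, y, lo = -10, hi = 10) {
  loglik <- function(b0, b1) {
    eta <- b0 + b1 * x
    sum(y * eta - log1p(exp(eta)))
  }
  centre <- c(0, 0)
  half <- (hi - lo) / 2
  step <- half / 40
  for (level in 1:4) {
    b0s <- seq(centre[1] - half, centre[1] + half, by = step)
    b1s <- seq(centre[2] - half, centre[2] + half, by = step)
    ll <- outer(b0s, b1s, Vectorize(loglik))
    best <- which(ll == max(ll), arr.ind = TRUE)[1, ]
    centre <- c(b0s[best[1]], b1s[best[2]])
    half <- 2 * step
    step <- half / 40
  }
  centre
}

# partial correlation of items i and j given all others, via the Schur
# complement of the remaining block (independent of the matrix-inverse
# anti-image route used by kmo_msa)
partial_cor_schur <- function(R, i, j) {
  rest <- setdiff(seq_len(ncol(R)), c(i, j))
  S <- R[c(i, j), c(i, j)] -
    R[c(i, j), rest] %*% solve(R[rest, rest]) %*% R[rest, c(i, j)]
  S[1, 2] / sqrt(S[1, 1] * S[2, 2])
}

planted_group_ids <- function() {
  gs <- default_group_spec()
  gs$group_id[gs$direction == "hpf_positive"]
}
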