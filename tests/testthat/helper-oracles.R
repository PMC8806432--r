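# Independent oracles used to cross-check the package's computations.
# These deliberately use naive/brute-force formulations, never the code
# paths they verify.

# Efron-tie Cox partial log-likelihood for a single binary covariate,
# vectorized over a grid of coefficients: risk-set counts are precomputed
# per distinct event time, then every beta is evaluated in closed form.
efron_loglik <- function(betas, time, event, x) {
  stopifnot(all(x %in% c(0, 1)))
  eb <- exp(betas)
  ll <- numeric(length(betas))
  for (t in unique(time[event == 1])) {
    D <- which(event == 1 & time == t)
    R <- which(time >= t)
    d <- length(D)
    d1 <- sum(x[D])                       # events with x = 1 at t
    r1 <- sum(x[R])                       # at-risk with x = 1
    r0 <- length(R) - r1
    ll <- ll + d1 * betas
    for (l in seq_len(d) - 1) {
      ll <- ll - log((r0 - (l / d) * (d - d1)) + (r1 - (l / d) * d1) * eb)
    }
  }
  ll
}

# Two-stage grid maximizer of the Efron partial likelihood.
efron_grid_mle <- function(time, event, x, lim = 4) {
  coarse <- seq(-lim, lim, by = 0.01)
  b0 <- coarse[which.max(efron_loglik(coarse, time, event, x))]
  fine <- seq(b0 - 0.02, b0 + 0.02, by = 1e-5)
  fine[which.max(efron_loglik(fine, time, event, x))]
}

# Exhaustive pair-indicator matrix: triple loop over i<j and samples.
brute_pair_matrix <- function(X) {
  g <- rownames(X)
  n <- nrow(X)
  rows <- list()
  ids <- character(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      rows[[length(rows) + 1]] <-
        vapply(seq_len(ncol(X)),
               function(s) as.integer(X[i, s] > X[j, s]), integer(1))
      ids <- c(ids, paste(g[i], g[j], sep = "|"))
    }
  }
  out <- do.call(rbind, rows)
  dimnames(out) <- list(ids, colnames(X))
  out
}

# Benjamini-Hochberg step-up by definition: q_(i) = min_{j>=i} m p_(j)/j.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    j <- i:m
    q[o[i]] <- min(1, min(m * p[o[j]] / j))
  }
  q
}

# Mann-Whitney AUC with ties counted 1/2.
mw_auc <- function(score, case) {
  s1 <- score[case]
  s0 <- score[!case]
  mean(outer(s1, s0, ">") + 0.5 * outer(s1, s0, "=="))
}

# Product-limit survival at t0, by hand.
km_brute <- function(time, event, t0) {
  s <- 1
  for (t in sort(unique(time[event == 1 & time <= t0]))) {
    d <- sum(time == t & event == 1)
    r <- sum(time >= t)
    s <- s * (1 - d / r)
  }
  s
}

# Two-group log-rank chi-square from 2x2 risk tables at each event time.
logrank_brute <- function(time, event, group) {
  g1 <- group == levels(factor(group))[1]
  o_minus_e <- 0
  v <- 0
  for (t in sort(unique(time[event == 1]))) {
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g1)
    n <- sum(time >= t)
    n1 <- sum(time >= t & g1)
    e1 <- d * n1 / n
    o_minus_e <- o_minus_e + d1 - e1
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# Random strictly increasing transform applied to a vector of
# non-negative values (power + affine; parameters per call).
random_monotone <- function(x) {
  a <- stats::runif(1, 0.2, 5)
  b <- stats::runif(1, 0, 10)
  g <- stats::runif(1, 0.3, 3)
  a * x^g + b
}

# All permutations of 1..n (n small), for exact permutation nulls.
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    for (p in combinat_perms(n - 1)) {
      out[[length(out) + 1]] <- c(i, rest[p])
    }
  }
  out
}
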