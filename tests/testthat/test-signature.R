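test_that("univariate Cox screen recovers a known hazard ratio", {
  set.seed(10)
  n <- 600
  x <- rbinom(n, 1, 0.5)
  time <- rexp(n, 0.001 * exp(log(2) * x))
  pm <- pm_from_indicator(x)
  surv <- surv_from(time, rep(1, n))
  out <- univariate_cox_screen(pm, surv)
  expect_equal(out$hr, 2, tolerance = 0.2)
  expect_true(out$ci_low < out$hr & out$hr < out$ci_high)
  expect_true(out$selected)
})

test_that("constant pair indicators are skipped", {
  set.seed(11)
  M <- rbind("a|b" = rep(1L, 40), "a|c" = rbinom(40, 1, 0.5))
  pm <- pm_from_rows(M)
  surv <- surv_from(rexp(40, 0.01), rep(1, 40))
  expect_message(out <- univariate_cox_screen(pm, surv), "skipped 1")
  expect_identical(out$pair_id, "a|c")
})

test_that("null pairs are retained at about the nominal screen rate", {
  set.seed(12)
  p_max <- 0.2
  hits <- replicate(300, {
    x <- rbinom(200, 1, 0.5)
    surv <- surv_from(rexp(200, 0.002), rbinom(200, 1, 0.8))
    out <- univariate_cox_screen(pm_from_indicator(x), surv, p_max = p_max)
    out$selected[1]
  })
  expect_gt(mean(hits), p_max - 0.07)
  expect_lt(mean(hits), p_max + 0.07)
})

test_that("the partial-likelihood maximizer matches grid search on small data", {
  set.seed(13)
  for (k in 1:3) {
    n <- sample(15:30, 1)
    x <- rbinom(n, 1, 0.5)
    if (length(unique(x)) < 2) x[1:2] <- c(0, 1)
    time <- round(rexp(n, 0.01 * exp(0.8 * x)), 1)  # rounding makes ties
    event <- rbinom(n, 1, 0.85)
    event[which.max(time)] <- 1
    out <- univariate_cox_screen(pm_from_indicator(x),
                                 surv_from(pmax(time, 0.1), event),
                                 p_max = 1)
    bgrid <- efron_grid_mle(pmax(time, 0.1), event, x)
    expect_equal(out$beta, bgrid, tolerance = 1e-4)
  }
})

test_that("LASSO-Cox finds a planted pair among many null pairs", {
  found <- vapply(1:5, function(s) {
    set.seed(100 + s)
    n <- 400
    M <- matrix(rbinom(51 * n, 1, 0.5), nrow = 51,
                dimnames = list(c("true|pair",
                                  paste0("null", 1:50, "|x")), NULL))
    time <- rexp(n, 0.002 * exp(1.5 * M[1, ]))
    pm <- pm_from_rows(M)
    surv <- surv_from(time, rep(1, n))
    sel <- lasso_cox_select(pm, surv, repeats = 3, seed = s)$selected
    "true|pair" %in% sel
  }, logical(1))
  expect_gte(sum(found), 4)
})

test_that("the LASSO path is zero at maximal penalty and screens duplicates sanely", {
  set.seed(14)
  n <- 300
  x <- rbinom(n, 1, 0.5)
  M <- rbind("a|b" = x, "dup1|x" = x, "dup2|x" = rbinom(n, 1, 0.5))
  time <- rexp(n, 0.002 * exp(1.2 * x))
  pm <- pm_from_rows(M)
  surv <- surv_from(time, rep(1, n))
  fit <- lasso_cox_select(pm, surv, repeats = 2, seed = 3)
  expect_true(all(fit$coef[, 1] == 0))            # penalty dominance
  expect_gte(length(fit$selected), 1)
  # identical columns must not enter with opposite signs
  cc <- as.numeric(fit$coef[c("a|b", "dup1|x"), which.min(abs(fit$lambda -
                                                                fit$lambda_min))])
  expect_false(all(cc != 0) && prod(sign(cc)) < 0)
})

test_that("backward AIC elimination prunes null pairs and keeps the signal", {
  kept <- vapply(1:5, function(s) {
    set.seed(200 + s)
    n <- 500
    M <- rbind("true|pair" = rbinom(n, 1, 0.5),
               "n1|x" = rbinom(n, 1, 0.5),
               "n2|x" = rbinom(n, 1, 0.5),
               "n3|x" = rbinom(n, 1, 0.5))
    time <- rexp(n, 0.002 * exp(1.2 * M[1, ]))
    pm <- pm_from_rows(M)
    surv <- surv_from(time, rbinom(n, 1, 0.85))
    sig <- stepwise_multivariate_cox(pm, surv, rownames(M))
    c(true_in = "true|pair" %in% sig$pair_id,
      nulls_out = sum(grepl("^n", sig$pair_id)) <= 1)
  }, logical(2))
  expect_true(all(kept["true_in", ]))
  expect_gte(mean(kept["nulls_out", ]), 0.8)
})

test_that("a single candidate is returned as-is; collinear ones collapse", {
  set.seed(15)
  n <- 100
  x <- rbinom(n, 1, 0.5)
  time <- rexp(n, 0.005 * exp(x))
  pm1 <- pm_from_indicator(x)
  surv <- surv_from(time, rep(1, n))
  sig <- stepwise_multivariate_cox(pm1, surv, "A|B")
  uni <- univariate_cox_screen(pm1, surv, p_max = 1)
  expect_equal(sig$beta, uni$beta, tolerance = 1e-8)

  M <- rbind("a|b" = x, "b|c" = x)
  pm2 <- pm_from_rows(M)
  sig2 <- suppressMessages(
    stepwise_multivariate_cox(pm2, surv, rownames(M)))
  expect_equal(nrow(sig2), 1)
})

test_that("the risk score is the coefficient-weighted sum of indicators", {
  sig <- data.frame(pair_id = c("a|b", "c|d"), beta = c(0.5, -1.0))
  pm <- pm_from_rows(rbind("a|b" = c(1L, 0L, 1L), "c|d" = c(1L, 0L, 0L)))
  s <- risk_score(sig, pm)
  expect_equal(unname(s), c(-0.5, 0, 0.5))

  sig3 <- data.frame(pair_id = c("a|b", "c|d", "e|f"),
                     beta = c(1.2, 0.7, -0.3))
  pm3 <- pm_from_rows(rbind("a|b" = 1L, "c|d" = 0L, "e|f" = 1L))
  expect_equal(unname(risk_score(sig3, pm3)), 0.9)
  expect_error(risk_score(sig3, pm), "missing from pair matrix: e\\|f")
})

test_that("risk groups split strictly above the cutoff", {
  g <- assign_risk_groups(c(p1 = 0.1, p2 = 0.5, p3 = 0.500001), 0.5)
  expect_identical(g$group, c("low", "low", "high"))
})
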