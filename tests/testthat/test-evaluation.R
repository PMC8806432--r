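test_that("with no censoring the horizon AUC is the Mann-Whitney statistic", {
  set.seed(20)
  n <- 150
  score <- rnorm(n)
  time <- rexp(n, 0.01 * exp(0.7 * score))
  surv <- surv_from(time, rep(1, n))
  names(score) <- surv$patient_id
  h <- stats::median(time)
  roc <- time_dependent_roc(score, surv, h)
  expect_equal(roc$auc, mw_auc(score, time <= h), tolerance = 1e-10)
})

test_that("a perfectly separating score reaches AUC 1 and noise stays near 0.5", {
  surv <- surv_from(c(rep(50, 5), rep(500, 5)), rep(1, 10))
  score <- stats::setNames(c(rep(2, 5), rep(1, 5)), surv$patient_id)
  expect_equal(time_dependent_roc(score, surv, 100)$auc, 1.0)

  set.seed(21)
  n <- 800
  surv2 <- surv_from(rexp(n, 0.01), rbinom(n, 1, 0.8))
  noise <- stats::setNames(rnorm(n), surv2$patient_id)
  auc <- time_dependent_roc(noise, surv2, 70)$auc
  expect_gt(auc, 0.43)
  expect_lt(auc, 0.57)
})

test_that("AUC is invariant to monotone transforms of the score", {
  set.seed(22)
  n <- 120
  score <- rnorm(n)
  surv <- surv_from(rexp(n, 0.01 * exp(score)), rbinom(n, 1, 0.75))
  names(score) <- surv$patient_id
  a1 <- time_dependent_roc(score, surv, 80)$auc
  a2 <- time_dependent_roc(exp(2 * score) + 5, surv, 80)$auc
  expect_equal(a1, a2, tolerance = 1e-12)
  expect_error(time_dependent_roc(score, surv, 1e-9), "no events")
})

test_that("the AIC cutoff separates two survival clusters and rejects constants", {
  surv <- surv_from(c(2000, 2100, 2200, 50, 60, 70),
                    c(0, 0, 0, 1, 1, 1))
  score <- stats::setNames(c(0.1, 0.2, 0.3, 2.1, 2.2, 2.3),
                           surv$patient_id)
  cut <- optimal_cutoff_aic(score, surv)
  expect_gt(cut$cutoff, 0.3)
  expect_lt(cut$cutoff, 2.1)
  expect_error(optimal_cutoff_aic(stats::setNames(rep(1, 6),
                                                  surv$patient_id), surv),
               "constant")
})

test_that("the AIC scan agrees with an independent likelihood evaluation", {
  set.seed(23)
  n <- 12
  score <- rnorm(n)
  surv <- surv_from(rexp(n, 0.01 * exp(score)), rbinom(n, 1, 0.9))
  names(score) <- surv$patient_id
  cut <- optimal_cutoff_aic(score, surv)
  aic_oracle <- vapply(cut$candidates, function(cc) {
    g <- as.integer(score > cc)
    bhat <- efron_grid_mle(surv$time, surv$event, g, lim = 20)
    -2 * efron_loglik(bhat, surv$time, surv$event, g) + 2
  }, numeric(1))
  expect_equal(cut$aic, aic_oracle, tolerance = 1e-4)
  expect_equal(cut$cutoff, cut$candidates[which.min(aic_oracle)])
})

test_that("Kaplan-Meier and log-rank match hand computation on fixtures", {
  time <- c(3, 5, 5, 8, 10, 12, 15, 20)
  event <- c(1, 1, 0, 1, 1, 0, 1, 0)
  surv <- surv_from(time, event)
  g <- stats::setNames(rep(c("high", "low"), 4), surv$patient_id)
  res <- km_logrank(g, surv)
  expect_equal(res$chisq, logrank_brute(time, event, g), tolerance = 1e-10)
  # KM from survfit equals the brute product-limit at several times
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  for (t0 in c(4, 9, 16)) {
    expect_equal(summary(fit, times = t0)$surv, km_brute(time, event, t0),
                 tolerance = 1e-12)
  }
})

test_that("identical group survival gives a null log-rank statistic", {
  time <- rep(c(5, 10, 20, 40), 2)
  event <- rep(c(1, 1, 0, 1), 2)
  surv <- surv_from(time, event)
  g <- stats::setNames(rep(c("high", "low"), each = 4), surv$patient_id)
  res <- km_logrank(g, surv)
  expect_lt(res$chisq, 1e-10)
  expect_gt(res$p, 0.999)
  expect_error(km_logrank(stats::setNames(rep("high", 8),
                                          surv$patient_id), surv),
               ">= 2 nonempty groups")
})

test_that("independence analysis flags the score and rejects aliased designs", {
  co <- simulate_cohort(simulation_spec(n_tumor = 400, n_normal = 20,
                                        seed = 30))
  tp <- co$truth$planted_pairs
  pm <- build_pair_matrix(co$expr,
                          genes = unique(unlist(tp[, c("gene_a", "gene_b")])))
  sig <- data.frame(pair_id = paste(tp$gene_a, tp$gene_b, sep = "|"),
                    beta = tp$beta)
  score <- risk_score(sig, pm)
  res <- independence_analysis(score, co$surv)
  expect_lt(res$multi_p[res$term == "risk_score"], 0.01)
  # clinical covariates are generated independently of the score
  expect_gt(min(res$multi_p[res$term != "risk_score"]), 1e-4)

  surv2 <- co$surv
  surv2$age2 <- surv2$age
  expect_error(independence_analysis(score, surv2,
                                     covariates = c("age", "age2")),
               "aliased")
})

test_that("strata split at the documented clinical boundaries", {
  expect_identical(split_by_age(c(60, 65, 66, 70)),
                   c("young", "young", "old", "old"))
  expect_identical(split_by_stage(c("I", "II", "III", "IV")),
                   c("early", "early", "late", "late"))

  co <- simulate_cohort(simulation_spec(n_tumor = 200, n_normal = 20,
                                        seed = 31))
  score <- stats::setNames(rnorm(200), co$surv$patient_id)
  res <- stratified_analysis(score, co$surv, "age", cutoff = 0)
  expect_setequal(names(res), c("young", "old"))
  # a stratum with a single risk group is not testable
  res2 <- stratified_analysis(score, co$surv, "age", cutoff = 1e6)
  expect_true(all(unlist(res2) == "not-testable"))
})

test_that("signature comparison ranks informative scores above noise", {
  set.seed(32)
  n <- 300
  score <- rnorm(n)
  surv <- surv_from(rexp(n, 0.005 * exp(score)), rbinom(n, 1, 0.8))
  names(score) <- surv$patient_id
  noise <- stats::setNames(rnorm(n), surv$patient_id)
  tab <- compare_signatures(list(fitted = score, competitor = noise,
                                 self = score),
                            surv, stats::median(surv$time))
  expect_equal(tab$auc[tab$signature == "fitted"],
               tab$auc[tab$signature == "self"])
  expect_gt(tab$auc[tab$signature == "fitted"],
            tab$auc[tab$signature == "competitor"])
  expect_error(compare_signatures(list(a = score, b = noise[-1]), surv, 100),
               "different patients")
})
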