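#' Specify a synthetic cohort
#'
#' Describes a tumor/normal expression cohort with the statistical structure
#' the pair-signature analysis assumes: a set of lncRNAs sharing latent
#' factors with immune genes (so the co-expression screen has true
#' positives), a differentially expressed subset of those, and survival
#' times drawn from a proportional-hazards model whose linear predictor is
#' a weighted sum of binary pair-ordering indicators computed from the
#' generated expression itself.
#'
#' Defaults describe the reference cohort used throughout the package's
#' examples and validation: 500 tumors, 50 normals, 300 lncRNAs of which 40
#' are immune-related and 20 differentially expressed, three planted
#' prognostic pairs with coefficients 1.2, -0.9 and 0.6, an exponential
#' baseline hazard with ~1000-day median, and 30% independent uniform
#' censoring.
#'
#' @param n_tumor,n_normal sample counts.
#' @param n_lncRNA,n_mRNA gene counts by biotype.
#' @param n_immune_genes immune-flagged mRNAs (first `n_immune_genes` of
#'   the mRNAs).
#' @param n_irlnc lncRNAs sharing a latent factor with an immune gene
#'   (must be <= `n_immune_genes` so each has its own partner).
#' @param n_de immune-related lncRNAs given a tumor-vs-normal shift
#'   (first `n_de` of the `n_irlnc`).
#' @param planted_pairs data.frame with columns `a`, `b` (indices into the
#'   DE lncRNAs, 1-based), `beta` (true Cox coefficient of the indicator
#'   "expression of a exceeds expression of b") and optional `mu_offset`
#'   (log2-scale mean difference a-b; 0 keeps the pair's one-frequency at
#'   0.5 in expectation).
#' @param de_shift tumor-minus-normal mean shift of DE genes on the log2
#'   scale (default 3.0, twice the usual 1.5 fold-change threshold).
#' @param de_up_fraction fraction of DE genes shifted up in tumors.
#' @param factor_sd,noise_sd latent-factor and residual standard deviations
#'   on the log2 scale; with the defaults (1 and 0.5) an immune gene and
#'   its partner lncRNA have expected Pearson r = 1/(1+noise_sd^2) = 0.8.
#' @param baseline_rate exponential baseline hazard per day (default
#'   log(2)/1000: 1000-day median at linear predictor 0).
#' @param weibull_shape if not 1, Weibull baseline with this shape and
#'   scale matching `baseline_rate`.
#' @param censor_rate target fraction censored, in [0, 1); censoring times
#'   are uniform on (0, tau) with tau solved so the expected censoring
#'   fraction equals `censor_rate`.
#' @param seed integer seed; the whole cohort is a deterministic function
#'   of the simulation spec.
#'
#' @return A list of class `SimulationSpec`.
#' @export
simulation_spec <- function(n_tumor = 500, n_normal = 50,
                            n_lncRNA = 300, n_mRNA = 200,
                            n_immune_genes = 60, n_irlnc = 40, n_de = 20,
                            planted_pairs = data.frame(
                              a = c(1L, 3L, 5L), b = c(2L, 4L, 6L),
                              beta = c(1.2, -0.9, 0.6), mu_offset = 0),
                            de_shift = 3.0, de_up_fraction = 0.8,
                            factor_sd = 1, noise_sd = 0.5,
                            baseline_rate = log(2) / 1000,
                            weibull_shape = 1,
                            censor_rate = 0.3,
                            seed = 1L) {
  spec <- list(n_tumor = as.integer(n_tumor), n_normal = as.integer(n_normal),
               n_lncRNA = as.integer(n_lncRNA), n_mRNA = as.integer(n_mRNA),
               n_immune_genes = as.integer(n_immune_genes),
               n_irlnc = as.integer(n_irlnc), n_de = as.integer(n_de),
               planted_pairs = as.data.frame(planted_pairs),
               de_shift = de_shift, de_up_fraction = de_up_fraction,
               factor_sd = factor_sd, noise_sd = noise_sd,
               baseline_rate = baseline_rate, weibull_shape = weibull_shape,
               censor_rate = censor_rate, seed = as.integer(seed))
  if (is.null(spec$planted_pairs$mu_offset)) spec$planted_pairs$mu_offset <- 0
  validate_spec(spec)
  structure(spec, class = "SimulationSpec")
}

validate_spec <- function(spec) {
  with(spec, {
    stopifnot(n_tumor >= 2, n_normal >= 2, n_lncRNA >= 2, n_mRNA >= 1,
              n_immune_genes >= 1, n_immune_genes <= n_mRNA,
              n_irlnc >= 1, n_irlnc <= min(n_lncRNA, n_immune_genes),
              n_de >= 2, n_de <= n_irlnc,
              censor_rate >= 0, censor_rate < 1,
              baseline_rate > 0, weibull_shape > 0)
    pp <- planted_pairs
    if (nrow(pp) > 0) {
      stopifnot(all(pp$a >= 1), all(pp$b >= 1),
                all(pp$a <= n_de), all(pp$b <= n_de),
                all(pp$a != pp$b))
      if (anyDuplicated(c(pp$a, pp$b))) {
        stop("planted pair members must be distinct genes across pairs")
      }
      # analytic one-frequency of a planted pair: the log-scale difference of
      # the two members is Gaussian with mean mu_offset and variance
      # 2*(factor_sd^2 + noise_sd^2)
      p1 <- stats::pnorm(pp$mu_offset /
                           sqrt(2 * (factor_sd^2 + noise_sd^2)))
      if (any(p1 <= 0.20 | p1 >= 0.80)) {
        stop("infeasible spec: planted pair one-frequency ",
             "outside the (0.2, 0.8) validity band by construction")
      }
    }
  })
  invisible(spec)
}

#' Simulate an expression + survival cohort with planted signal
#'
#' Draws the cohort described by a [simulation_spec()]. Expression is a
#' latent-factor Gaussian model on the log2 scale, exponentiated to
#' positive values: each immune-related lncRNA shares a standard-normal
#' factor with one immune gene, DE lncRNAs get a tumor-mean shift, and all
#' other genes are independent noise around gene-specific baselines.
#' Survival times for tumor samples come from a proportional-hazards model
#' whose linear predictor is `sum(beta * P)` over the planted pairs, with
#' `P` the binary ordering indicator computed from the generated
#' expression; censoring is independent uniform.
#'
#' @param spec a [simulation_spec()].
#' @return A list with elements `expr` (an [expression_matrix()]), `surv`
#'   (a [survival_table()]; `patient_id` equals the tumor sample id) and
#'   `truth` (planted facts: irlncRNA ids, DE ids and directions, planted
#'   pairs with gene ids and true betas, per-patient linear predictor,
#'   censoring horizon `tau`).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "SimulationSpec"))
  set.seed(spec$seed)
  n_s <- spec$n_tumor + spec$n_normal
  tumor_ids <- sprintf("P%04d", seq_len(spec$n_tumor))
  normal_ids <- sprintf("N%04d", seq_len(spec$n_normal))
  sample_ids <- c(tumor_ids, normal_ids)
  is_tumor <- c(rep(TRUE, spec$n_tumor), rep(FALSE, spec$n_normal))

  lnc_ids <- sprintf("LNC%04d", seq_len(spec$n_lncRNA))
  mrna_ids <- sprintf("GENE%04d", seq_len(spec$n_mRNA))
  gene_ids <- c(lnc_ids, mrna_ids)
  immune <- c(rep(FALSE, spec$n_lncRNA),
              seq_len(spec$n_mRNA) <= spec$n_immune_genes)
  biotype <- c(rep("lncRNA", spec$n_lncRNA), rep("mRNA", spec$n_mRNA))

  ir_idx <- seq_len(spec$n_irlnc)                   # lncRNA rows 1..n_irlnc
  de_idx <- seq_len(spec$n_de)                      # subset of ir_idx
  partner_idx <- spec$n_lncRNA + seq_len(spec$n_irlnc)  # immune gene rows

  mu <- stats::runif(length(gene_ids), 3, 7)
  # planted pair members share a baseline mean (plus any stated offset) so
  # their ordering indicator is informative rather than near-constant
  pp <- spec$planted_pairs
  if (nrow(pp) > 0) {
    for (k in seq_len(nrow(pp))) {
      mu[pp$b[k]] <- mu[pp$a[k]] - pp$mu_offset[k]
    }
  }

  logx <- matrix(stats::rnorm(length(gene_ids) * n_s, 0, spec$noise_sd),
                 nrow = length(gene_ids), ncol = n_s,
                 dimnames = list(gene_ids, sample_ids))
  # genes without a latent factor carry the factor variance as extra noise,
  # keeping marginal variances comparable across genes
  extra <- sqrt(spec$factor_sd^2) *
    matrix(stats::rnorm(length(gene_ids) * n_s), length(gene_ids), n_s)
  logx <- logx + extra
  fac <- matrix(stats::rnorm(spec$n_irlnc * n_s, 0, spec$factor_sd),
                nrow = spec$n_irlnc, ncol = n_s)
  logx[ir_idx, ] <- matrix(stats::rnorm(spec$n_irlnc * n_s, 0, spec$noise_sd),
                           spec$n_irlnc, n_s) + fac
  logx[partner_idx, ] <- matrix(stats::rnorm(spec$n_irlnc * n_s, 0,
                                             spec$noise_sd),
                                spec$n_irlnc, n_s) + fac
  logx <- logx + mu

  de_sign <- rep(-1, spec$n_de)
  de_sign[seq_len(ceiling(spec$de_up_fraction * spec$n_de))] <- 1
  # pair members must share their DE direction or the shift would push the
  # pair indicator out of the validity band in tumors
  if (nrow(pp) > 0) {
    for (k in seq_len(nrow(pp))) de_sign[pp$b[k]] <- de_sign[pp$a[k]]
  }
  logx[de_idx, is_tumor] <- logx[de_idx, is_tumor] +
    de_sign * spec$de_shift

  values <- 2^logx

  gene_meta <- data.frame(gene_id = gene_ids, biotype = biotype,
                          immune_flag = immune, stringsAsFactors = FALSE)
  expr <- expression_matrix(values,
                            ifelse(is_tumor, "tumor", "normal"), gene_meta)

  # linear predictor from the planted pair indicators (tumor samples)
  eta <- rep(0, spec$n_tumor)
  pair_truth <- data.frame(gene_a = character(0), gene_b = character(0),
                           beta = numeric(0))
  if (nrow(pp) > 0) {
    for (k in seq_len(nrow(pp))) {
      a <- lnc_ids[pp$a[k]]; b <- lnc_ids[pp$b[k]]
      P <- as.numeric(values[a, tumor_ids] > values[b, tumor_ids])
      eta <- eta + pp$beta[k] * P
      pair_truth <- rbind(pair_truth,
                          data.frame(gene_a = a, gene_b = b,
                                     beta = pp$beta[k]))
    }
  }

  rate <- spec$baseline_rate * exp(eta)
  u <- stats::runif(spec$n_tumor)
  t_event <- if (spec$weibull_shape == 1) -log(u) / rate else
    (-log(u) / rate)^(1 / spec$weibull_shape)

  if (spec$censor_rate > 0) {
    tau <- censor_horizon(rate, spec$censor_rate, spec$weibull_shape)
    c_time <- stats::runif(spec$n_tumor, 0, tau)
  } else {
    tau <- Inf
    c_time <- rep(Inf, spec$n_tumor)
  }
  time <- pmin(t_event, c_time)
  event <- as.integer(t_event <= c_time)
  time <- pmax(time, 1)  # follow-up recorded in whole days, at least 1

  age <- pmin(pmax(round(stats::rnorm(spec$n_tumor, 61, 11)), 25), 90)
  gender <- sample(c("male", "female"), spec$n_tumor, TRUE, c(0.7, 0.3))
  grade <- sample(c("G1", "G2", "G3"), spec$n_tumor, TRUE, c(0.2, 0.5, 0.3))
  stage <- sample(c("I", "II", "III", "IV"), spec$n_tumor, TRUE,
                  c(0.10, 0.10, 0.25, 0.55))
  surv <- survival_table(tumor_ids, time, event, age, gender, grade, stage)

  truth <- list(
    irlnc_ids = lnc_ids[ir_idx],
    de_ids = lnc_ids[de_idx],
    de_direction = ifelse(de_sign > 0, "up", "down"),
    planted_pairs = pair_truth,
    eta = stats::setNames(eta, tumor_ids),
    baseline_rate = spec$baseline_rate,
    censor_tau = tau,
    seed = spec$seed
  )
  list(expr = expr, surv = surv, truth = truth)
}

# Solve for the uniform-censoring horizon tau giving the target expected
# censoring fraction under per-subject exponential (or Weibull) event times.
censor_horizon <- function(rate, censor_rate, shape = 1) {
  pcens <- function(tau) {
    if (shape == 1) {
      mean((1 - exp(-rate * tau)) / (rate * tau))
    } else {
      # numeric integral of P(T > c) over c ~ U(0, tau)
      mean(vapply(rate, function(r) {
        stats::integrate(function(c) exp(-r * c^shape), 0, tau)$value / tau
      }, numeric(1)))
    }
  }
  stats::uniroot(function(tau) pcens(tau) - censor_rate,
                 lower = 1e-3, upper = 1e8, tol = 1e-6)$root
}

#' Write a simulated cohort to a directory
#'
#' Persists the three expression TSVs, the clinical TSV, and the truth
#' record as JSON, so downstream stages can be run and tested in isolation.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if missing).
#' @return The file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("expression.tsv", "gene_meta.tsv",
                            "sample_groups.tsv", "clinical.tsv",
                            "truth.json"))
  write_expression(cohort$expr, paths[1], paths[2], paths[3])
  write_survival(cohort$surv, paths[4])
  truth <- cohort$truth
  truth$eta <- as.list(truth$eta)
  jsonlite::write_json(truth, paths[5], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}
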