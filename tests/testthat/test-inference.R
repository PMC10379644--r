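# Hierarchical model construction, the joint log-density oracle, R-hat,
# sampler determinism and the shared likelihood code path.

test_that("the model enumerates fifteen free parameters per participant", {
  study <- simulate_study(small_spec(2, 2, 1), seed = 61)
  model <- build_model(study$trials)
  expect_identical(length(model$param_names), 15L)
  expect_identical(model$param_names,
                   c(drift_names(), "logA", "logk", "logt0"))
})

test_that("malformed trial tables are rejected with cell diagnostics", {
  study <- simulate_study(small_spec(2, 2, 1), seed = 62)
  tr <- study$trials
  expect_error(build_model(tr[tr$condition != "Med" | tr$group != "CI", ]),
               "empty design cells")
  bad <- tr; bad$condition[1] <- "Impossible"
  expect_error(build_model(bad), "unknown condition")
  bad <- tr; bad$rt_seconds[which(!bad$missing)[1]] <- 3.5
  expect_error(build_model(bad), "deadline")
  bad <- tr; bad$rt_seconds[which(!bad$missing)[1]] <- -1
  expect_error(build_model(bad), "positive rt_seconds")
})

test_that("model log-density matches an independently assembled prior + likelihood", {
  study <- simulate_study(small_spec(2, 1, 1), seed = 63)
  model <- build_model(study$trials)
  pr <- model$priors
  n <- nrow(model$participants)
  set.seed(64)
  theta <- matrix(c(rnorm(n * 12, 2.5, 0.3), rnorm(n, 0, 0.1),
                    rnorm(n, 0.5, 0.1), log(runif(n, 0.1, 0.2))), n, 15)
  mu <- rbind(c(rnorm(12, 2.5, 0.2), 0, 0.4, -1.7),
              c(rnorm(12, 2.5, 0.2), 0, 0.4, -1.7))
  sigma <- list(diag(runif(15, 0.2, 0.5)), diag(runif(15, 0.2, 0.5)))
  nmis <- model$n_missing
  tau <- rep(3.5, nmis)
  got <- model$log_posterior(theta, mu, sigma, tau)
  # oracle: likelihood via lba_log_likelihood per participant, multivariate
  # normal and inverse-Wishart densities assembled from first principles
  ldmvn <- function(x, m, S)
    -0.5 * (length(m) * log(2 * pi) + determinant(S)$modulus +
              t(x - m) %*% solve(S) %*% (x - m))
  ldiw <- function(S, nu, S0) {
    p <- ncol(S)
    lmg <- sum(lgamma((nu + 1 - 1:p) / 2)) + p * (p - 1) / 4 * log(pi)
    (nu / 2) * determinant(S0)$modulus - (nu * p / 2) * log(2) - lmg -
      ((nu + p + 1) / 2) * determinant(S)$modulus -
      0.5 * sum(diag(solve(S) %*% S0))
  }
  want <- 0
  mis_seen <- 0
  for (i in seq_len(n)) {
    rows <- study$trials$participant_id == model$participants$participant_id[i]
    tri <- study$trials[rows, ]
    nm <- sum(tri$missing)
    pars <- lba_params(exp(theta[i, 13]), exp(theta[i, 14]), exp(theta[i, 15]),
                       v = stats::setNames(theta[i, 1:12], drift_names()))
    want <- want + as.numeric(lba_log_likelihood(
      tri, pars, latent_missing_rts = tau[seq_len(nm) + mis_seen]))
    mis_seen <- mis_seen + nm
    g <- match(model$participants$group[i], model$groups)
    want <- want + as.numeric(ldmvn(theta[i, ], mu[g, ], sigma[[g]]))
  }
  for (g in 1:2)
    want <- want + as.numeric(ldiw(sigma[[g]], pr$nu0, pr$S0)) +
      as.numeric(ldmvn(mu[g, ], pr$m0, sigma[[g]] / pr$kappa0))
  expect_equal(got, want, tolerance = 1e-8)
})

test_that("sampler likelihood equals the lba_core path", {
  study <- simulate_study(small_spec(2, 2, 1), seed = 65)
  model <- build_model(study$trials)
  n <- nrow(model$participants)
  set.seed(66)
  theta <- matrix(c(rnorm(n * 12, 3, 0.5), rnorm(n, 0, 0.1), rnorm(n, 0.4, 0.1),
                    log(runif(n, 0.1, 0.2))), n, 15)
  tau <- rep(3.2, model$n_missing)
  by_p <- model$loglik_by_p(theta, tau)
  mis_seen <- 0
  for (i in seq_len(n)) {
    tri <- study$trials[study$trials$participant_id ==
                          model$participants$participant_id[i], ]
    nm <- sum(tri$missing)
    pars <- lba_params(exp(theta[i, 13]), exp(theta[i, 14]), exp(theta[i, 15]),
                       v = stats::setNames(theta[i, 1:12], drift_names()))
    expect_equal(by_p[i], as.numeric(lba_log_likelihood(
      tri, pars, latent_missing_rts = tau[seq_len(nm) + mis_seen])),
      tolerance = 1e-10)
    mis_seen <- mis_seen + nm
  }
})

test_that("compiled and reference defective densities agree", {
  set.seed(67)
  td <- c(-0.5, 0, runif(20, 0.05, 3))
  A <- 0.8; b <- 2.3; vw <- 3.1; vl <- 0.7
  got <- listeff:::.log_defective(td, A, b, vw, vl)
  ref <- log(pmax(lba_pdf(td, A, b, vw) * (1 - lba_cdf(td, A, b, vl)), 1e-300))
  ref[td <= 0] <- -Inf
  expect_equal(got, ref, tolerance = 1e-10)
})

test_that("split rank-normalized R-hat behaves as a convergence diagnostic", {
  expect_true(is.na(rhat(list(rep(1, 100), rep(1, 100)))))
  set.seed(68)
  same <- lapply(1:4, function(i) rnorm(10000))
  expect_lt(rhat(same), 1.01)
  shifted <- list(rnorm(1000), rnorm(1000) + 5)
  expect_gt(rhat(shifted), 1.2)
  # within-chain trend is also caught by splitting
  trend <- list(cumsum(rnorm(1000, 0.01)), cumsum(rnorm(1000, 0.01)))
  expect_gt(rhat(trend), 1.05)
  expect_error(rhat(list(rnorm(100))), "two chains")
  expect_error(rhat(list(rnorm(3), rnorm(3))), "4 draws")
})

test_that("a fixed seed reproduces draws exactly and counts are honoured", {
  fit <- tiny_fit()
  dr <- fit$draws
  expect_identical(n_draws(dr), 200L)
  expect_identical(length(dr$chains), 2L)
  study <- fit$study
  dr2 <- suppressWarnings(
    sample_posterior(fit$model, chains = 2, warmup = 100, iters = 100,
                     seed = 9, mh_sweeps = 2))
  expect_identical(dr$chains, dr2$chains)
  # tidy export covers every stored parameter
  df <- as.data.frame(dr)
  expect_identical(sort(unique(df$parameter)), sort(dr$param_names))
  expect_identical(nrow(df), 200L * length(dr$param_names))
})

test_that("posterior predictive simulation reports cell discrepancies", {
  fit <- tiny_fit()
  pp <- posterior_predictive(fit$draws, fit$study$trials, n_draws = 10, seed = 2)
  expect_identical(nrow(pp$cells), 12L)
  expect_true(is.finite(pp$mean_abs_rt_discrepancy))
  expect_true(all(is.finite(pp$cells$predicted_mean_rt)))
  # on a self-fit, predictions track the data at coarse tolerance
  expect_lt(pp$mean_abs_rt_discrepancy, 0.25)
})

test_that("draws persist as tidy CSV with a diagnostics sidecar", {
  fit <- tiny_fit()
  td <- withr::local_tempdir()
  write_draws(fit$draws, file.path(td, "draws.csv"), file.path(td, "diag.json"))
  back <- utils::read.csv(file.path(td, "draws.csv"))
  expect_identical(names(back), c("chain", "iter", "parameter", "value"))
  expect_identical(nrow(back), 200L * length(fit$draws$param_names))
  diag <- jsonlite::read_json(file.path(td, "diag.json"))
  expect_identical(diag$settings$chains, 2L)
  expect_true(all(fit$draws$param_names %in% names(diag$rhat)))
})

test_that("both proposal parameterizations target the same posterior", {
  spec <- design_spec(n_ci = 2, n_nh = 2, runs_per_participant = 1,
                      partial_completers = data.frame(
                        participant_id = character(0),
                        runs_completed = integer(0)))
  study <- simulate_study(spec, seed = 81)
  model <- build_model(study$trials)
  d1 <- suppressWarnings(
    sample_posterior(model, chains = 2, warmup = 200, iters = 800, seed = 5,
                     mh_sweeps = 4, proposal = "adaptive"))
  d2 <- suppressWarnings(
    sample_posterior(model, chains = 2, warmup = 200, iters = 800, seed = 6,
                     mh_sweeps = 4, proposal = "group-scaled"))
  m1 <- draws_matrix(d1, "^mu\\."); m2 <- draws_matrix(d2, "^mu\\.")
  # marginals agree in distribution up to Monte Carlo noise: most
  # correct-drift KS statistics small, all group-level means within a
  # fraction of their posterior spread
  ks <- vapply(grep("v\\.correct", colnames(m1), value = TRUE), function(p)
    suppressWarnings(stats::ks.test(m1[, p], m2[, p]))$statistic, numeric(1))
  # two independent MCMC runs of this length have KS noise of ~0.1 at the
  # chains' effective sample sizes; agreement is asserted at that precision
  expect_lt(median(ks), 0.1)
  expect_lt(max(ks), 0.2)
  sds <- apply(m1, 2, sd)
  expect_lt(max(abs(colMeans(m1) - colMeans(m2)) / pmax(sds, 0.05)), 1)
})
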