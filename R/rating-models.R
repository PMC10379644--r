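# Ordered beta regression for bounded visual-analog ratings: the response is
# a three-part mixture with point masses at exactly 0 and 1 governed by two
# ordered cutpoints on a latent logistic scale, and a beta-distributed
# continuous interior with mean logistic(eta) and precision phi. Also the
# unequal-variance Gaussian group model used for unbounded outcomes.

.check_ordbeta <- function(c1, c2, phi) {
  if (any(!(c1 < c2))) stop("cutpoints must satisfy c1 < c2")
  if (any(phi <= 0)) stop("phi must be positive")
}

#' Ordered beta log-density
#'
#' `P(y = 0) = 1 - logistic(eta - c1)`, `P(y = 1) = logistic(eta - c2)`, and
#' for `0 < y < 1` the density is
#' `[logistic(eta - c1) - logistic(eta - c2)] * Beta(y; mu*phi, (1-mu)*phi)`
#' with `mu = logistic(eta)`. The two point masses plus the continuous part
#' integrate to one for every `eta`.
#'
#' @param y Responses in `[0, 1]` (vectorized; 0 and 1 are genuine values).
#' @param eta Linear predictor (logit scale).
#' @param c1,c2 Ordered cutpoints, `c1 < c2`.
#' @param phi Beta precision (> 0).
#' @param log Return the log density/mass (default TRUE).
#' @return Log density/mass per observation.
#' @export
ordered_beta_loglik <- function(y, eta, c1, c2, phi, log = TRUE) {
  .check_ordbeta(c1, c2, phi)
  if (any(y < 0 | y > 1, na.rm = TRUE)) stop("ratings must lie in [0, 1]")
  p_low  <- stats::plogis(eta - c1)   # P(y > 0)
  p_high <- stats::plogis(eta - c2)   # P(y = 1)
  mu <- stats::plogis(eta)
  ll <- numeric(length(y))
  at0 <- y == 0; at1 <- y == 1; mid <- !at0 & !at1
  # recycle-safe indexing (eta may be scalar or per-observation)
  r <- function(x, idx) if (length(x) == 1) rep(x, sum(idx)) else x[idx]
  ll[at0] <- log(pmax(1 - r(p_low, at0), 1e-300))
  ll[at1] <- log(pmax(r(p_high, at1), 1e-300))
  if (any(mid)) {
    mu_m <- r(mu, mid); pm <- r(p_low, mid) - r(p_high, mid)
    ll[mid] <- log(pmax(pm, 1e-300)) +
      stats::dbeta(y[mid], mu_m * phi, (1 - mu_m) * phi, log = TRUE)
  }
  if (log) ll else exp(ll)
}

#' Sample from the ordered beta distribution
#'
#' @inheritParams ordered_beta_loglik
#' @param n Number of draws; `eta` is recycled to length `n`.
#' @return Numeric vector in `[0, 1]` including exact 0s and 1s.
#' @export
rordbeta <- function(n, eta, c1, c2, phi) {
  .check_ordbeta(c1, c2, phi)
  eta <- rep_len(eta, n)
  p_low <- stats::plogis(eta - c1); p_high <- stats::plogis(eta - c2)
  u <- stats::runif(n)
  mu <- stats::plogis(eta)
  y <- stats::rbeta(n, mu * phi, (1 - mu) * phi)
  y[u < 1 - p_low] <- 0
  y[u > 1 - p_high] <- 1
  y
}

#' Expected value of an ordered beta response
#'
#' `E[y] = P(y = 1) + P(0 < y < 1) * logistic(eta)`.
#'
#' @inheritParams ordered_beta_loglik
#' @return Expected rating in `[0, 1]`.
#' @export
ordered_beta_mean <- function(eta, c1, c2, phi = NULL) {
  if (!all(c1 < c2)) stop("cutpoints must satisfy c1 < c2")
  p_low <- stats::plogis(eta - c1); p_high <- stats::plogis(eta - c2)
  p_high + (p_low - p_high) * stats::plogis(eta)
}

# --- Bayesian ordered beta cell-means model ---------------------------------
# ratings ~ 0 + Group:Condition with participant random intercepts whose SD
# is group-specific. Estimated by adaptive random-walk Metropolis within
# Gibbs blocks: (cell coefficients, cutpoints, log phi) jointly, then all
# random intercepts (independent accept/reject per participant), then the
# group intercept SDs.

#' Fit the ordered beta rating model
#'
#' Bayesian cell-means model for one question's ratings: fixed effects for
#' every group x condition cell, participant random intercepts with
#' group-specific SDs, ordered beta likelihood. Priors: Normal(0, 5) on cell
#' coefficients and (induced-ordering) cutpoints, exponential(0.1) on the
#' beta precision, half-normal(0, 1) on the random-intercept SDs.
#'
#' @param ratings data.frame with `participant_id`, `group`, `condition`,
#'   `rating` (one question; rows with missing ratings are dropped).
#' @param chains,warmup,iters MCMC settings.
#' @param seed Integer seed.
#' @return List with `cell_means` (posterior mean and 95% CrI of each
#'   group x condition mean on the response scale), `draws` (matrix of cell
#'   mean draws), `rhat`, and acceptance diagnostics.
#' @export
fit_rating_model <- function(ratings, chains = 2, warmup = 500, iters = 500,
                             seed = 1) {
  ratings <- ratings[!is.na(ratings$rating), , drop = FALSE]
  cells <- expand.grid(group = sort(unique(ratings$group)),
                       condition = unique(ratings$condition),
                       stringsAsFactors = FALSE)
  cell_key <- paste(cells$group, cells$condition)
  obs_cell <- match(paste(ratings$group, ratings$condition), cell_key)
  if (anyNA(obs_cell)) stop("unmatched group/condition cell")
  if (!all(seq_len(nrow(cells)) %in% obs_cell))
    stop("every group x condition cell must be observed")
  pid <- factor(ratings$participant_id)
  pidx <- as.integer(pid)
  np <- nlevels(pid)
  pgroup <- ratings$group[match(levels(pid), ratings$participant_id)]
  grp_levels <- sort(unique(ratings$group))
  pgi <- match(pgroup, grp_levels)
  y <- ratings$rating
  nc <- nrow(cells)

  loglik <- function(beta, c1, c2, phi, u) {
    if (!(c1 < c2) || phi <= 0) return(-Inf)
    sum(ordered_beta_loglik(y, beta[obs_cell] + u[pidx], c1, c2, phi))
  }
  # per-participant likelihood sums, for vectorized intercept updates
  ll_by_p <- function(beta, c1, c2, phi, u) {
    lv <- ordered_beta_loglik(y, beta[obs_cell] + u[pidx], c1, c2, phi)
    as.numeric(rowsum(lv, pidx, reorder = TRUE))
  }
  lprior_fix <- function(beta, c1, gap, lphi) {
    sum(stats::dnorm(beta, 0, 5, log = TRUE)) +
      stats::dnorm(c1, 0, 5, log = TRUE) + stats::dnorm(c1 + exp(gap), 0, 5, log = TRUE) + gap +
      stats::dexp(exp(lphi), 0.1, log = TRUE) + lphi
  }

  run_chain <- function(ch) {
    set.seed(seed + 1000L * ch)
    beta <- stats::qlogis(pmin(pmax(tapply(y, obs_cell, mean), 0.02), 0.98))
    beta <- as.numeric(beta)
    c1 <- -3; gap <- log(6); lphi <- log(5)
    u <- rep(0, np); lsig <- rep(log(0.5), length(grp_levels))
    th <- c(beta, c1, gap, lphi)
    d <- length(th)
    scale_f <- 0.2; cov_f <- diag(d)
    hist_f <- matrix(0, warmup, d)
    scale_u <- rep(0.3, np)
    out <- matrix(NA_real_, iters, nc + 2 + length(grp_levels))
    cur_ll <- loglik(beta, c1, c1 + exp(gap), exp(lphi), u)
    cur_lp <- cur_ll + lprior_fix(beta, c1, gap, lphi)
    acc_f <- 0; tot_f <- 0
    cf <- chol(cov_f)
    for (it in seq_len(warmup + iters)) {
      # fixed-effects block
      for (s in 1:2) {
        prop <- th + scale_f * drop(crossprod(cf, stats::rnorm(d)))
        pb <- prop[1:nc]; pc1 <- prop[nc + 1]; pgap <- prop[nc + 2]; plphi <- prop[nc + 3]
        pll <- loglik(pb, pc1, pc1 + exp(pgap), exp(plphi), u)
        plp <- pll + lprior_fix(pb, pc1, pgap, plphi)
        tot_f <- tot_f + 1
        if (is.finite(plp) && log(stats::runif(1)) < plp - cur_lp) {
          th <- prop; beta <- pb; c1 <- pc1; gap <- pgap; lphi <- plphi
          cur_ll <- pll; cur_lp <- plp; acc_f <- acc_f + 1
        }
      }
      # random intercepts, independent proposals per participant
      c2v <- c1 + exp(gap); phiv <- exp(lphi)
      llp <- ll_by_p(beta, c1, c2v, phiv, u)
      up <- u + stats::rnorm(np, 0, scale_u)
      llq <- ll_by_p(beta, c1, c2v, phiv, up)
      lr <- (llq + stats::dnorm(up, 0, exp(lsig[pgi]), log = TRUE)) -
            (llp + stats::dnorm(u, 0, exp(lsig[pgi]), log = TRUE))
      acc <- log(stats::runif(np)) < lr
      u[acc] <- up[acc]
      if (it <= warmup) scale_u <- scale_u * exp(0.5 * (mean(acc) - 0.35) / sqrt(it))
      # group SDs (log scale, half-normal(0,1) prior on sd)
      for (g in seq_along(grp_levels)) {
        prop <- lsig[g] + stats::rnorm(1, 0, 0.3)
        ug <- u[pgi == g]
        lr <- sum(stats::dnorm(ug, 0, exp(prop), log = TRUE)) -
              sum(stats::dnorm(ug, 0, exp(lsig[g]), log = TRUE)) +
              (stats::dnorm(exp(prop), 0, 1, log = TRUE) + prop) -
              (stats::dnorm(exp(lsig[g]), 0, 1, log = TRUE) + lsig[g])
        if (log(stats::runif(1)) < lr) lsig[g] <- prop
      }
      cur_ll <- loglik(beta, c1, c1 + exp(gap), exp(lphi), u)
      cur_lp <- cur_ll + lprior_fix(beta, c1, gap, lphi)
      if (it <= warmup) {
        hist_f[it, ] <- th
        if (it %in% c(100, 250, warmup) && it >= 50) {
          cov_emp <- stats::cov(hist_f[seq_len(it), , drop = FALSE])
          cov_f <- cov_emp + diag(1e-6, d)
          cf <- chol(cov_f)
          scale_f <- 2.38 / sqrt(d)
        }
        rate <- acc_f / max(tot_f, 1)
        scale_f <- scale_f * exp(0.5 * (rate - 0.25) / sqrt(it))
      } else {
        cm <- ordered_beta_mean(beta, c1, c1 + exp(gap))
        out[it - warmup, ] <- c(cm, c1, c1 + exp(gap), exp(lsig))
      }
    }
    colnames(out) <- c(paste0("mean.", gsub(" ", ".", cell_key)), "c1", "c2",
                       paste0("sd.", grp_levels))
    out
  }
  ch <- lapply(seq_len(chains), run_chain)
  all <- do.call(rbind, ch)
  cm_cols <- seq_len(nc)
  cell_means <- data.frame(cells,
    mean = colMeans(all[, cm_cols, drop = FALSE]),
    t(apply(all[, cm_cols, drop = FALSE], 2, function(x) {
      h <- hdi(x); c(lower = h[1], upper = h[2]) })))
  names(cell_means)[4:5] <- c("lower", "upper")
  rh <- vapply(colnames(all), function(p)
    rhat(lapply(ch, function(m) m[, p])), numeric(1))
  list(cell_means = cell_means, draws = all, rhat = rh,
       settings = list(chains = chains, warmup = warmup, iters = iters, seed = seed))
}

#' Unequal-variance Gaussian group comparison
#'
#' Independent Gaussian models per group with group-specific variances and
#' flat priors on the means (Jeffreys prior on each variance); the posterior
#' is sampled exactly (scaled inverse-chi-square variance, conditional normal
#' mean), no MCMC needed.
#'
#' @param outcome Numeric outcome values.
#' @param group Group label per observation (two or more groups, >= 2
#'   observations each).
#' @param ndraws Number of posterior draws (default 8000).
#' @param seed Integer seed.
#' @return List with per-group posterior summaries (`mean`, `sd`, 95% CrIs),
#'   the matrix of mean draws, and pairwise group-difference summaries.
#' @export
fit_gaussian_unequal <- function(outcome, group, ndraws = 8000, seed = 1) {
  set.seed(seed)
  g <- factor(group)
  if (any(table(g) < 2)) stop("each group needs at least 2 observations")
  draws_mu <- sapply(levels(g), function(lev) {
    y <- outcome[g == lev]; n <- length(y)
    s2 <- stats::var(y)
    sig2 <- (n - 1) * s2 / stats::rchisq(ndraws, n - 1)
    stats::rnorm(ndraws, mean(y), sqrt(sig2 / n))
  })
  draws_sd <- sapply(levels(g), function(lev) {
    y <- outcome[g == lev]; n <- length(y)
    sqrt((n - 1) * stats::var(y) / stats::rchisq(ndraws, n - 1))
  })
  summ <- function(m) data.frame(
    group = colnames(m), mean = colMeans(m),
    lower = apply(m, 2, function(x) hdi(x)[1]),
    upper = apply(m, 2, function(x) hdi(x)[2]), row.names = NULL)
  diffs <- NULL
  if (nlevels(g) >= 2) {
    cmb <- utils::combn(levels(g), 2)
    diffs <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(j) {
      d <- draws_mu[, cmb[1, j]] - draws_mu[, cmb[2, j]]
      h <- hdi(d)
      data.frame(contrast = paste(cmb[1, j], "-", cmb[2, j]),
                 mean = mean(d), lower = h[1], upper = h[2])
    }))
  }
  list(mean = summ(draws_mu), sd = summ(draws_sd), difference = diffs,
       draws_mean = draws_mu, draws_sd = draws_sd)
}
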