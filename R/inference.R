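# Hierarchical Bayesian LBA estimation. Individual parameter vectors
# (12 drift means on the natural scale, log A, log k, log t0) follow a
# multivariate normal population distribution per group with a conjugate
# Normal-Inverse-Wishart prior, so group-level means and covariances are
# Gibbs-updated exactly; individual vectors move by adaptive random-walk
# Metropolis against the trial-level LBA likelihood; deadline-censored
# trials carry latent response times updated by Metropolis on a log-offset
# scale and contribute a chance-level (0.5/0.5) defective-density mixture.

#' Parameter names of one participant's vector
#'
#' The fifteen free parameters per participant: twelve drift-rate means
#' (2 responses x 3 conditions x 2 trial types, natural scale) plus
#' `logA`, `logk`, `logt0`.
#'
#' @return Character vector of length 15.
#' @export
lba_param_names <- function() c(drift_names(), "logA", "logk", "logt0")

#' Priors for the hierarchical LBA
#'
#' Conjugate Normal-Inverse-Wishart prior on each group's population mean
#' and covariance: `Sigma_g ~ IW(nu0, S0)`, `mu_g | Sigma_g ~
#' N(m0, Sigma_g / kappa0)`. Defaults are weakly informative but calibrated
#' to plausible between-participant variation: drift group means centred at
#' 2.5 with prior SD 2 and prior individual SD 1; structural parameters on
#' the log scale with group means `A ~ 1`, `k ~ 2`, `t0 ~ 0.25 s` (prior SD
#' 0.4 each) and prior individual SDs of 0.2 — non-decision times and
#' start-point ranges do not plausibly vary by an order of magnitude within
#' a screened adult cohort.
#'
#' @param m0 Prior mean vector (length 15, ordered as [lba_param_names()]).
#' @param kappa0 Prior pseudo-count for the mean (> 0).
#' @param nu0 Inverse-Wishart degrees of freedom (> 16 for a finite mean).
#' @param S0 Inverse-Wishart scale matrix (15 x 15 positive definite).
#' @return A `lba_priors` object.
#' @export
lba_priors <- function(m0 = c(rep(2.5, 12), 0, log(2), log(0.25)),
                       kappa0 = 0.25, nu0 = 17,
                       S0 = diag(c(rep(1, 12), 0.04, 0.04, 0.04))) {
  stopifnot(length(m0) == 15, kappa0 > 0, nu0 > 14, all(dim(S0) == c(15, 15)))
  structure(list(m0 = m0, kappa0 = kappa0, nu0 = nu0, S0 = S0),
            class = "lba_priors")
}

#' Build the hierarchical LBA model
#'
#' Validates the trial table, indexes it for fast vectorized likelihood
#' evaluation, and bundles priors and configuration. Every
#' group x condition x trial-type cell must contain observations.
#'
#' @param trials Trial records (see [simulate_behavior()] / [read_trials()]):
#'   columns `participant_id`, `group`, `condition`, `trial_type`, `correct`,
#'   `rt_seconds`, `missing`.
#' @param priors An `lba_priors` object.
#' @param deadline Response deadline in seconds (default 3).
#' @param cap Upper bound for latent missing RTs (default 10 s).
#' @param structural `"hierarchical"` (A, k, t0 vary over participants within
#'   group) or `"shared"` (single A, k, t0 value per group).
#' @return An `lba_model` object; `$param_names` enumerates the 15 free
#'   parameters per participant and `$log_posterior(theta, mu, sigma, tau)`
#'   evaluates the joint log density for oracle checks.
#' @export
build_model <- function(trials, priors = lba_priors(), deadline = 3, cap = 10,
                        structural = c("hierarchical", "shared")) {
  structural <- match.arg(structural)
  req <- c("participant_id", "group", "condition", "trial_type", "correct",
           "rt_seconds", "missing")
  miss <- setdiff(req, names(trials))
  if (length(miss)) stop("trials lack columns: ", paste(miss, collapse = ", "))
  bad_cond <- setdiff(unique(trials$condition), .conditions)
  if (length(bad_cond)) stop("unknown condition labels: ", paste(bad_cond, collapse = ", "))
  bad_tt <- setdiff(unique(trials$trial_type), .trial_types)
  if (length(bad_tt)) stop("unknown trial_type labels: ", paste(bad_tt, collapse = ", "))
  cells <- expand.grid(group = unique(trials$group), condition = .conditions,
                       trial_type = .trial_types, stringsAsFactors = FALSE)
  have <- unique(paste(trials$group, trials$condition, trials$trial_type))
  empty <- setdiff(paste(cells$group, cells$condition, cells$trial_type), have)
  if (length(empty))
    stop("empty design cells (group condition trial_type): ",
         paste(empty, collapse = "; "))
  obs <- !trials$missing
  if (any(obs & (is.na(trials$rt_seconds) | trials$rt_seconds <= 0)))
    stop("observed trials must have positive rt_seconds")
  if (any(obs & trials$rt_seconds > deadline))
    stop("observed rt_seconds exceed the deadline; such trials must be missing")
  if (any(obs & is.na(trials$correct)))
    stop("observed trials must have correctness defined")

  pid <- factor(trials$participant_id, levels = unique(trials$participant_id))
  participants <- data.frame(participant_id = levels(pid),
                             group = trials$group[match(levels(pid), trials$participant_id)])
  groups <- unique(participants$group)
  gidx <- match(participants$group, groups)
  pnum <- as.integer(pid)
  vnames <- drift_names()
  col_c <- match(paste("v", "correct", trials$condition, trials$trial_type, sep = "."), vnames)
  col_i <- match(paste("v", "incorrect", trials$condition, trials$trial_type, sep = "."), vnames)

  oi <- which(obs); mi <- which(!obs)
  dat <- list(
    n = nrow(participants), n_groups = length(groups),
    pid_o = pnum[oi], rt_o = trials$rt_seconds[oi],
    corr_o = trials$correct[oi], cc_o = col_c[oi], ci_o = col_i[oi],
    pid_m = pnum[mi], cc_m = col_c[mi], ci_m = col_i[mi],
    min_rt = vapply(seq_len(nrow(participants)), function(i) {
      r <- trials$rt_seconds[obs & pnum == i]
      if (length(r)) min(r) else deadline
    }, numeric(1)))

  loglik_by_p <- function(theta, tau, obs_sel = NULL, mis_sel = NULL) {
    A <- exp(theta[, 13]); b <- A + exp(theta[, 14]); t0 <- exp(theta[, 15])
    po <- dat$pid_o; ro <- dat$rt_o; co <- dat$corr_o
    cco <- dat$cc_o; cio <- dat$ci_o
    if (!is.null(obs_sel)) {
      po <- po[obs_sel]; ro <- ro[obs_sel]; co <- co[obs_sel]
      cco <- cco[obs_sel]; cio <- cio[obs_sel]
    }
    vw <- ifelse(co, theta[cbind(po, cco)], theta[cbind(po, cio)])
    vl <- ifelse(co, theta[cbind(po, cio)], theta[cbind(po, cco)])
    ll <- numeric(dat$n)
    lo <- .log_defective(ro - t0[po], A[po], b[po], vw, vl)
    s <- rowsum(lo, po)
    ll[as.integer(rownames(s))] <- s
    pm <- dat$pid_m; ccm <- dat$cc_m; cim <- dat$ci_m; tm <- tau
    if (!is.null(mis_sel)) {
      pm <- pm[mis_sel]; ccm <- ccm[mis_sel]; cim <- cim[mis_sel]
      tm <- tau[mis_sel]
    }
    if (length(pm)) {
      lm <- .log_missing_mix(tm, A[pm], b[pm], theta[cbind(pm, ccm)],
                             theta[cbind(pm, cim)], t0[pm])
      s <- rowsum(lm, pm)
      ll[as.integer(rownames(s))] <- ll[as.integer(rownames(s))] + s
    }
    ll
  }
  # per-missing-trial chance-mixture log densities (for latent RT updates)
  loglik_missing <- function(theta, tau) {
    if (!length(dat$pid_m)) return(numeric(0))
    A <- exp(theta[, 13]); b <- A + exp(theta[, 14]); t0 <- exp(theta[, 15])
    .log_missing_mix(tau, A[dat$pid_m], b[dat$pid_m],
                     theta[cbind(dat$pid_m, dat$cc_m)],
                     theta[cbind(dat$pid_m, dat$ci_m)], t0[dat$pid_m])
  }

  ldmvnorm_rows <- function(X, mu, chol_sig) {
    z <- backsolve(chol_sig, t(X) - mu, transpose = TRUE)
    -0.5 * colSums(z^2) - sum(log(diag(chol_sig))) - 0.5 * 15 * log(2 * pi)
  }
  ldinvwish <- function(S, nu, S0) {
    p <- ncol(S)
    chS <- chol(S); chS0 <- chol(S0)
    lgamma_p <- sum(lgamma((nu + 1 - seq_len(p)) / 2)) + p * (p - 1) / 4 * log(pi)
    nu / 2 * 2 * sum(log(diag(chS0))) - (nu * p / 2) * log(2) - lgamma_p -
      (nu + p + 1) / 2 * 2 * sum(log(diag(chS))) -
      0.5 * sum(diag(chol2inv(chS) %*% S0))
  }
  log_posterior <- function(theta, mu, sigma, tau = numeric(0)) {
    lp <- sum(loglik_by_p(theta, tau))
    for (g in seq_along(groups)) {
      rows <- which(gidx == g)
      chs <- chol(sigma[[g]])
      lp <- lp + sum(ldmvnorm_rows(theta[rows, , drop = FALSE], mu[g, ], chs)) +
        ldinvwish(sigma[[g]], priors$nu0, priors$S0) +
        ldmvnorm_rows(matrix(mu[g, ], 1), priors$m0,
                      chol(sigma[[g]] / priors$kappa0))
    }
    lp
  }

  structure(list(dat = dat, participants = participants, groups = groups,
                 gidx = gidx, priors = priors, deadline = deadline, cap = cap,
                 structural = structural, param_names = lba_param_names(),
                 n_missing = length(mi),
                 loglik_by_p = loglik_by_p, loglik_missing = loglik_missing,
                 log_posterior = log_posterior),
            class = "lba_model")
}

#' @export
print.lba_model <- function(x, ...) {
  cat("Hierarchical LBA model:", x$dat$n, "participants in",
      length(x$groups), "groups;",
      length(x$dat$rt_o), "observed and", x$n_missing, "missing trials;",
      length(x$param_names), "free parameters per participant (",
      x$structural, " structural parameters)\n")
  invisible(x)
}

# initial individual parameter vector: crude method-of-moments drift guesses
.init_theta <- function(model) {
  dat <- model$dat
  n <- dat$n
  theta <- matrix(0, n, 15)
  theta[, 13] <- 0                     # A = 1
  theta[, 14] <- log(1.5)              # k = 1.5
  theta[, 15] <- log(pmax(0.5 * dat$min_rt, 0.02))
  b <- 2.5
  vinit <- matrix(2, n, 12)
  dtime <- dat$rt_o - exp(theta[dat$pid_o, 15])
  v_hat <- b / pmax(dtime, 0.05)
  # winner's cell gets the method-of-moments rate; use medians per (pid, col)
  wcol <- ifelse(dat$corr_o, dat$cc_o, dat$ci_o)
  agg <- tapply(v_hat, list(dat$pid_o, wcol), stats::median)
  ii <- as.integer(rownames(agg))
  for (j in seq_len(ncol(agg))) {
    cc <- as.integer(colnames(agg))[j]
    ok <- !is.na(agg[, j])
    vinit[ii[ok], cc] <- pmin(pmax(agg[ok, j], 0.5), 8)
  }
  theta[, 1:12] <- vinit
  theta
}

#' Sample the hierarchical LBA posterior
#'
#' MH-within-Gibbs: per retained iteration the sampler performs `mh_sweeps`
#' adaptive random-walk Metropolis refreshes of every participant's
#' 15-parameter vector (proposal covariance learned during warmup), a
#' Metropolis refresh of each latent missing RT on a log-offset scale above
#' the deadline, and exact conjugate Gibbs draws of each group's population
#' mean and covariance. Defaults (4 chains, 1,000 warmup, 2,000 sampling)
#' retain 8,000 draws.
#'
#' @param model An `lba_model` from [build_model()].
#' @param chains Number of chains (>= 1; >= 2 needed for R-hat).
#' @param warmup,iters Warmup and retained iterations per chain.
#' @param seed Integer seed; chains use derived substreams, so a fixed seed
#'   reproduces draws exactly.
#' @param mh_sweeps Metropolis refreshes of the individual vectors per
#'   iteration (more sweeps decorrelate successive draws).
#' @param proposal `"adaptive"` (empirical covariance learned in warmup) or
#'   `"group-scaled"` (proposals shaped by the current group covariance, the
#'   random-walk analogue of non-centred coordinates).
#' @param progress Print stage messages.
#' @return An `lba_draws` object: per-chain draw matrices over group-level
#'   means (`mu.<group>.<par>`), group-level individual SDs
#'   (`sd.<group>.<par>`) and individual vectors (`alpha.<id>.<par>`), R-hat
#'   per stored parameter, and sampler settings. A warning lists parameters
#'   whose R-hat falls outside [0.99, 1.01].
#' @export
sample_posterior <- function(model, chains = 4, warmup = 1000, iters = 2000,
                             seed = 1, mh_sweeps = 3,
                             proposal = c("adaptive", "group-scaled"),
                             progress = FALSE) {
  stopifnot(inherits(model, "lba_model"), chains >= 1, warmup >= 10, iters >= 2)
  proposal <- match.arg(proposal)
  dat <- model$dat; priors <- model$priors
  n <- dat$n; G <- length(model$groups); gidx <- model$gidx
  pn <- model$param_names
  shared <- model$structural == "shared"
  dH <- if (shared) 12L else 15L   # dimensionality of the hierarchical block
  col_names <- c(
    unlist(lapply(model$groups, function(g) paste("mu", g, pn[seq_len(dH)], sep = "."))),
    unlist(lapply(model$groups, function(g) paste("sd", g, pn[seq_len(dH)], sep = "."))),
    if (shared) unlist(lapply(model$groups, function(g) paste("mu", g, pn[13:15], sep = "."))),
    unlist(lapply(model$participants$participant_id,
                  function(p) paste("alpha", p, pn, sep = "."))))

  m0 <- priors$m0[seq_len(dH)]; S0 <- priors$S0[seq_len(dH), seq_len(dH)]
  kappa0 <- priors$kappa0
  nu0 <- if (shared) priors$nu0 - 3 else priors$nu0

  # precomputed winner/loser drift column per observed trial
  cw_o <- as.integer(ifelse(dat$corr_o, dat$cc_o, dat$ci_o))
  cl_o <- as.integer(ifelse(dat$corr_o, dat$ci_o, dat$cc_o))
  eval_obs <- function(theta, idx)
    .cpp_eval_obs(theta, dat$pid_o[idx], cw_o[idx], cl_o[idx],
                  dat$rt_o[idx], 1)
  eval_mis <- function(theta, tau, idx) {
    if (!length(idx)) return(numeric(0))
    .cpp_eval_mis(theta, dat$pid_m[idx], as.integer(dat$cc_m[idx]),
                  as.integer(dat$ci_m[idx]), tau[idx], 1)
  }
  sum_by_p <- function(v, pids) {
    out <- numeric(n)
    if (length(v)) {
      s <- rowsum(v, pids)
      out[as.integer(rownames(s))] <- s
    }
    out
  }
  # trial index sets per cell, group and group x cell
  cell_o <- (dat$cc_o + 1L) / 2L
  cell_m <- if (length(dat$cc_m)) (dat$cc_m + 1L) / 2L else integer(0)
  idx_cell_o <- lapply(1:6, function(j) which(cell_o == j))
  idx_cell_m <- lapply(1:6, function(j) which(cell_m == j))
  idx_g_o <- lapply(seq_len(G), function(g) which(gidx[dat$pid_o] == g))
  idx_g_m <- lapply(seq_len(G), function(g) which(gidx[dat$pid_m] == g))
  idx_gc_o <- lapply(seq_len(G), function(g)
    lapply(1:6, function(j) which(gidx[dat$pid_o] == g & cell_o == j)))
  idx_gc_m <- lapply(seq_len(G), function(g)
    lapply(1:6, function(j) which(gidx[dat$pid_m] == g & cell_m == j)))
  all_o <- seq_along(dat$pid_o); all_m <- seq_along(dat$pid_m)

  # Laplace preconditioning: per participant, a penalized MAP of the
  # 15-parameter vector against that participant's observed trials, with the
  # inverse curvature (plus prior-scale precision) as the initial Metropolis
  # proposal covariance. This puts every chain in the typical set at
  # iteration 1 with proposals already on the posterior scale.
  theta0 <- .init_theta(model)
  idx_p_o <- lapply(seq_len(n), function(i) which(dat$pid_o == i))
  prior_prec <- diag(c(rep(1.5, 12), 4, 4, 4))
  laplace <- lapply(seq_len(n), function(i) {
    io <- idx_p_o[[i]]
    pid1 <- rep(1L, length(io))
    nll <- function(th) {
      v <- .cpp_eval_obs(matrix(th, 1), pid1, cw_o[io], cl_o[io],
                         dat$rt_o[io], 1)
      s <- -sum(v) + 0.5 * sum(((th - theta0[i, ]) / 5)^2)
      if (is.finite(s)) s else 1e10
    }
    fit <- tryCatch(
      stats::optim(theta0[i, ], nll, method = "L-BFGS-B",
                   lower = c(rep(-10, 12), -4, -4, -7),
                   upper = c(rep(15, 12), 3, 3, log(0.98 * dat$min_rt[i])),
                   control = list(maxit = 300), hessian = TRUE),
      error = function(e) NULL)
    if (is.null(fit)) return(list(map = theta0[i, ], cov = diag(0.05, 15)))
    H <- (fit$hessian + t(fit$hessian)) / 2 + prior_prec
    e <- eigen(H, symmetric = TRUE)
    ev <- pmin(pmax(e$values, 0.5), 1e7)
    list(map = fit$par,
         cov = e$vectors %*% diag(1 / ev) %*% t(e$vectors))
  })
  theta_map <- do.call(rbind, lapply(laplace, `[[`, "map"))

  run_chain <- function(ch) {
    set.seed(as.integer((as.numeric(seed) * 1009 + ch * 7919) %% 2147483629))
    theta <- theta_map
    tau <- rep(model$deadline + 0.3, model$n_missing)
    if (shared) for (g in seq_len(G)) {
      rows <- gidx == g
      theta[rows, 13] <- mean(theta[rows, 13])
      theta[rows, 14] <- mean(theta[rows, 14])
      theta[rows, 15] <- min(theta[rows, 15])
    }
    mu <- matrix(0, G, dH)
    sig_chol <- vector("list", G)
    for (g in seq_len(G)) {
      Xg <- theta[gidx == g, seq_len(dH), drop = FALSE]
      mu[g, ] <- colMeans(Xg)
      v0 <- pmax(apply(Xg, 2, stats::var), c(rep(0.05, 12), 0.01, 0.01, 0.005)[seq_len(dH)])
      sig_chol[[g]] <- chol(diag(v0))
    }
    prior_rows <- function(th) {
      lp <- numeric(n)
      for (g in seq_len(G)) {
        rows <- which(gidx == g)
        z <- backsolve(sig_chol[[g]],
                       t(th[rows, seq_len(dH), drop = FALSE]) - mu[g, ],
                       transpose = TRUE)
        lp[rows] <- -0.5 * colSums(z^2) - sum(log(diag(sig_chol[[g]])))
      }
      lp
    }
    mu_logpost <- function(mv, g) {
      chk <- sig_chol[[g]] / sqrt(kappa0)
      -0.5 * sum(backsolve(chk, mv - m0, transpose = TRUE)^2)
    }
    # per-trial log-likelihood caches
    llt_o <- eval_obs(theta, all_o)
    llt_m <- eval_mis(theta, tau, all_m)
    ll <- sum_by_p(llt_o, dat$pid_o) + sum_by_p(llt_m, dat$pid_m)
    lpri <- prior_rows(theta)

    # --- adaptation state ---
    blocks <- c(lapply(seq(1, 11, 2), function(j) c(j, j + 1)),
                if (!shared) list(13:15))
    nb <- length(blocks)
    lsc <- matrix(log(1), n, nb)
    pchol <- lapply(blocks, function(bl)
      lapply(seq_len(n), function(i)
        chol((2.38^2 / length(bl)) *
               (laplace[[i]]$cov[bl, bl, drop = FALSE] +
                  diag(1e-7, length(bl))))))
    dJ <- if (shared) 12L else 15L
    lsc_full <- rep(log(1), n)
    pchol_full <- lapply(seq_len(n), function(i)
      chol((2.38^2 / dJ) * (laplace[[i]]$cov[seq_len(dJ), seq_len(dJ)] +
                              diag(1e-7, dJ))))
    Ssum <- matrix(0, n, 15); nad <- 0
    ij <- which(upper.tri(diag(15), diag = TRUE), arr.ind = TRUE)
    SS <- matrix(0, n, nrow(ij))
    acc_n <- rep(0, n); try_n <- 0
    nbT <- if (shared) 6L else 7L
    ijH <- which(upper.tri(diag(dH), diag = TRUE), arr.ind = TRUE)
    musum <- matrix(0, G, dH); muSS <- matrix(0, G, nrow(ijH))
    lts <- matrix(log(1), G, nbT)       # translation scales
    tchol <- lapply(seq_len(G), function(g)
      lapply(c(lapply(seq(1, 11, 2), function(j) c(j, j + 1)),
               if (!shared) list(13:15)), function(bl)
        chol(diag(c(rep(0.03, 12), 0.01, 0.01, 0.01))[bl, bl, drop = FALSE])))
    ltsR <- rep(log(0.05), G)           # grouped structural ridge scale
    lsh <- rep(log(0.02), G)            # shared-structural proposal scale
    lscS <- matrix(log(0.1), G, nbT)    # group-scaling move scales
    lsa <- rep(log(1), n)               # start-point-ratio walk scale
    lsc_tau <- log(0.4)
    gam <- function(it) min(0.5, 3 / sqrt(it))

    # accept a per-participant proposal restricted to trial subsets
    # returns updated state via <<- on theta, ll, lpri, llt_o, llt_m
    pp_accept <- function(prop, idxo, idxm, lpp, extra = 0) {
      new_o <- eval_obs(prop, idxo)
      new_m <- eval_mis(prop, tau, idxm)
      dll <- sum_by_p(new_o, dat$pid_o[idxo]) + sum_by_p(new_m, dat$pid_m[idxm]) -
             sum_by_p(llt_o[idxo], dat$pid_o[idxo]) -
             sum_by_p(llt_m[idxm], dat$pid_m[idxm])
      bad <- sum_by_p((!is.finite(new_o)) + 0, dat$pid_o[idxo]) +
             sum_by_p((!is.finite(new_m)) + 0, dat$pid_m[idxm])
      acc <- log(stats::runif(n)) < dll + (lpp - lpri) + extra
      acc[bad > 0] <- FALSE
      if (any(acc)) {
        theta[acc, ] <<- prop[acc, ]
        ll[acc] <<- ll[acc] + dll[acc]
        lpri[acc] <<- lpp[acc]
        keep_o <- acc[dat$pid_o[idxo]]
        llt_o[idxo[keep_o]] <<- new_o[keep_o]
        if (length(idxm)) {
          keep_m <- acc[dat$pid_m[idxm]]
          llt_m[idxm[keep_m]] <<- new_m[keep_m]
        }
      }
      acc
    }
    # accept a whole-group proposal (theta rows + mu) on trial subsets
    grp_accept <- function(g, prop, mup, idxo, idxm, lpp_rows = NULL, ljac = 0) {
      rows <- which(gidx == g)
      new_o <- eval_obs(prop, idxo)
      new_m <- eval_mis(prop, tau, idxm)
      if (any(!is.finite(new_o)) || any(!is.finite(new_m))) return(FALSE)
      dll <- sum(new_o) + sum(new_m) - sum(llt_o[idxo]) - sum(llt_m[idxm])
      dpri <- if (is.null(lpp_rows)) 0 else sum(lpp_rows - lpri[rows])
      lr <- dll + dpri + mu_logpost(mup, g) - mu_logpost(mu[g, ], g) + ljac
      if (!is.finite(lr) || log(stats::runif(1)) >= lr) return(FALSE)
      theta[rows, ] <<- prop[rows, ]
      mu[g, ] <<- mup
      if (!is.null(lpp_rows)) lpri[rows] <<- lpp_rows
      llt_o[idxo] <<- new_o
      llt_m[idxm] <<- new_m
      ll <<- sum_by_p(llt_o, dat$pid_o) + sum_by_p(llt_m, dat$pid_m)
      TRUE
    }
    draw_steps <- function(chols, scales, d) {
      z <- matrix(stats::rnorm(n * d), n, d)
      t(vapply(seq_len(n), function(i)
        exp(scales[i]) * drop(crossprod(chols[[i]], z[i, ])), numeric(d)))
    }
    # RT-preserving drift map for structural moves: given old/new caution
    # c = k + A/2 and the change in t0, map each drift so the accumulator's
    # mean RT t0 + c/v is unchanged: v' = c' v / (c + v dt0). Returns the
    # mapped drifts and the log-Jacobian sum(log(c' c) - 2 log(c + v dt0)),
    # or NULL when the map degenerates.
    rt_map <- function(v, c_old, c_new, dt0) {
      den <- c_old + v * dt0
      if (any(den <= 0.02)) return(NULL)
      list(v = c_new * v / den,
           ljac = sum(log(c_new * c_old) - 2 * log(den)))
    }

    out <- matrix(NA_real_, iters, length(col_names))
    for (it in seq_len(warmup + iters)) {
      for (sw in seq_len(mh_sweeps)) {
        # (A) per-participant cell-block moves, cell-restricted likelihood
        for (bi in 1:6) {
          bl <- blocks[[bi]]
          prop <- theta
          prop[, bl] <- prop[, bl] + draw_steps(pchol[[bi]], lsc[, bi], 2L)
          lpp <- prior_rows(prop)
          acc <- pp_accept(prop, idx_cell_o[[bi]], idx_cell_m[[bi]], lpp)
          acc_n <- acc_n + acc; try_n <- try_n + 1
          if (it <= warmup) lsc[, bi] <- lsc[, bi] + gam(it) * (acc - 0.3) / mh_sweeps
        }
        # (B) structural moves, rotating over three complementary variants:
        # ridge-aligned (drifts rescale with the threshold), plain, and a
        # caution-preserving start-point-ratio walk. The last moves the
        # likelihood-flat direction a = A/b at fixed caution c = k + A/2;
        # the (logit a, log c) -> (log A, log k) map has unit Jacobian.
        if (!shared) {
          bi <- 7L
          variant <- sw %% 3
          prop <- theta
          extra <- 0
          if (variant == 0) {
            Acur <- exp(theta[, 13]); kcur <- exp(theta[, 14])
            bcur <- Acur + kcur
            caution <- kcur + Acur / 2
            la <- stats::qlogis(Acur / bcur) + exp(lsa) * stats::rnorm(n)
            a2 <- stats::plogis(la)
            b2 <- caution / (1 - a2 / 2)
            prop[, 13] <- log(a2 * b2)
            prop[, 14] <- log(b2 * (1 - a2))
          } else {
            step <- draw_steps(pchol[[bi]], lsc[, bi], 3L)
            prop[, 13:15] <- prop[, 13:15] + step
            if (variant == 1) {
              # RT-preserving: drifts follow the caution/t0 change so each
              # accumulator's mean RT is invariant
              c_old <- exp(theta[, 14]) + exp(theta[, 13]) / 2
              c_new <- exp(prop[, 14]) + exp(prop[, 13]) / 2
              dt0 <- exp(theta[, 15]) - exp(prop[, 15])
              extra <- numeric(n)
              for (i in seq_len(n)) {
                m <- rt_map(theta[i, 1:12], c_old[i], c_new[i], dt0[i])
                if (is.null(m)) {
                  prop[i, ] <- theta[i, ] # degenerate map: null move
                  extra[i] <- 0
                } else {
                  prop[i, 1:12] <- m$v
                  extra[i] <- m$ljac
                }
              }
            }
          }
          lpp <- prior_rows(prop)
          acc <- pp_accept(prop, all_o, all_m, lpp, extra)
          acc_n <- acc_n + acc; try_n <- try_n + 1
          if (it <= warmup) {
            if (variant == 0) lsa <- lsa + gam(it) * (acc - 0.4) / mh_sweeps
            else lsc[, bi] <- lsc[, bi] + gam(it) * (acc - 0.3) / mh_sweeps
          }
        }
        # (C) joint learned-covariance move, every other sweep
        if (sw %% 2 == 0) {
          prop <- theta
          prop[, seq_len(dJ)] <- prop[, seq_len(dJ)] +
            draw_steps(pchol_full, lsc_full, dJ)
          lpp <- prior_rows(prop)
          acc <- pp_accept(prop, all_o, all_m, lpp)
          if (it <= warmup) lsc_full <- lsc_full + gam(it) * (acc - 0.25) / mh_sweeps
        }
      }
      # shared structural parameters: one (logA, logk, logt0) per group,
      # ridge-aligned (odd) or plain (even) variants twice per iteration
      if (shared) {
        for (variant in 1:2) for (g in seq_len(G)) {
          rows <- which(gidx == g)
          prop <- theta
          shift <- exp(lsh[g]) * stats::rnorm(3)
          prop[rows, 13:15] <- sweep(prop[rows, 13:15, drop = FALSE], 2, shift, "+")
          mup <- mu[g, ]
          ljac <- 0
          if (variant == 1) {
            r <- (exp(prop[rows[1], 13]) + exp(prop[rows[1], 14])) /
                 (exp(theta[rows[1], 13]) + exp(theta[rows[1], 14]))
            prop[rows, 1:12] <- theta[rows, 1:12, drop = FALSE] * r
            mup <- mu[g, ] * r
            ljac <- 12 * (length(rows) + 1) * log(r)
          }
          zz <- backsolve(sig_chol[[g]],
                          t(prop[rows, seq_len(dH), drop = FALSE]) - mup,
                          transpose = TRUE)
          lpp_rows <- -0.5 * colSums(zz^2) - sum(log(diag(sig_chol[[g]])))
          dpr <- sum(stats::dnorm(prop[rows[1], 13:15], 0, 1, log = TRUE)) -
                 sum(stats::dnorm(theta[rows[1], 13:15], 0, 1, log = TRUE))
          ok <- grp_accept(g, prop, mup, idx_g_o[[g]], idx_g_m[[g]],
                           lpp_rows, ljac + dpr)
          if (it <= warmup)
            lsh[g] <- lsh[g] + gam(it) * ((if (ok) 1 else 0) - 0.3)
        }
      }
      # latent missing RTs: log-offset Metropolis against the cached mixture
      if (model$n_missing) {
        u <- log(tau - model$deadline)
        up <- u + stats::rnorm(model$n_missing, 0, exp(lsc_tau))
        taup <- model$deadline + exp(up)
        lm_prop <- eval_mis(theta, taup, all_m)
        lr <- (lm_prop + up) - (llt_m + u)
        lr[taup >= model$cap] <- -Inf
        acc <- log(stats::runif(model$n_missing)) < lr
        if (any(acc)) {
          tau[acc] <- taup[acc]
          d <- rowsum(lm_prop[acc] - llt_m[acc], dat$pid_m[acc])
          ll[as.integer(rownames(d))] <- ll[as.integer(rownames(d))] + d
          llt_m[acc] <- lm_prop[acc]
        }
        if (it <= warmup)
          lsc_tau <- lsc_tau + gam(it) * (mean(acc) - 0.35)
      }
      # conjugate Normal-Inverse-Wishart group updates
      for (g in seq_len(G)) {
        rows <- which(gidx == g)
        ng <- length(rows)
        X <- theta[rows, seq_len(dH), drop = FALSE]
        xb <- colMeans(X)
        Sx <- crossprod(sweep(X, 2, xb))
        kn <- kappa0 + ng; nun <- nu0 + ng
        mn <- (kappa0 * m0 + ng * xb) / kn
        Sn <- S0 + Sx + (kappa0 * ng / kn) * tcrossprod(xb - m0)
        Sn <- (Sn + t(Sn)) / 2
        W <- stats::rWishart(1, nun, chol2inv(chol(Sn)))[, , 1]
        Sig <- chol2inv(chol(W))
        Sig <- (Sig + t(Sig)) / 2
        ch2 <- chol(Sig)
        mu[g, ] <- mn + drop(crossprod(ch2, stats::rnorm(dH))) / sqrt(kn)
        sig_chol[[g]] <- ch2
      }
      lpri <- prior_rows(theta)
      # group translation and scaling rounds (non-centred directions)
      for (round_t in seq_len(max(1L, ceiling(mh_sweeps / 2)))) {
        for (g in seq_len(G)) {
          rows <- which(gidx == g)
          ng <- length(rows)
          for (bi in seq_len(nbT)) {
            bl <- if (bi <= 6) c(2L * bi - 1L, 2L * bi) else 13:15
            io <- if (bi <= 6) idx_gc_o[[g]][[bi]] else idx_g_o[[g]]
            im <- if (bi <= 6) idx_gc_m[[g]][[bi]] else idx_g_m[[g]]
            # translation: shift mu and all member vectors together
            delta <- exp(lts[g, bi]) *
              drop(crossprod(tchol[[g]][[bi]], stats::rnorm(length(bl))))
            prop <- theta
            prop[rows, bl] <- sweep(prop[rows, bl, drop = FALSE], 2, delta, "+")
            mup <- mu[g, ]; mup[bl] <- mup[bl] + delta
            ok <- grp_accept(g, prop, mup, io, im)
            if (it <= warmup)
              lts[g, bi] <- lts[g, bi] + gam(it) * ((if (ok) 1 else 0) - 0.3)
            # scaling: expand or contract member deviations around mu
            ce <- exp(exp(lscS[g, bi]) * stats::rnorm(1))
            prop <- theta
            prop[rows, bl] <- matrix(mu[g, bl], ng, length(bl), byrow = TRUE) +
              ce * (theta[rows, bl, drop = FALSE] -
                    matrix(mu[g, bl], ng, length(bl), byrow = TRUE))
            zz <- backsolve(sig_chol[[g]],
                            t(prop[rows, seq_len(dH), drop = FALSE]) - mu[g, ],
                            transpose = TRUE)
            lpp_rows <- -0.5 * colSums(zz^2) - sum(log(diag(sig_chol[[g]])))
            ok <- grp_accept(g, prop, mu[g, ], io, im, lpp_rows,
                             length(bl) * ng * log(ce))
            if (it <= warmup)
              lscS[g, bi] <- lscS[g, bi] + gam(it) * ((if (ok) 1 else 0) - 0.3)
          }
          if (!shared) {
            # grouped structural ridge: shift logA/logk/logt0 for the whole
            # group along the learned group-mean covariance; drifts of every
            # member (and of the group mean) follow via the RT-preserving map
            delta <- exp(ltsR[g]) *
              drop(crossprod(tchol[[g]][[nbT]], stats::rnorm(3)))
            prop <- theta
            prop[rows, 13:15] <- sweep(prop[rows, 13:15, drop = FALSE], 2, delta, "+")
            mup <- mu[g, ]
            mup[13:15] <- mup[13:15] + delta
            ljac <- 0
            bad_map <- FALSE
            for (i in rows) {
              m <- rt_map(theta[i, 1:12],
                          exp(theta[i, 14]) + exp(theta[i, 13]) / 2,
                          exp(prop[i, 14]) + exp(prop[i, 13]) / 2,
                          exp(theta[i, 15]) - exp(prop[i, 15]))
              if (is.null(m)) { bad_map <- TRUE; break }
              prop[i, 1:12] <- m$v
              ljac <- ljac + m$ljac
            }
            mmu <- rt_map(mu[g, 1:12],
                          exp(mu[g, 14]) + exp(mu[g, 13]) / 2,
                          exp(mup[14]) + exp(mup[13]) / 2,
                          exp(mu[g, 15]) - exp(mup[15]))
            if (!bad_map && !is.null(mmu)) {
              mup[1:12] <- mmu$v
              ljac <- ljac + mmu$ljac
              zz <- backsolve(sig_chol[[g]],
                              t(prop[rows, , drop = FALSE]) - mup,
                              transpose = TRUE)
              lpp_rows <- -0.5 * colSums(zz^2) - sum(log(diag(sig_chol[[g]])))
              ok <- grp_accept(g, prop, mup, idx_g_o[[g]], idx_g_m[[g]],
                               lpp_rows, ljac)
              if (it <= warmup)
                ltsR[g] <- ltsR[g] + gam(it) * ((if (ok) 1 else 0) - 0.3)
            }
          }
        }
      }
      # --- warmup adaptation of proposal shapes ---
      if (it <= warmup) {
        musum <- musum + mu
        muSS <- muSS + mu[, ijH[, 1], drop = FALSE] * mu[, ijH[, 2], drop = FALSE]
        if (it >= 50 && (it %% 50 == 0 || it == warmup)) {
          for (g in seq_len(G)) {
            m <- musum[g, ] / it
            C <- matrix(0, dH, dH)
            C[upper.tri(C, diag = TRUE)] <- muSS[g, ] / it
            C <- C + t(C) - diag(diag(C))
            C <- C - tcrossprod(m)
            for (bi in seq_len(nbT)) {
              bl <- if (bi <= 6) c(2L * bi - 1L, 2L * bi) else 13:15
              Cb <- C[bl, bl, drop = FALSE] + diag(1e-7, length(bl))
              pc <- tryCatch(chol((2.38^2 / length(bl)) * Cb),
                             error = function(e) NULL)
              if (!is.null(pc)) tchol[[g]][[bi]] <- pc
            }
          }
        }
      }
      if (it <= warmup && proposal == "adaptive") {
        Ssum <- Ssum + theta
        SS <- SS + theta[, ij[, 1]] * theta[, ij[, 2]]
        nad <- nad + 1
        if (nad >= 50 && (it %% 100 == 0 || it == warmup)) {
          for (i in seq_len(n)) {
            m <- Ssum[i, ] / nad
            C <- matrix(0, 15, 15)
            C[upper.tri(C, diag = TRUE)] <- SS[i, ] / nad
            C <- C + t(C) - diag(diag(C))
            C <- C - tcrossprod(m)
            for (bi in seq_len(nb)) {
              bl <- blocks[[bi]]
              Cb <- C[bl, bl, drop = FALSE] + diag(1e-6, length(bl))
              pc <- tryCatch(chol((2.38^2 / length(bl)) * Cb),
                             error = function(e) NULL)
              if (!is.null(pc)) pchol[[bi]][[i]] <- pc
            }
            Cf <- C[seq_len(dJ), seq_len(dJ), drop = FALSE] + diag(1e-6, dJ)
            pc <- tryCatch(chol((2.38^2 / dJ) * Cf), error = function(e) NULL)
            if (!is.null(pc)) pchol_full[[i]] <- pc
          }
        }
      }
      if (it <= warmup && proposal == "group-scaled" && it %% 100 == 0) {
        for (i in seq_len(n)) {
          full <- crossprod(sig_chol[[gidx[i]]])
          for (bi in seq_len(nb)) {
            bl <- blocks[[bi]]
            Cb <- if (all(bl <= dH)) full[bl, bl, drop = FALSE]
                  else diag(0.005, length(bl))
            pchol[[bi]][[i]] <- chol((2.38^2 / length(bl)) * Cb +
                                     diag(1e-6, length(bl)))
          }
        }
      }
      if (it == warmup && progress)
        message("chain ", ch, ": warmup done (mean acceptance ",
                round(mean(acc_n) / try_n, 3), ")")
      if (it > warmup) {
        sds <- t(vapply(seq_len(G), function(g) sqrt(diag(crossprod(sig_chol[[g]]))),
                        numeric(dH)))
        row <- c(t(mu), t(sds),
                 if (shared) c(t(theta[match(seq_len(G), gidx), 13:15])),
                 as.vector(t(theta)))
        out[it - warmup, ] <- row
      }
    }
    colnames(out) <- col_names
    attr(out, "acceptance") <- acc_n / try_n
    out
  }
  ch_out <- lapply(seq_len(chains), run_chain)
  rh <- if (chains >= 2) {
    vapply(col_names, function(p) rhat(lapply(ch_out, function(m) m[, p])), numeric(1))
  } else stats::setNames(rep(NA_real_, length(col_names)), col_names)
  draws <- structure(list(
    chains = ch_out, param_names = col_names, groups = model$groups,
    participants = model$participants, rhat = rh,
    acceptance = lapply(ch_out, attr, "acceptance"),
    settings = list(chains = chains, warmup = warmup, iters = iters,
                    seed = seed, mh_sweeps = mh_sweeps, proposal = proposal,
                    deadline = model$deadline, cap = model$cap,
                    structural = model$structural)),
    class = "lba_draws")
  bad <- names(rh)[!is.na(rh) & (rh < 0.99 | rh > 1.01)]
  if (chains >= 2 && length(bad))
    warning("R-hat outside [0.99, 1.01] for ", length(bad), " parameter(s): ",
            paste(utils::head(bad, 8), collapse = ", "),
            if (length(bad) > 8) ", ...")
  if (chains >= 2 && any(is.na(rh)))
    warning("R-hat undefined (zero variance) for ",
            sum(is.na(rh)), " parameter(s)")
  draws
}

#' @export
print.lba_draws <- function(x, ...) {
  s <- x$settings
  cat("LBA posterior draws:", s$chains, "chains x", s$iters, "iterations (",
      n_draws(x), "retained draws,", s$warmup, "warmup),",
      length(x$param_names), "stored parameters\n")
  rr <- range(x$rhat, na.rm = TRUE)
  cat("R-hat range: [", round(rr[1], 3), ",", round(rr[2], 3), "]\n")
  invisible(x)
}

#' Total retained draws
#' @param draws An `lba_draws` object.
#' @return chains x iterations.
#' @export
n_draws <- function(draws) sum(vapply(draws$chains, nrow, integer(1)))

#' Stack chains into one draw matrix
#'
#' @param draws An `lba_draws` object.
#' @param pattern Optional regular expression selecting parameter columns.
#' @return Numeric matrix (draws x parameters).
#' @export
draws_matrix <- function(draws, pattern = NULL) {
  m <- do.call(rbind, draws$chains)
  if (!is.null(pattern)) m <- m[, grepl(pattern, colnames(m)), drop = FALSE]
  m
}

#' @export
as.data.frame.lba_draws <- function(x, ...) {
  do.call(rbind, lapply(seq_along(x$chains), function(ch) {
    m <- x$chains[[ch]]
    data.frame(chain = ch, iter = rep(seq_len(nrow(m)), ncol(m)),
               parameter = rep(colnames(m), each = nrow(m)),
               value = as.vector(m))
  }))
}

#' Split rank-normalized R-hat
#'
#' Potential scale reduction factor computed on rank-normalized draws after
#' splitting each chain in half (the maximum of the bulk and the folded
#' statistic, which is sensitive to scale disagreement). Approaches 1 under
#' stationarity.
#'
#' @param chains List of numeric vectors, one per chain (>= 2 chains, >= 4
#'   draws each).
#' @return The R-hat statistic; `NA` when the draws are constant.
#' @export
rhat <- function(chains) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)), function(j) chains[, j])
  if (!is.list(chains) || length(chains) < 2)
    stop("rhat needs at least two chains")
  nmin <- min(lengths(chains))
  if (nmin < 4) stop("rhat needs at least 4 draws per chain")
  half <- floor(nmin / 2)
  sp <- unlist(lapply(chains, function(x)
    list(x[seq_len(half)], x[(nmin - half + 1):nmin])), recursive = FALSE)
  M <- do.call(cbind, sp)
  if (max(M) - min(M) < .Machine$double.eps * 100) return(NA_real_)
  zr <- function(v) {
    r <- rank(v, ties.method = "average")
    stats::qnorm((r - 3 / 8) / (length(v) + 1 / 4))
  }
  classic <- function(M) {
    nn <- nrow(M); mm <- ncol(M)
    W <- mean(apply(M, 2, stats::var))
    B <- nn * stats::var(colMeans(M))
    if (W == 0) return(NA_real_)
    sqrt(((nn - 1) / nn * W + B / nn) / W)
  }
  bulk <- classic(matrix(zr(as.vector(M)), nrow(M)))
  folded <- classic(matrix(zr(abs(as.vector(M) - stats::median(M))), nrow(M)))
  max(bulk, folded, na.rm = TRUE)
}

#' Posterior predictive simulation and discrepancy summary
#'
#' For sampled posterior draws, rebuilds every participant's natural-scale
#' parameters and simulates the full observed schedule through the LBA race,
#' then summarizes predicted cell-level mean RT, error rate and missing rate
#' against the observed data.
#'
#' @param draws An `lba_draws` object.
#' @param trials Observed trial records (the schedule with outcomes).
#' @param n_draws Number of posterior draws to simulate (default 50).
#' @param seed Integer seed.
#' @return List with `cells` (per group x condition x trial-type observed and
#'   predicted summaries plus discrepancies) and `mean_abs_rt_discrepancy`
#'   (mean absolute relative error of predicted cell mean RT).
#' @export
posterior_predictive <- function(draws, trials, n_draws = 50, seed = 1) {
  set.seed(seed)
  M <- draws_matrix(draws, "^alpha\\.")
  take <- sample(nrow(M), min(n_draws, nrow(M)))
  pids <- draws$participants$participant_id
  pn <- lba_param_names()
  schedule <- trials
  cell_key <- function(d) paste(d$group, d$condition, d$trial_type)
  obs_rt <- tapply(trials$rt_seconds[!trials$missing],
                   cell_key(trials[!trials$missing, ]), mean)
  obs_err <- tapply(!trials$correct[!trials$missing],
                    cell_key(trials[!trials$missing, ]), mean)[names(obs_rt)]
  pred_rt <- pred_err <- pred_miss <- NULL
  for (s in take) {
    par_tab <- data.frame(participant_id = pids)
    for (j in seq_along(pn)) {
      v <- M[s, paste("alpha", pids, pn[j], sep = ".")]
      par_tab[[pn[j]]] <- v
    }
    par_tab$A <- exp(par_tab$logA); par_tab$k <- exp(par_tab$logk)
    par_tab$t0 <- exp(par_tab$logt0)
    sim <- simulate_behavior(schedule, par_tab, deadline = draws$settings$deadline)
    k <- cell_key(sim[!sim$missing, ])
    pred_rt <- rbind(pred_rt, tapply(sim$rt_seconds[!sim$missing], k, mean)[names(obs_rt)])
    pred_err <- rbind(pred_err, tapply(!sim$correct[!sim$missing], k, mean)[names(obs_rt)])
    pred_miss <- rbind(pred_miss, tapply(sim$missing, cell_key(sim), mean)[names(obs_rt)])
  }
  cells <- data.frame(cell = names(obs_rt),
                      observed_mean_rt = as.numeric(obs_rt),
                      predicted_mean_rt = colMeans(pred_rt),
                      observed_error_rate = as.numeric(obs_err),
                      predicted_error_rate = colMeans(pred_err),
                      predicted_missing_rate = colMeans(pred_miss))
  cells$rt_rel_discrepancy <- (cells$predicted_mean_rt - cells$observed_mean_rt) /
    cells$observed_mean_rt
  list(cells = cells,
       mean_abs_rt_discrepancy = mean(abs(cells$rt_rel_discrepancy)))
}
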