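# Plausible-values association analysis: per-draw sample correlations
# between individual listening efficiency and external scores, the exact
# posterior of the population correlation rho under a uniform prior
# (mixed over draws), reliability decision rules, and the LMG
# relative-importance decomposition of a multiple linear regression.

#' Per-participant, per-draw listening efficiency
#'
#' Extracts each participant's sentence-trial differential drift rates from
#' the individual-level posterior draws and averages them across the three
#' conditions, one value per retained draw and participant.
#'
#' @param draws An `lba_draws` object.
#' @param participants Optional subset of participant ids.
#' @return Numeric matrix (draws x participants) with a `"group"` attribute
#'   giving each column's group.
#' @export
individual_efficiency <- function(draws, participants = NULL) {
  ptab <- draws$participants
  if (is.null(participants)) participants <- ptab$participant_id
  missing_p <- setdiff(participants, ptab$participant_id)
  if (length(missing_p))
    stop("participants missing from draws: ", paste(missing_p, collapse = ", "))
  M <- draws_matrix(draws, "^alpha\\.")
  eff <- sapply(participants, function(p) {
    acc <- 0
    for (cond in .conditions) {
      kc <- paste("alpha", p, "v", "correct", cond, "sentence", sep = ".")
      ki <- paste("alpha", p, "v", "incorrect", cond, "sentence", sep = ".")
      acc <- acc + (M[, kc] - M[, ki])
    }
    acc / length(.conditions)
  })
  eff <- matrix(eff, nrow = nrow(M), dimnames = list(NULL, participants))
  attr(eff, "group") <- ptab$group[match(participants, ptab$participant_id)]
  eff
}

#' Plausible-values correlations
#'
#' Pearson correlation across participants between each posterior draw of
#' individual efficiency and fixed external scores: one sample correlation
#' per retained draw.
#'
#' @param efficiency Draws x participants matrix (see
#'   [individual_efficiency()]).
#' @param scores Named numeric vector of scores (names = participant ids) or
#'   a vector aligned with the efficiency columns.
#' @return Numeric vector of per-draw correlations `r_s`.
#' @export
plausible_correlations <- function(efficiency, scores) {
  if (!is.null(names(scores))) {
    idx <- match(colnames(efficiency), names(scores))
    if (anyNA(idx)) stop("scores missing for participants: ",
                         paste(colnames(efficiency)[is.na(idx)], collapse = ", "))
    scores <- scores[idx]
  }
  n <- ncol(efficiency)
  if (n < 4) stop("at least 4 participants with scores required")
  if (length(scores) != n) stop("scores must align with efficiency columns")
  if (stats::sd(scores) == 0) stop("scores are constant; correlation undefined")
  sc <- scores - mean(scores)
  E <- efficiency - rowMeans(efficiency)
  num <- as.vector(E %*% sc)
  den <- sqrt(rowSums(E^2) * sum(sc^2))
  if (any(den == 0)) stop("efficiency draws constant across participants")
  num / den
}

# h(u) = (1 - u)^{-(n - 3/2)} * 2F1(1/2, 1/2; n - 1/2; (1 + u)/2), the only
# rho-dependent part of the sampling density of r beyond (1 - rho^2)^((n-1)/2)
.rho_kernel <- function(u, n, max_terms = 2000L, tol = 1e-12) {
  x <- (1 + u) / 2
  c0 <- n - 0.5
  term <- rep(1, length(x))
  s <- term
  for (k in 0:(max_terms - 1)) {
    term <- term * ((0.5 + k)^2 / ((c0 + k) * (k + 1))) * x
    s <- s + term
    if (max(term) < tol * max(s)) break
  }
  (1 - u)^(-(n - 1.5)) * s
}

#' Posterior of the population correlation
#'
#' Exact grid posterior of the population correlation rho given observed
#' sample correlation(s) from `n` participants, under a uniform prior on
#' (-1, 1). With a vector of per-draw plausible correlations the posterior is
#' the mixture over draws, propagating the latent-variable uncertainty.
#'
#' @param r Sample correlation(s); typically the per-draw values from
#'   [plausible_correlations()].
#' @param n Number of participants (>= 4).
#' @param grid_n Number of interior grid points over (-1, 1) (default 2001).
#' @param mass Credible mass (default 0.95).
#' @return List with `rho` (grid), `density` (normalized), `mean`, `cri`
#'   (equal-tailed credible interval), `p_pos` = P(rho > 0), `p_neg`, and the
#'   number of mixed draws.
#' @export
population_rho_posterior <- function(r, n, grid_n = 2001, mass = 0.95) {
  if (n < 4) stop("population rho posterior requires n >= 4")
  if (any(abs(r) > 1)) stop("correlations must lie in [-1, 1]")
  r <- pmin(pmax(r, -1 + 1e-9), 1 - 1e-9)
  rho <- seq(-1, 1, length.out = grid_n + 2)[2:(grid_n + 1)]
  base <- (n - 1) / 2 * log1p(-rho^2)
  # interpolate the one-dimensional kernel h(u), u = rho * r
  ug <- seq(-1 + 1e-9, 1 - 1e-9, length.out = 4001)
  lh <- log(.rho_kernel(ug, n))
  mix <- numeric(grid_n)
  ur <- outer(rho, r) # grid_n x draws
  lk <- matrix(stats::approx(ug, lh, xout = as.vector(ur), rule = 2)$y, grid_n)
  ld <- base + lk
  ld <- sweep(ld, 2, apply(ld, 2, max))
  d <- exp(ld)
  d <- sweep(d, 2, colSums(d), "/")
  mix <- rowMeans(d)
  h <- rho[2] - rho[1]
  dens <- mix / (sum(mix) * h)
  cdf <- cumsum(mix)
  qf <- function(p) {
    i <- which(cdf >= p)[1]
    if (i == 1) rho[1] else {
      p0 <- cdf[i - 1]
      rho[i - 1] + (rho[i] - rho[i - 1]) * (p - p0) / (cdf[i] - p0)
    }
  }
  alpha <- (1 - mass) / 2
  p_pos <- sum(mix[rho > 0]) + 0.5 * sum(mix[rho == 0])
  list(rho = rho, density = dens, mean = sum(rho * mix),
       cri = c(qf(alpha), qf(1 - alpha)), p_pos = p_pos, p_neg = 1 - p_pos,
       n = n, n_draws = length(r), mass = mass)
}

#' Reliability decision for a correlation
#'
#' A correlation is flagged reliable when the credible interval excludes
#' zero, or when the directional certainty `max(P(rho > 0), P(rho < 0))`
#' exceeds 0.90.
#'
#' @param post A posterior as returned by [population_rho_posterior()].
#' @param certainty_threshold Certainty cutoff (default 0.90).
#' @return List with `reliable`, `certainty`, `by_cri`, `by_certainty`.
#' @export
reliability_flag <- function(post, certainty_threshold = 0.90) {
  by_cri <- post$cri[1] > 0 || post$cri[2] < 0
  certainty <- max(post$p_pos, post$p_neg)
  list(reliable = by_cri || certainty > certainty_threshold,
       certainty = certainty, by_cri = by_cri,
       by_certainty = certainty > certainty_threshold)
}

#' LMG relative-importance decomposition
#'
#' Decomposes the R-squared of a multiple linear regression into
#' per-predictor shares: each predictor's share is its increment to
#' R-squared averaged over all orderings of the predictors (exact
#' enumeration; at most 8 predictors). Shares sum to the full-model
#' R-squared. The response may be a matrix of per-draw values, giving a
#' posterior distribution of shares.
#'
#' @param predictors Numeric matrix or data.frame (participants x predictors,
#'   full column rank).
#' @param response Numeric vector (participants) or matrix
#'   (draws x participants).
#' @return List with `shares` (draws x predictors matrix of LMG shares),
#'   `r_squared` (full-model R-squared per draw), and `mean_shares`.
#' @export
relative_importance <- function(predictors, response) {
  X <- as.matrix(predictors)
  p <- ncol(X)
  if (p < 1 || p > 8) stop("between 1 and 8 predictors supported")
  if (qr(X)$rank < p) stop("predictor matrix is rank deficient")
  Y <- if (is.matrix(response)) t(response) else matrix(response, ncol = 1)
  if (nrow(Y) != nrow(X)) stop("response length must match predictor rows")
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  XtX <- crossprod(Xc)
  Q <- crossprod(Xc, Yc)              # p x ndraws
  yty <- colSums(Yc^2)
  nsub <- 2^p
  r2 <- matrix(0, nsub, ncol(Y))      # R^2 per subset (row index = bitmask+1)
  sizes <- integer(nsub)
  for (m in seq_len(nsub - 1)) {
    S <- which(bitwAnd(m, bitwShiftL(1L, 0:(p - 1))) > 0)
    sizes[m + 1] <- length(S)
    Minv <- solve(XtX[S, S, drop = FALSE])
    r2[m + 1, ] <- colSums((Minv %*% Q[S, , drop = FALSE]) * Q[S, , drop = FALSE]) / yty
  }
  wt <- function(k) exp(lfactorial(k) + lfactorial(p - k - 1) - lfactorial(p))
  shares <- matrix(0, ncol(Y), p, dimnames = list(NULL, colnames(X)))
  for (j in seq_len(p)) {
    bit <- bitwShiftL(1L, j - 1L)
    for (m in 0:(nsub - 1)) {
      if (bitwAnd(m, bit) > 0) next
      k <- sizes[m + 1]
      shares[, j] <- shares[, j] + wt(k) * (r2[m + bit + 1, ] - r2[m + 1, ])
    }
  }
  list(shares = shares, r_squared = r2[nsub, ],
       mean_shares = colMeans(shares))
}
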