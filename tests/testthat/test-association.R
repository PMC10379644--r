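# Plausible-values correlations, the exact population-correlation
# posterior, reliability rules, and LMG relative importance.

# minimal lba_draws-like object with hand-set individual drift columns
fake_alpha_draws <- function(vals, pids = c("P1", "P2"), groups = c("CI", "CI")) {
  cols <- unlist(lapply(pids, function(p)
    paste("alpha", p, c(paste0("v.correct.", c("Easy", "Med", "Hard"), ".sentence"),
                        paste0("v.incorrect.", c("Easy", "Med", "Hard"), ".sentence")),
          sep = ".")))
  m <- matrix(vals, nrow(vals), length(cols), dimnames = list(NULL, cols))
  structure(list(chains = list(m), param_names = cols,
                 participants = data.frame(participant_id = pids, group = groups),
                 settings = list(chains = 1)),
            class = "lba_draws")
}

test_that("individual efficiency averages sentence vDiff across conditions", {
  # 3 draws x 2 participants, hand-computed
  vals <- cbind(
    # P1 correct Easy/Med/Hard, incorrect Easy/Med/Hard
    c(4, 5, 6), c(4, 5, 6), c(4, 5, 6), c(1, 1, 1), c(2, 2, 2), c(3, 3, 3),
    # P2
    c(2, 2, 2), c(3, 3, 3), c(4, 4, 4), c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  dr <- fake_alpha_draws(vals)
  eff <- individual_efficiency(dr)
  expect_equal(unname(eff[, "P1"]), c(4, 5, 6) - 2)
  expect_equal(unname(eff[, "P2"]), 3 - c(1, 2, 3))
  expect_identical(attr(eff, "group"), c("CI", "CI"))
  # permuting condition labels leaves the average unchanged (columns of the
  # per-condition sub-blocks swapped)
  perm <- vals[, c(2, 3, 1, 5, 6, 4, 8, 9, 7, 11, 12, 10)]
  expect_equal(individual_efficiency(fake_alpha_draws(perm))[, "P1"],
               eff[, "P1"])
  expect_error(individual_efficiency(dr, participants = "P9"), "missing")
})

test_that("plausible correlations are per-draw Pearson correlations", {
  set.seed(41)
  eff <- matrix(rnorm(50 * 10), 50, 10,
                dimnames = list(NULL, sprintf("P%02d", 1:10)))
  scores <- rnorm(10)
  rs <- plausible_correlations(eff, scores)
  expect_equal(rs, apply(eff, 1, function(x) cor(x, scores)), tolerance = 1e-12)
  # scores identical to the draw values give r = 1 in that draw
  rs1 <- plausible_correlations(eff, stats::setNames(eff[7, ], colnames(eff)))
  expect_equal(rs1[7], 1, tolerance = 1e-12)
  # independence: mean correlation near zero
  expect_lt(abs(mean(rs)), 3 / sqrt(10 * 50))
  expect_error(plausible_correlations(eff, rep(1, 10)), "constant")
  expect_error(plausible_correlations(eff[, 1:3], rnorm(3)), "4 participants")
})

test_that("population rho posterior is exact, normalized and stable", {
  post <- population_rho_posterior(0, n = 200)
  expect_lt(abs(post$mean), 0.01)
  expect_lt(abs(post$p_pos - 0.5), 0.02)
  h <- post$rho[2] - post$rho[1]
  expect_lt(abs(sum(post$density) * h - 1), 1e-6)
  # grid refinement changes the mean by less than 1e-3
  post2 <- population_rho_posterior(0.37, n = 24, grid_n = 2001)
  post3 <- population_rho_posterior(0.37, n = 24, grid_n = 4001)
  expect_lt(abs(post2$mean - post3$mean), 1e-3)
  # degenerate sample correlations pile mass at the boundary
  hi <- population_rho_posterior(rep(0.999999, 5), n = 24)
  expect_gt(hi$mean, 0.9)
  expect_error(population_rho_posterior(0.5, n = 3), "n >= 4")
  expect_error(population_rho_posterior(1.5, n = 24), "\\[-1, 1\\]")
})

test_that("rho posterior matches a simulation-consistency oracle at r = 0.5, n = 24", {
  post <- population_rho_posterior(0.5, n = 24)
  # oracle: sample rho uniformly, simulate 24-observation datasets, weight
  # candidate rho by a kernel on the observed sample correlation
  set.seed(42)
  nsim <- 3e5
  rho <- runif(nsim, -1, 1)
  z1 <- matrix(rnorm(nsim * 24), nsim)
  z2 <- matrix(rnorm(nsim * 24), nsim)
  x <- z1
  y <- rho * z1 + sqrt(1 - rho^2) * z2
  xc <- x - rowMeans(x); yc <- y - rowMeans(y)
  r <- rowSums(xc * yc) / sqrt(rowSums(xc^2) * rowSums(yc^2))
  w <- pmax(0, 1 - ((r - 0.5) / 0.03)^2)
  oracle_mean <- sum(rho * w) / sum(w)
  expect_lt(abs(post$mean - oracle_mean), 0.02)
  # Fisher-z approximation as a loose second oracle
  expect_lt(abs(post$mean - tanh(atanh(0.5))), 0.08)
})

test_that("reliability rules follow the interval and the certainty clause", {
  mk <- function(cri, p_pos) list(cri = cri, p_pos = p_pos, p_neg = 1 - p_pos)
  expect_true(reliability_flag(mk(c(0.1, 0.5), 0.99))$reliable)
  # interval covers zero but certainty is high: the certainty clause fires
  fl <- reliability_flag(mk(c(-0.07, 0.64), 0.954))
  expect_true(fl$reliable && !fl$by_cri && fl$by_certainty)
  expect_equal(fl$certainty, 0.954)
  expect_false(reliability_flag(mk(c(-0.3, 0.3), 0.55))$reliable)
  expect_true(reliability_flag(mk(c(-0.5, -0.1), 0.04))$reliable)
})

test_that("LMG shares sum to the full-model R-squared and respect symmetry", {
  set.seed(43)
  n <- 60
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("x", 1:5)))
  y <- X %*% c(1, 0.5, 0, -0.3, 0.2) + rnorm(n)
  li <- relative_importance(X, as.vector(y))
  full_r2 <- summary(lm(y ~ X))$r.squared
  expect_equal(sum(li$shares), full_r2, tolerance = 1e-10)
  expect_equal(li$r_squared, full_r2, tolerance = 1e-10)
  # permutation symmetry in predictor order
  perm <- c(3, 1, 5, 2, 4)
  li2 <- relative_importance(X[, perm], as.vector(y))
  expect_equal(li2$mean_shares[paste0("x", 1:5)], li$mean_shares,
               tolerance = 1e-10)
  # single predictor: share equals the simple R-squared
  li1 <- relative_importance(X[, 1, drop = FALSE], as.vector(y))
  expect_equal(unname(li1$mean_shares), as.numeric(cor(X[, 1], y))^2,
               tolerance = 1e-10)
})

test_that("LMG matches explicit ordering enumeration and orthogonal identity", {
  set.seed(44)
  n <- 40
  X <- matrix(rnorm(n * 4), n, 4)
  y <- rnorm(n)
  li <- relative_importance(X, y)
  # oracle: average R-squared increments over all 4! orderings
  r2 <- function(cols) if (!length(cols)) 0 else
    summary(lm(y ~ X[, cols, drop = FALSE]))$r.squared
  perms <- rbind(t(combn(4, 4)), NULL)
  allp <- do.call(rbind, lapply(1:4, function(a)
    do.call(rbind, lapply(setdiff(1:4, a), function(b)
      do.call(rbind, lapply(setdiff(1:4, c(a, b)), function(cc)
        c(a, b, cc, setdiff(1:4, c(a, b, cc)))))))))
  inc <- matrix(0, nrow(allp), 4)
  for (i in seq_len(nrow(allp))) {
    ord <- allp[i, ]
    for (j in 1:4)
      inc[i, ord[j]] <- r2(ord[1:j]) - r2(ord[seq_len(j - 1)])
  }
  expect_equal(unname(li$mean_shares), colMeans(inc), tolerance = 1e-10)
  # centred orthogonal predictors: shares equal their individual squared
  # correlations
  Z <- scale(matrix(rnorm(n * 3), n, 3), center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(Z))
  y2 <- Q %*% c(0.8, 0.4, -0.2) + rnorm(n, 0, 0.5)
  lo <- relative_importance(Q, as.vector(y2))
  expect_equal(unname(lo$mean_shares), as.vector(cor(Q, y2)^2), tolerance = 1e-10)
  # per-draw responses give one share vector per draw
  Y <- matrix(rnorm(5 * n), 5, n)
  lm5 <- relative_importance(X, Y)
  expect_identical(dim(lm5$shares), c(5L, 4L))
  for (s in 1:5)
    expect_equal(sum(lm5$shares[s, ]), lm5$r_squared[s], tolerance = 1e-10)
  expect_error(relative_importance(cbind(X, X[, 1]), y), "rank deficient")
  expect_error(relative_importance(matrix(rnorm(n * 9), n, 9), y), "8 predictors")
})
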