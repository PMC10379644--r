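# Synthetic study generator: design arithmetic, participant draws,
# behavioral simulation, rating and score generators, CSV round trips.

test_that("the default cohort design yields 8,064 observations", {
  spec <- design_spec()
  expect_identical(design_n_trials(spec), 8064)
  d <- build_design(spec, seed = 1)
  expect_identical(nrow(d), 8064L)
  per <- table(d$participant_id)
  expect_identical(sort(unique(as.integer(per))), c(84L, 168L))
  expect_identical(sum(per == 168L), 47L)
  expect_identical(sum(per == 84L), 2L)
})

test_that("row counts are a closed-form function of arbitrary specs", {
  set.seed(5)
  for (rep in 1:5) {
    nc <- sample(0:6, 1); nn <- sample(1:6, 1); runs <- sample(1:3, 1)
    spec <- design_spec(n_ci = nc, n_nh = nn, runs_per_participant = runs,
                        partial_completers = data.frame(
                          participant_id = character(0),
                          runs_completed = integer(0)))
    expect_identical(nrow(build_design(spec, seed = rep)),
                     as.integer(design_n_trials(spec)))
  }
  # single participant, single run: 84 rows, 54 sentence + 30 null
  s1 <- small_spec(1, 0, 1)
  d1 <- build_design(s1, seed = 2)
  expect_identical(nrow(d1), 84L)
  expect_identical(sum(d1$trial_type == "sentence"), 54L)
  expect_identical(sum(d1$trial_type == "null"), 30L)
  # empty design
  s0 <- design_spec(n_ci = 0, n_nh = 0,
                    partial_completers = data.frame(participant_id = character(0),
                                                    runs_completed = integer(0)))
  expect_identical(nrow(build_design(s0)), 0L)
})

test_that("invalid designs are rejected with diagnostics", {
  expect_error(design_spec(sentence_trials_per_block = 20), "must equal")
  expect_error(design_spec(n_ci = -1), "non-negative")
  expect_error(design_spec(conditions = c("Easy", "Hard")), "three")
  expect_error(design_spec(response_deadline = 0), "deadline")
  expect_error(design_spec(partial_completers = data.frame(
    participant_id = "XX99", runs_completed = 1L)), "unknown participant")
})

test_that("participant draws are reproducible, mean-accurate and positivity-safe", {
  spec <- small_spec(2, 2, 1)
  truth <- ground_truth()
  a <- draw_participants(truth, spec, seed = 7)
  b <- draw_participants(truth, spec, seed = 7)
  expect_identical(a, b)
  expect_true(all(as.matrix(a[, c(drift_names(), "A", "k", "t0")]) > 0))
  # degenerate covariance: every participant equals the group mean
  t0cov <- ground_truth(sd_log = c(drift = 1e-12, A = 1e-12, k = 1e-12, t0 = 1e-12))
  z <- draw_participants(t0cov, spec, seed = 8)
  expect_equal(z$t0, rep(0.21, 4), tolerance = 1e-6)
  expect_equal(z$v.incorrect.Easy.sentence, rep(1, 4), tolerance = 1e-6)
  # law of large numbers on the log scale at n = 10,000
  big <- design_spec(n_ci = 10000, n_nh = 0,
                     partial_completers = data.frame(participant_id = character(0),
                                                     runs_completed = integer(0)))
  zz <- draw_participants(truth, big, seed = 9)
  se <- 0.15 / sqrt(10000)
  expect_lt(abs(mean(log(zz$v.correct.Easy.sentence)) -
                  truth$groups$CI$mu_log[["v.correct.Easy.sentence"]]), 3 * se)
  # non-positive-definite covariance rejected
  bad <- truth
  bad$groups$CI$sigma_log[1, 2] <- 5
  expect_error(draw_participants(bad, spec, seed = 1), "positive definite")
})

test_that("behavior simulation respects the deadline rule", {
  spec <- small_spec(2, 2, 1)
  study <- simulate_study(spec, seed = 3)
  beh <- study$trials
  expect_true(all(beh$missing == (beh$response == "none")))
  expect_true(all(is.na(beh$rt_seconds[beh$missing])))
  ok <- !beh$missing
  expect_true(all(beh$rt_seconds[ok] <= spec$response_deadline))
  expect_true(all(beh$rt_seconds[ok] > study$params$t0[
    match(beh$participant_id[ok], study$params$participant_id)]))
  # deadline zero censors everything
  all_miss <- simulate_behavior(build_design(spec, seed = 3), study$params,
                                deadline = 0, seed = 4)
  expect_true(all(all_miss$missing))
})

test_that("simulated choice frequencies match the closed-form probabilities", {
  n <- 40000
  sched <- data.frame(participant_id = "P1", group = "NH", run = 1L,
                      block_index = 1L, condition = "Med",
                      trial_index = seq_len(n), trial_type = "sentence",
                      correct_response = sample(c("yes", "no"), n, TRUE),
                      onset_jitter = 8, response = NA_character_, correct = NA,
                      rt_seconds = NA_real_, missing = NA)
  p <- lba_params(A = 1, k = 1.5, t0 = 0.2,
                  v = setNames(rep(c(2.5, 1.2), 6), drift_names()))
  ptab <- data.frame(participant_id = "P1", group = "NH",
                     as.list(setNames(p$v, drift_names())),
                     A = p$A, k = p$k, t0 = p$t0, check.names = FALSE)
  beh <- simulate_behavior(sched, ptab, deadline = 100, seed = 5)
  cp <- choice_probability(p, "Med", "sentence")
  pc <- cp$p_correct / (cp$p_correct + cp$p_incorrect)
  se <- sqrt(pc * (1 - pc) / sum(!beh$missing))
  expect_lt(abs(mean(beh$correct[!beh$missing]) - pc), 3 * se)
})

test_that("published-scale parameters give far fewer errors for NH-like listeners", {
  spec <- design_spec(n_ci = 6, n_nh = 6, runs_per_participant = 2,
                      partial_completers = data.frame(participant_id = character(0),
                                                      runs_completed = integer(0)))
  beh <- simulate_study(spec, seed = 11)$trials
  err <- tapply(!beh$correct[!beh$missing], beh$group[!beh$missing], mean)
  expect_lt(err[["NH"]], err[["CI"]] / 2)
  expect_lt(err[["NH"]], 0.05)
})

test_that("rating generator matches the ordered beta model", {
  # boundary mass: linear predictor at -infinity limit
  set.seed(12)
  expect_true(all(rordbeta(200, eta = -40, c1 = -3, c2 = 3, phi = 8) == 0))
  expect_true(all(rordbeta(200, eta = 40, c1 = -3, c2 = 3, phi = 8) == 1))
  # generated cell mean matches the analytic three-part mixture mean
  for (eta in c(-1.2, 0.4, 2)) {
    y <- rordbeta(10000, eta, -3, 3, 8)
    m <- ordered_beta_mean(eta, -3, 3)
    expect_lt(abs(mean(y) - m), 3 * sd(y) / sqrt(10000))
  }
  # monotone construction: default effort effects increase with difficulty
  spec <- design_spec(n_ci = 200, n_nh = 200,
                      partial_completers = data.frame(participant_id = character(0),
                                                      runs_completed = integer(0)))
  rt <- simulate_ratings(spec, seed = 13)
  ef <- with(subset(rt, question == "EF" & group == "CI"),
             tapply(rating, condition, mean))
  expect_true(ef[["Easy"]] < ef[["Med"]] && ef[["Med"]] < ef[["Hard"]])
  expect_true(all(rt$rating >= 0 & rt$rating <= 1))
  expect_error(rating_effects(cutpoints = c(2, -2)), "ordered")
})

test_that("score generator hits the requested population correlation", {
  eff <- data.frame(participant_id = sprintf("P%02d", 1:1000), group = "CI",
                    efficiency = rnorm(1000, 2, 0.8))
  ins0 <- data.frame(instrument = "X", min = -1e9, max = 1e9, center = 0,
                     spread = 1, target_corr = 0)
  s0 <- simulate_scores(eff, ins0, seed = 14, clip = FALSE)
  expect_lt(abs(cor(s0$score, eff$efficiency)), 3 / sqrt(1000))
  ins1 <- ins0; ins1$target_corr <- 1
  s1 <- simulate_scores(eff, ins1, seed = 15, clip = FALSE)
  expect_equal(cor(s1$score, eff$efficiency), 1, tolerance = 1e-12)
  # long-run mean sample correlation at n = 24, target 0.4
  eff24 <- eff[1:24, ]
  ins4 <- ins0; ins4$target_corr <- 0.4
  set.seed(16)
  rr <- replicate(1000, {
    s <- simulate_scores(eff24, ins4, clip = FALSE)
    cor(s$score, eff24$efficiency)
  })
  expect_lt(abs(mean(rr) - 0.4), 0.02)
  insbad <- ins0; insbad$target_corr <- 1.4
  expect_error(simulate_scores(eff24, insbad), "\\[-1, 1\\]")
})

test_that("questionnaire totals round-trip through the unit-interval scaling", {
  raw <- list(EAS = c(0, 17.5, 60), FAS = c(10, 23, 40), HHQ = c(0, 55.2, 100),
              SSQ12 = c(0, 6.65, 10), RSpan = c(0, 0.62, 1))
  for (ins in names(raw)) {
    u <- score_to_unit(ins, raw[[ins]])
    expect_true(all(u >= 0 & u <= 1))
    expect_equal(unit_to_score(ins, u), raw[[ins]], tolerance = 1e-12)
  }
  expect_equal(score_to_unit("EAS", 30), 0.5)
  expect_equal(score_to_unit("FAS", 25), 0.5)
  expect_error(score_to_unit("nope", 1), "unknown instrument")
})

test_that("generated tables round-trip through the CSV layer without loss", {
  spec <- small_spec(2, 1, 1)
  study <- simulate_study(spec, seed = 21)
  td <- withr::local_tempdir()
  f <- file.path(td, "trials.csv")
  write_trials(study$trials, f)
  back <- read_trials(f)
  cols <- c("participant_id", "group", "run", "block_index", "condition",
            "trial_index", "trial_type", "response", "correct", "rt_seconds",
            "missing")
  orig <- study$trials[, cols]
  rownames(orig) <- NULL
  expect_identical(back$rt_seconds, orig$rt_seconds)
  expect_identical(back$correct, orig$correct)
  expect_identical(back[, c(1:8, 11)], orig[, c(1:8, 11)])
  rt <- simulate_ratings(spec, seed = 22)
  f2 <- file.path(td, "ratings.csv")
  write_ratings(rt, f2)
  expect_identical(read_ratings(f2)$rating, rt$rating)
  eff <- data.frame(participant_id = spec$participant_id, group = spec$group,
                    efficiency = rnorm(3))
  sc <- simulate_scores(eff, seed = 23)
  f3 <- file.path(td, "scores.csv")
  write_scores(sc, f3)
  expect_identical(read_scores(f3)$score, sc$score)
})
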