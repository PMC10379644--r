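# Shared fixtures: small designs, canonical parameter sets, and a tiny
# fitted posterior reused across inference tests.

table2_vdiff <- list(NH = c(4.14, 4.04, 3.62, 4.32, 4.20, 4.50),
                     CI = c(2.79, 2.16, 1.57, 3.60, 3.74, 4.10))

# an LBA parameter set typical of a fast, accurate listener
nh_like_params <- function(vdiff = 4.14, vi = 1) {
  lba_params(A = 1, k = 2.26, t0 = 0.21,
             v = stats::setNames(rep(c(vi + vdiff, vi), 6), drift_names()))
}

small_spec <- function(n_ci = 4, n_nh = 4, runs = 1) {
  design_spec(n_ci = n_ci, n_nh = n_nh, runs_per_participant = runs,
              partial_completers = data.frame(participant_id = character(0),
                                              runs_completed = integer(0)))
}

simulate_study <- function(spec, seed = 1, truth = ground_truth()) {
  sched <- build_design(spec, seed = seed)
  pp <- draw_participants(truth, spec, seed = seed + 1)
  list(trials = simulate_behavior(sched, pp, seed = seed + 2), params = pp)
}

# one small fitted posterior, computed once per test run
tiny_fit_cache <- new.env()
tiny_fit <- function() {
  if (is.null(tiny_fit_cache$fit)) {
    study <- simulate_study(small_spec(3, 3, 1), seed = 42)
    model <- build_model(study$trials)
    tiny_fit_cache$fit <- list(
      draws = suppressWarnings(
        sample_posterior(model, chains = 2, warmup = 100, iters = 100,
                         seed = 9, mh_sweeps = 2)),
      model = model, study = study)
  }
  tiny_fit_cache$fit
}
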