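# Synthetic study generator: a two-group (CI vs NH) speech-in-noise design
# with two runs of three SNR blocks (Easy/Med/Hard) of 28 trials each
# (18 sentence + 10 null), a 3 s response deadline, LBA-generated choices
# and RTs, ordered-beta visual-analog ratings, and questionnaire/cognitive
# score tables with controllable correlation to individual efficiency.

#' Study design specification
#'
#' @param n_ci,n_nh Number of cochlear-implant and normal-hearing
#'   participants (defaults 24 and 25).
#' @param runs_per_participant Number of runs (default 2).
#' @param conditions Exactly three ordered difficulty labels.
#' @param trials_per_block Trials per block (default 28).
#' @param sentence_trials_per_block,null_trials_per_block Per-block counts of
#'   the two trial types; must sum to `trials_per_block`.
#' @param response_deadline Response deadline in seconds (default 3).
#' @param partial_completers data.frame with columns `participant_id` and
#'   `runs_completed`, listing participants who completed fewer runs. The
#'   default mirrors a cohort in which two participants (one per group)
#'   completed a single run.
#' @return A `design_spec` object.
#' @export
design_spec <- function(n_ci = 24, n_nh = 25, runs_per_participant = 2,
                        conditions = c("Easy", "Med", "Hard"),
                        trials_per_block = 28,
                        sentence_trials_per_block = 18,
                        null_trials_per_block = 10,
                        response_deadline = 3.0,
                        partial_completers = NULL) {
  if (n_ci < 0 || n_nh < 0 || runs_per_participant < 0 ||
      trials_per_block < 0 || sentence_trials_per_block < 0 ||
      null_trials_per_block < 0)
    stop("counts must be non-negative")
  if (sentence_trials_per_block + null_trials_per_block != trials_per_block)
    stop("sentence (", sentence_trials_per_block, ") + null (",
         null_trials_per_block, ") trials must equal trials_per_block (",
         trials_per_block, ")")
  if (length(conditions) != 3L || anyDuplicated(conditions))
    stop("conditions must be exactly three distinct ordered labels")
  if (response_deadline <= 0) stop("response_deadline must be > 0")
  ids <- c(if (n_ci > 0) sprintf("CI%02d", seq_len(n_ci)),
           if (n_nh > 0) sprintf("NH%02d", seq_len(n_nh)))
  groups <- c(rep("CI", n_ci), rep("NH", n_nh))
  if (is.null(partial_completers)) {
    pc <- character(0)
    if (n_ci > 0) pc <- c(pc, sprintf("CI%02d", n_ci))
    if (n_nh > 0) pc <- c(pc, sprintf("NH%02d", n_nh))
    partial_completers <- if (runs_per_participant >= 2 && length(pc))
      data.frame(participant_id = pc, runs_completed = 1L)
    else data.frame(participant_id = character(0), runs_completed = integer(0))
  }
  if (!all(c("participant_id", "runs_completed") %in% names(partial_completers)))
    stop("partial_completers needs participant_id and runs_completed columns")
  if (!all(partial_completers$participant_id %in% ids))
    stop("unknown participant in partial_completers")
  if (any(partial_completers$runs_completed < 0 |
          partial_completers$runs_completed > runs_per_participant))
    stop("runs_completed out of range")
  structure(list(n_ci = n_ci, n_nh = n_nh,
                 runs_per_participant = runs_per_participant,
                 conditions = conditions,
                 trials_per_block = trials_per_block,
                 sentence_trials_per_block = sentence_trials_per_block,
                 null_trials_per_block = null_trials_per_block,
                 response_deadline = response_deadline,
                 partial_completers = partial_completers,
                 participant_id = ids, group = groups),
            class = "design_spec")
}

#' Expected number of trial rows for a design
#'
#' Closed-form row count: full completers contribute
#' `runs x 3 x trials_per_block` rows each, partial completers only their
#' completed runs.
#'
#' @param spec A `design_spec`.
#' @return Integer row count.
#' @export
design_n_trials <- function(spec) {
  stopifnot(inherits(spec, "design_spec"))
  per_run <- 3L * spec$trials_per_block
  runs <- rep(spec$runs_per_participant, length(spec$participant_id))
  names(runs) <- spec$participant_id
  runs[spec$partial_completers$participant_id] <- spec$partial_completers$runs_completed
  sum(runs) * per_run
}

#' Build the trial schedule
#'
#' Expands a design into one row per trial with randomized block (condition)
#' order per run and randomized interleaving of sentence and null trials
#' within block. Stimulus-onset jitter (uniform on 6-10 s) and the
#' instructed/probed correct response are carried as schedule metadata.
#' Outcome columns (`response`, `correct`, `rt_seconds`, `missing`) are NA.
#'
#' @param spec A `design_spec`.
#' @param seed Optional integer seed.
#' @return data.frame of trial records without outcomes.
#' @export
build_design <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "design_spec"))
  if (!is.null(seed)) set.seed(seed)
  runs <- rep(spec$runs_per_participant, length(spec$participant_id))
  names(runs) <- spec$participant_id
  runs[spec$partial_completers$participant_id] <- spec$partial_completers$runs_completed
  out <- vector("list", sum(runs) * 3L)
  k <- 0L
  for (p in seq_along(spec$participant_id)) {
    pid <- spec$participant_id[p]
    for (r in seq_len(runs[[pid]])) {
      block_conditions <- sample(spec$conditions)
      for (blk in 1:3) {
        types <- sample(rep(c("sentence", "null"),
                            c(spec$sentence_trials_per_block,
                              spec$null_trials_per_block)))
        n <- spec$trials_per_block
        k <- k + 1L
        out[[k]] <- data.frame(
          participant_id = pid, group = spec$group[p], run = r,
          block_index = blk, condition = block_conditions[blk],
          trial_index = seq_len(n), trial_type = types,
          correct_response = sample(c("yes", "no"), n, replace = TRUE),
          onset_jitter = stats::runif(n, 6, 10),
          response = NA_character_, correct = NA, rt_seconds = NA_real_,
          missing = NA)
      }
    }
  }
  if (k == 0L)
    return(data.frame(participant_id = character(0), group = character(0),
                      run = integer(0), block_index = integer(0),
                      condition = character(0), trial_index = integer(0),
                      trial_type = character(0), correct_response = character(0),
                      onset_jitter = numeric(0), response = character(0),
                      correct = logical(0), rt_seconds = numeric(0),
                      missing = logical(0)))
  do.call(rbind, out[seq_len(k)])
}

#' Generative ground truth
#'
#' Group-level means and covariance of the individual log-scale LBA
#' parameters. Defaults place the differential drift rates at the published
#' group posterior means for a CI/NH speech-in-noise cohort, with
#' `v_incorrect = 1` in every cell, `A = 1`, response caution 2.70 (CI) and
#' 2.76 (NH) giving `k = caution - A/2`, and `t0 = 0.21` s.
#'
#' @param vdiff Named list with `CI` and `NH` numeric vectors of 6 cell
#'   differential drifts in canonical order (Easy, Med, Hard within sentence,
#'   then null).
#' @param v_incorrect Incorrect-accumulator drift mean (natural scale).
#' @param A Start-point range.
#' @param caution Named vector of response caution (`k + A/2`) per group.
#' @param t0 Non-decision time (s).
#' @param sd_log Named vector of individual log-scale SDs for `drift`, `A`,
#'   `k`, `t0`.
#' @param corr Common pairwise correlation among individual log-parameters
#'   (default 0, i.e. diagonal covariance).
#' @param drift_sign Optional named vector of +/-1 per drift cell (a sign
#'   applied after exponentiation, allowing negative generative drifts);
#'   default all +1.
#' @return A `ground_truth` object with per-group `mu_log` (named 15-vector)
#'   and `sigma_log` (15 x 15 covariance).
#' @export
ground_truth <- function(vdiff = list(
                           NH = c(4.14, 4.04, 3.62, 4.32, 4.20, 4.50),
                           CI = c(2.79, 2.16, 1.57, 3.60, 3.74, 4.10)),
                         v_incorrect = 1, A = 1,
                         caution = c(CI = 2.70, NH = 2.76), t0 = 0.21,
                         sd_log = c(drift = 0.15, A = 0.15, k = 0.15, t0 = 0.10),
                         corr = 0, drift_sign = NULL) {
  nm <- c(drift_names(), "A", "k", "t0")
  if (is.null(drift_sign)) drift_sign <- stats::setNames(rep(1, 12), drift_names())
  stopifnot(all(abs(drift_sign) == 1), setequal(names(drift_sign), drift_names()))
  if (abs(corr) >= 1) stop("corr must lie in (-1, 1)")
  groups <- lapply(names(vdiff), function(g) {
    vd <- vdiff[[g]]
    stopifnot(length(vd) == 6)
    v <- numeric(12)
    # canonical order pairs (correct, incorrect) per cell
    v[seq(1, 12, 2)] <- v_incorrect + vd
    v[seq(2, 12, 2)] <- v_incorrect
    if (any(v <= 0)) stop("natural-scale generative drifts must be positive ",
                          "(use drift_sign for negative drifts)")
    k <- caution[[g]] - A / 2
    if (k <= 0) stop("caution must exceed A/2")
    mu <- log(c(v, A, k, t0))
    names(mu) <- nm
    sds <- c(rep(sd_log[["drift"]], 12), sd_log[["A"]], sd_log[["k"]], sd_log[["t0"]])
    sig <- diag(sds^2)
    if (corr != 0) sig <- outer(sds, sds) * (corr + diag(1 - corr, 15))
    dimnames(sig) <- list(nm, nm)
    list(mu_log = mu, sigma_log = sig)
  })
  names(groups) <- names(vdiff)
  structure(list(groups = groups, drift_sign = drift_sign[drift_names()]),
            class = "ground_truth")
}

#' Draw individual participant parameters
#'
#' Individual log-parameters are drawn from the group multivariate normal
#' and exponentiated to the natural scale (so A, k, t0 and drift magnitudes
#' are positive by construction); an optional per-cell sign field then flips
#' drift signs.
#'
#' @param truth A `ground_truth` object.
#' @param spec A `design_spec`.
#' @param seed Optional integer seed.
#' @return data.frame with `participant_id`, `group`, the 12 drift columns
#'   (natural scale) and `A`, `k`, `t0`.
#' @export
draw_participants <- function(truth, spec, seed = NULL) {
  stopifnot(inherits(truth, "ground_truth"), inherits(spec, "design_spec"))
  if (!is.null(seed)) set.seed(seed)
  nm <- c(drift_names(), "A", "k", "t0")
  rows <- lapply(seq_along(spec$participant_id), function(p) {
    g <- spec$group[p]
    gt <- truth$groups[[g]]
    if (is.null(gt)) stop("ground truth has no group ", g)
    ev <- tryCatch(chol(gt$sigma_log), error = function(e)
      stop("covariance for group ", g, " is not positive definite"))
    z <- drop(gt$mu_log + crossprod(ev, stats::rnorm(15)))
    x <- exp(z)
    x[seq_len(12)] <- x[seq_len(12)] * truth$drift_sign
    stats::setNames(as.list(x), nm)
  })
  cbind(data.frame(participant_id = spec$participant_id, group = spec$group),
        do.call(rbind, lapply(rows, as.data.frame)))
}

# lba_params object for one row of a participant-parameter table
.params_from_row <- function(row) {
  v <- unlist(row[drift_names()])
  lba_params(A = row$A, k = row$k, t0 = row$t0, v = v)
}

#' Simulate behavioral outcomes on a schedule
#'
#' Runs the two-accumulator LBA race for every scheduled trial using each
#' participant's parameters. Trials whose RT exceeds the deadline, or where
#' no accumulator finishes, are marked missing (response `"none"`, RT and
#' correctness undefined).
#'
#' @param schedule Trial schedule from [build_design()].
#' @param params Participant parameter table from [draw_participants()].
#' @param deadline Response deadline in seconds.
#' @param seed Optional integer seed.
#' @return The schedule with `response`, `correct`, `rt_seconds`, `missing`
#'   filled in.
#' @export
simulate_behavior <- function(schedule, params, deadline = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (deadline < 0) stop("deadline must be >= 0")
  n <- nrow(schedule)
  if (n == 0) return(schedule)
  idx <- match(schedule$participant_id, params$participant_id)
  if (anyNA(idx)) stop("schedule contains participants absent from params")
  key_c <- paste("v", "correct", schedule$condition, schedule$trial_type, sep = ".")
  key_i <- paste("v", "incorrect", schedule$condition, schedule$trial_type, sep = ".")
  vmat <- as.matrix(params[, drift_names()])
  vc <- vmat[cbind(idx, match(key_c, drift_names()))]
  vi <- vmat[cbind(idx, match(key_i, drift_names()))]
  A <- params$A[idx]; b <- params$A[idx] + params$k[idx]; t0 <- params$t0[idx]
  d_c <- stats::rnorm(n, vc, 1); d_i <- stats::rnorm(n, vi, 1)
  ft_c <- ifelse(d_c > 0, (b - stats::runif(n, 0, A)) / d_c, Inf)
  ft_i <- ifelse(d_i > 0, (b - stats::runif(n, 0, A)) / d_i, Inf)
  rt <- pmin(ft_c, ft_i) + t0
  winner_correct <- ft_c <= ft_i
  missing <- !is.finite(rt) | rt > deadline
  response <- ifelse(winner_correct, schedule$correct_response,
                     ifelse(schedule$correct_response == "yes", "no", "yes"))
  schedule$response <- ifelse(missing, "none", response)
  schedule$correct <- ifelse(missing, NA, winner_correct)
  schedule$rt_seconds <- ifelse(missing, NA_real_, rt)
  schedule$missing <- missing
  schedule
}

#' Default generative effects for task ratings
#'
#' Linear-predictor (logit-scale) cell effects for the three visual-analog
#' questions (EF perceived effort, IN perceived intelligibility, TD task
#' disengagement) by group and condition, chosen so effort and disengagement
#' increase and intelligibility decreases with difficulty, more steeply for
#' the CI group.
#'
#' @param cutpoints Ordered cutpoints (logit scale) governing the point
#'   masses at 0 and 1.
#' @param phi Beta precision of the continuous part.
#' @param intercept_sd SD of participant random intercepts (logit scale).
#' @return A `rating_effects` object.
#' @export
rating_effects <- function(cutpoints = c(-3, 3), phi = 8, intercept_sd = 0.5) {
  if (!(cutpoints[1] < cutpoints[2])) stop("cutpoints must be ordered c1 < c2")
  if (phi <= 0) stop("phi must be positive")
  eta <- expand.grid(group = c("CI", "NH"), condition = c("Easy", "Med", "Hard"),
                     question = c("EF", "IN", "TD"), stringsAsFactors = FALSE)
  base <- list(
    EF = list(CI = c(-1.0, 0.0, 1.0), NH = c(-2.5, -1.8, -1.0)),
    IN = list(CI = c(1.5, 0.8, -0.2), NH = c(3.0, 2.6, 2.1)),
    TD = list(CI = c(-2.5, -1.8, -1.0), NH = c(-4.0, -3.6, -3.0)))
  eta$eta <- mapply(function(g, cond, q)
    base[[q]][[g]][match(cond, c("Easy", "Med", "Hard"))],
    eta$group, eta$condition, eta$question)
  structure(list(eta = eta, cutpoints = cutpoints, phi = phi,
                 intercept_sd = intercept_sd), class = "rating_effects")
}

#' Simulate bounded visual-analog ratings
#'
#' One rating per participant x condition x question, drawn from the ordered
#' beta generative model (point masses at exactly 0 and 1 plus a beta
#' continuous interior) with participant random intercepts on the linear
#' predictor.
#'
#' @param spec A `design_spec`.
#' @param effects A `rating_effects` object.
#' @param seed Optional integer seed.
#' @return data.frame with columns `participant_id`, `group`, `condition`,
#'   `question`, `rating`.
#' @export
simulate_ratings <- function(spec, effects = rating_effects(), seed = NULL) {
  stopifnot(inherits(spec, "design_spec"), inherits(effects, "rating_effects"))
  if (!is.null(seed)) set.seed(seed)
  n <- length(spec$participant_id)
  u <- stats::rnorm(n, 0, effects$intercept_sd)
  grid <- expand.grid(i = seq_len(n), condition = spec$conditions,
                      question = unique(effects$eta$question),
                      stringsAsFactors = FALSE)
  key <- paste(spec$group[grid$i], grid$condition, grid$question)
  eff_key <- paste(effects$eta$group, effects$eta$condition, effects$eta$question)
  eta <- effects$eta$eta[match(key, eff_key)] + u[grid$i]
  if (anyNA(eta)) stop("missing cell effect for some group x condition x question")
  data.frame(participant_id = spec$participant_id[grid$i],
             group = spec$group[grid$i],
             condition = grid$condition, question = grid$question,
             rating = rordbeta(length(eta), eta, effects$cutpoints[1],
                               effects$cutpoints[2], effects$phi))
}

#' Default instrument table
#'
#' Score ranges, plausible location/spread, orientation, and target
#' correlations with individual listening efficiency used by
#' [simulate_scores()]. Positive orientation means higher scores accompany
#' higher efficiency.
#'
#' @return data.frame with one row per instrument.
#' @export
default_instruments <- function() {
  data.frame(
    instrument  = c("SSQ12", "EAS", "TRT", "FAS", "HHQ", "RSpan", "Age"),
    min         = c(0, 0, 30, 10, 0, 0, 18),
    max         = c(10, 60, 90, 40, 100, 1, 90),
    center      = c(6, 30, 58, 22, 40, 0.55, 62),
    spread      = c(1.6, 10, 8, 5, 18, 0.12, 9),
    target_corr = c(0.4, -0.3, -0.4, -0.1, -0.2, 0.2, -0.1))
}

#' Simulate score tables correlated with efficiency
#'
#' Gaussian-copula construction: each instrument's score is a linear blend of
#' the standardized efficiency values and independent Gaussian noise chosen
#' so the population correlation equals the target, then rescaled to the
#' instrument's location/spread and (optionally) clipped to its range.
#' Clipping slightly attenuates the realized correlation.
#'
#' @param efficiency data.frame with `participant_id`, `group`, `efficiency`.
#' @param instruments Instrument table as from [default_instruments()].
#' @param seed Optional integer seed.
#' @param clip Clip scores to the instrument range (default TRUE).
#' @return data.frame with columns `participant_id`, `group`, `instrument`,
#'   `score`.
#' @export
simulate_scores <- function(efficiency, instruments = default_instruments(),
                            seed = NULL, clip = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(c("participant_id", "group", "efficiency") %in% names(efficiency)))
  if (any(abs(instruments$target_corr) > 1))
    stop("target correlations must lie in [-1, 1]")
  if (any(instruments$min >= instruments$max)) stop("invalid instrument range")
  n <- nrow(efficiency)
  e <- efficiency$efficiency
  z <- if (stats::sd(e) > 0) (e - mean(e)) / stats::sd(e) else rep(0, n)
  out <- lapply(seq_len(nrow(instruments)), function(j) {
    rho <- instruments$target_corr[j]
    lat <- rho * z + sqrt(1 - rho^2) * stats::rnorm(n)
    s <- instruments$center[j] + instruments$spread[j] * lat
    if (clip) s <- pmin(pmax(s, instruments$min[j]), instruments$max[j])
    data.frame(participant_id = efficiency$participant_id,
               group = efficiency$group,
               instrument = instruments$instrument[j], score = s)
  })
  do.call(rbind, out)
}

#' Rescale questionnaire totals to the unit interval
#'
#' EAS totals are divided by 60, FAS totals map by `(score - 10)/30` (ten
#' items scored 1-5), HHQ by 100, SSQ12 by 10; RSpan is already a proportion
#' and TRT (an unmasked-text percentage) is divided by 100.
#'
#' @param instrument Instrument name(s).
#' @param score Raw score(s).
#' @return Values in `[0, 1]`.
#' @export
score_to_unit <- function(instrument, score) {
  lo <- c(SSQ12 = 0, EAS = 0, TRT = 0, FAS = 10, HHQ = 0, RSpan = 0)[instrument]
  sc <- c(SSQ12 = 10, EAS = 60, TRT = 100, FAS = 30, HHQ = 100, RSpan = 1)[instrument]
  if (anyNA(lo)) stop("unknown instrument: ",
                      paste(unique(instrument[is.na(lo)]), collapse = ", "))
  unname((score - lo) / sc)
}

#' @rdname score_to_unit
#' @param unit Values in `[0, 1]` to map back to the raw scale.
#' @export
unit_to_score <- function(instrument, unit) {
  lo <- c(SSQ12 = 0, EAS = 0, TRT = 0, FAS = 10, HHQ = 0, RSpan = 0)[instrument]
  sc <- c(SSQ12 = 10, EAS = 60, TRT = 100, FAS = 30, HHQ = 100, RSpan = 1)[instrument]
  if (anyNA(lo)) stop("unknown instrument")
  unname(unit * sc + lo)
}
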