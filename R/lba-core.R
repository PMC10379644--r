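# Exact linear ballistic accumulator (LBA) mathematics: single-accumulator
# first-passage density/CDF, defective joint density of (choice, RT), choice
# probabilities by quadrature, the race sampler, and the trial-level
# log-likelihood with chance-level treatment of deadline-censored trials.

# Canonical cell labels: 2 responses x 3 conditions x 2 trial types.
.responses   <- c("correct", "incorrect")
.conditions  <- c("Easy", "Med", "Hard")
.trial_types <- c("sentence", "null")

#' Drift-rate cell names
#'
#' The twelve drift-rate labels used throughout the package, in canonical
#' order: response (correct, incorrect) varying fastest, then condition
#' (Easy, Med, Hard), then trial type (sentence, null).
#'
#' @return Character vector of length 12, e.g. `"v.correct.Easy.sentence"`.
#' @export
drift_names <- function() {
  g <- expand.grid(response = .responses, condition = .conditions,
                   trial_type = .trial_types, stringsAsFactors = FALSE)
  paste("v", g$response, g$condition, g$trial_type, sep = ".")
}

#' Construct LBA parameters
#'
#' Bundle the decision-model parameters of a single participant (or of a
#' group-level mean). The start point of each accumulator is uniform on
#' `[0, A]`; the threshold is `b = A + k`, so `b > A` is structural.
#' `response_caution = k + A/2` is the average evidence required to respond.
#'
#' @param A Start-point range (> 0).
#' @param k Threshold gap `b - A` (> 0).
#' @param t0 Non-decision time in seconds (>= 0).
#' @param v Named numeric vector of 12 drift-rate means; names must be
#'   `drift_names()` (any order). Alternatively a single number, recycled.
#' @param sv Between-trial drift standard deviation; fixed to 1 by the model
#'   scaling constraint unless explicitly overridden.
#' @return An object of class `lba_params`.
#' @export
lba_params <- function(A, k, t0, v, sv = 1) {
  stopifnot(is.numeric(A), length(A) == 1L, is.numeric(k), length(k) == 1L,
            is.numeric(t0), length(t0) == 1L)
  if (!is.finite(A) || A <= 0) stop("A must be a positive finite number")
  if (!is.finite(k) || k <= 0) stop("k must be a positive finite number")
  if (!is.finite(t0) || t0 < 0) stop("t0 must be non-negative")
  if (!is.finite(sv) || sv <= 0) stop("sv must be positive")
  nm <- drift_names()
  if (length(v) == 1L && is.null(names(v))) v <- stats::setNames(rep(v, 12L), nm)
  if (is.null(names(v)) || !setequal(names(v), nm))
    stop("v must be a named vector covering all 12 drift cells (see drift_names())")
  v <- v[nm]
  structure(list(A = A, k = k, b = A + k, t0 = t0, v = v, sv = sv,
                 response_caution = k + A / 2),
            class = "lba_params")
}

#' @export
print.lba_params <- function(x, ...) {
  cat("LBA parameters: A =", signif(x$A, 4), " k =", signif(x$k, 4),
      " (b =", signif(x$b, 4), ")  t0 =", signif(x$t0, 4),
      " sv =", x$sv, "\n")
  cat("response caution (k + A/2):", signif(x$response_caution, 4), "\n")
  print(round(x$v, 3))
  invisible(x)
}

# look up the (correct, incorrect) drift pair for one design cell
.v_pair <- function(params, condition, trial_type) {
  condition <- match.arg(condition, .conditions)
  trial_type <- match.arg(trial_type, .trial_types)
  c(correct   = unname(params$v[paste("v", "correct", condition, trial_type, sep = ".")]),
    incorrect = unname(params$v[paste("v", "incorrect", condition, trial_type, sep = ".")]))
}

.check_acc <- function(A, b, s) {
  if (any(!is.finite(A)) || any(A <= 0)) stop("A must be positive")
  if (any(!is.finite(b)) || any(b < A)) stop("b must satisfy b >= A")
  if (any(!is.finite(s)) || any(s <= 0)) stop("s must be positive")
}

#' First-passage density of a single LBA accumulator
#'
#' Density of the time at which one accumulator (start point uniform on
#' `[0, A]`, drift drawn from Normal(`v`, `s`), threshold `b`) first reaches
#' threshold. The distribution is defective: total mass equals the
#' probability of a positive sampled drift (negative drifts never finish).
#'
#' @param t Decision time(s), in seconds (vectorized).
#' @param A,b,v,s Accumulator parameters; `b >= A > 0`, `s > 0`.
#' @return Density values; 0 for `t <= 0`.
#' @export
lba_pdf <- function(t, A, b, v, s = 1) {
  .check_acc(A, b, s)
  out <- numeric(length(t))
  pos <- is.finite(t) & t > 0
  if (any(pos)) {
    tt <- t[pos]
    ts <- tt * s
    z1 <- (b - A - tt * v) / ts
    z2 <- (b - tt * v) / ts
    f <- (-v * stats::pnorm(z1) + s * stats::dnorm(z1) +
           v * stats::pnorm(z2) - s * stats::dnorm(z2)) / A
    out[pos] <- pmax(f, 0) # guard tiny negative round-off
  }
  out
}

#' First-passage CDF of a single LBA accumulator
#'
#' @inheritParams lba_pdf
#' @return Probabilities in `[0, 1]`; 0 for `t <= 0`. As `t` grows the CDF
#'   approaches `1 - pnorm(-v/s)`, the probability of a positive drift.
#' @export
lba_cdf <- function(t, A, b, v, s = 1) {
  .check_acc(A, b, s)
  out <- numeric(length(t))
  pos <- is.finite(t) & t > 0
  if (any(pos)) {
    tt <- t[pos]
    ts <- tt * s
    z1 <- (b - A - tt * v) / ts
    z2 <- (b - tt * v) / ts
    F <- 1 + ((b - A - tt * v) / A) * stats::pnorm(z1) -
             ((b - tt * v) / A) * stats::pnorm(z2) +
             (ts / A) * (stats::dnorm(z1) - stats::dnorm(z2))
    out[pos] <- pmin(pmax(F, 0), 1)
  }
  out[is.infinite(t) & t > 0] <- 1 - stats::pnorm(-v / s)
  out
}

#' Defective joint density of (choice, RT)
#'
#' Density that the accumulator labelled `choice` wins the race at observed
#' response time `t` (decision time `t - t0`): the winner's first-passage
#' density times the probability the other accumulator has not yet finished.
#' No renormalization for the no-finisher event is applied.
#'
#' @param t Observed RT(s) in seconds (vectorized).
#' @param choice `"correct"` or `"incorrect"`.
#' @param params An `lba_params` object.
#' @param condition One of `"Easy"`, `"Med"`, `"Hard"`.
#' @param trial_type `"sentence"` or `"null"`.
#' @return Density values; 0 for `t <= t0`.
#' @export
defective_density <- function(t, choice, params, condition, trial_type) {
  stopifnot(inherits(params, "lba_params"))
  choice <- match.arg(choice, .responses)
  vp <- .v_pair(params, condition, trial_type)
  vw <- vp[[choice]]
  vl <- vp[[setdiff(.responses, choice)]]
  td <- t - params$t0
  lba_pdf(td, params$A, params$b, vw, params$sv) *
    (1 - lba_cdf(td, params$A, params$b, vl, params$sv))
}

#' Choice probabilities by quadrature
#'
#' Integrates the defective density over decision times. The three outcome
#' probabilities (correct, incorrect, no finisher) sum to one; the
#' no-finisher probability equals the chance that both sampled drifts are
#' negative, `pnorm(-v_c/s) * pnorm(-v_i/s)`.
#'
#' @inheritParams defective_density
#' @return Named list with `p_correct`, `p_incorrect`, `p_none`.
#' @export
choice_probability <- function(params, condition, trial_type) {
  stopifnot(inherits(params, "lba_params"))
  int <- function(ch) {
    r <- stats::integrate(function(t) defective_density(t, ch, params, condition, trial_type),
                          lower = params$t0, upper = Inf,
                          rel.tol = 1e-9, abs.tol = 1e-12, stop.on.error = FALSE)
    if (r$message != "OK" && r$abs.error > 1e-6)
      warning("quadrature did not converge for choice probability (", ch, "): ", r$message)
    r$value
  }
  vp <- .v_pair(params, condition, trial_type)
  p_none <- stats::pnorm(-vp[["correct"]] / params$sv) *
            stats::pnorm(-vp[["incorrect"]] / params$sv)
  list(p_correct = int("correct"), p_incorrect = int("incorrect"), p_none = p_none)
}

#' Simulate the two-accumulator LBA race
#'
#' Per trial, each accumulator draws a start point uniform on `[0, A]` and a
#' drift from Normal(`v`, `sv`); its finish time is `(b - start)/drift` for
#' positive drifts and infinite otherwise. The winner determines the choice
#' and `RT = finish + t0`. Trials where neither accumulator finishes are
#' flagged.
#'
#' @inheritParams defective_density
#' @param n Number of trials (>= 0).
#' @param seed Optional integer seed for reproducibility.
#' @return data.frame with columns `choice` (`"correct"`/`"incorrect"`/`NA`),
#'   `rt` (seconds, `Inf` when no accumulator finishes) and `finished`.
#' @export
simulate_race <- function(params, condition, trial_type, n, seed = NULL) {
  stopifnot(inherits(params, "lba_params"), n >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (n == 0)
    return(data.frame(choice = character(0), rt = numeric(0), finished = logical(0)))
  vp <- .v_pair(params, condition, trial_type)
  start_c <- stats::runif(n, 0, params$A)
  start_i <- stats::runif(n, 0, params$A)
  d_c <- stats::rnorm(n, vp[["correct"]], params$sv)
  d_i <- stats::rnorm(n, vp[["incorrect"]], params$sv)
  ft_c <- ifelse(d_c > 0, (params$b - start_c) / d_c, Inf)
  ft_i <- ifelse(d_i > 0, (params$b - start_i) / d_i, Inf)
  finished <- is.finite(ft_c) | is.finite(ft_i)
  choice <- ifelse(ft_c <= ft_i, "correct", "incorrect")
  choice[!finished] <- NA_character_
  rt <- pmin(ft_c, ft_i) + params$t0
  data.frame(choice = choice, rt = rt, finished = finished)
}

# Vectorized log defective density used by the likelihood and the sampler
# (compiled kernel; td is decision time rt - t0). Returns -Inf for
# structural violations (td <= 0); otherwise densities are floored at
# 1e-300 before logging so numerical underflow is distinguished from
# support violations.
.log_defective <- function(td, A, b, vw, vl, s = 1) {
  n <- length(td)
  .cpp_log_defective(td, rep_len(A, n), rep_len(b, n), rep_len(vw, n),
                     rep_len(vl, n), s)
}

# log of the chance-level mixture density for a censored trial at latent RT
# tau: log(0.5 * g_correct(tau) + 0.5 * g_incorrect(tau)).
.log_missing_mix <- function(tau, A, b, vc, vi, t0, s = 1) {
  n <- length(tau)
  .cpp_log_missing_mix(tau, rep_len(A, n), rep_len(b, n), rep_len(vc, n),
                       rep_len(vi, n), rep_len(t0, n), s)
}

#' Trial-level LBA log-likelihood
#'
#' Sum over observed trials of the log defective density at the recorded
#' (choice, RT). Each deadline-censored (missing) trial contributes the
#' chance-level mixture `log(0.5 g_correct(tau) + 0.5 g_incorrect(tau))`
#' evaluated at its latent response time `tau`, which must exceed the
#' deadline (and stay below `cap`, the latent upper bound).
#'
#' @param trials data.frame of trial records with columns `condition`,
#'   `trial_type`, `correct` (logical; the winning accumulator), `rt_seconds`
#'   and `missing`.
#' @param params An `lba_params` object.
#' @param latent_missing_rts Numeric vector, one latent RT per missing trial
#'   (in the order missing trials appear).
#' @param deadline Response deadline in seconds.
#' @param cap Upper bound for latent missing RTs (default 10 s).
#' @return Scalar log-likelihood. An observed RT at or below `t0` makes the
#'   result `-Inf` and is reported via the `"support_violations"` attribute.
#' @export
lba_log_likelihood <- function(trials, params, latent_missing_rts = numeric(0),
                               deadline = 3, cap = 10) {
  stopifnot(inherits(params, "lba_params"))
  obs <- trials[!trials$missing, , drop = FALSE]
  mis <- trials[trials$missing, , drop = FALSE]
  if (nrow(mis) != length(latent_missing_rts))
    stop("need exactly one latent RT per missing trial (", nrow(mis), " needed)")
  if (length(latent_missing_rts) &&
      any(latent_missing_rts <= deadline | latent_missing_rts >= cap))
    stop("latent missing RTs must lie in (deadline, cap)")
  ll <- 0
  viol <- 0L
  if (nrow(obs)) {
    vci <- .trial_drifts(obs, params)
    w <- ifelse(obs$correct, vci$vc, vci$vi)
    l <- ifelse(obs$correct, vci$vi, vci$vc)
    td <- obs$rt_seconds - params$t0
    lt <- .log_defective(td, params$A, params$b, w, l, params$sv)
    viol <- sum(td <= 0)
    ll <- ll + sum(lt)
  }
  if (nrow(mis)) {
    vci <- .trial_drifts(mis, params)
    ll <- ll + sum(.log_missing_mix(latent_missing_rts, params$A, params$b,
                                    vci$vc, vci$vi, params$t0, params$sv))
  }
  structure(ll, support_violations = viol)
}

# per-trial (v_correct, v_incorrect) lookup from an lba_params object
.trial_drifts <- function(trials, params) {
  key_c <- paste("v", "correct", trials$condition, trials$trial_type, sep = ".")
  key_i <- paste("v", "incorrect", trials$condition, trials$trial_type, sep = ".")
  bad <- !(key_c %in% names(params$v))
  if (any(bad))
    stop("unknown condition/trial_type labels: ",
         paste(unique(paste(trials$condition, trials$trial_type)[bad]), collapse = ", "))
  list(vc = unname(params$v[key_c]), vi = unname(params$v[key_i]))
}
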