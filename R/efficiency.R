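# Listening-efficiency metrics: differential drift rates (vDiff = v_correct
# - v_incorrect), per-draw condition contrasts (mean and slope across the
# three ordered SNR conditions), between-group differences, highest-density
# intervals, and Cliff's delta effect sizes on posterior-predicted data.

#' Per-draw differential drift rates
#'
#' Exact per-draw subtraction `vDiff = v_correct - v_incorrect` for every
#' group x condition x trial-type cell of the group-level posterior (no
#' aggregation).
#'
#' @param draws An `lba_draws` object, or a numeric matrix whose columns are
#'   named `mu.<group>.v.<response>.<condition>.<trial_type>`.
#' @return data.frame with columns `draw`, `group`, `condition`,
#'   `trial_type`, `vDiff`.
#' @export
differential_drift <- function(draws) {
  M <- if (inherits(draws, "lba_draws")) draws_matrix(draws, "^mu\\.") else as.matrix(draws)
  cn <- colnames(M)
  grp <- unique(sub("^mu\\.([^.]+)\\..*$", "\\1", cn[grepl("^mu\\.[^.]+\\.v\\.", cn)]))
  if (!length(grp)) stop("no group-level drift columns found")
  out <- list()
  for (g in grp) for (tt in .trial_types) for (cond in .conditions) {
    kc <- paste("mu", g, "v", "correct", cond, tt, sep = ".")
    ki <- paste("mu", g, "v", "incorrect", cond, tt, sep = ".")
    if (!(kc %in% cn) || !(ki %in% cn))
      stop("missing accumulator column for cell ", g, " ", cond, " ", tt)
    out[[length(out) + 1L]] <- data.frame(
      draw = seq_len(nrow(M)), group = g, condition = cond, trial_type = tt,
      vDiff = M[, kc] - M[, ki])
  }
  do.call(rbind, out)
}

#' Mean and slope across conditions, per draw
#'
#' For each draw, group and trial type: the arithmetic mean of the three
#' condition values and the ordinary least-squares slope on equally spaced
#' condition codes (1, 2, 3), which for three points equals
#' `(Hard - Easy) / 2`.
#'
#' @param vdiff data.frame as returned by [differential_drift()] (columns
#'   `draw`, `group`, `trial_type`, `condition`, `vDiff`).
#' @param conditions The ordered condition labels (exactly three).
#' @return data.frame with columns `draw`, `group`, `trial_type`, `mean`,
#'   `slope`.
#' @export
condition_contrasts <- function(vdiff, conditions = c("Easy", "Med", "Hard")) {
  if (length(conditions) != 3) stop("exactly three ordered conditions required")
  if (!all(vdiff$condition %in% conditions))
    stop("unknown condition labels: ",
         paste(setdiff(unique(vdiff$condition), conditions), collapse = ", "))
  x <- match(vdiff$condition, conditions)
  key <- interaction(vdiff$draw, vdiff$group, vdiff$trial_type, drop = TRUE)
  if (any(tapply(x, key, length) != 3))
    stop("each draw x group x trial_type needs exactly one value per condition")
  xc <- x - 2 # centred codes (-1, 0, 1); sum of squares 2
  mean_v <- tapply(vdiff$vDiff, key, mean)
  slope_v <- tapply(vdiff$vDiff * xc, key, sum) / 2
  ids <- do.call(rbind, strsplit(names(mean_v), ".", fixed = TRUE))
  data.frame(draw = as.integer(ids[, 1]), group = ids[, 2],
             trial_type = ids[, 3], mean = as.numeric(mean_v),
             slope = as.numeric(slope_v), row.names = NULL)
}

#' Per-draw between-group difference
#'
#' Aligned per-draw subtraction (first group minus second, NH - CI by
#' default) of one or more per-draw quantities, with posterior mean and 95%
#' HDI summaries.
#'
#' @param df Long data.frame containing `draw`, `group`, the value column(s)
#'   and any further keys (e.g. `condition`, `trial_type`).
#' @param value Names of value columns to difference.
#' @param groups Character vector of length 2: difference is
#'   `groups[1] - groups[2]`.
#' @param mass HDI mass for the summary (default 0.95).
#' @return List with `draws` (per-draw differences keyed by the remaining
#'   columns) and `summary` (posterior mean and HDI per key and value
#'   column).
#' @export
group_difference <- function(df, value, groups = c("NH", "CI"), mass = 0.95) {
  stopifnot(length(groups) == 2, all(groups %in% df$group))
  keys <- setdiff(names(df), c("group", value))
  a <- df[df$group == groups[1], , drop = FALSE]
  b <- df[df$group == groups[2], , drop = FALSE]
  ka <- do.call(paste, a[keys]); kb <- do.call(paste, b[keys])
  idx <- match(ka, kb)
  if (anyNA(idx) || nrow(a) != nrow(b))
    stop("draws are misaligned across groups")
  out <- a[keys]
  for (v in value) out[[v]] <- a[[v]] - b[[v]][idx]
  skeys <- setdiff(keys, "draw")
  sk <- if (length(skeys)) interaction(out[skeys], drop = TRUE) else factor(rep(1, nrow(out)))
  summ <- do.call(rbind, lapply(levels(sk), function(lv) {
    rows <- out[sk == lv, , drop = FALSE]
    do.call(rbind, lapply(value, function(v) {
      h <- if (nrow(rows) >= 20) hdi(rows[[v]], mass) else range(rows[[v]])
      cbind(rows[1, skeys, drop = FALSE],
            data.frame(quantity = v, mean = mean(rows[[v]]),
                       lower = h[1], upper = h[2]))
    }))
  }))
  rownames(summ) <- NULL
  list(draws = out, summary = summ)
}

#' Highest-density interval
#'
#' Shortest contiguous window of `ceiling(mass * n)` sorted draws; ties are
#' broken toward the smallest lower bound.
#'
#' @param x Numeric sample (>= 20 draws).
#' @param mass Probability mass in (0, 1) (default 0.95).
#' @return Numeric vector `c(lower, upper)`.
#' @export
hdi <- function(x, mass = 0.95) {
  if (!is.numeric(x) || length(x) < 20) stop("hdi needs at least 20 draws")
  if (!(mass > 0 && mass < 1)) stop("mass must lie in (0, 1)")
  s <- sort(x)
  n <- length(s)
  m <- ceiling(mass * n)
  if (m >= n) return(c(s[1], s[n]))
  w <- s[(m):n] - s[seq_len(n - m + 1)]
  i <- which.min(w) # which.min returns the first (smallest lower bound) tie
  c(s[i], s[i + m - 1])
}

#' Cliff's delta
#'
#' Nonparametric effect size `P(x > y) - P(x < y)` over all cross-group
#' pairs, computed via midranks (ties contribute zero).
#'
#' @param x,y Numeric samples from the two groups (non-empty).
#' @return Delta in `[-1, 1]`.
#' @export
cliffs_delta <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (!nx || !ny) stop("both groups must be non-empty")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2 # #(x>y) + 0.5 #(x=y)
  2 * U / (nx * ny) - 1
}

#' Cliff's delta over posterior draws
#'
#' Applies [cliffs_delta()] per posterior draw to posterior-predicted
#' participant-level values (rows = draws, columns = participants), yielding
#' a posterior distribution of the effect size. A pooled variant collapses
#' all draws into two samples first.
#'
#' @param a,b Numeric matrices of predicted values (draws x participants) for
#'   the two groups, with aligned rows.
#' @param mass HDI mass for the summary.
#' @param pooled If TRUE, compute a single delta over all draws pooled.
#' @return For the per-draw variant, a list with `delta` (per-draw values),
#'   `mean` and `cri`; for the pooled variant a single number.
#' @export
cliffs_delta_posterior <- function(a, b, mass = 0.95, pooled = FALSE) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!ncol(a) || !ncol(b)) stop("both groups must be non-empty")
  if (pooled) return(cliffs_delta(as.vector(a), as.vector(b)))
  if (nrow(a) != nrow(b)) stop("draw counts must be aligned")
  d <- vapply(seq_len(nrow(a)), function(s) cliffs_delta(a[s, ], b[s, ]),
              numeric(1))
  list(delta = d, mean = mean(d),
       cri = if (length(d) >= 20) hdi(d, mass) else range(d))
}

#' Table-style efficiency summary
#'
#' Posterior mean and 95% HDI per group, plus the between-group difference,
#' for the non-decision time, response caution, the six cell-level
#' differential drift rates, and the mean and slope across conditions per
#' trial type — the layout of the published group-comparison table.
#'
#' @param draws An `lba_draws` object.
#' @param groups Character vector of length 2 (difference is
#'   `groups[1] - groups[2]`).
#' @param mass HDI mass.
#' @return data.frame with one row per parameter and nine numeric columns
#'   (mean/lower/upper for each group and for the difference).
#' @export
efficiency_summary <- function(draws, groups = c("NH", "CI"), mass = 0.95) {
  M <- draws_matrix(draws, "^mu\\.")
  nd <- nrow(M)
  per_group <- function(g) {
    t0 <- exp(M[, paste0("mu.", g, ".logt0")])
    caution <- exp(M[, paste0("mu.", g, ".logk")]) +
      exp(M[, paste0("mu.", g, ".logA")]) / 2
    vd <- differential_drift(M[, grepl(paste0("^mu\\.", g, "\\."), colnames(M)),
                               drop = FALSE])
    cc <- condition_contrasts(vd)
    cols <- list(t0 = t0, resp_caution = caution)
    for (tt in c("sentence", "null")) {
      lab <- if (tt == "sentence") "Sentence" else "Null"
      for (cond in .conditions) {
        v <- vd$vDiff[vd$condition == cond & vd$trial_type == tt]
        cols[[paste0("vDiff.", lab, ".", cond)]] <- v[order(vd$draw[vd$condition == cond & vd$trial_type == tt])]
      }
      o <- order(cc$draw[cc$trial_type == tt])
      cols[[paste0("vDiff.", lab, ".Mean")]] <- cc$mean[cc$trial_type == tt][o]
      cols[[paste0("vDiff.", lab, ".Slope")]] <- cc$slope[cc$trial_type == tt][o]
    }
    cols
  }
  ga <- per_group(groups[1]); gb <- per_group(groups[2])
  rows <- names(ga)
  out <- do.call(rbind, lapply(rows, function(p) {
    da <- ga[[p]]; db <- gb[[p]]; dd <- da - db
    ha <- hdi(da, mass); hb <- hdi(db, mass); hd <- hdi(dd, mass)
    data.frame(parameter = p,
               mean_a = mean(da), lower_a = ha[1], upper_a = ha[2],
               mean_b = mean(db), lower_b = hb[1], upper_b = hb[2],
               mean_diff = mean(dd), lower_diff = hd[1], upper_diff = hd[2])
  }))
  names(out) <- c("parameter",
                  paste0(c("mean.", "lower.", "upper."), groups[1]),
                  paste0(c("mean.", "lower.", "upper."), groups[2]),
                  "mean.diff", "lower.diff", "upper.diff")
  out
}
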