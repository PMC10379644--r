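# Pipeline orchestration: simulate -> fit -> metrics -> associate -> ratings
# -> report, as a reproducible, configured, logged sequence with one
# top-level seed deriving deterministic per-stage substreams.

#' Pipeline configuration
#'
#' @param seed Top-level integer seed (mandatory); per-stage substreams are
#'   derived deterministically from it.
#' @param mode `"simulate"` (generate data from `truth`) or `"data"` (read
#'   the three CSVs from `paths`).
#' @param spec A `design_spec`.
#' @param truth A `ground_truth` (simulate mode).
#' @param paths Named list with `trials`, `scores`, `ratings` (data mode).
#' @param chains,warmup,iters,mh_sweeps Sampler settings.
#' @param hdi_mass Credible mass for all interval summaries.
#' @param rho_grid Grid size for the population-correlation posterior.
#' @param structural `"hierarchical"` or `"shared"` A/k/t0 within group.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(seed, mode = c("simulate", "data"),
                            spec = design_spec(), truth = ground_truth(),
                            paths = NULL, chains = 4, warmup = 1000,
                            iters = 2000, mh_sweeps = 3, hdi_mass = 0.95,
                            rho_grid = 2001,
                            structural = c("hierarchical", "shared")) {
  mode <- match.arg(mode)
  structural <- match.arg(structural)
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  if (mode == "data") {
    need <- c("trials", "scores", "ratings")
    if (is.null(paths) || !all(need %in% names(paths)))
      stop("data mode requires paths$trials, paths$scores, paths$ratings")
    absent <- !vapply(paths[need], file.exists, logical(1))
    if (any(absent))
      stop("missing input files: ", paste(unlist(paths[need])[absent], collapse = ", "))
  }
  structure(list(seed = as.integer(seed), mode = mode, spec = spec,
                 truth = truth, paths = paths, chains = chains,
                 warmup = warmup, iters = iters, mh_sweeps = mh_sweeps,
                 hdi_mass = hdi_mass, rho_grid = rho_grid,
                 structural = structural),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' The file holds the scalar settings plus optional `design` and
#' `ground_truth` blocks whose fields are passed to [design_spec()] and
#' [ground_truth()]; a top-level `seed` is required.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  spec <- do.call(design_spec, cfg$design %||% list())
  tr_args <- cfg$ground_truth %||% list()
  if (!is.null(tr_args$vdiff)) tr_args$vdiff <- lapply(tr_args$vdiff, unlist)
  if (!is.null(tr_args$caution)) tr_args$caution <- unlist(tr_args$caution)
  if (!is.null(tr_args$sd_log)) tr_args$sd_log <- unlist(tr_args$sd_log)
  truth <- do.call(ground_truth, tr_args)
  args <- cfg[intersect(names(cfg), c("seed", "mode", "paths", "chains",
                                      "warmup", "iters", "mh_sweeps",
                                      "hdi_mass", "rho_grid", "structural"))]
  do.call(pipeline_config, c(args, list(spec = spec, truth = truth)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic per-stage substream seeds from the top-level seed
.stage_seeds <- function(seed) {
  set.seed(seed)
  stats::setNames(sample.int(.Machine$integer.max - 1, 6),
                  c("design", "participants", "behavior", "ratings", "scores",
                    "sampler"))
}

# tiny FNV-1a hash of the JSON-serialized config, for the run manifest
.config_hash <- function(config) {
  s <- jsonlite::toJSON(config[c("seed", "mode", "chains", "warmup", "iters",
                                 "mh_sweeps", "hdi_mass", "rho_grid",
                                 "structural")],
                        auto_unbox = TRUE, force = TRUE)
  bytes <- utf8ToInt(as.character(s))
  h <- 2166136261
  for (b in bytes) h <- bitwAnd(bitwXor(h, b) * 16777619, 0xFFFFFFFF)
  sprintf("%08x", h)
}

#' Validate pipeline input tables
#'
#' Schema, range and referential checks on trial, score and rating tables:
#' unknown labels, non-positive RTs and deadline violations are fatal;
#' participants present in one table but absent from another are warnings.
#'
#' @param trials,scores,ratings Tables (as from the readers) or file paths.
#' @param deadline Response deadline in seconds.
#' @return data.frame with columns `severity` (`"error"`/`"warning"`) and
#'   `message`; zero rows when everything is clean.
#' @export
validate_inputs <- function(trials, scores = NULL, ratings = NULL, deadline = 3) {
  if (is.character(trials)) trials <- read_trials(trials)
  if (is.character(scores)) scores <- read_scores(scores)
  if (is.character(ratings)) ratings <- read_ratings(ratings)
  probs <- list()
  add <- function(sev, msg) probs[[length(probs) + 1]] <<- data.frame(severity = sev, message = msg)
  miss_cols <- setdiff(.trial_cols, names(trials))
  if (length(miss_cols)) {
    add("error", paste("trials lack columns:", paste(miss_cols, collapse = ", ")))
    return(do.call(rbind, probs))
  }
  bad <- setdiff(unique(trials$condition), .conditions)
  if (length(bad)) add("error", paste("unknown condition labels:", paste(bad, collapse = ", ")))
  bad <- setdiff(unique(trials$trial_type), .trial_types)
  if (length(bad)) add("error", paste("unknown trial types:", paste(bad, collapse = ", ")))
  obs <- !trials$missing
  if (any(obs & (is.na(trials$rt_seconds) | trials$rt_seconds <= 0)))
    add("error", "observed trials with undefined or non-positive rt_seconds")
  if (any(obs & trials$rt_seconds > deadline, na.rm = TRUE))
    add("error", sprintf("rt_seconds above the %.3g s deadline on trials not marked missing", deadline))
  if (any(trials$missing & trials$response != "none"))
    add("error", "missing trials must have response 'none'")
  if (any(obs & trials$response == "none"))
    add("error", "non-missing trials with response 'none'")
  tp <- unique(trials$participant_id)
  if (!is.null(scores)) {
    extra <- setdiff(unique(scores$participant_id), tp)
    if (length(extra))
      add("warning", paste("participants in scores but absent from trials:",
                           paste(extra, collapse = ", ")))
  }
  if (!is.null(ratings)) {
    extra <- setdiff(unique(ratings$participant_id), tp)
    if (length(extra))
      add("warning", paste("participants in ratings but absent from trials:",
                           paste(extra, collapse = ", ")))
    if (any(ratings$rating < 0 | ratings$rating > 1, na.rm = TRUE))
      add("error", "ratings outside [0, 1]")
  }
  if (length(probs)) do.call(rbind, probs)
  else data.frame(severity = character(0), message = character(0))
}

#' Run the full analysis pipeline
#'
#' simulate (or load) -> validate -> fit the hierarchical LBA -> efficiency
#' summary -> plausible-values associations -> rating models -> report. All
#' artifacts are written under `out_dir`: trial/score/rating CSVs (simulate
#' mode), posterior draws with diagnostics, the group-comparison efficiency
#' table, association JSON, rating-model cell means, and a run manifest with
#' the configuration hash and stage timings. Identical configurations yield
#' byte-identical numeric outputs.
#'
#' @param config A `pipeline_config`.
#' @param out_dir Output directory (created if needed).
#' @param progress Print stage messages.
#' @return Invisibly, a list with the in-memory results (`trials`, `draws`,
#'   `efficiency`, `associations`, `ratings_fit`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir, progress = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- .stage_seeds(config$seed)
  t_start <- proc.time()[["elapsed"]]
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    if (progress) message("[", name, "] ...")
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 2)
    res
  }
  deadline <- config$spec$response_deadline

  if (config$mode == "simulate") {
    trials <- stage("simulate", {
      sched <- build_design(config$spec, seed = seeds[["design"]])
      ppar <- draw_participants(config$truth, config$spec, seed = seeds[["participants"]])
      simulate_behavior(sched, ppar, deadline = deadline, seed = seeds[["behavior"]])
    })
    ratings <- simulate_ratings(config$spec, seed = seeds[["ratings"]])
    truth_eff <- local({
      ppar <- draw_participants(config$truth, config$spec, seed = seeds[["participants"]])
      vs <- as.matrix(ppar[, drift_names()])
      sent <- grepl("sentence", drift_names())
      vc <- vs[, sent & grepl("correct", drift_names()) & !grepl("incorrect", drift_names())]
      vi <- vs[, sent & grepl("incorrect", drift_names())]
      data.frame(participant_id = ppar$participant_id, group = ppar$group,
                 efficiency = rowMeans(vc - vi))
    })
    scores <- simulate_scores(truth_eff, seed = seeds[["scores"]])
    write_trials(trials, file.path(out_dir, "trials.csv"))
    write_ratings(ratings, file.path(out_dir, "ratings.csv"))
    write_scores(scores, file.path(out_dir, "scores.csv"))
  } else {
    trials <- read_trials(config$paths$trials)
    scores <- read_scores(config$paths$scores)
    ratings <- read_ratings(config$paths$ratings)
  }

  report <- stage("validate", validate_inputs(trials, scores, ratings, deadline))
  if (any(report$severity == "error"))
    stop("pipeline stage 'validate' failed:\n",
         paste(report$message[report$severity == "error"], collapse = "\n"),
         call. = FALSE)

  draws <- stage("fit", {
    model <- build_model(trials, deadline = deadline,
                         structural = config$structural)
    sample_posterior(model, chains = config$chains, warmup = config$warmup,
                     iters = config$iters, seed = seeds[["sampler"]],
                     mh_sweeps = config$mh_sweeps, progress = progress)
  })
  write_draws(draws, file.path(out_dir, "draws.csv"),
              file.path(out_dir, "diagnostics.json"))

  groups <- sort(unique(trials$group), decreasing = TRUE) # NH before CI
  eff_tab <- stage("metrics", efficiency_summary(draws, groups = groups,
                                                 mass = config$hdi_mass))
  utils::write.csv(eff_tab, file.path(out_dir, "efficiency_summary.csv"),
                   row.names = FALSE)

  assoc <- stage("associate", {
    eff <- individual_efficiency(draws)
    out <- list()
    for (g in unique(scores$group)) for (ins in unique(scores$instrument)) {
      sg <- scores[scores$group == g & scores$instrument == ins, ]
      cols <- colnames(eff)[attr(eff, "group") == g & colnames(eff) %in% sg$participant_id]
      if (length(cols) < 4) next
      rs <- plausible_correlations(eff[, cols, drop = FALSE],
                                   stats::setNames(sg$score, sg$participant_id))
      post <- population_rho_posterior(rs, n = length(cols),
                                       grid_n = config$rho_grid,
                                       mass = config$hdi_mass)
      fl <- reliability_flag(post)
      out[[paste(g, ins, sep = ".")]] <- list(
        group = g, instrument = ins, n = length(cols),
        r_mean = mean(rs), r_cri = as.numeric(stats::quantile(rs, c(0.025, 0.975))),
        rho_mean = post$mean, rho_cri = post$cri,
        p_pos = post$p_pos, p_neg = post$p_neg,
        certainty = fl$certainty, reliable = fl$reliable)
    }
    out
  })
  jsonlite::write_json(assoc, file.path(out_dir, "associations.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  ratings_fit <- stage("ratings", {
    lapply(split(ratings, ratings$question), function(rq)
      fit_rating_model(rq, chains = 2, warmup = 400, iters = 400,
                       seed = seeds[["sampler"]] %% 100000L))
  })
  cm <- do.call(rbind, lapply(names(ratings_fit), function(q)
    cbind(question = q, ratings_fit[[q]]$cell_means)))
  utils::write.csv(cm, file.path(out_dir, "rating_cell_means.csv"),
                   row.names = FALSE)

  manifest <- list(
    config_hash = .config_hash(config), seed = config$seed,
    mode = config$mode, stage_seeds = as.list(seeds),
    n_trials = nrow(trials), n_draws = n_draws(draws),
    rhat_range = range(draws$rhat, na.rm = TRUE),
    timings_seconds = timings,
    total_seconds = round(proc.time()[["elapsed"]] - t_start, 2),
    r_version = as.character(getRversion()))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(trials = trials, draws = draws, efficiency = eff_tab,
                 associations = assoc, ratings_fit = ratings_fit,
                 manifest = manifest))
}
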