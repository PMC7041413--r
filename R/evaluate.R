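#' Monte-Carlo estimate of the network error
#'
#' The error of a learned network is the expected error feedback
#' `E[L(x, y)]` under inputs drawn from the task's input distribution and
#' outputs sampled through the (frozen) network. Estimated from `m` fresh
#' activations; learning is never mutated.
#'
#' @param state A [synapse_state()].
#' @param task A `bump_task`.
#' @param m Number of evaluation samples.
#' @param k_A,k_B Bump widths used for evaluation.
#' @param width_rule Optional function mapping the live synapse count of
#'   the activated input neuron to `c(k_A, k_B)` (dynamic-width networks).
#' @return List with `mean`, `se` (standard error) and `m`.
#' @export
estimate_error <- function(state, task, m = 1000, k_A = 1, k_B = k_A,
                           width_rule = NULL) {
  stopifnot(m >= 1)
  gA <- state$grid_in
  gB <- state$grid_out
  circ <- gB$topology == "circular"
  live_counts <- if (!is.null(width_rule)) rowSums(state$p > 0) else NULL
  L <- numeric(m)
  for (s in seq_len(m)) {
    x <- task$sample_input()
    a <- encode_value(x, gA)
    a_flat <- flat_index(a, gA)
    if (!is.null(width_rule)) {
      kk <- width_rule(live_counts[a_flat])
      k_A_s <- min(kk[1], gA$n)
      k_B_s <- min(kk[2], gB$n)
    } else {
      k_A_s <- k_A
      k_B_s <- k_B
    }
    I <- make_bump(a, k_A_s, gA)
    center <- .cpp_activate_bernoulli(state$p, I$flat, gB$n, gB$d, k_B_s,
                                      circ)$center
    y <- drop(tuple_index(center, gB)) / gB$n
    L[s] <- task$feedback(x, y)
  }
  list(mean = mean(L), se = stats::sd(L) / sqrt(m), m = m)
}

#' Samples required to come close to the final error
#'
#' Reads a learning curve and returns the smallest sample count at which
#' the recorded error drops to `factor` times the final error, linearly
#' interpolating between recorded points. This discounts the slow approach
#' to final convergence when comparing sample efficiency.
#'
#' @param curve Data frame with columns `sample` and `error` (strictly
#'   increasing sample counts).
#' @param factor Multiple of the final error to reach (default 1.5).
#' @return Sample count (possibly fractional after interpolation).
#' @export
samples_to_threshold <- function(curve, factor = 1.5) {
  stopifnot(nrow(curve) >= 1, factor >= 1)
  err <- curve$error
  smp <- curve$sample
  thr <- factor * err[length(err)]
  idx <- which(err <= thr)
  if (!length(idx)) return(smp[length(smp)])
  i <- idx[1]
  if (i == 1L) return(smp[1])
  e1 <- err[i - 1]; e2 <- err[i]
  if (e1 <= e2) return(smp[i])
  smp[i - 1] + (e1 - thr) / (e1 - e2) * (smp[i] - smp[i - 1])
}

experiment_schema <- c("name", "algorithm", "task", "n", "seeds")

#' Run a replicated, seeded experiment
#'
#' Declarative driver: a config (R list, or path to a JSON/YAML file) names
#' a task or environment, an algorithm variant and its hyperparameters, and
#' a set of seeds. Each replicate is run under its own seed; per-replicate
#' learning curves, an aggregate mean/sd curve, optional synapse snapshots
#' and a JSON manifest (config, seeds, package version) are written to
#' `out_dir`. Deterministic given the seeds.
#'
#' Config keys: `name`; `algorithm` in `"static"`, `"dynamic"`
#' (simulation algorithms), `"theory_static"`, `"theory_dynamic"`, `"rl"`;
#' `task` (see [task_by_name()]); `n` (neurons per axis; `n_out` optional);
#' `seeds` (integer vector); plus an optional `params` list passed to the
#' matching config constructor ([adaptive_config()], [theory_config()] or
#' [rl_config()]) and optional `k` (static width), `snapshots` (logical).
#'
#' @param config List or file path.
#' @param out_dir Output directory (created); if `NULL`, nothing is written.
#' @return Invisibly, a list with `runs` (per-replicate `learning_run`s),
#'   `aggregate` (data frame) and `final` (per-replicate summary).
#' @export
run_experiment <- function(config, out_dir = NULL) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop("YAML configs require the 'yaml' package")
      }
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  missing_keys <- setdiff(experiment_schema, names(config))
  if (length(missing_keys)) {
    stop(sprintf("config is missing required keys: %s",
                 paste(missing_keys, collapse = ", ")))
  }
  bad <- setdiff(names(config),
                 c(experiment_schema, "params", "k", "n_out", "snapshots"))
  if (length(bad)) {
    stop(sprintf("unknown config keys: %s", paste(bad, collapse = ", ")))
  }
  algo <- config$algorithm
  task <- task_by_name(config$task)
  params <- config$params %||% list()
  seeds <- as.integer(config$seeds)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  runs <- list()
  final <- list()
  for (r in seq_along(seeds)) {
    set.seed(seeds[r])
    if (algo %in% c("static", "dynamic")) {
      gA <- population_grid(task$d_A, config$n)
      gB <- population_grid(task$d_B, config$n_out %||% config$n)
      acfg <- do.call(adaptive_config, params)
      if (!is.null(config$k)) acfg$k_static <- as.integer(config$k)
      res <- adaptive_train(task, gA, gB, acfg, variant = algo)
      run <- res$run
      state <- res$state
    } else if (algo == "theory_static") {
      gA <- population_grid(1, config$n)
      gB <- population_grid(1, config$n_out %||% config$n)
      tcfg <- do.call(theory_config, params)
      k <- as.integer(config$k %||% 10L)
      state <- static_theory_train(task, gA, gB, k_A = k,
                                   L_threshold = tcfg$L_hat_scale * 3 * k / config$n,
                                   config = tcfg)
      err <- estimate_error(state, task, m = tcfg$eval_m, k_A = k,
                            k_B = max(1, ceiling(tcfg$C * k)))
      run <- structure(list(algorithm = algo, variant = NULL, config = tcfg,
                            curve = data.frame(sample = attr(state, "M_used"),
                                               error = err$mean),
                            samples = attr(state, "M_used"),
                            converged = NA, final_error = err$mean),
                       class = "learning_run")
    } else if (algo == "theory_dynamic") {
      gA <- population_grid(1, config$n)
      gB <- population_grid(1, config$n_out %||% config$n)
      tcfg <- do.call(theory_config, params)
      res <- dynamic_theory_train(task, gA, gB, tcfg)
      state <- res$state
      run <- structure(list(algorithm = algo, variant = NULL, config = tcfg,
                            curve = data.frame(sample = res$phases$cum_samples,
                                               error = res$phases$est_error),
                            phases = res$phases,
                            samples = max(res$phases$cum_samples),
                            converged = TRUE,
                            final_error = res$phases$est_error[nrow(res$phases)]),
                       class = "learning_run")
    } else if (algo == "rl") {
      rcfg <- do.call(rl_config, params)
      res <- rl_train(task, rcfg)
      run <- res$run
      state <- res$state
    } else {
      stop(sprintf("unknown algorithm '%s'", algo))
    }
    runs[[r]] <- run
    final[[r]] <- data.frame(
      seed = seeds[r], samples = run$samples,
      final = if (algo == "rl") run$final_reward else run$final_error)
    if (!is.null(out_dir)) {
      utils::write.csv(run$curve,
                       file.path(out_dir, sprintf("curve_seed%d.csv", seeds[r])),
                       row.names = FALSE)
      if (!is.null(run$phases)) {
        utils::write.csv(run$phases,
                         file.path(out_dir, sprintf("phases_seed%d.csv", seeds[r])),
                         row.names = FALSE)
      }
      if (isTRUE(config$snapshots)) {
        write_synapse_snapshot(
          state, file.path(out_dir, sprintf("synapses_seed%d.csv", seeds[r])))
      }
    }
  }
  aggregate <- aggregate_curves(lapply(runs, `[[`, "curve"))
  final <- do.call(rbind, final)
  if (!is.null(out_dir)) {
    utils::write.csv(aggregate, file.path(out_dir, "aggregate.csv"),
                     row.names = FALSE)
    utils::write.csv(final, file.path(out_dir, "final.csv"),
                     row.names = FALSE)
    manifest <- list(config = config, seeds = seeds,
                     package_version = as.character(utils::packageVersion("bumpcode")))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(runs = runs, aggregate = aggregate, final = final))
}

#' Aggregate replicate learning curves
#'
#' Mean and standard deviation over replicates on the union grid of
#' recorded sample counts; shorter curves carry their last value forward
#' (converged runs hold their final error).
#'
#' @param curves List of data frames with columns `sample` and a metric in
#'   the second position (`error` or `reward`).
#' @return Data frame with `sample`, `mean`, `sd`, `n_runs`.
#' @export
aggregate_curves <- function(curves) {
  metric <- setdiff(names(curves[[1]]), "sample")[1]
  xname <- names(curves[[1]])[1]
  grid <- sort(unique(unlist(lapply(curves, function(cv) cv[[xname]]))))
  vals <- vapply(curves, function(cv) {
    idx <- findInterval(grid, cv[[xname]])
    v <- cv[[metric]][pmax(1L, idx)]
    v[idx == 0] <- NA  # before the first record of this curve
    v
  }, numeric(length(grid)))
  vals <- matrix(vals, nrow = length(grid))
  data.frame(sample = grid,
             mean = rowMeans(vals, na.rm = TRUE),
             sd = apply(vals, 1, stats::sd, na.rm = TRUE),
             n_runs = rowSums(!is.na(vals)))
}
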