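#' Configuration for the simulation learning algorithms
#'
#' Hyperparameters of the static- and dynamic-width simulation algorithms:
#' per-neuron running error thresholds with decay `alpha`, immediate
#' error-driven pruning, inactivity pruning after `theta_prune` misses,
#' consolidation below `theta_syn` surviving synapses, and (dynamic variant)
#' bump widths proportional to the live synapse count of the active input
#' neuron. Defaults were chosen by a coarse grid search on the 1-D mapping
#' tasks; all are exposed.
#'
#' @param alpha Running-average decay factor in `(0, 1]` for the per-neuron
#'   error thresholds `L_hat_i = alpha L + (1 - alpha) L_hat_i`.
#' @param c_A,c_B Width fractions: the dynamic variant sets
#'   `k = max(1, floor(c * count^{1/d_B}))` from the live synapse count of
#'   the active input neuron. `c_B` defaults to `width_ratio * c_A`.
#' @param theta_prune Inactivity limit: a synapse whose postsynaptic neuron
#'   missed the output bump on `theta_prune` consecutive activations of its
#'   presynaptic neuron is pruned.
#' @param theta_syn Consolidation threshold: a neuron whose live synapse
#'   count drops below `theta_syn` has its surviving probabilities set to 1.
#' @param L_hat_init Initial per-neuron error threshold; defaults to
#'   `10 * max_feedback` of the task, so no error pruning happens before
#'   the running averages are informative.
#' @param ell Desired precision: training stops once `mean(L_hat) < ell`.
#' @param k_static,k_B_static Fixed input/output widths (static variant);
#'   `k_B_static` defaults to `ceiling(width_ratio * k_static)`.
#' @param width_ratio Output/input width coupling; defaults to the task's
#'   Lipschitz constant.
#' @param p_init Initial synaptic probability.
#' @param max_samples Safety cap on the number of training samples.
#' @param eval_m Monte-Carlo samples per learning-curve point.
#' @param checkpoints Sample counts at which the learning curve is
#'   evaluated; defaults to a log-spaced grid.
#' @return An object of class `adaptive_config`.
#' @export
adaptive_config <- function(alpha = 0.1, c_A = 0.1, c_B = NULL,
                            theta_prune = 50, theta_syn = 10,
                            L_hat_init = NULL, ell = 0.01,
                            k_static = 10, k_B_static = NULL,
                            width_ratio = NULL, p_init = 0.5,
                            max_samples = 200000L, eval_m = 300L,
                            checkpoints = NULL) {
  if (alpha <= 0 || alpha > 1) stop("'alpha' must lie in (0, 1]")
  if (theta_prune < 1 || theta_syn < 1) stop("thresholds must be positive")
  structure(list(alpha = alpha, c_A = c_A, c_B = c_B,
                 theta_prune = as.integer(theta_prune),
                 theta_syn = as.integer(theta_syn),
                 L_hat_init = L_hat_init, ell = ell,
                 k_static = as.integer(k_static), k_B_static = k_B_static,
                 width_ratio = width_ratio, p_init = p_init,
                 max_samples = as.integer(max_samples),
                 eval_m = as.integer(eval_m), checkpoints = checkpoints),
            class = "adaptive_config")
}

# fill task-dependent defaults
resolve_adaptive_config <- function(config, task) {
  if (is.null(config$width_ratio)) config$width_ratio <- task$C
  if (is.null(config$c_B)) config$c_B <- config$width_ratio * config$c_A
  if (is.null(config$k_B_static)) {
    config$k_B_static <-
      max(1L, as.integer(ceiling(config$width_ratio * config$k_static)))
  }
  if (is.null(config$L_hat_init)) {
    config$L_hat_init <- 10 * task$max_feedback
  }
  if (is.null(config$checkpoints)) {
    ck <- integer(0)
    v <- 10
    while (v < config$max_samples) {
      ck <- c(ck, ceiling(v))
      v <- v * 1.2
    }
    config$checkpoints <- unique(as.integer(ck))
  }
  config
}

#' Exponential-moving-average error-threshold update
#'
#' `L_hat <- alpha * L + (1 - alpha) * L_hat`: the running average of the
#' error feedbacks observed while the neuron was active.
#'
#' @param L_hat Current threshold. @param L Observed feedback.
#' @param alpha Decay factor in `(0, 1]`.
#' @return Updated threshold.
#' @export
update_error_threshold <- function(L_hat, L, alpha) {
  stopifnot(alpha > 0, alpha <= 1, L >= 0)
  alpha * L + (1 - alpha) * L_hat
}

#' Adaptive bump width from the live synapse count
#'
#' `k = max(1, floor(c * count^{1/d}))` where `count` is the number of
#' surviving synapses of the active input neuron and `d` the dimensionality
#' of the space the synapses spread over (for `d = 1` this is the literal
#' constant-fraction rule). The count measures how well the input is
#' already learned, so widths shrink as learning proceeds.
#'
#' @param count Live synapse count (`>= 0`).
#' @param c Width fraction. @param d_out Output dimensionality.
#' @return Integer width `>= 1`.
#' @export
adaptive_width <- function(count, c, d_out = 1) {
  max(1L, as.integer(floor(c * count^(1 / d_out))))
}

# membership helper: logical over flat B indices for bump J
flat_membership <- function(J, grid) {
  m <- logical(grid$size)
  m[J$flat] <- TRUE
  m
}

#' One sample of the simulation algorithm (reference implementation)
#'
#' Draws an input, activates the network, and applies -- in this order --
#' error-driven pruning against the pre-update thresholds, the threshold
#' update, inactivity bookkeeping with `theta_prune` pruning, consolidation
#' and degenerate-row re-seeding. Works for any grid dimensionalities; the
#' fast trainer [adaptive_train()] uses an equivalent compiled loop for 1-D
#' populations.
#'
#' @param state A [synapse_state()] (with `L_hat` initialized).
#' @param task A `bump_task`.
#' @param config A resolved [adaptive_config()].
#' @param variant `"dynamic"` (adaptive width) or `"static"`.
#' @return List with `state` (updated) and `record` (x, y, L, widths,
#'   reseed flag).
#' @export
adaptive_step <- function(state, task, config,
                          variant = c("dynamic", "static")) {
  variant <- match.arg(variant)
  gA <- state$grid_in
  gB <- state$grid_out
  x <- task$sample_input()
  a <- encode_value(x, gA)
  a_flat <- flat_index(a, gA)
  if (variant == "static") {
    k_A <- config$k_static
    k_B <- config$k_B_static
  } else {
    cnt <- sum(state$p[a_flat, ] > 0)
    k_A <- adaptive_width(cnt, config$c_A, gB$d)
    k_B <- adaptive_width(cnt, config$c_B, gB$d)
  }
  if (k_A > gA$n || k_B > gB$n) {
    warning("bump width exceeds the population side length; clamping")
    k_A <- min(k_A, gA$n)
    k_B <- min(k_B, gB$n)
  }
  I <- make_bump(a, k_A, gA)
  act <- activate(I, k_B, state)
  y <- act$y
  L <- task$feedback(x, y)
  in_J <- flat_membership(act$output_bump, gB)
  reseeds <- 0L
  for (i in sort(I$flat)) {
    pre <- state$L_hat[i]
    if (state$consolidated[i]) {
      state$L_hat[i] <- update_error_threshold(pre, L, config$alpha)
      next
    }
    if (L >= pre) {  # immediate pruning of the co-active block
      state$p[i, in_J] <- 0
      state$d_inact[i, in_J] <- 0L
    }
    state$L_hat[i] <- update_error_threshold(pre, L, config$alpha)
    live <- state$p[i, ] > 0
    hit <- live & in_J
    miss <- live & !in_J
    state$d_inact[i, hit] <- 0L
    state$d_inact[i, miss] <- state$d_inact[i, miss] + 1L
    dead <- miss & state$d_inact[i, ] >= config$theta_prune
    state$p[i, dead] <- 0
    state$d_inact[i, dead] <- 0L
    n_live <- sum(live) - sum(dead)
    if (n_live > 0 && n_live < config$theta_syn) {
      state <- consolidate(state, i)
    } else if (n_live == 0) {
      if (gA$d == gB$d) {
        j0 <- encode_value(decode_center(drop(tuple_index(i, gA)), gA), gB)
      } else {
        j0 <- rep(as.integer(ceiling(gB$n / 2)), gB$d)
      }
      band <- make_bump(j0, config$theta_syn, gB)
      state$p[i, band$flat] <- state$p_init
      state$d_inact[i, band$flat] <- 0L
      reseeds <- 1L
    }
  }
  list(state = state,
       record = list(x = x, y = y, L = L, k_A = k_A, k_B = k_B,
                     reseeds = reseeds))
}

#' Train with the simulation algorithm
#'
#' Runs [adaptive_step()] samples until the mean per-neuron error threshold
#' drops below the desired precision `ell` or `max_samples` is reached, and
#' records a learning curve (Monte-Carlo error estimate, mean threshold,
#' mean live synapse count, mean width) at log-spaced checkpoints. For 1-D
#' input and output populations an equivalent compiled loop is used.
#'
#' @inheritParams adaptive_step
#' @param grid_in,grid_out [population_grid()]s for the two populations.
#' @return List with `state` (trained `bump_synapses`) and `run`, a
#'   `learning_run` with the curve and convergence information.
#' @export
adaptive_train <- function(task, grid_in, grid_out,
                           config = adaptive_config(),
                           variant = c("dynamic", "static")) {
  variant <- match.arg(variant)
  config <- resolve_adaptive_config(config, task)
  state <- synapse_state(grid_in, grid_out, p_init = config$p_init)
  state$L_hat <- rep(config$L_hat_init, grid_in$size)
  if (grid_in$d == 1L && grid_out$d == 1L) {
    code <- matrix(1L, grid_in$size, grid_out$size)
    res <- .cpp_adaptive_train(
      code, state$d_inact, state$L_hat, state$consolidated,
      task$feedback, config$alpha, config$p_init, config$theta_prune,
      config$theta_syn, config$ell, variant == "static", config$k_static,
      config$k_B_static, config$c_A, config$c_B, config$max_samples,
      config$eval_m, config$checkpoints,
      grid_in$topology == "circular", grid_out$topology == "circular")
    state$p <- (res$code == 1L) * config$p_init + (res$code == 2L) * 1
    state$d_inact <- res$d
    state$L_hat <- res$L_hat
    state$consolidated <- res$consolidated
    curve <- res$curve
    samples <- res$samples
    converged <- res$converged
    reseeds <- res$reseeds
  } else {
    curve <- NULL
    samples <- 0L
    converged <- FALSE
    reseeds <- 0L
    rows <- list()
    ck <- config$checkpoints
    width_rule <- if (variant == "dynamic") {
      function(cnt) c(adaptive_width(cnt, config$c_A, grid_out$d),
                      adaptive_width(cnt, config$c_B, grid_out$d))
    } else NULL
    for (t in seq_len(config$max_samples)) {
      step <- adaptive_step(state, task, config, variant)
      state <- step$state
      samples <- t
      reseeds <- reseeds + step$record$reseeds
      if (t %in% ck || mean(state$L_hat) < config$ell) {
        est <- estimate_error(state, task, m = config$eval_m,
                              k_A = config$k_static,
                              k_B = config$k_B_static,
                              width_rule = width_rule)
        rows[[length(rows) + 1L]] <- data.frame(
          sample = t, error = est$mean, mean_L_hat = mean(state$L_hat),
          mean_live = mean(rowSums(state$p > 0)), mean_k = NA_real_)
      }
      if (mean(state$L_hat) < config$ell) { converged <- TRUE; break }
    }
    curve <- do.call(rbind, rows)
  }
  run <- structure(
    list(algorithm = "adaptive", variant = variant, config = config,
         curve = curve, samples = samples, converged = converged,
         reseeds = reseeds,
         final_error = if (!is.null(curve) && nrow(curve))
           curve$error[nrow(curve)] else NA_real_),
    class = "learning_run")
  list(state = state, run = run)
}

#' @export
print.learning_run <- function(x, ...) {
  cat(sprintf(
    "<learning_run> %s (%s): %d samples, converged=%s, final=%.4g\n",
    x$algorithm, x$variant %||% "", x$samples, x$converged, x$final_error))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
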