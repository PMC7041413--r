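#' Configuration for the counter-based (analysis) algorithms
#'
#' @param C Lipschitz constant of the mapping; output and input bump widths
#'   are coupled by `k_B = ceiling(C * k_A)`.
#' @param ell Desired final precision (target error).
#' @param c_k Starting-width constant: the first phase of the dynamic
#'   algorithm uses `k_0 = floor(c_k * n)`. Must satisfy
#'   `0 < c_k <= 2 / (3 (d_A + d_B))`.
#' @param L_hat_scale Multiplier on the per-phase error threshold
#'   `L_hat = L_hat_scale * 3 k / n` (the bound scale of the static
#'   guarantee; 1 makes the threshold self-consistent with the bound).
#' @param sample_budget_scale Multiplier on the formula sample counts,
#'   reducible for desk-scale runs (assertions must be relaxed accordingly).
#' @param eval_m Monte-Carlo samples for the per-phase error estimate.
#' @return An object of class `theory_config`.
#' @export
theory_config <- function(C = 1, ell = 0.05, c_k = NULL, L_hat_scale = 1,
                          sample_budget_scale = 1, eval_m = 1000) {
  if (!is.null(c_k) && c_k <= 0) stop("'c_k' must be positive")
  structure(list(C = C, ell = ell, c_k = c_k, L_hat_scale = L_hat_scale,
                 sample_budget_scale = sample_budget_scale, eval_m = eval_m),
            class = "theory_config")
}

#' Sample count of the static counter-based algorithm
#'
#' `M = ceiling(c (n/k)^{d_A + d_B} log n)` with
#' `c = (d_A + d_B + 1) (2C)^{d_A} (d_A + d_B)^{d_A + d_B}` (natural log).
#' This is the number of uniform random samples after which the static
#' algorithm's pruning guarantees, with high probability, a final error
#' below `3k/n`.
#'
#' @param n Neurons per axis. @param k Bump width (`1 <= k < n`).
#' @param d_A,d_B Input/output dimensionalities. @param C Lipschitz constant.
#' @return Positive integer sample count.
#' @export
theory_sample_count <- function(n, k, d_A = 1, d_B = 1, C = 1) {
  if (k >= n || k < 1) stop("need 1 <= k < n")
  cc <- (d_A + d_B + 1) * (2 * C)^d_A * (d_A + d_B)^(d_A + d_B)
  ceiling(cc * (n / k)^(d_A + d_B) * log(n))
}

# euclidean volume of the d-dimensional ball of radius r
ball_volume <- function(d, r) pi^(d / 2) / gamma(d / 2 + 1) * r^d

#' Per-phase sample count of the dynamic counter-based algorithm
#'
#' In a phase at width `k`, exploration is already restricted to the
#' survivor band left by the previous phase, so the number of candidate
#' output bumps per input cell is bounded by a constant and the phase needs
#' `M = ceiling(c (n/k)^{d_A} log n)` samples, with
#' `c = 2^{d_A} (d_A + d_B + 1) Vol(S_{d_B}(2/c_k + d_A/2 + d_B/2))`
#' (`Vol(S_d(r))` the euclidean volume of the `d`-ball of radius `r`).
#' Summed over halving phases this yields the `epsilon^{-d_A} log n`
#' sample-complexity law.
#'
#' @inheritParams theory_sample_count
#' @param c_k Starting-width constant of the dynamic algorithm.
#' @return Positive integer sample count.
#' @export
dynamic_sample_count <- function(n, k, d_A = 1, d_B = 1, c_k = NULL) {
  if (is.null(c_k)) c_k <- 2 / (3 * (d_A + d_B))
  if (k >= n || k < 1) stop("need 1 <= k < n")
  cc <- 2^d_A * (d_A + d_B + 1) *
    ball_volume(d_B, 2 / c_k + d_A / 2 + d_B / 2)
  ceiling(cc * (n / k)^d_A * log(n))
}

#' Static counter-based training (analysis algorithm)
#'
#' Runs `M` uniform random samples. For each, the input bump of width `k_A`
#' is activated, the attractor samples an output bump of width
#' `k_B = ceiling(C k_A)`, and the counters `c_ij` of every synapse between
#' the two bumps are incremented if the feedback satisfies
#' `L(x, y) <= L_threshold` and decremented otherwise. Afterwards all
#' synapses with non-positive counters are pruned (`p = 0`); synapses whose
#' bumps never co-activated keep counter 0 and are pruned too. Activation
#' is always restricted to live synapses, so a pre-pruned `state` from an
#' earlier phase constrains exploration.
#'
#' Only 1-D populations are supported by this trainer (the regime of the
#' sample-complexity experiments).
#'
#' @param task A `bump_task` with `d_A = d_B = 1`.
#' @param grid_in,grid_out 1-D [population_grid()]s.
#' @param k_A Input bump width.
#' @param L_threshold Error threshold for the counter sign.
#' @param M Sample count; defaults to [theory_sample_count()].
#' @param state Optional pre-trained [synapse_state()] to continue from;
#'   counters are reset to 0.
#' @param config A [theory_config()] (supplies `C` and
#'   `sample_budget_scale`).
#' @return The trained `bump_synapses` state (counters as after the run).
#' @export
static_theory_train <- function(task, grid_in, grid_out, k_A, L_threshold,
                                M = NULL, state = NULL,
                                config = theory_config()) {
  if (grid_in$d != 1L || grid_out$d != 1L) {
    stop("the counter-based trainer supports d_A = d_B = 1")
  }
  k_B <- max(1L, as.integer(ceiling(config$C * k_A)))
  if (is.null(M)) {
    M <- theory_sample_count(grid_in$n, k_A, 1, 1, config$C)
    M <- max(1L, as.integer(ceiling(M * config$sample_budget_scale)))
  }
  if (is.null(state)) state <- synapse_state(grid_in, grid_out)
  live <- matrix(as.integer(state$p > 0), nrow(state$p), ncol(state$p))
  counters <- matrix(0L, nrow(state$p), ncol(state$p))
  res <- .cpp_theory_phase(live, counters, as.integer(M), as.integer(k_A),
                           k_B, state$p_init, L_threshold, task$feedback,
                           grid_in$topology == "circular",
                           grid_out$topology == "circular")
  state$p <- state$p_init * (res$live == 1L)
  state$c <- res$counters
  attr(state, "M_used") <- M
  state
}

#' Dynamic counter-based training (phase-halving analysis algorithm)
#'
#' Repeatedly applies [static_theory_train()] in phases: the bump width
#' starts at `k_0 = floor(c_k n)` and the width and error threshold
#' `L_hat = 3k/n` are halved in every phase, so each input neuron stays
#' connected to a shrinking band around its target. Counters restart at 0
#' each phase while surviving synapses constrain later exploration. The
#' procedure stops once the phase error scale `3k/n` drops to the desired
#' precision `ell`.
#'
#' @inheritParams static_theory_train
#' @param config A [theory_config()]; `ell` must be at least the resolution
#'   limit `3/n`.
#' @param eval_task Optional flag: estimate the network error after every
#'   phase (`config$eval_m` Monte-Carlo samples) and record it in the phase
#'   log.
#' @return List with `state` (trained `bump_synapses`) and `phases`, a
#'   data frame logging `phase, k, L_hat, M_used, cum_samples, est_error`.
#' @export
dynamic_theory_train <- function(task, grid_in, grid_out,
                                 config = theory_config(),
                                 eval_task = TRUE) {
  n <- grid_in$n
  d_sum <- 2  # d_A = d_B = 1
  c_k <- if (is.null(config$c_k)) 2 / (3 * d_sum) else config$c_k
  if (c_k > 2 / (3 * d_sum) + 1e-12) {
    stop("'c_k' exceeds its bound 2/(3(d_A+d_B))")
  }
  if (config$ell < 3 / n) {
    stop(sprintf("'ell' = %g is below the resolution limit 3/n = %g",
                 config$ell, 3 / n))
  }
  k <- max(1L, as.integer(floor(c_k * n)))
  state <- synapse_state(grid_in, grid_out)
  phases <- list()
  cum <- 0
  phase <- 0L
  repeat {
    phase <- phase + 1L
    L_hat <- config$L_hat_scale * 3 * k / n
    M <- dynamic_sample_count(n, k, 1, 1, c_k)
    M <- max(1L, as.integer(ceiling(M * config$sample_budget_scale)))
    state <- static_theory_train(task, grid_in, grid_out, k_A = k,
                                 L_threshold = L_hat, M = M, state = state,
                                 config = config)
    cum <- cum + M
    err <- NA_real_
    if (eval_task) {
      k_B <- max(1L, as.integer(ceiling(config$C * k)))
      err <- estimate_error(state, task, m = config$eval_m,
                            k_A = k, k_B = k_B)$mean
    }
    phases[[phase]] <- data.frame(
      phase = phase, k = k, L_hat = L_hat, M_used = M,
      cum_samples = cum, est_error = err)
    if (3 * k / n <= config$ell) break
    k <- max(1L, k %/% 2L)
  }
  list(state = state, phases = do.call(rbind, phases))
}
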