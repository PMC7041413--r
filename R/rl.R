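#' Configuration for the reinforcement-learning algorithm
#'
#' The policy is a static-width bump network from a state-encoding
#' population to an action-encoding population; a tabular value function
#' over discretized states supplies k-step temporal-difference return
#' estimates that drive gradual, clipped synaptic-probability updates.
#'
#' @param td_k Return horizon (number of bootstrapped reward steps).
#' @param alpha_v Value-table step size.
#' @param beta Policy step size: probabilities move by a fraction
#'   `clip(beta * G, -1, 1)` of their distance to the bounds 0.9 / 0.1.
#' @param k_A,k_B Static bump widths for the state and action populations.
#' @param n_state,n_action Neurons per axis of the two populations.
#' @param value_bins Bins per state dimension of the tabular value function.
#' @param episodes Training episodes.
#' @param p_init Initial synaptic probability; must lie inside the clip
#'   interval `[0.1, 0.9]`.
#' @return An object of class `rl_config`.
#' @export
rl_config <- function(td_k = 5, alpha_v = 0.1, beta = 0.002, k_A = 6,
                      k_B = 12, n_state = 30, n_action = 100,
                      value_bins = 50, episodes = 300, p_init = 0.5) {
  if (p_init < 0.1 || p_init > 0.9) stop("'p_init' must lie in [0.1, 0.9]")
  if (td_k < 1) stop("'td_k' must be a positive integer")
  structure(list(td_k = as.integer(td_k), alpha_v = alpha_v, beta = beta,
                 k_A = as.integer(k_A), k_B = as.integer(k_B),
                 n_state = as.integer(n_state),
                 n_action = as.integer(n_action),
                 value_bins = as.integer(value_bins),
                 episodes = as.integer(episodes), p_init = p_init),
            class = "rl_config")
}

#' k-step temporal-difference return
#'
#' `G_t = R_{t+1} + ... + R_{t+k} + v(S_{t+k}) - v(S_t)`. For steps within
#' `k` of the episode end the reward sum truncates at the terminal reward
#' and the bootstrap term is 0 (pass `v_end = 0`).
#'
#' @param rewards Numeric vector of the (up to `k`) rewards following `t`.
#' @param v_end Bootstrapped value `v(S_{t+k})` (0 at episode end).
#' @param v_start Current value `v(S_t)`.
#' @return The return `G_t`.
#' @export
compute_return <- function(rewards, v_end, v_start) {
  sum(rewards) + v_end - v_start
}

#' Tabular value update
#'
#' `v(S_t) <- v(S_t) + alpha_v * G_t`.
#'
#' @param v Current value. @param G Return estimate. @param alpha_v Step.
#' @return Updated value.
#' @export
value_update <- function(v, G, alpha_v) v + alpha_v * G

#' Clipped synaptic-probability update
#'
#' The reinforce-type policy update: for `G >= 0`,
#' `p <- p + (0.9 - p) * min(beta G, 1)`; for `G < 0`,
#' `p <- p + (p - 0.1) * max(beta G, -1)`. Because `beta G` is clipped to
#' `[-1, 1]`, probabilities stay in `[0.1, 0.9]` invariantly.
#'
#' @param p Probability (vector allowed), each in `[0.1, 0.9]`.
#' @param G Return estimate. @param beta Step size.
#' @return Updated probabilities, all in `[0.1, 0.9]`.
#' @export
policy_probability_update <- function(p, G, beta) {
  if (any(p < 0.1 - 1e-12) || any(p > 0.9 + 1e-12)) {
    stop("state corruption: probability outside [0.1, 0.9]")
  }
  if (G >= 0) p + (0.9 - p) * min(beta * G, 1)
  else p + (p - 0.1) * max(beta * G, -1)
}

#' Tabular value function over a state box
#'
#' @param state_box 2 x d matrix (rows `lo`, `hi`).
#' @param bins Bins per dimension.
#' @return An object of class `value_table` (values initialized to 0).
#' @export
value_table <- function(state_box, bins = 50) {
  d <- ncol(state_box)
  structure(list(state_box = state_box, bins = as.integer(bins), d = d,
                 v = numeric(bins^d)),
            class = "value_table")
}

#' Flat cell index of a state (nearest cell, clamped to the box)
#'
#' @param vt A [value_table()]. @param state Numeric state vector.
#' @return Integer flat index.
#' @export
value_cell <- function(vt, state) {
  lo <- vt$state_box[1, ]
  hi <- vt$state_box[2, ]
  z <- (state - lo) / (hi - lo)
  idx <- pmin(vt$bins - 1L, pmax(0L, as.integer(floor(z * vt$bins))))
  as.integer(sum(idx * vt$bins^(seq_along(idx) - 1L))) + 1L
}

# normalize a raw state into [0,1]^d, counting clamps
normalize_state <- function(state, box) {
  z <- (state - box[1, ]) / (box[2, ] - box[1, ])
  clamped <- any(z < 0 | z > 1)
  list(x = pmin(1, pmax(0, z)), clamped = clamped)
}

#' Train a bump policy with k-step temporal-difference learning
#'
#' Per step: the observed state is encoded as a bump in the state
#' population, the attractor activates an action bump through the
#' probabilistic synapses (exploration comes solely from the synapses and
#' the uniform tie-breaking; no noise is added), the decoded bump center is
#' mapped affinely onto the environment's action box and applied. Once `k`
#' rewards are buffered, the k-step return updates the value table and the
#' probabilities of all synapses between the step's two bumps via the
#' clipped rule. Near the episode end, returns truncate with a zero
#' bootstrap.
#'
#' @param env A `bump_env` (gym-style contract: `reset()`,
#'   `step(state, action)` returning state/reward/done, declared boxes).
#' @param config An [rl_config()].
#' @param track_p_range If `TRUE`, record the min/max synaptic probability
#'   after every episode (invariant monitoring).
#' @return List with `state` (`bump_synapses` policy), `values`
#'   (`value_table`) and `run` (a `learning_run` whose curve has columns
#'   `episode, reward, steps` and, optionally, `p_min, p_max`).
#' @export
rl_train <- function(env, config = rl_config(), track_p_range = FALSE) {
  grid_A <- population_grid(env$state_dim, config$n_state)
  grid_B <- population_grid(env$action_dim, config$n_action)
  pol <- synapse_state(grid_A, grid_B, p_init = config$p_init)
  vt <- value_table(env$state_box, config$value_bins)
  a_lo <- env$action_box[1, ]
  a_hi <- env$action_box[2, ]
  nB <- grid_B$n
  dB <- grid_B$d
  k <- config$td_k
  # precomputed bump membership (flat indices) per center, both populations
  bump_cache <- function(grid, width) {
    lapply(seq_len(grid$size), function(fl)
      make_bump(drop(tuple_index(fl, grid)), width, grid)$flat)
  }
  rows_of <- bump_cache(grid_A, config$k_A)
  cols_of <- bump_cache(grid_B, config$k_B)
  centers_B <- tuple_index(seq_len(grid_B$size), grid_B)
  curve <- vector("list", config$episodes)
  n_clamped <- 0L
  for (ep in seq_len(config$episodes)) {
    s <- env$reset()
    total <- 0
    t <- 0L
    rows_buf <- list()  # per step: I flat rows
    cols_buf <- list()  # per step: J flat cols
    cell_buf <- integer(0)
    rew_buf <- numeric(0)
    repeat {
      t <- t + 1L
      norm <- normalize_state(s, env$state_box)
      if (norm$clamped) n_clamped <- n_clamped + 1L
      a_flat <- flat_index(encode_value(norm$x, grid_A), grid_A)
      I_rows <- rows_of[[a_flat]]
      center <- .cpp_activate_bernoulli(pol$p, I_rows, nB, dB, config$k_B,
                                        FALSE)$center
      y <- centers_B[center, ] / nB
      action <- a_lo + y * (a_hi - a_lo)
      res <- env$step(s, action)
      rows_buf[[t]] <- I_rows
      cols_buf[[t]] <- cols_of[[center]]
      cell_buf[t] <- value_cell(vt, s)
      rew_buf[t] <- res$reward
      total <- total + res$reward
      s <- res$state
      if (t > k) {  # update step u = t - k with full k-step return
        u <- t - k
        G <- compute_return(rew_buf[u:(u + k - 1L)], vt$v[cell_buf[u + k]],
                            vt$v[cell_buf[u]])
        vt$v[cell_buf[u]] <- value_update(vt$v[cell_buf[u]], G,
                                          config$alpha_v)
        .cpp_policy_update(pol$p, rows_buf[[u]], cols_buf[[u]], G,
                           config$beta)
      }
      if (res$done || t >= env$max_steps) break
    }
    # flush the tail with truncated sums and zero bootstrap
    for (u in seq.int(max(1L, t - k + 1L), t)) {
      G <- compute_return(rew_buf[u:t], 0, vt$v[cell_buf[u]])
      vt$v[cell_buf[u]] <- value_update(vt$v[cell_buf[u]], G, config$alpha_v)
      .cpp_policy_update(pol$p, rows_buf[[u]], cols_buf[[u]], G, config$beta)
    }
    rec <- data.frame(episode = ep, reward = total, steps = t)
    if (track_p_range) {
      rec$p_min <- min(pol$p)
      rec$p_max <- max(pol$p)
    }
    curve[[ep]] <- rec
  }
  curve <- do.call(rbind, curve)
  if (n_clamped > 0) {
    warning(sprintf("%d states fell outside the declared state box and were clamped",
                    n_clamped))
  }
  run <- structure(
    list(algorithm = "rl", variant = env$name, config = config,
         curve = curve, samples = sum(curve$steps), converged = NA,
         final_error = NA_real_,
         final_reward = mean(utils::tail(curve$reward, 30))),
    class = "learning_run")
  list(state = pol, values = vt, run = run)
}

#' Trailing moving average of episode rewards
#'
#' Smoothing applied only at report time; raw rewards are always stored.
#'
#' @param x Numeric vector. @param window Window length.
#' @return Smoothed vector of the same length.
#' @export
smooth_rewards <- function(x, window = 10) {
  n <- length(x)
  vapply(seq_len(n), function(i) mean(x[max(1, i - window + 1):i]),
         numeric(1))
}
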