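#' @rdname mapping_tasks
#' @param name Task name.
#' @param d_A,d_B Input and output dimensionalities.
#' @param f Target mapping (or `NULL` when the optimal output is
#'   underdetermined, as in the ball-throwing task).
#' @param feedback Scalar error-feedback function `L(x, y) >= 0`.
#' @param C Lipschitz constant (or stated upper bound) of the mapping.
#' @param max_feedback Upper bound on the feedback, used to initialize
#'   per-neuron error thresholds.
#' @param sample_input Function drawing one input from the task's input
#'   distribution (default uniform on `[0,1]^{d_A}`).
#' @export
bump_task <- function(name, d_A, d_B, f, feedback, C, max_feedback,
                      sample_input = NULL) {
  if (is.null(sample_input)) {
    force(d_A)
    sample_input <- function() stats::runif(d_A)
  }
  structure(
    list(name = name, d_A = as.integer(d_A), d_B = as.integer(d_B), f = f,
         feedback = feedback, C = C, max_feedback = max_feedback,
         sample_input = sample_input),
    class = "bump_task"
  )
}

#' @export
print.bump_task <- function(x, ...) {
  cat(sprintf("<bump_task> %s: [0,1]^%d -> [0,1]^%d, C=%.3g\n",
              x$name, x$d_A, x$d_B, x$C))
  invisible(x)
}

#' One-dimensional benchmark mappings
#'
#' The three closed-form 1-D mappings used to probe the learners, all with
#' absolute-distance feedback `L(x, y) = |f(x) - y|`:
#' \describe{
#'   \item{identity}{`f(x) = x`, Lipschitz constant 1.}
#'   \item{sinus}{`f(x) = sin(x)` on `[0, 1]` (range within `[0, 0.842]`),
#'     Lipschitz constant 1.}
#'   \item{polynomial}{the second-order polynomial `g(x) = x^2 - 3x + 1`,
#'     which maps `[0,1]` onto `[-1, 1]`, affinely rescaled into the coded
#'     interval via `f = (g + 1)/2`; `|f'| <= 3/2`, so `C = 1.5`.}
#' }
#'
#' @return A named list of `bump_task` objects.
#' @export
mapping_tasks <- function() {
  abs_feedback <- function(f) {
    force(f)
    function(x, y) abs(f(x) - y)
  }
  id_f <- function(x) x
  sin_f <- function(x) sin(x)
  poly_f <- function(x) (x^2 - 3 * x + 2) / 2  # (g(x) + 1) / 2
  list(
    identity = bump_task("identity", 1, 1, id_f, abs_feedback(id_f),
                         C = 1, max_feedback = 1),
    sinus = bump_task("sinus", 1, 1, sin_f, abs_feedback(sin_f),
                      C = 1, max_feedback = 1),
    polynomial = bump_task("polynomial", 1, 1, poly_f, abs_feedback(poly_f),
                           C = 1.5, max_feedback = 1)
  )
}

#' Ball-throwing task
#'
#' The network receives a target distance `d` in `[0, 1]` and outputs a
#' vertical launch angle and an initial speed. Physics is drag-free
#' ballistics on flat ground with `g = 9.81`: the ball lands at
#' `range = v^2 sin(2 theta) / g`. The output coordinates decode as
#' `theta = y_1 * pi/2` in `(0, pi/2]` and `v = y_2 * sqrt(g)`, so the
#' maximal range is exactly 1. Feedback is `|range - d|`. The optimal
#' output is underdetermined: for every angle in `(0, pi/2)` some speed
#' hits any target.
#'
#' @return A `bump_task` with `d_A = 1`, `d_B = 2`.
#' @export
throw_ball_task <- function() {
  g <- 9.81
  fb <- function(x, y) {
    theta <- y[1] * pi / 2
    v <- y[2] * sqrt(g)
    abs(v^2 * sin(2 * theta) / g - x)
  }
  bump_task("throw_ball", 1, 2, f = NULL, feedback = fb,
            C = 1, max_feedback = 1)
}

#' Ball range for a throw
#'
#' Landing distance of a drag-free projectile launched at angle `theta`
#' (radians) and speed `v` from the ground: `v^2 sin(2 theta) / g`.
#'
#' @param theta Launch angle in radians.
#' @param v Launch speed.
#' @param g Gravity (default 9.81).
#' @return Landing distance.
#' @export
throw_range <- function(theta, v, g = 9.81) v^2 * sin(2 * theta) / g

#' Two-joint robotic-arm task
#'
#' A planar arm with two rigid links of length 0.5 each, anchored at the
#' workspace center. The input is a target position, the output two joint
#' angles decoded from `(0,1]^2` to `(-pi, pi]^2`; feedback is the euclidean
#' distance between the arm endpoint and the target. The radius-1 reachable
#' disc (arm coordinates) is affinely rescaled into the coded square
#' `[0,1]^2`, and targets are drawn uniformly from that disc, so every
#' target is reachable; distances are measured in rescaled units.
#'
#' @return A `bump_task` with `d_A = 2`, `d_B = 2`.
#' @export
robotic_arm_task <- function() {
  fb <- function(x, y) {
    ang <- (2 * y - 1) * pi
    e <- arm_endpoint(ang[1], ang[2])
    target <- 2 * x - 1  # back to arm coordinates
    sqrt(sum((e - target)^2)) / 2  # rescaled units
  }
  sample_disc <- function() {
    repeat {
      t <- stats::runif(2, -1, 1)
      if (sum(t^2) <= 1) return((t + 1) / 2)
    }
  }
  bump_task("robotic_arm", 2, 2, f = NULL, feedback = fb,
            C = 2, max_feedback = 1.5, sample_input = sample_disc)
}

#' Endpoint of the two-link arm (arm coordinates)
#'
#' @param alpha,beta Shoulder and elbow angles in radians.
#' @param l1,l2 Link lengths.
#' @return Numeric length-2 endpoint position.
#' @export
arm_endpoint <- function(alpha, beta, l1 = 0.5, l2 = 0.5) {
  c(l1 * cos(alpha) + l2 * cos(alpha + beta),
    l1 * sin(alpha) + l2 * sin(alpha + beta))
}

#' Continuous mountain-car environment
#'
#' Native implementation of the classical continuous-action mountain-car
#' control problem: an under-powered car in a valley must build momentum to
#' reach the hilltop. State is (position, velocity) with position in
#' `[-1.2, 0.6]` and velocity in `[-0.07, 0.07]`; the scalar action `a` in
#' `[-1, 1]` accelerates the car via
#' `velocity += 0.0015 a - 0.0025 cos(3 position)`. Reaching
#' `position >= 0.45` ends the episode with reward +100; every step costs
#' fuel, `-0.1 a^2`. Episodes start at rest with position uniform in
#' `[-0.6, -0.4]` and are capped at 999 steps.
#'
#' @return An object of class `bump_env` with fields `reset()` and
#'   `step(state, action)`; `step` is a pure function of its arguments.
#' @export
mountain_car_env <- function() {
  structure(list(
    name = "mountain_car",
    state_dim = 2L, action_dim = 1L,
    state_box = rbind(lo = c(-1.2, -0.07), hi = c(0.6, 0.07)),
    action_box = rbind(lo = -1, hi = 1),
    max_steps = 999L,
    reset = function() c(stats::runif(1, -0.6, -0.4), 0),
    step = function(state, action) {
      a <- min(1, max(-1, action[1]))
      v <- state[2] + 0.0015 * a - 0.0025 * cos(3 * state[1])
      v <- min(0.07, max(-0.07, v))
      p <- state[1] + v
      if (p < -1.2) { p <- -1.2; v <- max(0, v) }
      if (p > 0.6) p <- 0.6
      done <- p >= 0.45
      list(state = c(p, v),
           reward = -0.1 * a^2 + if (done) 100 else 0,
           done = done)
    }
  ), class = "bump_env")
}

#' Continuous-action cart-pole environment
#'
#' Classical cart-pole (inverted pendulum on a cart) with a continuous
#' force input, Euler-integrated at 0.02 s. State is
#' (cart position, cart velocity, pole angle, pole angular velocity); the
#' action `a` in `[-1, 1]` applies force `10 a` N. Reward is +1 per step
#' while the pole stays within 12 degrees of vertical and the cart within
#' `|x| <= 2.4`; episodes are capped at 1000 steps. Start states are
#' uniform in `[-0.05, 0.05]` on every coordinate.
#'
#' @return A `bump_env`.
#' @export
cartpole_env <- function() {
  gravity <- 9.8; masscart <- 1; masspole <- 0.1
  total <- masscart + masspole; l <- 0.5; polemass_l <- masspole * l
  force_mag <- 10; dt <- 0.02
  theta_max <- 12 * pi / 180; x_max <- 2.4
  structure(list(
    name = "cartpole",
    state_dim = 4L, action_dim = 1L,
    state_box = rbind(lo = c(-x_max, -3, -theta_max, -3),
                      hi = c(x_max, 3, theta_max, 3)),
    action_box = rbind(lo = -1, hi = 1),
    max_steps = 1000L,
    reset = function() stats::runif(4, -0.05, 0.05),
    step = function(state, action) {
      a <- min(1, max(-1, action[1]))
      force <- force_mag * a
      x <- state[1]; xd <- state[2]; th <- state[3]; thd <- state[4]
      costh <- cos(th); sinth <- sin(th)
      tmp <- (force + polemass_l * thd^2 * sinth) / total
      thacc <- (gravity * sinth - costh * tmp) /
        (l * (4 / 3 - masspole * costh^2 / total))
      xacc <- tmp - polemass_l * thacc * costh / total
      s2 <- c(x + dt * xd, xd + dt * xacc, th + dt * thd, thd + dt * thacc)
      done <- abs(s2[3]) > theta_max || abs(s2[1]) > x_max
      list(state = s2, reward = 1, done = done)
    }
  ), class = "bump_env")
}

#' @export
print.bump_env <- function(x, ...) {
  cat(sprintf("<bump_env> %s: %d-dim state, %d-dim action, cap %d steps\n",
              x$name, x$state_dim, x$action_dim, x$max_steps))
  invisible(x)
}

#' Look up a task or environment by name
#'
#' @param name One of `"identity"`, `"sinus"`, `"polynomial"`,
#'   `"throw_ball"`, `"robotic_arm"`, `"mountain_car"`, `"cartpole"`.
#' @return A `bump_task` or `bump_env`.
#' @export
task_by_name <- function(name) {
  maps <- mapping_tasks()
  if (name %in% names(maps)) return(maps[[name]])
  switch(name,
    throw_ball = throw_ball_task(),
    robotic_arm = robotic_arm_task(),
    mountain_car = mountain_car_env(),
    cartpole = cartpole_env(),
    stop(sprintf("unknown task or environment '%s'", name))
  )
}
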