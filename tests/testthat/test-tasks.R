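test_that("1-D mapping tasks evaluate to their closed forms", {
  tk <- mapping_tasks()
  expect_equal(tk$identity$feedback(0.3, 0.3), 0)
  expect_equal(tk$sinus$feedback(1, sin(1)), 0)
  expect_lt(abs(sin(1) - 0.8415), 1e-4)
  # raw polynomial g(x) = x^2 - 3x + 1 before the affine rescale (g+1)/2
  g <- function(x) 2 * tk$polynomial$f(x) - 1
  expect_equal(g(0), 1)
  expect_equal(g(1), -1)
  expect_equal(g(0.5), -0.25)
  # rescaled mapping stays inside the coded interval
  x <- seq(0, 1, length.out = 401)
  for (t in tk) {
    fx <- vapply(x, t$f, numeric(1))
    expect_true(all(fx >= 0 & fx <= 1))
  }
})

test_that("declared Lipschitz constants bound dense finite differences", {
  x <- seq(0, 1, length.out = 2001)
  for (t in mapping_tasks()) {
    fx <- vapply(x, t$f, numeric(1))
    slope <- max(abs(diff(fx)) / diff(x)[1])
    expect_lte(slope, t$C + 1e-6)
  }
})

test_that("every feedback is nonnegative and zero at a verifiable optimum", {
  set.seed(61)
  tk <- c(mapping_tasks(), list(tb = throw_ball_task(), arm = robotic_arm_task()))
  for (t in tk[1:3]) {
    for (rep in 1:50) {
      x <- t$sample_input()
      y <- runif(t$d_B)
      expect_gte(t$feedback(x, y), 0)
      expect_lt(t$feedback(x, t$f(x)), 1e-12)
    }
  }
  expect_gte(tk$tb$feedback(0.5, c(0.9, 0.1)), 0)
  expect_gte(tk$arm$feedback(c(0.5, 0.5), c(0.2, 0.8)), 0)
})

test_that("ball throwing follows drag-free ballistics with an underdetermined optimum", {
  tb <- throw_ball_task()
  gcv <- 9.81
  # theta = pi/4, v = sqrt(g d) lands exactly at d
  for (d in c(0.2, 0.5, 0.9)) {
    y <- c(0.5, sqrt(gcv * d) / sqrt(gcv))
    expect_lt(tb$feedback(d, y), 1e-12)
  }
  expect_equal(tb$feedback(0.7, c(0.4, 0)), 0.7)  # v = 0: lands at the feet
  expect_equal(throw_range(pi / 4, sqrt(9.81)), 1)
  # zero-feedback set is a curve: every angle whose maximal range (at the
  # speed cap) covers the target admits a speed that hits it
  for (d in c(0.25, 0.6)) {
    th_grid <- seq(0.1, 0.9, by = 0.05)
    reachable <- th_grid[sin(th_grid * pi) >= d + 0.02]
    expect_gte(length(reachable), 8L)
    hits <- vapply(reachable, function(th) {
      fb <- vapply(seq(0.01, 1, by = 0.002), function(v)
        tb$feedback(d, c(th, v)), numeric(1))
      min(fb) < 0.01
    }, logical(1))
    expect_true(all(hits))
  }
})

test_that("arm feedback vanishes exactly on the inverse-kinematics solution", {
  arm <- robotic_arm_task()
  expect_equal(arm_endpoint(0, 0), c(1, 0))
  set.seed(62)
  for (rep in 1:50) {
    ang <- runif(2, -pi, pi)
    target <- (arm_endpoint(ang[1], ang[2]) + 1) / 2
    y <- (ang / pi + 1) / 2
    expect_lt(arm$feedback(target, y), 1e-12)
  }
  # reachability: independent closed-form IK drives the feedback to ~0
  for (rep in 1:50) {
    t_arm <- runif(2, -1, 1)
    if (sum(t_arm^2) > 1) next
    ik <- arm_inverse_kinematics(t_arm)
    wrapped <- ((ik + pi) %% (2 * pi)) - pi
    y <- (wrapped / pi + 1) / 2
    expect_lt(arm$feedback((t_arm + 1) / 2, y), 1e-6)
  }
  # inputs are sampled inside the reachable disc
  set.seed(63)
  xs <- t(replicate(200, arm$sample_input()))
  expect_true(all(rowSums((2 * xs - 1)^2) <= 1 + 1e-12))
})

test_that("mountain car needs momentum and rewards the energy-pumping policy", {
  env <- mountain_car_env()
  s <- c(-0.5, 0)
  for (t in 1:999) {
    r <- env$step(s, 0)
    s <- r$state
    expect_false(r$done)
  }
  expect_lt(s[1], 0.45)
  # bang-bang: accelerate along the current velocity
  set.seed(64)
  s <- env$reset()
  total <- 0
  done <- FALSE
  for (t in 1:999) {
    a <- if (s[2] >= 0) 1 else -1
    r <- env$step(s, a)
    total <- total + r$reward
    s <- r$state
    if (r$done) { done <- TRUE; break }
  }
  expect_true(done)
  expect_gt(total, 0)
  expect_equal(env$step(c(-0.5, 0), 1)$reward, -0.1)
  expect_equal(env$step(c(-0.5, 0), -1)$reward, -0.1)
})

test_that("cart-pole holds the unstable equilibrium briefly and a linear law indefinitely", {
  env <- cartpole_env()
  s <- c(0, 0, 0, 0)
  for (t in 1:100) {
    r <- env$step(s, 0)
    s <- r$state
    expect_false(r$done)
  }
  # hard constant push: quick termination
  set.seed(65)
  s <- env$reset()
  t <- 0
  repeat {
    t <- t + 1
    r <- env$step(s, 1)
    s <- r$state
    if (r$done || t > 500) break
  }
  expect_lt(t, 200)
  # hand-tuned linear feedback survives the full cap
  gains <- c(0.2, 1, 8, 1.5)
  for (sd in 1:3) {
    set.seed(sd)
    s <- env$reset()
    t <- 0
    repeat {
      t <- t + 1
      r <- env$step(s, max(-1, min(1, sum(gains * s))))
      s <- r$state
      if (r$done || t >= env$max_steps) break
    }
    expect_equal(t, env$max_steps, ignore_attr = TRUE)
  }
})
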