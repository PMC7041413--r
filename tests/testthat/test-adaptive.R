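test_that("threshold update is the exact exponential moving average", {
  expect_equal(update_error_threshold(0.5, 0.5, 0.3), 0.5)  # fixed point
  expect_equal(update_error_threshold(7, 0.2, 1), 0.2)
  expect_equal(update_error_threshold(1.0, 0.0, 0.1), 0.9)
  expect_error(update_error_threshold(1, 0.1, 0), "alpha")
})

test_that("adaptive width is the floored constant fraction with a floor of 1", {
  expect_identical(adaptive_width(1000, 0.05), 50L)
  expect_identical(adaptive_width(0, 0.3), 1L)
  expect_identical(adaptive_width(10000, 0.05, d_out = 2), 5L)
  counts <- sort(sample(0:2000, 100))
  ks <- vapply(counts, adaptive_width, integer(1), c = 0.07)
  expect_true(all(diff(ks) >= 0))
})

test_that("limiting cases of the per-sample update behave as forced", {
  task <- mapping_tasks()$identity
  g <- population_grid(1, 30)
  # huge initial threshold: the first sample cannot error-prune
  st <- synapse_state(g, g)
  st$L_hat <- rep(1e6, 30)
  cfg <- resolve_adaptive_config(
    adaptive_config(k_static = 4, theta_prune = 1000), task)
  set.seed(41)
  out <- adaptive_step(st, task, cfg, variant = "static")
  expect_identical(sum(out$state$p == 0), 0L)
  # theta_prune = 1: every miss is pruned immediately
  cfg1 <- resolve_adaptive_config(
    adaptive_config(k_static = 4, theta_prune = 1, theta_syn = 2,
                    L_hat_init = 1e6), task)
  st1 <- synapse_state(g, g)
  st1$L_hat <- rep(1e6, 30)
  set.seed(42)
  out1 <- adaptive_step(st1, task, cfg1, variant = "static")
  I <- out1$record
  touched <- interval_k(encode_value(I$x, g), I$k_A, g)
  Jset <- interval_k(encode_value(I$y, g), I$k_B, g)
  for (i in touched) {
    expect_setequal(which(out1$state$p[i, ] > 0), Jset)
  }
  # consolidated rows are frozen
  st2 <- synapse_state(g, g)
  st2 <- prune(st2, list(i = 15L, j = setdiff(1:30, 14:16)))
  st2 <- consolidate(st2, 15L)
  st2$L_hat <- rep(0.001, 30)  # everything error-prunes
  p_before <- st2$p[15, ]
  cfg2 <- resolve_adaptive_config(adaptive_config(k_static = 30), task)
  set.seed(43)
  for (rep in 1:20) st2 <- adaptive_step(st2, task, cfg2, "static")$state
  expect_identical(st2$p[15, ], p_before)
})

test_that("compiled trainer matches the pure-R mirror sample for sample", {
  task <- mapping_tasks()$identity
  nA <- 40L
  for (variant in c("static", "dynamic")) {
    cfg <- resolve_adaptive_config(
      adaptive_config(k_static = 6, theta_prune = 8, theta_syn = 4,
                      ell = 0, max_samples = 400L, eval_m = 1L,
                      checkpoints = integer(0)), task)
    g <- population_grid(1, nA)
    set.seed(44)
    res <- adaptive_train(task, g, g, cfg, variant = variant)
    set.seed(44)
    ref <- adaptive_train_mirror(task, nA, nA, cfg, variant, 400L)
    code <- matrix(0L, nA, nA)
    code[res$state$p == cfg$p_init & !(res$state$consolidated &
                                         res$state$p > 0)] <- 1L
    code[res$state$consolidated & res$state$p > 0] <- 2L
    expect_identical(code, ref$code)
    expect_identical(res$state$d_inact, ref$d)
    expect_equal(res$state$L_hat, ref$L_hat)
    expect_identical(res$state$consolidated, ref$consolidated)
  }
})

test_that("training converges on the 1-D identity task and stops on the threshold rule", {
  task <- mapping_tasks()$identity
  g <- population_grid(1, 200)
  set.seed(45)
  res <- adaptive_train(task, g, g,
                        adaptive_config(ell = 0.05, max_samples = 50000),
                        variant = "dynamic")
  expect_true(res$run$converged)
  expect_lt(mean(res$state$L_hat), 0.05)
  # estimated true error at stopping is within EMA lag of the target
  expect_lt(res$run$final_error, 2 * 0.05)
  # learning curve samples strictly increase, metrics finite
  expect_true(all(diff(res$run$curve$sample) > 0))
  expect_true(all(is.finite(res$run$curve$error)))
})

test_that("the generic trainer handles multi-dimensional tasks", {
  task <- throw_ball_task()  # 1-D input, 2-D output
  gA <- population_grid(1, 12)
  gB <- population_grid(2, 12)
  set.seed(46)
  cfg <- adaptive_config(ell = 0.02, max_samples = 400, eval_m = 40,
                         k_static = 4, checkpoints = c(100L, 400L))
  res <- adaptive_train(task, gA, gB, cfg, variant = "static")
  expect_s3_class(res$run, "learning_run")
  expect_true(nrow(res$run$curve) >= 1)
  expect_true(all(is.finite(res$run$curve$error)))
})
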