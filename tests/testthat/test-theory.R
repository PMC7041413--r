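test_that("static sample-count formula matches independent arithmetic", {
  # c = (d_A+d_B+1) (2C)^{d_A} (d_A+d_B)^{d_A+d_B} = 3*2*4 = 24 for the
  # 1-D unit-Lipschitz case; M = ceil(24 * (100/10)^2 * ln 100)
  expect_identical(theory_sample_count(100, 10, 1, 1, 1),
                   ceiling(24 * 100 * log(100)))
  expect_identical(theory_sample_count(100, 10, 1, 1, 1), 11053)
  r <- theory_sample_count(200, 10) / theory_sample_count(100, 10)
  expect_lt(abs(r - 4 * log(200) / log(100)), 0.01)
  # fixed n/k: strictly increasing in n through the log factor
  ms <- sapply(c(50, 100, 200, 400), function(n) theory_sample_count(n, n / 10))
  expect_true(all(diff(ms) > 0))
  expect_error(theory_sample_count(10, 10), "k < n")
})

test_that("counter signs force survival and pruning in the limiting cases", {
  g <- population_grid(1, 20)
  always_good <- bump_task("zero", 1, 1, function(x) x,
                           function(x, y) 0, C = 1, max_feedback = 1)
  set.seed(31)
  st <- static_theory_train(always_good, g, g, k_A = 4, L_threshold = 0.5,
                            M = 400)
  # co-active synapses were only ever incremented; never-co-active ones
  # keep counter 0 and are pruned
  expect_true(all(st$p[st$c > 0] == st$p_init))
  expect_true(all(st$p[st$c == 0] == 0))
  expect_true(any(st$c > 0))
  always_bad <- bump_task("big", 1, 1, function(x) x,
                          function(x, y) 10, C = 1, max_feedback = 10)
  set.seed(32)
  st2 <- static_theory_train(always_bad, g, g, k_A = 4, L_threshold = 0.5,
                             M = 400)
  expect_true(all(st2$p == 0))
  expect_true(all(st2$c <= 0))
})

test_that("the static guarantee holds at the formula sample count", {
  task <- mapping_tasks()$identity
  g <- population_grid(1, 100)
  set.seed(33)
  st <- static_theory_train(task, g, g, k_A = 10, L_threshold = 0.3)
  expect_equal(attr(st, "M_used"), 11053, ignore_attr = TRUE)
  err <- estimate_error(st, task, m = 500, k_A = 10, k_B = 10)
  expect_lt(err$mean, 0.3)
})

test_that("phase widths halve and a one-phase run equals the static trainer", {
  task <- mapping_tasks()$identity
  g <- population_grid(1, 256)
  set.seed(34)
  res <- dynamic_theory_train(task, g, g,
                              theory_config(ell = 0.025, eval_m = 50))
  k <- res$phases$k
  expect_identical(k[1], as.integer(floor(256 / 3)))
  expect_identical(k[-1], pmax(1L, k[-length(k)] %/% 2L))
  expect_true(all(res$phases$L_hat == 3 * k / 256))
  expect_lte(3 * k[length(k)] / 256, 0.025)
  expect_error(
    dynamic_theory_train(task, g, g, theory_config(ell = 0.001)),
    "resolution")
  # ell reached by the starting width: degenerate single phase, identical
  # RNG stream to the static trainer
  g2 <- population_grid(1, 30)
  cfg <- theory_config(ell = 1, c_k = 1 / 3, eval_m = 10)
  set.seed(35)
  one <- dynamic_theory_train(task, g2, g2, cfg, eval_task = FALSE)
  expect_identical(nrow(one$phases), 1L)
  set.seed(35)
  direct <- static_theory_train(task, g2, g2, k_A = 10, L_threshold = 1,
                                M = one$phases$M_used, config = cfg)
  expect_identical(one$state$p, direct$p)
  expect_identical(one$state$c, direct$c)
})

test_that("survivors of a phase had more low-error than high-error co-activations", {
  task <- mapping_tasks()$identity
  g <- population_grid(1, 40)
  set.seed(36)
  st <- static_theory_train(task, g, g, k_A = 4, L_threshold = 0.3, M = 2000)
  expect_true(all(st$c[st$p > 0] > 0))
  # surviving bands sit near the identity diagonal
  rows <- which(rowSums(st$p > 0) > 0)
  off <- vapply(rows, function(i) {
    mean(abs(which(st$p[i, ] > 0) - i)) / 40
  }, numeric(1))
  expect_lt(max(off), 0.35)
})
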