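test_that("transmission is Bernoulli per synapse with the stored probability", {
  g1 <- population_grid(1, 20)
  st <- synapse_state(g1, g1, p_init = 1)
  I <- make_bump(10L, 4, g1)
  expect_true(all(sample_transmission(I, st) == 1L))
  st0 <- synapse_state(g1, g1, p_init = 0)
  expect_true(all(sample_transmission(I, st0) == 0L))
  set.seed(21)
  gbig <- population_grid(1, 500)
  sthalf <- synapse_state(population_grid(1, 20), gbig, p_init = 0.5)
  draw <- sample_transmission(make_bump(10L, 19, gbig), sthalf)
  frac <- mean(draw)  # 10^4 Bernoulli(0.5) draws
  expect_lt(abs(frac - 0.5), 0.02)
})

test_that("total synaptic input equals the brute-force double sum", {
  set.seed(22)
  g1 <- population_grid(1, 15)
  st <- synapse_state(g1, g1, p_init = 0.4)
  I <- make_bump(7L, 4, g1)
  draw <- sample_transmission(I, st)
  expect_identical(total_input(matrix(0L, nrow(draw), ncol(draw)),
                               make_bump(3L, 2, g1)), 0L)
  all_on <- matrix(1L, 3, 15)
  expect_identical(total_input(all_on, make_bump(2L, 4, g1)), 3L * 4L)
  J <- make_bump(9L, 3, g1)
  manual <- 0L
  for (r in seq_len(nrow(draw))) for (j in J$flat) manual <- manual + draw[r, j]
  expect_identical(total_input(draw, J), manual)
})

test_that("box-sum scores equal brute-force enumeration on random instances", {
  set.seed(23)
  for (rep in 1:40) {
    d <- sample(1:2, 1)
    n <- sample(4:12, 1)
    kB <- sample(0:4, 1)
    topo <- sample(c("bounded", "circular"), 1)
    gB <- population_grid(d, n, topo)
    gA <- population_grid(1, 6)
    st <- synapse_state(gA, gB, p_init = 0.5)
    I <- make_bump(3L, 2, gA)
    draw <- sample_transmission(I, st)
    ref <- brute_force_scores(draw, gB, kB)
    act <- activate(I, kB, st, draw = draw, return_scores = TRUE)
    expect_identical(act$scores, ref)
    expect_true(act$scores[flat_index(act$output_bump$center, gB)] ==
                  max(ref))
  }
})

test_that("a unique nonzero column band wins deterministically", {
  g1 <- population_grid(1, 30)
  st <- synapse_state(g1, g1, p_init = 0)
  b_star <- 17L
  band <- interval_k(b_star, 4, g1)
  st$p[10, band] <- 1
  I <- make_bump(10L, 0, g1)
  for (rep in 1:5) {
    act <- activate(I, 4, st)
    expect_identical(act$output_bump$center, b_star)
  }
})

test_that("global ties are broken uniformly at random", {
  g1 <- population_grid(1, 8, "circular")  # circular: all windows same size
  st <- synapse_state(g1, g1, p_init = 0)
  I <- make_bump(4L, 2, g1)
  set.seed(24)
  centers <- replicate(4000, activate(I, 2, st)$output_bump$center)
  tab <- table(factor(centers, levels = 1:8))
  expect_true(all(tab > 0))
  expect_gt(stats::chisq.test(tab)$p.value, 1e-4)
})

test_that("pruning and consolidation are idempotent and flag degeneracy", {
  g1 <- population_grid(1, 12)
  st <- synapse_state(g1, g1)
  pairs <- cbind(c(3L, 3L, 4L), c(1L, 2L, 7L))
  st1 <- prune(st, pairs)
  expect_identical(prune(st1, pairs)$p, st1$p)
  expect_true(all(st1$p[pairs] == 0))
  st2 <- prune(st, list(i = 5L, j = 1:7))  # 5 survivors in row 5
  st2c <- consolidate(st2, 5L)
  expect_true(st2c$consolidated[5])
  expect_identical(sum(st2c$p[5, ] == 1), 5L)
  expect_identical(consolidate(st2c, 5L)$p, st2c$p)
  empty <- prune(st, list(i = 2L, j = 1:12))
  expect_error(consolidate(empty, 2L), class = "bumpcode_degenerate_neuron")
  # fully pruned row: all-zero scores tie over every candidate bump
  set.seed(25)
  centers <- replicate(300, activate(make_bump(2L, 0, g1), 2, empty)$output_bump$center)
  expect_gt(length(unique(centers)), 5)
})

test_that("snapshots round-trip through CSV + JSON sidecar", {
  set.seed(26)
  g1 <- population_grid(1, 10)
  st <- synapse_state(g1, population_grid(1, 14))
  st$p[sample(length(st$p), 50)] <- 0
  st$c[] <- sample(-3:5, length(st$c), replace = TRUE)
  st$d_inact[] <- sample(0:4, length(st$c), replace = TRUE)
  st$L_hat <- runif(10)
  st <- consolidate(st, 3L)
  path <- file.path(tempdir(), "snap.csv")
  write_synapse_snapshot(st, path)
  back <- read_synapse_snapshot(path)
  expect_equal(back$p, st$p)
  expect_equal(back$c[st$p > 0], st$c[st$p > 0])
  expect_equal(back$d_inact[st$p > 0], st$d_inact[st$p > 0])
  expect_equal(back$L_hat, st$L_hat)
  expect_identical(back$consolidated, st$consolidated)
  unlink(c(path, paste0(path, ".json")))
})
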