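# Independent oracles used across the suite.

# Brute-force attractor scores: enumerate every candidate output bump and
# recount the transmitted synapses with a double sum. Independent of the
# box-sum path.
brute_force_scores <- function(draw, grid_B, k_B) {
  vapply(seq_len(grid_B$size), function(b) {
    J <- make_bump(drop(tuple_index(b, grid_B)), k_B, grid_B)
    sum(draw[, J$flat])
  }, numeric(1))
}

# Closed-form inverse kinematics of the two-link arm (l1 = l2 = 0.5, arm
# coordinates): for a target at radius r <= 1, beta = 2 acos(r) and alpha
# points the bisector at the target.
arm_inverse_kinematics <- function(target) {
  r <- sqrt(sum(target^2))
  beta <- 2 * acos(min(1, r))
  alpha <- atan2(target[2], target[1]) - beta / 2
  c(alpha = alpha, beta = beta)
}

# Pure-R mirror of the compiled simulation-algorithm loop, consuming the
# RNG stream in exactly the same order (uniform for the input, one binomial
# per output neuron with live stochastic synapses in ascending order, one
# uniform for the tie-break). Bounded topology, d_A = d_B = 1.
adaptive_train_mirror <- function(task, nA, nB, config, variant,
                                  max_samples) {
  code <- matrix(1L, nA, nB)
  dm <- matrix(0L, nA, nB)
  Lhat <- rep(config$L_hat_init, nA)
  cons <- rep(FALSE, nA)
  enc <- function(x, n) min(n, max(1, floor(x * n + 0.5)))
  iv <- function(a, k, n) {
    h <- k %/% 2
    max(1, a - h):min(n, a + h)
  }
  alpha <- config$alpha
  for (t in seq_len(max_samples)) {
    x <- runif(1)
    a <- enc(x, nA)
    if (variant == "static") {
      kA <- config$k_static
      kB <- config$k_B_static
    } else {
      cnt <- sum(code[a, ] > 0)
      kA <- max(1, floor(config$c_A * cnt))
      kB <- max(1, floor(config$c_B * cnt))
    }
    kA <- min(kA, nA)
    kB <- min(kB, nB)
    I <- iv(a, kA, nA)
    sub <- code[I, , drop = FALSE]
    cnt1 <- colSums(sub == 2L)
    cnt05 <- colSums(sub == 1L)
    s <- as.numeric(cnt1)
    idx <- which(cnt05 > 0)
    if (length(idx)) {
      s[idx] <- s[idx] + rbinom(length(idx), cnt05[idx], config$p_init)
    }
    pre <- c(0, cumsum(s))
    hB <- kB %/% 2
    W <- vapply(seq_len(nB), function(b)
      pre[min(nB, b + hB) + 1] - pre[max(1, b - hB)], numeric(1))
    ties <- which(W == max(W))
    u <- runif(1)
    b <- ties[min(length(ties), floor(u * length(ties)) + 1)]
    y <- b / nB
    L <- task$feedback(x, y)
    in_J <- logical(nB)
    in_J[iv(b, kB, nB)] <- TRUE
    for (i in I) {
      pre_l <- Lhat[i]
      if (cons[i]) {
        Lhat[i] <- alpha * L + (1 - alpha) * pre_l
        next
      }
      if (L >= pre_l) {
        code[i, in_J] <- 0L
        dm[i, in_J] <- 0L
      }
      Lhat[i] <- alpha * L + (1 - alpha) * pre_l
      live <- code[i, ] > 0L
      dm[i, live & in_J] <- 0L
      miss <- which(live & !in_J)
      dm[i, miss] <- dm[i, miss] + 1L
      dead <- miss[dm[i, miss] >= config$theta_prune]
      code[i, dead] <- 0L
      dm[i, dead] <- 0L
      nl <- sum(code[i, ] > 0L)
      if (nl > 0 && nl < config$theta_syn) {
        cons[i] <- TRUE
        code[i, code[i, ] > 0L] <- 2L  # scores now count the row at p = 1
      } else if (nl == 0) {
        band <- iv(enc(i / nA, nB), config$theta_syn, nB)
        code[i, band] <- 1L
        dm[i, band] <- 0L
      }
    }
  }
  list(code = code, d = dm, L_hat = Lhat, consolidated = cons)
}
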