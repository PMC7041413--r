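#' Probabilistic synapse state between two populations
#'
#' All-to-all probabilistic synapses from population A to population B.
#' Each synapse has a plastic release probability `p_ij` in `[0,1]` and a
#' fixed weight of 1 (transmission is Bernoulli). Alongside the
#' probabilities the state carries the bookkeeping used by the learning
#' algorithms: integer counters `c_ij` (counter-based algorithms),
#' inactivity counters `d_ij` (simulation algorithms), per-input-neuron
#' consolidation flags and running error thresholds `L_hat_i`.
#'
#' A pruned synapse has `p = 0`; a consolidated input neuron has all its
#' surviving synapses at `p = 1`.
#'
#' @param grid_in,grid_out [population_grid()]s for populations A and B.
#' @param p_init Initial release probability for every synapse (default 0.5,
#'   the midpoint of the biological 0.1-0.9 range).
#' @return An object of class `bump_synapses`.
#' @export
synapse_state <- function(grid_in, grid_out, p_init = 0.5) {
  nA <- grid_in$size
  nB <- grid_out$size
  if (as.double(nA) * nB > 2e7) {
    stop(sprintf(
      "synapse matrix would have %.3g entries (> 2e7); refusing to allocate",
      as.double(nA) * nB))
  }
  if (p_init < 0 || p_init > 1) stop("'p_init' must lie in [0, 1]")
  structure(
    list(
      grid_in = grid_in, grid_out = grid_out, p_init = p_init,
      p = matrix(p_init, nA, nB),
      c = matrix(0L, nA, nB),
      d_inact = matrix(0L, nA, nB),
      consolidated = rep(FALSE, nA),
      L_hat = rep(0, nA)
    ),
    class = "bump_synapses"
  )
}

#' @export
print.bump_synapses <- function(x, ...) {
  cat(sprintf(
    "<bump_synapses> %d x %d synapses, %.1f%% live, %d consolidated rows\n",
    nrow(x$p), ncol(x$p), 100 * mean(x$p > 0), sum(x$consolidated)))
  invisible(x)
}

#' Sample one stochastic transmission from an input bump
#'
#' Every synapse `(i, j)` with `i` in the input bump transmits independently
#' with probability `p_ij`; synapses from inactive neurons do not transmit.
#'
#' @param I A `bump_activation` in population A.
#' @param state A [synapse_state()].
#' @return Integer 0/1 matrix with one row per input-bump neuron (attribute
#'   `rows` holds their flat indices) and one column per output neuron.
#' @export
sample_transmission <- function(I, state) {
  rows <- I$flat
  sub <- state$p[rows, , drop = FALSE]
  draw <- matrix(as.integer(stats::runif(length(sub)) < sub),
                 nrow = length(rows))
  attr(draw, "rows") <- rows
  draw
}

#' Total synaptic input received by an output bump
#'
#' Sum of active-synapse indicators over the product of the input bump
#' (implicit in `draw`) and the output bump `J`; synaptic weights are 1, so
#' this is a plain count.
#'
#' @param draw A transmission draw from [sample_transmission()].
#' @param J A `bump_activation` in population B.
#' @return Nonnegative integer.
#' @export
total_input <- function(draw, J) {
  sum(draw[, J$flat])
}

#' Attractor activation of the output population
#'
#' Samples one transmission draw from the input bump and activates, via the
#' abstract continuous-attractor mechanism, the width-`k_B` output bump that
#' received the most synaptic input. Scores for all candidate centers are
#' computed with a separable box-sum (moving-window) over the
#' per-output-neuron input counts, which is exactly equivalent to summing
#' over all `I x J` synapse pairs for every candidate. Ties are broken
#' uniformly at random. A single draw is shared by all candidate bumps.
#'
#' @param I A `bump_activation` in population A.
#' @param k_B Output bump width.
#' @param state A [synapse_state()].
#' @param draw Optional frozen transmission draw (as returned by
#'   [sample_transmission()]); if `NULL`, a fresh draw is sampled.
#' @param return_scores If `TRUE`, include the per-center window scores.
#' @return An object of class `activation_sample`: list with `input_bump`,
#'   `output_bump`, `y` (the decoded output value) and optionally `scores`.
#' @export
activate <- function(I, k_B, state, draw = NULL, return_scores = FALSE) {
  gB <- state$grid_out
  circ <- gB$topology == "circular"
  if (is.null(draw)) {
    res <- .cpp_activate_bernoulli(state$p, I$flat, gB$n, gB$d, k_B, circ,
                                   return_scores)
    center_flat <- res$center
    scores <- if (return_scores) res$scores else NULL
  } else {
    s <- colSums(draw)
    scores <- .cpp_box_sum(s, gB$n, gB$d, k_B, circ)
    ties <- which(scores == max(scores))
    center_flat <- ties[sample.int(length(ties), 1L)]
  }
  center <- drop(tuple_index(center_flat, gB))
  out_bump <- make_bump(center, k_B, gB)
  structure(
    list(input_bump = I, output_bump = out_bump,
         y = decode_center(center, gB), scores = scores),
    class = "activation_sample"
  )
}

#' Prune synapses
#'
#' Sets `p = 0` for the listed synapse pairs. Idempotent.
#'
#' @param state A [synapse_state()].
#' @param pairs Two-column matrix of flat `(i, j)` indices, or a list with
#'   elements `i` and `j` (recycled against each other as a block).
#' @return The updated state.
#' @export
prune <- function(state, pairs) {
  if (is.list(pairs) && !is.data.frame(pairs)) {
    pairs <- as.matrix(expand.grid(i = pairs$i, j = pairs$j))
  }
  pairs <- as.matrix(pairs)
  state$p[pairs] <- 0
  state
}

#' Consolidate an input neuron
#'
#' Sets `p = 1` for every surviving synapse of input neuron `i` and marks
#' the neuron consolidated, freezing its learned mapping. Idempotent.
#' Consolidating a neuron with no surviving synapses raises an error of
#' class `bumpcode_degenerate_neuron`.
#'
#' @param state A [synapse_state()].
#' @param i Flat index of the input neuron.
#' @return The updated state.
#' @export
consolidate <- function(state, i) {
  live <- state$p[i, ] > 0
  if (!any(live)) {
    stop(structure(
      class = c("bumpcode_degenerate_neuron", "error", "condition"),
      list(message = sprintf(
        "input neuron %d has no surviving synapses; cannot consolidate", i),
        call = sys.call())))
  }
  state$p[i, live] <- 1
  state$consolidated[i] <- TRUE
  state
}

#' Write a synapse-state snapshot
#'
#' Live synapses (`p > 0`) go to a CSV with columns
#' `i_index, j_index, p, c, d_inact`; per-neuron fields (running error
#' thresholds, consolidation flags) and the grid geometry go to a JSON
#' sidecar `<path>.json`. Pruned synapses are implicit.
#'
#' @param state A [synapse_state()].
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_synapse_snapshot <- function(state, path) {
  live <- which(state$p > 0, arr.ind = TRUE)
  df <- data.frame(
    i_index = live[, 1], j_index = live[, 2],
    p = state$p[live], c = state$c[live], d_inact = state$d_inact[live])
  utils::write.csv(df, path, row.names = FALSE)
  side <- list(
    grid_in = state$grid_in[c("d", "n", "topology")],
    grid_out = state$grid_out[c("d", "n", "topology")],
    p_init = state$p_init,
    L_hat = state$L_hat,
    consolidated = state$consolidated)
  jsonlite::write_json(side, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a synapse-state snapshot written by [write_synapse_snapshot()]
#'
#' @param path CSV file path.
#' @return A [synapse_state()].
#' @export
read_synapse_snapshot <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  gi <- population_grid(side$grid_in$d, side$grid_in$n, side$grid_in$topology)
  go <- population_grid(side$grid_out$d, side$grid_out$n,
                        side$grid_out$topology)
  state <- synapse_state(gi, go, p_init = side$p_init)
  state$p[] <- 0
  df <- utils::read.csv(path)
  idx <- cbind(df$i_index, df$j_index)
  state$p[idx] <- df$p
  state$c[idx] <- as.integer(df$c)
  state$d_inact[idx] <- as.integer(df$d_inact)
  state$L_hat <- side$L_hat
  state$consolidated <- side$consolidated
  state
}
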