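#' Neural population grid
#'
#' A population of `n^d` binary neurons arranged on a `d`-dimensional grid.
#' Neuron index tuple `i` (components in `1..n`) represents the parameter
#' value `(i_1/n, ..., i_d/n)` in `(0, 1]^d`, so geometric neighbours encode
#' nearby values. The grid is the substrate for bump activations: contiguous
#' hyper-cubic sets of co-active neurons whose center encodes a value and
#' whose side length (the bump width) models the tuning-curve breadth.
#'
#' @param d Dimensionality of the encoded parameter (positive integer).
#' @param n Neurons per axis (positive integer); the population has `n^d`
#'   neurons.
#' @param topology `"bounded"` clamps bumps at the edges of the grid;
#'   `"circular"` wraps them modulo `n`, for periodic parameters such as
#'   head direction or orientation angles.
#' @return An object of class `population_grid` with fields `d`, `n`,
#'   `topology` and `size` (total neuron count).
#' @examples
#' g <- population_grid(d = 1, n = 100)
#' decode_center(encode_value(0.5, g), g)
#' @export
population_grid <- function(d, n, topology = c("bounded", "circular")) {
  topology <- match.arg(topology)
  if (length(d) != 1L || d < 1L || d != round(d)) {
    stop("'d' must be a positive integer")
  }
  if (length(n) != 1L || n < 1L || n != round(n)) {
    stop("'n' must be a positive integer")
  }
  structure(
    list(d = as.integer(d), n = as.integer(n), topology = topology,
         size = as.integer(round(n))^as.integer(d)),
    class = "population_grid"
  )
}

#' @export
print.population_grid <- function(x, ...) {
  cat(sprintf("<population_grid> d=%d, n=%d (%d neurons), topology=%s\n",
              x$d, x$n, x$n^x$d, x$topology))
  invisible(x)
}

check_index_tuple <- function(i, grid) {
  if (length(i) != grid$d) {
    stop(sprintf("index tuple has length %d, expected d=%d", length(i), grid$d))
  }
  if (any(i != round(i)) || any(i < 1L) || any(i > grid$n)) {
    stop("invalid neuron index: components must be integers in 1..n")
  }
  as.integer(i)
}

#' Per-axis neuron interval of a bump
#'
#' The set of axis indices within `k/2` of center index `a`: all integers in
#' the closed interval `[a - k/2, a + k/2]`. On a bounded grid the interval is
#' clamped to `[1, n]`; on a circular grid it wraps modulo `n`. For even `k`
#' the interior interval holds `k + 1` integers, for odd `k` it holds `k`
#' (the closed-interval rule is applied verbatim, no rounding up to `k`).
#'
#' @param a Center axis index in `1..n`.
#' @param k Nonnegative bump width.
#' @param grid A [population_grid()].
#' @return Integer vector of axis indices; always nonempty and containing `a`.
#' @export
interval_k <- function(a, k, grid) {
  n <- grid$n
  if (length(a) != 1L || a != round(a) || a < 1L || a > n) {
    stop("invalid index: 'a' must be an integer in 1..n")
  }
  if (k < 0) stop("'k' must be nonnegative")
  h <- floor(k / 2)
  if (grid$topology == "circular") {
    if (2 * h + 1 >= n) return(seq_len(n))
    ((seq.int(a - h, a + h) - 1L) %% n) + 1L
  } else {
    seq.int(max(1L, a - h), min(n, a + h))
  }
}

#' Encode a continuous value as a center neuron
#'
#' Maps a point of `[0,1]^d` to the index tuple minimizing
#' `max_j |i_j/n - x_j|`: each component is quantized to the nearest grid
#' index (round half up) and clamped to `1..n`.
#'
#' @param x Numeric vector of length `d`, components in `[0, 1]`.
#' @param grid A [population_grid()].
#' @return Integer index tuple of length `d`.
#' @export
encode_value <- function(x, grid) {
  if (length(x) != grid$d) {
    stop(sprintf("value has length %d, expected d=%d", length(x), grid$d))
  }
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop("value components must lie in [0, 1]")
  }
  pmin(grid$n, pmax(1L, as.integer(floor(x * grid$n + 0.5))))
}

#' Decode the value represented by a neuron
#'
#' Inverse of [encode_value()] up to the quantization error of at most
#' `1/(2n)` per axis: neuron `i` represents `(i_1/n, ..., i_d/n)`.
#'
#' @param i Integer index tuple.
#' @param grid A [population_grid()].
#' @return Numeric vector in `(0, 1]^d`.
#' @export
decode_center <- function(i, grid) {
  i <- check_index_tuple(i, grid)
  i / grid$n
}

#' Construct a bump activation
#'
#' A bump of width `k` with center `i` is the Cartesian product of the
#' per-axis intervals `interval_k(i_j, k)`: a hyper-cubic patch of co-active
#' neurons. Its center encodes a value, its width the tuning breadth.
#'
#' @param center Integer index tuple.
#' @param k Nonnegative bump width.
#' @param grid A [population_grid()].
#' @return An object of class `bump_activation` with fields `center`, `k`,
#'   `axes` (list of per-axis index vectors), `neurons` (matrix with one
#'   neuron index tuple per row) and `flat` (column-major flat indices into
#'   the grid).
#' @export
make_bump <- function(center, k, grid) {
  center <- check_index_tuple(center, grid)
  axes <- lapply(center, interval_k, k = k, grid = grid)
  neurons <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
  dimnames(neurons) <- NULL
  structure(
    list(center = center, k = k, axes = axes, neurons = neurons,
         flat = flat_index(neurons, grid)),
    class = "bump_activation"
  )
}

#' @export
print.bump_activation <- function(x, ...) {
  cat(sprintf("<bump_activation> center=(%s), k=%d, %d neurons\n",
              paste(x$center, collapse = ","), x$k, nrow(x$neurons)))
  invisible(x)
}

#' Column-major flat index of neuron tuples
#'
#' @param i Integer index tuple, or a matrix with one tuple per row.
#' @param grid A [population_grid()].
#' @return Integer vector of flat indices in `1..n^d`.
#' @export
flat_index <- function(i, grid) {
  if (is.null(dim(i))) i <- matrix(i, nrow = 1L)
  idx <- i[, 1L]
  if (grid$d > 1L) {
    for (j in 2L:grid$d) idx <- idx + (i[, j] - 1L) * grid$n^(j - 1L)
  }
  as.integer(idx)
}

#' Inverse of [flat_index()]
#'
#' @param idx Integer vector of flat indices.
#' @param grid A [population_grid()].
#' @return Matrix of index tuples, one per row.
#' @export
tuple_index <- function(idx, grid) {
  idx <- as.integer(idx) - 1L
  out <- matrix(0L, nrow = length(idx), ncol = grid$d)
  for (j in seq_len(grid$d)) {
    out[, j] <- idx %% grid$n + 1L
    idx <- idx %/% grid$n
  }
  out
}
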