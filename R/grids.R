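#' Discretised posterior over a probability parameter
#'
#' A posterior grid holds a probability mass function over a uniform grid of
#' midpoints in (0, 1). One-dimensional grids track a single probability
#' (the stationary frequency of high-intensity stimuli); two-dimensional
#' grids track the pair of free transition probabilities
#' (theta_{H|L}, theta_{L|H}).
#'
#' @param mass Numeric vector (1-D) or matrix (2-D) of non-negative weights.
#'   Normalised to sum to 1 on construction.
#' @param resolution Number of grid points per axis. Defaults to
#'   `length(mass)` for vectors and `nrow(mass)` for matrices.
#' @return An object of class `posterior_grid` with elements `theta`
#'   (midpoint locations per axis), `mass`, `resolution` and `ndim`.
#' @examples
#' g <- posterior_grid(rep(1, 100))
#' posterior_stats(g)
#' @export
posterior_grid <- function(mass, resolution = NULL) {
  if (is.matrix(mass)) {
    if (nrow(mass) != ncol(mass)) {
      stop("2-D posterior grids must be square")
    }
    res <- if (is.null(resolution)) nrow(mass) else resolution
    ndim <- 2L
  } else {
    res <- if (is.null(resolution)) length(mass) else resolution
    ndim <- 1L
  }
  if (any(mass < 0) || !all(is.finite(mass))) {
    stop("grid mass must be finite and non-negative")
  }
  tot <- sum(mass)
  if (tot <= 0) stop("grid mass must have positive total")
  structure(
    list(
      theta = grid_midpoints(res),
      mass = mass / tot,
      resolution = as.integer(res),
      ndim = ndim
    ),
    class = "posterior_grid"
  )
}

#' Uniform grid midpoints of (0, 1)
#'
#' @param resolution Number of points.
#' @return Numeric vector of midpoints `(i - 0.5) / resolution`.
#' @export
grid_midpoints <- function(resolution) {
  (seq_len(resolution) - 0.5) / resolution
}

#' @export
print.posterior_grid <- function(x, ...) {
  cat(sprintf(
    "<posterior_grid: %d-D, %d points per axis>\n", x$ndim, x$resolution
  ))
  s <- posterior_stats(x)
  cat(sprintf("  mean %.4f, sd %.4f\n", s[["mean"]], s[["sd"]]))
  invisible(x)
}

#' First two moments of a posterior grid
#'
#' For 2-D grids the moments are those of the first-axis marginal
#' (theta_{H|L}); conditional components of transition posteriors are
#' handled by the observer functions, which pass the relevant marginal.
#'
#' @param g A `posterior_grid`, or a bare numeric mass vector over the
#'   default midpoint grid.
#' @return Named numeric vector with elements `mean` and `sd`.
#' @export
posterior_stats <- function(g) {
  if (inherits(g, "posterior_grid")) {
    mass <- if (g$ndim == 2L) rowSums(g$mass) else g$mass
    theta <- g$theta
  } else {
    mass <- g / sum(g)
    theta <- grid_midpoints(length(g))
  }
  m <- sum(mass * theta)
  v <- sum(mass * theta^2) - m^2
  c(mean = m, sd = sqrt(max(v, 0)))
}

#' Kullback-Leibler divergence between two posterior grids
#'
#' Computes `sum(P * log(P / Q))` in nats over the shared grid, with the
#' convention `0 * log(0) = 0`. Masses are floored at 1e-300 before taking
#' logs, which guards against floating-point underflow; genuine disjoint
#' support cannot arise in the observer models because prior mixing keeps
#' support full.
#'
#' @param p,q `posterior_grid` objects on identical axes, or bare numeric
#'   mass vectors/matrices of equal shape (normalised internally).
#' @return KL divergence in nats (non-negative scalar).
#' @examples
#' compute_kl(c(0.5, 0.5), c(0.25, 0.75)) # 0.1438 nats
#' @export
compute_kl <- function(p, q) {
  if (inherits(p, "posterior_grid") || inherits(q, "posterior_grid")) {
    if (!inherits(p, "posterior_grid") || !inherits(q, "posterior_grid")) {
      stop("both arguments must be posterior_grid objects, or neither")
    }
    if (p$ndim != q$ndim || p$resolution != q$resolution) {
      stop("posterior grids have mismatched axes")
    }
    return(kl_mass(p$mass, q$mass))
  }
  if (length(p) != length(q)) stop("mass vectors have mismatched lengths")
  kl_mass(p / sum(p), q / sum(q))
}

# raw KL between two normalised mass arrays of identical shape
kl_mass <- function(p, q) {
  p <- pmax(p, 0)
  keep <- p > 0
  sum(p[keep] * (log(pmax(p[keep], 1e-300)) - log(pmax(q[keep], 1e-300))))
}

# Beta(a, b) density discretised on the midpoint grid and normalised.
# Used to place the analytic fixed-model posteriors on the shared grid so
# that KL updates are computed through one code path for all models.
discretise_beta <- function(a, b, resolution = 100L) {
  theta <- grid_midpoints(resolution)
  w <- stats::dbeta(theta, a, b)
  w / sum(w)
}
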