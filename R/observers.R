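#' @title Trial-by-trial observer models
#'
#' @description Six observer models of statistical learning over a binary
#' low/high stimulus stream. Each model emits, for every trial `t`, the
#' predictive probability that trial `t + 1` is high given the stimuli seen
#' so far (the quantity a probe rating is compared against), plus the
#' posterior mean, posterior SD and the Kullback-Leibler divergence between
#' the posteriors at `t` and `t - 1` where the model defines a posterior.
#'
#' The models are:
#' \describe{
#'   \item{random}{constant reciprocal probabilities; one parameter `p_l`,
#'     the fixed probability of a low stimulus.}
#'   \item{rw}{Rescorla-Wagner delta rule on the value of "low",
#'     `V <- V + alpha * (R - V)` with `R = 1` for a low stimulus;
#'     predictive p(H) = 1 - V. Parameters `alpha` (and optional start
#'     value `v0`, default 0.5).}
#'   \item{fixed_frequency}{Beta-Bernoulli learner of the stimulus
#'     frequency with leaky integration: stimuli `k` trials back get weight
#'     `exp(-k / d)` and stimuli beyond the last `w` trials get weight 0.
#'     Posterior is Beta(N_h + 1, N_l + 1) on the weighted counts.}
#'   \item{fixed_transition}{same leaky counting applied to stimulus pairs;
#'     the posterior is a product of independent Beta distributions over
#'     theta_{H|L} and theta_{L|H}.}
#'   \item{jump_frequency}{Bayesian change-point learner: the tracked
#'     frequency can be resampled from a flat prior with per-trial
#'     probability `p_jump`. Implemented as forward filtering of a hidden
#'     Markov model on a discretised 1-D grid.}
#'   \item{jump_transition}{the same change-point filter over the joint
#'     2-D grid of transition probabilities; a jump resamples both
#'     probabilities together, so the joint posterior does not factorise.}
#' }
#'
#' @param seq A `generative_sequence`, or a character vector of "L"/"H"
#'   stimuli, or a logical vector (TRUE = high).
#' @param model One of `"random"`, `"rw"`, `"fixed_frequency"`,
#'   `"fixed_transition"`, `"jump_frequency"`, `"jump_transition"`.
#' @param params Named list of model parameters (see Description).
#' @param resolution Grid points per axis for the grid-based quantities;
#'   defaults to 100 for frequency models and 41 for transition models.
#' @param compute_stats If FALSE, skip posterior SD and KL computation and
#'   return only the predictive series (used in the inner loop of fitting,
#'   where only predictions enter the regression).
#' @return An `observer_trace`: a data frame with columns `trial`,
#'   `stimulus`, `predictive_p_h`, `posterior_mean`, `posterior_sd`,
#'   `kl_update`, and attributes `model` and `params`. Models without a
#'   posterior (rw) carry NA in the posterior columns.
#' @examples
#' s <- generate_sequence(generator_config(n_blocks = 1), seed = 2)
#' tr <- run_observer(s, "jump_frequency", list(p_jump = 0.014))
#' head(tr)
#' @export
run_observer <- function(seq, model, params, resolution = NULL,
                         compute_stats = TRUE) {
  h <- stimuli_to_logical(seq)
  model <- match.arg(model, observer_model_names())
  trace <- switch(model,
    random = observer_random(h, params$p_l, compute_stats),
    rw = observer_rw(h, params$alpha,
                     if (is.null(params$v0)) 0.5 else params$v0),
    fixed_frequency = observer_fixed_frequency(
      h, params$w, params$d,
      resolution = resolution %||% 100L, compute_stats),
    fixed_transition = observer_fixed_transition(
      h, params$w, params$d,
      resolution = resolution %||% 41L, compute_stats),
    jump_frequency = observer_jump_frequency(
      h, params$p_jump,
      resolution = resolution %||% 100L, compute_stats),
    jump_transition = observer_jump_transition(
      h, params$p_jump,
      resolution = resolution %||% 41L, compute_stats)
  )
  trace$trial <- seq_along(h)
  trace$stimulus <- ifelse(h, "H", "L")
  trace <- trace[, c("trial", "stimulus", "predictive_p_h",
                     "posterior_mean", "posterior_sd", "kl_update")]
  structure(trace, model = model, params = params,
            class = c("observer_trace", "data.frame"))
}

#' Names of the available observer models
#' @return Character vector of the six model names.
#' @export
observer_model_names <- function() {
  c("random", "rw", "fixed_frequency", "fixed_transition",
    "jump_frequency", "jump_transition")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stimuli_to_logical <- function(seq) {
  if (inherits(seq, "generative_sequence") || is.data.frame(seq)) {
    seq <- seq$stimulus
  }
  if (is.character(seq)) {
    if (!all(seq %in% c("L", "H"))) stop("stimuli must be 'L' or 'H'")
    return(seq == "H")
  }
  if (is.logical(seq)) return(seq)
  if (is.numeric(seq) && all(seq %in% c(0, 1))) return(seq == 1)
  stop("cannot interpret stimulus input")
}

trace_frame <- function(pred, mean = NA_real_, sd = NA_real_,
                        kl = NA_real_) {
  n <- length(pred)
  data.frame(
    predictive_p_h = pred,
    posterior_mean = rep_len(mean, n),
    posterior_sd = rep_len(sd, n),
    kl_update = rep_len(kl, n)
  )
}

# --- random baseline ------------------------------------------------------

observer_random <- function(h, p_l, compute_stats = TRUE) {
  stopifnot(p_l > 0, p_l < 1)
  n <- length(h)
  # uncertainty is fixed by assumption; report the flat-prior SD (1/sqrt(12))
  trace_frame(rep(1 - p_l, n), mean = 1 - p_l, sd = sqrt(1 / 12), kl = 0)
}

# --- Rescorla-Wagner ------------------------------------------------------

observer_rw <- function(h, alpha, v0 = 0.5) {
  stopifnot(alpha > 0, alpha <= 1)
  r <- as.numeric(!h) # reinforcement 1 for low stimuli
  if (alpha == 1) {
    v <- r
  } else {
    v <- as.numeric(stats::filter(alpha * r, 1 - alpha,
                                  method = "recursive", init = v0))
  }
  trace_frame(1 - v, mean = 1 - v) # no posterior: SD and KL absent
}

# --- leaky windowed counts ------------------------------------------------

# weighted count of indicator series x over the last w trials, weight
# exp(-k/d) on the entry k trials back (k = 0 for the current trial)
windowed_counts <- function(x, w, d) {
  n <- length(x)
  w <- max(1L, min(as.integer(round(w)), n))
  wts <- exp(-(seq_len(w) - 1) / d)
  if (w == 1L) return(x)
  xp <- c(rep(0, w - 1L), x)
  as.numeric(stats::filter(xp, wts, sides = 1))[w:(n + w - 1L)]
}

# KL series between successive Beta posteriors, evaluated on the shared
# discretised grid (one code path with the grid-filtering models)
beta_kl_series <- function(a, b, resolution) {
  n <- length(a)
  theta <- grid_midpoints(resolution)
  dens <- matrix(stats::dbeta(rep(theta, n), rep(a, each = resolution),
                              rep(b, each = resolution)),
                 nrow = resolution)
  dens <- sweep(dens, 2, colSums(dens), "/")
  kl <- numeric(n)
  for (t in 2:n) kl[t] <- kl_mass(dens[, t], dens[, t - 1])
  kl
}

observer_fixed_frequency <- function(h, w, d, resolution = 100L,
                                     compute_stats = TRUE) {
  stopifnot(w >= 1, d > 0)
  n_h <- windowed_counts(as.numeric(h), w, d)
  n_l <- windowed_counts(as.numeric(!h), w, d)
  a <- n_h + 1
  b <- n_l + 1
  pred <- a / (a + b) # Laplace rule on weighted counts
  if (!compute_stats) return(trace_frame(pred, mean = pred))
  sd <- sqrt(a * b / ((a + b)^2 * (a + b + 1)))
  trace_frame(pred, mean = pred, sd = sd,
              kl = beta_kl_series(a, b, resolution))
}

observer_fixed_transition <- function(h, w, d, resolution = 41L,
                                      compute_stats = TRUE) {
  stopifnot(w >= 1, d > 0)
  n <- length(h)
  prev <- c(NA, h[-n])
  pair <- function(p, q) c(0, as.numeric(prev[-1] == p & h[-1] == q))
  n_hl <- windowed_counts(pair(FALSE, TRUE), w, d)
  n_ll <- windowed_counts(pair(FALSE, FALSE), w, d)
  n_lh <- windowed_counts(pair(TRUE, FALSE), w, d)
  n_hh <- windowed_counts(pair(TRUE, TRUE), w, d)
  # theta_{H|L} ~ Beta(a1, b1); theta_{L|H} ~ Beta(a2, b2)
  a1 <- n_hl + 1
  b1 <- n_ll + 1
  a2 <- n_lh + 1
  b2 <- n_hh + 1
  pred <- ifelse(h, b2 / (a2 + b2), a1 / (a1 + b1))
  if (!compute_stats) return(trace_frame(pred, mean = pred))
  sd1 <- sqrt(a1 * b1 / ((a1 + b1)^2 * (a1 + b1 + 1)))
  sd2 <- sqrt(a2 * b2 / ((a2 + b2)^2 * (a2 + b2 + 1)))
  # KL between successive joint posteriors; the joint is a product of the
  # two Beta components, so the grid KL is the sum of the per-axis KLs
  kl <- beta_kl_series(a1, b1, resolution) +
    beta_kl_series(a2, b2, resolution)
  trace_frame(pred, mean = pred, sd = ifelse(h, sd2, sd1), kl = kl)
}

# --- change-point (jump) models: grid HMM forward filtering ---------------

observer_jump_frequency <- function(h, p_jump, resolution = 100L,
                                    compute_stats = TRUE) {
  stopifnot(p_jump >= 0, p_jump <= 1, resolution >= 20L)
  out <- jump_frequency_filter(h, p_jump, as.integer(resolution),
                               compute_stats)
  if (isTRUE(out$underflow)) {
    warning("posterior mass underflow; renormalised to flat")
  }
  if (!compute_stats) return(trace_frame(out$pred, mean = out$mean))
  trace_frame(out$pred, mean = out$mean, sd = out$sd, kl = out$kl)
}

observer_jump_transition <- function(h, p_jump, resolution = 41L,
                                     compute_stats = TRUE) {
  stopifnot(p_jump >= 0, p_jump <= 1, resolution >= 20L)
  out <- jump_transition_filter(h, p_jump, as.integer(resolution),
                                compute_stats)
  if (isTRUE(out$underflow)) {
    warning("posterior mass underflow; renormalised to flat")
  }
  if (!compute_stats) return(trace_frame(out$pred, mean = out$mean))
  trace_frame(out$pred, mean = out$mean, sd = out$sd, kl = out$kl)
}

#' @export
print.observer_trace <- function(x, ...) {
  cat(sprintf("<observer_trace: %s, %d trials>\n", attr(x, "model"),
              nrow(x)))
  print.data.frame(utils::head(as.data.frame(x)))
  invisible(x)
}

#' Write an observer trace as tidy CSV
#'
#' @param trace An `observer_trace`.
#' @param path File path.
#' @export
write_trace_csv <- function(trace, path) {
  df <- as.data.frame(trace)
  df$model <- attr(trace, "model")
  p <- attr(trace, "params")
  df$params <- paste(names(p), unlist(p), sep = "=", collapse = ";")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
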