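#' @title Model fitting by BIC-scored rating regression
#'
#' @description Each observer model is fitted per subject by regressing the
#' subject's probe ratings on the model's predictive probabilities plus a
#' session covariate, `y_k ~ b0 + b1 * p_k + b2 * N_s + e`, and scoring the
#' fit with `BIC = n * log(sigma2) + k * log(n)` where `sigma2` is the mean
#' squared residual, `n` the number of probes and `k` the model's free
#' parameter count (the regression coefficients appear in every model and
#' are excluded from `k`). Free observer parameters are optimised by
#' bounded multi-start local search.
#' @name model_fitting
NULL

# registry of free observer parameters and their search spaces;
# probabilities are optimised on the logit scale, decay on the log scale,
# window on a log-spaced integer grid
model_param_info <- function(model, n_trials = 1500L) {
  switch(model,
    random = list(pars = "p_l", lower = 1e-4, upper = 1 - 1e-4, k = 1L),
    rw = list(pars = "alpha", lower = 1e-4, upper = 1 - 1e-6, k = 1L),
    jump_frequency = ,
    jump_transition = list(pars = "p_jump", lower = 1e-4, upper = 0.5,
                           k = 1L),
    fixed_frequency = ,
    fixed_transition = list(pars = c("w", "d"), w_max = n_trials,
                            d_lower = 1, d_upper = 1000, k = 2L),
    stop("unknown model: ", model)
  )
}

#' Regress probe ratings on model predictions
#'
#' Ordinary least squares of ratings on an intercept, the model's
#' predictive probabilities at the probe trials, and the session number as
#' a numeric covariate. Rank-deficient designs (constant predictions, or a
#' single session) drop the offending column; dropped coefficients are
#' reported as 0 and flagged.
#'
#' @param ratings Numeric vector of rated probabilities `y_k`.
#' @param predictions Model predictive probabilities aligned to the probes.
#' @param session_ids Session number per probe.
#' @return List with `beta0`, `beta1`, `beta2`, `sigma2` (mean squared
#'   residual), `residuals`, `n_obs`, `dropped` (logical flag).
#' @export
fit_rating_regression <- function(ratings, predictions, session_ids) {
  n <- length(ratings)
  if (n < 3L) stop("need at least 3 probes to fit the rating regression")
  if (length(predictions) != n || length(session_ids) != n) {
    stop("predictions and session ids must align with the ratings")
  }
  fit <- stats::lm(ratings ~ predictions + as.numeric(session_ids))
  cf <- stats::coef(fit)
  dropped <- any(is.na(cf))
  cf[is.na(cf)] <- 0
  res <- stats::residuals(fit)
  list(
    beta0 = unname(cf[1]),
    beta1 = unname(cf[2]),
    beta2 = unname(cf[3]),
    sigma2 = mean(res^2),
    residuals = unname(res),
    n_obs = n,
    dropped = dropped
  )
}

#' Bayesian information criterion from residual variance
#'
#' `BIC = n * log(max(sigma2, floor)) + k * log(n)`. The floor keeps the
#' criterion finite for perfect fits; a floored value is flagged via the
#' `"floored"` attribute.
#'
#' @param sigma2 Mean squared residual of the rating regression.
#' @param n_obs Number of rated probes.
#' @param k_params Number of free observer parameters.
#' @param floor Lower bound on `sigma2` (default 1e-9).
#' @return BIC value (scalar).
#' @examples
#' compute_bic(1, 100, 2) # 2 * log(100)
#' @export
compute_bic <- function(sigma2, n_obs, k_params, floor = 1e-9) {
  if (n_obs < k_params + 1L) stop("n_obs must exceed k_params")
  floored <- sigma2 < floor
  bic <- n_obs * log(max(sigma2, floor)) + k_params * log(n_obs)
  structure(bic, floored = floored)
}

#' Evaluate a model's BIC at fixed parameter values
#'
#' Runs the observer over the sequence, aligns predictions to the rated
#' probes, fits the rating regression and returns the BIC with its
#' regression components. This is the inner step of [fit_subject()] and is
#' exported for diagnostics and recovery analyses.
#'
#' @param ratings A `rating_dataset` (single subject).
#' @param seq The `generative_sequence` the ratings refer to.
#' @param model Observer model name.
#' @param params Named list of observer parameters.
#' @param resolution Optional grid resolution override.
#' @return List with `bic`, `beta0`, `beta1`, `beta2`, `sigma2`, `n_obs`,
#'   `k_params`, `dropped`.
#' @export
evaluate_model_bic <- function(ratings, seq, model, params,
                               resolution = NULL) {
  trace <- run_observer(seq, model, params, resolution = resolution,
                        compute_stats = FALSE)
  pred <- trace$predictive_p_h[ratings$trial]
  reg <- fit_rating_regression(ratings$rated_p_h, pred, ratings$session)
  info <- model_param_info(model, n_trials = nrow(seq))
  bic <- compute_bic(reg$sigma2, reg$n_obs, info$k)
  list(bic = as.numeric(bic), beta0 = reg$beta0, beta1 = reg$beta1,
       beta2 = reg$beta2, sigma2 = reg$sigma2, n_obs = reg$n_obs,
       k_params = info$k, dropped = reg$dropped)
}

logit_to_unit <- function(z, lo, hi) lo + (hi - lo) * stats::plogis(z)
unit_to_logit <- function(x, lo, hi) {
  stats::qlogis(pmin(pmax((x - lo) / (hi - lo), 1e-12), 1 - 1e-12))
}

# log-spaced integer grid of candidate window lengths
window_grid <- function(n_trials, n_points = 20L) {
  unique(round(exp(seq(log(1), log(n_trials), length.out = n_points))))
}

#' Fit one observer model to one subject's ratings
#'
#' Minimises the BIC of the rating regression over the model's free
#' parameters. Continuous parameters (probabilities, learning rate, decay)
#' are optimised by quasi-Newton search on a transformed unconstrained
#' scale from each restart's random start; the integer window length of the
#' leaky models is searched exhaustively on a log-spaced grid within each
#' restart. Following the study procedure the across-restart mean of
#' parameters and BIC is reported by default (`mode = "mean"`); the best
#' restart is available as `mode = "best"`.
#'
#' @param ratings A `rating_dataset` (single subject).
#' @param seq The `generative_sequence` the ratings refer to.
#' @param model Observer model name.
#' @param n_restarts Number of random restarts (default 100).
#' @param seed Optional integer seed for the restart draws.
#' @param mode `"mean"` (default) or `"best"`.
#' @param resolution Optional grid resolution override for grid models.
#' @return A `fit_result` list: `model`, `params` (named list), `bic`,
#'   `beta0/1/2`, `sigma2`, `n_obs`, `k_params`, `bic_at_params` (BIC
#'   re-evaluated at the reported parameters), `restarts` (per-restart
#'   data frame), `mode`.
#' @export
fit_subject <- function(ratings, seq, model, n_restarts = 100L,
                        seed = NULL, mode = c("mean", "best"),
                        resolution = NULL) {
  mode <- match.arg(mode)
  model <- match.arg(model, observer_model_names())
  if (!is.null(seed)) set.seed(seed)
  if (nrow(ratings) == 0L) stop("ratings are empty")
  n_trials <- nrow(seq)
  info <- model_param_info(model, n_trials)

  objective <- function(params) {
    evaluate_model_bic(ratings, seq, model, params, resolution)$bic
  }

  if (identical(info$pars, c("w", "d"))) {
    restarts <- fit_restarts_window(objective, info, n_restarts)
  } else {
    restarts <- fit_restarts_continuous(objective, info, n_restarts)
  }

  ok <- is.finite(restarts$bic)
  if (!any(ok)) stop("all restarts failed to produce a finite BIC")
  restarts <- restarts[ok, , drop = FALSE]

  par_cols <- info$pars
  if (mode == "best") {
    i <- which.min(restarts$bic)
    params <- as.list(restarts[i, par_cols, drop = FALSE])
    bic <- restarts$bic[i]
  } else {
    params <- as.list(colMeans(restarts[, par_cols, drop = FALSE]))
    bic <- mean(restarts$bic)
  }
  names(params) <- par_cols
  final <- evaluate_model_bic(ratings, seq, model, params, resolution)
  structure(
    list(model = model, params = params, bic = bic,
         beta0 = final$beta0, beta1 = final$beta1, beta2 = final$beta2,
         sigma2 = final$sigma2, n_obs = final$n_obs,
         k_params = final$k_params, bic_at_params = final$bic,
         restarts = restarts, mode = mode),
    class = "fit_result"
  )
}

# multi-start quasi-Newton search for a single bounded continuous parameter
fit_restarts_continuous <- function(objective, info, n_restarts) {
  par <- info$pars
  lo <- info$lower
  hi <- info$upper
  res <- data.frame(matrix(NA_real_, n_restarts, 2L))
  names(res) <- c(par, "bic")
  for (r in seq_len(n_restarts)) {
    x0 <- stats::runif(1, lo, hi)
    fn <- function(z) {
      p <- stats::setNames(list(logit_to_unit(z, lo, hi)), par)
      objective(p)
    }
    opt <- tryCatch(
      stats::optim(unit_to_logit(x0, lo, hi), fn, method = "BFGS",
                   control = list(maxit = 100, reltol = 1e-8)),
      error = function(e) NULL
    )
    if (!is.null(opt)) {
      res[r, par] <- logit_to_unit(opt$par, lo, hi)
      res[r, "bic"] <- opt$value
    }
  }
  res
}

# leaky models: exhaustive log-grid over the integer window, quasi-Newton
# over log-decay from each restart's random start
fit_restarts_window <- function(objective, info, n_restarts) {
  wgrid <- window_grid(info$w_max)
  res <- data.frame(w = rep(NA_real_, n_restarts), d = NA_real_,
                    bic = NA_real_)
  for (r in seq_len(n_restarts)) {
    d0 <- exp(stats::runif(1, log(info$d_lower), log(info$d_upper)))
    best <- list(bic = Inf)
    for (w in wgrid) {
      fn <- function(zd) {
        d <- exp(logit_to_unit(zd, log(info$d_lower), log(info$d_upper)))
        objective(list(w = w, d = d))
      }
      z0 <- unit_to_logit(log(d0), log(info$d_lower), log(info$d_upper))
      opt <- tryCatch(
        stats::optim(z0, fn, method = "BFGS",
                     control = list(maxit = 50, reltol = 1e-8)),
        error = function(e) NULL
      )
      if (!is.null(opt) && opt$value < best$bic) {
        best <- list(
          bic = opt$value, w = w,
          d = exp(logit_to_unit(opt$par, log(info$d_lower),
                                log(info$d_upper)))
        )
      }
    }
    if (is.finite(best$bic)) {
      res[r, ] <- c(best$w, best$d, best$bic)
    }
  }
  res
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result: %s, BIC %.2f (%s of %d restarts)>\n",
              x$model, x$bic, x$mode, nrow(x$restarts)))
  cat("  params:",
      paste(names(x$params), sprintf("%.4g", unlist(x$params)),
            sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Write a fit result to JSON
#'
#' Serialises the fitted parameters, regression coefficients and BIC of a
#' single subject/model fit (per-restart detail is omitted).
#'
#' @param fit A `fit_result`.
#' @param path File path.
#' @export
write_fit_json <- function(fit, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("jsonlite is required to write fit results")
  }
  out <- fit[c("model", "params", "bic", "beta0", "beta1", "beta2",
               "sigma2", "n_obs", "k_params", "mode")]
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Assemble and write a subjects-by-models BIC table
#'
#' @param fits Nested list: `fits[[subject]][[model]]` of `fit_result`
#'   objects (model names taken from the first subject).
#' @param path Optional CSV path; when supplied the table is written with
#'   a leading `subject` column.
#' @return Numeric matrix of BIC values, rows subjects, columns models
#'   (suitable for [evidence_matrix()]).
#' @export
bic_table <- function(fits, path = NULL) {
  models <- vapply(fits[[1]], function(f) f$model, character(1))
  m <- t(vapply(fits, function(sub)
    vapply(sub, function(f) f$bic, numeric(1)), numeric(length(models))))
  colnames(m) <- models
  rownames(m) <- names(fits)
  if (!is.null(path)) {
    df <- data.frame(subject = rownames(m) %||% seq_len(nrow(m)), m,
                     check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE)
  }
  m
}

#' Parameter recovery harness
#'
#' For each simulated subject: draw a true parameter set from the supplied
#' grid (cycled), generate a fresh stimulus sequence, simulate noisy probe
#' ratings from the observer, refit the generating model, and record true
#' versus recovered values.
#'
#' @param model Observer model name.
#' @param true_grid Data frame of true parameter sets (one column per free
#'   parameter), or a named list of vectors (crossed into a grid).
#' @param n_sims Number of simulated subjects (rows are cycled).
#' @param noise_sd Rating noise SD.
#' @param seed Integer seed for the whole harness.
#' @param config Sequence [generator_config()].
#' @param n_restarts,mode Passed to [fit_subject()].
#' @return A `recovery_report`: data frame of true and recovered values
#'   (columns `true_<par>`, `recovered_<par>`) with a `summary` attribute
#'   holding per-parameter Pearson correlation and mean bias.
#' @export
parameter_recovery <- function(model, true_grid, n_sims = NULL,
                               noise_sd = 0.1, seed = NULL,
                               config = generator_config(),
                               n_restarts = 10L, mode = "best") {
  if (!is.null(seed)) set.seed(seed)
  if (!is.data.frame(true_grid)) true_grid <- expand.grid(true_grid)
  if (is.null(n_sims)) n_sims <- nrow(true_grid)
  pars <- names(true_grid)
  rows <- vector("list", n_sims)
  if (n_sims > 0L) {
    for (i in seq_len(n_sims)) {
      tp <- as.list(true_grid[(i - 1L) %% nrow(true_grid) + 1L, ,
                              drop = FALSE])
      row <- stats::setNames(as.list(rep(NA_real_, 2L * length(pars))),
                             c(paste0("true_", pars),
                               paste0("recovered_", pars)))
      row[paste0("true_", pars)] <- tp
      fitted <- tryCatch({
        s <- generate_sequence(config)
        r <- simulate_observer_ratings(s, model, tp, noise_sd = noise_sd,
                                       subject = i)
        fit_subject(r, s, model, n_restarts = n_restarts, mode = mode)
      }, error = function(e) e)
      if (!inherits(fitted, "error")) {
        row[paste0("recovered_", pars)] <- fitted$params[pars]
      }
      rows[[i]] <- as.data.frame(row)
    }
  }
  out <- if (n_sims > 0L) do.call(rbind, rows) else
    stats::setNames(data.frame(matrix(numeric(0), 0, 2 * length(pars))),
                    c(paste0("true_", pars), paste0("recovered_", pars)))
  summ <- lapply(pars, function(p) {
    tv <- out[[paste0("true_", p)]]
    rv <- out[[paste0("recovered_", p)]]
    ok <- is.finite(tv) & is.finite(rv)
    data.frame(
      parameter = p,
      correlation = if (sum(ok) >= 3 && stats::sd(tv[ok]) > 0)
        stats::cor(tv[ok], rv[ok]) else NA_real_,
      bias = if (any(ok)) mean(rv[ok] - tv[ok]) else NA_real_,
      n = sum(ok)
    )
  })
  structure(out, summary = do.call(rbind, summ),
            class = c("recovery_report", "data.frame"))
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report: %d simulations>\n", nrow(x)))
  print(attr(x, "summary"))
  invisible(x)
}
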