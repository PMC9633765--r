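#' Assemble a subjects-by-models log-evidence matrix
#'
#' Converts per-subject BIC values into approximate log model evidence.
#' Under the Laplace approximation `log evidence ~ -BIC / 2` (the default);
#' the cruder `-BIC` convention is available for sensitivity checks. The
#' convention is stored as an attribute and honoured by
#' [fixed_effects_compare()].
#'
#' @param bic_matrix Numeric matrix or data frame, rows subjects, columns
#'   models, of BIC values.
#' @param convention `"half"` (log evidence = -BIC/2, default) or
#'   `"full"` (-BIC).
#' @return An `evidence_matrix`: numeric matrix of log evidence with the
#'   `convention` attribute.
#' @export
evidence_matrix <- function(bic_matrix, convention = c("half", "full")) {
  convention <- match.arg(convention)
  m <- as.matrix(bic_matrix)
  if (!all(is.finite(m))) stop("evidence matrix entries must be finite")
  ev <- if (convention == "half") -m / 2 else -m
  structure(ev, convention = convention, class = c("evidence_matrix",
                                                   class(ev)))
}

#' Random-effects Bayesian model selection
#'
#' Treats the model identity as a random effect across subjects: each
#' subject uses one model drawn from population frequencies `r` with a
#' Dirichlet prior. A variational Dirichlet-multinomial update iterates
#' subject responsibilities and Dirichlet counts to convergence, yielding
#' posterior model frequencies, exceedance probabilities (the probability
#' that a model is the most frequent, estimated by Monte Carlo draws from
#' the posterior Dirichlet), the Bayes omnibus risk (BOR; the posterior
#' probability of the null that all models are equally frequent, from the
#' free-energy comparison of the random-effects model against that null),
#' and protected exceedance probabilities
#' `pEP = EP * (1 - BOR) + BOR / K`.
#'
#' @param evidence An [evidence_matrix()] (or plain matrix of log model
#'   evidence), rows subjects, columns models.
#' @param n_mc_samples Monte Carlo draws for the exceedance probabilities
#'   (default 1e6).
#' @param seed Optional integer seed for the Monte Carlo step.
#' @param alpha0 Dirichlet prior count per model (default 1).
#' @param tol,max_iter Convergence controls for the variational update.
#' @return A `comparison_result` list: `frequencies`, `exceedance`,
#'   `protected_exceedance`, `bor`, `dirichlet_alpha`, `responsibilities`
#'   (subjects x models), `free_energy`, `null_evidence`, `n_mc_samples`,
#'   `n_iter`.
#' @examples
#' ev <- matrix(c(0, -3, 0, -4, 0, -2), nrow = 3, byrow = TRUE)
#' rfx_bms(ev, n_mc_samples = 1e4, seed = 1)
#' @export
rfx_bms <- function(evidence, n_mc_samples = 1e6, seed = NULL,
                    alpha0 = 1, tol = 1e-6, max_iter = 200L) {
  l <- unclass(as.matrix(evidence))
  n <- nrow(l)
  k <- ncol(l)
  if (n < 2L || k < 2L) {
    stop("random-effects comparison needs >= 2 subjects and >= 2 models")
  }
  if (!all(is.finite(l))) stop("log evidence must be finite")
  if (!is.null(seed)) set.seed(seed)

  a0 <- rep(alpha0, k)
  alpha <- a0
  g <- matrix(1 / k, n, k)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    # responsibilities: g_nk ~ exp(L_nk + psi(alpha_k) - psi(sum alpha))
    w <- sweep(l, 2, digamma(alpha) - digamma(sum(alpha)), "+")
    w <- w - apply(w, 1, max)
    g <- exp(w)
    g <- g / rowSums(g)
    alpha_new <- a0 + colSums(g)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      converged <- TRUE
      break
    }
    alpha <- alpha_new
  }
  if (!converged) {
    stop("variational update did not converge within ", max_iter,
         " iterations (last max |delta alpha| = ",
         format(max(abs(alpha_new - alpha))), ")")
  }

  freq <- alpha / sum(alpha)
  ep <- exceedance_mc(alpha, n_mc_samples)

  f1 <- rfx_free_energy(l, g, alpha, a0)
  # null: all subjects share equal frequencies 1/K
  f0 <- sum(apply(l - log(k), 1, log_sum_exp))
  bor <- 1 / (1 + exp(f1 - f0))
  pep <- ep * (1 - bor) + bor / k

  models <- colnames(l) %||% paste0("model", seq_len(k))
  names(freq) <- names(ep) <- names(pep) <- names(alpha) <- models
  colnames(g) <- models
  structure(
    list(frequencies = freq, exceedance = ep,
         protected_exceedance = pep, bor = bor, dirichlet_alpha = alpha,
         responsibilities = g, free_energy = f1, null_evidence = f0,
         n_mc_samples = n_mc_samples, n_iter = iter),
    class = "comparison_result"
  )
}

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# Monte Carlo exceedance: fraction of posterior Dirichlet draws in which
# each model has the largest frequency
exceedance_mc <- function(alpha, n_samples) {
  k <- length(alpha)
  draws <- matrix(stats::rgamma(n_samples * k, shape = rep(alpha,
                                                           each = n_samples)),
                  nrow = n_samples)
  ep <- tabulate(max.col(draws, ties.method = "random"), nbins = k)
  ep / n_samples
}

# variational free energy of the random-effects model (Dirichlet-multinomial
# mixture): E_q[log p(y, m, r)] + H[q(r)] + H[q(m)]
rfx_free_energy <- function(l, g, alpha, a0) {
  dg <- digamma(alpha) - digamma(sum(alpha))
  elj <- lgamma(sum(a0)) - sum(lgamma(a0)) + sum((a0 - 1) * dg) +
    sum(g * (sweep(l, 2, dg, "+")))
  sqf <- sum(lgamma(alpha)) - lgamma(sum(alpha)) - sum((alpha - 1) * dg)
  sqm <- -sum(g[g > 0] * log(g[g > 0]))
  elj + sqf + sqm
}

#' Fixed-effects comparison by averaged BIC
#'
#' Converts log evidence back to BIC under the evidence matrix's stored
#' convention, averages over subjects, and ranks models ascending (lowest
#' mean BIC = best).
#'
#' @param evidence An [evidence_matrix()] or plain log-evidence matrix.
#' @return Data frame with columns `model`, `mean_bic`, `rank`, ordered
#'   best first.
#' @export
fixed_effects_compare <- function(evidence) {
  conv <- attr(evidence, "convention") %||% "half"
  l <- unclass(as.matrix(evidence))
  bic <- if (conv == "half") -2 * l else -l
  mean_bic <- colMeans(bic)
  models <- colnames(l) %||% paste0("model", seq_along(mean_bic))
  ord <- order(mean_bic)
  data.frame(model = models[ord], mean_bic = mean_bic[ord],
             rank = seq_along(ord), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Per-subject model attribution
#'
#' Returns the converged responsibilities of the random-effects comparison:
#' each row is one subject's posterior probability over models.
#'
#' @param result A `comparison_result` from [rfx_bms()].
#' @return Numeric matrix, subjects x models, rows summing to 1.
#' @export
subject_attribution <- function(result) {
  if (!inherits(result, "comparison_result")) {
    stop("expected a comparison_result from rfx_bms()")
  }
  result$responsibilities
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result: %d models, %d subjects, BOR %.3f>\n",
              length(x$frequencies), nrow(x$responsibilities), x$bor))
  print(round(rbind(frequency = x$frequencies,
                    exceedance = x$exceedance,
                    protected = x$protected_exceedance), 4))
  invisible(x)
}

#' Write a comparison result to JSON and responsibilities to CSV
#'
#' @param result A `comparison_result`.
#' @param json_path Path for the JSON summary (requires jsonlite).
#' @param csv_path Optional path for the responsibilities CSV.
#' @export
write_comparison <- function(result, json_path, csv_path = NULL) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("jsonlite is required to write the JSON summary")
  }
  out <- result[c("frequencies", "exceedance", "protected_exceedance",
                  "bor", "dirichlet_alpha", "n_mc_samples", "n_iter")]
  # keep model names as JSON keys
  named <- c("frequencies", "exceedance", "protected_exceedance",
             "dirichlet_alpha")
  out[named] <- lapply(out[named], as.list)
  jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(csv_path)) {
    utils::write.csv(as.data.frame(result$responsibilities), csv_path,
                     row.names = FALSE)
  }
  invisible(json_path)
}
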