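#' Correlation between generative and rated probabilities
#'
#' Pairs each probe rating with the generative value active at that trial
#' and returns the within-subject Pearson correlation. For the transition
#' quantities, probes are restricted to those whose preceding stimulus
#' matches the conditioning state and the generative value is read directly
#' from the chunk's transition matrix. For the frequency, the generative
#' value is the stationary frequency of the active matrix, and the rated
#' frequency is derived from the most recent rating of each conditional
#' type (carried forward) through the same stationary formula
#' `r(H|L) / (r(H|L) + 1 - r(H|H))`; probes before both conditional types
#' have been rated at least once are dropped.
#'
#' @param seq A `generative_sequence`.
#' @param ratings A `rating_dataset` for one subject.
#' @param quantity `"frequency"`, `"p_h_given_l"` or `"p_h_given_h"`.
#' @return An `accuracy_record` list: `subject`, `quantity`, `pearson_r`,
#'   `n_probes`, plus the paired `generative` and `rated` vectors.
#' @export
generative_vs_rated <- function(seq, ratings,
                                quantity = c("frequency", "p_h_given_l",
                                             "p_h_given_h")) {
  quantity <- match.arg(quantity)
  tr <- ratings$trial
  if (any(tr < 1L | tr > nrow(seq))) {
    stop("rating trials do not resolve against the sequence")
  }
  if (quantity == "frequency") {
    # carry the latest conditional rating of each type forward
    r_hl <- NA_real_
    r_hh <- NA_real_
    gen <- rated <- numeric(0)
    for (i in seq_len(nrow(ratings))) {
      if (ratings$prev_stimulus[i] == "L") {
        r_hl <- ratings$rated_p_h[i]
      } else {
        r_hh <- ratings$rated_p_h[i]
      }
      if (is.na(r_hl) || is.na(r_hh)) next
      t <- tr[i]
      gen <- c(gen, stationary_frequency(seq$p_h_given_l[t],
                                         seq$p_h_given_h[t]))
      denom <- r_hl + 1 - r_hh
      rated <- c(rated, if (denom > 0) r_hl / denom else NA_real_)
    }
    keep <- is.finite(rated)
    gen <- gen[keep]
    rated <- rated[keep]
  } else {
    state <- if (quantity == "p_h_given_l") "L" else "H"
    sel <- ratings$prev_stimulus == state
    gen <- seq[[quantity]][tr[sel]]
    rated <- ratings$rated_p_h[sel]
  }
  if (length(gen) < 3L) stop("fewer than 3 usable probes for ", quantity)
  r <- if (stats::sd(gen) == 0 || stats::sd(rated) == 0) NA_real_ else
    stats::cor(gen, rated)
  structure(
    list(subject = ratings$subject[1], quantity = quantity, pearson_r = r,
         n_probes = length(gen), generative = gen, rated = rated),
    class = "accuracy_record"
  )
}

#' One-sample t-test of correlation coefficients against zero
#'
#' @param rs Numeric vector of per-subject correlations.
#' @return List with `t`, `df`, `p`, `cohens_d` (mean / SD).
#' @export
group_ttest <- function(rs) {
  rs <- rs[is.finite(rs)]
  if (length(rs) < 2L) stop("need at least 2 values")
  if (stats::sd(rs) == 0) {
    if (all(rs == 0)) {
      return(list(t = 0, df = length(rs) - 1L, p = 1, cohens_d = 0))
    }
    stop("zero variance across subjects; t-test degenerate")
  }
  tt <- stats::t.test(rs, mu = 0)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, cohens_d = mean(rs) / stats::sd(rs))
}

#' Paired z-test on Fisher-transformed correlations
#'
#' Fisher-transforms two paired sets of correlation coefficients and tests
#' whether their mean difference is zero with a two-sided z-test on the
#' paired differences. Coefficients at exactly +/- 1 are clipped (with a
#' warning) to keep the transform finite.
#'
#' @param r1s,r2s Paired numeric vectors of correlations.
#' @return List with `z` and `p`.
#' @export
fisher_z_compare <- function(r1s, r2s) {
  if (length(r1s) != length(r2s)) stop("correlation sets must be paired")
  clip <- function(r) {
    if (any(abs(r) >= 1)) {
      warning("correlations at |r| = 1 clipped before Fisher transform")
      r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
    }
    r
  }
  d <- atanh(clip(r1s)) - atanh(clip(r2s))
  if (stats::sd(d) == 0) {
    return(list(z = 0, p = 1))
  }
  z <- mean(d) / (stats::sd(d) / sqrt(length(d)))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Tidy table of accuracy records
#'
#' @param records List of `accuracy_record` objects.
#' @return Data frame with columns `subject`, `quantity`, `pearson_r`,
#'   `n_probes`.
#' @export
accuracy_table <- function(records) {
  do.call(rbind, lapply(records, function(a) {
    data.frame(subject = a$subject, quantity = a$quantity,
               pearson_r = a$pearson_r, n_probes = a$n_probes,
               stringsAsFactors = FALSE)
  }))
}
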