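#' Group-mean parameters across subject fits
#'
#' Averages each free parameter of the chosen model across subjects; the
#' winning model's first-level regressors are built from these group-mean
#' parameters rather than per-subject fits, which reduces parameter noise
#' in the imaging design.
#'
#' @param fit_results List of `fit_result` objects, all for the same model.
#' @return Named list of averaged parameters with attribute `model`.
#' @export
group_mean_params <- function(fit_results) {
  if (length(fit_results) == 0L) stop("need at least one fit result")
  models <- vapply(fit_results, function(f) f$model, character(1))
  if (length(unique(models)) != 1L) {
    stop("fit results mix models: ", paste(unique(models), collapse = ", "))
  }
  pars <- names(fit_results[[1]]$params)
  out <- lapply(pars, function(p) {
    mean(vapply(fit_results, function(f) as.numeric(f$params[[p]]),
                numeric(1)))
  })
  names(out) <- pars
  attr(out, "model") <- models[1]
  out
}

#' Build a first-level events table with parametric modulators
#'
#' Emits BIDS-style events: one `all` event per trial plus `high`/`low`
#' condition events, duration 0, with three parametric modulators attached
#' to the `all` events — the posterior mean probability of a high stimulus,
#' the trial-wise KL update, and the posterior SD. Modulators are
#' mean-centred within each session by default (matching the common
#' first-level software default); centring can be disabled for pipelines
#' that centre downstream. Modulators are exported un-orthogonalised.
#'
#' @param seq A `generative_sequence` (supplies stimulus identities and
#'   session/block ids).
#' @param trace An `observer_trace` computed at group-mean parameters.
#' @param onsets Numeric vector of stimulus onset times in seconds, one per
#'   trial (e.g. `(seq_len(n) - 1) * 3` for a 3 s ISI). Interpreted as
#'   within-session times; sessions are taken from the sequence's blocks.
#' @param center If TRUE (default) mean-centre modulators per session.
#' @return An `events_table` data frame with columns `onset`, `duration`,
#'   `trial_type`, `session`, `posterior_mean_h`, `kl_update`,
#'   `posterior_sd` (modulators NA on `high`/`low` rows).
#' @export
build_events <- function(seq, trace, onsets, center = TRUE) {
  n <- nrow(seq)
  if (length(onsets) != n) stop("onsets must have one entry per trial")
  if (nrow(trace) != n) stop("trace and sequence lengths differ")
  mods <- data.frame(
    posterior_mean_h = trace$posterior_mean,
    kl_update = trace$kl_update,
    posterior_sd = trace$posterior_sd
  )
  if (!all(is.finite(as.matrix(mods)))) {
    stop("modulators must be finite; run the observer with ",
         "compute_stats = TRUE and a model that defines a posterior")
  }
  if (center) {
    for (cn in names(mods)) {
      mods[[cn]] <- mods[[cn]] -
        stats::ave(mods[[cn]], seq$block, FUN = mean)
    }
  }
  all_ev <- data.frame(
    onset = onsets, duration = 0, trial_type = "all", session = seq$block,
    mods, stringsAsFactors = FALSE
  )
  cond_ev <- data.frame(
    onset = onsets, duration = 0,
    trial_type = ifelse(seq$stimulus == "H", "high", "low"),
    session = seq$block,
    posterior_mean_h = NA_real_, kl_update = NA_real_,
    posterior_sd = NA_real_, stringsAsFactors = FALSE
  )
  ev <- rbind(all_ev, cond_ev)
  ev <- ev[order(ev$session, ev$onset, ev$trial_type), ]
  rownames(ev) <- NULL
  structure(ev, class = c("events_table", "data.frame"))
}

#' Write / read a BIDS-style events TSV
#'
#' @param events An `events_table`.
#' @param path File path (conventionally `*_events.tsv`).
#' @return `read_events_tsv` returns the events data frame.
#' @export
write_events_tsv <- function(events, path) {
  df <- as.data.frame(events)
  # 17 significant digits so numeric columns survive the text round-trip
  for (cn in names(df)) {
    if (is.numeric(df[[cn]])) {
      v <- sprintf("%.17g", df[[cn]])
      v[is.na(df[[cn]])] <- "n/a"
      df[[cn]] <- v
    }
  }
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "n/a")
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  ev <- utils::read.delim(path, na.strings = "n/a",
                          stringsAsFactors = FALSE)
  structure(ev, class = c("events_table", "data.frame"))
}
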