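#' Simulate noisy probe ratings from a known observer
#'
#' Runs the chosen observer model over the stimulus sequence and, at every
#' probe trial, records the model's predictive probability of a high
#' stimulus plus additive Gaussian noise, clipped to [0, 1]. This is the
#' ground-truth generator used by parameter- and model-recovery analyses:
#' the rating emulates a participant pausing after the probe trial's
#' stimulus and rating the probability that the next stimulus is high.
#'
#' @param seq A `generative_sequence` (its probe schedule is used).
#' @param model Observer model name (see [run_observer()]).
#' @param params Named list of true observer parameters.
#' @param noise_sd Rating noise SD on the probability scale (default 0.1).
#' @param subject Subject identifier stored with the ratings.
#' @param seed Optional integer seed for the noise draws.
#' @return A `rating_dataset`: data frame with columns `subject`, `session`,
#'   `trial`, `prev_stimulus`, `rated_p_h`, and attributes `true_model` and
#'   `true_params`.
#' @examples
#' s <- generate_sequence(generator_config(n_blocks = 1), seed = 3)
#' r <- simulate_observer_ratings(s, "random", list(p_l = 0.5), noise_sd = 0)
#' all(r$rated_p_h == 0.5)
#' @export
simulate_observer_ratings <- function(seq, model, params, noise_sd = 0.1,
                                      subject = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  model <- match.arg(model, observer_model_names())
  probes <- attr(seq, "probe_indices")
  if (is.null(probes) || length(probes) == 0L) {
    stop("sequence carries no probe schedule")
  }
  trace <- run_observer(seq, model, params, compute_stats = FALSE)
  pred <- trace$predictive_p_h[probes]
  rated <- pred + stats::rnorm(length(probes), 0, noise_sd)
  rated <- pmin(pmax(rated, 0), 1)
  out <- data.frame(
    subject = subject,
    session = seq$block[probes],
    trial = probes,
    prev_stimulus = seq$stimulus[probes],
    rated_p_h = rated,
    stringsAsFactors = FALSE
  )
  structure(out, true_model = model, true_params = params,
            class = c("rating_dataset", "data.frame"))
}

#' Write / read probe ratings in the canonical CSV schema
#'
#' The canonical schema has one row per probe:
#' `subject, session, trial, prev_stimulus, rated_p_h`. `read_ratings_csv`
#' accepts a column mapping for externally deposited datasets whose headers
#' differ.
#'
#' @param ratings A `rating_dataset` or compatible data frame.
#' @param path File path.
#' @param mapping Optional named character vector mapping canonical column
#'   names to the file's column names, e.g.
#'   `c(rated_p_h = "rating", trial = "trial_index")`.
#' @return `read_ratings_csv` returns a `rating_dataset`.
#' @export
write_ratings_csv <- function(ratings, path) {
  utils::write.csv(as.data.frame(ratings), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ratings_csv
#' @export
read_ratings_csv <- function(path, mapping = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(mapping)) {
    for (canon in names(mapping)) {
      src <- mapping[[canon]]
      if (!src %in% names(df)) {
        stop("mapped column '", src, "' not found in ", path)
      }
      df[[canon]] <- df[[src]]
    }
  }
  needed <- c("subject", "session", "trial", "prev_stimulus", "rated_p_h")
  if (!all(needed %in% names(df))) {
    stop("ratings CSV is missing required columns: ",
         paste(setdiff(needed, names(df)), collapse = ", "))
  }
  if (any(df$rated_p_h < 0 | df$rated_p_h > 1)) {
    stop("ratings must lie in [0, 1]")
  }
  structure(df[, needed],
            class = c("rating_dataset", "data.frame"))
}
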