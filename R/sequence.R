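#' Configuration for the volatile Markov sequence generator
#'
#' The generative process emits binary low/high (L/H) stimuli from a 2-state
#' Markov chain whose transition matrix is occasionally resampled ("jumps").
#' Chunk lengths between jumps follow a geometric distribution with
#' per-trial change probability `p_jump`, truncated to
#' `[chunk_min, chunk_max]`. Each new matrix is drawn with both free
#' transition probabilities uniform on the grid
#' `seq(prob_grid_lo, prob_grid_hi, prob_grid_step)`, rejection-sampled
#' until at least one of p(H|L), p(L|H) moves by more than `min_change`
#' relative to the previous chunk. Probe trials, where an observer is asked
#' to rate the probability of the upcoming stimulus, are scheduled with
#' uniform gaps in `[probe_min, probe_max]`.
#'
#' @param n_trials_per_block Trials per block (default 300).
#' @param n_blocks Number of blocks/sessions (default 5).
#' @param p_jump Per-trial probability of resampling the matrix (default 0.014).
#' @param chunk_min,chunk_max Inclusive bounds on chunk length (6, 199).
#' @param prob_grid_lo,prob_grid_hi,prob_grid_step Transition-probability
#'   grid (0.15, 0.85, 0.05).
#' @param min_change Minimum change in at least one transition probability
#'   at a jump (default 0.2, strict inequality).
#' @param probe_min,probe_max Bounds on the gap between probes (12, 18).
#' @param max_reject Cap on matrix rejection-sampling iterations.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_trials_per_block = 300L,
                             n_blocks = 5L,
                             p_jump = 0.014,
                             chunk_min = 6L,
                             chunk_max = 199L,
                             prob_grid_lo = 0.15,
                             prob_grid_hi = 0.85,
                             prob_grid_step = 0.05,
                             min_change = 0.2,
                             probe_min = 12L,
                             probe_max = 18L,
                             max_reject = 1000L) {
  cfg <- list(
    n_trials_per_block = as.integer(n_trials_per_block),
    n_blocks = as.integer(n_blocks),
    p_jump = p_jump,
    chunk_min = as.integer(chunk_min),
    chunk_max = as.integer(chunk_max),
    prob_grid = seq(prob_grid_lo, prob_grid_hi, by = prob_grid_step),
    min_change = min_change,
    probe_min = as.integer(probe_min),
    probe_max = as.integer(probe_max),
    max_reject = as.integer(max_reject)
  )
  if (cfg$n_trials_per_block < 1L || cfg$n_blocks < 1L) {
    stop("trial and block counts must be positive")
  }
  if (cfg$p_jump <= 0 || cfg$p_jump >= 1) stop("p_jump must lie in (0, 1)")
  if (cfg$chunk_min <= 5L || cfg$chunk_max >= 200L ||
      cfg$chunk_min > cfg$chunk_max) {
    stop("chunk bounds must satisfy 5 < chunk_min <= chunk_max < 200")
  }
  if (cfg$probe_min < 1L || cfg$probe_min > cfg$probe_max) {
    stop("probe interval must be positive with probe_min <= probe_max")
  }
  class(cfg) <- "generator_config"
  cfg
}

#' Stationary frequency of high stimuli under a transition matrix
#'
#' For the 2-state chain with free entries p(H|L) and p(H|H), solves
#' `pi = pi P` for the stationary mass on H:
#' `p(H|L) / (p(H|L) + 1 - p(H|H))`.
#'
#' @param p_h_given_l Probability of H following L.
#' @param p_h_given_h Probability of H following H.
#' @return Stationary probability of a high stimulus.
#' @examples
#' stationary_frequency(0.8, 0.8) # 0.8
#' @export
stationary_frequency <- function(p_h_given_l, p_h_given_h) {
  denom <- p_h_given_l + 1 - p_h_given_h
  if (any(denom <= 0)) {
    stop("degenerate absorbing chain: p(H|L) + p(L|H) must be positive")
  }
  p_h_given_l / denom
}

#' Draw chunk lengths and transition matrices
#'
#' Samples `n` consecutive chunks of the generative process: lengths from
#' the truncated geometric, matrices from the probability grid under the
#' minimum-change constraint. Exposed separately from [generate_sequence()]
#' so that the chunk-level contract can be examined at scale without
#' simulating stimuli.
#'
#' @param n Number of chunks.
#' @param config A [generator_config()].
#' @param prev Optional numeric vector `c(p_h_given_l, p_h_given_h)` of the
#'   matrix preceding the first sampled chunk.
#' @return Data frame with columns `length`, `p_h_given_l`, `p_h_given_h`.
#' @export
sample_chunks <- function(n, config = generator_config(), prev = NULL) {
  lengths <- integer(n)
  phl <- numeric(n)
  phh <- numeric(n)
  for (i in seq_len(n)) {
    lengths[i] <- rgeom_truncated(config$p_jump, config$chunk_min,
                                  config$chunk_max)
    m <- sample_matrix(config, prev)
    phl[i] <- m[1]
    phh[i] <- m[2]
    prev <- m
  }
  data.frame(length = lengths, p_h_given_l = phl, p_h_given_h = phh)
}

# geometric chunk length (support 1, 2, ...) truncated by resampling
rgeom_truncated <- function(p, lo, hi) {
  for (i in 1:10000) {
    len <- stats::rgeom(1L, p) + 1L
    if (len >= lo && len <= hi) return(len)
  }
  stop("chunk-length sampling failed to land inside the truncation bounds")
}

# draw (p_h_given_l, p_h_given_h) from the grid; if prev is given, reject
# until at least one of p(H|L), p(L|H) changes by more than min_change.
# |delta p(L|H)| equals |delta p(H|H)| because the rows are complementary.
sample_matrix <- function(config, prev = NULL) {
  for (i in seq_len(config$max_reject)) {
    m <- sample(config$prob_grid, 2L, replace = TRUE)
    if (is.null(prev)) return(m)
    if (max(abs(m - prev)) > config$min_change) return(m)
  }
  stop("matrix rejection sampling exceeded the iteration cap; ",
       "check min_change against the probability grid")
}

#' Generate a volatile Markov stimulus sequence
#'
#' Produces `n_blocks * n_trials_per_block` binary stimuli. The active
#' transition matrix is constant within a chunk and resampled at jumps;
#' chunks run across block boundaries. The first stimulus of the run is a
#' fair coin; every later stimulus is drawn from the active matrix
#' conditioned on its predecessor. Probe trials are scheduled over the whole
#' run with uniform gaps.
#'
#' @param config A [generator_config()].
#' @param seed Optional integer seed; when supplied the sequence, probe
#'   schedule and all chunk draws are reproducible.
#' @return An object of class `generative_sequence`: a data frame with
#'   columns `block`, `trial`, `stimulus` ("L"/"H"), `p_h_given_l`,
#'   `p_h_given_h`, `is_jump`, `is_probe`, and attributes `jump_indices`,
#'   `probe_indices`, `chunks` and `config`.
#' @examples
#' seq <- generate_sequence(generator_config(n_blocks = 1), seed = 1)
#' table(seq$stimulus)
#' @export
generate_sequence <- function(config = generator_config(), seed = NULL) {
  if (!inherits(config, "generator_config")) {
    config <- do.call(generator_config, config)
  }
  if (!is.null(seed)) set.seed(seed)
  n_total <- config$n_trials_per_block * config$n_blocks

  # draw chunks until they cover the run; the last chunk is cut at n_total
  chunks <- sample_chunks(1L, config)
  while (sum(chunks$length) < n_total) {
    prev <- as.numeric(chunks[nrow(chunks), c("p_h_given_l", "p_h_given_h")])
    chunks <- rbind(chunks, sample_chunks(1L, config, prev = prev))
  }

  starts <- cumsum(c(1L, chunks$length))[seq_len(nrow(chunks))]
  chunk_id <- rep(seq_len(nrow(chunks)), times = chunks$length)[1:n_total]
  phl <- chunks$p_h_given_l[chunk_id]
  phh <- chunks$p_h_given_h[chunk_id]

  stim <- logical(n_total) # TRUE = H
  stim[1] <- stats::runif(1) < 0.5
  u <- stats::runif(n_total)
  for (t in 2:n_total) {
    p_h <- if (stim[t - 1L]) phh[t] else phl[t]
    stim[t] <- u[t] < p_h
  }

  jump_indices <- starts[starts > 1L & starts <= n_total]
  probe_indices <- schedule_probes(n_total,
                                   c(config$probe_min, config$probe_max))

  df <- data.frame(
    block = rep(seq_len(config$n_blocks), each = config$n_trials_per_block),
    trial = seq_len(n_total),
    stimulus = ifelse(stim, "H", "L"),
    p_h_given_l = phl,
    p_h_given_h = phh,
    is_jump = seq_len(n_total) %in% jump_indices,
    is_probe = seq_len(n_total) %in% probe_indices,
    stringsAsFactors = FALSE
  )
  structure(df,
            jump_indices = jump_indices,
            probe_indices = probe_indices,
            chunks = chunks,
            config = config,
            class = c("generative_sequence", "data.frame"))
}

#' Schedule probe trials with uniform gaps
#'
#' Successive gaps between probes are drawn uniformly from
#' `interval[1]:interval[2]`; indices exceeding `n_trials` are dropped.
#'
#' @param n_trials Sequence length.
#' @param interval Length-2 integer vector of gap bounds.
#' @param seed Optional integer seed.
#' @return Strictly increasing integer vector of probe trial indices.
#' @export
schedule_probes <- function(n_trials, interval = c(12L, 18L), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lo <- as.integer(interval[1])
  hi <- as.integer(interval[2])
  if (lo < 1L || lo > hi) stop("probe interval must satisfy 1 <= lo <= hi")
  if (lo > n_trials) {
    warning("probe interval wider than the sequence; empty schedule")
    return(integer(0))
  }
  # upper bound on the number of gaps needed, drawn in one vectorised call
  n_max <- ceiling(n_trials / lo) + 1L
  gaps <- sample(lo:hi, n_max, replace = TRUE)
  idx <- cumsum(gaps)
  idx[idx <= n_trials]
}

#' @export
print.generative_sequence <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf(
    "<generative_sequence: %d trials, %d blocks, %d chunks, %d probes>\n",
    nrow(x), cfg$n_blocks, nrow(attr(x, "chunks")),
    length(attr(x, "probe_indices"))
  ))
  print.data.frame(utils::head(as.data.frame(x)))
  invisible(x)
}

#' Write / read a generative sequence as tidy CSV
#'
#' @param seq A `generative_sequence`.
#' @param path File path.
#' @return `read_sequence_csv` returns a data frame with the same columns
#'   (`block, trial, stimulus, p_h_given_l, p_h_given_h, is_jump, is_probe`);
#'   chunk/config attributes are not round-tripped.
#' @export
write_sequence_csv <- function(seq, path) {
  utils::write.csv(as.data.frame(seq), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sequence_csv
#' @export
read_sequence_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("block", "trial", "stimulus", "p_h_given_l", "p_h_given_h")
  if (!all(needed %in% names(df))) {
    stop("sequence CSV is missing required columns: ",
         paste(setdiff(needed, names(df)), collapse = ", "))
  }
  structure(df,
            jump_indices = df$trial[which(df$is_jump)],
            probe_indices = df$trial[which(df$is_probe)],
            class = c("generative_sequence", "data.frame"))
}
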