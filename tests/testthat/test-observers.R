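test_that("random observer emits constant reciprocal predictions", {
  h <- c("L", "H", "H", "L")
  tr <- run_observer(h, "random", list(p_l = 0.5))
  expect_equal(tr$predictive_p_h, rep(0.5, 4))
  tr <- run_observer(h, "random", list(p_l = 0.3))
  expect_equal(tr$predictive_p_h, rep(0.7, 4))
  expect_equal(tr$kl_update[-1], rep(0, 3))
  expect_equal(tr$posterior_sd, rep(sqrt(1 / 12), 4))
})

test_that("Rescorla-Wagner follows the delta rule", {
  tr <- run_observer("L", "rw", list(alpha = 0.1, v0 = 0.5))
  expect_equal(tr$predictive_p_h, 1 - 0.55) # one delta-rule step
  h <- c("L", "H", "H", "L", "H")
  tr1 <- run_observer(h, "rw", list(alpha = 1))
  expect_equal(tr1$predictive_p_h, as.numeric(h == "H"))
  trL <- run_observer(rep("L", 50), "rw", list(alpha = 0.2))
  v <- 1 - trL$predictive_p_h
  expect_true(all(diff(v) > 0))
  expect_lt(max(v), 1)
})

test_that("fixed frequency observer applies the Laplace rule on counts", {
  tr <- run_observer(c("H", "H", "L"), "fixed_frequency",
                     list(w = 10, d = Inf))
  expect_equal(tr$predictive_p_h[3], 3 / 5)
  # Beta(3, 2) moment formula
  expect_equal(tr$posterior_sd[3], sqrt(3 * 2 / (5^2 * 6)))
  expect_equal(tr$posterior_sd[3], 0.2)
  # single-observation window: prediction depends only on the last stimulus
  tr1 <- run_observer(c("L", "L", "H"), "fixed_frequency",
                      list(w = 1, d = Inf))
  expect_equal(tr1$predictive_p_h[3], 2 / 3)
  tr2 <- run_observer(c("H", "H", "H"), "fixed_frequency",
                      list(w = 1, d = Inf))
  expect_equal(tr2$predictive_p_h[3], 2 / 3)
})

test_that("decay downweights older stimuli", {
  # two H then two L; with fast decay the prediction leans low
  tr_slow <- run_observer(c("H", "H", "L", "L"), "fixed_frequency",
                          list(w = 10, d = Inf))
  tr_fast <- run_observer(c("H", "H", "L", "L"), "fixed_frequency",
                          list(w = 10, d = 1))
  expect_equal(tr_slow$predictive_p_h[4], 3 / 6)
  expect_lt(tr_fast$predictive_p_h[4], tr_slow$predictive_p_h[4])
  # hand-computed weighted counts at d = 1: weights exp(0), exp(-1), ...
  wts <- exp(-(0:3))
  nh <- sum(wts[c(3, 4)])
  nl <- sum(wts[c(1, 2)])
  expect_equal(tr_fast$predictive_p_h[4], (nh + 1) / (nh + nl + 2))
})

test_that("fixed transition observer counts stimulus pairs", {
  # no pairs observed yet: flat Beta(1,1) prior
  tr <- run_observer(c("L", "H"), "fixed_transition", list(w = 10, d = Inf))
  expect_equal(tr$predictive_p_h[1], 0.5)
  # pairs H->L, L->H, H->L; last stimulus L
  tr <- run_observer(c("H", "L", "H", "L"), "fixed_transition",
                     list(w = 10, d = Inf))
  expect_equal(tr$predictive_p_h[4], 2 / 3)
  # long alternating sequence: predicted switch probability rises toward 1
  h <- rep(c("L", "H"), 30)
  tr <- run_observer(h, "fixed_transition", list(w = 100, d = Inf))
  p_switch <- ifelse(h == "L", tr$predictive_p_h, 1 - tr$predictive_p_h)
  expect_true(all(diff(p_switch[2:60]) >= 0))
  expect_gt(p_switch[60], 0.9)
})

test_that("jump observers collapse to the flat prior at p_jump = 1", {
  h <- fixture_sequence(100, seed = 2)$stimulus
  trf <- run_observer(h, "jump_frequency", list(p_jump = 1))
  trt <- run_observer(h, "jump_transition", list(p_jump = 1))
  expect_equal(trf$predictive_p_h, rep(0.5, 100))
  expect_equal(trt$predictive_p_h, rep(0.5, 100))
})

test_that("jump observers reduce to fixed observers without jumps", {
  # a stationary fixture: with no change-point evidence, a vanishing jump
  # prior reproduces the full-window no-decay fixed learners
  h <- stationary_sequence(300, 0.4, 0.7, seed = 5)
  trf <- run_observer(h, "fixed_frequency", list(w = 300, d = Inf))
  trj <- run_observer(h, "jump_frequency", list(p_jump = 1e-9))
  expect_lt(max(abs(trf$predictive_p_h - trj$predictive_p_h)), 1e-3)
  trt <- run_observer(h, "fixed_transition", list(w = 300, d = Inf))
  trjt <- run_observer(h, "jump_transition", list(p_jump = 1e-9))
  expect_lt(max(abs(trt$predictive_p_h - trjt$predictive_p_h)), 1e-3)
})

test_that("predictions stay in [0, 1] and posteriors behave", {
  s <- fixture_sequence(150, seed = 13)
  for (m in observer_model_names()) {
    params <- switch(m,
      random = list(p_l = 0.4), rw = list(alpha = 0.3),
      fixed_frequency = , fixed_transition = list(w = 20, d = 10),
      jump_frequency = , jump_transition = list(p_jump = 0.014))
    tr <- run_observer(s, m, params)
    expect_true(all(tr$predictive_p_h >= 0 & tr$predictive_p_h <= 1),
                info = m)
    if (m != "rw") {
      expect_true(all(tr$kl_update >= -1e-12), info = m)
      expect_equal(tr$kl_update[1], 0, info = m)
      expect_true(all(tr$posterior_sd >= 0), info = m)
    }
  }
})

test_that("jump learner tracks an abrupt frequency change faster", {
  # frequency steps from 0.2 to 0.8 at trial 151
  set.seed(88)
  h <- c(ifelse(runif(150) < 0.2, "H", "L"),
         ifelse(runif(150) < 0.8, "H", "L"))
  trj <- run_observer(h, "jump_frequency", list(p_jump = 0.014))
  trf <- run_observer(h, "fixed_frequency", list(w = 300, d = Inf))
  cross <- function(x) {
    i <- which(x[151:300] > 0.5)[1]
    if (is.na(i)) Inf else i
  }
  expect_lt(cross(trj$posterior_mean), cross(trf$posterior_mean))
})

test_that("fixed-frequency grid posterior matches the Beta closed form", {
  h <- stationary_sequence(200, 0.35, 0.6, seed = 21)
  hl <- h == "H"
  a <- cumsum(hl) + 1
  b <- cumsum(!hl) + 1
  # grid filter without jumps against the discretised analytic Beta
  trj <- run_observer(h, "jump_frequency", list(p_jump = 0))
  for (t in c(1, 10, 100, 200)) {
    expect_equal(trj$predictive_p_h[t], a[t] / (a[t] + b[t]),
                 tolerance = 1e-3)
  }
})

test_that("KL divergence is computed correctly and is asymmetric", {
  expect_equal(compute_kl(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(round(compute_kl(c(0.5, 0.5), c(0.25, 0.75)), 4), 0.1438)
  expect_equal(round(compute_kl(c(0.25, 0.75), c(0.5, 0.5)), 4), 0.1308)
  g1 <- posterior_grid(rep(1, 50))
  g2 <- posterior_grid(seq_len(50))
  expect_gt(compute_kl(g2, g1), 0)
  expect_error(compute_kl(posterior_grid(rep(1, 50)),
                          posterior_grid(rep(1, 60))), "mismatch")
})

test_that("posterior grid moments are correct", {
  g <- posterior_grid(rep(1, 1000))
  s <- posterior_stats(g)
  expect_equal(unname(s["mean"]), 0.5)
  expect_equal(unname(s["sd"]), 1 / sqrt(12), tolerance = 1e-3)
  point <- rep(0, 1000)
  point[700] <- 1 # mass at theta = 0.6995
  sp <- posterior_stats(posterior_grid(point))
  expect_equal(unname(sp["mean"]), 699.5 / 1000)
  expect_equal(unname(sp["sd"]), 0)
})

test_that("synthetic ratings reproduce the trace at zero noise", {
  s <- fixture_sequence(200, seed = 31)
  r <- simulate_observer_ratings(s, "jump_frequency", list(p_jump = 0.014),
                                 noise_sd = 0, seed = 1)
  tr <- run_observer(s, "jump_frequency", list(p_jump = 0.014))
  expect_equal(r$rated_p_h, tr$predictive_p_h[r$trial])
  r0 <- simulate_observer_ratings(s, "random", list(p_l = 0.5),
                                  noise_sd = 0)
  expect_true(all(r0$rated_p_h == 0.5))
  # same seed, bit-identical ratings
  r1 <- simulate_observer_ratings(s, "rw", list(alpha = 0.2),
                                  noise_sd = 0.1, seed = 5)
  r2 <- simulate_observer_ratings(s, "rw", list(alpha = 0.2),
                                  noise_sd = 0.1, seed = 5)
  expect_identical(r1$rated_p_h, r2$rated_p_h)
})

test_that("rating noise magnitude matches the folded-normal mean", {
  s <- generate_sequence(generator_config(probe_min = 2L, probe_max = 3L),
                         seed = 41)
  noise_sd <- 0.05
  r <- simulate_observer_ratings(s, "jump_frequency", list(p_jump = 0.014),
                                 noise_sd = noise_sd, seed = 6)
  tr <- run_observer(s, "jump_frequency", list(p_jump = 0.014))
  dev <- abs(r$rated_p_h - tr$predictive_p_h[r$trial])
  expected <- noise_sd * sqrt(2 / pi)
  se <- noise_sd * sqrt(1 - 2 / pi) / sqrt(length(dev))
  expect_lt(abs(mean(dev) - expected), 4 * se)
})
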