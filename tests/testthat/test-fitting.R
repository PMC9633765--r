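test_that("rating regression recovers exact and degenerate fits", {
  p <- seq(0.1, 0.9, length.out = 20)
  s <- rep(1, 20)
  fit <- fit_rating_regression(p, p, s)
  expect_equal(fit$beta1, 1)
  expect_equal(fit$beta0, 0, tolerance = 1e-10)
  expect_lt(fit$sigma2, 1e-20)
  expect_true(fit$dropped) # single session drops the session column
  fit2 <- fit_rating_regression(rep(0.5, 20), p, s)
  expect_equal(fit2$beta1, 0, tolerance = 1e-10)
  expect_equal(fit2$beta0, 0.5)
  expect_error(fit_rating_regression(c(0.1, 0.2), c(0.1, 0.2), c(1, 1)),
               "at least 3")
})

test_that("rating regression recovers known coefficients under noise", {
  set.seed(12)
  n <- 100
  p <- runif(n)
  sess <- rep(1:5, each = 20)
  y <- 0.2 + 0.7 * p + rnorm(n, 0, 0.05)
  fit <- fit_rating_regression(y, p, sess)
  # OLS sampling theory: recovered betas within 3 standard errors
  lmfit <- lm(y ~ p + as.numeric(sess))
  se <- sqrt(diag(vcov(lmfit)))
  expect_lt(abs(fit$beta0 - 0.2), 3 * se[1])
  expect_lt(abs(fit$beta1 - 0.7), 3 * se[2])
  expect_lt(abs(fit$beta2 - 0), 3 * se[3])
})

test_that("BIC formula and its guards", {
  expect_equal(as.numeric(compute_bic(1, 100, 2)), 2 * log(100))
  b2 <- compute_bic(0.3, 80, 2)
  b3 <- compute_bic(0.3, 80, 3)
  expect_equal(as.numeric(b3 - b2), log(80))
  b0 <- compute_bic(0, 50, 1)
  expect_true(is.finite(b0))
  expect_true(attr(b0, "floored"))
  expect_error(compute_bic(1, 2, 2), "exceed")
})

test_that("BIC is invariant to probe ordering", {
  sub <- synthetic_subject("jump_frequency", list(p_jump = 0.02),
                           noise_sd = 0.1, seed = 14, n_blocks = 2)
  perm <- sample(nrow(sub$ratings))
  shuffled <- sub$ratings[perm, ]
  a <- evaluate_model_bic(sub$ratings, sub$seq, "jump_frequency",
                          list(p_jump = 0.02))
  b <- evaluate_model_bic(shuffled, sub$seq, "jump_frequency",
                          list(p_jump = 0.02))
  expect_equal(a$bic, b$bic)
})

test_that("fit_subject recovers simple generative structure", {
  sub <- synthetic_subject("random", list(p_l = 0.5), noise_sd = 0,
                           seed = 15, n_blocks = 2)
  # constant-0.5 ratings carry no gradient for p_l; the restart mean sits
  # at the centre of the search interval
  f <- fit_subject(sub$ratings, sub$seq, "random", n_restarts = 20,
                   seed = 2, mode = "mean")
  expect_equal(f$params$p_l, 0.5, tolerance = 0.15)

  sub_rw <- synthetic_subject("rw", list(alpha = 0.3), noise_sd = 0.05,
                              seed = 16)
  f_rw <- fit_subject(sub_rw$ratings, sub_rw$seq, "rw", n_restarts = 5,
                      seed = 3, mode = "best")
  expect_lt(abs(f_rw$params$alpha - 0.3), 0.1)

  sub_j <- synthetic_subject("jump_frequency", list(p_jump = 0.014),
                             noise_sd = 0.1, seed = 17)
  f_j <- fit_subject(sub_j$ratings, sub_j$seq, "jump_frequency",
                     n_restarts = 4, seed = 4, mode = "best")
  f_r <- fit_subject(sub_j$ratings, sub_j$seq, "random", n_restarts = 4,
                     seed = 4, mode = "best")
  expect_lt(f_j$bic, f_r$bic)
})

test_that("best-restart BIC is no worse than BIC at mean parameters", {
  sub <- synthetic_subject("jump_frequency", list(p_jump = 0.02),
                           noise_sd = 0.1, seed = 18, n_blocks = 2)
  f_best <- fit_subject(sub$ratings, sub$seq, "jump_frequency",
                        n_restarts = 6, seed = 5, mode = "best")
  f_mean <- fit_subject(sub$ratings, sub$seq, "jump_frequency",
                        n_restarts = 6, seed = 5, mode = "mean")
  expect_lte(f_best$bic, f_mean$bic_at_params + 1e-8)
})

test_that("fit results serialise and tabulate into an evidence table", {
  sub <- synthetic_subject("rw", list(alpha = 0.4), noise_sd = 0.1,
                           seed = 20, n_blocks = 1)
  f1 <- fit_subject(sub$ratings, sub$seq, "rw", n_restarts = 2, seed = 6,
                    mode = "best")
  f2 <- fit_subject(sub$ratings, sub$seq, "random", n_restarts = 2,
                    seed = 6, mode = "best")
  jp <- tempfile(fileext = ".json")
  write_fit_json(f1, jp)
  back <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(back$model, "rw")
  expect_equal(back$bic, f1$bic)
  cp <- tempfile(fileext = ".csv")
  tab <- bic_table(list(s1 = list(f1, f2), s2 = list(f1, f2)), cp)
  expect_equal(dim(tab), c(2L, 2L))
  expect_equal(colnames(tab), c("rw", "random"))
  expect_equal(unname(tab[1, 1]), f1$bic)
  on_disk <- utils::read.csv(cp, check.names = FALSE)
  expect_equal(on_disk$rw, rep(f1$bic, 2))
  unlink(c(jp, cp))
})

test_that("parameter recovery harness reports noiseless RW recovery", {
  rep0 <- parameter_recovery("rw", list(alpha = c(0.2, 0.5)), n_sims = 0)
  expect_equal(nrow(rep0), 0)
  cfg <- generator_config(n_blocks = 1)
  rec <- parameter_recovery(
    "rw", list(alpha = c(0.1, 0.3, 0.5, 0.7, 0.9)), n_sims = 5,
    noise_sd = 0, seed = 19, config = cfg, n_restarts = 3, mode = "best"
  )
  summ <- attr(rec, "summary")
  expect_gt(summ$correlation[summ$parameter == "alpha"], 0.95)
})
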