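test_that("fit_standard recovers a known data-generating process", {
  set.seed(100)
  n <- 500
  x <- rnorm(n)
  d <- data.frame(score = 2 + 1 * x + rnorm(n), x = x)
  f <- fit_standard(d, model_spec("score", "x"),
                    config = sampler_config(seed = 1))
  s <- summary(f)
  truth <- c(Intercept = 2, x = 1, sigma = 1)
  for (p in names(truth)) {
    row <- s[s$parameter == p, ]
    expect_lt(abs(row$mean - truth[[p]]), 3 * row$sd)
  }
  expect_true(all(s$rhat < 1.05))
  # flat-prior large-n regime: posterior mean within 0.02 of OLS
  ols <- coef(lm(score ~ x, data = d))
  expect_lt(max(abs(s$mean[1:2] - unname(ols))), 0.02)
})

test_that("rank-deficient designs fail with the collinear column named", {
  d <- data.frame(score = rnorm(30), x = rnorm(30))
  d$x_copy <- d$x
  expect_error(fit_standard(d, model_spec("score", c("x", "x_copy"))),
               "x_copy")
})

test_that("complete-case handling logs dropped rows, missing columns error", {
  d <- data.frame(score = rnorm(40), x = rnorm(40))
  d$x[3] <- NA
  expect_message(fit_standard(d, model_spec("score", "x"),
                              config = sampler_config(n_iterations = 50,
                                                      n_warmup = 10)),
                 "dropped 1 row")
  expect_error(fit_standard(d, model_spec("score", "absent")), "absent")
  expect_error(fit_me(d, model_spec("score", "x", account_for_me = TRUE)),
               "sem")
})

test_that("degenerate measurement error reduces fit_me to fit_standard", {
  d <- sim_scored(300, seed = 42)
  d$sem <- 1e-6
  cfg <- sampler_config(seed = 2)
  f_std <- fit_standard(d, model_spec("score", "x"), config = cfg)
  f_me <- fit_me(d, model_spec("score", "x", account_for_me = TRUE),
                 config = cfg)
  delta <- abs(colMeans(f_std$draws) - colMeans(f_me$draws))
  expect_lt(max(delta), 0.02)
})

test_that("fit_me separates residual SD from measurement error", {
  set.seed(7)
  n <- 500
  x <- rnorm(n)
  sem <- runif(n, 0.3, 0.6)
  true_score <- 1 + 0.8 * x + rnorm(n, 0, 0.5)
  d <- data.frame(score = true_score + rnorm(n, 0, sem), x = x, sem = sem)
  cfg <- sampler_config(seed = 3)
  f_me <- fit_me(d, model_spec("score", "x", account_for_me = TRUE),
                 config = cfg)
  s <- summary(f_me)
  sig <- s[s$parameter == "sigma", ]
  expect_lt(abs(sig$mean - 0.5), 3 * sig$sd)
  # the standard model absorbs the SEM variance into sigma
  f_std <- fit_standard(d, model_spec("score", "x"), config = cfg)
  expect_gt(mean(f_std$draws[, "sigma"]), 0.5)
  expect_error(fit_me(transform(d, sem = -sem),
                      model_spec("score", "x", account_for_me = TRUE)),
               "negative SEM")
})

test_that("zero-SEM rows are treated as known truth in fit_me", {
  d <- sim_scored(200, seed = 13)
  d$sem[1:50] <- 0
  f <- fit_me(d, model_spec("score", "x", account_for_me = TRUE),
              config = sampler_config(seed = 5), keep_latent = TRUE)
  expect_equal(f$latent_mean[1:50], d$score[1:50], tolerance = 1e-12)
  expect_gt(mean(abs(f$latent_mean[51:200] - d$score[51:200])), 0)
})

test_that("marginal GLS oracle: homoscedastic limit and consistency with fit_me", {
  set.seed(31)
  n <- 200
  x <- rnorm(n)
  d <- data.frame(score = 0.5 + 1.2 * x + rnorm(n, 0, 0.8), x = x, sem = 0)
  g <- marginal_gls_fit(d, model_spec("score", "x", account_for_me = TRUE,
                                      sem = "sem"))
  ols <- lm(score ~ x, data = d)
  expect_equal(unname(g$beta), unname(coef(ols)), tolerance = 1e-5)
  expect_equal(g$sigma2, sum(resid(ols)^2) / n, tolerance = 1e-5)
  expect_gte(g$sigma2, 0)
  # cross-method agreement on heteroscedastic data
  d2 <- sim_scored(300, b0 = 0.3, b1 = 0.9, resid_sd = 0.6, seed = 8)
  g2 <- marginal_gls_fit(d2, model_spec("score", "x", account_for_me = TRUE,
                                        sem = "sem"))
  f2 <- fit_me(d2, model_spec("score", "x", account_for_me = TRUE),
               config = sampler_config(seed = 6))
  expect_lt(max(abs(colMeans(f2$draws)[1:2] - g2$beta)), 0.05)
})

test_that("split R-hat matches an independently coded reference", {
  set.seed(55)
  for (dims in list(c(100, 2), c(250, 3), c(61, 4))) {
    m <- matrix(rnorm(prod(dims)), dims[1], dims[2]) +
      matrix(rep(runif(dims[2], -0.2, 0.2), each = dims[1]), dims[1])
    expect_equal(split_rhat(m), oracle_split_rhat(m), tolerance = 1e-10)
  }
  # converged chains sit near 1; separated chains blow past the gate
  long <- matrix(rnorm(20000), ncol = 2)
  expect_gt(split_rhat(long), 0.99)
  expect_lt(split_rhat(long), 1.01)
  bimodal <- cbind(rnorm(500, 0), rnorm(500, 5))
  expect_gt(split_rhat(bimodal), 1.05)
  expect_warning(r <- split_rhat(matrix(1, 20, 2)), "zero within-chain")
  expect_true(is.na(r))
})

test_that("split R-hat extracts chains correctly from fits", {
  d <- sim_scored(100, seed = 17)
  f <- fit_standard(d, model_spec("score", "x"),
                    config = sampler_config(seed = 9))
  m <- matrix(f$draws[, "sigma"][order(f$chain)], ncol = f$n_chains)
  expect_equal(split_rhat(f, "sigma"), oracle_split_rhat(m), tolerance = 1e-10)
})

test_that("posterior SDs contract as n grows", {
  sds <- vapply(c(100, 400, 1600), function(n) {
    d <- sim_scored(n, seed = n)
    f <- fit_standard(d, model_spec("score", "x"),
                      config = sampler_config(seed = n + 1))
    sd(f$draws[, "x"])
  }, numeric(1))
  expect_true(all(diff(sds) < 0))
})

test_that("doubling the intercept prior scale leaves R-squared unchanged", {
  d <- sim_scored(1084, seed = 23)
  cfg <- sampler_config(seed = 12)
  ms <- model_spec("score", "x")
  r2_a <- bayes_r2(fit_standard(d, ms, prior_spec(), cfg))$summary["mean"]
  r2_b <- bayes_r2(fit_standard(d, ms, prior_spec(intercept_scale = 5),
                                cfg))$summary["mean"]
  expect_lt(abs(r2_a - r2_b), 0.005)
})
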