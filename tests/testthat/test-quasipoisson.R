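test_that("intercept-only fit recovers log of the mean in closed form", {
  y <- c(1, 2, 3)
  fit <- fit_quasipoisson(y, cbind(intercept = rep(1, 3)))
  expect_equal(unname(coef(fit)), log(2), tolerance = 1e-10)
  # Pearson dispersion by hand: sum((y-2)^2/2) / (3-1) = 0.5
  expect_equal(fit$dispersion, 0.5, tolerance = 1e-10)
  expect_equal(fit$residual_df, 2)
})

test_that("two-group design recovers the log rate ratio", {
  y <- c(2, 4, 6, 3, 9, 12)
  g <- c(0, 0, 0, 1, 1, 1)
  fit <- fit_quasipoisson(y, cbind(1, group = g))
  m0 <- mean(y[g == 0]); m1 <- mean(y[g == 1])
  expect_equal(unname(coef(fit)), c(log(m0), log(m1 / m0)),
               tolerance = 1e-9)
  # brute-force likelihood grid around the closed form
  grid <- seq(log(m1 / m0) - 0.5, log(m1 / m0) + 0.5, length.out = 2001)
  loglik <- vapply(grid, function(b1) {
    mu <- exp(log(m0) + b1 * g)
    sum(stats::dpois(y, mu, log = TRUE))
  }, numeric(1))
  expect_equal(grid[which.max(loglik)], unname(coef(fit)[2]),
               tolerance = 1e-3)
})

test_that("fits agree with the reference GLM implementation", {
  set.seed(303)
  for (i in 1:10) {
    n <- sample(20:60, 1)
    x1 <- runif(n); x2 <- rnorm(n)
    y <- rpois(n, exp(0.3 + 0.6 * x1 - 0.4 * x2))
    fit <- fit_quasipoisson(y, cbind(1, x1, x2))
    ref <- glm(y ~ x1 + x2, family = quasipoisson,
               control = glm.control(epsilon = 1e-12))
    sref <- summary(ref)
    # Pearson dispersion evaluated at the reference fitted means
    # (summary.glm quotes it from stale last-iteration working
    # residuals, which is only ~1e-7 accurate)
    phi_ref <- sum((y - fitted(ref))^2 / fitted(ref)) / ref$df.residual
    expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-8)
    expect_equal(fit$dispersion, phi_ref, tolerance = 1e-8)
    Xr <- model.matrix(ref)
    cov_ref <- solve(crossprod(Xr * sqrt(fitted(ref))))
    expect_equal(unname(fit$standard_errors),
                 unname(sqrt(phi_ref * diag(cov_ref))),
                 tolerance = 1e-8)
    expect_equal(unname(fit$p_values),
                 unname(sref$coefficients[, 4]), tolerance = 1e-5)
    expect_equal(fit$residual_df, ref$df.residual)
  }
})

test_that("score equations hold at convergence", {
  set.seed(304)
  n <- 80
  x <- runif(n)
  y <- rpois(n, exp(1 + 0.5 * x))
  X <- cbind(1, x)
  fit <- fit_quasipoisson(y, X)
  expect_lt(max(abs(crossprod(X, y - fit$fitted_means))), 1e-6)
  expect_true(fit$converged)
})

test_that("dispersion scales uncertainty but not the point estimates", {
  set.seed(305)
  x <- runif(50)
  y <- rnbinom(50, mu = exp(1 + x), size = 2)   # overdispersed counts
  fit <- fit_quasipoisson(y, cbind(1, x))
  pois <- glm(y ~ x, family = poisson,
              control = glm.control(epsilon = 1e-12))
  expect_equal(unname(coef(fit)), unname(coef(pois)), tolerance = 1e-8)
  expect_gt(fit$dispersion, 1)
  expect_equal(unname(fit$standard_errors),
               unname(sqrt(diag(vcov(pois))) * sqrt(fit$dispersion)),
               tolerance = 1e-7)
})

test_that("offsets model rates per unit exposure", {
  set.seed(306)
  expo <- runif(40, 1, 10)
  x <- runif(40)
  y <- rpois(40, expo * exp(0.2 + 0.7 * x))
  fit <- fit_quasipoisson(y, cbind(1, x), offset = log(expo))
  ref <- glm(y ~ x + offset(log(expo)), family = quasipoisson,
             control = glm.control(epsilon = 1e-12))
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-8)
})

test_that("rank-deficient designs error naming the collinear column", {
  y <- rpois(20, 3)
  x <- runif(20)
  expect_error(fit_quasipoisson(y, cbind(a = 1, b = x, c = 2 * x)), "c")
  expect_error(fit_quasipoisson(c(-1, 2), cbind(1, 1:2)), "non-negative")
})

test_that("the inbreeding model yields the study's residual df at n = 151", {
  # a subsample structured like the study's genotyped subset
  cfg <- default_study_config(n = 151, sex_probs = c(
    male = 78 / 151, female = 50 / 151, unknown = 23 / 151))
  rec <- simulate_cohort(cfg, seed = 9)
  fit <- fit_age_inbreeding(rec)
  expect_equal(fit$residual_df, 149)
  expect_equal(attr(fit, "n_used"), 151)
  fit2 <- fit_age_inbreeding(rec, interaction_with_cause = TRUE)
  expect_equal(length(coef(fit2)), 4)
})

test_that("records with missing heterozygosity are dropped with a count", {
  rec <- simulate_cohort(default_study_config(n = 50), seed = 2)
  rec$heterozygosity[1:10] <- NA
  expect_message(fit <- fit_age_inbreeding(rec), "10 record")
  expect_equal(attr(fit, "n_used"), 40)
  rec$heterozygosity <- NA_real_
  expect_error(suppressMessages(fit_age_inbreeding(rec)), "usable")
})

test_that("the heterozygosity Wald test holds its nominal size", {
  # null simulation at the genotyped-subset sample size
  set.seed(505)
  reps <- 400L
  cfg <- default_study_config(n = 151, ihet_age_slope = 0)
  rej <- 0L
  for (i in seq_len(reps)) {
    rec <- simulate_cohort(cfg, seed = 700000L + i)
    fit <- fit_age_inbreeding(rec)
    rej <- rej + (fit$p_values["heterozygosity"] < 0.05)
  }
  rate <- rej / reps
  expect_gt(rate, 0.05 - 3 * sqrt(0.05 * 0.95 / reps))
  expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("a configured heterozygosity effect is recovered", {
  cfg <- default_study_config(n = 20000, ihet_age_slope = -2)
  rec <- simulate_cohort(cfg, seed = 77)
  # males carry a constant base hazard, under which the generator's
  # odds-scale thinning makes E[age | ihet] exactly log-linear in ihet
  fit <- fit_age_inbreeding(rec[rec$sex == "male", ])
  est <- unname(coef(fit)["heterozygosity"])
  se <- unname(fit$standard_errors["heterozygosity"])
  expect_lt(abs(est - (-2)), 4 * se)
})
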