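test_that("a dominating coefficient prior pins the posterior draws", {
  toy <- toy_regression()
  pr <- nig_prior(sigma_df = 3, sigma_scale = 2, coef_mean = c(2, -1),
                  coef_scale = diag(1e-12, 2))
  set.seed(1)
  draws <- t(replicate(200, {
    th <- draw_nig_posterior(toy$y, toy$X, pr)
    c(th$alpha, th$beta)
  }))
  expect_lt(max(abs(sweep(draws, 2, c(2, -1)))), 1e-4)
  expect_lt(max(apply(draws, 2, sd)), 1e-5)
})

test_that("diffuse-prior posterior means match ordinary least squares", {
  set.seed(2024)
  n <- 200
  x <- rnorm(n)
  y <- 1 + 0.5 * x + rnorm(n, sd = sqrt(2))
  X <- cbind(1, x)
  pr <- nig_prior(sigma_df = 0.02, sigma_scale = 0.02, coef_mean = c(0, 0),
                  coef_scale = diag(1e8, 2))
  ndraw <- 4000
  draws <- t(replicate(ndraw, {
    th <- draw_nig_posterior(y, X, pr)
    c(th$alpha, th$beta, th$sigma)
  }))
  ols <- lm(y ~ x)
  mcse <- apply(draws[, 1:2], 2, sd) / sqrt(ndraw)
  expect_lt(abs(mean(draws[, 1]) - coef(ols)[1]), 3 * mcse[1] + 1e-3)
  expect_lt(abs(mean(draws[, 2]) - coef(ols)[2]), 3 * mcse[2] + 1e-3)
})

test_that("posterior draws match a dense grid evaluation of the posterior", {
  # independent oracle: tabulate the unnormalized NIG posterior of
  # (alpha, beta, sigma) on a 3-d grid and integrate moments numerically
  toy <- toy_regression()
  pr <- nig_prior(sigma_df = 3, sigma_scale = 2, coef_mean = c(0, 0),
                  coef_scale = diag(4, 2))
  log_post <- function(a, b, s) {
    mu <- a + b * toy$X[, 2]
    fcsprior:::ldinvgamma(s, pr$shape, pr$rate) +
      fcsprior:::ldmvnorm(c(a, b), pr$coef_mean, s * pr$coef_scale) +
      sum(dnorm(toy$y, mu, sqrt(s), log = TRUE))
  }
  av <- seq(-0.5, 2.5, length.out = 60)
  bv <- seq(-1.0, 2.0, length.out = 60)
  sv <- exp(seq(log(0.4), log(9), length.out = 60))
  g <- expand.grid(a = av, b = bv, s = sv)
  lp <- mapply(log_post, g$a, g$b, g$s)
  w <- exp(lp - max(lp)) * g$s            # log-spaced sigma: ds = s dlog(s)
  w <- w / sum(w)
  grid_mean <- c(sum(w * g$a), sum(w * g$b), sum(w * g$s))
  grid_var <- c(sum(w * g$a^2), sum(w * g$b^2), sum(w * g$s^2)) - grid_mean^2

  set.seed(8)
  draws <- t(replicate(10000, {
    th <- draw_nig_posterior(toy$y, toy$X, pr)
    c(th$alpha, th$beta, th$sigma)
  }))
  expect_equal(colMeans(draws), grid_mean, tolerance = 0.02)
  expect_equal(apply(draws, 2, var), grid_var, tolerance = 0.05)
})

test_that("sigma draws follow the analytic inverse-gamma posterior", {
  toy <- toy_regression()
  pr <- nig_prior(sigma_df = 3, sigma_scale = 2, coef_mean = c(0, 0),
                  coef_scale = diag(4, 2))
  # analytic posterior of sigma after integrating the coefficients
  V0_inv <- solve(pr$coef_scale)
  K <- V0_inv + crossprod(toy$X)
  mN <- solve(K, drop(crossprod(toy$X, toy$y)))
  aN <- pr$shape + length(toy$y) / 2
  bN <- pr$rate + 0.5 * (sum(toy$y^2) - drop(crossprod(mN, K %*% mN)))
  set.seed(9)
  sig <- replicate(10000, draw_nig_posterior(toy$y, toy$X, pr)$sigma)
  ks <- suppressWarnings(ks.test(sig, function(q)
    pgamma(1 / q, shape = aN, rate = bN, lower.tail = FALSE)))
  expect_gt(ks$p.value, 0.01)
})

test_that("predictive draws have the stated normal law", {
  th0 <- theta_conditional(4, 0, 1e-12)
  X <- cbind(1, rnorm(5))
  expect_equal(draw_predictive_normal(X, th0), rep(4, 5), tolerance = 1e-5)

  set.seed(10)
  th <- theta_conditional(4, 0, 1)
  v <- draw_predictive_normal(matrix(1, 1e5, 2), th)
  expect_equal(mean(v), 4, tolerance = 0.011)
  expect_equal(var(v), 1, tolerance = 0.025)
})

test_that("NIW posterior draws concentrate correctly", {
  # tau -> Inf pins mu at mu0
  set.seed(11)
  Y <- generate_mvn(50, c(0, 0), diag(2))
  pr_inf <- niw_prior(c(5, -5), tau = 1e10, m = 3, Lambda = diag(2))
  mus <- t(replicate(50, draw_niw_posterior(Y, pr_inf)$mu))
  expect_lt(max(abs(sweep(mus, 2, c(5, -5)))), 1e-3)

  # large-n consistency
  set.seed(12)
  Yb <- generate_mvn(10000, study$mu, study$Sigma)
  draws <- replicate(400, draw_niw_posterior(Yb, study$prior)$mu)
  pm <- rowMeans(draws)
  mcse <- apply(draws, 1, sd) / sqrt(400)
  se_data <- sqrt(diag(study$Sigma) / 10000)
  for (j in 1:3)
    expect_lt(abs(pm[j] - study$mu[j]), 3 * (mcse[j] + se_data[j]))
})

test_that("p = 1 NIW update reduces to the scalar normal-inverse-gamma update", {
  set.seed(13)
  y <- rnorm(30, 2, 1.5)
  pr <- niw_prior(mu0 = 0, tau = 2, m = 3, Lambda = matrix(4))
  n <- length(y)
  # scalar conjugate algebra done by hand
  tau_n <- pr$tau + n
  mu_n <- (pr$tau * 0 + n * mean(y)) / tau_n
  nu_n <- pr$iw_df + n
  psi_n <- pr$iw_scale[1] + sum((y - mean(y))^2) +
    pr$tau * n / tau_n * mean(y)^2
  draws <- t(replicate(8000, {
    th <- draw_niw_posterior(matrix(y), pr)
    c(th$mu, th$Sigma)
  }))
  expect_equal(mean(draws[, 2]), psi_n / (nu_n - 2), tolerance = 0.02)
  expect_equal(mean(draws[, 1]), mu_n, tolerance = 0.02)
  expect_equal(var(draws[, 1]), (psi_n / (nu_n - 2)) / tau_n, tolerance = 0.05)
})

test_that("conditional imputation draws agree with the decomposition", {
  th <- theta_joint(study$mu, study$Sigma)
  row_full <- c(1.5, 3.2, 8.1)
  expect_identical(draw_mis_given_theta(row_full, th), row_full)

  set.seed(14)
  full <- t(replicate(1e5, draw_mis_given_theta(rep(NA_real_, 3), th)))
  expect_equal(colMeans(full), unname(study$mu), tolerance = 0.03)
  expect_equal(unname(cov(full)), unname(study$Sigma), tolerance = 0.12)

  # one missing coordinate: mean/variance equal the regression decomposition
  dec <- theta_joint_to_conditional(th, 2)
  row <- c(2, NA, 7)
  set.seed(15)
  v <- replicate(2e4, draw_mis_given_theta(row, th)[2])
  expect_equal(mean(v), dec$cond$alpha + sum(dec$cond$beta * c(2, 7)),
               tolerance = 0.05)
  expect_equal(var(v), dec$cond$sigma, tolerance = 0.08)
})

test_that("draws are bit-reproducible under a fixed seed", {
  toy <- toy_regression()
  pr <- nig_prior(3, 2, c(0, 0), diag(4, 2))
  set.seed(123); d1 <- draw_nig_posterior(toy$y, toy$X, pr)
  set.seed(123); d2 <- draw_nig_posterior(toy$y, toy$X, pr)
  expect_identical(d1, d2)

  set.seed(123); y1 <- draw_predictive_normal(toy$X, d1)
  set.seed(123); y2 <- draw_predictive_normal(toy$X, d1)
  expect_identical(y1, y2)

  Y <- matrix(rnorm(60), 20, 3)
  set.seed(5); t1 <- draw_niw_posterior(Y, study$prior)
  set.seed(5); t2 <- draw_niw_posterior(Y, study$prior)
  expect_identical(t1, t2)

  set.seed(6); r1 <- draw_mis_given_theta(c(NA, 2, NA), t1)
  set.seed(6); r2 <- draw_mis_given_theta(c(NA, 2, NA), t1)
  expect_identical(r1, r2)

  expect_identical(derive_seed(42, 7), derive_seed(42, 7))
  expect_false(derive_seed(42, 7) == derive_seed(42, 8))
})

test_that("alternating P- and I-steps leave the theta marginal stationary", {
  # Geweke-style smoke test on complete data: no drift between halves
  set.seed(16)
  Y <- generate_mvn(100, study$mu, study$Sigma)
  Ymis <- Y; Ymis[sample(100, 30), 2] <- NA
  mus <- numeric(400)
  X <- initialize_fill(Ymis)
  for (it in 1:400) {
    th <- draw_niw_posterior(X, study$prior)
    for (i in which(is.na(Ymis[, 2])))
      X[i, ] <- draw_mis_given_theta(Ymis[i, ], th)
    mus[it] <- th$mu[2]
  }
  a <- mus[51:225]; b <- mus[226:400]
  z <- (mean(a) - mean(b)) /
    sqrt(batch_means_se(a, 5)^2 + batch_means_se(b, 5)^2)
  expect_lt(abs(z), 3)
})
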