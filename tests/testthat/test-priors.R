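test_that("hyperparameter partition is lossless and places variable j first", {
  pr <- niw_prior(c(0, 0, 0), tau = 1, m = 3, Lambda = diag(60, 3))
  part <- partition_hyperparams(pr, 1)
  expect_equal(part$Lambda_j, 60)
  expect_equal(part$psi_j, c(0, 0))
  expect_equal(part$Lambda_minus_j, diag(60, 2))

  set.seed(101)
  pr4 <- random_niw(4)
  for (j in 1:4) {
    part <- partition_hyperparams(pr4, j)
    # reassemble and compare bit-exactly
    Lambda <- matrix(NA_real_, 4, 4)
    Lambda[j, j] <- part$Lambda_j
    Lambda[-j, j] <- part$psi_j
    Lambda[j, -j] <- part$psi_j
    Lambda[-j, -j] <- part$Lambda_minus_j
    mu0 <- numeric(4)
    mu0[j] <- part$mu0_j
    mu0[-j] <- part$mu0_minus_j
    expect_identical(Lambda, pr4$Lambda)
    expect_identical(mu0, pr4$mu0)
  }
  expect_error(partition_hyperparams(pr, 4), "out of range")
})

test_that("schur_lambda matches direct block inversion and diagonal shortcut", {
  pr <- niw_prior(c(0, 0, 0), tau = 1, m = 3, Lambda = diag(60, 3))
  expect_equal(schur_lambda(partition_hyperparams(pr, 1)), 60)

  pr2 <- niw_prior(c(0, 0), tau = 1, m = 2,
                   Lambda = matrix(c(4, 2, 2, 4), 2))
  expect_equal(schur_lambda(partition_hyperparams(pr2, 1)), 3)

  # 1/(Lambda^-1)[j,j] brute-force oracle on random SPD matrices
  set.seed(77)
  for (rep in 1:5) {
    pr4 <- random_niw(4)
    for (j in 1:4) {
      lam <- schur_lambda(partition_hyperparams(pr4, j))
      oracle <- 1 / solve(pr4$Lambda)[j, j]
      expect_equal(lam, oracle, tolerance = 1e-10)
    }
  }
})

test_that("study prior transforms to the stated conditional NIG prior", {
  pr <- study$prior
  for (j in 1:3) {
    nig <- niw_to_nig(pr, j)
    expect_equal(nig$sigma_df, 3)         # sigma ~ W^-1(3, 60)
    expect_equal(nig$sigma_scale, 60)
    expect_equal(nig$coef_mean, c(0, 0, 0))
    # slope block of the sigma-conditional covariance is Lambda_{-j}^{-1}
    expect_equal(nig$coef_scale[2:3, 2:3], diag(1 / 60, 2))
    expect_equal(nig$coef_scale[1, 1], 1)  # tau = 1, mu0 = 0
  }
})

test_that("zero cross-block and centered location give zero prior coefficient means", {
  pr <- niw_prior(c(0, 0, 0, 0), tau = 2, m = 5,
                  Lambda = diag(c(1, 2, 3, 4)))
  for (j in 1:4) expect_equal(niw_to_nig(pr, j)$coef_mean, rep(0, 4))
  expect_error(niw_to_nig(niw_prior(0, 1, 1, matrix(2)), 1), "p < 2")
})

test_that("joint NIW prior factorizes into the NIG and marginal blocks", {
  # non-informative margins: the log joint prior (plus the |Sigma_-j| Jacobian
  # of the reparameterization) minus both block log-priors is constant in theta
  set.seed(515)
  for (conv in c("scale_literal", "density_literal")) {
    for (rep in 1:5) {
      pr <- random_niw(3, convention = conv)
      j <- sample(3, 1)
      nig <- niw_to_nig(pr, j)
      vals <- replicate(50, {
        th <- theta_joint(rnorm(3, sd = 2), random_spd(3))
        dec <- theta_joint_to_conditional(th, j)
        log_joint_prior(th, pr) +
          determinant(dec$Sigma_minus, logarithm = TRUE)$modulus -
          log_nig_prior(dec$cond, nig) -
          log_margin_prior(dec$mu_minus, dec$Sigma_minus, pr, j)
      })
      expect_lt(var(vals), 1e-10)
    }
  }
})

test_that("log joint prior evaluates its stated kernel", {
  pr <- niw_prior(c(1, 2), tau = 3, m = 2.5, Lambda = random_spd(2))
  S <- random_spd(2)
  # mu = mu0 zeroes the mean term
  expect_equal(log_joint_prior(theta_joint(pr$mu0, S), pr),
               -((pr$iw_df + 4) / 2) * determinant(S, TRUE)$modulus[1] -
                 0.5 * sum(pr$iw_scale * solve(S)))

  # p = 1: matches a 1-d inverse-gamma x normal hand evaluation
  pr1 <- niw_prior(0.5, tau = 2, m = 1.5, Lambda = matrix(3))
  sig <- 1.7; mu <- -0.3
  hand <- -((pr1$iw_df + 3) / 2) * log(sig) - pr1$iw_scale[1] / (2 * sig) -
    pr1$tau * (mu - 0.5)^2 / (2 * sig)
  expect_equal(log_joint_prior(theta_joint(mu, matrix(sig)), pr1), hand)

  # scaling Sigma -> c Sigma shifts the log-determinant term by
  # -((nu+p+2)/2) p log c plus the change in the exponential terms
  cc <- 1.9
  mu <- c(0.4, -1)
  base <- log_joint_prior(theta_joint(mu, S), pr)
  scaled <- log_joint_prior(theta_joint(mu, cc * S), pr)
  d <- mu - pr$mu0
  expected <- base - ((pr$iw_df + 2 + 2) / 2) * 2 * log(cc) +
    (1 - 1 / cc) * (0.5 * sum(pr$iw_scale * solve(S)) +
                    (pr$tau / 2) * drop(crossprod(d, solve(S, d))))
  expect_equal(scaled, expected)
})

test_that("conditional decomposition reproduces the printed study regression", {
  th <- theta_joint(study$mu, study$Sigma)
  dec <- theta_joint_to_conditional(th, 2)  # y given (x, z)
  expect_equal(dec$cond$beta, c(0.4375, 0.125))
  expect_equal(dec$cond$alpha, 2.4375)
  expect_equal(dec$cond$sigma, 2.875)

  # diagonal Sigma: independence
  thd <- theta_joint(c(1, 2, 3), diag(c(2, 3, 4)))
  dd <- theta_joint_to_conditional(thd, 3)
  expect_equal(dd$cond$beta, c(0, 0))
  expect_equal(dd$cond$alpha, 3)
  expect_equal(dd$cond$sigma, 4)
})

test_that("marginal x conditional reconstructs the joint normal density", {
  set.seed(99)
  for (rep in 1:4) {
    th <- theta_joint(rnorm(3), random_spd(3))
    j <- sample(3, 1)
    dec <- theta_joint_to_conditional(th, j)
    for (k in 1:20) {
      yv <- rnorm(3, sd = 3)
      joint <- fcsprior:::ldmvnorm(yv, th$mu, th$Sigma)
      cond_mean <- dec$cond$alpha + sum(dec$cond$beta * yv[-j])
      split <- fcsprior:::ldmvnorm(yv[-j], dec$mu_minus, dec$Sigma_minus) +
        dnorm(yv[j], cond_mean, sqrt(dec$cond$sigma), log = TRUE)
      expect_equal(joint, split, tolerance = 1e-10)
    }
  }
})

test_that("decomposition round-trips through reassembly", {
  set.seed(31)
  for (rep in 1:5) {
    th <- theta_joint(rnorm(4), random_spd(4))
    j <- sample(4, 1)
    dec <- theta_joint_to_conditional(th, j)
    back <- theta_conditional_to_joint(dec$cond, dec$mu_minus,
                                       dec$Sigma_minus, j)
    expect_equal(back$mu, th$mu, tolerance = 1e-12)
    expect_equal(back$Sigma, th$Sigma, tolerance = 1e-12)
  }
})

test_that("marginal coefficient priors are t with df 2m - p + 1", {
  tt <- marginal_coef_t(study$prior, 2)
  expect_equal(tt$beta$df, 4)   # m = 3, p = 3
  expect_equal(tt$alpha$df, 4)
  expect_equal(tt$beta$location, c(0, 0))

  set.seed(5)
  pr <- random_niw(4)
  expect_equal(marginal_coef_t(pr, 1)$beta$df, 2 * pr$m - 4 + 1)

  # large m: the t density converges to the stated normal approximation
  pr200 <- niw_prior(c(0, 0, 0), tau = 1, m = 200, Lambda = diag(60, 3))
  tt <- marginal_coef_t(pr200, 2)
  s <- sqrt(tt$beta$scale[1, 1])
  sn <- sqrt(tt$normal_approx$beta_cov[1, 1])
  grid <- seq(-5 * sn, 5 * sn, length.out = 401)
  dt_dens <- dt(grid / s, df = tt$beta$df) / s
  dn_dens <- dnorm(grid, 0, sn)
  expect_lt(max(abs(dt_dens - dn_dens)) * sn, 1e-3)
})
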