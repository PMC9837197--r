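#' Normal-inverse-Wishart prior for a multivariate normal model
#'
#' Constructs the joint prior for \eqn{\theta = (\mu, \Sigma)} of a p-variate
#' normal model: \eqn{\mu | \Sigma \sim N(\mu_0, \tau^{-1}\Sigma)} and
#' \eqn{\Sigma \sim W^{-1}(m, \Lambda)}.
#'
#' The inverse-Wishart notation \eqn{W^{-1}(m, \Lambda)} is ambiguous between
#' parameterizations, so the prior carries an explicit `convention` flag that
#' fixes the textbook inverse-Wishart pair \eqn{(\nu, \Psi)} (density
#' \eqn{\propto |\Sigma|^{-(\nu+p+1)/2} \exp\{-\frac12 tr(\Psi\Sigma^{-1})\}})
#' actually used by every computation:
#' \describe{
#'   \item{`"scale_literal"` (default)}{\eqn{\nu = m}, \eqn{\Psi = \Lambda}:
#'     \eqn{\Lambda} is the inverse-Wishart scale matrix. Under this reading the
#'     implied conditional residual-variance prior is \eqn{W^{-1}(m, \lambda_j)}
#'     with \eqn{\lambda_j} the Schur complement of \eqn{\Lambda}, and the slope
#'     prior mean is \eqn{\Lambda_{-j}^{-1}\psi_j}.}
#'   \item{`"density_literal"`}{\eqn{\nu = m + 1}, \eqn{\Psi = \Lambda^{-1}}:
#'     the reading in which the joint prior density carries the exponent
#'     \eqn{-(m+p+2)/2} and the kernel \eqn{tr(\Lambda^{-1}\Sigma^{-1})}.}
#' }
#' Both conventions satisfy the non-informative-margins factorization (see
#' [niw_to_nig()]); the default is the one that also reproduces the standard
#' weakly-informative prior mapping \eqn{\Lambda = 60 I \rightarrow
#' \sigma \sim W^{-1}(3, 60)}.
#'
#' @param mu0 numeric p-vector, prior location of \eqn{\mu}.
#' @param tau positive scalar, prior precision multiplier on \eqn{\mu}.
#' @param m scalar degrees-of-freedom hyperparameter, \eqn{m \ge p}.
#' @param Lambda p x p symmetric positive-definite scale hyperparameter.
#' @param convention `"scale_literal"` or `"density_literal"`.
#' @return An object of class `niw_prior` with fields `mu0`, `tau`, `m`,
#'   `Lambda`, `convention` plus the derived textbook pair `iw_df` and
#'   `iw_scale`.
#' @seealso [niw_to_nig()], [log_joint_prior()], [draw_niw_posterior()]
#' @export
#' @examples
#' pr <- niw_prior(mu0 = c(0, 0, 0), tau = 1, m = 3, Lambda = diag(60, 3))
#' pr
niw_prior <- function(mu0, tau, m, Lambda,
                      convention = c("scale_literal", "density_literal")) {
  convention <- match.arg(convention)
  mu0 <- as.numeric(mu0)
  p <- length(mu0)
  Lambda <- as.matrix(Lambda)
  if (!all(dim(Lambda) == c(p, p)))
    stop("'Lambda' must be ", p, " x ", p, " to match 'mu0'")
  check_spd(Lambda, "Lambda")
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0)
    stop("'tau' must be a positive scalar")
  if (!is.numeric(m) || length(m) != 1L || m < p)
    stop("'m' must be a scalar with m >= p")
  iw <- switch(convention,
    scale_literal   = list(df = m, scale = Lambda),
    density_literal = list(df = m + 1, scale = chol2inv(chol(Lambda)))
  )
  structure(
    list(mu0 = mu0, tau = tau, m = m, Lambda = Lambda,
         convention = convention, p = p,
         iw_df = iw$df, iw_scale = iw$scale),
    class = "niw_prior"
  )
}

#' @export
print.niw_prior <- function(x, ...) {
  cat("Normal-inverse-Wishart prior (p = ", x$p, ", convention = ",
      x$convention, ")\n", sep = "")
  cat("  mu | Sigma ~ N(mu0, Sigma / tau),  tau =", format(x$tau), "\n")
  cat("  Sigma ~ W^-1(m, Lambda),  m =", format(x$m), "\n")
  cat("  mu0:", paste(format(x$mu0), collapse = " "), "\n")
  cat("  Lambda:\n")
  print(x$Lambda)
  invisible(x)
}

#' Conditional normal-inverse-gamma prior for one normal linear model
#'
#' The prior of the regression \eqn{Y_j = \alpha_j + \beta_j^T Y_{-j} +
#' \epsilon}, \eqn{\epsilon \sim N(0, \sigma_j)}: the residual variance has a
#' one-dimensional inverse-Wishart (inverse-gamma) law and the coefficients
#' \eqn{(\alpha_j, \beta_j)} given \eqn{\sigma_j} are jointly normal with
#' covariance \eqn{\sigma_j V_0}.
#'
#' `sigma_df` and `sigma_scale` are the textbook 1-d inverse-Wishart pair, so
#' \eqn{\sigma_j \sim IG(\mathrm{sigma\_df}/2, \mathrm{sigma\_scale}/2)}
#' (shape/rate).
#'
#' @param sigma_df positive scalar, 1-d inverse-Wishart degrees of freedom.
#' @param sigma_scale positive scalar scale \eqn{\lambda_j}.
#' @param coef_mean numeric q-vector, prior mean of (intercept, slopes).
#' @param coef_scale q x q SPD matrix \eqn{V_0}; the prior covariance of the
#'   coefficients given \eqn{\sigma_j} is \eqn{\sigma_j V_0}.
#' @return An object of class `nig_prior`; fields include the derived
#'   inverse-gamma `shape` and `rate` for \eqn{\sigma_j}.
#' @seealso [niw_to_nig()], [draw_nig_posterior()]
#' @export
nig_prior <- function(sigma_df, sigma_scale, coef_mean, coef_scale) {
  coef_mean <- as.numeric(coef_mean)
  q <- length(coef_mean)
  coef_scale <- as.matrix(coef_scale)
  if (!all(dim(coef_scale) == c(q, q)))
    stop("'coef_scale' must be ", q, " x ", q)
  if (sigma_df <= 0 || sigma_scale <= 0)
    stop("'sigma_df' and 'sigma_scale' must be positive")
  check_spd(coef_scale, "coef_scale")
  structure(
    list(sigma_df = sigma_df, sigma_scale = sigma_scale,
         coef_mean = coef_mean, coef_scale = coef_scale,
         shape = sigma_df / 2, rate = sigma_scale / 2),
    class = "nig_prior"
  )
}

#' @export
print.nig_prior <- function(x, ...) {
  cat("Normal-inverse-gamma prior (", length(x$coef_mean), " coefficients)\n",
      sep = "")
  cat("  sigma ~ W^-1(", format(x$sigma_df), ", ", format(x$sigma_scale),
      ")  [IG(shape ", format(x$shape), ", rate ", format(x$rate), ")]\n",
      sep = "")
  cat("  (alpha, beta) | sigma ~ N(coef_mean, sigma * coef_scale)\n")
  cat("  coef_mean:", paste(format(x$coef_mean), collapse = " "), "\n")
  cat("  coef_scale:\n")
  print(x$coef_scale)
  invisible(x)
}

#' Joint parameter of the multivariate normal model
#'
#' @param mu numeric p-vector mean.
#' @param Sigma p x p SPD covariance matrix.
#' @return An object of class `theta_joint`.
#' @export
theta_joint <- function(mu, Sigma) {
  mu <- as.numeric(mu)
  Sigma <- as.matrix(Sigma)
  if (!all(dim(Sigma) == rep(length(mu), 2)))
    stop("'Sigma' must be square and match 'mu'")
  check_spd(Sigma, "Sigma")
  structure(list(mu = mu, Sigma = Sigma), class = "theta_joint")
}

#' Parameter of one conditional normal linear model
#'
#' @param alpha scalar intercept.
#' @param beta numeric vector of slopes.
#' @param sigma positive scalar residual variance.
#' @return An object of class `theta_conditional`.
#' @export
theta_conditional <- function(alpha, beta, sigma) {
  if (sigma <= 0) stop("'sigma' must be positive")
  structure(list(alpha = as.numeric(alpha), beta = as.numeric(beta),
                 sigma = as.numeric(sigma)),
            class = "theta_conditional")
}

#' Partition NIW hyperparameters around one variable
#'
#' Extracts the blocks of \eqn{\mu_0} and \eqn{\Lambda} with variable `j`
#' placed first: \eqn{\mu_{0j}}, \eqn{\mu_{0,-j}}, \eqn{\Lambda_j},
#' \eqn{\psi_j} (cross block) and \eqn{\Lambda_{-j}}. The partition is lossless:
#' reassembling the blocks reproduces the inputs exactly.
#'
#' @param prior a [niw_prior()].
#' @param j variable index in `1..p`.
#' @return A list of class `partitioned_hyperparams` with fields `j`, `mu0_j`,
#'   `mu0_minus_j`, `Lambda_j`, `psi_j`, `Lambda_minus_j`.
#' @export
partition_hyperparams <- function(prior, j) {
  stopifnot(inherits(prior, "niw_prior"))
  p <- prior$p
  if (!(j %in% seq_len(p))) stop("'j' out of range 1..", p)
  structure(
    list(j = j,
         mu0_j = prior$mu0[j],
         mu0_minus_j = prior$mu0[-j],
         Lambda_j = prior$Lambda[j, j],
         psi_j = prior$Lambda[-j, j],
         Lambda_minus_j = prior$Lambda[-j, -j, drop = FALSE]),
    class = "partitioned_hyperparams"
  )
}

#' Schur complement of the scale hyperparameter
#'
#' \eqn{\lambda_j = \Lambda_j - \psi_j^T \Lambda_{-j}^{-1} \psi_j}, the
#' conditional scale left for variable `j` after regressing out the others.
#' Positive whenever \eqn{\Lambda} is SPD.
#'
#' @param part a [partition_hyperparams()] result.
#' @return positive scalar \eqn{\lambda_j}.
#' @export
schur_lambda <- function(part) {
  stopifnot(inherits(part, "partitioned_hyperparams"))
  check_spd(part$Lambda_minus_j, "Lambda_minus_j")
  lam <- part$Lambda_j -
    sum(part$psi_j * solve(part$Lambda_minus_j, part$psi_j))
  as.numeric(lam)
}

#' Transform a joint NIW prior into the conditional NIG prior of one variable
#'
#' The change of variables \eqn{(\mu, \Sigma) \leftrightarrow (\theta_j,
#' \theta_{-j})} with \eqn{\theta_j = (\alpha_j, \beta_j, \sigma_j)} factorizes
#' the NIW prior into independent blocks (the non-informative-margins
#' condition). This function returns the \eqn{\theta_j} block: writing
#' \eqn{(\nu, \Psi)} for the prior's textbook inverse-Wishart pair and
#' partitioning \eqn{\Psi} with variable `j` first,
#' \deqn{\sigma_j \sim IG(\nu/2, \Psi_{11\cdot2}/2), \quad
#'       \beta_j | \sigma_j \sim N(\Psi_{22}^{-1}\Psi_{21}, \sigma_j
#'       \Psi_{22}^{-1}),}
#' and \eqn{\alpha_j | \beta_j, \sigma_j \sim N(\mu_{0j} - \beta_j^T
#' \mu_{0,-j}, \sigma_j/\tau)}, which combine into one joint normal on
#' \eqn{(\alpha_j, \beta_j)} given \eqn{\sigma_j} with covariance
#' \eqn{\sigma_j V_0}. Under the default `scale_literal` convention
#' \eqn{\Psi_{11\cdot2} = \lambda_j} (the Schur complement, [schur_lambda()])
#' and the slope prior mean is \eqn{\Lambda_{-j}^{-1}\psi_j}.
#'
#' The returned prior satisfies the factorization identity checked by
#' [log_joint_prior()] together with [log_nig_prior()] and
#' [log_margin_prior()]: the log joint prior minus the two block log-priors is
#' constant in \eqn{\theta}.
#'
#' @inheritParams partition_hyperparams
#' @return A [nig_prior()] for the regression of variable `j` on the others,
#'   with coefficient order (intercept, slopes in the original variable order
#'   with `j` removed).
#' @export
#' @examples
#' pr <- niw_prior(c(0, 0, 0), tau = 1, m = 3, Lambda = diag(60, 3))
#' niw_to_nig(pr, 2)
niw_to_nig <- function(prior, j) {
  stopifnot(inherits(prior, "niw_prior"))
  p <- prior$p
  if (p < 2) stop("no conditional model exists for p < 2")
  if (!(j %in% seq_len(p))) stop("'j' out of range 1..", p)
  Psi <- prior$iw_scale
  psi11 <- Psi[j, j]
  psi21 <- Psi[-j, j]
  Psi22 <- Psi[-j, -j, drop = FALSE]
  Psi22_inv <- chol2inv(chol(Psi22))
  b0 <- drop(Psi22_inv %*% psi21)
  psi11_2 <- psi11 - sum(psi21 * b0)
  mu0j <- prior$mu0[j]
  mu0m <- prior$mu0[-j]
  a0 <- mu0j - sum(b0 * mu0m)
  # joint (alpha, beta) | sigma covariance sigma * V0:
  # alpha = mu0j - beta' mu0m + e, e ~ N(0, sigma/tau) independent of beta
  q <- p - 1L
  V0 <- matrix(0, q + 1L, q + 1L)
  V0[1L, 1L] <- 1 / prior$tau + drop(crossprod(mu0m, Psi22_inv %*% mu0m))
  V0[1L, -1L] <- -drop(Psi22_inv %*% mu0m)
  V0[-1L, 1L] <- V0[1L, -1L]
  V0[-1L, -1L] <- Psi22_inv
  nig_prior(sigma_df = prior$iw_df, sigma_scale = psi11_2,
            coef_mean = c(a0, b0), coef_scale = V0)
}

#' Marginal t-distributions of the conditional prior coefficients
#'
#' Integrating \eqn{\sigma_j} out of the conditional NIG prior makes the
#' marginal priors of \eqn{\beta_j} and \eqn{\alpha_j} Student-t. The reported
#' degrees of freedom follow the closed form \eqn{2m - p + 1}; the scale
#' matrices are calibrated so the t variance equals the large-sample normal
#' approximation \eqn{\lambda_j \Lambda_{-j}^{-1}/(m-1)} for the slopes (and
#' the analogous \eqn{\tau^{-1}\lambda_j/(m-1)} for the intercept), which is
#' the limit the exact inverse-gamma mixture attains as \eqn{m} grows.
#'
#' @inheritParams partition_hyperparams
#' @return A list with components `beta = list(location, scale, df)`,
#'   `alpha = list(location, scale, df)` and the large-sample
#'   `normal_approx = list(beta_mean, beta_cov, alpha_mean, alpha_var)`.
#' @export
marginal_coef_t <- function(prior, j) {
  stopifnot(inherits(prior, "niw_prior"))
  p <- prior$p
  m <- prior$m
  df <- 2 * m - p + 1
  if (df <= 0) stop("non-positive degrees of freedom 2m - p + 1")
  if (m <= 1) stop("normal approximation requires m > 1")
  part <- partition_hyperparams(prior, j)
  lam <- schur_lambda(part)
  Lm_inv <- chol2inv(chol(part$Lambda_minus_j))
  b0 <- drop(Lm_inv %*% part$psi_j)
  a0 <- part$mu0_j - sum(b0 * part$mu0_minus_j)
  beta_cov <- lam * Lm_inv / (m - 1)
  alpha_var <- lam / (prior$tau * (m - 1)) +
    drop(crossprod(part$mu0_minus_j, beta_cov %*% part$mu0_minus_j))
  fac <- if (df > 2) (df - 2) / df else 1
  list(
    beta = list(location = b0, scale = beta_cov * fac, df = df),
    alpha = list(location = a0, scale = alpha_var * fac, df = df),
    normal_approx = list(beta_mean = b0, beta_cov = beta_cov,
                         alpha_mean = a0, alpha_var = alpha_var)
  )
}

#' Unnormalized log joint NIW prior density
#'
#' Evaluates \eqn{\log \pi(\mu, \Sigma)} up to an additive constant under the
#' prior's convention: \eqn{-(\nu + p + 2)/2 \log|\Sigma| - \frac12
#' tr(\Psi\Sigma^{-1}) - \frac{\tau}{2}(\mu-\mu_0)^T\Sigma^{-1}(\mu-\mu_0)}
#' (the \eqn{-\frac12\log|\Sigma|} of the conditional normal for \eqn{\mu} is
#' included).
#'
#' @param theta a [theta_joint()].
#' @param prior a [niw_prior()].
#' @return scalar log-density (unnormalized).
#' @export
log_joint_prior <- function(theta, prior) {
  stopifnot(inherits(theta, "theta_joint"), inherits(prior, "niw_prior"))
  if (length(theta$mu) != prior$p) stop("dimension mismatch")
  R <- chol(theta$Sigma)
  logdet <- 2 * sum(log(diag(R)))
  Sinv <- chol2inv(R)
  d <- theta$mu - prior$mu0
  -((prior$iw_df + prior$p + 2) / 2) * logdet -
    0.5 * sum(prior$iw_scale * Sinv) -
    (prior$tau / 2) * drop(crossprod(d, Sinv %*% d))
}

#' Normalized log-density of the conditional NIG prior block
#'
#' \eqn{\log \pi(\theta_j)} for \eqn{\theta_j = (\alpha_j, \beta_j, \sigma_j)}:
#' inverse-gamma for \eqn{\sigma_j} times the joint normal for the coefficients
#' given \eqn{\sigma_j}.
#'
#' @param cond a [theta_conditional()].
#' @param prior a [nig_prior()].
#' @return scalar log-density.
#' @export
log_nig_prior <- function(cond, prior) {
  stopifnot(inherits(cond, "theta_conditional"), inherits(prior, "nig_prior"))
  ldinvgamma(cond$sigma, prior$shape, prior$rate) +
    ldmvnorm(c(cond$alpha, cond$beta), prior$coef_mean,
             cond$sigma * prior$coef_scale)
}

#' Normalized log-density of the marginal prior block
#'
#' \eqn{\log \pi(\theta_{-j})} for \eqn{\theta_{-j} = (\mu_{-j}, \Sigma_{-j})}:
#' inverse-Wishart \eqn{\Sigma_{-j} \sim W^{-1}(\nu - 1, \Psi_{22})} times
#' \eqn{\mu_{-j} | \Sigma_{-j} \sim N(\mu_{0,-j}, \tau^{-1}\Sigma_{-j})}.
#'
#' @param mu_minus numeric (p-1)-vector.
#' @param Sigma_minus (p-1) x (p-1) SPD matrix.
#' @param prior a [niw_prior()].
#' @param j index of the variable removed.
#' @return scalar log-density.
#' @export
log_margin_prior <- function(mu_minus, Sigma_minus, prior, j) {
  stopifnot(inherits(prior, "niw_prior"))
  Psi22 <- prior$iw_scale[-j, -j, drop = FALSE]
  ldinvwishart(Sigma_minus, prior$iw_df - 1, Psi22) +
    ldmvnorm(mu_minus, prior$mu0[-j], Sigma_minus / prior$tau)
}

#' Conditional linear model implied by a joint normal parameter
#'
#' The conditional of \eqn{Y_j} given \eqn{Y_{-j}} under \eqn{N(\mu, \Sigma)}
#' is the regression with slopes \eqn{\beta_j^T = \xi_j^T\Sigma_{-j}^{-1}},
#' intercept \eqn{\alpha_j = \mu_j - \xi_j^T\Sigma_{-j}^{-1}\mu_{-j}} and
#' residual variance \eqn{\sigma_j = \omega_j -
#' \xi_j^T\Sigma_{-j}^{-1}\xi_j}.
#'
#' @param theta a [theta_joint()].
#' @param j index of the response variable.
#' @return A list with `cond` (a [theta_conditional()]; slopes ordered by the
#'   remaining variables), `mu_minus` and `Sigma_minus`.
#' @export
theta_joint_to_conditional <- function(theta, j) {
  stopifnot(inherits(theta, "theta_joint"))
  p <- length(theta$mu)
  if (!(j %in% seq_len(p))) stop("'j' out of range 1..", p)
  if (p < 2) stop("no conditional model exists for p < 2")
  Sm <- theta$Sigma[-j, -j, drop = FALSE]
  xi <- theta$Sigma[-j, j]
  beta <- drop(solve(Sm, xi))
  mu_m <- theta$mu[-j]
  alpha <- theta$mu[j] - sum(beta * mu_m)
  sigma <- theta$Sigma[j, j] - sum(xi * beta)
  if (sigma <= 0) stop("implied residual variance not positive")
  list(cond = theta_conditional(alpha, beta, sigma),
       mu_minus = mu_m, Sigma_minus = Sm)
}

#' Reassemble a joint normal parameter from a conditional decomposition
#'
#' Inverse of [theta_joint_to_conditional()]: given \eqn{(\alpha_j, \beta_j,
#' \sigma_j)} and \eqn{(\mu_{-j}, \Sigma_{-j})}, reconstructs \eqn{(\mu,
#' \Sigma)} with variable `j` back in its original position.
#'
#' @param cond a [theta_conditional()].
#' @param mu_minus numeric (p-1)-vector.
#' @param Sigma_minus (p-1) x (p-1) SPD matrix.
#' @param j position of the response variable in the joint parameter.
#' @return A [theta_joint()].
#' @export
theta_conditional_to_joint <- function(cond, mu_minus, Sigma_minus, j) {
  stopifnot(inherits(cond, "theta_conditional"))
  p <- length(mu_minus) + 1L
  idx_minus <- setdiff(seq_len(p), j)
  mu <- numeric(p)
  mu[j] <- cond$alpha + sum(cond$beta * mu_minus)
  mu[idx_minus] <- mu_minus
  Sigma <- matrix(0, p, p)
  xi <- drop(Sigma_minus %*% cond$beta)
  Sigma[idx_minus, idx_minus] <- Sigma_minus
  Sigma[j, idx_minus] <- xi
  Sigma[idx_minus, j] <- xi
  Sigma[j, j] <- cond$sigma + sum(cond$beta * xi)
  theta_joint(mu, Sigma)
}

# ---- internal density helpers -----------------------------------------------

# SPD check via symmetric eigenvalues, tolerance relative to largest eigenvalue
check_spd <- function(A, name = "matrix") {
  if (!isTRUE(all.equal(A, t(A), tolerance = 1e-8)))
    stop("'", name, "' must be symmetric")
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  if (ev[1L] <= 0 || ev[length(ev)] < 1e-10 * ev[1L])
    stop("'", name, "' must be positive definite")
  invisible(TRUE)
}

ldmvnorm <- function(x, mean, Sigma) {
  Sigma <- as.matrix(Sigma)
  R <- chol(Sigma)
  d <- backsolve(R, x - mean, transpose = TRUE)
  -0.5 * length(x) * log(2 * pi) - sum(log(diag(R))) - 0.5 * sum(d * d)
}

ldinvgamma <- function(x, shape, rate) {
  shape * log(rate) - lgamma(shape) - (shape + 1) * log(x) - rate / x
}

lmvgamma <- function(p, a) {
  (p * (p - 1) / 4) * log(pi) + sum(lgamma(a + (1 - seq_len(p)) / 2))
}

# textbook inverse-Wishart: W ~ IW_p(df, S), density
# |S|^{df/2} 2^{-df p/2} Gamma_p(df/2)^{-1} |W|^{-(df+p+1)/2} exp(-tr(S W^-1)/2)
ldinvwishart <- function(W, df, S) {
  W <- as.matrix(W)
  S <- as.matrix(S)
  p <- nrow(W)
  Rw <- chol(W)
  Winv <- chol2inv(Rw)
  (df / 2) * determinant_chol(S) - (df * p / 2) * log(2) - lmvgamma(p, df / 2) -
    ((df + p + 1) / 2) * 2 * sum(log(diag(Rw))) - 0.5 * sum(S * Winv)
}

determinant_chol <- function(A) {
  2 * sum(log(diag(chol(A))))
}
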