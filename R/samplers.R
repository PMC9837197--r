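#' Derive a reproducible substream seed
#'
#' Deterministic integer hash of a root seed and a stream id, kept inside the
#' 32-bit integer range. Engines use it to give every chain and replication its
#' own seed so that parallel chains never share a random-number stream.
#'
#' @param seed integer root seed.
#' @param id non-negative integer stream id.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, id) {
  s <- (as.numeric(seed) %% 94906249) + 1
  as.integer((s * 22695477 + as.numeric(id) * 1000003 + 12345) %% 2147483647)
}

#' Draw from the normal-inverse-gamma posterior of a linear regression
#'
#' Exact conjugate draw for the model \eqn{y | X, \alpha, \beta, \sigma \sim
#' N(X(\alpha,\beta)^T, \sigma I)} under a [nig_prior()]: with prior
#' \eqn{\sigma \sim IG(a_0, b_0)} and coefficients \eqn{\sim N(m_0, \sigma
#' V_0)}, the posterior is \eqn{IG(a_0 + n/2, b_n)} for \eqn{\sigma} and
#' \eqn{N(m_n, \sigma K_n^{-1})} for the coefficients, where \eqn{K_n =
#' V_0^{-1} + X^TX}, \eqn{m_n = K_n^{-1}(V_0^{-1}m_0 + X^Ty)} and \eqn{b_n =
#' b_0 + (y^Ty + m_0^TV_0^{-1}m_0 - m_n^TK_nm_n)/2}. \eqn{\sigma} is drawn
#' first, then the coefficients given \eqn{\sigma}, matching the prior's
#' \eqn{p(\sigma)p(\beta|\sigma)} factorization. Draws consume the current R
#' random-number stream.
#'
#' @param y numeric n-vector response (no missing values).
#' @param X n x q design matrix whose first column is the intercept column of
#'   ones.
#' @param prior a [nig_prior()] with q coefficients.
#' @return A [theta_conditional()] with `beta` holding the q-1 slopes.
#' @export
draw_nig_posterior <- function(y, X, prior) {
  stopifnot(inherits(prior, "nig_prior"))
  X <- as.matrix(X)
  n <- length(y)
  if (n < 1L) stop("need at least one observation")
  if (nrow(X) != n) stop("'X' and 'y' sizes differ")
  q <- ncol(X)
  if (length(prior$coef_mean) != q) stop("prior dimension does not match 'X'")
  if (anyNA(y) || anyNA(X)) stop("missing values in regression data")
  V0_inv <- chol2inv(chol(prior$coef_scale))
  K <- V0_inv + crossprod(X)
  Rk <- chol(K)
  rhs <- drop(V0_inv %*% prior$coef_mean) + drop(crossprod(X, y))
  mN <- backsolve(Rk, backsolve(Rk, rhs, transpose = TRUE))
  aN <- prior$shape + n / 2
  bN <- prior$rate + 0.5 * (sum(y * y) +
    drop(crossprod(prior$coef_mean, V0_inv %*% prior$coef_mean)) -
    sum(rhs * mN))
  if (bN <= 0) bN <- .Machine$double.eps  # guard against roundoff at tiny residuals
  sigma <- 1 / stats::rgamma(1L, shape = aN, rate = bN)
  coefs <- mN + sqrt(sigma) * backsolve(Rk, stats::rnorm(q))
  theta_conditional(coefs[1L], coefs[-1L], sigma)
}

#' Predictive draws from a conditional normal linear model
#'
#' Independent draws \eqn{N(x_i^T(\alpha, \beta), \sigma)} for each design row,
#' used to impute the missing values of one variable.
#'
#' @param Xmis design rows (with leading ones column) of the cases to impute.
#' @param theta a [theta_conditional()].
#' @return numeric vector of imputed values, one per row of `Xmis`.
#' @export
draw_predictive_normal <- function(Xmis, theta) {
  stopifnot(inherits(theta, "theta_conditional"))
  Xmis <- as.matrix(Xmis)
  if (nrow(Xmis) == 0L) return(numeric(0))
  mu <- drop(Xmis %*% c(theta$alpha, theta$beta))
  mu + sqrt(theta$sigma) * stats::rnorm(length(mu))
}

#' Draw from the normal-inverse-Wishart posterior given complete data
#'
#' Exact conjugate draw of \eqn{(\mu, \Sigma)} given an n x p complete data
#' matrix under a [niw_prior()] (textbook pair \eqn{(\nu, \Psi)}): the
#' posterior is NIW with \eqn{\tau_n = \tau + n}, \eqn{\mu_n = (\tau\mu_0 +
#' n\bar y)/\tau_n}, \eqn{\nu_n = \nu + n} and \eqn{\Psi_n = \Psi + S +
#' \frac{\tau n}{\tau_n}(\bar y - \mu_0)(\bar y - \mu_0)^T}, with \eqn{S} the
#' centered cross-product matrix. \eqn{\Sigma} is drawn first
#' (inverse-Wishart via [stats::rWishart()]), then \eqn{\mu | \Sigma \sim
#' N(\mu_n, \Sigma/\tau_n)}.
#'
#' @param Y complete n x p numeric matrix.
#' @param prior a [niw_prior()].
#' @return A [theta_joint()].
#' @export
draw_niw_posterior <- function(Y, prior) {
  stopifnot(inherits(prior, "niw_prior"))
  Y <- as.matrix(Y)
  n <- nrow(Y)
  if (n < 1L) stop("need at least one observation")
  if (ncol(Y) != prior$p) stop("'Y' does not match the prior dimension")
  if (anyNA(Y)) stop("missing values in 'Y'")
  ybar <- colMeans(Y)
  Yc <- sweep(Y, 2L, ybar)
  S <- crossprod(Yc)
  tau_n <- prior$tau + n
  mu_n <- (prior$tau * prior$mu0 + n * ybar) / tau_n
  nu_n <- prior$iw_df + n
  d <- ybar - prior$mu0
  Psi_n <- prior$iw_scale + S + (prior$tau * n / tau_n) * tcrossprod(d)
  Psi_n <- (Psi_n + t(Psi_n)) / 2
  prec <- stats::rWishart(1L, df = nu_n, Sigma = chol2inv(chol(Psi_n)))[, , 1L]
  Sigma <- chol2inv(chol(prec))
  Sigma <- (Sigma + t(Sigma)) / 2
  mu <- mu_n + drop(stats::rnorm(prior$p) %*% chol(Sigma / tau_n))
  theta_joint(mu, Sigma)
}

#' Impute the missing block of one case from the conditional multivariate normal
#'
#' For a row with observed coordinates `obs` and missing coordinates `mis`,
#' draws the missing block from \eqn{N(\mu_{m} + \Sigma_{mo}\Sigma_{oo}^{-1}
#' (y_o - \mu_o),\; \Sigma_{mm} - \Sigma_{mo}\Sigma_{oo}^{-1}\Sigma_{om})}.
#' Fully observed rows are returned unchanged; fully missing rows are drawn
#' from \eqn{N(\mu, \Sigma)}.
#'
#' @param row numeric p-vector with `NA` in the missing coordinates.
#' @param theta a [theta_joint()].
#' @return the completed p-vector.
#' @export
draw_mis_given_theta <- function(row, theta) {
  stopifnot(inherits(theta, "theta_joint"))
  mis <- is.na(row)
  if (!any(mis)) return(row)
  p <- length(row)
  if (length(theta$mu) != p) stop("dimension mismatch")
  if (all(mis)) {
    row[] <- theta$mu + drop(stats::rnorm(p) %*% chol(theta$Sigma))
    return(row)
  }
  Soo <- theta$Sigma[!mis, !mis, drop = FALSE]
  Smo <- theta$Sigma[mis, !mis, drop = FALSE]
  B <- Smo %*% chol2inv(chol(Soo))
  cond_mean <- theta$mu[mis] + drop(B %*% (row[!mis] - theta$mu[!mis]))
  cond_var <- theta$Sigma[mis, mis, drop = FALSE] - tcrossprod(B, Smo)
  cond_var <- (cond_var + t(cond_var)) / 2
  row[mis] <- cond_mean + drop(stats::rnorm(sum(mis)) %*% chol(cond_var))
  row
}
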