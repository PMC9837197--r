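#' Configuration for the joint-modelling imputation engine
#'
#' @param prior a [niw_prior()].
#' @param n_iter total data-augmentation iterations.
#' @param burn_in iterations discarded before retaining draws
#'   (`n_iter > burn_in >= 0`).
#' @param m number of imputed datasets, taken at evenly spaced post-burn-in
#'   iterations to reduce between-dataset autocorrelation.
#' @param seed optional integer seed.
#' @return An object of class `jm_config`.
#' @export
jm_config <- function(prior, n_iter = 1100L, burn_in = 100L, m = 5L,
                      seed = NULL) {
  stopifnot(inherits(prior, "niw_prior"))
  if (!(n_iter > burn_in && burn_in >= 0)) stop("need n_iter > burn_in >= 0")
  if (m < 1L || m > n_iter - burn_in) stop("invalid 'm'")
  structure(list(prior = prior, n_iter = as.integer(n_iter),
                 burn_in = as.integer(burn_in), m = as.integer(m),
                 seed = seed),
            class = "jm_config")
}

#' Multiple imputation by joint modelling (data augmentation)
#'
#' Gibbs sampler alternating a P-step, [draw_niw_posterior()] on the currently
#' completed data, and an I-step, [draw_mis_given_theta()] applied per
#' missing-data pattern group. Post-burn-in draws of \eqn{\theta = (\mu,
#' \Sigma)} are retained; `m` imputed datasets are taken at evenly spaced
#' post-burn-in iterations. This is the gold-standard joint Bayesian posterior
#' against which the chained-equations engine is compared.
#'
#' @param data numeric matrix (or data frame) with `NA` for missing cells.
#' @param config a [jm_config()].
#' @return An object of class `jm_result`: `imputations` (list of m completed
#'   matrices), `mu` ((n_iter - burn_in) x p matrix of retained mean draws),
#'   `Sigma` (list of retained covariance draws), `mask`.
#' @export
run_jm <- function(data, config) {
  stopifnot(inherits(config, "jm_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  X0 <- incomplete_data(data)
  mask <- attr(X0, "mask")
  p <- ncol(X0)
  if (p != config$prior$p) stop("prior dimension does not match data")
  groups <- split(seq_len(nrow(X0)), attr(X0, "row_pattern"))
  groups <- groups[names(groups) != ""]  # fully observed rows never change
  X <- initialize_fill(X0)
  keep <- config$n_iter - config$burn_in
  mu_draws <- matrix(NA_real_, keep, p, dimnames = list(NULL, colnames(X0)))
  Sigma_draws <- vector("list", keep)
  imp_at <- config$burn_in +
    unique(round(seq_len(config$m) * keep / config$m))
  imputations <- vector("list", length(imp_at))
  for (it in seq_len(config$n_iter)) {
    theta <- draw_niw_posterior(X, config$prior)
    for (g in groups) {
      for (i in g) X[i, ] <- draw_mis_given_theta(X0[i, ], theta)
    }
    if (it > config$burn_in) {
      k <- it - config$burn_in
      mu_draws[k, ] <- theta$mu
      Sigma_draws[[k]] <- theta$Sigma
      if (it %in% imp_at) imputations[[match(it, imp_at)]] <- X
    }
  }
  structure(list(imputations = imputations, mu = mu_draws,
                 Sigma = Sigma_draws, mask = mask, prior = config$prior),
            class = "jm_result")
}

#' @export
print.jm_result <- function(x, ...) {
  cat("JM (data augmentation) imputation: ", length(x$imputations),
      " imputed dataset(s), ", nrow(x$mu), " retained theta draws\n", sep = "")
  invisible(x)
}

#' Map joint posterior draws to the conditional regression scale
#'
#' Applies [theta_joint_to_conditional()] draw-wise so that joint-model
#' posterior draws of \eqn{(\mu, \Sigma)} can be compared with
#' chained-equations draws of one variable's regression parameters
#' \eqn{(\alpha, \beta, \sigma)}.
#'
#' @param jm a `jm_result` (or a list with `mu` matrix and `Sigma` list).
#' @param j response variable (index or column name).
#' @return a matrix with columns `alpha`, `b1` ... `b(p-1)` (slopes on the
#'   remaining variables in original order) and `sigma`, one row per draw.
#' @export
theta_to_regression <- function(jm, j) {
  mu <- jm$mu
  if (is.character(j)) j <- match(j, colnames(mu))
  n <- nrow(mu)
  p <- ncol(mu)
  out <- matrix(NA_real_, n, p + 1L)
  colnames(out) <- c("alpha", paste0("b", seq_len(p - 1L)), "sigma")
  for (k in seq_len(n)) {
    th <- theta_joint_to_conditional(
      theta_joint(mu[k, ], jm$Sigma[[k]]), j)$cond
    out[k, ] <- c(th$alpha, th$beta, th$sigma)
  }
  out
}
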