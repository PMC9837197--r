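#' Pool estimates across imputed datasets by Rubin's rules
#'
#' \eqn{\bar q} is the mean of the m estimates, \eqn{\bar u} the mean
#' within-imputation variance, \eqn{b} the between-imputation sample variance,
#' and the total variance \eqn{T = \bar u + (1 + 1/m) b}. Degrees of freedom
#' use the classical large-sample formula, combined with the Barnard-Rubin
#' small-sample adjustment when the complete-data degrees of freedom `n_com`
#' are supplied. The confidence interval is the symmetric t-interval.
#'
#' @param estimates numeric vector of m point estimates.
#' @param variances numeric vector of m within-imputation variances.
#' @param n_com optional complete-data degrees of freedom (e.g. n - 1 for a
#'   mean), enabling the Barnard-Rubin adjustment.
#' @param conf confidence level, default 0.95.
#' @return An object of class `pooled_estimate` with fields `qbar`, `ubar`,
#'   `b`, `t` (total variance), `df`, `ci_low`, `ci_high`, `m`.
#' @export
rubin_pool <- function(estimates, variances, n_com = NULL, conf = 0.95) {
  m <- length(estimates)
  if (m == 0L) stop("no estimates to pool")
  if (length(variances) != m) stop("'estimates' and 'variances' sizes differ")
  qbar <- mean(estimates)
  ubar <- mean(variances)
  if (m == 1L) {
    b <- 0
    tv <- ubar
    df <- if (is.null(n_com)) Inf else n_com
    warning("m = 1: between-imputation variance cannot be estimated")
  } else {
    b <- stats::var(estimates)
    tv <- ubar + (1 + 1 / m) * b
    r <- (1 + 1 / m) * b / ubar
    df_old <- if (b > 0) (m - 1) * (1 + 1 / r)^2 else Inf
    if (is.null(n_com)) {
      df <- df_old
    } else {
      gamma <- (1 + 1 / m) * b / tv
      df_obs <- (n_com + 1) / (n_com + 3) * n_com * (1 - gamma)
      df <- 1 / (1 / df_old + 1 / df_obs)
    }
  }
  half <- stats::qt(1 - (1 - conf) / 2, df) * sqrt(tv)
  structure(list(qbar = qbar, ubar = ubar, b = b, t = tv, df = df,
                 ci_low = qbar - half, ci_high = qbar + half, m = m),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf(
    "Pooled estimate (m = %d): %.4f  [%.4f, %.4f]\n  ubar %.5f  b %.5f  T %.5f  df %.1f\n",
    x$m, x$qbar, x$ci_low, x$ci_high, x$ubar, x$b, x$t, x$df))
  invisible(x)
}

#' Complete-case estimate of a column mean
#'
#' Listwise deletion: the mean of the chosen column over the rows with no
#' missing value in any column, with the standard t-interval.
#'
#' @param data matrix or data frame with `NA` for missing cells.
#' @param column column name or index.
#' @param conf confidence level.
#' @return A list with `estimate`, `variance` (of the mean), `df`, `ci_low`,
#'   `ci_high`, `n_complete`.
#' @export
cca_estimate <- function(data, column, conf = 0.95) {
  X <- as.matrix(data)
  cc <- stats::complete.cases(X)
  ncc <- sum(cc)
  if (ncc < 2L) stop("fewer than 2 complete cases")
  v <- X[cc, column]
  est <- mean(v)
  se2 <- stats::var(v) / ncc
  half <- stats::qt(1 - (1 - conf) / 2, ncc - 1) * sqrt(se2)
  list(estimate = est, variance = se2, df = ncc - 1,
       ci_low = est - half, ci_high = est + half, n_complete = ncc)
}

#' Bias / coverage / interval-width experiment for the mean of y
#'
#' Repeats the full study pipeline `n_reps` times: generate `n` cases from the
#' trivariate normal population, ampute under the chosen mechanism, impute by
#' chained equations under the transformed prior, estimate E(Y) in each imputed
#' dataset (sample mean, variance `var/n`), pool by Rubin's rules, and score
#' bias, coverage of the nominal 95\% interval, and interval width against the
#' population value. The same replications are scored by complete-case
#' analysis.
#'
#' @param n_reps number of replications.
#' @param mechanism `"MCAR"` or `"MARr"`.
#' @param n cases per replication.
#' @param prior a [niw_prior()] (default: the study prior).
#' @param m imputations per replication.
#' @param n_iter chained-equations iterations.
#' @param visit visit sequence.
#' @param column variable whose mean is the estimand.
#' @param true_value population value of the estimand.
#' @param overall_prop within-pattern missingness fraction.
#' @param seed integer root seed; replication r uses `derive_seed(seed, r)`.
#' @param verbose emit a progress message every 50 replications.
#' @return An object of class `coverage_report`: per-replication data frame
#'   `reps` and a `summary` data frame with one row per method
#'   (`FCS`, `CCA`) carrying `bias`, `coverage`, `ciw`, `n_reps`.
#' @export
coverage_experiment <- function(n_reps, mechanism = c("MCAR", "MARr"),
                                n = 200L, prior = simulation_defaults()$prior,
                                m = 5L, n_iter = 10L,
                                visit = simulation_defaults()$visit,
                                column = "y", true_value = 4,
                                overall_prop = 0.5, seed = 1L,
                                verbose = FALSE) {
  mechanism <- match.arg(mechanism)
  defs <- simulation_defaults()
  spec <- amputation_spec(mechanism = mechanism, overall_prop = overall_prop)
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(derive_seed(seed, r))
    Y <- generate_mvn(n, defs$mu, defs$Sigma)
    amp <- ampute(Y, spec)
    cfg <- fcs_config(prior, visit_sequence = visit, n_iter = n_iter, m = m,
                      seed = derive_seed(seed, r + 500000L))
    fit <- run_fcs(amp, cfg)
    est <- vapply(fit$imputations, function(d) mean(d[, column]), 0)
    vr <- vapply(fit$imputations, function(d) stats::var(d[, column]) / n, 0)
    pool <- rubin_pool(est, vr, n_com = n - 1)
    cca <- cca_estimate(amp, column)
    rows[[r]] <- data.frame(
      rep = r,
      fcs_est = pool$qbar, fcs_lo = pool$ci_low, fcs_hi = pool$ci_high,
      cca_est = cca$estimate, cca_lo = cca$ci_low, cca_hi = cca$ci_high)
    if (verbose && r %% 50L == 0L)
      message("  replication ", r, " / ", n_reps)
  }
  reps <- do.call(rbind, rows)
  summ <- rbind(
    summarize_method(reps$fcs_est, reps$fcs_lo, reps$fcs_hi, true_value,
                     "FCS", mechanism),
    summarize_method(reps$cca_est, reps$cca_lo, reps$cca_hi, true_value,
                     "CCA", mechanism))
  structure(list(reps = reps, summary = summ, mechanism = mechanism,
                 true_value = true_value, n_reps = n_reps),
            class = "coverage_report")
}

summarize_method <- function(est, lo, hi, truth, method, mechanism) {
  data.frame(method = method, mechanism = mechanism,
             bias = mean(est) - truth,
             coverage = mean(lo <= truth & truth <= hi),
             ciw = mean(hi - lo),
             n_reps = length(est))
}

#' @export
print.coverage_report <- function(x, ...) {
  cat("Coverage experiment (", x$n_reps, " replications, ", x$mechanism,
      ", estimand E(Y) = ", x$true_value, ")\n", sep = "")
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Batch-means Monte-Carlo standard error
#'
#' Partitions the series into `n_batches` equal subsequences and estimates the
#' standard error of the overall mean as the standard deviation of the batch
#' means divided by the square root of the number of batches. A tail that does
#' not fill a batch is dropped with a warning.
#'
#' @param series numeric vector (an MCMC trace).
#' @param n_batches number of batches (>= 2), default 20.
#' @return scalar standard error of `mean(series)`.
#' @export
batch_means_se <- function(series, n_batches = 20L) {
  if (n_batches < 2L) stop("need at least 2 batches")
  len <- length(series) %/% n_batches
  if (len < 1L) stop("series shorter than the number of batches")
  used <- len * n_batches
  if (used < length(series)) {
    warning("series length not divisible by 'n_batches'; dropping ",
            length(series) - used, " tail values")
    series <- series[seq_len(used)]
  }
  bm <- colMeans(matrix(series, nrow = len))
  stats::sd(bm) / sqrt(n_batches)
}

#' Augmented chained-equations chain for the order-effect diagnostic
#'
#' Runs the visit sequence (z, x, y) with the iteration augmented as: impute z;
#' fit the least-squares regression y ~ x + z on the completed data and record
#' the x-coefficient as `b1z`; impute x; refit and record `b1x`; impute y.
#' Differences `b1z - b1x` from the `n_record` post-burn-in iterations measure
#' any systematic dependence of the imputations on the position within the
#' visit sequence.
#'
#' @param amp incomplete matrix with columns x, y, z.
#' @param priors named list of [nig_prior()]s (or a [niw_prior()]).
#' @param burn_in burn-in iterations (default 10).
#' @param n_record recorded iterations (default 1000).
#' @param inject_shift constant added to x's imputed values in the completed
#'   data used for the `b1x` recording (the chain itself is not perturbed);
#'   nonzero values create an artificial order effect used as a power check.
#'   Default 0.
#' @return A list with vectors `b1z`, `b1x`, `diff`.
#' @export
order_effect_chain <- function(amp, priors, burn_in = 10L, n_record = 1000L,
                               inject_shift = 0) {
  X0 <- incomplete_data(amp)
  cols <- colnames(X0)
  stopifnot(all(c("x", "y", "z") %in% cols))
  priors <- resolve_priors(priors, cols)
  mask <- attr(X0, "mask")
  X <- initialize_fill(X0)
  jx <- match("x", cols); jy <- match("y", cols); jz <- match("z", cols)
  ols_x <- function(M) .lm.fit(cbind(1, M[, c(jx, jz)]), M[, jy])$coefficients[2L]
  impute_one <- function(M, j) {
    obs <- !mask[, j]
    Xd <- cbind(1, M[, -j, drop = FALSE])
    th <- draw_nig_posterior(M[obs, j], Xd[obs, , drop = FALSE],
                             priors[[cols[j]]])
    if (any(!obs)) M[!obs, j] <- draw_predictive_normal(
      Xd[!obs, , drop = FALSE], th)
    M
  }
  total <- burn_in + n_record
  b1z <- b1x <- numeric(n_record)
  for (it in seq_len(total)) {
    X <- impute_one(X, jz)
    rec <- it > burn_in
    if (rec) b1z[it - burn_in] <- ols_x(X)
    X <- impute_one(X, jx)
    if (rec) {
      # the power check perturbs only the data seen by the second recording,
      # leaving the chain itself untouched
      Xrec <- X
      if (inject_shift != 0)
        Xrec[mask[, jx], jx] <- Xrec[mask[, jx], jx] + inject_shift
      b1x[it - burn_in] <- ols_x(Xrec)
    }
    X <- impute_one(X, jy)
  }
  list(b1z = b1z, b1x = b1x, diff = b1z - b1x)
}

#' Order-effect experiment
#'
#' Repeats the augmented chain of [order_effect_chain()] over freshly generated
#' and MCAR-amputed datasets. Per replication the mean difference
#' \eqn{\bar d = \mathrm{mean}(\hat\beta_1^z - \hat\beta_1^x)} is tested
#' against the null of no order effect (mean zero) with the batch-means
#' standard error: the replication is flagged when \eqn{|\bar d| >
#' 1.96\,\mathrm{SE}}. Under convergence to a joint distribution the flag
#' count stays small.
#'
#' @param n_reps replications (the full design uses 500).
#' @param n cases per replication.
#' @param prior a [niw_prior()].
#' @param burn_in,n_record chain lengths per replication.
#' @param n_batches batches for the batch-means standard error.
#' @param overall_prop within-pattern missingness fraction.
#' @param inject_shift artificial order effect for the power check.
#' @param seed integer root seed.
#' @param verbose emit a progress message every 50 replications.
#' @return An object of class `order_effect_report`: data frame `reps`
#'   (`mean_diff`, `se`, `ci_low`, `ci_high`, `excludes_zero`) and the count
#'   `n_exclusions`.
#' @export
order_effect_experiment <- function(n_reps, n = 200L,
                                    prior = simulation_defaults()$prior,
                                    burn_in = 10L, n_record = 1000L,
                                    n_batches = 20L, overall_prop = 0.5,
                                    inject_shift = 0, seed = 1L,
                                    verbose = FALSE) {
  defs <- simulation_defaults()
  spec <- amputation_spec("MCAR", overall_prop = overall_prop)
  nigs <- resolve_priors(prior, defs$names)
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(derive_seed(seed, r))
    Y <- generate_mvn(n, defs$mu, defs$Sigma)
    amp <- ampute(Y, spec)
    ch <- order_effect_chain(amp, nigs, burn_in = burn_in,
                             n_record = n_record,
                             inject_shift = inject_shift)
    md <- mean(ch$diff)
    se <- batch_means_se(ch$diff, n_batches)
    rows[[r]] <- data.frame(rep = r, mean_diff = md, se = se,
                            ci_low = md - 1.96 * se, ci_high = md + 1.96 * se,
                            excludes_zero = abs(md) > 1.96 * se)
    if (verbose && r %% 50L == 0L)
      message("  replication ", r, " / ", n_reps)
  }
  reps <- do.call(rbind, rows)
  structure(list(reps = reps, n_exclusions = sum(reps$excludes_zero),
                 n_reps = n_reps, n_record = n_record),
            class = "order_effect_report")
}

#' @export
print.order_effect_report <- function(x, ...) {
  cat("Order-effect diagnostic: ", x$n_exclusions, " of ", x$n_reps,
      " 95% CIs exclude zero (", x$n_record,
      " recorded iterations per replication)\n", sep = "")
  invisible(x)
}

#' Compare two posterior samples (QQ pairs and KS statistic)
#'
#' Quantile-quantile pairs and the two-sample Kolmogorov-Smirnov statistic
#' between posterior draws of the same parameter obtained by two samplers
#' (typically chained equations versus joint modelling after
#' [theta_to_regression()]).
#'
#' @param draws1,draws2 numeric vectors of posterior draws.
#' @param n_q number of quantile pairs to return.
#' @return A list with `ks` (the KS statistic), `qq` (data frame `p`, `q1`,
#'   `q2`).
#' @export
posterior_compare <- function(draws1, draws2, n_q = 100L) {
  if (length(draws1) == 0L || length(draws2) == 0L) stop("empty sample")
  ks <- suppressWarnings(
    stats::ks.test(draws1, draws2)$statistic)
  pr <- seq(0.005, 0.995, length.out = n_q)
  list(ks = unname(ks),
       qq = data.frame(p = pr,
                       q1 = stats::quantile(draws1, pr, names = FALSE),
                       q2 = stats::quantile(draws2, pr, names = FALSE)))
}

#' Long-run posterior draws of one variable's regression parameters, by FCS
#'
#' Runs a single long chained-equations chain and collects the post-burn-in
#' draws of \eqn{(\alpha, \beta, \sigma)} for the chosen response variable —
#' the chained-equations side of the JM-versus-FCS posterior comparison.
#'
#' @param amp incomplete matrix.
#' @param prior a [niw_prior()] (transformed internally) or named list of
#'   [nig_prior()]s.
#' @param response column name of the response variable.
#' @param burn_in,n_draws chain lengths.
#' @param visit visit sequence (default column order).
#' @param seed optional integer seed.
#' @return matrix with columns `alpha`, `b1`, ..., `sigma`; one row per draw.
#' @export
fcs_posterior_draws <- function(amp, prior, response, burn_in = 10L,
                                n_draws = 2000L, visit = NULL, seed = NULL) {
  cfg <- fcs_config(prior, visit_sequence = visit,
                    n_iter = burn_in + n_draws, m = 1L, seed = seed)
  fit <- run_fcs(amp, cfg)
  tr <- fit$trace
  tr <- tr[tr$variable == response & tr$iteration > burn_in, ]
  as.matrix(tr[, c("alpha", grep("^b[0-9]+$", names(tr), value = TRUE),
                   "sigma")])
}
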