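#' Configuration for the chained-equations imputation engine
#'
#' @param priors either a [niw_prior()] (transformed per variable via
#'   [niw_to_nig()]) or a named list with one [nig_prior()] per column.
#' @param visit_sequence character vector, the order in which the incomplete
#'   variables are visited within an iteration; default: column order.
#' @param n_iter number of iterations per chain (burn-in; the final iteration's
#'   matrix is the chain's imputation). Default 10.
#' @param m number of parallel chains, i.e. imputed datasets. Default 5.
#' @param seed optional integer root seed; chain c uses the derived substream
#'   seed `derive_seed(seed, c)`.
#' @return An object of class `fcs_config`.
#' @export
fcs_config <- function(priors, visit_sequence = NULL, n_iter = 10L, m = 5L,
                       seed = NULL) {
  if (n_iter < 1L) stop("'n_iter' must be >= 1")
  if (m < 1L) stop("'m' must be >= 1")
  structure(list(priors = priors, visit_sequence = visit_sequence,
                 n_iter = as.integer(n_iter), m = as.integer(m), seed = seed),
            class = "fcs_config")
}

# resolve per-column nig priors from the config, in column order of `cols`
resolve_priors <- function(priors, cols) {
  if (inherits(priors, "niw_prior")) {
    if (priors$p != length(cols)) stop("prior dimension does not match data")
    out <- lapply(seq_along(cols), function(j) niw_to_nig(priors, j))
    names(out) <- cols
    return(out)
  }
  if (!all(cols %in% names(priors)))
    stop("need one nig_prior per column, named by the columns")
  lapply(priors[cols], function(pr) {
    stopifnot(inherits(pr, "nig_prior")); pr
  })
}

#' Initialize an incomplete matrix by marginal draws
#'
#' Replaces every missing cell with a uniform random draw from the observed
#' values of its own column; observed cells are untouched.
#'
#' @param data matrix with `NA` for missing cells; every column needs at least
#'   one observed value.
#' @param seed optional integer seed.
#' @return the completed matrix.
#' @export
initialize_fill <- function(data, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- as.matrix(data)
  for (j in seq_len(ncol(X))) {
    mis <- is.na(X[, j])
    if (!any(mis)) next
    obs <- X[!mis, j]
    if (length(obs) == 0L) stop("column ", j, " is fully missing")
    X[mis, j] <- obs[sample.int(length(obs), sum(mis), replace = TRUE)]
  }
  X
}

#' One iteration of the chained-equations sampler
#'
#' For each variable j in the visit sequence: draw \eqn{\theta_j} from its
#' normal-inverse-gamma posterior given the rows where \eqn{Y_j} is observed
#' (regressing on the current completed values of the other variables), then
#' overwrite only the missing cells of \eqn{Y_j} with predictive draws. Within
#' the iteration each fit uses the most recent values of the other columns
#' (Gibbs-style sequential update).
#'
#' @param current completed matrix from the previous iteration.
#' @param mask logical matrix, TRUE where the original data are missing.
#' @param priors named list with one [nig_prior()] per column.
#' @param visit character or integer vector of columns to visit.
#' @return a list with `data` (updated completed matrix) and `theta` (named
#'   list of [theta_conditional()] draws, one per visited column).
#' @export
fcs_step <- function(current, mask, priors, visit = colnames(current)) {
  X <- current
  theta <- vector("list", length(visit))
  names(theta) <- visit
  for (v in visit) {
    j <- if (is.character(v)) match(v, colnames(X)) else v
    obs <- !mask[, j]
    Xd <- cbind(1, X[, -j, drop = FALSE])
    th <- draw_nig_posterior(X[obs, j], Xd[obs, , drop = FALSE],
                             priors[[colnames(X)[j]]])
    if (any(!obs))
      X[!obs, j] <- draw_predictive_normal(Xd[!obs, , drop = FALSE], th)
    theta[[as.character(v)]] <- th
  }
  list(data = X, theta = theta)
}

#' Multiple imputation by fully conditional specification
#'
#' Runs `m` independent chains; each chain starts from its own
#' [initialize_fill()] and iterates [fcs_step()] `n_iter` times. The final
#' iteration's matrix is that chain's imputed dataset. Per-iteration draws of
#' every visited variable's \eqn{(\alpha, \beta, \sigma)} are retained as a
#' trace.
#'
#' @param data numeric matrix (or data frame) with `NA` for missing cells.
#' @param config an [fcs_config()].
#' @return An object of class `fcs_result`: a list with `imputations` (list of
#'   m completed matrices), `trace` (data frame with chain, iteration,
#'   variable, alpha, slope columns, sigma), `visit`, and the input `mask`.
#' @export
run_fcs <- function(data, config) {
  stopifnot(inherits(config, "fcs_config"))
  X0 <- incomplete_data(data)
  mask <- attr(X0, "mask")
  cols <- colnames(X0)
  visit <- config$visit_sequence
  if (is.null(visit)) visit <- cols
  if (!setequal(visit, cols))
    stop("'visit_sequence' must be a permutation of the columns")
  priors <- resolve_priors(config$priors, cols)
  imputations <- vector("list", config$m)
  traces <- vector("list", config$m)
  for (chain in seq_len(config$m)) {
    if (!is.null(config$seed)) set.seed(derive_seed(config$seed, chain))
    X <- initialize_fill(X0)
    rows <- vector("list", config$n_iter)
    for (it in seq_len(config$n_iter)) {
      step <- fcs_step(X, mask, priors, visit)
      X <- step$data
      rows[[it]] <- theta_trace_rows(step$theta, chain, it, cols)
    }
    attr(X, "mask") <- NULL
    attr(X, "row_pattern") <- NULL
    imputations[[chain]] <- X
    traces[[chain]] <- do.call(rbind, rows)
  }
  structure(list(imputations = imputations,
                 trace = do.call(rbind, traces),
                 visit = visit, mask = mask, data = X0),
            class = "fcs_result")
}

# slopes are stored positionally (b1, b2, ...); the predictors of variable v
# are the remaining columns in their original order
theta_trace_rows <- function(theta, chain, iteration, cols) {
  do.call(rbind, lapply(names(theta), function(v) {
    th <- theta[[v]]
    slopes <- as.list(th$beta)
    names(slopes) <- paste0("b", seq_along(slopes))
    as.data.frame(c(list(chain = chain, iteration = iteration, variable = v,
                         alpha = th$alpha), slopes, list(sigma = th$sigma)))
  }))
}

#' @export
print.fcs_result <- function(x, ...) {
  cat("FCS imputation: ", length(x$imputations), " imputed dataset(s), ",
      max(x$trace$iteration), " iteration(s), visit sequence ",
      paste(x$visit, collapse = " -> "), "\n", sep = "")
  cat("  ", sum(x$mask), " missing cells in ", nrow(x$mask), " x ",
      ncol(x$mask), " data\n", sep = "")
  invisible(x)
}
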