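#' Study conditions of the simulation design
#'
#' The trivariate normal population, the weakly-informative joint prior and the
#' chained-equations settings used throughout the package's validation
#' experiments: 200 cases of \eqn{(x, y, z) \sim N(\mu, \Sigma)} with
#' \eqn{\mu = (1, 4, 9)} and \eqn{\Sigma = ((4,2,2),(2,4,2),(2,2,9))}; prior
#' \eqn{\mu_0 = 0}, \eqn{\tau = 1}, \eqn{m = 3}, \eqn{\Lambda = 60 I}; visit
#' sequence (z, x, y); m = 5 imputations after 10 iterations.
#'
#' @return A list with `n`, `mu`, `Sigma`, `names`, `prior` (a [niw_prior()]),
#'   `visit`, `m`, `n_iter`.
#' @export
simulation_defaults <- function() {
  Sigma <- matrix(c(4, 2, 2,
                    2, 4, 2,
                    2, 2, 9), 3, 3, byrow = TRUE)
  dimnames(Sigma) <- list(c("x", "y", "z"), c("x", "y", "z"))
  list(
    n = 200L,
    mu = c(x = 1, y = 4, z = 9),
    Sigma = Sigma,
    names = c("x", "y", "z"),
    prior = niw_prior(mu0 = c(0, 0, 0), tau = 1, m = 3,
                      Lambda = diag(60, 3)),
    visit = c("z", "x", "y"),
    m = 5L,
    n_iter = 10L
  )
}

#' Generate multivariate normal data
#'
#' @param n number of cases.
#' @param mu mean vector (default: the study population mean).
#' @param Sigma covariance matrix (default: the study population covariance).
#' @param seed optional integer seed.
#' @return an n x p numeric matrix with column names taken from `mu`.
#' @export
generate_mvn <- function(n, mu = simulation_defaults()$mu,
                         Sigma = simulation_defaults()$Sigma, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Sigma <- as.matrix(Sigma)
  check_spd(Sigma, "Sigma")
  p <- length(mu)
  if (n == 0L) {
    out <- matrix(numeric(0), 0L, p)
  } else {
    out <- MASS::mvrnorm(n, mu = mu, Sigma = Sigma)
    if (n == 1L) out <- matrix(out, 1L, p)
  }
  colnames(out) <- names(mu)
  out
}

#' Amputation specification
#'
#' Describes how complete cases are made incomplete: the missingness mechanism,
#' the fraction of cases within each pattern that lose their designated
#' variable, and the one-variable-per-case patterns with their weight vectors
#' over the remaining (observed) variables.
#'
#' @param mechanism `"MCAR"` or `"MARr"` (right-tailed missing at random:
#'   higher weighted scores of the observed variables raise the missingness
#'   probability).
#' @param overall_prop fraction in `[0, 1]` of cases within a pattern whose
#'   designated variable is set missing (0.5 reproduces the fifty-percent
#'   missingness design).
#' @param patterns character vector (or list) naming the variable each pattern
#'   removes; default one pattern per variable.
#' @param pattern_probs pattern assignment probabilities, equal by default.
#' @param mar_slope logistic slope on the standardized score under `"MARr"`.
#' @return An object of class `amputation_spec`.
#' @export
amputation_spec <- function(mechanism = c("MCAR", "MARr"),
                            overall_prop = 0.5,
                            patterns = NULL,
                            pattern_probs = NULL,
                            mar_slope = 1) {
  mechanism <- match.arg(mechanism)
  if (overall_prop < 0 || overall_prop > 1)
    stop("'overall_prop' must lie in [0, 1]")
  if (!is.null(pattern_probs)) {
    if (any(pattern_probs < 0) || abs(sum(pattern_probs) - 1) > 1e-8)
      stop("'pattern_probs' must be non-negative and sum to 1")
  }
  structure(list(mechanism = mechanism, overall_prop = overall_prop,
                 patterns = patterns, pattern_probs = pattern_probs,
                 mar_slope = mar_slope),
            class = "amputation_spec")
}

#' Ampute complete data
#'
#' Each case is assigned to one missing-data pattern (by default one pattern
#' per variable, equal probabilities); within a pattern the designated variable
#' is set missing — under MCAR with probability `overall_prop` independent of
#' the data, under MARr with probability `plogis(a + k s)` where `s` is the
#' standardized unit-weight sum of the pattern's observed variables, `k` the
#' slope and the intercept `a` is solved by bisection so that the expected
#' within-pattern missing fraction equals `overall_prop`. At most one variable
#' is missing per case, so missingness never depends on unobserved values
#' (MAR by construction).
#'
#' @param data complete numeric matrix or data frame.
#' @param spec an [amputation_spec()].
#' @param seed optional integer seed.
#' @return a numeric matrix with `NA` in the amputed cells, an attribute
#'   `"pattern"` giving each case's assigned pattern and a logical attribute
#'   `"amputed"` marking the cases actually made incomplete.
#' @export
ampute <- function(data, spec = amputation_spec(), seed = NULL) {
  stopifnot(inherits(spec, "amputation_spec"))
  if (!is.null(seed)) set.seed(seed)
  X <- as.matrix(data)
  n <- nrow(X)
  p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(p))
  patterns <- spec$patterns
  if (is.null(patterns)) patterns <- colnames(X)
  k <- length(patterns)
  probs <- spec$pattern_probs
  if (is.null(probs)) probs <- rep(1 / k, k)
  pat <- sample.int(k, n, replace = TRUE, prob = probs)
  miss <- rep(FALSE, n)
  for (g in seq_len(k)) {
    rows <- which(pat == g)
    if (length(rows) == 0L) next
    jmis <- match(patterns[[g]], colnames(X))
    if (is.na(jmis)) stop("unknown pattern variable: ", patterns[[g]])
    pr <- if (spec$mechanism == "MCAR" || spec$overall_prop %in% c(0, 1)) {
      rep(spec$overall_prop, length(rows))
    } else {
      score <- rowSums(X[rows, -jmis, drop = FALSE])
      s <- (score - mean(score)) / stats::sd(score)
      eta <- spec$mar_slope * s
      a <- calibrate_intercept(eta, spec$overall_prop)
      stats::plogis(a + eta)
    }
    miss[rows] <- stats::runif(length(rows)) < pr
  }
  for (g in seq_len(k)) {
    rows <- which(pat == g & miss)
    X[rows, match(patterns[[g]], colnames(X))] <- NA_real_
  }
  attr(X, "pattern") <- pat     # assigned pattern, whether amputed or not
  attr(X, "amputed") <- miss
  X
}

# intercept a with mean(plogis(a + eta)) == prop, solved by bisection
calibrate_intercept <- function(eta, prop, tol = 1e-6) {
  f <- function(a) mean(stats::plogis(a + eta)) - prop
  lo <- -20; hi <- 20
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

#' Validate an incomplete data matrix
#'
#' Checks the rectangular numeric values / missingness-mask pair the imputation
#' engines expect: numeric entries and no fully missing column. Returns the
#' data as a numeric matrix with a `"mask"` attribute.
#'
#' @param data numeric matrix or data frame with `NA` for missing cells.
#' @return the validated matrix, with attributes `"mask"` (TRUE = missing) and
#'   per-row pattern labels `"row_pattern"`.
#' @export
incomplete_data <- function(data) {
  X <- as.matrix(data)
  if (is.logical(X) && all(is.na(X))) storage.mode(X) <- "double"
  if (!is.numeric(X)) stop("data must be numeric")
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  mask <- is.na(X)
  if (any(colSums(!mask) == 0L)) stop("a column is fully missing")
  attr(X, "mask") <- mask
  attr(X, "row_pattern") <- apply(mask, 1L, function(r)
    paste(colnames(X)[r], collapse = "+"))
  X
}
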