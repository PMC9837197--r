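# shared fixtures: small SPD matrices and a reproducible toy regression

random_spd <- function(p, jitter = 1) {
  A <- matrix(rnorm(p * p), p)
  crossprod(A) + diag(jitter, p)
}

random_niw <- function(p = 3, convention = "scale_literal") {
  niw_prior(mu0 = rnorm(p), tau = runif(1, 0.5, 2),
            m = p + runif(1, 0, 3), Lambda = random_spd(p),
            convention = convention)
}

toy_regression <- function(n = 20, seed = 421) {
  set.seed(seed)
  x <- rnorm(n)
  y <- 1 + 0.5 * x + rnorm(n, sd = sqrt(2))
  list(y = y, X = cbind(1, x))
}

study <- simulation_defaults()
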