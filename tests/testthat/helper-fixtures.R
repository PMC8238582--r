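# Shared fixtures: all synthetic, generated in code at test time.

# random symmetric positive definite matrix with well-separated spectrum
rand_spd <- function(p, cond = 100) {
  Q <- qr.Q(qr(matrix(rnorm(p * p), p, p)))
  gam <- exp(seq(log(cond), 0, length.out = p))
  Q %*% diag(gam, p) %*% t(Q)
}

# minimal "gamma_mle"-shaped object with a prescribed system, for testing
# the shrinkage filters and selectors on controlled spectra
make_fit_stub <- function(D, beta, phi = 1) {
  es <- eigen_sorted(D)
  structure(list(
    D = D,
    coefficients = beta,
    dispersion = phi,
    eigenvalues = es$values,
    vectors = es$vectors,
    alpha = drop(crossprod(es$vectors, beta)),
    converged = TRUE
  ), class = "gamma_mle")
}

# small gamma regression dataset with known truth
make_gamma_data <- function(n = 40, p = 3, rho = 0.3, phi = 0.5,
                            beta = NULL, intercept = FALSE) {
  X <- sim_design(n, p, rho)
  if (intercept) X <- cbind(1, X)
  if (is.null(beta)) beta <- rep(1 / sqrt(ncol(X)), ncol(X))
  y <- sim_response(X, beta, phi)
  list(y = y, X = X, beta = beta, phi = phi)
}

# sign-symmetric near-flat design: rows come in +/- pairs so that odd
# moments vanish and the asymptotic covariance formulas hold to Monte-Carlo
# precision at moderate n (see the methods vignette)
make_symmetric_design <- function(n_half, p, scale = 0.04) {
  Z <- matrix(rnorm(n_half * p), n_half, p)
  scale * rbind(Z, -Z)
}
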