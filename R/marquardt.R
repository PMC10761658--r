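## Damped least-squares (gradient-expansion / Levenberg-Marquardt-type)
## minimizer shared by the sensitivity calibration fit and the joint
## activity-depth estimator. Minimizes sum(r(theta)^2) for a user-supplied
## residual function; residuals arrive already weighted (divided by sigma),
## so the returned covariance solve(t(J) %*% J) is on the parameter scale.

marquardt <- function(par0, resid_fn, jac_fn, tol = 1e-8, max_iter = 200L,
                      lambda0 = 1e-3) {
  par <- as.numeric(par0)
  p <- length(par)
  r <- resid_fn(par)
  chi2 <- sum(r^2)
  lambda <- lambda0
  converged <- FALSE
  iter <- 0L
  message <- "max iterations reached"
  while (iter < max_iter) {
    iter <- iter + 1L
    J <- jac_fn(par)
    A <- crossprod(J)
    g <- crossprod(J, r)   # gradient of chi2 / 2
    stepped <- FALSE
    ## inner damping loop: inflate lambda until a step reduces chi2
    for (k in 1:60) {
      Adamp <- A + lambda * diag(diag(A), p, p)
      delta <- tryCatch(solve(Adamp, -g), error = function(e) NULL)
      if (is.null(delta)) {
        lambda <- lambda * 10
        next
      }
      cand <- par + as.numeric(delta)
      rc <- resid_fn(cand)
      chi2c <- sum(rc^2)
      if (is.finite(chi2c) && chi2c <= chi2) {
        rel <- max(abs(as.numeric(delta)) / pmax(abs(par), 1e-12))
        par <- cand
        r <- rc
        chi2 <- chi2c
        lambda <- max(lambda / 10, 1e-12)
        stepped <- TRUE
        if (rel < tol) {
          converged <- TRUE
          message <- "relative parameter change below tolerance"
        }
        break
      }
      lambda <- lambda * 10
      if (lambda > 1e14) break
    }
    if (!stepped) {
      ## no downhill step found: treat current iterate as the optimum
      converged <- TRUE
      message <- "no further chi-square reduction possible"
    }
    if (converged) break
  }
  J <- jac_fn(par)
  A <- crossprod(J)
  cov <- tryCatch(solve(A), error = function(e) matrix(NA_real_, p, p))
  list(par = par, chi2 = chi2, converged = converged, n_iterations = iter,
       cov = cov, message = message)
}
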