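## Generalized-inverse-Gaussian random variates.
##
## Density: f(x) propto x^(lambda-1) exp(-(chi/x + psi*x)/2), x > 0.
## The sampler serves the local-shrinkage update of the Gibbs chain, where
## the default prior shape makes lambda = 1/2; that case (and lambda = -1/2)
## reduces to the inverse-Gaussian distribution and is drawn in closed form,
## vectorized. General lambda falls back to Devroye's (2014) rejection
## scheme, scalar.

## Inverse Gaussian IG(mu, shape), Michael-Schucany-Haas; vectorized.
rinvgauss <- function(n, mu, shape) {
  nu <- stats::rnorm(n)
  y <- nu^2
  x <- mu + mu^2 * y / (2 * shape) -
    mu / (2 * shape) * sqrt(4 * mu * shape * y + mu^2 * y^2)
  x <- pmax(x, .Machine$double.xmin)
  u <- stats::runif(n)
  ifelse(u <= mu / (mu + x), x, mu^2 / x)
}

.psi_dev <- function(x, alpha, lam) {
  -alpha * (cosh(x) - 1) - lam * (exp(x) - x - 1)
}
.dpsi_dev <- function(x, alpha, lam) {
  -alpha * sinh(x) - lam * (exp(x) - 1)
}

## Devroye's ratio-of-uniforms sampler for the two-parameter
## GIG(lam, omega, omega), transformed to the three-parameter form.
.rgig_devroye <- function(lambda, chi, psi) {
  omega <- sqrt(chi * psi)
  swap <- lambda < 0
  lam <- abs(lambda)
  alpha <- sqrt(omega^2 + lam^2) - lam

  x <- -.psi_dev(1, alpha, lam)
  t <- if (x >= 0.5 && x <= 2) 1
  else if (x > 2) sqrt(2 / (alpha + lam))
  else log(4 / (alpha + 2 * lam))

  x <- -.psi_dev(-1, alpha, lam)
  s <- if (x >= 0.5 && x <= 2) 1
  else if (x > 2) sqrt(4 / (alpha * cosh(1) + lam))
  else if (alpha == 0) 1 / lam
  else if (lam == 0) log(1 + 1 / alpha + sqrt(1 / alpha^2 + 2 / alpha))
  else min(1 / lam, log(1 + 1 / alpha + sqrt(1 / alpha^2 + 2 / alpha)))

  eta <- -.psi_dev(t, alpha, lam)
  zeta <- -.dpsi_dev(t, alpha, lam)
  theta <- -.psi_dev(-s, alpha, lam)
  xi <- .dpsi_dev(-s, alpha, lam)
  pp <- 1 / xi
  rr <- 1 / zeta
  td <- t - rr * eta
  sd_ <- s - pp * theta
  q <- td + sd_

  repeat {
    U <- stats::runif(1); V <- stats::runif(1); W <- stats::runif(1)
    if (U < q / (pp + q + rr)) {
      rnd <- -sd_ + q * V
    } else if (U < (q + rr) / (pp + q + rr)) {
      rnd <- td - rr * log(V)
    } else {
      rnd <- -sd_ + pp * log(V)
    }
    f <- if (rnd >= -sd_ && rnd <= td) 1
    else if (rnd > td) exp(-eta - zeta * (rnd - t))
    else exp(-theta + xi * (rnd + s))
    if (W * f <= exp(.psi_dev(rnd, alpha, lam))) break
  }
  out <- exp(rnd) * (lam / omega + sqrt(1 + lam^2 / omega^2))
  if (swap) out <- 1 / out
  out / sqrt(psi / chi)
}

#' Generalized-inverse-Gaussian random deviates
#'
#' Draws from \code{f(x) ~ x^(lambda - 1) exp(-(chi/x + psi x)/2)}.
#' \code{chi} and \code{psi} are vectorized (recycled to length \code{n});
#' \code{lambda} is scalar. Boundary cases \code{chi = 0} (gamma, needs
#' \code{lambda > 0}) and \code{psi = 0} (inverse gamma, needs
#' \code{lambda < 0}) are handled in closed form.
#'
#' @param n number of draws.
#' @param lambda shape.
#' @param chi,psi nonnegative rate parameters.
#' @return numeric vector of positive draws.
#' @export
rgig <- function(n, lambda, chi, psi) {
  chi <- rep_len(chi, n)
  psi <- rep_len(psi, n)
  assert_that(all(chi >= 0) && all(psi >= 0), "rgig: negative parameter")
  out <- numeric(n)
  eps <- .Machine$double.eps

  zero_chi <- chi < eps
  if (any(zero_chi)) {
    assert_that(lambda > 0, "rgig: chi = 0 requires lambda > 0")
    out[zero_chi] <- stats::rgamma(sum(zero_chi), shape = lambda,
                                   rate = psi[zero_chi] / 2)
  }
  zero_psi <- !zero_chi & psi < eps
  if (any(zero_psi)) {
    assert_that(lambda < 0, "rgig: psi = 0 requires lambda < 0")
    out[zero_psi] <- chi[zero_psi] /
      (2 * stats::rgamma(sum(zero_psi), shape = -lambda, rate = 1))
  }
  rest <- !zero_chi & !zero_psi
  if (any(rest)) {
    if (abs(abs(lambda) - 0.5) < 1e-12) {
      k <- sum(rest)
      if (lambda > 0) {
        ## X ~ GIG(1/2, chi, psi)  <=>  1/X ~ IG(sqrt(psi/chi), psi)
        y <- rinvgauss(k, sqrt(psi[rest] / chi[rest]), psi[rest])
        out[rest] <- 1 / y
      } else {
        out[rest] <- rinvgauss(k, sqrt(chi[rest] / psi[rest]), chi[rest])
      }
    } else {
      idx <- which(rest)
      for (i in idx) {
        out[i] <- .rgig_devroye(lambda, chi[i], psi[i])
      }
    }
  }
  out
}
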