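#' The Generalized Extreme Value distribution
#'
#' Density, distribution function, quantile function and random generation
#' for the generalized extreme value (GEV) distribution with location
#' `mu`, scale `sigma` (> 0) and shape `xi`. The density is
#' \deqn{G(x) = \frac{1}{\sigma}\, t^{\xi+1} e^{-t}, \qquad
#'   t = \left(1 + \xi \frac{x-\mu}{\sigma}\right)^{-1/\xi},}
#' with the Gumbel limit \eqn{t = e^{-(x-\mu)/\sigma}} taken when
#' \eqn{|\xi|} is below a small numerical threshold. The support is the
#' set where \eqn{1 + \xi (x-\mu)/\sigma > 0}; the density is 0 (and the
#' cdf 0 or 1) outside it.
#'
#' Used throughout the package to model axon- and outer-fiber-diameter
#' populations, whose long right tails this family captures with the
#' shape ("tailedness") parameter `xi`.
#'
#' @param x,q vector of quantiles (diameters, in µm in typical use).
#' @param p vector of probabilities.
#' @param n number of draws.
#' @param mu location parameter.
#' @param sigma scale parameter, > 0.
#' @param xi shape parameter.
#' @param log,log.p logical; if TRUE, probabilities/densities are
#'   returned on the log scale.
#' @return `dgev` the density, `pgev` the cdf, `qgev` the quantile
#'   function, `rgev` random draws (by inversion, reproducible under
#'   `set.seed`).
#' @examples
#' integrate(dgev, -2, 20, mu = 0.5, sigma = 0.15, xi = 0.2)
#' qgev(pgev(1, 0.5, 0.15, 0.1), 0.5, 0.15, 0.1)
#' @name gev
NULL

.gev_eps <- 1e-8

check_gev_params <- function(mu, sigma, xi) {
  if (!is.finite(mu) || !is.finite(sigma) || !is.finite(xi))
    stop_domain("GEV parameters must be finite")
  if (sigma <= 0) stop_domain("GEV scale parameter sigma must be > 0")
}

#' @rdname gev
#' @export
dgev <- function(x, mu, sigma, xi, log = FALSE) {
  check_gev_params(mu, sigma, xi)
  z <- (x - mu) / sigma
  if (abs(xi) < .gev_eps) {
    logd <- -log(sigma) - z - exp(-z)
  } else {
    s <- 1 + xi * z
    logd <- rep(-Inf, length(z))
    ok <- s > 0
    logd[ok] <- -log(sigma) - (1 + 1 / xi) * log(s[ok]) - s[ok]^(-1 / xi)
  }
  if (log) logd else exp(logd)
}

#' @rdname gev
#' @export
pgev <- function(q, mu, sigma, xi, log.p = FALSE) {
  check_gev_params(mu, sigma, xi)
  z <- (q - mu) / sigma
  if (abs(xi) < .gev_eps) {
    logp <- -exp(-z)
  } else {
    s <- pmax(1 + xi * z, 0)
    logp <- -s^(-1 / xi)  # s = 0: xi>0 -> -Inf (p=0); xi<0 -> 0 (p=1)
  }
  if (log.p) logp else exp(logp)
}

#' @rdname gev
#' @export
qgev <- function(p, mu, sigma, xi) {
  check_gev_params(mu, sigma, xi)
  if (any(p < 0 | p > 1)) stop_domain("probabilities must be in [0, 1]")
  if (abs(xi) < .gev_eps) {
    mu - sigma * log(-log(p))
  } else {
    mu + sigma * ((-log(p))^(-xi) - 1) / xi
  }
}

#' @rdname gev
#' @export
rgev <- function(n, mu, sigma, xi) {
  check_gev_params(mu, sigma, xi)
  qgev(stats::runif(n), mu, sigma, xi)
}

#' GEV moments and mode
#'
#' Closed-form mean, variance and mode of the GEV distribution. The mean
#' exists for `xi < 1`, the variance for `xi < 1/2`; `Inf` is returned
#' otherwise.
#'
#' @inheritParams gev
#' @return a numeric scalar.
#' @examples
#' gev_mean(0.5, 0.15, 0.1)  # mu + sigma * (gamma(1 - xi) - 1) / xi
#' @export
gev_mean <- function(mu, sigma, xi) {
  check_gev_params(mu, sigma, xi)
  if (xi >= 1) return(Inf)
  if (abs(xi) < .gev_eps) return(mu + sigma * 0.5772156649015329)
  mu + sigma * (gamma(1 - xi) - 1) / xi
}

#' @rdname gev_mean
#' @export
gev_var <- function(mu, sigma, xi) {
  check_gev_params(mu, sigma, xi)
  if (xi >= 0.5) return(Inf)
  if (abs(xi) < .gev_eps) return(sigma^2 * pi^2 / 6)
  g1 <- gamma(1 - xi); g2 <- gamma(1 - 2 * xi)
  sigma^2 * (g2 - g1^2) / xi^2
}

#' @rdname gev_mean
#' @export
gev_mode <- function(mu, sigma, xi) {
  check_gev_params(mu, sigma, xi)
  if (abs(xi) < .gev_eps) return(mu)
  mu + sigma * ((1 + xi)^(-xi) - 1) / xi
}
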