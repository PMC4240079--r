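## Candidate distribution families for NFC fitting.
##
## Each family is a list with:
##   label     display name
##   positive  TRUE if support is (0, Inf) (zeros dropped before fitting)
##   npar      parameter count
##   fit(x)    either NULL (no closed form) or list(params, loglik)
##   start(x)  moment-based start on the unconstrained scale
##   untrans(p)  unconstrained -> named natural parameters
##   logdens(x, params)  log density at natural parameters
##
## Numeric MLE maximizes sum(logdens) over the unconstrained scale with
## Nelder-Mead; scale/shape parameters are log-transformed so the search is
## unconstrained.

mle_sigma <- function(x) sqrt(mean((x - mean(x))^2))

.fam_lognormal <- list(
  label = "log-normal", positive = TRUE, npar = 2,
  fit = function(x) {
    lx <- log(x)
    mu <- mean(lx); sigma <- mle_sigma(lx)
    if (sigma <= 0) return(NULL)  # degenerate sample, boundary MLE
    p <- c(mu = mu, sigma = sigma)
    list(params = p, loglik = sum(stats::dlnorm(x, mu, sigma, log = TRUE)))
  },
  logdens = function(x, p) stats::dlnorm(x, p[["mu"]], p[["sigma"]], log = TRUE)
)

.fam_normal <- list(
  label = "normal", positive = FALSE, npar = 2,
  fit = function(x) {
    mu <- mean(x); sigma <- mle_sigma(x)
    if (sigma <= 0) return(NULL)
    p <- c(mu = mu, sigma = sigma)
    list(params = p, loglik = sum(stats::dnorm(x, mu, sigma, log = TRUE)))
  },
  logdens = function(x, p) stats::dnorm(x, p[["mu"]], p[["sigma"]], log = TRUE)
)

.fam_rayleigh <- list(
  label = "Rayleigh", positive = TRUE, npar = 1,
  fit = function(x) {
    s <- sqrt(mean(x^2) / 2)
    p <- c(sigma = s)
    ll <- sum(log(x) - 2 * log(s) - x^2 / (2 * s^2))
    list(params = p, loglik = ll)
  },
  logdens = function(x, p) {
    s <- p[["sigma"]]
    log(x) - 2 * log(s) - x^2 / (2 * s^2)
  }
)

.fam_invgauss <- list(
  label = "inverse Gaussian", positive = TRUE, npar = 2,
  fit = function(x) {
    mu <- mean(x)
    d <- mean(1 / x - 1 / mu)
    if (d <= 0) return(NULL)
    lambda <- 1 / d
    p <- c(mu = mu, lambda = lambda)
    ll <- sum(0.5 * (log(lambda) - log(2 * pi) - 3 * log(x)) -
                lambda * (x - mu)^2 / (2 * mu^2 * x))
    list(params = p, loglik = ll)
  },
  logdens = function(x, p) {
    0.5 * (log(p[["lambda"]]) - log(2 * pi) - 3 * log(x)) -
      p[["lambda"]] * (x - p[["mu"]])^2 / (2 * p[["mu"]]^2 * x)
  }
)

.fam_logistic <- list(
  label = "logistic", positive = FALSE, npar = 2, fit = NULL,
  start = function(x) c(mean(x), log(max(sd(x) * sqrt(3) / pi, 1e-8))),
  untrans = function(q) c(location = q[1], scale = exp(q[2])),
  logdens = function(x, p)
    stats::dlogis(x, p[["location"]], p[["scale"]], log = TRUE)
)

.fam_loglogistic <- list(
  label = "log-logistic", positive = TRUE, npar = 2, fit = NULL,
  start = function(x) {
    lx <- log(x)
    c(mean(lx), log(max(sd(lx) * sqrt(3) / pi, 1e-8)))
  },
  untrans = function(q) c(location = q[1], scale = exp(q[2])),
  # logistic density of log(x), Jacobian 1/x
  logdens = function(x, p)
    stats::dlogis(log(x), p[["location"]], p[["scale"]], log = TRUE) - log(x)
)

# minimum-type Gumbel ("extreme value" in the engineering convention)
.fam_ev <- list(
  label = "extreme value", positive = FALSE, npar = 2, fit = NULL,
  start = function(x) {
    s <- max(sd(x) * sqrt(6) / pi, 1e-8)
    c(mean(x) + 0.5772156649 * s, log(s))
  },
  untrans = function(q) c(location = q[1], scale = exp(q[2])),
  logdens = function(x, p) {
    z <- (x - p[["location"]]) / p[["scale"]]
    z - exp(z) - log(p[["scale"]])
  }
)

.fam_gev <- list(
  label = "generalized extreme value", positive = FALSE, npar = 3, fit = NULL,
  start = function(x) {
    s <- max(sd(x) * sqrt(6) / pi, 1e-8)
    c(mean(x) - 0.5772156649 * s, log(s), 0.1)
  },
  untrans = function(q) c(location = q[1], scale = exp(q[2]), shape = q[3]),
  logdens = function(x, p) {
    z <- (x - p[["location"]]) / p[["scale"]]
    xi <- p[["shape"]]
    if (abs(xi) < 1e-8) return(-z - exp(-z) - log(p[["scale"]]))
    t <- 1 + xi * z
    out <- rep(-Inf, length(x))
    ok <- t > 0
    out[ok] <- -log(p[["scale"]]) - (1 + 1 / xi) * log(t[ok]) - t[ok]^(-1 / xi)
    out
  }
)

.fam_bisa <- list(
  label = "Birnbaum-Saunders", positive = TRUE, npar = 2, fit = NULL,
  start = function(x) {
    mx <- mean(x); hx <- 1 / mean(1 / x)
    a0 <- sqrt(2 * max(sqrt(mx / hx) - 1, 1e-4))
    c(log(a0), log(sqrt(mx * hx)))
  },
  untrans = function(q) c(shape = exp(q[1]), scale = exp(q[2])),
  logdens = function(x, p) {
    s <- sqrt(x / p[["scale"]])
    xi <- (s - 1 / s) / p[["shape"]]
    log(s + 1 / s) - log(2 * p[["shape"]] * x) + stats::dnorm(xi, log = TRUE)
  }
)

.fam_nakagami <- list(
  label = "Nakagami", positive = TRUE, npar = 2, fit = NULL,
  start = function(x) {
    x2 <- x^2
    omega0 <- mean(x2)
    m0 <- omega0^2 / max(var(x2), 1e-12)
    c(log(min(max(m0, 0.1), 100)), log(omega0))
  },
  untrans = function(q) c(shape = exp(q[1]), spread = exp(q[2])),
  logdens = function(x, p) {
    m <- p[["shape"]]; om <- p[["spread"]]
    log(2) + m * log(m) - lgamma(m) - m * log(om) +
      (2 * m - 1) * log(x) - m * x^2 / om
  }
)

.fam_rician <- list(
  label = "Rician", positive = TRUE, npar = 2, fit = NULL,
  start = function(x) {
    s2 <- max(var(x) / 2, 1e-8)
    nu0 <- sqrt(max(mean(x^2) - 2 * s2, 1e-4))
    c(log(nu0), log(sqrt(s2)))
  },
  untrans = function(q) c(noncentrality = exp(q[1]), sigma = exp(q[2])),
  logdens = function(x, p) {
    nu <- p[["noncentrality"]]; s2 <- p[["sigma"]]^2
    z <- x * nu / s2
    log(x) - log(s2) - (x^2 + nu^2) / (2 * s2) +
      log(besselI(z, 0, expon.scaled = TRUE)) + z
  }
)

.fam_tls <- list(
  label = "t location-scale", positive = FALSE, npar = 3, fit = NULL,
  start = function(x) c(median(x), log(max(sd(x) * 0.8, 1e-8)), log(5)),
  untrans = function(q) c(location = q[1], scale = exp(q[2]), df = exp(q[3])),
  logdens = function(x, p)
    stats::dt((x - p[["location"]]) / p[["scale"]], df = p[["df"]],
              log = TRUE) - log(p[["scale"]])
)

# Beta on samples scaled into (0,1) by 1/M, M slightly above max(x);
# the log-likelihood carries the Jacobian -n*log(M) so it is comparable
# with the unscaled families.
.fam_beta <- list(
  label = "Beta", positive = TRUE, npar = 2, fit = NULL, scaled = TRUE,
  start = function(y) {
    m <- mean(y); v <- max(var(y), 1e-12)
    k <- max(m * (1 - m) / v - 1, 0.1)
    c(log(m * k), log((1 - m) * k))
  },
  untrans = function(q) c(shape1 = exp(q[1]), shape2 = exp(q[2])),
  logdens = function(y, p)
    stats::dbeta(y, p[["shape1"]], p[["shape2"]], log = TRUE)
)

#' Candidate distribution families for NFC fitting
#'
#' The thirteen named families considered when characterizing a codon's NFC
#' distribution: Beta, Birnbaum-Saunders, extreme value, generalized extreme
#' value, inverse Gaussian, logistic, log-logistic, log-normal, Nakagami,
#' normal, Rayleigh, Rician, and t location-scale. The registry is an
#' ordinary named list, so additional families can be registered by supplying
#' an entry with the same fields (see the package source for the contract).
#'
#' @return named list of family definitions
#' @export
nfc_families <- function() {
  list(
    beta = .fam_beta,
    bisa = .fam_bisa,
    ev = .fam_ev,
    gev = .fam_gev,
    invgauss = .fam_invgauss,
    logistic = .fam_logistic,
    loglogistic = .fam_loglogistic,
    lognormal = .fam_lognormal,
    nakagami = .fam_nakagami,
    normal = .fam_normal,
    rayleigh = .fam_rayleigh,
    rician = .fam_rician,
    tls = .fam_tls
  )
}
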