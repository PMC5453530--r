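## Degree distributions: empirical CCDF, and maximum-likelihood fitting of
## the discrete exponentially truncated power law
##   p(d) = d^(-alpha) * exp(-d / d_c) / C(alpha, d_c, d_min),  d >= d_min,
## the degree model typical of large social-proximity networks (power-law
## body with an exponential cutoff at d_c).

#' Empirical degree CCDF
#'
#' `P(d)` is the fraction of nodes with degree greater than or equal to
#' `d`, evaluated on the distinct observed degrees.
#'
#' @param degrees non-empty multiset of non-negative integer degrees.
#' @return `data.frame` with columns `d` (ascending distinct degrees), `p`
#'   (fraction equal to `d`) and `P` (fraction `>= d`).
#' @export
degree_ccdf <- function(degrees) {
  if (!length(degrees)) svcn_abort("parameter_error", "no degrees supplied")
  if (any(degrees < 0) || any(degrees != trunc(degrees))) {
    svcn_abort("parameter_error", "degrees must be non-negative integers")
  }
  tab <- table(degrees)
  d <- as.integer(names(tab))
  p <- as.numeric(tab) / length(degrees)
  P <- rev(cumsum(rev(p)))
  data.frame(d = d, p = p, P = P)
}

# ---- truncated power-law model ---------------------------------------------

## Normalizing constant C(alpha, lambda, d_min) = sum_{d>=d_min} d^-alpha
## e^{-lambda d}. Direct summation; when lambda is (near) zero the heavy
## tail is finished off with a midpoint-rule integral, whose relative error
## at the hand-off point (1e5) is far below 1e-9.
tpl_log_norm <- function(alpha, lambda, d_min, d_sum_max = 100000L) {
  d <- seq.int(d_min, d_sum_max)
  logf <- -alpha * log(d) - lambda * d
  keep <- logf > max(logf) - 745  # drop exact underflows
  s <- logsumexp(logf[keep])
  last <- logf[length(logf)]
  if (last > s + log(1e-16)) {
    if (lambda == 0 && alpha <= 1) {
      svcn_abort("parameter_error",
                 "pure power law requires alpha > 1 to normalize")
    }
    ## midpoint-rule tail: sum_{d > D} f(d) ~ int_{D+1/2}^inf f(x) dx,
    ## relative error ~ alpha(alpha+1)/(24 D^2) — negligible at D = 1e5
    lo <- d_sum_max + 0.5
    tail <- if (lambda == 0) {
      lo^(1 - alpha) / (alpha - 1)
    } else {
      ## substitute u = log x for a well-behaved finite-range integrand
      u_hi <- log(750 / lambda)
      if (u_hi <= log(lo)) 0 else
        stats::integrate(function(u) exp((1 - alpha) * u - lambda * exp(u)),
                         log(lo), u_hi, rel.tol = 1e-10)$value
    }
    if (tail > 0) s <- logsumexp(c(s, log(tail)))
  }
  s
}

#' Truncated power-law probability mass function
#'
#' @param d integer degrees `>= d_min`.
#' @param alpha power-law exponent (> 0).
#' @param d_c exponential cutoff degree (> 0; `Inf` gives the pure power
#'   law, which then requires `alpha > 1`).
#' @param d_min lower support bound (integer >= 1).
#' @return `p(d)`; zero outside the support.
#' @export
tpl_pmf <- function(d, alpha, d_c, d_min = 1L) {
  lambda <- if (is.infinite(d_c)) 0 else 1 / d_c
  check_tpl_params(alpha, lambda, d_min)
  logC <- tpl_log_norm(alpha, lambda, d_min)
  out <- numeric(length(d))
  ok <- d >= d_min & d == trunc(d)
  out[ok] <- exp(-alpha * log(d[ok]) - lambda * d[ok] - logC)
  out
}

check_tpl_params <- function(alpha, lambda, d_min) {
  if (!is.numeric(alpha) || alpha <= 0 || !is.finite(alpha)) {
    svcn_abort("parameter_error", "alpha must be positive")
  }
  if (!is.numeric(lambda) || lambda < 0 || !is.finite(lambda)) {
    svcn_abort("parameter_error", "1/d_c must be finite and >= 0")
  }
  if (!is_count(d_min) || d_min < 1) {
    svcn_abort("parameter_error", "d_min must be an integer >= 1")
  }
  if (lambda == 0 && alpha <= 1) {
    svcn_abort("parameter_error",
               "pure power law requires alpha > 1 to normalize")
  }
  invisible(TRUE)
}

#' Fit a discrete exponentially truncated power law by maximum likelihood
#'
#' Maximizes `sum log p(d)` over `(alpha, lambda = 1/d_c)` with `lambda`
#' constrained to `[0, inf)`; the boundary `lambda = 0` is the pure
#' discrete power law. Optimization is a bounded quasi-Newton search from
#' five dispersed starting points; the best optimum is returned.
#'
#' @param degrees integer degrees; only values `>= d_min` enter the fit.
#' @param d_min lower support bound (default 1).
#' @param min_n minimum tail sample size required (default 50).
#' @return a `tpl_fit`: list with `alpha`, `d_c`, `lambda`, `d_min`,
#'   `loglik`, `n_tail`, `convergence` (0 = converged).
#' @export
fit_truncated_power_law <- function(degrees, d_min = 1L, min_n = 50L) {
  if (!is_count(d_min) || d_min < 1) {
    svcn_abort("parameter_error", "d_min must be an integer >= 1")
  }
  d <- degrees[degrees >= d_min]
  n <- length(d)
  if (n < min_n) {
    svcn_abort("fit_error",
               sprintf("only %d observations with degree >= %d (need >= %d)",
                       n, d_min, min_n))
  }
  slogd <- sum(log(d))
  sd_ <- sum(d)
  negll <- function(par) {
    alpha <- par[1L]; lambda <- par[2L]
    if (alpha <= 0 || lambda < 0) return(1e18)
    if (lambda == 0 && alpha <= 1) return(1e18)
    n * tpl_log_norm(alpha, lambda, d_min) + alpha * slogd + lambda * sd_
  }
  mean_d <- mean(d)
  starts <- list(c(1.0, 1 / (10 * mean_d)),
                 c(1.5, 1 / mean_d),
                 c(0.5, 1 / (2 * mean_d)),
                 c(2.5, 1e-6),
                 c(1.1, 1 / (50 * mean_d)))
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      stats::optim(st, negll, method = "L-BFGS-B",
                   lower = c(1e-3, 0), upper = c(25, 5),
                   control = list(factr = 10)),  # ~1e-8 relative on loglik
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    svcn_abort("fit_error",
               "truncated power-law fit failed from all starting points")
  }
  alpha <- best$par[1L]
  lambda <- best$par[2L]
  structure(list(alpha = alpha,
                 lambda = lambda,
                 d_c = if (lambda > 0) 1 / lambda else Inf,
                 d_min = as.integer(d_min),
                 loglik = -best$value,
                 n_tail = n,
                 convergence = best$convergence),
            class = "tpl_fit")
}

#' @export
print.tpl_fit <- function(x, ...) {
  cat(sprintf(
    "<tpl_fit> alpha=%.4f, d_c=%s, d_min=%d, n=%d, loglik=%.2f\n",
    x$alpha,
    if (is.finite(x$d_c)) sprintf("%.2f", x$d_c) else "Inf (pure power law)",
    x$d_min, x$n_tail, x$loglik))
  invisible(x)
}

#' Log-likelihood of degrees under a truncated power law
#' @param degrees integer degrees (all must be `>= d_min`).
#' @param alpha,d_c,d_min model parameters, see [tpl_pmf()].
#' @return total log-likelihood.
#' @export
tpl_loglik <- function(degrees, alpha, d_c, d_min = 1L) {
  lambda <- if (is.infinite(d_c)) 0 else 1 / d_c
  check_tpl_params(alpha, lambda, d_min)
  if (any(degrees < d_min)) {
    svcn_abort("parameter_error", "all degrees must be >= d_min")
  }
  n <- length(degrees)
  -n * tpl_log_norm(alpha, lambda, d_min) -
    alpha * sum(log(degrees)) - lambda * sum(degrees)
}

#' Sample from the discrete truncated power law
#'
#' Exact inverse-CDF sampling: the pmf table is extended until the
#' remaining tail mass is below 1e-10 of the total.
#'
#' @param n number of draws.
#' @param alpha,d_c,d_min model parameters, see [tpl_pmf()].
#' @param seed integer seed (same seed, same sample).
#' @return integer vector of `n` degrees, all `>= d_min`.
#' @export
sample_truncated_power_law <- function(n, alpha, d_c, d_min = 1L,
                                       seed = 1L) {
  lambda <- if (is.infinite(d_c)) 0 else 1 / d_c
  check_tpl_params(alpha, lambda, d_min)
  if (!is_count(n) || n < 1) {
    svcn_abort("parameter_error", "n must be a positive integer")
  }
  logC <- tpl_log_norm(alpha, lambda, d_min)
  d_hi <- d_min + 1000L
  repeat {
    d <- seq.int(d_min, d_hi)
    pm <- exp(-alpha * log(d) - lambda * d - logC)
    if (1 - sum(pm) < 1e-10 || d_hi >= 2e6) break
    d_hi <- d_hi * 4L
  }
  cum <- cumsum(pm)
  cum[length(cum)] <- max(cum[length(cum)], 1)  # absorb residual tail mass
  withr_seed(seed, {
    u <- runif(n)
    d[findInterval(u, cum, left.open = TRUE) + 1L]
  })
}

#' Analytic mean of the truncated power law
#' @param alpha,d_c,d_min model parameters; the mean requires `alpha > 2`
#'   when `d_c` is infinite.
#' @return `sum(d * p(d))` over the support.
#' @export
tpl_mean <- function(alpha, d_c, d_min = 1L) {
  lambda <- if (is.infinite(d_c)) 0 else 1 / d_c
  check_tpl_params(alpha, lambda, d_min)
  if (lambda == 0 && alpha <= 2) {
    svcn_abort("parameter_error",
               "mean of the pure power law requires alpha > 2")
  }
  # sum d^{1-alpha} e^{-lambda d} / C  ==  C(alpha-1) / C(alpha) with the
  # same machinery, valid because tpl_log_norm only needs its exponent > 1
  # at lambda = 0
  exp(tpl_log_norm(alpha - 1, lambda, d_min) -
        tpl_log_norm(alpha, lambda, d_min))
}
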