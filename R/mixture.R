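#' Tail probability of a mixture of chi-squared variables
#'
#' Upper-tail probability P(Q > q) for Q = sum_j lambda_j * chisq_1,
#' the null distribution of a variance-component score statistic. The
#' default evaluates Imhof's exact inversion of the characteristic
#' function by adaptive quadrature; if the quadrature fails, or returns a
#' value outside (0, 1), the Liu-Tang-Zhang moment-matching approximation
#' (matching skewness where possible, else kurtosis, via a non-central
#' chi-squared surrogate) is used instead. The returned p is clamped to
#' \[1e-300, 1\] so downstream log/reciprocal transforms stay finite.
#'
#' @param q observed statistic (non-negative scalar).
#' @param lambdas non-negative mixture weights; at least one must be
#'   positive.
#' @param acc absolute accuracy requested from the quadrature.
#' @param method `"imhof"` (exact inversion with Liu fallback) or `"liu"`.
#' @return p-value in \[1e-300, 1\].
#' @export
mixture_chisq_pvalue <- function(q, lambdas, acc = 1e-9,
                                 method = c("imhof", "liu")) {
  method <- match.arg(method)
  if (any(lambdas < 0)) stop("negative mixture weight")
  lambdas <- lambdas[lambdas > 0]
  if (length(lambdas) == 0L) stop("at least one positive mixture weight required")
  if (!is.finite(q)) stop("non-finite statistic")
  if (q <= 0) return(1)
  if (length(lambdas) == 1L) {
    return(clamp_p(stats::pchisq(q / lambdas, df = 1, lower.tail = FALSE)))
  }
  if (method == "liu") return(clamp_p(liu_pvalue(q, lambdas)))
  p <- imhof_pvalue(q, lambdas, acc)
  if (is.na(p) || p <= 0 || p >= 1) p <- liu_pvalue(q, lambdas)
  clamp_p(p)
}

clamp_p <- function(p) min(max(p, 1e-300), 1)

# Numerical inversion of the characteristic function (Imhof's integral
# evaluated by a Davies-style midpoint sum):
#   P(Q > q) = 1/2 + (1/pi) int_0^inf sin(theta(u)) / (u * rho(u)) du,
#   theta(u) = (sum_j atan(lambda_j u) - q u) / 2,
#   rho(u)   = prod_j (1 + lambda_j^2 u^2)^(1/4).
# The integral is summed at midpoints u_j = (j - 1/2) * delta. By Poisson
# summation the aliasing error of the discretization is the mixture mass
# beyond q + 2*pi/delta, so delta is chosen to push that mass below acc
# (assessed with the Liu tail). Truncation stops once the remaining tail
# is below acc by either of two bounds on the decreasing envelope
# 1/(u * rho(u)): direct integration of the power-law envelope, or the
# alternating-series bound envelope * half-period (the phase derivative
# approaches -q/2, so successive half-periods of length 2*pi/q cancel).
imhof_pvalue <- function(q, lambdas, acc = 1e-9) {
  k <- length(lambdas)
  mu <- sum(lambdas)
  sd <- sqrt(2 * sum(lambdas^2))
  s <- 16
  while (s < 256 && liu_pvalue(q + mu + s * sd, lambdas) > acc / 10) {
    s <- s * 2
  }
  delta <- 2 * pi / (q + mu + s * sd)
  lam2 <- lambdas^2
  total <- 0
  j0 <- 0L
  chunk <- 1024L
  max_terms <- 6e6
  repeat {
    u <- (j0 + seq_len(chunk) - 0.5) * delta
    th <- 0.5 * (colSums(atan(lambdas %o% u)) - q * u)
    lr <- 0.25 * colSums(log1p(lam2 %o% (u^2)))
    total <- total + sum(sin(th) * exp(-lr) / u)
    j0 <- j0 + chunk
    U <- j0 * delta
    env <- exp(-0.25 * sum(log1p(lam2 * U^2))) / U
    tail_bound <- min(env * U * (2 / k), 2 * env / q) / pi
    if (tail_bound < acc) break
    if (j0 >= max_terms) return(NA_real_)  # caller falls back to Liu
    chunk <- min(chunk * 2L, 65536L)
  }
  0.5 + total * delta / pi
}

# Liu-Tang-Zhang (2009) moment matching, modified to match kurtosis when
# the skewness condition fails (as in common SKAT implementations).
liu_params <- function(lambdas) {
  c1 <- sum(lambdas); c2 <- sum(lambdas^2)
  c3 <- sum(lambdas^3); c4 <- sum(lambdas^4)
  s1 <- c3 / c2^1.5
  s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    d <- s1 * a^3 - a^2
    l <- a^2 - 2 * d
  } else {
    l <- 1 / s2
    d <- 0
  }
  list(mu_q = c1, sigma_q = sqrt(2 * c2), l = l, d = d,
       mu_x = l + d, sigma_x = sqrt(2) * sqrt(l + 2 * d))
}

liu_pvalue <- function(q, lambdas) {
  pp <- liu_params(lambdas)
  tstar <- (q - pp$mu_q) / pp$sigma_q
  x <- tstar * pp$sigma_x + pp$mu_x
  stats::pchisq(x, df = pp$l, ncp = pp$d, lower.tail = FALSE)
}

liu_cdf <- function(q, lambdas) {
  # vectorized in q; lower-tail companion used by the grid search in
  # optimal_combine
  pp <- liu_params(lambdas)
  x <- (q - pp$mu_q) / pp$sigma_q * pp$sigma_x + pp$mu_x
  stats::pchisq(x, df = pp$l, ncp = pp$d)
}

# Upper-tail quantile: smallest q with P(Q > q) = p. Liu start, refined by
# root finding on the Imhof tail so grid quantiles in optimal_combine are
# calibrated.
mixture_chisq_quantile <- function(p, lambdas, refine = TRUE) {
  lambdas <- lambdas[lambdas > 0]
  if (length(lambdas) == 1L) {
    return(lambdas * stats::qchisq(p, df = 1, lower.tail = FALSE))
  }
  pp <- liu_params(lambdas)
  x <- stats::qchisq(p, df = pp$l, ncp = pp$d, lower.tail = FALSE)
  q0 <- (x - pp$mu_x) / pp$sigma_x * pp$sigma_q + pp$mu_q
  q0 <- max(q0, 1e-12)
  if (!refine) return(q0)
  f <- function(q) imhof_pvalue(q, lambdas) - p
  lo <- q0 / 2; hi <- q0 * 2
  flo <- f(lo); fhi <- f(hi)
  tries <- 0
  while (flo < 0 && tries < 30) { lo <- lo / 2; flo <- f(lo); tries <- tries + 1 }
  while (fhi > 0 && tries < 60) { hi <- hi * 2; fhi <- f(hi); tries <- tries + 1 }
  if (is.na(flo) || is.na(fhi) || flo < 0 || fhi > 0) return(q0)
  stats::uniroot(f, c(lo, hi), tol = 1e-8 * q0)$root
}
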