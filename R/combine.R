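#' Fisher's combination of the two independent component p-values
#'
#' Because the burden and variance-component statistics are decorrelated,
#' their p-values are independent under the joint null and
#' F = -2(log p_theta + log p_tau) is chi-squared with 4 degrees of
#' freedom.
#'
#' @param p_theta,p_tau component p-values in (0, 1\]; exact zeros are
#'   clamped to 1e-300 with a warning.
#' @return combined p-value.
#' @export
fisher_combine <- function(p_theta, p_tau) {
  p <- clamp_inputs(c(p_theta, p_tau))
  f <- -2 * sum(log(p))
  stats::pchisq(f, df = 4, lower.tail = FALSE)
}

#' Adaptively weighted combination of the component p-values
#'
#' Takes the smaller of the two component p-values and corrects for the
#' implicit selection: p = 1 - (1 - min)^2, the Sidak-adjusted minimum,
#' which is exact when the components are independent.
#'
#' @inheritParams fisher_combine
#' @return combined p-value.
#' @export
adaptive_combine <- function(p_theta, p_tau) {
  p <- clamp_inputs(c(p_theta, p_tau))
  pm <- min(p)
  pm * (2 - pm)  # 1 - (1 - pm)^2 without cancellation for tiny pm
}

clamp_inputs <- function(p, floor = 1e-300) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  if (any(p == 0)) {
    warning("p-value of 0 clamped to ", floor)
    p[p == 0] <- floor
  }
  p
}

#' Optimally weighted combination of the two score statistics
#'
#' Grid search over T_rho = rho * S_theta + (1 - rho) * Q_tau for rho in
#' `rho_grid`. Under the joint null S_theta is chi-squared(1) and Q_tau is
#' the mixture sum_j lambda_j chisq_1, independent of S_theta by the
#' decorrelation construction, so each T_rho is itself a chi-squared
#' mixture with weights (rho, (1 - rho) lambda). The overall p-value of
#' the minimum grid p-value is computed exactly by one-dimensional
#' integration over the chi-squared(1) component: conditioning on
#' S_theta = s, the event "all grid statistics below their level-p_min
#' quantiles" requires s < q_1 and Q_tau < min over rho < 1 of
#' (q_rho - rho s) / (1 - rho).
#'
#' @param s_theta_stat observed burden statistic.
#' @param q_tau_stat observed variance-component statistic.
#' @param lambdas mixture weights of Q_tau's null distribution.
#' @param rho_grid grid of weights in \[0, 1\] (default 0, 0.1, ..., 1).
#' @param nodes number of Gauss-Legendre nodes for the outer integral.
#' @return combined p-value; with an empty or all-zero `lambdas` the
#'   burden p-value is returned.
#' @export
optimal_combine <- function(s_theta_stat, q_tau_stat, lambdas,
                            rho_grid = seq(0, 1, by = 0.1), nodes = 512L) {
  lambdas <- lambdas[lambdas > 0]
  if (length(lambdas) == 0L) {
    return(stats::pchisq(s_theta_stat, df = 1, lower.tail = FALSE))
  }
  p_rho <- vapply(rho_grid, function(rho) {
    tstat <- rho * s_theta_stat + (1 - rho) * q_tau_stat
    w <- c(rho, (1 - rho) * lambdas)
    mixture_chisq_pvalue(tstat, w[w > 0])
  }, numeric(1))
  p_min <- min(p_rho)
  if (p_min >= 1) return(1)

  # level-p_min upper quantiles of every grid statistic
  q_rho <- vapply(rho_grid, function(rho) {
    if (rho == 1) return(stats::qchisq(p_min, df = 1, lower.tail = FALSE))
    w <- c(rho, (1 - rho) * lambdas)
    mixture_chisq_quantile(p_min, w[w > 0], refine = FALSE)
  }, numeric(1))

  inner <- rho_grid < 1
  rho_i <- rho_grid[inner]
  q_i <- q_rho[inner]
  if (length(rho_i) == 0L) return(p_min)  # grid is {1}: the chi2_1 point
  q1 <- if (any(rho_grid == 1)) q_rho[rho_grid == 1] else Inf

  # integrate over s = z^2 with z half-normal to avoid the density
  # singularity at s = 0
  zmax <- if (is.finite(q1)) sqrt(q1) else 8.5
  gl <- gauss_legendre(nodes, 0, zmax)
  s_vals <- gl$x^2
  bound <- vapply(s_vals, function(s) {
    min((q_i - rho_i * s) / (1 - rho_i))
  }, numeric(1))
  cdf_q <- numeric(length(bound))
  pos <- bound > 0
  if (any(pos)) cdf_q[pos] <- liu_cdf(bound[pos], lambdas)
  cdf_q[cdf_q < 0] <- 0; cdf_q[cdf_q > 1] <- 1
  p_none <- sum(gl$w * 2 * stats::dnorm(gl$x) * cdf_q)
  p <- 1 - p_none
  # guard against quadrature noise: result can never beat the raw minimum
  min(max(p, p_min), 1)
}

.gl_cache <- new.env(parent = emptyenv())

gauss_legendre <- function(n, a, b) {
  # Golub-Welsch: nodes/weights from the Jacobi matrix eigendecomposition,
  # cached per n on the reference interval [-1, 1]
  key <- as.character(n)
  if (is.null(.gl_cache[[key]])) {
    i <- seq_len(n - 1)
    beta <- i / sqrt(4 * i^2 - 1)
    J <- matrix(0, n, n)
    J[cbind(i, i + 1)] <- beta
    J[cbind(i + 1, i)] <- beta
    es <- eigen(J, symmetric = TRUE)
    .gl_cache[[key]] <- list(x = es$values, w = 2 * es$vectors[1, ]^2)
  }
  ref <- .gl_cache[[key]]
  list(x = (b - a) / 2 * ref$x + (a + b) / 2, w = (b - a) / 2 * ref$w)
}

#' Upper-tail probability of the Landau distribution
#'
#' Pr(Landau(mu, sigma) > x) in the standard location-scale convention
#' whose tail satisfies Pr(X > x) ~ (2/pi) * sigma / x. Evaluated by
#' quadrature of exact integral representations of the Landau law: for the
#' bulk and left tail a Gil-Pelaez inversion of the characteristic
#' function, and for the right tail a rescaled direct tail integral that
#' remains accurate arbitrarily far out. The result is monotone
#' non-increasing in x.
#'
#' @param x evaluation point (finite scalar).
#' @param mu location parameter.
#' @param sigma scale parameter (> 0).
#' @return tail probability in \[0, 1\].
#' @export
landau_tail <- function(x, mu = 0, sigma = 1) {
  if (!is.finite(x)) stop("non-finite x")
  if (sigma <= 0) stop("sigma must be positive")
  z <- (x - mu) / sigma
  # mass below z = -3.5 is < 1e-13
  if (z < -3.5) return(1)
  v <- pi / 2 * z + log(pi / 2)  # classic Landau-form coordinate
  if (v > 1) {
    # tail(v) = (1/pi) int_0^inf exp(-t log t - v t) sin(pi t) / t dt,
    # computed with s = v t so the effective support is O(1) for any v
    f <- function(s) {
      exp(-(s / v) * (log(s) - log(v)) - s) * sin(pi * s / v) / s
    }
    val <- stats::integrate(f, 0, Inf, rel.tol = 1e-12, abs.tol = 1e-12,
                            subdivisions = 1000L)$value / pi
    return(min(max(val, 0), 1))
  }
  # Gil-Pelaez on the characteristic function exp(-t - i (2t/pi) log t):
  # F(z) = 1/2 + (1/pi) int_0^inf exp(-t) sin(t z + (2t/pi) log t) / t dt
  f <- function(t) {
    out <- exp(-t) * sin(t * z + (2 * t / pi) * log(t)) / t
    out[t == 0] <- 0
    out
  }
  val <- stats::integrate(f, 0, Inf, rel.tol = 1e-12, abs.tol = 1e-12,
                          subdivisions = 2000L)$value
  min(max(0.5 - val / pi, 0), 1)
}

#' Harmonic mean p-value
#'
#' Combines L (possibly dependent) p-values through their weighted
#' harmonic mean and calibrates the reciprocal against the Landau
#' distribution with location log(L) + 0.874 and scale pi/2, which is the
#' asymptotically exact null law of the reciprocal harmonic mean of
#' uniform p-values. Inputs are floored at 1e-10 before taking
#' reciprocals, with a warning, to avoid overflow.
#'
#' @param p_values vector of p-values in (0, 1\], length L >= 1.
#' @param weights non-negative weights summing to 1 (default equal).
#' @param location `"log_L"` (default, calibrated) or `"log_T"`, which
#'   replaces log(L) by log of the harmonic mean statistic itself.
#' @return combined p-value in \[0, 1\]; for L = 1 the input is returned.
#' @export
hmp_combine <- function(p_values, weights = NULL,
                        location = c("log_L", "log_T")) {
  location <- match.arg(location)
  L <- length(p_values)
  if (L < 1L) stop("need at least one p-value")
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  if (any(p_values < 1e-10)) {
    warning("p-value(s) below 1e-10 floored before harmonic mean")
    p_values <- pmax(p_values, 1e-10)
  }
  if (is.null(weights)) weights <- rep(1 / L, L)
  if (any(weights < 0)) stop("weights must be non-negative")
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  if (L == 1L) return(p_values)
  hm <- 1 / sum(weights / p_values)
  loc <- if (location == "log_L") log(L) + 0.874 else log(hm) + 0.874
  p <- landau_tail(1 / hm, mu = loc, sigma = pi / 2)
  min(max(p, 0), 1)
}

#' Joint transfer-learning eGene test for one gene
#'
#' Orchestrates the full per-gene procedure: fit the decorrelated pair of
#' score tests, combine them by the optimally weighted, adaptively
#' weighted and Fisher combinations, aggregate the three combined
#' p-values with the harmonic mean p-value, and also report the plain
#' variance-component score test (no transfer) for comparison.
#'
#' When gamma is identically zero, or the burden is collinear with the
#' covariates, the theta p-value is missing and all combined tests reduce
#' to the plain score test.
#'
#' @param e numeric n-vector of expression values for the gene.
#' @param X n x p covariate design including the intercept.
#' @param G n x m harmonized dosage matrix of the gene's cis-SNPs.
#' @param gamma m-vector of harmonized auxiliary effects.
#' @param rho_grid grid for [optimal_combine()].
#' @return object of class `tlegene_result`: list with `p_score`,
#'   `p_theta`, `p_tau`, `p_oscore`, `p_ascore`, `p_fscore`, `p_hmp`,
#'   `m` (number of variants), `degenerate`, and `pair` (the underlying
#'   [decorrelated_pair()]).
#' @export
tlegene_test <- function(e, X, G, gamma, rho_grid = seq(0, 1, by = 0.1)) {
  X <- as.matrix(X); G <- as.matrix(G)
  pair <- decorrelated_pair(e, X, G, gamma)
  p_score <- if (pair$degenerate) {
    pair$q_tau$p_value
  } else {
    vc_score_test(pair$null_theta, G)$p_value
  }
  if (pair$degenerate) {
    out <- list(p_score = p_score, p_theta = NA_real_, p_tau = p_score,
                p_oscore = p_score, p_ascore = p_score, p_fscore = p_score,
                p_hmp = p_score, m = ncol(G), degenerate = TRUE, pair = pair)
  } else {
    p_theta <- pair$s_theta$p_value
    p_tau <- pair$q_tau$p_value
    p_f <- fisher_combine(p_theta, p_tau)
    p_a <- adaptive_combine(p_theta, p_tau)
    p_o <- optimal_combine(pair$s_theta$statistic, pair$q_tau$statistic,
                           pair$q_tau$df_or_lambdas, rho_grid = rho_grid)
    p_h <- hmp_combine(c(p_o, p_a, p_f))
    out <- list(p_score = p_score, p_theta = p_theta, p_tau = p_tau,
                p_oscore = p_o, p_ascore = p_a, p_fscore = p_f,
                p_hmp = p_h, m = ncol(G), degenerate = FALSE, pair = pair)
  }
  class(out) <- "tlegene_result"
  out
}

#' @export
print.tlegene_result <- function(x, ...) {
  cat("tlegene_test on", x$m, "variants",
      if (x$degenerate) "(degenerate burden; all joint tests = Score)\n" else "\n")
  p <- unlist(x[c("p_score", "p_theta", "p_tau", "p_oscore", "p_ascore",
                  "p_fscore", "p_hmp")])
  print(signif(p, 4))
  invisible(x)
}
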