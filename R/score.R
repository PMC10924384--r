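#' Fit the null regression model
#'
#' Least-squares fit of expression on the fixed-effect design, with the
#' residual variance estimated by the unbiased divisor n - p. This is the
#' null model under which both the burden and the variance-component score
#' statistics are formed.
#'
#' @param e numeric n-vector of expression values for one gene.
#' @param X n x p design matrix including an intercept column.
#' @return object of class `null_model`: list with `design`, `qr`,
#'   `alpha_hat`, `residuals`, `sigma2_hat`, `n`, `p`, `df_resid`.
#' @export
fit_null_model <- function(e, X) {
  X <- as.matrix(X)
  e <- as.numeric(e)
  n <- length(e); p <- ncol(X)
  if (nrow(X) != n) stop("design rows do not match expression length")
  if (n <= p) stop("need more samples than design columns")
  qx <- qr(X)
  if (qx$rank < p) {
    drop_cols <- setdiff(seq_len(p), qx$pivot[seq_len(qx$rank)])
    nm <- colnames(X)
    nm <- if (is.null(nm)) paste0("column ", drop_cols) else nm[drop_cols]
    stop("design matrix is rank deficient; collinear: ",
         paste(nm, collapse = ", "))
  }
  alpha <- qr.coef(qx, e)
  r <- qr.resid(qx, e)
  rss <- sum(r^2)
  sigma2 <- rss / (n - p)
  if (sigma2 <= 1e-12 * max(stats::var(e), .Machine$double.eps)) {
    stop("degenerate fit: expression lies in the span of the design")
  }
  structure(
    list(design = X, qr = qx, alpha_hat = alpha, residuals = r,
         sigma2_hat = sigma2, n = n, p = p, df_resid = n - p),
    class = "null_model"
  )
}

#' @export
print.null_model <- function(x, ...) {
  cat("null_model: n =", x$n, ", p =", x$p,
      ", sigma2_hat =", format(x$sigma2_hat, digits = 4), "\n")
  invisible(x)
}

score_result <- function(statistic, p_value, df_or_lambdas, method) {
  structure(list(statistic = statistic, p_value = p_value,
                 df_or_lambdas = df_or_lambdas, method = method),
            class = "score_result")
}

#' @export
print.score_result <- function(x, ...) {
  cat(x$method, ": statistic =", format(x$statistic, digits = 4),
      ", p =", format(x$p_value, digits = 4), "\n")
  invisible(x)
}

degenerate_burden_condition <- function(msg) {
  structure(class = c("tlegene_degenerate_burden", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

#' Burden (fixed-effect) score test
#'
#' Score test for the coefficient of a single burden vector s added to the
#' null design: S = (s'r)^2 / (sigma2_hat * s'P0 s), where r are the null
#' residuals and P0 the projection off the design. Under the null S is
#' chi-squared with 1 degree of freedom; S equals the squared z-statistic
#' of s's coefficient in the refitted regression.
#'
#' @param null a [fit_null_model()] object.
#' @param s numeric n-vector (the weighted genetic score G gamma).
#' @return `score_result` with `df_or_lambdas = "chi2_1"`. Signals a
#'   condition of class `tlegene_degenerate_burden` if s is (numerically)
#'   inside the span of the design, e.g. when gamma is identically zero.
#' @export
burden_score_test <- function(null, s) {
  stopifnot(inherits(null, "null_model"))
  s <- as.numeric(s)
  if (length(s) != null$n) stop("burden vector length does not match model")
  ps <- qr.resid(null$qr, s)
  den <- sum(ps^2)
  if (den <= 1e-12 * max(sum(s^2), 1)) {
    stop(degenerate_burden_condition(
      "burden vector is collinear with the null design (degenerate burden)"))
  }
  num <- sum(ps * null$residuals)
  stat <- num^2 / (null$sigma2_hat * den)
  score_result(stat, stats::pchisq(stat, df = 1, lower.tail = FALSE),
               "chi2_1", "burden")
}

#' Variance-component score test
#'
#' SKAT-style score test of H0: tau = 0 for the random-effect model
#' e = X alpha + G b + eps with b ~ N(0, tau). The statistic is
#' Q = r'G G'r; its null distribution is the mixture
#' sum_j lambda_j chisq_1 with lambda_j = sigma2_hat times the eigenvalues
#' of G'P0 G (P0 from the null model's own design). Eigenvalues below
#' 1e-10 times the largest are truncated to zero to handle
#' LD-collinear genotype columns.
#'
#' @param null a [fit_null_model()] object (its design defines P0).
#' @param G n x m dosage matrix.
#' @return `score_result` with the retained eigenvalues in
#'   `df_or_lambdas`. If G lies entirely in the span of the design the
#'   statistic is 0 and p = 1.
#' @export
vc_score_test <- function(null, G) {
  stopifnot(inherits(null, "null_model"))
  G <- as.matrix(G)
  if (nrow(G) != null$n) stop("genotype rows do not match model")
  if (ncol(G) < 1L) stop("need at least one variant")
  pg <- qr.resid(null$qr, G)
  K <- crossprod(pg)
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  # rank handling: relative truncation for LD-collinear columns, plus an
  # absolute guard against G lying entirely in the design span
  ev[ev < 1e-10 * max(ev, 0)] <- 0
  if (max(ev, 0) <= 1e-12 * max(colSums(G^2), 1)) ev[] <- 0
  lam <- null$sigma2_hat * ev
  qstat <- sum(crossprod(G, null$residuals)^2)
  if (all(lam <= 0)) {
    return(score_result(0, 1, numeric(0), "vc_score"))
  }
  p <- mixture_chisq_pvalue(qstat, lam)
  score_result(qstat, p, lam[lam > 0], "vc_score")
}

#' Decorrelated burden and variance-component score tests
#'
#' The joint null is theta = 0 and tau = 0 for the transfer model
#' e = X alpha + (G gamma) theta + G b + eps. The burden statistic for
#' theta is computed under the full null; the variance-component statistic
#' for tau is computed under the null of only tau = 0, i.e. with the
#' burden vector G gamma entering the fixed design. Including the burden
#' in the tau-test's design renders the two statistics asymptotically
#' independent, so they can be combined directly.
#'
#' When gamma is identically zero (or G gamma is collinear with X) the
#' burden test is degenerate: the theta p-value is reported as missing
#' and the tau test falls back to the plain variance-component test under
#' design X.
#'
#' @param e numeric n-vector of expression values.
#' @param X n x p covariate design including the intercept.
#' @param G n x m dosage matrix.
#' @param gamma m-vector of harmonized auxiliary effects.
#' @return object of class `decorrelated_pair`: list with `s_theta`
#'   (`score_result` or NULL when degenerate), `q_tau`, `degenerate`
#'   (logical), and `null_theta`/`null_tau` models.
#' @export
decorrelated_pair <- function(e, X, G, gamma) {
  X <- as.matrix(X); G <- as.matrix(G)
  if (length(gamma) != ncol(G)) stop("gamma length does not match variants")
  null0 <- fit_null_model(e, X)
  s <- as.numeric(G %*% gamma)
  s_theta <- tryCatch(burden_score_test(null0, s),
                      tlegene_degenerate_burden = function(c) NULL)
  if (is.null(s_theta)) {
    q_tau <- vc_score_test(null0, G)
    out <- list(s_theta = NULL, q_tau = q_tau, degenerate = TRUE,
                null_theta = null0, null_tau = null0)
  } else {
    Xs <- cbind(X, burden = s)
    null1 <- fit_null_model(e, Xs)
    q_tau <- vc_score_test(null1, G)
    out <- list(s_theta = s_theta, q_tau = q_tau, degenerate = FALSE,
                null_theta = null0, null_tau = null1)
  }
  class(out) <- "decorrelated_pair"
  out
}

#' @export
print.decorrelated_pair <- function(x, ...) {
  if (x$degenerate) {
    cat("decorrelated_pair (degenerate burden; theta test missing)\n")
  } else {
    cat("decorrelated_pair:\n  S_theta =",
        format(x$s_theta$statistic, digits = 4), "(p =",
        format(x$s_theta$p_value, digits = 4), ")\n")
  }
  cat("  Q_tau =", format(x$q_tau$statistic, digits = 4), "(p =",
      format(x$q_tau$p_value, digits = 4), ")\n")
  invisible(x)
}
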