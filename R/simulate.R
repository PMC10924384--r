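#' Simulation configuration
#'
#' Full parameterization of one simulation scenario: an auxiliary eQTL
#' study whose per-SNP marginal effect estimates are transferred into a
#' target study where the true effects are beta = gamma * theta + b with
#' b ~ N(0, tau). Defaults reproduce the main study conditions: 300 target
#' and 165 auxiliary individuals, the number of cis-SNPs m uniform on
#' 20..50, 30% of SNPs null in the auxiliary study, auxiliary PVE 0.3,
#' one binary and one continuous covariate each with effect 0.50,
#' AR(1) linkage disequilibrium with correlation 0.5 and MAFs uniform on
#' (0.05, 0.5).
#'
#' @param n_target,n_aux sample sizes of the target and auxiliary studies.
#' @param m_range inclusive integer range for the number of cis-SNPs.
#' @param prop_null fraction of SNPs with zero auxiliary effect.
#' @param pve_aux fraction of auxiliary expression variance explained by
#'   the SNPs (relative to SNPs + residual noise).
#' @param theta indirect (transferred) effect of the auxiliary study.
#' @param tau variance of the direct target effects b.
#' @param covariate_effects effects of the binary and continuous covariate.
#' @param maf_range range of the uniform MAF distribution.
#' @param ld_rho AR(1) correlation of the latent Gaussian copula in \[0,1).
#' @param seed integer master seed.
#' @return object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(n_target = 300, n_aux = 165,
                              m_range = c(20, 50), prop_null = 0.3,
                              pve_aux = 0.3, theta = 0, tau = 0,
                              covariate_effects = c(0.5, 0.5),
                              maf_range = c(0.05, 0.5), ld_rho = 0.5,
                              seed = 1L) {
  stopifnot(n_target > 0, n_aux > 0,
            length(m_range) == 2, m_range[1] >= 1, m_range[1] <= m_range[2],
            prop_null >= 0, prop_null <= 1,
            pve_aux >= 0, pve_aux < 1,
            tau >= 0,
            length(covariate_effects) == 2,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            ld_rho >= 0, ld_rho < 1)
  if (pve_aux == 0 && prop_null < 1) {
    stop("pve_aux = 0 requires prop_null = 1 (non-null SNPs must explain variance)")
  }
  structure(
    list(n_target = n_target, n_aux = n_aux, m_range = as.integer(m_range),
         prop_null = prop_null, pve_aux = pve_aux, theta = theta, tau = tau,
         covariate_effects = covariate_effects, maf_range = maf_range,
         ld_rho = ld_rho, seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Simulate LD-structured genotypes
#'
#' Gaussian-copula model: each haplotype draws a latent m-vector from
#' N(0, Sigma) with Sigma_jk = ld_rho^|j-k|, carries the minor allele where
#' the latent value falls below the MAF quantile, and the dosage is the sum
#' of two independent haplotypes. Dosages are therefore in {0, 1, 2} with
#' per-column allele frequency maf_j and AR(1)-decaying LD.
#'
#' @param n number of samples.
#' @param m number of variants.
#' @param mafs m-vector of minor allele frequencies in (0, 0.5\].
#' @param ld_rho AR(1) correlation of the latent copula.
#' @param seed optional integer seed; the draw is deterministic given it.
#' @param chrom,pos_start metadata for the generated variant table.
#' @return a [genotype_matrix()] with variants `snp_1..snp_m`.
#' @export
simulate_genotypes <- function(n, m, mafs, ld_rho = 0.5, seed = NULL,
                               chrom = "1", pos_start = 1e6) {
  stopifnot(length(mafs) == m, all(mafs > 0), all(mafs <= 0.5),
            ld_rho >= 0, ld_rho < 1)
  if (!is.null(seed)) set.seed(seed)
  U <- chol(ld_rho^abs(outer(seq_len(m), seq_len(m), "-")))
  thr <- stats::qnorm(mafs)
  hap <- function() {
    z <- matrix(stats::rnorm(n * m), n, m) %*% U
    sweep(z, 2, thr, "<") + 0
  }
  dos <- hap() + hap()
  variants <- data.frame(
    id = paste0("snp_", seq_len(m)), chrom = chrom,
    pos = as.integer(pos_start + (seq_len(m) - 1L) * 1000L),
    effect_allele = "A", other_allele = "G", stringsAsFactors = FALSE
  )
  genotype_matrix(dos, variants, paste0("sample_", seq_len(n)))
}

#' Per-SNP marginal effect estimates
#'
#' j-th entry is the coefficient of G_j in the regression of e on
#' \[X, G_j\], computed for all SNPs at once by first projecting e and G
#' off X (Frisch-Waugh-Lovell). Columns collinear with X (including
#' monomorphic SNPs) yield a missing entry.
#'
#' @param e numeric n-vector of expression values.
#' @param G n x m dosage matrix.
#' @param X n x p covariate design including the intercept.
#' @return m-vector of marginal effect estimates (NA where degenerate).
#' @export
estimate_marginal_effects <- function(e, G, X) {
  G <- as.matrix(G); X <- as.matrix(X)
  qx <- qr(X)
  er <- qr.resid(qx, as.numeric(e))
  gr <- qr.resid(qx, G)
  den <- colSums(gr^2)
  est <- colSums(gr * er) / den
  est[den <= 1e-10 * pmax(colSums(G^2), 1)] <- NA_real_
  est
}

#' Simulate one auxiliary + target study pair
#'
#' Draws m ~ Uniform{m_range}, MAFs and LD-structured genotypes for both
#' studies from the same variant panel; assigns auxiliary effects gamma
#' (a `prop_null` fraction exactly zero, the rest normal, rescaled so the
#' genetic share of the auxiliary expression variance equals `pve_aux`
#' against unit residual noise); generates auxiliary expression, estimates
#' the per-SNP marginal effects `gamma_hat` used for transfer; and builds
#' the target expression with true effects beta = gamma * theta + b,
#' b ~ N(0, tau), unit residual noise, and the two covariates (binary and
#' standard normal, effects 0.50 each) in both studies.
#'
#' @param cfg a [simulation_config()].
#' @param seed optional seed overriding `cfg$seed`.
#' @return object of class `simulated_study`: list with `auxiliary` and
#'   `target` (each `G` [genotype_matrix()], `e`, `X` without intercept),
#'   `true_gamma`, `true_beta`, `gamma_hat`, `m`, `config`.
#' @export
simulate_study <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(if (is.null(seed)) cfg$seed else seed)
  m <- sample(cfg$m_range[1]:cfg$m_range[2], 1L)
  mafs <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])

  g_aux <- simulate_genotypes(cfg$n_aux, m, mafs, cfg$ld_rho)
  g_tgt <- simulate_genotypes(cfg$n_target, m, mafs, cfg$ld_rho)

  n_null <- round(cfg$prop_null * m)
  gamma <- numeric(m)
  if (n_null < m) {
    idx <- sample.int(m, m - n_null)
    gamma[idx] <- stats::rnorm(m - n_null)
    gvar <- stats::var(as.numeric(g_aux$dosages %*% gamma))
    if (gvar > 0 && cfg$pve_aux > 0) {
      # genetic variance v_g with v_g / (v_g + 1) = pve against unit noise
      gamma <- gamma * sqrt(cfg$pve_aux / (1 - cfg$pve_aux) / gvar)
    } else if (cfg$pve_aux > 0) {
      gamma[] <- 0
    }
  }

  make_x <- function(n) {
    cbind(x1 = stats::rbinom(n, 1, 0.5), x2 = stats::rnorm(n))
  }
  x_aux <- make_x(cfg$n_aux)
  e_aux <- as.numeric(x_aux %*% cfg$covariate_effects +
                        g_aux$dosages %*% gamma + stats::rnorm(cfg$n_aux))
  gamma_hat <- estimate_marginal_effects(e_aux, g_aux$dosages,
                                         cbind(1, x_aux))

  b <- stats::rnorm(m, 0, sqrt(cfg$tau))
  beta <- gamma * cfg$theta + b
  x_tgt <- make_x(cfg$n_target)
  e_tgt <- as.numeric(x_tgt %*% cfg$covariate_effects +
                        g_tgt$dosages %*% beta + stats::rnorm(cfg$n_target))

  structure(
    list(auxiliary = list(G = g_aux, e = e_aux, X = x_aux),
         target = list(G = g_tgt, e = e_tgt, X = x_tgt),
         true_gamma = gamma, true_beta = beta, gamma_hat = gamma_hat,
         m = m, config = cfg),
    class = "simulated_study"
  )
}

run_replicates <- function(cfg, reps, seed = cfg$seed) {
  # master seed spawns one substream seed per replicate
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, reps)
  tests <- c("score", "theta", "tau", "oscore", "ascore", "fscore", "hmp")
  pmat <- matrix(NA_real_, reps, length(tests),
                 dimnames = list(NULL, tests))
  stats <- matrix(NA_real_, reps, 2, dimnames = list(NULL, c("s_theta", "q_tau")))
  for (i in seq_len(reps)) {
    study <- simulate_study(cfg, seed = rep_seeds[i])
    gh <- study$gamma_hat
    gh[is.na(gh)] <- 0
    X <- cbind(1, study$target$X)
    res <- tlegene_test(study$target$e, X, study$target$G$dosages, gh)
    pmat[i, ] <- c(res$p_score, res$p_theta, res$p_tau, res$p_oscore,
                   res$p_ascore, res$p_fscore, res$p_hmp)
    if (!res$degenerate) {
      stats[i, ] <- c(res$pair$s_theta$statistic, res$pair$q_tau$statistic)
    }
  }
  list(pvalues = pmat, statistics = stats, rep_seeds = rep_seeds)
}

#' Empirical type I error of all tests
#'
#' Runs `reps` replicates of the scenario with theta = 0 and tau = 0 and
#' reports, for each test, the fraction of replicates with p <= alpha,
#' together with QQ-plot data (-log10 expected vs observed quantiles) and
#' the raw p-values and component statistics. Bit-reproducible for a
#' given (config, seed).
#'
#' @param cfg a [simulation_config()]; theta and tau must be 0.
#' @param reps number of replicates (>= 1000 recommended).
#' @param alpha significance level(s) at which size is evaluated.
#' @param seed master seed (defaults to `cfg$seed`).
#' @return list of class `type1_evaluation`: `sizes` (data.frame test x
#'   alpha), `pvalues`, `statistics` (S_theta, Q_tau per replicate),
#'   `qq` (long data.frame), `reps`, `seed`.
#' @export
evaluate_type1 <- function(cfg, reps = 5000, alpha = 0.05,
                           seed = cfg$seed) {
  stopifnot(inherits(cfg, "simulation_config"), reps >= 1)
  if (cfg$theta != 0 || cfg$tau != 0) {
    stop("type I error evaluation requires theta = 0 and tau = 0")
  }
  run <- run_replicates(cfg, reps, seed)
  sizes <- do.call(rbind, lapply(colnames(run$pvalues), function(t) {
    data.frame(test = t,
               alpha = alpha,
               size = vapply(alpha, function(a) {
                 mean(run$pvalues[, t] <= a, na.rm = TRUE)
               }, numeric(1)),
               stringsAsFactors = FALSE)
  }))
  qq <- do.call(rbind, lapply(colnames(run$pvalues), function(t) {
    p <- sort(run$pvalues[, t])
    n <- length(p)
    data.frame(test = t,
               expected = -log10(stats::ppoints(n)),
               observed = -log10(p),
               stringsAsFactors = FALSE)
  }))
  structure(list(sizes = sizes, pvalues = run$pvalues,
                 statistics = run$statistics, qq = qq, reps = reps,
                 seed = seed),
            class = "type1_evaluation")
}

#' Empirical power of all tests over a (theta, tau) grid
#'
#' Runs `reps` replicates per grid cell (cells with theta = tau = 0 are
#' skipped) and reports rejection rates at level `alpha` for each test.
#'
#' @param cfg a [simulation_config()] providing every setting other than
#'   theta and tau.
#' @param theta_grid,tau_grid parameter values to cross.
#' @param reps replicates per cell.
#' @param alpha significance level.
#' @param seed master seed (a distinct substream per cell).
#' @return data.frame with columns `theta`, `tau`, `test`, `power`,
#'   `reps`.
#' @export
evaluate_power <- function(cfg, theta_grid = c(0, 0.1, 0.2, 0.3, 0.4),
                           tau_grid = c(0, 0.02, 0.04), reps = 1000,
                           alpha = 0.05, seed = cfg$seed) {
  stopifnot(inherits(cfg, "simulation_config"))
  grid <- expand.grid(theta = theta_grid, tau = tau_grid)
  grid <- grid[!(grid$theta == 0 & grid$tau == 0), , drop = FALSE]
  set.seed(seed)
  cell_seeds <- sample.int(.Machine$integer.max - 1L, nrow(grid))
  out <- vector("list", nrow(grid))
  for (k in seq_len(nrow(grid))) {
    cfg_k <- cfg
    cfg_k$theta <- grid$theta[k]
    cfg_k$tau <- grid$tau[k]
    run <- run_replicates(cfg_k, reps, cell_seeds[k])
    out[[k]] <- data.frame(
      theta = grid$theta[k], tau = grid$tau[k],
      test = colnames(run$pvalues),
      power = colMeans(run$pvalues <= alpha, na.rm = TRUE),
      reps = reps, stringsAsFactors = FALSE, row.names = NULL
    )
  }
  do.call(rbind, out)
}
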