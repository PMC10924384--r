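#' Adjust p-values for multiple testing
#'
#' Bonferroni (min(1, m p)) or Benjamini-Hochberg step-up, with m the
#' number of non-missing p-values; missing entries are passed through.
#'
#' @param ps vector of p-values in \[0, 1\] (NAs allowed).
#' @param method `"bonferroni"` or `"bh"`.
#' @return adjusted p-values in input order.
#' @export
adjust_pvalues <- function(ps, method = c("bonferroni", "bh")) {
  method <- match.arg(method)
  if (any(ps < 0 | ps > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(ps, method = if (method == "bh") "BH" else "bonferroni",
                  n = sum(!is.na(ps)))
}

#' Per-gene transfer-learning eGene scan
#'
#' Harmonizes the genotypes with the auxiliary effects, intersects samples
#' across inputs, and for each annotated gene extracts the cis-SNPs and
#' runs [tlegene_test()] (plus the plain variance-component score test).
#' Bonferroni and Benjamini-Hochberg adjustment is applied across genes to
#' every p-value column; genes whose auxiliary effects are all zero after
#' harmonization fall back to the score test and are annotated.
#'
#' @param genotypes a QC'd [genotype_matrix()].
#' @param expression genes x samples matrix (row names = gene ids).
#' @param covariates samples x p numeric matrix (row names = sample ids);
#'   an intercept is added internally.
#' @param aux an [aux_effects()] table.
#' @param annotation gene annotation data.frame from
#'   [read_gene_annotation()].
#' @param window cis-window in bp on each side of the gene body.
#' @param sig_level significance level for the eGene flags.
#' @return data.frame with one row per annotated gene (annotation order):
#'   `gene_id`, `m_snps`, `p_theta`, `p_tau`, `p_score`, `p_oscore`,
#'   `p_ascore`, `p_fscore`, `p_hmp`, a `reason` column for genes that
#'   could not be tested or were degenerate, and per-test `*_bonf_sig` /
#'   `*_fdr_sig` flags. The harmonization report is attached as attribute
#'   `harmonization`.
#' @export
scan_genes <- function(genotypes, expression, covariates, aux, annotation,
                       window = 1e6, sig_level = 0.05) {
  harm <- harmonize(genotypes, aux)
  if (nrow(harm$aux) == 0L) stop("empty SNP overlap between target and auxiliary")
  al <- align_samples(harm$genotypes, expression, covariates)
  X <- cbind(intercept = 1, al$covariates)
  gamma_all <- harm$gamma

  rows <- lapply(seq_len(nrow(annotation)), function(i) {
    gene <- annotation[i, ]
    row <- data.frame(gene_id = gene$gene_id, m_snps = 0L,
                      p_theta = NA_real_, p_tau = NA_real_,
                      p_score = NA_real_, p_oscore = NA_real_,
                      p_ascore = NA_real_, p_fscore = NA_real_,
                      p_hmp = NA_real_, reason = NA_character_,
                      stringsAsFactors = FALSE)
    if (!(gene$gene_id %in% rownames(al$expression))) {
      row$reason <- "no_expression"
      return(row)
    }
    cis <- extract_cis(al$genotypes, gene, window)
    if (nrow(cis$variants) == 0L) {
      row$reason <- "no_cis_snps"
      return(row)
    }
    idx <- match(cis$variants$id, al$genotypes$variants$id)
    gam <- gamma_all[idx]
    e <- as.numeric(al$expression[gene$gene_id, ])
    res <- tlegene_test(e, X, cis$dosages, gam)
    row$m_snps <- res$m
    row$p_theta <- res$p_theta; row$p_tau <- res$p_tau
    row$p_score <- res$p_score; row$p_oscore <- res$p_oscore
    row$p_ascore <- res$p_ascore; row$p_fscore <- res$p_fscore
    row$p_hmp <- res$p_hmp
    if (res$degenerate) row$reason <- "degenerate_burden"
    row
  })
  tab <- do.call(rbind, rows)
  for (t in c("score", "oscore", "ascore", "fscore", "hmp")) {
    p <- tab[[paste0("p_", t)]]
    tab[[paste0(t, "_bonf_sig")]] <- adjust_pvalues(p, "bonferroni") < sig_level
    tab[[paste0(t, "_fdr_sig")]] <- adjust_pvalues(p, "bh") < sig_level
  }
  attr(tab, "harmonization") <- harm$report
  tab
}

#' Traditional single-SNP eGene scan
#'
#' For each gene, regresses expression on each cis-SNP separately
#' (adjusting for the covariates), takes the minimum single-SNP p-value,
#' and Bonferroni-corrects it within the gene by the number of cis-SNPs.
#' An eGene is declared when the corrected p-value is below `sig_level`.
#'
#' @inheritParams scan_genes
#' @return data.frame per gene: `gene_id`, `m_snps`, `min_p`, `p_bonf`,
#'   `egene` (logical), `top_snp`, `reason`.
#' @export
traditional_scan <- function(genotypes, expression, covariates, annotation,
                             window = 1e6, sig_level = 0.05) {
  al <- align_samples(genotypes, expression, covariates)
  X <- cbind(intercept = 1, al$covariates)
  qx <- qr(X)
  n <- length(al$samples)
  df <- n - ncol(X) - 1L
  rows <- lapply(seq_len(nrow(annotation)), function(i) {
    gene <- annotation[i, ]
    row <- data.frame(gene_id = gene$gene_id, m_snps = 0L,
                      min_p = NA_real_, p_bonf = NA_real_, egene = NA,
                      top_snp = NA_character_, reason = NA_character_,
                      stringsAsFactors = FALSE)
    if (!(gene$gene_id %in% rownames(al$expression))) {
      row$reason <- "no_expression"
      return(row)
    }
    cis <- extract_cis(al$genotypes, gene, window)
    m <- nrow(cis$variants)
    if (m == 0L) {
      row$reason <- "no_cis_snps"
      return(row)
    }
    e <- as.numeric(al$expression[gene$gene_id, ])
    er <- qr.resid(qx, e)
    gr <- qr.resid(qx, cis$dosages)
    den <- colSums(gr^2)
    ok <- den > 1e-10 * pmax(colSums(cis$dosages^2), 1)
    slope <- colSums(gr * er) / den
    rss <- sum(er^2) - slope^2 * den
    se <- sqrt(pmax(rss, 0) / df / den)
    p <- 2 * stats::pt(abs(slope / se), df = df, lower.tail = FALSE)
    p[!ok] <- NA_real_
    if (all(is.na(p))) {
      row$reason <- "all_snps_degenerate"
      return(row)
    }
    row$m_snps <- m
    j <- which.min(p)
    row$min_p <- p[j]
    row$p_bonf <- min(1, m * p[j])
    row$egene <- row$p_bonf < sig_level
    row$top_snp <- cis$variants$id[j]
    row
  })
  do.call(rbind, rows)
}

#' Per-gene correlation of target and auxiliary SNP effects
#'
#' For each gene with at least `min_snps` SNPs, regresses the target
#' marginal SNP effects on the auxiliary effects (with intercept) and
#' reports the slope, its p-value and the coefficient of determination;
#' slope p-values are Benjamini-Hochberg adjusted across genes. The
#' summary attribute reports the fraction of genes with FDR < 0.05 and the
#' fraction with R^2 > 0.10.
#'
#' @param effects data.frame with columns `gene_id`, `beta_target`,
#'   `gamma_aux`, one row per SNP.
#' @param min_snps minimum SNPs per gene (genes below are skipped).
#' @param sig_level FDR level for the significance flag and summary.
#' @return data.frame per included gene: `gene_id`, `n_snps`, `slope`,
#'   `r2`, `p_slope`, `fdr`, `fdr_flag`. Attributes `skipped` (gene ids
#'   with fewer than `min_snps` SNPs) and `summary` (named vector with
#'   `n_genes`, `frac_fdr_sig`, `frac_r2_gt_0.10`).
#' @export
effect_correlation <- function(effects, min_snps = 5, sig_level = 0.05) {
  stopifnot(all(c("gene_id", "beta_target", "gamma_aux") %in% names(effects)))
  effects <- effects[stats::complete.cases(
    effects[, c("gene_id", "beta_target", "gamma_aux")]), , drop = FALSE]
  split_g <- split(effects, effects$gene_id)
  n_per <- vapply(split_g, nrow, integer(1))
  skipped <- names(split_g)[n_per < min_snps]
  split_g <- split_g[n_per >= min_snps]
  rows <- lapply(split_g, function(d) {
    fit <- stats::lm(beta_target ~ gamma_aux, data = d)
    sm <- summary(fit)
    co <- sm$coefficients
    has_slope <- "gamma_aux" %in% rownames(co)
    data.frame(
      gene_id = d$gene_id[1], n_snps = nrow(d),
      slope = if (has_slope) co["gamma_aux", "Estimate"] else NA_real_,
      r2 = sm$r.squared,
      p_slope = if (has_slope) co["gamma_aux", "Pr(>|t|)"] else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (is.null(tab)) {
    tab <- data.frame(gene_id = character(0), n_snps = integer(0),
                      slope = numeric(0), r2 = numeric(0),
                      p_slope = numeric(0))
  }
  tab$fdr <- adjust_pvalues(tab$p_slope, "bh")
  tab$fdr_flag <- !is.na(tab$fdr) & tab$fdr < sig_level
  attr(tab, "skipped") <- skipped
  attr(tab, "summary") <- c(
    n_genes = nrow(tab),
    frac_fdr_sig = mean(tab$fdr_flag),
    frac_r2_gt_0.10 = mean(tab$r2 > 0.10, na.rm = TRUE)
  )
  tab
}

#' Detection-rate comparison between gene groups
#'
#' Compares the eGene detection rate among genes with significant
#' target-auxiliary effect correlation against the rate among genes
#' without, via a Pearson chi-squared test (1 df, no continuity
#' correction by default) on the 2x2 table. Rates are reported as
#' percentages; the print method rounds to one decimal.
#'
#' @param n_sig_hit,n_sig_total detected and total genes in the
#'   significant-correlation group.
#' @param n_nonsig_hit,n_nonsig_total detected and total genes in the
#'   non-significant group.
#' @param exact use Fisher's exact test instead of the chi-squared test
#'   (for small tables).
#' @return object of class `detection_rate_test`: list with `rate_sig`,
#'   `rate_nonsig` (percentages), `ratio`, `chi2_stat`, `p_value`,
#'   `table`, `infinite_ratio` flag, `method`.
#' @export
detection_rate_test <- function(n_sig_hit, n_sig_total, n_nonsig_hit,
                                n_nonsig_total, exact = FALSE) {
  stopifnot(n_sig_total > 0, n_nonsig_total > 0,
            n_sig_hit >= 0, n_nonsig_hit >= 0,
            n_sig_hit <= n_sig_total, n_nonsig_hit <= n_nonsig_total)
  rate_sig <- 100 * n_sig_hit / n_sig_total
  rate_nonsig <- 100 * n_nonsig_hit / n_nonsig_total
  infinite <- rate_nonsig == 0
  ratio <- if (infinite) Inf else rate_sig / rate_nonsig
  tab <- matrix(c(n_sig_hit, n_sig_total - n_sig_hit,
                  n_nonsig_hit, n_nonsig_total - n_nonsig_hit),
                nrow = 2,
                dimnames = list(c("hit", "miss"), c("sig", "nonsig")))
  if (exact) {
    ht <- stats::fisher.test(tab)
    stat <- NA_real_
    method <- "fisher_exact"
  } else {
    ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    stat <- unname(ht$statistic)
    method <- "pearson_chi2"
  }
  structure(
    list(rate_sig = rate_sig, rate_nonsig = rate_nonsig, ratio = ratio,
         chi2_stat = stat, p_value = ht$p.value, table = tab,
         infinite_ratio = infinite, method = method),
    class = "detection_rate_test"
  )
}

#' @export
print.detection_rate_test <- function(x, ...) {
  cat("Detection rate: ", round(x$rate_sig, 1), "% vs ",
      round(x$rate_nonsig, 1), "% (ratio ",
      if (x$infinite_ratio) "Inf" else round(x$ratio, 1), ")\n", sep = "")
  cat(x$method, "p =", format(x$p_value, digits = 3), "\n")
  invisible(x)
}
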