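# Multi-gene synthetic dataset for the scan tests: `n_genes` genes spaced
# 3 Mb apart on one chromosome, 10 cis-SNPs each, one gene carrying a
# transferred (theta) signal and the rest null.
make_scan_dataset <- function(n = 200, n_genes = 6, planted = 3,
                              theta = 0.4, seed = 61) {
  set.seed(seed)
  m <- 10
  blocks <- vector("list", n_genes)
  gammas <- vector("list", n_genes)
  ann <- data.frame(gene_id = paste0("gene", seq_len(n_genes)),
                    chrom = "1",
                    start = 3e6 * seq_len(n_genes),
                    end = 3e6 * seq_len(n_genes) + 20000,
                    strand = "+", stringsAsFactors = FALSE)
  for (k in seq_len(n_genes)) {
    gk <- simulate_genotypes(n, m, runif(m, 0.1, 0.5), ld_rho = 0.4,
                             pos_start = ann$start[k])
    gk$variants$id <- sprintf("rs%d_%02d", k, seq_len(m))
    blocks[[k]] <- gk
    gammas[[k]] <- rnorm(m, 0, 0.3)
  }
  dosages <- do.call(cbind, lapply(blocks, function(b) b$dosages))
  variants <- do.call(rbind, lapply(blocks, function(b) b$variants))
  g <- genotype_matrix(dosages, variants, blocks[[1]]$samples)
  covariates <- cbind(x1 = rbinom(n, 1, 0.5), x2 = rnorm(n))
  rownames(covariates) <- g$samples
  expr <- matrix(NA_real_, n_genes, n,
                 dimnames = list(ann$gene_id, g$samples))
  for (k in seq_len(n_genes)) {
    base <- covariates %*% c(0.5, 0.5) + rnorm(n)
    if (k == planted) {
      # transferred signal along the auxiliary effects, scaled so the
      # genetic component explains half the residual variance
      sig <- blocks[[k]]$dosages %*% (gammas[[k]] * theta)
      base <- base + sig / sd(sig) * sqrt(0.5)
    }
    expr[k, ] <- base
  }
  aux <- aux_effects(data.frame(
    id = variants$id,
    effect_allele = variants$effect_allele,
    other_allele = variants$other_allele,
    beta = unlist(gammas), stringsAsFactors = FALSE
  ), provenance = "synthetic auxiliary study")
  list(genotypes = g, expression = expr, covariates = covariates,
       aux = aux, annotation = ann, planted = ann$gene_id[planted])
}
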