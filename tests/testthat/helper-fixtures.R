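# Small deterministic fixtures shared across test files.

make_genotypes <- function(n = 30, m = 8, seed = 11, mafs = NULL,
                           ld_rho = 0.3) {
  if (is.null(mafs)) {
    set.seed(seed)
    mafs <- runif(m, 0.1, 0.5)
  }
  simulate_genotypes(n, m, mafs, ld_rho = ld_rho, seed = seed)
}

# matching aux effects table for a genotype_matrix
make_aux <- function(g, beta = NULL, seed = 12) {
  set.seed(seed)
  m <- nrow(g$variants)
  if (is.null(beta)) beta <- rnorm(m, 0, 0.2)
  aux_effects(data.frame(
    id = g$variants$id,
    effect_allele = g$variants$effect_allele,
    other_allele = g$variants$other_allele,
    beta = beta,
    stringsAsFactors = FALSE
  ), provenance = "test")
}

write_mini_vcf <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", "s3", sep = "\t"),
    paste("1", "100", "rs1", "G", "A", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/1", sep = "\t"),
    paste("1", "200", "rs2", "C", "T,G", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/1", sep = "\t"),
    paste("1", "300", "rs3", "A", "C", ".", "PASS", ".", "GT",
          "0/1", "./.", "1/1", sep = "\t")
  )
  writeLines(lines, path)
  path
}
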