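test_that("MAF filter is strict and monomorphic columns are removed", {
  # maf 0.04 at threshold 0.05 -> removed; maf exactly 0.05 -> removed too
  dos <- cbind(
    low = c(rep(0, 46), 1, 1, 1, 1),        # maf 0.04
    edge = c(rep(0, 45), rep(1, 5)),        # maf 0.05 (<= threshold)
    keep = c(rep(0, 40), rep(1, 10)),       # maf 0.10
    mono = rep(2, 50)                       # monomorphic
  )
  v <- data.frame(id = colnames(dos), chrom = "1", pos = 1:4 * 100L,
                  effect_allele = "A", other_allele = "G")
  g <- genotype_matrix(dos, v)
  out <- qc_genotypes(g, maf_min = 0.05)
  expect_equal(out$variants$id, "keep")
  rep <- attr(out, "qc_report")
  expect_setequal(rep$id, c("low", "edge", "mono"))
  expect_equal(rep$reason[rep$id == "mono"], "monomorphic")
  expect_equal(sort(rep$reason[rep$id != "mono"]), c("low_maf", "low_maf"))
})

test_that("mean imputation preserves the column mean", {
  dos <- cbind(a = c(0, NA, 2, 1, 1, 0, 2, 1))
  v <- data.frame(id = "a", chrom = "1", pos = 100L,
                  effect_allele = "A", other_allele = "G")
  g <- genotype_matrix(dos, v)
  mean_before <- mean(dos, na.rm = TRUE)
  out <- qc_genotypes(g, maf_min = 0)
  expect_false(anyNA(out$dosages))
  expect_equal(mean(out$dosages[, 1]), mean_before)
  expect_equal(out$dosages[2, 1], mean_before)
})

test_that("qc never increases variant count and empty results are signalled", {
  g <- make_genotypes(n = 40, m = 10, seed = 5)
  out <- qc_genotypes(g, maf_min = 0.05)
  expect_lte(nrow(out$variants), nrow(g$variants))
  # removing everything flags the empty matrix rather than erroring
  dos <- cbind(a = rep(0, 10))
  v <- data.frame(id = "a", chrom = "1", pos = 1L,
                  effect_allele = "A", other_allele = "G")
  empty <- qc_genotypes(genotype_matrix(dos, v))
  expect_true(attr(empty, "empty"))
  expect_equal(nrow(empty$variants), 0L)
})

test_that("harmonization applies the removal rules and the sign flip", {
  dos <- matrix(rep(c(0, 1, 2, 1), 6), nrow = 4)
  v <- data.frame(
    id = c("rs_at", "rs_ok", "rs_swap", ".", "rs_mismatch", "rs_onlytarget"),
    chrom = "1", pos = 1:6 * 100L,
    effect_allele = c("A", "A", "A", "A", "A", "A"),
    other_allele = c("T", "G", "G", "G", "G", "G"),
    stringsAsFactors = FALSE
  )
  g <- genotype_matrix(dos, v)
  aux <- aux_effects(data.frame(
    id = c("rs_at", "rs_ok", "rs_swap", "rs_mismatch", "rs_onlyaux"),
    effect_allele = c("A", "A", "G", "C", "A"),
    other_allele = c("T", "G", "A", "T", "G"),
    beta = c(0.5, 0.2, 0.3, 0.4, 0.1)
  ))
  h <- harmonize(g, aux)
  expect_equal(h$genotypes$variants$id, c("rs_ok", "rs_swap"))
  # swapped alleles negate beta so it refers to the target effect allele
  expect_equal(h$gamma, c(0.2, -0.3))
  expect_equal(unname(h$report["strand_ambiguous"]), 2L)
  expect_equal(unname(h$report["no_rs_id"]), 1L)
  expect_equal(unname(h$report["allele_mismatch"]), 1L)
  expect_equal(unname(h$report["n_flipped"]), 1L)
  expect_equal(unname(h$report["n_kept"]), 2L)
})

test_that("harmonize is idempotent and alleles match as sets afterwards", {
  g <- make_genotypes(n = 25, m = 12, seed = 9)
  # vary the allele codes, including swaps
  set.seed(10)
  g$variants$effect_allele <- sample(c("A", "C"), 12, replace = TRUE)
  g$variants$other_allele <- ifelse(g$variants$effect_allele == "A", "G", "T")
  aux <- make_aux(g)
  swap <- c(2, 5)
  aux$effect_allele[swap] <- g$variants$other_allele[swap]
  aux$other_allele[swap] <- g$variants$effect_allele[swap]
  h1 <- harmonize(g, aux)
  aux2 <- aux_effects(data.frame(
    id = h1$genotypes$variants$id,
    effect_allele = h1$genotypes$variants$effect_allele,
    other_allele = h1$genotypes$variants$other_allele,
    beta = h1$gamma
  ))
  h2 <- harmonize(h1$genotypes, aux2)
  expect_equal(h2$genotypes$variants$id, h1$genotypes$variants$id)
  expect_equal(h2$gamma, h1$gamma)
  # allele pairs agree as sets for every surviving variant
  tv <- h1$genotypes$variants
  av <- h1$aux
  expect_true(all((tv$effect_allele == av$effect_allele &
                     tv$other_allele == av$other_allele) |
                    (tv$effect_allele == av$other_allele &
                       tv$other_allele == av$effect_allele)))
})

test_that("empty overlap raises a warning signal", {
  g <- make_genotypes(n = 10, m = 3)
  aux <- aux_effects(data.frame(id = c("rsX", "rsY"),
                                effect_allele = c("A", "C"),
                                other_allele = c("G", "T"),
                                beta = c(0.1, 0.2)))
  expect_warning(h <- harmonize(g, aux), "empty overlap")
  expect_equal(unname(h$report["n_kept"]), 0L)
})

test_that("cis extraction uses a closed interval on the gene's chromosome", {
  v <- data.frame(
    id = paste0("rs", 1:4),
    chrom = c("1", "1", "1", "2"),
    pos = c(5000L, 9000L, 26000L, 15000L),
    effect_allele = "A", other_allele = "G"
  )
  g <- genotype_matrix(matrix(1, 2, 4), v, c("s1", "s2"))
  gene <- data.frame(gene_id = "g1", chrom = "1", start = 10000L,
                     end = 20000L)
  # window 5000: [5000, 25000]; rs1 sits exactly on the lower boundary
  cis <- extract_cis(g, gene, window = 5000)
  expect_equal(cis$variants$id, c("rs1", "rs2"))
  # window 0: only intragenic; same-position other-chromosome variant excluded
  cis0 <- extract_cis(g, gene, window = 0)
  expect_equal(nrow(cis0$variants), 0L)
  gene2 <- data.frame(gene_id = "g2", chrom = "1", start = 8000L,
                      end = 16000L)
  expect_equal(extract_cis(g, gene2, window = 0)$variants$id, "rs2")
})
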