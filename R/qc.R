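#' Genotype quality control
#'
#' Removes variants whose minor allele frequency is at or below `maf_min`
#' (strict inequality: MAF > `maf_min` is retained) and monomorphic
#' variants, then mean-imputes remaining missing dosages per variant.
#' Imputation after filtering leaves each column mean unchanged.
#'
#' @param g a [genotype_matrix()].
#' @param maf_min MAF threshold in \[0, 0.5); default 0.05.
#' @return A [genotype_matrix()] with no missing entries and every column
#'   polymorphic. Attribute `qc_report` is a data.frame of removed variants
#'   with a `reason` column (`"monomorphic"` or `"low_maf"`; the reasons
#'   partition the removed set, monomorphic taking precedence).
#' @export
qc_genotypes <- function(g, maf_min = 0.05) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (!(maf_min >= 0 && maf_min < 0.5)) stop("maf_min must lie in [0, 0.5)")
  maf <- compute_maf(g$dosages)
  v <- apply(g$dosages, 2, stats::var, na.rm = TRUE)
  mono <- is.na(v) | v == 0
  low <- !mono & (is.na(maf) | maf <= maf_min)
  reason <- rep(NA_character_, ncol(g$dosages))
  reason[mono] <- "monomorphic"
  reason[low] <- "low_maf"
  drop <- mono | low
  report <- data.frame(id = g$variants$id[drop],
                       maf = maf[drop],
                       reason = reason[drop],
                       stringsAsFactors = FALSE)
  if (all(drop)) {
    out <- subset_variants(g, !drop)
    attr(out, "qc_report") <- report
    attr(out, "empty") <- TRUE
    return(out)
  }
  out <- subset_variants(g, !drop)
  if (anyNA(out$dosages)) {
    mu <- colMeans(out$dosages, na.rm = TRUE)
    idx <- which(is.na(out$dosages), arr.ind = TRUE)
    out$dosages[idx] <- mu[idx[, 2]]
    out$variants$maf <- compute_maf(out$dosages)
  }
  attr(out, "qc_report") <- report
  attr(out, "empty") <- FALSE
  out
}

VALID_ALLELES <- c("A", "C", "G", "T")

is_strand_ambiguous <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

has_rs_id <- function(id) {
  !is.na(id) & id != "" & id != "."
}

#' Harmonize target genotypes with auxiliary effect estimates
#'
#' Aligns the auxiliary per-SNP effects to the target study's effect
#' alleles, applying in order: (1) drop non-biallelic SNPs and variants
#' with alleles outside A/C/G/T, (2) drop strand-ambiguous variants
#' (A/T, C/G), (3) drop variants without an rs identifier, (4) drop
#' duplicated ids (all copies, since the duplicates cannot be told apart),
#' (5) intersect target and auxiliary on id, (6) drop variants whose allele
#' pairs do not match as a set, and (7) where effect and other alleles are
#' swapped between the studies, negate the auxiliary beta so it refers to
#' the target effect allele. The operation is idempotent.
#'
#' @param g QC'd target [genotype_matrix()].
#' @param aux an [aux_effects()] table.
#' @return list with elements `genotypes` (variants in target order),
#'   `gamma` (auxiliary effects aligned to the target effect alleles, same
#'   order), `aux` (the matching auxiliary rows) and `report` (named counts
#'   of removals per rule plus `n_flipped` and `n_kept`).
#' @export
harmonize <- function(g, aux) {
  stopifnot(inherits(g, "genotype_matrix"))
  report <- c(nonbiallelic = 0L, strand_ambiguous = 0L, no_rs_id = 0L,
              duplicated_id = 0L, not_shared = 0L, allele_mismatch = 0L)

  tv <- g$variants
  t_bi <- if (!is.null(tv$biallelic)) tv$biallelic else rep(TRUE, nrow(tv))
  t_bi <- t_bi & tv$effect_allele %in% VALID_ALLELES &
    tv$other_allele %in% VALID_ALLELES
  a_bi <- aux$effect_allele %in% VALID_ALLELES &
    aux$other_allele %in% VALID_ALLELES
  report["nonbiallelic"] <- sum(!t_bi) + sum(!a_bi)
  g <- subset_variants(g, t_bi); tv <- g$variants
  aux <- aux[a_bi, , drop = FALSE]

  t_amb <- is_strand_ambiguous(tv$effect_allele, tv$other_allele)
  a_amb <- is_strand_ambiguous(aux$effect_allele, aux$other_allele)
  report["strand_ambiguous"] <- sum(t_amb) + sum(a_amb)
  g <- subset_variants(g, !t_amb); tv <- g$variants
  aux <- aux[!a_amb, , drop = FALSE]

  t_rs <- has_rs_id(tv$id)
  a_rs <- has_rs_id(aux$id)
  report["no_rs_id"] <- sum(!t_rs) + sum(!a_rs)
  g <- subset_variants(g, t_rs); tv <- g$variants
  aux <- aux[a_rs, , drop = FALSE]

  t_dup <- tv$id %in% tv$id[duplicated(tv$id)]
  a_dup <- aux$id %in% aux$id[duplicated(aux$id)]
  report["duplicated_id"] <- sum(t_dup) + sum(a_dup)
  g <- subset_variants(g, !t_dup); tv <- g$variants
  aux <- aux[!a_dup, , drop = FALSE]

  shared <- intersect(tv$id, aux$id)
  report["not_shared"] <- (nrow(tv) - length(shared)) +
    (nrow(aux) - length(shared))
  keep <- tv$id %in% shared
  g <- subset_variants(g, keep); tv <- g$variants
  aux <- aux[match(tv$id, aux$id), , drop = FALSE]

  same <- tv$effect_allele == aux$effect_allele &
    tv$other_allele == aux$other_allele
  swapped <- tv$effect_allele == aux$other_allele &
    tv$other_allele == aux$effect_allele
  mismatch <- !(same | swapped)
  report["allele_mismatch"] <- sum(mismatch)
  g <- subset_variants(g, !mismatch)
  aux <- aux[!mismatch, , drop = FALSE]
  swapped <- swapped[!mismatch]

  gamma <- aux$beta
  gamma[swapped] <- -gamma[swapped]
  report <- c(report, n_flipped = sum(swapped), n_kept = nrow(aux))
  if (nrow(aux) == 0L) {
    warning("no variants remain after harmonization (empty overlap)")
  }
  list(genotypes = g, gamma = gamma, aux = aux, report = report)
}

#' Extract cis variants for a gene
#'
#' Keeps variants on the gene's chromosome whose position falls in the
#' closed interval \[start - window, end + window\]; variant order is
#' preserved.
#'
#' @param g a [genotype_matrix()].
#' @param gene one-row data.frame (or list) with `gene_id`, `chrom`,
#'   `start`, `end`.
#' @param window window in base pairs on each side of the gene body
#'   (default 1 Mb).
#' @return A [genotype_matrix()] restricted to the cis window (possibly
#'   with zero variants).
#' @export
extract_cis <- function(g, gene, window = 1e6) {
  stopifnot(window >= 0)
  lo <- gene$start - window
  hi <- gene$end + window
  keep <- g$variants$chrom == gene$chrom &
    g$variants$pos >= lo & g$variants$pos <= hi
  subset_variants(g, keep)
}
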