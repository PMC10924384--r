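#' Construct a genotype matrix
#'
#' A `genotype_matrix` bundles an n x m dosage matrix with per-variant
#' metadata. Dosages count copies of the effect allele, so each entry lies
#' in \[0, 2\] (missing values are allowed before quality control).
#'
#' @param dosages numeric n x m matrix, samples in rows, variants in columns.
#' @param variants data.frame with one row per variant and columns
#'   `id`, `chrom`, `pos`, `effect_allele`, `other_allele`. A `maf` column
#'   is recomputed from the dosages.
#' @param samples character vector of sample identifiers (length n).
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `samples`, `variants` (including a `maf` column) and `dosages`.
#' @export
genotype_matrix <- function(dosages, variants, samples = rownames(dosages)) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(samples)) samples <- paste0("sample_", seq_len(nrow(dosages)))
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  required <- c("id", "chrom", "pos", "effect_allele", "other_allele")
  missing_cols <- setdiff(required, names(variants))
  if (length(missing_cols) > 0L) {
    stop("variant table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(variants) != ncol(dosages)) {
    stop("number of variants (", nrow(variants),
         ") does not match dosage columns (", ncol(dosages), ")")
  }
  if (length(samples) != nrow(dosages)) {
    stop("number of samples does not match dosage rows")
  }
  ok <- is.na(dosages) | (dosages >= 0 & dosages <= 2)
  if (!all(ok)) stop("dosages must lie in [0, 2] or be missing")
  variants$pos <- as.integer(variants$pos)
  variants$maf <- compute_maf(dosages)
  rownames(dosages) <- samples
  colnames(dosages) <- variants$id
  structure(
    list(samples = as.character(samples), variants = variants,
         dosages = dosages),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$samples), "samples x",
      nrow(x$variants), "variants\n")
  n_miss <- sum(is.na(x$dosages))
  if (n_miss > 0) cat("  missing dosages:", n_miss, "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Minor allele frequency from dosages
#'
#' Column-wise MAF computed from non-missing dosages: the effect-allele
#' frequency folded onto \[0, 0.5\].
#'
#' @param dosages numeric matrix of dosages in \[0, 2\].
#' @return numeric vector of MAFs, one per column.
#' @export
compute_maf <- function(dosages) {
  af <- colMeans(dosages, na.rm = TRUE) / 2
  af[is.nan(af)] <- NA_real_
  pmin(af, 1 - af)
}

subset_variants <- function(g, keep) {
  # keep: logical or integer index over variants
  genotype_matrix(g$dosages[, keep, drop = FALSE],
                  g$variants[keep, , drop = FALSE],
                  g$samples)
}

subset_samples <- function(g, keep) {
  genotype_matrix(g$dosages[keep, , drop = FALSE], g$variants,
                  g$samples[keep])
}

#' Read genotypes from VCF or a dosage table
#'
#' For VCF input the `DS` FORMAT field is used when present, otherwise
#' dosages are counted from `GT`. Multi-allelic records are kept but marked
#' non-biallelic so that [harmonize()] removes them; they are listed in the
#' `flagged` attribute of the result. For the tab-separated dosage dialect
#' the first five columns are `id`, `chrom`, `pos`, `effect_allele`,
#' `other_allele`, followed by one column per sample; empty cells become
#' missing dosages.
#'
#' @param path path to the input file.
#' @param format `"vcf"` or `"dosage_tsv"`.
#' @return A [genotype_matrix()]; variant order is file order. Attribute
#'   `flagged` is a data.frame of variants flagged at load time.
#' @export
read_genotypes <- function(path, format = c("vcf", "dosage_tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_tsv(path)
}

read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  multi <- grepl(",", alt)
  ids <- fix[, "ID"]
  ids[is.na(ids)] <- "."
  variants <- data.frame(
    id = ids, chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    effect_allele = sub(",.*$", "", alt), other_allele = ref,
    stringsAsFactors = FALSE
  )
  fmt <- vcf@gt[, 1, drop = TRUE]
  has_ds <- all(grepl("(^|:)DS(:|$)", fmt))
  if (has_ds) {
    ds <- vcfR::extract.gt(vcf, element = "DS")
    dos <- apply(ds, 2, as.numeric)
  } else {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    count_alt <- function(x) {
      a <- strsplit(gsub("\\|", "/", x), "/", fixed = TRUE)
      vapply(a, function(al) {
        if (any(al == "." | is.na(al))) return(NA_real_)
        sum(al != "0")
      }, numeric(1))
    }
    dos <- apply(gt, 2, count_alt)
  }
  if (is.null(dim(dos))) dos <- matrix(dos, nrow = nrow(variants))
  dos <- t(dos)  # vcfR is variants x samples; we store samples x variants
  samples <- colnames(vcf@gt)[-1]
  g <- genotype_matrix(dos, variants, samples)
  g$variants$biallelic <- !multi
  flagged <- g$variants[multi, c("id", "chrom", "pos"), drop = FALSE]
  if (nrow(flagged) > 0) flagged$reason <- "multiallelic"
  attr(g, "flagged") <- flagged
  g
}

read_genotypes_tsv <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("", "NA"))
  required <- c("id", "chrom", "pos", "effect_allele", "other_allele")
  if (!all(required %in% names(tab))) {
    stop("dosage table must start with columns: ",
         paste(required, collapse = ", "))
  }
  sample_cols <- setdiff(names(tab), required)
  if (length(sample_cols) == 0L) stop("dosage table has no sample columns")
  dos <- t(as.matrix(tab[, sample_cols, drop = FALSE]))
  if (!is.numeric(dos)) {
    bad <- which(apply(tab[, sample_cols, drop = FALSE], 1,
                       function(r) any(is.na(suppressWarnings(as.numeric(r))) & !is.na(r))))
    stop("non-numeric dosage at table row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  variants <- tab[, required]
  g <- genotype_matrix(dos, variants, sample_cols)
  g$variants$biallelic <- TRUE
  miss <- colSums(is.na(g$dosages)) > 0
  flagged <- g$variants[miss, c("id", "chrom", "pos"), drop = FALSE]
  if (nrow(flagged) > 0) flagged$reason <- "missing_dosage"
  attr(g, "flagged") <- flagged
  g
}

#' Write a genotype matrix as a dosage table
#'
#' Inverse of `read_genotypes(format = "dosage_tsv")`; round-trips dosages
#' exactly (full precision, tab-separated, header line).
#'
#' @param g a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dosage_tsv <- function(g, path) {
  tab <- cbind(
    g$variants[, c("id", "chrom", "pos", "effect_allele", "other_allele")],
    as.data.frame(t(g$dosages))
  )
  names(tab) <- c("id", "chrom", "pos", "effect_allele", "other_allele",
                  g$samples)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read auxiliary per-SNP effect estimates
#'
#' Summary statistics of the auxiliary study: one row per SNP with the
#' estimated effect `beta` aligned to the declared `effect_allele`.
#' Duplicate ids cannot be resolved to a single record and are dropped
#' entirely, with a warning.
#'
#' @param path tab-separated file with columns `id`, `effect_allele`,
#'   `other_allele`, `beta` (extra columns such as `chrom`, `pos`, `se`
#'   are carried along).
#' @param provenance free-text label describing the source study.
#' @return data.frame of class `aux_effects` with attribute `provenance`.
#' @export
read_aux_effects <- function(path, provenance = basename(path)) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  aux_effects(tab, provenance = provenance)
}

#' @rdname read_aux_effects
#' @param tab data.frame with the columns described above.
#' @export
aux_effects <- function(tab, provenance = "unspecified") {
  required <- c("id", "effect_allele", "other_allele", "beta")
  if (!all(required %in% names(tab))) {
    stop("auxiliary effects need columns: ", paste(required, collapse = ", "))
  }
  if (any(!is.finite(tab$beta))) stop("non-finite beta in auxiliary effects")
  dup <- tab$id %in% tab$id[duplicated(tab$id)]
  if (any(dup)) {
    warning(sum(dup), " record(s) with duplicated ids dropped from auxiliary effects")
    tab <- tab[!dup, , drop = FALSE]
  }
  structure(tab, class = c("aux_effects", "data.frame"),
            provenance = provenance)
}

#' Read an expression table
#'
#' @param path tab-separated file, first column `gene_id`, one column per
#'   sample.
#' @return numeric matrix, genes in rows (named), samples in columns.
#' @export
read_expression <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  storage.mode(m) <- "double"
  m
}

#' Read a covariate table
#'
#' @param path tab-separated file, first column `sample_id`, remaining
#'   columns numeric covariates.
#' @return numeric matrix, samples in rows (named).
#' @export
read_covariates <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  storage.mode(m) <- "double"
  m
}

#' Read gene annotation
#'
#' Accepts either a header-less BED file (0-based half-open; converted to
#' 1-based inclusive on read) or a tab-separated table with a header line
#' and columns `gene_id`, `chrom`, `start`, `end`, `strand` already in
#' 1-based inclusive coordinates.
#'
#' @param path input path.
#' @param format `"tsv"` or `"bed"`.
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (1-based inclusive).
#' @export
read_gene_annotation <- function(path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "bed") {
    tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                             stringsAsFactors = FALSE)
    ann <- data.frame(
      gene_id = tab[[4]], chrom = tab[[1]],
      start = as.integer(tab[[2]]) + 1L,  # BED is 0-based half-open
      end = as.integer(tab[[3]]),
      strand = if (ncol(tab) >= 6) tab[[6]] else "+",
      stringsAsFactors = FALSE
    )
  } else {
    ann <- utils::read.delim(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    required <- c("gene_id", "chrom", "start", "end")
    if (!all(required %in% names(ann))) {
      stop("annotation needs columns: ", paste(required, collapse = ", "))
    }
    if (is.null(ann$strand)) ann$strand <- "+"
    ann$start <- as.integer(ann$start)
    ann$end <- as.integer(ann$end)
  }
  bad <- ann$start > ann$end
  if (any(bad)) stop("annotation has start > end for: ",
                     paste(utils::head(ann$gene_id[bad], 5), collapse = ", "))
  ann
}

#' Align samples across genotypes, expression and covariates
#'
#' Intersects sample identifiers and returns all three objects restricted
#' to the common samples, in a single shared order.
#'
#' @param g a [genotype_matrix()].
#' @param expression genes x samples matrix with sample column names.
#' @param covariates samples x p matrix with sample row names.
#' @return list with elements `genotypes`, `expression`, `covariates`,
#'   `samples`.
#' @export
align_samples <- function(g, expression, covariates) {
  common <- intersect(intersect(g$samples, colnames(expression)),
                      rownames(covariates))
  if (length(common) == 0L) stop("no samples shared across inputs")
  x <- covariates[common, , drop = FALSE]
  if (qr(cbind(1, x))$rank < ncol(x) + 1L) {
    stop("covariate matrix is rank deficient after adding an intercept")
  }
  list(
    genotypes = subset_samples(g, match(common, g$samples)),
    expression = expression[, common, drop = FALSE],
    covariates = x,
    samples = common
  )
}
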