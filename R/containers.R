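#' Genotype matrix container
#'
#' Minor-allele dosage matrix (individuals x variants) with per-variant
#' metadata. The coded (counted) allele is always the cohort minor allele:
#' constructors re-orient columns whose coded-allele frequency exceeds 0.5 by
#' replacing dosages with `2 - dosage` and swapping the allele labels, so
#' `colMeans(dosage)/2 <= 0.5` up to monomorphic edge cases.
#'
#' @param dosage integer/numeric matrix, n individuals x m variants; entries in
#'   {0, 1, 2} or NA for missing calls.
#' @param variants data.frame with columns `rsid`, `chr`, `pos`, `ref`, `alt`
#'   (one row per column of `dosage`; `alt` is the coded minor allele).
#' @param sample_ids character vector of length n.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, variants, sample_ids = NULL) {
  dosage <- as.matrix(dosage)
  if (is.null(sample_ids)) {
    sample_ids <- rownames(dosage) %||% paste0("sample_", seq_len(nrow(dosage)))
  }
  stopifnot(nrow(variants) == ncol(dosage), length(sample_ids) == nrow(dosage))
  required <- c("rsid", "chr", "pos", "ref", "alt")
  missing_cols <- setdiff(required, names(variants))
  if (length(missing_cols)) {
    stop_mlm("variants data.frame lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  variants$chr <- as.character(variants$chr)
  bad <- !(dosage %in% c(0, 1, 2) | is.na(dosage))
  if (any(bad)) stop_mlm("dosages must be 0, 1, 2 or NA")
  # orient each column to the cohort minor allele
  f <- colMeans(dosage, na.rm = TRUE) / 2
  flip <- !is.na(f) & f > 0.5
  if (any(flip)) {
    dosage[, flip] <- 2 - dosage[, flip]
    tmp <- variants$ref[flip]
    variants$ref[flip] <- variants$alt[flip]
    variants$alt[flip] <- tmp
  }
  dimnames(dosage) <- list(sample_ids, variants$rsid)
  structure(
    list(dosage = dosage, variants = as.data.frame(variants, stringsAsFactors = FALSE),
         sample_ids = sample_ids),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", nrow(x$dosage), " individuals x ", ncol(x$dosage),
      " variants on ", length(unique(x$variants$chr)), " chromosome(s)\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix by variant
#'
#' @param genotypes a `genotype_matrix`.
#' @param keep logical or integer index over variants (columns).
#' @return a `genotype_matrix` restricted to the kept variants.
#' @export
subset_variants <- function(genotypes, keep) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  dos <- genotypes$dosage[, keep, drop = FALSE]
  if (ncol(dos) == 0L) stop_mlm("variant subset is empty")
  genotype_matrix(dos, genotypes$variants[keep, , drop = FALSE], genotypes$sample_ids)
}

#' Expression matrix container
#'
#' Genes x individuals matrix of (already normalized/standardized) expression
#' values with gene coordinates used for cis/trans classification.
#'
#' @param expr numeric matrix, genes x individuals.
#' @param genes data.frame with columns `gene_id`, `chr`, `start`, `end`.
#' @param sample_ids character vector matching the columns of `expr`.
#' @return an object of class `expression_matrix`.
#' @export
expression_matrix <- function(expr, genes, sample_ids = NULL) {
  expr <- as.matrix(expr)
  if (is.null(sample_ids)) {
    sample_ids <- colnames(expr) %||% paste0("sample_", seq_len(ncol(expr)))
  }
  stopifnot(nrow(genes) == nrow(expr), length(sample_ids) == ncol(expr))
  required <- c("gene_id", "chr", "start", "end")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols)) {
    stop_mlm("genes data.frame lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  genes$chr <- as.character(genes$chr)
  dimnames(expr) <- list(genes$gene_id, sample_ids)
  structure(
    list(expr = expr, genes = as.data.frame(genes, stringsAsFactors = FALSE),
         sample_ids = sample_ids),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("<expression_matrix> ", nrow(x$expr), " gene(s) x ", ncol(x$expr),
      " individuals\n", sep = "")
  invisible(x)
}
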