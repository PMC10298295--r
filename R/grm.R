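#' Genomic similarity matrix
#'
#' Computes the n x n genomic similarity (relationship) matrix
#' \deqn{g_{jk} = \frac{1}{n_v}\sum_{i=1}^{n_v}
#'       \frac{(\tau_{ij}-2f_i)(\tau_{ik}-2f_i)}{2f_i(1-f_i)}}
#' where \eqn{\tau_{ij}} is individual j's minor-allele dosage at variant i and
#' \eqn{f_i} the sample minor-allele frequency of variant i. Missing dosages
#' are mean-imputed to \eqn{2f_i} (contributing zero after centering).
#' Frequencies come from the analysis sample itself, not an external
#' reference; this is recorded in the returned object.
#'
#' @param genotypes a [genotype_matrix()].
#' @param mask logical or integer index over variants to include (default all).
#' @param excluded_chromosome label recorded in metadata (used by
#'   [loco_grm()]); purely descriptive here.
#' @return an object of class `grm`: list with `matrix` (n x n, symmetric),
#'   `n_variants_used`, `excluded_chromosome`, `sample_ids`, `variant_ids`.
#' @export
compute_grm <- function(genotypes, mask = NULL,
                        excluded_chromosome = NA_character_) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  dos <- genotypes$dosage
  if (!is.null(mask)) dos <- dos[, mask, drop = FALSE]
  ids <- colnames(dos)
  if (ncol(dos) < 1L) stop_mlm("masked variant panel is empty")
  f <- colMeans(dos, na.rm = TRUE) / 2
  mono <- f <= 0 | f >= 1
  if (any(mono)) {
    stop_mlm("monomorphic variant(s) in GRM mask: ",
             paste(utils::head(ids[mono], 5), collapse = ", "))
  }
  center <- sweep(dos, 2, 2 * f, "-")
  center[is.na(center)] <- 0  # mean imputation
  Z <- sweep(center, 2, sqrt(2 * f * (1 - f)), "/")
  G <- tcrossprod(Z) / ncol(dos)
  dimnames(G) <- list(genotypes$sample_ids, genotypes$sample_ids)
  structure(
    list(matrix = G, n_variants_used = ncol(dos),
         excluded_chromosome = excluded_chromosome,
         sample_ids = genotypes$sample_ids, variant_ids = ids,
         allele_freq_source = "analysis sample"),
    class = "grm"
  )
}

#' @export
print.grm <- function(x, ...) {
  cat("<grm> ", length(x$sample_ids), " individuals, ", x$n_variants_used,
      " variants", sep = "")
  if (!is.na(x$excluded_chromosome)) cat(", excluding chr ", x$excluded_chromosome, sep = "")
  cat("\n")
  invisible(x)
}

#' Leave-one-chromosome-out GRM
#'
#' Recomputes the genomic similarity matrix excluding every variant on the
#' candidate variant's chromosome, so the candidate's own signal (and variants
#' linked to it) cannot be absorbed into the polygenic term. If the candidate
#' chromosome has no variants in the panel the result equals the full GRM.
#'
#' @param genotypes a [genotype_matrix()].
#' @param candidate_chr chromosome label of the candidate variant (normalized
#'   with [normalize_chr()] before comparison).
#' @return a `grm` with `excluded_chromosome` recorded.
#' @export
loco_grm <- function(genotypes, candidate_chr) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  chr_norm <- normalize_chr(genotypes$variants$chr)
  target <- normalize_chr(candidate_chr)
  mask <- chr_norm != target
  if (!any(mask)) {
    stop_mlm("all panel variants lie on chromosome ", candidate_chr,
             "; LOCO GRM undefined")
  }
  compute_grm(genotypes, mask = mask, excluded_chromosome = target)
}

#' Precompute the eigendecomposition of a GRM
#'
#' One symmetric eigendecomposition lets every subsequent REML fit against the
#' same GRM work in rotated coordinates where the covariance is diagonal;
#' a transcriptome scan therefore decomposes each LOCO GRM once.
#'
#' @param G a `grm`, or a plain symmetric matrix.
#' @return an object of class `grm_eigen` with `vectors`, `values`,
#'   `sample_ids`.
#' @export
grm_eigen <- function(G) {
  if (inherits(G, "grm_eigen")) return(G)
  ids <- NULL
  if (inherits(G, "grm")) {
    ids <- G$sample_ids
    G <- G$matrix
  }
  eg <- eigen(G, symmetric = TRUE)
  structure(list(vectors = eg$vectors, values = eg$values,
                 sample_ids = ids %||% rownames(G)),
            class = "grm_eigen")
}

#' Write a GRM as a lower-triangle TSV
#'
#' Columns: id_i, id_j, g_ij for j <= i.
#'
#' @param G a `grm`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_grm_tsv <- function(G, path) {
  stopifnot(inherits(G, "grm"))
  idx <- which(lower.tri(G$matrix, diag = TRUE), arr.ind = TRUE)
  out <- data.frame(id_i = G$sample_ids[idx[, 1]], id_j = G$sample_ids[idx[, 2]],
                    g = G$matrix[idx])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
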