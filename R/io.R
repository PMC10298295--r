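#' Write a genotype panel as plain-text VCF v4.2
#'
#' Emits one biallelic record per variant with an unphased GT field: the ALT
#' column is the coded minor allele, so dosage k becomes a genotype with k ALT
#' alleles ("0/0", "0/1", "1/1"; missing calls become "./.").
#'
#' @param genotypes a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  v <- genotypes$variants
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  dos <- genotypes$dosage
  gt <- matrix("./.", nrow(dos), ncol(dos))
  ok <- !is.na(dos)
  gt[ok] <- gt_code[as.character(dos[ok])]
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=mlmeqtl",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", genotypes$sample_ids), collapse = "\t")
  )
  body <- paste(v$chr, v$pos, v$rsid, v$ref, v$alt, ".", "PASS", ".", "GT",
                apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a VCF into a minor-allele dosage matrix
#'
#' Parses diploid GT calls (phased or unphased), skips multi-allelic records
#' with a warning, flags missing calls as NA, and orients every variant to the
#' cohort minor allele (so a site whose ALT frequency is 0.8 is re-coded to
#' count the 0.2-frequency allele).
#'
#' @param path VCF file path (plain or bgzipped; parsed with vcfR).
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt) | is.na(alt)
  if (all(multi)) stop_mlm("no biallelic records in ", path)
  if (any(multi)) {
    warning(sum(multi), " multi-allelic record(s) skipped", call. = FALSE)
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = length(alt))
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  # diploid GT -> ALT-allele count
  gt_clean <- gsub("\\|", "/", gt)
  dos <- matrix(NA_real_, nrow(gt_clean), ncol(gt_clean))
  dos[gt_clean == "0/0"] <- 0
  dos[gt_clean %in% c("0/1", "1/0")] <- 1
  dos[gt_clean == "1/1"] <- 2
  unknown <- !is.na(gt_clean) & !(gt_clean %in% c("0/0", "0/1", "1/0", "1/1", "./."))
  if (any(unknown)) stop_mlm("malformed GT field(s), e.g. ", gt_clean[unknown][1])
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
  variants <- data.frame(
    rsid = ids, chr = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"], alt = fix[, "ALT"],
    stringsAsFactors = FALSE
  )
  genotype_matrix(t(dos), variants, sample_ids = colnames(gt))
}

#' Write an expression matrix as TSV
#'
#' Columns: gene_id, chr, start, end, then one column per sample.
#'
#' @param expression an [expression_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(expression, path) {
  stopifnot(inherits(expression, "expression_matrix"))
  out <- cbind(expression$genes, as.data.frame(expression$expr, check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression TSV written by [write_expression_tsv()]
#'
#' @param path TSV path.
#' @return an [expression_matrix()].
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  meta_cols <- c("gene_id", "chr", "start", "end")
  expression_matrix(as.matrix(df[, setdiff(names(df), meta_cols), drop = FALSE]),
                    df[, meta_cols, drop = FALSE])
}

#' Write / read a signal catalog TSV
#'
#' @param catalog a `signal_catalog` data.frame.
#' @param path TSV path.
#' @return `path` (write) or a `signal_catalog` (read).
#' @export
write_catalog_tsv <- function(catalog, path) {
  utils::write.table(catalog, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_catalog_tsv
#' @export
read_catalog_tsv <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", stringsAsFactors = FALSE)
  out$pos <- as.integer(out$pos)
  if ("source_maf" %in% names(out)) out$source_maf <- as.numeric(out$source_maf)
  class(out) <- c("signal_catalog", "data.frame")
  out
}

#' Echo a simulation config to a JSON sidecar
#'
#' @param config a [sim_config()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_config_json <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
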