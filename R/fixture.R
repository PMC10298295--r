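#' Load the packaged eGene reference table
#'
#' A transcription of the published table of significant eGene associations
#' for Hodgkin-lymphoma-specific GWAS signals (80 variant-gene rows across 20
#' distinct signals, each with the mixed-model effect estimate and p-value;
#' positive beta means the minor allele increased expression). Ships as a
#' versioned TSV under `extdata`.
#'
#' @return data.frame with columns snp_id, snp_chr, snp_pos, major_allele,
#'   minor_allele, maf, egene_id, egene_chr, beta, p.
#' @export
load_egene_reference <- function() {
  path <- system.file("extdata", "hl_egenes_reference.tsv", package = "mlmeqtl",
                      mustWork = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "character", "integer",
                                         "character", "character", "numeric",
                                         "character", "character", "numeric",
                                         "numeric"),
                          stringsAsFactors = FALSE)
  validate_fixture(df)
  df
}

validate_fixture <- function(df) {
  required <- c("snp_id", "snp_chr", "snp_pos", "major_allele", "minor_allele",
                "maf", "egene_id", "egene_chr", "beta", "p")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop_mlm("malformed fixture: missing column(s) ",
             paste(missing_cols, collapse = ", "))
  }
  if (anyNA(df[required])) stop_mlm("malformed fixture: NA entries")
  if (any(df$p <= 0 | df$p > 1)) stop_mlm("malformed fixture: p out of range")
  invisible(df)
}

#' Summarize an eGene table as a scan summary
#'
#' Counts associations at `p < alpha` (strict): eGene rows, distinct signals,
#' and the cis/trans split under the same-chromosome rule of
#' [classify_cis_trans()]. Works on the packaged reference table or any table
#' with the same columns.
#'
#' @param fixture data.frame as returned by [load_egene_reference()].
#' @param alpha significance threshold (default 4e-5).
#' @return a `scan_summary`.
#' @export
summarize_fixture <- function(fixture, alpha = 4e-5) {
  validate_fixture(fixture)
  keep <- fixture$p < alpha
  sig <- fixture[keep, , drop = FALSE]
  ct <- classify_cis_trans(sig$snp_chr, sig$egene_chr)
  structure(
    list(n_signals_tested = length(unique(fixture$snp_id)),
         n_signals_with_egene = length(unique(sig$snp_id)),
         n_egenes = nrow(sig),
         n_cis = sum(ct == "cis"),
         n_trans = sum(ct == "trans"),
         alpha = alpha),
    class = "scan_summary"
  )
}
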