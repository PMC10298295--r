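#' Classify variant-gene pairs as cis or trans
#'
#' Operational definition: cis iff the variant and the gene lie on the same
#' (normalized) chromosome, with no distance window; otherwise trans. This
#' same-chromosome rule exactly reproduces the published cis/trans split of
#' the packaged reference table.
#'
#' @param snp_chr,gene_chr chromosome label vectors (recycled to a common
#'   length).
#' @return character vector of "cis"/"trans".
#' @export
classify_cis_trans <- function(snp_chr, gene_chr) {
  s <- normalize_chr(snp_chr)
  g <- normalize_chr(gene_chr)
  if (any(is.na(s) | s == "" | is.na(g) | g == "")) {
    stop_mlm("missing chromosome label")
  }
  ifelse(s == g, "cis", "trans")
}

#' Transcriptome-wide mixed-model scan over signal-gene pairs
#'
#' For every (signal, gene) pair: builds (once per chromosome) the
#' leave-one-chromosome-out GRM and its eigendecomposition, re-fits the
#' AI-REML variance components for the pair, and Wald-tests the variant
#' effect ([test_variant()]). Pairs with `p < alpha` (strict) are retained as
#' eGene associations. Per-pair failures are caught, logged, and skipped —
#' never silently dropped.
#'
#' @param signals a `signal_set`, `signal_catalog`, or data.frame with an
#'   `rsid` column; every rsid must be genotyped in `genotypes`.
#' @param expression an [expression_matrix()] (samples must match the panel).
#' @param genotypes a QC'd [genotype_matrix()].
#' @param alpha significance threshold (default 4e-5).
#' @return an object of class `eqtl_scan`: list with `results` (all tested
#'   pairs), `significant` (the `p < alpha` subset with a `cis_trans`
#'   column), `summary` (a `scan_summary`), and `failures`.
#' @export
run_scan <- function(signals, expression, genotypes, alpha = 4e-5) {
  if (inherits(signals, "signal_set")) signals <- signals$signals
  stopifnot(inherits(expression, "expression_matrix"),
            inherits(genotypes, "genotype_matrix"))
  if (!identical(expression$sample_ids, genotypes$sample_ids)) {
    stop_mlm("expression and genotype sample ids differ (order matters)")
  }
  rsids <- unique(signals$rsid)
  vidx <- match(rsids, genotypes$variants$rsid)
  if (anyNA(vidx)) {
    stop_mlm("signal(s) not genotyped: ",
             paste(utils::head(rsids[is.na(vidx)], 5), collapse = ", "))
  }
  snp_chr <- normalize_chr(genotypes$variants$chr[vidx])
  snp_pos <- genotypes$variants$pos[vidx]
  snp_maf <- colMeans(genotypes$dosage[, vidx, drop = FALSE], na.rm = TRUE) / 2
  eig_cache <- new.env(parent = emptyenv())
  get_loco_eigen <- function(chr) {
    if (is.null(eig_cache[[chr]])) {
      eig_cache[[chr]] <- grm_eigen(loco_grm(genotypes, chr))
    }
    eig_cache[[chr]]
  }
  rows <- vector("list", length(rsids) * nrow(expression$expr))
  fails <- list()
  k <- 0L
  for (si in seq_along(rsids)) {
    eg <- tryCatch(get_loco_eigen(snp_chr[si]), error = function(e) e)
    for (gi in seq_len(nrow(expression$expr))) {
      k <- k + 1L
      gene_id <- expression$genes$gene_id[gi]
      if (inherits(eg, "error")) {
        fails[[length(fails) + 1L]] <- data.frame(
          snp_id = rsids[si], gene_id = gene_id, error = conditionMessage(eg))
        next
      }
      res <- tryCatch(
        test_variant(expression$expr[gi, ], genotypes$dosage[, vidx[si]], eg,
                     snp_id = rsids[si], gene_id = gene_id),
        error = function(e) e)
      if (inherits(res, "error")) {
        fails[[length(fails) + 1L]] <- data.frame(
          snp_id = rsids[si], gene_id = gene_id, error = conditionMessage(res))
        next
      }
      rows[[k]] <- data.frame(
        snp_id = rsids[si], snp_chr = snp_chr[si], snp_pos = snp_pos[si],
        maf = unname(snp_maf[si]), gene_id = gene_id,
        gene_chr = normalize_chr(expression$genes$chr[gi]),
        beta = res$beta, se = res$se, statistic = res$statistic,
        p = res$p, log10_p = res$log10_p,
        sigma_g2 = res$vc$sigma_g2, sigma_e2 = res$vc$sigma_e2,
        converged = res$vc$converged, stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(results)) {
    results <- data.frame(snp_id = character(), snp_chr = character(),
                          snp_pos = integer(), maf = numeric(),
                          gene_id = character(), gene_chr = character(),
                          beta = numeric(), se = numeric(),
                          statistic = numeric(), p = numeric(),
                          log10_p = numeric(), sigma_g2 = numeric(),
                          sigma_e2 = numeric(), converged = logical(),
                          stringsAsFactors = FALSE)
  }
  sig <- results[results$p < alpha, , drop = FALSE]
  if (nrow(sig)) sig$cis_trans <- classify_cis_trans(sig$snp_chr, sig$gene_chr)
  else sig$cis_trans <- character(0)
  rownames(sig) <- NULL
  failures <- if (length(fails)) do.call(rbind, fails) else
    data.frame(snp_id = character(), gene_id = character(), error = character())
  if (nrow(failures)) {
    message(nrow(failures), " pair(s) failed and were skipped")
  }
  structure(
    list(results = results, significant = sig,
         summary = scan_summary_from_pairs(sig, n_signals_tested = length(rsids),
                                           alpha = alpha),
         failures = failures),
    class = "eqtl_scan"
  )
}

# build a scan_summary from a significant-pair table
scan_summary_from_pairs <- function(sig, n_signals_tested, alpha) {
  ct <- if (nrow(sig)) classify_cis_trans(sig$snp_chr, sig$gene_chr) else character(0)
  structure(
    list(n_signals_tested = n_signals_tested,
         n_signals_with_egene = length(unique(sig$snp_id)),
         n_egenes = nrow(sig),
         n_cis = sum(ct == "cis"),
         n_trans = sum(ct == "trans"),
         alpha = alpha),
    class = "scan_summary"
  )
}

#' @export
print.scan_summary <- function(x, ...) {
  cat("<scan_summary> ", x$n_egenes, " eGene association(s) across ",
      x$n_signals_with_egene, "/", x$n_signals_tested, " signal(s) at p < ",
      format(x$alpha), " (", x$n_cis, " cis / ", x$n_trans, " trans)\n", sep = "")
  invisible(x)
}

#' @export
print.eqtl_scan <- function(x, ...) {
  print(x$summary)
  invisible(x)
}

#' Write scan results and summary to disk
#'
#' Emits a reference-table-style TSV of significant pairs sorted by
#' (snp_chr, snp_pos, ascending p) with p formatted in scientific notation at
#' 3 significant digits (diff-stable), plus a JSON summary.
#'
#' @param scan an `eqtl_scan` from [run_scan()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default "scan").
#' @return named character vector of paths, invisibly.
#' @export
report_scan <- function(scan, dir, prefix = "scan") {
  stopifnot(inherits(scan, "eqtl_scan"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sig <- scan$significant
  ord <- order(sig$snp_chr, sig$snp_pos, sig$p)
  sig <- sig[ord, , drop = FALSE]
  sig$p <- formatC(sig$p, format = "e", digits = 2)
  for (col in c("beta", "se", "statistic", "sigma_g2", "sigma_e2", "log10_p", "maf")) {
    sig[[col]] <- signif(sig[[col]], 6)
  }
  tsv <- file.path(dir, paste0(prefix, "_egenes.tsv"))
  utils::write.table(sig, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  js <- file.path(dir, paste0(prefix, "_summary.json"))
  jsonlite::write_json(unclass(scan$summary), js, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(egenes = tsv, summary = js))
}

#' Read back a summary JSON written by [report_scan()]
#'
#' @param path JSON path.
#' @return a `scan_summary`.
#' @export
read_scan_summary <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x[c("n_signals_tested", "n_signals_with_egene", "n_egenes",
                "n_cis", "n_trans", "alpha")], class = "scan_summary")
}
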