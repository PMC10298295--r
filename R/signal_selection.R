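#' Deduplicate a GWAS signal catalog
#'
#' Keeps the first occurrence of each (rsid, trait_group) pair. The same rsid
#' appearing in both trait groups is retained in both — cross-group
#' duplication is the job of [exclude_shared()], not dedup.
#'
#' @param catalog a `signal_catalog` data.frame.
#' @return the deduplicated catalog.
#' @export
deduplicate <- function(catalog) {
  keep <- !duplicated(paste(catalog$rsid, catalog$trait_group, sep = "\r"))
  out <- catalog[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter catalog signals against the genotype panel
#'
#' Drops signals that are absent from the panel or fail the panel-level minor
#' allele frequency / Hardy-Weinberg filters; retained signals carry their
#' panel statistics. Dropped records (with a reason: "absent", "maf", "hwe")
#' are attached as the `"dropped"` attribute.
#'
#' @param catalog a `signal_catalog`.
#' @param variant_stats per-variant statistics from [variant_stats()].
#' @param maf_min,hwe_alpha filter thresholds (defaults 0.05, 1e-6; exclusion
#'   strict, boundary kept).
#' @return the retained catalog with `maf` and `hwe_p` columns added.
#' @export
filter_by_panel <- function(catalog, variant_stats, maf_min = 0.05,
                            hwe_alpha = 1e-6) {
  idx <- match(catalog$rsid, variant_stats$rsid)
  reason <- rep("", nrow(catalog))
  reason[is.na(idx)] <- "absent"
  maf <- variant_stats$maf[idx]
  hwe <- variant_stats$hwe_p[idx]
  reason[!is.na(idx) & maf < maf_min] <- "maf"
  reason[!is.na(idx) & maf >= maf_min & hwe < hwe_alpha] <- "hwe"
  keep <- reason == ""
  out <- catalog[keep, , drop = FALSE]
  out$maf <- maf[keep]
  out$hwe_p <- hwe[keep]
  rownames(out) <- NULL
  dropped <- catalog[!keep, , drop = FALSE]
  dropped$reason <- reason[!keep]
  attr(out, "dropped") <- dropped
  class(out) <- c("signal_catalog", "data.frame")
  out
}

#' Exclude signals shared between the trait groups
#'
#' Returns target-group signals whose rsids do not occur in the other group,
#' with the funnel counts (target before, shared, target-specific after).
#' Idempotent: re-running on the result changes nothing.
#'
#' @param catalog a `signal_catalog` with a binary `trait_group` column
#'   ("target" / "other").
#' @return an object of class `signal_set`: list with `signals` (the
#'   target-specific catalog rows) and `counts`
#'   (`n_target`, `n_other`, `n_shared`, `n_target_specific`).
#' @export
exclude_shared <- function(catalog) {
  target <- catalog[catalog$trait_group == "target", , drop = FALSE]
  other <- catalog[catalog$trait_group == "other", , drop = FALSE]
  shared_ids <- intersect(unique(target$rsid), unique(other$rsid))
  keep <- !(target$rsid %in% shared_ids)
  signals <- target[keep, , drop = FALSE]
  rownames(signals) <- NULL
  structure(
    list(signals = signals,
         counts = list(n_target = nrow(target), n_other = nrow(other),
                       n_shared = length(shared_ids),
                       n_target_specific = nrow(signals))),
    class = "signal_set"
  )
}

#' @export
print.signal_set <- function(x, ...) {
  cat("<signal_set> ", x$counts$n_target, " target - ", x$counts$n_shared,
      " shared = ", x$counts$n_target_specific, " target-specific signal(s)\n",
      sep = "")
  invisible(x)
}

#' Greedy r-squared pruning to independent signals
#'
#' Iterates signals in input order and drops any signal whose squared
#' genotype correlation with a previously kept signal on the same chromosome
#' exceeds `r2_max`. Signals on different chromosomes never prune each other.
#'
#' @param signals a `signal_catalog` or the `signals` element of a
#'   `signal_set`; rows must be genotyped in `genotypes`.
#' @param genotypes a [genotype_matrix()].
#' @param r2_max pruning threshold (default 0.8).
#' @return the kept signals, with dropped rows (plus `pruned_by`) in the
#'   `"dropped"` attribute.
#' @export
prune_independent <- function(signals, genotypes, r2_max = 0.8) {
  idx <- match(signals$rsid, genotypes$variants$rsid)
  if (anyNA(idx)) {
    stop_mlm("signals not genotyped in panel: ",
             paste(utils::head(signals$rsid[is.na(idx)], 5), collapse = ", "))
  }
  chr <- normalize_chr(genotypes$variants$chr[idx])
  kept <- integer(0)
  pruned_by <- rep(NA_character_, nrow(signals))
  for (i in seq_len(nrow(signals))) {
    clash <- NA_character_
    for (k in kept) {
      if (chr[k] != chr[i]) next
      r2 <- stats::cor(genotypes$dosage[, idx[i]], genotypes$dosage[, idx[k]],
                       use = "pairwise.complete.obs")^2
      if (!is.na(r2) && r2 > r2_max) {
        clash <- signals$rsid[k]
        break
      }
    }
    if (is.na(clash)) kept <- c(kept, i) else pruned_by[i] <- clash
  }
  out <- signals[kept, , drop = FALSE]
  rownames(out) <- NULL
  dropped <- signals[is.na(match(seq_len(nrow(signals)), kept)), , drop = FALSE]
  dropped$pruned_by <- pruned_by[!seq_len(nrow(signals)) %in% kept]
  attr(out, "dropped") <- dropped
  out
}

#' Funnel report for the signal-selection stages
#'
#' @param counts named list/vector of per-stage counts, in funnel order.
#' @param path JSON output path.
#' @return `path`, invisibly.
#' @export
write_funnel_json <- function(counts, path) {
  jsonlite::write_json(counts, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
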