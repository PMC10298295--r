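#' Minor allele frequency from genotype counts
#'
#' Counts are (n_AA, n_Aa, n_aa) with A the major allele; the raw a-allele
#' frequency `(n_Aa + 2 n_aa) / (2 n)` is folded to `min(f, 1 - f)` so the
#' result is always in `[0, 0.5]`.
#'
#' @param counts integer vector of length 3: homozygous-major, heterozygous,
#'   homozygous-minor counts over non-missing calls.
#' @return folded minor allele frequency.
#' @export
minor_allele_frequency <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) != 3 || any(counts < 0)) stop_mlm("counts must be 3 non-negative values")
  n <- sum(counts)
  if (n == 0) stop_mlm("no genotype calls")
  f <- (counts[2] + 2 * counts[3]) / (2 * n)
  min(f, 1 - f)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test on a biallelic genotype table: conditional on the
#' observed allele counts, the p-value sums the probabilities of all
#' heterozygote counts whose conditional probability does not exceed that of
#' the observed count. Probabilities are accumulated by the standard
#' recurrence over heterozygote counts of matching parity. A monomorphic site
#' returns p = 1 by convention.
#'
#' @param counts integer vector (n_AA, n_Aa, n_aa).
#' @return exact p-value in `[0, 1]` (never above 1).
#' @export
hwe_test <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) != 3 || any(counts < 0)) stop_mlm("counts must be 3 non-negative values")
  n <- sum(counts)
  if (n == 0) stop_mlm("no genotype calls")
  n_het <- counts[2]
  n_rare <- 2 * min(counts[1], counts[3]) + n_het
  if (n_rare == 0 || n_rare == 2 * n) return(1)
  # heterozygote counts share the parity of the rare-allele count
  hets <- seq(n_rare %% 2, min(n_rare, 2 * n - n_rare), by = 2)
  # recurse outward from (near) the conditional mode so the unnormalized
  # probabilities never overflow:
  #   P(h+2)/P(h) = 4 hom_r hom_c / ((h+2)(h+1))
  #   P(h-2)/P(h) = h (h-1) / (4 (hom_r+1)(hom_c+1))
  h_exp <- n_rare * (2 * n - n_rare) / (2 * n)
  mid <- which.min(abs(hets - h_exp))
  k <- length(hets)
  probs <- numeric(k)
  probs[mid] <- 1
  if (mid < k) {
    for (i in seq(mid, k - 1)) {
      h <- hets[i]
      hom_r <- (n_rare - h) / 2
      hom_c <- n - h - hom_r
      probs[i + 1] <- probs[i] * 4 * hom_r * hom_c / ((h + 2) * (h + 1))
    }
  }
  if (mid > 1) {
    for (i in seq(mid, 2)) {
      h <- hets[i]
      hom_r <- (n_rare - h) / 2
      hom_c <- n - h - hom_r
      probs[i - 1] <- probs[i] * h * (h - 1) / (4 * (hom_r + 1) * (hom_c + 1))
    }
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_het, hets)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}

#' Per-variant genotype statistics
#'
#' @param genotypes a [genotype_matrix()].
#' @return data.frame with rsid, chr, pos, ref, alt, n_AA, n_Aa, n_aa
#'   (A = major allele), n_missing, maf, hwe_p.
#' @export
variant_stats <- function(genotypes) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  dos <- genotypes$dosage
  n_aa <- colSums(dos == 2, na.rm = TRUE)   # homozygous minor
  n_Aa <- colSums(dos == 1, na.rm = TRUE)
  n_AA <- colSums(dos == 0, na.rm = TRUE)
  stats_df <- genotypes$variants
  stats_df$n_AA <- n_AA
  stats_df$n_Aa <- n_Aa
  stats_df$n_aa <- n_aa
  stats_df$n_missing <- colSums(is.na(dos))
  stats_df$maf <- mapply(function(a, h, b) minor_allele_frequency(c(a, h, b)),
                         n_AA, n_Aa, n_aa)
  stats_df$hwe_p <- mapply(function(a, h, b) hwe_test(c(a, h, b)),
                           n_AA, n_Aa, n_aa)
  rownames(stats_df) <- NULL
  stats_df
}

#' Apply minor-allele-frequency and Hardy-Weinberg variant filters
#'
#' Retains variants with `maf >= maf_min` and `hwe_p >= hwe_alpha` (exclusion
#' is strict, i.e. the boundary stays in). Counts removed per criterion are
#' reported via `message()` and attached as the `"filter_log"` attribute.
#'
#' @param genotypes a [genotype_matrix()].
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @param hwe_alpha minimum Hardy-Weinberg exact p (default 1e-6).
#' @return filtered [genotype_matrix()] with the per-variant statistics of the
#'   kept panel in attribute `"stats"`.
#' @export
apply_variant_filters <- function(genotypes, maf_min = 0.05, hwe_alpha = 1e-6) {
  st <- variant_stats(genotypes)
  fail_maf <- st$maf < maf_min
  fail_hwe <- st$hwe_p < hwe_alpha
  keep <- !fail_maf & !fail_hwe
  if (!any(keep)) stop_mlm("all ", nrow(st), " variants removed by QC filters")
  message(sum(fail_maf), " variant(s) failed MAF < ", maf_min, "; ",
          sum(fail_hwe), " failed HWE p < ", format(hwe_alpha), "; ",
          sum(keep), "/", nrow(st), " retained")
  out <- subset_variants(genotypes, keep)
  attr(out, "stats") <- st[keep, , drop = FALSE]
  attr(out, "filter_log") <- list(n_input = nrow(st), n_fail_maf = sum(fail_maf),
                                  n_fail_hwe = sum(fail_hwe), n_kept = sum(keep),
                                  maf_min = maf_min, hwe_alpha = hwe_alpha)
  out
}

#' Write a variant-statistics TSV with pass/fail annotation
#'
#' @param stats output of [variant_stats()].
#' @param path TSV path.
#' @param maf_min,hwe_alpha filter thresholds used for the pass/fail column.
#' @return `path`, invisibly.
#' @export
write_variant_stats_tsv <- function(stats, path, maf_min = 0.05, hwe_alpha = 1e-6) {
  stats$pass <- stats$maf >= maf_min & stats$hwe_p >= hwe_alpha
  stats$fail_reason <- ifelse(stats$maf < maf_min, "maf",
                              ifelse(stats$hwe_p < hwe_alpha, "hwe", ""))
  utils::write.table(stats, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
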