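#' EM haplotype-frequency estimation for a variant pair
#'
#' Estimates the four haplotype frequencies (p_AB, p_Ab, p_aB, p_ab) from
#' unphased diploid dosages of two biallelic variants, where A/B denote the
#' coded (minor) alleles of variants 1 and 2. Only the double-heterozygote
#' cell is phase-ambiguous; the EM iteration splits it between the AB/ab and
#' Ab/aB phases in proportion to the current frequency products, which
#' maximizes the multinomial likelihood. With no double heterozygotes the
#' estimate equals direct counting and EM converges in one step. From the
#' frequencies: `D = p_AB - p_A p_B`, `D' = |D| / Dmax`, and
#' `r2 = D^2 / (p_A p_a p_B p_b)`.
#'
#' @param g1,g2 dosage vectors in {0,1,2} (NA allowed; pairwise-complete
#'   samples are used).
#' @param tol EM convergence tolerance on the frequency change (default
#'   1e-10).
#' @param max_iter maximum EM iterations (default 1000).
#' @return an object of class `pairwise_ld`: `haplotype_freqs` (named,
#'   sums to 1), `p_A`, `p_B`, `D`, `dprime`, `r2`, `dprime_ci` (90%
#'   two-sided, from [dprime_ci()]), `n_informative`, `table`, `loglik`,
#'   `n_iter`.
#' @export
em_haplotypes <- function(g1, g2, tol = 1e-10, max_iter = 1000L) {
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]
  g2 <- g2[ok]
  n <- length(g1)
  if (n == 0L) stop_mlm("no pairwise-complete samples")
  if (stats::var(g1) == 0 || stats::var(g2) == 0) stop_mlm("monomorphic input variant")
  tab <- matrix(0, 3, 3, dimnames = list(paste0("g1_", 0:2), paste0("g2_", 0:2)))
  for (i in 0:2) for (j in 0:2) tab[i + 1, j + 1] <- sum(g1 == i & g2 == j)
  # unambiguous haplotype counts (A = coded allele of g1, B = of g2):
  # cell (i,j) = counts of individuals with i copies of A and j of B
  nAB <- 2 * tab[3, 3] + tab[3, 2] + tab[2, 3]
  nAb <- 2 * tab[3, 1] + tab[3, 2] + tab[2, 1]
  naB <- 2 * tab[1, 3] + tab[1, 2] + tab[2, 3]
  nab <- 2 * tab[1, 1] + tab[1, 2] + tab[2, 1]
  ndh <- tab[2, 2]  # double heterozygotes: AB/ab or Ab/aB
  freqs <- c(AB = nAB + ndh / 2, Ab = nAb + ndh / 2,
             aB = naB + ndh / 2, ab = nab + ndh / 2)
  freqs <- freqs / sum(freqs)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    num_cis <- unname(freqs["AB"] * freqs["ab"])
    num_trans <- unname(freqs["Ab"] * freqs["aB"])
    w <- if (num_cis + num_trans > 0) num_cis / (num_cis + num_trans) else 0.5
    new <- c(AB = nAB + ndh * w, Ab = nAb + ndh * (1 - w),
             aB = naB + ndh * (1 - w), ab = nab + ndh * w)
    new <- new / sum(new)
    delta <- max(abs(new - freqs))
    freqs <- new
    if (ndh == 0L || delta < tol || iter >= max_iter) break
  }
  pA <- freqs["AB"] + freqs["Ab"]
  pB <- freqs["AB"] + freqs["aB"]
  D <- unname(freqs["AB"] - pA * pB)
  Dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB) else min(pA * pB, (1 - pA) * (1 - pB))
  dprime <- if (Dmax > 0) abs(D) / Dmax else 0
  denom <- pA * (1 - pA) * pB * (1 - pB)
  r2 <- if (denom > 0) D^2 / denom else 0
  out <- structure(
    list(haplotype_freqs = freqs, p_A = unname(pA), p_B = unname(pB), D = D,
         dprime = min(dprime, 1), r2 = min(r2, 1), n_informative = n,
         table = tab, loglik = ld_table_loglik(tab, freqs), n_iter = iter,
         dprime_ci = NULL),
    class = "pairwise_ld"
  )
  out$dprime_ci <- dprime_ci(out)
  out
}

# multinomial log-likelihood of the 3x3 genotype table under random union of
# gametes with the given haplotype frequencies
ld_table_loglik <- function(tab, freqs) {
  pAB <- freqs["AB"]; pAb <- freqs["Ab"]; paB <- freqs["aB"]; pab <- freqs["ab"]
  probs <- matrix(0, 3, 3)
  probs[3, 3] <- pAB^2
  probs[3, 2] <- 2 * pAB * pAb
  probs[3, 1] <- pAb^2
  probs[2, 3] <- 2 * pAB * paB
  probs[2, 2] <- 2 * (pAB * pab + pAb * paB)
  probs[2, 1] <- 2 * pAb * pab
  probs[1, 3] <- paB^2
  probs[1, 2] <- 2 * paB * pab
  probs[1, 1] <- pab^2
  sum(tab[tab > 0] * log(pmax(probs[tab > 0], 1e-300)))
}

#' Likelihood-based confidence interval for D'
#'
#' Profiles the multinomial log-likelihood of the genotype table over a fixed
#' 101-point grid of D' in `[0, 1]` (holding the allele-frequency marginals at
#' their EM estimates and the sign of D at its point estimate), normalizes the
#' likelihood curve, and reports the 5th and 95th percentiles of the
#' normalized curve as the two-sided 90% interval — the construction used for
#' Gabriel-style block finding. Bounds are clamped to bracket the point
#' estimate (grid discreteness).
#'
#' @param pairwise a `pairwise_ld` from [em_haplotypes()].
#' @param grid_points number of grid points (default 101).
#' @return numeric `c(low, high)`.
#' @export
dprime_ci <- function(pairwise, grid_points = 101L) {
  stopifnot(inherits(pairwise, "pairwise_ld"))
  pA <- pairwise$p_A
  pB <- pairwise$p_B
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1) stop_mlm("degenerate frequency table")
  sgn <- if (pairwise$D >= 0) 1 else -1
  Dmax <- if (sgn > 0) min(pA * (1 - pB), (1 - pA) * pB) else min(pA * pB, (1 - pA) * (1 - pB))
  grid <- seq(0, 1, length.out = grid_points)
  ll <- vapply(grid, function(dp) {
    D <- sgn * dp * Dmax
    freqs <- c(AB = pA * pB + D, Ab = pA * (1 - pB) - D,
               aB = (1 - pA) * pB - D, ab = (1 - pA) * (1 - pB) + D)
    freqs <- pmax(freqs, 0)
    ld_table_loglik(pairwise$table, freqs / sum(freqs))
  }, numeric(1))
  lik <- exp(ll - max(ll))
  cum <- cumsum(lik) / sum(lik)
  # both bounds are the grid cells where the cumulative curve crosses the
  # 5th / 95th percentile (the crossing cell is included on both sides)
  low <- grid[which(cum >= 0.05)[1]]
  high <- grid[which(cum >= 0.95)[1]]
  c(low = min(low, pairwise$dprime), high = max(high, pairwise$dprime))
}

#' @export
print.pairwise_ld <- function(x, ...) {
  cat("<pairwise_ld> D' = ", round(x$dprime, 3), " [",
      round(x$dprime_ci[1], 3), ", ", round(x$dprime_ci[2], 3),
      "], r2 = ", round(x$r2, 3), " (n = ", x$n_informative, ")\n", sep = "")
  invisible(x)
}

#' Gabriel-style haplotype block partition of one chromosome
#'
#' Classifies every variant pair by the D' confidence interval from
#' [dprime_ci()]: "strong LD" when CI low >= `ci_low_strong` and CI high >=
#' `ci_high_strong`; "strong recombination" when CI high < `ci_high_recomb`;
#' otherwise uninformative. A candidate span of two or more consecutive
#' variants is accepted when it has at least one informative pair and the
#' strong-LD fraction among informative pairs is at least `frac_strong`.
#' Overlapping candidates are resolved greedily, longest (variant count)
#' first, ties broken by leftmost start position. Markers below `maf_min` are
#' skipped. Thresholds default to the Haploview values.
#'
#' @param genotypes a [genotype_matrix()] whose variants lie on one
#'   chromosome (or use `chr` to select one).
#' @param chr optional chromosome label to subset to.
#' @param maf_min minimum MAF for a marker to enter block finding
#'   (default 0.05).
#' @param ci_low_strong,ci_high_strong,ci_high_recomb,frac_strong Gabriel rule
#'   thresholds (defaults 0.70, 0.98, 0.90, 0.95).
#' @return list of `haplo_block` objects, each with `chr`, `variant_ids`,
#'   `start_pos`, `end_pos`, `indices` (into the filtered marker set), plus
#'   attribute `"markers"` (the marker table used) and `"pair_class"`.
#' @export
gabriel_blocks <- function(genotypes, chr = NULL, maf_min = 0.05,
                           ci_low_strong = 0.70, ci_high_strong = 0.98,
                           ci_high_recomb = 0.90, frac_strong = 0.95) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  v <- genotypes$variants
  keep <- rep(TRUE, nrow(v))
  if (!is.null(chr)) keep <- normalize_chr(v$chr) == normalize_chr(chr)
  if (length(unique(normalize_chr(v$chr[keep]))) > 1) {
    stop_mlm("variants span multiple chromosomes; pass `chr`")
  }
  dos <- genotypes$dosage[, keep, drop = FALSE]
  v <- v[keep, , drop = FALSE]
  maf <- colMeans(dos, na.rm = TRUE) / 2
  poly <- maf >= maf_min & maf <= 1 - maf_min
  dos <- dos[, poly, drop = FALSE]
  v <- v[poly, , drop = FALSE]
  ord <- order(v$pos)
  dos <- dos[, ord, drop = FALSE]
  v <- v[ord, , drop = FALSE]
  m <- ncol(dos)
  blocks <- list()
  if (m >= 2) {
    cls <- matrix(NA_character_, m, m)
    for (i in seq_len(m - 1)) {
      for (j in seq(i + 1, m)) {
        ld <- em_haplotypes(dos[, i], dos[, j])
        ci <- ld$dprime_ci
        cls[i, j] <- if (ci[1] >= ci_low_strong && ci[2] >= ci_high_strong) "strong"
        else if (ci[2] < ci_high_recomb) "recomb"
        else "uninformative"
      }
    }
    cand <- list()
    for (i in seq_len(m - 1)) {
      for (j in seq(i + 1, m)) {
        sub <- cls[i:j, i:j]
        pair_cls <- sub[upper.tri(sub)]
        n_inf <- sum(pair_cls != "uninformative")
        if (n_inf >= 1 && sum(pair_cls == "strong") / n_inf >= frac_strong) {
          cand[[length(cand) + 1L]] <- c(i = i, j = j)
        }
      }
    }
    if (length(cand)) {
      lens <- vapply(cand, function(z) z["j"] - z["i"] + 1L, numeric(1))
      starts <- vapply(cand, function(z) v$pos[z["i"]], numeric(1))
      used <- rep(FALSE, m)
      for (k in order(-lens, starts)) {
        i <- cand[[k]]["i"]; j <- cand[[k]]["j"]
        if (!any(used[i:j])) {
          used[i:j] <- TRUE
          blocks[[length(blocks) + 1L]] <- structure(
            list(chr = v$chr[i], variant_ids = v$rsid[i:j],
                 start_pos = v$pos[i], end_pos = v$pos[j],
                 indices = i:j),
            class = "haplo_block")
        }
      }
      # report blocks left-to-right
      blocks <- blocks[order(vapply(blocks, function(b) b$start_pos, numeric(1)))]
    }
    attr(blocks, "pair_class") <- cls
  }
  attr(blocks, "markers") <- v
  blocks
}

#' Attach a significant variant to its haplotype block
#'
#' @param variant_id rsid of a significant variant.
#' @param blocks list of `haplo_block`s for its chromosome
#'   (from [gabriel_blocks()]).
#' @return the containing `haplo_block`, or a singleton marker of class
#'   `singleton_signal` when the variant lies in no block.
#' @export
assign_to_block <- function(variant_id, blocks) {
  for (b in blocks) {
    if (variant_id %in% b$variant_ids) return(b)
  }
  structure(list(variant_id = variant_id), class = "singleton_signal")
}

#' Collapse significant variants into independent eQTL signals
#'
#' Significant variants falling in the same Gabriel block are one independent
#' signal; the most significant member (smallest p) is retained as the index
#' variant. Variants outside every block are their own singleton signals.
#'
#' @param sig data.frame with columns `snp_id` and `p` (or `log10_p`).
#' @param blocks list of `haplo_block`s covering the variants' chromosome.
#' @return data.frame of independent signals: `index_snp`, `p`, `n_members`,
#'   `block_start`, `block_end` (NA for singletons).
#' @export
collapse_to_independent <- function(sig, blocks) {
  if (nrow(sig) == 0) {
    return(data.frame(index_snp = character(), p = numeric(),
                      n_members = integer(), block_start = numeric(),
                      block_end = numeric(), stringsAsFactors = FALSE))
  }
  key <- vapply(sig$snp_id, function(id) {
    for (bi in seq_along(blocks)) if (id %in% blocks[[bi]]$variant_ids) return(paste0("block_", bi))
    paste0("singleton_", id)
  }, character(1))
  out <- do.call(rbind, lapply(split(sig, key), function(grp) {
    best <- grp[which.min(grp$p), , drop = FALSE]
    bi <- if (startsWith(key[match(best$snp_id, sig$snp_id)], "block_")) {
      as.integer(sub("block_", "", key[match(best$snp_id, sig$snp_id)]))
    } else NA_integer_
    data.frame(index_snp = best$snp_id, p = best$p, n_members = nrow(grp),
               block_start = if (!is.na(bi)) blocks[[bi]]$start_pos else NA_real_,
               block_end = if (!is.na(bi)) blocks[[bi]]$end_pos else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$p), , drop = FALSE]
}

#' Write Gabriel blocks as BED and pairwise LD as TSV
#'
#' BED uses 0-based half-open intervals.
#'
#' @param blocks output of [gabriel_blocks()].
#' @param path_bed BED output path.
#' @return `path_bed`, invisibly.
#' @export
write_blocks_bed <- function(blocks, path_bed) {
  if (!length(blocks)) {
    writeLines(character(0), path_bed)
    return(invisible(path_bed))
  }
  lines <- vapply(seq_along(blocks), function(i) {
    b <- blocks[[i]]
    paste(b$chr, b$start_pos - 1L, b$end_pos, paste0("block_", i),
          length(b$variant_ids), sep = "\t")
  }, character(1))
  writeLines(lines, path_bed)
  invisible(path_bed)
}
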