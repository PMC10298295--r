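#' Simulation configuration
#'
#' Bundles the generative parameters of the synthetic cohort: panel geometry,
#' minor-allele-frequency spectrum, block-wise linkage disequilibrium, and the
#' variance components of the single-variant mixed model
#' \deqn{y = x\beta + g + \epsilon,\qquad g \sim N(0, G\sigma_g^2),\quad
#'       \epsilon \sim N(0, I\sigma_e^2).}
#'
#' @param n_individuals number of diploid individuals (n > 0).
#' @param n_chromosomes number of chromosomes in the panel.
#' @param variants_per_chr variants simulated per chromosome.
#' @param maf_range length-2 numeric in (0, 0.5]; population minor-allele
#'   frequencies are drawn uniformly from this interval.
#' @param ld_block_span number of consecutive variants per LD block.
#' @param ld_rho within-block haplotype correlation in `[0, 1]`: the
#'   probability that two variants of a block share their haplotype's latent
#'   ancestral allele (0 = linkage equilibrium, 1 = perfect copying; see
#'   [simulate_genotypes()]).
#' @param beta fixed effect of the causal variant, in expression-SD units per
#'   minor allele.
#' @param sigma_g2 polygenic variance component (>= 0).
#' @param sigma_e2 residual variance component (>= 0; 0 is the noise-free
#'   testing limit).
#' @param seed integer seed; fully determines every simulated output.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_individuals, n_chromosomes = 3L, variants_per_chr = 50L,
                       maf_range = c(0.05, 0.5), ld_block_span = 5L, ld_rho = 0,
                       beta = 0, sigma_g2 = 0.4, sigma_e2 = 0.6, seed = 1L) {
  if (n_individuals < 1 || n_chromosomes < 1 || variants_per_chr < 1 || ld_block_span < 1) {
    stop_mlm("dimensions must be positive")
  }
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stop_mlm("maf_range must lie within (0, 0.5]")
  }
  if (ld_rho < 0 || ld_rho > 1) stop_mlm("ld_rho must be in [0, 1]")
  if (sigma_g2 < 0) stop_mlm("sigma_g2 must be >= 0")
  if (sigma_e2 < 0) stop_mlm("sigma_e2 must be >= 0")
  structure(
    list(n_individuals = as.integer(n_individuals),
         n_chromosomes = as.integer(n_chromosomes),
         variants_per_chr = as.integer(variants_per_chr),
         maf_range = as.numeric(maf_range),
         ld_block_span = as.integer(ld_block_span),
         ld_rho = as.numeric(ld_rho),
         beta = as.numeric(beta),
         sigma_g2 = as.numeric(sigma_g2),
         sigma_e2 = as.numeric(sigma_e2),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate a diploid genotype panel
#'
#' Haplotypes are drawn per LD block by ancestral copying: each haplotype
#' carries one latent ancestral allele per block (drawn at the block's first
#' variant's frequency), and every variant in the block copies that ancestral
#' allele with probability `sqrt(ld_rho)`, otherwise draws fresh from its own
#' frequency. Any two variants in a block therefore share the ancestral state
#' with probability `ld_rho`, giving an equicorrelated within-block LD
#' structure (D-prime ~ `ld_rho` for every pair when frequencies are similar)
#' — the haplotype-block pattern, rather than a per-step decay. Two
#' independent haplotypes are paired per individual, so Hardy-Weinberg
#' equilibrium holds in expectation at every variant. Dosages are re-oriented
#' to the cohort minor allele.
#'
#' @param config a [sim_config()].
#' @return a [genotype_matrix()] with `chr` labels `"1" ... "K"`, positions
#'   spaced 5 kb apart, and ref/alt alleles assigned deterministically under
#'   the config seed.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_individuals
  nhap <- 2L * n
  mk <- config$variants_per_chr
  bases <- c("A", "C", "G", "T")
  dos_all <- vector("list", config$n_chromosomes)
  meta_all <- vector("list", config$n_chromosomes)
  for (chr in seq_len(config$n_chromosomes)) {
    f <- stats::runif(mk, config$maf_range[1], config$maf_range[2])
    block_id <- (seq_len(mk) - 1L) %/% config$ld_block_span
    c_copy <- sqrt(config$ld_rho)
    hap <- matrix(0L, nhap, mk)
    ancestor <- NULL
    for (j in seq_len(mk)) {
      fresh <- stats::rbinom(nhap, 1L, f[j])
      new_block <- j == 1L || block_id[j] != block_id[j - 1L]
      if (new_block) ancestor <- stats::rbinom(nhap, 1L, f[j])
      if (config$ld_rho == 0) {
        hap[, j] <- fresh
      } else {
        copy <- stats::runif(nhap) < c_copy
        hap[, j] <- ifelse(copy, ancestor, fresh)
      }
    }
    dos <- hap[seq(1L, nhap, by = 2L), , drop = FALSE] +
      hap[seq(2L, nhap, by = 2L), , drop = FALSE]
    ref <- sample(bases, mk, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
    meta_all[[chr]] <- data.frame(
      rsid = sprintf("rs%d%05d", chr, seq_len(mk)),
      chr = as.character(chr),
      pos = 5000L * seq_len(mk),
      ref = ref, alt = alt,
      stringsAsFactors = FALSE, row.names = NULL
    )
    dos_all[[chr]] <- dos
  }
  genotype_matrix(do.call(cbind, dos_all), do.call(rbind, meta_all),
                  sample_ids = sprintf("ind_%04d", seq_len(n)))
}

#' Simulate expression for one gene under the mixed model
#'
#' Draws `y = x beta + g + eps` where `x` is the minor-allele dosage of the
#' causal variant, `g ~ N(0, G sigma_g2)` with `G` the leave-one-chromosome-out
#' genomic similarity matrix excluding the causal variant's chromosome (bent to
#' positive semidefinite by flooring eigenvalues at zero before
#' factorization), and `eps` iid `N(0, sigma_e2)`. With `sigma_g2 = 0` no GRM
#' is formed and `g = 0`.
#'
#' Seeding: uses `config$seed + 1` so the draw is deterministic whether or not
#' [simulate_genotypes()] ran just before.
#'
#' @param genotypes a [genotype_matrix()].
#' @param causal_variant rsid of the causal variant (must exist in the panel).
#' @param config a [sim_config()]; supplies beta, sigma_g2, sigma_e2, seed.
#' @param gene_id,gene_chr,gene_start,gene_end gene annotation; defaults place
#'   the gene on the causal variant's chromosome around its position (a cis
#'   configuration).
#' @return list with `expression` (an [expression_matrix()] of one gene) and
#'   `truth` (beta, sigma_g2, sigma_e2, causal_variant, gene_id).
#' @export
simulate_expression <- function(genotypes, causal_variant, config,
                                gene_id = "gene_1", gene_chr = NULL,
                                gene_start = NULL, gene_end = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"), inherits(config, "sim_config"))
  idx <- match(causal_variant, genotypes$variants$rsid)
  if (is.na(idx)) stop_mlm("unknown causal variant: ", causal_variant)
  n <- nrow(genotypes$dosage)
  x <- genotypes$dosage[, idx]
  causal_chr <- genotypes$variants$chr[idx]
  set.seed(config$seed + 1L)
  g <- rep(0, n)
  if (config$sigma_g2 > 0) {
    G <- loco_grm(genotypes, causal_chr)
    eg <- eigen(G$matrix, symmetric = TRUE)
    d <- pmax(eg$values, 0)  # bend to PSD
    g <- as.vector(eg$vectors %*% (sqrt(d * config$sigma_g2) * stats::rnorm(n)))
  }
  eps <- if (config$sigma_e2 > 0) stats::rnorm(n, 0, sqrt(config$sigma_e2)) else rep(0, n)
  y <- x * config$beta + g + eps
  pos <- genotypes$variants$pos[idx]
  genes <- data.frame(
    gene_id = gene_id,
    chr = gene_chr %||% causal_chr,
    start = gene_start %||% max(1L, pos - 1000L),
    end = gene_end %||% (pos + 1000L),
    stringsAsFactors = FALSE
  )
  list(
    expression = expression_matrix(matrix(y, nrow = 1), genes, genotypes$sample_ids),
    truth = list(beta = config$beta, sigma_g2 = config$sigma_g2,
                 sigma_e2 = config$sigma_e2, causal_variant = causal_variant,
                 gene_id = gene_id)
  )
}

#' Simulate a two-trait GWAS signal catalog
#'
#' Produces `n_target` signals labeled for the target trait and `n_other` for
#' the contrast trait group, with exactly `n_shared` rsIDs present in both
#' groups (the overlap the downstream exclusion step removes).
#'
#' @param n_target,n_other group sizes.
#' @param n_shared number of rsIDs shared by both groups; must not exceed
#'   `min(n_target, n_other)`.
#' @param seed integer seed.
#' @return a `signal_catalog` data.frame with columns rsid, chr, pos, ref,
#'   alt, trait_group ("target"/"other"), source_maf.
#' @export
simulate_signal_catalog <- function(n_target, n_other, n_shared, seed = 1L) {
  if (n_shared > min(n_target, n_other)) {
    stop_mlm("n_shared may not exceed min(n_target, n_other)")
  }
  set.seed(seed)
  n_unique <- n_target + n_other - n_shared
  rsid_pool <- sprintf("rs%07d", sample.int(9999999L, n_unique))
  shared <- rsid_pool[seq_len(n_shared)]
  target_only <- rsid_pool[n_shared + seq_len(n_target - n_shared)]
  other_only <- rsid_pool[n_target + seq_len(n_other - n_shared)]
  make_rows <- function(ids, group) {
    m <- length(ids)
    if (m == 0L) {
      return(data.frame(rsid = character(), chr = character(), pos = integer(),
                        ref = character(), alt = character(),
                        trait_group = character(), source_maf = numeric(),
                        stringsAsFactors = FALSE))
    }
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, m, replace = TRUE)
    data.frame(
      rsid = ids,
      chr = as.character(sample.int(22L, m, replace = TRUE)),
      pos = sample.int(2e8L, m),
      ref = ref,
      alt = vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1)),
      trait_group = group,
      source_maf = round(stats::runif(m, 0.05, 0.5), 3),
      stringsAsFactors = FALSE
    )
  }
  # shared rsIDs keep identical annotation in both groups
  shared_rows <- make_rows(shared, "target")
  shared_other <- shared_rows
  shared_other$trait_group <- rep("other", nrow(shared_other))
  out <- rbind(
    shared_rows,
    make_rows(target_only, "target"),
    shared_other,
    make_rows(other_only, "other")
  )
  rownames(out) <- NULL
  class(out) <- c("signal_catalog", "data.frame")
  out
}
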