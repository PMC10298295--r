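# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: brute-force enumeration, double loops,
# dense grids.

# Exact HWE p by direct enumeration: P(h | n, n_rare) from the log-factorial
# formula, no recurrence.
hwe_enum_p <- function(counts) {
  n <- sum(counts)
  n_het <- counts[2]
  n_rare <- 2 * min(counts[1], counts[3]) + n_het
  if (n_rare == 0 || n_rare == 2 * n) return(1)
  hets <- seq(n_rare %% 2, min(n_rare, 2 * n - n_rare), by = 2)
  logp <- vapply(hets, function(h) {
    hom_r <- (n_rare - h) / 2
    hom_c <- n - h - hom_r
    lfactorial(n) - lfactorial(hom_r) - lfactorial(h) - lfactorial(hom_c) +
      h * log(2) + lfactorial(n_rare) + lfactorial(2 * n - n_rare) -
      lfactorial(2 * n)
  }, numeric(1))
  probs <- exp(logp - max(logp))
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_het, hets)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}

# Double-loop evaluation of the genomic-similarity formula on a dosage matrix
# (individuals x variants), mean-imputing missing dosages.
grm_bruteforce <- function(dos) {
  n <- nrow(dos)
  m <- ncol(dos)
  f <- colMeans(dos, na.rm = TRUE) / 2
  G <- matrix(0, n, n)
  for (j in seq_len(n)) {
    for (k in seq_len(n)) {
      acc <- 0
      for (i in seq_len(m)) {
        tj <- dos[j, i]
        tk <- dos[k, i]
        if (is.na(tj)) tj <- 2 * f[i]
        if (is.na(tk)) tk <- 2 * f[i]
        acc <- acc + (tj - 2 * f[i]) * (tk - 2 * f[i]) / (2 * f[i] * (1 - f[i]))
      }
      G[j, k] <- acc / m
    }
  }
  G
}

# Two-stage dense grid search for the REML-optimal variance ratio
# h = sg / (sg + se), profiling the total variance in closed form and scoring
# each candidate with the package's dense restricted_log_likelihood.
grid_reml_h <- function(y, X, G) {
  n <- length(y)
  p <- ncol(X)
  eval_h <- function(h) {
    K <- h * G + (1 - h) * diag(n)
    Ki <- solve(K)
    XtKX <- t(X) %*% Ki %*% X
    P <- Ki - Ki %*% X %*% solve(XtKX, t(X) %*% Ki)
    s <- as.numeric(t(y) %*% P %*% y) / (n - p)
    restricted_log_likelihood(y, X, G, h * s, (1 - h) * s)
  }
  coarse <- seq(0, 0.999, by = 0.001)
  ll <- vapply(coarse, eval_h, numeric(1))
  h0 <- coarse[which.max(ll)]
  fine <- seq(max(0, h0 - 0.0015), min(0.99999, h0 + 0.0015), by = 1e-5)
  llf <- vapply(fine, eval_h, numeric(1))
  fine[which.max(llf)]
}

# Fine grid search over p_AB maximizing the multinomial genotype-table
# likelihood with the allele-frequency marginals held at their observed
# values; independent of the EM route.
grid_em_pAB <- function(g1, g2, step = 1e-5) {
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]; g2 <- g2[ok]
  tab <- matrix(0, 3, 3)
  for (i in 0:2) for (j in 0:2) tab[i + 1, j + 1] <- sum(g1 == i & g2 == j)
  pA <- mean(g1) / 2
  pB <- mean(g2) / 2
  lo <- max(0, pA + pB - 1)
  hi <- min(pA, pB)
  grid <- seq(lo, hi, by = step)
  ll <- vapply(grid, function(pAB) {
    f <- c(pAB, pA - pAB, pB - pAB, 1 - pA - pB + pAB)
    f <- pmax(f, 1e-12)
    probs <- matrix(0, 3, 3)
    probs[3, 3] <- f[1]^2;          probs[3, 2] <- 2 * f[1] * f[2]
    probs[3, 1] <- f[2]^2;          probs[2, 3] <- 2 * f[1] * f[3]
    probs[2, 2] <- 2 * (f[1] * f[4] + f[2] * f[3])
    probs[2, 1] <- 2 * f[2] * f[4]; probs[1, 3] <- f[3]^2
    probs[1, 2] <- 2 * f[3] * f[4]; probs[1, 1] <- f[4]^2
    sum(tab[tab > 0] * log(probs[tab > 0]))
  }, numeric(1))
  grid[which.max(ll)]
}

# Random GRM built from a simulated panel (monomorphic draws dropped). Note a
# sample-frequency GRM is exactly singular (rows sum to zero), so use
# rand_pd_matrix when an invertible G is required.
rand_grm_matrix <- function(n, nv, seed) {
  cfg <- sim_config(n_individuals = n, n_chromosomes = 1L, variants_per_chr = nv,
                    maf_range = c(0.1, 0.5), ld_rho = 0, seed = seed)
  gt <- simulate_genotypes(cfg)
  f <- colMeans(gt$dosage) / 2
  compute_grm(gt, mask = f > 0 & f < 1)$matrix
}

# Random well-conditioned positive-definite covariance with unit-scale
# diagonal, for exercising the Henderson route (needs G invertible).
rand_pd_matrix <- function(n, seed) {
  set.seed(seed)
  A <- matrix(rnorm(2 * n * n), 2 * n, n)
  G <- crossprod(A) / (2 * n)
  G / mean(diag(G))
}

# Panel with a planted high-LD block: `n_flank` independent variants, then a
# `span`-variant block copied at rate rho, then `n_flank` more independents;
# all on one chromosome with increasing positions.
make_planted_block_panel <- function(n = 200, n_flank = 3, span = 5,
                                     rho = 0.95, seed = 1) {
  cfg_flank1 <- sim_config(n, 1L, n_flank, maf_range = c(0.2, 0.5),
                           ld_rho = 0, seed = seed)
  cfg_block <- sim_config(n, 1L, span, maf_range = c(0.25, 0.45),
                          ld_block_span = span, ld_rho = rho, seed = seed + 1L)
  cfg_flank2 <- sim_config(n, 1L, n_flank, maf_range = c(0.2, 0.5),
                           ld_rho = 0, seed = seed + 2L)
  parts <- lapply(list(cfg_flank1, cfg_block, cfg_flank2), simulate_genotypes)
  dos <- do.call(cbind, lapply(parts, function(g) g$dosage))
  m <- ncol(dos)
  variants <- data.frame(
    rsid = sprintf("pv%02d", seq_len(m)), chr = "1", pos = 10000L * seq_len(m),
    ref = "A", alt = "G", stringsAsFactors = FALSE)
  list(panel = genotype_matrix(dos, variants),
       block_ids = sprintf("pv%02d", n_flank + seq_len(span)))
}

# Greedy r2-pruning replayed naively (reference for prune_independent).
prune_bruteforce <- function(signals, genotypes, r2_max) {
  idx <- match(signals$rsid, genotypes$variants$rsid)
  chr <- normalize_chr(genotypes$variants$chr[idx])
  kept <- c()
  for (i in seq_len(nrow(signals))) {
    drop <- FALSE
    for (k in kept) {
      if (chr[k] == chr[i] &&
          cor(genotypes$dosage[, idx[i]], genotypes$dosage[, idx[k]])^2 > r2_max) {
        drop <- TRUE
        break
      }
    }
    if (!drop) kept <- c(kept, i)
  }
  signals$rsid[kept]
}
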