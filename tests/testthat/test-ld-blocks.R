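test_that("unambiguous phase converges in one EM step to direct counts", {
  # no double heterozygotes: haplotypes fully determined
  g1 <- c(0, 0, 2, 2, 1, 0, 2)
  g2 <- c(0, 0, 2, 2, 0, 1, 2)
  ld <- em_haplotypes(g1, g2)
  expect_equal(ld$n_iter, 1L)
  n_hap <- 2 * length(g1)
  # hand count: individuals (2,2) x3 give six AB; (1,0) gives Ab+ab; (0,1) aB+ab
  expect_equal(unname(ld$haplotype_freqs["AB"]), 6 / n_hap)
  expect_equal(sum(ld$haplotype_freqs), 1)
})

test_that("a variant is in perfect LD with itself", {
  set.seed(41)
  g <- rbinom(200, 2, 0.3)
  ld <- em_haplotypes(g, g)
  expect_equal(ld$dprime, 1)
  expect_equal(ld$r2, 1)
  expect_gte(ld$dprime_ci[1], 0.9)  # CI low -> 1 at large n
  expect_error(em_haplotypes(g, rep(1, 200)), "monomorphic")
})

test_that("EM frequencies sum to one and preserve the allele-frequency marginals", {
  set.seed(42)
  for (r in 1:20) {
    g1 <- rbinom(50, 2, runif(1, 0.15, 0.5))
    g2 <- rbinom(50, 2, runif(1, 0.15, 0.5))
    if (var(g1) == 0 || var(g2) == 0) next
    ld <- em_haplotypes(g1, g2)
    expect_equal(sum(ld$haplotype_freqs), 1, tolerance = 1e-9)
    expect_equal(ld$p_A, mean(g1) / 2, tolerance = 1e-8)
    expect_equal(ld$p_B, mean(g2) / 2, tolerance = 1e-8)
    expect_lte(ld$r2, 1)
    expect_lte(ld$dprime, 1)
    expect_true(ld$dprime_ci[1] <= ld$dprime && ld$dprime <= ld$dprime_ci[2])
  }
})

test_that("EM matches a fine grid search of the multinomial likelihood", {
  set.seed(43)
  done <- 0
  while (done < 8) {
    f1 <- runif(1, 0.2, 0.5)
    g1 <- rbinom(30, 2, f1)
    # induce correlation for some pairs
    g2 <- if (done %% 2) rbinom(30, 2, runif(1, 0.2, 0.5)) else
      pmin(2, pmax(0, g1 + rbinom(30, 1, 0.3) - rbinom(30, 1, 0.3)))
    if (var(g1) == 0 || var(g2) == 0) next
    done <- done + 1
    ld <- em_haplotypes(g1, g2)
    expect_equal(unname(ld$haplotype_freqs["AB"]), grid_em_pAB(g1, g2),
                 tolerance = 1e-4)
  }
})

test_that("D' statistics are invariant to variant order and allele relabeling", {
  set.seed(44)
  g1 <- rbinom(120, 2, 0.35)
  g2 <- pmin(2, pmax(0, g1 + rbinom(120, 1, 0.4) - rbinom(120, 1, 0.4)))
  ld <- em_haplotypes(g1, g2)
  swapped <- em_haplotypes(g2, g1)
  expect_equal(swapped$dprime, ld$dprime, tolerance = 1e-9)
  expect_equal(swapped$r2, ld$r2, tolerance = 1e-9)
  expect_equal(swapped$dprime_ci, ld$dprime_ci, tolerance = 1e-9)
  relabeled <- em_haplotypes(2 - g1, g2)
  expect_equal(relabeled$dprime, ld$dprime, tolerance = 1e-9)
  expect_equal(relabeled$r2, ld$r2, tolerance = 1e-9)
  expect_equal(relabeled$dprime_ci, ld$dprime_ci, tolerance = 1e-9)
})

test_that("the D' confidence interval matches brute-force likelihood-curve integration", {
  g1 <- c(rep(0, 10), rep(1, 12), rep(2, 8))
  g2 <- c(rep(0, 9), rep(1, 13), rep(2, 8))
  ld <- em_haplotypes(g1, g2)
  # independent re-integration of the normalized likelihood curve
  pA <- ld$p_A; pB <- ld$p_B
  sgn <- if (ld$D >= 0) 1 else -1
  Dmax <- if (sgn > 0) min(pA * (1 - pB), (1 - pA) * pB) else
    min(pA * pB, (1 - pA) * (1 - pB))
  grid <- seq(0, 1, length.out = 101)
  tab <- ld$table
  ll <- sapply(grid, function(dp) {
    D <- sgn * dp * Dmax
    f <- pmax(c(pA * pB + D, pA * (1 - pB) - D,
                (1 - pA) * pB - D, (1 - pA) * (1 - pB) + D), 0)
    f <- f / sum(f)
    pr <- c(f[1]^2, 2 * f[1] * f[2], f[2]^2, 2 * f[1] * f[3],
            2 * (f[1] * f[4] + f[2] * f[3]), 2 * f[2] * f[4],
            f[3]^2, 2 * f[3] * f[4], f[4]^2)
    cnt <- c(tab[3, 3], tab[3, 2], tab[3, 1], tab[2, 3], tab[2, 2],
             tab[2, 1], tab[1, 3], tab[1, 2], tab[1, 1])
    sum(cnt[cnt > 0] * log(pmax(pr[cnt > 0], 1e-300)))
  })
  lik <- exp(ll - max(ll))
  cum <- cumsum(lik) / sum(lik)
  expect_equal(unname(ld$dprime_ci["low"]),
               min(grid[which(cum >= 0.05)[1]], ld$dprime))
  expect_equal(unname(ld$dprime_ci["high"]),
               max(grid[which(cum >= 0.95)[1]], ld$dprime))
})

test_that("independent variants get wide, low D' confidence intervals", {
  set.seed(45)
  g1 <- rbinom(400, 2, 0.3)
  g2 <- rbinom(400, 2, 0.4)
  ld <- em_haplotypes(g1, g2)
  expect_lt(ld$dprime_ci[1], 0.7)
})

test_that("Gabriel blocks recover a planted high-LD block and nothing else", {
  planted <- make_planted_block_panel(n = 200, n_flank = 3, span = 5,
                                      rho = 0.95, seed = 46)
  blocks <- gabriel_blocks(planted$panel)
  expect_length(blocks, 1L)
  expect_setequal(blocks[[1]]$variant_ids, planted$block_ids)

  # self-audit: the emitted block satisfies its own rule
  cls <- attr(blocks, "pair_class")
  idx <- blocks[[1]]$indices
  sub <- cls[idx, idx]
  pair_cls <- sub[upper.tri(sub)]
  n_inf <- sum(pair_cls != "uninformative")
  expect_gte(n_inf, 1)
  expect_gte(sum(pair_cls == "strong") / n_inf, 0.95)
})

test_that("two variants in perfect LD form a 2-variant block; independent panels give none", {
  cfg <- sim_config(200, 1, 2, maf_range = c(0.3, 0.4), ld_block_span = 2,
                    ld_rho = 1, seed = 47)
  gt <- simulate_genotypes(cfg)
  blocks <- gabriel_blocks(gt)
  expect_length(blocks, 1L)
  expect_length(blocks[[1]]$variant_ids, 2L)

  cfg0 <- sim_config(200, 1, 8, maf_range = c(0.2, 0.5), ld_rho = 0, seed = 48)
  expect_length(gabriel_blocks(simulate_genotypes(cfg0)), 0L)
})

test_that("significant variants are assigned to blocks and collapsed to index signals", {
  planted <- make_planted_block_panel(n = 200, seed = 49)
  blocks <- gabriel_blocks(planted$panel)
  inside <- planted$block_ids[1]
  outside <- "pv01"
  b <- assign_to_block(inside, blocks)
  expect_s3_class(b, "haplo_block")
  s <- assign_to_block(outside, blocks)
  expect_s3_class(s, "singleton_signal")

  sig <- data.frame(snp_id = c(planted$block_ids[1], planted$block_ids[3], outside),
                    p = c(1e-8, 1e-10, 1e-6), stringsAsFactors = FALSE)
  ind <- collapse_to_independent(sig, blocks)
  expect_equal(nrow(ind), 2L)  # two block members collapse to one signal
  expect_equal(ind$index_snp[1], planted$block_ids[3])  # stronger member indexes
  expect_equal(ind$n_members[1], 2L)
  expect_true(outside %in% ind$index_snp)
})

test_that("blocks export as BED with 0-based half-open intervals", {
  planted <- make_planted_block_panel(n = 200, seed = 50)
  blocks <- gabriel_blocks(planted$panel)
  path <- withr::local_tempfile(fileext = ".bed")
  write_blocks_bed(blocks, path)
  bed <- read.table(path, sep = "\t")
  expect_equal(nrow(bed), length(blocks))
  expect_equal(bed$V2[1], blocks[[1]]$start_pos - 1L)
  expect_equal(bed$V3[1], blocks[[1]]$end_pos)
})
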