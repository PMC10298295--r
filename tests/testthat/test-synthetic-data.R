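test_that("invalid simulation configs are rejected", {
  expect_error(sim_config(0), "positive")
  expect_error(sim_config(10, maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(10, maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(sim_config(10, ld_rho = 1.2), "ld_rho")
  expect_error(sim_config(10, sigma_g2 = -1), "sigma_g2")
})

test_that("the same seed reproduces genotypes, expression and catalogs exactly", {
  cfg <- sim_config(60, n_chromosomes = 2, variants_per_chr = 20,
                    ld_rho = 0.4, beta = 0.3, seed = 11)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1, g2)
  e1 <- simulate_expression(g1, g1$variants$rsid[5], cfg)
  e2 <- simulate_expression(g2, g2$variants$rsid[5], cfg)
  expect_identical(e1, e2)
  expect_identical(simulate_signal_catalog(10, 20, 3, seed = 4),
                   simulate_signal_catalog(10, 20, 3, seed = 4))
})

test_that("perfect copying within a block gives r2 = 1", {
  cfg <- sim_config(100, n_chromosomes = 1, variants_per_chr = 2,
                    maf_range = c(0.3, 0.4), ld_block_span = 2, ld_rho = 1,
                    seed = 2)
  gt <- simulate_genotypes(cfg)
  expect_equal(cor(gt$dosage[, 1], gt$dosage[, 2])^2, 1)
})

test_that("under linkage equilibrium the panel is in HWE and dosages match 2f", {
  cfg <- sim_config(10000, n_chromosomes = 1, variants_per_chr = 400,
                    maf_range = c(0.3, 0.3), ld_rho = 0, seed = 5)
  gt <- simulate_genotypes(cfg)
  expect_equal(mean(colMeans(gt$dosage)), 0.6, tolerance = 0.01)
  st <- variant_stats(gt)
  # exact-test rejection rate at alpha = 0.05 sits at ~5% (the exact test is
  # slightly conservative); binomial Monte-Carlo tolerance over 400 variants
  rej <- mean(st$hwe_p <= 0.05)
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.08)
})

test_that("expression generator degenerates correctly and matches its variance decomposition", {
  cfg0 <- sim_config(2000, n_chromosomes = 2, variants_per_chr = 10,
                     maf_range = c(0.3, 0.3), beta = 0, sigma_g2 = 0,
                     sigma_e2 = 0.7, seed = 8)
  gt <- simulate_genotypes(cfg0)
  sim <- simulate_expression(gt, gt$variants$rsid[1], cfg0)
  expect_equal(var(sim$expression$expr[1, ]), 0.7, tolerance = 0.08)

  # noise-free limit: y = x * beta exactly
  cfg_nf <- sim_config(200, n_chromosomes = 2, variants_per_chr = 10,
                       maf_range = c(0.5, 0.5), beta = 0.5, sigma_g2 = 0,
                       sigma_e2 = 0, seed = 9)
  gtn <- simulate_genotypes(cfg_nf)
  simn <- simulate_expression(gtn, gtn$variants$rsid[3], cfg_nf)
  expect_true(all(simn$expression$expr[1, ] %in% c(0, 0.5, 1)))
  expect_equal(simn$expression$expr[1, ], 0.5 * gtn$dosage[, 3],
               ignore_attr = TRUE)

  # Var(y) ~ sigma_g2 * mean diag(G) + sigma_e2 + beta^2 * 2 f (1 - f)
  cfg_v <- sim_config(400, n_chromosomes = 3, variants_per_chr = 200,
                      maf_range = c(0.3, 0.3), beta = 0.3, sigma_g2 = 0.4,
                      sigma_e2 = 0.6, seed = 10)
  gtv <- simulate_genotypes(cfg_v)
  causal <- gtv$variants$rsid[1]
  G <- loco_grm(gtv, "1")
  expected <- 0.4 * mean(diag(G$matrix)) + 0.6 + 0.3^2 * 2 * 0.3 * 0.7
  vars <- vapply(1:25, function(r) {
    cfg_r <- sim_config(400, 3, 200, maf_range = c(0.3, 0.3), beta = 0.3,
                        sigma_g2 = 0.4, sigma_e2 = 0.6, seed = 10 + r)
    var(simulate_expression(gtv, causal, cfg_r)$expression$expr[1, ])
  }, numeric(1))
  expect_equal(mean(vars), expected, tolerance = 0.05)
})

test_that("simulate_expression rejects unknown causal ids", {
  cfg <- sim_config(30, 1, 5, seed = 1, sigma_g2 = 0)
  gt <- simulate_genotypes(cfg)
  expect_error(simulate_expression(gt, "rs_not_there", cfg), "unknown causal")
})

test_that("signal catalogs honor group sizes and overlap", {
  cat1 <- simulate_signal_catalog(40, 272, 16, seed = 3)
  expect_equal(sum(cat1$trait_group == "target"), 40)
  expect_equal(sum(cat1$trait_group == "other"), 272)
  shared <- intersect(cat1$rsid[cat1$trait_group == "target"],
                      cat1$rsid[cat1$trait_group == "other"])
  expect_length(shared, 16)

  disjoint <- simulate_signal_catalog(5, 5, 0, seed = 6)
  expect_length(intersect(disjoint$rsid[disjoint$trait_group == "target"],
                          disjoint$rsid[disjoint$trait_group == "other"]), 0)

  full <- simulate_signal_catalog(3, 3, 3, seed = 6)
  expect_setequal(full$rsid[full$trait_group == "target"],
                  full$rsid[full$trait_group == "other"])

  expect_error(simulate_signal_catalog(3, 5, 4, seed = 1), "n_shared")
})

test_that("simulated panels round-trip through VCF and TSV exactly", {
  cfg <- sim_config(25, 2, 8, maf_range = c(0.2, 0.5), ld_rho = 0.3, seed = 13)
  gt <- simulate_genotypes(cfg)
  gt$dosage[3, 2] <- NA  # a missing call survives the round trip
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(gt, vcf)
  back <- read_vcf(vcf)
  expect_equal(unname(back$dosage), unname(gt$dosage))
  expect_equal(back$variants$rsid, gt$variants$rsid)
  expect_equal(back$variants$alt, gt$variants$alt)

  cfg2 <- sim_config(25, 2, 8, sigma_g2 = 0, beta = 0.4, seed = 13)
  sim <- simulate_expression(gt, gt$variants$rsid[1], cfg2)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_expression_tsv(sim$expression, tsv)
  expr_back <- read_expression_tsv(tsv)
  expect_equal(expr_back$expr, sim$expression$expr, tolerance = 1e-12)
  expect_equal(expr_back$genes$chr, sim$expression$genes$chr)

  cat1 <- simulate_signal_catalog(6, 4, 2, seed = 20)
  ctsv <- withr::local_tempfile(fileext = ".tsv")
  write_catalog_tsv(cat1, ctsv)
  cat_back <- read_catalog_tsv(ctsv)
  expect_equal(cat_back$rsid, cat1$rsid)
  expect_equal(cat_back$trait_group, cat1$trait_group)

  js <- withr::local_tempfile(fileext = ".json")
  write_config_json(cfg, js)
  echoed <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(echoed$seed, cfg$seed)
  expect_equal(echoed$maf_range, cfg$maf_range)
})
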