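#!/usr/bin/env Rscript
# Step 1 — simulate the study cohort.
#
# Builds a synthetic cohort with the generative structure the mixed model
# assumes: a diploid genotype panel in HWE with block-wise LD, one gene whose
# expression carries a true variant effect plus a polygenic component drawn
# from the leave-one-chromosome-out GRM, three null genes, and a two-trait
# GWAS-signal catalog whose target group overlaps the contrast group.
# Everything is written under results/cohort/ for the later steps.

suppressMessages(library(mlmeqtl))

out_dir <- "results/cohort"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(
  n_individuals = 250, n_chromosomes = 3, variants_per_chr = 40,
  maf_range = c(0.02, 0.5),   # includes rare variants so QC has work to do
  ld_block_span = 5, ld_rho = 0.9,
  beta = 0.8, sigma_g2 = 0.3, sigma_e2 = 0.7,
  seed = 20230524L
)
write_config_json(cfg, file.path(out_dir, "sim_config.json"))

genotypes <- simulate_genotypes(cfg)
causal <- genotypes$variants$rsid[5]
message("simulated ", nrow(genotypes$dosage), " individuals x ",
        ncol(genotypes$dosage), " variants; causal variant ", causal,
        " (chr", genotypes$variants$chr[5], ")")
write_vcf(genotypes, file.path(out_dir, "genotypes.vcf"))

sim <- simulate_expression(genotypes, causal, cfg, gene_id = "gene_causal")
set.seed(cfg$seed + 2L)
null_expr <- matrix(rnorm(3 * cfg$n_individuals), nrow = 3)
expression <- expression_matrix(
  rbind(sim$expression$expr, null_expr),
  rbind(sim$expression$genes,
        data.frame(gene_id = paste0("gene_null", 1:3), chr = "2",
                   start = 1000L, end = 2000L)),
  genotypes$sample_ids)
write_expression_tsv(expression, file.path(out_dir, "expression.tsv"))
jsonlite::write_json(sim$truth, file.path(out_dir, "truth.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

# catalog: target group = causal + two other genotyped variants + one absent
# rsid; contrast group shares one genotyped variant with the target group
set.seed(cfg$seed + 3L)
panel_ids <- genotypes$variants$rsid
catalog <- data.frame(
  rsid = c(causal, panel_ids[c(45, 85)], "rs99999999",
           panel_ids[c(45, 60, 100)]),
  chr = "NA", pos = 0L, ref = "N", alt = "N",
  trait_group = c(rep("target", 4), rep("other", 3)),
  source_maf = NA_real_, stringsAsFactors = FALSE)
write_catalog_tsv(catalog, file.path(out_dir, "signal_catalog.tsv"))

message("cohort written to ", out_dir)
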