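#!/usr/bin/env Rscript
# Step 2 — genotype quality control.
#
# Reads the cohort VCF, computes per-variant genotype counts, minor allele
# frequencies and Hardy-Weinberg exact-test p-values, applies the study's
# exclusion rule (drop maf < 0.05 or HWE p < 1e-6), and writes both the full
# statistics table and the QC'd panel.

suppressMessages(library(mlmeqtl))

cohort <- "results/cohort"
out_dir <- "results/qc"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

genotypes <- read_vcf(file.path(cohort, "genotypes.vcf"))
stats <- variant_stats(genotypes)
write_variant_stats_tsv(stats, file.path(out_dir, "variant_stats.tsv"),
                        maf_min = 0.05, hwe_alpha = 1e-6)

panel <- apply_variant_filters(genotypes, maf_min = 0.05, hwe_alpha = 1e-6)
log <- attr(panel, "filter_log")
message(log$n_kept, "/", log$n_input, " variants pass QC (",
        log$n_fail_maf, " failed MAF, ", log$n_fail_hwe, " failed HWE)")

write_vcf(panel, file.path(out_dir, "genotypes_qc.vcf"))
jsonlite::write_json(log, file.path(out_dir, "qc_log.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
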