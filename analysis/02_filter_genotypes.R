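#!/usr/bin/env Rscript
# Stage 2: genotype QC on the simulated VCF.
#
# Reads the fixture VCF back through the standard input path, applies the
# strict <5% missingness rule and (for the neutral-structure track) the
# exact Hardy-Weinberg screen, and LD-prunes a copy for structure analyses.
# The scan track keeps the unscreened SNP set.

suppressMessages(library(islescan))
fx <- "results/fixtures"
out <- "results/analysis"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

gm <- read_vcf(file.path(fx, "genotypes.vcf"))
message("loaded ", n_sites(gm), " SNPs x ", length(gm$samples), " samples")

flt <- filter_sites(gm, max_missing = 0.05, hwe_alpha = 0.05,
                    apply_hwe = TRUE)
write_tsv(flt$report, file.path(out, "filter_report.tsv"))
message("after missingness + HWE screen: ", n_sites(flt$genotypes), " SNPs")

pruned <- ld_prune(flt$genotypes, window_snps = 50, step_snps = 10,
                   r2_max = 0.1)
message("LD-pruned set for structure analyses: ", n_sites(pruned), " SNPs")
write_vcf(pruned, file.path(out, "pruned.vcf"))
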