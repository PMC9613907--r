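#!/usr/bin/env Rscript
# Stage 5: population diversity and differentiation summary.
#
# Per population: observed heterozygosity (mean/SD over individuals),
# private alleles raw and rarefied to 9 individuals (the two smallest
# mainland populations are merged for rarefaction so every unit reaches the
# rarefaction depth), allele-sharing F_IS and F_IT; plus the overall FST
# and the full pairwise FST matrix.

suppressMessages(library(islescan))
fx <- "results/fixtures"
out <- "results/analysis"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

gm <- read_vcf(file.path(fx, "genotypes.vcf"))
sheet <- read_sample_sheet(file.path(fx, "samples.tsv"))

ds <- diversity_summary(
  gm, sheet, g = 9, reps = 200, seed = 7,
  merge_for_rarefaction = list(populations = c("PT", "MA"), into = "PT+MA"))
write_tsv(ds$table, file.path(out, "diversity_table.tsv"))
message("per-population summary:")
print(ds$table, digits = 3)
message(sprintf("overall FST: %.4f", ds$fst_overall))

mm <- matching_matrix(gm)
pops <- unique(sheet$population)
fst <- matrix(NA_real_, length(pops), length(pops),
              dimnames = list(pops, pops))
for (i in seq_along(pops)) for (j in seq_along(pops)) if (i < j) {
  v <- pairwise_fst(mm, samples_of(sheet, populations = pops[i]),
                    samples_of(sheet, populations = pops[j]))
  fst[i, j] <- fst[j, i] <- v
}
write_tsv(cbind(population = rownames(fst), as.data.frame(fst)),
          file.path(out, "pairwise_fst.tsv"))
message("pairwise FST matrix:")
print(round(fst, 3))
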