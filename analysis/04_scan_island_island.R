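#!/usr/bin/env Rscript
# Stage 4: east-vs-west island scan with the dual calling rule.
#
# On the two-island fixture, windows carry the EC-WC pairwise FST plus each
# island's population-specific FST. A region needs >= 2 overlapping windows
# above the pairwise five-sigma threshold AND above the 99th genome-wide
# quantile of that island's specific FST - high between-island
# differentiation coinciding with high within-island similarity.

suppressMessages(library(islescan))
fx <- "results/fixtures/two_island"
out <- "results/analysis"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

gm <- read_vcf(file.path(fx, "genotypes.vcf"))
sheet <- read_sample_sheet(file.path(fx, "samples.tsv"))

ctr <- scan_contrasts(
  fst_pairwise = list(fst_ec_wc = list(a = "EC", b = "WC")),
  fst_specific = list(fst_ec = list(target = "EC", reference = "WC"),
                      fst_wc = list(target = "WC", reference = "EC")),
  dxy = list(dxy_ec_wc = list(a = "EC", b = "WC")),
  pi = list(pi_ec = "EC", pi_wc = "WC"))
rows <- scan_windows(gm, sheet, ctr, min_snps = 10)
write_tsv(rows, file.path(out, "windows_island_island.tsv"))

thr <- sigma_threshold(rows$fst_ec_wc, 5)
message(sprintf("five-sigma threshold on EC-WC pairwise FST: %.3f", thr))

for (pop in c("ec", "wc")) {
  stat <- paste0("fst_", pop)
  reg <- call_regions_dual(rows, "fst_ec_wc", thr, stat, 0.99)
  message(sprintf("%s-specific regions (pairwise 5SD AND %s > q99 = %.3f): %d",
                  toupper(pop), stat,
                  attr(reg, "thresholds")[stat], nrow(reg)))
  print(reg)
  write_bed(reg, file.path(out, sprintf("regions_%s.bed", pop)))
}
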