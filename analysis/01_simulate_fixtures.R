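#!/usr/bin/env Rscript
# Stage 1: generate the study-shaped synthetic inputs.
#
# Emits the island/mainland genotype fixture (five populations at the study
# sample sizes, one 1-Mb swept haplotype shared by all island individuals),
# the two-island fixture (EC- and WC-private 240-kb sweeps), the tiled gene
# annotation, and the niche env/occurrence tables. Everything downstream
# reads these files, so the whole workflow runs without external data.

suppressMessages(library(islescan))
seed <- 1L
out <- "results/fixtures"

message("island/mainland fixture (planted 1-Mb sweep) ...")
files <- write_fixtures(default_sim_config(seed = seed), out,
                        niche = simulate_niche(
                          n_sites = 80, n_vars = 5,
                          offset = c(2, 0, 0, 0, 0),
                          records = c(specialist = 60, generalist = 120),
                          seed = seed))
message("  wrote: ", paste(basename(files), collapse = ", "))

message("two-island fixture (EC- and WC-private sweeps) ...")
files2 <- write_fixtures(dual_island_config(seed = seed),
                         file.path(out, "two_island"))
message("  wrote: ", paste(basename(files2), collapse = ", "))

truth <- simulate_genotypes(default_sim_config(seed = seed))$truth$planted[[1]]
message(sprintf("planted region: %s:%d-%d (f_island = %.2f)",
                truth$scaffold, truth$start, truth$end, truth$f_island))
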