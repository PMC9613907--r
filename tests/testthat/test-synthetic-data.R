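two_pop_cfg <- function(f, seed = 1, n_snps = 20000L) {
  sim_config(
    data.frame(name = c("P1", "P2"), size = c(10L, 10L), f = c(f, f),
               group = c("island", "mainland")),
    n_snps = n_snps, contigs = c(ctg = 2e7), seed = seed)
}

test_that("the generator is deterministic bit for bit", {
  cfg <- default_sim_config(seed = 5)
  a <- simulate_genotypes(cfg)
  b <- simulate_genotypes(default_sim_config(seed = 5))
  expect_identical(a$genotypes$dosage, b$genotypes$dosage)
  expect_identical(a$genotypes$sites, b$genotypes$sites)
  expect_identical(a$truth$p_pop, b$truth$p_pop)

  # and the written fixture files are byte-identical
  d1 <- tempfile(); d2 <- tempfile()
  f1 <- write_fixtures(sim_config(
    data.frame(name = c("A", "B"), size = c(3L, 3L), f = c(0.1, 0.1),
               group = c("island", "mainland")),
    n_snps = 300L, contigs = c(c1 = 3e5), seed = 2), d1)
  f2 <- write_fixtures(sim_config(
    data.frame(name = c("A", "B"), size = c(3L, 3L), f = c(0.1, 0.1),
               group = c("island", "mainland")),
    n_snps = 300L, contigs = c(c1 = 3e5), seed = 2), d2)
  for (k in names(f1))
    expect_identical(readLines(f1[[k]]), readLines(f2[[k]]))
})

test_that("pairwise FST recovers the configured drift coefficient", {
  sim <- simulate_neutral(two_pop_cfg(0.1, seed = 77))
  mm <- matching_matrix(sim$genotypes)
  fst <- pairwise_fst(mm, samples_of(sim$sheet, populations = "P1"),
                      samples_of(sim$sheet, populations = "P2"))
  expect_lt(abs(fst - 0.1), 0.02)
})

test_that("the panmixia limit gives near-zero differentiation", {
  sim <- simulate_neutral(two_pop_cfg(1e-4, seed = 78))
  mm <- matching_matrix(sim$genotypes)
  fst <- pairwise_fst(mm, samples_of(sim$sheet, populations = "P1"),
                      samples_of(sim$sheet, populations = "P2"))
  expect_lt(abs(fst), 0.01)
})

test_that("a fully fixed sweep zeroes island diversity inside the region", {
  cfg <- sim_config(
    data.frame(name = c("EC", "WC", "PT"), size = c(6L, 6L, 6L),
               f = c(0.1, 0.1, 0.05),
               group = c("island", "island", "mainland")),
    n_snps = 4000L,
    contigs = c(c1 = 2e6),
    planted = list(scaffold = "c1", start = 5e5, end = 1e6, f_island = 1,
                   populations = c("EC", "WC")),
    seed = 13)
  sim <- simulate_genotypes(cfg)
  gm <- sim$genotypes
  isl <- samples_of(sim$sheet, groups = "island")
  ml <- samples_of(sim$sheet, groups = "mainland")
  in_reg <- gm$sites$scaffold == "c1" & (gm$sites$pos - 1) >= 5e5 &
    (gm$sites$pos - 1) < 1e6
  ec <- samples_of(sim$sheet, populations = "EC")
  wc <- samples_of(sim$sheet, populations = "WC")
  expect_equal(window_pi(gm, isl, 5e5, sites = which(in_reg)), 0)
  expect_equal(window_dxy(gm, ec, wc, 5e5, sites = which(in_reg)), 0)
  mm <- matching_matrix(subset_genotypes(gm, sites = which(in_reg)))
  fst_in <- group_specific_fst(mm, isl, ml)$fst_specific
  mm_all <- matching_matrix(gm)
  fst_all <- group_specific_fst(mm_all, isl, ml)$fst_specific
  expect_gt(fst_in, fst_all + 0.2)
})

test_that("the planted sweep leaves the haplotype LD signature", {
  cfg <- default_sim_config(seed = 3)
  sim <- simulate_genotypes(cfg)
  gm <- sim$genotypes
  isl <- samples_of(sim$sheet, groups = "island")
  ml <- samples_of(sim$sheet, groups = "mainland")
  lb_isl <- ld_blocks(gm, isl, block_snps = 100)
  lb_ml <- ld_blocks(gm, ml, block_snps = 100)
  reg <- sim$truth$planted[[1]]
  block_means <- function(lb, scf, lo, hi) {
    b <- lb[[scf]]$blocks
    inside <- b$pos_first >= lo & b$pos_last <= hi
    list(inside = mean(diag(lb[[scf]]$r2)[inside], na.rm = TRUE),
         outside = mean(diag(lb[[scf]]$r2)[!inside], na.rm = TRUE))
  }
  bi <- block_means(lb_isl, reg$scaffold, reg$start, reg$end)
  bm <- block_means(lb_ml, reg$scaffold, reg$start, reg$end)
  expect_gt(bi$inside, bi$outside + 0.1)            # island LD surge
  expect_lt(abs(bm$inside - bm$outside), 0.1)       # absent on the mainland
})

test_that("simulated niche data shows the planted specialist asymmetry", {
  wins <- 0
  for (seed in 1:20) {
    nd <- simulate_niche(n_sites = 60, n_vars = 5,
                         offset = c(2, 0, 0, 0, 0), seed = seed)
    et <- standardize_env(nd$env)
    res <- omi_analysis(et, nd$occ, n_axes = 2)
    omi <- setNames(res$species$omi, res$species$species)
    if (omi["specialist"] > omi["generalist"]) wins <- wins + 1
  }
  expect_gte(wins, 19)   # >= 95% of seeds

  # one dominant offset axis concentrates the marginality variability
  nd <- simulate_niche(n_sites = 80, n_vars = 5, offset = c(2, 0, 0, 0, 0),
                       seed = 4)
  res <- omi_analysis(standardize_env(nd$env), nd$occ, n_axes = 2)
  expect_gt(res$axis_pct_all[1], 5 * res$axis_pct_all[2])

  # zero offset: both species are generalists with tiny OMI
  nd0 <- simulate_niche(n_sites = 200, n_vars = 3, offset = c(0, 0, 0),
                        records = c(specialist = 500, generalist = 500),
                        seed = 11)
  res0 <- omi_analysis(standardize_env(nd0$env), nd0$occ, n_axes = 1)
  expect_true(all(res0$species$omi < 0.1))
})

test_that("a config can plant multiple population-private regions", {
  cfg <- dual_island_config(seed = 2)
  sim <- simulate_genotypes(cfg)
  expect_length(sim$truth$planted, 2)
  regA <- sim$truth$planted[[1]]; regB <- sim$truth$planted[[2]]
  expect_equal(regA$populations, "EC")
  expect_equal(regB$populations, "WC")
  gm <- sim$genotypes
  ec <- samples_of(sim$sheet, populations = "EC")
  wc <- samples_of(sim$sheet, populations = "WC")
  inA <- which(gm$sites$scaffold == regA$scaffold &
                 (gm$sites$pos - 1) >= regA$start &
                 (gm$sites$pos - 1) < regA$end)
  # EC diversity collapses in its own region; WC is untouched there
  piA_ec <- window_pi(gm, ec, regA$end - regA$start, sites = inA)
  piA_wc <- window_pi(gm, wc, regA$end - regA$start, sites = inA)
  expect_lt(piA_ec, piA_wc / 3)
})

test_that("the fixture GFF tiles genes deterministically", {
  cfg <- default_sim_config(seed = 1)
  p1 <- tempfile(fileext = ".gff3"); p2 <- tempfile(fileext = ".gff3")
  make_fixture_gff(cfg, p1)
  make_fixture_gff(cfg, p2)
  expect_identical(readLines(p1), readLines(p2))

  ann <- read_gff(p1)
  # genes every 100 kb, 20 kb long: the 1-Mb planted region [2e6, 3e6)
  # on contig_03 contains exactly the 10 genes starting at 2.0 .. 2.9 Mb;
  # the gene starting at 3.0 Mb abuts the half-open boundary
  reg <- data.frame(scaffold = "contig_03", start = 2e6, end = 3e6,
                    n_support_windows = 2L, peak_value = 1)
  ov <- annotate_regions(reg, ann)
  expect_equal(length(ov$regions$genes[[1]]), 10)
})

test_that("planting into a region without SNPs is refused", {
  cfg <- sim_config(
    data.frame(name = c("A", "B"), size = c(3L, 3L), f = c(0.1, 0.1),
               group = c("island", "mainland")),
    n_snps = 10L, contigs = c(c1 = 1e7), seed = 6)
  sim <- simulate_neutral(cfg)
  # 10 SNPs on 10 Mb: some 1 kb interval will be empty
  gaps <- which(diff(sim$genotypes$sites$pos) > 2000)[1]
  lo <- sim$genotypes$sites$pos[gaps] + 10
  expect_error(plant_sweep(sim, list(scaffold = "c1", start = lo,
                                     end = lo + 1000, f_island = 0.9,
                                     populations = "A")),
               "no SNPs")
})
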