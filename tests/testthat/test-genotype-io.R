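write_toy_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(lines, path)
  path
}

toy_vcf_lines <- function(records, samples = c("s1", "s2")) {
  c("##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=100000>",
    "##contig=<ID=Super-Scaffold_13,length=100000>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    records)
}

test_that("read_vcf keeps biallelic SNPs, drops excluded scaffolds, maps GT to dosage", {
  rec <- c("chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0/1\t1|1",
           "chr1\t200\t.\tG\tC,T\t.\tPASS\t.\tGT\t0/1\t0/0",   # multiallelic
           "chr1\t300\t.\tC\tG\t.\tPASS\t.\tGT\t./.\t0/0",
           "Super-Scaffold_13\t50\t.\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/0")
  path <- write_toy_vcf(toy_vcf_lines(rec))

  gm <- read_vcf(path)
  expect_equal(n_sites(gm), 3)          # multiallelic record excluded

  gm2 <- read_vcf(path, exclude_scaffolds = "Super-Scaffold_13")
  expect_equal(n_sites(gm2), 2)
  expect_false("Super-Scaffold_13" %in% gm2$sites$scaffold)
  expect_false("Super-Scaffold_13" %in% names(gm2$contig_lengths))

  # dosage mapping: 0/1 -> 1, 1|1 (phased) -> 2, ./. -> NA
  expect_equal(unname(gm2$dosage[1, ]), c(1L, 2L))
  expect_true(is.na(gm2$dosage[2, "s1"]))
  expect_equal(unname(gm2$dosage[2, "s2"]), 0L)
})

test_that("read_vcf rejects duplicated sample names", {
  rec <- "chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0/1\t1/1"
  path <- write_toy_vcf(toy_vcf_lines(rec, samples = c("dup", "dup")))
  expect_error(read_vcf(path), "dup")
})

test_that("VCF round-trip preserves the genotype matrix", {
  cfg <- sim_config(
    data.frame(name = c("P1", "P2"), size = c(4L, 4L), f = c(0.05, 0.05),
               group = c("island", "mainland")),
    n_snps = 200L, contigs = c(ctgA = 1e5, ctgB = 5e4), seed = 11)
  gm <- simulate_neutral(cfg)$genotypes
  gm$dosage[3, 2] <- NA  # exercise missing-genotype round-trip
  path <- tempfile(fileext = ".vcf")
  write_vcf(gm, path)
  back <- read_vcf(path)
  expect_identical(back$dosage, gm$dosage)
  expect_equal(back$sites, gm$sites)
  expect_equal(back$contig_lengths, gm$contig_lengths)
})

test_that("exact HWE test matches hand values and the pairing oracle", {
  expect_equal(hwe_exact_test(5, 0, 0), 1)          # monomorphic
  expect_equal(hwe_exact_test(1, 0, 1), 1 / 3, tolerance = 1e-12)
  # against exhaustive enumeration of allele pairings for small panels
  cases <- list(c(1, 0, 1), c(2, 1, 1), c(1, 2, 1), c(0, 3, 1), c(2, 2, 0))
  for (cs in cases)
    expect_equal(hwe_exact_test(cs[1], cs[2], cs[3]),
                 oracle_hwe_p(cs[1], cs[2], cs[3]), tolerance = 1e-9)
})

test_that("the Levene heterozygote distribution is a valid distribution", {
  combos <- list(c(1, 1), c(2, 2), c(5, 3), c(9, 1), c(20, 8), c(7, 3))
  for (cs in combos) {  # nA + na must be even (2n allele copies)
    d <- islescan:::hwe_het_distribution(cs[1], cs[2])
    expect_equal(sum(d$prob), 1, tolerance = 1e-12)
    expect_true(all(d$prob >= 0))
  }
})

test_that("filter_sites applies the strict missingness rule and the HWE screen", {
  d <- matrix(1L, 3, 10)
  d[2, 1] <- NA                       # 10% missing -> dropped at 5%
  colnames(d) <- sprintf("s%02d", 1:10)
  gm <- genotype_matrix(d, data.frame(scaffold = "c", pos = 1:3,
                                      ref = "A", alt = "T"))
  res <- filter_sites(gm, max_missing = 0.05)
  expect_equal(n_sites(res$genotypes), 2)
  expect_equal(res$report$sites[res$report$step == "missingness"], 1)

  # (1,0,1): HWE exact p = 1/3 >= 0.05 -> kept
  gm2 <- toy_gm(a = c(0L), b = c(2L))
  res2 <- filter_sites(gm2, apply_hwe = TRUE, hwe_alpha = 0.05)
  expect_equal(n_sites(res2$genotypes), 1)

  # complete data in HWE: identity, and filtering is idempotent
  gm3 <- panmictic_gm(50, 10, seed = 3)
  once <- filter_sites(gm3, apply_hwe = TRUE)
  twice <- filter_sites(once$genotypes, apply_hwe = TRUE)
  expect_identical(once$genotypes$dosage, twice$genotypes$dosage)
  expect_error(filter_sites(gm3, max_missing = 1.5), "max_missing")
})

test_that("ld_prune removes the later SNP of correlated pairs", {
  # duplicated loci: r^2 = 1 -> later copy removed
  gm <- toy_gm(a = c(0L, 0L), b = c(1L, 1L), c = c(2L, 2L), d = c(1L, 1L))
  pruned <- ld_prune(gm, window_snps = 50, step_snps = 10, r2_max = 0.1)
  expect_equal(n_sites(pruned), 1)
  expect_equal(pruned$sites$pos, 10L)

  # hand-built triple: r^2(1,2) = 0.5, locus 3 uncorrelated -> only locus 2 goes
  gm3 <- toy_gm(a = c(0L, 0L, 0L), b = c(1L, 0L, 1L),
                c = c(1L, 2L, 1L), d = c(2L, 2L, 0L))
  pruned3 <- ld_prune(gm3)
  expect_equal(pruned3$sites$pos, c(10L, 30L))

  # mutually independent loci survive untouched
  gm0 <- toy_gm(a = c(0L, 1L), b = c(1L, 0L), c = c(1L, 2L), d = c(2L, 1L))
  expect_equal(n_sites(ld_prune(gm0)), 2)
  expect_error(ld_prune(gm0, window_snps = 1), "window_snps")
})

test_that("ld_prune output has no within-window pair above r2_max (brute force)", {
  for (seed in 1:3) {
    gm <- panmictic_gm(60, 12, seed = seed)
    pruned <- ld_prune(gm, window_snps = 20, step_snps = 5, r2_max = 0.3)
    X <- t(pruned$dosage)
    n <- ncol(X)
    # pairs within window - step of each other are always co-windowed
    for (i in seq_len(n - 1)) {
      jmax <- min(n, i + 15)
      for (j in (i + 1):jmax) {
        r2 <- suppressWarnings(cor(X[, i], X[, j]))^2
        if (!is.na(r2)) expect_lte(r2, 0.3 + 1e-9)
      }
    }
  }
})

test_that("read_gff extracts gene rows with the half-open convention", {
  path <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t101\t200\t.\t+\t.\tID=g1;Name=GENE1",
    "chr1\tsrc\tmRNA\t101\t200\t.\t+\t.\tID=t1;Parent=g1",
    "chr2\tsrc\tgene\t501\t900\t.\t-\t.\tID=g2"), path)
  ann <- read_gff(path)
  expect_equal(nrow(ann), 2)
  expect_equal(ann$start, c(100, 500))     # 1-based inclusive -> 0-based
  expect_equal(ann$end, c(200, 900))
  expect_equal(ann$scaffold, c("chr1", "chr2"))
  expect_equal(ann$gene_name[1], "GENE1")
  expect_equal(ann$gene_name[2], "g2")     # falls back to ID

  mrna_only <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tmRNA\t101\t200\t.\t+\t.\tID=t1"), mrna_only)
  expect_warning(ann2 <- read_gff(mrna_only), "gene")
  expect_equal(nrow(ann2), 0)
})
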