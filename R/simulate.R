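#' Simulation configuration
#'
#' Describes a Balding-Nichols island-model genotype simulation: populations
#' with sizes, drift coefficients F and group labels; a contig layout; the
#' number of SNPs; an optional planted swept-haplotype region; ancestral
#' allele-frequency bounds; and the RNG seed.
#'
#' @param populations data.frame with columns `name`, `size`, `f` (drift
#'   coefficient in (0, 1)), `group`
#' @param n_snps number of SNPs to draw
#' @param contigs named numeric vector of contig lengths (bp)
#' @param planted optional list(scaffold=, start=, end= (0-based half-open),
#'   f_island = 0.97, populations = <target populations>) describing the
#'   swept region
#' @param freq_bounds ancestral-frequency bounds (default c(0.05, 0.95),
#'   emulating a SNP-set input with no rare monomorphic draws)
#' @param seed integer RNG seed
#' @return object of class `sim_config`
#' @export
sim_config <- function(populations, n_snps, contigs,
                       planted = NULL, freq_bounds = c(0.05, 0.95),
                       seed = 1L) {
  stopifnot(is.data.frame(populations),
            all(c("name", "size", "f", "group") %in% names(populations)),
            all(populations$f > 0 & populations$f < 1),
            n_snps >= 1, length(contigs) >= 1, !is.null(names(contigs)))
  if (!is.null(planted)) {
    if (!is.null(planted$scaffold)) planted <- list(planted)
    planted <- lapply(planted, function(reg) {
      if (!reg$scaffold %in% names(contigs))
        stop("planted region scaffold not in contig layout")
      if (reg$start < 0 || reg$end > contigs[[reg$scaffold]] ||
          reg$start >= reg$end)
        stop("planted region outside its contig")
      if (is.null(reg$f_island)) reg$f_island <- 0.97
      if (is.null(reg$populations))
        reg$populations <- populations$name[populations$group == "island"]
      if (reg$f_island < 0 || reg$f_island > 1)
        stop("f_island must be in [0, 1]")
      reg
    })
  }
  structure(list(populations = populations, n_snps = n_snps,
                 contigs = contigs, planted = planted,
                 freq_bounds = freq_bounds, seed = as.integer(seed)),
            class = "sim_config")
}

#' Default simulation configuration
#'
#' Five populations at the study's sample sizes — two island (EC n=10,
#' WC n=9) and three mainland (MA n=3, PT n=9, IS n=9) — with drift
#' coefficients matching the population-specific differentiation scale of
#' the system (about 0.05-0.11 for islands, lower on the mainland); 30,000
#' SNPs over ten 5-Mb contigs; and one 1-Mb planted swept region shared by
#' all island individuals.
#'
#' @param seed integer RNG seed
#' @param planted logical; include the planted swept region?
#' @return a [sim_config()]
#' @export
default_sim_config <- function(seed = 1L, planted = TRUE) {
  pops <- data.frame(
    name = c("EC", "WC", "MA", "PT", "IS"),
    size = c(10L, 9L, 3L, 9L, 9L),
    f = c(0.11, 0.10, 0.02, 0.02, 0.05),
    group = c("island", "island", "mainland", "mainland", "mainland"),
    stringsAsFactors = FALSE)
  contigs <- stats::setNames(rep(5e6, 10), sprintf("contig_%02d", 1:10))
  reg <- if (planted)
    list(scaffold = "contig_03", start = 2e6, end = 3e6,
         f_island = 0.97, populations = c("EC", "WC"))
  else NULL
  sim_config(pops, n_snps = 30000L, contigs = contigs, planted = reg,
             seed = seed)
}

#' Null (no-sweep) simulation configuration
#'
#' The five-population island/mainland design with no planted region, on a
#' 10-Mb genome (four 2.5-Mb contigs, 6,000 SNPs - the same per-window SNP
#' density as [default_sim_config()]); sized so that many replicate
#' false-positive runs of the full scan-and-call pipeline stay cheap.
#'
#' @param seed integer RNG seed
#' @return a [sim_config()]
#' @export
null_sim_config <- function(seed = 1L) {
  cfg <- default_sim_config(seed = seed, planted = FALSE)
  cfg$contigs <- stats::setNames(rep(2.5e6, 4), sprintf("contig_%02d", 1:4))
  cfg$n_snps <- 6000L
  cfg
}

#' Island-vs-island simulation configuration
#'
#' The two-island design: only the EC and WC populations (at their study
#' sample sizes), a 25-Mb genome at higher SNP density (so windowed
#' statistics are tight enough for the dual five-sigma + 99th-quantile
#' rule), and two planted 240-kb swept regions - one private to EC, one to
#' WC - on different contigs.
#'
#' @param seed integer RNG seed
#' @return a [sim_config()]
#' @export
dual_island_config <- function(seed = 1L) {
  pops <- data.frame(
    name = c("EC", "WC"), size = c(10L, 9L), f = c(0.11, 0.10),
    group = c("island", "island"), stringsAsFactors = FALSE)
  contigs <- stats::setNames(rep(5e6, 5), sprintf("contig_%02d", 1:5))
  sim_config(pops, n_snps = 30000L, contigs = contigs,
             planted = list(
               list(scaffold = "contig_01", start = 1e6, end = 1.24e6,
                    f_island = 0.97, populations = "EC"),
               list(scaffold = "contig_05", start = 3e6, end = 3.24e6,
                    f_island = 0.97, populations = "WC")),
             seed = seed)
}

#' Simulate neutral genotypes under the Balding-Nichols model
#'
#' Per site, an ancestral frequency is drawn uniformly within
#' `freq_bounds`; each population's frequency follows the Balding-Nichols
#' beta distribution Beta(p(1-F)/F, (1-p)(1-F)/F); individual genotypes are
#' Binomial(2, p_pop) draws. Sites are placed uniformly (without
#' replacement) along contigs proportional to length. Sites that come out
#' monomorphic across all individuals are dropped (the emulated input is a
#' SNP set). Fully seeded and deterministic.
#'
#' @param cfg a [sim_config()] (any `planted` entry is ignored here; see
#'   [plant_sweep()] / [simulate_genotypes()])
#' @return list with `genotypes` (a [genotype_matrix()]), `sheet`
#'   (a [sample_sheet()]) and `truth` (list: `p_anc`, `p_pop` sites x
#'   populations matrix, `planted` = NULL)
#' @export
simulate_neutral <- function(cfg) {
  set.seed(cfg$seed)
  n <- cfg$n_snps
  contig_n <- as.vector(
    stats::rmultinom(1, n, cfg$contigs / sum(cfg$contigs)))
  names(contig_n) <- names(cfg$contigs)
  sites <- do.call(rbind, lapply(names(cfg$contigs), function(s) {
    k <- contig_n[[s]]
    if (k == 0) return(NULL)
    data.frame(scaffold = s,
               pos = sort(sample.int(cfg$contigs[[s]], k)),
               stringsAsFactors = FALSE)
  }))
  n <- nrow(sites)
  alle <- c("A", "C", "G", "T")
  sites$ref <- sample(alle, n, replace = TRUE)
  sites$alt <- vapply(sites$ref, function(r) sample(setdiff(alle, r), 1), "")

  p_anc <- stats::runif(n, cfg$freq_bounds[1], cfg$freq_bounds[2])
  pops <- cfg$populations
  p_pop <- matrix(NA_real_, n, nrow(pops),
                  dimnames = list(NULL, pops$name))
  dosage <- matrix(NA_integer_, n, sum(pops$size))
  ids <- unlist(lapply(seq_len(nrow(pops)), function(i)
    sprintf("%s_%02d", pops$name[i], seq_len(pops$size[i]))))
  colnames(dosage) <- ids
  col0 <- 0L
  for (i in seq_len(nrow(pops))) {
    f <- pops$f[i]
    pp <- stats::rbeta(n, p_anc * (1 - f) / f, (1 - p_anc) * (1 - f) / f)
    # guard against numerically degenerate beta draws
    pp[is.na(pp)] <- round(p_anc[is.na(pp)])
    p_pop[, i] <- pp
    for (j in seq_len(pops$size[i]))
      dosage[, col0 + j] <- stats::rbinom(n, 2, pp)
    col0 <- col0 + pops$size[i]
  }
  poly <- rowSums(dosage) > 0 & rowSums(dosage) < 2 * ncol(dosage)
  gm <- genotype_matrix(dosage[poly, , drop = FALSE],
                        sites[poly, , drop = FALSE], cfg$contigs)
  sheet <- sample_sheet(ids,
                        rep(pops$name, pops$size),
                        group_of = stats::setNames(pops$group, pops$name))
  truth <- list(p_anc = p_anc[poly], p_pop = p_pop[poly, , drop = FALSE],
                planted = NULL)
  list(genotypes = gm, sheet = sheet, truth = truth)
}

#' Plant a swept haplotype into a simulated dataset
#'
#' Inside the region, a single swept haplotype (one allele per site, drawn
#' once from the ancestral frequencies) is copied into the target
#' individuals: each carries it on both chromosomes with probability
#' f_island^2, on one with 2 f (1 - f), and otherwise none, the remaining
#' chromosomes being redrawn from the individual's population frequency.
#' The per-individual copy number is drawn once for the whole region, which
#' is what generates region-wide linkage disequilibrium, reduced diversity
#' and reduced island-island divergence. Other populations are untouched.
#'
#' @param sim output of [simulate_neutral()]
#' @param region list(scaffold=, start=, end=, f_island=, populations=) as
#'   in [sim_config()]'s `planted` entry
#' @return the modified `sim` with `truth$planted` set
#' @export
plant_sweep <- function(sim, region) {
  gm <- sim$genotypes
  in_reg <- gm$sites$scaffold == region$scaffold &
    (gm$sites$pos - 1) >= region$start & (gm$sites$pos - 1) < region$end
  if (!any(in_reg))
    stop("planted region contains no SNPs; increase SNP density")
  f <- if (is.null(region$f_island)) 0.97 else region$f_island
  target_pops <- region$populations
  target <- samples_of(sim$sheet, populations = target_pops)
  hap <- stats::rbinom(sum(in_reg), 1, sim$truth$p_anc[in_reg])
  pop_of <- sim$sheet$population[match(target, sim$sheet$individual)]
  # per-individual swept-copy numbers, drawn once for the whole region
  # (this is what generates the region-wide LD). For f < 1 the draw is
  # conditioned on >= 2 non-swept chromosomes in the target set, so the
  # region keeps residual polymorphism segregating among carriers of the
  # background chromosomes - the near-fixed-but-polymorphic regime the
  # haplotype signature (high LD, low pi, low dxy) describes.
  repeat {
    copies <- sample(0:2, length(target), replace = TRUE,
                     prob = c((1 - f)^2, 2 * f * (1 - f), f^2))
    if (f >= 1 || sum(2L - copies) >= 2L) break
  }
  for (k in seq_along(target)) {
    pp <- sim$truth$p_pop[in_reg, pop_of[k]]
    extra <- if (copies[k] < 2) stats::rbinom(sum(in_reg), 2 - copies[k], pp)
             else 0L
    gm$dosage[in_reg, target[k]] <- copies[k] * hap + extra
  }
  sim$genotypes <- gm
  rec <- c(region[c("scaffold", "start", "end")],
           list(f_island = f, populations = target_pops, hap = hap))
  sim$truth$planted <- c(sim$truth$planted, list(rec))
  sim
}

#' Simulate genotypes (neutral background plus any planted region)
#'
#' Convenience wrapper: runs [simulate_neutral()] and then [plant_sweep()]
#' for the config's `planted` entry (if any), all under the single RNG
#' stream started by the config seed, so identical configs give identical
#' output bit for bit.
#'
#' @param cfg a [sim_config()]
#' @return as [simulate_neutral()]
#' @export
simulate_genotypes <- function(cfg) {
  sim <- simulate_neutral(cfg)
  for (reg in cfg$planted) sim <- plant_sweep(sim, reg)
  sim
}

#' Simulate niche data with a planted specialist
#'
#' Site environments are standard-normal draws (sites x variables). The
#' specialist species samples sites with probability proportional to
#' exp(z . offset) — a displaced, narrow niche along the offset direction —
#' while the generalist samples sites uniformly. A zero offset makes both
#' species generalists.
#'
#' @param n_sites number of sites
#' @param n_vars number of environment variables
#' @param offset numeric vector of length `n_vars`: the specialist's niche
#'   displacement
#' @param records named numeric vector: records per species, e.g.
#'   c(specialist = 40, generalist = 80)
#' @param seed integer RNG seed
#' @return list with `env` (an [env_table()]), `occ` (an
#'   [occurrence_table()]) and `truth` (the offset)
#' @export
simulate_niche <- function(n_sites = 60, n_vars = 5,
                           offset = c(2, rep(0, 4)),
                           records = c(specialist = 40, generalist = 80),
                           seed = 1L) {
  stopifnot(length(offset) == n_vars)
  set.seed(seed)
  Z <- matrix(stats::rnorm(n_sites * n_vars), n_sites, n_vars,
              dimnames = list(paste0("site", seq_len(n_sites)),
                              paste0("bio", seq_len(n_vars))))
  pr_spec <- exp(Z %*% offset)
  pr_spec <- pr_spec / sum(pr_spec)
  draw <- function(prob, n) tabulate(
    sample.int(n_sites, n, replace = TRUE, prob = prob), n_sites)
  occ <- rbind(specialist = draw(pr_spec, records[["specialist"]]),
               generalist = draw(rep(1 / n_sites, n_sites),
                                 records[["generalist"]]))
  colnames(occ) <- rownames(Z)
  list(env = env_table(Z), occ = occurrence_table(occ),
       truth = list(offset = offset))
}

#' Write a deterministic fixture gene annotation (GFF3)
#'
#' Tiles genes every 100 kb (gene length 20 kb) along every contig of the
#' configuration, giving a known, countable overlap with any planted
#' region. Identical configs give identical file bytes.
#'
#' @param cfg a [sim_config()]
#' @param path output GFF3 path
#' @return `path`, invisibly
#' @export
make_fixture_gff <- function(cfg, path) {
  lines <- c("##gff-version 3")
  for (s in names(cfg$contigs)) {
    len <- cfg$contigs[[s]]
    lines <- c(lines,
               sprintf("##sequence-region %s 1 %d", s, as.integer(len)))
    starts0 <- seq.int(0, len - 20000, by = 100000)
    k <- seq_along(starts0)
    lines <- c(lines, sprintf(
      "%s\tislescan\tgene\t%d\t%d\t.\t+\t.\tID=gene_%s_%03d;Name=gene_%s_%03d",
      s, as.integer(starts0 + 1), as.integer(starts0 + 20000),
      s, k, s, k))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write the complete simulated fixture set to a directory
#'
#' Emits VCF, sample-sheet TSV, fixture GFF3, truth TSV and (optionally)
#' niche env/occ TSVs, the on-disk interface of every downstream stage.
#'
#' @param cfg a [sim_config()]
#' @param dir output directory (created if needed)
#' @param niche optional output of [simulate_niche()] to write alongside
#' @return named character vector of the files written
#' @export
write_fixtures <- function(cfg, dir, niche = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_genotypes(cfg)
  files <- c(vcf = file.path(dir, "genotypes.vcf"),
             sheet = file.path(dir, "samples.tsv"),
             gff = file.path(dir, "genes.gff3"),
             truth = file.path(dir, "truth.tsv"))
  write_vcf(sim$genotypes, files[["vcf"]])
  write_tsv(sim$sheet, files[["sheet"]])
  make_fixture_gff(cfg, files[["gff"]])
  truth_df <- cbind(sim$genotypes$sites[, c("scaffold", "pos")],
                    p_anc = sim$truth$p_anc,
                    as.data.frame(sim$truth$p_pop))
  write_tsv(truth_df, files[["truth"]])
  if (!is.null(niche)) {
    files <- c(files, env = file.path(dir, "env.tsv"),
               occ = file.path(dir, "occ.tsv"))
    write_tsv(cbind(site = rownames(niche$env$env),
                    as.data.frame(niche$env$env)), files[["env"]])
    write_tsv(cbind(species = rownames(niche$occ),
                    as.data.frame(unclass(niche$occ))), files[["occ"]])
  }
  files
}
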