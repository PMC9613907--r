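#' Observed heterozygosity per individual and population
#'
#' Per individual: the fraction of its non-missing sites that are
#' heterozygous. Population means and SDs are taken over individuals.
#'
#' @param gm a [genotype_matrix()]
#' @param sheet a [sample_sheet()]
#' @return list with `individual` (data.frame: individual, population, h_o)
#'   and `population` (data.frame: population, n, h_o_mean, h_o_sd)
#' @export
observed_heterozygosity <- function(gm, sheet) {
  check_sheet_covers(gm, sheet)
  X <- gm$dosage
  h <- colSums(X == 1, na.rm = TRUE) / colSums(!is.na(X))
  ind <- data.frame(individual = colnames(X),
                    population = sheet$population[match(colnames(X),
                                                        sheet$individual)],
                    h_o = unname(h), stringsAsFactors = FALSE)
  pop <- do.call(rbind, lapply(split(ind, ind$population), function(d)
    data.frame(population = d$population[1], n = nrow(d),
               h_o_mean = mean(d$h_o), h_o_sd = stats::sd(d$h_o))))
  rownames(pop) <- NULL
  list(individual = ind, population = pop)
}

# internal: per-population allele presence at every site.
# Returns list(alt = pops x sites logical, ref = ...): whether the allele is
# observed (dosage evidence from >= 1 non-missing carrier) in the population.
allele_presence <- function(gm, sheet) {
  pops <- unique(sheet$population)
  alt <- ref <- matrix(FALSE, length(pops), n_sites(gm),
                       dimnames = list(pops, NULL))
  for (p in pops) {
    X <- gm$dosage[, samples_of(sheet, populations = p), drop = FALSE]
    alt[p, ] <- rowSums(X > 0, na.rm = TRUE) > 0
    ref[p, ] <- rowSums(X < 2, na.rm = TRUE) > 0
  }
  list(alt = alt, ref = ref)
}

#' Private allele counts per population
#'
#' An allele (ref or alt) at a site is private to a population when it is
#' observed there (at least one non-missing carrier genotype) and in no
#' other population. Counts are summed over both alleles and all sites.
#'
#' @param gm a [genotype_matrix()]
#' @param sheet a [sample_sheet()]
#' @return named integer vector, one count per population
#' @export
private_alleles <- function(gm, sheet) {
  check_sheet_covers(gm, sheet)
  if (length(unique(sheet$population)) < 2)
    stop("private alleles need >= 2 populations")
  pres <- allele_presence(gm, sheet)
  count_private(pres)
}

# internal: count alleles present in exactly one population
count_private <- function(pres) {
  tot_alt <- colSums(pres$alt)
  tot_ref <- colSums(pres$ref)
  n_priv_alt <- pres$alt & rep(tot_alt == 1, each = nrow(pres$alt))
  n_priv_ref <- pres$ref & rep(tot_ref == 1, each = nrow(pres$ref))
  rowSums(n_priv_alt) + rowSums(n_priv_ref)
}

#' Rarefied private allele counts
#'
#' Monte-Carlo rarefaction: in each replicate, `g` individuals are drawn
#' without replacement from every population (after any configured
#' population merging on the sample sheet) and private alleles are
#' recounted; the mean and SD over replicates are reported. An exhaustive
#' mode enumerates every subsample combination instead (feasible only for
#' tiny panels; used as the test oracle).
#'
#' @param gm a [genotype_matrix()]
#' @param sheet a [sample_sheet()]
#' @param g rarefaction depth (individuals per population, default 9)
#' @param reps Monte-Carlo replicates (default 1000)
#' @param seed RNG seed for reproducibility
#' @param exhaustive enumerate all subsamples instead of sampling
#' @return data.frame: population, mean, sd
#' @export
rarefied_private_alleles <- function(gm, sheet, g = 9, reps = 1000,
                                     seed = 1L, exhaustive = FALSE) {
  check_sheet_covers(gm, sheet)
  pops <- unique(sheet$population)
  by_pop <- split(sheet$individual, sheet$population)[pops]
  small <- names(by_pop)[vapply(by_pop, length, 1L) < g]
  if (length(small))
    stop("population(s) smaller than g = ", g, ": ",
         paste(small, collapse = ", "))
  if (exhaustive) {
    combos <- lapply(by_pop, function(ids)
      utils::combn(ids, g, simplify = FALSE))
    grids <- expand.grid(lapply(combos, seq_along))
    counts <- matrix(0, nrow(grids), length(pops),
                     dimnames = list(NULL, pops))
    for (k in seq_len(nrow(grids))) {
      chosen <- unlist(lapply(pops, function(p)
        combos[[p]][[grids[k, p]]]))
      counts[k, ] <- rarefaction_recount(gm, sheet, chosen, pops)
    }
  } else {
    set.seed(seed)
    counts <- matrix(0, reps, length(pops), dimnames = list(NULL, pops))
    for (k in seq_len(reps)) {
      chosen <- unlist(lapply(by_pop, function(ids) sample(ids, g)))
      counts[k, ] <- rarefaction_recount(gm, sheet, chosen, pops)
    }
  }
  sds <- if (nrow(counts) > 1) apply(counts, 2, stats::sd)
         else stats::setNames(rep(0, ncol(counts)), colnames(counts))
  data.frame(population = pops,
             mean = colMeans(counts)[pops],
             sd = sds[pops],
             row.names = NULL, stringsAsFactors = FALSE)
}

# internal: private-allele counts on a chosen subsample of individuals
rarefaction_recount <- function(gm, sheet, chosen, pops) {
  sub_sheet <- sheet[sheet$individual %in% chosen, , drop = FALSE]
  sub <- subset_genotypes(gm, samples = sub_sheet$individual)
  pres <- allele_presence(sub, sub_sheet)
  count_private(pres)[pops]
}

#' Merge populations on a sample sheet
#'
#' Relabels the given populations with a single merged label (e.g. pooling
#' two mainland populations before rarefaction). Group labels are kept.
#'
#' @param sheet a [sample_sheet()]
#' @param populations character vector of labels to merge
#' @param into the merged label
#' @return a new `sample_sheet`
#' @export
merge_populations <- function(sheet, populations, into) {
  sheet$population[sheet$population %in% populations] <- into
  sheet
}

#' Inbreeding coefficients and overall FST in the allele-sharing framework
#'
#' Per individual, the self-matching M_self (probability its two alleles
#' match) plays the role of the pair matching:
#' F_IT,i = (M_self,i - Mb) / (1 - Mb) with Mb the mean matching over all
#' distinct pairs in the panel; F_IS,i uses the baseline restricted to
#' distinct pairs within i's population. Overall FST contrasts the mean
#' within-population pair matching with the mean between-population pair
#' matching.
#'
#' @param gm a [genotype_matrix()]
#' @param sheet a [sample_sheet()] (>= 2 individuals per population)
#' @return list with `individual` (individual, population, f_is, f_it),
#'   `population` (population, f_is_mean, f_is_sd), `fst_overall`
#' @export
inbreeding_coefficients <- function(gm, sheet) {
  check_sheet_covers(gm, sheet)
  mm <- matching_matrix(gm)
  ids <- mm$samples
  pop <- sheet$population[match(ids, sheet$individual)]
  mb_all <- mean_pairs(mm$M, ids, ids)
  f_it <- (mm$self_matching - mb_all) / (1 - mb_all)
  f_is <- vapply(seq_along(ids), function(i) {
    within <- ids[pop == pop[i]]
    if (length(within) < 2) return(NA_real_)
    mb <- mean_pairs(mm$M, within, within)
    if (is.na(mb) || mb >= 1) return(NA_real_)
    (mm$self_matching[i] - mb) / (1 - mb)
  }, numeric(1))
  ind <- data.frame(individual = ids, population = pop,
                    f_is = unname(f_is), f_it = unname(f_it),
                    stringsAsFactors = FALSE)
  popdf <- do.call(rbind, lapply(split(ind, ind$population), function(d)
    data.frame(population = d$population[1],
               f_is_mean = mean(d$f_is), f_is_sd = stats::sd(d$f_is),
               f_it_mean = mean(d$f_it), f_it_sd = stats::sd(d$f_it))))
  rownames(popdf) <- NULL
  # overall FST: within-population vs between-population pair matching
  same_pop <- outer(pop, pop, "==")
  ut <- upper.tri(mm$M)
  mw <- mean(mm$M[ut & same_pop], na.rm = TRUE)
  mb <- mean(mm$M[ut & !same_pop], na.rm = TRUE)
  fst <- if (is.na(mb) || mb >= 1) NA_real_ else (mw - mb) / (1 - mb)
  list(individual = ind, population = popdf, fst_overall = fst)
}

#' Population diversity summary table
#'
#' Combines observed heterozygosity, private alleles (raw and rarefied) and
#' inbreeding coefficients into one per-population table, plus the overall
#' FST.
#'
#' @param gm a [genotype_matrix()]
#' @param sheet a [sample_sheet()]
#' @param g rarefaction depth; `NULL` skips rarefaction
#' @param reps,seed passed to [rarefied_private_alleles()]
#' @param merge_for_rarefaction optional list(populations=, into=) applied
#'   to the sheet only for the rarefaction step
#' @return list with `table` (per-population data.frame) and `fst_overall`
#' @export
diversity_summary <- function(gm, sheet, g = 9, reps = 1000, seed = 1L,
                              merge_for_rarefaction = NULL) {
  het <- observed_heterozygosity(gm, sheet)
  priv <- private_alleles(gm, sheet)
  inb <- inbreeding_coefficients(gm, sheet)
  tab <- het$population
  tab$private_alleles <- unname(priv[tab$population])
  if (!is.null(g)) {
    rsheet <- sheet
    if (!is.null(merge_for_rarefaction))
      rsheet <- merge_populations(rsheet, merge_for_rarefaction$populations,
                                  merge_for_rarefaction$into)
    rar <- rarefied_private_alleles(gm, rsheet, g = g, reps = reps,
                                    seed = seed)
    key <- tab$population
    if (!is.null(merge_for_rarefaction))
      key[key %in% merge_for_rarefaction$populations] <-
        merge_for_rarefaction$into
    tab$rarefied_unit <- key
    tab$rarefied_pa_mean <- rar$mean[match(key, rar$population)]
    tab$rarefied_pa_sd <- rar$sd[match(key, rar$population)]
  }
  tab$f_is_mean <- inb$population$f_is_mean[
    match(tab$population, inb$population$population)]
  tab$f_is_sd <- inb$population$f_is_sd[
    match(tab$population, inb$population$population)]
  tab$f_it_mean <- inb$population$f_it_mean[
    match(tab$population, inb$population$population)]
  list(table = tab, fst_overall = inb$fst_overall)
}
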