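#' Exact Hardy-Weinberg test (Levene's conditional distribution)
#'
#' Conditional on the observed allele counts, the number of heterozygotes
#' n_Aa follows Levene's exact distribution
#' \deqn{P(n_{Aa}) = \frac{n!\,2^{n_{Aa}}\,n_A!\,n_a!}{n_{AA}!\,n_{Aa}!\,n_{aa}!\,(2n)!}}
#' The p-value sums the probabilities of all outcomes no more probable than
#' the observed one (two-sided by probability ordering).
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative integers)
#' @return p-value in \[0, 1\]; monomorphic input gives 1
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("at least one genotype required")
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  if (nA == 0 || na == 0) return(1)
  dist <- hwe_het_distribution(nA, na)
  p_obs <- dist$prob[dist$n_het == n_Aa]
  sum(dist$prob[dist$prob <= p_obs + 1e-12 * p_obs])
}

# internal: full Levene distribution of the heterozygote count given allele
# counts nA + na = 2n. Returns all feasible n_het values with probabilities.
hwe_het_distribution <- function(nA, na) {
  n <- (nA + na) / 2
  # n_het shares the parity of nA (= of na) and cannot exceed min(nA, na)
  n_het <- seq.int(nA %% 2, min(nA, na), by = 2)
  logp <- lfactorial(n) + n_het * log(2) + lfactorial(nA) + lfactorial(na) -
    lfactorial((nA - n_het) / 2) - lfactorial(n_het) -
    lfactorial((na - n_het) / 2) - lfactorial(2 * n)
  data.frame(n_het = n_het, prob = exp(logp))
}

#' Filter sites on missingness and Hardy-Weinberg equilibrium
#'
#' Keeps sites with a missing-genotype fraction strictly below `max_missing`
#' and (optionally) removes sites whose exact Hardy-Weinberg test over all
#' samples pooled has p < `hwe_alpha`.
#'
#' @param gm a [genotype_matrix()]
#' @param max_missing sites with missing fraction >= this value are dropped
#' @param hwe_alpha significance level of the exact HWE test
#' @param apply_hwe logical; apply the HWE filter? Off by default: the HWE
#'   screen serves neutral-structure analyses, and scans may prefer the
#'   unscreened set.
#' @return list with `genotypes` (the filtered matrix) and `report`
#'   (data.frame of counts per filter step)
#' @export
filter_sites <- function(gm, max_missing = 0.05, hwe_alpha = 0.05,
                         apply_hwe = FALSE) {
  if (max_missing < 0 || max_missing > 1)
    stop("max_missing must be in [0, 1]")
  if (n_sites(gm) == 0) stop("empty genotype matrix")
  n_in <- n_sites(gm)
  miss_frac <- rowMeans(is.na(gm$dosage))
  keep <- miss_frac < max_missing   # strict: fraction >= threshold is dropped
  n_miss_drop <- sum(!keep)
  gm <- subset_genotypes(gm, sites = keep)
  n_hwe_drop <- 0L
  if (apply_hwe && n_sites(gm) > 0) {
    d <- gm$dosage
    p <- vapply(seq_len(nrow(d)), function(i) {
      x <- d[i, ]
      hwe_exact_test(sum(x == 0, na.rm = TRUE), sum(x == 1, na.rm = TRUE),
                     sum(x == 2, na.rm = TRUE))
    }, numeric(1))
    keep2 <- p >= hwe_alpha
    n_hwe_drop <- sum(!keep2)
    gm <- subset_genotypes(gm, sites = keep2)
  }
  report <- data.frame(
    step = c("input", "missingness", "hwe", "output"),
    sites = c(n_in, n_miss_drop, n_hwe_drop, n_sites(gm)),
    action = c("total", "dropped", "dropped", "retained"))
  list(genotypes = gm, report = report)
}

#' Greedy LD pruning of a genotype matrix
#'
#' PLINK-style `--indep-pairwise` pass: per scaffold, within each window of
#' `window_snps` consecutive SNPs any pair with squared dosage correlation
#' above `r2_max` loses its later-positioned member; the window then advances
#' by `step_snps`. Deterministic given the input order.
#'
#' @param gm a [genotype_matrix()]
#' @param window_snps window width in SNPs (default 50)
#' @param step_snps window step in SNPs (default 10)
#' @param r2_max retain only pairs with r^2 <= this (default 0.1)
#' @return the pruned `genotype_matrix`
#' @export
ld_prune <- function(gm, window_snps = 50, step_snps = 10, r2_max = 0.1) {
  if (window_snps < 2) stop("window_snps must be >= 2")
  keep <- rep(TRUE, n_sites(gm))
  for (scf in unique(gm$sites$scaffold)) {
    idx <- which(gm$sites$scaffold == scf)
    # windows run over the list of currently retained SNPs; passes repeat
    # until no window holds a pair above r2_max
    repeat {
      cur <- idx[keep[idx]]
      removed <- FALSE
      if (length(cur) >= 2) {
        for (s in seq.int(1L, length(cur), by = step_snps)) {
          win <- cur[s:min(length(cur), s + window_snps - 1L)]
          win <- win[keep[win]]
          if (length(win) < 2) next
          X <- t(gm$dosage[win, , drop = FALSE])
          r2 <- suppressWarnings(
            stats::cor(X, use = "pairwise.complete.obs"))^2
          for (j in 2:length(win)) {
            if (!keep[win[j]]) next
            for (i in 1:(j - 1)) {
              if (!keep[win[i]]) next
              if (!is.na(r2[i, j]) && r2[i, j] > r2_max) {
                keep[win[j]] <- FALSE
                removed <- TRUE
                break
              }
            }
          }
        }
      }
      if (!removed) break
    }
  }
  subset_genotypes(gm, sites = keep)
}
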