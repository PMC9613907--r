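#' Allele-sharing (matching) matrix
#'
#' For a pair of individuals with dosages x_i, x_j at a site, the matching
#' proportion — the probability that two alleles, one drawn from each
#' individual, are identical — is
#' \deqn{m = \frac{x_i x_j + (2 - x_i)(2 - x_j)}{4}.}
#' M_ij averages m over the sites where both genotypes are observed (ratio
#' of sums). Self-matching M_ii is the probability that an individual's own
#' two alleles match: 1 at homozygous sites, 0 at heterozygous ones,
#' averaged over the individual's observed sites. These quantities carry the
#' whole Weir-Goudet moment machinery (beta relatedness, population-specific
#' and pairwise FST, F_IS/F_IT).
#'
#' @param gm a [genotype_matrix()]
#' @param samples optional character vector restricting the panel
#' @param min_snps pairs with fewer jointly observed sites than this get a
#'   missing entry (default 1)
#' @return object of class `matching_matrix`: list with `samples`, `M`
#'   (symmetric pair-matching matrix, diagonal `NA`), `self_matching`,
#'   `n_sites_used` (per-pair count of jointly observed sites)
#' @export
matching_matrix <- function(gm, samples = NULL, min_snps = 1) {
  X <- gm$dosage
  if (!is.null(samples)) X <- X[, samples, drop = FALSE]
  matching_from_dosage(X, min_snps)
}

# internal: the computation behind matching_matrix, on a bare dosage matrix
matching_from_dosage <- function(X, min_snps = 1) {
  if (ncol(X) < 2) stop("need at least 2 samples")
  obs <- !is.na(X)
  A <- X; A[!obs] <- 0
  B <- 2 - X; B[!obs] <- 0
  W <- matrix(as.numeric(obs), nrow(X))
  denom <- crossprod(W)
  num <- crossprod(A) + crossprod(B)
  M <- num / (4 * denom)
  M[denom < min_snps | denom == 0] <- NA
  diag(M) <- NA
  self <- colSums((X == 0 | X == 2) & obs) / colSums(obs)
  dimnames(M) <- dimnames(denom) <- list(colnames(X), colnames(X))
  structure(list(samples = colnames(X), M = M,
                 self_matching = stats::setNames(self, colnames(X)),
                 n_sites_used = denom),
            class = "matching_matrix")
}

#' @export
print.matching_matrix <- function(x, ...) {
  cat("matching_matrix over", length(x$samples), "samples;",
      "mean pair matching", sprintf("%.4f", mean_pairs(x$M, x$samples, x$samples)),
      "\n")
  invisible(x)
}

# internal: mean of M over pairs. For a == b: mean over unordered distinct
# pairs within the set; otherwise over all a x b pairs (sets must be disjoint
# in that case for the group contrasts, enforced by callers).
mean_pairs <- function(M, a, b) {
  if (identical(sort(a), sort(b))) {
    sub <- M[a, a, drop = FALSE]
    mean(sub[upper.tri(sub)], na.rm = TRUE)
  } else {
    mean(M[a, b, drop = FALSE], na.rm = TRUE)
  }
}

#' Group-specific FST from a matching matrix
#'
#' The population- (here group-) specific FST of a target set relative to a
#' reference set:
#' \deqn{F_{ST}^{target} = \frac{\bar M_w - \bar M_b}{1 - \bar M_b}}
#' with \eqn{\bar M_w} the mean matching over unordered pairs of distinct
#' target individuals (including cross-population pairs inside the target
#' group) and \eqn{\bar M_b} the mean matching over target x reference
#' pairs. It measures excess allele sharing in the target relative to the
#' target-reference baseline, without assuming independent populations.
#'
#' @param mm a [matching_matrix()]
#' @param target character vector of sample ids, at least 2
#' @param reference character vector of sample ids, at least 1, disjoint
#'   from `target`
#' @return list of class `group_contrast` with `m_within`, `m_between`,
#'   `fst_specific`
#' @export
group_specific_fst <- function(mm, target, reference) {
  stopifnot(length(target) >= 2, length(reference) >= 1)
  if (length(intersect(target, reference)))
    stop("target and reference sets must be disjoint")
  mw <- mean_pairs(mm$M, target, target)
  mb <- mean_pairs(mm$M, target, reference)
  fst <- if (is.na(mb) || is.na(mw)) NA_real_
  else if (mb >= 1) { warning("M_between = 1: FST undefined"); NA_real_ }
  else (mw - mb) / (1 - mb)
  structure(list(target = target, reference = reference,
                 m_within = mw, m_between = mb, fst_specific = fst),
            class = "group_contrast")
}

#' Pairwise FST between two populations from a matching matrix
#'
#' \deqn{F_{ST} = \frac{\bar M_w - \bar M_b}{1 - \bar M_b}}, with
#' \eqn{\bar M_w} the unweighted average of the two within-population mean
#' matchings and \eqn{\bar M_b} the mean matching over cross-population
#' pairs.
#'
#' @param mm a [matching_matrix()]
#' @param popA,popB character vectors of sample ids (>= 2 each, disjoint)
#' @return numeric FST (possibly `NA`)
#' @export
pairwise_fst <- function(mm, popA, popB) {
  stopifnot(length(popA) >= 2, length(popB) >= 2)
  if (length(intersect(popA, popB))) stop("popA and popB must be disjoint")
  mw <- (mean_pairs(mm$M, popA, popA) + mean_pairs(mm$M, popB, popB)) / 2
  mb <- mean_pairs(mm$M, popA, popB)
  if (is.na(mb) || is.na(mw)) return(NA_real_)
  if (mb >= 1) { warning("M_between = 1: FST undefined"); return(NA_real_) }
  (mw - mb) / (1 - mb)
}

#' Individual beta relatedness
#'
#' Beta relatedness of each pair relative to the panel-wide baseline
#' \eqn{\bar M_B} (mean matching over all distinct pairs):
#' \deqn{\beta_{ij} = \frac{M_{ij} - \bar M_B}{1 - \bar M_B}.}
#' The mean of beta over all pairs is 0 by construction.
#'
#' @param mm a [matching_matrix()]
#' @return list of class `relatedness_matrix` with `beta` (symmetric matrix,
#'   diagonal `NA`) and `baseline`
#' @export
beta_relatedness <- function(mm) {
  mb <- mean_pairs(mm$M, mm$samples, mm$samples)
  beta <- (mm$M - mb) / (1 - mb)
  structure(list(beta = beta, baseline = mb, samples = mm$samples),
            class = "relatedness_matrix")
}

#' Long-format beta relatedness table
#'
#' One row per unordered pair: matching proportion, beta, and the number of
#' jointly observed sites.
#' @param mm a [matching_matrix()]
#' @return data.frame with columns `id1`, `id2`, `M`, `beta`, `n_sites`
#' @export
beta_table <- function(mm) {
  rel <- beta_relatedness(mm)
  idx <- which(upper.tri(mm$M), arr.ind = TRUE)
  data.frame(id1 = mm$samples[idx[, 1]], id2 = mm$samples[idx[, 2]],
             M = mm$M[idx], beta = rel$beta[idx],
             n_sites = mm$n_sites_used[idx],
             stringsAsFactors = FALSE)
}
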