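# Shared toy builders and independent brute-force oracles.

# Build a genotype_matrix from named per-sample dosage vectors.
toy_gm <- function(..., pos = NULL, scaffold = NULL, contig_len = 1e6) {
  cols <- list(...)
  d <- do.call(cbind, lapply(cols, as.integer))
  colnames(d) <- names(cols)
  n <- nrow(d)
  if (is.null(pos)) pos <- seq_len(n) * 10L
  if (is.null(scaffold)) scaffold <- rep("chr1", n)
  sites <- data.frame(scaffold = scaffold, pos = pos,
                      ref = rep("A", n), alt = rep("T", n),
                      stringsAsFactors = FALSE)
  lens <- tapply(rep(contig_len, n), scaffold, max)
  genotype_matrix(d, sites, setNames(as.numeric(lens), names(lens)))
}

# Matching proportion by exhaustive enumeration of the 4 allele pairings
# per site (alt allele coded 1, ref 0).
oracle_matching <- function(x, y) {
  stopifnot(length(x) == length(y))
  vals <- mapply(function(a, b) {
    if (is.na(a) || is.na(b)) return(NA_real_)
    ai <- c(rep(1, a), rep(0, 2 - a))
    bj <- c(rep(1, b), rep(0, 2 - b))
    mean(outer(ai, bj, "=="))
  }, x, y)
  mean(vals, na.rm = TRUE)
}

# Site-by-site pi with the n/(n-1) correction, plain loops.
oracle_pi <- function(X, window_bp) {
  tot <- 0
  for (i in seq_len(nrow(X))) {
    x <- X[i, ][!is.na(X[i, ])]
    n <- 2 * length(x)
    if (n < 2) next
    p <- sum(x) / n
    tot <- tot + 2 * p * (1 - p) * n / (n - 1)
  }
  tot / window_bp
}

# Site-by-site dxy, plain loops.
oracle_dxy <- function(XA, XB, window_bp) {
  tot <- 0
  for (i in seq_len(nrow(XA))) {
    a <- XA[i, ][!is.na(XA[i, ])]
    b <- XB[i, ][!is.na(XB[i, ])]
    if (!length(a) || !length(b)) next
    pA <- sum(a) / (2 * length(a))
    pB <- sum(b) / (2 * length(b))
    tot <- tot + pA * (1 - pB) + pB * (1 - pA)
  }
  tot / window_bp
}

# All permutations of a small vector (for the exact HWE pairing oracle).
all_permutations <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in all_permutations(v[-i]))
      out[[length(out) + 1]] <- c(v[i], rest)
  out
}

# Exact HWE distribution by brute force: enumerate every ordering of the
# allele multiset into diploid pairs and tally heterozygote counts.
oracle_hwe_distribution <- function(nA, na) {
  alleles <- c(rep(1, nA), rep(0, na))
  perms <- all_permutations(alleles)
  n_het <- vapply(perms, function(p) {
    pairs <- matrix(p, ncol = 2, byrow = TRUE)
    sum(pairs[, 1] != pairs[, 2])
  }, numeric(1))
  tab <- table(n_het) / length(perms)
  data.frame(n_het = as.integer(names(tab)), prob = as.numeric(tab))
}

oracle_hwe_p <- function(n_AA, n_Aa, n_aa) {
  dist <- oracle_hwe_distribution(2 * n_AA + n_Aa, 2 * n_aa + n_Aa)
  p_obs <- dist$prob[dist$n_het == n_Aa]
  sum(dist$prob[dist$prob <= p_obs + 1e-12])
}

# OMI by explicit loops: centroids, inertia decomposition and the
# eigen-decomposition of the weighted centroid cross-product.
oracle_omi <- function(Z, w_sites, occ) {
  ns <- nrow(occ); p <- ncol(Z)
  C <- matrix(0, ns, p)
  omi <- tol <- inertia <- numeric(ns)
  for (s in seq_len(ns)) {
    f <- occ[s, ] / sum(occ[s, ])
    for (k in seq_len(nrow(Z))) C[s, ] <- C[s, ] + f[k] * Z[k, ]
    omi[s] <- sum(C[s, ]^2)
    for (k in seq_len(nrow(Z))) inertia[s] <- inertia[s] + f[k] * sum(Z[k, ]^2)
    if (omi[s] > 1e-12) {
      u <- C[s, ] / sqrt(omi[s])
      for (k in seq_len(nrow(Z)))
        tol[s] <- tol[s] + f[k] * (sum(Z[k, ] * u) - sqrt(omi[s]))^2
    }
  }
  W <- rowSums(occ) / sum(occ)
  B <- matrix(0, p, p)
  for (s in seq_len(ns)) B <- B + W[s] * C[s, ] %*% t(C[s, ])
  ev <- eigen(B, symmetric = TRUE)$values
  ev <- ev[ev > max(ev, 0) * 1e-12]
  list(omi = omi, tol = tol, rtol = inertia - omi - tol,
       inertia = inertia, axis_pct = ev / sum(ev) * 100)
}

# A small panmictic population: iid Binomial(2, p) genotypes.
panmictic_gm <- function(n_snps, n_ind, p = NULL, seed = 1) {
  set.seed(seed)
  if (is.null(p)) p <- runif(n_snps, 0.05, 0.95)
  d <- matrix(rbinom(n_snps * n_ind, 2, rep(p, n_ind)), n_snps, n_ind)
  colnames(d) <- sprintf("ind_%02d", seq_len(n_ind))
  sites <- data.frame(scaffold = "chr1", pos = seq_len(n_snps) * 10L,
                      ref = "A", alt = "T", stringsAsFactors = FALSE)
  genotype_matrix(d, sites, c(chr1 = n_snps * 10 + 100))
}
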