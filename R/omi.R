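#' Build an environment table
#'
#' Sites x variables matrix of climatic (or other) conditions with site
#' weights summing to 1 (uniform by default, or e.g. raster-cell areas).
#'
#' @param env numeric matrix or data.frame, sites in rows, variables in
#'   columns; must have column names
#' @param site_weights optional non-negative weights, one per site;
#'   normalised to sum to 1
#' @return object of class `env_table`: list with `env` (matrix),
#'   `weights`
#' @export
env_table <- function(env, site_weights = NULL) {
  env <- as.matrix(env)
  if (nrow(env) < 2) stop("need >= 2 sites")
  if (anyNA(env)) stop("environment table must not contain missing values")
  if (is.null(colnames(env)))
    colnames(env) <- paste0("var", seq_len(ncol(env)))
  if (is.null(rownames(env)))
    rownames(env) <- paste0("site", seq_len(nrow(env)))
  w <- if (is.null(site_weights)) rep(1, nrow(env)) else site_weights
  if (any(w < 0)) stop("site weights must be >= 0")
  structure(list(env = env, weights = w / sum(w)), class = "env_table")
}

#' Drop exactly redundant environment variables
#'
#' Removes later columns whose absolute Pearson correlation with an earlier
#' column is 1 (within `tol`), mirroring the trimming of duplicated
#' bioclimatic layers before ordination.
#'
#' @param et an [env_table()]
#' @param tol tolerance on |correlation| - 1
#' @return the trimmed `env_table`
#' @export
drop_redundant <- function(et, tol = 1e-12) {
  cc <- abs(stats::cor(et$env))
  keep <- rep(TRUE, ncol(et$env))
  for (j in seq_len(ncol(et$env))[-1])
    if (any(cc[seq_len(j - 1), j] >= 1 - tol & keep[seq_len(j - 1)]))
      keep[j] <- FALSE
  env_table(et$env[, keep, drop = FALSE], et$weights)
}

#' Standardize an environment table
#'
#' Centres each variable to weighted mean 0 and scales to weighted variance
#' 1 under the site weights, so that the origin of the niche space is the
#' mean habitat condition of the sampling area.
#'
#' @param et an [env_table()]
#' @return the standardized `env_table`
#' @export
standardize_env <- function(et) {
  w <- et$weights
  mu <- colSums(et$env * w)
  centred <- sweep(et$env, 2, mu)
  v <- colSums(centred^2 * w)
  zero <- v <= 0
  if (any(zero))
    stop("zero-variance variable(s): ",
         paste(colnames(et$env)[zero], collapse = ", "))
  env_table(sweep(centred, 2, sqrt(v), "/"), w)
}

#' Build an occurrence table
#'
#' Species x sites non-negative weights (typically presence counts
#' aggregated per site or raster cell).
#'
#' @param occ numeric matrix or data.frame, species in rows, sites in
#'   columns matching the environment table's sites
#' @return object of class `occurrence_table`
#' @export
occurrence_table <- function(occ) {
  occ <- as.matrix(occ)
  if (any(occ < 0)) stop("occurrence weights must be >= 0")
  if (any(rowSums(occ) <= 0)) stop("every species needs positive total weight")
  if (is.null(rownames(occ)))
    rownames(occ) <- paste0("species", seq_len(nrow(occ)))
  structure(occ, class = c("occurrence_table", class(occ)))
}

#' Outlying Mean Index niche analysis
#'
#' For each species, the niche centroid is the occurrence-weighted mean of
#' the standardized site environments, and OMI is its squared Euclidean
#' norm: the squared distance between the species' mean habitat conditions
#' and those of the sampling area (the origin, representing a hypothetical
#' ubiquitous species). Ordination axes come from the eigen-decomposition
#' of the species-total-weighted cross-product of the centroid matrix; each
#' axis carries eigenvalue / sum(eigenvalues) of the marginality
#' variability. Per species, total occurrence-weighted inertia decomposes
#' as OMI + Tol + Rtol, where Tol is the weighted variance of the species'
#' site scores along its own centroid direction (niche breadth along the
#' marginality direction) and Rtol the remaining within-species inertia.
#'
#' @param et a standardized [env_table()] (see [standardize_env()])
#' @param occ an [occurrence_table()] whose columns match `et`'s sites
#' @param n_axes number of ordination axes to return (default 2)
#' @return object of class `niche_result`: list with `species` (data.frame:
#'   species, omi, tol, rtol, inertia), `axis_pct`, `axis_loadings`
#'   (variables x axes), `species_scores`, `site_scores`
#' @export
omi_analysis <- function(et, occ, n_axes = 2) {
  Z <- et$env
  if (ncol(occ) != nrow(Z))
    stop("occurrence table sites do not match environment table")
  fr <- occ / rowSums(occ)              # species occurrence profiles
  C <- fr %*% Z                         # species centroids (species x p)
  omi <- rowSums(C^2)
  inertia <- as.vector(fr %*% rowSums(Z^2))
  tol <- numeric(nrow(C))
  for (s in seq_len(nrow(C))) {
    if (omi[s] > 1e-12) {
      u <- C[s, ] / sqrt(omi[s])
      sc <- Z %*% u                     # site scores along centroid direction
      tol[s] <- sum(fr[s, ] * (sc - sqrt(omi[s]))^2)
    } else tol[s] <- 0
  }
  rtol <- inertia - omi - tol

  W <- rowSums(occ) / sum(occ)          # species total weights
  B <- crossprod(C * sqrt(W))           # weighted cross-product (p x p)
  eig <- eigen(B, symmetric = TRUE)
  pos <- eig$values > max(eig$values, 0) * 1e-12
  rank <- sum(pos)
  if (n_axes > rank) {
    message("requested ", n_axes, " axes but rank is ", rank,
            "; truncating")
    n_axes <- rank
  }
  vals <- eig$values[pos]
  pct <- vals / sum(vals) * 100
  vec <- eig$vectors[, which(pos)[seq_len(n_axes)], drop = FALSE]
  # deterministic axis orientation: largest-|loading| entry positive
  for (a in seq_len(ncol(vec))) {
    i <- which.max(abs(vec[, a]))
    if (vec[i, a] < 0) vec[, a] <- -vec[, a]
  }
  dimnames(vec) <- list(colnames(Z), paste0("OMI", seq_len(ncol(vec))))
  structure(list(
    species = data.frame(species = rownames(occ), omi = unname(omi),
                         tol = unname(tol), rtol = unname(rtol),
                         inertia = unname(inertia),
                         stringsAsFactors = FALSE),
    axis_pct = pct[seq_len(n_axes)],
    axis_pct_all = pct,
    axis_loadings = vec,
    species_scores = C %*% vec,
    site_scores = Z %*% vec),
    class = "niche_result")
}

#' @export
print.niche_result <- function(x, ...) {
  cat("OMI niche analysis:", nrow(x$species), "species;",
      "axis shares (%):",
      paste(sprintf("%.1f", x$axis_pct_all), collapse = ", "), "\n")
  print(x$species)
  invisible(x)
}

#' Permutation test of OMI significance
#'
#' Random row shifts of the occurrence profiles under a fixed seed; the
#' p-value is the fraction of permutations (plus the observed) with OMI at
#' least as large as observed. Off by default in the workflow.
#'
#' @param et a standardized [env_table()]
#' @param occ an [occurrence_table()]
#' @param n_perm number of permutations (default 999)
#' @param seed RNG seed
#' @return data.frame: species, omi, p_value
#' @export
omi_permutation_test <- function(et, occ, n_perm = 999, seed = 1L) {
  obs <- omi_analysis(et, occ, n_axes = 1)$species$omi
  set.seed(seed)
  n_sites <- ncol(occ)
  count <- rep(1L, nrow(occ))
  for (k in seq_len(n_perm)) {
    perm <- occ[, sample(n_sites), drop = FALSE]
    o <- omi_analysis(et, occurrence_table(perm), n_axes = 1)$species$omi
    count <- count + (o >= obs - 1e-12)
  }
  data.frame(species = rownames(occ), omi = obs,
             p_value = count / (n_perm + 1), stringsAsFactors = FALSE)
}
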