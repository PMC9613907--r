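#' Sliding windows over contigs
#'
#' Fixed-size windows laid per scaffold at 0, step, 2*step, ... while the
#' whole window fits inside the contig; trailing partial windows are not
#' emitted.
#'
#' @param contig_lengths named numeric vector, scaffold -> length (bp)
#' @param size window size in bp (default 100 kb)
#' @param step window step in bp (default 20 kb)
#' @return data.frame with `scaffold`, `start` (0-based), `end` (half-open)
#' @export
make_windows <- function(contig_lengths, size = 100000, step = 20000) {
  stopifnot(size >= step, step >= 1)
  out <- lapply(names(contig_lengths), function(scf) {
    len <- contig_lengths[[scf]]
    if (len < size) return(NULL)
    starts <- seq.int(0, len - size, by = step)
    data.frame(scaffold = scf, start = starts, end = starts + size,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(scaffold = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Nucleotide diversity of a group over a window
#'
#' Per-bp pi with the unbiased per-site factor n/(n-1):
#' \deqn{\pi = \sum_{sites} 2 p (1-p) \frac{n}{n-1} \; / \; L}
#' where p is the group's alternate-allele frequency, n the number of
#' observed allele copies at the site, and L the window length in bp.
#' Positions absent from the SNP set count as invariant.
#'
#' @param gm a [genotype_matrix()]
#' @param group character vector of sample ids
#' @param window_bp window length L in bp
#' @param sites optional site index restricting the computation
#' @return per-bp pi, or `NA` if no site has >= 2 observed allele copies
#' @export
window_pi <- function(gm, group, window_bp, sites = NULL) {
  X <- gm$dosage[, group, drop = FALSE]
  if (!is.null(sites)) X <- X[sites, , drop = FALSE]
  if (nrow(X) == 0) return(0)
  n <- 2 * rowSums(!is.na(X))
  p <- rowSums(X, na.rm = TRUE) / n
  use <- n >= 2
  if (!any(use)) return(NA_real_)
  sum(2 * p[use] * (1 - p[use]) * n[use] / (n[use] - 1)) / window_bp
}

#' Absolute divergence (dxy) between two groups over a window
#'
#' \deqn{d_{xy} = \sum_{sites} [p_A (1 - p_B) + p_B (1 - p_A)] / L}
#' with group alternate-allele frequencies p_A, p_B and window length L.
#'
#' @param gm a [genotype_matrix()]
#' @param groupA,groupB character vectors of sample ids
#' @param window_bp window length L in bp
#' @param sites optional site index restricting the computation
#' @return per-bp dxy, or `NA` if either group is unobserved at every site
#' @export
window_dxy <- function(gm, groupA, groupB, window_bp, sites = NULL) {
  XA <- gm$dosage[, groupA, drop = FALSE]
  XB <- gm$dosage[, groupB, drop = FALSE]
  if (!is.null(sites)) {
    XA <- XA[sites, , drop = FALSE]
    XB <- XB[sites, , drop = FALSE]
  }
  if (nrow(XA) == 0) return(0)
  nA <- 2 * rowSums(!is.na(XA)); nB <- 2 * rowSums(!is.na(XB))
  pA <- rowSums(XA, na.rm = TRUE) / nA
  pB <- rowSums(XB, na.rm = TRUE) / nB
  use <- nA >= 1 & nB >= 1
  if (!any(use)) return(NA_real_)
  sum(pA[use] * (1 - pB[use]) + pB[use] * (1 - pA[use])) / window_bp
}

#' Declare the contrasts of a window scan
#'
#' Each element is named by the output column it produces. Populations are
#' referred to by their sample-sheet labels.
#'
#' @param fst_specific named list; each element
#'   `list(target = <pops>, reference = <pops>)`
#' @param fst_pairwise named list; each element `list(a = <pops>, b = <pops>)`
#' @param dxy named list; each element `list(a = <pops>, b = <pops>)`
#' @param pi named list; each element a character vector of populations
#' @return object of class `scan_contrasts`
#' @export
scan_contrasts <- function(fst_specific = list(), fst_pairwise = list(),
                           dxy = list(), pi = list()) {
  structure(list(fst_specific = fst_specific, fst_pairwise = fst_pairwise,
                 dxy = dxy, pi = pi),
            class = "scan_contrasts")
}

# internal: resolve contrast population labels to sample ids, erroring on
# unknown labels before any computation starts
resolve_contrasts <- function(contrasts, sheet) {
  res <- list(
    fst_specific = lapply(contrasts$fst_specific, function(cc)
      list(target = samples_of(sheet, populations = cc$target),
           reference = samples_of(sheet, populations = cc$reference))),
    fst_pairwise = lapply(contrasts$fst_pairwise, function(cc)
      list(a = samples_of(sheet, populations = cc$a),
           b = samples_of(sheet, populations = cc$b))),
    dxy = lapply(contrasts$dxy, function(cc)
      list(a = samples_of(sheet, populations = cc$a),
           b = samples_of(sheet, populations = cc$b))),
    pi = lapply(contrasts$pi, function(pp)
      samples_of(sheet, populations = pp)))
  res
}

#' Windowed genome scan
#'
#' For each window, builds the allele-sharing matrix of the in-window SNPs
#' and evaluates every configured statistic: group-specific FST, pairwise
#' FST, dxy and pi. Windows with fewer than `min_snps` SNPs are emitted with
#' missing statistics so downstream threshold estimation can exclude them.
#'
#' @param gm a [genotype_matrix()]
#' @param sheet a [sample_sheet()] covering the samples of `gm`
#' @param contrasts a [scan_contrasts()]
#' @param windows window table from [make_windows()]; defaults to 100 kb /
#'   20 kb windows over `gm$contig_lengths`
#' @param min_snps minimum SNPs per window for statistics to be computed
#' @return data.frame, one row per window, sorted by (scaffold, start):
#'   `scaffold`, `start`, `end`, `n_snps`, then one column per statistic
#' @export
scan_windows <- function(gm, sheet, contrasts, windows = NULL, min_snps = 10) {
  check_sheet_covers(gm, sheet)
  rc <- resolve_contrasts(contrasts, sheet)
  if (is.null(windows))
    windows <- make_windows(gm$contig_lengths)
  windows <- windows[order(windows$scaffold, windows$start), , drop = FALSE]

  need_mm <- length(rc$fst_specific) + length(rc$fst_pairwise) > 0
  mm_samples <- unique(unlist(c(
    lapply(rc$fst_specific, unlist), lapply(rc$fst_pairwise, unlist))))
  stat_names <- c(names(rc$fst_specific), names(rc$fst_pairwise),
                  names(rc$dxy), names(rc$pi))
  stats_mat <- matrix(NA_real_, nrow(windows), length(stat_names),
                      dimnames = list(NULL, stat_names))
  n_snps <- integer(nrow(windows))

  pos0 <- gm$sites$pos - 1  # windows are 0-based half-open
  by_scf <- split(seq_len(n_sites(gm)), gm$sites$scaffold)
  for (w in seq_len(nrow(windows))) {
    in_scf <- by_scf[[windows$scaffold[w]]]
    if (length(in_scf)) {
      p <- pos0[in_scf]  # sorted within scaffold
      lo <- findInterval(windows$start[w] - 0.5, p) + 1L
      hi <- findInterval(windows$end[w] - 0.5, p)
      idx <- if (hi >= lo) in_scf[lo:hi] else integer()
    } else idx <- integer()
    n_snps[w] <- length(idx)
    if (length(idx) < min_snps) next
    wbp <- windows$end[w] - windows$start[w]
    if (need_mm) {
      mm <- matching_from_dosage(
        gm$dosage[idx, mm_samples, drop = FALSE])
      for (nm in names(rc$fst_specific))
        stats_mat[w, nm] <- group_specific_fst(
          mm, rc$fst_specific[[nm]]$target,
          rc$fst_specific[[nm]]$reference)$fst_specific
      for (nm in names(rc$fst_pairwise))
        stats_mat[w, nm] <- pairwise_fst(
          mm, rc$fst_pairwise[[nm]]$a, rc$fst_pairwise[[nm]]$b)
    }
    for (nm in names(rc$dxy))
      stats_mat[w, nm] <- window_dxy(gm, rc$dxy[[nm]]$a, rc$dxy[[nm]]$b,
                                     wbp, sites = idx)
    for (nm in names(rc$pi))
      stats_mat[w, nm] <- window_pi(gm, rc$pi[[nm]], wbp, sites = idx)
  }
  out <- cbind(windows, n_snps = n_snps,
               as.data.frame(stats_mat, optional = TRUE))
  rownames(out) <- NULL
  out
}

#' Blocked linkage-disequilibrium matrix
#'
#' Within a sample group, SNPs with minor-allele frequency strictly above
#' `maf_min` are grouped per scaffold into consecutive blocks of
#' `block_snps`; the entry (u, v) is the mean squared Pearson correlation of
#' dosages over all SNP pairs with one member in each block (distinct pairs
#' only within a block). The final block of a scaffold may be partial and is
#' flagged.
#'
#' @param gm a [genotype_matrix()]
#' @param group character vector of sample ids (>= 2)
#' @param maf_min SNPs with group MAF <= this are excluded (strict "over")
#' @param block_snps block size in SNPs (default 100)
#' @return list of class `ld_block_matrix`, one element per scaffold, each
#'   with `blocks` (data.frame: index, first/last site position, n_snps,
#'   partial flag) and `r2` (symmetric matrix of block-pair mean r^2)
#' @export
ld_blocks <- function(gm, group, maf_min = 0.05, block_snps = 100) {
  if (length(group) < 2) stop("LD needs at least 2 samples in the group")
  X <- gm$dosage[, group, drop = FALSE]
  n_obs <- rowSums(!is.na(X))
  p <- rowSums(X, na.rm = TRUE) / (2 * n_obs)
  maf <- pmin(p, 1 - p)
  keep <- !is.na(maf) & maf > maf_min
  out <- list()
  for (s in unique(gm$sites$scaffold)) {
    idx <- which(gm$sites$scaffold == s & keep)
    if (length(idx) < 2) next
    nb <- ceiling(length(idx) / block_snps)
    block_of <- rep(seq_len(nb), each = block_snps, length.out = length(idx))
    blocks <- data.frame(
      block = seq_len(nb),
      pos_first = gm$sites$pos[idx[!duplicated(block_of)]],
      pos_last = gm$sites$pos[idx[!duplicated(block_of, fromLast = TRUE)]],
      n_snps = as.integer(table(block_of)),
      partial = tabulate(block_of, nb) < block_snps)
    r2 <- matrix(NA_real_, nb, nb)
    for (u in seq_len(nb)) {
      xu <- t(X[idx[block_of == u], , drop = FALSE])
      for (v in u:nb) {
        xv <- t(X[idx[block_of == v], , drop = FALSE])
        cc <- suppressWarnings(
          stats::cor(xu, xv, use = "pairwise.complete.obs"))^2
        if (u == v) {
          val <- mean(cc[upper.tri(cc)], na.rm = TRUE)
        } else {
          val <- mean(cc, na.rm = TRUE)
        }
        r2[u, v] <- r2[v, u] <- val
      }
    }
    out[[s]] <- list(blocks = blocks, r2 = r2)
  }
  structure(out, class = "ld_block_matrix")
}
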