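#' Five-sigma style outlier threshold
#'
#' mean + k * SD over the non-missing values, with the sample standard
#' deviation (n - 1 denominator). Computed once genome-wide per run.
#'
#' @param values numeric vector of windowed statistic values
#' @param k sigma multiplier (default 5)
#' @return the threshold
#' @export
sigma_threshold <- function(values, k = 5) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("need >= 2 non-missing values")
  mean(values) + k * stats::sd(values)
}

#' Upper-tail probability of a sigma multiplier
#'
#' One-sided standard-normal tail beyond k standard deviations: the chance
#' that a window exceeds the mean + k * SD threshold under normality. At
#' k = 5 this is about 2.87e-7, i.e. one chance in roughly 3.5 million.
#'
#' @param k sigma multiplier (> 0 for a meaningful tail; k = 0 gives 0.5)
#' @return upper-tail probability in (0, 1)
#' @export
tail_probability <- function(k) {
  stats::pnorm(k, lower.tail = FALSE)
}

# internal: cluster above-threshold windows by genomic-span overlap within a
# scaffold; returns the region table
cluster_windows <- function(rows, pass, stat_col, min_windows) {
  hits <- rows[pass, , drop = FALSE]
  if (nrow(hits) == 0)
    return(data.frame(scaffold = character(), start = numeric(),
                      end = numeric(), n_support_windows = integer(),
                      peak_value = numeric(), stringsAsFactors = FALSE))
  out <- list()
  for (s in unique(hits$scaffold)) {
    h <- hits[hits$scaffold == s, , drop = FALSE]
    h <- h[order(h$start), , drop = FALSE]
    ir <- IRanges::IRanges(start = h$start + 1, end = h$end)  # 1-based closed
    # min.gapwidth = 0: merge genuinely overlapping spans only, not abutting
    red <- IRanges::reduce(ir, with.revmap = TRUE, min.gapwidth = 0)
    revmap <- S4Vectors::mcols(red)$revmap
    for (ci in seq_along(red)) {
      members <- revmap[[ci]]
      if (length(members) < min_windows) next
      out[[length(out) + 1]] <- data.frame(
        scaffold = s,
        start = IRanges::start(red)[ci] - 1,
        end = as.numeric(IRanges::end(red)[ci]),
        n_support_windows = length(members),
        peak_value = max(h[[stat_col]][members]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(scaffold = character(), start = numeric(),
                      end = numeric(), n_support_windows = integer(),
                      peak_value = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$scaffold, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Call candidate selected regions from windowed statistics
#'
#' Windows with the statistic strictly above the threshold are clustered by
#' genomic-span overlap on the same scaffold (with steps smaller than the
#' window size, consecutive outlier windows always overlap); clusters
#' supported by at least `min_windows` windows become regions spanning the
#' union of their windows.
#'
#' @param rows window table from [scan_windows()]
#' @param statistic name of the statistic column
#' @param threshold numeric threshold (typically from [sigma_threshold()])
#' @param min_windows minimum supporting windows per region (default 2)
#' @return data.frame with `scaffold`, `start`, `end` (0-based half-open
#'   union), `n_support_windows`, `peak_value`
#' @export
call_regions <- function(rows, statistic, threshold, min_windows = 2) {
  if (!statistic %in% names(rows))
    stop("unknown statistic: ", statistic)
  stopifnot(is.finite(threshold))
  rows <- rows[order(rows$scaffold, rows$start), , drop = FALSE]
  pass <- !is.na(rows[[statistic]]) & rows[[statistic]] > threshold
  cluster_windows(rows, pass, statistic, min_windows)
}

#' Call regions under the dual pairwise + population-quantile rule
#'
#' A window supports a region only if the pairwise statistic exceeds its
#' five-sigma style threshold AND the population-specific statistic exceeds
#' its own genome-wide `pop_quantile` quantile (computed over non-missing
#' windows with linear interpolation). Clustering as in [call_regions()].
#' The thresholds actually applied are attached as attribute `thresholds`.
#'
#' @param rows window table from [scan_windows()]
#' @param pair_stat name of the pairwise statistic column
#' @param pair_threshold numeric threshold for `pair_stat`
#' @param pop_stat name of the population-specific statistic column
#' @param pop_quantile quantile level for `pop_stat` (default 0.99)
#' @param min_windows minimum supporting windows per region (default 2)
#' @return region data.frame as in [call_regions()], with a `thresholds`
#'   attribute recording both applied cutoffs
#' @export
call_regions_dual <- function(rows, pair_stat, pair_threshold,
                              pop_stat, pop_quantile = 0.99,
                              min_windows = 2) {
  for (s in c(pair_stat, pop_stat))
    if (!s %in% names(rows)) stop("unknown statistic: ", s)
  q <- stats::quantile(rows[[pop_stat]], pop_quantile, na.rm = TRUE,
                       names = FALSE, type = 7)
  rows <- rows[order(rows$scaffold, rows$start), , drop = FALSE]
  pass <- !is.na(rows[[pair_stat]]) & rows[[pair_stat]] > pair_threshold &
    !is.na(rows[[pop_stat]]) & rows[[pop_stat]] > q
  res <- cluster_windows(rows, pass, pair_stat, min_windows)
  attr(res, "thresholds") <- c(stats::setNames(pair_threshold, pair_stat),
                               stats::setNames(q, pop_stat))
  res
}

#' Annotate regions with overlapping genes
#'
#' A gene is assigned to a region when their half-open intervals overlap by
#' at least 1 bp. Gene lists are deduplicated within a region and ordered by
#' position.
#'
#' @param regions region table from [call_regions()]
#' @param genes a `gene_annotation` from [read_gff()]
#' @return list with `regions` (the input plus a `genes` list-column of gene
#'   ids) and `gene_table` (flat data.frame: region id, gene id, gene name,
#'   overlap bp)
#' @export
annotate_regions <- function(regions, genes) {
  regions$genes <- vector("list", nrow(regions))
  gene_table <- data.frame(region = character(), gene_id = character(),
                           gene_name = character(), overlap_bp = numeric(),
                           stringsAsFactors = FALSE)
  if (nrow(genes) == 0) {
    warning("empty gene annotation: no genes assigned")
    return(list(regions = regions, gene_table = gene_table))
  }
  if (nrow(regions) == 0)
    return(list(regions = regions, gene_table = gene_table))
  gr_reg <- GenomicRanges::GRanges(
    regions$scaffold, IRanges::IRanges(regions$start + 1, regions$end))
  gr_gen <- GenomicRanges::GRanges(
    genes$scaffold, IRanges::IRanges(genes$start + 1, genes$end))
  ov <- GenomicRanges::findOverlaps(gr_reg, gr_gen)
  rows <- list()
  for (r in seq_len(nrow(regions))) {
    g <- S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) == r]
    g <- unique(g[order(genes$start[g])])
    regions$genes[[r]] <- genes$gene_id[g]
    if (length(g)) {
      olap <- pmin(regions$end[r], genes$end[g]) -
        pmax(regions$start[r], genes$start[g])
      rows[[length(rows) + 1]] <- data.frame(
        region = sprintf("region_%03d", r),
        gene_id = genes$gene_id[g], gene_name = genes$gene_name[g],
        overlap_bp = olap, stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) gene_table <- do.call(rbind, rows)
  rownames(gene_table) <- NULL
  list(regions = regions, gene_table = gene_table)
}
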