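#' Construct a genotype matrix
#'
#' The central container of the package: a sites x samples matrix of diploid
#' alternate-allele dosages (0, 1, 2 or `NA` for missing) together with site
#' metadata and contig lengths. All downstream statistics (allele sharing,
#' FST, pi, dxy, LD) consume this object.
#'
#' @param dosage integer matrix, sites in rows, samples in columns; values in
#'   {0, 1, 2, NA}. Column names are the sample identifiers.
#' @param sites data.frame with columns `scaffold`, `pos` (1-based, as in
#'   VCF), `ref`, `alt` (single-character nucleotides).
#' @param contig_lengths named numeric vector, scaffold -> length in bp.
#'   May be empty if no windowed analysis is intended.
#'
#' @return an object of class `genotype_matrix`: a list with elements
#'   `dosage`, `sites`, `contig_lengths`, `samples`.
#' @export
genotype_matrix <- function(dosage, sites, contig_lengths = numeric()) {
  dosage <- as.matrix(dosage)
  stopifnot(is.data.frame(sites),
            all(c("scaffold", "pos", "ref", "alt") %in% names(sites)))
  if (nrow(dosage) != nrow(sites))
    stop("dosage has ", nrow(dosage), " rows but sites has ", nrow(sites))
  if (is.null(colnames(dosage)))
    stop("dosage must have sample identifiers as column names")
  if (anyDuplicated(colnames(dosage)))
    stop("duplicated sample names: ",
         paste(unique(colnames(dosage)[duplicated(colnames(dosage))]),
               collapse = ", "))
  bad <- !(dosage %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stop("dosage values must be 0, 1, 2 or NA")
  if (any(sites$pos < 1)) stop("site positions must be >= 1 (1-based)")
  if (any(sites$ref == sites$alt)) stop("ref and alt alleles must differ")
  ord <- order(sites$scaffold, sites$pos)
  if (is.unsorted(ord)) {
    dosage <- dosage[ord, , drop = FALSE]
    sites <- sites[ord, , drop = FALSE]
  }
  if (anyDuplicated(sites[, c("scaffold", "pos")]))
    stop("duplicate (scaffold, position) entries in sites")
  rownames(sites) <- NULL
  structure(
    list(dosage = dosage, sites = sites,
         contig_lengths = contig_lengths, samples = colnames(dosage)),
    class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosage), "sites x",
      ncol(x$dosage), "samples on",
      length(unique(x$sites$scaffold)), "scaffold(s)\n")
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missing genotypes: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' Number of sites in a genotype matrix
#' @param gm a [genotype_matrix()]
#' @return integer count of sites
#' @export
n_sites <- function(gm) nrow(gm$dosage)

#' Subset a genotype matrix by site index and/or samples
#'
#' @param gm a [genotype_matrix()]
#' @param sites integer or logical index over sites (rows)
#' @param samples character vector of sample ids, or index
#' @return a `genotype_matrix` restricted to the selection
#' @export
subset_genotypes <- function(gm, sites = NULL, samples = NULL) {
  d <- gm$dosage
  s <- gm$sites
  if (!is.null(sites)) {
    d <- d[sites, , drop = FALSE]
    s <- s[sites, , drop = FALSE]
  }
  if (!is.null(samples)) d <- d[, samples, drop = FALSE]
  genotype_matrix(d, s, gm$contig_lengths)
}

#' Construct a sample sheet
#'
#' Maps each individual to its population and each population to a group
#' (typically `"island"` / `"mainland"`), defining the contrasts of the scan.
#'
#' @param individual character vector of sample ids
#' @param population character vector, same length, population label per
#'   individual
#' @param group_of named character vector mapping population label -> group
#'   label; populations absent from the map get group `NA`.
#' @return a data.frame of class `sample_sheet` with columns `individual`,
#'   `population`, `group`
#' @export
sample_sheet <- function(individual, population, group_of = NULL) {
  stopifnot(length(individual) == length(population))
  if (anyDuplicated(individual))
    stop("duplicated individuals in sample sheet")
  group <- if (is.null(group_of)) rep(NA_character_, length(individual))
           else unname(group_of[population])
  out <- data.frame(individual = as.character(individual),
                    population = as.character(population),
                    group = as.character(group),
                    stringsAsFactors = FALSE)
  class(out) <- c("sample_sheet", class(out))
  out
}

#' Read a sample sheet from TSV
#'
#' Expects columns `individual`, `population` and optionally `group`.
#' @param path TSV file with a header row
#' @return a `sample_sheet`
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("individual", "population") %in% names(df)))
    stop("sample sheet needs 'individual' and 'population' columns")
  if (is.null(df$group)) df$group <- NA_character_
  sample_sheet(df$individual, df$population,
               group_of = stats::setNames(df$group, df$population))
}

#' Individuals belonging to given populations or groups
#'
#' @param sheet a [sample_sheet()]
#' @param populations character vector of population labels (optional)
#' @param groups character vector of group labels (optional)
#' @return character vector of sample ids
#' @export
samples_of <- function(sheet, populations = NULL, groups = NULL) {
  keep <- rep(FALSE, nrow(sheet))
  if (!is.null(populations)) {
    unknown <- setdiff(populations, sheet$population)
    if (length(unknown))
      stop("unknown population label(s): ", paste(unknown, collapse = ", "))
    keep <- keep | sheet$population %in% populations
  }
  if (!is.null(groups)) {
    unknown <- setdiff(groups, sheet$group)
    if (length(unknown))
      stop("unknown group label(s): ", paste(unknown, collapse = ", "))
    keep <- keep | sheet$group %in% groups
  }
  sheet$individual[keep]
}

# internal: check that every sample of gm is covered exactly once
check_sheet_covers <- function(gm, sheet) {
  missing <- setdiff(gm$samples, sheet$individual)
  if (length(missing))
    stop("samples absent from sample sheet: ", paste(missing, collapse = ", "))
  invisible(TRUE)
}
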