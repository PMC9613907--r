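#' Read a VCF into a genotype matrix
#'
#' Retains biallelic SNP records only (single-nucleotide REF and ALT, exactly
#' one ALT), drops records on excluded scaffolds (e.g. sex-linked
#' super-scaffolds), and converts GT fields to alternate-allele dosage.
#' Phased and unphased genotypes are treated identically; `./.` (or `.|.`,
#' `.`) becomes missing.
#'
#' @param path VCF v4.x file, plain or bgzipped
#' @param exclude_scaffolds character vector of scaffold names to drop
#' @param contig_lengths optional named vector of contig lengths; when `NULL`
#'   lengths are taken from `##contig` header lines (if present)
#' @return a [genotype_matrix()]
#' @export
read_vcf <- function(path, exclude_scaffolds = character(),
                     contig_lengths = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("no records in VCF: ", path)

  keep <- !is.na(fix$REF) & !is.na(fix$ALT) &
    nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T") &
    !(fix$CHROM %in% exclude_scaffolds)
  if (!any(keep)) stop("no biallelic SNPs left after filtering scaffolds")

  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  if (anyDuplicated(colnames(gt)))
    stop("duplicated sample names in VCF: ",
         paste(unique(colnames(gt)[duplicated(colnames(gt))]), collapse = ", "))

  dosage <- gt_to_dosage(gt)
  sites <- data.frame(scaffold = fix$CHROM,
                      pos = as.integer(fix$POS),
                      ref = fix$REF, alt = fix$ALT,
                      stringsAsFactors = FALSE)
  if (is.null(contig_lengths)) {
    contig_lengths <- contig_lengths_from_meta(vcf@meta)
    contig_lengths <- contig_lengths[!(names(contig_lengths) %in%
                                         exclude_scaffolds)]
  }
  genotype_matrix(dosage, sites, contig_lengths)
}

# internal: GT strings -> dosage via a lookup over the distinct codes present
gt_to_dosage <- function(gt) {
  codes <- unique(as.vector(gt))
  val <- vapply(codes, function(g) {
    if (is.na(g)) return(NA_integer_)
    alleles <- strsplit(gsub("|", "/", g, fixed = TRUE), "/", fixed = TRUE)[[1]]
    if (any(alleles == ".") || length(alleles) == 0) return(NA_integer_)
    suppressWarnings(a <- as.integer(alleles))
    if (anyNA(a)) stop("malformed GT field: '", g, "'")
    sum(a > 0L)
  }, integer(1))
  matrix(val[match(as.vector(gt), codes)], nrow = nrow(gt),
         dimnames = list(NULL, colnames(gt)))
}

# internal: parse ##contig=<ID=...,length=...> header lines
contig_lengths_from_meta <- function(meta) {
  lines <- grep("^##contig=", meta, value = TRUE)
  if (!length(lines)) return(numeric())
  ids <- sub('.*ID=([^,>]+).*', "\\1", lines)
  lens <- suppressWarnings(as.numeric(sub('.*length=([0-9]+).*', "\\1", lines)))
  stats::setNames(lens, ids)[!is.na(lens)]
}

#' Write a genotype matrix as VCF v4.2
#'
#' Emits a minimal GT-only VCF (with `##contig` header lines) suitable for
#' round-tripping through [read_vcf()] and for consumption by external tools.
#'
#' @param gm a [genotype_matrix()]
#' @param path output file; a `.gz` suffix triggers gzip compression
#' @return `path`, invisibly
#' @export
write_vcf <- function(gm, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(gm$contig_lengths),
            as.integer(gm$contig_lengths)),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t"))
  gtcode <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- matrix("./.", nrow = nrow(gm$dosage), ncol = ncol(gm$dosage))
  obs <- !is.na(gm$dosage)
  gt[obs] <- gtcode[as.character(gm$dosage[obs])]
  body <- paste(gm$sites$scaffold, gm$sites$pos, ".",
                gm$sites$ref, gm$sites$alt, ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Read gene records from a GFF3 annotation
#'
#' Keeps rows of feature type `gene`. GFF 1-based inclusive coordinates are
#' converted to the package-internal 0-based half-open convention. The gene
#' name comes from the `Name` attribute, falling back to `ID`; records with
#' neither are skipped with a warning.
#'
#' @param path GFF3 file
#' @return data.frame of class `gene_annotation` with columns `scaffold`,
#'   `start` (0-based), `end` (half-open), `strand`, `gene_id`, `gene_name`
#' @export
read_gff <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[!is.na(gr$type) & gr$type == "gene"]
  empty <- data.frame(scaffold = character(), start = numeric(),
                      end = numeric(), strand = character(),
                      gene_id = character(), gene_name = character(),
                      stringsAsFactors = FALSE)
  if (length(gr) == 0) {
    warning("no 'gene' features found in ", path)
    return(structure(empty, class = c("gene_annotation", "data.frame")))
  }
  id <- if (!is.null(gr$ID)) as.character(gr$ID) else rep(NA_character_, length(gr))
  nm <- if (!is.null(gr$Name)) as.character(gr$Name) else rep(NA_character_, length(gr))
  anon <- is.na(id) & is.na(nm)
  if (any(anon)) {
    warning(sum(anon), " gene record(s) without ID or Name skipped")
    gr <- gr[!anon]; id <- id[!anon]; nm <- nm[!anon]
  }
  out <- data.frame(
    scaffold = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,   # to 0-based half-open
    end = as.numeric(GenomicRanges::end(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_id = ifelse(is.na(id), nm, id),
    gene_name = ifelse(is.na(nm), id, nm),
    stringsAsFactors = FALSE)
  out <- out[order(out$scaffold, out$start), ]
  rownames(out) <- NULL
  structure(out, class = c("gene_annotation", "data.frame"))
}

#' Write a data.frame as TSV
#'
#' Tab-separated with a header row and `NA` for missing values — the format
#' used for all tabular outputs of the workflow.
#' @param df data.frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write regions as BED
#'
#' BED3 plus name and score columns; BED is natively 0-based half-open so
#' region coordinates are written unchanged.
#' @param regions region table from [call_regions()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_bed <- function(regions, path) {
  bed <- data.frame(regions$scaffold, as.integer(regions$start),
                    as.integer(regions$end),
                    sprintf("region_%03d", seq_len(nrow(regions))),
                    regions$peak_value)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
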