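read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) stop("input file not found: ", path)
  x <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    stop(basename(path), " lacks required columns: ",
         paste(missing, collapse = ", "))
  }
  x
}

#' Read a probe annotation table
#'
#' Tab-separated with header: `snp_id`, `chrom`, `pos`, `allele_a`, `allele_b`,
#' `flank`, `variant_index` (1-based). MSRE site counts are computed from the
#' flanks unless `msre_sites_a`/`msre_sites_b` columns are already present.
#'
#' @param path File path.
#' @param enzymes Enzyme table for site counting.
#' @return Probe annotation data.frame with site counts.
#' @export
read_probe_annotation <- function(path, enzymes = msre_enzymes()) {
  x <- read_tsv_checked(path, c("snp_id", "chrom", "pos", "allele_a",
                                "allele_b", "flank", "variant_index"))
  x$chrom <- as.character(x$chrom)
  if (!all(c("msre_sites_a", "msre_sites_b") %in% names(x))) {
    x <- add_site_counts(x, enzymes)
  }
  x
}

#' Read a long-format intensity table
#'
#' Tab-separated with header: `sample_id`, `condition` (G/D/U), `snp_id`,
#' `intensity_a`, `intensity_b`.
#'
#' @param path File path.
#' @return Intensity data.frame.
#' @export
read_intensities <- function(path) {
  x <- read_tsv_checked(path, c("sample_id", "condition", "snp_id",
                                "intensity_a", "intensity_b"))
  validate_intensities(x)
  x
}

#' Read a genotype call table
#'
#' Tab-separated with header: `sample_id`, `snp_id`, `call` (AA/AB/BB/NoCall).
#'
#' @param path File path.
#' @return Genotype data.frame.
#' @export
read_genotypes <- function(path) {
  x <- read_tsv_checked(path, c("sample_id", "snp_id", "call"))
  validate_genotypes(x)
  x
}

#' Read a susceptibility-locus table
#'
#' Either a tab-separated table with header (`locus_id`, `tag_snp`, `chrom`,
#' `gene_name`, `gene_start`, `gene_end`; 1-based inclusive coordinates) or a
#' BED file (`.bed` extension; 0-based half-open, converted to 1-based
#' inclusive on reading, name column used as `gene_name`).
#'
#' @param path File path.
#' @return Locus data.frame in 1-based inclusive coordinates.
#' @export
read_loci <- function(path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    x <- utils::read.delim(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
    if (ncol(x) < 4) stop("BED locus file needs chrom, start, end, name")
    out <- data.frame(locus_id = x[[4]], tag_snp = NA_character_,
                      chrom = as.character(x[[1]]), gene_name = x[[4]],
                      gene_start = x[[2]] + 1L, gene_end = x[[3]],
                      stringsAsFactors = FALSE)
    return(out)
  }
  x <- read_tsv_checked(path, c("locus_id", "tag_snp", "chrom", "gene_name",
                                "gene_start", "gene_end"))
  x$chrom <- as.character(x$chrom)
  x
}

#' Read a long-format pyrosequencing table
#'
#' Tab-separated with header: `sample_id`, `genotype`, `allele`, `cpg_index`,
#' `methylation_pct`.
#'
#' @param path File path.
#' @return Pyrosequencing data.frame.
#' @export
read_pyro <- function(path) {
  x <- read_tsv_checked(path, c("sample_id", "genotype", "allele", "cpg_index",
                                "methylation_pct"))
  validate_pyro(x)
  x
}

#' Read a long-format expression table
#'
#' Tab-separated with header: `gene_name`, `sample_id`, `fpkm`.
#'
#' @param path File path.
#' @return Expression data.frame.
#' @export
read_expression <- function(path) {
  read_tsv_checked(path, c("gene_name", "sample_id", "fpkm"))
}

#' Write a tab-separated table with header
#'
#' @param x data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
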