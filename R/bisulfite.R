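#' Bisulfite-convert a sequence given a methylation mask
#'
#' Applies the bisulfite conversion rule on the top strand: every cytosine that
#' is not a methylated CpG cytosine is deaminated to uracil and read as thymine
#' after PCR; methylated CpG cytosines are protected and stay C. Non-C bases
#' are untouched, so the output has the same length as the input.
#'
#' @param seq Uppercase DNA string (A/C/G/T/N).
#' @param methylated_cpg Integer vector of 1-based positions, each pointing at
#'   the C of a CpG dinucleotide that is methylated.
#' @return The converted sequence.
#' @examples
#' bisulfite_convert("ACGA", 2)   # methylated CpG preserved: "ACGA"
#' bisulfite_convert("ACGA")      # unmethylated CpG converted: "ATGA"
#' @export
bisulfite_convert <- function(seq, methylated_cpg = integer()) {
  check_dna(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  methylated_cpg <- as.integer(methylated_cpg)
  for (p in methylated_cpg) {
    if (is.na(p) || p < 1L || p > length(chars)) {
      stop("methylated CpG position ", p, " out of bounds")
    }
    if (chars[p] != "C" || p == length(chars) || chars[p + 1L] != "G") {
      stop("position ", p, " does not begin a CpG dinucleotide")
    }
  }
  convert <- chars == "C"
  convert[methylated_cpg] <- FALSE
  chars[convert] <- "T"
  paste(chars, collapse = "")
}

#' Are two SNP alleles distinguishable after bisulfite conversion?
#'
#' On the bisulfite-converted top strand an unmethylated C reads as T, so a C/T
#' SNP collapses: the converted C allele is indistinguishable from the native T
#' allele. Any other allele pair remains readable. This check decides whether
#' allele-specific PCR can target the SNP directly or needs a proxy SNP in
#' complete linkage disequilibrium.
#'
#' @param allele_1,allele_2 Two distinct single bases.
#' @return `FALSE` for the pair \{C, T\}, `TRUE` otherwise.
#' @examples
#' alleles_distinguishable_after_bisulfite("C", "T")  # FALSE: needs a proxy SNP
#' alleles_distinguishable_after_bisulfite("A", "G")  # TRUE
#' @export
alleles_distinguishable_after_bisulfite <- function(allele_1, allele_2) {
  stopifnot(nchar(allele_1) == 1L, nchar(allele_2) == 1L)
  a <- toupper(c(allele_1, allele_2))
  if (!all(a %in% c("A", "C", "G", "T"))) stop("alleles must be A/C/G/T")
  if (a[1] == a[2]) stop("alleles must be distinct")
  !setequal(a, c("C", "T"))
}

#' Allele-specific PCR specificity gate
#'
#' Pass/fail check on the measured specificity of an allele-specific PCR
#' product (percentage of reads carrying the targeted allele at the
#' discriminating position), used before trusting per-allele methylation calls.
#'
#' @param specificity_pct Measured specificity in percent.
#' @param min_pct Minimum acceptable specificity (default 85).
#' @return Logical.
#' @export
allele_pcr_specific <- function(specificity_pct, min_pct = 85) {
  stopifnot(is.numeric(specificity_pct), is.numeric(min_pct))
  specificity_pct >= min_pct
}
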