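#' Methylation-sensitive restriction enzyme table
#'
#' The default MSRE cocktail used for the digestion arm of an MSNP experiment:
#' HpaII (C^CGG), HhaI (GCG^C) and AciI (C^CGC). Each enzyme cleaves its
#' recognition site only when the internal CpG is unmethylated, which is what
#' makes the digested (D) array condition informative about methylation.
#'
#' AciI is the only non-palindromic enzyme of the three; double-stranded DNA is
#' cut when either strand presents the site, so scanning considers the reverse
#' complement (GCGG) as well.
#'
#' @return A data.frame with one row per enzyme and columns `name`,
#'   `recognition` (A/C/G/T string), `cut_offset` (1-based position after which
#'   the enzyme cuts within the recognition site), `cpg_offset` (1-based
#'   position of the C of the internal CpG), and `palindromic`.
#' @examples
#' msre_enzymes()
#' @export
msre_enzymes <- function() {
  enz <- data.frame(
    name        = c("HpaII", "HhaI", "AciI"),
    recognition = c("CCGG", "GCGC", "CCGC"),
    cut_offset  = c(1L, 3L, 1L),
    cpg_offset  = c(2L, 2L, 2L),
    palindromic = c(TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  validate_enzymes(enz)
  enz
}

validate_enzymes <- function(enzymes) {
  stopifnot(is.data.frame(enzymes), nrow(enzymes) >= 1)
  need <- c("name", "recognition", "cut_offset", "cpg_offset", "palindromic")
  missing <- setdiff(need, names(enzymes))
  if (length(missing) > 0) {
    stop("enzyme table lacks columns: ", paste(missing, collapse = ", "))
  }
  if (!all(grepl("^[ACGT]+$", enzymes$recognition))) {
    stop("enzyme recognition sequences must contain only A/C/G/T")
  }
  if (any(nchar(enzymes$recognition) < 4)) {
    stop("enzyme recognition sequences must be at least 4 bp")
  }
  # methylation sensitivity requires an internal CpG
  if (!all(grepl("CG", enzymes$recognition, fixed = TRUE))) {
    stop("every methylation-sensitive enzyme must contain a CpG in its site")
  }
  invisible(enzymes)
}

reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

check_dna <- function(seq, allow_n = TRUE) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    stop("sequence must be a single character string")
  }
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  if (!grepl(pat, seq)) {
    stop("sequence contains non-DNA characters: only A/C/G/T",
         if (allow_n) "/N" else "", " are allowed")
  }
  invisible(seq)
}

#' Scan a sequence for methylation-sensitive restriction sites
#'
#' Finds every occurrence (including overlapping ones) of each enzyme's
#' recognition sequence. Palindromic sites are reported once, on the plus
#' strand. For non-palindromic enzymes the reverse complement of the
#' recognition sequence is also searched and reported as a minus-strand hit at
#' its position on the given (top) strand. `N` bases never match, so a site
#' overlapping an `N` is not called.
#'
#' @param seq A single uppercase DNA string (A/C/G/T/N).
#' @param enzymes An enzyme table as returned by [msre_enzymes()].
#' @return A data.frame with columns `enzyme`, `start` (1-based offset of the
#'   site on `seq`), and `strand` (`"+"` or `"-"`), sorted by `start`.
#' @examples
#' scan_msre_sites("CCGG")            # one HpaII site
#' scan_msre_sites("GCGGCC")          # AciI on the minus strand
#' @export
scan_msre_sites <- function(seq, enzymes = msre_enzymes()) {
  check_dna(seq)
  validate_enzymes(enzymes)
  if (nchar(seq) == 0L) {
    return(data.frame(enzyme = character(), start = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  subject <- Biostrings::DNAString(seq)
  hits <- vector("list", 2L * nrow(enzymes))
  k <- 0L
  for (i in seq_len(nrow(enzymes))) {
    rec <- enzymes$recognition[i]
    if (nchar(seq) >= nchar(rec)) {
      st <- Biostrings::start(Biostrings::matchPattern(rec, subject, fixed = TRUE))
      if (length(st) > 0) {
        k <- k + 1L
        hits[[k]] <- data.frame(enzyme = enzymes$name[i], start = as.integer(st),
                                strand = "+", stringsAsFactors = FALSE)
      }
      if (!enzymes$palindromic[i]) {
        rc <- reverse_complement(rec)
        st <- Biostrings::start(Biostrings::matchPattern(rc, subject, fixed = TRUE))
        if (length(st) > 0) {
          k <- k + 1L
          hits[[k]] <- data.frame(enzyme = enzymes$name[i], start = as.integer(st),
                                  strand = "-", stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (k == 0L) {
    return(data.frame(enzyme = character(), start = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits[seq_len(k)])
  out <- out[order(out$start, out$enzyme, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count intact MSRE sites for each allele of a probe
#'
#' Substitutes each allele at the variant position of the probe's flanking
#' sequence and counts recognition sites via [scan_msre_sites()]. A probe
#' belongs to the MSNP analysis population iff at least one allele carries at
#' least one site (`max(count_a, count_b) >= 1`): only then can digestion
#' change its signal.
#'
#' @param flank Flanking DNA sequence containing the variant position.
#' @param allele_a,allele_b The two alleles (single bases).
#' @param variant_index 1-based position of the variant within `flank`.
#' @param enzymes Enzyme table, see [msre_enzymes()].
#' @return Named integer vector `c(count_a = , count_b = )`.
#' @examples
#' probe_site_counts("AACCGGAA", "C", "T", 4)   # CCGG made/broken by the allele
#' @export
probe_site_counts <- function(flank, allele_a, allele_b, variant_index,
                              enzymes = msre_enzymes()) {
  check_dna(flank)
  stopifnot(length(allele_a) == 1L, length(allele_b) == 1L,
            nchar(allele_a) == 1L, nchar(allele_b) == 1L)
  if (identical(allele_a, allele_b)) stop("alleles must differ")
  variant_index <- as.integer(variant_index)
  if (is.na(variant_index) || variant_index < 1L || variant_index > nchar(flank)) {
    stop("variant_index out of flank bounds")
  }
  count_for <- function(base) {
    s <- flank
    substr(s, variant_index, variant_index) <- base
    nrow(scan_msre_sites(s, enzymes))
  }
  c(count_a = count_for(allele_a), count_b = count_for(allele_b))
}

#' Annotate a probe table with per-allele MSRE site counts
#'
#' Convenience wrapper applying [probe_site_counts()] to every row of a probe
#' annotation table; adds/overwrites `msre_sites_a` and `msre_sites_b` and an
#' `in_analysis_population` flag.
#'
#' @param probes Probe annotation data.frame with columns `snp_id`, `allele_a`,
#'   `allele_b`, `flank`, `variant_index`.
#' @param enzymes Enzyme table.
#' @return The probe table with site-count columns added.
#' @export
add_site_counts <- function(probes, enzymes = msre_enzymes()) {
  need <- c("snp_id", "allele_a", "allele_b", "flank", "variant_index")
  missing <- setdiff(need, names(probes))
  if (length(missing) > 0) stop("probe table lacks columns: ",
                                paste(missing, collapse = ", "))
  counts <- vapply(seq_len(nrow(probes)), function(i) {
    probe_site_counts(probes$flank[i], probes$allele_a[i], probes$allele_b[i],
                      probes$variant_index[i], enzymes)
  }, integer(2))
  probes$msre_sites_a <- counts[1L, ]
  probes$msre_sites_b <- counts[2L, ]
  probes$in_analysis_population <- pmax(probes$msre_sites_a,
                                        probes$msre_sites_b) >= 1L
  probes
}
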