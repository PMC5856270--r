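#' Heterozygous samples for a SNP
#'
#' Samples whose G-array genotype call at the given SNP is `AB`, in the stable
#' order of the genotype table. `NoCall` samples are never selected.
#'
#' @param genotypes Genotype call table (`sample_id`, `snp_id`, `call`).
#' @param snp_id SNP identifier.
#' @return Character vector of sample ids (possibly empty).
#' @export
select_heterozygotes <- function(genotypes, snp_id) {
  validate_genotypes(genotypes)
  genotypes$sample_id[genotypes$snp_id == snp_id & genotypes$call == "AB"]
}

#' Classify the direction of per-heterozygote RAS shifts
#'
#' Distinguishes cis-regulated ASM from imprinting-like ASM. Under cis
#' regulation the methylated allele is determined by the genotype, so the RAS
#' shift after digestion moves in one direction in every heterozygote
#' (monoallelic call conversion). Under imprinting the methylated allele is
#' parental-origin dependent, so shifts occur in both directions (biallelic).
#' Shifts smaller than `min_shift` in magnitude are ignored as noise.
#'
#' @param shifts Per-heterozygote signed RAS shifts (`RAS_D - RAS_G`).
#' @param concordance_frac Fraction of qualifying shifts that must share one
#'   sign for a monoallelic call (default 0.9).
#' @param min_shift Minimum absolute shift to qualify (default 0.05).
#' @return `"monoallelic"`, `"biallelic"`, or `"indeterminate"` (fewer than two
#'   qualifying shifts).
#' @examples
#' classify_direction(c(0.3, 0.25, 0.28, 0.31))    # monoallelic
#' classify_direction(c(0.3, -0.3, 0.28, -0.25))   # biallelic
#' @export
classify_direction <- function(shifts, concordance_frac = 0.9,
                               min_shift = 0.05) {
  stopifnot(is.numeric(shifts), concordance_frac > 0.5, concordance_frac <= 1,
            min_shift >= 0)
  shifts <- shifts[!is.na(shifts)]
  if (length(shifts) < 2L) return("indeterminate")
  q <- shifts[abs(shifts) >= min_shift]
  if (length(q) < 2L) return("indeterminate")
  pos <- mean(q > 0)
  neg <- mean(q < 0)
  if (pos >= concordance_frac || neg >= concordance_frac) return("monoallelic")
  if (pos >= 1 - concordance_frac && neg >= 1 - concordance_frac) {
    return("biallelic")
  }
  "indeterminate"
}

#' Is a SNP within a window around a susceptibility gene?
#'
#' TRUE iff the SNP is on the same chromosome and its position lies in
#' `[gene_start - window_bp, gene_end + window_bp]`, boundaries inclusive
#' ("within 100 kbp" is read as a closed interval). Start/end are normalised so
#' a swapped interval behaves identically. Vectorised over loci.
#'
#' @param chrom,pos SNP chromosome and 1-based position.
#' @param locus_chrom,gene_start,gene_end Locus chromosome and 1-based
#'   inclusive gene interval (vectorised).
#' @param window_bp Window size in bp on each side (default 100000).
#' @return Logical vector.
#' @export
within_window <- function(chrom, pos, locus_chrom, gene_start, gene_end,
                          window_bp = 100000) {
  stopifnot(window_bp >= 0)
  lo <- pmin(gene_start, gene_end)
  hi <- pmax(gene_start, gene_end)
  chrom == locus_chrom & pos >= lo - window_bp & pos <= hi + window_bp
}

#' Quantitative probe QC replacing visual cluster inspection
#'
#' Three numeric surrogates for manual review of signal cluster plots:
#' \describe{
#'   \item{cut_site_artifact}{heterozygote RAS on the fully unmethylated U
#'     control shifted from RAS on G by more than `u_shift_max` on average:
#'     the allele difference itself creates or destroys a cut site, so the D
#'     shift is not evidence of methylation.}
#'   \item{unstable_hybridization}{coefficient of variation of the per-sample
#'     G-condition signal distance above `cv_max`.}
#'   \item{insufficient_heterozygotes}{fewer than `min_het_candidate` valid
#'     heterozygote pairs (a single heterozygote cannot establish ASM).}
#' }
#'
#' @param ras_g,ras_u Per-heterozygote RAS in G and U (same order).
#' @param g_distances Per-sample G-condition signal distances
#'   `sqrt(A^2 + B^2)`, all samples.
#' @param n_het Number of valid heterozygote pairs.
#' @param u_shift_max Maximum mean `|RAS_U - RAS_G|` (default 0.1).
#' @param cv_max Maximum CV of G distances (default 1.0).
#' @param min_het_candidate Minimum heterozygotes for a candidate (default 4).
#' @return Character vector of raised flags (empty when all checks pass).
#' @export
cluster_qc <- function(ras_g, ras_u, g_distances, n_het,
                       u_shift_max = 0.1, cv_max = 1.0,
                       min_het_candidate = 4L) {
  flags <- character()
  ok <- !is.na(ras_g) & !is.na(ras_u)
  if (any(ok) && mean(abs(ras_u[ok] - ras_g[ok])) > u_shift_max) {
    flags <- c(flags, "cut_site_artifact")
  }
  g_distances <- g_distances[is.finite(g_distances)]
  if (length(g_distances) >= 2 && mean(g_distances) > 0 &&
      stats::sd(g_distances) / mean(g_distances) > cv_max) {
    flags <- c(flags, "unstable_hybridization")
  }
  if (n_het < min_het_candidate) {
    flags <- c(flags, "insufficient_heterozygotes")
  }
  flags
}

#' Extract cis-ASM candidate SNPs (the selection funnel)
#'
#' Reproduces the candidate-selection funnel: (1) analysis population = probes
#' with at least one MSRE site on either allele; (2) exclusion criteria on the
#' G/U and D/U distance ratios; (3) ASM detection, `delta_ras_bar` above the
#' threshold over at least `min_het` heterozygotes; (4) proximity window around
#' susceptibility genes; (5) quantitative cluster QC and direction
#' classification. Candidates are returned sorted by `delta_ras_bar`
#' descending, with matched genes, direction (monoallelic = cis-consistent,
#' biallelic = imprinting-like) and QC flags; probes with raised QC flags are
#' dropped from the candidate table but retained in the per-stage report.
#'
#' @param stats Per-probe statistics from [probe_asm_stats()].
#' @param probes Probe annotation with `snp_id`, `chrom`, `pos` and MSRE site
#'   counts (`msre_sites_a`, `msre_sites_b`; see [add_site_counts()]).
#' @param loci Susceptibility locus table (`locus_id`, `tag_snp`, `chrom`,
#'   `gene_name`, `gene_start`, `gene_end`). Zero-width loci
#'   (`gene_start == gene_end` at a tag-SNP position) give tag-SNP windowing.
#' @param intensities,genotypes Raw inputs, used for the QC stage.
#' @param asm_threshold `delta_ras_bar` threshold (default 0.1).
#' @param window_bp Proximity window (default 100000).
#' @param min_het Minimum heterozygote pairs for evaluability (default 2).
#' @param concordance_frac,min_shift Direction-classification parameters, see
#'   [classify_direction()].
#' @param u_shift_max,cv_max,min_het_candidate QC thresholds, see
#'   [cluster_qc()].
#' @return List with `candidates` (QC-passing candidate table), `report` (all
#'   window-stage probes with direction and flags), and `funnel` (named integer
#'   vector of per-stage counts).
#' @export
extract_candidates <- function(stats, probes, loci, intensities, genotypes,
                               asm_threshold = 0.1, window_bp = 100000,
                               min_het = 2L, concordance_frac = 0.9,
                               min_shift = 0.05, u_shift_max = 0.1,
                               cv_max = 1.0, min_het_candidate = 4L) {
  if (is.null(loci) || nrow(loci) == 0) {
    stop("susceptibility locus table is empty")
  }
  need <- c("snp_id", "chrom", "pos", "msre_sites_a", "msre_sites_b")
  missing <- setdiff(need, names(probes))
  if (length(missing) > 0) stop("probe table lacks columns: ",
                                paste(missing, collapse = ", "))

  funnel <- c(total = nrow(stats))

  # stage 1: analysis population (>=1 MSRE site on either allele)
  pop_ids <- probes$snp_id[pmax(probes$msre_sites_a, probes$msre_sites_b) >= 1]
  s <- stats[stats$snp_id %in% pop_ids, ]
  funnel["analysis_population"] <- nrow(s)

  # stage 2: exclusion criteria
  s <- s[!is.na(s$excluded_by) & s$excluded_by == "keep", ]
  funnel["pass_exclusion"] <- nrow(s)

  # stage 3: ASM detection among evaluable probes
  s <- s[s$evaluable & !is.na(s$delta_ras_bar) &
           s$delta_ras_bar > asm_threshold, ]
  funnel["asm_detected"] <- nrow(s)

  # stage 4: proximity to susceptibility genes
  pr <- probes[match(s$snp_id, probes$snp_id), ]
  matched <- lapply(seq_len(nrow(s)), function(i) {
    hit <- within_window(pr$chrom[i], pr$pos[i], loci$chrom,
                         loci$gene_start, loci$gene_end, window_bp)
    if (!any(hit)) return(NULL)
    lo <- pmin(loci$gene_start[hit], loci$gene_end[hit])
    hi <- pmax(loci$gene_start[hit], loci$gene_end[hit])
    dist <- pmax(0, pmax(lo - pr$pos[i], pr$pos[i] - hi))
    paste0(loci$gene_name[hit], " (", dist, " bp)", collapse = "; ")
  })
  in_window <- !vapply(matched, is.null, logical(1))
  s <- s[in_window, ]
  s$matched_genes <- unlist(matched[in_window], use.names = FALSE)
  funnel["in_window"] <- nrow(s)

  # stage 5: direction classification + quantitative cluster QC
  if (nrow(s) > 0) {
    pairs <- het_ras_pairs(intensities, genotypes)
    gint <- intensities[intensities$condition == "G", ]
    gdist <- sqrt(gint$intensity_a^2 + gint$intensity_b^2)
    s$direction <- NA_character_
    s$qc_flags <- NA_character_
    for (i in seq_len(nrow(s))) {
      p <- pairs[pairs$snp_id == s$snp_id[i], ]
      shifts <- p$ras_d - p$ras_g
      s$direction[i] <- classify_direction(shifts, concordance_frac, min_shift)
      flags <- cluster_qc(p$ras_g, p$ras_u, gdist[gint$snp_id == s$snp_id[i]],
                          n_het = s$n_het[i], u_shift_max = u_shift_max,
                          cv_max = cv_max,
                          min_het_candidate = min_het_candidate)
      s$qc_flags[i] <- paste(flags, collapse = ",")
    }
  } else {
    s$direction <- character(0)
    s$qc_flags <- character(0)
  }
  report <- s[order(-s$delta_ras_bar), ]
  rownames(report) <- NULL
  candidates <- report[report$qc_flags == "", ]
  rownames(candidates) <- NULL
  funnel["qc_pass"] <- nrow(candidates)
  funnel["monoallelic"] <- sum(candidates$direction == "monoallelic")

  list(candidates = candidates, report = report, funnel = funnel)
}
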