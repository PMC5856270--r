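#' Relative allele score
#'
#' RAS = A / (A + B), the fraction of a probe's total fluorescence attributable
#' to the A allele (the analogue of a B-allele frequency). Heterozygotes sit
#' near 0.5 on the genomic (G) array; allele-specific methylation shows up as a
#' shift of RAS on the digested (D) array.
#'
#' @param intensity_a,intensity_b Non-negative channel intensities (vectorised).
#' @return Numeric vector in \[0, 1\]; `NA` where `A + B == 0` (such records are
#'   dropped from downstream RAS sets).
#' @examples
#' compute_ras(500, 500)  # 0.5
#' compute_ras(30, 70)    # 0.3
#' @export
compute_ras <- function(intensity_a, intensity_b) {
  stopifnot(is.numeric(intensity_a), is.numeric(intensity_b))
  if (any(!is.finite(intensity_a)) || any(!is.finite(intensity_b))) {
    stop("intensities must be finite")
  }
  if (any(intensity_a < 0) || any(intensity_b < 0)) {
    stop("intensities must be non-negative")
  }
  total <- intensity_a + intensity_b
  out <- intensity_a / total
  out[total == 0] <- NA_real_
  out
}

#' Mean allele intensities for one probe in one array condition
#'
#' Arithmetic means of the A and B channel intensities across all samples
#' assayed in a condition. These condition means (bar quantities) feed the
#' exclusion-ratio computation; they are taken over every sample regardless of
#' genotype, because the exclusion criteria concern cutting and hybridisation
#' physics, not genotype.
#'
#' @param intensity_a,intensity_b Channel intensities across samples.
#' @return Named numeric vector `c(mean_a = , mean_b = )`.
#' @export
condition_means <- function(intensity_a, intensity_b) {
  stopifnot(length(intensity_a) >= 1, length(intensity_a) == length(intensity_b))
  c(mean_a = mean(intensity_a), mean_b = mean(intensity_b))
}

#' Exclusion ratios from condition-mean intensities
#'
#' `distance(X)` is the Euclidean norm of the mean intensity pair
#' `sqrt(mean_a^2 + mean_b^2)` of condition X, i.e. the distance of the
#' condition's mean signal from the origin of the two-channel cluster plot.
#' Returns `distance(G)/distance(U)` and `distance(D)/distance(U)`.
#'
#' @param mean_g,mean_d,mean_u Length-2 numeric vectors `(mean_a, mean_b)` for
#'   the G, D and U conditions.
#' @return Named numeric vector `c(ratio_g_u = , ratio_d_u = )`; `NA` ratios if
#'   `distance(U)` is zero (probe not evaluable).
#' @examples
#' exclusion_ratios(c(300, 400), c(100, 0), c(30, 40))  # ratio_g_u = 10
#' @export
exclusion_ratios <- function(mean_g, mean_d, mean_u) {
  stopifnot(length(mean_g) == 2, length(mean_d) == 2, length(mean_u) == 2)
  d <- function(x) sqrt(sum(x^2))
  du <- d(mean_u)
  if (du == 0) {
    return(c(ratio_g_u = NA_real_, ratio_d_u = NA_real_))
  }
  c(ratio_g_u = d(mean_g) / du, ratio_d_u = d(mean_d) / du)
}

#' Apply the two probe exclusion criteria
#'
#' Criterion 1 removes probes whose U signal is not reduced relative to G
#' (`distance(G)/distance(U) < threshold`): the probe is either not cut by the
#' enzyme cocktail or cut fragments still hybridise, so digestion is
#' uninformative. Criterion 2 removes probes whose D signal is reduced as much
#' as U (`distance(D)/distance(U) < threshold`): both alleles are unmethylated
#' and fully cut, so no allele contrast is measurable. Criterion 1 is tested
#' first.
#'
#' @param ratio_g_u,ratio_d_u Exclusion ratios (vectorised).
#' @param threshold Ratio threshold, default 1.2.
#' @return Character vector: `"criterion1"`, `"criterion2"`, `"keep"`, or `NA`
#'   for non-finite ratios.
#' @examples
#' apply_exclusion_criteria(1.0, 5.0)  # "criterion1"
#' apply_exclusion_criteria(5.0, 1.0)  # "criterion2"
#' apply_exclusion_criteria(5.0, 5.0)  # "keep"
#' @export
apply_exclusion_criteria <- function(ratio_g_u, ratio_d_u, threshold = 1.2) {
  stopifnot(length(ratio_g_u) == length(ratio_d_u), threshold > 0)
  out <- rep(NA_character_, length(ratio_g_u))
  ok <- is.finite(ratio_g_u) & is.finite(ratio_d_u)
  out[ok & ratio_g_u < threshold] <- "criterion1"
  out[ok & ratio_g_u >= threshold & ratio_d_u < threshold] <- "criterion2"
  out[ok & ratio_g_u >= threshold & ratio_d_u >= threshold] <- "keep"
  out
}

#' Average RAS change over heterozygotes (the ASM statistic)
#'
#' For each heterozygous individual the G and D arrays are paired within that
#' individual and the RAS shift `RAS_D - RAS_G` computed. The ASM statistic
#' `delta_ras_bar` is the mean of the absolute shifts (robust to mixtures of
#' directions, so imprinted probes score as ASM too); the signed mean is kept
#' separately for cis-versus-imprinting classification downstream. Pairs where
#' either RAS is `NA` (zero total intensity) are dropped record-wise.
#'
#' @param ras_g,ras_d Per-heterozygote RAS in G and D (same individual order).
#' @param min_het Minimum valid pairs for the probe to be evaluable (default 2).
#' @param asm_threshold ASM detection threshold on `delta_ras_bar` (default 0.1).
#' @return List with `delta_ras_bar`, `signed_delta`, `n_het` (valid pairs),
#'   `evaluable`, and `asm` (`NA` when not evaluable).
#' @examples
#' delta_ras_bar(c(0.5, 0.5), c(0.8, 0.2))  # abs-mean 0.3, signed mean 0
#' @export
delta_ras_bar <- function(ras_g, ras_d, min_het = 2L, asm_threshold = 0.1) {
  stopifnot(length(ras_g) == length(ras_d))
  ok <- !is.na(ras_g) & !is.na(ras_d)
  g <- ras_g[ok]
  d <- ras_d[ok]
  n <- length(g)
  if (n < min_het) {
    return(list(delta_ras_bar = NA_real_, signed_delta = NA_real_,
                n_het = n, evaluable = FALSE, asm = NA))
  }
  shifts <- d - g
  dbar <- mean(abs(shifts))
  list(delta_ras_bar = dbar, signed_delta = mean(shifts), n_het = n,
       evaluable = TRUE, asm = dbar > asm_threshold)
}

validate_intensities <- function(intensities) {
  need <- c("sample_id", "condition", "snp_id", "intensity_a", "intensity_b")
  missing <- setdiff(need, names(intensities))
  if (length(missing) > 0) stop("intensity table lacks columns: ",
                                paste(missing, collapse = ", "))
  bad <- !intensities$condition %in% c("G", "D", "U")
  if (any(bad)) stop("condition must be one of G, D, U")
  if (any(!is.finite(intensities$intensity_a)) ||
      any(!is.finite(intensities$intensity_b)) ||
      any(intensities$intensity_a < 0) || any(intensities$intensity_b < 0)) {
    stop("intensities must be finite and non-negative")
  }
  invisible(intensities)
}

validate_genotypes <- function(genotypes) {
  need <- c("sample_id", "snp_id", "call")
  missing <- setdiff(need, names(genotypes))
  if (length(missing) > 0) stop("genotype table lacks columns: ",
                                paste(missing, collapse = ", "))
  bad <- !genotypes$call %in% c("AA", "AB", "BB", "NoCall")
  if (any(bad)) stop("genotype calls must be AA, AB, BB or NoCall")
  if (anyDuplicated(genotypes[, c("sample_id", "snp_id")])) {
    stop("one genotype call per (sample, snp) is required")
  }
  invisible(genotypes)
}

#' Per-heterozygote RAS values across conditions
#'
#' Joins the G, D and U records of each heterozygous individual per probe and
#' computes RAS in each condition. Only G-array heterozygotes (call `AB`) are
#' returned; U is carried along for cut-site-artifact QC, not for pairing.
#'
#' @param intensities Long intensity table (`sample_id`, `condition`, `snp_id`,
#'   `intensity_a`, `intensity_b`).
#' @param genotypes Genotype calls (`sample_id`, `snp_id`, `call`), from the G
#'   arrays.
#' @return data.frame `snp_id`, `sample_id`, `ras_g`, `ras_d`, `ras_u`.
#' @export
het_ras_pairs <- function(intensities, genotypes) {
  validate_intensities(intensities)
  validate_genotypes(genotypes)
  het <- genotypes[genotypes$call == "AB", c("sample_id", "snp_id")]
  one_cond <- function(cond, name) {
    x <- intensities[intensities$condition == cond, ]
    x[[name]] <- compute_ras(x$intensity_a, x$intensity_b)
    x[, c("sample_id", "snp_id", name)]
  }
  out <- merge(het, one_cond("G", "ras_g"), by = c("sample_id", "snp_id"))
  out <- merge(out, one_cond("D", "ras_d"), by = c("sample_id", "snp_id"),
               all.x = TRUE)
  out <- merge(out, one_cond("U", "ras_u"), by = c("sample_id", "snp_id"),
               all.x = TRUE)
  out <- out[order(out$snp_id, out$sample_id),
             c("snp_id", "sample_id", "ras_g", "ras_d", "ras_u")]
  rownames(out) <- NULL
  out
}

#' Per-probe ASM statistics from raw MSNP intensities
#'
#' The core per-probe computation: condition-mean intensities over all samples,
#' exclusion ratios and the exclusion decision, and the heterozygote-paired
#' RAS statistics (`delta_ras_bar`, signed mean shift).
#'
#' @param intensities Long intensity table covering conditions G, D and U.
#' @param genotypes Genotype calls from the G arrays.
#' @param min_het Minimum valid heterozygote pairs for evaluability (default 2).
#' @param asm_threshold `delta_ras_bar` detection threshold (default 0.1).
#' @param exclusion_threshold Ratio threshold for the exclusion criteria
#'   (default 1.2).
#' @return data.frame with one row per probe: condition means, `ratio_g_u`,
#'   `ratio_d_u`, `excluded_by`, `n_het`, `delta_ras_bar`, `signed_delta`,
#'   `evaluable`, `asm`.
#' @export
probe_asm_stats <- function(intensities, genotypes, min_het = 2L,
                            asm_threshold = 0.1, exclusion_threshold = 1.2) {
  validate_intensities(intensities)
  validate_genotypes(genotypes)

  means <- stats::aggregate(
    cbind(mean_a = intensity_a, mean_b = intensity_b) ~ snp_id + condition,
    data = intensities, FUN = mean)
  wide <- stats::reshape(means, idvar = "snp_id", timevar = "condition",
                         direction = "wide", sep = "_")
  names(wide) <- tolower(names(wide))
  for (col in c("mean_a_g", "mean_b_g", "mean_a_d", "mean_b_d",
                "mean_a_u", "mean_b_u")) {
    if (is.null(wide[[col]])) wide[[col]] <- NA_real_
  }
  dist <- function(a, b) sqrt(a^2 + b^2)
  du <- dist(wide$mean_a_u, wide$mean_b_u)
  wide$ratio_g_u <- ifelse(is.na(du) | du == 0, NA_real_,
                           dist(wide$mean_a_g, wide$mean_b_g) / du)
  wide$ratio_d_u <- ifelse(is.na(du) | du == 0, NA_real_,
                           dist(wide$mean_a_d, wide$mean_b_d) / du)
  wide$excluded_by <- apply_exclusion_criteria(wide$ratio_g_u, wide$ratio_d_u,
                                               exclusion_threshold)

  pairs <- het_ras_pairs(intensities, genotypes)
  stat_list <- lapply(split(pairs, pairs$snp_id), function(p) {
    s <- delta_ras_bar(p$ras_g, p$ras_d, min_het = min_het,
                       asm_threshold = asm_threshold)
    data.frame(snp_id = p$snp_id[1], n_het = s$n_het,
               delta_ras_bar = s$delta_ras_bar, signed_delta = s$signed_delta,
               evaluable = s$evaluable, asm = s$asm, stringsAsFactors = FALSE)
  })
  if (length(stat_list) > 0) {
    ras_stats <- do.call(rbind, stat_list)
  } else {
    ras_stats <- data.frame(snp_id = character(), n_het = integer(),
                            delta_ras_bar = numeric(), signed_delta = numeric(),
                            evaluable = logical(), asm = logical())
  }
  out <- merge(wide, ras_stats, by = "snp_id", all.x = TRUE)
  out$n_het[is.na(out$n_het)] <- 0L
  out$evaluable[is.na(out$evaluable)] <- FALSE
  out <- out[order(out$snp_id), ]
  rownames(out) <- NULL
  out
}
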