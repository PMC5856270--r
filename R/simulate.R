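#' Simulation configuration for a synthetic MSNP panel
#'
#' Defines the generative model for array intensity triples (G/D/U) with
#' planted allele-specific methylation. Probe classes:
#' \describe{
#'   \item{cis_asm}{one allele methylated at `methylation_high`, the other at
#'     `methylation_low`, the methylated allele fixed by genotype.}
#'   \item{imprinted}{one of the two chromosome copies methylated at
#'     `methylation_high` per individual, chosen at random (parental origin),
#'     independent of genotype.}
#'   \item{null}{both alleles methylated at `null_methylation`: in the analysis
#'     population, survives digestion, no allele contrast.}
#'   \item{unmethylated}{both alleles unmethylated: fully cut in D, excluded by
#'     criterion 2.}
#'   \item{no_site}{no MSRE site on either allele: digestion changes nothing,
#'     excluded by criterion 1.}
#' }
#'
#' The intensity model is multiplicative log-normal noise with an additive
#' background: most array noise is probe-level hybridisation scale shared by
#' the two allele channels (`noise_cv`, per sample/probe/condition), with a
#' smaller independent per-channel residual (`allele_noise_cv`); this is what
#' keeps relative-allele-score clusters tight on real genotyping arrays while
#' absolute intensities vary substantially. Digestion acts independently per
#' site: a copy with methylation `m` survives one site with probability
#' `m + (1 - m) * residual_uncut`, and survival multiplies across sites. The U
#' condition uses `m = 0` at every site and an independent DNA source, modelled
#' as a small per-probe multiplicative offset (`u_baseline_log_sd`).
#'
#' @param n_probes,n_samples Panel dimensions (defaults 1000 probes, 15
#'   individuals).
#' @param het_freq Per-probe heterozygote frequency (default 0.42).
#' @param asm_fraction,imprint_fraction,unmethylated_fraction,no_site_fraction
#'   Probe class fractions; the remainder is `null`.
#' @param methylation_high,methylation_low Per-allele CpG methylation under
#'   planted ASM (defaults 0.9 / 0.1).
#' @param null_methylation Methylation of both alleles for `null` probes
#'   (default 0.5).
#' @param residual_uncut Fraction of templates escaping digestion at an
#'   unmethylated site (default 0.05).
#' @param baseline_log_mean,baseline_log_sd Per-probe baseline intensity scale
#'   (log units).
#' @param u_baseline_log_sd Log-sd of the U-source baseline offset (default
#'   0.02).
#' @param noise_cv Shared multiplicative noise CV per sample/probe/condition
#'   (default 0.2).
#' @param allele_noise_cv Per-channel residual noise CV (default 0.05).
#' @param background Additive background intensity (default 50).
#' @param flank_len Flank length on each side of the variant (default 35 bp).
#' @param n_loci Number of susceptibility loci on the synthetic chromosome.
#' @param in_window_frac Fraction of ASM-class probes placed inside locus
#'   windows (default 0.5).
#' @param window_bp Locus window used for placement (default 100000).
#' @param seed Integer seed.
#' @return A list of class `msnp_sim_config`.
#' @export
sim_config <- function(n_probes = 1000L, n_samples = 15L, het_freq = 0.42,
                       asm_fraction = 0.05, imprint_fraction = 0.05,
                       unmethylated_fraction = 0.2, no_site_fraction = 0.2,
                       methylation_high = 0.9, methylation_low = 0.1,
                       null_methylation = 0.5, residual_uncut = 0.05,
                       baseline_log_mean = log(2000), baseline_log_sd = 0.5,
                       u_baseline_log_sd = 0.02, noise_cv = 0.2,
                       allele_noise_cv = 0.05, background = 50,
                       flank_len = 35L, n_loci = 5L, in_window_frac = 0.5,
                       window_bp = 100000, seed = 1L) {
  cfg <- list(n_probes = as.integer(n_probes), n_samples = as.integer(n_samples),
              het_freq = het_freq, asm_fraction = asm_fraction,
              imprint_fraction = imprint_fraction,
              unmethylated_fraction = unmethylated_fraction,
              no_site_fraction = no_site_fraction,
              methylation_high = methylation_high,
              methylation_low = methylation_low,
              null_methylation = null_methylation,
              residual_uncut = residual_uncut,
              baseline_log_mean = baseline_log_mean,
              baseline_log_sd = baseline_log_sd,
              u_baseline_log_sd = u_baseline_log_sd,
              noise_cv = noise_cv, allele_noise_cv = allele_noise_cv,
              background = background, flank_len = as.integer(flank_len),
              n_loci = as.integer(n_loci), in_window_frac = in_window_frac,
              window_bp = window_bp, seed = as.integer(seed))
  probs <- c(cfg$asm_fraction, cfg$imprint_fraction, cfg$unmethylated_fraction,
             cfg$no_site_fraction, cfg$het_freq, cfg$in_window_frac,
             cfg$methylation_high, cfg$methylation_low, cfg$null_methylation,
             cfg$residual_uncut)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  frac_sum <- cfg$asm_fraction + cfg$imprint_fraction +
    cfg$unmethylated_fraction + cfg$no_site_fraction
  if (frac_sum > 1) stop("probe class fractions sum to more than 1")
  if (cfg$methylation_high <= cfg$methylation_low) {
    stop("methylation_high must exceed methylation_low for planted ASM")
  }
  stopifnot(cfg$n_probes >= 1, cfg$n_samples >= 1, cfg$noise_cv >= 0,
            cfg$allele_noise_cv >= 0, cfg$background >= 0, cfg$n_loci >= 1)
  structure(cfg, class = "msnp_sim_config")
}

# Flank with exactly k MSRE sites per allele: an A/T backbone (which cannot
# form any recognition site, all of which need >= 3 C/G bases) with k CCGG
# sites inserted upstream of the variant. A single variant base in an A/T
# context cannot create a site either, so both alleles carry exactly k sites.
build_flank <- function(k, flank_len) {
  len <- 2L * flank_len + 1L
  chars <- sample(c("A", "T"), len, replace = TRUE)
  if (k > 0) {
    starts <- 1L + 6L * (seq_len(k) - 1L)
    stopifnot(max(starts) + 3L < flank_len)  # sites stay clear of the variant
    for (s in starts) chars[s:(s + 3L)] <- c("C", "C", "G", "G")
  }
  paste(chars, collapse = "")
}

#' Simulate a synthetic probe panel with susceptibility loci and truth table
#'
#' Draws probe classes, per-allele MSRE site counts, flanking sequences
#' consistent with those counts, genomic positions (a configurable fraction of
#' ASM-class probes inside locus windows), and a small susceptibility-locus
#' table. Deterministic under the config seed.
#'
#' @param config A [sim_config()].
#' @return List `probes` (annotation with site counts), `loci`, `truth`
#'   (`snp_id`, `class`, `methylated_allele`, `sites_a`, `sites_b`,
#'   `in_window`).
#' @export
simulate_panel <- function(config = sim_config()) {
  stopifnot(inherits(config, "msnp_sim_config"))
  set.seed(config$seed)
  n <- config$n_probes
  chrom <- "1"
  genome_len <- 250e6

  # loci evenly spaced, 50 kb genes, tag-SNP at the gene centre
  centers <- round(genome_len * seq_len(config$n_loci) /
                     (config$n_loci + 1))
  loci <- data.frame(
    locus_id = sprintf("locus%02d", seq_len(config$n_loci)),
    tag_snp = sprintf("rs_tag%02d", seq_len(config$n_loci)),
    chrom = chrom,
    gene_name = sprintf("GENE%02d", seq_len(config$n_loci)),
    gene_start = centers - 25000,
    gene_end = centers + 25000,
    stringsAsFactors = FALSE
  )

  classes <- sample(c("cis_asm", "imprinted", "unmethylated", "no_site", "null"),
                    n, replace = TRUE,
                    prob = c(config$asm_fraction, config$imprint_fraction,
                             config$unmethylated_fraction,
                             config$no_site_fraction,
                             1 - config$asm_fraction - config$imprint_fraction -
                               config$unmethylated_fraction -
                               config$no_site_fraction))
  k <- ifelse(classes == "no_site", 0L,
              sample(1:3, n, replace = TRUE, prob = c(0.5, 0.3, 0.2)))

  win_lo <- loci$gene_start - config$window_bp
  win_hi <- loci$gene_end + config$window_bp
  inside_any <- function(p) any(p >= win_lo & p <= win_hi)
  draw_pos <- function(inside) {
    if (inside) {
      i <- sample.int(nrow(loci), 1L)
      round(stats::runif(1, win_lo[i], win_hi[i]))
    } else {
      repeat {
        p <- round(stats::runif(1, 1, genome_len))
        if (!inside_any(p)) return(p)
      }
    }
  }
  is_asm_class <- classes %in% c("cis_asm", "imprinted")
  place_inside <- is_asm_class & stats::runif(n) < config$in_window_frac
  pos <- vapply(place_inside, draw_pos, numeric(1))

  allele_pairs <- t(vapply(seq_len(n), function(i) {
    sample(c("A", "C", "G", "T"), 2L)
  }, character(2)))
  flanks <- vapply(k, build_flank, character(1), flank_len = config$flank_len)

  probes <- data.frame(
    snp_id = sprintf("snp%04d", seq_len(n)),
    chrom = chrom,
    pos = as.integer(pos),
    allele_a = allele_pairs[, 1],
    allele_b = allele_pairs[, 2],
    flank = flanks,
    variant_index = config$flank_len + 1L,
    msre_sites_a = as.integer(k),
    msre_sites_b = as.integer(k),
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    snp_id = probes$snp_id,
    class = classes,
    methylated_allele = ifelse(classes == "cis_asm",
                               sample(c("A", "B"), n, replace = TRUE),
                               ifelse(classes == "imprinted", "parental",
                                      "none")),
    sites_a = as.integer(k),
    sites_b = as.integer(k),
    in_window = vapply(pos, inside_any, logical(1)),
    stringsAsFactors = FALSE
  )
  list(probes = probes, loci = loci, truth = truth)
}

#' Simulate genotype calls for a probe panel
#'
#' Each sample is heterozygous at each probe with probability `het_freq`,
#' otherwise homozygous AA or BB with equal probability.
#'
#' @param probes Probe annotation (only `snp_id` is used).
#' @param n_samples Number of individuals.
#' @param het_freq Heterozygote frequency.
#' @param seed Integer seed.
#' @return Genotype call table (`sample_id`, `snp_id`, `call`).
#' @export
simulate_genotypes <- function(probes, n_samples = 15L, het_freq = 0.42,
                               seed = 1L) {
  set.seed(seed)
  samples <- sprintf("S%02d", seq_len(n_samples))
  grid <- expand.grid(sample_id = samples, snp_id = probes$snp_id,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  u <- stats::runif(nrow(grid))
  grid$call <- ifelse(u < het_freq, "AB",
                      ifelse(u < het_freq + (1 - het_freq) / 2, "AA", "BB"))
  grid
}

# per-site survival of one template copy with methylation m
site_survival <- function(m, k, residual_uncut) {
  (m + (1 - m) * residual_uncut)^k
}

#' Simulate two-channel intensities for the G, D and U array conditions
#'
#' Implements the generative intensity model described in [sim_config()]. For
#' each probe, sample and condition, the A and B channel signals are the sum
#' over chromosome copies of that allele of the per-copy digestion survival,
#' scaled by the probe baseline and multiplicative noise, plus additive
#' background. In the G condition survival is 1 (no digestion); in U every
#' copy is unmethylated.
#'
#' @param probes Probe annotation.
#' @param truth Truth table from [simulate_panel()].
#' @param genotypes Genotype calls from [simulate_genotypes()].
#' @param config A [sim_config()].
#' @param seed Integer seed (default derived from the config seed).
#' @return Long intensity table (`sample_id`, `condition`, `snp_id`,
#'   `intensity_a`, `intensity_b`).
#' @export
simulate_intensities <- function(probes, truth, genotypes,
                                 config = sim_config(),
                                 seed = config$seed + 2L) {
  stopifnot(inherits(config, "msnp_sim_config"))
  set.seed(seed)
  n <- nrow(probes)
  tr <- truth[match(probes$snp_id, truth$snp_id), ]

  # per-probe baselines
  i0 <- exp(stats::rnorm(n, config$baseline_log_mean, config$baseline_log_sd))
  i0_u <- i0 * exp(stats::rnorm(n, 0, config$u_baseline_log_sd))

  g <- genotypes
  idx <- match(g$snp_id, probes$snp_id)
  copies_a <- (g$call == "AA") * 2L + (g$call == "AB") * 1L
  copies_b <- (g$call == "BB") * 2L + (g$call == "AB") * 1L
  k <- tr$sites_a[idx]
  m_high <- config$methylation_high
  m_low <- config$methylation_low
  s_high <- site_survival(m_high, k, config$residual_uncut)
  s_low <- site_survival(m_low, k, config$residual_uncut)
  s_null <- site_survival(config$null_methylation, k, config$residual_uncut)
  s_zero <- site_survival(0, k, config$residual_uncut)

  cls <- tr$class[idx]
  meth_allele <- tr$methylated_allele[idx]
  # per-copy survival in D, summed over the copies of each allele
  surv_of <- function(m_copy) ifelse(m_copy, s_high, s_low)
  imprint_pick <- stats::runif(nrow(g)) < 0.5  # which copy is parental-methylated
  d_surv_a <- numeric(nrow(g))
  d_surv_b <- numeric(nrow(g))
  for (class_name in unique(cls)) {
    sel <- cls == class_name
    if (class_name == "cis_asm") {
      sa <- ifelse(meth_allele[sel] == "A", s_high[sel], s_low[sel])
      sb <- ifelse(meth_allele[sel] == "B", s_high[sel], s_low[sel])
      d_surv_a[sel] <- copies_a[sel] * sa
      d_surv_b[sel] <- copies_b[sel] * sb
    } else if (class_name == "imprinted") {
      het <- g$call[sel] == "AB"
      # het: the random parental copy is one allele or the other;
      # hom: one of the two same-allele copies is methylated
      pa <- imprint_pick[sel]
      d_surv_a[sel] <- ifelse(het, ifelse(pa, s_high[sel], s_low[sel]),
                              ifelse(copies_a[sel] == 2L,
                                     s_high[sel] + s_low[sel], 0))
      d_surv_b[sel] <- ifelse(het, ifelse(pa, s_low[sel], s_high[sel]),
                              ifelse(copies_b[sel] == 2L,
                                     s_high[sel] + s_low[sel], 0))
    } else if (class_name == "null") {
      d_surv_a[sel] <- copies_a[sel] * s_null[sel]
      d_surv_b[sel] <- copies_b[sel] * s_null[sel]
    } else {  # unmethylated, no_site (s_zero is 1 when k = 0)
      d_surv_a[sel] <- copies_a[sel] * s_zero[sel]
      d_surv_b[sel] <- copies_b[sel] * s_zero[sel]
    }
  }

  sdlog <- sqrt(log(1 + config$noise_cv^2))
  sdlog_a <- sqrt(log(1 + config$allele_noise_cv^2))
  noise_shared <- function() {
    exp(stats::rnorm(nrow(g), -sdlog^2 / 2, sdlog))
  }
  noise_channel <- function() {
    exp(stats::rnorm(nrow(g), -sdlog_a^2 / 2, sdlog_a))
  }
  bg <- function() {
    if (config$background == 0) return(0)
    config$background * exp(stats::rnorm(nrow(g), -sdlog^2 / 2, sdlog))
  }
  one_condition <- function(cond, base, surv_a, surv_b) {
    sh <- noise_shared()
    data.frame(sample_id = g$sample_id, condition = cond, snp_id = g$snp_id,
               intensity_a = base * sh * noise_channel() * surv_a + bg(),
               intensity_b = base * sh * noise_channel() * surv_b + bg(),
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    one_condition("G", i0[idx], copies_a, copies_b),
    one_condition("D", i0[idx], d_surv_a, d_surv_b),
    one_condition("U", i0_u[idx], copies_a * s_zero, copies_b * s_zero)
  )
  rownames(out) <- NULL
  out
}

#' Simulate an allele-specific pyrosequencing table
#'
#' Per-sample, per-allele, per-CpG methylation percentages: planted allele mean
#' plus Gaussian noise, truncated to \[0, 100\]. Heterozygotes contribute both
#' alleles; homozygotes contribute only their own.
#'
#' @param mean_1,mean_2 Planted per-allele methylation means (percent) for
#'   `alleles[1]` and `alleles[2]`.
#' @param n_het Heterozygous samples (default 4).
#' @param n_hom_1,n_hom_2 Homozygous samples per allele (defaults 1 and 3).
#' @param n_cpg CpGs per assay (default 2).
#' @param noise_sd Gaussian noise SD in percentage points (default 8).
#' @param alleles Allele labels (default C/T).
#' @param seed Integer seed.
#' @return Long-format pyrosequencing table.
#' @export
simulate_pyro <- function(mean_1 = 80, mean_2 = 65, n_het = 4L, n_hom_1 = 1L,
                          n_hom_2 = 3L, n_cpg = 2L, noise_sd = 8,
                          alleles = c("C", "T"), seed = 1L) {
  stopifnot(n_het >= 2L, noise_sd >= 0)
  set.seed(seed)
  geno <- c(rep(paste0(alleles[1], alleles[2]), n_het),
            rep(paste0(alleles[1], alleles[1]), n_hom_1),
            rep(paste0(alleles[2], alleles[2]), n_hom_2))
  sample_id <- sprintf("P%02d", seq_along(geno))
  rows <- list()
  for (i in seq_along(geno)) {
    present <- unique(strsplit(geno[i], "")[[1]])
    for (al in present) {
      mu <- if (al == alleles[1]) mean_1 else mean_2
      for (cpg in seq_len(n_cpg)) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sample_id[i], genotype = geno[i], allele = al,
          cpg_index = cpg,
          methylation_pct = min(100, max(0, mu + stats::rnorm(1, 0, noise_sd))),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a dosage-linear expression panel
#'
#' `fpkm = intercept + slope * dosage + N(0, noise_sd)`, floored at zero.
#'
#' @param dosages data.frame `sample_id`, `dosage`.
#' @param slope,intercept Linear model parameters (FPKM per allele copy,
#'   baseline FPKM).
#' @param noise_sd Gaussian noise SD (default 20).
#' @param gene_name Gene label.
#' @param seed Integer seed.
#' @return Long expression table (`gene_name`, `sample_id`, `fpkm`).
#' @export
simulate_expression <- function(dosages, slope = 38.28, intercept = 43.91,
                                noise_sd = 20, gene_name = "GENE1",
                                seed = 1L) {
  stopifnot(all(c("sample_id", "dosage") %in% names(dosages)),
            length(unique(dosages$dosage)) >= 2)
  set.seed(seed)
  fpkm <- pmax(0, intercept + slope * dosages$dosage +
                 stats::rnorm(nrow(dosages), 0, noise_sd))
  data.frame(gene_name = gene_name, sample_id = dosages$sample_id,
             fpkm = fpkm, stringsAsFactors = FALSE)
}

#' Simulate a full MSNP dataset
#'
#' Convenience wrapper: panel, genotypes and intensities from one config, with
#' sub-seeds derived from the config seed.
#'
#' @param config A [sim_config()].
#' @return List `probes`, `loci`, `truth`, `genotypes`, `intensities`.
#' @export
simulate_msnp_dataset <- function(config = sim_config()) {
  panel <- simulate_panel(config)
  genotypes <- simulate_genotypes(panel$probes, config$n_samples,
                                  config$het_freq, seed = config$seed + 1L)
  intensities <- simulate_intensities(panel$probes, panel$truth, genotypes,
                                      config, seed = config$seed + 2L)
  c(panel, list(genotypes = genotypes, intensities = intensities))
}
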