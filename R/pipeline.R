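#' Pipeline configuration
#'
#' Thresholds and windows for the end-to-end ASM analysis. Defaults are the
#' published analysis constants: `delta_ras_threshold` 0.1,
#' `exclusion_threshold` 1.2, a 100 kbp candidate window and a 500 kbp
#' expression window.
#'
#' @param delta_ras_threshold ASM detection threshold on `delta_ras_bar`.
#' @param exclusion_threshold Distance-ratio threshold of the exclusion
#'   criteria.
#' @param window_bp Candidate proximity window around susceptibility genes.
#' @param expr_window_bp Expression-association window around the SNP.
#' @param min_het Minimum heterozygote pairs for a probe to be evaluable.
#' @param min_het_candidate Minimum heterozygotes for a reported candidate.
#' @param concordance_frac,min_shift Direction-classification parameters.
#' @param u_shift_max,cv_max Cluster-QC thresholds.
#' @param min_mean_fpkm Expression filter threshold.
#' @param out_dir Optional output directory for tab-separated reports.
#' @return A list of class `msnp_config`.
#' @export
pipeline_config <- function(delta_ras_threshold = 0.1,
                            exclusion_threshold = 1.2,
                            window_bp = 100000, expr_window_bp = 500000,
                            min_het = 2L, min_het_candidate = 4L,
                            concordance_frac = 0.9, min_shift = 0.05,
                            u_shift_max = 0.1, cv_max = 1.0,
                            min_mean_fpkm = 1.0, out_dir = NULL) {
  stopifnot(delta_ras_threshold > 0, exclusion_threshold > 0,
            window_bp >= 0, expr_window_bp >= 0, min_het >= 1)
  structure(list(delta_ras_threshold = delta_ras_threshold,
                 exclusion_threshold = exclusion_threshold,
                 window_bp = window_bp, expr_window_bp = expr_window_bp,
                 min_het = as.integer(min_het),
                 min_het_candidate = as.integer(min_het_candidate),
                 concordance_frac = concordance_frac, min_shift = min_shift,
                 u_shift_max = u_shift_max, cv_max = cv_max,
                 min_mean_fpkm = min_mean_fpkm, out_dir = out_dir),
            class = "msnp_config")
}

maybe_read <- function(x, reader) {
  if (is.character(x) && length(x) == 1L) reader(x) else x
}

#' Run the full ASM analysis pipeline
#'
#' Orchestrates the stages end to end: MSRE analysis-population gating,
#' per-probe RAS statistics and exclusion criteria, the candidate-selection
#' funnel around susceptibility loci, and (when the corresponding inputs are
#' supplied) the pyrosequencing validation report and the expression
#' association report. Inputs may be data.frames or paths to the tab-separated
#' dialects of the `read_*` functions. The pipeline itself is deterministic:
#' it draws no random numbers.
#'
#' @param probes Probe annotation (data.frame or path); site counts computed
#'   from flanks if absent.
#' @param intensities Long intensity table (data.frame or path).
#' @param genotypes Genotype calls (data.frame or path).
#' @param loci Susceptibility loci (data.frame or path, TSV or BED).
#' @param pyro Optional pyrosequencing table (data.frame or path).
#' @param expression Optional expression table (data.frame or path).
#' @param expr_genes Optional gene annotation for the expression stage.
#' @param expr_dosages Optional `sample_id`/`dosage` table.
#' @param expr_snp Optional list `list(chrom =, pos =)` locating the SNP for
#'   the expression window.
#' @param pyro_alleles Allele labels for the pyro comparison (default C/T).
#' @param config A [pipeline_config()].
#' @return List with `stats`, `candidates`, `report`, `funnel`, and (when
#'   inputs were given) `pyro_report`, `expression_report`. Written as
#'   tab-separated files under `config$out_dir` when set.
#' @export
run_pipeline <- function(probes, intensities, genotypes, loci,
                         pyro = NULL, expression = NULL, expr_genes = NULL,
                         expr_dosages = NULL, expr_snp = NULL,
                         pyro_alleles = c("C", "T"),
                         config = pipeline_config()) {
  stopifnot(inherits(config, "msnp_config"))
  probes <- maybe_read(probes, read_probe_annotation)
  intensities <- maybe_read(intensities, read_intensities)
  genotypes <- maybe_read(genotypes, read_genotypes)
  loci <- maybe_read(loci, read_loci)
  if (!all(c("msre_sites_a", "msre_sites_b") %in% names(probes))) {
    probes <- add_site_counts(probes)
  }

  stats <- probe_asm_stats(intensities, genotypes,
                           min_het = config$min_het,
                           asm_threshold = config$delta_ras_threshold,
                           exclusion_threshold = config$exclusion_threshold)
  cand <- extract_candidates(stats, probes, loci, intensities, genotypes,
                             asm_threshold = config$delta_ras_threshold,
                             window_bp = config$window_bp,
                             min_het = config$min_het,
                             concordance_frac = config$concordance_frac,
                             min_shift = config$min_shift,
                             u_shift_max = config$u_shift_max,
                             cv_max = config$cv_max,
                             min_het_candidate = config$min_het_candidate)
  out <- list(stats = stats, candidates = cand$candidates,
              report = cand$report, funnel = cand$funnel)

  if (!is.null(pyro)) {
    pyro <- maybe_read(pyro, read_pyro)
    out$pyro_report <- pyro_report(pyro, alleles = pyro_alleles)
  }
  if (!is.null(expression)) {
    expression <- maybe_read(expression, read_expression)
    if (is.null(expr_genes) || is.null(expr_dosages) || is.null(expr_snp)) {
      stop("expression stage needs expr_genes, expr_dosages and expr_snp")
    }
    out$expression_report <- expression_report(
      expression, expr_dosages, expr_genes,
      snp_chrom = expr_snp$chrom, snp_pos = expr_snp$pos,
      window_bp = config$expr_window_bp,
      min_mean_fpkm = config$min_mean_fpkm)
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(out$stats, file.path(config$out_dir, "probe_stats.tsv"))
    write_tsv(out$candidates, file.path(config$out_dir, "candidates.tsv"))
    write_tsv(out$report, file.path(config$out_dir, "candidate_report.tsv"))
    write_tsv(data.frame(stage = names(out$funnel),
                         n = as.integer(out$funnel)),
              file.path(config$out_dir, "funnel_counts.tsv"))
    if (!is.null(out$pyro_report)) {
      write_tsv(out$pyro_report, file.path(config$out_dir, "pyro_report.tsv"))
    }
    if (!is.null(out$expression_report)) {
      write_tsv(out$expression_report,
                file.path(config$out_dir, "expression_report.tsv"))
    }
  }
  out
}
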