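validate_genes <- function(genes) {
  need <- c("gene_name", "chrom", "gene_start", "gene_end")
  missing <- setdiff(need, names(genes))
  if (length(missing) > 0) stop("gene table lacks columns: ",
                                paste(missing, collapse = ", "))
  invisible(genes)
}

#' Genes within a window around a SNP
#'
#' Returns the genes whose `[gene_start, gene_end]` interval intersects the
#' closed window `[pos - window_bp, pos + window_bp]` on the same chromosome
#' (intersection rule: a gene spanning the window edge is included).
#'
#' @param genes Gene annotation (`gene_name`, `chrom`, `gene_start`,
#'   `gene_end`), 1-based inclusive coordinates.
#' @param chrom,pos SNP chromosome and position.
#' @param window_bp Window half-width in bp (default 500000).
#' @return Character vector of gene names.
#' @export
genes_in_window <- function(genes, chrom, pos, window_bp = 500000) {
  validate_genes(genes)
  stopifnot(window_bp >= 0)
  lo <- pmin(genes$gene_start, genes$gene_end)
  hi <- pmax(genes$gene_start, genes$gene_end)
  hit <- genes$chrom == chrom & hi >= pos - window_bp & lo <= pos + window_bp
  genes$gene_name[hit]
}

#' Flag genes with too little expression to analyse
#'
#' Genes whose mean FPKM across samples falls below `min_mean_fpkm` are marked
#' non-analysable; their association results are reported as missing rather
#' than as a meaningless regression on near-zero counts.
#'
#' @param expression Long expression table (`gene_name`, `sample_id`, `fpkm`).
#' @param min_mean_fpkm Mean-FPKM threshold (default 1.0).
#' @return data.frame `gene_name`, `mean_fpkm`, `analyzable`.
#' @export
filter_low_expression <- function(expression, min_mean_fpkm = 1.0) {
  need <- c("gene_name", "sample_id", "fpkm")
  missing <- setdiff(need, names(expression))
  if (length(missing) > 0) stop("expression table lacks columns: ",
                                paste(missing, collapse = ", "))
  if (any(expression$fpkm < 0, na.rm = TRUE)) stop("fpkm must be non-negative")
  mean_fpkm <- tapply(expression$fpkm, expression$gene_name, mean)
  data.frame(gene_name = names(mean_fpkm),
             mean_fpkm = as.numeric(mean_fpkm),
             analyzable = as.numeric(mean_fpkm) >= min_mean_fpkm,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Simple linear regression of expression on genotype dosage
#'
#' Ordinary least squares of FPKM on the additive allele dosage (0/1/2 copies
#' of the tested allele), with the two-sided slope p-value, R-squared and
#' adjusted R-squared `1 - (1 - R2) (n - 1) / (n - 2)`. With fewer than 3
#' samples or a single genotype class the gene is reported as not analysed.
#'
#' @param fpkm Numeric vector of expression values.
#' @param dosage Numeric vector of allele dosages (same order).
#' @return List `n`, `slope`, `intercept`, `p`, `r_squared`, `adj_r_squared`,
#'   `analyzed`.
#' @export
dosage_regression <- function(fpkm, dosage) {
  stopifnot(length(fpkm) == length(dosage))
  ok <- is.finite(fpkm) & is.finite(dosage)
  fpkm <- fpkm[ok]
  dosage <- dosage[ok]
  n <- length(fpkm)
  not_analyzed <- list(n = n, slope = NA_real_, intercept = NA_real_,
                       p = NA_real_, r_squared = NA_real_,
                       adj_r_squared = NA_real_, analyzed = FALSE)
  if (n < 3 || length(unique(dosage)) < 2) return(not_analyzed)
  if (stats::var(fpkm) == 0) {
    # constant response: zero slope, no variance explained
    return(list(n = n, slope = 0, intercept = fpkm[1], p = 1, r_squared = 0,
                adj_r_squared = 1 - (n - 1) / (n - 2), analyzed = TRUE))
  }
  fit <- stats::lm(fpkm ~ dosage)
  # summary.lm warns on exact fits; they are legitimate here (noise-free data)
  sm <- suppressWarnings(summary(fit))
  r2 <- sm$r.squared
  p <- sm$coefficients["dosage", "Pr(>|t|)"]
  list(n = n,
       slope = unname(stats::coef(fit)["dosage"]),
       intercept = unname(stats::coef(fit)["(Intercept)"]),
       p = p,
       r_squared = r2,
       adj_r_squared = 1 - (1 - r2) * (n - 1) / (n - 2),
       analyzed = TRUE)
}

#' Genotype-dosage association of genes near a SNP
#'
#' For every gene within `window_bp` of the SNP: per-genotype-group mean FPKM
#' and, for genes passing the expression filter, the simple linear regression
#' of FPKM on allele dosage.
#'
#' @param expression Long expression table (`gene_name`, `sample_id`, `fpkm`).
#' @param dosages data.frame `sample_id`, `dosage` (0/1/2 copies of the tested
#'   allele).
#' @param genes Gene annotation (`gene_name`, `chrom`, `gene_start`,
#'   `gene_end`).
#' @param snp_chrom,snp_pos SNP location.
#' @param window_bp Window half-width (default 500000).
#' @param min_mean_fpkm Expression filter threshold (default 1.0).
#' @return data.frame with one row per gene in the window: group means
#'   (`mean_fpkm_0/1/2` by dosage), `mean_fpkm`, `analyzed`, `n`, `slope`,
#'   `p`, `r_squared`, `adj_r_squared`.
#' @export
expression_report <- function(expression, dosages, genes, snp_chrom, snp_pos,
                              window_bp = 500000, min_mean_fpkm = 1.0) {
  validate_genes(genes)
  stopifnot(all(c("sample_id", "dosage") %in% names(dosages)))
  sel <- genes_in_window(genes, snp_chrom, snp_pos, window_bp)
  expr <- merge(expression[expression$gene_name %in% sel, ], dosages,
                by = "sample_id")
  filt <- filter_low_expression(expr, min_mean_fpkm)
  rows <- lapply(sel, function(g) {
    e <- expr[expr$gene_name == g, ]
    gm <- tapply(e$fpkm, e$dosage, mean)
    means <- stats::setNames(rep(NA_real_, 3), c("0", "1", "2"))
    means[names(gm)] <- gm
    analyzable <- filt$analyzable[filt$gene_name == g]
    if (length(analyzable) == 1 && analyzable) {
      reg <- dosage_regression(e$fpkm, e$dosage)
    } else {
      reg <- list(n = nrow(e), slope = NA_real_, p = NA_real_,
                  r_squared = NA_real_, adj_r_squared = NA_real_,
                  analyzed = FALSE)
    }
    data.frame(gene_name = g,
               mean_fpkm_0 = unname(means["0"]),
               mean_fpkm_1 = unname(means["1"]),
               mean_fpkm_2 = unname(means["2"]),
               mean_fpkm = mean(e$fpkm),
               analyzed = reg$analyzed, n = reg$n, slope = reg$slope,
               p = reg$p, r_squared = reg$r_squared,
               adj_r_squared = reg$adj_r_squared,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Expand per-genotype group means into a per-sample expression panel
#'
#' Turns a table of per-genotype-group mean FPKM values (the form in which
#' published results are often reported) into a per-sample long expression
#' table plus a matching dosage table, assigning each sample its group mean.
#' Useful for demonstration runs of the association stage when only group
#' summaries are available; it is a synthetic expansion, not the original
#' per-sample data.
#'
#' @param group_means data.frame with `gene_name` and columns `fpkm_0`,
#'   `fpkm_1`, `fpkm_2` (mean FPKM by dosage group).
#' @param n_per_group Integer vector: samples per dosage group `c(0, 1, 2)`.
#' @return List `expression` (long table) and `dosages`.
#' @export
expand_group_means <- function(group_means, n_per_group = c(6L, 4L, 1L)) {
  stopifnot(all(c("gene_name", "fpkm_0", "fpkm_1", "fpkm_2") %in%
                  names(group_means)), length(n_per_group) == 3)
  dosage <- rep(0:2, times = n_per_group)
  sample_id <- sprintf("S%02d", seq_along(dosage))
  expr <- do.call(rbind, lapply(seq_len(nrow(group_means)), function(i) {
    data.frame(gene_name = group_means$gene_name[i],
               sample_id = sample_id,
               fpkm = c(group_means$fpkm_0[i], group_means$fpkm_1[i],
                        group_means$fpkm_2[i])[dosage + 1L],
               stringsAsFactors = FALSE)
  }))
  list(expression = expr,
       dosages = data.frame(sample_id = sample_id, dosage = dosage,
                            stringsAsFactors = FALSE))
}
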