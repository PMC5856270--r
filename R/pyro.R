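validate_pyro <- function(pyro) {
  need <- c("sample_id", "genotype", "allele", "cpg_index", "methylation_pct")
  missing <- setdiff(need, names(pyro))
  if (length(missing) > 0) stop("pyrosequencing table lacks columns: ",
                                paste(missing, collapse = ", "))
  if (any(pyro$methylation_pct < 0 | pyro$methylation_pct > 100, na.rm = TRUE)) {
    stop("methylation_pct must lie in [0, 100]")
  }
  invisible(pyro)
}

is_het_genotype <- function(genotype) {
  substr(genotype, 1, 1) != substr(genotype, 2, 2)
}

#' Per-allele methylation summary from pyrosequencing data
#'
#' Means and sample standard deviations (n - 1 denominator) of the per-allele
#' methylation percentages at one CpG, either over heterozygous samples only
#' (each contributing both alleles) or over all samples (homozygotes
#' contributing their single allele).
#'
#' @param pyro Long-format pyrosequencing table (`sample_id`, `genotype`,
#'   `allele`, `cpg_index`, `methylation_pct`).
#' @param cpg_index Which CpG to summarise.
#' @param population `"het_only"` or `"all"`.
#' @return data.frame with one row per allele: `allele`, `n`, `mean`, `sd`.
#' @export
per_allele_summary <- function(pyro, cpg_index,
                               population = c("het_only", "all")) {
  validate_pyro(pyro)
  population <- match.arg(population)
  x <- pyro[pyro$cpg_index == cpg_index & !is.na(pyro$methylation_pct), ]
  if (population == "het_only") x <- x[is_het_genotype(x$genotype), ]
  if (nrow(x) == 0) stop("no measurements for cpg_index ", cpg_index)
  groups <- split(x$methylation_pct, x$allele)
  if (any(lengths(groups) == 0)) stop("empty allele group")
  out <- data.frame(
    allele = names(groups),
    n = lengths(groups),
    mean = vapply(groups, mean, numeric(1)),
    sd = vapply(groups, stats::sd, numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Paired t-test between alleles in heterozygotes
#'
#' Classical paired t-test on the per-sample within-individual allele
#' difference of methylation at one CpG. Pairing within the individual cancels
#' between-individual environmental variation, which is the point of comparing
#' the two alleles of the same heterozygote.
#'
#' @param pyro Long-format pyrosequencing table.
#' @param cpg_index Which CpG.
#' @param alleles Length-2 character: difference is `alleles[1] - alleles[2]`.
#' @return List `t`, `df`, `p`, `n`, `mean_diff`. If the differences have zero
#'   variance the p-value is degenerate (1 when all differences are zero, 0
#'   otherwise) and a warning is raised.
#' @export
paired_allele_test <- function(pyro, cpg_index, alleles = c("C", "T")) {
  validate_pyro(pyro)
  stopifnot(length(alleles) == 2)
  x <- pyro[pyro$cpg_index == cpg_index & is_het_genotype(pyro$genotype), ]
  a1 <- x[x$allele == alleles[1], c("sample_id", "methylation_pct")]
  a2 <- x[x$allele == alleles[2], c("sample_id", "methylation_pct")]
  m <- merge(a1, a2, by = "sample_id", suffixes = c("_1", "_2"))
  m <- m[stats::complete.cases(m), ]
  n <- nrow(m)
  if (n < 2) stop("need at least 2 heterozygous samples with both alleles")
  d <- m$methylation_pct_1 - m$methylation_pct_2
  if (stats::sd(d) == 0) {
    warning("zero variance of paired differences; p-value is degenerate")
    if (all(d == 0)) {
      return(list(t = 0, df = n - 1L, p = 1, n = n, mean_diff = 0))
    }
    return(list(t = sign(mean(d)) * Inf, df = n - 1L, p = 0, n = n,
                mean_diff = mean(d)))
  }
  tt <- stats::t.test(m$methylation_pct_1, m$methylation_pct_2, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, n = n, mean_diff = unname(tt$estimate))
}

# Exact two-sided p for the midrank rank-sum statistic, by dynamic programming
# over the subset-sum distribution of doubled midranks (doubling makes the
# midranks integral even with ties). All C(n, n1) group assignments are
# equally likely under the null; the two-sided p is the probability of a
# rank-sum at least as far from its null mean as the observed one.
rank_sum_exact_p <- function(x, y) {
  n1 <- length(x)
  n <- n1 + length(y)
  r2 <- as.integer(round(2 * rank(c(x, y))))
  w2 <- sum(r2[seq_len(n1)])
  mu2 <- n1 * (n + 1)  # doubled null mean of the rank-sum
  max_s <- sum(sort(r2, decreasing = TRUE)[seq_len(n1)])
  # dp[k + 1, s + 1] = number of size-k subsets with doubled rank-sum s
  dp <- matrix(0, nrow = n1 + 1L, ncol = max_s + 1L)
  dp[1L, 1L] <- 1
  for (r in r2) {
    kmax <- n1
    for (k in kmax:1L) {
      shifted <- c(rep(0, r), dp[k, seq_len(max_s + 1L - r)])
      dp[k + 1L, ] <- dp[k + 1L, ] + shifted
    }
  }
  counts <- dp[n1 + 1L, ]
  sums <- seq_along(counts) - 1L
  extreme <- abs(sums - mu2) >= abs(w2 - mu2) - 1e-9
  sum(counts[extreme]) / choose(n, n1)
}

#' Exact rank-sum (Mann-Whitney) comparison of two allele groups
#'
#' Compares per-allele methylation between the two allele groups pooled over
#' all samples (heterozygotes contribute both alleles, homozygotes one), where
#' the groups are unpaired and may have unequal sizes. The test is the exact
#' Wilcoxon rank-sum / Mann-Whitney test with midranks for ties: the exact null
#' distribution of the rank-sum over all group assignments is computed by
#' dynamic programming, so ties are handled exactly rather than by a normal
#' approximation. For very large groups (more than `max_exact` assignments) a
#' normal approximation with tie correction is used.
#'
#' @param pyro Long-format pyrosequencing table.
#' @param cpg_index Which CpG.
#' @param alleles Length-2 character; the rank-sum is taken over `alleles[1]`.
#' @param max_exact Maximum number of group assignments for the exact
#'   computation (default 1e7).
#' @return List `rank_sum` (W of the first group), `u` (Mann-Whitney U),
#'   `p` (two-sided), `n1`, `n2`, `exact`.
#' @export
combined_rank_test <- function(pyro, cpg_index, alleles = c("C", "T"),
                               max_exact = 1e7) {
  validate_pyro(pyro)
  x0 <- pyro[pyro$cpg_index == cpg_index & !is.na(pyro$methylation_pct), ]
  x <- x0$methylation_pct[x0$allele == alleles[1]]
  y <- x0$methylation_pct[x0$allele == alleles[2]]
  rank_sum_test(x, y, max_exact = max_exact)
}

#' @rdname combined_rank_test
#' @param x,y Numeric vectors of the two groups' values.
#' @export
rank_sum_test <- function(x, y, max_exact = 1e7) {
  if (length(x) == 0 || length(y) == 0) stop("both groups must be non-empty")
  n1 <- length(x)
  n <- n1 + length(y)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  u <- w - n1 * (n1 + 1) / 2
  if (length(unique(c(x, y))) == 1L) {
    return(list(rank_sum = w, u = u, p = 1, n1 = n1, n2 = n - n1, exact = TRUE))
  }
  if (choose(n, n1) <= max_exact) {
    p <- rank_sum_exact_p(x, y)
    exact <- TRUE
  } else {
    mu <- n1 * (n + 1) / 2
    ties <- table(r)
    sigma2 <- n1 * (n - n1) / 12 *
      ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (w - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    exact <- FALSE
  }
  list(rank_sum = w, u = u, p = min(1, p), n1 = n1, n2 = n - n1, exact = exact)
}

#' Full pyrosequencing validation report
#'
#' For each CpG index present: the heterozygote-only per-allele summary and
#' paired t-test, and the all-sample per-allele summary and exact rank-sum
#' test.
#'
#' @param pyro Long-format pyrosequencing table.
#' @param alleles Length-2 character vector of the two alleles.
#' @return data.frame with one row per CpG and the summary/test columns.
#' @export
pyro_report <- function(pyro, alleles = c("C", "T")) {
  validate_pyro(pyro)
  cpgs <- sort(unique(pyro$cpg_index))
  rows <- lapply(cpgs, function(cpg) {
    het <- per_allele_summary(pyro, cpg, "het_only")
    all <- per_allele_summary(pyro, cpg, "all")
    tt <- paired_allele_test(pyro, cpg, alleles)
    rk <- combined_rank_test(pyro, cpg, alleles)
    pick <- function(df, a, col) df[[col]][df$allele == a]
    data.frame(
      cpg_index = cpg,
      het_mean_1 = pick(het, alleles[1], "mean"),
      het_sd_1 = pick(het, alleles[1], "sd"),
      het_mean_2 = pick(het, alleles[2], "mean"),
      het_sd_2 = pick(het, alleles[2], "sd"),
      paired_t = tt$t, paired_df = tt$df, paired_p = tt$p,
      all_mean_1 = pick(all, alleles[1], "mean"),
      all_n_1 = pick(all, alleles[1], "n"),
      all_mean_2 = pick(all, alleles[2], "mean"),
      all_n_2 = pick(all, alleles[2], "n"),
      rank_sum = rk$rank_sum, rank_p = rk$p,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
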