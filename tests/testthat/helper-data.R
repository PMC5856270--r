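# Per-sample, per-allele pyrosequencing methylation percentages around a
# validated cis-ASM SNP: 4 C/T heterozygotes, 1 CC and 3 TT homozygotes,
# two CpGs per assay. Built in code so tests do not depend on the packaged
# fixture file (one test checks the fixture matches this).
table3_pyro <- function() {
  het <- data.frame(
    sample_id = rep(c("CD4", "CD5", "UC1", "UC4"), each = 4),
    genotype = "CT",
    allele = rep(c("C", "T"), times = 8),
    cpg_index = rep(rep(1:2, each = 2), times = 4),
    methylation_pct = c(77, 49, 67, 42,
                        89, 73, 86, 64,
                        77, 77, 74, 69,
                        87, 78, 82, 74),
    stringsAsFactors = FALSE
  )
  hom <- data.frame(
    sample_id = rep(c("CD7", "CD6", "CD8", "UC5"), each = 2),
    genotype = rep(c("CC", "TT", "TT", "TT"), each = 2),
    allele = rep(c("C", "T", "T", "T"), each = 2),
    cpg_index = rep(1:2, times = 4),
    methylation_pct = c(82, 76, 60, 53, 69, 66, 61, 55),
    stringsAsFactors = FALSE
  )
  rbind(het, hom)
}

# Group-mean FPKM around the same SNP (TT/CT/CC = dosage 0/1/2 of the C
# allele) with gene spans, mirroring the packaged expression fixture.
table6_group_means <- function() {
  data.frame(
    gene_name = c("SMAD6", "SMAD3", "IQCH", "C15orf61", "MAP2K5", "SKOR1"),
    chrom = "15",
    gene_start = c(66994673, 67357990, 67547137, 67547137, 67835020, 68112041),
    gene_end = c(67074338, 67487569, 67819641, 67819641, 68099455, 68126174),
    fpkm_0 = c(0.02, 43.91, 0.10, 17.97, 10.44, 0.02),
    fpkm_1 = c(0, 76.33, 0.07, 20.62, 8.42, 0.01),
    fpkm_2 = c(0, 120.47, 0, 18.43, 6.71, 0),
    stringsAsFactors = FALSE
  )
}

# Exhaustive enumeration oracle for the two-sided rank-sum p-value:
# every assignment of n1 of the pooled values to group 1 is equally likely.
rank_sum_enum_p <- function(x, y) {
  vals <- c(x, y)
  n <- length(vals)
  n1 <- length(x)
  r <- rank(vals)
  w_obs <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  combos <- utils::combn(n, n1)
  w_all <- apply(combos, 2, function(idx) sum(r[idx]))
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# Small deterministic intensity/genotype tables for hand-checkable cases.
toy_intensities <- function(snp_id = "snp1",
                            samples = c("s1", "s2"),
                            g = list(c(500, 500), c(400, 600)),
                            d = list(c(900, 100), c(800, 200)),
                            u = list(c(50, 50), c(40, 60))) {
  row <- function(s, cond, ab) {
    data.frame(sample_id = s, condition = cond, snp_id = snp_id,
               intensity_a = ab[1], intensity_b = ab[2],
               stringsAsFactors = FALSE)
  }
  do.call(rbind, c(
    mapply(row, samples, "G", g, SIMPLIFY = FALSE),
    mapply(row, samples, "D", d, SIMPLIFY = FALSE),
    mapply(row, samples, "U", u, SIMPLIFY = FALSE)
  ))
}

# Compare a computed value against a published value at its printed precision.
# (Published tables round halves up; base round() rounds half to even.)
expect_printed <- function(actual, printed, digits = 1) {
  expect_lte(abs(actual - printed), 0.5 * 10^(-digits) + 1e-9)
}
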