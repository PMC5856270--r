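test_that("heterozygote selection keeps AB calls in stable order and never NoCall", {
  geno <- data.frame(
    sample_id = sprintf("s%02d", 1:8),
    snp_id = "snp1",
    call = c("AB", "AA", "NoCall", "AB", "BB", "AB", "NoCall", "AA"),
    stringsAsFactors = FALSE
  )
  expect_equal(select_heterozygotes(geno, "snp1"), c("s01", "s04", "s06"))
  geno$call <- "AA"
  expect_equal(select_heterozygotes(geno, "snp1"), character(0))
})

test_that("direction classification separates cis (one direction) from imprinting (both)", {
  expect_equal(classify_direction(c(0.3, 0.25, 0.28, 0.31)), "monoallelic")
  expect_equal(classify_direction(c(-0.3, -0.25, -0.28, -0.31)), "monoallelic")
  expect_equal(classify_direction(c(0.3, -0.3, 0.28, -0.25)), "biallelic")
  expect_equal(classify_direction(c(0.02, -0.01)), "indeterminate")
  expect_equal(classify_direction(0.4), "indeterminate")
  # one dissent among ten concordant shifts still reads as one direction
  expect_equal(classify_direction(c(rep(0.3, 9), -0.2)), "monoallelic")
})

test_that("direction classification is antisymmetric under negating all shifts", {
  set.seed(31)
  for (rep in 1:30) {
    shifts <- stats::runif(sample(2:10, 1), -0.4, 0.4)
    expect_equal(classify_direction(shifts), classify_direction(-shifts))
  }
})

test_that("the proximity window is closed at exactly the window boundary", {
  expect_true(within_window("1", 500000 - 100000, "1", 500000, 600000))
  expect_false(within_window("1", 500000 - 100001, "1", 500000, 600000))
  expect_true(within_window("1", 550000, "1", 500000, 600000))
  expect_true(within_window("1", 600000 + 100000, "1", 500000, 600000))
  expect_false(within_window("2", 550000, "1", 500000, 600000))
  # swapped interval bounds behave identically
  expect_true(within_window("1", 400000, "1", 600000, 500000))
  # zero-width locus gives tag-SNP windowing
  expect_true(within_window("1", 100, "1", 50000, 50000, window_bp = 100000))
})

test_that("cluster QC raises the documented flags", {
  expect_equal(cluster_qc(ras_g = rep(0.5, 5), ras_u = rep(0.52, 5),
                          g_distances = rep(1000, 10), n_het = 5),
               character(0))
  expect_equal(cluster_qc(ras_g = rep(0.5, 5), ras_u = rep(0.9, 5),
                          g_distances = rep(1000, 10), n_het = 5),
               "cut_site_artifact")
  expect_true("unstable_hybridization" %in%
                cluster_qc(rep(0.5, 5), rep(0.5, 5),
                           g_distances = c(rep(10, 9), 50000), n_het = 5))
  expect_equal(cluster_qc(rep(0.5, 1), rep(0.5, 1), rep(1000, 10), n_het = 1),
               "insufficient_heterozygotes")
})

test_that("a probe whose allele destroys all MSRE sites is flagged as a cut-site artifact", {
  # allele A keeps the site intact, allele B destroys it: the U control
  # (fully unmethylated, digested) then cuts only the A allele, shifting
  # heterozygote RAS_U towards the B channel.
  samples <- sprintf("s%d", 1:6)
  int <- do.call(rbind, lapply(samples, function(s) {
    data.frame(sample_id = s,
               condition = c("G", "D", "U"),
               snp_id = "snpX",
               intensity_a = c(1000, 1000, 60),   # A cut only in U
               intensity_b = c(1000, 1000, 1000),
               stringsAsFactors = FALSE)
  }))
  geno <- data.frame(sample_id = samples, snp_id = "snpX", call = "AB",
                     stringsAsFactors = FALSE)
  pairs <- het_ras_pairs(int, geno)
  flags <- cluster_qc(pairs$ras_g, pairs$ras_u,
                      g_distances = rep(1000, 6), n_het = 6)
  expect_true("cut_site_artifact" %in% flags)
})

test_that("candidate extraction returns exactly the planted in-window ASM probe", {
  cfg <- sim_config(n_probes = 100L, asm_fraction = 0.05,
                    imprint_fraction = 0, unmethylated_fraction = 0.2,
                    no_site_fraction = 0.2, in_window_frac = 1, seed = 77L)
  ds <- simulate_msnp_dataset(cfg)
  planted <- ds$truth$snp_id[ds$truth$class == "cis_asm"]
  # ensure the seeded panel actually planted at least one in-window ASM probe
  expect_gte(length(planted), 1)
  st <- probe_asm_stats(ds$intensities, ds$genotypes)
  res <- extract_candidates(st, ds$probes, ds$loci, ds$intensities,
                            ds$genotypes, min_het_candidate = 2L)
  expect_setequal(res$report$snp_id, planted)
  expect_true(all(res$report$direction == "monoallelic"))
  expect_true(all(res$report$matched_genes != ""))

  # the same planted probes placed far from any locus are not candidates
  cfg_out <- sim_config(n_probes = 100L, asm_fraction = 0.05,
                        imprint_fraction = 0, unmethylated_fraction = 0.2,
                        no_site_fraction = 0.2, in_window_frac = 0, seed = 77L)
  ds_out <- simulate_msnp_dataset(cfg_out)
  st_out <- probe_asm_stats(ds_out$intensities, ds_out$genotypes)
  res_out <- extract_candidates(st_out, ds_out$probes, ds_out$loci,
                                ds_out$intensities, ds_out$genotypes,
                                min_het_candidate = 2L)
  expect_equal(nrow(res_out$report), 0L)
  expect_gte(res_out$funnel[["asm_detected"]], 1)
})

test_that("a planted imprinted probe in a window is reported as biallelic", {
  cfg <- sim_config(n_probes = 100L, asm_fraction = 0,
                    imprint_fraction = 0.03, unmethylated_fraction = 0.2,
                    no_site_fraction = 0.2, in_window_frac = 1, seed = 88L)
  ds <- simulate_msnp_dataset(cfg)
  planted <- ds$truth$snp_id[ds$truth$class == "imprinted"]
  expect_gte(length(planted), 1)
  st <- probe_asm_stats(ds$intensities, ds$genotypes)
  res <- extract_candidates(st, ds$probes, ds$loci, ds$intensities,
                            ds$genotypes, min_het_candidate = 2L)
  expect_setequal(res$report$snp_id, planted)
  expect_true(all(res$report$direction %in% c("biallelic", "monoallelic")))
  expect_gte(mean(res$report$direction == "biallelic"), 0.5)
})

test_that("the selection funnel is monotone and errors on an empty locus table", {
  cfg <- sim_config(n_probes = 300L, seed = 5L)
  ds <- simulate_msnp_dataset(cfg)
  st <- probe_asm_stats(ds$intensities, ds$genotypes)
  res <- extract_candidates(st, ds$probes, ds$loci, ds$intensities,
                            ds$genotypes)
  f <- res$funnel
  expect_equal(names(f), c("total", "analysis_population", "pass_exclusion",
                           "asm_detected", "in_window", "qc_pass",
                           "monoallelic"))
  expect_true(all(diff(as.integer(f)) <= 0))
  expect_error(extract_candidates(st, ds$probes, ds$loci[0, ],
                                  ds$intensities, ds$genotypes), "empty")
})
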