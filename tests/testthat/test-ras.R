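test_that("relative allele score is A/(A+B) with zero-total records flagged NA", {
  expect_equal(compute_ras(500, 500), 0.5)
  expect_equal(compute_ras(800, 0), 1.0)
  expect_equal(compute_ras(30, 70), 0.3)
  expect_true(is.na(compute_ras(0, 0)))
  expect_error(compute_ras(-1, 5), "non-negative")
  expect_error(compute_ras(Inf, 5), "finite")
})

test_that("RAS of the two channels is complementary", {
  set.seed(3)
  a <- stats::runif(50, 0, 1000)
  b <- stats::runif(50, 0, 1000)
  expect_equal(compute_ras(a, b) + compute_ras(b, a), rep(1, 50))
})

test_that("condition means are plain arithmetic means over samples", {
  expect_equal(condition_means(c(100, 300), c(300, 100)),
               c(mean_a = 200, mean_b = 200))
  expect_equal(condition_means(50, 70), c(mean_a = 50, mean_b = 70))
  expect_equal(condition_means(c(10, 20, 30), c(0, 0, 0)),
               c(mean_a = 20, mean_b = 0))
})

test_that("exclusion ratios are Euclidean-norm ratios against the U condition", {
  expect_equal(exclusion_ratios(c(1000, 1000), c(1000, 1000), c(1000, 1000)),
               c(ratio_g_u = 1, ratio_d_u = 1))
  expect_equal(exclusion_ratios(c(1200, 0), c(600, 0), c(100, 0)),
               c(ratio_g_u = 12, ratio_d_u = 6))
  r <- exclusion_ratios(c(300, 400), c(300, 400), c(30, 40))
  expect_equal(unname(r["ratio_g_u"]), 10)
  expect_true(all(is.na(exclusion_ratios(c(1, 1), c(1, 1), c(0, 0)))))
})

test_that("the two exclusion criteria are applied in order with threshold 1.2", {
  expect_equal(apply_exclusion_criteria(1.0, 5.0), "criterion1")
  expect_equal(apply_exclusion_criteria(5.0, 1.0), "criterion2")
  expect_equal(apply_exclusion_criteria(5.0, 5.0), "keep")
  expect_equal(apply_exclusion_criteria(c(1.19, 1.2), c(2, 1.19)),
               c("criterion1", "criterion2"))
  expect_true(is.na(apply_exclusion_criteria(NA_real_, 2)))
})

test_that("delta-RAS-bar averages absolute per-heterozygote shifts", {
  r <- delta_ras_bar(c(0.5, 0.5), c(0.5, 0.5))
  expect_equal(r$delta_ras_bar, 0)
  expect_false(r$asm)

  r <- delta_ras_bar(rep(0.5, 4), rep(0.8, 4))
  expect_equal(r$delta_ras_bar, 0.3)
  expect_equal(r$signed_delta, 0.3)
  expect_equal(r$n_het, 4L)
  expect_true(r$asm)

  # imprinting-like signature: large magnitude, signed mean near zero
  r <- delta_ras_bar(c(0.5, 0.5), c(0.8, 0.2))
  expect_equal(r$delta_ras_bar, 0.3)
  expect_equal(r$signed_delta, 0)

  r <- delta_ras_bar(0.5, 0.9)  # below min_het
  expect_false(r$evaluable)
  expect_true(is.na(r$asm))

  # NA pairs are dropped record-wise
  r <- delta_ras_bar(c(0.5, NA, 0.5), c(0.7, 0.9, 0.7))
  expect_equal(r$n_het, 2L)
})

test_that("per-probe statistics match an independent brute-force recomputation", {
  set.seed(99)
  n_probes <- 15
  samples <- sprintf("s%02d", 1:6)
  snps <- sprintf("p%02d", seq_len(n_probes))
  grid <- expand.grid(sample_id = samples, condition = c("G", "D", "U"),
                      snp_id = snps, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid$intensity_a <- stats::runif(nrow(grid), 0, 2000)
  grid$intensity_b <- stats::runif(nrow(grid), 0, 2000)
  geno <- expand.grid(sample_id = samples, snp_id = snps,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  geno$call <- sample(c("AA", "AB", "BB", "NoCall"), nrow(geno),
                      replace = TRUE, prob = c(0.25, 0.45, 0.25, 0.05))

  got <- probe_asm_stats(grid, geno)

  for (snp in snps) {
    x <- grid[grid$snp_id == snp, ]
    dist <- function(cond) {
      sqrt(mean(x$intensity_a[x$condition == cond])^2 +
             mean(x$intensity_b[x$condition == cond])^2)
    }
    want_gu <- dist("G") / dist("U")
    want_du <- dist("D") / dist("U")
    row <- got[got$snp_id == snp, ]
    expect_equal(row$ratio_g_u, want_gu)
    expect_equal(row$ratio_d_u, want_du)
    want_excl <- if (want_gu < 1.2) "criterion1" else
      if (want_du < 1.2) "criterion2" else "keep"
    expect_equal(row$excluded_by, want_excl)

    hets <- geno$sample_id[geno$snp_id == snp & geno$call == "AB"]
    deltas <- c()
    for (s in hets) {
      gg <- x[x$sample_id == s & x$condition == "G", ]
      dd <- x[x$sample_id == s & x$condition == "D", ]
      rg <- gg$intensity_a / (gg$intensity_a + gg$intensity_b)
      rd <- dd$intensity_a / (dd$intensity_a + dd$intensity_b)
      deltas <- c(deltas, rd - rg)
    }
    if (length(deltas) >= 2) {
      expect_equal(row$delta_ras_bar, mean(abs(deltas)))
      expect_equal(row$signed_delta, mean(deltas))
      expect_equal(row$n_het, length(deltas))
    } else {
      expect_false(row$evaluable)
    }
  }
})

test_that("global allele relabeling flips the signed shift and preserves the magnitude", {
  set.seed(17)
  cfg <- sim_config(n_probes = 40L, seed = 23L)
  ds <- simulate_msnp_dataset(cfg)
  st <- probe_asm_stats(ds$intensities, ds$genotypes)
  flipped_int <- ds$intensities
  names(flipped_int)[match(c("intensity_a", "intensity_b"), names(flipped_int))] <-
    c("intensity_b", "intensity_a")
  flipped_gen <- ds$genotypes
  flipped_gen$call <- c(AA = "BB", AB = "AB", BB = "AA",
                        NoCall = "NoCall")[flipped_gen$call]
  st2 <- probe_asm_stats(flipped_int, flipped_gen)
  expect_equal(st2$delta_ras_bar, st$delta_ras_bar)
  expect_equal(st2$signed_delta, -st$signed_delta)
  # magnitude bounds and the triangle inequality hold throughout
  ok <- !is.na(st$delta_ras_bar)
  expect_true(all(st$delta_ras_bar[ok] >= 0 & st$delta_ras_bar[ok] <= 1))
  expect_true(all(abs(st$signed_delta[ok]) <= st$delta_ras_bar[ok] + 1e-12))
})

test_that("uninformative and fully unmethylated probes are excluded by the criteria", {
  # probes with no MSRE site: U indistinguishable from G, criterion 1 applies
  cfg <- sim_config(n_probes = 2000L, asm_fraction = 0, imprint_fraction = 0,
                    unmethylated_fraction = 0, no_site_fraction = 1, seed = 101L)
  ds <- simulate_msnp_dataset(cfg)
  st <- probe_asm_stats(ds$intensities, ds$genotypes)
  expect_gte(mean(st$excluded_by == "criterion1"), 0.99)

  # probes unmethylated on both alleles: D falls with U, criterion 2 applies
  cfg <- sim_config(n_probes = 500L, asm_fraction = 0, imprint_fraction = 0,
                    unmethylated_fraction = 1, no_site_fraction = 0, seed = 102L)
  ds <- simulate_msnp_dataset(cfg)
  st <- probe_asm_stats(ds$intensities, ds$genotypes)
  expect_gte(mean(st$excluded_by == "criterion2"), 0.95)
})
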