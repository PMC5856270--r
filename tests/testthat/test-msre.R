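# Brute-force oracle: slide a window of each recognition length over the
# sequence and compare against the recognition sequences and, for
# non-palindromic enzymes, their reverse complements.
scan_brute_force <- function(seq, enzymes = msre_enzymes()) {
  hits <- data.frame(enzyme = character(), start = integer(),
                     strand = character(), stringsAsFactors = FALSE)
  rc <- function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }
  for (i in seq_len(nrow(enzymes))) {
    rec <- enzymes$recognition[i]
    L <- nchar(rec)
    for (s in seq_len(max(0, nchar(seq) - L + 1))) {
      win <- substr(seq, s, s + L - 1)
      if (win == rec) {
        hits <- rbind(hits, data.frame(enzyme = enzymes$name[i], start = s,
                                       strand = "+"))
      }
      if (!enzymes$palindromic[i] && win == rc(rec)) {
        hits <- rbind(hits, data.frame(enzyme = enzymes$name[i], start = s,
                                       strand = "-"))
      }
    }
  }
  hits[order(hits$start, hits$enzyme, hits$strand), ]
}

test_that("MSRE site scanning finds known sites on the correct strands", {
  h <- scan_msre_sites("CCGG")
  expect_equal(h$enzyme, "HpaII")
  expect_equal(h$start, 1L)
  expect_equal(h$strand, "+")

  expect_equal(nrow(scan_msre_sites("ATATAT")), 0L)

  h <- scan_msre_sites("GCGGCC")  # reverse complement of an AciI site
  expect_equal(h$enzyme, "AciI")
  expect_equal(h$start, 1L)
  expect_equal(h$strand, "-")

  h <- scan_msre_sites("CCGCGC")
  expect_equal(h$enzyme, c("AciI", "HhaI"))
  expect_equal(h$start, c(1L, 3L))
  expect_equal(h$strand, c("+", "+"))
})

test_that("overlapping occurrences of a recognition site are all reported", {
  h <- scan_msre_sites("CCGCCGC")  # AciI sites at 1 and 4 share a base
  aci <- h[h$enzyme == "AciI" & h$strand == "+", ]
  expect_equal(aci$start, c(1L, 4L))
})

test_that("site scanning agrees with window-by-window enumeration", {
  set.seed(42)
  for (rep in 1:25) {
    seq <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE,
                        prob = c(0.2, 0.3, 0.3, 0.2)), collapse = "")
    got <- scan_msre_sites(seq)
    want <- scan_brute_force(seq)
    expect_equal(got$start, want$start, info = seq)
    expect_equal(got$enzyme, want$enzyme, info = seq)
    expect_equal(got$strand, want$strand, info = seq)
  }
})

test_that("N bases suppress site calls and invalid characters error", {
  expect_equal(nrow(scan_msre_sites("CCGN")), 0L)
  expect_equal(nrow(scan_msre_sites("NCGG")), 0L)
  expect_equal(scan_msre_sites("CCGGNACCGG")$start, c(1L, 7L))
  expect_error(scan_msre_sites("CCXG"), "non-DNA")
})

test_that("strand symmetry: AciI hits mirror between a sequence and its reverse complement", {
  set.seed(7)
  for (rep in 1:10) {
    seq <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
                 collapse = "")
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    fwd <- scan_msre_sites(seq)
    rev <- scan_msre_sites(rc)
    expect_equal(sum(fwd$enzyme == "AciI" & fwd$strand == "+"),
                 sum(rev$enzyme == "AciI" & rev$strand == "-"))
    expect_equal(sum(fwd$enzyme == "AciI" & fwd$strand == "-"),
                 sum(rev$enzyme == "AciI" & rev$strand == "+"))
  }
})

test_that("per-allele site counts gate the analysis population", {
  expect_equal(probe_site_counts("AACCGGAA", "C", "T", 4),
               c(count_a = 1L, count_b = 0L))
  expect_equal(probe_site_counts("TTTTATTTT", "A", "G", 5),
               c(count_a = 0L, count_b = 0L))
  expect_equal(probe_site_counts("CCGGACCGG", "A", "C", 5),
               c(count_a = 2L, count_b = 2L))
  expect_error(probe_site_counts("AACCGGAA", "C", "C", 4), "differ")
  expect_error(probe_site_counts("AACCGGAA", "C", "T", 99), "bounds")
})

test_that("site counts are invariant under swapping allele labels", {
  set.seed(11)
  for (rep in 1:10) {
    flank <- paste(sample(c("A", "C", "G", "T"), 21, replace = TRUE),
                   collapse = "")
    al <- sample(c("A", "C", "G", "T"), 2)
    fwd <- probe_site_counts(flank, al[1], al[2], 11)
    swp <- probe_site_counts(flank, al[2], al[1], 11)
    expect_equal(unname(fwd), unname(rev(swp)))
  }
})

test_that("bisulfite conversion preserves methylated CpGs and converts the rest", {
  expect_equal(bisulfite_convert("ACGA", 2), "ACGA")
  expect_equal(bisulfite_convert("ACGA"), "ATGA")
  expect_equal(bisulfite_convert("CCACG", 4), "TTACG")
  expect_error(bisulfite_convert("ACGA", 1), "CpG")
  expect_error(bisulfite_convert("ACGA", 9), "bounds")
})

test_that("bisulfite conversion is idempotent and keeps exactly the methylated Cs", {
  set.seed(5)
  for (rep in 1:20) {
    seq <- paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE),
                 collapse = "")
    chars <- strsplit(seq, "")[[1]]
    cpg <- which(chars == "C" & c(chars[-1], "") == "G")
    keep <- cpg[stats::runif(length(cpg)) < 0.5]
    conv <- bisulfite_convert(seq, keep)
    expect_equal(nchar(conv), nchar(seq))
    expect_equal(bisulfite_convert(conv, keep), conv)  # idempotence
    all_meth <- bisulfite_convert(seq, cpg)
    expect_equal(sum(strsplit(all_meth, "")[[1]] == "C"), length(cpg))
  }
})

test_that("bisulfite conversion makes C/T alleles indistinguishable, others not", {
  expect_false(alleles_distinguishable_after_bisulfite("C", "T"))
  expect_false(alleles_distinguishable_after_bisulfite("T", "C"))
  expect_true(alleles_distinguishable_after_bisulfite("A", "G"))
  expect_true(alleles_distinguishable_after_bisulfite("A", "C"))
  expect_error(alleles_distinguishable_after_bisulfite("C", "C"), "distinct")
})

test_that("allele-specific PCR specificity gate", {
  expect_true(allele_pcr_specific(98))
  expect_true(allele_pcr_specific(86))
  expect_false(allele_pcr_specific(80))
})
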