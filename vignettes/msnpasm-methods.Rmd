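---
title: "Detecting cis-regulated allele-specific methylation from MSNP arrays"
author: "msnpasm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting cis-regulated allele-specific methylation from MSNP arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msnpasm)
```

## The measurement design

A methylation-sensitive SNP array (MSNP) experiment genotypes each individual
three times on the same SNP array:

* **G** — untreated genomic DNA;
* **D** — genomic DNA digested with a cocktail of methylation-sensitive
  restriction enzymes (MSREs): HpaII (C^CGG), HhaI (GCG^C) and AciI (C^CGC).
  Each enzyme cuts only when the CpG inside its recognition site is
  unmethylated, so digestion destroys the template around *unmethylated*
  alleles;
* **U** — whole-genome-amplified DNA (amplification erases methylation, so the
  DNA is fully unmethylated) digested with the same cocktail. U controls for
  sequence effects: it shows what digestion does to each probe when no
  methylation protects it, including cases where the SNP itself creates or
  destroys a cut site.

At a SNP with probes for alleles A and B, the **relative allele score** is

$$\mathrm{RAS} = \frac{A}{A + B},$$

the fraction of total probe fluorescence from the A allele (the analogue of a
B-allele frequency). A heterozygote sits near RAS = 0.5 in G. If the CpGs
around one allele are methylated and those around the other are not
(allele-specific methylation, ASM), digestion removes the unmethylated
allele's template and the heterozygote's RAS in D moves toward 0 or 1 — in
the limit, an A/B call converts to an apparent homozygous call.

## Per-probe statistics

Only probes with at least one MSRE site on at least one allele can respond to
digestion; `probe_site_counts()` substitutes each allele into the flanking
sequence and counts sites (AciI is non-palindromic, so its reverse complement
GCGG is scanned as a minus-strand site — double-stranded DNA is cut when
either strand presents the site). These probes form the *analysis population*.

Two exclusion criteria operate on condition-mean intensities. With
$\mathrm{distance}(\bar X) = \sqrt{\bar A_X^2 + \bar B_X^2}$ (the Euclidean
norm of the mean two-channel signal in condition $X$), a probe is excluded
when

1. $\mathrm{distance}(\bar G)/\mathrm{distance}(\bar U) < 1.2$ — digestion of
   fully unmethylated DNA did not reduce the signal, so the probe is either
   not cut or cut fragments still hybridise; digestion is uninformative here;
2. $\mathrm{distance}(\bar D)/\mathrm{distance}(\bar U) < 1.2$ — the sample
   DNA lost as much signal as the unmethylated control, i.e. both alleles are
   unmethylated and no allele contrast can exist.

The means are taken over **all** samples assayed, regardless of genotype:
the criteria concern cutting and hybridisation physics, which affect every
genotype class alike, and using all samples makes the means stable.

The ASM statistic pairs each heterozygote's G and D arrays within the
individual:

$$\overline{\Delta \mathrm{RAS}}
  = \frac{1}{n_\text{het}} \sum_i \left| \mathrm{RAS}_{D,i} -
  \mathrm{RAS}_{G,i} \right|,$$

with ASM called when $\overline{\Delta \mathrm{RAS}} > 0.1$. The absolute
value matters: under genomic imprinting the methylated allele is
parental-origin dependent, so individual heterozygotes shift in *both*
directions and a signed mean would cancel. We therefore keep the magnitude as
the detection statistic and retain the signed mean separately; downstream,
`classify_direction()` labels a probe **monoallelic** (cis-regulated: at
least 90% of shifts of magnitude ≥ 0.05 share one sign) or **biallelic**
(imprinting-like: both directions occur). Records with zero total intensity
have no defined RAS and are dropped record-wise; a probe needs at least
`min_het = 2` valid pairs to be evaluable at all, and at least
`min_het_candidate = 4` heterozygotes to be reported as a candidate (a probe
observed in a single heterozygote cannot be evaluated).

## The candidate funnel

`extract_candidates()` applies the stages in order — analysis population,
exclusion criteria, $\overline{\Delta \mathrm{RAS}} > 0.1$, proximity to
susceptibility genes, then quantitative QC — and logs a per-stage count so
the funnel's monotone shrinkage is visible. Proximity means the SNP position
lies within 100 kbp of the gene interval, boundaries inclusive ("within" is
read as a closed interval); zero-width loci at tag-SNP positions give tag-SNP
windowing with the same machinery. Manual inspection of signal cluster plots
is replaced by three numeric rules (`cluster_qc()`): a heterozygote RAS shift
between G and U larger than 0.1 flags a cut-site artifact (the allele itself
makes or breaks a site, so U — not methylation — explains the D shift); a
coefficient of variation of the per-sample G signal distance above 1.0 flags
unstable hybridisation; fewer than 4 heterozygotes flags insufficient
evidence. `plot_signal_clusters()` still draws the plots for manual review.

## Bisulfite-pyrosequencing validation

Bisulfite treatment converts unmethylated C to U (read as T after PCR) and
leaves methylated CpG cytosines intact; conversion is modelled on the top
strand only, with the assay strand a design-time choice. A consequence
checked by `alleles_distinguishable_after_bisulfite()`: a C/T SNP collapses
after conversion (the converted C is indistinguishable from the native T), so
allele-specific PCR must target a proxy SNP in complete linkage
disequilibrium. Allele-specific PCR products are accepted when their measured
specificity is at least 85%.

Given per-allele methylation percentages, two comparisons are made per CpG:

* **heterozygotes only** — a classical paired t-test on the within-individual
  allele difference. Pairing inside the individual cancels environmental
  (smoking, diet, inflammation, treatment) variation between patients, which
  is the core advantage of comparing the two alleles of the same cell
  population. Summaries report the sample SD (n − 1 denominator).
* **all samples** — homozygotes contribute their single allele, so the groups
  are unpaired and of unequal size. The implemented test is the exact
  Wilcoxon rank-sum (Mann–Whitney) test with midranks for ties: the null
  distribution of the rank-sum over all group assignments is computed by
  dynamic programming over the subset-sum distribution of doubled midranks,
  exact even with ties (for more than `max_exact` assignments a
  tie-corrected normal approximation takes over). A signed-rank test is not
  defined for unpaired groups of sizes 5 and 7, which is why the rank-sum
  test is used here.

Degenerate inputs are reported, not hidden: zero-variance paired differences
give p = 1 (all differences zero) or p = 0 with a warning; identical groups
give a rank-sum p of 1.

## Expression association

For genes whose interval intersects a closed 500 kbp window around the SNP,
expression (FPKM) is regressed on the additive allele dosage (0/1/2 copies of
the tested allele) by ordinary least squares — a single regression line over
the three genotype groups — reporting the two-sided slope p-value, $R^2$ and
adjusted $R^2 = 1 - (1 - R^2)(n-1)/(n-2)$. Genes with mean FPKM below 1 are
reported as not analysed rather than regressed on noise, mirroring the dash
rows of published tables. With only one sample in a genotype class the
regression is still fit (no leverage exclusion); with a single class present
it is not. Dosage coding was chosen over ordinal-genotype coding because the
published analysis fits one regression line across the three genotype groups;
for a single regressor the two give identical tests anyway up to scaling.

One packaged reference table deserves a note: the six genes shipped in
`expression_group_means_rs36221701.tsv` are all described in their source as
lying within 500 kbp of the SNP at 15:67356489, but the printed span of
*SKOR1* (15:68112041–68126174) begins 755 kbp away. The windowing here is
implemented as stated — closed-interval intersection — so five of the six
genes fall inside the window; the fixture keeps all six rows as printed.

## The synthetic-data generator

`simulate_msnp_dataset()` emulates the study design: by default 1,000 probes
and 15 individuals (the study's sample size), heterozygote frequency 0.42
(the mean heterozygote count among the published candidate SNPs is 6.33 of
15), and five probe classes — `cis_asm` (5%), `imprinted` (5%),
`unmethylated` (20%), `no_site` (20%), remainder `null`. Planted ASM uses
per-allele methylation 0.9 vs 0.1; `null` probes carry 0.5 on both alleles.
Flanking sequences are built so that `probe_site_counts()` on the annotation
reproduces the truth table exactly: an A/T backbone (no recognition site of
the cocktail can form with fewer than three C/G bases) with the configured
number of CCGG sites inserted clear of the variant.

The intensity model, per probe $p$, sample $s$, condition $X$ and allele
channel $a$:

$$\text{signal} = I_{0,p,X} \cdot \varepsilon_{s,p,X} \cdot \eta_{s,p,X,a}
  \cdot \sum_{\text{copies of } a} \prod_{\text{sites}} \big(m + (1 - m)\,
  r\big) \; + \; \text{background},$$

where $m$ is the copy's methylation, $r$ = `residual_uncut` (default 0.05)
is the fraction of templates escaping digestion at an unmethylated site
(survival is 1 in G; $m = 0$ everywhere in U), $\varepsilon$ is log-normal
with CV `noise_cv` = 0.2 shared by both channels, and $\eta$ is a log-normal
per-channel residual with CV `allele_noise_cv` = 0.05. The decomposition is
deliberate: on real genotyping arrays most intensity variation is probe-level
hybridisation scale, which multiplies both allele channels together and
cancels in RAS — that is why genotype clusters are tight. A single
independent per-channel noise of CV 0.2 would give per-heterozygote
$|\mathrm{RAS}_D - \mathrm{RAS}_G|$ noise of about 0.08 and push roughly a
fifth of null probes over the 0.1 threshold, which no usable array platform
exhibits. The U condition's separate DNA source is modelled as a small
per-probe multiplicative offset (`u_baseline_log_sd` = 0.02); a fully
independent U baseline would randomise the exclusion ratios and defeat the
exclusion criteria for every probe, informative or not. Under genomic
imprinting, one of the two chromosome copies per individual is methylated,
chosen uniformly at random and independent of genotype.

What the generator does **not** emulate: Axiom probe chemistry and
cross-hybridisation, batch and plate effects, genotype-calling error
(`NoCall` handling is exercised with hand-built tables in the tests),
linkage between probes, and realistic genome annotation. Passing recovery
tests on this generator therefore demonstrates that the statistics detect
the planted signal under the stated noise model — not performance on raw
Axiom data.

With the defaults, digestion separates cleanly: a heterozygote of a planted
cis-ASM probe with one site has expected
$\mathrm{RAS}_D \approx 0.905 / (0.905 + 0.145) = 0.86$ against
$\mathrm{RAS}_G \approx 0.5$, far above the 0.1 threshold, while null probes
have RAS noise of about 0.02. In the exact limit case — complete one-allele
methylation, `residual_uncut = 0`, zero background and noise — heterozygotes
give $\mathrm{RAS}_G = 0.5$ and $\mathrm{RAS}_D = 1$ for the methylated
allele exactly, the idealised AB→AA call conversion.

```{r limit-case}
cfg <- sim_config(n_probes = 10, n_samples = 6, asm_fraction = 1,
                  imprint_fraction = 0, unmethylated_fraction = 0,
                  no_site_fraction = 0, methylation_high = 1,
                  methylation_low = 0, residual_uncut = 0, background = 0,
                  noise_cv = 0, allele_noise_cv = 0, seed = 2)
ds <- simulate_msnp_dataset(cfg)
pairs <- het_ras_pairs(ds$intensities, ds$genotypes)
range(pairs$ras_g)
table(pairs$ras_d)
```

## Numerical choices and problem sizes

* Thresholds (0.1 for $\overline{\Delta \mathrm{RAS}}$, 1.2 for the exclusion
  ratios, 100 kbp and 500 kbp windows) are configuration values defaulting to
  the published constants.
* No between-array normalisation is applied by default: RAS and the exclusion
  ratios are scale-free within an array, so a global scale factor cancels.
* Coordinates are 1-based inclusive internally; BED input is converted at the
  reader. Window boundaries are inclusive.
* Exclusion criterion 1 is tested before criterion 2, so a probe failing both
  is attributed to criterion 1.
* The exact rank-sum enumeration is used up to 10^7 group assignments
  (total n of about 30 at balance), far beyond every use here; ties are
  handled by midranks throughout.
* Test and example panels use 100–2,000 probes and 5–15 samples; the recovery
  analyses use the default 1,000-probe, 15-sample panel, which runs in a few
  seconds. These sizes give recovery-rate estimates with standard errors of a
  few percent, adequate for the 90%/5% recovery margins checked in the test
  suite.

## Known limitations

* The $\overline{\Delta \mathrm{RAS}}$ threshold is a fixed constant, not a
  per-probe significance test; probes with few heterozygotes are handled by
  evaluability and QC gates rather than by a variance model.
* Direction classification needs at least two qualifying heterozygote shifts;
  with very few heterozygotes an imprinted probe can look monoallelic by
  chance (all shifts the same sign), which bounds the biallelic-recovery rate
  on small panels.
* Bisulfite logic is top-strand only; assays on the bottom strand must be
  declared by the caller after reverse-complementing.
* The expression stage fits one gene at a time with no multiple-testing
  adjustment by default, matching the published analysis; apply `p.adjust`
  to the report column if a corrected screen is wanted.
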