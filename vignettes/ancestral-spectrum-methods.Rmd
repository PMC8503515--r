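---
title: "Ancestral spectrum analysis: model, estimators and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ancestral spectrum analysis: model, estimators and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ancspec)
```

## The problem

Deep-sequencing studies show that most detected variants are rare and
restricted to a single continental population. Such population-specific
variants are typically recent mutations and carry strong ancestry signal,
but classical PCA- or model-based admixture tools are built around common
variants and require either an eigendecomposition over all samples or a
joint likelihood fit. `ancspec` implements a supervised alternative: fix a
set of K reference populations, build a panel of SNPs polymorphic in exactly
one of them, and score any study individual against the panel using nothing
but the reference minor allele frequencies (MAFs). No eigenanalysis, no
reference genotypes and no other study individuals enter the computation, so
results are comparable across studies scored with the same panel and immune
to genetic outliers, relatedness or sample size in the target cohort.

## The model

Index the reference populations k = 1..K. The panel assigns SNP m to exactly
one population, with reference MAF f_km > 0 there and 0 elsewhere; write
mu_km = 2 f_km for the expected allele count of a population-k member and
sigma^2_km = 2 f_km (1 - 2 f_km) for its variance under the rare-allele 0/1
genotype approximation.

An admixed individual n has ancestral proportions p_n1..p_nK (>= 0, not
forced to sum to one). Each of the two haplotypes at SNP m in G_k descends
from population k with probability p_nk and then carries the specific allele
with probability f_km, so the allele count is Binomial(2, p_nk f_km),
independent across SNPs (rare alleles have negligible linkage
disequilibrium). This is exactly the law the simulator
(`simulate_genotypes()`) draws from.

## Estimators

Two linear estimators of p_nk are computed from the genotype row X(n, .):

* **Principal score** `a_nk = sum_m X(n,m) b_k(m)` with the MAF-weighted
  loading b_k = mu_k / sum(mu_km^2), the projection of the genotype vector
  onto the asymptotic principal direction of population k. It is unbiased,
  equals 1 in expectation for a population-k member, and is exactly 0 for an
  individual carrying no population-k allele. Among linear unbiased
  estimators it has *maximal* variance in the class spanned by these
  weightings: it up-weights the higher-MAF SNPs.
* **Ancestral information** `p_hat_nk = sum_{m in G_k} X(n,m) / sum mu_km`,
  the equal-weight ratio of observed to expected specific-allele count. It
  is the best linear unbiased estimator (BLUE) of p_nk for rare alleles:
  minimising sum(w_m^2 sigma^2_m) subject to sum(w_m mu_m) = 1 gives weights
  proportional to 1/(1 - mu_m), essentially constant when mu is small.

The vector of K information values is the individual's *ancestral spectrum*.
Totals are deliberately unconstrained: a total well below one signals an
ancestral source missing from the reference set, and values above one arise
when the study population carries the reference's specific alleles at higher
frequency than the reference itself (frequency drift). Both behaviours are
diagnostic and would be destroyed by renormalisation, so values are never
clipped or rescaled.

A maximum likelihood refinement solves the score equation of the binomial
0/1 likelihood, `p * sum_m mu_m (1 - X_m) / (1 - p mu_m) = sum_m X_m`, by
bracketed root finding (`uniroot`, absolute tolerance 1e-10) on
[0, (1 - 1e-9)/max(mu)]; the upper end enforces 1 - p mu_m > 0 for every
SNP while still allowing estimates above one. A row with no specific allele
has MLE exactly 0; a row where every panel allele is observed leaves the
score equation without an interior root and returns the bracket end with a
boundary flag. For small MAFs the MLE and the moment estimator agree
closely; for common alleles the binomial approximation degrades while the
moment estimator remains valid, which is why the moment estimator is the
default and the MLE is opt-in.

## The GRM-PS and its expectation

For reference samples, the genetic relationship matrix on panel SNPs,
Z = (1/M) X X', is block-diagonal with exact zero cross-population entries
(disjoint allele support). Its expectation has compound-symmetric blocks
with diagonal z_k = (1/M) sum 2 f_km and off-diagonal
z_kk = (1/M) sum 4 f_km^2, hence one population-informative eigenvalue
lambda_k = z_k + (N_k - 1) z_kk per block (eigenvector 1/sqrt(N_k)) and an
(N_k - 1)-fold eigenvalue z_k - z_kk = (1/M) sum sigma^2_km that reflects
only intra-population noise. `egrm_params()`, `egrm_eigen()` and
`build_egrm()` expose these closed forms for diagnostics and validation;
they are not needed for inference, which is the method's point.

## Panel construction rules

`compute_maf()` designates the minor allele once, on the pooled reference
sample (frequency <= 0.5 pooled; at exactly 0.5 the lexicographically
smaller allele character wins). A per-population designation would risk
assigning different alleles of one SNP to different populations; at the
low-MAF windows used for panels the two conventions agree in practice.
"Polymorphic" means strictly f > 0 on observed calls, so singletons count as
population specific; the MAF window then excludes them from panels. Window
endpoints are treated as closed on both ends — the permissive reading of "a
MAF between the bounds". A SNP with an undefined frequency in any population
(no non-missing calls) is ineligible. Subsampling to the target panel size
is a seeded uniform draw without replacement, making the panel file
byte-reproducible; multi-allelic sites are excluded at VCF reading.

## Numerical and data-handling choices

* **Diploid counts.** Genotypes are kept as 0/1/2 everywhere linear: the
  moment estimator and the scores stay unbiased under the two-independent-
  haplotypes model. Only the MLE likelihood, defined on {0,1}, truncates 2
  to 1 (with a warning).
* **Missing calls** contribute 0 copies to numerators and the denominators
  are *not* rescaled — for rare alleles the missing call is almost surely
  homozygous major, and rescaling would break linearity and batch
  invariance. A per-individual call rate is reported so users can judge the
  residual downward bias.
* **Batch invariance** is enforced bit-for-bit: projections are computed one
  individual at a time (`crossprod` per row) rather than as one matrix
  product, whose blocked accumulation order would otherwise let batch
  composition perturb the last floating-point bit.
* **VCF matching** is by chromosome, position and unordered allele pair,
  never by rsID (IDs drift across call sets). If the panel minor allele is
  the VCF REF, counts are 2 - dosage. Strand flips are never guessed:
  palindromic A/T and C/G sites are matched literally and listed in a
  warning, because silent strand correction corrupts rare-allele counts.

## What the simulator emulates — and what it does not

`simulate_panel()` draws reference MAFs (default uniform on the [0.01, 0.05]
panel window); `simulate_genotypes()` draws Binomial(2, p f) genotypes under
an admixture design; `simulate_drifted_population()` emulates, at the
expectation level, the two phenomena that move ancestral information away
from one in real cohorts: uniform frequency drift (MAFs scaled by a
constant) and bottleneck site loss (a random retained subset of sites,
the rest fixed absent). The expected information of a drifted cohort is the
scale factor times the retained share of sum(mu) — e.g. a cohort whose mean
MAF is 0.021 against a reference mean of 0.016 has expected information
0.021/0.016 = 1.3125, and retaining 5,454 of 50,000 sites cuts expected
information to about 0.109.

The generator deliberately omits linkage disequilibrium, coalescent noise in
the drifted frequencies (scaling is deterministic, not Wright–Fisher),
genotyping error and reference-panel misclassification. Passing recovery
tests therefore demonstrates estimator correctness under the stated model,
not robustness to platform artefacts or to reference populations that are
poor proxies of the true sources — in real data the information must then be
read as co-ancestry rather than an ancestral proportion.

## Problem sizes used in validation

The package's checks run at the study scale where the asymptotics bite but a
desktop stays comfortable: panels of 50,000 SNPs per population (the size
used for continental reference panels), cohorts of 99–500 individuals, 20
replicates for the variance-ordering check, and 100 random parameter sets
for the eigenstructure identity at tolerance 1e-10. Unit tests re-run the
same properties at reduced sizes for speed.

## Known limitations

* Reference MAFs are treated as known constants; their estimation error
  (finite N_k) propagates into the scores but is not quantified per
  individual. Large, outlier-screened reference samples remain the user's
  responsibility.
* Ancestral information is interpretable as an ancestral *proportion* only
  when the reference population is a good proxy of the true admixing
  source; otherwise it measures shared rare-allele co-ancestry.
* No per-individual standard errors, no constrained (sum-to-one)
  estimation, and no local-ancestry inference along the genome — the first
  is future work, the latter two are out of scope by design.
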