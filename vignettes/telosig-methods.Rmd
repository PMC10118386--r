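---
title: "telosig: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{telosig: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

telosig implements the statistical machinery used to interrogate whether
genetically predicted leukocyte telomere length (LTL) influences lung
cancer risk, and how that germline signal propagates into tumour gene
expression. The real analyses of this kind run on consortium-held GWAS
summary statistics and controlled-access tumour cohorts; every stage
here is therefore paired with a ground-truth simulator so the whole
pipeline is testable end to end on synthetic data. This vignette
documents the models, the tunable parameters, the numerical choices, and
the places where the design was genuinely open.

## 1. Summary-statistic plumbing

Variants are keyed by id string only — there is no positional fallback
matching, because silent position-based joins across genome builds are a
classic source of irreproducibility. Coordinates are 1-based inclusive
and the genome build is an opaque label carried through unchanged.
`read_sumstats()` drops rows that violate the record invariants
(non-positive SE, p outside (0,1], identical alleles, out-of-range EAF,
duplicate ids) and reports per-reason counts rather than failing; the
single exception is p-value underflow, which is clamped to 1e-300 and
flagged, since an underflowed p-value is evidence of a very strong
association, not of a bad row.

`read_ld_matrix()` repairs asymmetries up to 1e-6 by averaging and
forces the diagonal to 1 within the same tolerance; anything larger is a
hard error, because it indicates a malformed panel rather than floating
point noise. LD is stored *signed* so that proxy substitution can orient
alleles through the sign of the proxy–target correlation.

`extract_region()` reads a "150 kb window" as a *total* width centred on
the lead variant (&plusmn;75 kb), following the "centred on" phrasing
used for such windows; the boundary convention is
`(pos - 75000, pos + 75000]`.

## 2. Instruments, harmonisation, PRS, power

Instrument selection is greedy p-value-ordered LD clumping: candidates
must pass `p < 5e-8` and MAF &ge; 1%, and are accepted when their
r&sup2; with every previously accepted variant is below 0.01. Ties on p
are broken lexicographically by variant id so the output is a pure
function of its inputs.

Harmonisation aligns outcome effects to the exposure effect allele,
recognising swapped and strand-complemented allele pairs. Palindromic
(A/T, C/G) variants are aligned by allele frequency when both MAFs are
below 0.3 and dropped otherwise — the conventional cutoff; the
frequency signal is too weak to orient a palindrome near MAF 0.5.
Instruments missing from the outcome are replaced by their best LD proxy
when r&sup2; exceeds 0.8, with the signed correlation deciding the
orientation of the proxy's effect.

`compute_prs()` is the beta-weighted dosage sum with per-variant mean
imputation of missing dosages (standard PRS-software behaviour) and
population-SD standardisation, so a three-sample cohort with dosages
(0,1,2) and unit weight scores (&minus;1.2247, 0, 1.2247).

`mr_power()` is the asymptotic two-sided Wald power for a binary
outcome: &Phi;(&radic;(N r&sup2; &phi;(1&minus;&phi;))·|log OR| &minus;
z) plus the opposite tail, so the null returns exactly &alpha;. The
Monte-Carlo rejection rate of the corresponding Wald test is the test
oracle.

## 3. Two-sample MR estimators

All estimators consume aligned exposure/outcome effect pairs and treat
case-control outcome betas as log-ORs; ORs are obtained by
exponentiation.

* **IVW (multiplicative random effects)** — weighted regression of
  b_Y on b_X through the origin with weights 1/s&sup2;_Y; the SE is the
  fixed-effect SE inflated by max(1, &radic;(Q/(J&minus;1))). The floor
  at 1 means the random-effects SE can never undercut the fixed-effect
  one. &tau;&sup2; is DerSimonian–Laird on the Wald ratios (the ratio
  scale was chosen over regression residuals; the choice is recorded in
  the output notes).
* **MR-Egger** — instruments are first oriented so every b_X &ge; 0,
  then an intercept is added. The intercept estimates mean directional
  pleiotropy; under InSIDE the slope is the corrected causal effect.
  t(J&minus;2) reference distributions, overdispersion floored at 1.
* **Weighted median** — cumulative-weight interpolation over the sorted
  Wald ratios; SE by seeded parametric bootstrap. Consistent while
  instruments carrying &ge;50% of the weight are valid.
* **Contamination mixture** — profile likelihood over a grid of
  candidate effects, each instrument classified valid
  N(&theta;, se&sup2;) or invalid N(0, se&sup2;+&psi;&sup2;) by the
  larger likelihood. The default &psi; is 1.5&times;SD of the ratios.
  The profile peak is refined by quadratic interpolation to remove the
  grid-step bias; the 95% confidence set is the 3.84-drop region and may
  be disjoint, in which case the envelope is returned with a flag.

**Known finite-strength properties** (quantified by the acceptance
suite): when exposure effects are observed with sampling noise, Egger's
slope attenuates by var(b_true)/(var(b_true)+s&sup2;_X) — the NOME
violation familiar from the I&sup2;_GX literature — which at a
465k-sample exposure GWAS and an effect spread of 0.01 is about
&minus;2% of &theta;. The contamination mixture's zero-centred invalid
component captures the weakest valid instruments nearest the null,
biasing the estimate away from zero by a few percent of &theta; when all
instruments are genuinely valid. Neither is an implementation defect;
both vanish as instrument strength grows, and both are asserted (and
allowed to fail visibly) in the acceptance tests rather than hidden.

Multivariable MR fits all exposures jointly (weighted multiple
regression through the origin); the Egger variant orients on the first
exposure; the LASSO variant gives every instrument an L1-penalised
intercept with the exposure effects unpenalised, picks the largest
&lambda; whose post-selection IVW heterogeneity Q is below the
&chi;&sup2; 95th percentile, and refits IVW on the retained instruments.

## 4. Colocalisation

Per-variant evidence is the Wakefield log approximate Bayes factor
`0.5 log(1-r) + 0.5 r z^2`, `r = W/(W+se^2)`, with prior effect SD 0.15
(scaled by sdY) for quantitative traits and 0.2 on the log-OR scale for
case-control traits. `coloc_abf()` enumerates the five
single-causal-variant hypotheses with priors p1 = 1e-3, p2 = 1e-4,
p12 = 1e-5 (roughly: a 75% prior that a signal appears only in the
better-powered trait and under 0.01% for sharing), in log space; a
literal configuration-enumeration oracle checks it to 1e-10 in tests.

Secondary signals are detected by stepwise conditioning: lead |z|,
condition, repeat while the conditional lead has p < 1e-5, at most 3
signals (both knobs exposed; the thresholds are conventional rather than
prescribed). Conditioning uses the approximate conditional z,
`(z - r_c z_c)/sqrt(1 - r_c^2)`, with variants in near-perfect LD with
the conditioning variant (|r_c| &ge; 0.99) masked, because their
conditional statistics are numerically meaningless. Per-trait analysis
"views" are then built — unadjusted; conditioned to isolate each
signal; masked of LD partners (r&sup2; > 0.01) of the other signals —
and `coloc_abf` runs on every pair of views. The *unweighted mean PP4*
over runs is the reported posterior belief, with every run returned
alongside so the averaging set is never opaque. PP4 > 0.70 is treated as
strong evidence, the usual cutoff.

The multi-trait routine is a deliberate simplification of full
clustering algorithms such as HyPrColoc (no regional/alignment
factorisation, no branch-and-bound): the posterior that all traits in a
set share one causal variant — per-SNP products of ABFs under a shared
per-SNP prior (1e-5) — is weighed against full independence *and* every
leave-one-out partial-sharing alternative (per-trait association prior
3e-4, the geometric mean of p1 and p2, keeping two-trait behaviour close
to `coloc_abf`). The leave-one-out alternatives matter: without them a
flat trait rides along with any strongly shared cluster, because its
null Bayes factor penalty (~e^-3) is smaller than the prior gain. While
the posterior is below 0.7 the trait whose removal most improves it is
removed greedily, and the removed pool is re-clustered.

## 5. LD-score regression

Heritability is the slope of z&sup2; on N·&ell;/M with a free intercept
(absorbing confounding inflation); genetic covariance is the slope of
z&#8321;z&#8322; on &radic;(N&#8321;N&#8322;)·&ell;/M, whose intercept
absorbs sample overlap. Weights are updated once from an unweighted pass
(deterministic two-pass behaviour); the predicted per-SNP chi-square in
the weight formula is floored at 1 — its null expectation — because a
negative fitted intercept on a noisy first pass otherwise gives low-LD
SNPs enormous weight and can flip the sign of the estimate.
r_g = &rho;_g/&radic;(h&sup2;&#8321;h&sup2;&#8322;); uncertainty is a
delete-a-block jackknife over 200 contiguous blocks applied to the full
ratio (all three regressions recomputed per deleted block), and r_g is
reported clamped to [&minus;1.25, 1.25] with a flag. Non-positive
heritability makes r_g undefined and it is returned as flagged missing
rather than a number. Observed-scale only; HLA exclusion is an upstream
coordinate mask.

## 6. The tumour-transcriptome arm

**Normalisation.** A full-quantile within/between-lane normalisation was
deliberately replaced by a lighter deterministic procedure with the same
invariances: (1) drop genes with &ge;5 reads in fewer than 20% of
samples; (2) within each sample, remove GC- and log-length trends by
binned-median regression computed on expressed genes only — computing on
the log scale over nonzero counts makes the correction *exactly*
commute with depth rescaling; (3) upper-quartile scale each sample's
expressed counts to a fixed common depth (1000), so the output is
invariant to multiplying any sample's counts by a constant. Output is
log2(x+1).

**PCA.** Genes are centred and unit-scaled; a provisional SVD flags
samples beyond 6 SDs on either of the first two components (an
operational reading of "extreme outliers"); the decomposition is refit
without them. Loading signs are fixed by making each column's
largest-magnitude entry positive, so results are reproducible across
LAPACK implementations.

**Alignment.** Train and validation embeddings are aligned by orthogonal
Procrustes: R = UV&#7488; from the SVD of L&#7515;&#7488;L&#8348;.
Because both PCAs centre their data, the translation component of a
rigid transformation is already absorbed; only rotation/reflection is
estimated.

**Signature.** Genes are screened by BH-FDR < 0.05 on correlation with
the component score (BH for screening; Bonferroni is reserved for the
top-loading-gene export, mirroring how the two corrections are
conventionally split); screened genes are z-scaled and a LASSO of the
component score on them is tuned by out-of-bag RMSE over seeded
bootstrap resamples — the tuning always selects &lambda; rather than
fixing it, since a near-zero printed &lambda; in any one dataset is a
tuning artefact, not a transferable constant. `apply_signature()`
z-scales each signature gene *within the target cohort* by default
(supporting cross-cohort comparisons between histologies on a common
internal scale); training-frozen scaling is a switch. Zero-variance
signature genes in a target are dropped with a warning and a flag.

**Association models.** `associate_prs_pcs()` regresses each component
score on the standardised PRS plus covariates (sex, age, smoking,
ancestry PCs — the covariate set is an argument because different
analyses legitimately use different sets). `feature_association()` fits
each feature alone and all jointly; in univariate mode the PRS row is
additionally ancestry-adjusted when ancestry PCs are supplied, matching
how a PRS is conventionally handled in a univariate table.

## 7. The synthetic world

Each generator is a pure function of parameters + seed.

* **MR instruments**: true per-variant exposure effects |N(0.03,
  0.01&sup2;)| (a 144-variant instrument of this strength explains a few
  percent of exposure variance); exposure betas observed with noise from
  a 464,716-sample GWAS; outcome SEs use the binary-trait form
  1/&radic;(N&phi;(1&minus;&phi;)) with N = 85,689 and case fraction
  0.341 (a 29k-case lung-cancer consortium GWAS); pleiotropy
  N(&mu;, &sigma;&sup2;) independent of instrument strength, so InSIDE
  holds by construction.
* **Regional data**: AR(1) LD (r = &rho;^|i-j|, one decay knob);
  marginal z-means are causal noncentralities propagated through LD;
  one MVN draw per trait. The default causal effect 0.06 at n = 10,000
  puts the lead variant at z &asymp; 6 — a clearly genome-wide-
  significant locus, which is the setting in which colocalisation is
  actually run.
* **LDSC traits**: per-SNP z pairs from the marginal bivariate model
  var(z) = 1 + N h&sup2;&ell;/M, cov = r_g&radic;(h&sup2;h&sup2;NN)&ell;/M
  + overlap, with the overlapping-sample phenotypic correlation
  approximated by the genetic covariance. LD scores 1 + Exp(mean 50).
* **Tumour cohort**: 343 samples by default; dosages Binomial(2, f);
  five latent factors load on disjoint gene modules with decreasing
  magnitude (base loading 0.7, chosen so the five-factor share of
  log-expression variance sits near the ~54% reported for real
  adenocarcinoma expression); factor 2 carries the planted PRS effect
  (0.17 per SD) plus modest sex/age/smoking/stage effects, all scaled to
  keep the factor near unit variance so the planted effect lives on the
  SD scale it is recovered on; counts are negative binomial (dispersion
  0.3, log-normal baselines, lognormal depth).

What a green test does *not* establish: the generators use idealised LD
(AR(1) or supplied), produce no population stratification, batch
effects, tumour purity variation or genotyping error, and the
expression factors are exactly low-rank. Green means the estimators
recover the parameters of this stated world at the stated tolerances,
not that restricted-data results are reproduced.

## 8. Numerical choices

Log-space summation (`logsumexp`/`logdiffexp`) everywhere Bayes factors
are combined; ridge 1e-4 on LD before the conditioning eigenvalue check;
p-value underflow clamped at 1e-300; conmix grid 512 points with
quadratic peak interpolation; clumping ties broken lexicographically;
PCA sign convention as above; all bootstraps, splits and simulations
take explicit seeds and restore the caller's RNG state.

## 9. Known limitations

Steiger filtering, bidirectional MR, winner's-curse correction,
liability-scale heritability, partitioned LDSC, SuSiE/eCAVIAR-style
colocalisation, full HyPrColoc, tumour purity and batch correction, and
survival analysis are out of scope. The multi-trait colocalisation is a
simplified divisive procedure and its posteriors should not be read as
HyPrColoc posteriors. The conditional z-score approximation ignores the
change in LD structure induced by conditioning.
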