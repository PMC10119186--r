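---
title: "Rare high-impact variant burden analysis: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare high-impact variant burden analysis: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ajburden)
```

`ajburden` implements a complete case-control pipeline for rare, predicted
high-impact coding variants in a founder population: genetic cohort
definition, quality control, deleteriousness filtering, gene-level burden
association, biological-distance prioritization, pathway-consensus ranking
and rare-variant polygenic risk scoring. This vignette explains the models
behind each stage, the tunable parameters and their defaults, the synthetic
cohort generator used to validate everything, and the numerical choices that
required a decision.

## The scientific setting

Founder populations carry an excess of rare, relatively recent deleterious
alleles on a homogeneous genetic background, which makes them unusually
informative for rare-variant association. The pipeline assumes exome-style
genotypes for thousands of cases and controls, a per-variant annotation
table (gene, consequence, reference-population allele frequency, CADD
deleteriousness score), per-gene metric tables (the mutation significance
cutoff, MSC, and the gene damage index, GDI), a variant blacklist, a known
disease-gene list, a gene-by-gene biological distance matrix, and
tab-delimited GWAS summary statistics. Real inputs of this kind are usually
access-controlled; every structure the pipeline needs can be generated by
the `synth` functions with the statistical properties the analysis assumes.

## Cohort definition by supervised admixture fractions

The target subpopulation is identified genetically, not by self-report.
Markers are first pre-masked (`premask_markers`: minor allele frequency
strictly above 0.02, call rate strictly above 95%, optional removal of
strand-ambiguous A/T and C/G markers) and LD-pruned (`ld_prune`: sliding
windows of 50 markers advancing by 5, greedy left-to-right removal until no
retained pair within a window has r² > 0.2). Pruning is deterministic given
marker order and depends only on the genotype correlations.

Ancestry is then estimated by a *supervised* two-population binomial
likelihood (`estimate_fractions`): with reference-panel frequencies
$p^A_m, p^B_m$ fixed, each sample's admixture fraction $q$ maximizes

$$\ell(q) = \sum_m \log \mathrm{Binom}\!\left(g_m;\, 2,\; q\,p^A_m + (1-q)\,p^B_m\right),$$

solved by bounded one-dimensional optimization to tolerance $10^{-6}$.
This is a deliberate substitution for unsupervised model-based clustering
at K = 2: with reference panels available, fixing the ancestral frequencies
makes the estimator deterministic, fast and directly testable, at the cost
of ignoring uncertainty in the panel frequencies. Samples with fewer than
50 informative markers are flagged unreliable; a panel with identical
frequencies in both populations leaves $q$ unidentifiable and the estimator
returns 0.5 with an explicit flag rather than an arbitrary optimum.

Assignment (`assign_population`) uses the *minimum reference fraction* rule:
the cutoff is the smallest $\hat q$ observed among the reference samples,
and candidates at or above it (boundary inclusive) are retained. A second
round re-estimates the non-reference ancestral frequencies from the
candidates rejected in round 1 — the analogue of re-running structure
estimation on the refined cohort, which sharpens the contrast between the
two ancestral profiles — and re-applies the updated cutoff. The cutoff is
always computed from the data, never hard-coded; once the assignment is
stable, further rounds change nothing. PCA (`pca_project`, markers scaled
by $\sqrt{2p(1-p)}$, missing genotypes mean-imputed, deterministic sign
convention) validates the assignment visually and supplies the 10
covariate components used by the association tests.

## Quality control

Variant-level rules (`qc_variants`): mean depth ≥ 10 and mean genotype
quality ≥ 20 when per-genotype DP/GQ are available, at least one
alternate-allele carrier meeting both thresholds, call rate ≥ 95%,
Hardy-Weinberg exact-test p ≥ 10⁻⁶, and case/control differential
missingness (Fisher exact) p ≥ 10⁻⁵. HWE is computed **in controls only**:
a true risk variant can legitimately deviate in cases, and standard
practice avoids discarding it. The HWE test is the Levene-Haldane exact
enumeration, implemented from log-factorials.

Sample-level rules (`qc_samples`): het/hom, Ti/Tv and ins/del ratios
outside 4 median absolute deviations from the cohort median (a zero-MAD
metric is skipped — the degenerate-spread contract — and cohorts under 10
samples skip the MAD rule entirely); missing rate above 3%; and one member
of any pair with kinship above 0.185, resolved by dropping the
higher-missingness member. Kinship (`kinship`) uses the robust
shared-heterozygosity estimator
$\varphi = (N_{Aa,Aa} - 2N_{AA,aa}) / (N_{Aa,i} + N_{Aa,j})$,
which gives 0.5 for duplicates, ≈0.25 for parent-offspring and ≈0 for
unrelated pairs without requiring allele frequency estimates.

## The six-rule high-impact filter

`high_impact_filter` retains a variant only if **all** rules hold:

1. *(site quality, when fields are present)* DP > 10 and MQ > 40;
2. *(consequence)* the annotation is one of the 12 whitelisted high-impact
   classes (`whitelist_consequences()`); synonymous and non-coding variants
   never qualify;
3. *(frequency)* the effective MAF — the reference-population MAF when
   recorded, otherwise the cohort allele frequency — is ≤ 0.01. The
   boundary is inclusive; the rule's two published phrasings ("remove
   > 0.01" vs "retain < 0.01") disagree only at the boundary and the
   inclusive reading was chosen and is logged;
4. *(deleteriousness)* CADD ≥ the gene's MSC; a gene with no MSC falls back
   to a configurable absolute CADD threshold (default 15);
5. *(gene damage)* GDI < 13.34, the generalized disease-gene cutoff; genes
   with no GDI are treated as passing;
6. *(blacklist)* the variant is not on the supplied blacklist.

The filter is a pure set intersection: order-independent, monotone in every
threshold, with per-rule attrition counts reported. Variants without a gene
assignment are excluded and counted separately.

## Gene-level association

Qualifying variants are collapsed per gene (`collapse_by_gene`), with a
cohort-MAF ≤ 0.01 guard inside the block so that variants rare in the
reference but common in the cohort cannot inflate a gene. Three tests are
provided.

**Carrier burden** (`carrier_burden_test`): the 2×2 carrier-by-status table,
odds ratio $ad/bc$, and a 1-df chi-squared **without** continuity
correction — the uncorrected statistic reproduces the scale of published
carrier-set results; the corrected version is available behind a flag. Zero
cells get the Haldane-Anscombe 0.5 correction with a flag; all-carrier and
no-carrier tables are flagged degenerate with no p-value.

**SKAT-O** (`skat_o_test`): the score-statistic family
$Q_\rho = (1-\rho)\,Q_{\text{SKAT}} + \rho\,Q_{\text{burden}}$ over the grid
$\rho \in \{0, 0.01, 0.04, 0.09, 0.16, 0.25, 0.5, 1\}$ (the grid of the
original optimal-test publication, since no grid is printed in the sources
this package follows), with Beta(1, 25) MAF weights, a logistic null model
on covariates only, and missing dosages imputed to twice the allele
frequency. Per-ρ tail probabilities come from a four-moment matched
mixture-of-chi-squares approximation ("liu"), with a Kuonen saddlepoint
("saddlepoint", the default for its relative tail accuracy) and an exact
characteristic-function inversion ("imhof") available. The omnibus p
integrates the minimum-p statistic over the shared χ²₁ component of the
decomposition $Q_\rho = (1-\rho)\kappa + \tau(\rho)\eta_0$. At $\rho = 1$
the statistic is exactly the weighted burden score test and is referred to
a 1-df chi-square; a single-variant block collapses to the score test for
any ρ.

**Small-count correction.** With MAFs in the 10⁻⁴–10⁻³ range a gene's score
vector is a sum over a few dozen carrier rows of ±-valued residuals; its
null distribution is discrete and *lighter-tailed* than any
Gaussian-quadratic approximation, making all eigenvalue-based p-values
conservative and the min-p combination doubly so. `skat_o_test(resample = B)`
therefore applies a residual parametric bootstrap: carrier-row residuals
are redrawn exactly as $y^* \sim \mathrm{Bern}(\hat\mu_i)$, a first-order
refitting correction $A_1 W^{-1} X'(y^*-\hat\mu)$ (exact on carrier rows,
Gaussian-limit on the rest) reproduces the covariate-projected score
covariance, and the whole ρ family is recomputed per replicate, so
discreteness and inter-variant dependence are captured. Mid-p counting
(half-weight on replicates that tie the observed statistic) keeps the
p-value distribution centred where carrier configurations produce sizeable
atoms. The calibration this buys is verified by the suite's null-cohort
study: the full pipeline on effect-free data keeps the empirical type-I
error at 0.05 and 0.01 inside its binomial confidence band and the genomic
inflation factor near 1 — bands the purely asymptotic p-values do not
reliably hold at these carrier counts. Asymptotic p-values below
`resample_below` (default 2×10⁻³) are kept as-is: they are beyond bootstrap
resolution and only their ranks matter downstream. `skat_o_scan` applies
the bootstrap by default; rank-only studies (power benchmarks) disable it
for speed, which cannot change which genes occupy the extreme ranks.

**Calibration checks** (`inflation_check`): λ_GC as the ratio of the median
observed 1-df chi-square to its null median, usable for the
synonymous-neutral model and controls-vs-controls splits alike.
`bonferroni_threshold` supplies the genome-wide cutoff.

**Gene-level phenome scan** (`phewas_scan`): per phenotype with ≥ 100
cases, controls are drawn 10:1 from a designated pool after removing
overlapping individuals, and the gene block is tested with the first two
principal components as covariates — the unbalanced-design guard and the
ratio are part of the scan's contract.

## Biological-distance prioritization

With a distance matrix $D$ and a known disease-gene set $B$, a candidate's
proximity is its mean distance to $B$ (self-pairs excluded — the zero
diagonal would deflate means mechanically; candidates already in $B$ stay
eligible). The set-level statistic is the mean of per-candidate means; when
no pairs are missing and the sets are disjoint this equals the flat mean
over all pairs, a property the tests assert. A candidate is retained when
its proximity is *strictly* smaller than the within-set baseline
(`within_set_baseline`, computed with self-pairs excluded).

`resample_empirical_p` draws same-size random gene sets from the pool of
all scanned genes and reports the fraction of draws strictly closer than
the observed set. The plain count/iters convention is the default —
matching a 6-lower-in-1000 reading of 0.006 exactly — with the add-one
variant behind a flag; ties count as not-closer per the strict wording.
The null draws are kept so the 2.5%/97.5% percentile band can be reported.
`fga_cluster` performs average-linkage agglomerative clustering on the
distances (no linkage is named in the sources; average linkage is the
conventional choice for proximity matrices and is recorded here as the
package's own) and quantifies candidate/known intermixing as the average
fraction of each candidate's nearest neighbours that are known genes.

## Pathway-consensus ranking

`intersect_methods` takes per-method prioritized gene sets and returns the
strict intersection plus per-gene hit counts for relaxed k-of-n use.
`importance_score` sums, over all significant pathways or modules
containing a gene (per-method significance cutoffs are supplied per source,
not unified), the number of known disease genes among the members — scores
are additive over methods. `joint_top_fraction` returns genes in the top
fraction (default 10%) of both the importance ranking and the association
ranking; boundary ties are admitted inclusively so no arbitrary ordering
can change the result.

## Rare-variant polygenic risk scores

`harmonize_summary` removes strand-ambiguous (A/T, C/G) variants and flips
effects stated on the reference allele. `shrink_effects` computes posterior
mean effects under a point-normal prior — zero with probability
$1 - p$, otherwise $N(0, h^2/(Mp))$ — by Gibbs sampling over LD windows
estimated from a reference genotype panel, with all prior fractions of the
canonical grid $(1, 0.3, 0.1, 0.03, 0.01, 0.003, 0.001)$ run as parallel
chains through a single sweep. Effects are standardized internally
($\tilde\beta = z/\sqrt{n}$, unit noise variance $1/n$) and the
Rao-Blackwellized posterior mean is averaged after burn-in. At $p = 1$ the
closed-form infinitesimal solution $(R + \frac{M}{h^2 n} I)^{-1}\tilde\beta$
is used; without LD it reduces to $\tilde\beta \cdot h^2 n/(h^2 n + M)$,
the identity the tests verify to 10⁻¹⁰. When no heritability is supplied
it is estimated crudely from the summary chi-squares
($\hat h^2 = M(\overline{\chi^2} - 1)/\bar n$, floored at 10⁻³);
windows default to 50 markers.

`score_individuals` forms $\mathrm{PRS}_i = \sum_m g_{im}\hat\beta_m$ with
missing dosages imputed to twice the allele frequency. `classify` runs a
random forest on the 7 PRS features with stratified, seeded k-fold
cross-validation (500 trees, default depth — fixed so runs are comparable)
and reports per-fold and mean out-of-fold AUC; `idi` implements the
four-mean integrated discrimination improvement.

## The synthetic cohort generator

`sim_spec` + `simulate_study` generate every input under one global seed,
expanded into per-stage child seeds by a documented polynomial hash
(`child_seed`), so artifacts are byte-reproducible and stages stay
decoupled.

* **Populations.** Balding-Nichols: ancestral frequencies
  Uniform(0.05, 0.95), population frequencies
  $\mathrm{Beta}\!\left(p\frac{1-F_{ST}}{F_{ST}}, (1-p)\frac{1-F_{ST}}{F_{ST}}\right)$,
  clipped to [0.01, 0.99]; default $F_{ST} = 0.1$, a deliberately strong
  two-population contrast. Genotypes are Binomial(2, q·p^A + (1−q)·p^B) at
  independent markers.
* **Rare variants.** MAFs log-uniform on [10⁻⁴, 5×10⁻³] so the 0.01
  frequency rule is exercised from below, with a 4% admixture of deliberate
  cutoff-straddlers drawn Uniform(0.011, 0.05). Twelve variants per gene by
  default: after filtering this leaves roughly four to five qualifying
  variants per gene, matching the density of published exome-wide
  qualifying sets (≈64k variants over ≈13.6k genes).
* **Annotations.** Consequence categories (45% missense, 15% other
  whitelisted, 25% synonymous, 15% non-coding), CADD ~ N(18, 6²) truncated
  at 0, per-gene MSC ~ N(15, 4²) with 10% missing, GDI log-normal around 5
  with ≈12% above the 13.34 cutoff, 20% missing reference MAFs (to
  exercise the cohort-frequency fallback) and 2% blacklisted.
* **Phenotypes.** A carrier-level (dominant) logistic model: the intercept
  is solved to hit the target prevalence and each *risk gene carried*
  multiplies the odds by `risk_carrier_or` (a per-allele option exists
  behind a flag). Defaults: 1,500/1,500 target cohort, 5 risk genes,
  carrier odds ratio 3, per-risk-gene carrier frequency calibrated to 10%
  by rescaling the gene's qualifying MAFs. Because the spiked design is
  only coherent if the designed signal can survive the pipeline's own
  guards, each designated risk gene is guaranteed at least 7 qualifying
  variants (non-qualifying ones have their attributes rewritten) and the
  rescaled MAFs are capped at 0.008 — strictly below the 0.01 cohort-MAF
  guard — so the 10% carrier target is attainable without any variant
  being stripped downstream; genes saturating the cap realize the largest
  attainable carrier frequency instead. `risk_carrier_or = 1` produces
  the null cohort used for calibration. The carrier-effect architecture of
  any real cohort is unknown; the dominant choice is a stand-in, not an
  inference.
* **Distances.** Gamma-distributed with mean 5 within the designated core
  set and 15 elsewhere (shape 10), symmetric with zero diagonal — a
  proximate disease-gene core against an exchangeable background.
* **Summary statistics.** Vectorized single-variant score regression
  (U/V effect, 1/√V standard error) on a training split; monomorphic
  variants are flagged with zero effect and infinite SE, perfect
  correlation with the phenotype is flagged as separation.

What the generator does **not** emulate: linkage disequilibrium between
markers (markers are independent; the LD-pruning and PRS-window machinery
is exercised on induced or trivial correlation only), sequencing-level
artifacts (depth/quality fields are synthetic when supplied), sex
chromosomes, relatedness structure beyond deliberately injected duplicates
and constructed parent-offspring pairs, and realistic site-frequency
spectra. Passing tests therefore demonstrate the *statistical contracts* of
each stage — calibration, recovery, oracle equivalence — not performance on
real exomes.

## Validation problem sizes

The package's own validation suites (tests and the reproduction script)
use: null calibration on 2,500 simulated genes (≈2,230 testable blocks,
10,000 bootstrap draws per gene); power over 20 seeds of 1,000-gene
cohorts with the default spike; distance-statistic oracles on 50-gene
matrices with 200-replicate exchangeable-null calibration; ancestry
recovery at 5,000 markers and $F_{ST}=0.1$, with the reference panel's
admixture fractions spread down to ~0.7 below a 0.9 target cluster — the
minimum-reference cutoff can only separate clusters cleanly when the
panel's minimum lies below the cluster it defines (with reference and
candidates drawn from one distribution, each candidate falls below the
reference minimum with probability $1/(n_{\mathrm{ref}}+1)$ regardless of
marker count); and the population-transfer
benchmark on 300-gene cohorts over 10 seeds with a polygenic architecture
of 30 risk genes (a polygenic score's transferability is only measurable
on a trait many genes drive; under an oligogenic spike both scores sit at
the noise floor), 50% population-private qualifying variants and
log-normal frequency jitter SD 0.5 on the rest — rare variants are
predominantly population-private between long-separated populations, and
the benchmark's claim is directional, not a reproduction of any published
AUC. These sizes were chosen as the smallest designs
whose acceptance properties are stable across seeds.

## Known limitations

* The supervised ancestry estimator ignores reference-panel sampling noise;
  with small panels the cutoff inherits that noise.
* The bootstrap tail correction conditions on the fitted null means; its
  refitting correction is first-order, and p-values below the switch point
  remain asymptotic.
* The Gibbs shrinkage uses hard LD windows; long-range LD across window
  boundaries is ignored by construction.
* The phenome scan treats phenotypes independently; no multiplicity
  adjustment across phenotype codes is applied beyond what the caller does.
* Meta-analysis across sub-cohorts and conditional/joint analyses of
  neighbouring association signals are out of scope; per-cohort outputs are
  written in formats suitable for external meta-analysis tools.
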