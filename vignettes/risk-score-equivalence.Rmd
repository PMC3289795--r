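---
title: "Genetic risk scores, Naive Bayes classifiers, and why their classification rules coincide"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic risk scores, Naive Bayes classifiers, and why their classification rules coincide}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grsnbc)
```

## The problem

Given unphased genotypes at $k$ biallelic SNPs $\Sigma = \{S_1,\dots,S_k\}$
and a dichotomous trait $T$, we want a classification score
$Sc(\Sigma) \in \mathbb{R}$ and a rule "$Sc(\Sigma) > \tau \Rightarrow$
classify as $T$". Alleles at each SNP are labelled $(A, B)$ in
lexicographic order ($A < C < G < T$), irrespective of frequency, so the
three genotype states AA, AB, BB are unambiguous. Two families of scores
dominate applied work:

1. **Genetic risk scores (GRS)** summarize the profile as a weighted sum
   $\mathrm{GRS} = \sum_i w_i X_{iAA} + v_i X_{iAB} + z_i X_{iBB}$ and
   calibrate a univariate logistic model
   $\operatorname{logit} p(T \mid \mathrm{GRS}) = \gamma_0 + \gamma_1\,
   \mathrm{GRS}$.
2. **Naive Bayes classifiers (NBC)** score by the posterior probability
   $p(T \mid \Sigma)$ under conditional independence of SNPs given $T$.

This package implements both, the three standard GRS weighting schemes,
and the closed-form threshold mappings under which the corresponding rules
are *identical* — plus a case-control simulator and a nested-model AUC
experiment that demonstrate the identity and its failure modes at genome
scale.

## The three weighting schemes

* **Case 1 (risk-allele counting).** Each SNP's risk allele $R$ is the B
  allele when the additive per-B-copy slope is $\ge 0$, else the A allele.
  Weights are $(w, v, z) = (2\delta(A{=}R),\, 1,\, 2\delta(B{=}R))$, so
  the score is the subject's total count of risk alleles. All effect-size
  information is discarded.
* **Case 2 (additive log-odds-ratio weights).** $w = 0$, $v_i$ = the MLE
  slope of the one-SNP logistic regression on B-allele dosage 0/1/2,
  $z_i = 2 v_i$. `fit_additive()` maximizes the grouped-count likelihood
  (identical to the subject-level one) via iteratively reweighted least
  squares.
* **Case 3 (genotypic log-odds-ratio weights).** $w = 0$; $v_i$ and $z_i$
  are the AB-vs-AA and BB-vs-AA log-odds-ratios of the 2-df genotypic
  model, which for a single SNP have closed form as cross-product ratios
  of the 2×3 count table (`fit_genotypic()`).

## The NBC and the equivalence

With prior $p(T)$ and per-group conditional genotype frequencies
$p(S_i \mid T)$, $p(S_i \mid \mathrm{not}\,T)$, the NBC posterior log-odds
decomposes additively:

$$\operatorname{logit} p(T \mid \Sigma) = \operatorname{logit} p(T) +
\sum_i \log \frac{p(S_i \mid T)}{p(S_i \mid \mathrm{not}\,T)}.$$

Because the conditionals are relative frequencies from the same 2×3 tables
that define the case-3 weights, the per-SNP summand at genotype AB exceeds
the summand at AA by exactly $v_i$, and at BB by exactly $z_i$. Hence

$$\operatorname{logit} p(T \mid \Sigma) = \mathrm{GRS}_{\text{case 3}} +
\Big(\operatorname{logit} p(T) + \sum_i \mathrm{llr}_i(\mathrm{AA})\Big),$$

an *exact affine identity* (slope 1), which `verify_equivalence()` checks
to a sup-norm residual below 1e-10. Three consequences, each implemented
and tested:

* **Intercept irrelevance.** Scores differing only by intercept give
  label-identical rules at threshold $\tau + \beta_0 - \alpha_0$
  (`shift_threshold_intercept()`). Useful because case-control intercepts
  are biased for the population odds anyway.
* **Slope irrelevance.** Calibrations $(\gamma_0,\gamma_1)$ vs
  $(\beta_0,\beta_1)$ of the same GRS give label-identical rules at
  $\beta_0 + \beta_1(\tau-\gamma_0)/\gamma_1$
  (`shift_threshold_slope()`), assuming same-sign slopes (a sign flip
  reverses the rule's orientation; the function warns rather than
  silently inverting).
* **GRS/NBC rule equivalence.** The NBC rule at loss ratio $\lambda$
  ("classify as $T$ iff posterior $> \lambda/(1+\lambda)$") equals the
  calibrated case-3 GRS rule at
  $\tau = \gamma_0 - \gamma_1 \sum_i \ell_i(\mathrm{AA}) +
  \gamma_1 \log\lambda$, where $\ell_i(\mathrm{AA})$ is the per-SNP AA
  posterior log-odds (`nbc_to_grs_threshold()`). Since AUC is invariant
  under strictly increasing transforms, the two scores also have exactly
  equal AUC.

### The prior and the decomposition

The per-SNP-log-odds form of the decomposition absorbs the prior once per
SNP, while the joint posterior absorbs it once; the two agree exactly when
$p(T) = 0.5$. The package therefore defaults to `prior_T = 0.5` — the
natural choice for case-control data, where the prior is not estimable and
only moves the threshold — and the $\tau \leftrightarrow \lambda$ mapping
is exact there. For any other prior the *ranking* of subjects (hence AUC)
is unchanged; only the constant in the mapping differs. This is tested as
a rank-invariance property across priors 0.1/0.5/0.9.

## Numerical choices

* **Smoothing.** A single Haldane–Anscombe-style rule shared by
  `fit_genotypic()` and `fit_nbc()`: the pseudo-count (default 0.5) is
  added to *every* cell of a SNP's 2×3 table *iff* some cell is zero.
  Adding it only when needed leaves clean tables exactly at their MLE;
  adding it to all six cells (not just the zero one) keeps the smoothed
  table a single shared object, so the affine identity — and with it the
  rule equivalence — survives smoothing bit-exactly.
* **Log space everywhere.** NBC products over hundreds of thousands of
  SNPs underflow in linear space; all scores are accumulated as sums of
  log-likelihood-ratios and converted with `plogis()`/`qlogis()`.
* **Separation.** `fit_additive()` and `calibrate()` detect perfect
  separation (exploding standard errors / unbounded estimates) and return
  an infinite-magnitude sentinel with a warning instead of a quietly
  absurd finite number.
* **Tie-breaking.** `rank_snps()` sorts by evidence, ties broken by
  SNP id, so ranking is a deterministic function of the count tables and
  invariant to input order. The evidence reported by the default method is
  the log posterior odds of association (BIC approximation, equal prior
  odds) rather than the posterior probability itself: the probability
  saturates to 1.0 in double precision for strong SNPs, which would
  surrender the ordering of exactly the SNPs that matter to the id
  tie-break. The log-odds is a strictly monotone transform of it, so the
  contract (ordering) is unchanged; the probability is still reported in a
  `posterior` column.
* **Classification boundary.** All rules use a strict `>`; e.g. at
  $\lambda = 3$ a posterior of exactly 0.75 is classified as not-$T$.

## The simulator: the stated world

`simulation_design()` defaults encode the reference experiment: 3000
cases / 3000 controls per split, causal SNPs at every combination of OR
$\in \{1.2,\dots,1.6\}$, MAF $\in \{0.1,\dots,0.5\}$ and
additive/recessive/dominant inheritance (75 SNPs), 500,000 null SNPs with
MAF $\sim U(0.05, 0.5)$, five replicates, each with an independent
discovery and replication set. Controls follow Hardy–Weinberg triples
$[p^2, 2p(1-p), (1-p)^2]$; case triples apply the mode's odds tilt and
renormalize:
additive $[p^2,\, 2\,\mathrm{OR}\,p(1-p),\, \mathrm{OR}^2(1-p)^2]$,
recessive $[p^2,\, 2p(1-p),\, \mathrm{OR}(1-p)^2]$,
dominant $[p^2,\, 2\,\mathrm{OR}\,p(1-p),\, \mathrm{OR}(1-p)^2]$.

Two deliberate readings of that parameterization:

* **The tilt sits on the major-allele homozygote.** Taken literally, the
  OR multiplies the $(1-p)^2$ genotype, i.e. the *major* allele is the
  risk allele even though $p$ is called the minor-allele frequency. We
  implement the formulas as printed; `risk_on_minor = TRUE` transposes
  the tilt for users who want the other convention. Cross-product odds
  ratios — and therefore every AUC — are identical under either choice.
* **Null MAFs are drawn once per replicate** and shared by that
  replicate's discovery and replication splits (the splits are samples
  from one population), but redrawn across replicates.

Reproducibility is by per-(replicate, split, SNP) substreams expanded from
the root seed. A useful consequence: simulating a *subset* of SNPs yields
bit-identical columns to the full panel, which is what lets
`run_experiment()` rank half a million SNPs on simulated *count tables*
(the sufficient statistic — distributionally identical to tabulating
subjects, via a vectorized binomial chain) and then materialize
subject-level genotypes only for the top-ranked SNPs. This is exact, not
an approximation, because SNPs are independent given case/control status.

What the generator does **not** emulate: linkage disequilibrium (SNPs are
independent), population structure, genotyping error or missingness
patterns, and prevalence-based sampling (subjects are drawn by outcome
group). A green test therefore establishes the algebraic and statistical
claims under independence; it says nothing about LD-induced redundancy of
ranked SNPs in real panels.

## The nested-model experiment

Per replicate: rank all SNPs by genotypic-association evidence on the
discovery counts; for increasing $k$, estimate weights and conditionals on
the discovery counts of the top-$k$ SNPs; score the replication subjects;
record the AUC; average curves across replicates (mean of AUCs, not AUC of
pooled scores). The default $k$ grid steps by 1 through the causal range
and by 5 for 30 SNPs beyond — fine enough to localize the curve maximum.
AUC is computed on raw scores: calibration is strictly increasing and
cannot change it.

Expected shape, which the acceptance tests assert: NBC and case-3 curves
are *pointwise identical*; all curves rise while true positives enter and
decline once false positives dominate; the decline is steepest for the
unweighted case-1 score, whose fixed $\pm$1/2 weights give a false
positive the same votes as a true strong SNP.

One subtlety the scaled-down experiment exposes: "additive weights lose
accuracy on non-additive SNPs" is a statement about *peak* accuracy. Deep
in the ranked list (e.g. $k = 75$ when many weak causal SNPs rank below
the null floor), the two-parameter genotypic weights carry roughly twice
the estimation variance of the additive ones, which can offset the
additivity bias — a plain bias–variance trade-off. The acceptance check
for the additivity loss is therefore made at the genotypic curve's
maximum, the causal-saturated point; with a large discovery set
(near-true weights) the genotypic score dominates at every depth.

## Known limitations

* No covariate adjustment, LD modelling, phasing, multi-allelic sites,
  X-chromosome handling, or quantitative traits.
* The additive-constrained NBC (estimating conditionals under an additive
  model) is not implemented; the exact rule equivalence is certified for
  the genotypic (case 3) pairing, and for case 2 only the breakdown on
  non-additive data is demonstrated.
* The ranking statistic is a BIC surrogate for a fully Bayesian
  association score; near the noise floor a different monotone evidence
  would admit different SNPs into the nested models, shifting the curve
  maximum by a few SNPs.
* Missing genotypes simply drop their per-SNP summand from both GRS and
  NBC scores (marginal neutrality). This keeps the two treatments
  symmetric — the equivalence survives missingness — but is a repository
  decision; informative missingness is out of scope.
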