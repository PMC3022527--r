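---
title: "Synthetic associations: models, simulators and power methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthetic associations: models, simulators and power methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synthassoc)
```

## The problem

A *synthetic association* is an association signal at a common SNP that is not
caused by a common causal allele but by the aggregate effect of one or more
low-frequency (1–5% MAF), higher-penetrance causal variants that happen to
reside preferentially on one allele's haplotype background. The canonical
example is the NOD2 region in Crohn's disease: three low-frequency coding
variants (MAFs 0.04, 0.01, 0.02; carrier and homozygote odds ratios of about
3 and 38) are absent from genotyping arrays and poorly tagged individually,
yet jointly distort the case/control frequencies of nearby common SNPs enough
to create genome-wide-significant signals there. The diagnostic signature is
*ablation*: once carrier status for the rare cluster enters the regression,
the common-SNP signal collapses.

This package provides the three quantitative tools needed to study the
phenomenon:

1. closed-form single-locus genetics (genotype frequencies, penetrance
   calibration, familial relative risks, affected-sib-pair IBD sharing);
2. an exact haplotype-pool simulator that reproduces the mechanism and
   samples ascertained case-control and affected-sib-pair (ASP) cohorts;
3. association scans with and without carrier conditioning, and analytic plus
   Monte-Carlo power comparisons of ASP linkage versus case-control GWAS.

## The locus model

A locus carries $N \ge 0$ risk variants. Variant $i$ has risk-allele
frequency $p_i \le 0.5$ and genotype relative risks $(\gamma_{1i},
\gamma_{2i})$ for heterozygotes and homozygotes versus non-carriers; the
default within-variant model is multiplicative, $\gamma_{2} = \gamma_1^2$,
but the pair can be set freely (the NOD2 carrier/homozygote pattern of 3/38
is far from multiplicative). Penetrance is
$f(g) = \min\!\big(1,\; f_0 \prod_i \gamma_i(g_i)\big)$ on a baseline $f_0$
for carriers of zero risk alleles, with variants combined multiplicatively
and assumed in linkage equilibrium. The clamp at 1 is reachable only for
multi-variant homozygote combinations whose population frequency is
astronomically small (below $10^{-10}$ for every model used here); it exists
so that extreme user-chosen models remain well defined.

The disease prevalence $K$, the compound-carrier frequency
$1 - \prod_i (1-p_i)^2$, and the familial relative risks all follow in
closed form. For a single variant with penetrance triple $(f_0, f_1, f_2)$
and frequency $p$ ($q = 1-p$), the additive and dominance variance
components are

$$V_A = 2pq\,[\,p(f_2 - f_1) + q(f_1 - f_0)\,]^2, \qquad
  V_D = (pq)^2 (f_2 - 2f_1 + f_0)^2,$$

giving offspring, monozygotic-twin and sibling relative risks

$$\lambda_o = 1 + \frac{V_A/2}{K^2}, \qquad
  \lambda_m = 1 + \frac{V_A + V_D}{K^2}, \qquad
  \lambda_s = 1 + \frac{V_A/2 + V_D/4}{K^2}.$$

These ratios are invariant to the penetrance scale, so $f_0$ cancels from
the per-variant $\lambda$s (it still sets $K$ and the sampling model).

**Combining fully linked variants.** For several variants at one locus with
no recombination between them, we condition on the sib pair's
shared-haplotype count (prior $\tfrac14, \tfrac12, \tfrac14$). Given the
shared state, per-variant recurrence ratios multiply under linkage
equilibrium and multiplicative penetrance, so

$$\lambda_o^{(L)} = \prod_i \lambda_{oi}, \qquad
  \lambda_m^{(L)} = \prod_i \lambda_{mi}, \qquad
  \lambda_s^{(L)} = \frac{\lambda_m^{(L)} + 2\lambda_o^{(L)} + 1}{4}.$$

With $N = 1$ this reduces exactly to the single-variant formula. We verified
the combination against exact enumeration of all parental haplotype
configurations at $N = 2$ (agreement to seven digits) and against Monte-Carlo
ASP simulation on the full model grid; the unit tests keep both checks.

**Calibration from printed odds ratios.** Published effect sizes are odds
ratios, and "carrier" pools heterozygotes and homozygotes. Given target
carrier and homozygote ORs, `calibrate_relative_risks()` inverts the odds
transform through the full penetrance table (no rare-disease approximation):
the homozygote penetrance comes directly from its OR, the carrier-average
penetrance from its OR, and the heterozygote penetrance by de-mixing with
Hardy–Weinberg weights. The solution is exact, and infeasible targets
(implied penetrance outside $(0,1)$) are an error. Note a consequence that
surprises at first sight: even as $f_0 \to 0$ the returned `grr_het` for
targets (3, 38) is slightly below 3, because the carrier OR is a
het/hom mixture.

**Baseline penetrance.** The disease prevalence behind the NOD2 numbers is
not part of the published model, so $f_0$ is a free parameter, default 0.01.
All closed-form identities are checked across $f_0 \in \{0.001, 0.01,
0.05\}$ in the tests.

## The haplotype pool

`build_pool()` constructs a finite set of haplotype *classes* over
`n_common` common SNPs plus one site per risk variant, with exact class
frequencies — the pool is a population distribution, not a sample, so every
configured allele frequency is reproduced to machine precision.

Because the simulated region is a single locus, there is no recombination
within it. A non-recombining region evolving under the infinite-sites model
has a genealogy in which every derived allele is carried by exactly one
clade: allele sets are nested or disjoint (the four-gamete condition). The
generator therefore builds the pool by successive carving: common-SNP
frequencies are drawn uniformly from `common_freq_range`, sorted in
descending order, and each derived allele is carved as a single piece of
exactly its target frequency out of one existing class (chosen with
probability proportional to class frequency among classes large enough to
host it). This produces genealogically consistent linkage disequilibrium —
strong but not degenerate; for 20 SNPs the effective number of independent
tests in a scan is roughly 5–10 rather than 20.

Rare causal alleles are placed the same way, after the common SNPs: each
rides exactly one common-SNP background class (a single mutational origin —
the mechanism that makes synthetic associations possible), carved so that
its marginal frequency equals the variant MAF exactly. Placement draws the
host proportional to frequency among *feasible* backgrounds (frequency at
least the MAF, not already carrying another rare allele); if no background
can host the variant the generator raises an infeasible-placement error
rather than silently distorting frequencies.

For a rare allele of frequency $p_r$ nested inside a background of frequency
$p_c$, the tag correlation is $r^2 = p_r(1-p_c)\,/\,p_c(1-p_r)$ — small for
any individually rare variant, which is why none of the causal variants is
well tagged even though the cluster jointly shifts tag frequencies.

`split_two_populations()` models population restriction of low-frequency
variation: population B shares the common SNPs, optionally loses all rare
causal alleles (`privacy = TRUE`, frequency exactly zero), and its class
frequencies can be perturbed by log-normal reweighting of magnitude
`divergence_noise`. Reweighting classes, rather than site marginals, keeps
the perturbation internally consistent (site frequencies are coupled through
the shared classes) and reduces to the identity at zero noise.

## Ascertained cohorts by exact conditional sampling

Both samplers avoid rejection sampling entirely. An individual is two
haplotypes drawn independently from the pool, and the case distribution is
$P(h_1, h_2 \mid \text{case}) \propto P(h_1)P(h_2) f(g)$ — a discrete
distribution over class pairs that can be enumerated and sampled directly.
This is the same distribution a rejection sampler converges to, with
deterministic runtime; for affected sib pairs, where
$P(\text{both affected}) \approx K^2\lambda_s \sim 10^{-4}$, rejection would
be infeasible at the $10^5$-pair scales used for Monte-Carlo oracles.

`sample_asp_pairs()` exploits a factorisation: given the four Mendelian
transmission choices (16 patterns), the double-affection weight is a product
over variants of terms involving only that variant's four parental alleles.
The transmission pattern — and hence the true IBD state — is drawn from its
exact conditional distribution, then per-variant parental alleles are drawn
conditionally, all under the model's linkage-equilibrium assumption that
also underlies the $\lambda$ formulas. Common-SNP backgrounds are filled in
from the pool conditional on each haplotype's rare content; penetrance does
not depend on them, so the decoration cannot bias the ascertainment. A
haplotype carrying several rare alleles (absent from the single-origin pool;
about 0.4% of haplotypes at $N = 9$, $p = 0.01$) takes the background of one
of its variants at random — this affects only the cosmetic common-SNP
decoration of ASP cohorts, never IBD or affection.

The two samplers deliberately differ in the rare-variant haplotype
structure. Case-control cohorts use the single-origin pool as-is, where
distinct rare alleles never co-occur on one haplotype: that mutual
exclusivity is part of the mechanism under study, and the expected
case/control tag frequencies (`expected_site_frequencies()`, by Bayes
inversion over the exact pair distribution) are computed from the same pool,
so the GWAS-side analytics and simulations agree with each other. ASP
cohorts sample rare content under linkage equilibrium, matching the
variance-components analytics; with mutual exclusivity instead, the mean
sharing at $N = 9$, OR 3 would drop from 0.583 to about 0.554 — a reminder
that "independent risk alleles" is a modelling idealisation that a literal
single-origin haplotype structure does not satisfy.

## Association scans and the ablation analysis

The per-SNP scan statistic is the likelihood-ratio test of the allele-dosage
term in a logistic regression (IRLS, convergence tolerance $10^{-8}$, at
most 50 iterations). Complete or quasi-complete separation is flagged
(`converged = FALSE`, P set to `NA`) rather than raised; monomorphic sites
are flagged not-testable. The Cochran–Armitage trend test (scores 0/1/2,
computed via `stats::prop.trend.test`) is provided as a fast, asymptotically
equivalent alternative and is used inside the Monte-Carlo power loops.

`conditional_scan()` runs every common site twice — without covariates and
with rare-variant carrier conditioning — mirroring the diagnostic analysis.
The default conditioning covariate is the single *compound-carrier*
indicator (at least one alternate allele across the listed rare sites); a
per-site indicator mode is also available. Two properties deserve emphasis:

* **Multiplicity.** The minimum P over a region of $m$ correlated sites is
  not uniform; under perfect ablation its median is about
  $1 - 0.5^{1/m_{\mathrm{eff}}}$. Any criterion phrased as "conditional
  minimum P exceeds a threshold" inherits this floor.
* **Carrier status is a coarsening.** When homozygotes carry much higher
  risk than heterozygotes (the 3-vs-38 OR pattern), a binary carrier
  indicator does not capture the full causal genotype, and a genuine
  residual dosage signal survives conditioning. The ablation is therefore
  dramatic (typically five or more orders of magnitude at the top SNP) but
  not literally complete; conditioning on the full rare dosages removes the
  residual entirely. Both behaviours are quantified in the test suite.

The contrast experiment — a truly common causal variant plus null rare
variants — shows the converse signature: conditioning on rare sites leaves
the common signal essentially unchanged (within one log10 unit), which is
how conditional analysis discriminates synthetic from ordinary common-variant
associations.

## Linkage versus GWAS power

For affected sib pairs, the familial risks map to IBD-state probabilities

$$z_0 = \frac{1/4}{\lambda_s}, \quad
  z_1 = \frac{(1/2)\,\lambda_o}{\lambda_s}, \quad
  z_2 = \frac{(1/4)\,\lambda_m}{\lambda_s}, \qquad
  Y = z_2 + z_1/2,$$

and the linkage test is the one-sided mean-sharing test at a fully
informative marker: per-pair sharing proportion with null variance $1/8$,
alternative mean $Y$ and variance $z_1/4 + z_2 - Y^2$, normal approximation:

$$\text{power} = \Phi\!\left(\frac{(Y - \tfrac12)\sqrt{n} -
  z_{1-\alpha}\,\sigma_0}{\sigma_{\mathrm{alt}}}\right).$$

The full LOD-score machinery is out of scope; the mean test is the standard
analytic vehicle for ASP power and is what the Monte-Carlo check
(`asp_mean_test()` over simulated cohorts) implements as well.

GWAS power comes in two forms. The analytic form is the two-sided 1-df
trend-test power from the noncentrality implied by case/control allele
frequencies at a *single* tag SNP (case frequency from the allelic OR via
the odds transform). The empirical form (`gwas_power_empirical()`) simulates
whole ascertained cohorts and declares a hit when the minimum trend-test P
over all common SNPs in the region falls below `alpha` — how a GWAS region
is actually declared — or, with `site = "best_tag"`, tests only the single
common SNP with the largest expected induced OR so that it estimates exactly
what the analytic formula computes. `power_curve()` assembles the
linkage/GWAS comparison over a grid of per-allele ORs and variant counts
(risk-allele frequency 0.01 by default; 2,658 sib pairs at
$\alpha = 10^{-4}$ versus 3,000 cases and 3,000 controls by default, with
2,000 against 2,000 or 3,000 equally valid configurations), and reports the
smallest OR at which linkage power reaches empirical GWAS power. The
genome-wide GWAS threshold defaults to $5\times10^{-8}$ and is exposed as a
parameter, since the appropriate region-wise threshold depends on context.
The qualitative outcome — linkage overtakes GWAS when individual ORs reach
about 3 or when many independent risk alleles act — is reproduced by the
shipped `fig3` preset.

## Numerical and reproducibility choices

* **RNG contract.** One root seed per run; every stage derives a child seed
  from the root and a fixed text label, so adding a stage never perturbs the
  streams of existing stages. Identical configuration and seed reproduce
  every output file byte-identically (the VCF writer uses binary-mode
  connections with fixed newlines, and manifests contain no timestamps).
* **Exactness.** Pool frequencies are exact by construction (validated to
  $10^{-9}$); the $\lambda$ identities are tested against enumeration at
  $10^{-10}$; calibration reproduces its OR targets at $10^{-10}$.
* **Problem sizes.** The test suite uses 2,000 null cohorts of 500+500 for
  calibration, 200 replicates of 2,000 cases/3,000 controls for the ablation
  experiment, $10^5$ sib pairs for sharing oracles and 2,000 replicates for
  power agreement — sizes at which binomial Monte-Carlo error is small
  enough for 3-SE comparisons while the whole suite stays in the
  couple-of-minutes range on one CPU.
* **Ties and degeneracies.** Monomorphic sites, empty variant lists, zero
  acceptance mass, rank-deficient designs and infeasible placements are all
  explicit, tested error or flag paths.

## What the generator does and does not emulate

The pool reproduces the features the synthetic-association argument needs:
common SNPs in genealogically consistent LD, rare causal alleles on single
haplotype backgrounds, multiplicative penetrance, case/control and ASP
ascertainment, and population-private rare variation. It deliberately omits
recombination and gene conversion, recurrent mutation, mutation-rate and
demographic realism (no coalescent machinery), genotyping error and
imputation. Consequently, passing tests show that the *methods* behave
correctly under the stated model; they do not show that real regions have
this LD structure, and quantitative power values transfer to real data only
to the extent that the induced tag OR and the effective number of tests do.
The region's LD here does not decay with distance (no recombination), so
"region length" is bookkeeping, not a population-genetic parameter.

## Known limitations

* The per-variant calibration applies the printed carrier/homozygote OR pair
  to each variant separately and combines variants multiplicatively; the
  original report quotes locus-level ORs, so compound heterozygotes here
  carry the product of two heterozygote risks rather than the homozygote OR.
* Carrier conditioning leaves a true residual signal under strongly
  non-multiplicative within-variant models (see above); full ablation in the
  strict sense requires conditioning on dosages.
* The linkage test assumes a fully informative marker and the normal
  approximation; exact small-sample linkage tests are not provided.
* Analytic GWAS power assumes Hardy–Weinberg allele independence within
  cases, which holds for multiplicative models but only approximately
  otherwise.
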