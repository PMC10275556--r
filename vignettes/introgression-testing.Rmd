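---
title: "Testing cross-species introgression: models, estimators and design choices"
author: "msciTools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing cross-species introgression: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msciTools)
```

## The model

`msciTools` works with the multispecies coalescent with introgression
(MSci).  A *species network* is an ultrametric species tree — node ages
$\tau$ measured backward from the present in expected substitutions per
site — with a population-size parameter $\theta = 4N\mu$ (same units)
attached to every branch, plus a set of horizontal *hybrid edges*.  Traced
backward in time, lineages inside a population coalesce in pairs at rate
$2/\theta$; when a lineage on the recipient branch of a hybrid edge reaches
the edge's time, it switches to the donor branch with probability
$\varphi$, the introgression probability.  At speciation nodes, lineages
merge into the ancestral population.  Gene trees drawn from this process
vary across loci; sequences evolve along each gene tree under Jukes–Cantor
(JC69), sites independent, root state uniform.

Two families of tests for $H_0{:}\ \varphi = 0$ are implemented.

**Quartet site-pattern tests.**  For a quartet ordered (O, P1, H, P2) —
outgroup, first parent, putative hybrid, second parent — the three
parsimony-informative column patterns are $iijj$ (O=P1 $\ne$ H=P2),
$ijij$ (O=H $\ne$ P1=P2) and $ijji$ (O=P2 $\ne$ P1=H).  Under the symmetric
hybrid-speciation model, gene trees are a $\varphi : (1-\varphi)$ mixture
over the two parental trees, which gives

$$p_{iijj} = \varphi a + (1-\varphi) b,\qquad
  p_{ijij} = b,\qquad
  p_{ijji} = \varphi b + (1-\varphi) a,$$

with $a$ the matching- and $b < a$ the mismatching-class probability under
either parental tree.  Eliminating $a$ and $b$ yields the estimator

$$\hat\varphi =
  \frac{\hat p_{iijj} - \hat p_{ijij}}
       {\hat p_{iijj} - 2\hat p_{ijij} + \hat p_{ijji}},$$

implemented in `hyde_phi()`; `hyde_test()` tests $\varphi > 0$ and
`d_statistic()` computes the ABBA–BABA statistic
$D = (n_{ABBA}-n_{BABA})/(n_{ABBA}+n_{BABA})$ with a delete-one-locus
jackknife standard error.  The mixture derivation requires gene flow *into*
the hybrid position from a nonsister lineage, with symmetric parental
divergence times and population sizes ($\tau_S=\tau_T$,
$\theta_S=\theta_T$); `check_hyde_assumptions()` audits a network against
these conditions and also reports the coalescent rate–time products
$2(\tau_R-\tau_S)/\theta_S$ and $2(\tau_R-\tau_T)/\theta_T$ — equal
products equalize the *probability* of parental-side coalescence but not
its timing, so both $\tau$ and $\theta$ symmetry are needed separately.

**Savage–Dickey Bayes factors.**  The MSci model with $\varphi = 0$ is
nested in the model with $\varphi$ free, and with agreeing priors on the
shared parameters the Bayes factor equals the prior-to-posterior density
ratio at the null value, $B_{10} = \pi(0)/\pi(0\mid x)$, computable from a
posterior MCMC sample of $\varphi$ alone.  `bf_savage_dickey_kde()`
estimates the posterior ordinate with a Gaussian kernel,
$h = 0.9\,\min(\mathrm{SD}, \mathrm{IQR}/1.34)\,N^{-1/5}$, and
`bf_null_region()` uses the more robust null-region odds

$$B_{10,\varepsilon} =
  \frac{[1-P(R\mid x)]/P(R\mid x)}{[1-P(R)]/P(R)},
  \qquad R:\ \varphi < \varepsilon,$$

which converges to the density ratio as $\varepsilon \to 0$ and avoids
density estimation at the boundary.  $B_{10} \ge 20$ is treated as strong
and $\ge 100$ as extremely strong evidence (posterior model probabilities
0.95 and 0.99 at even prior odds).

## The conjugate-normal validation example

Because the MSci posterior is expensive, the Bayes-factor machinery is
validated on a model where everything is closed-form: test
$H_0{:}\ \mu=0$ from a sample of size $n$ from $N(\mu, 1)$ with prior
$\mu \sim N(0, \sigma_0^2)$.  The posterior is
$N\!\big(n\bar x/(n + 1/\sigma_0^2),\ 1/(n + 1/\sigma_0^2)\big)$ and

$$B_{10} = (1+n\sigma_0^2)^{-1/2}
  \exp\!\Big\{\tfrac{n\bar x^2}{2[1+1/(n\sigma_0^2)]}\Big\}.$$

Data enter only through the standardized mean $z=\sqrt n\,|\bar x|$: the
likelihood-ratio statistic $n\bar x^2$ equals $z^2$, which is what makes
the familiar 3.84 cutoff apply; `msciTools` adopts this parameterization
throughout.  On the $n\bar x^2$ scale the three decision rules order as

$$\chi^2_{1,\alpha} \;<\; \chi^2_{1,\alpha}\big[1+\tfrac1{n\sigma_0^2}\big]
  \;<\; 2\big[1+\tfrac1{n\sigma_0^2}\big]\log\{19\sqrt{1+n\sigma_0^2}\},$$

so the rejection regions nest: Bayes factor $\subseteq$ posterior CI
$\subseteq$ LRT.  The LRT is most powerful and most false-positive-prone;
the Bayes-factor rule is the most conservative, and with diffuse priors
(large $\sigma_0$) the two philosophies can disagree outright — data the
LRT rejects at 1% while $B_{10} < 1$ favors the null:

```{r}
normal_example(n = 100, xbar = 0.258, sigma0 = 2)
```

`sample_posterior()` draws from the exact posterior so that the
KDE and null-region estimators can be checked against the closed form;
the test suite requires agreement within Monte-Carlo error at
$N = 10^6$ draws.

## The simulator and its defaults

`simulate_gene_tree()` implements the backward-time process directly:
branches are partitioned into segments at hybrid-edge attachment times,
exponential waiting times drive coalescence within each segment, and edge
crossings are independent Bernoulli($\varphi$) draws that are logged per
lineage (`hybrid_log()`), so that realized edge-usage frequencies can be
compared with $\varphi$.  `simulate_alignment()` adds JC69 sequences;
`simulate_dataset()` derives one seed per locus from the master seed, so a
dataset is reproducible from `(seed, network, samples, L, n_sites)`
regardless of evaluation order.  Simultaneous distinct events are rejected
at validation, with one deliberate exception described below.

The four built-in templates in `template_network()` represent the modes of
gene flow that matter for the quartet tests: `sister-flow` (donor and
recipient are sisters; two sequences are sampled from the recipient so a
quartet can be formed at all), `outflow` (the recipient is P2, not H),
`inflow-asym` (inflow, but asymmetric divergence times) and `inflow-sym`
(the hybrid-speciation model — the only template satisfying the
site-pattern test's assumptions).  The numeric defaults were fixed once at
values realistic for a shallow mammalian radiation studied with
genome-scale data: $\tau_{QR} = 4.17\times10^{-4}$,
$\tau_{QRD} = 7\times10^{-4}$, sister divergence $2.9\times10^{-3}$, root
$5\times10^{-3}$, introgression times $3.37\times10^{-4}$ (ingroup) and
$8.96\times10^{-4}$ (sister), $\theta = 2\times10^{-3}$ for every
population, and default $\varphi$ of 0.625 (sister) and 0.106 (others) —
the magnitudes of posterior estimates reported for such data.  Sequence
length defaults to 500 sites and experiments use $L \in \{500, 2000,
8000\}$ loci.

The `inflow-sym` template places the hybrid edge exactly at the hybrid's
divergence time from P1 ($\tau_{\mathrm{edge}} = \tau_{QR}$).  This is the
hybrid-speciation limit, and it requires relaxing the "strictly inside the
branch" rule on the recipient side: the edge time may equal the recipient
branch's parent age, and at a tied time the Bernoulli rerouting is applied
*before* the speciation merge.  This ordering is exactly the hybrid-origin
model (each hybrid lineage picks one of two parents at the divergence
time) and is the only tie permitted by validation.

**What the generator does and does not emulate.**  Loci are independent
and recombination-free; there is no rate variation across sites or loci,
no base-composition bias (JC69), no missing data, and no sequencing error.
Passing tests therefore demonstrate correctness of the coalescent and
mutation processes and the estimators' behavior under those processes —
not robustness to alignment error, rate heterogeneity or intra-locus
recombination in real data.  Diploid unphased output (`diploidize()`, with
two-state IUPAC codes and the 0.5/0.5 scoring split in `classify_site()`)
is available for exercising heterozygote handling, but the simulation
studies use haploid sequences.

## Numerical and statistical choices

* **HYDE standard error.**  With per-locus subtotals available,
  `hyde_test()` standardizes the contrast
  $\hat p_{iijj} - \hat p_{ijij}$ by a delete-one-locus jackknife.  Sites
  within a locus share one genealogy, so pooled counts are overdispersed
  relative to a multinomial; in calibration runs under the
  `inflow-sym` null the iid-multinomial delta-method z rejected 15% of
  replicates at the 5% level, while the jackknife z is nominal.  For plain
  pooled count vectors (no locus structure) the multinomial delta method
  on $\hat\varphi$ is used, and it is calibrated in that iid setting; when
  $\hat\varphi$ is invalid the z falls back to the raw count contrast
  $(n_{iijj}-n_{ijij})/\sqrt{n_{iijj}+n_{ijij}}$.
* **Invalid estimates.**  $\hat\varphi \notin (0,1)$, including a zero
  denominator, is reported as invalid, excluded from mean/SD summaries and
  tallied as a proportion — an informative diagnostic in its own right
  (under sister-lineage flow roughly half of all replicates are invalid).
* **D-statistic orientation.**  Counts are read with
  $(P1, P2, P3, O) = (P1, H, P2, O)$, under which ABBA is the $iijj$ class
  and BABA the $ijij$ class of the (O, P1, H, P2) ordering; the sign of
  $D$ is reproducible from this convention.
* **Null-region default.**  $\varepsilon = 0.01$, with the expectation
  (checked in tests) that $\varepsilon = 0.001$ gives very similar values
  for smooth posteriors.  When no posterior sample falls below
  $\varepsilon$, $B_{10} = \infty$ is reported together with a finite
  lower bound obtained by substituting $P(R\mid x) = 1/(N+1)$.
* **KDE boundary.**  For parameters supported on $[0,1]$ the kernel
  estimate at 0 uses reflection (samples mirrored across the boundary);
  for the unbounded normal example no reflection is applied.  Reflection
  is a choice: other boundary kernels exist, and the null-region estimator
  is the default precisely because it sidesteps the issue.
* **Heterozygotes and missing symbols.**  Two-state IUPAC codes split
  0.5/0.5 over their resolutions, recursively across positions; gaps, `N`
  and three/four-state codes make the site unscorable for that quartet
  combination and are tallied separately rather than guessed.
* **Ties and degeneracies.**  Two hybrid edges may not share a time; a
  hybrid time may not coincide with an unrelated node age; zero-spread
  traces are rejected by the bandwidth rule rather than silently producing
  $h = 0$.
* **Tolerances.**  Network symmetry checks (`check_hyde_assumptions()`)
  default to a relative $10^{-9}$, appropriate for exactly specified
  models; supply a looser tolerance for networks carrying estimated
  parameters.

## Problem sizes in the test suite

The packaged tests run reduced-scale versions of the simulation studies,
sized so the full suite completes in minutes while keeping Monte-Carlo
error well inside the asserted bounds: 80 replicates at $L = 2000$ for the
sister-flow study, 60 null and 40 power replicates (at $L = 500$, 2000,
8000) for the hybrid-speciation study, and $1.5\times10^4$–$2\times10^4$
genealogies for the coalescent oracles.  All bounds are stated as three
binomial/Monte-Carlo standard errors of the quantity being estimated, so
they scale correctly with the chosen sizes.

## Known limitations

* The full MSci likelihood and posterior sampling over species networks
  are out of scope; Bayes factors are computed *from* MCMC traces produced
  elsewhere.
* Continuous migration (isolation-with-migration) is not modeled; gene
  flow is pulse-like through hybrid edges.
* `check_hyde_assumptions()` audits networks with a single hybrid edge;
  multi-edge networks must be audited edge by edge.
* The quartet tests inherit the intrinsic limits of pooled site-pattern
  counts: gene flow between sister lineages is undetectable in
  expectation, and outflow yields little power — the simulation templates
  exist to demonstrate exactly this.
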