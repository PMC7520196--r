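---
title: "Noninvasive genetic monitoring: from replicated genotypes to abundance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Noninvasive genetic monitoring: from replicated genotypes to abundance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haremark)
```

## The problem

Noninvasive genetic (NiG) monitoring estimates the abundance and
demography of elusive animals from genotypes amplified out of field-collected
remnants — here, fecal pellets of alpine hares sampled twice a year
(spring mating season, fall post-reproduction) over multiple years. Fecal
DNA is degraded, so microsatellite genotyping is noisy: alleles of
heterozygotes drop out, spurious "false alleles" appear, whole PCRs fail,
and the male-specific sex marker can silently fail in males. Uncorrected,
these errors fabricate genotypes that look like additional animals
("ghosts") and inflate abundance estimates.

`haremark` implements the complete analysis chain for such a study:

1. **Consensus genotyping** from a multi-tube design (three PCR replicates
   per sample) with strict acceptance rules, sex calling from a dominant
   Y-linked marker, and error-rate quantification.
2. **Individual identification** by mismatch-tolerant clustering of
   accepted multilocus genotypes.
3. **Population-genetic summaries** of the marker panel (heterozygosity,
   PIC, probabilities of identity, Hardy–Weinberg tests).
4. **Robust-design capture–mark–recapture (CMR) with misidentification**:
   maximum-likelihood estimation of survival, temporary emigration,
   capture/recapture rates, the correct-identification probability
   $\alpha$, and the undetected count $f_0$; AICc ranking, model
   averaging, and derived abundance, density and sex ratio.
5. **Species assignment** of monitored genotypes against a labeled tissue
   reference panel by PCA and nearest centroid.
6. A **synthetic-data generator** that reproduces the statistical
   structure all of the above assumes, with ground truth, so every stage
   can be validated by recovery tests.

## Consensus calling and error rates

Each sample is genotyped in $R = 3$ independent replicates per locus. The
consensus rules are deliberately asymmetric:

* a **homozygote** $A/A$ is accepted only if all three replicates
  amplified and all equal $A/A$ — this is the strict rule that protects
  against allelic dropout masquerading as homozygosity;
* a **heterozygote** $A/B$ is accepted if at least two replicates equal
  $A/B$ and no third allele appears in any replicate.

Everything else is a no-call. A sample's multilocus genotype is accepted
when at least `min_loci` (default 6 of 7) loci could be scored. Sex is
called male if the dominant marker amplified in *any* replicate and
female otherwise, which makes female calls fallible in males — the
false-female reclassification below is the downstream correction.

Two error rates summarize data quality: the proportion of missing
replicate genotypes (`missing_rate()`), and the proportion of homozygous
replicates within sample/locus combinations whose consensus is
heterozygous (`false_homozygote_rate()`), the observable footprint of
allelic dropout. Note a conditioning subtlety the test suite relies on:
with per-replicate dropout probability $d$ and the rules above, a true
heterozygote is scored heterozygous only when at most one replicate
dropped out, so the expected false-homozygote fraction among qualifying
replicates is $d/(1+2d)$, not $d$.

## Individual identification

Accepted genotypes are clustered with single linkage under an allele
mismatch threshold (default 2, counted by maximal pairing per locus;
qualitative "pattern" loci, scored categorically rather than biallelically,
contribute 2 per differing class). Samples are processed in sorted order,
so clustering is invariant to input order; pairs sharing fewer than 5
comparable loci never merge, which guards sparse genotypes against
spurious merging. Within a cluster containing any male-called sample,
female-called samples are reclassified as false females. Each individual's
genotype is the modal allele pair per locus; capture histories are binary
detections per (individual, session, day), optionally restricted to
systematically collected samples.

With a seven-locus panel of modest polymorphism, genuinely distinct
individuals can fall within two mismatches of each other — the reason the
original field protocol consulted two additional qualitative loci. The
package flags all merges at distance 1–2 (`$borderline`) for review
rather than pretending the threshold is infallible.

## The CMR model with misidentification

Detection histories follow Pollock's robust design: primary sampling
occasions (sessions, open population between them) containing secondary
occasions (days, population closed within). Genotyping error enters
through a per-capture correct-identification probability $\alpha$: each
capture is assigned to its true individual with probability $\alpha$ and
otherwise spawns a unique ghost genotype, observed exactly once ever.

The likelihood is a documented composite of three parts, per sex group:

* **Within-session emissions.** For an on-site animal, the recorded
  detection pattern over the $K$ days follows a thinned capture process —
  capture with probability $p$ (before the first true capture of the
  session) or $c$ (after), recorded with probability $\alpha$. A
  two-state recursion gives $q(\omega)$ for any pattern, the
  recorded-empty probability $q_0$, and the expected ghost spawn rate per
  occasion.
* **Open component.** Each genotype with $\ge 2$ total detections is
  certainly real; from its first detection session onward its state
  (on-site, temporary emigrant, dead) evolves as a hidden Markov chain
  with survival $\phi$ and Markovian emigration
  $\gamma''$ (leave) / $\gamma'$ (stay away), evaluated by forward
  recursion. Conditioning mirrors CJS: the first detection contributes
  its within-session pattern given detection; later sessions contribute
  unconditional emissions.
* **Singletons, ghosts and $f_0$.** Single-detection genotypes are a
  mixture of once-caught real animals and ghosts. Ghost counts per
  occasion are modeled as Poisson with intensity $N_t \hat g_j$, and the
  number of real animals among a session's singletons is marginalized
  *exactly* via an elementary-symmetric-polynomial recursion, jointly
  with a closed-population count term that carries $f_0$ (the on-site
  animals recorded undetected). The count term uses the Stirling
  (Poisson-population) form of the binomial coefficient, so closed-model
  estimates coincide with the classical Darroch / Lincoln–Petersen
  estimators; at its $f_0$-profile the term is exactly zero, which keeps
  detection information counted once.

With $\alpha = 1$ the ghost intensity vanishes and each session reduces
to the standard closed full likelihood inside the standard robust design;
on a single session with occasion-varying $p$ and $c = p$ the MLE of
abundance is exactly $n_1 n_2 / m_2$ (verified in the test suite on the
50/40/20 instance). Because the components share data summaries, the
product is a composite likelihood: point estimates are consistent in our
simulations, and standard errors are computed by default with the
composite-likelihood sandwich $H^{-1} J H^{-1}$, where $J$ sums score
outer products over per-history and per-cell units
(`se_method = "hessian"` switches to plain inverse-Hessian SEs).
Confidence intervals are Wald intervals on the link scale — the
convention of standard CMR software — rather than profile intervals,
whose cost would be prohibitive inside simulation studies.

Structures per parameter family are `constant`, `sex`, `season`,
`sex_season`, `occasion` (for $p$/$c$), `equal_p` (for $c$), or fixed
values (`rd_fixed(1)`/`rd_fixed(0)` on $\gamma'$/$\gamma''$ is the
no-movement model). AICc uses the total number of detection events as
effective sample size by default (`n_eff = "histories"` is the
alternative; the convention is not settled in the field). Model averaging
follows the study's convention: models with relative likelihood $> 0.2$
and weight $> 0.05$ are kept, weights renormalized, estimates and SEs
averaged as weighted means (the Burnham–Anderson unconditional variance
is available via `se_method = "unconditional"` in `rd_average()`).
Abundance per session and sex is the number of genotypes estimated to be
real — repeat-detection genotypes plus the expected real fraction of
singletons — plus $\hat f_0$; density divides by the sampled area, and
the sex ratio is male over female abundance.

### Numerical choices

Optimization is BFGS on the link scale (logit for probabilities, log for
$f_0$) with relative tolerance $10^{-8}$ and a deterministic, data-driven
start: $p$ and $c$ at the crude per-occasion detection fraction, $\phi$
at 0.8, $\gamma$s at 0.3, $\alpha$ at 0.9 (misidentification is rare in
practice, and low $\alpha$ starts sit across a likelihood ridge where
$\alpha \to 1$ is a local optimum), $f_0$ at half the mean detected
count. Multi-start (default 3: the base start and fixed $\pm 0.8$
link-scale offsets) guards against the local optima we observed;
boundary estimates (e.g. $\gamma'$ on data with few emigrants) get
pseudo-inverse variances with `NA` SEs on the affected parameters rather
than invalidating the fit.

## The synthetic-data generator

`sim_config()` defaults describe the monitored system: a two-sex
population (13 females, 17 males initially) over 10 sessions alternating
spring/fall with 8 sampling days each; sex-specific survival (0.90 / 0.76
per interval), Markovian temporary emigration ($\gamma'' = 0.05$,
$\gamma' = 0.77$), sex- and season-specific capture and recapture rates
(taken from the monitored population's estimates), misidentification
$\alpha = 0.85$, and replicate-level error rates (dropout 0.10, false
alleles 0.02, missing replicates 0.15, sex-marker dropout 0.20 — chosen
as plausible fecal-DNA values; the study reports only consensus-level
proxies, so the per-replicate rates are config-stated, not inferred). The
marker panel mirrors the real one: seven loci with 3, 5, 7, 2, 6, 3, 5
alleles and skewed frequencies ($p_i \propto 1/i$). Recruitment defaults
to zero (closed tests); recovery tests inject recruits between sessions
to keep abundance quasi-stationary, as the real population's fall
sessions record summer offspring. Ghost genotypes are fabricated from a
reserved allele range, heterozygous at every locus, so they can never
collide with real genotypes or each other — matching the model assumption
that errors create singletons.

What the generator does *not* emulate: missingness is i.i.d. per
replicate-locus, whereas real missingness clusters by sample quality
(a low-DNA pellet fails everywhere) — so at equal mean missing rate the
generator rejects more samples at the 6-of-7 acceptance step than the
field data did; there are no spatial home ranges, no pellet-age effects,
and season-specific DNA quality enters only through season-specific
rates. Passing recovery tests therefore validate the estimators under
the model's assumptions, not the field workflow itself.

## Species assignment

Monitored genotypes are assigned to species by joint PCA of an
individuals-by-alleles count matrix (0/1/2 copies, mean-imputed missing
loci, centered columns) with a labeled tissue panel; group centroids on
the first two axes classify queries by nearest centroid. This mechanizes
the visual reading of a two-species PCA; Bayesian admixture analysis is
deliberately out of scope, and for weakly diverged species the two
approaches need not agree — assignments come with centroid distances so
borderline cases are visible.

## Problem sizes used in the shipped tests

Simulation-based checks run at deliberately modest scale: recovery of
individuals on error-free data uses 50 individuals and ~400 samples; the
CMR parameter-recovery study uses 100 replicates of a 10-session,
8-day design with ~90 true individuals plus ghosts, fit with two
optimization starts; Monte-Carlo oracles use 500 to $4\times 10^4$
draws. These sizes give stable 3-sigma bounds while keeping the full
suite fast.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_pso = 6, seed = 11,
                  recruits_per_interval = matrix(rep(c(2L, 3L), 5),
                                                 5, 2, byrow = TRUE))
sim <- simulate_dataset(cfg)
cons <- call_consensus(sim$replicates, min_loci = 6)
inds <- cluster_individuals(cons, calendar = sim$truth$calendar)
hist <- build_histories(inds, sim$truth$calendar)

fits <- list(
  `phi(sex) p(season)` = rd_fit(hist, rd_model(phi = "sex", p = "season",
                                               c = "season",
                                               alpha = "season",
                                               f0 = "season")),
  `no movement` = rd_fit(hist, rd_model(phi = "sex",
                                        gamma_prime = rd_fixed(1),
                                        gamma_dprime = rd_fixed(0),
                                        p = "season", c = "season",
                                        alpha = "season", f0 = "sex")))
rd_rank(fits)
avg <- rd_average(fits)
derived_abundance(avg, area_km2 = 3.5)
```

## Known limitations

* The likelihood is composite, not a full joint likelihood: entry into
  the population is not modeled (no recruitment parameter), dead and
  permanently emigrated states are confounded (apparent survival), and
  the decoupled-sessions identity holds up to the first-detection
  conditioning factors rather than exactly.
* The Poisson approximation for ghost counts ignores the (weak) negative
  correlation between an animal's recorded pattern and its spawned
  ghosts; at study scale this leaves a small ($\approx 0.01$) downward
  bias in $\hat\alpha$.
* $\gamma'$ is weakly identified in populations with little temporary
  emigration; expect boundary estimates and wide or `NA` intervals.
* The null-allele statistic is the Chakraborty-style
  $(H_E - H_O)/(H_E + H_O)$ estimator; published values computed with
  homozygote-frequency iterative schemes are not directly comparable.
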