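---
title: "Gompertz growth-curve analysis for slow-growing chicken flocks: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gompertz growth-curve analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flockgrowth)
```

## The problem

Slow-growing local chicken breeds — here typified by the two Piedmontese
breeds *Bianca di Saluzzo* (BS) and *Bionda Piemontese* (BP) — are reared
for meat on low-input, antibiotic-free systems and slaughtered around 180
days. Management decisions (age for sale, selection versus mating-scheme
improvement) hinge on a quantitative description of their growth:
when growth is fastest, what mature weight is approached, and how far along
the trajectory a bird is at slaughter. This package implements that
analysis as a reusable, tested pipeline: per-bird Gompertz fits in two
parameterizations, derived maturity traits, group-level inference, a
candidate-gene association scan, and a synthetic-flock generator that
stands in for raw weighing data, which are rarely deposited.

## The growth model

The classical ("G1") Gompertz form is

$$BW(t) = BW_a \exp(-b\,e^{-kt}),$$

with asymptotic weight $BW_a$ (g), dimensionless shape $b$ and relative
growth rate $k$ (1/day). The lag-time ("G2") form, originally popular for
bacterial growth in food, is

$$BW(t) = BW_a \exp\{-\exp[(e\mu/BW_a)(\lambda - t) + 1]\},$$

where $\mu$ is the absolute growth rate at the inflection point (g/day)
and $\lambda$ the lag time (days): the intercept of the inflection tangent
with the time axis. The two forms describe exactly the same
three-parameter family; equating exponents gives

$$\mu = BW_a k / e, \qquad \lambda = (\ln b - 1)/k,$$

implemented in `convert_g1_to_g2()` / `convert_g2_to_g1()` with round
trips exact to floating precision. Because the family is the same, the
choice between forms is one of interpretability, not of fit: any
difference in residual sums of squares between a fitted G1 and a fitted G2
is optimizer noise, and the package drives both to the common optimum
(see *Numerical choices*). Goodness-of-fit orderings between the forms can
therefore only tie up to numerical precision, which is how the package
treats "which form fits better" questions.

Derived traits (`derive_traits()`):

* inflection weight $BW_{ip} = BW_a/e$ — the Gompertz constant is kept at
  full precision ($1/e = 0.367879\ldots$), never the display rounding
  0.368;
* inflection age $T_{ip} = \ln(b)/k$, equivalently
  $\lambda + BW_a/(e\mu)$ in the lag-time form (the closed form is
  cross-checked against a numeric root of $BW(t) = BW_a/e$ at $10^{-6}$ d);
* maximum growth rate $MGR = BW_{ip}k = \mu$;
* predicted slaughter weight $BW_s = BW(180\,\mathrm{d})$ and degree of
  maturity $D_m = BW_s/BW_a$;
* the model-implied hatch weight $BW_a e^{-b}$, which is known to be an
  unreliable estimate of the true hatch weight and is reported for
  diagnostics only.

Time is measured in days throughout; week-numbered inputs are converted as
$7\times$week with hatch at day 0. Negative lag times are mathematically
valid (they occur whenever $b < e$, i.e. birds growing fast from hatch)
and are accepted with a warning rather than rejected, since nothing in the
model bounds $\lambda$ below.

## Fitting

`gompertz_fit()` minimizes unweighted least squares by Levenberg-Marquardt
with analytic Jacobians and box bounds; `fit_flock()` maps it over a long
table of weighing records. Bounds — asymptote in (max observed weight,
10 times it], shape in (0.1, 20], rate in (1e-4, 1) — prevent asymptote
collapse or run-away on trajectories with a mid-growth slowdown.
Heteroscedasticity of weighing error is handled through the simulation
noise model, not through weighting, since per-bird records are short (17
points) and the parameter of interest is the curve, not the error law.

Per-bird fits only: group curves are summarized as means of per-bird
parameters. This is why a printed group-mean inflection age can differ
slightly from the algebra applied to rounded group-mean parameters.

Goodness of fit is the adjusted $r^2$ and an AIC computed as
$n\ln(\mathrm{rss}/n) + 2(p+1)$, counting the residual variance as a
parameter. AIC conventions differ by an additive constant across software,
so only orderings are ever interpreted.

### Numerical choices

* Convergence: relative tolerances $10^{-12}$ on both the residual sum of
  squares and the parameters, 200 iterations.
* Restart polishing: when a box constraint is active at the optimum
  (typical for the asymptote floor on noisy, far-from-asymptote
  trajectories), a single Levenberg-Marquardt run can stall on the
  boundary; the engine restarts from its own solution until the fit stops
  improving (at most 4 restarts).
* Cross-parameterization multi-start: when both forms are fitted,
  whichever found the lower residual sum of squares seeds a refit of the
  other (via the exact conversion) until both agree. Both forms then
  report the same curve, as the algebra says they must.
* Starting values: asymptote at 1.2 times the largest weight, shape from
  the first weight, rate from the classical log-log linearization; fixed
  fallbacks (2500 g, 3.5, 0.015/day — a typical medium slow-growing
  bird) on degenerate input.
* Degenerate inputs: constant trajectories are rejected up front ("no
  growth signal"); non-convergence is flagged on the result, never
  silent; fits with fewer than 5 points are refused by default
  (`min_obs` lowers this only for interpolation checks, three points
  being the exact-determination minimum for three parameters).

## Group-level inference

`lm1_anova()` tests breed, sex and breed-by-sex on a trait with an
optional random effect whose covariance is proportional to an
allele-sharing relationship matrix — an animal-model-style substitute for
pedigree, estimated from marker genotypes by
`relationship_from_markers()` (proportion of shared alleles, averaged over
markers). The single variance ratio is profiled by restricted likelihood
on a one-dimensional grid with local refinement; with no (or an identity)
relationship matrix the analysis reduces exactly to ordinary two-way
ANOVA, which is tested against `aov()`. Main effects are tested
respecting marginality (type-II style) with the error taken from the full
model. `backward_eliminate()` removes the least significant removable
term (interaction before its main effects) at the chosen threshold and
keeps the elimination trail. Weekly ANOVAs across the 17 ages are
reported without multiplicity correction, matching practice in this
literature; a Bonferroni flag is available in the association scan.

### Waller-Duncan letters

Mean separation uses the minimum-average-risk Bayes rule with k-ratio 100
(the conventional choice, roughly a 5% test). The critical value
$t_B(k, F, q, f)$ is computed numerically from first principles: the
posterior of the between-to-within variance ratio $\gamma$ given the
ANOVA $F$ (scale-invariant prior on $\gamma \ge 1$) induces a posterior
on the shrinkage factor $b = 1 - 1/\gamma$; for a linear loss, the
expected loss of declaring a difference at standardized distance $t$ is
proportional to $\psi_f(\pm\sqrt{b}\,t)$ with
$\psi_f(m) = m F_f(m) + \frac{f+m^2}{f-1} f_f(m)$ ($F_f$, $f_f$ the
t cdf/pdf with $f$ error df), and $t_B$ solves the monotone equation
"loss ratio = k". The construction reproduces the qualitative behaviour
of the published tables: $t_B$ falls from large values at small $F$
towards about 1.72 (k = 100) as $F \to \infty$. Letters follow a sweep
from the largest mean with per-pair least significant differences
$t_B\sqrt{\mathrm{mse}(1/n_i + 1/n_j)}$, and the assignment is invariant
to group ordering.

`dimorphism_delta()` is the sexual-dimorphism percentage
$((\bar{x}_M - \bar{x}_F)/\bar{x}_F)\times 100$, rounded only at display.

## Candidate-gene analysis

The PAX7 intron-3 minisatellite has a 31-bp unit: three units (E allele,
588 bp amplicon), two (F, 557 bp), one unit plus a single-nucleotide
deletion (G, 525 bp = 557 − 31 − 1). `call_alleles()` assigns measured
fragment lengths to the nearest reference within ±3 bp (capillary
electrophoresis is accurate to a few bp at this size); the E allele stays
in the model even where only F and G segregate.

`hwe_randomization_test()` checks random-mating proportions by shuffling
the pooled alleles and re-pairing them (2000 randomizations by default);
the deviation statistic is the absolute observed-minus-expected
heterozygosity difference. The p-value counts randomizations at least as
extreme as the observation, which is slightly conservative on the
discrete null — the calibration test shows type-I error a little below
the nominal 5% but inside the ±2% band. `fst_between()` is the
Weir-Cockerham variance-components estimator for one multi-allelic locus;
with allele counts only, within-population heterozygosity defaults to its
random-mating expectation (observed proportions can be supplied).
`lm2_assoc()` is the one-way genotype ANOVA within a breed-sex group with
Waller-Duncan letters, and `pax7_assoc_scan()` applies it per age —
each age independently, the simplest reading of a per-week association
model (a repeated-measures variant is out of scope).

## The synthetic-flock generator

`simulate_flock()` emulates the study design: four breed-sex groups of
46/47/54/54 birds, weighed biweekly from hatch to 224 days (17 ages).
Group-level truth defaults to the published group means of the
classical-form parameters (with the BP-female asymptote taken as 2012 g;
the grouped table prints a typographic "201" for that cell). Choices a
user should know about:

* Between-bird parameter variation is log-normal (positivity) and
  mean-preserving. Default CVs are back-calculated from the published
  SEMs times $\sqrt{n}$: 0.16 for the asymptote and 0.11 for the shape;
  the rate's SEM prints as 0.000 at table precision, so its CV is set to
  0.10, the same order as the shape. Parameters are drawn independently;
  a correlation structure between them is a known omission (real flocks
  show, e.g., negative rate-asymptote correlation) and can be emulated
  only through the fitting stage.
* Measurement noise is multiplicative with CV 0.05 — weights span 39 g to
  about 2.5 kg, so a constant-CV error is the defensible default.
* The optional biphasic slowdown rescales growth *increments* inside a
  91-147 day window (13-21 weeks), keeping trajectories monotone; it
  reproduces the systematic underfit of a single sigmoid seen in real
  slow-growing flocks in that age range.
* Genotypes are drawn under random mating from per-breed allele
  frequencies. The source study does not print its allele frequencies;
  the defaults (F/G = 0.65/0.35 in BS, 0.55/0.45 in BP) were chosen once
  to give a small between-breed differentiation of the order reported
  (Fst ≈ 0.03) and are not tuned further. The additive genotype effect
  (grams per G allele) switches on as a step at the onset age (default
  98 d); a step is the simplest shape consistent with an association that
  appears from a given week onward.
* Marker genotypes for the relationship matrix are unlinked and
  equifrequent, optionally in full-sib blocks.

Everything is a deterministic function of the seed.

What passing tests on these data do *not* show: real weighing error is
not exactly log-normal-multiplicative, real between-bird parameter
variation is correlated, the biphasic dip is smoother than an increment
rescale, and real genotype effects grow with age rather than stepping on.
The generator is a test harness for the pipeline's statistical
properties, not a physiological model.

## Validation summary

The test suite (all computed at run time; none of these numbers is
asserted from the literature):

* algebraic identities: inflection constant $1/e$ for every fit,
  conversion round trips at $10^{-10}$, prediction equality of the two
  forms at $10^{-8} BW_a$;
* exact recovery of noiseless trajectories and three-point interpolation;
* parameter recovery at the study scale: simulating 50 birds/group at the
  published group means with 5% noise and between-bird CV 0.08, 200
  replicates, recovers group-mean asymptote, shape and rate within 5%
  (observed bias under 1%);
* calibration: type-I error of the Hardy-Weinberg randomization test and
  of both ANOVAs within 5% ± 2% under their nulls (500-1000 replicates);
* power: a genotype effect of half a within-group SD switched on at 98 d
  is detected from that age onward (letters separating the homozygotes)
  and essentially never before.

Problem sizes in the suite (replicate counts, group sizes) are the
package's chosen validation scale: large enough for the stated bands,
small enough to run routinely.

## Known limitations

Single-sigmoid models only (no logistic/Richards alternatives, no
multiphasic mixtures); the biphasic window is simulated, not fitted; one
variance component in the mixed ANOVA; the Waller-Duncan critical value
follows the minimum-average-risk construction with a scale-invariant
prior, so it can differ in the second decimal from historical tables;
per-age association scans ignore the longitudinal correlation of weights.
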