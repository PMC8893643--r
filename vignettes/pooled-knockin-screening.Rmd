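---
title: "Methods: pooled knock-in screening statistics and conversion-tract calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled knock-in screening statistics and conversion-tract calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdrscreen)
```

# The experimental design this package analyses

CRISPR/Cas9 knock-in transgenesis in mosquitoes (and many other
non-model insects) is screened generationally: injected survivors (G0)
are crossed in cages of roughly 20 individuals, each cage is a *pool*,
and a pool is scored positive when at least one G1 offspring expresses
the fluorescent transgene marker. Three quantitative questions follow
from that design, and the package implements one module for each:

1. **How efficient was integration?** The conventional report is the
   *minimum integration rate*: positive pools / surviving G0 × 100%.
   It is a lower bound, because one positive pool can hide several
   independent integration events. Construct-to-construct differences
   are assessed with exact binomial tests.
2. **What was the underlying per-founder rate?** Pool positivity is a
   group-testing observation: a pool of $n$ founders is positive with
   probability $1-(1-pd)^n$ when each founder independently yields a
   detectable transgenic with probability $p$ and detection probability
   is $d$. Inverting this link gives a likelihood for $p$, a maximum
   likelihood estimate, and compatibility intervals.
3. **What repair mechanism produced the integrations?** Recoded
   homology arms carry engineered SNPs at known signed offsets from the
   predicted double-strand break (DSB). Sequencing the integration
   junctions shows which donor SNPs were copied into the genome: the
   *gene conversion tract*. Direction (5′, 3′, both, neither), censored
   tract extents and continuity discriminate synthesis-dependent strand
   annealing (SDSA) with one-ended invasion (unidirectional tracts)
   from two-ended SDSA or Holliday-junction branch migration
   (bidirectional tracts).

# Rate statistics and test conventions

`minimum_integration_rate(k, n)` reports $100k/n$ rounded **half away
from zero** (`round_half_up()`), the rounding convention of screening
reports, not base R's round-half-to-even. Every estimate carries an
exact Clopper–Pearson interval on the underlying proportion.

`exact_binomial_test()` is written in the package rather than delegated,
because the two-sided convention matters and must be explicit:

* One-sided p-values are exact binomial tail sums.
* The default two-sided p-value is the *minimum-likelihood* ("minlike")
  sum: all outcomes no more probable than the observed one, with a
  relative tolerance of $10^{-7}$ for floating-point ties. This is the
  same convention as `stats::binom.test`, which the test suite uses as
  an independent oracle (alongside a $2^n$ outcome-enumeration oracle
  at small $n$); the package routine additionally exposes the
  "central" (doubled one-sided) definition as an option, since the two
  can differ by more than a factor of two for asymmetric nulls.
* When construct B is compared against construct A,
  `compare_constructs()` takes the null proportion to be A's *point
  estimate* $k_A/n_A$. This treats the comparator as fixed and is the
  convention that matches how such comparisons are quoted in screening
  reports; it understates uncertainty in A, which is why the
  group-testing module reports interval overlap as the more honest
  between-construct comparison. A reference with $k_A=0$ makes every
  comparison degenerate and triggers a machine-readable warning.

# The group-testing model

For pools $i = 1,\dots,K$ with sizes $n_i$ and outcomes $y_i \in
\{0,1\}$, the log-likelihood of the per-founder rate $p$ is

$$\ell(p) = \sum_{i: y_i=1} \log\left(1-(1-pd)^{n_i}\right)
          + \sum_{i: y_i=0} n_i \log(1-pd).$$

`estimate_individual_rate()` evaluates $\ell$ on a $10^{-4}$ grid over
$[0,1]$ (with local refinement of the optimum and of interval
endpoints by root finding), which is ample resolution for rates
resolved by tens of pools. For equal pools the MLE has the closed form
$\hat p = 1-(1-X/K)^{1/n}$ ($X$ positive pools), which the grid search
is tested against. Detection probability defaults to $d = 1$,
preserving the "minimum" semantics of the conventional estimator; a
sensitivity analysis can set $d < 1$.

## Interval construction

Three compatibility intervals are computed and reported:

* **mid-p exact inversion (default):** invert the mid-p test on $X \sim
  \mathrm{Bin}(K, q)$ for the pool positivity $q$, then transform both
  bounds through $p = 1-(1-q)^{1/n}$ (monotone, so coverage is
  preserved).
* **profile likelihood:** $\{p : \ell(p) \ge \ell(\hat p) -
  \chi^2_{1,\mathrm{level}}/2\}$.
* **exact (Clopper–Pearson) inversion**, transformed the same way.

The default deserves a note. With ~10–15 pools the sufficient statistic
$X$ is very discrete, and the asymptotic $\chi^2$ cutoff behind the
profile interval calibrates poorly — its exact coverage (computable by
summing the binomial distribution of $X$, no simulation needed) falls
well below nominal at plausible rates, while the Clopper–Pearson
inversion is conservative by construction. The mid-p inversion sits
between the two and is close to nominal across the rate range these
screens occupy, which is why it is the default. The chunk below
computes exact coverage of all three constructions for 15 pools of 20
founders; the test suite asserts the same calibration property by
simulation.

```{r coverage, eval = FALSE}
coverage <- function(p_true, method, K = 15, n = 20) {
  q <- pool_positive_prob(p_true, n)
  covers <- vapply(0:K, function(x) {
    pools <- data.frame(n_founders = n, positive = seq_len(K) <= x)
    f <- estimate_individual_rate(pools, interval = method)
    f$interval[1] <= p_true && p_true <= f$interval[2]
  }, logical(1))
  sum(dbinom(0:K, K, q) * covers)
}
sapply(c(0.01, 0.05, 0.10), coverage, method = "midp")
sapply(c(0.01, 0.05, 0.10), coverage, method = "profile")
sapply(c(0.01, 0.05, 0.10), coverage, method = "exact")
```

Boundary data are handled explicitly: with every pool positive the MLE
is the upper boundary and only the lower bound is informative (the
upper bound is reported as 1); symmetrically for all-negative data.
With heterogeneous pool sizes there is no scalar sufficient statistic,
so the mid-p and exact constructions fall back to the profile interval
with a warning.

`overlap_assessment()` reports whether two constructs' intervals
intersect and, in each direction, the maximum probability of one
construct's complete pool outcome under rates inside the other's
interval — a direct reading of "could one rate have produced both
observations?".

## Estimator bias

`expected_minimum_rate()` gives the closed-form expectation of the
conventional estimator, $100\,(1-(1-pd)^n)/n$, which is $\le 100\,pd$
for every $p$ (Bernoulli's inequality) with equality only at 0. The
pooled minimum rate is therefore never anti-conservative, and at a 10%
per-founder rate with pools of 20 it expects only ~4.4% — the reason
an all-pools-positive construct should be read through the
group-testing likelihood rather than its minimum rate.

# Tract calling

Coordinates are signed bp anchored at the predicted DSB (offset 0,
blunt cut assumed 3 bp 5′ of the PAM), negative 5′ of the cut; this
convention is written into every output header because reported tract
distances are otherwise ambiguous. Per side of the cut:

* `extent_min` is the magnitude of the outermost donor-state SNP
  (0 when the side has no donor call);
* `extent_max` is the magnitude of the innermost *wildtype* SNP beyond
  it, or the sequenced-span boundary when none exists — the true tract
  end is interval-censored between the two;
* the side is *continuous* when every SNP strictly between the
  outermost donor call and the DSB is donor or unread.

Unread SNPs (Sanger coverage gaps) are non-informative by design: they
do not break continuity and they widen censoring intervals; treating
them as wildtype would manufacture false "discontinuous" calls. An
event whose SNPs are all unread is `indeterminate` and refuses
aggregation. Discontinuous conversion — reported in other species — is
flagged, never rejected.

Direction is a pure function of which sides carry donor calls, and the
mechanism label is a pure function of direction (never of extents):
unidirectional → SDSA with one-ended invasion; bidirectional →
two-ended SDSA or Holliday-junction branch migration (the junction data
cannot distinguish these); non-conversion → no label.
`censoring_interval_report()` additionally emits, for *unconverted*
sides, the interval $(0, \text{innermost wildtype SNP})$ — any tract
there was too short to reach a marker. The per-event record keeps the
extent fields of an unconverted side at 0 so that direction and extents
stay consistent; the censoring report is where partial information
about such sides lives.

# The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
so that every stage is testable without external data:

* `simulate_experiment()`: founders integrate independently
  (`p_individual`), are detected independently (`detection_prob`,
  default 1), pools of `founders_per_pool` (default 20, the cage
  size); a pool is positive iff it contains a detected carrier.
  Defaults of 15 pools of 20 founders mirror a realistic screen arm.
  An optional events-per-carrier multiplicity (default exactly 1)
  feeds bias studies without affecting positivity.
* `generate_snp_map()`: SNP offsets drawn uniformly outside a
  `guard_bp` window (default 50 bp, the SNP-free perfect-homology
  margin engineered next to the cut in recoded arms) up to
  `arm_len_bp` (default 2000, a typical homology-arm length). 25 SNPs
  per 2 kb arm reproduce the ~1.25% heterology of recoded designs.
* `simulate_conversion_events()`: each event draws a direction class
  (defaults 60% unidirectional split evenly between sides, 20%
  non-conversion, 20% bidirectional — the observed mixture in
  characterised HDR events), then per converted side a tract length
  $1+\mathrm{Geometric}(1/\texttt{mean\_tract\_bp})$, i.e. memoryless
  per-base extension. The default mean of 150 bp puts most tract ends
  within a few hundred bp of the cut, matching the short-heavy,
  long-tailed extents seen in junction sequencing; it is configurable
  because this distribution is an assumption, not an observation.
  Tracts are continuous intervals anchored at the DSB by construction.

What the generator does **not** model — and what passing tests
therefore do not establish about real data: sequence-level repair (no
NHEJ indel spectrum, no partial/off-target integration structure),
mosaicism and per-oviposition screening detail (detection is a single
per-founder probability, which the pooling analysis anyway reduces
to), correlation between founders in one cage, and any side bias in
unidirectional conversion (split 50/50 by default).

# Numerical choices and degenerate inputs

* Rounding: half away from zero, applied only at the reporting layer.
* Minlike ties: relative tolerance $10^{-7}$, matching standard
  practice for exact tests.
* Grid: $10^{-4}$ spacing, endpoints refined by `uniroot` to
  $10^{-10}$; results are deterministic.
* $p = 0$ with an observed positive pool gives $\ell = -\infty$,
  accepted (not an error); all-negative data at $p=0$ give $\ell = 0$.
* Degenerate nulls ($p_0 \in \{0,1\}$) short-circuit to p-value 1 on
  the consistent outcome, 0 otherwise.
* Simulation sizes in the test suite (10⁴ pools for convergence checks,
  500 replicates per rate for interval calibration, 10⁴ random events
  for oracle equivalence of the tract caller) were chosen to put
  Monte-Carlo error well below the tested tolerances while keeping the
  default suite fast.

# Known limitations

* The pooling likelihood conditions on pool sizes as recorded; "~20"
  cages entered as exactly 20 founders inject a small systematic error
  into the transformed bounds. Per-pool counts should be recorded when
  available.
* The comparator-point-estimate null in `compare_constructs()` ignores
  the reference's sampling error (see above); interval overlap from
  the group-testing module is the recommended complement.
* Mechanism labels express the standard SDSA interpretation of tract
  direction; they are a classification convention, not an inference
  with error control.
* Multiple independent integrations within one founder or pool are
  unobservable in this design; everything downstream of pool
  positivity is deliberately agnostic to them.
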