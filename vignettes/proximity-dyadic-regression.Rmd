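---
title: "Proximity networks and dyadic regression: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proximity networks and dyadic regression: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proxqap)
```

## The setting

Wearable RFID badges record when two people face each other at close range,
producing a stream of timestamped pairwise contact events. Within a closed
group — here, two student cohorts spending a weekend together — these
streams can be aggregated into a weighted interaction network and related
to survey attributes collected beforehand: depressive symptoms (CES-D),
age, gender, organization membership, and directed friendship nominations.
The scientific questions are dyad-level ("is a pair with more depressive
symptoms less likely to interact?"), which makes ordinary regression
inference invalid: dyads sharing an actor are not independent. The package
therefore pairs a standard OLS point estimate with permutation-based
(QAP-style) inference.

## From signals to a dependent matrix

Badges fragment one continuous conversation into several short signals.
Following the validation work for this sensor class, signals of the same
dyad separated by **at most 75 seconds** are merged into one event spanning
first start to last end; the gap time counts as interaction, because the
merge asserts that the interaction never actually stopped. The boundary is
inclusive (a 75 s gap merges, 76 s does not) and the threshold is a
configuration knob (`max_gap_s`). Merging operates on half-open intervals
`[start, end)`, so abutting events coalesce without double counting, and it
is idempotent.

Merged durations are summed per unordered dyad into a symmetric matrix of
seconds, then divided by the observation window in hours, since the two
cohorts were observed for different lengths of time (37 h and 32 h in the
generator's default design). The window length is a study-design input, not
a data-derived quantity; when unspecified the code falls back to the span
of the log and says so in the object.

The dependent variable of the regression is `log(y + offset)` with `y` in
seconds/hour. The raw durations are strongly right-skewed, and the log
restores approximate normality of residuals. Because many dyads never
interact (`y = 0`), a nonnegative offset is needed; the default is 1
second/hour, it is recorded in all exported headers, and sensitivity runs
can change it. When every dyad has positive duration — as in the
generator's output — offset 0 makes the log transform the exact inverse of
the generative model, which is why the parameter-recovery and calibration
tests run at offset 0.

## Dyadic and group interaction time

To separate two-person from group sociality, the package sweeps the event
boundaries; between consecutive boundaries the set of co-active events is
constant, and the co-active events form a graph over actors. An actor's
time in a connected component of exactly two actors is *dyadic*, in a
component of three or more *group*. Components are the weakest defensible
reading of "at least three individuals present in the interaction": if A
talks to B while B talks to C, all three are treated as one gathering even
without an A–C signal. The stricter reading — A is in a group only when an
active triangle contains A — is available as `mode = "clique"`. Each
actor-second is classified exactly once, so dyadic + group time equals
total active time by construction; the test suite verifies the sweep
against a per-second brute-force classifier.

The decomposition runs on merged events, matching the treatment of the
dependent matrix.

## The covariates

For a numeric attribute `v` (depression score, age), two dyadic encodings
are used: the pair **mean** `(v_i + v_j)/2` and the **similarity**
`-|v_i - v_j|`, which is 0 for identical values (the reference category)
and increasingly negative with dissimilarity. Age enters as a *centered*
mean (per-sample mean over actors with observed values subtracted);
depression enters uncentered, so its coefficient reads as the effect of
both members being equally depressed by that raw amount, and the worked
examples below stay on the raw scale. Gender and organization membership
enter as dyad dummies. For the organization variable the three dyad
categories (neither member, exactly one, both) admit only one
non-collinear two-dummy coding alongside an intercept: *at least one
member* and *same status* (both or neither). "Same status" and "exactly
one" are complements and cannot coexist with an intercept.

Friendship nominations are directed; the model's friendship predictor is
the symmetrized *any* tie (at least one nomination in either direction),
with *mutual* (both directions) and *asymmetric* (exactly one) matrices
available for strength-of-tie analyses; `any = mutual + asymmetric` holds
elementwise. Because published tie tallies are sometimes quoted per dyad
and sometimes per nomination (a mutual dyad carries two nominations), the
builder reports both conventions.

Missing survey values propagate: any covariate touching a non-respondent
is missing, and the design stacking applies listwise deletion, reporting
dyad counts before and after. Two samples of 73 and 50 actors yield
`2628 + 1225 = 3853` dyads before deletion.

## Multi-group MRQAP

The model is `y_ij = b0 + sum_k b_k x^k_ij + e_ij`, estimated by OLS on
the surviving dyads with samples pooled and a sample dummy included.
Inference comes from **Y-permutations**: an actor relabeling is applied
simultaneously to the rows and columns of the dependent matrix, the
predictors stay fixed, and the model is refit; with several samples each
sample is relabeled within itself, since actors are exchangeable only
inside their own network. The deletion mask is defined by the predictors
(actor survey missingness), which permutations hold fixed, so the mask is
re-applied unchanged after each relabeling.

For each coefficient the null sample yields its expectation `E(beta)`,
2.5th/97.5th percentiles (nearest order statistic — no interpolation, so
reported bounds are realized null values), and a percent-rank p-value
computed with mid-ranks (ties contribute half) and with the observed
statistic counted in the null set, which bounds p below by the permutation
resolution and keeps the test valid. Two conventions are exposed because
reporting practice differs: the default doubles the smaller tail and caps
at 1 (`two_sided_doubled`); `percent_rank` reports the smaller tail itself
(a percent rank of 0.99 becomes p = 0.01). One master seed drives a single
sequential permutation stream, making any run exactly reproducible.

Values within a relative `1e-8` of the observed statistic count as ties,
so permutations that are analytically equivalent are not split by
round-off between the QR-based observed fit and the normal-equations
permutation operator.

## Selection tables

With the coefficients for intercept, depression mean, depression
similarity and their product, the model-implied duration for a dyad with
scores `(d_i, d_j)` and all other predictors at reference is
`exp(b0 + b_m*mean + b_s*sim + b_ms*mean*sim)` seconds per hour. The
back-transform deliberately ignores the log offset and any smearing
correction, matching how such worked examples are conventionally printed;
a multiplicative smearing factor can be supplied. With the package's
reference coefficient set, two actors scoring 5 each are predicted to
interact `exp(2.504 - 0.059*5) = 9.11` s/h and two actors scoring 20 each
`3.76` s/h. The default grid runs over scores 0–36 (an observed range in
this population); a 1–36 variant is a flag away.

## The synthetic generator

The generator's purpose is to give every stage a realistic, fully
controlled input; its defaults *are* the study conditions the analysis
targets, chosen once:

- two samples of 73 and 50 actors, windows 37 h and 32 h;
- whole-survey non-response at rates 20/73 and 2/50 (emulating 73% and
  96% response); non-respondents neither answer items nor nominate;
- CES-D items drawn independently as Binomial(3, p) with per-sample p of
  10.28/60 and 11.98/60, matching the target cohort means (item
  independence is a simplification; internal-consistency tests construct
  correlated items separately);
- ages as rounded normals (20.75 +/- 2.09, 21.73 +/- 3.24), female
  proportions 0.37/0.60, 14 organization members per sample;
- friendship seeds per dyad at densities 38/2628 and 68/1225 with
  reciprocity 10/38 and 39/68, reproducing sparse early-acquaintance
  nomination structure;
- per-hour dyadic durations `y = exp(gamma' x + eps)` with `gamma` the
  reference coefficient set and `eps` Gaussian with sd 1.5 on the log
  scale (log-normal, heavy-tailed durations; the sd is a choice — only
  coarse moments of real durations are published), capped at 80% of the
  hour so events fit into the window;
- each dyad's total is split into contact episodes separated by gaps
  longer than the merge threshold, and episodes are fragmented into
  signals with internal gaps of at most 75 s; the construction preserves
  episode spans exactly, so merging at the matching threshold recovers
  the drawn totals to machine precision — this is what makes the pipeline
  exactly invertible at zero noise and underlies the parameter-recovery
  test;
- synchronous triads (three pairwise events with one span) injected at 2
  per hour create genuine group time; they add duration outside the
  dyadic model, so recovery and calibration runs switch them off.

What the generator does *not* emulate: circadian/bursty event timing,
sensor false negatives beyond fragmentation, item covariance within the
CES-D, and any built-in link between depression and the dyadic-isolation
ratio. Passing tests therefore certify the statistical machinery and the
processing contracts, not behavioral realism of the event streams.

Replicated checks (type-I calibration of the depression-mean test at
alpha = 0.05 with 200 replicates of 500 permutations; bias of the
recovered coefficients against the generative truth over 100 replicates)
run at the duration-matrix level of the generator rather than re-placing
event streams, which the closure test covers once; this keeps the full
suite around a minute of compute without weakening what is asserted.

## Numerical and degenerate-input choices

- Intervals are half-open; a zero-length event is invalid.
- `merge_events` with a negative gap, double per-hour normalization,
  rank-deficient designs (the offending columns are named), constant
  vectors in correlation tests, all-missing attributes, and an empty
  selection range are errors, not warnings.
- Quantiles of null distributions use type 1 (order statistics).
- Cronbach's alpha requires at least two items and non-degenerate total
  variance; complete rows only.
- Residual skewness uses the standard moment estimator.

## Limitations

- Y-permutation is the only implemented MRQAP scheme (it is the most
  conservative of the standard choices); double-semi-partialling and
  X-permutation variants are out of scope, as are ERGM/SAOM and
  relational-event models, which address different estimands.
- The dyadic/group decomposition is quadratic-ish in boundary count and
  meant for event logs in the tens of thousands, not millions.
- The permutation correlation test blocks by sample by default; pooled
  permutation is available because published analyses sometimes pool
  (degrees of freedom quoted over both cohorts) without stating the
  blocking.
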