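---
title: "Counterpropagation networks for MCI screening: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counterpropagation networks for MCI screening: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpnmci)
```

## The screening problem

Mild cognitive impairment (MCI) sits between normal aging and dementia and
is badly under-detected in primary care. The variables that are actually
available at that level are few: age, years of education (YOE), and three
short instruments — the MMSE (0–30, lower is more impaired), the FAQ
(functional assessment, higher is more impaired) and the GDS (depressive
symptoms). `cpnmci` implements a decision-support classifier over exactly
these five variables, plus the feature-selection and diagnostic-accuracy
machinery needed to choose among them and to judge the result in clinical
terms.

## The Counterpropagation Network

The classifier is a Counterpropagation Network (CPN): a hybrid of an
unsupervised competitive layer and a supervised linear readout.

**Competitive layer (SOM).** Each map unit $l$ holds a prototype vector
$w_l$ in the scaled input space. For an input $x$ the net input is the
Euclidean distance $\mathrm{net}_l = \lVert x - w_l \rVert$, and
competition is winner-take-all: $u_l = 1$ for the unit with the smallest
distance (ties go to the lowest index, which makes replays deterministic),
$u_l = 0$ otherwise. Learning pulls the winner *and its lattice
neighbourhood* $N$ toward the input,

$$\Delta w_{li} = \alpha\,(x_i - w_{li}) \quad \text{for } l \in N,$$

with crisp neighbourhood membership: every unit within the current radius
gets the full rate $\alpha$, everything else is untouched. We deliberately
do not use a Gaussian neighbourhood kernel — the update rule above is the
model as stated, and the crisp form keeps the reference implementation and
the compiled one trivially comparable.

Units live on a `rows × cols` lattice, square or hexagonal, planar or
toroidal. Square lattices use the Chebyshev metric (radius 1 = the 8
surrounding cells); hexagonal lattices use axial hex distance on odd-row
offset coordinates; toroidal wrap takes the minimum-image distance over
the lattice periods. The model names its geometries; the metric choices
are ours and are encapsulated in `lattice_distances()`.

**Readout layer (Grossberg outstar).** A single output unit carries one
weight $z_l$ per map unit. Its activation for an input won by unit $l$ is
simply $y = z_l$. Training is the outstar rule,

$$\Delta z_{l} = \gamma\,(d - y)\,u_l,$$

a convex pull of the winner's weight toward the desired output $d \in
\{0, 1\}$ (1 = MCI). Both layers are updated on every presentation —
there is no two-phase training. Because inputs are scaled to $[0,1]^k$,
prototypes and readout weights provably stay inside $[0,1]$.

We use **one** output unit rather than a two-unit one-hot encoding: the
score $z_{\text{winner}} \in [0,1]$ is then directly the quantity a
threshold sweep and a ROC analysis operate on. A record is classed MCI
when its score is *strictly greater* than the threshold $\theta$.

### Schedules and defaults

All rates decay linearly over the run ($T$ = epochs × records,
$t$ = presentation counter): $\alpha(t) = \alpha_0 (1 - t/T)$,
$\gamma(t) = \gamma_0 (1 - t/T)$; the neighbourhood radius shrinks
linearly from $r_0$ to zero over the first half of training and is
winner-only thereafter. Defaults: an 8×8 map, $\alpha_0 = 0.5$,
$\gamma_0 = 0.1$, $r_0 = \max(\text{rows}, \text{cols})/2$, 100 epochs,
prototypes initialized from a seeded uniform on $[0,1]$ and $z$ at 0.5
(maximal uncertainty). These were chosen once for stability on the
reference synthetic cohort; every one of them is an argument. Zero-epoch
training is legal and yields a usable, uninformative model — convenient
as a null object in tests.

All randomness (initialization, per-epoch shuffles) is drawn in R from a
single seed before the compiled training loop runs, so a naive loop-based
R implementation of the same equations reproduces the compiled path
bit-for-bit; the test suite includes exactly that comparison on small
instances, across all four lattice geometries.

## Cohorts, scaling, and the reference split

A cohort is a validated data frame (`subject_id`, the five features, a
0/1 label). Scaling is per-feature min–max to $[0,1]$, learned on the
training split only; test values outside the training range are clipped
rather than extrapolated so SOM inputs stay inside the unit hypercube.
Linear min–max was chosen over standardization because it is
order-preserving and maps naturally onto the unit-hypercube weight
domain.

`stratified_split()` preserves the control/MCI ratio: the control
(majority) stratum receives $\lfloor m \cdot n_{\text{ctrl}}/n \rfloor$
of the $m$ test slots and the MCI stratum the remainder. For the
reference cohort (331 subjects, 128 MCI) and $m = 76$ this yields **30
MCI / 46 controls** — the composition implied by the comparison tables,
whose sensitivities are all integer multiples of $1/30$ and specificities
of $1/46$. Proportional rounding alone would give 29/47; the
floor-on-controls rule is the convention we fixed to make the reference
composition reproducible, and it is documented here precisely because it
is a convention, not a derivation.

## The synthetic cohort generator

Real ADNI records are access-controlled, so the package ships a generator
(`adni_like_spec()`, `generate_cohort()`) that emulates the *group-wise
marginal structure* of the development sample: 203 controls and 128 MCI
subjects with the published per-group means, SDs and ranges (control MMSE
29.1 (1.2) in 24–30, MCI FAQ 3.6 (4.4) in 0–20, and so on; note the GDS
ranges differ by group: controls 0–6, MCI 0–5).

Each feature is drawn from a truncated normal confined to its range, with
integer instruments rounded after truncation and ages kept at 0.1-year
resolution. Truncation and rounding bias the realized mean away from the
nominal one (severely so for FAQ, which is clipped hard at 0), so the
parent normal's location is calibrated by root-finding until the realized
post-truncation, post-rounding expectation equals the profile mean. The
profile SD is applied to the parent normal as-is; the realized SD is
therefore attenuated where the range clips hard (MCI FAQ realizes an SD
near 2.7 against the nominal 4.4). Matching both moments exactly is
impossible in this family — a truncated normal on $[0, \infty)$ cannot
have a coefficient of variation above 1, and FAQ's nominal cv is 3 in
controls — and we prioritized the mean because group separation, and
hence everything downstream, is driven by it.

Features are drawn independently within group; the published table gives
marginals only, so no inter-feature correlation (e.g. MMSE–FAQ) is
modelled, and no label noise is simulated. Passing tests on this cohort
therefore demonstrate that the pipeline recovers *marginal* group
structure, not that it would reach the same AUC on correlated real data.

## Feature-subset search

The wrapper search scores candidate subsets by the performance of the
actual classifier. Admissible subsets have at least two features and
(configurably) at least one diagnostic instrument among MMSE/FAQ/GDS;
with the five standard features that yields 25 subsets, or 26 without the
instrument constraint. The source material is internally inconsistent
here — it states 24 feature vectors, prints 26 rows including the
instrument-free Age+YOE pair, and the constraint arithmetic gives 25 — so
the enumerator exposes the constraint as a flag instead of silently
picking a count.

Per subset, a grid of CPN variants is trained (by default the four
lattice geometries at 8×8, one seeded restart each) and the subset is
represented by its best variant; fitness is the **convex-hull AUC** on
the held-out test split, the quantity the published ranking is sorted by.
The best single configuration wins — nothing is averaged — because the
reference report shape has one row per subset. `backward_eliminate()`
runs the classic backward pass under the same fitness and constraints and
returns every evaluated subset, flagging the chosen path.

## Evaluation suite

All diagnostic metrics flow from an integer confusion matrix.
`confusion_from_rates()` inverts printed sensitivity/specificity pairs
back to counts (`tp = round(sen · n_pos)`, etc.) and verifies the
inversion to half a unit of the printed precision, which is what makes
published-table cells recomputable exactly.

The ROC sweep moves the threshold over every distinct score (strict
`>` for a positive call), always producing (0,0) and (1,1). AUC is the
trapezoid rule; the suite cross-checks it against the Mann–Whitney
rank-statistic form to 1e-12, ties included. The convex hull is the upper
envelope over the curve plus the corners, built with a monotone chain;
collinear points are dropped (they change no area). Hull AUC dominates
raw AUC by construction and is the ranking statistic; both are reported.

The operating threshold is chosen to balance sensitivity and specificity
(minimum $|sen - spc|$, ties toward higher sensitivity) — the tuning rule
stated for the original system. Clinical utility indices are
CUI+ = sensitivity × PPV and CUI− = specificity × NPV, graded
excellent/good/satisfactory/poor at 0.81/0.64/0.49. When a rater makes no
false-positive calls but some true positives, PPV is defined as 1 (and
symmetrically for NPV); without this convention the 100%-specificity
physician rows would have undefined CUI+.

Single-instrument baselines (`best_scale_cutoff()`) sweep every integer
boundary of a scale (MMSE oriented lower-is-impaired, FAQ/GDS
higher-is-impaired) and pick the accuracy-maximizing cut-off, ties toward
higher sensitivity. Accuracy — rather than Youden's J — is the criterion
because the published FAQ row attains the table's best accuracy at its
stated cut-off; this is an assumption and is confined to one function.

## Numerical and reproducibility notes

* Problem sizes used by the shipped tests: the reference 331-subject
  cohort with a 76-subject test split for system-level checks; 20-record,
  ≤10-unit instances for the bit-identity oracle; 1000 random score sets
  for the ROC property suite; 20 master seeds for the search
  Monte-Carlos. A full exhaustive search (25 subsets × 4 geometries) runs
  in a few seconds.
* One master seed fans out to every stage through a counter-based
  derivation (`derive_seed()`), so stages can be re-run independently and
  whole-pipeline reruns are byte-identical at the report level.
* Published-table verification tolerates one unit in the last printed
  digit: a handful of cells in the wider subset table were double-rounded
  at the source (e.g. 63/76 = 82.89 printed as 82.90), while every cell
  of the head-to-head comparison table reconstructs exactly.
* Degenerate inputs are first-class: constant features are rejected at
  scaling time with the feature named; single-class cohorts are rejected
  before training; zero-width profile ranges with positive SD are
  rejected by the generator; a profile SD of 0 collapses a feature to its
  (rounded, clipped) mean.

## Known limitations

Independent-marginal synthesis (no ADNI correlation structure), no
missing-data handling, no longitudinal records, and no confidence
intervals on AUC or CUI — the evaluation reports point estimates in the
same shape as the published tables. The CPN itself is the plain
sequential variant: no batch updates, no growing maps, no momentum.
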