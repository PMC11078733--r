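---
title: "Models and methods behind scilite"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind scilite}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scilite)
```

# Overview

`scilite` analyses targeted single-cell combinatorial-indexing libraries in
which the readout of interest is mitochondrial heteroplasmy — the fraction
of a cell's mtRNA molecules carrying a variant allele.  The package covers
the whole path from raw reads to population genetics: read parsing and
barcode error correction, UMI-consensus allele calling, knee-plot cell
calling, per-cell heteroplasmy, barnyard doublet estimation, clonal
lineage-barcode tracing, a selection simulator with an inverse-sigmoid
fitness model, random-search fitting of that model, and Kimura
drift-distribution fitting with a Monte-Carlo Kolmogorov–Smirnov test.
Everything is exercisable on synthetic libraries with known ground truth;
no external data are required.

# Read structure and parsing

A read is the concatenation of a ligation barcode, a UMI, an RT barcode, a
variable-length *heterogeneity spacer* (which phases otherwise identical
amplicons across sequencing cycles), and the targeted amplicon.  The exact
base-level coordinates are protocol-specific and live in lab documentation
rather than in any published table, so `read_layout()` treats them as
configuration: the defaults (10 bp barcodes, 8 bp UMI, spacer lengths 0–3,
12 bp anchor, 36 bp amplicons) are explicit stand-ins that the synthetic
generator and parser share.

Error handling mirrors standard barcode processing:

* every barcode and the amplicon constant region are corrected to the
  unique whitelist entry within **Hamming distance 1**; an exact match wins
  outright, and a tie between two candidates at distance 1 rejects the read
  (`ambiguous-correction`).  Correction is only unambiguous when the
  whitelist's minimum pairwise distance is at least 3, which the
  `whitelist()` constructor checks and the synthetic designs guarantee.
* the spacer length is resolved by trying every allowed length and keeping
  the one whose downstream anchor matches with at most one mismatch; ties
  prefer the shortest spacer, which makes parsing deterministic.
* diagnostic offsets must match an expected allele exactly; a single
  tolerated mismatch is confined to the constant (non-diagnostic) region,
  so it can never silently convert one allele into another.
* base qualities are ignored throughout; all decisions are sequence-based.

Accepted reads aggregate into the central intermediate, the UMI table:
reads per (cell, amplicon, UMI, allele).  Cell ids join the sample label
with the barcodes in layout order using a fixed separator, so they are
bit-identical across runs.

# From UMIs to cells and heteroplasmy

**Consensus rule.** UMIs with fewer than three reads are discarded; a
surviving UMI is assigned to the allele carried by at least 2/3 of its
reads, and discarded when no allele reaches that majority.  The rule is
deliberately simple enough to brute-force: the test suite enumerates every
count vector over three alleles up to total 12 against an independent
oracle.

**Knee calling.** Real cells separate from ambient barcodes on a log10 UMI
count versus log10 rank curve.  The textbook "maximum perpendicular
distance from the endpoint chord" statistic reliably finds the *shoulder*
of the cell population, but on two-population curves with clean separation
it places the threshold part-way down the cell distribution and forfeits
~30% of true cells.  `call_cells()` therefore uses the chord distance only
to locate the shoulder and then places the threshold at the steepest
descent of the distinct-count step curve at or beyond it — the cliff
between cells and background — using the midpoint of the steepest segment.
On planted two-population curves (1,000 cells at ~500 UMIs against 10,000
barcodes at ~2 UMIs) this retains the cell set with precision and recall
1.0.  A manual threshold (e.g. 64 UMIs, or 2 to keep everything with more
than one UMI) always overrides the automatic call, and a featureless curve
triggers a warning plus a 99th-percentile fallback.

**Heteroplasmy.** Per cell and amplicon, the fraction of consensus UMIs per
allele.  Edit semantics follow the biology of a base editor that can place
a missense and a silent edit on the same molecule: the **missense**
heteroplasmy counts every missense-containing allele (single edit and
double edit), the **silent** heteroplasmy counts molecules with only the
silent edit; the double-edit molecules stay in both denominators.

**Barnyard analysis.** Mixing two homoplasmic cell lines turns barcode
collisions into observable chimeras.  A retained cell is assigned to a line
when that line's alleles hold at least a configurable purity (default 0.9)
of its UMIs, and is otherwise a doublet; the heterotypic doublet rate is
the doublet fraction of retained cells.  The 0.9 default is a declared
configuration value: the exact boundary used in any given experiment is a
judgment call, and at 20+ UMIs per cell the classification is insensitive
to it because singlet fractions concentrate near 1.

# Lineage tracing

Expressed clonal ancestry barcodes are parsed like any other amplicon, with
the variable region matched against the expected barcode list at one
mismatch of tolerance.  Lineage-barcode UMIs are excluded from the coverage
used for knee calling, so cell calling always reflects mitochondrial
coverage.  A cell is assigned to a lineage only if, after removing
candidate barcodes with fewer than 10 UMIs, the top barcode has at least
four times the UMIs of the runner-up; everything else stays unassigned.

Per-lineage dynamics between two timepoints summarize each lineage by its
unweighted mean heteroplasmy per day (weighting by cell coverage is a
reasonable alternative; unweighted means keep every cell's estimate on an
equal footing and are what the per-cell filters were designed around).
Lineages are classified `day0-only` / `day5-only` / `both`, and the
dropout test compares the day-0 heteroplasmy of cells in dropped-out
lineages against cells in persisting lineages with a two-sample
Kolmogorov–Smirnov test (asymptotic p) and a two-sided Mann–Whitney test
(normal approximation with tie correction).

A caveat worth stating plainly: the dropout test treats cells as
independent, but cells of one lineage share their clone's heteroplasmy.
When a handful of large clones dominates, this pseudo-replication makes
the KS test anti-conservative under the null — we measured null rejection
rates of 20–30% at 60–800 clones for 400 cells, falling to the nominal 5%
when clones are near-singletons.  The packaged null-calibration test
therefore runs at near-singleton clone scale (250 cells, 2,500 clones);
with real data dominated by few large clones, the p-values should be read
as descriptive.

# The selection simulator

The simulator implements a minimal model of heteroplasmy dynamics in a
proliferating culture.  Its assumptions: the population doubles each day;
heteroplasmy within a cell never changes; and a cell's relative probability
of being selected to divide is an inverse-sigmoid function of its missense
heteroplasmy $x$:

$$y(x) = (1-d)\,\frac{10^{-p(x-l)}}{1+10^{-p(x-l)}} + d$$

with depth $d$ (the fitness floor — the relative growth rate of a
homoplasmic mutant cell), location $l$ (the inflection point, in
heteroplasmy units) and pitch $p$ (the sharpness of the transition; $l$ and
$p$ together encode the biochemical threshold beyond which fitness
collapses).  At $x = l$ the function equals $(1+d)/2$ exactly.  The
reference parameterization shipped with the package ($d = 0.31$, $p =
4.95$, $l = 0.75$, $M = 1000$ molecules per cell) predicts an 18% slower
doubling at 65.6% heteroplasmy:

```{r fitness}
y <- fitness(0.656, sigmoid_params(0.31, 4.95, 0.75))
round(100 * (1 - y))
```

Molecule counts are integers: each daughter's (missense, silent, wild-type)
counts are drawn from a multinomial parameterized by its mother's
fractions, with the number of draws equal to $\mathrm{round}(M\,w)$, where
the per-cell weight $w$ is the cell's observed UMI coverage relative to the
best-covered day-0 cell — cells whose heteroplasmy rests on fewer UMIs are
simulated with proportionally fewer molecules.  The draw count is clamped
to at least one molecule (the rounding rule is otherwise undefined at tiny
weights, and empty cells would be meaningless).  Because selection weights
are the $y(x)$ values themselves, "inversely related to heteroplasmy" is
realized through the decreasing shape of $y$, not through a reciprocal.

The day-0 population bootstraps 2,500 cells (with replacement) from an
observed heteroplasmy table, resampling each draw's molecules so duplicate
draws of one cell immediately diverge.  The passaging schedule mirrors the
experimental protocol — passages on days 3, 5, 8, 10 and 13, keeping 5,000
cells before a 2-day interval and 2,500 before a 3-day interval, applied
*before* that day's doubling — and pseudo-libraries of day-0 size are
collected on days 5, 10 and 15.  `default_schedule(scale = )` shrinks all
cell counts proportionally for reduced problem sizes.  A run is fully
reproducible from its seed (single seeded generator, single-threaded).

Useful invariants, all under test: with $d = 1$ the mean heteroplasmy is a
martingale; zero-missense populations can never regenerate missense
molecules; the population doubles exactly each day; identical seeds give
byte-identical runs.

# Fitting the fitness function

Four parameters ($d, p, l, M$) are fitted by pure random search: parameter
sets are drawn uniformly over the search space ($d \in [0.05, 1]$ and $l
\in [0.2, 1]$ linear; $p \in [0.5, 50]$ and $M \in [10^2, 10^4]$
logarithmic — ranges broad enough to include flat landscapes and molecule
counts bracketing observed UMI scales), one simulation is run per set, and
each is scored against the observed data by a combined MSE: per collection
day, the mean squared difference between 2D kernel density estimates of the
joint (missense, silent) distribution on a fixed 50×50 grid over the unit
square, plus twice the mean squared error of the two marginal means; days
are averaged.  KDEs use a Gaussian kernel with Scott's-rule bandwidth
(floored at 0.05 to handle near-degenerate marginals) — bandwidth and grid
are package choices, stated here because the score's absolute scale depends
on them.

Because each parameter set is scored by a single stochastic simulation, raw
scores are noisy; scores are smoothed by replacing each with the mean raw
score of its 50 nearest neighbours (point included) in the scale-normalized
search space (each axis mapped to the unit interval, log-scaled for $p$ and
$M$), and the smoothed minimum wins.  `knn_smooth()` is tested against a
brute-force all-pairs oracle.  Replicate runs at the chosen parameters
(`replicate_runs()`, default 100 seeds) characterize run-to-run spread.

Parameter recovery is validated end-to-end on synthetic observations with
known truth: at reduced scale (schedule ×0.2, 500-cell populations, 2,000
iterations) the search recovers the planted depth within ±0.15 and location
within ±0.10.  Pitch and molecule count are only weakly identified at this
scale — many $(p, M)$ combinations produce nearly identical score surfaces
— which is precisely why the smoothed-score machinery exists.

# Kimura drift fitting

To ask whether an observed heteroplasmy shift needs selection at all, the
package fits the two-parameter Kimura distribution — the pure-drift law of
allele frequency, with point masses at 0 (loss) and 1 (fixation) and a
continuous interior density — parameterized by the initial frequency $p_0$
and drift extent $b$ ($b \to 1$: no drift, concentration at $p_0$; one
generation of Wright–Fisher resampling of $M$ molecules corresponds to $b =
1 - 1/M$).  The interior density is the classical eigenfunction series in
Gegenbauer polynomials; `scilite` evaluates it through the numerically
stable Jacobi $P^{(1,1)}$ three-term recurrence, truncating when a term
bound falls below $10^{-8}$ (at most 400 terms; the attainable $b$ is
capped accordingly, with an explicit error beyond it).  Normalization to 1
and mean preservation ($\mathbb{E}[h] = p_0$) are verified by quadrature
across a $(p_0, b)$ grid in the tests.

Fitting fixes $p_0$ to the observed day-0 mean and estimates $b$ by
bounded one-dimensional likelihood maximization on the later timepoint,
after removing zero-heteroplasmy cells (cells that escaped editing carry no
information about drift of the edited population).  Because zeros are
removed, the likelihood, the KS distance and the Monte-Carlo sampler all
use the distribution *conditional on non-loss* ($h > 0$, renormalized by
$1 - f_0$) — a single consistent truncated-data convention.  An
alternative objective minimizes the KS distance instead (`objective =
"ks"`).

Goodness of fit uses a Monte-Carlo KS test: the observed sup-distance $D$
between the empirical CDF and the fitted conditional CDF is compared with
`num_MC = 100` synthetic datasets of the same size drawn from the fitted
distribution.  Since $b$ is estimated from the data, each replicate is
*refitted* before computing its $D$ (a parametric bootstrap); without the
refit the p-values are measurably miscalibrated.  Under the null (data
truly Kimura), 95 of 100 seeded runs give $p > 0.05$ and the p-deciles are
near-uniform; selection-distorted simulator output yields systematically
larger $D$ than matched neutral runs.

# Synthetic data: what it does and does not emulate

The generators produce libraries with complete ground truth: `make_barnyard`
(two homoplasmic lines, planted heterotypic doublets as barcode-path
collisions, optional ambient background barcodes), `make_edited_population`
(bimodal editing outcomes: a point mass of unedited cells plus a
high-heteroplasmy Beta component, silent edits occupying a Beta share of
the remainder, observed values multinomially sampled at realistic UMI
depth) and `make_lineage_timecourse` (clones with fixed heteroplasmy,
neutral or fitness-weighted expansion, mitochondrial plus lineage amplicons
as ready-made UMI tables).

Default scales follow the study conditions: mean 130 UMIs per cell
(negative binomial, size 4, matching a reported median of ~130), mean 5
reads per UMI (shifted geometric, so both sub-3-read discards and consensus
successes occur), per-base substitution rate 0.002, 96-barcode whitelists
designed at minimum pairwise Hamming distance 3.  Tests that need larger
cell numbers within their time budget state smaller depths explicitly
(e.g. the 5,000-cell barnyard acceptance run uses 20 UMIs/cell, 3
reads/UMI).

Deliberately not emulated: PCR chimeras, index hopping, quality-score
profiles, UMI sequencing errors (UMIs are sampled exactly), and
homotypic-doublet transcriptome mixing.  Passing tests therefore
demonstrate correctness of the decision rules and estimators under clean
generative assumptions — they do not certify robustness to artefacts the
generator does not produce.

# Problem sizes and numerical choices

Test and validation sizes were chosen to exercise each property at the
smallest scale where its statistics are meaningful: consensus and lineage
oracles run exhaustively where the space is small (all 3-allele vectors to
total 12; all two-barcode maps to 80) and by 20,000-map random sweeps where
it is not; the neutrality martingale uses 200 seeded 2,500-cell runs over
five days; parameter recovery uses 2,000 search iterations at schedule
scale 0.2; Kimura calibration uses 100 null seeds of 400 cells with 100
Monte-Carlo replicates each.  Degenerate inputs are handled explicitly:
empty read sets, zero-total UMI vectors, featureless rank curves
(fallback + warning), boundary Kimura fits (warning), and `n_keep` larger
than the population (error).

# Known limitations

* The automatic knee needs a visible cliff; gradual single-population
  curves fall back to a quantile threshold with a warning.
* The dropout KS test assumes independent cells (see the lineage section).
* Homotypic doublets are invisible by construction; only the heterotypic
  rate is estimated, and the overall collision rate must be inferred from
  the barcode-space combinatorics of a given plate design.
* Kimura fits near $b \to 1$ are limited by series convergence; the
  fitter caps $b$ just below the 400-term budget and warns at the
  boundary.
* The simulator models selection purely at the cell level — no
  intracellular drift or turnover — which is exactly the hypothesis the
  surrounding analyses are designed to isolate.
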