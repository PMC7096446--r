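---
title: "Methods: charged-domain scanning and the capsid-genome charge balance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: charged-domain scanning and the capsid-genome charge balance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chargescan)
```

## The problem

Many icosahedral viruses carry arginine-rich, positively charged terminal
segments ("R-arms") on their capsid proteins. These segments point into the
particle interior, contact the packaged genome, and in several model viruses
are required for assembly and stability. They are hard to find by sequence
profile or structure comparison: they are poorly conserved, variable in
length, and usually disordered. What they do share is a simple biophysical
signature — a short stretch of sequence with an unusually high net positive
charge. `chargescan` finds and characterises such stretches, and tests the
electrostatic bookkeeping they imply: does the total positive charge a
capsid presents to its interior track the negative charge of the genome it
packs?

## Net-charge model

Each residue contributes an integer charge: K and R count +1, D and E count
-1, and every other residue — including histidine and the ambiguity codes
B, Z, X, U, O — counts 0. Terminal amine/carboxyl charges are ignored. This
integer scheme is deliberately simple; fractional pKa-based charges at fixed
pH give closely similar rankings of windows while complicating exact
reasoning about window sums, and are not implemented.

The net charge of a window of `w` residues starting at 1-based position `s`
is the sum of its residue charges, written `Q`; its charge concentration is
`Qc = Q / w`. Windows include both endpoints, so a protein of length `L` has
`L - w + 1` windows.

### Fixed-frame scan

`scan_fixed()` computes `Q` for every window of a fixed frame (default 30
residues, a typical disordered N-arm length; 10 and 60 are common
alternatives) in one rolling pass. `max_fixed_window()` keeps the earliest
window of maximal charge: a stored window is replaced only when a later
window is *strictly* higher, which makes the tie-break reproducible and
order-independent of implementation details. Proteins shorter than the
frame are scored as one whole-sequence window and flagged `truncated`; they
are kept in per-protein tables but excluded from fragment-frequency
statistics, which are normalized by window counts.

### Variable-frame search

A fixed frame cannot resolve domain size. `variable_frame_search()` starts
from the best window at a minimum frame (default 10) and then considers the
best window at every larger frame up to the protein length. A longer
candidate replaces the stored domain only if its charge is strictly higher
*and* an acceptance gate passes. Two gates are provided:

* **fixed-threshold** (default): the candidate's `Qc` must be at least
  `qc_threshold` (default 0.23). This is the rule used for the package's
  domain-size analyses; the threshold is the published operating point that
  keeps one positive charge per ~4.3 residues.
* **monotone-ratio**: the candidate's `Qc` must exceed the stored domain's
  own `Qc`. This stricter reading forces the concentration to improve with
  every replacement.

Both rules suppress long stretches that dilute charge. The two modes can
disagree; the default reproduces the behaviour the fixed threshold was
calibrated for, and the alternative is kept behind the `mode` argument
because the verbal descriptions of the procedure admit both readings. Within
one frame size the maximal-`Q` window is also the maximal-`Qc` window, so
the gate needs to be evaluated only for the per-frame best.

## Enrichment statistics

Charge spectra are fragment counts per integer charge value `j`, normalized
per group. Whether a group is over-represented at a charge value is tested
with a right-sided hypergeometric test: with `m` reference fragments at
charge `j`, `n` reference fragments at other charges, and `k` fragments in
the group, the probability of observing `x` or more is
`P[X >= x] = 1 - F(x - 1; m, n, k)`, computed via `stats::phyper` in the
stable log-space tail. The expected count is `m k / (m + n)` and the fold
change is `x` over that expectation. The family of tests for one
group-versus-reference panel is adjusted by Benjamini-Hochberg
(`fdr_adjust()`, a checked wrapper over `stats::p.adjust`); the family is
per panel because each heatmap panel is interpreted on its own. The group is
not removed from the reference when it is a subset of it, matching the urn
definition over the whole proteome. Only enrichment is tested; depletion is
visible as fold < 1 without a p-value.

## Composition profiling

`rk_ratio_by_charge()` pools arginine and lysine counts over all windows at
each charge value and reports `J_j = sum(R) / sum(K)` with its log2. Pooling
is exact integer arithmetic, identical to the count-weighted combination
over windows. When a charge value has no lysines at all the ratio is
reported as `Inf` (rendered as the extreme of a heatmap scale); a
pseudo-count mode `(R+1)/(K+1)` exists but is off by default because it
silently shifts every ratio.

`positional_heatmap()` places each window with `Q` at or above a threshold
(default +7, the charge that all families in the balance fit reach) at its
normalized start position, `(start - 1) / (L - frame + 1)`, binned at width
0.01 and clamped to bin 99. The start anchor is used because it is the
position the scanning algorithm stores; centre or end anchors would shift
profiles by a constant fraction of the frame.

`census_filter()` lists proteins having at least one window that passes both
a charge threshold (+7 or +14) and a within-window composition ratio
(R/K >= 4 or K/R >= 4). The ratio is evaluated inside the qualifying window,
not over the whole protein, because the signature of interest is a compact
segment. A window with R > 0 and K = 0 passes R/K >= 4 (infinite ratio).

## Capsid-genome charge balance

For a virus with known capsid stoichiometry, the total interior charge is
`Total Q_max = sum over protein species of copies x Q_max30res`, using
actual copy numbers (e.g. 360 copies of a pentamer protein plus 72 of a
minor protein). The genome charge magnitude `Q_genome` counts one charge
per nucleotide residue of the longest genome segment. A double-stranded
genome has residues on both strands, so each bp contributes two charges by
default; `single_strand_count = TRUE` flips this for sensitivity analysis,
because published analyses do not always state which convention they use.
Phages that pump their genome with an ATP-dependent motor do not rely on
R-arms and are excluded from the fit by default (`motor_packaged` flag).

`rout_fit()` fits `capsid ~ genome` robustly and flags outliers:

1. iteratively reweighted least squares under the Lorentzian (Cauchy) loss,
   weights `1 / (1 + (r/s)^2)`, starting from ordinary least squares,
   with the scale `s` re-estimated each iteration, until the relative
   parameter change is below `1e-8` (cap 100 iterations);
2. the robust scale is the RSDR: the 68.27th percentile of absolute
   residuals times `sqrt(N / (N - 2))`;
3. each point's `t = |r| / RSDR` gets a two-tailed p-value on `N - 2`
   degrees of freedom, and a Benjamini-Hochberg step at rate `Q` (default
   5%) flags the outliers;
4. slope, intercept, Pearson r and its two-tailed p-value are recomputed on
   the inliers by ordinary least squares.

This follows the published ROUT outline (robust fit, RSDR-scaled residuals,
FDR step at Q = 5%); bit-exact parity with commercial implementations is
not claimed — the validation here is recovery of planted structure in
generated data. The reciprocal of the slope is the capsid/genome charge
ratio. Both the robust and the inlier-OLS coefficients are reported so
either reading of "the fitted line" can be checked, and the inlier Pearson
correlation is also reported after removing whole families that contain an
outlier, since family-level and virus-level exclusion are both defensible.

FDR control means a small number of *extra* flags among many true
detections is expected behaviour, not an error; the false-positive rate on
clean data and the recall of grossly displaced points are the properties
the test suite asserts.

## Synthetic data

The generators make every stage testable without external downloads, under
one global seed with per-generator substreams (adding a generator never
shifts another's stream; reruns are byte-identical).

* `gen_proteome()` draws i.i.d. background residues (default uniform over
  the 20 canonical residues) and implants, in a chosen fraction of
  proteins, a domain of exact net charge `Q*`, length `L*`, and R:K mix
  `rho`, padded with neutral residues drawn from A, G, S, T, P — chemically
  plausible spacers that cannot perturb the charge. The truth table records
  the implant position and parameters.
* `gen_capsid_dataset()` draws genome lengths uniformly (default 1-12 knt,
  the span of small icosahedral viruses), sets
  `capsid = beta * genome * (1 + eps)` with `eps ~ N(0, sigma)` (defaults
  `beta = 1/1.4`, `sigma = 0.02`), rounds to integers, back-derives a
  per-subunit charge from a drawn subunit count (60/120/180/240), and
  displaces planted outliers by a multiple of the local noise SD. Because
  the displacement scales with each virus's own genome while the detector
  uses a global residual scale, truth-recovery checks use a genome range
  within a ~3x span so every planted outlier is globally gross.
* `gen_enrichment_groups()` draws a reference spectrum from a discrete
  near-Gaussian core with a heavy uniform tail (so extreme charges are rare
  but present, as in real proteomes) and a group with one charge value
  oversampled by a chosen fold; fold 1 gives an exact null draw.

What the generators do *not* emulate: real amino-acid composition and its
correlations along sequences, phylogenetic correlation between related
viruses, family-level clustering of capsid architectures, and curation
noise in stoichiometry tables. Passing tests therefore demonstrate
algorithmic correctness and statistical calibration under the stated
models, not the field-data effect sizes themselves, which require the
curated external datasets.

## Numerical choices and degenerate inputs

* Window sums are exact integer arithmetic; the rolling scan is verified
  against naive summation, and the variable-frame search against brute
  force over all substrings, at test time.
* Hypergeometric tails are computed in log space; small-urn values are
  verified against exhaustive enumeration (all urns with `m + n <= 12`).
* `rout_fit` requires at least 5 points and non-degenerate `x`; a perfect
  fit (RSDR 0) short-circuits with no outliers; an all-equal `y` returns
  slope 0 and r = 0.
* Sequences shorter than the frame: one truncated whole-sequence window,
  excluded from spectra, included (flagged) in per-protein tables.
* Empty FASTA files warn and return an empty table; malformed records,
  duplicate accessions, residues outside the accepted alphabet, copy
  numbers below 1, and unknown genome types are hard errors that name the
  offending record or row.

## Problem sizes used by the test suite

The suite validates the scanners on 1,000 (fixed) and 500 (variable)
random sequences against independent oracles, outlier control on 200
seeded clean datasets of n = 50, slope recovery on simulated capsid sets of
n = 50, the full pipeline on a 133-virus simulation with 20 planted
outliers, and enrichment calibration on 150 null draws plus 20 spiked
draws. These sizes make the statistical properties measurable while
keeping the default test run fast on a single CPU.

## Worked example

```{r example}
fasta <- system.file("extdata", "synthetic_proteins.fasta",
                     package = "chargescan")
records <- read_fasta(fasta)
qmax_table(records, frame = 30)

sim <- gen_capsid_dataset(n_viruses = 60, beta = 1 / 1.4, sigma = 0.02,
                          n_outliers = 3L, displacement = 10, seed = 7L)
rep <- balance_report(sim$entries)
glance(rep$fit)
```

## Limitations

* The integer charge model ignores pH, phosphorylation, and context
  effects; it ranks windows, it does not compute electrostatics.
* Capsid totals depend on curated copy numbers; uncertain stoichiometries
  (e.g. minor peptides) propagate directly into `Total Q_max`.
* The outlier procedure assumes homoscedastic residuals around a single
  line; strongly heteroscedastic data (charge scaling with genome size)
  will under-flag small-genome outliers.
* Group-versus-reference tests assume the group is drawn from the
  reference universe; disjoint comparisons where a group charge count
  exceeds the reference's are rejected rather than silently mis-modelled.
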