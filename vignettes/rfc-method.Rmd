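---
title: "Predicting phosphoinositide binding of PH domains with a log-ratio scoring matrix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting phosphoinositide binding of PH domains with a log-ratio scoring matrix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rfcph)
```

## The model

`rfcph` treats PIP binding of a pleckstrin homology (PH) domain as a
property predictable from its aligned sequence alone. The training input
is a multiple sequence alignment (width $L$ columns, alphabet of the 20
standard amino acids plus the gap character) together with a binary label
per sequence: *binder* or *non-binder*, as determined by a single-molecule
vesicle-pulldown assay.

For each label group a position $\times$ amino-acid probability matrix is
estimated by simple counting:

$$ P^{B}_{ja} \;=\; \frac{\#\{\text{binder sequences with residue } a
\text{ at column } j\}}{\#\{\text{binder sequences with any residue at
column } j\}} $$

and analogously $P^{NB}$ for the non-binders. The scoring matrix is the
entrywise log-ratio $M_{ja} = \log\!\left(P^{B}_{ja} / P^{NB}_{ja}\right)$,
and a domain with residues $r_1 \dots r_L$ scores

$$ S_{\mathrm{RFC}} \;=\; \sum_{j \,:\, r_j \neq \text{gap}} M_{j r_j}. $$

The additive form encodes the model's central assumption: **each column
contributes independently** to binding. This is the same naive-Bayes-style
independence assumption underlying classical position-specific scoring
matrices; it ignores covariation between positions (e.g. compensatory
pairs across the β1–β2 and β3–β4 loops) and is a known simplification.

Because the score is a sum over columns, it decomposes exactly over any
partition of the columns. `score_all()` therefore reports, alongside the
full score, per-region components (e.g. the β1–β2/β3–β4/β6–β7 variable
loops plus the complement, "rest of domain"), and `region_fractions()`
normalizes them into relative contributions per sequence. When all
components are zero the fractions are undefined and reported as missing
rather than propagated as `NaN`.

Candidate determinant positions are ranked by the per-column contribution

$$ c_j \;=\; \frac{1}{20}\sum_{a} M_{ja}^2, $$

the mean of the squared matrix entries across the 20 amino acids. The
mean is taken over the amino-acid axis (the only reading under which
$c_j$ is comparable across columns regardless of how many residues were
observed); ranking ties are broken toward the lower column index so the
ordering is deterministic.

## Zero frequencies: two policies, two uses

$\log(P^B/P^{NB})$ is undefined when either frequency is zero, which with
group sizes of a few dozen sequences happens constantly. Two policies are
implemented and every serialized matrix records which one produced it:

* **`zero-out`** (scoring default): the entry is set to 0 whenever either
  group frequency is 0. Residues absent from a group are treated as
  uninformative, all scores stay finite, and a query residue never seen
  in either group contributes exactly 0. This matches the convention that
  an amino acid enters the probability matrix only if observed at least
  once in the group.
* **`pseudocount`**: $\varepsilon = 0.5$ is added to every count and
  $20\varepsilon$ to every denominator, so all entries are finite.

The two policies suit different questions. For *scoring and
classification* the zero-out rule is a conservative default. For
*determinant discovery* it has a structural blind spot: at a strongly
discriminating column the binder-preferred residue is often entirely
absent from the non-binder group, and zero-out deletes precisely that
entry — the strongest evidence the column carries. The contribution
profile then under-ranks true determinants. For contribution profiling
the pseudocount policy is therefore the recommended choice, and the
package's own determinant-recovery analyses use it (reported with the
policy name, as all results should be).

## The scrambled-sequence null and the binding call

The binding-call cutoff is derived from sequences in which the signal has
been destroyed but the composition retained: each sequence's non-gap
residues are uniformly permuted among its non-gap positions (the gap mask
is fixed, preserving per-column support; a `scramble_gaps` switch permutes
across all positions for sensitivity analysis). Each sequence is scrambled
once by default — `n_replicates` can tighten the null — and scored with
the same matrix. The threshold is

$$ t \;=\; \bar{S}_{\text{scr}} + k \cdot \mathrm{SD}(S_{\text{scr}}),
\qquad k = 3 \text{ by default}, $$

with the sample SD ($n-1$ denominator; the standard estimator). A domain
is called a predicted binder **iff** $S_{\mathrm{RFC}} > t$, strictly: a
score exactly at the threshold is a non-binder call. The scramble is
driven by a single recorded integer seed and is exactly reproducible; two
runs with identical inputs, policies and seed produce identical null
distributions, thresholds and calls. With fewer than two scrambled scores
the SD is undefined and the derivation refuses to proceed. A degenerate
all-zero matrix gives a threshold of exactly 0 for any $k$.

`run_pipeline()` derives the null from the pooled training-plus-query
sequences, mirroring the family-wide null of the original analysis (the
published cutoff was derived from all 242 domains, assayed and not).

## Evaluation conventions

Predictions are crossed with binary assay outcomes into a confusion
matrix; accuracy, precision, recall and F1 follow the standard formulas,
and any metric with an undefined denominator is reported as missing,
never silently 0. Proteins that bound vesicles promiscuously (including
the lipid-free control — likely misfolded) are excluded from the
binder/non-binder cross but remain in the denominator of the assayed
binder fraction: they were assayed, and simply did not bind PIPs with
specificity. That convention reproduces the published 36/67 (54%)
arithmetic from the packaged outcome tables. Printed percentages are
rounded to the nearest integer, half away from zero; metrics are reported
to three decimals.

The packaged fixtures deserve a caveat: the 67-protein outcome table is a
full transcription of the published assay tables, whereas in the
31-protein validation fixture only the single false positive (PSD3) and
one false negative (CYTH3) are identified by name — the remaining ids are
placeholders and the fixture's ground truth is the published *counts*
(19/1/3/8), not the identities. The training-label fixture likewise
carries 5 placeholder ids for second PH domains of multi-domain proteins
(hence its `_synthetic` suffix).

## The synthetic generator: what it emulates, and what it does not

`simulate_alignment()` draws fixed-width alignments column-independently:
every column uses a common background distribution over the 20 residues
(uniform by default; `empirical_background()` of any real alignment can
substitute), except at a chosen set of *determinant columns*, where the
binder group's distribution is mixed with probability mass `effect` on a
column-specific preferred residue. With `contrast = "both"` the
non-binders are likewise enriched for a different residue, mimicking
positions that penalize binding. Gaps are i.i.d. per position at
`gap_rate`. `effect = 0` makes the groups exchangeable by construction.
Generation is byte-reproducible from the spec's seed, and the returned
ground truth can be fed back to generate held-out sequences from the same
planted preferences under a new seed.

The generator deliberately mirrors the scorer's independence assumption,
which makes it a *calibration* instrument, not a realism instrument. It
does not emulate:

* **conservation structure** — real PH-domain columns are far from
  uniform; many are strongly conserved in both groups, so their
  log-ratios are near zero and the scrambled null is tight. A uniform
  background is the maximum-entropy worst case: with ~40 sequences per
  group every non-determinant column contributes sampling-noise
  log-ratios, inflating the null SD and hence the mean + 3 SD threshold.
  Classification of synthetic held-out data at that threshold is
  consequently high-precision but recall-limited at these sample sizes —
  the package's acceptance script computes exactly this behaviour — while
  on real alignments the same cutoff is far less punishing. Passing
  synthetic tests therefore demonstrates correctness and calibration of
  the machinery, not the sensitivity attainable on real data;
* **phylogenetic correlation** — sequences are i.i.d., with no shared
  ancestry;
* **indel structure** — gaps are independent per position, not block
  insertions; alignment curation is out of scope.

## Numerical and interface choices

* **Coordinates are 1-based closed intervals** everywhere (R's native
  convention, as in IRanges), including region files; a region file may
  declare `# coords: 0-half-open` in a header comment and is converted on
  read.
* **Logarithm base**: natural log by default; base 10 available
  (`log_base = "10"`), which scales every entry, score and threshold by
  exactly $1/\ln 10$. The choice cannot be disambiguated from published
  summary numbers alone, so it is explicit and recorded in every output.
* **Frequency denominator**: non-gap count at the column (default), so
  partially gapped columns still normalize to 1; `"group-size"` divides
  by the number of group sequences instead. Both are provided because the
  treatment of gaps in the published matrices is unstated.
* **Alphabet**: strictly the 20 standard amino acids; nonstandard codes
  (B, J, O, U, X, Z) are rejected unless explicitly masked to gaps.
* **Degenerate inputs**: all-gap columns yield all-zero probability rows;
  an empty label group, ragged alignment rows, out-of-range intervals and
  unknown residues all fail fast with the offending id or column named.
* **Additivity tolerance**: region components are validated against the
  full score at $10^{-9}$ (floating-point summation order differs between
  the region-wise and full sums).
* **Determinism**: every seeded helper restores the caller's RNG state,
  so library calls never perturb a user's random stream.

## Problem sizes in the test suite

The package's tests run the full pipeline at deliberately compact sizes
chosen to exercise every code path with comfortable statistical margins:
training sets of 40+40 sequences over 100 columns with 8 planted
determinants for recovery and power analyses, 20-seed averages for null
calibration (held-out $n = 100$ per seed, observed false-call rate well
under 1%), 50-seed averages for exchangeability at zero effect, and
100 random instances for the exact equivalence check between the
vectorized scorer and a naive per-residue reference loop.

## Known limitations

The method is strictly binary — it predicts *whether* a PH domain binds
PIPs, not *which* PIP species — and its accuracy on real data is bounded
by the label noise of a binary pulldown assay and by alignment quality
(it consumes a structure-aware alignment; it does not compute one).
Columns absent from the training alignment's variability, covarying
position pairs, and determinants lying outside the aligned region are
invisible to it.
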