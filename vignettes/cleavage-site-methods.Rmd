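---
title: "Models and methods for prohormone cleavage-site prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for prohormone cleavage-site prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(procleave)
```

## The problem

Neuropeptide prohormones are secreted precursor proteins processed in
the regulated secretory pathway: a signal peptidase removes the
N-terminal signal peptide, and prohormone convertases then cut the
mature region, almost exclusively C-terminal to basic residues, to
release bioactive peptides. Predicting which K/R residues are cleaved
is a binary classification problem over candidate sites, and the basis
for deciding whether a newly annotated precursor can produce a given
peptide at all.

`procleave` operationalises this as follows. Every K or R residue is a
**candidate site** (the broadest convention under which "proportion of
possible sites that are cleaved" is well defined); consecutive basic
residues each yield their own candidate, and annotation matching is
exact-position. Candidates inside the annotated signal peptide are
excluded by default, because the signal is removed by signal
peptidase, not by a convertase; the exclusion is toggleable
(`site_config(exclude_signal =)`) since curated data sets differ in
whether signal-region basics are even annotated.

Positional nomenclature: the P1 residue precedes the scissile bond; P2
and P4 are one and three residues N-terminal of P1. The named motifs
are `xxKR` (K at P2, R at P1), `xxRR` (R at P2, R at P1), `RxxR` (R at
P4, R at P1) and `singleR` (R at P1, nothing basic at P2 or P4). Tags
overlap by construction — an `RR` pair with an arginine at P4 is both
`xxRR` and `RxxR` — and sites matching nothing named (including every
K-at-P1 site without a dibasic partner) are tagged `other`, so each
site carries at least one tag. Dibasic variants with K at P1 (`xxKK`,
`xxRK`) stay under `other` because only the four patterns above have
an established name in the cleavage literature; the known-motif *rule*
still fires on them, since convertase specificity is to the basic pair
rather than to its orientation.

All coordinates, internal and reported, are 1-based — the natural
convention in R — and every output header states it.

## Predictors

**Known-motif rule.** A site is called cleaved iff P1,P2 ∈ {K,R} or
P1 = P4 = R. This is a zero-parameter model encoding cross-species
convertase specificity; its scores are in {0, 1}, so a full ROC curve
is degenerate and no AUC is reported for it.

**Logistic regression.** Windows are encoded position-major: per
position a one-hot over 21 symbols (20 residues + `X` for
pad/unknown), optionally followed by that position's physicochemical
property values (scheme `AA_PROP`). The fit minimises the Bernoulli
negative log-likelihood plus a ridge penalty `n·l2/2·‖w‖²` (intercept
unpenalised). Two deliberate choices here:

* the penalty guarantees a finite, unique optimum even when the
  encoding linearly separates the classes — which happens routinely
  with 21 indicators per window position;
* scaling the penalty by the number of observations makes the fit
  exactly invariant to duplicating the training set, a property the
  test suite checks.

The default `l2 = 1e-4` (per observation) is weak enough to leave
coefficients essentially unshrunk at realistic sample sizes. The solve
is full-batch BFGS from a zero start (relative tolerance 1e-10, cap
1000 iterations), hence deterministic; the `seed` argument is recorded
in the artifact for a uniform contract across model kinds.

**Neural network.** One hidden layer of logistic units (default 5)
with a sigmoid output, trained by full-batch BFGS on the penalised
cross-entropy (same per-observation ridge on weights, biases free)
from a seeded uniform(−0.5, 0.5) initialisation; relative tolerance
1e-6, default cap 5000 iterations, non-convergence recorded in
`train_meta` with a warning but the model still returned. Hidden units
buy exactly one thing over the logistic model: positional
interactions. The test suite demonstrates this on an XOR-structured
window problem that provably (by grid enumeration over additive
scores) admits no linear separator but is solved with two hidden
units. Training is single-threaded and deterministic given inputs and
seed; identical calls reproduce bit-identical parameters. Because the
objective is non-convex, different seeds can reach different local
optima — the seed is part of the model's identity.

**Thresholding.** Scores are turned into calls by `score ≥ threshold`
with default 0.5; published evaluations in this field report single
operating points without stating cutoffs, so the midpoint is the only
neutral choice, and it is stored in (and overridable on) every model.

## Physicochemical property set

The `AA_PROP` scheme ships five classical scales: Kyte–Doolittle
hydropathy, residue volume (Å³), net side-chain charge at pH 7,
Grantham polarity, and Chou–Fasman helix propensity. Which scales the
published human models used is not recoverable, so the set is a
declared package default: it is configurable
(`load_property_table(path)`), versioned as a plain TSV, z-score
standardised over the 20 residues at load time (so scales are
commensurable regardless of units), and embedded with a hash in every
serialised model artifact. The pad symbol `X` maps to the all-zero
property vector — neutral after standardisation.

## Evaluation suite

`compute_metrics()` derives CCR, sensitivity, specificity, PPV, NPV
and Matthews correlation from the confusion quadruple; any statistic
with a zero denominator is *undefined* and reported as such (printed
`"undefined"`, stored `NA`), never silently propagated — curated data
never hit this case, so a convention had to be chosen, and "undefined"
is less misleading than 0. ROC AUC uses the rank (Mann–Whitney) form
with mid-rank tie correction, which is threshold-free and exact; the
tests verify it against exhaustive pairwise enumeration and an
independent ROC implementation. Display rounding is half-away-from-zero
to 4 decimals (`round_half_up()`), matching the convention of
published comparison tables; R's own `round()` rounds half to even and
would disagree on boundary cases.

`compare_models()` lays results out as the standard criteria × models
matrix (four counts, six statistics, AUC) and ranks models by CCR.

## The synthetic generator

`generate_prohormones()` emulates the statistical structure a curated
prohormone set presents to this pipeline: 70–300 aa sequences, a
signal peptide of 18–30 aa with probability 0.9, background K/R at
rate 0.11 (the natural K+R frequency, split evenly), a target cleaved
prevalence of 0.146 among candidates, and a motif mixture over cleaved
sites of xxKR 0.45 / xxRR 0.20 / RxxR 0.15 / singleR 0.20. The
mixture was chosen once so that the *marginal* tag frequencies
approximate the overlapping ~71/41/34% dibasic pattern plus a
single-digit-percent monobasic minority seen in curated mammalian
data; the published overlapping percentages constrain but do not
determine a joint distribution, so the mix is a declared
approximation.

Mechanics worth knowing:

* Planting writes only the residues a motif constrains (R at P1; K or
  R at P2; R at P4; for single-R, non-basic residues at P2/P4);
  everything else is background, so decoy dibasics arise naturally at
  the background rate.
* Planted P1 positions are at least 8 residues apart — the smallest
  spacing at which the constrained block of one plant can never enter
  the P2/P4 lookback of another plant's candidates — and never inside
  the signal.
* Prevalence is realised, not assumed: after an initial growth phase
  the generator adds (or drops) planted sites one at a time,
  recounting candidates after each change, until the realised
  cleaved/candidate ratio is as close to the target as a single site
  allows. The "within 3 binomial standard errors" checks in the test
  suite therefore measure the construction, not a tuned constant.
* `no_decoy_dibasics = TRUE` is an oracle mode: the background
  contains no K/R at all, so every candidate is a planted site or one
  of its support residues, and no uncleaved candidate matches the
  default rule. Support residues alone then bound prevalence near 1/2,
  so this mode plants one site per ~30 mature residues and ignores the
  prevalence target. It exists to make "the rule model is a perfect
  oracle on rule-generated data" an exact statement.
* The truth table (`attr(records, "truth")`) carries every candidate
  with its planted motif, letting `truth_confusion()` score predictions
  without the annotation I/O in the loop.

What the generator does *not* emulate: real amino-acid composition
beyond the basic rate (background is uniform over the other 18
residues), sequence conservation and homology structure, convertase
tissue specificity, and post-translational context (amidation
signals, C-terminal processing). Consequently, passing tests show the
pipeline is correct and well calibrated on populations with the
assumed independence structure — not that the trained toy models
transfer to real precursors. In the generated populations, cleavage
depends on the window only through its (P4, P2, P1) basic pattern,
which is why the optimal ("Bayes") classification rate is computable
by grouping candidates by that pattern; the test suite checks that
held-out logistic accuracy lands within 5 points of it.

## Numerical and format choices

* Annotation dialect (`ANNOT.md`): a `.`/`|` track aligned under the
  sequence, 60 residues per line. Chosen over positional lists for
  human readability and lossless byte-identical round trips, which the
  suite asserts. Strictness is a switch: a `|` under a non-basic
  residue is an error by default, a warning in lenient mode (useful
  for data sets that annotate non-convertase cleavages).
* Model artifacts are single self-describing JSON files (schema
  version, kind, scheme, window config, property table + hash,
  parameters, threshold, training metadata); predictions survive a
  round trip to 1e-12.
* The CLI (`run_cli()`, wrapped by `exec/procleave`) logs a manifest
  (parameters, input hashes, timestamp) to stderr and stamps output
  files only with the deterministic manifest hash, so identical seed
  and inputs give byte-identical outputs. Exit codes: 0 success, 1
  data/validation error, 2 usage error.
* Degenerate inputs: sequences without K/R yield empty site tables
  (not errors); training demands both classes; `roc_auc()` refuses
  single-class inputs; `apply_threshold()` refuses cutoffs outside
  (0, 1).

## Problem sizes

The shipped tests and the acceptance script use populations of 10–500
records (up to ~12,000 candidate sites), a held-out third for
generalisation checks, 200 random instances for the AUC brute-force
oracle, and the full 21⁴ grid of P1–P4 windows for the rule/taxonomy
consistency check. These sizes give the binomial checks standard
errors a few times smaller than the tolerances they are tested
against while keeping a full run in well under a minute.

## Known limitations

* The trainable models are surrogates trained on synthetic or
  user-supplied data; the package deliberately does not ship published
  model weights, and "mammalian" vs "human" style models differ only
  in the training corpus supplied, not in code path.
* Sites cleaved by non-convertase proteases (e.g. natriuretic-peptide
  processing by corin) fall outside the motif framework and will be
  systematically missed.
* Whether published evaluations scored every K/R site or a
  pre-filtered subset is not always documented; `procleave` scores
  every enumerated candidate, which can deflate specificity relative
  to filtered setups.
* The ANN objective is non-convex; reproducibility is per-seed, not
  per-problem.
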