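---
title: "fraglogp: model, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fraglogp: model, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope

`fraglogp` estimates the octanol/water partition coefficient (LogP) of a
small molecule from a fragment-count fingerprint with a small feedforward
neural network, and uses the estimate to call fluorescent probes
cell-permeant (`LogP >= 1`) or impermeant (`LogP < 1`). This vignette
records the model, the tunable parameters, and the design decisions that
were genuinely open — in enough detail that a maintainer can audit or
revisit any of them.

## The fingerprint

Each molecule is encoded as an ordered vector of 319 non-negative values,
defined by the *feature registry* (`load_registry()`), a versioned TSV data
file rather than code, so users can audit or extend the vocabulary and
models can record which registry they were trained against. The default
registry has two blocks:

1. **79 E-state atom types** (Hall & Kier's electrotopological classes:
   `sCH3`, `aaCH`, `sOH`, ...). Every heavy atom is assigned to at most one
   class — first matching class in vocabulary order wins — and the feature
   value is the per-class atom count. Only the counts are used; the E-state
   index values themselves (which mix in bonding environment information)
   are deliberately not computed. Atoms outside the vocabulary (e.g. noble
   gases) stay untyped and are reported, not errors.
2. **240 SMARTS fragment features** curated for small-molecule and
   probe-relevant chemistry: functional groups, hydrocarbon and halogen
   environments, element and charge counts, ring/aromatic-system
   membership, saturated and aromatic heterocycles, fused aromatics and
   fluorophore motifs (xanthene bridge, BODIPY BF2, cyanine chain, ...).
   Fragment values are substructure match counts, *deduplicated by matched
   atom set*: symmetry-equivalent mappings onto the same atoms count once,
   so benzene matches the benzene-ring pattern once rather than 12 times.
   Raw isomorphism counts explode on symmetric patterns, which is why the
   unique-set convention is fixed package-wide. Named ring-system scaffolds
   are presence-only (`value_mode = "boolean"`, clipped to 0/1); everything
   else is a count.

The registry is this package's own curation. The atom-type block is the
published Hall–Kier vocabulary; the fragment block was chosen for coverage
of probe chemistry and is not claimed to match any particular external
feature list — the loader only enforces the structural contract (unique
names, contiguous indices, valid SMARTS, and 319 features for the default).

Other fingerprint conventions:

- **Hydrogens are implicit**; SMARTS hydrogen-count primitives are
  evaluated against total hydrogen counts, the standard 2-D fingerprint
  convention.
- **Salts**: multi-fragment SMILES keep the largest covalent fragment
  before featurization (probe tables commonly carry counter-ions, which
  would otherwise distort the counts); stripping is logged and can be
  disabled.
- **Charge states are taken as written** — no neutralization or tautomer
  standardization — so users control protonation upstream.
- **No feature scaling**: raw counts feed the network; the sigmoid input
  layer receives them as-is.
- SMARTS semantics follow the OpenBabel engine that backs the package
  (via ChemmineOB). Two documented cross-toolkit differences are worth
  knowing: ring-membership primitives like `[r6]` mean "in *some* ring of
  size 6" here (other toolkits read them as smallest-ring size), and
  aromaticity perception can differ on exotic ring systems. Within one
  engine the fingerprint is fully deterministic.

## The regression network

The network is a plain sequential stack:

| layer  | units | activation |
|--------|------:|------------|
| input  | 319   | sigmoid    |
| hidden 1 | 256 | sigmoid    |
| hidden 2 | 164 | tanh       |
| hidden 3 | 10  | sigmoid    |
| output | 1     | none (linear) |

One reading of "an input layer with an activation" is a pass-through; the
other is a trainable dense layer. This package implements the input layer
as a **trainable dense 319-to-319 layer with sigmoid activation**. The
choice changes the parameter count, so both are pinned in tests: the
hidden/output stack alone has 125,729 parameters, and the full model
227,809 (adding 319x319 + 319). The architecture file written by
`save_model()` records the reading so a stored model is unambiguous.

Training (`train_model()`):

- **Loss**: mean squared error is optimized; RMSE is the monitored
  quantity recorded per epoch (gradient-equivalent up to a factor, and RMSE
  is the natural reporting scale for a LogP model).
- **Optimizer**: minibatch SGD with Nesterov momentum, default learning
  rate 0.01 and momentum 0.9, batch size 32 — deliberately simple and
  fully reproducible.
- **Epochs**: fixed 78, no early stopping; the returned model is the
  final-epoch model and the full train/validation RMSE history is kept.
- **Shuffling**: the training set is shuffled once before the first epoch
  (seeded). A `reshuffle_each_epoch` flag exists but is off by default, to
  keep the single-shuffle protocol exactly.
- **Initialization**: uniform Glorot draws,
  `limit = sqrt(6/(fan_in + fan_out))`, biases zero — the standard choice
  for sigmoid/tanh stacks — under a caller-supplied seed. Identical seeds
  give bit-identical initial weights, training runs and final models.
- **Divergence**: a non-finite loss aborts with a diagnostic pointing at
  the learning rate rather than silently returning NaN weights.
- **Targets**: experimental LogP values; for ionizable compounds the
  distribution coefficient LogD is accepted as the target and the
  `logp_kind` field keeps the distinction auditable.

Gradient correctness is tested against central finite differences on a
micro-network (relative error at most 1e-4), and persistence
(`save_model()`/`load_model()`) round-trips to bit-identical predictions.
Models persist as **two files**: a human-readable JSON architecture file
(shapes, activations, registry version, history) and a weights file in R's
native serialization at full precision. Loading cross-checks weight shapes
against the architecture and fails loudly on mismatch.

## Dataset assembly

`assemble_split()` implements the assembly rule for the experimental-LogP
reference collection: training = reference training set + auxiliary
molecules; any validation record whose molecule also occurs among the
auxiliary set is removed *from validation* (never from training). Decisions
a maintainer should know:

- **Identity key**: canonical-SMILES equality. It is robust to spelling
  and needs no external identifiers; removals are logged with both
  spellings.
- Duplicates *within* a source table are left untouched — only the
  auxiliary-versus-validation rule is applied.
- Every record must carry an experimental value; assembly fails otherwise.
- The result reports provenance counts, the removed records and
  per-split `distribution_stats()` (mean/min/max plus an equal-width
  histogram), so final split sizes can be audited rather than assumed.
- Reference tables are user-supplied CSV/TSV paths with a column map; the
  package does not download data and hard-codes no column names.

## Permeability statistics

- **Threshold rule**: `LogP >= threshold` is permeant; the boundary value
  itself is permeant. The threshold defaults to 1.0 and is configurable;
  the rule direction is not.
- **Per-class fractions** are reported raw and as round-half-up
  percentages (the common reporting style for such panels).
- **Missing descriptor values** (a tool failing on a molecule) are
  excluded from that descriptor's statistics and surfaced in a `missing`
  count — silent imputation would bias accuracy.
- **Welch t-test**: two-sided, unequal variances, Satterthwaite degrees of
  freedom, computed via `stats::t.test`; the test suite pins it against
  the closed-form textbook formula to 1e-10. Two-sided is the conservative
  default for class-difference reporting.
- **Ranking**: descending accuracy with alphabetical tie-break, so
  benchmark reports are deterministic.
- Box-plot numbers (`boxplot_summary()`) are quartiles with 1.5 IQR
  whiskers clamped to the data range; plotting itself is left to the user.

## Synthetic data: what it emulates and what it does not

The generators exist so the full pipeline — generate, featurize (or
bypass into feature space), train, classify — runs end to end with known
ground truth and no downloads.

`generate_regression_set()` draws integer features from a truncated
Poisson (mean 1, clipped to 0–4), emulating sparse fragment counts, and
builds targets as an exact sparse linear map plus Gaussian noise. The
default weight scale (normal, s.d. 0.4, 20 nonzero entries) makes the
target spread match a realistic experimental LogP distribution (s.d. near
1.8, range roughly -4 to 8). The recovery experiment used by the
acceptance checks trains the full 319-input network on n = 5000 such
molecules (noise s.d. 0.1) and evaluates on 1000 held-out molecules; these
problem sizes keep a full run in the minutes range on one CPU.

`generate_probe_set()` emulates a labelled probe panel: descriptor values
are normal with unit s.d., centred at `1 + separation` (permeant) and
`1 - separation` (impermeant). The default panel is 99 permeant / 25
impermeant — the class balance of the curated reference panel — and the
default separation of 1.75 puts about 96% of each class on its correct
side of the threshold, i.e. a strongly but not perfectly separating
descriptor. `separation = 5` makes threshold classification essentially
perfect; `separation = 0` reduces it to a coin flip, and both extremes are
asserted in tests with bounds derived from normal tail probabilities.

What passing these tests shows: the featurizer contract, the optimizer,
the statistics and the plumbing are correct, and the network can recover a
known structure-to-LogP map. What it does not show: performance on real
chemistry. Real LogP is not a sparse linear function of fragment counts,
real descriptor distributions are not Gaussian, and real panels carry
curation noise; claims about experimental data require the external
reference tables and probe panel, which users must supply themselves.

## Numerical and degenerate-input conventions

- Canonicalization is idempotent and is the package-wide identity key.
- OpenBabel accepts some malformed SMILES (an unclosed branch parses as
  methane), so a lexical balance check rejects such strings first.
- `distribution_stats()` puts all mass in one bin when min equals max;
  empty input is an error.
- `welch_ttest()` returns t = 0, p = 1 for identical samples (including
  the zero-variance case with equal means) and errors on samples of size
  below 2 or zero variance with unequal means; `evaluate_descriptor()`
  omits the test when a class is too small instead of failing the whole
  evaluation.
- `regression_metrics()` refuses zero-variance truth (R-squared
  undefined).
- Classifier ties at the threshold go to the permeant class, always.

## Known limitations

- The fragment vocabulary is a curation; chemistry outside it contributes
  nothing to the fingerprint, and extending the registry changes the model
  input contract (the registry version recorded in saved models guards
  against silent mismatches).
- Aromaticity and ring perception follow OpenBabel; fingerprints computed
  with other toolkits can differ on edge-case ring systems.
- No tautomer/protonation standardization: the same molecule drawn as
  different tautomers featurizes differently.
- The LogP >= 1 rule is a deliberately simple screen: no ROC analysis, no
  threshold calibration, no multi-class localization prediction.
- Training is CPU-oriented and single-threaded beyond BLAS; it is sized
  for datasets in the tens of thousands, not millions.
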