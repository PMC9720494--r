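---
title: "Methods: spectral-prediction-informed PSM rescoring"
author: "psmRescore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral-prediction-informed PSM rescoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A database search engine assigns each MS2 scan the best-matching peptide
from a reference database, producing peptide-spectrum matches (PSMs) with
an engine score. Error control is by target-decoy competition: decoy
(reversed-sequence) hits estimate how many target hits above a score
threshold are false. In immunopeptidomics the search is unspecific — any
substring of the proteome is a candidate — so the search space is enormous,
engine scores separate poorly, and few PSMs survive a 1% false discovery
rate (FDR) threshold.

Rescoring recovers identifications by replacing the single engine score
with a learned combination of richer evidence. This package's evidence is
built on *predicted* MS2 spectra and retention times: if the peptide
assignment is right, the measured spectrum should resemble the prediction
for that sequence, and the measured retention time should sit near the
value implied by the predicted retention index.

## Feature model

For a PSM with peptide $p$ and precursor charge $z$, theoretical b/y
fragment m/z values are computed from monoisotopic residue masses
(fragment charges $1..\min(3, z)$), and each fragment is matched to the
nearest spectrum peak within 0.02 Th (ties to the lower m/z; one peak may
serve several fragments). The predicted and observed intensity vectors are
aligned on the predicted fragment set, with unmatched predicted positions
observed as 0. The central similarity is the normalised spectral contrast
angle

$$\mathrm{SA} = 1 - \frac{2}{\pi}\arccos
  \frac{\langle p, e\rangle}{\lVert p\rVert\,\lVert e\rVert},$$

computed on raw (not square-root) intensities; it is scale-invariant in
each argument, 1 for a perfect match, and defined as 0 when nothing
matched. Observed peaks with no predicted fragment do not enter the SA but
are counted in the "fraction of observed intensity explained" feature.

The full per-PSM vector (the canonical set, printed in every run report so
runs are self-describing): engine score; spectral angle; Pearson
correlation of aligned intensities; predicted and matched coverage of the
dominant and lesser ion series plus overall MS2 coverage (the dominant
series is the one with greater predicted coverage, ties to y; predicted
coverage counts fragments above 1% of the base peak, since predictors emit
near-zero noise intensities elsewhere); median and maximum absolute
fragment m/z error, signed mean error, and the number of matched fragments
(all errors 0 with `nMatched = 0` when nothing matched); fractions of
predicted intensity matched and of observed intensity explained;
retention-time error in minutes under a least-squares line mapping the
predicted retention index to observed minutes (fitted on the 100
highest-scoring targets; at least 10 pairs with non-constant index are
required); peptide length; and a precursor-charge one-hot over charges
1–6. Optional blocks: the seven delta-summary features (below), and in
affinity mode the binding %Rank (minimum over the sample's alleles) plus
its negative log. A peptide absent from the %Rank table receives the worst
rank observed in the table — imputation preserves ordering semantics and
the feature matrix never contains missing values.

Compatibility filtering precedes everything: peptides must be 7–30
residues, carry no modification other than oxidised Met or
carbamidomethyl Cys, and contain no unmodified Cys (the spectral predictor
assumes carbamidomethylation). The filter is idempotent and logs a reason
per rejected PSM; chimeric spectra (several PSMs on one scan) are always
retained.

## Collision-energy calibration

Predicted fragmentation patterns depend on the collision energy (CE)
setting, so predictions are only comparable to measured spectra at the
right CE. Calibration takes the 1000 highest engine-score unmodified
target PSMs (the count is a package default; any value large enough to
stabilise the mean works), computes the mean spectral angle against
predictions at every integer CE from 20 to 40 inclusive, and selects the
argmax, breaking ties toward the lowest CE for determinism.

## Adjacent-swap sensitivity (delta features)

In large search spaces, wrong assignments are often *near misses*:
the true sequence with two adjacent residues exchanged. For some
sequences the predicted spectrum barely changes under such a swap; those
assignments deserve less confidence. The delta of site $s$ is

$$\delta_s = \mathrm{SA}(\mathrm{predict}(\mathrm{swap}_s(p)), e)
           - \mathrm{SA}(\mathrm{predict}(p), e),$$

against the experimental spectrum $e$. Computing every swap's prediction
doubles prediction cost, so a lightweight gradient-boosted regressor
(xgboost; maximum depth 16, minimum child weight 2, learning rate 0.15,
gamma 0.1, column subsample 0.9 — a tuned configuration; boosting rounds
fixed at 150) predicts $\delta_s$ from local features of the swap site:
one-hot residues at positions $s-1..s+2$ (padding token at the termini),
site index from both termini, peptide length, precursor charge, collision
energy, the monoisotopic masses of the swapped pair, their absolute mass
difference, and an identical-pair indicator. Identical-residue swaps stay
in training with delta 0 — they teach insensitivity. Training samples five
distinct random sites per PSM (all sites for short peptides), and the
train/test split is peptide-disjoint; peptide overlap is an error, not a
warning. The per-peptide site profile enters rescoring as seven summary
features: minimum, maximum, median, first and third quartile
(linear-interpolation quantiles, type 7 — fixed and documented since the
convention matters at few sites), and the fractions of deltas strictly
above $-0.1$ and strictly above $0$.

The trained model is serialised with an embedded feature-schema version
and refuses to load or predict under a different schema.

## Rescoring

Given the feature table, the package's self-contained rescorer mirrors the
semi-supervised cross-validation design of established rescoring engines:
PSMs are split into 3 folds by a deterministic hash of their scan key, so
all PSMs of one scan (chimeric candidates) share a fold and no PSM is ever
scored by a model trained on its own fold. Per fold, an L2-regularised
linear logistic scorer is trained iteratively (10 iterations): positives
are targets at $q \le 0.01$ under the current score (initially the engine
score; if fewer than five qualify, the top ten targets bootstrap the
first round), negatives are all decoys. Features are z-scored with
training-fold statistics only; the ridge penalty is chosen once per fold
from a 3-point grid on a nested scan-level split, by identifications at
the training FDR. The best-performing iteration's weights score the
held-out fold; per-fold scores are normalised (decoy median to 0, the
score at the $q = 0.01$ threshold to 1) before merging. No subsetting of
training PSMs is ever applied — subsampling is known to destabilise
cross-validation on small datasets.

Final q-values use target-decoy competition with the +1 correction:
$\widehat{\mathrm{FDR}}(s) = (1 + \#\{d \ge s\}) / \max(1, \#\{t \ge s\})$,
monotonised from worst to best score and capped at 1. The correction is
deliberately conservative on small sets. Ties share the counts of their
tie block. The alternative path for users of an external rescoring engine
is a Percolator-format pin export plus re-import of external scores, after
which only q-values and counts are computed.

## Ground-truth benchmarking

To measure rescoring quality as precision and recall rather than only
estimated FDR, a benchmark embeds two-thirds of a known peptide set into a
reference database (replacing same-length spans at random positions;
spans never overlap, so one embedding cannot destroy another) and excludes
the remaining third. An excluded peptide found in the database by chance
is re-labelled discoverable and logged rather than removed. Two
non-overlapping fragments of each excluded peptide (random split point,
each piece at least 3 residues) are appended so database composition is
not biased against them. Invariants — every discoverable peptide present
as a substring, no undiscoverable peptide present — are verified
exhaustively after every build.

Precision at a score cutoff is correct PSMs over all PSMs above the
cutoff; recall is correct PSMs over the number of discoverable peptides.
Correctness is an exact residue match of the assigned plain sequence
against the truth; modifications are ignored and isoleucine/leucine are
**not** collapsed. The headline statistic is the maximum recall among
cutoffs with precision at or above 0.99.

## The synthetic data generator

The generator defines the package's study conditions; it stands in for
raw instrument data plus an external spectral predictor, and everything
downstream is exercised against it.

The toy predictor is deterministic by construction: fragment base
intensities come from a version-pinned mixing hash (never a runtime hash,
so fixtures are stable across platforms and R sessions) of the residue
pair flanking the fragmentation site, mixed 0.7/0.3 with a
position-dependent component. The pair-dominant structure matters: it
makes the delta-recovery experiment meaningful, because the target
function is then mostly a function of features the delta model actually
sees, rather than an unlearnable lookup table. The y series is scaled by
1.2 before renormalisation to base peak 1. The CE response is
*per fragment*: each fragment's intensity is scaled by
$\exp(-(ce - o_i)^2/72)$ with a fragment-specific optimum $o_i$ within
$\pm 4$ of a peptide-level optimum ($26 + \mathrm{hash}(p) \bmod 5$). A
uniform CE scaling would leave the spectral angle unchanged (SA is
scale-invariant), so a shape-changing response is the only design under
which CE calibration can recover the acquisition setting — which is
exactly what calibration must do on real data. The retention index is a
composition-only hydropathy sum: additive, order-insensitive, adequate for
exercising the alignment and the RT-error feature, and documented as not
order-sensitive.

The default benchmark has 2,000 PSMs: 1,100 true (spectra are noisy
realisations of the toy prediction at the instrument CE optimum of 28),
350 wrong (spectra generated from *excluded* peptides but assigned a
same-length discoverable peptide — what a search engine does when the
real answer is not in its database), and 550 reversed-sequence decoys
referencing existing scans (decoys are ~27% of the total, matching the
target:decoy ratio typical of unspecific searches). Engine scores are
Normal(25, 5) for correct and Normal(15, 5) for incorrect assignments —
two standard deviations of separation, so the engine score alone
identifies a minority at 1% FDR and the spectral gain is measurable.
Noise: lognormal intensity multipliers (sigma 0.3), 10% fragment dropout,
0.005 Th m/z jitter, and 10 uniform noise peaks per spectrum. Ground-truth
peptides are 8–14 residues (immunopeptidome-like), charges 1–3 with
probabilities 0.15/0.6/0.25, drawn from a 19-letter alphabet without Cys
(so the compatibility filter, which is exercised by dedicated fixtures,
does not silently remove true PSMs here). A synthetic %Rank table makes
ground-truth peptides behave like eluted ligands (log-uniform ranks
between 0.01 and 5) and everything else like random peptides
(uniform 0–100).

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: fragmentation physics (mobile-proton effects,
neutral losses, multiply charged fragments), isotope envelopes,
chromatographic peak shape, order-sensitive retention, correlated noise,
and real search-engine score distributions. Every true PSM has a scan in
the benchmark, so the maximum attainable recall is 1 by construction;
real benchmarks are bounded below 1 by peptides the engine never found.

## Numerical choices and degenerate inputs

Peak-match ties go to the lower m/z. CE calibration ties go to the lowest
CE. Quantiles are type 7. The q-value tie-blocks share counts at the
block end. Empty spectra match nothing; all-zero observed vectors have
SA 0; a feature table refuses non-finite values at construction; a fold
without decoys, a degenerate (constant-index) RT fit, a %Rank outside
[0, 100], a peptide with a modification token on the wrong residue, and
an ambiguous delimiter (tabs and commas in one header) are all hard
errors rather than guesses. Problem sizes in the shipped tests and the
acceptance script — a 2,000-PSM benchmark, 1,000 peptides for the mass
identity, 20,000 delta samples, ten seeds for the error-rate check — are
the package's chosen experiment sizes, small enough to run anywhere yet
large enough that the checked orderings are not noise.

## Known limitations

The rescorer is a documented stand-in for an external semi-supervised
rescoring engine, not a clone of one; its internals (ridge logistic
discriminant, 3-point penalty grid, scan-hash folds) are fixed and
described here precisely because no published specification exists to
copy. The delta predictor is defined for the built-in toy predictor's
feature contract; modifications beyond the two in scope are not part of
its feature space. The Mascot reader expects a flattened CSV export, not
the native DAT format; vendor raw files and mzIdentML are out of scope.
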