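---
title: "Predicting chaperone response of AGAL mutations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting chaperone response of AGAL mutations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(FabryPSSM)
```

## The problem and the model

Most AGAL missense mutations destabilize the enzyme rather than destroy
its active site; those mutants can often be rescued by the pharmacological
chaperone DGJ. The predictive idea is purely evolutionary: if the mutant
residue is tolerated at that position across AGAL homologs, the
substitution is likely compatible with a foldable, rescuable enzyme.
Tolerance is quantified by a position-specific substitution matrix built
from a homolog alignment, and a mutation is scored by the matrix entry of
the *mutant* residue at the mutated position.

Construction follows the standard profile recipe:

1. **Sequence weights.** Position-based (Henikoff) weighting: each
   alignment column distributes one unit of mass equally among the residue
   types present, then equally among the sequences sharing each type.
   Raw weights are normalized to sum to `n_eff`, the mean number of
   distinct residue types per column — the same bookkeeping classic
   profile tools use for their pseudocount mixing weight. A fully
   redundant alignment therefore collapses to `n_eff = 1` no matter how
   many copies it holds. `weighting = "uniform"` (all weights 1,
   `n_eff = N`) is appropriate when sequences are known to be independent
   draws, as in our simulations.

2. **Column frequencies.** Weighted residue frequencies per query
   position. Gaps and `X` carry no mass and are excluded from the
   denominator; columns where the query is gapped are dropped, so the
   matrix coordinates are exactly the 1-based positions of the ungapped
   query (HGVS protein numbering).

3. **Pseudocounts.** Observed frequencies are smoothed toward
   substitution-plausible pseudo-frequencies
   `g(a) = sum_b f(b) P(a|b)`, mixed as
   `(alpha f + beta g) / (alpha + beta)` with `alpha = n_eff - 1`. The
   conditional prior `P(a|b)` is recovered from the BLOSUM62 score matrix
   by inverting its half-bit log-odds against the BLOSUM62 marginal
   frequencies and renormalizing rows. With `beta = 0` the observed
   frequencies pass through; with `n_eff = 1` (no information beyond one
   sequence) the prior speaks alone.

4. **Scores.** `S(i,a) = round(scale * ln(p_i(a)/b(a)))`, rounded half
   away from zero, once, after scaling.

## Tunable parameters

| parameter | default | units / range | why |
|---|---|---|---|
| `pseudocountWeight` (beta) | 10 | pseudo-observations | the customary profile-search constant; balances prior and data at typical alignment depths (~13 homologs) |
| `scale` | 2/ln 2 | half-bits per nat | places conserved-position scores in the small-integer range (-7..+1) in which the published per-mutation scores live |
| `background` | BLOSUM62 marginals | frequencies, sum 1 | consistent with the substitution prior; any strictly positive 20-vector is accepted |
| `weighting` | `henikoff` | — | robust to database redundancy; use `uniform` for i.i.d. synthetic data |
| `scoreFloor` | -16 | score units | keeps log-odds of zero-probability residues finite when `beta = 0`; matches common integer-PSSM floors |
| `activityCall` threshold | 15 | % of wild-type activity | the residual-activity level separating classic from attenuated phenotypes (~12%) rounded up for assay error; inclusive |
| classification rule | `three_zone` | — | score > -2 responsive, -2 twilight, < -2 non-responsive; `binary_ge_minus1` is the original benchmarked threshold |

Score semantics are a genuine design point: the score is the plain matrix
entry of the mutant residue, not a mutant-minus-wild-type delta. Wild-type
conservation already shapes the column through the profile, and the
published per-mutation integers are plain lookups. A delta variant exists
behind `scoreMutation(..., delta = TRUE)` but is not the default.

## The packaged panels

Two panels are shipped as TSV transcriptions, locked by MD5 checksums and
row counts: nine newly tested mutations (with DGJ fold increase, PSSM
score, MUPRO/SDM stability, accessibility, secondary structure, domain,
active-site flag and phenotype) and nineteen literature mutations with the
same annotations plus reported responsiveness. Annotation columns printed
as `NA` stay missing — they are consumed as annotations, never recomputed.
The literature panel's `p.L166` is printed without a target residue; it is
stored with a missing mutant residue, excluded from score lookups, but
retained wherever counting is keyed on the printed score (its score-0 bin,
zone counts, accuracy). The responsiveness column of the nine-mutation
panel encodes the 15%-of-wild-type rule applied to the reported assays:
all respond except A230T and E341D.

Active-site mutations (A230T, C142W, D231G, S297F) are uniformly
non-responsive in the data, but `predictResponsiveness()` only *flags*
them — overriding the numeric call would silently repair the method's one
known false positive (A230T) and misstate its measured precision.

## Evaluation statistics

`binByScore()` counts responsive/total per integer score and per decision
zone; `predictedPositiveRate()` gives the precision-style 12/14 figure on
the pooled panels; `panelAccuracy()` computes 100(TP+TN)/N with a policy
flag for twilight calls (default: counted non-responsive, the conservative
reading, which makes the three-zone rule coincide with the binary one).
`fisherExact()` implements the standard two-tailed convention — sum the
hypergeometric probabilities of all tables with the observed margins that
are no more likely than the observed table — with log-factorials;
`pearsonR()` pairs the sample correlation with the exact
`t = r sqrt((n-2)/(1-r^2))` test. Both are cross-checked in the test suite
against brute-force enumeration and `stats` oracles respectively. The
published comparison against a 42% baseline response rate cannot be
recomputed because the baseline's raw counts were never printed;
`fisherExact()` therefore takes an explicit 2x2 table and the package
never guesses a denominator. Likewise the published cross-validated
accuracy and the full score-response correlation belong to a training
compendium that is not part of the panels shipped here; the package
computes the analogous curve on its own panels and labels it as such.

## Synthetic data: what it does and does not emulate

`makeProfile()` defines per-position truth as a conservation mixture:
the dominant residue carries `c + (1-c)/20`, every other residue
`(1-c)/20`. Our simulations use length-30 profiles with conservation
drawn once from Uniform(0.8, 0.98) — the regime of a well-conserved
enzyme family whose homologs span roughly 30–95% identity — and a 5% gap
rate, never in the query. `sampleAlignment()` draws sequences i.i.d. per
position; `sampleMutationPanel()` plants a logistic score-response
relationship `P(responsive) = plogis(slope * S + intercept)`.

This establishes that the estimator recovers a known profile (sup-norm
error below 0.05 at 500 sequences, at least halving from 50 to 500) and
that the full pipeline detects a planted signal (>= 95% responsive among
predicted positives under a steep model). It deliberately does *not*
emulate phylogenetic correlation between homologs, alignment error,
indel structure beyond i.i.d. gaps, or the biophysics that makes real
responsiveness depend on stability and active-site geometry as well as
conservation — passing these tests validates the arithmetic, not the
biology. One subtlety: a logistic midpoint placed exactly on an integer
score makes labels at that score a coin flip, so "perfect separation"
checks put the midpoint between scores (-1.5).

## Numerical choices and degenerate inputs

Rounding is half-away-from-zero, applied once after scaling (base R's
`round()` rounds half to even, which would disagree with printed-integer
conventions at .5 boundaries). Probabilities are kept unrounded in the
`PSSM` object; only scores are integers. Zero-probability residues floor
at -16 rather than -Inf. A column with no residue mass at all (possible
only through `X`-saturated input) falls back to the background
distribution, score 0, with a warning. Ties in Fisher's two-sided sum use
the conventional `p <= p_obs * (1 + 1e-7)` tolerance. Degenerate margins
give p = 1; perfect correlation gives p = 0; zero-variance input,
empty panels and all-negative predictions raise errors rather than
returning NaN. Fixture integrity failures (checksum or row count) abort
before any statistic is computed.

## Known limitations

The matrix here is a clean-room implementation of the standard profile
recipe, not a re-run of the legacy PSI-BLAST binary the original scores
came from; the exact homolog set is not recoverable, so printed
per-mutation scores are treated as fixture data and fresh matrices from
other alignments will differ in detail. The score is blind to structure:
stability outliers (E341D: buried, destabilized, high score, poor
response) and active-site lesions (A230T) are exactly the failure modes
the annotations warn about. Thresholds were calibrated on AGAL and DGJ;
porting to another enzyme/chaperone pair requires re-benchmarking. cDNA
notation is carried but never validated against a transcript model.
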