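---
title: "The H-factor: model, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The H-factor: model, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Homology modelling produces not one structure but a family of plausible
models for a target sequence, built on an experimentally solved template.
Unlike a crystallographic refinement, which carries the R-factor as a
running measure of agreement with the data, a modelling run has no
built-in figure of merit tied to its own inputs. The H-factor fills that
role: it confronts the model ensemble with the data that produced it —
the template structure, the target/template alignment, the
secondary-structure prediction, and the structural record of the
target's domains — and condenses the comparison into a percentage, 0%
best and 100% worst.

The metric works on the Cα backbone only. That is a deliberate modelling
assumption: a correct Cα trace is a prerequisite for any valid model,
side-chain placement is a second-order concern at the accuracy level
homology models reach, and a Cα-only data model keeps every operation
(superposition, averaging, fragment comparison) well-defined across
models that may differ in side-chain completeness.

Four component scores, each an affine map of a raw statistic onto
[0, 10]:

* **Score 1 — secondary-structure agreement.** Per alignment column:
  penalty 0 when the predicted state of the target residue matches the
  observed state of the aligned template residue, `c + 1` on a mismatch
  (`c` the integer prediction confidence), 1 on a gap column. The score
  is `1.3 * mean(penalty) + 0.9`. A confident wrong prediction is
  penalised harder than an unconfident one — confidence should be earned.
* **Score 2 — sequence identity.** `10 * (1 - identities / N)` over the
  `N` alignment columns. Gap columns count as non-identity and stay in
  `N`: the formula normalises by alignment length with no gap-exclusion
  clause, so a gappy alignment is (correctly) treated as more distant.
* **Score 3 — ensemble heterogeneity.** Mean cRMS of each model to the
  ensemble's average model, mapped by `1.3 * spread + 0.87`. The offsets
  anchor the scale: a 0.1 Å spread scores 1, a 7 Å spread scores (about)
  10. Heterogeneity among models built from the same input is itself a
  quality signal — alignment or template errors surface as structural
  disagreement.
* **Score 4 — domain consistency.** Domains identified on the target cut
  the average model into fragments; each fragment is compared, by
  alignment-mediated cRMS, to the known structures of the same domain,
  and the grand mean over all fragment/reference pairs is mapped with the
  same `1.3`/`0.87` calibration.

The aggregate divides the sum of available scores by 10 times their
count: all four give the sum/40 rule, a structure-only run (scores 3 and
4 only, the mode appropriate for NMR-style ensembles or bare model sets)
gives the sum/20 rule. This generalises cleanly to any availability
pattern, and the package treats it that way: a missing input makes a
score *unavailable* (never silently zero) and the denominator adapts.
One hard requirement remains: the metric measures ensemble
heterogeneity, so it cannot be computed on a single model.

## Tunable parameters

All knobs live in `hfactor_config()`:

| parameter | default | units | role |
|---|---|---|---|
| `a1`, `b1` | 1.3, 0.9 | score units | affine map of score 1 |
| `a3`, `b3` | 1.3, 0.87 | score units per Å, score units | affine map of score 3 (0.1 Å → 1) |
| `a4`, `b4` | 1.3, 0.87 | as above | affine map of score 4 |
| `clamp` | `TRUE` | — | clamp components into [0, 10] |
| `evalue_cutoff` | 1e-10 | — | domain-hit E-value filter |
| `max_fragments` | 5 | count | cap on domain fragments scored |
| `confidence_shift` | `TRUE` | — | shift raw psipred 0–9 digits to 1–10 |

Clamping deserves a note: the stated coefficients do not strictly confine
the scores to [0, 10] (`1.3 * 8 + 0.87 > 10`), so the range is asserted
by clamping after the affine map. With `clamp = FALSE` the raw affine
values are returned.

The mismatch penalty in score 1 is `c + 1` with `c` on the 1–10 scale
(raw psipred digits 0–9 are shifted up by one on reading;
`confidence_shift = FALSE` keeps them raw). The alternative convention of
dividing the penalty by 10 was rejected at design time because it caps
score 1 near 2.2 and destroys the score's ability to flag confidently
wrong predictions on hard targets, where values as high as 7 are
meaningful.

## Numerical choices

* **Superposition.** The Kabsch least-squares fit is computed via SVD of
  the 3×3 cross-covariance, with the usual determinant sign correction so
  reflections are excluded; every returned rotation has determinant +1.
  Structures whose centred coordinates are (near-)collinear — second
  singular value below 1e-8 of the first — are rejected as degenerate
  rather than silently fitted, because the rotation is then
  ill-determined.
* **Average model.** Iterate: superpose every model onto the current
  reference (initially the first model), take the coordinate-wise mean,
  repeat until the mean coordinates move less than `tol = 1e-4` Å RMS or
  100 iterations. Non-convergence is flagged on the returned object, not
  an error. The mean-squared deviation to the current mean is
  non-increasing across iterations (tested). The average model's
  stereochemistry is deliberately unconstrained — like an NMR mean
  structure, it is a statistical object, not a physical model.
* **Pairing.** Within an ensemble, residues are paired positionally
  (residue *i* to residue *i*): models of one target share numbering.
  Across proteins (score 4), pairing comes from a global
  Needleman–Wunsch alignment under BLOSUM62 with affine gaps (opening 10,
  extension 0.5) — standard mid-range parameters for domain-scale
  comparisons; pairs with fewer than 3 aligned positions are skipped
  with a warning.
* **Domain hits.** Hits are filtered by the per-domain *independent*
  E-value (domain-table column 13), sorted ascending with ties kept in
  file order, and capped at `max_fragments`; envelope coordinates
  (columns 20/21) define the fragment bounds. Among the E-values a
  domain table offers, the independent per-domain one is the right
  granularity for ranking *fragments*.
* **Rounding.** All internal arithmetic is unrounded; only reports round
  (components to 1–2 decimals, the aggregate percentage to the nearest
  integer, half away from zero).
* **Secondary-structure reduction.** Helix classes H/G/I → H, extended
  classes E/B/b → S, everything else → C. The letter S is a fixed point
  of the table (it is the strand letter of the 3-state alphabet, and
  stride never emits it), which makes the reduction idempotent; DSSP's
  bend code — unfortunately also "S" — is mapped to blank by the DSSP
  reader before reduction, so bends still reduce to C.
* **Residue bookkeeping.** PDB parsing is fixed-column over ATOM/MODEL
  records only; HETATM is ignored, alternate locations resolve to the
  highest occupancy (first listed on ties), insertion codes are appended
  to the residue key, and one chain is read per model (first encountered
  by default). A residue lacking its Cα in any model is dropped from all
  models with a warning, keeping traces in 1:1 correspondence; wholesale
  numbering mismatches are an error.
* **Internal fallback assigner.** When no stride/DSSP file is available
  for the template, a Cα-only geometric assigner (in the spirit of
  P-SEA) labels helices and strands from the short-range distances
  d2/d3/d4 with windows derived from ideal geometry (helix: d3 ≈ 5.1 Å,
  d4 ≈ 6.2 Å; strand: d2 ≥ 5.5 Å, d3 ≥ 8.5 Å). It is deterministic and
  rigid-motion invariant, and an external assignment always takes
  precedence when supplied — the fallback exists because the data model
  carries no backbone N/O atoms for a hydrogen-bond-based method.
* **Clustal input.** FASTA alignments are read through seqinr; the
  Clustal dialect is parsed by a small internal block reader, after the
  available reader proved unreliable on single-block files. Rows are
  upper-cased, "." is treated as a gap, and gap-vs-gap columns are
  removed on reading, so no downstream code ever sees one.

## The synthetic-data generator

Every input the metric consumes can be generated at toy scale with known
ground truth (`fixture_spec()` and the `make_*()` family), which is what
makes the whole pipeline testable offline:

* **Ensembles** are a smooth self-avoiding walk with 3.8 Å Cα steps
  (non-neighbour contacts kept above 2.5 Å) plus iid Gaussian
  perturbations per model, rescaled against the package's own
  superposition engine until the realised spread is within 15% of the
  target (in practice well under 2%), then hit with independent random
  rigid motions that the spread is invariant to.
* **Alignments** plant an exact identical-column count,
  `round(identity_fraction * N)`, and an exact gap-column count, so
  score 2 is known in closed form.
* **Prediction/assignment pairs** copy the observed track onto the
  aligned target positions and flip an exact number of them, making
  score 1 a closed-form function of the planted parameters.
* **Domain cases** build references as the fragment plus a noise field
  projected orthogonal to the six rigid-body modes and rescaled once
  against the real alignment-mediated cRMS, so the realised cRMS matches
  the request to a fraction of a percent.

Default study conditions are 20 models per ensemble and chains of 40–60
residues; the test suite and the acceptance script run at these sizes
(plus 100-pair superposition sweeps and 1000-trial filter checks), which
the package treats as its standard toy scale — large enough for the
statistics to be meaningful, small enough that the whole suite runs in
well under a minute.

What the generator does **not** emulate: real protein stereochemistry
(no side chains, only loose self-avoidance), correlated model errors
(real MODELLER ensembles disagree most in loops, not uniformly),
realistic secondary-structure segment statistics, or genuine profile-HMM
score distributions. Passing tests therefore demonstrate that the
*metric* is computed correctly and that its calibration behaves as
designed — not that the H-factor's empirical correlation with model
quality on real CASP-scale data is reproduced here, which would require
the original model sets, templates and domain databases.

## Known limitations

* Single-framework only: multi-template modelling is out of scope, as is
  any side-chain assessment.
* Score 3 saturates: past roughly 7 Å of spread the clamp binds and the
  score no longer discriminates among very bad ensembles.
* Score 4 depends on the domain reference set supplied; with no
  reference structures the score is unavailable, and references are
  taken from local files via a manifest — no database retrieval is
  attempted.
* The aggregate percentage is comparable across targets of different
  sizes, but its two printed modes (/40 and /20) sit on different
  denominators; reports always state the mode alongside the number.
* mmCIF input, occupancy-weighted ensembles and full-atom parsing are
  out of scope.
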