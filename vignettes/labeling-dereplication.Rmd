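---
title: "Labeling-based dereplication of polyphenolic mixtures: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Labeling-based dereplication of polyphenolic mixtures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(derepms)
```

This vignette documents the models, parameter choices and numerical
conventions behind `derepms`, and what its synthetic-data tests do and do
not demonstrate about real data.

## The measurement model

All spectra are centroided negative-mode peak lists. The only ion species
modeled is the singly charged deprotonated molecule:
m/z = M − 1.007276467, where M is the neutral monoisotopic mass and the
subtracted constant is the proton mass (the electron stays with the
anion). Polyphenols ionize efficiently as \[M−H\]⁻, which is why this is
the default and only implemented mode; positive mode and multiple charging
raise an explicit not-implemented error rather than silently producing
wrong masses. Monoisotopic atomic masses are H = 1.0078250319,
D = 2.0141017780, C = 12 (exact), O = 15.9949146221, Br = 78.9183376 Da.
Isotopologue fine structure (¹³C satellites and the like) is out of scope:
only monoisotopic peaks are modeled, assigned and simulated.

## Formula assignment

For a peak at m/z the neutral mass is recovered and all CHO formulae
within the configured bounds are enumerated. Rather than a triple loop,
the search scans the (C, O) grid and pins the hydrogen count from the
residual mass — the tolerance window (sub-ppm, hence < 0.0004 Da below
800 Da) is far narrower than one hydrogen mass, so at most two integer
candidates per (C, O) pair can qualify. Defaults: C ≤ 40, H ≤ 80, O ≤ 40,
H/C ∈ [0.3, 2.2], O/C ≤ 1, DBE an integer ≥ 0, tolerance 0.5 ppm. These
cover the < 800 Da CHO polyphenol space; they are configuration, not
claims about any particular instrument, and the unit tests verify the fast
scan against a literal triple-loop oracle.

Each peak keeps its single best candidate (smallest |error|, ties broken
by fewer oxygens then fewer carbons, so the mapping is a deterministic
function); peaks with two or more in-tolerance candidates are flagged
ambiguous rather than silently resolved, and unassignable peaks are
dropped but counted. Within a CHO-only space at integer DBE the closest
formula pairs sit ≥ ~15 mDa apart (e.g. C₄ vs O₃), so sub-ppm collisions
are essentially absent below 800 Da — the recovery tests confirm ≥ 99%
exact recovery at 0.2 ppm.

## Labeling series

A labeling reaction shifts mass by a fixed Δ per event: H/D exchange
m(D) − m(H) = 1.0062767 Da, deuteromethylation (OH → OCD₃)
m(C) + 3m(D) − m(H) = 17.0344803 Da, deuteride reduction (C=O → CHD–OH)
m(H) + m(D) = 3.0219268 Da, NBS bromination (aromatic H → Br)
m(Br) − m(H) = 77.9105126 Da. The constructors assert agreement of these
recomputed values with their conventional five-decimal reference constants
to 10⁻⁵ Da, so a typo in the atomic-mass table cannot pass silently.

`detect_series()` reports, for every base peak, the maximal *consecutive*
chain of peaks at `base + k·Δ`. Three conventions needed fixing and are
used identically by the brute-force oracle in the tests:

* member positions are measured from the base (tolerance does not
  accumulate along the chain);
* at each k the nearest peak within tolerance is taken, exact ties
  breaking toward the lower m/z;
* a chain is reported once, under its lowest-m/z base — a peak that could
  itself be the k = 1 member of a lower base is not reported as a base.

The default tolerance is absolute, 0.0003 m/z, reflecting the sub-ppm
mass-difference accuracy of FTICR instruments between peaks of a series
(it is deliberately not a ppm tolerance). `k_max` defaults to 12, an upper
bound on exchangeable-hydrogen counts for < 800 Da polyphenols. Shrinking
the tolerance can only remove series, which the property tests assert.

Series filtration requires the base to carry an unlabeled (d = 0) formula
assignment and the observed event count to be chemically feasible:
H/D ≤ H; deuteromethylation ≤ ⌊O/2⌋ (a carboxyl consumes two oxygens);
reduction ≤ O minus known carboxyl events; bromination ≤ round(DBE) − 3
(an aromatic ring needs DBE ≥ 4) and is interpreted downstream only as
presence/absence — whether longer bromination series could count aromatic
hydrogens quantitatively is left open, so the conservative reading was
chosen. All rules are replaceable through `series_rules()` because they
are heuristics, not measurements.

## Exogenous-component detection

A component record requires a *labeling series* in the administered-tissue
spectra, not mere peak presence: an endogenous compound can share a
formula (and hence a peak) with a mixture component, but it cannot carry
deuterium. Consequently a series base present in any control spectrum
vetoes the record, while an unlabeled control *peak* at the same m/z does
not — one of the unit tests pins exactly this distinction. Matching the
base against the labeled reference material is recorded as a flag rather
than used as a veto, because direct-ESI reference spectra can miss genuine
components through ionization suppression; the flag becomes a criterion
only in the final filter, where each criterion's attrition is logged
separately so users can audit (or disable) any filtration scheme.

Final-filter defaults: replicate support ≥ 2, reference flag required,
H/C ∈ [0.3, 2.2], O/C ∈ [0, 1]. Descriptor aggregation runs the tagging
experiments on the parent material (not the tissue extracts), matches
series by base formula, and distinguishes "experiment run, no series"
(count 0) from "experiment not run" (unknown) via the experiment-coverage
argument.

## Fraction profiling

Number-averaged metrics use the unweighted mean over assigned formulae —
the (O/C)ₙ convention of ultrahigh-resolution MS — with intensity
weighting available as an option; the number average is invariant to
intensity rescaling, which is tested. Compound classes are assigned from
atomic ratios and the CHO-restricted aromaticity index
AI = (1 + C − O − 0.5·H)/(C − O), clamped to 0 on degenerate
denominators, with deuterium counted as hydrogen everywhere so labeling
never moves a compound between classes. The cascade is: lipid-like
(H/C ≥ 1.7 and O/C ≤ 0.25), aliphatic (H/C ≥ 1.5), condensed aromatic
(AI ≥ 0.67), aromatic (AI > 0.5), else unsaturated. The 0.5/0.67 AI
thresholds are the conventional aromatic/condensed cut-offs; the lipid
rule encodes "saturated and oxygen-poor, unlikely indigenous to
polyphenolic material" and is excluded from class shares by default. All
five thresholds are configuration.

Enrichment of a fraction in a target-component set is the summed relative
intensity of target formulae within the fraction's own spectrum, so
fractions of different total ion current are comparable; class shares and
enrichment could alternatively be computed on formula counts, and both
views are available (`count_share` vs `intensity_share`), with intensity
as the default since enrichment is an intensity-budget question.

## Candidate filtering

SMILES handling (validity, canonicalization, SMARTS-based group counting,
aromatic-ring perception) is delegated to OpenBabel via
ChemmineOB/ChemmineR. Stereochemistry is stripped before
canonicalization — MS-derived constraints cannot see stereocenters.
Carboxyls are `C(=O)OH`; hydroxyls are any O–H not in a carboxyl
(phenolic and alcoholic alike, both ionizable in negative ESI); carbonyls
are ketone/aldehyde C=O, excluding carboxyls and esters (the reduction
chemistry targets ketones and aldehydes); aromatic rings are counted as
fused ring systems. The "at least one of the three enumerated moieties"
criterion is read as structure-level presence (lenient mode); strict mode
additionally requires count equality against the matched component's
measured descriptors wherever those are known. Both readings are offered
because the requirement is genuinely ambiguous, and the stage-count
report makes their difference observable on any input.

## The synthetic-data generator

The generator defines the package's test conditions; its defaults are
fixed once and the tests run against them.

* **Formulae** are sampled by carbon number (6–40), DBE (biased to the
  aromatic-rich midrange, mean ≈ 0.62·C) and a low-biased oxygen count
  (binomial, p ≈ 0.22), reflecting the oxygen-poor, substantially
  aromatic character of degraded-lignin polyphenols — number-averaged O/C
  stays below 0.3, and the class mix spans unsaturated (~40%), aromatic
  and condensed-aromatic (~20% each) with minor aliphatic/lipid-like
  tails. Masses default to 150–800 Da. Ground-truth group counts respect
  the descriptor invariants (n_COOH ≤ ⌊O/2⌋, n_C=O ≤ O − 2·n_COOH,
  1 ≤ n_exch ≤ H).
* **Spectra**: intensities are log-normal (no intensity distribution is
  implied by the physics that matters here — only relative values are
  used downstream); m/z jitter is Gaussian with SD 5·10⁻⁵ Th by default,
  comfortably inside the 3·10⁻⁴ series tolerance; decoy peaks are uniform
  over the m/z span.
* **Labeling efficiency** models in-vivo back-exchange as a consecutive
  prefix: each next series member survives with probability `efficiency`
  (default 0.9 in administration spectra) and the series stops at the
  first loss — an incompletely labeled molecule still carries all lighter
  labels. Reference-material and chemical-tagging spectra default to
  efficiency 1, since derivatization of the pure material is
  near-quantitative; back-exchange is the tissue-side effect. No kinetic
  modeling is attempted.
* **Sample sets** default to 3 replicate spectra per role, 500 endogenous
  background formulae, 5000 decoys per spectrum, and route subsets that
  both cover the whole mixture (`route_overlap = 1`); partial-overlap
  subsets exist for exercising the merge arithmetic.
* **Fraction profiles** implement a solvent gradient: the target boost
  declines geometrically from the pure-methanol fraction, inventories
  shrink, and class weights shift from unsaturated toward
  condensed-aromatic with increasing water content.

What passing these tests shows: the algorithms recover planted signal
exactly or near-exactly under realistic densities of interfering peaks,
with deterministic, auditable behavior. What they do not show: robustness
to FTICR artifacts absent from the generator — space-charge frequency
shifts, intensity-dependent mass error, isotopologue interference,
ion-suppression structure in real matrices — nor the correctness of any
particular instrument's calibration. Tolerances are therefore exposed as
configuration rather than fixed truths.

## Problem sizes and determinism

The shipped tests use cohorts of 50 planted compounds against 500
background formulae and 5000 decoys per spectrum (about 5700 peaks each,
15 spectra per sample set), 100-spectrum oracle-equivalence sweeps, 500
formula-recovery cases and 1000 toy structures; these sizes exercise every
code path at interference densities comparable to real FTICR peak lists
while keeping a full run in tens of seconds. Every generator takes an
explicit seed and is bit-reproducible given it; the acceptance script
derives all of its randomness from a single `--seed` argument.

## Known limitations

Only C, H, O (plus D and Br as labels) are handled — no N/S/P chemistry;
adducts other than \[M−H\]⁻, multiple charging and isotope patterns are
not modeled; back-exchange is a thinning probability, not kinetics;
aromatic-ring counting treats fused systems as one unit; and the final
filtration criteria, like the series feasibility rules, are explicit
configurable heuristics rather than recovered experimental protocol.
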