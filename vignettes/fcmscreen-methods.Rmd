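---
title: "Methods: GC-EI-HRMS screening and TTC risk assessment with fcmscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GC-EI-HRMS screening and TTC risk assessment with fcmscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcmscreen)
```

## The screening problem

Plastic food contact materials (FCM) release substances into food: additives
and other intentionally added substances (IAS), and non-intentionally added
substances (NIAS) — impurities, reaction and degradation products. Recycled
polymers such as post-consumer LDPE are a particular concern because their
history is unknown. A practical safety screen has three stages:

1. **Tentative identification** of the deconvoluted GC-EI-HRMS features of a
   solvent extract, against an EI spectral library under restrictive
   criteria.
2. **Semi-quantification** of the identified substances from internal-standard
   response factors, expressed as migration into food.
3. **Risk screening**: specific migration limits (SML) for authorized
   substances, and the threshold of toxicological concern (TTC) for
   everything else.

`fcmscreen` implements this chain end to end on deconvoluted feature lists
(peak integration and deconvolution happen upstream; features arrive as
retention time, area and a centroided spectrum).

## Spectral matching

### Search index (SI)

The classical EI library-search similarity is implemented as the Stein–Scott
composite: peaks of query and library spectrum are paired greedily by
smallest m/z difference within a pairing tolerance (default **0.005 Th**,
appropriate for high-resolution centroids), each spectrum is weighted as

$$w_i = I_i^{0.6}\, m_i^{3},$$

and the squared-cosine dot product over paired peaks is blended with a
paired-peak intensity-ratio term, weighted by peak counts and scaled to
0–100. The commercial search indices used by vendor software are
unpublished; the Stein–Scott composite is the de-facto open standard and has
closely similar rank behaviour, which is what matters here because the
identification gate consumes only the score's ordering near its threshold.
The score is invariant under uniform intensity scaling of either spectrum.

### High-resolution filtering (HRF)

High mass accuracy adds an orthogonal constraint: every genuine EI fragment
of a candidate must be a *subformula* of its molecular formula. The HRF
score is the fraction of spectral intensity (peaks above an intensity floor,
default **0.1 % of the base peak**) that is explainable by at least one
subformula of the candidate within a mass tolerance (default **2 ppm**),
scaled to 0–100. Subformulas are enumerated exhaustively; parents are capped
at **120 atoms**, beyond which the enumeration is rejected as combinatorial
(the cap comfortably covers common FCM migrants, e.g. a C42 phosphite
antioxidant at 109 atoms).

Mass conventions: EI produces radical cations, so the theoretical m/z of
both the molecular ion and fragment subformulas subtracts one electron mass
(5.48580e-4 Da). At m/z 200 the electron mass is ≈ 2.7 ppm — larger than the
2 ppm gate — so the correction is not optional. Masses come from a static
embedded table of principal-isotope masses so that 2 ppm decisions cannot
drift with dependency versions.

### Total score

The composite score is a weighted arithmetic mean of SI and HRF (default
weights **0.5/0.5**, configurable). The vendor mixture is unpublished; the
design position taken here is that only the behaviour around the gate
threshold (> 90) is calibrated, and the weights are exposed rather than
guessed more elaborately. Records without a molecular formula cannot be HRF
scored: their total degenerates to SI with an `si_only` flag, and because
they can never satisfy the fragment-annotation criterion they can never be
tentatively identified — exact-mass annotation is constitutive of the
identification claim, not an optional bonus.

### Fragment annotation and ties

The `top_n` (default 10, minimum 3) most intense query peaks are annotated
with their best subformula by lowest |ppm error|; errors are recorded as
computed, without clipping. A peak equidistant between two subformulas is
assigned the one with fewer heteroatoms (CH fragments are the EI default
expectation) and all tied alternatives are kept in a diagnostics attribute.
The molecular ion is "observed" when any peak falls within tolerance of the
radical-cation mass of the full formula.

## Retention index

Under a temperature-programmed oven ramp the linear (van den Dool–Kratz)
convention applies: retention index interpolates linearly in retention time
between bracketing n-alkanes, the alkane of *n* carbons defining
RI = 100·n. The logarithmic Kovats form is for isothermal work and is not
implemented. Retention times outside the ladder are extrapolated linearly
from the terminal anchor pair and flagged, but still pass through the gate —
the RI criterion restricts distance to the library value, not the RI range.
Where the upper ladder holds only even carbon numbers, interpolation simply
spans 200 RI units; no special casing. Library RIs are compared verbatim;
matching the library's column class (semi-standard non-polar) is the user's
responsibility and a known caveat.

## The identification gate

A candidate is tentatively identified only if **all** of:

* total score **> 90** (strict),
* **≥ 3** annotated fragments within **2 ppm**, or **≥ 2** plus the
  molecular ion when observed,
* |ΔRI| **< 50** (strict) whenever the library provides an RI — the
  criterion is vacuous when it does not, in which case the top-ranked
  candidate by the usual ordering is taken as the most probable compound.

All comparisons are strict, matching the printed form of the criteria; a
candidate at exactly 90 or exactly ΔRI = 50 is rejected. Candidate ordering
is total score, then fragments within tolerance, then |ΔRI|, then name — the
final key making output byte-deterministic. A feature whose top two
candidates both pass and lie within 1 total-score point is reported
`ambiguous` rather than silently resolved.

Replicate handling: extraction is in triplicate; a compound is reported when
identified in at least 2 replicates (capped at the number of replicates
present, so single-injection data still works), keeping the best-scoring
instance and reporting the maximum total score across replicates. The
majority rule is a design choice where the procedure is otherwise silent;
it is configurable (`gate_config(min_replicates=)`).

A hit in a local mass list with the molecular ion observed raises a
`mass_list_hit` confidence annotation but is deliberately **not** a gate
criterion.

## Semi-quantification and migration

The average response factor is the mean over internal standards and
replicates of (area / spiked concentration); spiking defaults to
**200 ng/mL** per standard. Unknown concentrations are area / RF. This is
semi-quantitative by construction — compound-specific response differences
are ignored — so results carry `method = "response_factor"` and are never
confused with calibrated values. For compounds confirmed with standards,
ordinary least-squares calibration (optionally 1/x-weighted) of area ratio
versus concentration over a 20–500 ng/mL design is provided, with inverse
prediction and an extrapolation flag.

Migration conversion is the unique dimensionally consistent chain given the
extraction geometry:

$$\text{migration (mg/kg)} = c\,(\text{mg/mL}) \times
  \frac{V_\text{extract}\,(\text{mL})}{A_\text{film}\,(\text{dm}^2)} \times
  6\ \text{dm}^2/\text{kg},$$

with defaults 1 mL, 0.25 dm² (a 5 cm × 5 cm portion) and the conventional
6 dm² of contact surface per kg of food. Geometry is configuration, not
hard-coded.

## TTC risk screen

* Substances with migration **strictly above 0.00015 mg/kg** (the ceiling
  applicable while genotoxicity is not discarded) enter the assessment;
  at or below, they are `excluded_below_threshold`.
* **NIAS**: Cramer class → TDI (Class I 1.80, II 0.54, III 0.09
  mg person⁻¹ day⁻¹); EDI = migration × 1 kg/day (the default adult
  consumption assumption); verdict `pass` iff EDI ≤ TDI. NIAS at or above
  the **0.01 mg/kg** functional-barrier ceiling are additionally flagged.
  That comparison is made after rounding migration to the report's printed
  precision (default 3 decimals): a substance reported at 0.010 mg/kg is
  counted at the limit, which is how such tables are read.
* **IAS**: verdict `pass` iff migration ≤ SML; substances authorized
  without a listed SML pass with an explicit note. IAS are not additionally
  TTC-screened — the SML is their legal reference point.

Cramer classes are **consumed as annotations** (e.g. from Toxtree output),
never derived from structure here: the Cramer decision tree is a separate,
well-maintained tool and re-implementing its structural rules would add
risk, not value. For screening runs without annotations the pipeline can
apply a conservative default (`default_cramer_class = "III"`), which only
ever tightens verdicts.

## The bundled reference dataset

`ldpe_identified()`, `ldpe_risk()` and `union_list_subset()` expose a
transcribed reference screen of a post-consumer recycled LDPE film: 83
tentatively identified substances (12 on the Union list of authorized
substances) and the 45 with migration above the consideration threshold,
with SMLs, Cramer classes, TDIs and EDIs at their reported precision. The
files are checksummed at load. `ldpe_screen_input()` assembles them into
the risk-screen input contract; substances absent from the risk table sat
below the consideration threshold and are represented with migration 0,
which affects no count or verdict. On this dataset the screen yields 45
considered, 9 at or above the functional-barrier level, and 0 exceedances
of any TDI or SML.

## Synthetic data: what it does and does not show

The generator builds libraries whose fragment peaks sit at **exact**
radical-cation subformula masses (random atom-subset deletion with
log-normal intensities, molecular ion included when inside the acquired
m/z 40–500 range), a piecewise-linear RI→RT model through the alkane
anchors (so `compute_ri()` inverts it exactly, making RI tests closed
loops), triplicate injections with uniform perturbations (defaults:
**±1 ppm** m/z, **±5 %** intensity, ±0.02 min retention jitter), areas
consistent with a configured true response factor, and internal standards
spiked at 200 ng/mL. Decoys shuffle all peak m/z values across compounds
(plus a small offset), preserving intensity statistics while destroying
exact-mass structure. Everything is deterministic under the configured
seed, and ground-truth sidecars carry true concentrations and migrations.

These defaults are the validation conditions; the packaged checks run 20
planted compounds plus 20 decoys in triplicate (120 features against a
20-record library), requiring ≥ 95 % of planted compounds to rank first
and pass the gate with zero decoys passing, and a 10-compound noiseless
run whose migrations must be recovered to machine precision.

What passing does **not** show: the generator does not model EI
fragmentation chemistry (no bond energies, no rearrangements), isotope
clusters, chromatographic peak shape, co-elution/deconvolution artefacts,
matrix background, or library spectra measured on other instruments. Real
data will show lower SI scores and genuinely ambiguous candidates; the
synthetic results validate the scoring, gating and bookkeeping machinery,
not instrument-level identification rates.

## Numerical choices and degenerate inputs

* Empty spectra, all-zero intensities, non-positive areas/RTs, ladders with
  fewer than two anchors or non-monotone RTs, calibration with < 3 points
  or a single concentration, and considered NIAS without a Cramer class are
  all hard errors naming the offending object — a screening tool must not
  guess.
* Score clamping: HRF is clamped at 100 against floating-point summation
  overshoot; SI is clamped into [0, 100].
* MSP dialect: `Num Peaks`/`NumPeaks` accepted case-insensitively, peak
  pairs split on whitespace or `;`; output is always NIST style. A record
  whose declared peak count disagrees with its peak lines is rejected by
  name. Records without a formula load, flagged unusable for HRF.
* Seeds: generator functions save and restore the caller's RNG state, so
  simulation calls do not perturb user code.

## Limitations

* The SI and total-score formulas are open re-implementations of
  unpublished vendor metrics; absolute score values are not comparable to
  vendor output, only the gate behaviour is aligned.
* RI comparison ignores the library column class.
* Semi-quantification inherits the single-response-factor approximation;
  order-of-magnitude accuracy is the honest claim.
* Mixture (cocktail) toxicity and the unidentified-feature residual are out
  of scope; the screen addresses identified substances only.
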