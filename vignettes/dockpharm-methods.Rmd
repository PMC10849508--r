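---
title: "Methods: from docked library to in vivo pharmacology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from docked library to in vivo pharmacology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dockpharm)
```

dockpharm implements the quantitative stages that connect a large-library
docking screen to in vitro and in vivo pharmacology, modelled on a
cannabinoid-1 receptor (CB1R) agonist discovery workflow. This vignette
explains the models and procedures, the parameters that matter, the
synthetic-data generators used to test everything, and the numerical
choices and limitations a user should know about.

## The hit-triage cascade

A docking campaign scores hundreds of millions of poses and returns a
score-ranked library. The triage cascade reduces this to a short list of
synthesizable, novel, plausibly binding candidates:

1. **Property window** (`property_filter()`). The docking library is
   restricted to molecules with molecular weight 350-500 amu and
   calculated logP between 3 and 5 - large and lipophilic enough to
   complement a big hydrophobic orthosteric pocket, while retaining
   polarity advantages over classical cannabinoids. Both intervals are
   closed: a molecule at exactly 350 amu or cLogP exactly 3 is kept.

2. **Fingerprints and similarity** (`fingerprint()`, `tanimoto()`).
   Chemotype comparisons use hashed circular substructure fingerprints of
   radius 2 folded to 2048 bits - the conventional ECFP4 equivalent. The
   fingerprinter is the package's own: SMILES are canonicalised and
   perceived through OpenBabel (via ChemmineR/ChemmineOB) and then each
   atom's environment is hashed from its element, heavy-atom degree,
   bond-order sum, ring membership (bridge detection on the molecular
   graph) and implied hydrogen count, with bond labels combining order
   and ring membership. Formal charge is not part of the invariant - the
   generators emit neutral molecules, and the SDF charge block is not
   uniformly exposed by the parser - which is a deliberate
   simplification. Bit-exact compatibility with any other toolkit's
   ECFP4 is **not** promised: every threshold in the cascade
   (clustering 0.5, novelty 0.38, analogs 0.5) is interpreted with this
   one self-consistent fingerprinter.

3. **Leader clustering** (`leader_cluster()`). The top-ranked molecules
   are clustered by a single greedy pass in score order: each molecule
   joins the first existing cluster whose leader it matches at
   Tc >= 0.5, otherwise it founds a new cluster. Because the pass runs
   best-score-first, cluster representatives are automatically the
   best-scoring members. Ties in score are broken by ascending id. This
   is deliberately not complete-linkage clustering: the procedure being
   modelled is representative-by-best-score triage of a ranked list,
   and whether the original threshold was strict or inclusive is not
   stated, so the inclusive `>=` convention is used and documented.

4. **Novelty filter** (`novelty_filter()`). Candidates are compared
   against a reference set of known ligands; a candidate whose maximum
   Tc to any reference reaches 0.38 is rejected. The rejection side is
   inclusive (`>= 0.38` rejects) because the rule being implemented is
   "at or above this similarity, not pursued". An empty reference set
   keeps everything with `max_tc = 0`.

5. **Analog retrieval** (`analog_search()`): pool members with
   Tc >= 0.5 to a named hit, sorted by descending similarity - the
   analog-by-catalog expansion step.

6. **Bookkeeping** (`campaign_summary()`, `hit_rate()`,
   `fulfilment_rate()`). Derived sampling totals (orientations x
   conformations, reported in millions to 3 significant figures) and
   screening rates. `hit_rate()` counts strictly-over-threshold
   displacements ("displaced over 50%" is a strict inequality);
   rates are reported both unrounded and rounded to the nearest
   integer. The summary reports the computed product of its inputs and
   does not arbitrate between differently rounded totals quoted for the
   same campaign.

The 300,000-molecule, 60,420-cluster scale of the original campaign is
not reproduced; all guarantees are stated and tested at desk scale
(hundreds of molecules), where the brute-force oracle can be run.

## Pose geometry

**Symmetry-corrected RMSD** (`symmetry_rmsd()`). When a docked pose is
compared with an experimental pose of the same ligand, topologically
equivalent atoms (the two oxygens of a carboxylate, for instance) may
carry swapped labels; index-matched RMSD then overstates the error. The
corrected metric re-matches atoms *within each element class* by solving
the optimal assignment problem on the squared-distance cost matrix - the
Hungarian algorithm, implemented here as the O(n^3)
shortest-augmenting-path form with row and column potentials - and takes
the RMSD over the optimal matching. The solver is verified in the test
suite against an exhaustive permutation oracle on up to 8 atoms per
element class.

Two scope decisions follow the comparison being modelled. First, no
superposition is performed: docked and experimental poses already share
the receptor frame, so the metric is computed in the common frame (a
separate alignment step would hide genuine placement error). Second,
assignment is restricted by element only, with no bond-topology or
graph-automorphism check; this matches the element-class Hungarian
approach and is documented as potentially permissive relative to
automorphism-restricted RMSD (it can match atoms that are not
chemically equivalent, which lowers, never raises, the reported value).
`naive_rmsd()` provides the index-matched baseline; the corrected value
never exceeds it.

**Polar-contact filter** (`polar_contact_filter()`). Docked poses were
filtered for proximity of their polar atoms to named receptor probes
(the serine/threonine/histidine polar network of the binding site).
The implementation measures heavy-atom to heavy-atom distances from
ligand N and O atoms (sulfur excluded by default; an explicit `polar`
column overrides) to each probe, passing when the required combination
(`any` by default, matching an S-or-T-or-H rule) is within the cutoff.
No cutoff was stated for the original filter, so the conventional
3.5 Angstrom heavy-atom hydrogen-bond limit is the default, inclusive at
the boundary, and exposed as a parameter. Hydrogen positions and
donor-acceptor angles are out of scope: the filter is distance-only,
which is what a coordinates-only pose file supports.

## Concentration-response pharmacology

**4PL fitting** (`fit_4pl()`). Concentration-response data are fit with
the four-parameter logistic on log10 concentration,

$$y = \mathrm{bottom} + \frac{\mathrm{top} - \mathrm{bottom}}
{1 + 10^{(-\mathrm{pEC_{50}} - x)\,h}}, \qquad x = \log_{10}[A],$$

by unweighted Levenberg-Marquardt least squares on replicate-level
points (replicates are fit as independent observations, matching
triplicate designs with no stated weighting). Rising agonist curves have
Hill slope h > 0. Starting values come from the response extremes, the
half-maximal crossing of the concentration means, and unit Hill slope;
if the optimizer cannot step from there, a small grid of fallback starts
(pEC50 at quantiles of the tested range, Hill slope 0.5-2) is tried
before the fit is declared failed. Standard errors are asymptotic Wald
from the Jacobian, with t-based 95% intervals - the same granularity as
standard curve-fitting software. Flat curves (no concentration
dependence, or fitted span numerically zero) and optimizer failures
return `converged = FALSE` with a diagnostic instead of an error, so
that screening pipelines can continue. The fitted object supports
`tidy()`, `glance()` and `autoplot()`.

**Normalisation** (`normalize_to_reference()`) rescales raw responses so
the reference agonist's fitted bottom and top map to 0% and 100%. If the
reference did not respond (flat or failed fit), the data pass through
unchanged with `normalized = FALSE` - unnormalisable data are flagged,
not transformed.

**Cheng-Prusoff** (`cheng_prusoff()`): $K_i = \mathrm{IC}_{50} / (1 +
[L]/K_d)$. The radioligand concentration and affinity are required
inputs because they are assay constants that cannot be inferred from the
IC50 itself. **Percent activity** (`percent_activity()`) implements the
plate-reader equation $100 (\bar{S}_{test} - \bar{S}_{vehicle}) /
(\bar{S}_{ref,max} - \bar{S}_{ref,baseline})$; the denominator is read
as the reference compound's span, the interpretation under which the
reference itself scores 100%, and that reading is recorded in the
output's metadata. **Fold change** (`fold_change()`) reports
$K_i^{parent}/K_i^{analog}$ exactly and rounded, and requires the caller
to name the parent compound - when several plausible parents exist, the
choice changes the answer, so it is never guessed.

## BRET signaling signatures

Raw BRET ratios are standardised with the universal BRET transform
(`ubret()`), an affine map sending the negative-control ratio to 0 and
the positive-control ratio to 10,000. Per pathway and compound, agonist
activity is summarised as $\log_{10}(E_{max}/\mathrm{EC}_{50})$
(`log_r()`); with Emax in percent-of-reference and EC50 in molar the
absolute value is unit-dependent, but the between-compound difference

$$\Delta \log(E_{max}/\mathrm{EC}_{50}) =
\log R_{compound} - \log R_{reference}$$

is unit-invariant, and that difference is what is reported.
`relative_efficacy()` computes the per-experiment log-ratios, their
means, the propagated standard error
$\sqrt{\mathrm{SEM}_c^2 + \mathrm{SEM}_{ref}^2}$ with
$\mathrm{SEM} = \sigma/\sqrt{n}$, the relative efficacy
$\mathrm{RE} = 10^{\Delta}$, and a two-tailed unpaired Student t-test on
the per-experiment values (Welch available via `var_equal = FALSE`).
With fewer than two experiments in either group the point estimates are
still returned and the p-value is `NA`. A pathway where a compound shows
no response carries `NA` through as missing rather than RE = 0: absence
of a fit is not evidence of zero efficacy. No multiplicity correction is
applied across pathways by default, matching per-pathway pairwise
reporting; `p_adjust = "holm"` is available. `radar_table()` and
`plot_radar()` produce the wide table and polar plot conventionally used
to display these signatures, with the reference compound as a ring of
1s.

## Noncompartmental pharmacokinetics

`nca()` computes the model-free summary of a concentration-time profile:
Cmax/Tmax by lookup among quantifiable points; the terminal slope
$\lambda_z$ by log-linear regression; $T_{1/2} = \ln 2/\lambda_z$;
AUC to the last quantifiable point by the linear trapezoid rule; and
$\mathrm{AUC}_{\infty} = \mathrm{AUC}_{last} + C_{last}/\lambda_z$ with
the extrapolated fraction reported.

Three conventions deserve explanation:

- **Terminal window selection.** The original analysis names its
  software but not its point-selection rule, so the conventional
  automatic rule is used: among candidate windows of >= 3 quantifiable
  points after (strictly excluding) Tmax, choose the window with the
  best adjusted R-squared. `lambda_z_points` overrides this. A
  non-negative terminal slope leaves the half-life undefined with a
  diagnostic rather than reporting a negative rate.
- **Below-quantitation (BLQ) handling** follows the stated
  bioanalytical rules exactly: BLQ values before the first quantifiable
  point are set to zero for concentration summaries, and all BLQ values
  are treated as missing for the terminal fit, protecting the half-life
  from noise at the quantitation floor.
- **Trapezoid flavour.** Whether the original used linear or log-linear
  trapezoids is unstated; the linear rule is the simplest defensible
  default (and exact under linear interpolation - the test suite checks
  invariance under insertion of collinear points). For extravascular
  profiles a (0, 0) anchor is prepended when no time-zero sample exists;
  for bolus profiles C0 is back-extrapolated log-linearly from the first
  two quantifiable points.

Mass-per-volume readouts convert to molar only with a caller-supplied
molecular weight (`ng_ml_to_nm()`), since MW cannot be inferred from a
profile.

## Behavioral metrics

`therapeutic_window()` implements the therapeutic index as the ratio of
the minimum dose producing the side-effect phenotype to the minimum dose
producing analgesia. When no tested side-effect dose was significant,
the highest tested side-effect dose is used and the result is flagged
`lower_bound_only` - a "window of at least x-fold". Significance flags
are inputs: the underlying dose-group hypothesis tests (ANOVAs with
post-hoc corrections) are the caller's statistics and are out of scope
here, so the onset dose is simply the smallest tested dose flagged
significant. `cpp_score()` is the conditioned-place-preference score,
per-chamber test-day minus pretest-day time. `fold_to_ddg()` converts an
affinity ratio to a binding free-energy difference,
$\Delta\Delta G = -RT\ln(\mathrm{fold})$ with
R = 1.987e-3 kcal/(mol K), negative for gains.

## Synthetic data: what it emulates, and what it does not

Every pipeline stage is exercised against seeded generators
(`sim_library()`, `sim_pose_pair()`, `sim_dose_response()`,
`sim_pk_profile()`); all restore the caller's RNG state and are
byte-reproducible given a seed.

- `sim_library()` plants chemotype families: each family is one scaffold
  from a built-in set of 22 chemically diverse cores with small
  enumerated substituents appended as SMILES fragments. The scaffold and
  substituent sets were chosen once so that, under the package
  fingerprinter, intra-family similarity is typically above the 0.5
  clustering threshold and inter-family similarity below the 0.38
  novelty threshold - the separability structure the triage cascade
  assumes of a real ranked library. Properties are sampled uniformly in
  the 350-500 amu and cLogP 3-5 windows; scores are family-level base
  scores (uniform on -45 to -25, a docking-score-like range) plus
  Gaussian noise of SD 2. What this does *not* emulate: real libraries
  have continuous chemotype gradation, property-score correlation and
  score-rank noise far from Gaussian, so a clean family recovery here
  shows the clustering logic is correct, not that real libraries
  separate this cleanly.
- `sim_pose_pair()` plants a known atom permutation and a known
  optimal-assignment RMSD. Atoms sit on a jittered 3 Angstrom lattice,
  displacements are rescaled to the target RMSD and kept below half the
  minimum same-element separation, which makes the planted matching
  provably optimal (every cross-assignment distance exceeds every
  planted-assignment distance), so `true_rmsd` is exact by construction.
  The price is realism: targets much above ~1 Angstrom at default
  geometry are rejected rather than generated ambiguously.
- `sim_dose_response()` adds independent Gaussian noise (SD as a
  fraction of span) to an exact 4PL - the simplest model consistent with
  SEM-based replicate summaries. Real plate data have
  concentration-dependent variance and occasional outliers.
- `sim_pk_profile()` is the one-compartment extravascular model
  $C(t) = \frac{F \cdot D \cdot k_a}{V(k_a - k_e)}
  (e^{-k_e t} - e^{-k_a t})$ with an LLOQ flag. Defaults emulate the
  sparse 5-1440 min sampling design at a 0.2 mg/kg dose, with rate
  constants giving a terminal half-life near 114 min and a volume
  giving peak concentrations near 17 ng/mL - the brain-tissue exposure
  scale at which the terminal phase stays quantifiable above an LLOQ
  of 1. Multi-compartment kinetics are out of scope.

## Problem sizes and numerical choices

The test suite and the acceptance script run everything at desk scale,
chosen as the smallest sizes at which the statistical assertions are
stable: family recovery on 500-molecule/20-family libraries over 10
seeds; RMSD oracle equivalence on 100 six-atom pose pairs (tolerance
1e-9); 4PL recovery on a pEC50 {6,7,8,9} x Hill {0.7,1,1.5} grid with 25
simulations per cell at 5% noise (bias < 0.05 log units);
relative-efficacy recovery of a planted +0.30 shift over 300 simulated
pathways and test size over 2,000 null pathways (n = 4 per group,
sigma = 0.1). Fingerprint hashing uses a multiplicative integer mix
carried out in double precision below 2^53, so bit patterns are
identical across platforms. The Hungarian solver works on finite costs
only and breaks cost ties by scan order, which cannot affect the
minimal total.

## Known limitations

- The fingerprinter targets self-consistency, not interoperability;
  thresholds tuned against another toolkit's ECFP4 should be re-examined
  (similarity values are comparable in spirit, not bit-exact).
- Element-class assignment RMSD can be permissive versus
  graph-automorphism RMSD for ligands with many same-element atoms in
  chemically distinct positions.
- The 4PL confidence intervals are asymptotic; for very shallow curves
  or few concentrations they can under-cover, which the coverage test
  bounds only at the simulated design.
- NCA assumes the terminal phase is log-linear within the selected
  window; multi-phasic profiles need manual `lambda_z_points`.
- Behavioral significance flags are consumed, never computed: the
  package summarises dose-outcome tables, it does not test them.
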