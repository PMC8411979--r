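---
title: "Measuring, validating and restraining Watson-Crick base-pair geometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring, validating and restraining Watson-Crick base-pair geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucval)
```

## The problem

Crystallographic and cryo-EM refinement has long been protein-centric:
nucleic-acid models in the same structures often carry distorted
Watson-Crick (WC) base pairs — hydrogen bonds stretched past 4 Å,
exaggerated buckling — that standard covalent-geometry dictionaries
cannot see, because the distortions live in *non-covalent* degrees of
freedom. `nucval` measures those degrees of freedom, scores them
against target distributions mined from high-quality structures, and
turns the same targets into external restraints that a refinement
program can use to pull distorted pairs back.

## Geometry: base frames and the simple parameters

Every canonical base (A, C, G, T, U) carries a fixed *standard
reference frame* (Tsukuba convention), shipped as plain-text
coordinates in `inst/extdata/standard_bases.tsv`. For an observed
residue, the standard base's ring atoms (9 for purines, 6 for
pyrimidines; exocyclic atoms never enter the fit) are superposed onto
the observed ring atoms by least-squares rotation (Kabsch/SVD with a
determinant guard against reflections), and the base frame is the
standard frame carried through that rigid motion. The fit RMSD is
retained as a per-base quality diagnostic.

For a pair, base J is treated as the antiparallel partner: its y and z
axes are negated before combination. With aligned normals $z_i$ and
$\tilde z_j$:

* pair $z$ = normalized mean of $z_i$ and $\tilde z_j$;
* pair $y$ = unit C1′(j)→C1′(i) vector orthogonalized against $z$;
* pair $x = y \times z$;
* **shear, stretch, stagger** = components of $o_i - o_j$ along
  $(x, y, z)$;
* with interbase angle $\gamma$ and hinge axis
  $a = \widehat{\tilde z_j \times z_i}$:
  **buckle** $= \gamma\,(a \cdot x)$ and **propeller**
  $= \gamma\,(a \cdot y)$;
* **opening** = signed angle between the projections of the two
  y axes onto the pair plane.

The hinge-axis decomposition is chosen so that
$\mathrm{buckle}^2 + \mathrm{propeller}^2 = \gamma^2$ holds exactly
(the hinge is perpendicular to the pair normal by construction), which
the property tests verify. Two consequences pin the conventions:

* **Rigid-body invariance.** All six parameters are unchanged (to
  1e-9) under any rotation + translation of the whole pair.
* **Order antisymmetry.** Exchanging the two bases flips the sign of
  shear and buckle and preserves the rest. Pairs are therefore always
  reported purine-first (`canonical_order()`), negating shear and
  buckle when the input order had to be reversed; without this the
  mined means for those two parameters would collapse toward zero.

Sign conventions cannot be fixed by symmetry alone; they are anchored
by the mined table itself (e.g. the G-C shear mean is −0.215 Å, not
+0.215 Å), and the order-independence test asserts that a model and
its reversed-residue copy validate identically.

## Pair detection and classification

Detection is deliberately permissive, because restraint generation
must find poorly modelled pairs — the very pairs whose "hydrogen
bonds" are 4 Å long. Defaults (all exposed via `default_screen()`):
base-frame origins within 15 Å; at least one inter-base N/O–N/O
contact ≤ 4.5 Å; aligned interbase angle ≤ 65°; |stagger| ≤ 2.5 Å.
Only base-moiety N/O atoms are screened, so phosphate contacts never
create candidates. Classification then requires a canonical base
combination ({A,T}, {A,U}, {G,C}), antiparallel normals, and all
standard bond atoms present; everything else is a *rejection with a
machine-readable reason* (`non-WC-combination`,
`vertical-separation`, …), not an error. When candidates share a
residue, the pair with more satisfied hydrogen bonds wins, ties broken
by smaller mean deviation from the bond target means. These cutoffs
are calibration points, not published constants; they were chosen once
so that stacked neighbors are excluded by the stagger screen while
badly stretched pairs are retained.

## Targets

Two embedded tables (TSV, swappable via every function's `targets`
argument) carry the mined targets at 3-decimal transcription
precision:

* 17 hydrogen-bond length targets: N1–N3 and N6–O4 for A–T/A–U, plus
  O6–N4, N1–N3, N2–O2 for G–C, split by DNA–DNA, RNA–RNA and DNA–RNA
  because the distributions differ significantly between nucleic-acid
  types and could not be pooled;
* 28 simple-parameter targets (7 pair classes × shear, stretch,
  buckle, propeller).

Lookups are exact: there is deliberately no fallback across
categories, so asking for a DNA A–U target is an error (those
observations were too rare to support targets). Modified nucleotides
are mapped to their parent base (editable table in
`inst/extdata/modified_base_parents.tsv`, ring-atom matching as
fallback) and validated against the natural pair's targets, a choice
supported by Welch tests showing modified pairs are statistically
indistinguishable from their natural counterparts. One published
oddity is reproduced as printed rather than "corrected": the RNA–RNA
A–U class lists 301 observations in the bond table but 602 in the
parameter table.

## Validation scores

Each measured quantity is standardized against its class target,
$Z = (x - \mu)/\sigma$. Per pair, the four simple-parameter Z scores
combine into $Z_{bpG}$, by default the root mean square of the four
(the mean of |Z| is available via `zbpg_form = "mean_abs"`; the RMS
form is the shipped default and the four published worked values
remain the external calibration anchors for anyone with access to the
deposited models). Pairs with $Z_{bpG} > 3.00$ are flagged as
outliers — a flag, not a verdict: genuine, density-supported
deviations exist, and the flag only marks decreasing likelihood.
Hydrogen-bond Z scores enter the hydrogen-bond rmsZ only, never
$Z_{bpG}$.

Model-level metrics are rmsZ values (root mean square of Z over the
model) for the hydrogen bonds and for each simple parameter, each with
a leave-one-out jackknife standard deviation
$\sqrt{\frac{n-1}{n}\sum_i (\theta_{(i)} - \bar\theta)^2}$; an empty
metric is reported absent, never as zero. Between two models of the
same entry, $Z_{change} = (M_1 - M_2)/\sqrt{\sigma_1^2 + \sigma_2^2}$
with |Z| > 2.6 significant; the combined-σ denominator is this
package's reading of the published description, which names a single
σ without fully specifying the combination. For the whole-model
rmsZ_bpG slider, only |Δ| > 0.5 counts as meaningful — twice the
magnitude that plain re-refinement produces on its own.

A small bond-valence utility ($\sum \exp((R_o - d)/B)$) supports
metal-site checks such as distinguishing genuine divalent-cation
coordination from misfit sites; the coordination cutoff is 3.0 Å, a
package choice since the source material states coordination numbers
without a cutoff.

## Restraints

`generate_restraints()` emits, for models with data worse than 1.70 Å
resolution: one distance restraint per standard bond per WC pair
(target and sigma verbatim from the bond table, block weight 2) and
one parallel-plane stacking restraint per sequential stacked contact
(interplanar target 3.4 Å, block weight 5). At 1.70 Å or better the
gate closes and targets serve validation only; `--nonucrest` disables
generation entirely. Residues with alternate conformations are
excluded. Stacking partners are consecutive same-chain residues whose
base-frame origins are 2.5–5.0 Å apart along the mean normal — this
neighbor definition is the package's own, as the upstream tool's
selection rule is not published. Weights are written as per-block
scale directives rather than baked into sigmas, keeping the table
values inspectable in the restraint file. The writer is timestamp-free
by design: regenerating on an unchanged model is byte-identical, and
regeneration after coordinate changes can alter pair membership only,
never targets.

## Mining

The mining pipeline re-derives target tables from an annotated
collection: extract one observation record per classified WC pair;
filter to records where *both* partners have RSCC ≥ 0.95 and the entry
resolution is ≤ 1.60 Å (records without RSCC are dropped — the mining
set is meant to be exclusively density-confirmed); aggregate per-cell
counts, sample means and sample (n−1) standard deviations, with
shear/buckle signs already canonical. Welch (unequal-variance) t-tests
at α = 0.01 support pooling decisions; "two-sided t-test" alone does
not fix the variance assumption, and Welch is the safer default for
unequal class sizes. A resolution sweep (2.00 → 1.50 Å in 0.05 Å
steps) tabulates per-class counts so the analyst can pick the cutoff;
the package reports the trade-off but does not automate the choice.

## The synthetic builder

`build_pair()` is the exact inverse of the measurement: bases are
placed symmetrically about an internal pair frame (half-rotations
about the hinge and normal, half-translations along the axes), then
the placement is refined by fixed-point iteration because the
*measured* frame depends on the built C1′ positions. Convergence is
below 1e-10 in a handful of iterations for |buckle|, |propeller| <
45°; prescriptions approaching 90° are rejected as non-invertible.
Hydrogen-bond lengths are *emergent*, not prescribed — bond lengths
and stretch are geometrically coupled, and the ideal standard-frame
pair already implies bonds near 2.87–3.0 Å; the mined negative stretch
means (≈ −0.13 Å) move them onto the observed means, which is a useful
physical consistency check. Tests needing specific bond lengths set
stretch accordingly (≈ −1 Å of stretch per +1 Å of mean bond length).

`build_duplex()` stacks pairs with a given rise and twist (defaults
3.4 Å / 36°, B-form-like) for pairing and stacking fixtures; only base
atoms and C1′ are built, since no consumer in the package needs a
backbone trace. `synth_collection()` emulates the mining corpus with
known truth, either as pre-extracted records (bond lengths drawn
directly from the bond Gaussians) or as full coordinate models
(parameters drawn from the parameter Gaussians; stagger σ = 0.1 Å and
opening σ = 1.5°, values typical of well-refined WC pairs, since the
target tables do not constrain those two). RSCC values are Gaussian
truncated at 1 (default 0.975 ± 0.01) and resolutions uniform on a
configurable range. All randomness flows from the seed; equal seeds
give byte-identical mmCIF fixtures.

What passing synthetic tests shows — and does not. The generator
produces idealized isolated pairs and regular duplexes: no backbone
strain, no crystal contacts, no correlated noise, no density. Passing
recovery tests therefore demonstrates that the measurement, scoring
and mining machinery is self-consistent and correctly calibrated, not
that any particular deposited model will score well.

## Numerical choices and degenerate inputs

* Superposition requires ≥ 3 non-collinear points (second singular
  value > 1e-8) and always returns a proper rotation.
* Aligned interbase angles beyond 90° are "not pairable" rather than
  wildly-valued parameters.
* Coincident hinge degeneracy (γ = 0) sets buckle = propeller = 0
  exactly.
* sd ≤ 0 targets are rejected at load time; empty metrics propagate
  as absent (NA), never as 0.
* Occupancy-zero atoms are retained for validation; altloc-flagged
  residues are excluded from restraints only.
* Problem sizes in the test-suite simulations (10⁴ draws for rmsZ and
  Welch calibration, 200-entry collections for mining recovery,
  duplexes of 2–4 pairs) were chosen as the smallest sizes at which
  the statistical assertions have comfortable power.

## Known limitations

* Only Watson-Crick pairs are validated; Hoogsteen, wobble and the
  other pair families are detected as candidates but rejected with
  reasons, and carry no targets.
* Pairing across crystallographic symmetry copies is not considered;
  the model is taken as given in the asymmetric unit.
* RSCC values are consumed from sidecar tables, never computed; no
  electron-density handling of any kind.
* Databank-wide percentiles for the reported metrics are out of
  scope and serialized as null.
* The local (CEHS) parameter set, step parameters and groove
  geometry are not computed.
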