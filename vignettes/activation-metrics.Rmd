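---
title: "Modelling axonal recruitment: field metrics, cable models and fibre filtering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling axonal recruitment: field metrics, cable models and fibre filtering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the science it implements:
the models, their assumptions, the tunable parameters and their defaults,
what the synthetic data generator does and does not emulate, and the
numerical choices made where the design was genuinely open.

## Why three metrics

Extracellular stimulation recruits myelinated axons, and their response
can be modelled at several levels of abstraction. The cheapest proxy is
the electric field magnitude $\|E\|$ along the fibre, usually binarised at
a fixed threshold. Because an axon is polarised by the field component
*parallel* to it, projecting the field onto the local fibre tangent,
$|E\cdot\hat t|$, is theoretically more informative at essentially the
same cost. Neither, however, can represent the simultaneous
depolarisation/hyperpolarisation pattern of bipolar stimulation — for
that a cable model driven by the extracellular potential distribution is
required. The package implements all three and, crucially, makes each
*probabilistic*, so that uncertainty about axonal morphology is carried
into the group-level statistics rather than discarded at a hard
threshold.

## The volume conductor

The bundled conductor is an infinite homogeneous isotropic medium with
point current sources at the active contacts:

$$V(x)=\sum_i \frac{I_i}{4\pi\sigma\|x-x_i\|},\qquad
  E(x)=\sum_i \frac{I_i\,(x-x_i)}{4\pi\sigma\|x-x_i\|^3},$$

with currents in mA, distances in mm ($V$ in volts, $E$ in V/m) and
default conductivity $\sigma = 0.1$ S/m, a standard bulk value for brain
tissue at DBS-relevant frequencies. The metric and axon layers are
agnostic to the field's provenance: a 4-D NIfTI grid of field components
(with optional potential volume) can be imported and is sampled by
trilinear interpolation with a strict out-of-domain error, so fields from
finite-element conductors can be substituted without touching anything
downstream.

Three deliberate simplifications: (i) voltage-controlled protocols are
converted to current by an isolated-sphere access-resistance model,
$I = 4\pi\sigma r_c V$ with $r_c = 0.635$ mm (the radius of a standard
DBS lead); this is a declared approximation, not a model of any pulse
generator. (ii) Queries within 0.05 mm of a source raise an error rather
than being silently clipped — near-singular values would otherwise leak
into aggregates. (iii) The temporal and spatial problems are separated
quasi-statically: the spatial field is computed once per protocol and
scaled by a rectangular pulse waveform in time.

## Field metrics

Fibres are resampled to uniform arc length (default step 0.5 mm — the
sampling density is not critical for the peak aggregator, which is the
default for exactly that reason; sum and mean are provided as well, and
the sum scales with the number of sample points). The projection uses the
absolute dot product by default. This makes both field metrics invariant
under a global polarity flip, which is their documented limitation
relative to PAM and the behaviour assumed by the binarisation thresholds;
a signed variant is available behind the `signed` flag for research use.

Binarisation thresholds default to 200 V/m for the magnitude and 125 V/m
for the projection — the lower projection threshold roughly matches the
counts of "activated" fibres between the two metrics, since the
projection is bounded above by the magnitude. Threshold comparison is
closed on the left (`value >= threshold`).

The sigmoid that converts fibre-wise values to activation probabilities
is anchored so that $p = 0.5$ at the binarisation threshold and
$p = 0.95$ at $1.5\times$ the threshold ($k = \ln 19 / 0.5\theta$). The
anchoring constants are declared package defaults: they encode the
reasonable requirement that the soft and hard readings of the same
threshold agree at the midpoint, and that a value 50 % above threshold is
nearly certain. Both $\theta$ and $k$ are configurable.

The discrete activating function — the second difference of the
extracellular potential along the fibre, $f_i = (V_{i-1} - 2V_i +
V_{i+1})/h^2$ — is implemented as an independent cross-check of the cable
model (action potentials should initiate near its maximum), not as a
headline metric.

## The axon model

The cable model is the classic McNeal formulation: excitable nodes of
Ranvier connected by perfectly insulating internodes, with
Frankenhaeuser–Huxley membrane kinetics at the nodes (sodium, potassium
and non-specific currents as Goldman–Hodgkin–Katz fluxes plus leak).
Morphology follows the standard scaling rules for a fibre of outer
diameter $D$: internodal length $100\,D$, axial diameter $0.7\,D$, node
length 2.5 µm, nodal capacitance 2 µF/cm², axoplasmic resistivity
110 Ω·cm. All of these are overridable in `axon_spec()`. Rates are
Q10-scaled from their 20 °C reference values to 37 °C; the leak reversal
is solved at initialisation so the resting state is an exact equilibrium
(the zero-drive drift over 10 ms is below 10⁻¹⁵ mV).

Nodes are placed along the fibre's arc length, centred so one node sits
at mid-arc; fibres shorter than two internodal lengths are excluded with
a reported geometry error. The nodal extracellular potentials are
$V_e(x_i)\,w(t)$ with a rectangular monophasic pulse (onset 0.1 ms,
simulation window = onset + pulse width + 3 ms).

Numerics: Crank–Nicolson on the axial coupling with an
implicitly-linearised ionic term and exponential-Euler gate updates, at
dt = 5 µs. The GHK fluxes switch to their asymptotic linear branches for
exponents beyond ±200 so that the volt-scale passive polarisation of
nodes close to a contact cannot overflow; the divergence guard is
$|V_m| > \max(500\ \mathrm{mV},\ 1.5\max|V_e| + 100)$ — beyond both the
physiological envelope and anything the drive could passively impose —
and raises a per-fibre solver error that batch drivers log and skip.

**Detection criterion.** An axon counts as activated when its membrane
potential crosses 0 mV (absolute; rest ≈ −70 mV) at either *terminal*
node, i.e. the action potential must propagate to a fibre end. This is a
conservative criterion: for long, thin fibres (conduction velocity scales
with diameter) the fixed 3 ms post-pulse window can expire before the
spike reaches a distant terminal, so small-diameter activations on long
fibres are under-counted relative to a mid-fibre detection rule. This is
a documented modelling choice, consistent with reading "activation" as
transmission.

Threshold search (`find_threshold()`) sweeps the amplitude scale
geometrically upward from the bottom of the bracket and then bisects to
1 % relative tolerance. The upward sweep rather than probing the bracket
top is deliberate: at extreme amplitudes conduction fails through virtual
anodes and depolarisation block, so activation is not globally monotone
in amplitude, and a top-down bracket can falsely report "no threshold".
On the reference fixture (3 µm fibre, 60 µs pulse, source at 1 mm) the
model reproduces the canonical orderings: thresholds strictly decrease
with diameter, longer pulses have lower thresholds, and the anodic
threshold exceeds the cathodic one by a factor of about 4.

**Probabilistic PAM.** Diameters are sampled on a deterministic
equispaced grid over [1, 4] µm with N = 10 by default. We read "uniformly
sampled" as the equispaced grid because it is reproducible and its
estimator of the activated fraction has no Monte-Carlo variance; a seeded
random-uniform mode is provided for the strict reading. The certainty is
$p(A) = N_\mathrm{activated}/N_\mathrm{samples}$, always an exact
multiple of $1/N$. Single-pulse simulation only: the protocol frequency
is recorded but unused — pulse-train effects such as fibre-following at
130 Hz are out of scope in this version, as are charge-balanced biphasic
waveforms.

**Flagged fibres.** Fibres intersecting the electrode body are not
simulated (the field there is unphysical for a point-source conductor and
undefined for a FEM one). With $c$ the centre point between the active
contacts and $R$ the distance from $c$ to the most remote activated
fibre, a flagged fibre is deemed activated iff its minimum point distance
to $c$ is smaller than $R$. The fibre's reference point is its closest
point — the natural choice where none is specified. In the pipeline,
flagging is evaluated per stimulation against that stimulation's lead
position, which also guarantees that every simulated sample point stays
outside the conductor's singularity guard.

## Group statistics

Activation profiles are per-pathway percentages of activated fibres;
probabilistic metrics are binarised at $p(A) \ge 0.5$ for profiles and
filters, with raw probabilities reserved for the weighted tests. Profile
similarity uses Spearman rank correlation (average ranks, t-approximation
p-values), and sets of correlations are compared by a paired t-test on
Fisher-z (atanh) transformed values — we read "z-scored rank
correlations" as Fisher's variance-stabilising transform, the standard
tool for comparing correlations; standardising across the sample would be
the alternative reading.

Fibre filtering contrasts outcomes between stimulations that do and do
not activate each fibre with a pooled-variance (Student) unpaired t-test
— the default reading of "unpaired two-sample t-test"; Welch's form is
behind a flag. The prevalence filter requires activation in at least 20 %
of stimulations *and* non-activation in at least 2 — the second guard is
ours: without it the contrast group can be empty and T undefined. No
multiple-comparison correction is applied and p-values are off by
default: the T-values are used as a ranking (top-k pathway
distributions), not as formal tests. Ties at the k-th rank break by
ascending fiber_id, so top-k sets are deterministic.

The probability-weighted t-test gives each stimulation weight $w = p(A)$
in the activated group and $1-w$ in the other, uses weighted means and
sums of squares, and replaces group sizes with Kish effective sizes
$n_\mathrm{eff} = (\sum w)^2/\sum w^2$; with binary weights it reduces
exactly (to machine precision) to the pooled test, which is the anchor
property the tests assert. For binary outcomes a weighted 2×2 table
yields an odds ratio with Haldane–Anscombe correction and a Wald CI.

Bilateral cohorts are pooled by *mirroring*: assuming symmetric effects,
left-hemisphere stimulations are re-indexed onto the mirrored
right-hemisphere fibres (the synthetic frame places the mid-sagittal
plane at x = 0, so mirroring is x-negation) and all stimulations enter
one analysis.

## The synthetic study

The generator defines the study conditions; it is not a tuning knob. The
default atlas places four bundles around a four-level lead (contact
spacing 2 mm, radius 0.635 mm): a perpendicular passing bundle (40
fibres, 1.2–3.6 mm offsets — the range an activation radius sweeps across
at clinical amplitudes), a short arc bundle terminating 0.9–2.2 mm from
the lead near contacts 1–2 (the polarity-sensitive scenario), a long
lead-parallel bundle at 2–4 mm, and a small bundle crossing the lead body
(flagged by construction). Fibres are exact translates of each bundle's
template curve plus Gaussian jitter (SD 0.15 mm); everything derives
deterministically from one seed via per-component substreams.

The cohort emulates the canonical clinical design: 15 patients, bilateral
bipolar stimulation, one stimulation per hemisphere, adjacent-contact
pairs with random polarity orientation, voltages 1.5–5 V, pulse widths
60–90 µs, frequencies 90–160 Hz, and a per-hemisphere electrode
displacement (SD 0.8 mm) that emulates implantation variability — and,
importantly, decorrelates recruitment of the different bundles so that
outcome associations are attributable. The outcome is
$\mathrm{baseline} + \alpha \cdot \overline{\mathrm{frac}} +
\mathcal N(0, \sigma_n)$ with the activated fraction of one designated
pathway (default: the passing bundle) under the generator's reference
metric — binary peak $\|E\| \ge 200$ V/m, chosen because it is cheap and
deterministic — averaged over the two hemispheres, $\alpha = 40$ % per
unit fraction and noise SD 5 %. Recovery tests then run all three
analysis metrics against this cohort, mirroring the cross-metric design
of the studies this package supports.

What the generator does *not* emulate: anatomically realistic bundle
shapes, tissue heterogeneity/anisotropy or electrode encapsulation,
patient-specific warps, and outcome structure beyond a single driving
pathway plus Gaussian noise. Passing tests therefore demonstrate internal
consistency and recoverability under known ground truth — not clinical
validity on real cohorts.

## Problem sizes and runtime

The shipped study sizes are chosen to keep a full desk-scale analysis in
the minutes range on one CPU: 180 fibres bilaterally, 30 stimulations,
10-diameter pPAM (≈ 27,000 cable solves per cohort, each a 60–300-node
tridiagonal system stepped at 5 µs for ~3 ms). The bundled reproducibility
fixture (`inst/extdata/fixture_config.json`) uses 3 patients and 4
diameters for fast byte-identity checks. All CSV floats are written at 9
significant digits, and run manifests record content hashes but no
wall-clock timestamps, so a rerun with the same seed is byte-identical.

## Known limitations

* Single monophasic pulse per protocol; no pulse trains, no biphasic or
  active-recharge waveforms.
* The point-source conductor overestimates near-contact fields; the
  per-stimulation flagging rule absorbs the worst cases, but fibres just
  outside the lead radius still see stronger drives than a FEM conductor
  would predict.
* Terminal-node AP detection under-counts slow (thin) fibres on long
  trajectories within the fixed post-pulse window.
* The voltage-to-current conversion is an access-resistance
  approximation; absolute activation extents in voltage mode inherit its
  bias, while orderings and contrasts do not.
* Hemisphere mirroring assumes exact structural symmetry, which the
  synthetic frame satisfies by construction but real anatomy does not.
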