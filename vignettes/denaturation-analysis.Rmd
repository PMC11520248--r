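---
title: "Three-state analysis of oligomer disassembly and monomer unfolding"
author: "im30unfold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-state analysis of oligomer disassembly and monomer unfolding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(im30unfold)
```

## The scientific problem

IM30 (Vipp1), a bacterial ESCRT-III superfamily member, self-assembles into
large barrel-like oligomers. In urea titrations two processes overlap:
disassembly of the oligomer (complete by roughly 3.5 M urea, visible as a
~six-fold drop in static light scattering) and unfolding of the released
monomer (a sigmoidal transition near 3 M urea, visible in Trp fluorescence
and far-UV CD). Because the two transitions overlap, a fraction of monomers
is always unfolding before the last barrels have disassembled; quantifying
that overlap requires a model that separates the two steps.

This package implements a three-state equilibrium analysis together with the
secondary-structure statistics used for coarse-grained unfolding
trajectories, a helix-coil stand-in model for H-bond-strength scans, and
solvent-accessible surface areas of the single Trp reporter in different
structural contexts.

## The three-state model and its assumptions

States: native oligomer **N**, folded-core intermediate **I** (a released
monomer whose α1–3 coiled-coil is still folded while the C-terminal helices
are disordered), unfolded monomer **U**, with fractions summing to one.

The key simplification is that intermediate and unfolded monomers scatter
equally and far less than the barrel, so the *normalized* scattering signal
is itself the native fraction:

$$S_{norm} = \frac{S - S_{I,U}}{S_N - S_{I,U}} = f_N.$$

Barrel disassembly — a cascade of transitions between many oligomeric
species — therefore never needs an explicit model; `fN` is taken from data
(`interpolateFractionNative()`, linear interpolation clipped to $[0,1]$).

Only the I ⇌ U step is modelled, via the linear extrapolation model (LEM)
written in midpoint form:

$$K(U) = \frac{c_U}{c_I} = e^{-(c_{50}-U)/d}, \qquad
f_I = \frac{1-f_N}{1+K}, \qquad f_U = K f_I.$$

Here $c_{50}$ (mol/L) is the urea concentration where I and U are equally
populated and $d = RT/m$ (mol/L) is the reciprocal m-value. We parameterize
with $(c_{50}, d)$ rather than $(\Delta G^\circ_{H_2O}, m)$ because the pair
is far less correlated in fitting; `deltaGWater()` converts back
($m = RT/d$, $\Delta G^\circ_{H_2O} = m\,c_{50}$, default 293.15 K).

The observed normalized signals are linear mixtures of the three species:

$$F_{norm} = f_N + a f_I, \qquad D_{norm} = b f_I + f_U,$$

with contrast constants $a = (F_I-F_U)/(F_N-F_U)$ and
$b = (D_I-D_N)/(D_U-D_N)$. Conventions: fluorescence is 1 for pure native
and CD is 1 for fully unfolded protein. Both constants are ratios of
signal levels of an intermediate bracketed by the two end states, so the
fitting bounds default to $[0,1]$. Constructs that never form large
oligomers reduce to the two-state logistic $F_{norm} = 1/(1+K)$,
$D_{norm} = K/(1+K)$ (`predictTwoState()`, `fitTwoState()`).

All logistic expressions are evaluated in log space via `plogis`, so urea
concentrations far above $c_{50}$ cannot overflow.

## Preprocessing choices

* **Smoothing**: a ±5 nm moving average on a uniform grid, with the window
  *truncated* at spectrum edges. Truncation preserves endpoints without
  fabricating data; the alternatives (reflection, zero-padding) bias the
  very regions where λmax reporting matters least but plateau levels matter
  most.
* **Scalar probes**: nearest-grid-point lookup (grids are 1 nm; no
  interpolation), λmax ties broken toward the lowest wavelength so reported
  red shifts are deterministic, scattering read as the mean over
  300 ± 5 nm.
* **222/208 ratio**: values above 1 indicate interacting helices
  (coiled-coil). Ratios measured above 4.5 M urea are flagged unusable by
  default because urea absorbance drowns the 208 nm signal.
* **Normalization**: plateau means over configurable urea windows, defaults
  native = [0, 0.5] M and unfolded = [6.5, 7] M. Whether the original
  analysis pooled plateau points or used single endpoints is not stated
  anywhere we could find; pooling two points halves the variance of the
  anchors and is the package default. Points pushed outside $[0,1]$ by
  noise are kept and flagged, never clipped — clipping would bias plateau
  fits. Kinetic traces are anchored at 6 ms (past mixing artifacts) and
  100 s (before photobleaching matters).

## Global fitting

`fitThreeState()` concatenates fluorescence and CD residuals with equal
weight (inverse-SD weighting is available but not default: the generator's
noise is homoscedastic on the normalized scale, and empirical SD weights
from three replicates add more variance than they remove) and minimizes
with Levenberg–Marquardt (`minpack.lm::nls.lm`), sharing $(c_{50}, d, a, b)$
across probes. Initialization: $c_{50}$ at the CD half-amplitude
concentration, $d = 0.5$ M, $a = 0.8$, $b = 0.2$; five deterministically
jittered starts guard against local minima without touching the caller's
RNG stream. On 9-concentration synthetic curves the optimum agrees with an
exhaustive grid search (0.01-step grids) to within one grid cell — the grid
oracle lives in the test suite, independent of the LM path.

**Parameter uncertainty.** Standard errors come from the Jacobian-based
covariance at the optimum scaled by reduced chi-square, *plus* a
delta-method term propagating the uncertainty of the scattering means into
the parameters. The second term matters: $f_N$ is a measured regressor, and
treating it as exact understates SE($c_{50}$) by roughly 10% under the
default noise model, which pushes nominal 95% intervals to ~89% coverage.
With the propagation term, coverage in a 200-dataset study is ~94%. The
term vanishes identically when the scattering series is noiseless, so exact
round-trips are unaffected.

**The b = 0 test.** Fixing $b = 0$ asks whether the intermediate's
secondary structure could equal the oligomer-embedded monomer's. On data
generated with $b > 0$ the restricted fit always has larger residual sum of
squares (nested models) and systematically misses the low-urea CD rise —
its low-urea CD residuals are one-sided across seeds, which a sign test
detects. This mirrors the scientific argument for a partially disordered
intermediate.

## The synthetic-data generator

The generator defines the study conditions; it is the package's stand-in
for instrument data, which are not deposited anywhere.

* Urea grid 0–7 M in 0.5 M steps, three replicates.
* Scattering: linear decay from $S_N$ to $S_{I,U} = S_N/6$ at 3.5 M urea,
  constant beyond — the observed near-linear decay to a six-fold lower
  plateau.
* Truth parameters $c_{50} = 3.0$ M, $a = 0.81$, $b = 0.24$ (the fitted
  values of the study this analysis reimplements). $d$ is not reported
  anywhere in the main text; the default 0.45 M is chosen once so the
  fluorescence/CD transition spans roughly 2.5–4.5 M urea, as observed.
* Noise: additive Gaussian on raw signals, with SD expressed relative to
  each probe's full amplitude (scattering 5%, fluorescence 3%, CD 4% —
  chosen to match the magnitude of published replicate error bars only
  qualitatively). A single additive term is assumed; instrument versus
  preparation variance cannot be separated without the raw data.
* Emission spectra: Gaussian bands (SD 18 nm) at 335 nm (native and
  intermediate — the Trp stays inside the coiled-coil) and 344 nm
  (unfolded), with the unfolded band's amplitude set so its contribution
  *at 335 nm* equals the unfolded fluorescence level; this keeps the
  extracted I335 series consistent with the tabulated dataset. CD spectra
  mix a helix-like shape (negative bands at 208 and 222 nm, positive band
  near 193 nm) with a coil-like shape (single negative band near 201 nm),
  each scaled to reproduce the per-species 222 nm level exactly.
* Determinism: every generator call is seeded and restores the caller's
  RNG state; identical configurations give bit-identical data.

Two normalizations are returned. The *truth-normalized* series divide by
the exact per-species signal levels the generator knows; fitting them
recovers noiseless parameters to machine precision. The *plateau-normalized*
route (what an experimenter would do) carries a small systematic distortion
of order $10^{-4}$–$10^{-2}$, because the three-state model's plateaus are
not exactly 0 and 1 (e.g. $F_{norm}(7\,\mathrm{M}) = a/(1+K) > 0$). The
end-to-end pipeline test bounds this distortion at 2%.

What passing these tests does *not* show: real spectra have asymmetric
emission bands, wavelength-correlated noise, drifting baselines and
urea-dependent absorbance; the generator has none of these, so the tests
validate the estimator under its stated assumptions, not instrument
robustness.

## Helicity statistics

For coarse-grained trajectories, a residue is in *helical form* when
$\varphi \in (-160^\circ, -20^\circ)$ and $\psi \in (-120^\circ, 50^\circ)$;
it is part of an *α-helix* when it and both neighbours are in helical form
(terminal residues never are); its *propensity* is the fraction of frames
in which it is α-helical. Boundary angles are treated as excluded — the
defining windows say "between" without stating inclusivity, the choice is
measure-zero, and we document it for reproducibility. Missing dihedrals
(termini, incomplete backbones, colinear geometry) propagate as
non-helical rather than being dropped: the propensity denominator is always
the full frame count. Equilibration frames are not excluded by default; the
caller decides what enters the `DihedralSeries`.

φ/ψ are computed from backbone N/Cα/C′ coordinates with the standard
atan2 torsion (sign convention checked against `bio3d::torsion.xyz`), and
`idealHelixCoords()` provides a geometric ground truth built from canonical
bond lengths and angles. Region aggregation defaults follow the construct
boundary at residue 156 (α0–3 vs α4–6); exact per-helix ranges are supplied
by the caller because they are structure-specific.

The backbone H-bond potential
$V = \lambda\,\epsilon_{hb}\,[5(\sigma_{hb}/r)^{12} - 6(\sigma_{hb}/r)^{10}]
\cos^2\theta_N \cos^2\theta_C$ (zero when either angle reaches 90°) has its
minimum $-\lambda\,\epsilon_{hb}$ exactly at $r = \sigma_{hb}$; the
prefactor $\lambda \le 1$ mimics urea-weakened hydrogen bonds.

## The helix-coil stand-in

Quantitative per-residue propensities require the full coarse-grained force
field and replica exchange, which are out of scope. To still reason about
*trends* — helicity falling as H-bond strength falls, stronger-ε regions
melting later — the package ships an explicitly simplified cooperative
helix-coil chain: configuration weight $s^{n_h} \sigma_{nuc}^{n_{runs}}$.
`meanHelicityExact()` evaluates the expected helical fraction exactly by
propagating the partition sum and its count-weighted companion (rescaled
each step, so chains of thousands of residues are stable); for $n \le 12$
it matches $2^n$ enumeration to $10^{-12}$. `sampleHelicityMC()` is a
single-flip Metropolis sampler (20% burn-in, batch-mean standard errors)
checked against the exact value. The λ → s mapping
$s = e^{\lambda\epsilon/kT - c_0}$ uses one offset $c_0$ calibrated so the
*reference* energy has $s = 1$ at a configurable midpoint λ (default
0.875, the centre of the 0.75–1.0 biasing range); with
$c_0 = \lambda_{mid}\,\bar\epsilon/kT$, regions with larger ε retain
helicity to lower λ, which is the behaviour the scan is meant to expose.
All scan output rows are labelled `"helix-coil stand-in"`.

## SASA and the Trp-pocket contexts

`shrakeRupley()` implements the classic sample-sphere algorithm: 960
quasi-uniform points per atom on the accessible sphere (vdW radius + 1.4 Å
probe), counting points not inside any neighbour's accessible sphere.
Bondi-style heavy-atom radii; hydrogens are excluded (cryo-EM models carry
none). The point sphere is rotated deterministically per atom
(golden-angle rotations): with a shared orientation, sampling errors of
neighbouring atoms correlate and sums over atom groups converge no faster
than single atoms; decorrelating the orientations brings the
960-vs-1920-point difference of a 9-atom indole sum from ~1.5% to well
under 1%.

The single Trp reporter sits inside the α1–2 coiled-coil, further buried in
a pocket formed by neighbouring protomers in the barrel. Its indole SASA is
compared across three contexts — full assembly, the isolated chain's
coiled-coil hairpin, the Trp-carrying helix alone — with
`trpIndoleSasa()`. Because the deposited barrel structure cannot be shipped
with the package, `syntheticTrpPocket()` builds an explicitly synthetic
stand-in from ideal helix geometry: a two-helix hairpin whose first helix
carries a full-atom Trp pointing into the groove, flanked by four
neighbour helices closing a pocket. On this structure the robust claims
hold and are what the tests assert: exposure is strictly ordered
full assembly < coiled-coil < single helix, and the exposure gained by
removing the pocket while keeping the hairpin is much smaller than the
gain from stripping down to a lone helix. The absolute areas printed for
the deposited structure are *not* asserted; reproducing them would also
require the (unstated) atom selections, radii set and probe conventions of
the original calculation.

## Problem sizes and numerical settings

The shipped tests and the acceptance script use: 15-concentration titration
grids with 3 replicates; 200 simulated datasets for the recovery study;
0.01-step grid-search oracles on 9-concentration curves; $2^n$ enumeration
up to $n = 12$ and $10^4$ Metropolis sweeps for the helix-coil model;
$10^4$ random flag strings for the triplet rule; 960-point SASA spheres on
a ~500-atom pocket. LM convergence tolerances are set to $10^{-15}$
(ftol/ptol) with up to 1000 iterations; Jacobians for covariance are
central differences with step $10^{-7}$.

## Known limitations

* The analysis inherits the model's central assumption — scattering is
  proportional to barrel content and blind to monomer folding; systems with
  scattering intermediates violate it.
* Plateau normalization biases fitted contrasts by up to ~1% of amplitude
  when transitions are incomplete at the titration ends.
* The helix-coil stand-in makes trend-level statements only; none of its
  numbers are comparable to force-field propensities.
* The synthetic Trp pocket validates the SASA machinery and the context
  logic, not the absolute areas of any deposited structure.
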