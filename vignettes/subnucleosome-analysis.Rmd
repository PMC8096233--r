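---
title: "Quantifying H3 tail accessibility and dynamics across subnucleosomes"
author: "h3tails"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying H3 tail accessibility and dynamics across subnucleosomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(h3tails)
```

## The scientific question

Nucleosomes lose H2A/H2B dimers during transcription, replication and
remodelling, producing hexasomes (one dimer lost, ~30–40 bp of DNA
unwrapped on the dimer-free side) and tetrasomes (both dimers lost, only
~66 bp wrapped). The N-terminal tail of histone H3 (residues 1–37) is a
disordered, DNA-bound ensemble whose accessibility gates reader-domain
binding and enzymatic modification. `h3tails` implements the quantitative
machinery needed to ask how dimer loss changes the H3 tail's conformation,
dynamics and accessibility, using three complementary data streams:

1. **Proteolysis kinetics.** Trypsin digestion of the tail is followed on
   gels as the fraction of full-length H3 remaining. Under a rapid
   conformational pre-equilibrium between protected and exposed tail
   states, and a first-order dependence of the observed rate on enzyme
   concentration, the observed rate constant $k_\mathrm{obs}$ is
   proportional to the site-exposure equilibrium constant, so rate ratios
   between species are relative accessibilities.
2. **Amide NMR.** Peak positions report tail conformation via the combined
   chemical-shift difference
   $\Delta\delta = \sqrt{(\Delta\delta_H)^2 + (0.154\,\Delta\delta_N)^2}$;
   the hexasome shows two peaks per residue, classified against the
   nucleosome and tetrasome references into nucleosome-like (hex-N) and
   tetrasome-like (hex-T) subsets. Peak-height ratios, $^{15}$N $T_1$,
   $T_2$ and heteronuclear NOE report dynamics.
3. **Trajectory ensembles.** RMSF, convergence (RAC), radius of gyration,
   SASA, tail–DNA contacts binned by superhelical location (SHL),
   inter-residue distances, dihedral Kullback–Leibler divergence and
   tail-Cα PCA quantify ensemble differences between species.

A synthetic-data module generates all three streams with planted,
recoverable parameters, so every stage of the pipeline is verifiable
without any external data.

## Site-exposure kinetics

The fraction of full-length H3 remaining at time $t$ is the ratio of the
H3 band volume to the pre-digestion lane of the same replicate. The mean
course is fitted by weighted least squares to

$$f(t) = A_0\, e^{-k_\mathrm{obs} t},$$

with no constant offset (the digest is constrained to decay to zero) and
$0 < A_0 \le 1$; an intercept below one absorbs particles lost during
initial mixing. Weights are $1/\sigma_t^2$ from the replicate SDs.

Numerical choices, made once:

- **SD flooring.** A zero or missing per-timepoint SD (the $t=0$ anchor,
  or noiseless synthetic data) is floored at the median nonzero SD of the
  series; with no nonzero SD at all, weights are uniform. This keeps
  weights finite and makes the fit invariant to uniform rescaling of all
  SDs.
- **Bounds.** The fit uses box-constrained Levenberg–Marquardt
  (`minpack.lm`); solutions at the $A_0 = 1$ or $k = 0$ bound carry a
  boundary flag (and a warning for degenerate, non-decaying input).
- **Errors.** Parameter errors are square roots of the covariance
  diagonal; the ratio of two rates carries first-order (delta-method)
  propagated error. Standard propagation from $0.012 \pm 0.002$ and
  $0.19 \pm 0.02\ \mathrm{min}^{-1}$ gives a ratio error near $\pm 2.9$;
  we report standard propagation throughout.
- **Mixture prediction.** The hexasome course is predicted as the
  half-weighted sum of the nucleosome and tetrasome decays (one
  nucleosomal plus one tetrasomal tail), and compared to observation with
  a Welch two-sample t-test on the per-timepoint means (the specific
  t-test variant is a package choice).
- **Endpoint assay.** Fixed-endpoint digests across trypsin dilutions are
  compared by a two-way fixed-effects ANOVA (species × trypsin, with
  interaction) followed by Tukey HSD restricted to species contrasts
  within a trypsin level, at $\alpha = 0.05$.

```{r kinetics}
spec <- proteolysisSpec("tetrasome", k = 0.19, a0 = 1.0, seed = 1)
fit <- fitExposureKinetics(fractionFullLength(simulateProteolysis(spec)))
fit
```

## NMR analysis

Peak lists are matched by residue number (assignment is upstream of this
package). Classification of the two hexasome peaks of a residue considers
both assignments (peak 1 → hex-N, peak 2 → hex-T, and the swap) and takes
the one with the smaller total $\Delta\delta$; a peak nearly equidistant
from both references (within 0.005 ppm) is flagged ambiguous, and exact
ties go to hex-N so the output is deterministic. Mean $\Delta\delta$
summaries exclude overlap-flagged residues. Relaxation series are fitted
per residue to $H_0 e^{-d/T}$ without offset, duplicate delays entering as
independent observations; $R = 1/T$, $T_1/T_2$ and hetNOE errors use
standard first-order propagation. The 0.154 nitrogen weight in
$\Delta\delta$ is fixed; overriding it warns.

## Trajectory metrics

- **Superposition** uses the Kabsch algorithm with proper rotations only;
  the reference is the frame-average structure refined once (frames are
  refitted to the average of the first-pass fit). For RMSF the fit
  selection is the rigid histone core, so tail fluctuation is measured in
  the core frame.
- **RAC** averages coordinates over every window of length $\tau$ and
  reports the mean RMSD of the window averages to the whole-trajectory
  average; RAC(1) is the ordinary average RMSD and RAC(N) is identically
  zero.
- **Contacts** are heavy-atom pairs within 4.5 Å (inclusive), counted per
  (tail residue, base pair) cell and averaged over frames. The "total
  contacts" of a tail is the rounded sum of the matrix — the aggregation
  convention is a package choice, documented rather than asserted.
  SHL binning maps base pair $b$ to $(b - \mathrm{dyad})/10$, rounded
  half-up to 0.5 steps and clamped to $[-7, 7]$, with the dyad at bp 74
  of 147.
- **SASA** is a Shrake–Rupley estimate on a golden-spiral lattice
  (default 960 points, probe 1.4 Å); pseudo-atoms carry explicit radii.
- **KLD** between dihedral ensembles uses 60 histogram bins over
  $[-180°, 180°)$ with a pseudo-count of 0.5 per bin, reported as
  KLD(system ‖ reference) with a Jensen–Shannon option; backbone
  (pseudo-)dihedrals over four consecutive beads are the default internal
  coordinates. Significance comes from permuting replicate-run labels.
- **PCA** eigen-decomposes the pooled covariance of tail Cα coordinates
  after tail-only superposition; PC1 is oriented so the most extended
  pooled conformation (largest tail radius of gyration) projects
  negative, making "more extended ensemble" read as "more negative PC1".

## What the synthetic generators emulate

- **Gels.** Band volumes follow the mixture decay
  $\sum_j w_j A_{0,j} e^{-k_j t}$ plus Gaussian densitometry noise,
  clamped at zero, with a separate pre-digestion reference lane per
  replicate. Defaults are the study conditions: timepoints 0, 2, 5, 10,
  15, 20, 30, 50 min, triplicates, nucleosome truth
  $(k, A_0) = (0.012\ \mathrm{min}^{-1}, 0.87)$, tetrasome $(0.19, 1.0)$,
  hexasome the half/half mixture. The densitometry noise SD (0.02,
  fraction units) is a tunable chosen to give replicate scatter of the
  size seen on such gels, not a measured value.
- **Peak lists.** Nucleosome reference positions are drawn in the amide
  region; tetrasome offsets are isotropic in combined-shift units with
  mean $\Delta\delta$ 0.09 ppm (resampled to keep every residue at least
  0.02 ppm separated); each hexasome subset sits within mean 0.006 ppm of
  its parent, reflecting the near-coincident overlay of hex-N with
  nucleosome and hex-T with tetrasome peaks; hex-T heights are a planted
  2.4-fold multiple of hex-N with 5% multiplicative noise.
- **Relaxation.** Single-exponential decays without offset over the
  experimental delay schedules (`relaxationDelays()`).
- **Toy particle.** 147 pseudo-bp on an ideal left-handed superhelix
  (radius 41.9 Å, pitch 25.9 Å, 1.84 turns — literature-typical geometry
  used as a generator convention), three heavy pseudo-atoms per bp,
  straight tangent extensions for unwrapped stretches, a rigid jittering
  core, and two 37-bead tails following AR(1)
  (Ornstein–Uhlenbeck-discretised) fluctuations, so RMSF
  ($\sqrt{3}\sigma$ per bead) and temporal correlations have closed
  forms. The hexasome preset unwraps 40 bp on the low-bp side (the
  retained dimer sits on the high-bp, TA-rich-analogue side) and gives
  the unwrapped-side tail 1.6-fold larger fluctuation amplitudes; the
  tetrasome preset unwraps both sides leaving 66 bp wrapped.

What passing tests on these generators do **not** show: the toy particle
has no forcefield energetics, no solvent, no DNA sequence identity and no
realistic tail–DNA binding equilibrium, so trajectory-metric tests
demonstrate the *pipeline's* correctness (oracle equalities, closed-form
recoveries, detection of planted asymmetries), not agreement with
all-atom MD observables, which would require microseconds of sampling.
Likewise the peak-list generator plants shift offsets statistically; it
does not model ring currents or exchange broadening.

## Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen as
the package's own verification conditions: 50 seeds × triplicate
8-timepoint courses for kinetics recovery; 36-residue peak lists;
5000-frame single-bead-chain trajectories for RMSF/stationarity checks;
$10^5$ samples for the KLD closed-form comparison; toy particles of a few
hundred frames for contact/PCA checks.

## Known limitations

- Gel densitometry, spectral processing and peak picking are out of
  scope; the package starts from band volumes and peak tables.
- The proteolysis model assumes rapid pre-equilibrium, enzyme
  concentrations far below $K_m$, and that cleavage reports on the native
  tail ensemble; none of these are testable from within the data.
- The relative site-exposure ratio error is reported by standard
  first-order propagation; conventions that yield tighter printed errors
  exist but are not reproducible from the fit covariances alone.
- The NMR-STAR reader covers the chemical-shift loop only (enough to
  recompute $\Delta\delta$ profiles from deposited shifts); it is not a
  general STAR parser.
- Lipari–Szabo model-free analysis of the relaxation data is deliberately
  not implemented; the analysis stops at $T_1$, $T_2$, $T_1/T_2$ and
  hetNOE.
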