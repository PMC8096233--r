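# h3tails

Quantitative analysis of histone **H3 tail accessibility and dynamics**
across the nucleosome → hexasome → tetrasome series, for chromatin
biophysicists working with trypsin proteolysis gels, amide NMR peak
tables and (coarse or all-atom) trajectory ensembles.

Loss of an H2A/H2B dimer unwraps DNA and frees one of the two H3 tails.
`h3tails` implements the three analyses that quantify this:

- **Site-exposure kinetics.** The fraction of full-length H3 remaining in
  a trypsin digest is fitted to a weighted single exponential
  `f(t) = A0 · exp(−k_obs · t)`, constrained to decay to zero with
  intercept `0 < A0 ≤ 1`. Under rapid conformational pre-equilibrium the
  ratio of `k_obs` between two species is their relative site-exposure
  equilibrium constant. The hexasome time course is predicted as the
  half-weighted sum of the nucleosome and tetrasome decays (one
  nucleosome-like and one tetrasome-like tail) and compared by a
  two-sample t-test; endpoint digests are compared by two-way ANOVA with
  Tukey post-hoc.
- **Amide NMR.** Combined chemical-shift differences
  `Δδ = √(ΔδH² + (0.154·ΔδN)²)`, classification of the hexasome's doubled
  peaks into hex-N / hex-T subsets by shift overlap with the nucleosome /
  tetrasome references, hex-T/hex-N peak-intensity asymmetry, and ¹⁵N
  relaxation fitting (T1, T2, T1/T2, hetNOE) with covariance-based and
  propagated errors.
- **Trajectory metrics.** Kabsch superposition, per-residue RMSF with
  replicate SEM, RAC convergence curves, radius of gyration,
  Shrake–Rupley SASA, tail–DNA heavy-atom contacts (4.5 Å cutoff) binned
  by superhelical location, inter-residue distance maps, dihedral
  Kullback–Leibler divergence with permutation significance, and tail-Cα
  PCA.

A first-class **synthetic-data module** generates all three streams with
planted, recoverable parameters — exponential gel decays with
densitometry noise, paired peak lists with controlled offsets and
intensity asymmetry, relaxation decays, and a toy superhelical particle
(147 pseudo-bp, two 37-bead AR(1) tails, tunable DNA unwrapping) — so the
whole pipeline is testable without external data.

## Worked example

```r
library(h3tails)

## triplicate digestion time courses at the experimental schedule
nuc <- proteolysisSpec("nucleosome", k = 0.012, a0 = 0.87, seed = 1)
tet <- proteolysisSpec("tetrasome",  k = 0.19,  a0 = 1.0,  seed = 2)
fitN <- fitExposureKinetics(fractionFullLength(simulateProteolysis(nuc)))
fitT <- fitExposureKinetics(fractionFullLength(simulateProteolysis(tet)))
fitN
#> ExposureFit [nucleosome]: k_obs = 0.01175 +/- 0.00035 1/min; A0 = 0.875 +/- 0.0046
fitT
#> ExposureFit [tetrasome]: k_obs = 0.1883 +/- 0.0091 1/min; A0 = 1 +/- 0.019 (at constraint boundary)

siteExposureRatio(fitT, fitN)
#>   numerator denominator    ratio     error
#> 1 tetrasome  nucleosome 16.02207 0.9033671
```

The fitted rates recover the planted truth (0.012 and 0.19 min⁻¹), and
their ratio — the relative site-exposure equilibrium constant — says the
H3 tail is ~16-fold more accessible in the tetrasome than in the
nucleosome. The tetrasome intercept sits at its true value on the `A0 ≤ 1`
bound and is flagged as such. A hexasome generated as the half/half
mixture of the two states is statistically indistinguishable from the
mixture prediction:

```r
hex <- proteolysisSpec("hexasome", k = c(0.012, 0.19), a0 = c(0.87, 1),
                       weights = c(0.5, 0.5), seed = 3)
pred <- predictMixture(list(fitN, fitT), c(0.5, 0.5))
compareToPrediction(fractionFullLength(simulateProteolysis(hex)), pred)
#>   statistic       df   p.value
#> 1 -0.080735 13.99912 0.9367956
```

On the NMR side, classifying a synthetic hexasome's doubled peaks against
the nucleosome/tetrasome references and averaging the per-residue
height ratios recovers the planted 2.4-fold hex-T intensity excess, the
signature of a more dynamic tetrasome-like tail:

```r
pk  <- simulatePeakLists(seed = 4)
lab <- classifyHexasomePeaks(pk$hexasome, pk$nucleosome, pk$tetrasome)
asym <- intensityAsymmetry(lab)
c(mean = attr(asym, "mean"), sd = attr(asym, "sd"))
#>      mean        sd
#> 2.4664969 0.1762219
```

`runDemo(list(seed = 1, outputDir = "demo"))` chains all three stages
(simulate → analyse → report) and writes TSV results plus a JSON manifest
with per-file checksums; identical config and seed reproduce identical
checksums. See the vignette (`vignettes/subnucleosome-analysis.Rmd`) for
the models, conventions and their rationale.

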