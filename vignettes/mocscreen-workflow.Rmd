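---
title: "Screening metal-organic cage self-assembly with mocscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening metal-organic cage self-assembly with mocscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mocscreen)
```

## The screening problem

Metal-organic cages (MOCs) form by subcomponent self-assembly: a tritopic
triamine and a monoaldehyde condense to imines while coordinating to a metal
ion, all in one pot. A single precursor combination can yield a tetrahedron
(M4L4), a pseudo-icosahedron (M12L12), triple-stranded helicates built from
the full ligand L and/or the ditopic intermediate I (M2L3, M2IL2, M2I2L,
M2I3), or no discrete assembly at all. High-throughput screens prepare dozens
of such reactions in parallel and read each one out by high-resolution ESI
mass spectrometry (which species formed?) and 1H NMR (did the imine
condensation go to completion?). mocscreen automates that readout: it
enumerates what could have formed, predicts the ions each candidate would
give, searches experimental peak lists for them, triages conversion, and
quantifies host-guest binding in a plate-based single-point assay.

## Formula arithmetic and candidate enumeration

Every species is tracked as an elemental composition (a map from element
symbol to atom count). Each imine condensation adds one aldehyde and removes
one water:

$$\mathrm{L} = \mathrm{T} + 3\,\mathrm{A} - 3\,\mathrm{H_2O}, \qquad
  \mathrm{I} = \mathrm{T} + 2\,\mathrm{A} - 2\,\mathrm{H_2O},$$

so for the triamine 1,3,5-tris(4-aminophenyl)benzene (C24H21N3) and
2-formylpyridine (C6H5NO) the tritopic ligand is C42H30N6. Assemblies are
metal ions plus a linker multiset; a divalent metal gives total cation charge
$2m$ for $m$ metals. ESI spectra of an assembly with charge $2m$ show a
counterion-retention ladder

$$[\mathrm{M}_m\mathrm{L}_n\cdot(\mathrm{X})_k]^{(2m-k)+}, \quad k = 0,\dots,2m-1,$$

one hypothesis per retained-counterion count $k$ (the neutral $k = 2m$ member
is invisible to the mass spectrometer). Metal-free L and I are searched as
protonated ions. Formula strings are the canonical representation; SMILES
input is supported through Open Babel (ChemmineOB) as an optional convenience,
so the core needs no chemistry toolkit.

## Isotopologue patterns

Each ion hypothesis carries a predicted isotope pattern. The engine convolves
per-element multinomial isotope distributions iteratively (element by
element, with exponentiation-by-squaring over atom counts), pruning
negligible probability mass after every step. Design choices that matter:

* **Pruning budget.** The user-facing `prune` (default `1e-4`) bounds the
  *total* discarded probability. Probability discarded before a squaring step
  roughly doubles after it, so internally the per-step threshold is scaled by
  the atom count (loss of at most about $4n\delta$ when building an
  $n$-atom element) and by the number of cross-element convolutions. Tests
  assert `retained_prob >= 1 - prune` for compositions up to the full
  Zn4L4 cage.
* **Fine-structure merging.** Peaks are merged by single-linkage clustering
  with a gap threshold of `resolution` (default 0.01 Da), keeping the
  intensity-weighted mean mass of each cluster. A fixed-grid binning would
  quantize peak positions to the grid and destroy the adjacent-spacing
  signal (about $1.00335/z$) that the charge-assignment step depends on;
  the clustering keeps isotopologues of one nominal mass together (13C2 vs
  34S vs 66Zn differ by about 0.01 Da) while leaving envelope spacing exact.
* **m/z convention.** Cation m/z is $(M - z\,m_e)/z$: the charge is intrinsic
  (electrons removed), not protonation, except for the explicitly protonated
  free-linker ions where the added protons are part of the composition.

The engine is validated against exhaustive enumeration of every isotopologue
for small formulas (up to 6 atoms), which is the only regime where brute
force is tractable.

## HRMS speciation and charge verification

Matching searches an experimental centroided peak list for each hypothesis's
envelope: a hypothesis matches when at least `min_isotope_peaks` (default 3)
of its predicted isotopologue peaks (at or above 1% relative intensity) each
find an experimental peak within `tol_ppm` (default 5 ppm). Each match
produces one record with the six screen-report fields — formula, found m/z,
found intensity, predicted m/z, predicted intensity, predicted charge — built
from the most intense matched peak.

The observed charge is then assigned from the data itself:
$z_\mathrm{obs} = \mathrm{round}(1.00335/\tilde{s})$ where $\tilde{s}$ is the
median adjacent spacing of the matched peaks; if any spacing deviates from
the median by more than 20% the charge is unassignable. Records whose
observed charge disagrees with the predicted charge are discarded. This
filter is not cosmetic: because M12L12 is exactly three times the M4L4
composition, the ladders coincide in m/z at $k' = 3k$, and only the observed
spacing distinguishes a tetrahedron ion from a subsampled icosahedron
candidate. The tolerance, minimum matched-peak count and the major/minor
intensity split (50% of the spectrum base peak) are not dictated by the
underlying method, so all three are exposed as configuration with those
defaults.

A reaction's MS outcome is summarized per topology class — MNLN (M4L4,
M12L12), M2X3 (the helicates), free (L, I) — as major, minor or absent. An
M2X3 ion may of course be a fragmentation product of a larger cage rather
than evidence of a discrete helicate; the classification reports what was
detected and leaves that interpretation to the analyst.

## NMR triage

Peak picking takes local maxima that exceed `snr_threshold` (default 10)
times a robust noise estimate (MAD of the first differences, scaled) in both
amplitude and topographic prominence. The prominence requirement exists
because Lorentzian tails of intense peaks lift nearby noise ripples above any
amplitude-only threshold; prominence (height above the higher of the two
bracketing minima) rejects them without a baseline model. Peaks are typed by
chemical-shift windows (acetonitrile-d3 defaults: aldehyde 9.7-10.3 ppm,
cage imine 8.0-9.5 ppm, aromatic 6.5-8.0 ppm); the windows are a solvent
profile and fully configurable.

Conversion triage is qualitative — no internal standard is assumed — so the
residual aldehyde percentage is the largest aldehyde amplitude relative to
the largest cage-imine (or aromatic) amplitude. Default bins: below 1%
"minor", 1-5% "still considered for scale-up", above 5% "conversion not
satisfactory". The middle bin is closed on both edges (a boundary convention
the bin definition leaves open; it is deterministic and tested). The coarser
stoichiometry-screen bins (5/20% edges) use the same operation with a
different configuration.

Two manual-interpretation helpers round out the module. The
tetrahedron:helicate molar ratio divides the 12H tetrahedron imine integral
(8.7-8.8 ppm) and the 9H helicate integral (8.5-8.6 ppm) by their proton
counts: $r = (I_\mathrm{hel}/9)/(I_\mathrm{tet}/12)$, reported as $1{:}r$.
The solvodynamic size factor between two species measured by diffusion NMR
is $D_\mathrm{minor}/D_\mathrm{major}$, since the Stokes-Einstein radius is
inversely proportional to the diffusion coefficient at fixed temperature and
viscosity; diffusion coefficients are inputs, not fitted here.

## Single-point host-guest assay

Wells mix host and guest stocks; at the default design (500 uL of 0.0008 M
host, 75 uL of 0.0214 M guest) the guest is at 4.0 equivalents. In slow
exchange the free host and the host-guest complex give separate resonances,
so with per-proton-normalized integrals the bound fraction is
$f = I_\mathrm{HG}/(I_\mathrm{H} + I_\mathrm{HG})$ and, assuming single-guest
occupancy,

$$K_a = \frac{f\,H_0}{(1-f)\,H_0\,(G_0 - f\,H_0)}.$$

The design point is chosen so that $K_a \approx 10^3\ \mathrm{M^{-1}}$ gives
comparable free and bound host ($f \approx 0.7$ at these concentrations),
which is where a single-point readout is most informative. Affinity classes
operationalize "much stronger / comparable / much weaker" as decade cutoffs
around $10^3\ \mathrm{M^{-1}}$ (configurable). Degenerate readouts are
flagged rather than extrapolated: $f = 1$ means Ka is unbounded below by the
detection limit (classed strong, infeasible), and an implied complex
concentration exceeding the delivered guest marks the integrals as
inconsistent. The host-by-guest heatmap keeps the largest Ka across
timepoints, since encapsulation can be slower than the first measurement.

Single-point estimates are screening quantities: they rank binders and flag
candidates for full titrations, but carry no error model. Full isotherm
fitting and fast-exchange (chemical-shift) analysis are deliberately out of
scope.

## Synthetic data: what it does and does not emulate

The generators exist so that every analysis stage has a ground truth:

* `synth_ms` sums predicted envelopes (optionally intensity-noised and
  m/z-jittered) and adds decoy peaks drawn uniform in m/z with log-uniform
  intensities. Decoys keep an exclusion window of $3\times$ the jitter around
  every planted peak, floored at 20 ppm so that a 5-ppm matcher cannot be
  handed a decoy sitting on a planted position even at zero jitter — without
  the floor, "exact recovery" would not be a well-posed requirement.
* `synth_nmr` sums Lorentzians with specified integrals on a 0-12 ppm grid
  (0.001 ppm step, 400 MHz default) plus Gaussian baseline noise.
* `synth_assay` solves the 1:1 mass-balance quadratic for the bound fraction
  of each planted Ka and emits the integrals a slow-exchange readout would
  give.

Each generator takes a mandatory seed and is bit-reproducible. What they do
*not* emulate: real line-shape distortions (phase, shimming, solvent
suppression), profile-mode MS data, chromatographic dimensions, overlapping
multiplets, ion-suppression effects, or exchange kinetics. Passing the
planted-recovery tests therefore demonstrates the correctness of the
arithmetic and the matching logic under the stated noise model, not
instrument-grade robustness; on real spectra the configurable thresholds
(ppm tolerance, SNR, ppm windows) carry the burden the generators do not.

## Problem sizes and numerical choices

The test suite and the acceptance script run the full candidate enumeration
for one reaction (8 topologies, 50 ion hypotheses including the 24-member
M12L12 ladder), 100 replicate jitter draws over the 8-charge-state ladder
for charge assignment, planted-spectrum recovery with 50 decoys over
several seeds, a 9-point Ka grid spanning $10^1$-$10^5\ \mathrm{M^{-1}}$, and
NMR grids of 12001 points — sizes chosen so a desk run completes in seconds
while still exercising every code path at realistic complexity. Ties and
degenerate inputs are resolved deterministically throughout (documented
closed bin edges, error signalling for empty references, `NA` for
unassignable charges rather than guesses).

## Worked example

```{r example, eval = FALSE}
p <- example_precursors()

# enumerate the screen
rx <- enumerate_reactions(p[c("A", "B")], p[c("1", "2", "3", "4")],
                          p[c("ZnNTf2", "ZnOTf", "ZnBF4")])
nrow(rx)  # 24

# candidate ions for one reaction, matched against a synthetic spectrum
sp <- candidate_assemblies(p$A, p$`1`, p$ZnNTf2)
hyps <- unlist(lapply(sp, enumerate_ions, counterion = p$NTf2),
               recursive = FALSE)
syn <- synth_ms(hyps[4:5], intensities = c(100, 80), n_decoys = 50,
                jitter_ppm = 2, seed = 1)
rec <- filter_charge_consistent(match_spectrum(syn$peaklist, hyps))
classify_reaction_ms(rec, syn$peaklist)

# conversion triage on a synthetic spectrum with 3% residual aldehyde
nmr <- synth_nmr(data.frame(ppm = c(10.0, 8.6), integral = c(0.03, 1)),
                 noise_sd = 1e-5, seed = 1)
aldehyde_conversion(pick_peaks(nmr$spectrum, snr_threshold = 20))

# single-point Ka at the plate design
mix <- plate_mix(500, 8e-4, 75, 0.0214)
ka_single_point(I_H = 0.3, I_HG = 0.7, mix$H_tot, mix$G_tot)
```
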