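# MechanoCT

Cross-section morphometry and mechanostat simulation of cortical bone
adaptation in the mouse tibia axial loading model.

## What it does, and for whom

In the tibia loading model, one hind limb is loaded in compression while
the contralateral limb is the internal control; endpoint micro-CT of both
tibiae shows where the cortex added or removed bone. MechanoCT is for
researchers analysing such experiments (or testing adaptation models
against them). It provides:

- **Measurement.** From binarised cross-section slices: cavity filling,
  sub-pixel contour extraction, principal-axis registration (marrow
  centroid at the origin, minimal second-moment axis along *y*),
  horizontal mirroring of controls, automated fine alignment, and
  per-point adaptation measures on a normalised position grid
  *P* ∈ [0, 1): periosteal and endosteal surface movement Δη (signed
  minimum distance to the fourfold-interpolated baseline,
  formation-positive) and cortical thickness change ΔCt.Th (hybrid
  minimum-distance / normal-ray rule), with per-point group mean, SD and
  one-sample *t* tests.

- **Simulation.** Forward-Euler evolution of both cortical surfaces under
  a mechanostat. Longitudinal strain comes from the generalised flexure
  formula for an eccentric axial load (the tibia carries 90 % of the peak
  load *F*, Young's modulus 14.8 GPa):

  ε_z = (1/E) · [ −0.9F/A + (Mx·Iyy + My·Ixy)/(Ixx·Iyy − Ixy²)·(y − y_c)
  − (My·Ixx + Mx·Ixy)/(Ixx·Iyy − Ixy²)·(x − x_c) ]

  Surface rates follow a lazy-zone law: no response while
  |ε_z| ≤ ε_hom, beyond it a rate k · (|ε_z| − ε_hom)/ε_hom, plus a
  constant endosteal disuse resorption k_SN = 1.398 µm/day on every day.
  Four model classes (M1–M4) tie the four formation rates together, from
  one universal rate to surface- and strain-direction-specific rates with
  thresholds 2785 µε (periosteal) and 1100 µε (endosteal). The default
  schedule is 5 disuse days + 14 loading days + 2 disuse days (21 days).

- **Calibration.** Staged full-factorial grid search of the formation
  rates against measured Δη fields, scored by combined RMS error over 500
  points per surface: a coarse 0.5 µm/day sweep, then refinements at 0.1,
  0.01, 0.001 µm/day around the carried-forward best.

- **Synthetic cohorts.** A generator for tibia-like annular sections
  (Fourier-modulated radii plus a posterior ridge bump) with per-animal
  shape jitter, contour roughness, pose jitter and 9.56 µm rasterisation,
  whose loaded limbs are forward simulations of a known ground-truth
  mechanostat — so the whole pipeline can be validated by parameter
  recovery.

## Worked example

Simulate 21 days of adaptation under a 10 N peak load with the four-rate
mechanostat, and read off adaptation at the four anatomical stations:

```r
library(MechanoCT)
base <- makeBaselineGeometry(geometrySpec(), n = 500)
params <- mechanostatParams("M4", kPT = 2.148, kPC = 0.981,
                            kET = 7.055, kEC = 0.794)
params
#> MechanostatParams [M4]
#>   thresholds: periosteal 2785, endosteal 1100 microstrain
#>   rates (um/day): kPT 2.148, kPC 0.981, kET 7.055, kEC 0.794; kSN 1.398

sched <- simulationSchedule(loadCase(10, loadPoint = c(0, -1000)))
sched
#> SimulationSchedule: 5 d SN + 14 d loading + 2 d SN (dt = 1 d), F = 10 N

end <- simulateAdaptation(base$periosteal, base$endosteal, params, sched)
dP <- surfaceAdaptation(end$periosteal, base$periosteal)
dE <- surfaceAdaptation(end$endosteal, base$endosteal)
```

At the stations *P* = 0.27 (lateral), 0.46 (anterior), 0.68 (medial),
0.99 (posterior) this prints:

```
     P deltaEtaP_um deltaEtaE_um
1 0.27        -0.49       -29.34
2 0.46         2.05        23.86
3 0.68         0.00       -29.32
4 0.99         9.41        -6.74
```

Read: the lateral and medial stations sit on the neutral axis, so the
periosteum is untouched and the endosteum shows pure disuse resorption
(−29.3 µm ≈ 21 days × 1.398 µm/day). The anterior endosteum lies in the
tensile region, where the large k_ET drives net formation (+23.9 µm)
against the disuse loss; the posterior periosteum is the compressive apex
and forms 9.4 µm. A zero-load schedule reproduces the disuse closed form
(uniform −29.358 µm endosteal, zero periosteal) to 1e−9 µm.

The configuration-driven pipeline (`readRunConfig()`, `runSynth()`,
`runMeasure()`, `runSimulate()`, `runOptimize()`, `runEvaluate()`) runs
the same steps from a single YAML/JSON file and writes slices (PNG + JSON
sidecar), contour/measurement CSVs, fit JSON and a search log to disk.

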