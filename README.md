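# weightsense

Contact-less body weight estimation from RGB-D(-T) point clouds, for
lying, standing and walking subjects.

## Why

Weight-based dosing — thrombolysis of ischemic stroke with rtPA at
0.9 mg/kg is the motivating case — needs a patient's weight within about
±10 %, immediately, from a patient who usually cannot stand on a scale.
Visual guesses by clinical staff miss that band for roughly every third
patient. A depth camera above the stretcher (optionally fused with a
thermal camera) can do better, and the same feature set carries over to
people standing in front of, or walking toward, a sensor.

## What it does

Given a scene point cloud `P`, the pipeline:

1. segments the person `Pp` from the environment `PE` (`P = Pp + PE`):
   region cropping, RANSAC plane removal (stretcher / floor), thermal
   thresholding, background subtraction, statistical outlier filtering,
   largest Euclidean component, morphological cleanup;
2. extracts a 19-component descriptor **f1–f19**: frontal-mesh volume
   `v` and surface `s`, point count `|Pp|`, density `|Pp|/|P|`, scatter
   eigenvalues λ1 ≥ λ2 ≥ λ3 with sphericity λ3/Σλ, flatness
   2(λ2−λ3)/Σλ, linearity (λ1−λ2)/Σλ, moment statistics, sensor
   distance `d`, silhouette contour/hull length and area, gender `g`;
3. regresses weight in kg with a three-layer feed-forward network
   (tanh hidden layer, linear output) trained by resilient propagation
   (iRPROP⁻) with weight decay and subject-level early stopping;
4. for a walking sequence `w1..wN`, aggregates per-frame estimates by
   mean-pairwise-distance clustering: rank frames by
   d̄i = Σ_{j≠i}|wi−wj|/(N−1), keep the densest 20 %, average — one
   robust estimate per stream.

A synthetic scene generator (parametric 14-ellipsoid humanoids with
exact analytic volume and weight = density × volume, rendered through a
pinhole depth sensor with noise, thermal contrast and per-point labels)
makes the whole pipeline testable and reproducible with no recordings.

Evaluation follows the standard metrics: relative error
ε = (x̂−x̃)/x̂, MAE, MSE, and the share of subjects within ±5/10/20 %.

## Worked example

```r
library(weightsense)

subj  <- samplePopulation(3, seed = 7)[[2]]
subj
#> SyntheticSubject #2: male, 1.85 m, 88.4 kg (V = 0.0897 m^3)

scene <- renderScene(subj, sceneSpec("lying"), seed = 42)
seg   <- segmentLying(scene$cloud)
seg
#> SegmentedScene: person 5094 pts / environment 36570 pts
#>   support plane normal: -0.000122 -0.00352 -1  offset: 1.999

fv <- extractFeatures(personCloud(seg), scene = scene$cloud,
                      plane = supportPlane(seg), gender = subj@gender)
featureValues(fv)[c("volume", "surface", "flatness", "distance")]
#>   volume  surface flatness distance
#>   0.1316   0.7984   0.2895   1.765
```

The segmentation recovered the stretcher plane at 2.0 m (its true
distance) and a frontal volume of 0.132 m³ for an 88 kg subject — the
frontal volume deliberately over-covers the body volume (it includes
the skirt down to the back plane); the network learns the mapping.

A full experiment — 300 synthetic subjects, 70/30 subject split,
median of three network trials:

```r
r <- runExperiment("lying", nSubjects = 300, seed = 1)
r$table
#>    mode  n rel_min rel_max rel_mean rel_sd within5 within10 within20   mae  mse
#>   lying 90   -4.17   18.35     0.20   2.44   96.67    98.89      100 0.878 6.27
```

Standing mode (no back plane, so no volume feature) reaches 98.9 %
within ±10 % with MAE 2.12 kg on the same population; walking streams
(14 subjects × 20 frames, stream-clustered) land every aggregated
estimate within ±10 %. The per-frame stream demo:

```r
streamEstimate(c(70, 71, 72, 100, 101))   # keep densest 20% -> 72
```

A command-line front-end over the same functions lives at
`inst/scripts/weightsense.R` (subcommands simulate / segment / extract /
train / predict / stream / evaluate / run).

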