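# eogaze

Gaze-motion tracking from two-channel electrooculography (EOG), with
per-quadrant affine calibration and two-link planar robot kinematics.

The EOG — the standing corneo-retinal potential picked up by electrodes
around the eyes — varies approximately linearly with gaze rotation over the
central visual field. `eogaze` turns that signal into on-screen gaze
positions and robot pointing commands, for researchers building or studying
biosignal human–machine interfaces:

1. **Saccade features.** Traces are low-pass filtered at 60 Hz
   (second-order Butterworth section, bilinear-discretized), then each wave
   yields a *polarity* (which threshold it crosses first), a screen
   *quadrant* from the (Ch1, Ch2) polarity pair, and the *full-wave
   integral* `int = |∫_{x>Th+} x dt| + |∫_{x<Th−} x dt|`.
2. **Pixels.** Normalized integrals map to signed pixel displacements
   through per-direction affine gains, `distance = A·norm_int + B`.
3. **Calibration.** A factored homogeneous transform per screen quadrant —
   `Dilatation · Shear · Translation⁻¹ · Rotation · Translation` — is
   fitted on a 24-target grid and moves the raw ("actual") pixels onto the
   gazed targets.
4. **Kinematics.** Corrected pixels convert to centimeters, shift into the
   robot frame, and solve the closed-form inverse kinematics of a two-link
   (30 cm + 30 cm) planar arm:
   `β = acos((Px²+Py²−L1²−L2²)/(2L1L2))`,
   `α = atan2(Py,Px) − atan2(L2 sinβ, L1+L2 cosβ)`.

A synthetic-signal module generates ground-truth-labeled traces and
calibration sessions with known distortions, so the entire chain is tested
by parameter and target recovery. See the vignette
(`vignettes/eog-gaze-tracking.Rmd`) for the model details and design
decisions.

## Worked example

Simulate a training session with a known per-quadrant distortion, calibrate,
and inspect the result:

```r
library(eogaze)

cfg <- simulation_config(distortions = default_distortions(42), seed = 42)
session <- generate_training_session(cfg)        # 24 targets x 5 repeats
cal <- calibrate_all(session, normalizers = default_normalizers())
cal
#> <calibration_set>
#>   area 1: theta= 41.27 deg, s=(0.927, 0.697), m=(-0.007, +0.137)
#>   area 2: theta= 18.66 deg, s=(0.781, 0.855), m=(+0.048, -0.004)
#>   area 3: theta= 38.12 deg, s=(0.844, 0.758), m=(-0.002, +0.049)
#>   area 4: theta= 45.82 deg, s=(0.686, 0.762), m=(+0.134, -0.002)

evaluate_accuracy(cal,
  cbind(session$actual_u, session$actual_v),
  cbind(session$target_u, session$target_v), areas = session$area)
#> <accuracy_report> 120 test pairs
#>   horizontal: 1.44 +/- 1.10 px  (0.069 +/- 0.052 deg)
#>   vertical:   1.38 +/- 1.17 px  (0.074 +/- 0.063 deg)
#>   area 1: 2.97 +/- 1.82 px (Euclidean, n=30)
#>   area 2: 1.80 +/- 1.10 px (Euclidean, n=30)
#>   area 3: 1.89 +/- 0.87 px (Euclidean, n=30)
#>   area 4: 2.14 +/- 0.86 px (Euclidean, n=30)
```

The fitted rotations and dilatations are the generator's truth back (θ in
the 13.7–47.7° band, scales in 0.6–0.95); the residual 1–3 px comes from the
2 px gaze scatter the generator injects. With `pixel_noise_sd = 0` the
recovery is exact to machine precision.

Joint angles for a screen target, e.g. `(300, 180)` px:

```r
ik <- inverse_kinematics(target_to_endeffector(pixels_to_cm(c(300, 180))))
sprintf("%.2f,%.2f", ik$alpha, ik$beta)
#> "58.14,105.86"
```

i.e. a 58° shoulder and 106° elbow — bracketed by the angles the three
operators reached for that target (56–60° and 105–109°,
`operator_joint_angles()`).

## Command line

A thin shell entry point wraps the same functions
(`inst/exec/eogaze`, or call `run_cli()` directly):

```sh
eogaze simulate  --out session                     # trace + ground truth CSVs
eogaze calibrate --out cal.txt --trace session-trace.csv --schedule sched.csv
eogaze track     --trace session-trace.csv --calibration cal.txt --angles angles.txt
eogaze ik        --u 300 --v 180                   # prints 58.14,105.86
```

Exit codes: 0 success, 2 validation error, 3 runtime error (unreachable
target, incomplete session).

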