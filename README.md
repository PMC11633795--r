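# dirqa — patient-specific QA for deformable image registration

Deformable image registration (DIR) underpins dose accumulation in
adaptive abdominal radiotherapy: contours and dose computed on one CT are
mapped onto another through a displacement vector field (DVF). Commercial
DIR engines report no per-voxel accuracy, yet pancreatic targets sit next
to a stomach and bowel that move several millimetres between fractions. A
registration that looks plausible can still misplace dose gradients by
clinically relevant amounts.

`dirqa` implements a patient-specific QA workflow for intensity-based DIR:
it builds a **known ground-truth deformation** of CT-like anatomy
(smooth superior–inferior respiratory motion peaking at the diaphragm,
plus uniform 5 mm anterior–posterior/lateral shifts of the digestive
organs), deforms the planning image with it, lets a candidate DIR try to
recover it, and then quantifies — voxel by voxel — both the **geometric
error** of the candidate field and the **dosimetric error** it would
inject into dose accumulation. Everything runs from code: a synthetic
abdominal phantom and an analytic dose model replace protected patient
data, and a built-in multi-resolution demons registration stands in for a
commercial engine (external DVFs import through `import_dvf()`).

## The metrics

With candidate field $u^{c}$ and ground truth $u^{gt}$ (components in the
anterior–posterior, left–right and superior–inferior directions, mm), the
per-voxel **magnitude error** on a common 1 mm isotropic, origin-aligned
analysis grid is

$$E(x) \;=\; \sqrt{\big(u^{c}_{AP}-u^{gt}_{AP}\big)^2 + \big(u^{c}_{LR}-u^{gt}_{LR}\big)^2 + \big(u^{c}_{SI}-u^{gt}_{SI}\big)^2}$$

summarised per ROI (GTV, stomach+duodenum, small bowel, whole body) as
mean, 90th percentile, maximum and histograms.

The **dose error** uses a three-step point correspondence on the planning
grid: each planning voxel $A$ maps to $A' = A + u^{gt}(A)$ under the truth
and to $A'' = A + u^{c}(A)$ under the candidate; the signed error is
$D(A') - D(A'')$ in cGy, with $D$ the planned dose as a function of
physical position. Per ROI the package reports six signed summaries, each
as a percentage of the highest prescription level: Dmax error, Dmin error,
mean and maximum voxel error, 95th percentile, and the mean error over the
worst 1 cm³ — plus DVH-metric errors (Dmax, Dmin, D95%, V100%).

Finally the **binned correlation analysis** groups voxels into 50–100
equal-width bins (by ground-truth motion magnitude, or by DIR magnitude
error) and correlates the bin centres with the per-bin mean and with the
per-bin 25th–75th-percentile range of the tracked statistic, linking how
much error a registration makes to how much dose error it causes.

## Worked example

```r
library(dirqa)
cfg <- qa_config(phantom = phantom_config(n = 48, spacing_mm = 4),
                 seed = 7, candidate = "demons")
report <- run_workflow(cfg)
print(report)
```

```
<qa_report> candidate: demons

Ground-truth motion range (mm):
               roi n_voxels max_mm mean_mm
1              gtv     6720   12.2    6.36
2 stomach_duodenum    44989   34.2   22.41
3      small_bowel    83670   13.7    7.69
4             body  2939328   37.9    8.39

DIR magnitude error (mm):
               roi n_voxels mean_mm p90_mm max_mm
1              gtv     6720   0.714  0.862  0.971
2 stomach_duodenum    44989   8.976 15.389 23.737
3      small_bowel    83670   4.446  8.127 21.498
4             body  2939328   5.657 16.284 32.601

Dose-error panel (% of highest prescription):
               roi Dmax_err_pct Dmin_err_pct mean_err_pct max_err_pct
1              gtv     -0.00349    -1.918676        0.530        2.60
2 stomach_duodenum     -9.52313    -0.081404        5.294       15.83
3      small_bowel     -4.88185    -0.000151        0.866        5.97
4             body     -0.00349     0.000000        0.361       16.28
```

Reading it: the ground truth moved the stomach+duodenum 22.4 mm on
average (respiratory SI motion plus the 5 mm digestive shifts). The
demons candidate recovers the GTV region well (0.71 mm mean error — the
tumour sits near the quasi-static spine) but misses much of the
discontinuous digestive shift (9.0 mm mean error in the stomach), and
that geometric failure translates into a dose-accumulation error of up to
15.8 % of the 7500 cGy prescription inside the stomach+duodenum — exactly
the kind of clinically silent failure this QA is built to expose.
`render_report(report, "qa_out")` writes the full machine-readable QA
record (JSON, embedding all sign/percentile conventions) and CSV tables.

A thin command line over the same functions ships in `inst/cli/dirqa.R`
(`simulate`, `register`, `import-dvf`, `qa-geom`, `run-all`), driven by a
YAML config.

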