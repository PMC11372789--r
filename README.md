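# screwfe

Finite-element comparison of compression-screw pretension modeling methods
for screw-fixed implants.

## What this package is for

When an implant plate is fixed to bone with compression screws, tightening
each screw leaves an axial pretension force `F_P` in its core.  Whether a
screw is likely to *pull out* (bone threads strip) or *fail in fatigue*
(cyclic core stress above the endurance limit) depends on how that
pretension and the subsequent service loads are represented in a
finite-element model — and the common modeling choices are not equivalent.
`screwfe` is for biomechanics and implant-design analysts who want to
compare those choices quantitatively on controlled, reproducible models:

* **TIE** — screw heads tied to the implant, no preload (appropriate for
  locking screws, not compression screws);
* **BL-CF / BL-CL** — a bolt-load section in the screw core held at
  constant force, or locked at its converged length;
* **ISO / ORT** — isotropic or axial-only pseudo-thermal contraction of
  the screw shank, calibrated to the target pretension;
* **FOR** — an equal-and-opposite force pair on the shank end faces,
  calibrated.

## The model chain

Per-screw pretension targets come from published empirical relations.
With bone apparent density `rho` (from CT via
`BMD = 0.0008 INT − 0.8037`, `rho = BMD/0.626`), trabecular shear strength
`S = 0.44 · 19.08 rho^2.15` (MPa), and thread geometry (major diameter
`D`, minor `d`, pitch `p`, engaged length `L`):

```
F_PO  = S L π D (0.5 + 0.57735 ((D−d)/2)/p)          pullout threshold
T_str = F_PO r (p + 2 μ r)/(2 r − μ p),  r = (D+d)/4  stripping torque
T_ins = 0.65 T_str                                    insertion torque
F_P   = T_ins / (0.159 p + 0.578·2r μ_G + (d_Km/2) μ_K)
```

Each method then runs as a two-step linear-elastic FE analysis on a
conforming tetrahedral mesh: a pretension step (no external loads) and a
simulation step (preload conditions maintained, external load applied).
The physics-based devices (ISO/ORT/FOR) are calibrated by a simultaneous
per-screw Secant iteration until every induced free-zone force is within
5% of its target.  Post-processing extracts axial force profiles along
each core, free-zone forces, peak von Mises stress (first 3 mm excluded)
and pullout/fatigue flags.  A synthetic-assembly generator builds the
screw–implant–bone models, so everything runs without external data.

## Worked example

```r
library(screwfe)

# pretension chain for the published screw (6.5/3.0 mm, pitch 2.75 mm),
# starting from a printed pullout threshold
tab <- infer_pretension_table(list(screw_spec(id = "cancellous1")),
                              F_PO_override = c(cancellous1 = 1026.7))
tab
#>       screw_id   F_PO    T_str    T_ins      F_P
#> 1  cancellous1 1026.7 3218.401 2091.961 694.4107
round(tab$F_PO / tab$F_P, 2)
#> [1] 1.48
```

`T_ins` is in N·mm: 2.1 N·m of insertion torque converts to a 694.4 N
pretension; the threshold-to-pretension ratio 1.48 is a pure
geometry/friction constant.

```r
# a full method run on the packaged single-screw fixture
a   <- build_assembly(load_recipe("single_cancellous"))
tgt <- assembly_targets(a)          # F_PO = 442.1 N, F_P = 299.0 N
cal <- calibrate_assembly(a, "FOR", tgt$F_P)
res <- run_two_step(a, "FOR", tgt$F_P, cal$controls,
                    load_cases = c("gait1", "liftoff"))
free_zone_force(a, res$pretension, 1)          # ~299 N: the induced preload
free_zone_force(a, res$simulation$gait1, 1)    # rises under the gait load
free_zone_force(a, res$simulation$liftoff, 1)  # ~0: the head has unseated
```

The six-method comparison, agreement matrix and failure flags come from
`run_method_comparison()`; solutions export to legacy VTK via
`export_solution_vtk()` and reports to JSON via `write_comparison_json()`.

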