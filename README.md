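# rbreg — recursive boundary registration of cortical surfaces

`rbreg` registers a cortical grey–white boundary surface (e.g. a FreeSurfer
reconstruction) to a geometrically distorted functional volume, such as an
echo-planar image (EPI) whose B0 inhomogeneity displaces tissue by several
millimetres along the phase-encoding axis. It is aimed at laminar fMRI
preprocessing, where the surface must sit on the functional grey–white
boundary with sub-millimetre accuracy and must remain a topological sphere
for downstream cortical-depth (level-set) analysis.

## The method

Boundary-based registration (BBR) scores a surface position by the intensity
contrast sampled across the boundary: at each vertex with outward normal
`n_i`, intensity is sampled a projection distance `p` inside (`w_i`) and
outside (`g_i`) the surface, giving the signed percent contrast

    Q_i = s · 100 (g_i − w_i) / (½ (g_i + w_i)),

with polarity `s = +1` for T2\*-like targets (grey brighter than white). The
cost

    J = (1/N) Σ_i w_i (1 + tanh( M (Q0 − Q_i) / 2 ))  ∈ [0, 2]

is minimised over a constrained affine (by default translation + scale along
the phase-encoding axis `y`) with a Nelder–Mead simplex.

A single affine cannot undo spatially varying distortion, so the fit is
applied *recursively*: the volume's bounding box is split into `8^d` cuboids
at depth `d`, each cuboid (and six half-splits of it, for robustness) is
fitted separately, the fitted transforms deposit corner displacements on a
shared control-point lattice, each control point takes the componentwise
median of its candidates and is smoothed with its 6-connected neighbours
(`d ← α d + (1 − α) M(x)`, default `α = 0.9`), and the mesh is deformed by
exact per-tetrahedron affines on a fixed six-tetrahedra (Kuhn) subdivision of
each cuboid — continuous across all cell boundaries by construction, so only
vertex positions move and the mesh topology is preserved. Depths proceed from
the whole volume down to cuboids of 4 voxels (or fewer than 100 vertices),
each pass refining the mesh left by the coarser ones. Regions with too few
vertices or no usable contrast keep the identity ("no change").

The package also ships the full synthetic validation design: gyrified-sphere
phantoms rendered as three-tissue volumes, smooth cubic-root-tapered
displacement fields (synthetic voxel-displacement maps), registration quality
metrics (signed-residual histograms with KDE-based FWHM, average absolute
distance), a noise-robustness experiment, FreeSurfer/NIfTI I/O and a CLI.

## Worked example

```r
library(rbreg)

# a small cortical-like phantom: folded sphere + rendered 3-tissue volume
spec <- phantom_spec(radius = 16, subdivisions = 4, gyr_amplitude = 1.2,
                     gyr_frequency = 12, voxel_size = 1.2, margin = 5,
                     seed = 1)
ph <- make_phantom(spec)
ph$mesh
#> surface_mesh: 2562 vertices, 5120 faces
#>   bounding box [mm]: x [-17.51, 16.61], y [-17.51, 16.61], z [-17.51, 16.61]

# distort the surface along y with a smooth, cubic-root-tapered field
vdm <- make_distortion(distortion_spec(target_mean_abs = 2, seed = 6),
                       ph$volume, ph$mesh)
distorted <- distort_mesh(ph$mesh, vdm)
displacement_report(ph$mesh, distorted, axis = "y")
#> displacement_report (2562 vertices, axis y)
#>   mean -1.1476 mm, median -1.9826 mm, FWHM 1.3252 mm, 6.6% sub-millimetre

# register it back to the volume (contrast-matched sampling for this phantom)
cfg <- rbr_config(bbr = bbr_params(projection_distance = 1, slope = 0.05))
res <- rbr(ph$volume, distorted, cfg)
res
#> rbr_result
#>   linear init: cost 0.3506 -> 0.2508
#>   depth 0: 1/1 cuboids fitted, mean |d| = 3.044 mm, neg. Jacobians: 0
#>   depth 1: 8/8 cuboids fitted, mean |d| = 0.756 mm, neg. Jacobians: 0
#>   depth 2: 8/64 cuboids fitted, mean |d| = 0.093 mm, neg. Jacobians: 0
#>   depth 3: 0/512 cuboids fitted, mean |d| = 0.000 mm, neg. Jacobians: 0
#>   final mesh: 2562 vertices

displacement_report(ph$mesh, res$mesh, axis = "y")
#> displacement_report (2562 vertices, axis y)
#>   mean 0.2071 mm, median 0.1973 mm, FWHM 0.8421 mm, 85.6% sub-millimetre

check_topology(res$mesh)$euler_characteristic   # still a topological sphere
#> [1] 2
```

At this toy size only the coarse lattice depths clear the 100-vertex minimum,
so most of the 2 mm distortion is removed but a few-tenths-of-a-millimetre
residual remains; the full-scale experiment below, with a 16x denser mesh,
refines down to 4.8 mm cells.

The "before" histogram is wide and bimodal (the taper pushes displacements
away from zero on purpose); after registration the residuals concentrate
around zero and the face array is untouched.

The same pipeline is available from a shell:

```sh
inst/cli/rbr simulate --out-dir fixtures --seed 1 --subdivisions 4
inst/cli/rbr register --volume fixtures/volume.nii.gz \
    --surface fixtures/distorted.white --out-surface fixtures/registered.white \
    --out-field fixtures/field.nii.gz --log fixtures/log.json
inst/cli/rbr evaluate --surface-a fixtures/truth.white \
    --surface-b fixtures/registered.white --out fixtures/report.json
```

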