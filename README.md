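# epilens

Three-dimensional mapping of the lens epithelial cell (LEC) monolayer in
intact eye lenses.

The lens epithelium covers the anterior hemisphere of the eye lens as a
single cell layer organized into three zones: a sparse, quiescent **central
zone (CZ)** around the anterior pole, a dense proliferative **germinative
zone (GZ)** next to the equator, and short aligned **meridional rows (MR)**
just below it. `epilens` turns a whole-lens confocal z-stack (Hoechst-stained
nuclei, strongly anisotropic voxels) into a quantitative 3D cell map:

- **Nuclei detection** — scale-normalized Laplacian-of-Gaussian likelihood
  map (`-σ²∇²(G∗I)`, σ = R/√3 per axis in physical µm), local maxima by
  grayscale dilation with an ellipsoidal element of physical radius R,
  marker-controlled watershed splitting of partially overlapping nuclei, and
  intensity/circularity filtering (circularity = √(λ_min/λ_max) of the
  region's second-moment matrix).
- **Lens geometry** — a circumcircle through three user-picked landmarks at
  the GZ/MR boundary fixes the near-equatorial plane; the anterior pole (AP)
  is the nucleus met by the ray from the circle centre along the oriented
  plane normal; an axisymmetric spheroid fit refines the equatorial radius
  R_max, polar radius R_min and centre; radial distances D1–D4 are reported.
- **Spherical mapping** — the cloud is rigidly realigned (mounting tilt
  removed), affinely normalized `(x/R_max, y/R_max, z/R_min)` onto the unit
  sphere, and each nucleus gets polar angle θ (pole 0°, equator 90°) and
  azimuth φ.
- **Density analysis** — θ-binned surface-density profiles with exact band
  areas `2πR²(cosθ₁ − cosθ₂)`, profile extremum angles, CZ/GZ/MR
  segmentation with zone area percentages, per-cell k-nearest-neighbour
  densities for heat maps, and transect (ROI) density profiles.
- **Synthetic lens phantoms** — ground-truthed spheroid-cap epithelia with a
  planted zone-density profile, rendered as noisy anisotropic stacks, used
  to validate every stage end to end (no public whole-lens ground truth
  exists). The `mature` preset plants the adult phenotype (aspect ratio
  0.7, density minimum 75°, maximum 90°, 5% MR); `young` plants the
  juvenile one (aspect 0.9, mild maximum at 95°).

## Worked example

Generate a mature-lens phantom, recover its frame from three GZ/MR
landmarks, and run the zonal analysis:

```r
library(epilens)

cfg   <- lens_preset("mature", seed = 1)   # aspect 0.7, ~5000 cells, 35° tilt
truth <- sample_epithelium(cfg)            # ground-truth point cloud
pts   <- mounted_points(truth)             # as-mounted (tilted) cloud
lm    <- gz_mr_landmarks(cfg)              # 3 landmarks at the GZ/MR boundary

frame <- build_frame(pts, lm)
frame
#> lens_frame: R_max 1000.0 um, R_min 700.0 um (aspect 0.700)
#>   landmark circle radius 924.5 um, D1-D4: 924.5, 924.5, 924.5, 966.9 um

mapped <- map_points(pts, frame)           # adds theta_deg / phi_deg
prof   <- theta_density_profile(mapped, frame = frame)
zone_segmentation(prof, mapped)
#> zone_segmentation: min 72.5 deg, max 92.5 deg, MR onset 112.5 deg, edge 116.9 deg
#>   percent of epithelium: CZ 48.1 / GZ 47.0 / MR 4.8
```

Reading the output: the fitted equatorial radius is 1000 µm and polar
radius 700 µm (aspect ratio 0.700 — the planted value; note the raw
landmark circle is smaller than the true equator because the landmarks sit
at the GZ/MR boundary, which is why the spheroid refinement exists). The
density-profile minimum is recovered at 72.5° and the maximum at 92.5° —
within one 5° bin of the planted 75° and 90° — and the meridional rows
cover 4.8% of the epithelium (planted: 5%).

Detection on a rendered stack works the same way on real images:

```r
grid <- render_stack(truth, cfg)        # or read_stack("lens.tif")
det  <- detect_nuclei(grid, detection_params(R = 6))
```

On phantom renderings at default noise this recovers nuclei with precision
and recall above 0.9 (see `tests/testthat/test-acceptance.R`).

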