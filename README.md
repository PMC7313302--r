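# curvemi

Hybrid mono- and multi-modal affine registration of 3D brain volumes
(MRI, PET, CT) in R.

Most registration tools switch similarity measures between mono- and
multi-modal pairs. `curvemi` implements a single hybrid pipeline that
serves both: the moving image is denoised by Perona–Malik anisotropic
diffusion, both images are decomposed into multiscale multidirectional
curvelet coefficient bands, each matched band pair is modelled as a
bivariate Gaussian fitted by maximum likelihood, and the 12-parameter
affine transform (translation, rotation, scale, shear) is found by
maximizing an *adaptive mutual information* — the energy-weighted sum of
closed-form Gaussian band MIs,

    AMI = Σ_b w_b · ( -½ · log₂(1 - ρ_b²) ),   w_b ∝ pooled band energy,

which is even in ρ and therefore indifferent to contrast polarity — a
white-matter-bright MRI and a gray-matter-bright PET score alike. The
search is a derivative-free direction-set (Powell-style) method inside a
coarse-to-fine pyramid, with an SPM-style rigidity prior and data-driven
resolution matching between the two images (see the methods vignette,
`vignettes/curvemi-methods.Rmd`). Registration quality is reported as
normalized mutual information,

    NMI = 2·(H(I_f) + H(I_m)) / (H(I_f) + H(I_m) + H(I_f|I_m) + H(I_m|I_f)),

ranging 1 (independent) to 2 (identical), and as the normalized
cross-correlation coefficient (NCCC, the overlap Pearson correlation).

The package reads and writes NIfTI-1 (plus PNG/TIFF for 2D demos),
ships a deterministic synthetic brain-phantom generator with known
ground-truth transforms for validation, and exposes a small command-line
tool (`exec/curvemi`) with `register`, `evaluate` and `simulate`
subcommands.

## Worked example

Register a multimodal (T1-like fixed, PET-like moving) 96³ phantom pair
whose true misalignment is known:

```r
library(curvemi)

truth <- randomAffine(11, spacing = c(2, 2, 2))   # hidden misalignment
pair  <- makePhantomPair(phantomSpec(shape = c(96, 96, 96), seed = 1,
                                     transform = truth),
                         multimodal = TRUE)
res <- registerVolumes(pair$fixed, pair$moving)
res
```

```
RegistrationResult (converged):
AffineParams (12-dof):
  translation (mm): -7.04709, -16.2723, 0.269922
  rotation (deg):   -10.4605, -10.5463, 9.11466
  scale:            0.997169, 1.02851, 1.07067
  shear (xy,xz,yz): 0.00188102, 0, 0.0059082
  center (mm):      95, 95, 95
  NMI  1.0736 -> 1.1611
  NCCC 0.7608 -> 0.8660
  AMI  0.6706 -> 1.1375 bits
```

The ground truth was translation (−7.13, −15.98, 0.34) mm and rotation
(−9.72, −8.71, 9.10)°: the translation is recovered to well under half a
voxel and the rotations to within about 2° despite the moving image
having swapped tissue contrast, PET-like blur and independent noise. NMI
rises from 1.07 toward its maximum of 2, and NCCC — which the contrast
swap depresses — still improves because the registered geometry aligns.
`registeredVolume(res)` returns the moving image resampled onto the fixed
grid (cubic interpolation of the original, undiffused intensities), and
`writeVolume()` / `writeAffine()` save the result.

From the shell, the same experiment is:

```sh
Rscript exec/curvemi simulate --out pair/ --multimodal --seed 1 --trans-seed 11
Rscript exec/curvemi register --fixed pair/fixed.nii.gz --moving pair/moving.nii.gz --out reg/
```

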