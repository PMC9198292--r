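# npvreg — non-rigid multimodal image registration in R

`npvreg` aligns multimodal 2-D/3-D medical images (CT/MRI/PET-like pairs)
whose intensities are related only through the anatomy they share. It is
aimed at users who need an intensity-based registration pipeline that is
fully inspectable in R: every primitive — histogram accumulation, the
similarity measure, the transform models, the optimizer — is an exported,
tested function, and a synthetic phantom generator provides ground-truth
test cases so the whole pipeline can be validated without any image
database.

## Method

Registration maximizes **normalized mutual information**

    NMI(R, F) = (H(R) + H(F)) / H(R, F),      NMI in [1, 2],

where the entropies come from a B×B joint gray-level histogram. The
histogram is accumulated without interpolating intensities: each floating
sample p maps to q = T(p) between reference voxels, and its unit mass is
split over the neighboring voxels n with separable kernel weights,

    h[R(n), F(p)] += prod_a f(n_a - q_a).

With the linear kernel `1 − |x|` this is classical **partial-volume (PV)**
interpolation; with a cubic kernel satisfying the same nonnegativity and
partition-of-unity conditions it is the smoother **NPV** variant (cubic
Hermite `2|x|³ − 3x² + 1`, or the non-interpolating cubic B-spline that
also suppresses the grid-point extrema interpolating kernels produce).

Transforms map floating coordinates into the reference frame and form a
hierarchy: a centroid-initialized **affine** stage (optionally restricted
to rigid), then a **cubic B-spline free-form deformation** whose
control-point displacements (spacing λ voxels) are blended with the
B₀..B₃ basis. Both stages are optimized by a **DFP quasi-Newton** scheme
with Armijo backtracking on −NMI, using central finite-difference
gradients. See the methods vignette (`vignettes/npv-registration.Rmd`)
for the assumptions, tunable parameters and numerical choices.

## Worked example

```r
library(npvreg)

# synthetic multimodal pair: same anatomy, permuted tissue contrasts,
# rotated by a known 10 degrees
cs  <- make_registration_case(c(64, 64), "rigid", 10, noise_sigma = 0, seed = 3)

res <- register(cs$reference, cs$floating,
                registration_config(affine_model = "rigid", do_ffd = FALSE))
res
#> <npv_result> npv interpolation | NMI: initial 1.6495 -> affine 1.7249 -> final 1.7249

str(evaluate_case(res, cs))
#> $ mean_field_error  : num 0.11
#> $ max_field_error   : num 0.161
#> $ translation_error : num 0.101
#> $ rotation_error_deg: num 0.269
#> $ nmi_initial       : num 1.65
#> $ nmi_final         : num 1.72
```

The registration raised NMI from 1.65 to 1.72 and recovered the 10°
rotation to within 0.27° — a mean alignment error of 0.11 voxel over the
anatomy. `aligned_floating(res)` resamples the floating image into the
reference frame, and `fuse_falsecolor(res$ref, aligned_floating(res))`
builds the green/magenta overlay (aligned structures look gray).

A thin command-line front end is installed with the package:

```sh
npvreg phantom case1 --shape 64x64 --kind rigid --magnitude 10
npvreg register case1/reference.png case1/floating.png -o out
npvreg measure  case1/reference.png out/warped.png
npvreg evaluate out/transform.json case1
```

(`npvreg` lives in the package's `exec/` directory; call it via
`file.path(find.package("npvreg"), "exec", "npvreg")` if it is not on your
PATH.)

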