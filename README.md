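# pipmorph

Outline morphometrics and discriminant classification of grape pips
(*Vitis vinifera* seeds).

Archaeobotanists routinely ask two questions of a waterlogged seed
assemblage: are these pips from wild or domesticated vines, and — if
domesticated — which modern cultivars do they most resemble? Both questions
are answered morphometrically: domestication elongated the pip and its
beak, so the dorsal-view outline alone carries a strong signal. `pipmorph`
implements the full analysis as a tested, reusable R pipeline:

1. **Outline extraction** — binarise a scanned silhouette, trace the outer
   contour of the largest 8-connected component (Moore-neighbour boundary
   following), and resample it to 360 points at equal arc length.
2. **Elliptic Fourier descriptors (EFDs)** — each closed outline
   \((x(t), y(t))\) is expanded in the Kuhl–Giardina closed form
   \[
   x(t) = A_0 + \sum_{n} a_n \cos\tfrac{2\pi n t}{T} + b_n \sin\tfrac{2\pi n t}{T},
   \qquad
   y(t) = C_0 + \sum_{n} c_n \cos\tfrac{2\pi n t}{T} + d_n \sin\tfrac{2\pi n t}{T},
   \]
   with \(t\) the cumulative arc length and \(T\) the perimeter. After
   normalising for centroid position, centroid size, and the position of the
   first point relative to the centroid, the coefficients of harmonics 1–6
   (24 values) form the feature vector; harmonics 1–6 carry well over 95% of
   the total harmonic power \(P_n = (a_n^2+b_n^2+c_n^2+d_n^2)/2\).
3. **Stepwise linear discriminant analysis** — variables enter by the
   largest Wilks'-lambda partial *F* exceeding *F*-to-enter = 3.84, leave
   when *F*-to-remove < 2.71, with a tolerance (collinearity) floor of
   0.001; classification functions
   \(C_j(x) = \mu_j' W^{-1} x - \tfrac12 \mu_j' W^{-1} \mu_j + \ln \pi_j\)
   use the pooled within-class covariance, and accuracy is estimated by
   leave-one-out cross-validation (an exact rank-one downdate, equivalent to
   refitting per case).
4. **Two-stage classification and reporting** — stage 1 separates wild from
   domestic on a deliberately balanced reference (1319 + 1319 pips by
   default); stage 2 assigns domestic-classified unknowns to individual
   cultivars (330 by default, equal priors); reports give per-site status
   percentages and berry-colour / geographic-origin breakdowns of the
   assigned pips.

Because no archaeological images or germplasm reference collections are
distributable, the package ships a **synthetic silhouette generator**: each
shape class is a Gaussian in normalised-EFD space (a roundish short-beak
"wild" template, an elongated long-beak "domestic" template), sampled
coefficients are reconstructed by the inverse transform and rasterised at a
realistic scale (142 px ≈ 6 mm at 600 dpi). Class separation is specified
as a Mahalanobis distance Δ and calibrated so the *extracted* features
realise it; the two-class Bayes accuracy Φ(Δ/2) then provides a closed-form
oracle for the whole pipeline.

## Worked example

A scaled-down end-to-end run (the packaged demo configuration: 144
reference pips over 12 cultivars and 4 wild accessions, two sites with 40
and 30 unknown pips):

```r
library(pipmorph)
run <- run_pipeline(demo_config(), seed = 7)
print(run)
#> <pip_run> seed 7: 144 reference + 70 unknown pips, stage-1 LOOCV 0.967
#> <allocation_report>
#>
#> Status by site:
#> # A tibble: 4 × 4
#>   site   status       n   pct
#>   <chr>  <chr>    <int> <dbl>
#> 1 Site A domestic    29    73
#> 2 Site A wild        11    28
#> 3 Site B domestic    17    57
#> 4 Site B wild        13    43
#>
#> Cultivars with >= 2 assigned pips: 9 (of 11)
```

The per-site wild/domestic split is the headline archaeobotanical result
(percentages are rounded half away from zero, so a 72.5/27.5 split prints
as 73/28). The demo sites were generated with 90% and 70% domestic pips;
at this small demo scale the between-cultivar scatter pushes a slice of
the domestic pips across the morphotype boundary, which is exactly the
kind of allocation uncertainty the report quantifies. Fitted objects
follow broom conventions:

```r
glance(run$stage1$loocv)
#> # A tibble: 1 × 3
#>   accuracy     n n_groups
#>      <dbl> <int>    <int>
#> 1    0.967   120        2

head(tidy(run$stage1$selection), 4)
#> # A tibble: 3 × 6
#>    step action variable statistic lambda tolerance
#>   <int> <chr>  <chr>        <dbl>  <dbl>     <dbl>
#> 1     1 enter  d1           234.   0.335     1
#> 2     2 enter  d4            14.8  0.297     0.979
#> 3     3 enter  c2            10.8  0.272     0.918
```

`d1` — the first-harmonic elongation coefficient — enters first, as it
should: elongation is the domestication signal. `autoplot()` methods are
available for descriptor sets, populations, LOOCV confusions and
allocation reports, e.g. `autoplot(run$report, type = "colour")`.

At full scale (`default_config()`: 2640 reference + 2228 unknown pips, 330
cultivars) the pipeline runs in a few minutes on one CPU.

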