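# TreeSpectra

Component classification of fruit-tree point clouds acquired with
hyperspectral LiDAR (HSL).

An HSL scanner records, for every point, a 3D coordinate plus a spectrum
of laser echo intensities — here 101 channels from 550 nm to 1050 nm at
5 nm. TreeSpectra labels each point of such a scan as **wood**, **leaf**,
**ripe fruit** or **unripe fruit**, for orchard phenotyping uses such as
fruit counting, maturity staging and canopy structure analysis. It is
aimed at researchers working with spectral point clouds who need a
reproducible, scriptable pipeline rather than manual point-cloud editing.

## Method

1. **Reflectance calibration** against a scanned reference whiteboard of
   known reflectance ρ_b (≈0.99):

   ρ_t(λᵢ) = V_t(λᵢ) / V_b(λᵢ) · ρ_b(λᵢ)

2. **Spectral features** — nine per-point parameters: R700, R730, R780,
   R850, R900; the mean reflectance over 760–930 nm; the red-edge
   chlorophyll index CI = R780/R710 − 1;
   NDVI = (R800 − R670)/(R800 + R670);
   NDRE = (R790 − R720)/(R790 + R720).

3. **Preliminary classification** with a random forest (8 trees; SVM and
   BPNN variants included) after a 7:3 train/validation split.

4. **Spatial reprogramming** — the key enhancement step. Spectral
   classifiers fail at component *edges*, where the laser footprint
   straddles components and the spectrum flattens. Every point k is
   therefore revisited and re-assigned the plurality class among its
   N = 12 nearest neighbors by Euclidean distance
   S(i,j) = √((i_x−j_x)² + (i_y−j_y)² + (i_z−j_z)²), which corrects
   edge errors using the surrounding component interior.

5. **Evaluation** by coordinate-matched comparison with truth labels:
   per-class accuracy K_j = T_j/H_j and overall accuracy
   K_Overall = ΣT_j / ΣH_j.

6. **Colored 3D reconstruction** — standard PLY export with one RGB color
   per class, plus a two-color rendering of the points the reprogramming
   step changed.

Because real HSL orchard scans are not publicly deposited, the package
includes a first-class synthetic scene generator (`generateScene()`)
reproducing their statistical structure — four component spectra with the
characteristic shapes, tree geometry from simple primitives, and
attenuated, flattened edge-point spectra — so the whole pipeline is
testable end to end.

## Worked example

```r
library(TreeSpectra)

spc <- generateScene(sceneConfig(seed = 1))   # 5,000-point synthetic tree
spc
#> SpectralPointCloud: 5000 points, 101 channels (550-1050 nm), kind=reflectance
#> labels: UnripeFruit=1000 RipeFruit=1000 Wood=1500 Leaf=1500
#> edge-flagged: 792

res <- runPipeline(spc, seed = 1)             # train RF, predict, reprogram, score
res$reports$preliminary
#> ClassificationReport
#>        class total correct      K
#>  UnripeFruit  1000     951 0.9510
#>    RipeFruit  1000     979 0.9790
#>         Wood  1500    1456 0.9707
#>         Leaf  1500    1437 0.9580
#> K_Overall = 0.9646 (4823/5000 points)

res$reports$enhanced
#> ClassificationReport
#>        class total correct      K
#>  UnripeFruit  1000     990 0.9900
#>    RipeFruit  1000    1000 1.0000
#>         Wood  1500    1455 0.9700
#>         Leaf  1500    1499 0.9993
#> K_Overall = 0.9888 (4944/5000 points)

sum(res$changed)                              # points the reprogramming changed
#> [1] 228                                     # 81% of them edge-flagged
```

The preliminary spectral classifier reaches K_Overall = 0.9646, with its
errors concentrated on edge points; one reprogramming pass at N = 12
lifts it to 0.9888, and the points it changes sit overwhelmingly on the
flagged component edges — the behavior the two-stage design is built
around. `sweepNeighbors(spc, N = 9:15)` reproduces the neighborhood-size
experiment (the curve is flat near its maximum around N ≈ 10–12 on these
scenes).

A thin command-line front end wraps the same functions:

```sh
Rscript inst/exec/treeclass simulate --seed 7 --out scene.csv
Rscript inst/exec/treeclass run --in scene.csv --seed 7 --out run_out
Rscript inst/exec/treeclass sweep-n --in scene.csv --seed 7
```

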