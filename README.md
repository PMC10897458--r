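# smlmorph

Spatiotemporal clustering and morphological fingerprinting of
single-molecule localization microscopy (SMLM) data.

SMLM techniques (STORM, PALM, PAINT, and time-resolved variants) produce
tables of localizations — `(x, y)` positions in nanometres, optionally
with a frame index `t` — in which biological assemblies such as protein
aggregates, receptor clusters or nuclear pore complexes appear as dense
point groups amid background detections. `smlmorph` extracts the
individual assemblies from such tables with a self-parameterizing,
density-based pipeline and quantifies each one by a named vector of 40+
morphological features, so heterogeneous structures can be separated,
classified and measured without per-dataset hand tuning.

## The method in brief

**Clustering.** Localizations are z-scored in all available axes
(scale invariance), then an initial density model — DBSCAN for fields
below 1500 points per standardized area, HDBSCAN above — proposes regions
of interest, with a density-contour failsafe when nothing is found.
Each region is MinMax-rescaled and refined frame by frame using a
data-derived search range

&nbsp;&nbsp;&nbsp;&nbsp;r<sub>search</sub> = √(radius_ratio · SEM),&nbsp;&nbsp;SEM = sd(d ∈ IQR(pdist)) / √m,

the standard error of the interquartile pairwise distances: new
aggregation seeds are detected by DBSCAN at `eps = r_search` among points
away from existing labels, and growth joins each unlabeled point to its
nearest labelled neighbor within r<sub>search</sub>, so assemblies that
overlap in space but started at different times are dissected. A smart
density filter finally rejects candidates whose local point density
(k-NN estimate) does not exceed the noise baseline (mean + 1 SD of
sampled background densities above their 25th percentile).

**Fingerprinting.** Every extracted assembly is aligned to its principal
axes and summarized by four feature families: geometric interior
(pruned-Delaunay `Area`, `density = N/Area`, `max_extent`), graph network
(radius-graph and minimum-spanning-tree statistics, the weighted graph
diameter, path-straightness ratios `L_s_ratio`/`L_l_ratio`, optional
local-density Gaussian fit `mu_N`/`sig_N`/`W_N`), circularity (density
contour shape: isoperimetric quotient 4πA/P², aspect ratio, radial CV,
solidity, equivalent-radius ratio) and symmetry (quadrant occupancy and
extent balances). Fingerprints feed seeded UMAP embedding, DBSCAN
grouping, random-forest feature ranking, and size quantification via
r = √(A/π) with σ_d = 2σ_r.

Ground-truth simulators (isotropic KDE growth, steric-hindrance growth,
branching fibrils, sparse nanostructures, fluorophore blinking, uniform
and heterogeneous noise) and evaluation utilities (per-aggregate accuracy
TP/(TP+FP+FN), precision/recall/F1 at micro/macro/weighted aggregation,
growth-onset offsets) complete the package. The methods vignette
(`vignettes/methods.Rmd`) documents every model, default and numerical
convention.

## Worked example

```r
library(smlmorph)

# simulate a labelled movie: 5 isotropic + 5 fibril assemblies, 40x40 um,
# 400 frames, uniform background noise
mv <- assemble_movie(movie_spec(c(isotropic = 5, fibril = 5)), seed = 7)
mv
#> <simulated_movie: 10 assemblies (isotropic, fibril), 24894 points (5745 noise)>

res <- cluster_localizations(mv$points, pipeline_config("simulation", seed = 7))
res
#> <cluster_result: 12 assemblies, 10994/24894 points labelled (dbscan)>

evaluate_clustering(res$labels, mv$points$assembly_id, mv$points$t,
                    setNames(mv$assemblies$frame_start, mv$assemblies$assembly_id))
#> <metrics_report: 10 assemblies | accuracy mean 0.666 median 0.634 | macro P 0.936 R 0.687 F1 0.774>
#>   onset offset mean 2.2 frames (0 unmatched)

fp <- fingerprint_assemblies(mv$points, res$labels)   # 12 x 47 features
fp[1:3, c("assembly_id", "Area", "max_extent", "L_s_ratio", "N_points")]
#>   assembly_id     Area max_extent L_s_ratio N_points
#> 1           1 11729284   5806.662     1.110     1788
#> 2           2  5434065   7165.764     1.008      196
#> 3           3 16494426   7169.876     1.005      147

quantify_radius(fp$Area[fp$Area > 0])
#> <quantification: d = 3091.6 +/- 1260.9 nm (N = 12)>
```

The generic `simulation` profile recovers all ten assemblies (plus two
fragments) with high precision; the per-class profiles (`isotropic`,
`steric`, `fibril`, `sparse-4` … `sparse-25`) carry the tuned settings
for each morphology regime, and the metrics report shows exactly where
localizations were lost (here: the diffuse isotropic rims, scored as
false negatives). Growth onsets are located to within a few frames.

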