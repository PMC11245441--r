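# mlbundle

Multi-layer bundling (MLB) of correlation networks in R.

High-dimensional biological data — gene expression, metabolite panels,
protein abundances — usually hide an underlying interaction network, and
the standard way in is clustering of a similarity matrix. Spectral
clustering is powerful here but forces a choice of the cluster number
`k`, and different defensible choices ("clustering regimes") split the
data in different, sometimes orthogonal, ways. `mlbundle` implements
multi-layer bundling, which sidesteps that choice: instead of picking one
regime it intersects the most prominent ones.

Given a sample-by-feature matrix **S** (m × n), the method:

1. builds the affinity matrix **A** = |**R**| from the Pearson
   correlations **R** between features, and the symmetric normalized
   graph Laplacian **Q̂** = **D**⁻¹ᐟ² (**D** − **A**) **D**⁻¹ᐟ², with
   D\_ii = Σ\_{j≠i} A\_ij;
2. ranks the eigengaps δᵢ = λᵢ₊₁ − λᵢ of the ascending spectrum of
   **Q̂**; the i-th most prominent clustering regime Cᵢ has κᵢ clusters,
   where κᵢ is the index of the i-th largest gap, and labels are
   assigned with the cluster-qr algorithm on the spectral embedding;
3. forms **bundles**: a layer-ℓ bundle β is a maximal set of features
   that co-cluster in every one of regimes C₁…C\_ℓ (a nonempty
   intersection of one cluster per regime). Layers refine — once two
   features split, they never rejoin;
4. scores each cluster or bundle x as a **bridge set** with the bridge
   factor γₓ = Π\_{y∈Nₓ} |y|/|x| (0 when x has ≤ 1 neighbor): small
   sets joining two or more much larger neighbors get large γ;
5. reconstructs a **network of bundles** at layer k from the bundle
   affinity matrix **H** (mean cross-bundle affinity), the bundle
   co-cluster matrix **L** (how strongly two bundles share clusters over
   regimes 1..r), and their normalized sum **LH**, using a row-maximum
   edge rule plus a component-merging completion; reconstructions are
   scored against the ground-truth bundle network with the Jaccard index
   |E\_r ∩ E\_t| / |E\_r ∪ E\_t|.

The package also ships the synthetic benchmark generator the method is
validated on: a branched structural network (branching parameter φ, ten
random extra cycle edges) with signed edges (half "+", half "−"), and
feature values propagated over the network with Gaussian noise
(μᵢ = Σ\_{j∈N\*ᵢ} εⱼ cⱼ / |N\*ᵢ|), so every stage can be checked against
known structure.

## Worked example

```r
library(mlbundle)
library(dplyr)

# synthetic ground truth: 500 features, 400 samples, hub-rich network
d <- simulate_mlb_data(synth_config(phi = 0.8, n = 500, m = 400,
                                    sigma = 0.2, seed = 1))
d$network
#> <structural_network> 500 nodes, 509 edges (254 positive / 255 negative)

fit <- mlb(d$features, k = 5, r = 12)
fit
#> <mlb_fit> 500 features, 400 samples; k=5, r=12
#>   regime cluster counts: 1, 2, 3, 5, 6, 7, 4, 8, 10, 14, 9, 494
#>   bundles per layer: 1, 2, 5, 8, 11
```

The regime cluster counts are the eigengap ranking: the most prominent
regime is the whole dataset (κ₁ = 1), then 2, 3, 5, … clusters.
Intersecting the top regimes gives 5, 8 and 11 bundles at layers 3–5 —
the global-to-local progression.

```r
bridge_factors_by_layer(fit, d$network) |>
  arrange(desc(gamma)) |>
  head(3)
#>   layer group_id  size n_neighbors gamma log10_gamma
#> 1     5        9     4           3 7765.        3.89
#> 2     3        4     2           2 4292         3.63
#> 3     4        7     2           2 2886         3.46
```

The strongest bridge set is a 4-feature layer-5 bundle whose three
neighbors are hundreds of times larger (γ ≈ 7.8 × 10³): a small
transitional group coupling large modules.

```r
evaluate_reconstructions(fit, net = d$network)$report
#>   method n_edges    tp    fn    fp jaccard
#> 1 H           10     5    15     5     0.2
#> 2 L           10    10    10     0     0.5
#> 3 LH          10    10    10     0     0.5
```

On this realization the co-cluster information (L) recovers half of the
true bundle-network edges with no false positives, and the combined LH
network keeps that performance; averaged over replicates LH beats both
inputs (see the methods vignette).

A command-line front-end with subcommands `simulate`, `bundle`,
`bridges`, `network`, `evaluate` and `all` is installed at
`inst/cli/mlb.R`; every output is a `#`-headed TSV.

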