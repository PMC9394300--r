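# vizclust

Visual clustering of bulk tumour transcriptomes — t-SNE maps and an
adapted UMAP — depends as much on how the expression values were
transformed as on the biology in them. vizclust is an R package for
anyone who reads 2-D embeddings of FPKM matrices (computational
oncologists, RNA-seq analysts, methods reviewers) and wants that
dependence made explicit, quantified, and reproducible instead of judged
by eye.

## What it computes

Given a nonnegative genes × samples FPKM matrix **X** and per-sample
annotations (resection site, sample type, optional known subgroup), the
package runs the full comparison grid

* three transformations: unprocessed X; log₁₀ X with exact zeros kept at 0
  (sub-1 values keep their negative logs); log₁₀(X + 1);
* two reduction methods:
  * **t-SNE** with PCA preprocessing to 50 components, perplexity 27,
    learning rate 300;
  * an **adapted UMAP** implemented from scratch: squared pairwise
    Euclidean distances; per-sample offset ρᵢ (nearest-neighbour
    distance) and bandwidth σᵢ solved by binary search so that
    Σⱼ exp(−max(0, Dᵢⱼ − ρᵢ)/σᵢ) = log₂(15) over the 15 nearest
    neighbours; directed affinities over a 50-neighbour edge set (25 for
    cohorts under 50 samples); half-sum symmetrisation
    Pᵢⱼ = (p_{j|i} + p_{i|j})/2; a fitted low-dimensional kernel
    w(d) = 1/(1 + a·d^{2b}) with min_dist = 0.25; and full-batch gradient
    descent on the cross-entropy C = −Σ P̂ᵢⱼ log(Qᵢⱼ + ε) with Q the
    kernel weights normalised to a distribution;

then clusters every map (k-means k ∈ {2, 3, 4} plus an elbow-selected k;
Leiden on the unweighted 15/50/100-NN graph at resolution 0.05 and 1),
scores cluster–label association (adjusted Rand index, χ², Cramér's V),
and compares every pair of maps with a scale-dependent k-NN overlap
matrix whose entry (k_a, k_b) is the mean |NN_A(i,k_a) ∩ NN_B(i,k_b)| /
min(k_a, k_b). Every figure carries a UTMC legend
(`U: <unit> | T: <transformation> | M: <method> | C: <clustering>`) so it
stays self-describing.

A synthetic FPKM generator (log-normal baseline, disjoint marker panels
with 2^effect fold changes, independent exact zeros, site labels drawn
independently of expression, optional primary↔metastatic mixing gradient)
provides ground truth for all of it offline.

## Worked example

```r
library(vizclust)
library(dplyr)

co <- generate_fpkm(synthetic_spec(n_genes = 300, n_samples = 70,
                                   n_marker_genes_per_subgroup = 50, seed = 3))
co
#> <vc_cohort> 300 genes x 70 samples; 30.2% zeros

g <- run_grid(co, config = grid_config(seed = 5,
       tsne = tsne_params(perplexity = 15, n_iter = 200),
       umap = umap_params(n_iter = 60)))

g$associations |>
  group_by(method, transform) |>
  summarise(best_subgroup_ari = max(ari_subgroup, na.rm = TRUE),
            median_site_ari = median(ari_site), .groups = "drop")
#>   method   transform best_subgroup_ari median_site_ari
#> 1   tsne       log10            0.9151       -0.005342
#> 2   tsne     log10p1            0.7203        0.000483
#> 3   tsne unprocessed            0.5765       -0.007424
#> 4   umap       log10            0.9151       -0.007057
#> 5   umap     log10p1            0.7203        0.003195
#> 6   umap unprocessed            0.0764       -0.020746
```

Two facts are visible at once. The planted subgroups are recovered well
or badly depending on the *transformation* (unprocessed FPKM under the
adapted UMAP carries almost no subgroup signal, ARI 0.08), and the
resection-site label — drawn independently of expression — never aligns
with any clustering (median ARI ≈ 0 in every cell).

The map-similarity stage shows the same thing geometrically: maps of
differently transformed data agree globally but not locally.

```r
g$similarity_summary |> filter(method == "umap")
#>   method transform_a transform_b mean_overlap mean_local mean_global
#> 1   umap unprocessed       log10         0.51       0.16        0.75
#> 2   umap unprocessed     log10p1         0.44       0.11        0.74
#> 3   umap       log10     log10p1         0.71       0.31        0.82

emb <- g$embeddings$umap__log10p1
cl  <- leiden_cluster(knn_graph(emb, 15), resolution = 1, seed = 4)
format_utmc(utmc_from_embedding(emb, cl))
#> [1] "U: FPKM | T: log10 + 1 | M: UMAP | C: Leiden(res=1)"
autoplot(emb, colour_by = cl)   # scatter with the UTMC caption
```

With an output directory, `run_grid(co, config = ..., out_dir = "out")`
writes one folder per grid cell (embedding TSV + provenance JSON +
cluster table), a `similarity/` folder, UTMC-annotated figures, and a
deterministic `summary.json` that is byte-identical across re-runs with
the same seed.

A thin command-line front end in `inst/cli/vizclust.R` exposes the same
three entry points (`synth`, `run`, `compare`) for shell pipelines.

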