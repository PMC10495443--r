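# graphTumorNet

Graph-convolutional input processing and comparable CNN variants for
four-class brain-MRI tumor classification (glioma, meningioma,
pituitary tumor, no tumor), for researchers who want to study how
injecting pixel-lattice relational structure into a CNN's input affects
classification, and to do so reproducibly without access to clinical
data.

## The method

A standard CNN treats an image as a dense matrix and ignores explicit
pixel-to-pixel relations.  This package prepends a graph stage to the
classifier:

1. **Preprocess** each image: Gaussian denoising (discrete kernel
   proportional to `exp(-(x^2+y^2)/(2σ^2))`, renormalised to sum 1),
   luminance grayscale, per-image min-max normalisation to [0, 1],
   bilinear resize to 30 × 30.
2. **Superpose an adjacency kernel**: a fixed n × n weight matrix `K`
   with entries in [0, 1] (i.i.d. Gaussian, uniform or log-normal
   draws, min-max rescaled; or a radial Gaussian) is overlaid
   element-wise, `H⁰ = X ⊙ K`, turning the image into a weighted graph
   of node features on the pixel lattice.
3. **Graph convolution**: `k` synchronous rounds of neighbor averaging
   over the 4- or 8-connected lattice,
   `Hᵤ⁽ᵏ⁺¹⁾ = mean{ Hᵥ⁽ᵏ⁾ : v ∈ N(u) }`, an aggregation that is
   independent of any traversal order.
4. **Classify** with one of five comparable networks: `Net-0`
   (15-layer baseline CNN, raw input), `Net-1` (15 layers, graph
   input, Gaussian kernel), `Net-2`/`Net-3`/`Net-4` (26 layers with
   batch normalisation and two dropout layers; graph input with
   Gaussian / uniform / log-normal kernels).
5. **Evaluate** with the a1.1–a4 metric suite: per-class one-vs-rest
   precision (`a1.x`) and recall (`a2.x`), testing accuracy `a3`
   (confusion-matrix trace / total) and average testing accuracy `a4`
   (macro-averaged recall), plus a cross-network comparison table.

A seeded synthetic **phantom generator** produces four visually
separable classes of brain-like images (elliptical background with
class-specific lesion geometry plus Gaussian noise) so the entire
pipeline can be trained and tested at desk scale.  The CNN engine
(im2col convolutions, batchnorm, max pooling, dropout, Adam) is
implemented in RcppArmadillo, is single-threaded and fully seeded, and
its backpropagation is verified against finite differences in the test
suite; seeded runs are bit-for-bit reproducible.

## Worked example

```r
library(graphTumorNet)

## a seeded two-variant experiment on deliberately noisy phantoms
cfg <- defaultExperimentConfig(variants = c("Net-0", "Net-2"),
                               nPerClass = 100L, epochs = 10L, seed = 42L)
cfg$data$phantom$noiseSigma <- 0.2      # a harder, noisier phantom set
cfg$data$phantom$lesionContrast <- 0.3
res <- runExperiment(cfg, outputDir = "results/demo")
print(res$comparison)
```

```
 metric Net-0 Net-2
   a1.1  1.00  1.00
   a1.2  0.92  1.00
   a1.3  0.73  0.90
   a1.4  0.95  0.76
   a2.1  0.92  0.96
   a2.2  0.96  0.88
   a2.3  0.88  0.76
   a2.4  0.80  1.00
     a3  0.89  0.90
     a4  0.89  0.90
```

The rows are the metric suite (per-class precision a1.1–a1.4 and
recall a2.1–a2.4 for glioma/meningioma/no-tumor/pituitary, testing
accuracy a3, average testing accuracy a4) on the held-out phantom
testing split (100 images); the columns are the requested network
variants.  At this noise level (additive sd 0.2 against lesion
contrast 0.3) both networks are imperfect: the graph-input 26-layer
network edges out the raw-input baseline on overall accuracy (0.90 vs
0.89) with a different error profile — it recovers every pituitary
phantom (a2.4 = 1.00) but confuses more no-tumor images (a2.3 =
0.76).  At the package's default benchmark noise (sd 0.05) both
variants classify the split perfectly.  The results directory
additionally contains per-variant
metrics (JSON/CSV), confusion matrices, training histories, the
exported adjacency kernels, manifests, a log and a copy of the
resolved configuration; re-running with the same configuration and
seed reproduces the metric CSVs byte for byte.

Individual stages are exported too:

```r
k <- makeAdjacencyKernel("gaussian", "iid", n = 30L, seed = 1L)
g <- superposeKernel(matrix(runif(900), 30L), k)     # H0 = X (*) K
g <- graphConvolve(g, pixelLattice(30L, 4L), hops = 1L)
hopsApplied(g)
#> [1] 1
```

A thin command-line wrapper with `phantoms` / `kernel` / `compare`
subcommands lives at `inst/scripts/graphTumorNet-cli.R`.

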