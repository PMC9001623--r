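# nucpot

Effective inter-nucleosomal pair potentials from nucleosome positioning
data.

Nucleosome positioning tracks (binary occupancy per basepair, as produced
from MNase-seq by callers such as iNPS) contain more than the positions of
individual nucleosomes: the *statistics* of the spacings encode how tightly
and how regularly nucleosomes pack, section by section along a chromosome.
`nucpot` turns those statistics into physics. For each 50 kb section (with
12.5 kb overlaps on both sides) it:

1. computes the 1D radial distribution function G(r) of nucleosome centers;
2. fits a generalized Lennard-Jones pair potential
   V(r) = 4ε[(σ/r)^δ − (σ/r)^ν]
   by reverse Monte Carlo — an inner Metropolis simulation of hard-core
   particles under each candidate potential, and an outer *intuitive
   selection strategy* (a tournament over a candidate pool evaluated at
   geometrically increasing Monte Carlo precision, robust to noisy scores);
3. estimates the reduced isothermal compressibility χ_T^∞ by the block
   density distribution method with 1/L finite-size extrapolation;
4. classifies all sections by k-means on (δ, ν, χ_T^∞) into chromatin-like
   states (heterochromatin-like, euchromatin-like, and beyond), with a PCA +
   silhouette diagnostic for the cluster count.

Everything is testable without external data: synthetic generators produce
Poisson (ideal gas), Tonks (hard rod), and known-potential tracks with
ground truth, including a multi-chromosome genome fixture.

The inner Monte Carlo loop is compiled (Rcpp); a full two-chromosome
test-scale pipeline runs in about two minutes on one core.

## Worked example

```r
library(nucpot)

# a synthetic two-chromosome genome built from three interaction families
fx  <- make_genome_fixture("genome_fx", seed = 20)
cfg <- test_scale_config(seed = 20)
res <- pipeline_run(fx$tracks, cfg, out_dir = "genome_out", verbose = FALSE)

head(res[, c("chrom", "section", "epsilon", "sigma", "delta_exp",
             "nu_exp", "chi_inf", "class_label")])
#>   chrom section  epsilon    sigma delta_exp    nu_exp    chi_inf class_label
#> 1 chrS1       0 2.354330 155.5359 17.693271 11.908464 0.03508060           1
#> 2 chrS1       1 2.354330 155.5359 17.693271 11.908464 0.03217305           1
#> 3 chrS1       2 2.354330 155.5359 17.693271 11.908464 0.04820926           1
#> 4 chrS1       3 3.382940 165.0095  3.471209  2.249338 0.03337689           0
#> 5 chrS1       4 3.382940 165.0095  3.471209  2.249338 0.03028632           0
#> 6 chrS1       5 0.830528 164.0283  9.096062  4.296435 0.09373052           0

rand_index(res$class_label, as.integer(factor(fx$truth$family)))
#> [1] 0.9281046
```

Reading the output: sections 0–2 of `chrS1` were generated from the dense
deep-well family — the fit recovers a steep-repulsion/short-attraction
potential with its minimum near 168 bp and a very low compressibility
(χ_T^∞ ≈ 0.03, a rigid regular array). Sections 3–5 come from the
wide-spacing family: the fitted exponents move to the soft 4–2-like corner
because the well minimum sits near 226 bp. Class labels are canonical
(0 = least compressible cluster), and the Rand index against the generating
families is 0.93. The sparse hard-rod sections (not shown) fit shallow
potentials with χ_T^∞ ≈ 0.6, close to the exact Tonks value (1 − η)².

Individual stages are plain functions — `compute_rdf()`,
`mean_field_potential()`, `run_mc()`, `tune_lambda()`, `iss_fit()`,
`section_chi()`, `kmeans_classify()` — see the package vignette for the
model, the parameter defaults, and the numerical choices. A thin
command-line wrapper with `simulate` / `fit` / `chi` / `classify` /
`run-all` subcommands ships in `inst/scripts/nucpot.R`.

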