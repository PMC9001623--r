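---
title: "Extracting inter-nucleosomal pair potentials from positioning data"
author: "nucpot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting inter-nucleosomal pair potentials from positioning data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucpot)
```

# The model

Nucleosome positioning experiments (MNase-seq processed by a peak caller)
yield, per chromosome, a binary occupancy track: 1 where a basepair is
covered by a nucleosome, 0 in voids. `nucpot` treats the nucleosome centers
of a genomic section as a one-dimensional fluid of identical particles and
asks which effective pair potential would reproduce their spatial
statistics. The observable is the 1D radial distribution function (RDF)

$$G(r) = \frac{1}{\rho N S_1} \sum_{i=1}^N \sum_{j \ne i} \delta(r - r_{ij}),$$

with $N$ nucleosomes at density $\rho = N/L$ on a section of length $L$, and
$S_1$ the 1D shell normalization. A first, assumption-free estimate of the
interaction is the potential of mean force $-\log G(r)$ (in units of
$k_BT$); its shape on real and synthetic data motivates a generalized
Lennard-Jones ansatz

$$V(r) = 4\epsilon\left[\left(\frac{\sigma}{r}\right)^{\delta} -
\left(\frac{\sigma}{r}\right)^{\nu}\right],$$

where $\epsilon$ sets the well amplitude, $\sigma$ the length scale (the
zero crossing, in bp), and the exponents $\delta > \nu > 0$ the steepness of
the short-range repulsion and the range of the attraction. The potential is
cut and shifted to zero at `r_cut` so Monte Carlo energies are continuous.

The fit is a reverse Monte Carlo: an inner Metropolis simulation of $N$
hard-core particles under a candidate $V(r)$ produces a simulated RDF, which
is compared to the section's target RDF by the mean squared residual

$$\mathrm{MSR} = \frac{1}{n - p}\sum_{\text{bins}} (x - \hat{x})^2,$$

with $p = 5$ (four potential parameters plus an intercept). Because each MSR
evaluation is itself noisy, the outer optimization is not a Markov chain but
an *intuitive selection strategy* (ISS): a pool of candidate potentials is
evaluated at low inner-MC precision, the best fraction $\theta$ survives,
the precision (sweep count) is raised, and the tournament repeats until one
candidate remains. Selection with noisy scores is a well-posed problem
exactly because early rounds only need to rank candidates coarsely.

From the fitted potential, each section's reduced isothermal compressibility
$\chi_T^\infty$ is estimated by the block density distribution method:
conformations from a long Monte Carlo run are divided into $M_b$ equal
blocks, $\chi_T(L, L_0) = (\langle N^2\rangle - \langle N\rangle^2) /
\langle N\rangle$ is computed from the pooled block counts, and the linear
finite-size bias (proportional to $1/L$, hence to $M_b$ at fixed section
size $L_0$) is removed by ordinary least squares extrapolation to
$M_b = 0$. Finally the sections are clustered by k-means on the
standardized features $(\delta, \nu, \chi_T^\infty)$ into chromatin-like
classes, with a PCA projection and silhouette table as the diagnostic for
choosing the cluster count.

# Parameters that matter

| parameter | default | unit | meaning |
|---|---|---|---|
| `section.core_len` | 50,000 | bp | section proper; the genome is classified at this resolution |
| `section.overlap` | 12,500 | bp | symmetric extra data on each side; blurs section boundaries |
| `rdf.bin_width` | 10 | bp | RDF resolution; resolves the 160–180 bp well while keeping bins populated |
| `rdf.r_max` | 1,000 | bp | longest separation retained |
| `iss.r_cut` | 500 | bp | potential cutoff (cut-and-shifted) |
| `iss.theta` | 0.25 | – | ISS survival ratio |
| `iss.pool_size` | 64 | – | candidate potentials; 64 → 16 → 4 → 1 under θ = 0.25 |
| `iss.step_ladder` | 10³…10⁶ | sweeps | inner-MC precision per round |
| `chi.M_b_list` | 4…64 | – | block numbers for the compressibility extrapolation |
| `mc.boundary` | periodic | – | minimum-image distances; a `walls` mode exists for sensitivity checks |

Candidate domains are $\epsilon \in [0.1, 5]\,k_BT$, $\sigma \in [140,
170]$ bp, $\nu \in [1, 12]$, $\delta \in (\nu, 24]$; $\delta$ is sampled
above the candidate's $\nu$, so the repulsion/attraction ordering holds by
construction. $k_BT = 1$ throughout. The hard-core diameter equals the
section's mean nucleosome length, and the maximum displacement $\lambda$ is
chosen, by short pilot runs over a geometric ladder, as the smallest value
whose acceptance is at or below 50%. The ladder spans $2^0$–$2^{10}$ bp: at
the hard-rod densities typical of sections (mean gaps of ~200 bp), the 50%
point sits near 400–600 bp, so a ladder capped at a few hundred bp could
never reach it.

# Numerical choices

**RDF normalization.** The 1D shell measure of a bin is $2\Delta r$ (a
neighbor can sit on either side). On the open data span of a section, each
bin is additionally weighted by the fraction $(L - r)/L$ of pair placements
that can geometrically realize separation $r$; in the periodic simulation
box, minimum-image distances are used and no edge factor is needed. Both
conventions make an ideal gas read $G \approx 1$ in every bin, which is
verified by simulation in the test suite.

**Fitting window.** MSR compares bins with $r$ between the hard-core
diameter and `r_cut`: below the core both curves are identically zero and
would dilute the residual.

**Floor for the mean-field potential.** $-\log G$ diverges where $G = 0$;
$G$ is floored at one pseudo-count relative to the number of pair slots,
$\Delta r / (N\, r_\mathrm{max})$.

**Ensemble correction for block counts.** The section simulation holds $N$
fixed. Sampling a fraction $1/M_b$ of a closed system suppresses the count
variance by the factor $1 - 1/M_b$ (exactly binomial for an ideal gas), so
`section_chi()` divides each raw block estimate by this factor before
extrapolating; the thermodynamic limit is defined for unconstrained
fluctuations. Without this correction, the extrapolation of an ideal gas
with $M_b \in \{4,\dots,32\}$ would read ~0.78 instead of 1. The raw Eq.-5
arithmetic is preserved in `chi_block()`.

**Common random numbers.** Within an ISS round, all candidates share one
inner-MC seed, so the comparison between candidates is paired rather than
doubly noisy. The pipeline goes one step further and evaluates *every
section* against one shared candidate pool with shared per-round streams:
differences between fitted sections then reflect their data rather than
Monte Carlo luck. This matters for classification, where fitted parameters
of different sections are compared: the exponent pair $(\delta, \nu)$ is
only weakly identified by a single noisy section RDF (many well shapes fit
within noise — visible as criss-crossing potential curves in the well
region), and paired evaluation removes the part of the scatter that is
purely computational.

**Ties and determinism.** Candidates with equal MSR resolve toward the
lower index; k-means labels are renumbered by ascending cluster-mean
$\chi_T^\infty$ (label 0 = least compressible, most
heterochromatin-like), making labels reproducible across runs and restart
orders. All stochastic stages draw seeds from one master seed through a
counter scheme (`derive_seed`).

**Degenerate inputs.** All-zero tracks yield an empty nucleosome set with
undefined mean length (flagged). Sections with fewer than 20 nucleosomes
are flagged unfit instead of raising, so genome runs complete. Negative
extrapolated compressibilities are clipped to zero with a warning. A
chromosome shorter than one core becomes a single clipped section, and the
trailing remainder of a chromosome is merged into the last section's data
span — with 50 kb cores this is what makes a 2,231,883 bp chromosome come
out as exactly 44 sections rather than 44 full sections plus a 31,883 bp
stub.

# What the synthetic generators emulate

Three generators cover the statistical regimes the method must handle:

* `poisson` — centers placed uniformly at random (ideal gas). Oracle:
  $G \equiv 1$, $\chi_T^\infty = 1$.
* `tonks` — hard rods of the nucleosome length, sampled exactly (uniform
  points in the free volume plus cumulative rod offsets). Oracle: $G = 0$
  below the rod length and $\chi_T^\infty = (1 - \eta)^2$ at packing
  fraction $\eta$ — the exact 1D hard-rod result.
* `glj` — an equilibrium Monte Carlo sample under a known potential, for
  parameter-recovery experiments.

Tracks are painted as runs of 1s (overlapping nucleosomes merge, as a
binary track cannot represent overlap), and `corrupt_track()` mimics the
missing-data noise of MNase-derived tracks by independent nucleosome
dropout and Gaussian center jitter.

The genome fixture (`make_genome_fixture()`) builds chromosomes from an
initial pad of one overlap length plus consecutive 50 kb blocks, so the
pipeline's section cores coincide with the generated blocks; families are
assigned in runs of three consecutive sections. The three default families
are chosen so that each leaves a distinct signature in the *measurable*
features: a dense 12–6 family with a deep well at the canonical ~168 bp
spacing; a dense 4–2 family preferring ~226 bp spacing, which forces the
fitted exponents into a different region because the well position is the
best-identified feature of the fit; and a sparse hard-rod family whose
compressibility (~0.6 versus ~0.03 for the dense families) is a strong
outlier. What passing the end-to-end test shows is that the pipeline
separates sections whose underlying interactions differ in well position,
depth and density; it does not show that the exponent pair of an arbitrary
potential is individually recoverable from one section of real, noisy data
— on the contrary, the exponents are strongly degenerate at that noise
level, which is why the compressibility enters the classification at all.

# Problem sizes

The package defaults target genome-scale runs (inner-MC ladders up to
$10^6$ sweeps, as appropriate for production fits). The test suite and the
worked examples use `test_scale_config()`: pool 48, ladder
300/1,000/3,000/8,000 sweeps, $2 \times 10^4$-sweep compressibility runs,
and an 18-section two-chromosome fixture. At these sizes a full pipeline
run takes about two minutes on one core; parameter-recovery experiments
(ten independent fits against a known-potential target) take a similar
time. These sizes were chosen as the smallest at which the physics oracles
(ideal gas, Tonks gas, Boltzmann pair statistics) hold with comfortable
margins.

# Known limitations

* The model is continuous along the section axis: basepair-level sequence
  preferences, remodeler footprints, and methylation effects are outside
  its scope.
* $(\delta, \nu)$ are reported per section but should be interpreted as a
  family label, not as precisely measured exponents (see above).
* The compressibility extrapolation assumes the $1/L$ form; at very small
  blocks ($\langle N \rangle \lesssim 5$) higher-order terms bend the
  curve, which is why `M_b` stops at 64.
* Upstream peak calling is not included; inputs are occupancy tracks or
  BED-like nucleosome intervals.
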