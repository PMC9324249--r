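---
title: "Methods: simulated glioma cohorts and graph-theoretical connectivity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated glioma cohorts and graph-theoretical connectivity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`gliomaconn` implements a resting-state functional-connectivity analysis
for three-group glioma studies — low-grade glioma (LGG), high-grade
glioma (HGG) and healthy controls (HC) — starting from region-of-interest
(ROI) timeseries.  Everything upstream of the ROI level (image
reconstruction, realignment, normalisation, smoothing, atlas fitting) is
out of scope: the package's inputs are per-subject T × N matrices of ROI
signals plus a parcellation table assigning each ROI a hemisphere and a
lobe.  Because clinical rs-fMRI cohorts of this kind are not openly
deposited, the package pairs the analysis with a synthetic-cohort
generator whose covariance structure plants group effects of the kind
reported for glioma populations, so that every stage of the pipeline can
be exercised and verified end to end without patient data.

# The analysis model

## From timeseries to graphs

Each subject's ROI signals are denoised at the ROI level in the standard
order: removal of the mean and linear trend, optional regression of
nuisance timecourses (e.g. CSF and white-matter signals), and band-pass
filtering to the resting-state band 0.01–0.1 Hz.  The band-pass is a
hard frequency-domain mask on the discrete Fourier grid: components with
frequency inside the band are kept, everything else (including DC) is
zeroed.  A masking filter was chosen over an IIR family because it is
deterministic, exactly idempotent, and has no transient or order
parameter to tune; its sharp cutoff is documented behaviour rather than
an approximation.

Connectivity is the Fisher-transformed Pearson correlation
`z = atanh(r)` between every ROI pair.  Correlations are clipped to
±(1 − 10⁻⁷) before the transform so that degenerate inputs (duplicated
or anti-correlated columns) stay finite.  The diagonal is stored as zero
and excluded from every downstream computation.  Zero-variance columns
yield an all-zero row/column and a warning rather than an error, so a
flat-lined ROI cannot abort a cohort run.

A subject's binary graph contains the edge (i, j) when the standardized
Fisher statistic

```
z_stat = atanh(r_ij) * sqrt(T_eff - 3)
```

exceeds 2 **and** its one-sided normal p-value is below 0.05.  Reading
the threshold on the standardized scale makes the rule sample-size aware
and makes the paired p-condition meaningful; reading it on the raw
Fisher-z scale instead would demand `r > 0.964` and produce near-empty
graphs at any realistic scan length.  At `T_eff ≥ 8` the p-condition is
implied by the z-condition (the one-sided p at `z_stat = 2` is 0.0228),
a consistency that is asserted in the test suite.  Negative correlations
never create edges by default; a two-sided variant
(`threshold_spec(positive_only = FALSE)`) is available for sensitivity
analyses.

## The seven nodal metrics

For each node of the undirected graph the package computes degree, cost
(`degree / (n − 1)`, asserted exactly on every construction), global
efficiency (mean inverse geodesic distance, unreachable pairs
contributing zero), local efficiency (mean pairwise inverse distance in
the subgraph induced by the node's neighbours), betweenness centrality
(Brandes' algorithm, normalized by `(n − 1)(n − 2)/2` so it is a ratio
in [0, 1]), average path length, and the clustering coefficient.  The
implementation is compiled (BFS over 64-bit adjacency bitsets) because
a cohort analysis evaluates tens of thousands of dense graphs; its
correctness is pinned to independent brute-force oracles
(Floyd–Warshall distances, exhaustive shortest-path enumeration for
betweenness) and to `igraph` in the test suite.

Degenerate cases follow explicit conventions so that group means are
always defined: isolated nodes have path length 0, and nodes of degree
< 2 have clustering 0 and local efficiency 0.  Average path length is
taken over *reachable* nodes only — on a disconnected graph "the
shortest distance to all other nodes" is otherwise undefined, and the
harmonic treatment of unreachability already lives in global
efficiency.  These conventions matter when comparing sparse graphs and
are therefore stated here rather than hidden.

## Group designs

Three designs are run over a cohort:

* **Whole-brain and hemispheric analysis.**  Per subject, nodal metrics
  are averaged over the whole brain, the left hemisphere and the right
  hemisphere; hemispheric metrics are computed on the hemispheric
  *subgraph* (equivalently, on the graph rebuilt from the hemispheric
  block of the connectivity matrix — thresholding is elementwise, so the
  two constructions coincide and the equality is tested).  Group pairs
  (LGG–HC, HGG–HC, LGG–HGG) are compared per metric; additionally the
  left and right hemispheric means are contrasted *within* each group.
  The within-group contrast is paired per subject, since both
  hemispheres come from the same scan; an unpaired variant is available
  by flag.
* **Lobar analysis.**  For each lobe hosting tumors, patient groups are
  restricted to subjects with that tumor location and every node of the
  lobe (both hemispheres) is compared per metric; HC always enter in
  full.  Lobes with no patients are never compared — a cohort without
  occipital tumors emits zero occipital rows.
* **Connectograms.**  For a seed ROI and one group, each target ROI's
  Fisher z is tested against zero with a two-sided one-sample t-test —
  the standard second-level model for seed-based connectivity — and the
  N − 1 target p-values are FDR-adjusted.  Counts of significant
  connections can then be compared across groups with a two-tailed
  Student t-test.

## Test choice and multiplicity

Every two-group comparison is gated by the Jarque–Bera normality test,
`JB = n/6 (S² + (K − 3)²/4)` with biased moment estimators and a χ²(2)
upper tail: when both samples pass at `alpha_normality` (default 0.05 —
the gate level is a convention, stated here because it is not a
universal standard) the branch is a two-tailed pooled-variance Student
t-test, otherwise a two-tailed Mann–Whitney U-test.  Pooled variance
(not Welch) is the default because the classical Student test is the
reference procedure for this design; Welch is available by flag.
Samples smaller than 8 cannot support a moment-based normality test and
are routed to the Mann–Whitney branch.  The U-test uses the exact null
distribution when `n_a · n_b ≤ 400` and the samples are tie-free, and
the tie-corrected normal approximation otherwise.  If the pooled data
are completely degenerate (all values identical) the comparison reports
p = 1 by convention and logs it.

False-discovery control is Benjamini–Hochberg throughout.  Families are
chosen to mirror how the result tables are read: within the hemispheric
analysis, the seven metrics of one (scope, pairing) cell form a family;
within the lobar analysis, the nodes of one (lobe, metric, pairing)
triple form a family.  The family choice is a genuine design decision —
nodal tables could equally be corrected across metrics — and is recorded
in the output so readers can re-correct differently if they prefer.
Note that adjusted p-values are *decision* devices: re-running the BH
step-up on already-adjusted values does not reproduce them (adjusted
values are not a fixed point of the procedure); what is invariant, and
what the tests assert, is that thresholding adjusted values at α
reproduces the BH decision taken on the raw p-values.

## Confound screen

Because patient age and tumor size could drive apparent group
differences, every whole-brain network-mean metric is screened against
both covariates: Pearson correlation, covariance of the standardized
variables and the simple-regression slope are reported, with a flag when
|correlation| exceeds a configurable bound (default 0.4).  In the
default synthetic cohort, age *is* associated with group (LGG younger
than HGG, as in real populations), so a non-zero age–metric correlation
through group structure is expected and visible in the screen — the
screen reports it rather than hiding it.

# The synthetic cohort generator

## Covariance model

The generator is the package's study-design object, not a test fixture.
A cohort is defined by group sizes (default 20 HC / 30 LGG / 30 HGG —
the reference design), scan length (default 160 volumes at TR 2.5 s,
i.e. a ~6.7 min resting-state run) and a block-structured ROI-to-ROI
correlation matrix over a parcellation of 136 ROIs split evenly between
hemispheres.  Four baseline coupling classes are distinguished:

| coupling class              | default r | rationale                                  |
|-----------------------------|-----------|--------------------------------------------|
| same lobe, same hemisphere  | 0.45      | strong local (lobar) coupling              |
| same hemisphere, inter-lobe | 0.06      | weak long-range intra-hemispheric coupling |
| homotopic (mirror) pair     | 0.30      | well-known strong interhemispheric mirror connectivity |
| other cross-hemisphere      | 0.02      | sparse background                          |

With the default threshold, these values give modular baseline graphs:
lobar blocks are almost always supra-threshold, long-range edges are
mostly sub-threshold, and the graph stays connected through homotopic
and chance edges.  The baseline is deliberately *modular* because the
contrast between local clustering and global integration is exactly the
axis on which the planted group effects move.

Group effects are signed increments on this structure: LGG adds
`delta_left_global = +0.08` to left intra-hemispheric inter-lobe
couplings and `delta_local = −0.33` to left within-lobe couplings —
a redistribution of coupling weight from local to long-range
connections, the "shift from locality to integration" phenotype, which
raises left global efficiency while *lowering* left clustering and
local efficiency; HGG adds `delta_right = −0.10` to all right
intra-hemispheric couplings — a remote attenuation (diaschisis-like)
phenotype that lowers right degree and cost.  Effect sizes are not
reported in the clinical literature at the level of raw correlations;
these defaults were calibrated once so that the standard group designs
recover the corresponding signatures with high probability at the
reference sample sizes, and are not claimed to be clinically realistic
magnitudes.  An `effect_spec` can also carry a `tumor_location`, which
restricts the deltas to couplings involving that lobe — the focal
variant used to exercise the lobar design.

All modified correlations must stay inside (−0.95, 0.95).  If the
assembled matrix is not positive definite it is repaired by clipping
eigenvalues at 10⁻⁸ and rescaling to unit diagonal; the repair is
deterministic, logged, and flagged on the returned matrix.  The default
configurations are positive definite without repair (tested).

## Temporal model

Subject timeseries follow a stationary Gaussian AR(1) process with
cross-sectionally correlated innovations:

```
x_1 = L' e_1,    x_t = phi * x_{t-1} + sqrt(1 - phi^2) * L' e_t
```

with `L` the Cholesky factor of the target covariance and `phi = 0.3`.
The innovation scaling preserves the spatial covariance exactly in
expectation at every timepoint, so the planted correlation structure is
what the sample correlations converge to (verified at T = 5000 within
0.02); the AR(1) coefficient gives the series fMRI-like temporal
smoothness inside the analysis band.  This is the simplest temporal
model compatible with the analysis; it deliberately omits hemodynamic
response shape, physiological noise, motion artifacts and
non-stationarity.

Ages are Gaussian (means 48/40/62 years for HC/LGG/HGG, sd 10),
mirroring the age asymmetry of real glioma populations; tumor sizes
(product of perpendicular diameters) are Gaussian (mean 12 cm², sd 6)
truncated above 0.5 cm² and drawn for patients only.  These covariates
exist to exercise the confound screen, nothing more.  Tumor locations
are apportioned deterministically within each patient group in
proportion to the lobar mix typical of left-hemispheric glioma series
(frontal/temporal/parietal/insular; no occipital involvement), by
largest-remainder rounding.

## Reproducibility

A cohort is a pure function of (parcellation, cohort spec, effects,
master seed).  Each subject's seed is derived as
`master_seed + hash(subject_id) mod 2³¹−1` with a stable string hash, so
any subject can be regenerated in isolation without replaying the whole
cohort.  The end-to-end runner writes every intermediate as TSV, hashes
every output file (MD5) into a run manifest alongside the full
configuration, and is hash-identical across runs with the same seed
(tested).

# What the simulations do and do not show

The generator emulates: group-specific stationary covariance at the ROI
level, realistic scan length and band, temporal autocorrelation,
realistic group sizes and age structure, and focal (lobe-restricted)
versus hemisphere-wide effects.  It does not emulate: voxel-level noise
and preprocessing residue, subject-to-subject heterogeneity of the
*baseline* connectome (all subjects of a group share one covariance, so
between-subject variance is sampling variance only), motion and
physiological artifacts, lesion mass effects on parcellation, or
non-Gaussian BOLD features.  Consequently, recovery of the planted
signatures demonstrates that the pipeline's statistics detect the
encoded covariance differences at these sample sizes — it does not
demonstrate that real glioma cohorts carry effects of this size, and
power figures from these simulations should not be transferred to
clinical designs.

# Simulation study sizes

The packaged verification studies use: the full reference design
(136 ROIs, 20/30/30 subjects, 160 volumes) replicated 100 times for
signature recovery; 500 replicate null cohorts (40 ROIs, 10 subjects
per group, 160 volumes, all deltas zero) for calibration of the raw
significance rate; and 20 replicates of a focal-frontal design
(40 ROIs) for lobar specificity.  The null cohorts are smaller in ROI
count because calibration concerns the statistical layer, not graph
size; 40 ROIs keeps the network means effectively continuous (very
small graphs make the metrics so discrete that rank tests go
conservative, which is itself documented behaviour, not a calibration
failure of the pipeline).

# Known limitations

* The hemisphere-wide default effects are spatially uniform within
  their coupling class; real reorganization is patchy.
* The left-vs-right contrast assumes hemispherically balanced
  parcellations (equal lobe counts per side), which the default
  parcellation guarantees.
* The Mann–Whitney branch falls back to a normal approximation in the
  presence of ties; for the very small, heavily tied samples that arise
  from near-degenerate graphs this is conservative.
* Community structure (modularity) detection is intentionally absent:
  the analysis covers nodal metrics and their group statistics only.

```{r session, eval = FALSE}
# A minimal worked run (2-3 s):
library(gliomaconn)
cfg <- default_run_config(master_seed = 1L)
cfg$n_roi <- 40L; cfg$n_hc <- cfg$n_lgg <- cfg$n_hgg <- 10L
res <- run_cohort_analysis(cfg)
subset(res$hemispheric, scope == "L" & metric == "global_efficiency")
```
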