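---
title: "Methods: integrative case-control methylome and transcriptome analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative case-control methylome and transcriptome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methnet)
```

`methnet` implements a case-control analysis chain for paired DNA
methylation (Illumina 450K-style beta matrices) and RNA-seq expression
data, of the kind used in small post-mortem brain cohorts: probe-level
quality control, per-CpG differential methylation, kernel-based region
calling, detection of protein-interaction modules enriched for
differential methylation, epigenetic-clock age acceleration, expression
filtering and differential expression, cross-source network integration
with hub selection, and DMR-anchored transcription-factor regulatory
networks. This vignette describes the models, the parameters that matter,
and the design choices where a procedure was genuinely open.

## Data model

Methylation is carried as beta values $\beta \in [0,1]$ (methylated
fraction per probe and sample) and modelled on the M scale,
$M = \log_2 \beta/(1-\beta)$, which stabilises variance near the
boundaries. All probe-by-sample tables are tibbles whose first column is
the feature id; `as_value_matrix()`/`as_value_tbl()` convert to and from
the numeric matrices used internally.

## Probe quality control

`filter_probes()` removes, in a fixed order, (1) SNP-associated probes,
(2) probes whose detection p exceeds 0.05 in at least one sample,
(3) non-CpG probes and (4) sex-chromosome probes. The surviving set is
order-invariant; only the *attribution* of a probe removed by several
rules depends on the order, and each probe is counted once under the
first rule that catches it. Both the detection-p threshold and the
minimum number of failing samples are arguments. Input betas are assumed
normalised; between-array normalisation and background correction are
out of scope and must happen upstream.

## Per-CpG differential methylation

`fit_dms()` fits, per probe, OLS of $M$ on group plus covariates
(covariates are ordinary sample-sheet columns — e.g. age always, cell
composition only for regions where groups differ; nothing is hardcoded
per region). By default the residual variances are moderated by
empirical Bayes: a scaled-F model $s_g^2 \sim s_0^2 F(d, d_0)$ is fitted
to the residual variances by method of moments on the mean and variance
of $s_g^2$, and the moderated $t$ uses the posterior variance with
$d + d_0$ degrees of freedom. A non-positive moment denominator means no
excess dispersion and collapses to complete shrinkage ($d_0 = \infty$).
The moments are matched on the variances themselves rather than their
logs, so moderated statistics differ slightly from implementations that
moment-match on the log scale; `moderate = FALSE` gives the exact
textbook OLS fit, which the test suite holds to an independent `lm()`
oracle at $10^{-9}$. Effect sizes are reported both in M units and as
$\Delta\beta$ (difference of group mean betas), and `bh_adjust()` applies
Benjamini-Hochberg step-up correction.

## Region calling

`call_dmrs()` is a deliberately transparent kernel caller:

1. per chromosome, squared $t$ statistics are smoothed with a Gaussian
   kernel of bandwidth `lambda` (default 1000 bp, truncated at
   4 bandwidths);
2. a probe is flagged if its adjusted p is at most `site_fdr` (0.05) *or*
   its smoothed statistic exceeds the genome-wide $1 -$ `site_fdr`
   quantile;
3. flagged probes within `lambda` bp merge into candidate regions,
   regions need at least `min_cpgs` (2) probes;
4. the region p is Fisher's combination of member raw p-values,
   BH-adjusted across regions;
5. regions pass with `fdr < 0.05` and a region $|\Delta\beta| \ge 0.10$.

The $\Delta\beta$ gate defaults to the **maximum** member probe
$|\Delta\beta|$ rather than the region mean (both are reported,
`dmr_params(delta_filter=)` switches). The quantile flag rule always
marks the top 5% of smoothed statistics, and around a true region those
are its kernel halo — unshifted neighbours whose smoothed statistic is
inflated by proximity. The halo dilutes the region mean below any fixed
threshold as the probe density grows, whereas the maximum reads the
gate as "the region contains a $\ge 10\%$ methylation change", which is
the quantity the planted-recovery tests can verify (sensitivity
$\ge 0.9$ at $\Delta\beta = 0.2$, 5 probes, 8 vs 8 samples, with $\le
0.5$ expected false regions per null replicate). Coordinates are 1-based
half-open internally, 0-based half-open in BED output.

## Methylation modules on a PPI graph

`gene_stats()` aggregates per-probe $|t|$ to genes (mean by default, max
optionally, with an optional promoter-only filter — methylation effects
depend on the feature context, so both views are exposed).
`detect_modules()` searches a confidence-scored protein-interaction graph
for subnetworks whose members carry coordinated differential
methylation: node weight is the gene statistic (zero for genes without
probes), edge weight the mean of its endpoint weights, and the module
score the mean internal edge weight. Seeds are local maxima of the node
weight ranked by weight. Growth is greedy with a tolerance: the best
neighbour is accepted while its average incident edge weight stays
within `grow_tol` (0.2) of the peak module score. Two details are load
bearing and worth stating plainly:

* with zero tolerance the mean-edge-weight score is maximised by the
  single heaviest edge, so every module would stop at a pair; the
  tolerance is what lets a coherent high-statistic neighbourhood
  assemble, while anchoring at the *peak* score (not the current one)
  prevents the acceptance threshold from drifting down and absorbing
  background;
* nodes claimed by a previously accepted (higher-ranked) module are not
  regrown into later modules.

Significance uses label permutations of the node statistics over the
fixed graph. Because permutation preserves the heavy tail of the
statistics, a random adjacent pair of high-statistic nodes scores as
well as a full planted module on mean edge weight alone; the test
statistic is therefore the centred, size-adjusted *mass*
$(\text{score} - \bar w)\sqrt{m}$ with $m$ the internal edge count and
$\bar w$ the (permutation-invariant) mean node weight. Each observed
module's mass is compared against the permutation distribution of
maximum mass with the add-one estimator, so `emp_p` is never zero and is
exactly calibrated under exchangeability (measured false-positive rate
0.05 over 200 null runs). This greedy search stands in for spin-glass
style module optimisation; the contract it preserves — planted-module
recovery and a calibrated permutation null — is what the tests pin down.

## Epigenetic clock

`predict_age()` applies a Horvath-style clock: a linear predictor
$x = b_0 + \sum_i w_i \beta_i$ mapped through the inverse of the
calibration transform

$$F(a) = \begin{cases}\log(a+1) - \log(a_\text{adult}+1) & a \le a_\text{adult}\\
(a - a_\text{adult})/(a_\text{adult}+1) & a > a_\text{adult}\end{cases}$$

with $a_\text{adult} = 20$ by default; $F$ and $F^{-1}$ are exact
inverses and smooth at the knot. No published coefficient set is
bundled — coefficient versions drift and licences differ — so the clock
is a file format (`read_clock_csv()`: `probe_id,weight` with an
`(Intercept)` row) and the synthetic generator plants clocks for
testing. Age acceleration is reported both as the difference
(DNAm age − chronological age) and as the residual of DNAm age regressed
on chronological age; the residual fit pools all samples passed in one
call (stratify by brain region upstream if regions should be fitted
separately — the pooled-versus-per-group choice is the caller's),
and residuals are mean-zero by construction. `compare_groups_aa()` runs
Welch t-tests per measure.

## Expression filtering and differential expression

`cpm_filter()` keeps a gene when its CPM is at least 0.3 in at least
half of the samples of at least one group; the filter is idempotent and
order-invariant. `simple_de()` is an intentionally plain model —
$\log_2(\text{CPM}+0.5)$ OLS on group plus covariates with BH
adjustment — because downstream integration only consumes a DEG list;
negative-binomial Wald fits, shrinkage and surrogate-variable adjustment
are deliberately out of scope, and a user-supplied DEG table with
columns `gene`, `lfc`, `p`, `adj_p`, `direction` drops in unchanged.
The DEG export gate is raw `p < 0.01` by default (`use_adjusted`
switches), mirroring the common convention for small-cohort brain
studies.

## Cross-source network integration

`build_integrated_network()` restricts the PPI table to genes carrying at
least one source label (DEG, DMR-gene, or module gene), keeps edges with
confidence $\ge 0.7$, and retains an edge only when its endpoints can be
labelled from two *different* sources — a node may carry several labels,
and the edge qualifies if any cross-label pairing exists. The result is
the largest connected component (ties broken by the lexicographically
smallest node set, a deterministic rule). `compute_centralities()`
reports seven metrics: degree, average neighbour degree, closeness
$(n-1)/\sum d$, eigenvector (principal adjacency eigenvector,
L2-normalised), Katz ($\alpha = 0.9/\lambda_{max}$ for guaranteed
convergence, $\beta = 1$, L2-normalised), betweenness (normalised by
$2/((n-1)(n-2))$) and the local clustering coefficient. Hubs are the
union, over metrics, of nodes at or above the 95th percentile of that
metric (linear-interpolation quantile by default, nearest-rank by
option; ties at the threshold are included, so a constant metric selects
everyone). `hypergeom_enrich()` performs one-sided hypergeometric
over-representation with sets intersected against the universe, a
minimum effective set size of 5, and BH correction.

## TF regulatory networks

Regions — in the strict reading, those not attributable to genes; by
default all regions, with `intergenic_only` available — are overlapped
against TF binding-cluster intervals (`annotate_dmrs_to_tfs()`,
half-open semantics, minimum overlap 1 bp, all multi-overlaps recorded,
and an explicit error when chromosome naming conventions disagree).
`build_regulatory_network()` joins the supported TFs to their targets
restricted to the DEG list, keeping the interaction mode (activation /
repression / unknown, case-normalised) and the target's regulation
direction; supported TFs with no DEG target are listed separately rather
than dropped silently.

## Cohort statistics

`ttest_from_summary()` (pooled Student by default — for the kind of
matched-cohort age row this reproduces, Student and Welch agree to two
decimals — Welch by option), `fisher_exact_2x2()` (exact two-sided by
the point-probability rule) and `mannwhitney_exact()` (exact by full
enumeration of group assignments for combined $n \le 20$, ties handled
exactly; normal approximation with tie correction beyond) cover the
three test types of a demographics table. `cohort_table()` drives them
from a sample sheet.

## Synthetic data and what the tests do and do not show

`simulate_study()` generates every input with planted truth: a manifest
with exponential probe spacing and QC flags; betas from a two-component
Beta mixture (Beta(2,10) unmethylated / Beta(10,2) methylated, 60/40 —
plausible bimodality, exact values immaterial) with group shifts applied
on the beta scale and clipped to (0.001, 0.999), plus M-scale noise
(default SD 0.15); planted multi-probe regions; a dense planted PPI
module whose genes also carry shifted probes; a planted linear clock
whose companion rule makes DNAm age equal chronological age exactly at
zero noise; negative-binomial counts with log-normal library sizes and
planted fold changes; and TF clusters/targets overlapping the planted
regions. Defaults mirror a small matched post-mortem design: 8 cases vs
8 controls, ages 50-90.

Every generator is a pure function of its arguments including the seed.
The generator emulates the statistical structure the pipeline tests
need — bimodal betas, spatially clustered region signal, a dense module,
NB counts — but not probe-chemistry artefacts, batch effects, cell-type
composition shifts, or correlated probe noise; passing planted-recovery
tests therefore demonstrates algorithmic correctness at realistic effect
sizes, not robustness to the technical structure of raw array data.

Problem sizes used by the test suite and acceptance script (chosen as
comfortable desk-scale replicates of the statistical setting): 2000
probes and 20 replicates for region recovery, a 100-gene graph with 200
permutations and 20 replicates for module recovery, 5000 probes / 2000
genes for the null-uniformity checks, and 200 null runs at 99
permutations on 50-gene graphs for permutation-test calibration.

## Numerical choices and degenerate inputs

M-value clipping at $\varepsilon = 10^{-3}$ keeps the logit finite;
`beta_to_m()`/`m_to_beta()` are exact inverses inside the clip bounds.
Identical groups yield $t = 0$, $p = 1$ rather than 0/0; group
comparisons on numerically degenerate vectors (variance at float-noise
level) report $p = 1$ instead of a t-test on rounding error. Fisher's
region combination floors p-values at $10^{-300}$. The empirical-Bayes
moment solution is clamped to $d_0 > 4$, inside the domain of the
variance formula it is derived from. Eigenvector and Katz vectors are
reported with non-negative orientation. Quantile-based hub thresholds
include ties. `emp_p` uses the add-one estimator.

## Known limitations

No IDAT import, probe-chemistry normalisation, batch correction or
cell-composition estimation (inputs are assumed preprocessed); the DE
model is a documented stand-in, not a replacement for count-based
inference; module search is greedy, not exhaustive, so module boundaries
are approximate even when the permutation p is small; enrichment
assumes the supplied gene-set collection is already non-redundant; and
published result counts from any specific cohort are functions of that
cohort's data and external database snapshots, which this package
deliberately takes as file inputs.
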