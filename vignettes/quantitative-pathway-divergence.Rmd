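---
title: "Quantitative pathway divergence between treatments: model and methods"
author: "qpathdiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative pathway divergence between treatments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qpathdiff)
```

# The problem

Multi-target interventions — a multi-herb formula and its decomposed
recipes, combination therapies, dose arms — are often compared against a
common disease model with one expression array per group. The usual
per-gene differential expression answers *which genes* move under each
treatment, and set enrichment answers *which pathways* are touched, but
neither answers the comparative question: **does the same pathway respond
differently to two treatments?** qpathdiff quantifies pathway activity per
treatment as a fold-change profile, places all treatments' profiles in one
common ordination space, and turns "the same pathway sits far apart for
these two treatments" into a permutation-tested call.

# The pipeline

## Differential expression

Each treatment is contrasted against the reference (disease model) group.
Fold change defaults to the geometric definition,
$\mathrm{FC}_g = 2^{\overline{\log_2 x}_{T} - \overline{\log_2 x}_{R}}$,
the standard for microarray intensity summaries (an arithmetic ratio of
linear means is available for compatibility); testing is a per-gene
one-way ANOVA of $\log_2$ intensity on group, which for two groups is
identical to the pooled-variance two-sided t-test ($F = t^2$) — the
implementation is vectorized but the test suite enforces that identity to
$10^{-12}$. A gene is called a DEG when $p < 0.05$ and
$\mathrm{FC} > 2$ or $< 0.5$, with strict inequalities (a fold change of
exactly 2 is not significant). No multiple-testing correction is applied
at this stage: the calling convention these thresholds come from uses raw
p-values, and the bundled seven-gene example table reproduces its printed
significance pattern only under raw-p calling. BH-corrected enrichment
happens downstream, where the multiplicity lives.

Log transformation of the (linear, nonnegative) input intensities is the
package's choice: it stabilizes variance and makes the two-group ANOVA
defensible. Zeros are replaced by a configurable positive offset
(default 1.0) before taking logs.

## Pathway profiles

For one contrast, the *quantitative pathway profile* is a genes ×
pathways table over the contrast's DEGs: a cell holds the gene's linear
fold change when the gene belongs to the pathway and the neutral value 1
otherwise. Because rows are DEGs, member cells are always outside
$[0.5, 2]$. The neutral value 1 is kept verbatim in the stored object —
the table *is* the method's central data structure — and the log
transform that turns "no change" into 0 is deferred to the ordination
preprocessing. Genes in no selected pathway stay as all-1 rows (they
carry no signal and can be dropped with a flag). When a common pathway
set is imposed across treatments (the union of the per-contrast enriched
sets), a pathway with no DEG member in some contrast keeps an all-neutral
column there, behind an explicit `allowEmpty` flag; the default remains
strict (every column needs a member).

Pathway selection uses the one-sided hypergeometric upper tail — with $N$
universe genes, $K$ pathway members, $n$ DEGs and $k$ DEG members, $p =
P(X \ge k)$ — with BH correction across pathways (the field standard;
the test is configurable off). The universe is the assayed gene panel,
not the union of set members: when run from files the pipeline passes the
expression matrix's genes explicitly, otherwise a fully-covered GMT would
make every test degenerate. Treatments are then compared on the
intersection (default) or union of their enriched sets.

## Multiple co-inertia analysis

Each treatment's profile is transposed to a *statistical triplet*
$(X_k, Q_k, D)$: rows are the shared pathways ($n$ of them), columns that
treatment's DEGs ($p_k$), row weights $D$ (uniform $1/n$) common to all
tables, column weights $Q_k$ (uniform $1/p_k$). The default
`log_center` preprocessing takes $\log_2$ of each cell — mapping the
neutral 1 to 0, the natural origin for a fold-change table — and centers
each gene column under $D$. A nonsymmetric-correspondence variant
(`nsc`) is provided for cross-checking against correspondence-analysis
conventions.

MCOA finds, per axis $f$, the unit-$D$-norm synthetic direction $v_f$
maximizing the summed squared co-inertia
$\sum_k w_k \langle s_{k,f}, v_f\rangle_D^2$, which is the leading
eigenvector of $M = \sum_k w_k X_k Q_k X_k^\top$ symmetrized in the $D$
metric. Per-table loadings are $u_{k,f} = X_k^\top D v_f$ normalized to
unit $Q_k$-norm, per-table pathway scores $s_{k,f} = X_k Q_k u_{k,f}$,
and tables are deflated by the $D$-projector on $v_f$ before the next
axis, so the synthetic axes are $D$-orthonormal and the criterion values
$\lambda_f$ non-increasing. Table weights default to `lambda1`,
$w_k = 1/\lambda_1^{(k)}$, the convention of the multi-omics co-inertia
literature: each table is scaled by its own leading eigenvalue, so no
single table dominates and the result is invariant to a global rescaling
of any one table. Uniform weights are available. Two axes are fitted by
default — the method reasons about planar relative position.

Numerical choices: the symmetric eigensolver's deterministic ordering
resolves ties, with near-degeneracy (relative gap below $10^{-10}$)
reported; each axis's sign is fixed by making the largest-magnitude
synthetic loading positive, so runs are reproducible; the eigenvector
residual is checked against $10^{-8}\lambda$; axes requested beyond the
numerical rank are truncated with a warning; pathway rows that are zero
in *every* table are dropped (they carry no signal), while a row zero in
just one table legitimately projects near the origin for that table.

## Divergence scores and the permutation test

Pathway $i$'s divergence between treatments $j$ and $k$ is the Euclidean
distance between its two table scores over the first $F$ axes, after
dividing each axis by $\sqrt{\lambda_f}$ so axis 1 does not drown axis 2
(standardization can be switched off for sensitivity analysis).
Identical tables give all-zero distances; the distance is symmetric in
the pair.

Significance comes from a value-relabelling null: one random permutation
of the member-gene identities is drawn per replicate and applied to
**every** table, so each gene's fold-change values travel together to a
new slot in the fixed membership pattern, and the full MCOA plus
distances are recomputed. Two properties of this scheme matter:

* a gene keeps a single value across all its member cells, preserving
  the duplication structure that overlapping pathways induce;
* relabelling jointly across tables preserves the cross-table
  correlation of fold changes that the shared reference group creates
  (all contrasts reuse the same model samples, so per-gene fold changes
  are correlated between tables at about $\rho = 0.5$). Shuffling each
  table independently destroys that correlation and makes the test
  markedly conservative — in null simulations the false-positive rate
  drops from the nominal 0.05 to below 0.01.

With the joint scheme the test is exact whenever member genes are
exchangeable: under a simulated null in which every pathway carries the
same planted effect, the measured false-positive rate at $\alpha = 0.05$
is 0.042 over 200 datasets (B = 199). The p-value is the standard
permutation tail $p = (1 + \#\{d_b \ge d_{obs}\})/(B+1)$, BH-corrected
across pathways within each treatment pair; a pathway is called
"different" for a pair at $q < 0.05$. Defaults: $B = 999$, $F = 2$,
$\alpha = 0.05$.

# The synthetic-data generator

Real multi-group array data for this design are rarely deposited, so the
generator is a first-class module: $\log_2$ intensity = per-gene baseline
(uniform on [6, 12]) + planted effect + i.i.d. Gaussian noise, exported
on the linear scale. Effects are additive on the log scale and a gene in
several pathways sums their effects — overlap therefore creates hub-like
strong responders, which is deliberate. Gene sets are drawn without
replacement; an `overlap` fraction routes members through a core block
shared by all sets (at overlap 0.5 the mean pairwise Jaccard index is
about 1/3), and `coreGroups` give named groups of pathways a private
shared core, emulating the dense local sharing of related pathways in
curated collections. Ground truth marks a (pathway, pair) divergent when
the planted effects differ by at least a threshold $\tau$; the default
$\tau$ is effectively "any difference", and scenarios set it explicitly.

The generator emulates group-mean shifts on log-intensities with
homoscedastic noise. It does not emulate probe-level artifacts, spatial
effects, cross-hybridization, heteroscedasticity, or count data; passing
tests on it demonstrate the statistical machinery, not robustness to
array pathology.

## The three-arm study

`threeArmScenario()` encodes the design the package is built around: a
full formula (QSG) and its two decomposed recipes (QJ, WYH) against a
model group — 400 genes, 20 pathways × 12 genes, 5 samples per group,
noise sd 0.45 log2. Seventeen concordant pathways respond identically in
all arms (alternating sign, magnitudes 1.3–2.1). Three pathways (P04,
P10, P16) respond divergently *in amplitude*: QJ +2.2, WYH +1.3, QSG at
the root-mean-square midpoint +1.81, so the full formula's pathway
positions sit between the recipes in the quadratic score geometry. The
trio shares a private 6-gene core. With $\tau = 0.75$ the ground truth is
exactly: three divergent pathways for the QJ/WYH pair, none for either
QSG pair.

Two constraints shaped this construction, and both are worth stating
because they are properties of the method, not of the simulator:

* **Positions obey a triangle inequality.** If QJ and WYH genuinely
  differ on a pathway, the full formula cannot be indistinguishable from
  both under a test of unlimited power; "no significant difference for
  the QSG pairs" is a statement about effect gaps sitting below the
  test's resolution. The scenario therefore places QSG midway and was
  calibrated — by pilot simulation over a small grid of recipe effects
  and noise levels, then frozen — so that the half-gaps stay below the
  permutation test's detection floor while the full QJ–WYH gap is
  reliably the top-ranked signal (and flagged at $q<0.05$ in roughly
  three quarters of runs at $B = 199$).
* **The score geometry is quadratic.** Each table's pathway score is a
  quadratic form in that table's values, so inverting every member fold
  change of a pathway whose genes are shared with no other pathway
  leaves its scores *exactly* unchanged — a sign-inversion on disjoint
  support is invisible (the test suite asserts this identity). Planted
  divergence is therefore an amplitude difference, which the geometry
  sees as a norm difference. Relatedly, with fully disjoint gene sets
  the summed operator is near-diagonal and two axes can only expose one
  or two pathway directions; the trio's shared core merges their
  directions into one dominant axis so all three are visible at
  $F = 2$. Real curated collections overlap heavily, which is exactly
  what makes the ordination informative in practice.

## The null study

`nullScenario()` plants the same +2.5 effect on every (treatment,
pathway): member genes are strongly differentially expressed in both
contrasts, their fold-change tuples are exchangeable across genes, and
the DEG selection never interacts with the values (the threshold sits
many standard errors below the effect). This is the exact null of the
permutation test and is what the type-I-error acceptance check simulates.
A weaker planted effect would put genes near the DEG boundary, couple a
gene's presence in a table to its value, and bias the measured rate
downward — a selection effect, documented here deliberately because it
also applies to real data where DEG lists sit near thresholds: the test
is then conservative, not anti-conservative.

# Study sizes used in the checks

The test suite and the acceptance script use: 100 random instances
($n \le 8$, $p_k \le 6$, $K \le 3$) against a dense explicit-loop oracle
with 10,000 random-probe criterion evaluations each; 200 simulated null
datasets at $B = 199$ for the type-I rate; 50 replicates of the three-arm
study at $B = 199$ for the recovery pattern; exhaustive hypergeometric
enumeration on universes up to 20 genes; 1000 replicates for enrichment
super-uniformity.

# Known limitations

* Sign-blindness on disjoint support (above): a pathway that flips
  direction between treatments while keeping magnitude, and shares no
  genes with other selected pathways, is invisible to the divergence
  score. Inspect per-gene DE tables alongside the pathway calls.
* The permutation test's exactness degrades into conservativeness when
  many member genes sit near the DEG thresholds (presence/value
  coupling) — it does not become anti-conservative.
* With `lambda1` weighting, a table whose dominant structure is the
  divergent signal itself is renormalized by it; in extreme cases
  (divergence comparable to the strongest concordant structure) this can
  push the divergent direction off the leading axes. Uniform weighting
  is the safer choice when one table is expected to carry a much
  stronger overall response.
* $F = 2$ axes summarize, and can hide, higher-rank divergence
  structure; raise `nAxes` when many pathways are expected to diverge
  independently.
* Pathway ids are matched as opaque strings across treatments; no
  identifier mapping is attempted.
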