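---
title: "Methods: bipartite regulome networks, centrality shifts and the supporting assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bipartite regulome networks, centrality shifts and the supporting assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regulomeShift)
```

# The model

`regulomeShift` asks a structural question about a knockdown experiment:
not merely *which genes change*, but *which genes become important to
the cell's functional organisation once the cofactor is gone*. The
object of study is a weighted bipartite graph per condition. Gene nodes
point at the biological-process (BP) nodes they are annotated to, and
every edge from gene $g$ carries the same weight $w_g$ — the gene's
*representation*, its mean abundance across the condition's replicates.
A gene therefore influences the graph through two quantities only: how
strongly it is expressed, and how many processes it participates in.
These are exactly the two levers the synthetic generator plants (see
below).

Importance is eigenvector centrality: the dominant eigenvector $x$ of
the adjacency, $Ax = \lambda_1 x$, scores a node by the importance of
its neighbours. We compute it on the **symmetrised** adjacency. A
strictly directed gene→BP graph gives every gene zero in-degree, so
directed eigenvector centrality collapses all gene scores to zero —
symmetrisation preserves the "traffic between nodes" interpretation
while keeping gene scores informative. The direction is retained in the
data model and in the GraphML export; it is dropped only inside the
centrality computation.

Scores are max-normalised ($\max_i x_i = 1$), and *relative importance*
is $100\,x_i$ percent. Between conditions we report, per gene,

$$ R = 100\,\frac{C_{KO} - C_{WT}}{C_{WT}}, $$

with sentinels for genes present in only one network (`novel_in_ko`,
$R = +\infty$; `absent_in_ko`, $R = -100$). Two classifiers sit on top:

* **functional complements** — $R > 1000\%$ (strict, or new to the KO
  network) *and* up-regulated ($\log_2\mathrm{FC} > 0$);
* **reduced importance** — KO relative importance $< 1\%$ (strict).

Both cutoffs are exposed as arguments. The up-regulation requirement
(`require_up = TRUE`) is a default, not a certainty about how such
screens must be run: a gene whose centrality explodes while its
expression falls is arithmetically possible (centrality is relative),
and the flag lets users inspect that regime.

Because centrality is relative twice over — the eigenvector is defined
up to scale, and we max-normalise — all reported scores are invariant
under uniform scaling of the edge weights. This is tested to 1e-10.

# Numerical choices

**Power iteration with an adaptive Perron shift.** A connected bipartite
graph has a symmetric extreme spectrum: $+\lambda_1$ and $-\lambda_1$
are both eigenvalues, so plain power iteration oscillates between the
two parities and never converges. We iterate on $A + sI$, which shifts
eigenvalues but not eigenvectors. The shift is updated every sweep to
the Rayleigh quotient $v^\top A v$ of the current (positive) iterate;
for a symmetric matrix this never exceeds $\lambda_1$, and as the
iterate converges the $-\lambda_1$ branch is damped by a factor
approaching $2\lambda_1$ while the gap to $\lambda_2$ stays wide. A
fixed large shift (e.g. the maximum weighted degree) also converges but
can be impractically slow under heavy-tailed weights, where the bound
is loose. Convergence is declared when successive L2-normalised
iterates differ by less than `tol` (default 1e-10) and is an error
after `max_iter` (default 1000) sweeps. Equivalence with a dense
eigendecomposition is tested to 1e-8 on hundreds of random graphs.

**Strict thresholds.** Selection bounds ($|\log_2\mathrm{FC}| > 2$,
$R > 1000\%$, importance $< 1\%$) are strict inequalities; a gene at
exactly the bound is excluded. Published threshold prose is rarely
explicit about the boundary, and the strict reading is applied
uniformly so the rules compose predictably.

**Zero handling in fold changes.** $\log_2(\mathrm{KO}/\mathrm{WT})$
adds a floor (default 1.0 expression unit) to *both* means, and only
when one of them is zero, keeping the statistic finite and symmetric
without perturbing well-measured genes.

**Degenerate t-tests.** With few replicates, both groups can be
numerically constant. Instead of erroring (as the textbook formula
would, dividing by a zero standard error), the test returns $t = 0$,
$p = 1$ when the means agree — with a `zero_variance` flag — and
$p = 0$ with infinite $t$ when they differ. Peptide arrays with $n = 2$
technical replicates hit this case routinely.

**Louvain determinism.** The greedy modularity sweep is order-dependent
under ties, so vertices are shuffled by a seeded RNG before calling the
igraph implementation; the same seed gives the same partition. The
resolution parameter defaults to 1.

**Ontology levels.** OBO `is_a` edges define term depth with the root
at level 1, so "level 3" means two `is_a` steps below the root — the
convention of common annotation tools. The root-counting choice is
stated here because published "level 3" annotations rarely say whether
the root is level 0 or 1; the function returns all levels, so a user
preferring the other convention subtracts one.

**ITC units and corrections.** The single-site (Wiseman) model works in
molar concentrations, µL volumes, kcal/mol enthalpies and µcal heats;
the cumulative heat after injection $i$ is
$Q_i = 10^3\, n\, M_t\, \Delta H\, v_0\, \Theta_i$ with $\Theta_i$ the
occupied-site fraction from the single-site quadratic, and injection
heats apply the standard displaced-volume correction
$q_i = Q_i - Q_{i-1} + \frac{v_{inj}}{v_0}\,\frac{Q_i + Q_{i-1}}{2}$.
Cell-concentration bookkeeping uses the usual perfusion approximation
$M_t = M_0 (1 - \frac{dV}{2v_0})/(1 + \frac{dV}{2v_0})$, which agrees
with an exact per-injection mixing simulation to a fraction of a
percent at the 19 × 2 µL / 200 µL geometry. The cell volume defaults to
200 µL, typical of the instrument class used for such measurements, and
is configurable. Fitting is Levenberg–Marquardt on
$(\log_{10} K_a, \Delta H, \log n)$ — the log parameterisations enforce
positivity — multi-started over $K_a \in 10^{3..8}$ /M with the
enthalpy seeded from the observed total heat; an essentially-zero
isotherm is reported as unidentifiable (`converged = FALSE`) rather
than fitted. An optional flag drops the first injection, the common
correction for the first-injection anomaly; it is off by default.

**Array normalisation.** The default empty-spot mode is *subtract*
(background correction, floored at zero), with *ratio* behind a flag;
"normalised against empty spots" admits both readings and subtraction
is the commoner array convention. Subtract-mode comparisons are
invariant to adding a constant to every spot, which is tested.

# Open design points, decided

* **Variance assumption.** The RNA-seq-style per-gene test defaults to
  the pooled-variance Student's *t*; Welch is a flag
  (`equal_variance = FALSE`) and is the natural choice for qPCR-style
  comparisons.
* **Multiple testing.** Raw *p*-values against $\alpha = 0.05$ by
  default, matching the screening character of the method;
  Benjamini–Hochberg is available (`adjust = "BH"`) but off, and with
  it on, far fewer genes pass — users doing confirmatory work should
  turn it on.
* **Weighted vs unweighted centrality.** Weighted is the default; an
  unweighted toggle exists because desktop graph tools historically
  ignore weights in this statistic, and the two can rank genes quite
  differently.
* **BP identity.** Coverage analysis matches processes by term id;
  name-based, case-folded matching is behind a flag for tables that
  only carry names.

# What the synthetic generator emulates — and what it does not

`synth_config()` encodes the emulated study design: 2 conditions × 3
biological replicates; log-normal baseline abundances
(`meanlog = 5`, `sdlog = 1`, i.e. a heavy-tailed distribution with a
median of ~150 units); replicate coefficient of variation 10 %; 10 % of
genes differentially expressed at $|\log_2\mathrm{FC}| = 3$ with random
sign; six planted complements; gene→BP annotations of 1–4 random
memberships per background gene over 20 BPs; an interacting-protein
table covering all BPs except 4 designated ones.

Two structural choices deserve emphasis, because they are what makes
the planted phenomenon exist at all:

* **Induction starts low.** Genes planted as up-regulated — background
  DE genes and complements alike — draw their WT baseline from the low
  end of the abundance distribution (below the median; complements
  below the 15th percentile). A gene that is already a top hub cannot
  meaningfully *gain* relative importance, and a uniformly applied
  8-fold boost on a heavy-tailed baseline would manufacture KO giants
  that dominate the max-normalisation and mask everything else.
  Strongly induced genes rising from near-silence is also the
  biologically coherent picture of de-repression.
* **Complements are the most up-regulated genes and co-annotated.**
  Planted complements gain 32-fold in KO (one doubling above any
  background DE gene, twice over) and receive 5 memberships drawn from
  a shared 6-BP pool, so they reinforce one another the way a
  co-regulated immune-effector programme does. Both levers — expression
  and membership — are what the centrality model rewards.

At these defaults the screen recovers planted complements with
sensitivity ≥ 0.9 and false-positive rate ≤ 0.1 over 20 seeded
replicates (measured in the test suite and the acceptance script). What
passing these tests shows is that the *pipeline arithmetic* is right
and that the classifier separates the planted signal at the stated
thresholds. What it does **not** show is that real knockdown data obey
the generator's assumptions: real abundances are not log-normal with a
common CV, annotation in real GO slices is far denser and deeper than
20 flat BPs, replicate noise is not independent across genes, and real
complements need not be co-annotated in a tight pool. Results on real
data depend on annotation quality and on the thresholds in a way no
synthetic benchmark can certify.

The generator's other outputs follow the same pattern: arrays are
Gaussian spots over a flat background with designated binder peptides
(null arrays show a type-I rate near $\alpha$ across 100 seeds); ITC
traces are the single-site model plus Gaussian noise. All generators
are deterministic given the config seed and restore the caller's RNG
state.

# Problem sizes used in the checks

The shipped checks run at desk scale, chosen so the full suite
completes in well under a minute of compute per module: oracle
equivalence on 200 random bipartite graphs of ≤ 12 nodes; recovery on
20 synthetic studies of 200 genes × 20 BPs; the exhaustive
$\{0..3\}^6$ t-test grid (4096 cases); 1000 random membership tables
($k \le 4$); 20 ITC fits spanning the Wiseman parameter
$c = n K_a M_0 \in [1, 1000]$ at 2 % noise, where the well-known
identifiability limits at the ends of the range are visible in the
per-fit errors while the median stays below 10 %.

# Known limitations

* Centrality changes carry no significance statement — $R$ is a
  descriptive screen, and no null distribution for it is implemented.
* The BP "level" filter follows `is_a` edges only; `part_of` and
  regulatory relations are ignored, and no GO reasoning beyond levels
  is attempted.
* The coverage analysis treats the IP annotation table as ground truth;
  incompleteness of interaction databases directly inflates the
  "cofactor-only" set.
* The ITC module fits a single-site model only; multi-site,
  competitive, or kinetic-limited data will be misfit without warning
  beyond the residual.
* The monotonicity of a gene's centrality in its own representation is
  an empirical observation on the tested graphs, not a theorem; the
  test logs counterexamples if they arise.

```{r example, eval = FALSE}
cfg <- synth_config(seed = 1)
sim <- simulate_study(cfg, tempfile("study"))
run_pipeline(list(expr = sim$paths$expr, conditions = sim$paths$conditions,
                  ann = sim$paths$ann, ip_ann = sim$paths$ip_ann,
                  out_dir = tempfile("out"), seed = 1))
```
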