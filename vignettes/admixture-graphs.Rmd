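---
title: "Inferring population splits and mixtures with admixgraph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring population splits and mixtures with admixgraph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(admixgraph)
```

## The model

The package models the allele frequency of a SNP in a descendant
population as its ancestor's frequency plus Gaussian drift:

$$x \mid p \sim N\!\left(p,\; c\,p(1-p)\right),$$

where $c$ absorbs the demographic details of the branch (approximately
$t/2N_e$ for $t$ generations at effective size $N_e$). The approximation
follows from the diffusion limit of Wright-Fisher drift when drift is
small; it ignores the frequency boundaries at 0 and 1 and new mutations,
so it is most trustworthy for variants at intermediate ancestral
frequency and for populations separated by modest drift.

Populations are related by a rooted directed acyclic graph (`popgraph`).
Tree edges carry drift lengths $c \ge 0$. A population may additionally
receive "migration" edges: if a node has incoming weights $w_1, \dots,
w_m$ (the tree edge implicitly carrying $1 - \sum w$), its frequency is
the weighted average of its parents' frequencies plus its own drift. On
a tree the implied covariance of tip frequencies relative to the root,
$V_{ij}$, is the drift shared by the root paths of $i$ and $j$; with
admixture each tip has several weighted root paths and $V_{ij}$ sums
path-pair overlaps. `predicted_covariance()` computes this exactly
through per-node path weights; an independent implementation of the same
quantity by symbolic covariance propagation serves as its cross-check in
the test suite.

Frequencies are used untransformed. Variance-stabilising transformations
(arcsine square-root, or scaling by $\bar p(1-\bar p)$) up-weight
ancestrally rare variants — exactly where the Gaussian approximation is
weakest — and the arcsine transform additionally distorts expectations
near the boundaries, so neither is offered.

### Drift on an admixed population

The drift specific to an admixed population accrues partly before and
partly after the mixture, and the components are not separately
identifiable. The package estimates a single parameter and, by default,
gives it coefficient 1 in the variance (the parameter is read as
post-mixture drift); `drift_weighting = "squared"` switches to the
$\sum_k w_k^2$ convention in which the parameter is read as pre-mixture
drift accrued on both parental lineages. The choice moves a little drift
between an admixed tip's terminal branch and its neighbours but does not
change topology inference in our tests. Which convention other
implementations use is not something we rely on.

Migration edges themselves carry no drift; all drift lives on tree
edges. This keeps the branch-length system linear and well-posed. By
convention the tree edge into an admixed node is the one with the
largest incoming weight; fitted graphs are normalised to satisfy this,
and `validate_popgraph()` reports violations.

## Estimation

### The sample covariance

The ancestral frequency is unobserved, so inference rests on the
*centered* sample covariance across the $P$ populations,
$\widehat W_{ij} = \mathrm{mean}_l\,(\hat p_{il} - \bar p_l)(\hat p_{jl}
- \bar p_l)$, compared with the model's centered covariance
$W(G) = C V(G) C'$, $C = I - \mathbf{1}\mathbf{1}'/P$. Centering removes
the unknown per-SNP mean; its cost is that only contrasts are
identified, with two consequences the package makes explicit:

* the position of the root is not identified on a tree (drift evolves
  reversibly here), so the root is placed using a declared outgroup
  (`build_tree(..., outgroup = )` is mandatory);
* with a degree-2 root, only the *sum* of the two root-adjacent lengths
  is identified; the fitted sum is split evenly between them.

Finite samples inflate the estimate: sampling $n$ chromosomes behaves
like extra drift of variance $p(1-p)/n$, biasing mainly the diagonal
(and, through centering, the off-diagonal mildly). We subtract
$C \bar S C'$, where $\bar S$ is diagonal with entries
$\bar v_i = \mathrm{mean}_l\, \hat h_{il}/(2 n_{il})$ and
$\hat h = 2\hat p(1-\hat p)n/(n-1)$ is the unbiased heterozygosity, so
$\hat h/(2n)$ is unbiased for $p(1-p)/n$. This correction is the
package's own construction; the centering matrix automatically carries
the diagonal correction into the off-diagonal terms. Populations with a
single sampled chromosome (ancient DNA, single genomes) have no
within-population heterozygosity estimate: supply `het_override`
(e.g. `c(archaic = 0.13)`), a per-population scalar that replaces
$\hat h$. In practice this only affects the terminal branch lengths of
those populations.

### Blocks and the composite likelihood

Nearby SNPs are correlated (linkage disequilibrium), so per-SNP standard
errors would be too small. The genome is split into blocks of
`block_size_k` consecutive SNPs in input order (default 500; choose
blocks longer than the LD scale of your data); $\widehat W$ is computed
per block, averaged, and each entry's standard error is the standard
error of that mean over the $K$ blocks. Trailing SNPs that do not fill a
block are discarded. SNPs with a zero sample in any population are
dropped up front: the estimator wants a complete matrix.

The objective is a composite likelihood: the product over unordered
population pairs — diagonal included, since terminal-branch drift is
informative — of Gaussian densities
$N(\widehat W_{ij};\, W_{ij}(G),\, \hat\sigma_{ij}^2)$. A Wishart
likelihood would model the joint distribution of the matrix but needs
repeated matrix inversions; the composite form is accurate enough for
point estimation and vastly cheaper. It is *not* a real likelihood:
entries are correlated, so likelihood-ratio tests on it are invalid —
hence the jackknife below. Standard errors below `se_floor` (default
1e-12) are floored with a warning rather than producing infinite
densities.

### Fitting a given topology

With weights fixed, $W(G)$ is linear in the drift lengths: one equation
per population pair, solved by non-negative least squares
(Lawson-Hanson; plain rather than variance-weighted least squares —
weighting would be a straightforward extension we have not needed).
Weights are then optimised one migration edge at a time by
golden-section search on $[0,1]$, refitting all branch lengths at every
evaluation, and the two steps alternate until the log-likelihood
improves by less than `tol` (default 1e-6; golden-section bracket
`weight_tol` default 1e-4, both configurable). This coordinate ascent
never decreases the objective, a property the test suite asserts.

### Searching topologies

`build_tree()` is greedy stepwise addition: a random starting triple
(all three rooted resolutions fit), remaining populations inserted in
random order at the best branch, a round of nearest-neighbor
interchanges after each insertion, and final rooting at the outgroup.
The randomness is governed by `search_config(seed = )`; on clean data
different seeds reach the same topology.

Migration edges are then added one at a time (`n_migration` of them).
Candidates come from the residuals $R = \widehat W - W(G)$: the
`m_top_pairs` (default 10) worst pairs are found, each member is widened
to the tips within `n_neighborhood` (default 5) tree edges, and for
every resulting pair each ordered combination of nodes on the two root
paths is a candidate source/destination — kept only if all residuals
between the two descendant tip sets are positive, the sets are
disjoint, and the edge keeps the graph acyclic. The defaults cover
every population in graphs of a few dozen tips; ties in the residual
ranking are broken lexicographically so runs are reproducible. Each
candidate is fit, the single best edge kept, and a greedy round of local
moves follows: interchanges at the source and destination, moving each
migration endpoint to adjacent nodes, and flipping edge directions —
each accepted only on likelihood improvement, with direction flips
additionally required to beat `direction_tol` (default 1e-6) because
near-tied directions are a known ambiguity; such ties are recorded on
the result. We stop at a user-chosen number of edges rather than adding
until non-significance: graphs stay interpretable, and significance is
assessed afterwards.

### Significance of an edge

`test_migration()` holds the graph structure fixed and jackknifes over
blocks: the target edge's weight is re-optimised (branch lengths refit)
with each block deleted, and the delete-one estimates give the standard
jackknife point estimate and standard error for a Wald test. Two points
deserve emphasis:

* the weight is re-estimated over $[-1, 1]$, not $[0, 1]$: under the
  null the constrained estimator sits on the boundary, every delete-one
  estimate coincides, and the test degenerates, whereas the
  unconstrained estimator is approximately normal around zero and the
  p-values calibrate (the suite checks uniformity of null p-values);
* the p-value compares a fixed graph with and without one edge. It does
  not certify the graph around it, and with $\sim P^2$ potential edges
  no multiplicity correction is applied — treat small p-values as
  necessary, not sufficient. The f-statistics below are the
  less-parameterised companions.

### f-statistics

`f3(target; A, B)` is the mean of
$(\hat p_T - \hat p_A)(\hat p_T - \hat p_B)$ minus the target's
sampling-bias term $\hat p_T(1-\hat p_T)/(n_T-1)$; significantly
negative values indicate the target is admixed between relatives of A
and B (one-sided Z). An unadmixed target instead returns its own drift,
a positive number. `f4(A,B; C,D)` is the mean of
$(\hat p_A - \hat p_B)(\hat p_C - \hat p_D)$, zero when $(A,B)$ versus
$(C,D)$ is a genuine split (two-sided Z). No heterozygosity
normalisation is applied to f3 — the unnormalised form matches the test
we cross-reference against the covariance model. Standard errors come
from a delete-one jackknife over blocks of `block_size_k` consecutive
SNPs (the last block may be short and is kept); SNPs with missing data
are dropped per statistic, not globally.

## The simulator

`simulate_frequencies()` and `sample_counts()` generate data from
exactly the model above: ancestral frequency drawn from
Uniform(0.05, 0.95) by default, drift $N(0, c\,p_0(1-p_0))$ along each
tree edge (every branch scaled by the *root* SNP's $p(1-p)$ — the
small-drift approximation the model itself invokes), weighted mixing at
admixed nodes, truncation to $[0,1]$, and binomial sampling of $n$
chromosomes. `serial_divergence_graph()` builds the ladder of serially
founded populations used throughout the tests: drift 0.005 per
inter-split interval by default, i.e. roughly 100 generations at
$N_e = 10{,}000$, with every tip equidistant from the root.

What the simulator emulates and what it does not:

* SNPs are independent by default. Real panels have LD; the
  block-standard-error machinery exists for that reason but is only
  mildly exercised by iid data. `ld_factor = r` repeats each simulated
  SNP $r$ times with jitter, creating blocks of dependent SNPs for
  stress-testing the jackknife; it is off by default.
* Truncation at the frequency boundaries is the only boundary effect;
  there is no mutation, no fixation dynamics, no ascertainment bias
  unless `ascertain()` is applied. The fraction of truncated draws is
  reported as an attribute; test scenarios keep it below 1%, and at the
  default ladder settings with ancestral frequencies near the ends of
  Uniform(0.05, 0.95) it reaches a few percent, visible as slight
  model misfit.
* Coalescent noise, recombination and population-size dynamics are
  absent. Passing tests therefore certify the estimators against their
  own model assumptions, not against every feature of real data; a
  coalescent simulator can be substituted by writing its output in the
  counts format and reading it with `read_counts()`.

## Problem sizes and known limitations

The test suite runs the pipeline at sizes chosen to exercise the
statistics meaningfully on a single core: 20-population ladders with
20,000–50,000 SNPs for topology recovery and variance explained (the
fitted tree explains more than 99.5% of covariance variance there), 100
replicates for the null p-value calibration at 6 populations, and a
10-point admixture-weight grid at 10 populations. `scripts/acceptance.R`
reruns the two headline quantities from a seed.

Known limitations, deliberate and otherwise:

* Weights of strong admixture events are mildly underestimated, and the
  bias grows with the true proportion; the weight-recovery test demands
  correlation with truth, not unbiasedness.
* Migration between closely related populations lacking outgroups in
  the sample is the hard regime: topology recovery degrades and
  direction errors become likely. The tests assert only the easy
  regime; expect to need f-statistics and multiple runs elsewhere.
* The search is greedy hill-climbing. Different seeds can reach
  different local optima on hard data; run several seeds and compare
  likelihoods.
* An equilibrium migration structure can produce the same covariance as
  a history of splits and mixtures; the graph is a summary of
  covariance, and its historical reading is an interpretation.
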