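---
title: "Common modules in multilayer networks: model, algorithm and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Common modules in multilayer networks: model, algorithm and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comodule)
```

## The problem

Gene expression and DNA methylation are coupled but heterogeneous readouts:
methylation regulates expression, yet the sign of the coupling varies from
locus to locus, so collapsing both into a single network discards
information. `comodule` instead keeps one network per data type — a gene
co-expression layer and a gene co-methylation layer over the same genes —
and looks for **common modules**: gene sets that are densely interconnected
in *every* layer simultaneously. A common module of these two layers is an
epigenetic module, a set of genes that is both co-expressed and
co-methylated, with no assumption about the sign of the
methylation–expression relationship. Nothing in the machinery is specific
to two layers or to omics data; any collection of symmetric non-negative
networks over a shared vertex set works.

## Quality model

For a vertex set $C$ and layer $m$ with weights $w_{ijm}$ and degrees
$d_{im} = \sum_j w_{ijm}$, the per-layer connectivity is the modularity
density

$$D_m(C) = \frac{L(C,C) - L(C,\bar C)}{\sum_{v_i \in C} d_{im}},
\qquad L(C,C) = \sum_{v_i \in C}\sum_{v_j \in C} w_{ijm},$$

i.e. internal minus external weight, normalized by the module's total
degree. $L(C,C)$ sums over ordered pairs (both orientations), which is the
self-consistent reading: the whole vertex set of any layer with positive
weight then scores exactly 1, and an isolated clique scores 1. Scores can
be negative for sets with more weight leaving than staying.

Across layers the module quality is the geometric mean
$D(C) = (\prod_m D_m(C))^{1/M}$, and a partition's quality is
$\sum_l D(C_l)$ (`partition_score()`). The geometric mean encodes the
"common" requirement: a module must be good in *all* layers, and a single
bad layer drags the score down hard. Because the geometric mean is
undefined for non-positive factors, any module with $D_m(C) \le 0$ in some
layer is floored at 0 — it simply does not count as a common module. This
keeps scores of genuine modules comparable and order-preserving.

Edge **density** ($2|E(C)|/(|C|(|C|-1))$, reported by
`module_diagnostics()`) counts edges combinatorially; for weighted layers
an edge is any pair with positive weight. Weights influence quality through
$D_m$, not through the density.

## The joint factorization

Direct maximization of the partition score is combinatorial, so modules are
found by jointly factorizing the layer adjacency matrices with a shared
non-negative basis:

$$\min_{B, F_m \ge 0} \sum_{m=1}^{M} \lVert W_m - B\,F_m \rVert_F^2
\quad \text{(bi-factor, the default)},$$

optionally with an extra free $k \times k$ factor $H$ between them
(`mode = "tri"`). The basis $B$ ($n \times k$) is shared across layers, so
its columns must explain the block structure of every layer at once; the
per-layer coefficients $F_m$ absorb layer-specific weight patterns. Hard
modules are read off $B$ by row argmax (`extract_modules()`): vertex $i$
joins the column where its loading is largest (ties to the lowest column
index; columns that win no vertex are dropped, reducing $k$).

Optimization uses the classical multiplicative updates for each factor in
turn (see `jnmf_update()` for the exact rules). They preserve
non-negativity, never increase the objective, and leave an exact
factorization unchanged. Denominators are floored at $10^{-12}$ so $0/0$
cannot occur.

### Why the default drops H

With a free $H$ the model $W_m \approx B H F_m$ can reach the same
reconstruction with $B$ replaced by $B R$ for suitable non-negative mixing
$R$, so the basis is only loosely identified. In practice this shows up as
restart-to-restart variability of $B$ even when every restart finds an
equally good optimum — which both degrades the argmax module assignment and
inflates the instability statistic used for rank selection. With $H$ fixed
at the identity the basis is pinned to the block structure: on
planted-partition benchmarks at low noise every restart converges to the
same basis up to column permutation (instability numerically 0) and module
recovery is exact. The tri-factor mode remains available for the extra
modelling freedom, and all optimizer guarantees (monotonicity, fixed
points, non-negativity) are tested in both modes.

### Initialization, termination, restarts

* **Initialization.** All factors are i.i.d. uniform on $(0, 1]$, scaled by
  $\overline{W}^{1/2}$ per factor (bi) or $\overline{W}^{1/3}$ (tri), where
  $\overline{W}$ is the mean entry over all layers. Strict positivity
  matters: multiplicative updates can never revive an entry that starts at
  zero. The scaling makes the initial reconstruction match the data's
  magnitude, and makes the whole seeded trajectory exactly equivariant
  under rescaling of $W$.
* **Termination.** A restart stops when one full sweep decreases the
  objective by less than `tol` (default $10^{-2}$, an absolute error
  threshold), or after `max_iter` sweeps (default 1000). The absolute
  criterion was chosen over a relative one deliberately: multiplicative
  updates typically pass through an early plateau — after the first large
  drop the *relative* per-iteration decrease briefly falls below $10^{-2}$
  around iteration 2–3, long before the basis has differentiated — so a
  relative rule at this tolerance halts essentially at the initialization
  and recovers nothing. The absolute rule only fires on the true
  convergence tail. Its one cost is scale dependence: on networks whose
  objective is many orders of magnitude away from $O(10^3)$, `tol` should
  be rescaled accordingly (or set small, letting `max_iter` bind).
* **Restarts.** The objective is non-convex; `restarts` independent
  initializations are run (default 50) and the lowest final objective wins.
  Every source of randomness is derived deterministically from `seed`, so
  runs are bit-reproducible.

## Choosing the number of modules

`select_k()` scans candidate ranks and picks the one minimizing the
**instability of the factorization**: run the fit `runs` times from
independent random starts (one restart each), and average the
column-matching dissimilarity of the resulting bases over all pairs,

$$\mathrm{diss}(B_a, B_b) = 1 - \frac{1}{2k}\Big(\sum_i \max_j C_{ij} +
\sum_j \max_i C_{ij}\Big),$$

with $C$ the matrix of cosines between L2-normalized columns. The
dissimilarity is 0 iff the bases agree up to column permutation and
positive rescaling, and 1 for column-wise orthogonal bases. At the true
rank the optimum is well determined and restarts agree; below it, modules
are merged in ways that vary by restart; above it, the surplus column
splits an arbitrary module. Only $B$ enters the statistic — modules are
read from $B$, so stability of $B$ is what matters. Ties break toward the
smaller (more parsimonious) $k$.

## The benchmark generator

`gn_homo_net()` and `gn_heter_net()` produce planted-partition multilayer
networks in the classic four-communities style: $n$ vertices (default 128)
in $q$ equal communities (default 4, hence 32 vertices each), expected
per-vertex degree fixed (default 16), of which `z_out` edges on average
leave the community. Edges are independent Bernoulli draws with
$p_{in} = (degree - z_{out})/(n/q - 1)$ and
$p_{out} = z_{out}/(n - n/q)$ — degree is fixed *in expectation*, as in the
classic benchmark; exact-degree sampling would over-constrain the planted
blocks. The homogeneous variant uses the same `z_out` in every layer; the
heterogeneous variant fixes layer 1 at `z_fixed` (default 4) and varies
the rest. All layers share the planted partition — without that, common
modules would not exist. Layer streams are derived from the master seed by
layer index, so layers are independent but reproducible.

What the simulations do *not* emulate about real co-expression networks:
weighted and heavy-tailed degree distributions, correlated noise across
layers, unequal module sizes, and vertices belonging to no module. Passing
benchmark tests therefore demonstrates correctness of the machinery and
behaviour under controlled noise, not performance on any particular data
set.

## Building layers from profiles

`build_multinet()` turns two profile matrices (genes × samples) into a
two-layer network: Pearson correlation per layer, then the PCIT trio
filter, with surviving edges weighted $|r|$ (the quality model needs
non-negative weights; the sign of co-regulation is deliberately not
interpreted). PCIT examines every gene trio $(x, y, z)$: from the
first-order partial correlations it forms the tolerance
$\varepsilon = \tfrac12(|r_{xz \cdot y}/r_{xz}| + |r_{yz \cdot x}/r_{yz}|)$
and flags edge $(x,y)$ when $|r_{xy}| < \varepsilon|r_{xz}|$ and
$|r_{xy}| < \varepsilon|r_{yz}|$. An edge is removed only when **every**
admissible third gene flags it — it must be indefensible in all trios.
Trios with near-zero direct correlations (undefined ratios) abstain, and
degenerate partial correlations ($|r| = 1$) are treated as 0 with a
warning. The filter never adds edges and only sees correlations, so it is
invariant to positive rescaling of any gene's profile. The implementation
precomputes all first-order partial correlations (an $n^3$ array; time and
memory are cubic in gene count), which is comfortable up to a few hundred
genes; genome-scale inputs should be pre-filtered to the genes of
interest. Rows with missing values are dropped, not imputed.

## Evaluation

`nmi()` scores a partition against ground truth with normalized mutual
information computed from the module-overlap contingency table, natural
logarithms, $0\log 0 = 0$: identical partitions (up to relabeling) score
1, independent ones near 0. When both partitions are the trivial single
module the value is defined as 1 (they agree), and a trivial against a
non-trivial partition scores 0 (it carries no information about it).

## Numerical and testing choices

* Symmetry of input layers is enforced with relative tolerance $10^{-8}$;
  small asymmetries are averaged out, self-loops are stripped.
* The monotonicity of the objective is asserted with slack
  $10^{-10} \cdot \max(1, e)$ to absorb the denominator flooring.
* Test and validation problem sizes: benchmark experiments use the default
  $n = 128$, $M = 2$ configuration with 5 seeds per noise level and 20
  restarts per fit; the rank-selection experiment uses 50 single-restart
  runs per candidate $k \in \{2, \dots, 10\}$; scalability is exercised at
  $n = 512$ and $n = 1024$ with 5 restarts (a $n = 4096$ run works the
  same way and takes a few minutes; it is not part of the routine suite).
  Exhaustive-enumeration oracles use $n \le 12$.

## Limitations

* Hard, non-overlapping modules only; every vertex is assigned somewhere,
  including vertices with no meaningful module membership.
* All layers must share one vertex set; genes absent from a layer must be
  dropped or added as isolated vertices beforehand.
* The absolute termination threshold is calibrated for objectives of
  moderate magnitude (see above).
* Rank selection compares candidate $k$ by restart concordance; it can
  prefer a smaller $k$ when the data contain hierarchically nested
  modules that admit several equally stable resolutions.
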