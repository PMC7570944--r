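---
title: "Quantifying social attraction and repulsion in tracked herds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying social attraction and repulsion in tracked herds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herdrank)
```

## The problem

High-accuracy localisation systems can record the planar position of every
animal in a group many times per second. The question this package answers
is how to turn such trajectories into statements about *social* structure:
which animals are bonded, which individual the group orbits around, and
which individuals are avoided or avoid the others.

Physical distances are a poor currency for this. A herd contracts while
resting and stretches over a hundred metres while walking, so a fixed
distance threshold means different things at different moments. The package
therefore works with *distance ranks*: at every timeslot each animal sorts
all others by distance, and only the resulting order is kept. Ranks are
invariant to the herd expanding or shrinking, which is what makes the
closeness measure comparable across activity states.

## The closeness matrix W

Let $R_{ij}(t) \in \{1, \dots, N-1\}$ be the rank of animal $j$ in animal
$i$'s ascending distance order at timeslot $t$ (1 = nearest). The
closeness matrix is the time average

$$W_{ij} = \frac{1}{T} \sum_{t=1}^{T} R_{ij}(t),$$

with $W_{ii} = 0$. Each row is an average of permutations of
$1,\dots,N-1$, so each row sums to $N(N-1)/2$ exactly — a structural
identity the test suite asserts and that `verify_table1()` checks on any
fixture within a rounding budget. $W$ is asymmetric ($W_{ij} \neq W_{ji}$
in general): each animal ranks the others from its own position, and a
bond may matter more to one member of a pair than to the other. $W$ can be
read as a bidirectional weighted graph with $N(N-1)$ directed edges.

Two conventions needed fixing and are worth stating prominently:

* **Polarity.** *Small* $W_{ij}$ means *close*. A habitual neighbour has a
  small average rank. All downstream machinery treats the reciprocal
  products $W_{ij} W_{ji}$ as **dissimilarities**: bonded pairs have small
  products. (The bundled ten-cattle example confirms this reading: the
  strongly bonded pair 8–10 holds the smallest entries of its matrix, and
  the repelled animals 1 and 7 the largest.)
* **Orientation.** Rows are "animal $i$'s own view": entry $(i, j)$ ranks
  $j$ within $i$'s distance list. Because only the row-permutation
  structure is observable this cannot be distinguished from its transpose
  by row sums; `closeness_matrix(transpose = TRUE)` exposes the other
  orientation. Every symmetric product is identical either way.

Ties in distance are broken by animal order (earlier identifier gets the
smaller rank). They are measure-zero for continuous coordinates; the rule
exists so that degenerate inputs (coincident animals, simulated zero-noise
herds) remain exactly reproducible.

## The variation matrix

Stability of a relationship is measured on the *reciprocal* rank
$X_{ij}(t) = 1/R_{ij}(t) \in [1/(N-1), 1]$, which compresses differences
among distant ranks (being 8th vs 9th is socially uninformative; being 1st
vs 4th is not). The variation matrix is the population variance over time,

$$D_v(i,j) = \frac{1}{T}\sum_t X_{ij}(t)^2 -
  \Big(\frac{1}{T}\sum_t X_{ij}(t)\Big)^2,$$

which is non-negative, bounded by $0.25$, and zero exactly when a pair's
relative standing never changes. Dispersion could equally be summarised
as a standard deviation; the package commits to the population variance
(non-negative, as a dissimilarity ingredient must be, and additive over
independent sources) and offers the standard deviation through
`variation_matrix(stat = "sd")`.
Like $W$, $D_v$ is symmetrised by reciprocal products before embedding.
Pairs with small product variation had a *stable* relationship — which
includes stably-avoiding pairs, not only bonded ones.

## Classical MDS and K-means with silhouette selection

A symmetric dissimilarity $D$ is embedded by classical (Torgerson)
scaling: with $C = I - \tfrac1N \mathbf{1}\mathbf{1}^\top$,

$$B = -\tfrac12\, C\, (D \circ D)\, C, \qquad
  X = V_2\, \Lambda_2^{1/2},$$

where $\Lambda_2$ holds the two algebraically largest eigenvalues of $B$.
Rank products are not Euclidean distances, so some eigenvalues of $B$ are
negative; if a *retained* one is non-positive the corresponding coordinate
column is zeroed with a warning rather than inventing imaginary
coordinates. Axis signs are canonicalised (first nonzero loading of each
eigenvector positive) so results do not depend on the eigensolver's sign
choices; beyond that the configuration is defined only up to rotation and
reflection, and all tests compare configurations after Procrustes
alignment. The implementation is a direct `eigen()` construction because
these conventions are part of the contract; `stats::cmdscale` serves as an
independent cross-check in the test suite.

Because the coordinate columns are centred, the embedding's centroid is
the origin, and the animal with minimal norm — `central_animal()` — is the
one whose (squared) dissimilarities to the rest of the group are smallest
as seen by the retained dimensions: the group's most influential
individual.

K-means on the embedding uses best-of-50 random restarts under a fixed
seed, and the number of clusters is chosen by maximising the mean
silhouette width over $k \in \{2, \dots, \min(8, N-2)\}$ (ties to the
smaller $k$). Silhouette widths follow the cluster-package convention
that a singleton cluster has width 0. This convention matters:
it penalises partitions that isolate genuine loners as singletons, and is
one reason automatic $K$ selection on a rounded published matrix can
return a smaller $k$ than the original analysis chose. The alternative
convention (singleton width 1) was examined and rejected: it degenerates
towards selecting as many singletons as the range allows.

## The indegree–outdegree agglomerative hierarchy

For asymmetric closeness the affinity between an animal $j$ and a cluster
$C$ multiplies how close $C$ keeps to $j$ (indegree, a column average)
with how close $j$ keeps to $C$ (outdegree, a row average):

$$\deg_j^-(C) = \frac{1}{|C|}\sum_{m \in C} W_{mj}, \quad
  \deg_j^+(C) = \frac{1}{|C|}\sum_{m \in C} W_{jm}, \quad
  A_{j \to C} = \deg_j^-(C)\, \deg_j^+(C).$$

The directed cluster affinity sums this over the members of the other
cluster, $A_{C_b \to C_a} = \sum_{j \in C_b} \deg_j^-(C_a) \deg_j^+(C_a)$
(the reading consistent with the single-animal case), and the symmetric
affinity adds the two directions. The package reports the *average* form
(half the sum) by default so that two singletons have affinity exactly
$W_{ij} W_{ji}$ — the closeness product — matching the worked example's
first merge height; the raw sum is available and never changes merge
order.

Agglomeration merges the pair with the **minimum** affinity first: under
the small-is-close polarity the product affinity is smallest for bonded
pairs, and the dendrogram's height axis then reads as a dissimilarity. A
`polarity = "max"` flag preserves the literal maximum-affinity rule for
inverted rank conventions. This linkage is not reducible, so heights can
invert; inversions are counted in a message and rendered as computed.
Export goes through `as.hclust()` and `dendrogram_to_newick()` (branch
lengths are half the height differences, the standard hclust-to-phylo
convention).

## Spatial herd statistics

Independently of rank space, `herd_statistics()` clusters the raw
positions at every timeslot with K-means at a fixed $k$ (default 4, the
value used in the motivating deployment) and tallies:

* **alone counts** — timeslots in which an animal forms a singleton
  cluster ("alone" is exactly *singleton spatial cluster*; no distance
  threshold is added);
* **co-membership** — for each pair, timeslots spent in the same cluster
  (row sums mark central individuals);
* **size profile** — per animal, the proportion of time spent in clusters
  of each size;
* **connectors** — per cluster and snapshot, the member nearest the
  centroid.

$k$ is deliberately fixed rather than re-selected per timeslot: snapshots
are 0.1 s apart, per-slot silhouette analysis would dominate the cost, and
a fixed $k$ matches how the statistic is interpreted (a time budget over
comparable partitions). Each timeslot re-seeds K-means deterministically
(`seed + t`): reproducible, but not warm-started from the previous slot,
so consecutive clusterings are statistically independent given the
positions. When K-means would need more clusters than there are distinct
positions, one cluster per distinct location is returned ($K' < k$).

## The synthetic herd

No trajectory data accompany the published worked example, so the package
carries its own generator, `simulate_herd()`, used as the acceptance
harness for every pipeline stage. It is a discrete-time linear-attraction
(Ornstein–Uhlenbeck-like) scheme chosen for analysability, not a
behavioural model of cattle:

* the **leader** performs a bounded random walk whose step size is a small
  fraction (default 0.2) of the follower step noise — a leader that moved
  as fast as its followers' jitter would habitually sit at the *front* of
  the group (the herd lags by roughly $\sigma(1-a)/a$), making it
  peripheral rather than central in rank space;
* **followers** relax towards the leader with gain 0.3 per slot plus
  isotropic Gaussian noise (1 m per slot by default);
* **loners** are *episodic*: a two-state bout process (mean solo bout 400
  slots, mean social bout 600, stationary solo fraction 0.4) switches them
  between following the leader like everyone else and being repelled from
  the herd centroid with gain 0.2. Permanently repelled individuals would
  pin to the paddock walls, where two of them frequently become each
  other's nearest neighbour and masquerade as a bonded outcast pair in
  rank space; episodic solitude is also what repelled animals actually
  show in tracking data (alone for a third of the time, not always);
* **bonded subgroups** share a satellite attraction target offset a few
  metres from the leader (distinct directions per subgroup), so they graze
  together slightly apart from the main knot;
* deterministic drifts are capped at 5 m per slot (an explicit speed
  limit; centroid repulsion is otherwise exponentially unstable) and
  positions reflect off the paddock walls (clamping would pile animals on
  the boundary and distort rank rows).

Defaults: $N = 10$ (1 leader, 7 followers, 2 loners), $T = 5000$ slots,
150 × 50 m paddock, `dt` 0.1 s. `dt` is pure metadata — nothing downstream
uses wall-clock time.

What the generator does *not* emulate: behavioural state switching
(grazing/resting/walking), realistic speeds or gaits, inter-animal
collision avoidance, and measurement noise of a localisation system.
Passing recovery tests therefore demonstrate that the pipeline's
statistics identify planted structure through rank dynamics; they do not
validate any claim about real cattle.

`recovery_report()` checks four things on a simulated herd: the planted
leader is the embedding's central animal; planted loners come out as
silhouette singletons; planted loners hold the largest alone counts; and
planted subgroups complete their internal merges before any cross-subgroup
join. The checks are stochastic across seeds. The alone-count check is
essentially always satisfied at the default effect sizes; the
leader-centrality and loner-singleton checks are the marginal ones — the
leader's advantage lives partly in embedding dimensions beyond the two
retained, and the singleton-width-0 silhouette convention leans towards
merging the two loners when their embedding directions happen to align.

## Numerical and testing choices

* Row-sum identity $\sum_j W_{ij} = N(N-1)/2$ is asserted exactly (to
  floating-point addition) on computed matrices and within ±0.05 per row
  on the two-decimal published fixture.
* The MDS oracle draws random planar configurations ($N \le 12$) and
  requires Procrustes residuals below $10^{-6}$; the variation oracle
  recomputes reciprocal-rank variances by direct summation to $10^{-12}$;
  the hierarchy oracle replays every merge against a brute-force
  evaluation of the affinity definition to $10^{-10}$.
* Recovery statistics use 20 simulated herds at $T = 5000$; matrix-level
  unit tests use $T \le 200$ and $N \le 12$, sizes at which every oracle
  can be exhaustive (the spatial-inertia test enumerates all set
  partitions of 7 points into 3 blocks).

## Known limitations

* The published ten-cattle matrix is printed to two decimals; automatic
  silhouette selection on the rounded matrix picks $k = 2$, and the
  k-means optimum at $k = 4$ differs from the originally reported
  partition in the placement of one animal. The central-animal and
  first-merge results are insensitive to the rounding and reproduce
  exactly. `verify_table1()` therefore checks the structural identities
  and the stable headline results, not the full partition.
* With only two retained dimensions, strong repulsion structure (two
  loners) occupies both embedding axes and within-herd detail is
  projected out; leader identification from the embedding is noticeably
  noisier than from the full-rank Gram matrix.
* The affinity linkage offers no monotonicity guarantee; consumers of the
  Newick export should expect occasional negative branch lengths.
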