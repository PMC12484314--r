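---
title: "Classes of phylogenetic networks, leaf restriction, and dichotomy constants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classes of phylogenetic networks, leaf restriction, and dichotomy constants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netclasses)
```

## The objects

A rooted binary phylogenetic network on leaf set $\{1,\dots,n\}$ is a simple
directed acyclic graph whose non-leaf vertices are a root (in-degree 0,
out-degree 1, sitting atop an *ancestral root edge*), tree vertices
(in-degree 1, out-degree 2) or reticulations (in-degree 2, out-degree 1);
leaves have out-degree 0 and carry distinct positive integer labels.
Reticulations model hybridization and lateral gene transfer. Counting
degrees shows every such network has exactly $2n + 2r$ vertices, where $r$
is the number of reticulations — an identity the test suite checks on every
enumerated network. Networks are compared only up to isomorphism fixing
each leaf label; vertex ids are opaque.

Seven classes are implemented in `classify_network()`:

* **trees** — no reticulations;
* **tree-child** — every non-leaf vertex has a child that is a tree vertex
  or leaf;
* **normal** — tree-child without a *shortcut* (an edge $(u,v)$ admitting a
  second directed $u \to v$ path);
* **galled networks** — every reticulation is the bottom of exactly one
  *reticulation cycle* (a pair of internally vertex-disjoint directed paths
  from a common top tree vertex to a common bottom reticulation);
* **galled trees** — galled networks whose cycles are pairwise
  edge-disjoint (level-1 networks);
* **simplicial** — every reticulation's child is a leaf;
* **semi-simplicial** — every reticulation's child is a leaf or the root of
  a pendant tree.

### Two conventions the definitions leave open

**Height.** Height is not standardized for networks with a root edge. This
package counts edges on the longest root-to-leaf path *including* the
ancestral root edge, so the single-edge network root $\to$ leaf has height
1. One convention, used everywhere (in particular by the closed class
"height at most $k$"); no flag switches it.

**"Root of a tree" in the semi-simplicial definition.** We read it
literally: the reticulation's child $c$, together with everything below
$c$, must contain no reticulation, so the pendant sub-DAG at $c$ is a tree
(a leaf qualifies trivially; a reticulation child never does, since it
would be a reticulation in its own pendant sub-DAG). This reading makes the
expected inclusions — simplicial $\subseteq$ semi-simplicial $\subseteq$
galled — provable, and the package asserts them on the full enumeration
census. We document the reading rather than claim it is the only possible
one.

## Restriction and closure

`restrict_network(net, Y)` implements the induced subnetwork $N|Y$: keep
the vertices and edges on some root-to-$Y$ path, then iterate *merge
parallel edges, suppress (1,1) vertices* to a fixpoint. The fixpoint is
order-independent, but the sweep order is fixed (merge before suppress) so
runs are deterministic. The root is never suppressed: the ancestral root
edge survives every restriction. Restriction never increases the
reticulation count or the height, and it composes:
$(N|Y)|Z \simeq N|Z$ for $Z \subseteq Y$ — a property test, not an
assumption.

A class is *closed* if it is stable under relabelling and restriction and
has vertex counts bounded by a function of $n$. Because restriction
composes, a network $N$ lies in the maximal closed subclass of a class
$\mathcal{C}$ iff **every** restriction $N|Y$ lies in $\mathcal{C}$;
`in_maximal_closed()` checks all $2^n - 1$ subsets (guarded at $n \le 6$).
Two characterizations are verified exhaustively on the census
($n \le 4$, $r \le 2$):

* within tree-child networks, the maximal closed subclass is exactly the
  galled trees;
* within normal networks, it is exactly the trees.

Conversely, the classes listed as closed (galled trees, galled networks,
simplicial, semi-simplicial, bounded reticulation number, bounded height)
produce no closure counterexample anywhere on the census.

## Enumeration

`enumerate_trees()` uses the classic leaf-insertion recursion, generating
each labeled topology exactly once; completeness is certified against
$(2n-3)!!$ up to $n = 6$. Reticulate networks are generated from *tree
skeletons*: in any network with $r \le 2$ reticulations one can delete one
in-edge per reticulation, with pairwise distinct tree-vertex sources (the
root is never a reticulation parent, and a reticulation with two
reticulation parents needs $r \ge 3$), leaving a phylogenetic tree whose
edges carry the $2r$ deleted-edge endpoints as subdivision points.
Enumerating all trees, all ordered placements of role-labeled subdivision
points, and all acyclic simple completions therefore reaches every network
with $r \le 2$; duplicates are removed via a canonical code. For $r \ge 3$
the generator refuses to run rather than risk silent undercounting. The
strongest completeness evidence is arithmetic: the enumerated simplicial
tree-child counts match the closed form
$\binom{\ell}{k} (2\ell-2)!/(2^{\ell-1}(\ell-k-1)!)$ at every
$(\ell, k)$ the census covers, including $(3,1) = 18$ and $(2,1) = 2$.

Canonical codes use partition refinement (vertex kind, reachable leaf-label
set, iterated neighbour colours) followed by a lexicographic-minimum search
over the few surviving orderings; labeled trees take a direct
recursive-sorting path. The test suite compares code equality against a
brute-force permutation search over all internal-vertex bijections on the
$n \le 3$, $r \le 1$ census.

## Exact counting and the asymptotic registry

Counting sequences are exact big integers (`bigint`, base-$10^6$ limb
vectors with exact add/multiply/divide and a log method): double
factorials, Catalan numbers, the leaf-subset tree count
$|\mathcal{T}_n| = \sum_j \binom{n}{j} (2j-3)!!$ (computed by three
independent routes that must agree exactly), the simplicial tree-child
closed form, and arbitrary binomial convolutions
$\sum_j \binom{n}{j} a_j$.

`asym_registry()` stores the first-order growth forms
$C\,\ell^{\alpha}\gamma^{\ell}\ell^{m\ell} e^{s(3\ell)^{1/3}}$
for the counting sequences of each class, with the constants kept as exact
closed-form log-expressions (e.g. $\log C_{\mathrm{GN}} =
\tfrac12(\log 2 + \tfrac54) - \log 4$), evaluated in double precision.
That representation keeps every derived ratio accurate to full double
precision ($\sim 16$ significant digits), which comfortably covers the
10-digit checks in the test suite; $\ell$-dependent values are always
handled on the log scale. Order-bounds are represented too: the
$\Theta$-form for tree-child networks carries the stretched-exponential
Airy term ($s = a_1 \approx -2.3381074105$, the least-negative zero of
$\mathrm{Ai}$), and $\Omega$-forms with unspecified constants; neither kind
may enter a limit ratio, and the code enforces that.

The binomial convolution of a sequence on the tree scale
($m = 1$, $\gamma = 2/e$) is dominated by the top terms and acquires a
factor $\sqrt{e}$ (Laplace method); on the network scale ($m = 2$) the top
term dominates outright and the constant is unchanged.
`binomial_transfer()` implements exactly this dichotomy, and the law is
validated numerically: the exact big-integer convolution of the tree
sequence at $n = 500$ is within 0.3% of the transferred form. Limiting
class ratios then *emerge* from the registry:

```{r limits}
limit_ratio(binomial_transfer(asym_registry("SN")),
            binomial_transfer(asym_registry("GN")))   # exp(-3/8)
limit_ratio(binomial_transfer(asym_registry("SN")),
            binomial_transfer(asym_registry("SSN")))  # exp(-1/16)
limit_ratio(binomial_transfer(asym_registry("STC_le_k", k = 1)),
            binomial_transfer(asym_registry("TC_le_k", k = 1)))
```

No limit constant is hardcoded in the package; the duplicates live only in
tests, where they anchor the expected values.

## Monte-Carlo experiments

`sample_tree(n)` draws uniformly over the $(2n-3)!!$ topologies by
attaching leaf $j+1$ to one of the $2j-1$ edges uniformly;
`sample_from_union(n)` first draws the leaf-set size with probability
proportional to $\binom{n}{j}(2j-3)!!$. Uniformity is tested by chi-square
against the enumerated 15 topologies at $n = 4$ (15,000 draws, fixed seed,
$\alpha = 0.01$).

`containment_probability()` estimates the probability that a uniform tree
contains a *pendant* subtree of a given unlabeled shape. "Contains a
subtree of shape $\tau$" could also be read as embedded-minor containment;
the pendant reading is implemented and documented, and the qualitative
conclusion (containment probability increasing toward 1 in $n$) does not
depend on the choice. Estimates carry Wilson 95% intervals — preferred to
Wald near 1 — and the monotone-trend test allows interval overlap rather
than asserting strict numeric targets. Two short-circuits skip simulation:
the single-leaf shape is always contained, and every binary tree with at
least two leaves contains a cherry, so the cherry estimate is reported as
exactly 1 for $n \ge 2$ (under the union sampler this is conditional on
drawing at least two leaves; the single-leaf atom has probability
$n/|\mathcal{T}_n|$, below $10^{-3}$ already at $n = 8$ and vanishing with
$n$). Defaults: 2,000 replicates, seed 42; all stochastic output is
bit-reproducible given the seed.

## What the generated data do and do not show

All inputs here are exhaustively enumerated or uniformly sampled
*combinatorial* objects: every network on $[n]$ with $r$ reticulations
appears exactly once, with no branch lengths, no sequence data, and no
model of how real phylogenies are distributed. Passing tests therefore
certify the combinatorial claims (predicate correctness, closure behaviour,
counts, limit constants) — they say nothing about how often empirically
reconstructed networks fall into these classes. The asymptotic constants
are first-order only; second-order error terms are out of scope, so
convergence tests use empirical tolerances (1–2% at the problem sizes
below) rather than asserting the cited error rates.

## Problem sizes and budgets

Chosen once, as the package's own desk-scale defaults: the enumeration
census runs to $n \le 4$, $r \le 2$ (4,530 networks at the largest
stratum, about half a minute to generate and memoised per session);
closure scans check all $2^n - 1$ leaf subsets per network; exact
big-integer checks run at $n = 500$; the chi-square uses 15,000 draws; the
containment ladder uses $n \in \{8, 32, 128, 512\}$ with 2,000 replicates.
The acceptance script verifies the maximal-closed characterizations at
$n \le 3$, $r \le 2$, where each agreement fraction is computed in a few
seconds; the test suite carries the same check at the full census size.

## Known limitations

* The enumerator is certified complete only for $r \le 2$ (it errors above
  rather than undercounting); exact counting of tree-child or galled
  networks at large $n$ is deliberately out of scope.
* Non-binary and unrooted networks, branch lengths, and the orchard /
  tree-based predicates are not implemented.
* `in_maximal_closed()` is exponential in the leaf number by design
  (exhaustive subset scan) and guarded at $n \le 6$.
* Asymptotic evaluation of $\Theta$/$\Omega$ forms is meaningful only up
  to unspecified constants, and the package refuses to use them where a
  sharp constant is required.
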