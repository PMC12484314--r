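# netclasses

Combinatorics of rooted binary phylogenetic networks: class predicates,
leaf restriction and closure, exhaustive enumeration, and exact/asymptotic
counting.

## The problem

Phylogenetic networks generalize phylogenetic trees by allowing
reticulations — vertices of in-degree 2 that model hybridization and
lateral gene transfer. Many named classes of networks are studied
(tree-child, normal, galled networks, galled trees, simplicial and
semi-simplicial networks), and a property with direct biological meaning
separates them: is the class **closed** under restricting a network to a
subset of its leaves? Species go extinct or lack data, so an analysis that
drops taxa should not silently leave the class it assumed. Tree-child and
normal networks are *not* closed; galled networks, galled trees and
simplicial networks are.

When a class is not closed, how big is the largest closed subclass inside
it? For several classes the answer is a sharp dichotomy: every proper
closed subclass occupies a vanishing fraction of the class as the leaf
number grows ("tight" classes), while for others a proper closed subclass
retains a positive limiting share, with computable constants such as

$$
\lim_{n\to\infty}
\frac{|\mathcal{C}\cap\mathcal{N}_n|}{|\mathcal{N}_n|}
= e^{-3/8} \quad
(\mathcal{C} = \text{simplicial}, \ \mathcal{N} = \text{galled networks}).
$$

This package provides the machinery to verify those results at desk scale:
membership predicates for the seven classes, the restriction operator
$N|Y$ with closure testing, exhaustive enumeration of all labeled networks
for small leaf and reticulation numbers (the brute-force oracle for
everything else), exact big-integer counting sequences, and a registry of
first-order asymptotic forms
$C\,\ell^{\alpha}\gamma^{\ell}\ell^{m\ell}e^{s(3\ell)^{1/3}}$ with
Laplace-method transfer of binomial convolutions, from which the limit
constants above emerge by arithmetic rather than by being typed in.

## Worked example

```r
library(netclasses)

net <- read_enewick("((1,(2)#H1),(#H1,3));")  # one reticulation, child = leaf 2
net
#> <phylo_network> 3 leaves, 1 reticulation(s), height 4, 8 vertices
#>   ((1,(2)#H1),(3,#H1));

classify_network(net)
#>            tree      tree_child          normal  galled_network
#>           FALSE            TRUE            TRUE            TRUE
#>     galled_tree      simplicial semi_simplicial
#>            TRUE            TRUE            TRUE
```

The network is normal. Restrict it to leaves {1, 2} — the reticulation's
two paths collapse onto each other and a shortcut edge appears, so the
restriction is *not* normal (this is exactly why the normal class is not
closed):

```r
sub <- restrict_network(net, c(1, 2))
write_enewick(sub)
#> [1] "((2)#H1,(1,#H1));"
classify_network(sub)[c("tree_child", "normal")]
#> tree_child     normal
#>       TRUE      FALSE
```

Enumeration and exact counting agree — there are 21 networks with 3 leaves
and one reticulation, 18 of which are simplicial tree-child, matching the
closed form:

```r
length(enumerate_networks(3, 1))
#> [1] 21
as.numeric(stc_count(3, 1))
#> [1] 18
```

And the limiting share of simplicial networks among galled networks comes
out of the asymptotic registry:

```r
limit_ratio(binomial_transfer(asym_registry("SN")),
            binomial_transfer(asym_registry("GN")))
#> [1] 0.6872892788   # = exp(-3/8)
```

A command-line interface wrapping these functions is installed at
`system.file("cli", "netclasses.R", package = "netclasses")`, with
subcommands `classify`, `restrict`, `enumerate`, `count`, `limit`,
`closure-test` and `experiment`.

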