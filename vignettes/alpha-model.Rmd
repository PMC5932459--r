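---
title: "Exact probabilities under Ford's alpha-model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact probabilities under Ford's alpha-model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fordalpha)
```

## The model

Ford's alpha-model is a one-parameter family of probability distributions on
rooted bifurcating phylogenetic trees that interpolates between the two
classical null models of tree shape: the Yule (pure-birth) model at
$\alpha = 0$ and the uniform (PDA) model, under which all
$(2n-3)!!$ cladograms on $n$ leaves are equiprobable, at $\alpha = 1/2$.
Trees come in four flavours, connected by forgetful maps:

* a **cladogram** is a rooted tree in which every internal node has exactly
  two children and the leaves are bijectively labelled by a taxon set;
* a **tree shape** is a cladogram with the labels forgotten;
* the **ordered** variants additionally carry a significant left/right order
  at every internal node.

The model is defined by sequential leaf addition.  Starting from the cherry
on $\{1,2\}$, leaf $m$ (for $m = 3, \dots, n$) attaches to one of the
$2(m-1)-1$ positions of the current tree: each of the $m-1$ pendant arcs with
weight $1-\alpha$, and each of the $m-3$ internal arcs or the position above
the root with weight $\alpha$.  At leaf count $\ell$ the weights total
$\ell - \alpha$, so every step is a probability distribution for all
$\alpha \in [0,1]$.  Every cladogram on $\{1,\dots,n\}$ arises from exactly
one sequence of attachments, and the probability of a shape is the total mass
of the attachment histories producing it.

## The closed forms

All four distributions are products over the **numerical splits** of the
tree: each internal node $v$ contributes the pair $(a, b)$ of leaf counts of
its two child subtrees.  With
$$\Gamma_\alpha(n) = \prod_{i=1}^{n-1}(i - \alpha), \qquad
  \varphi_\alpha(a,b) = \tfrac{\alpha}{2}\binom{a+b}{a}
    + (1 - 2\alpha)\binom{a+b-2}{a-1}, \qquad
  q_\alpha(a,b) = \frac{\Gamma_\alpha(a)\,\Gamma_\alpha(b)}
                       {\Gamma_\alpha(a+b)}\varphi_\alpha(a,b),$$
the probabilities are

* cladogram: $P(T) = \dfrac{2^{n-1}}{n!\,\Gamma_\alpha(n)}
    \prod_{(a,b)\in NS(T)} \varphi_\alpha(a,b)$;
* tree shape with $k$ symmetric branch points (internal nodes whose child
  subtrees are isomorphic): $P^*(T^*) = \dfrac{2^{n-k-1}}{\Gamma_\alpha(n)}
    \prod \varphi_\alpha(a,b)$, i.e. $n!/2^k$ times the cladogram value;
* ordered shape: $P^{(o,*)} = \prod q_\alpha(a,b) = P^*/2^{n-1-k}$;
* ordered cladogram: $P^{(o)} = P/2^{n-1}$.

The kernel $\varphi_\alpha$ is pinned down by four laws that the test suite
enforces: the 2-leaf cladogram has probability 1; the closed form agrees with
the exhaustive growth-history enumeration; $\alpha = 1/2$ gives
$1/(2n-3)!!$ for every cladogram; and $\alpha = 0$ gives the Yule law
$2^{n-1}/n!\prod_v 1/(\kappa(v)-1)$.

```{r worked}
tt <- parse_newick("(((1,2),(3,4)),(((5,6),7),8));")
prob_cladogram(tt)          # symbolic, exactly reduced
prob_cladogram(tt, "1/2")   # the uniform value 1/135135
prob_yule(tt)               # 1/39690, the alpha = 0 value
```

## The published-formula comparator

The package deliberately ships a second, clearly marked implementation,
`prob_cladogram_ford_published()`, of the *original published* product
formula for cladogram probabilities, whose kernel doubles
$q_\alpha(a,b)$ whenever $a \neq b$.  That bookkeeping undercounts trees
containing an internal node whose children carry *equally many* leaves but
*differently shaped* subtrees.  The smallest such tree is the 8-leaf
cladogram above (a balanced 4-leaf tree joined to a 4-leaf caterpillar): the
published expression returns exactly half its true probability, and summed
over all 135135 cladograms on 8 leaves the published values fall short of 1
by exactly the mass of the 2520 relabelings of this tree that went missing.
On every cladogram with at most 7 leaves the two formulas agree.  The
comparator is never used by any other function.

```{r published}
prob_cladogram(tt)$fun == 2 * prob_cladogram_ford_published(tt)$fun
```

## Markov branching structure

The cladogram law satisfies
$P(T_m \star T_{n-m}) = \frac{2\,q_\alpha(m, n-m)}{\binom{n}{m}}
 P(T_m)P(T_{n-m})$ for root joins on disjoint label sets, and the ordered
shape law satisfies the cleaner
$P^{(o,*)}(T^* \star T'^*) = q_\alpha(m, n-m)\,P^{(o,*)}(T^*)P^{(o,*)}(T'^*)$.
No such recurrence can exist at the unordered shape level:
`demonstrate_no_shape_markov()` exhibits two distinct 6-leaf shapes with the
same number of symmetric branch points whose root joins force the two
incompatible factors $q_\alpha(6,6)$ and $2q_\alpha(6,6)$.

```{r markov}
demonstrate_no_shape_markov(6)
```

## Design choices

**Exact arithmetic.**  All headline quantities are exact rational identities
(probabilities such as $1/135135$ must come out bit-exactly), so nothing in
the main pipeline uses floating point.  The package implements its exact
layer directly: integers are carried in IEEE doubles, which represent
integers exactly up to $2^{53}$, and *every* arithmetic step is guarded so
that an operation whose result would reach $2^{53}$ raises an error rather
than rounding silently.  Within the enumeration range the model's exact
tables cover (cladograms to $n = 8$, shapes to $n = 10$) all intermediate
quantities stay orders of magnitude below the guard; far larger inputs fail
loudly, never wrongly.  Exact rationals, integer-coefficient polynomials in
$\alpha$ and canonically reduced rational functions are built on top.  Two
representational choices matter:

* A rational function is stored as a numerator/denominator pair of
  integer-coefficient polynomials with the polynomial gcd and any common
  integer content removed and a positive leading denominator coefficient.
  The representation is unique, so the "equals the closed form" assertions in
  the tests are structural identities, and evaluation at a fixed $\alpha$
  substitutes *after* reduction -- removable $0/0$ points (notably
  $\alpha = 1$, where $\Gamma_\alpha(2) = 0$) evaluate correctly, and a zero
  of the reduced denominator is a genuine pole and raises an error.
* Polynomial gcds are computed by locating rational roots (numerically via
  `polyroot()`, then *verified in exact arithmetic* before use) and dividing
  shared linear factors out.  Every denominator the model produces is a
  product of linear factors with small rational roots, so this is complete
  here, and it avoids the intermediate coefficient explosion of
  remainder-sequence gcds; a generic primitive-remainder-sequence fallback
  covers polynomials that do not split.

**Canonical forms.**  Unordered trees are stored with children sorted by
(leaf count, canonical shape encoding, smallest descendant label), so
structural equality is isomorphism and `write_newick()` is a canonical form.
The Newick dialect is deliberately minimal -- strictly binary, no branch
lengths, shapes written with empty leaf names -- and the parser reports
character positions on malformed input.

**Summation strategy.**  At a fixed rational $\alpha = p/q$ every cladogram
probability on $n$ leaves equals an integer divided by the fixed constant
$n!\,\Gamma_\alpha(n)\,q^{\,n-1}$ (in reduced form, a divisor of it), so
exact normalization sums accumulate through least-common-multiple addition
and never approach the overflow guard even over all 135135 trees.

**Sampling.**  `grow_cladogram()` draws each attachment in two stages --
first pendant-versus-internal by aggregate weight, then uniformly within the
class over a deterministic position ordering (pendant arcs by leaf label,
then internal arcs in traversal order, then the root position).  This is
equivalent to a flat cumulative-weight draw and reproducible for a given
seed.  `sample_from_model()` converts the grown chain into draws from the
model laws: taking the shape of a grown cladogram is exact for shapes, and
relabelling a grown shape by a uniform random permutation is exact for
cladograms (a shape with $k$ symmetric branch points spreads its mass evenly
over its $n!/2^k$ labelings).  $\alpha = 1$ is supported: pendant weights
vanish and attachments are uniform over the remaining $\ell - 1$ positions.

## What the tests do (and do not) show

The suite validates the implementation *within the exact enumeration range*:
worked symbolic examples at $n \le 8$; normalization of all four
distributions (exactly, at several rational $\alpha$ and symbolically);
agreement of the closed forms with the independent exhaustive growth-history
oracle (symbolically to $n = 6$--$7$, at rational $\alpha$ for $n = 8$,
where the 135135 histories are enumerated outright); the limit laws; the
Markov recurrences on all small pairs; and chi-square goodness of fit of the
seeded sampler ($n = 5$, $10^5$ draws, $\alpha \in \{0, 1/2\}$, significance
$10^{-4}$).  Problem sizes were chosen as the full range over which the
model's exact tables are defined ($n \le 8$ for cladograms); they are not
estimates or samples, so the exact checks are exhaustive rather than
statistical.  What none of this shows is anything about real phylogenies:
the generator *is* the model, so the tests validate the mathematics and the
code, not the biological adequacy of the alpha-model as a null distribution.

## Limitations

* Exact mode targets the enumeration range; very large trees trip the
  overflow guard (clearly, with an error).  Floating-point evaluation of the
  symbolic forms is available at any size that the polynomial construction
  itself supports.
* Multifurcating and unrooted trees, branch lengths, and taxon-name handling
  beyond uniqueness are out of scope, as is estimating $\alpha$ from data.
* The growth-history enumerator is exponential by nature ($ (2n-3)!!$
  histories) and is capped at $n = 8$.
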