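# fordalpha

Exact probabilities of rooted bifurcating phylogenetic trees under Ford's
alpha-model.

Tree-shape statistics need null models, and the two classical ones — the Yule
(pure-birth) model and the uniform/PDA model, under which all `(2n-3)!!`
cladograms on `n` leaves are equiprobable — are the endpoints of Ford's
one-parameter alpha-model (`alpha = 0` and `alpha = 1/2` respectively), a
sequential leaf-addition process in which a new leaf attaches to a pendant arc
with weight `1 - alpha` and to an internal arc or above the root with weight
`alpha`.  This package is an exact toolkit for that model, aimed at anyone who
needs the probability of a concrete tree (or of all trees of a given size) as
an exact number or as a function of alpha: the corrected closed-form
probabilities of the four kinds of trees, the growth process itself, small-n
enumeration, and a comparator reproducing the factor-of-2 error in the
originally published product formula.

With `Gamma_a(n) = prod_{i=1..n-1} (i - a)` and the split kernel

    phi_a(a,b) = (a/2) * C(a+b, a) + (1 - 2a) * C(a+b-2, a-1)
    q_a(a,b)   = Gamma_a(a) Gamma_a(b) / Gamma_a(a+b) * phi_a(a,b)

the probability of a cladogram `T` on `n` leaves is the product over its
numerical splits (the leaf-count pairs `(a,b)` at each internal node)

    P(T) = 2^(n-1) / (n! Gamma_a(n)) * prod_{(a,b) in NS(T)} phi_a(a,b)

and the shape, ordered-shape and ordered-cladogram laws follow by the exact
transport factors `n!/2^k`, `2^(n-1-k)` and `2^(n-1)` (`k` = number of
symmetric branch points).  Everything is computed in exact integer/rational
arithmetic; symbolic results are canonically reduced rational functions of
alpha, so equality checks are structural.

## Worked example

The smallest cladogram on which the originally published formula goes wrong
has 8 leaves — a balanced 4-leaf tree joined with a 4-leaf caterpillar:

```r
library(fordalpha)
tt <- parse_newick("(((1,2),(3,4)),(((5,6),7),8));")

prob_cladogram(tt)
#> P = (1-a)^2*(2-a)/(126*(3-a)*(5-a)*(6-a)*(7-a))

prob_cladogram(tt, "1/2")$value   # the uniform-model value
#> 1/135135
prob_yule(tt)                     # the alpha = 0 value
#> 1/39690

prob_cladogram_ford_published(tt)
#> P = (1-a)^2*(2-a)/(252*(3-a)*(5-a)*(6-a)*(7-a))
```

The published value is exactly half the true one: the tree's root joins two
subtrees with equal leaf counts but different shapes, the case the published
kernel's doubling rule misses.  Because of it the published probabilities on
8 leaves no longer sum to 1, while the corrected ones do — exactly:

```r
total <- rational(0)
for_each_cladogram(8, function(t) {
  total <<- total + prob_cladogram(t, "1/4", symbolic = FALSE)$value
})
total
#> 1
```

An independent route to the same number runs the growth process exhaustively:

```r
h <- enumerate_histories(8, "1/2")          # all 135135 attachment histories
mass <- history_mass(h, shape_of(tt))       # P* of the shape: 8/429
mass / rational(2520)                       # / (8!/2^4) labelings
#> 1/135135
```

A command-line interface is installed as `exec/fordalpha` (`prob`,
`enumerate`, `sample`, `verify`), e.g.

```sh
fordalpha prob --tree '(((1,2),(3,4)),(((5,6),7),8));' --alpha 1/2
fordalpha enumerate --n 5 --level shapes
fordalpha sample --n 8 --alpha 1/3 --count 10 --seed 7
```

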