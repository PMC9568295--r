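# topodnn

Degree-based topological indices for arbitrary undirected simple graphs and,
in closed form, for the layered complete-bipartite graph family
`DNN(M; N1..Nr; N)` that models fully connected deep neural networks.

Topological indices are single-number graph invariants used throughout
chemical graph theory and QSPR/QSAR modeling, where they correlate with
physicochemical properties (boiling point, molar refractivity, enthalpy of
vaporization, ...). The degree-based family has the form

    I(G) = Σ_{uv ∈ E} f(d_u, d_v)   or   I(G) = Π_{uv ∈ E} f(d_u, d_v),

a sum or product over edges of a symmetric function of the endpoint degrees.
`topodnn` implements twelve classical members:

| name | definition | | name | definition |
|---|---|---|---|---|
| `randic` | χ = Σ (d_u d_v)^(−1/2) | | `hyper_zagreb` | HM = Σ (d_u+d_v)² |
| `general_randic` | R_α = Σ (d_u d_v)^α | | `abc` | Σ √((d_u+d_v−2)/(d_u d_v)) |
| `zagreb1` | M₁ = Σ (d_u+d_v) | | `sci` | Σ (d_u+d_v)^(−1/2) |
| `zagreb2` | M₂ = Σ d_u d_v | | `ga` | Σ 2√(d_u d_v)/(d_u+d_v) |
| `mult_zagreb1` | PM₁ = Π (d_u+d_v) | | `forgotten` | F = Σ (d_u²+d_v²) |
| `mult_zagreb2` | PM₂ = Π d_u d_v | | `azi` | Σ (d_u d_v/(d_u+d_v−2))³ |

For the layered family the package evaluates these **without building the
graph**: all nodes of layer *i* share the degree N₍ᵢ₋₁₎+N₍ᵢ₊₁₎ (with N₀ = M,
N₍ᵣ₊₁₎ = N), so the edges between consecutive layers collapse into at most
r+1 degree classes — the *edge-partition method*. A brute-force evaluator on
the explicitly constructed graph serves as an independent oracle, and
`verify_closed_forms()` checks the two routes against each other on random
architectures, exactly for integer-valued indices. Multiplicative Zagreb
values are kept as exact arbitrary-precision integers with a log10 companion.

## Worked example

The five-hidden-layer architecture `DNN(4; 4,5,6,4,3; 3)`:

```r
library(topodnn)
spec <- parse_architecture("4,4,5,6,4,3,3")
spec
#> DNN(4; 4,5,6,4,3; 3): 5 hidden layer(s), 29 nodes, 111 edges
closed_form_partition(spec)
#> edge partition: 5 class(es), 111 edge(s)
#>   d1 d2 count
#> 1  3  7     9
#> 2  4  9    16
#> 3  7  9    12
#> 4  9  9    24
#> 5  9 10    50
```

The 111 edges fall into five degree classes (the 4·5 and 5·6 inter-layer
blocks coincide on the pair (9, 10) and merge). Evaluating over the classes:

```r
index_report(spec, indices = c("zagreb1", "randic", "mult_zagreb2"))
#>          index alpha         value exact                 log10
#> 1      zagreb1    NA  1.872000e+03  1872                    NA
#> 2       randic    NA  1.407962e+01  <NA>                    NA
#> 3 mult_zagreb2    NA 8.103380e+201  8103...(202 digits)  201.9086662
```

M₁ = 1872 matches the independent node-side oracle Σ_v d_v² on the
constructed graph; PM₂ ≈ 10^201.9 is why product indices carry an exact
big-integer and a log10 field rather than a bare double. The same numbers
come from the CLI:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","topodnn.R",package="topodnn"))')" \
    dnn --arch 4,4,5,6,4,3,3 --indices zagreb1,randic
#> index  alpha  value             exact  log10
#> zagreb1       1872              1872
#> randic        14.0796150044415
```

Subcommands: `dnn` (closed-form evaluation of an architecture), `graph`
(brute force on an edge-list TSV: two tab-separated labels per line, `#`
comments), `verify` (closed form vs. oracle on random architectures, exits
nonzero on any mismatch) and `sweep` (index growth with depth).

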