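---
title: "Degree-based topological indices and the edge-partition method for layered networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Degree-based topological indices and the edge-partition method for layered networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topodnn)
```

## The model

A degree-based topological index is a graph invariant of the form

$$ I(G) = \sum_{uv \in E(G)} f(d_u, d_v)
   \quad\text{or}\quad
   I(G) = \prod_{uv \in E(G)} f(d_u, d_v), $$

a sum or product over the edges of a symmetric function of the two endpoint
degrees. Such invariants originate in chemical graph theory, where they serve
as molecular descriptors in QSPR/QSAR work: the Randić connectivity index
correlates with boiling points of alkanes, the Zagreb indices arose in
$\pi$-electron energy calculations, and the ABC and GA indices are in routine
use as structure descriptors. `topodnn` implements the twelve classical
members listed by `index_catalog()`:

```{r catalog}
index_catalog()
```

The same machinery applies to any undirected simple graph, but the package's
focus is the layered graph family behind fully connected feed-forward neural
networks: `DNN(M; N1..Nr; N)` has an input layer of $M$ nodes, $r \ge 1$
hidden layers of widths $N_1, \dots, N_r$, an output layer of $N$ nodes, and
complete bipartite wiring between consecutive layers only. Because every node
of a layer is adjacent to all nodes of the two neighboring layers, all nodes
of layer $i$ share the degree $N_{i-1} + N_{i+1}$ under the boundary
convention $N_0 = M$, $N_{r+1} = N$ (and width zero beyond the input and
output). The input layer has degree $N_1$ and the output layer degree $N_r$.

## The edge-partition method

Since an index term depends only on the endpoint degrees, edges can be
grouped into classes of equal degree pairs and each class evaluated once:

$$ I(G) = \sum_{\text{classes } (a,b)} m_{(a,b)} \, f(a, b), $$

with $m_{(a,b)}$ the class count. For the layered family the partition is
available in closed form from the widths alone: the $N_i N_{i+1}$ edges
between layers $i$ and $i+1$ form a single class. That reduces an
$O(|E|)$ computation to $O(r)$ and is exactly what
`closed_form_partition()` and `closed_form_index()` implement:

```{r partition}
spec <- dnn_spec(4, c(4, 5, 6, 4, 3), 3)  # 29 nodes, 111 edges
closed_form_partition(spec)
closed_form_index(spec, "zagreb1")
```

Degree pairs are canonicalized as $(\min, \max)$ and coincident classes from
different layer gaps are merged (for the architecture above, the gaps 1–2 and
2–3 both produce the pair $(9, 10)$). Merging changes no index value because
every term is symmetric; it makes the partition a well-defined multiset map.

## Verification design

The package deliberately carries two independent routes to every value:

* the **oracle** route, `evaluate_on_graph()`, which materializes the graph
  with `build_dnn_graph()` and sums over individual edges; and
* the **closed-form** route, `closed_form_index()`, which never builds a
  graph and works purely with width arithmetic.

`verify_closed_forms()` compares the two on seeded random architectures
(depth uniform on $1..8$, widths uniform on $1..12$ by default — small widths
deliberately hit the degenerate shapes where derivations slip: width-1
layers, coinciding degree classes, $r \le 2$ where the deep-form expressions
reference undefined widths). Integer-valued indices must agree *exactly*, as
arbitrary-precision integers where applicable; real-valued ones to $10^{-9}$
relative. A third route, `theorem_literal_index()`, transcribes the published
deep-architecture ($r \ge 3$) closed-form expressions verbatim — five
boundary terms plus an interior sum over $i = 2..r-2$ — and is itself checked
against the partition evaluator. The test suite runs these sweeps at 200
architectures, which takes seconds.

```{r verify}
verify_closed_forms(trials = 25, seed = 1)
```

## Numerical choices

**Exact multiplicative indices.** $PM_1 = \prod (d_u + d_v)$ and
$PM_2 = \prod d_u d_v$ explode: even the modest 29-node example above has
$PM_2 \approx 10^{202}$. The package therefore carries product indices as
exact arbitrary-precision integers (a small internal base-$10^4$ bignum
layer) together with a `log10` companion computed in log space; the `value`
field degrades gracefully to `Inf` past the double range. Exact integers are
serialized as *strings* in JSON so downstream consumers do not round them
silently through doubles.

**Domain edge cases.** The ABC term is $0$ on an edge joining two degree-1
nodes (zero numerator under the root); the AZI term is undefined there (zero
denominator) and is rejected with an error — no valid layered architecture
can produce such an edge, since every edge touches a hidden-adjacent node of
degree $\ge 2$, but arbitrary input graphs can. An edgeless graph evaluates
to the aggregation identity ($0$ for sums, $1$ for products) with a warning.

**Resolved ambiguities.** Two definitional choices were genuinely open and
are fixed as follows. First, the source material prints identical formulas
for both multiplicative Zagreb indices; the package follows the unambiguous
product-expansion forms, $PM_1$ over degree *sums* and $PM_2$ over degree
*products*. Second, the Randić index is sometimes quoted with exponent
$+1/2$ rather than the classical $-1/2$; here `randic` is the classical
$\chi = \sum (d_u d_v)^{-1/2}$, while `general_randic` takes any real
$\alpha$ (so both conventions are one call away), and the literal
deep-architecture evaluator provides the $+1/2$ form as `randic_half`. The
published deep-form expressions for ABC, GA and AZI contain evident
typographical damage (stray "$-2$" factors); those indices are computed from
the partition with the standard definitions rather than transcribed, and the
literal cross-check is restricted to the Zagreb/Randić family where the
printed forms are sound.

## What the generators emulate — and what they do not

`random_dnn_specs()` draws architectures from the regime described above;
`random_graph()` draws Erdős–Rényi-style graphs ($n \le 30$, edge
probability $0.15$–$0.9$ in the tests) used for the identity suite:
$HM = F + 2M_2$, $M_1 = \sum_v d_v^2$, $PM_2 = \prod_v d_v^{d_v}$,
$R_0 = |E|$, $R_{-1/2} = \chi$, and $GA \le |E|$ with equality exactly on
degree-regular edges. These are algebraic identities, so passing them on
synthetic graphs establishes correctness of the evaluators themselves; no
claim about real molecular graphs or about trained networks is implied.
In particular the layered family models connectivity only — weights,
activations, and anything a network *learns* are outside the graph
abstraction, and index values say nothing about accuracy.

## Growth with depth

For the uniform-width family `DNN(k; k,...,k; k)`, appending one hidden
layer adds $k^2$ edges of degree class $(2k, 2k)$ and alters no existing
degree, so every sum-aggregated index with positive terms is strictly
increasing in depth ($M_1$ grows by exactly $4k^3$ per layer):

```{r growth}
growth_profile(2, 5, indices = c("zagreb1", "randic"))
```

## Limitations

* Only degree-based indices: distance-based invariants (Wiener, Harary, PI)
  and spectral invariants (graph energy, Estrada, Kirchhoff) are out of
  scope.
* Graphs are undirected, simple and unweighted; multigraphs and directed
  wirings (and hence convolutional or sparse layer patterns) are not
  representable.
* Molecular file formats (SMILES/SDF) are not parsed; any tool that can emit
  a two-column edge list (e.g. via igraph or RDKit) can feed the
  `graph` subcommand of the CLI.
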