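# logimodel

Logical (Boolean and multivalued) models are a standard formalism for
cellular networks: each component takes a discrete activity level and has one
update rule over its regulators. As curated models grow to hundreds of
components, full dynamical exploration becomes intractable and rule curation
becomes error-prone. `logimodel` is for modellers who build such networks and
need two things that scale with model size:

* **Value propagation (percolation).** A biological context — persistent
  receptor activation, a knockout, an ectopic expression — is a set of
  *clamps*: components fixed at constant levels, overriding their own rules.
  Clamped values are inserted into downstream rules; every rule that
  simplifies to a constant freezes its component, whose value propagates
  further, until quiescence. For a model $M=(V,f)$ and clamp set $P$, the
  result splits $V$ into frozen components (forced to a level by $P$ alone)
  and free ones (retaining a residual rule). The frozen assignment is a trap
  space of the clamped model, and every stable state of the clamped model
  agrees with it. Differential comparison of two clamp sets classifies each
  component (frozen OFF/ON under both, under one only, free) and exports the
  classification onto the regulatory graph.
* **Specification-based verification.** Units of biological knowledge become
  machine-checkable *specifications*: a context plus expected component
  activities, checked against the stable states ($f(x)=x$), the minimal trap
  spaces (subspaces closed under any updating), or the propagation result of
  the (sub)model. Suites of specifications (YAML) run like unit tests, with
  pass / fail / vacuous / error statuses, so every rule change is re-checked
  against the entire knowledge base. Sub-model extraction
  ($S = C \cup \bigcup_{c\in C} R(c)$, boundary regulators turned into free
  inputs) lets fragmentary knowledge be tested locally.

Models are read and written as bnet-style rule tables (`target, expression`
lines; Boolean) or a native JSON dialect (multivalued, threshold atoms
`X:2`). Stable states and minimal trap spaces are enumerated by
propagation-pruned search, validated in the test suite against exhaustive
brute-force oracles on hundreds of seeded random models.

## Worked example

A six-node toy: four inputs `A`, `B`, `C`, `F` and two core nodes
`D = A | B | C`, `E = D & !F`. Clamping the input `C` on:

```r
library(logimodel)
m <- toy_model("figure3")
propagate(m, c(C = 1))
#> <propagation_result> 1 clamp(s); 2 frozen, 1 free (non-input)
#> # A tibble: 6 × 4
#>   component status level residual
#>   <chr>     <chr>  <int> <chr>
#> 1 A         input     NA <NA>
#> 2 B         input     NA <NA>
#> 3 C         frozen     1 <NA>
#> 4 F         input     NA <NA>
#> 5 D         frozen     1 <NA>
#> 6 E         free      NA !F
```

`C = 1` activates `D` independently of the other inputs, while `E` becomes
completely dependent on `F` (residual `!F`). Comparing two alternative
clamps, `C = 1` versus `F = 1`, yields the frozen-inactive / frozen-active /
free tally per condition and for their intersection (counted over non-input
components; the intersection column counts components frozen at the same
level under both):

```r
cmp <- compare_propagations(propagate(m, c(C = 1)), propagate(m, c(F = 1)))
comparison_table(cmp)
#> # A tibble: 3 × 4
#>   impact              A     B intersection
#>   <chr>           <int> <int>        <int>
#> 1 frozen_inactive     0     1            0
#> 2 frozen_active       1     0            0
#> 3 free                1     1            0
```

(`C = 1` freezes `D` on; `F = 1` freezes `E` off; nothing is frozen under
both.) `export_annotated_graph(cmp, "fig.dot")` writes the colour-coded
regulatory graph; `autoplot(cmp)` plots the category counts.

Verification catches bad rules. With the generic rule
`Calcium_ER = SERCA & !IP3R1` for the ER calcium reservoir, no stable state
can have a full reservoir with idle pumps — the shipped suite fails exactly
there, and passes on the corrected rule
`(SERCA | Calcium_ER) & !IP3R1`:

```r
suite <- load_suite(system.file("extdata", "calcium_suite.yaml", package = "logimodel"))
run_suite(toy_model("calcium_default"), suite)
#> <verification_report> 'calcium_module': 2 pass, 1 fail, 0 vacuous, 0 error
#>   [fail]     rest_full_reservoir_without_pumping
#>              none of the 2 solution(s) satisfies all expectations
#>   [pass]     no_ip3r_stimulation_calcium_in_er
#>   [pass]     no_ip3r_stimulation_calcium_in_cytoplasm
run_suite(toy_model("calcium_corrected"), suite)
#> <verification_report> 'calcium_module': 3 pass, 0 fail, 0 vacuous, 0 error
```

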