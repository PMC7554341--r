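---
title: "Value propagation and specification-based verification of logical models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Value propagation and specification-based verification of logical models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(logimodel)
```

## The modelling framework

A logical model is a pair $M = (V, f)$: a set of components $V$, each taking a
discrete activity level in $0..m_c$ ($m_c = 1$ for Boolean components,
$m_c = 2$ for ternary ones), and one update function $f_c$ per component. An
update function is an ordered list of cases $(\varphi_i, t_i)$: in a state
$x$, the target level of $c$ is the $t_i$ of the first condition $\varphi_i$
satisfied by $x$, and $0$ when none is. Conditions are built from threshold
atoms ($X{:}k$ is true iff the level of $X$ is at least $k$), negation,
conjunction and disjunction. The regulators $R(c)$ are the components that
appear in the atoms of $f_c$.

Dynamics are stepwise: an unstable component moves one level per update
toward its target. Synchronous updating moves all unstable components at
once; asynchronous updating moves one at a time. Two kinds of asymptotic
objects matter here:

* a **stable state** (fixed point) satisfies $f(x) = x$;
* a **trap space** is a subspace (hypercube) of the state space that no
  trajectory can leave, under any updating mode. Minimal trap spaces
  approximate the attractors, including cyclic ones; every stable state is a
  minimal trap space with no free component. Reachability of these objects is
  deliberately out of scope.

A component whose rule is exactly itself (`A, A`) is an **input**: an
environmental degree of freedom rather than a regulated node. Inputs are
reported separately in every tally.

## Value propagation

A cellular context — persistent receptor activation, a knockout, an ectopic
expression — is formalised as a set of *clamps*: components fixed at constant
levels, overriding their own rules (mutant semantics). `propagate()` inserts
each clamped value into the rules of its targets, simplifies, freezes every
rule that becomes constant, and iterates until quiescence:

```{r}
m <- toy_model("figure3")
propagate(m, c(C = 1))
```

Clamping the input `C` freezes the core node `D` on regardless of the other
inputs, and leaves `E` with the residual rule `!F`: `E` has become completely
dependent on `F`.

Two choices deserve emphasis:

* **Constancy is decided semantically, not syntactically.** A folded rule is
  declared constant iff it evaluates to a single level over *every*
  combination of its remaining free regulators, by exhaustive enumeration.
  The cost is bounded by the rule's in-degree, which is small in curated
  models; in exchange the test is complete, so e.g. `A | !A` freezes where
  algebraic rewriting might miss it. Residuals are reported constant-folded
  but not minimised further — only constancy matters for freezing.
* **The fixpoint is order-independent.** Freezing is monotone (a rule
  constant under an assignment stays constant, with the same value, under any
  extension), so the worklist order cannot change the result. `propagate()`
  exposes a `worklist_order` seed purely to make this confluence property
  testable; the test suite checks ten scrambled orders per model, and
  idempotence (`propagate(m, frozen)` returns the frozen set unchanged).

The frozen assignment is always a trap space of the clamped model, and every
stable state of the clamped model agrees with it on the frozen components;
both facts are verified against exhaustive oracles in the test suite. This is
why propagation is informative: whatever the asymptotic behaviour, the frozen
components have lost their degrees of freedom.

Unclamped inputs are never frozen (their rule is the identity) and are
excluded from `tally_propagation()`. This is what makes frozen/free counts
comparable across perturbations of the same model.

### Differential comparison

`compare_propagations()` classifies every component by how two alternative
perturbations freeze it: OFF or ON under both, under only one condition,
conflicting, free under both, or input. `comparison_table()` summarises the
classification as the 3×3 matrix (frozen-inactive / frozen-active / free ×
condition A / condition B / intersection); the intersection column counts
components frozen at the *same* level under both conditions, so its sum can
be smaller than the other two. `export_annotated_graph()` writes the
classification onto the regulatory graph as a DOT or GraphML document, and
`autoplot()` gives a category bar chart. This is the workflow for contrasting
two receptor activations on one model — e.g. persistent CTLA4 versus PD-1
checkpoint signalling on a curated 216-node T cell activation model, where
the PD-1 frozen set turns out to be contained in the CTLA4 one. For ternary receptors the clamp level matters; the command-line
`compare` defaults to the maximal level but lets the user choose.

## Sub-model extraction

Biological knowledge usually covers a handful of components, not the whole
network. `extract_submodel(model, C)` builds $M' = (S, f')$ with
$S = C \cup \bigcup_{c \in C} R(c)$; a component of $S$ keeps its rule when
all its regulators are in $S$ and otherwise becomes an external input. The
boundary components are made *inputs* rather than constants so the
verification harness can explore every boundary valuation. Exactly one
regulator layer is added — no recursion — and re-extracting the same
selection is the identity, which the tests check. Transitive-closure
extraction and variable-elimination reduction are non-goals.

## Stable states and minimal trap spaces

`stable_states()` enumerates fixed points by depth-first search over
component assignments, reusing propagation as a constraint propagator: each
decision percolates, and a branch dies as soon as a percolated constant
contradicts a decided value. `minimal_trap_spaces()` branches over
fixing-or-freeing each component, using the closure condition "each fixed
component's rule is constantly equal to its fixed value within the subspace"
(the same complete constancy test as propagation), then filters to the
minimal closed subspaces. Both are exact; both are compared against
brute-force oracles — full state enumeration and full subspace enumeration
with a successor-based closure check — on hundreds of seeded random models in
the test suite.

Multivalued models are handled natively: the closure condition transfers
verbatim to stepwise multivalued dynamics (a fixed component must have its
target constantly equal to its fixed level, otherwise some state steps off
the hypercube), so no encoding detour is needed. A threshold-indicator
Boolean encoding is nevertheless provided (`booleanize()` /
`debooleanize()`), with indicator $b_k$ on iff the level is at least $k$;
states violating $b_{k+1} \Rightarrow b_k$ are inadmissible and are dropped
when decoding. Stable states of the encoding, restricted to admissible
states, correspond one-to-one to multivalued stable states, which the tests
verify by brute force on random multivalued models.

These algorithms use no external solver. That is a deliberate trade-off: the
package's analyses of large models rest on propagation (polynomial per
freeze), while exact attractor enumeration is reserved for desk-scale
(sub)models where the exhaustive oracles can confirm it. Published
constraint-solver pipelines are the right tool above that scale;
output-for-output parity with any of them is not a goal.

## The verification harness

A *specification* pairs a context (clamps: stimulation conditions and
perturbations are expressed identically) with expected component activities,
and names the oracle that produces the observed values:

* `stable_states` — solutions are total states;
* `trap_spaces` — solutions are the minimal trap spaces of the clamped
  model; a component left free by a trap space satisfies no constraint;
* `propagation` — the single frozen assignment; a constraint on a free
  component fails as `unconstrained`.

The default oracle is `trap_spaces` with quantifier `all`: trap spaces also
cover cyclic behaviour, and "all" is the natural reading of a biological
assertion ("under no stimulation the cell is quiescent"). `exists` asks for a
witness instead. "Active" means level ≥ 1 — the natural reading for
multivalued components — and exact levels can be demanded with `level=k`.
When a case's context admits *no* solution under `all`, the status is
**vacuous**, not pass: a context without attractors should alert the
modeller, never silently satisfy a suite. Cases run independently, so one
error (e.g. a renamed component) cannot mask the others.

Suites are YAML documents (`load_suite()`), with unknown fields rejected so
that typos fail loudly; `run_suite()` returns a report with `tidy()`,
`glance()`, `autoplot()` and a JSON serialisation whose exit-code convention
(`verify` CLI: 0 iff no fail/error) slots into any continuous-testing setup.
Since specifications are plain R objects, a suite can equally be transposed
into native `testthat` blocks; the YAML form is canonical.

The shipped example reproduces a rule-refinement episode from the modelling
of calcium handling at the endoplasmic reticulum. With the generic rule
`Calcium_ER = SERCA & !IP3R1` ("filled when the pumps are on and the channel
closed"), no stable state has a full reservoir with idle pumps — biologically
wrong, and caught by a one-line specification. The corrected rule
`(SERCA | Calcium_ER) & !IP3R1` lets a full reservoir persist whenever the
channel stays closed:

```{r}
spec <- specification("rest_full_reservoir_without_pumping",
  context = c(IP3R_stim = 0), oracle = "stable_states", quantifier = "exists",
  expect = c(Calcium_ER = "active", SERCA = "inactive")
)
run_case(toy_model("calcium_default"), spec)$status
run_case(toy_model("calcium_corrected"), spec)$status
```

The exact corrected rule text is a reconstruction from the described
behaviour, as is the six-node worked example; both are labelled as such in
`?toy_model`.

## The random-model generator

Property tests and oracle comparisons run on models from `random_model()`,
which emulates curated rule tables at desk scale: named components, the first
`n_inputs` of them inputs, every other rule a random expression tree over at
most `max_in_degree` distinct regulators (default 2, matching the sparse
in-degrees of curated networks), AND chosen over OR with probability
`expression_bias` (default 0.5), literals negated with probability
`negation_prob` (default 0.25, activation being more common than inhibition
in curated signalling rules). Multivalued components give each case a
read-once condition over its own disjoint regulator group, which makes every
case reachable by construction, so generated models always pass
`validate_model()`. Rules are trees, not random truth tables, so generated
models stay readable in bnet form.

What the generator does *not* emulate: scale-free topology, autoregulation
patterns, or the long feedback cycles of real signalling networks. Passing
the oracle-equivalence suites therefore certifies the *algorithms* on the
full space of small rule structures, not any biological fidelity of the
ensembles.

## Numerical and interface choices

* **Grammar**: `!` > `&` > `|`, parentheses allowed, `#` comments,
  case-sensitive identifiers; `target, expression` lines for Boolean models.
  Multivalued models use the JSON dialect only — bnet is Boolean by
  construction. Writing then parsing reproduces the model tree exactly
  (same-kind nested connectives are re-parenthesised to keep the round trip
  structural, not just semantic).
* **Determinism**: stable states and trap spaces are emitted in lexicographic
  order by component declaration; the generator isolates its RNG from the
  global stream; every stochastic test fixes its seeds.
* **Degenerate inputs**: empty clamp sets are legal (constant rules still
  percolate); conflicting duplicate clamps are an error; the empty
  expectation map can pass or be vacuous but never fail; an empty selection
  for sub-model extraction is an error.
* **Exhaustion caps**: `is_trap_space()` refuses subspaces above `2^20`
  states by default — it is an oracle for desk-scale models, not an analysis
  tool.
* **Problem sizes in the shipped tests**: oracle equivalence uses 200 random
  models with up to 12 components for stable states, 100 with up to 8 for
  minimal trap spaces (full `3^n` subspace enumeration on the oracle side),
  100 with up to 10 for percolation soundness, and 50 models × 10 worklist
  permutations for confluence. These sizes keep every oracle exact while the
  whole suite runs in a few minutes on one CPU.

## Limitations

* Attractor *reachability*, temporal-logic properties and stochastic
  simulation are out of scope by design; trap spaces only approximate complex
  attractors.
* Exact attractor enumeration is exponential and meant for sub-models;
  analyses of models with hundreds of components should rely on propagation.
* GINML/SBML-qual are not parsed; externally published models must be
  converted to a rule table (bnet or the JSON dialect) first.
* The full-scale application — contrasting checkpoint receptor clamps on a
  curated 216-node T cell model — requires that model as an external input;
  the package ships only desk-scale fixtures, so such tallies are produced
  with the `compare` command on a user-supplied rule table, not recomputed
  anywhere in the package itself.
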