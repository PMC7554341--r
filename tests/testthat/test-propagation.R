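# Value propagation: rule simplification, percolation fixpoint, tallies,
# differential comparison and graph export.

test_that("simplify_under folds assigned atoms and decides constancy completely", {
  m <- toy_model("figure3")
  expect_equal(simplify_under(m, "D", c(C = 1)), list(kind = "constant", level = 1L))

  r <- simplify_under(m, "E", c(D = 1))
  expect_equal(r$kind, "residual")
  expect_equal(logimodel:::deparse_expr(r$fn$cases[[1]]$cond), "!F")

  m2 <- parse_model("A, A\nB, B\nX, A & !B")
  expect_equal(simplify_under(m2, "X", c(B = 1)), list(kind = "constant", level = 0L))

  # constancy decided semantically, not syntactically: A | !A is constant 1
  m3 <- parse_model("A, A\nT, A | !A")
  expect_equal(simplify_under(m3, "T", c()), list(kind = "constant", level = 1L))

  expect_error(simplify_under(m, "D", c(Q = 1)), "unknown")
})

test_that("propagate reproduces the worked single-clamp example", {
  m <- toy_model("figure3")
  r <- propagate(m, c(C = 1))
  expect_equal(r$frozen, c(C = 1L, D = 1L))
  d <- tidy(r)
  expect_equal(d$status[d$component %in% c("A", "B", "F")], rep("input", 3))
  expect_equal(d$residual[d$component == "E"], "!F")
})

test_that("constant rules percolate even with no clamps, clamps override rules", {
  r <- propagate(parse_model("A, 1\nB, A"), c())
  expect_equal(r$frozen, c(A = 1L, B = 1L))

  r0 <- propagate(parse_model("A, 0\nB, A"))
  expect_equal(tally_propagation(r0),
    tibble::tibble(frozen_inactive = 2L, frozen_active = 0L, free = 0L))

  # mutant semantics: A's own rule (!B) is discarded
  toggle <- parse_model("A, !B\nB, !A")
  r1 <- propagate(toggle, c(A = 1))
  expect_equal(r1$frozen, c(A = 1L, B = 0L))

  expect_error(propagate(toggle, c(A = 1, A = 0)), "conflicting")
})

test_that("tally counts non-input components only, clamped ones included", {
  m <- toy_model("figure3")
  expect_equal(
    tally_propagation(propagate(m, c(C = 1))),
    tibble::tibble(frozen_inactive = 0L, frozen_active = 1L, free = 1L)
  )
  # clamped core node is itself counted
  expect_equal(tally_propagation(propagate(m, c(D = 1)))$frozen_active, 1L)
  # no constant rules, no clamps: everything non-input stays free
  expect_equal(tally_propagation(propagate(parse_model("A, A\nB, !A")))$free, 1L)
})

test_that("propagation is idempotent and confluent", {
  for (seed in 1:25) {
    m <- random_model(4L + seed %% 7L, n_inputs = 1L + seed %% 3L, max_in_degree = 3, seed = 100 + seed)
    clamps <- random_clamps(m, 2L, seed)
    r <- propagate(m, clamps)
    # re-propagating the frozen assignment is a fixed point
    r2 <- propagate(m, r$frozen)
    expect_equal(r2$frozen, r$frozen)
    expect_equal(r2$residuals, r$residuals)
    # result independent of worklist processing order
    for (k in 1:4) {
      rk <- propagate(m, clamps, worklist_order = k * 7919L + seed)
      expect_equal(rk$frozen, r$frozen)
      expect_equal(rk$residuals, r$residuals)
    }
  }
})

test_that("frozen assignments are trap spaces of the clamped model", {
  for (seed in 1:30) {
    m <- random_model(3L + seed %% 8L, n_inputs = seed %% 3L, max_in_degree = 3, seed = 200 + seed)
    clamps <- random_clamps(m, 1L + seed %% 3L, seed)
    r <- propagate(m, clamps)
    expect_true(is_trap_space(apply_clamps(m, clamps), r$frozen))
  }
})

test_that("stable states of the residual model extend to those of the clamped model", {
  for (seed in 1:15) {
    m <- random_model(3L + seed %% 6L, n_inputs = 1L, max_in_degree = 2, seed = 300 + seed)
    clamps <- random_clamps(m, 1L, seed)
    r <- propagate(m, clamps)
    full <- stable_states(m, clamps)
    # every stable state of the clamped model agrees with the frozen values
    if (nrow(full) > 0 && length(r$frozen) > 0) {
      for (i in seq_len(nrow(full))) {
        expect_equal(unlist(full[i, names(r$frozen)]), r$frozen)
      }
    }
    # and the free coordinates are exactly the stable states of the residual
    # model over the free components (inputs included as themselves)
    free <- setdiff(logimodel:::component_names(m), names(r$frozen))
    if (length(free) > 0 && nrow(full) > 0) {
      reduced <- oracle_stable_states(apply_clamps(m, r$frozen))
      expect_equal(
        unname(as.matrix(full[, free, drop = FALSE])),
        unname(as.matrix(reduced[, free, drop = FALSE]))
      )
    }
  }
})

test_that("differential classification partitions components and fills the 3x3 table", {
  m <- toy_model("figure3")
  ra <- propagate(m, c(C = 1))
  rb <- propagate(m, c(F = 1))
  cmp <- compare_propagations(ra, rb)
  d <- tidy(cmp)
  expect_equal(nrow(d), 6L)
  expect_equal(d$category[d$component == "C"], "frozen_on_A_only")
  expect_equal(d$category[d$component == "D"], "frozen_on_A_only")
  expect_equal(d$category[d$component == "E"], "frozen_off_B_only") # E = D & !F dies under F=1
  expect_equal(d$category[d$component == "A"], "input")

  tab <- comparison_table(cmp)
  n_counted <- sum(!m$components$input)
  expect_equal(sum(tab$A), n_counted)
  expect_equal(sum(tab$B), n_counted)

  # identity comparison: no *_only category, intersection equals each side
  cmp_same <- compare_propagations(ra, propagate(m, c(C = 1)))
  expect_false(any(grepl("_only$", tidy(cmp_same)$category)))
  tsame <- comparison_table(cmp_same)
  expect_equal(tsame$A, tsame$intersection)

  expect_error(
    compare_propagations(ra, propagate(parse_model("A, A"), c())),
    "different models"
  )
})

test_that("same-level agreement defines the intersection column", {
  for (seed in 1:10) {
    m <- random_model(8, n_inputs = 2, max_in_degree = 3, seed = 400 + seed)
    ra <- propagate(m, random_clamps(m, 2L, seed))
    rb <- propagate(m, random_clamps(m, 2L, seed + 1000L))
    cmp <- compare_propagations(ra, rb)
    d <- tidy(cmp)
    expect_equal(nrow(d), 8L) # categories cover every component exactly once
    expect_true(all(d$category %in% names(logimodel:::CATEGORY_FILL)))
    tab <- comparison_table(cmp)
    agree <- !d$input & !is.na(d$frozen_a) & !is.na(d$frozen_b) & d$frozen_a == d$frozen_b
    expect_equal(sum(tab$intersection[1:2]), sum(agree))
  }
})

test_that("annotated graph export colours nodes by category", {
  m <- toy_model("figure3")
  cmp <- compare_propagations(propagate(m, c(C = 1)), propagate(m, c(F = 1)))
  dot <- export_annotated_graph(cmp)
  expect_match(dot, "digraph")
  for (cn in logimodel:::component_names(m)) {
    expect_match(dot, paste0("\\b", cn, " \\[style=filled"))
  }
  expect_match(dot, "A \\[style=filled, fillcolor=gray")
  expect_match(dot, "D \\[style=filled, fillcolor=darkblue")
  expect_match(dot, "A -> D;", fixed = FALSE)

  gml <- export_annotated_graph(cmp, format = "graphml")
  expect_match(gml, "graphml")
  expect_match(gml, "<node id=\"E\"><data key=\"category\">frozen_off_B_only</data>")

  # all-free classification on a clamp-free comparison
  m2 <- parse_model("A, A\nX, !Y\nY, !X")
  cmp2 <- compare_propagations(propagate(m2, c()), propagate(m2, c()))
  dot2 <- export_annotated_graph(cmp2)
  expect_match(dot2, "X \\[style=filled, fillcolor=white")
  expect_match(dot2, "A \\[style=filled, fillcolor=gray")

  tmp <- tempfile(fileext = ".dot")
  export_annotated_graph(cmp, file = tmp)
  expect_true(file.exists(tmp))
})
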