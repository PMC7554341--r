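# Parsing, writing, regulators, single-step dynamics, validation.

fig3_text <- "D, A | B | C\nE, D & !F\nA, A\nB, B\nC, C\nF, F"

test_that("bnet parsing builds the declared structure and detects inputs", {
  m <- parse_model("A, B\nB, !A")
  expect_equal(logimodel:::component_names(m), c("A", "B"))
  expect_equal(regulators(m, "A"), "B")
  expect_equal(regulators(m, "B"), "A")
  expect_false(any(m$components$input))

  m3 <- parse_model(fig3_text)
  expect_equal(nrow(m3$components), 6L)
  expect_equal(sort(logimodel:::input_names(m3)), c("A", "B", "C", "F"))
  expect_setequal(regulators(m3, "D"), c("A", "B", "C"))
  expect_setequal(regulators(m3, "E"), c("D", "F"))
})

test_that("bnet parse errors carry line numbers and catch duplicates", {
  expect_error(parse_model("A, &B"), "line 1")
  expect_error(parse_model("A, B\nB, (A"), "line 2")
  expect_error(parse_model("A, 1\nA, 0"), "duplicate")
  expect_error(parse_model("A, B & Q"), "undeclared")
  expect_error(parse_model(""), "non-empty")
  # comments and blank lines are ignored
  m <- parse_model("# two-node toggle\nA, !B # negation\n\nB, !A")
  expect_equal(nrow(m$components), 2L)
})

test_that("regulators of constant and self-input rules", {
  expect_equal(regulators(parse_model("A, 1"), "A"), character(0))
  expect_equal(regulators(parse_model("A, A"), "A"), "A")
  expect_error(regulators(parse_model("A, A"), "Z"), "unknown")
})

test_that("write/parse round-trips and bnet rejects multivalued models", {
  m3 <- parse_model(fig3_text)
  expect_true(model_identical(m3, parse_model(write_model(m3))))
  expect_match(write_model(parse_model("A, A")), "A, A", fixed = TRUE)
  expect_true(model_identical(m3, parse_model(write_model(m3, "json"), dialect = "json")))

  ternary <- parse_model('{
    "components": [{"name": "X", "max_level": 2, "input": true},
                   {"name": "Y", "max_level": 1, "input": false}],
    "rules": {"Y": [{"condition": "X:2", "target": 1}]}
  }', dialect = "json")
  expect_error(write_model(ternary, "bnet"), "Boolean-only")
  expect_true(model_identical(ternary, parse_model(write_model(ternary, "json"), "json")))
  expect_setequal(regulators(ternary, "Y"), "X")
})

test_that("evaluate_component follows first-match case semantics", {
  m3 <- parse_model(fig3_text)
  st <- c(A = 0, B = 0, C = 1, F = 0, D = 0, E = 0)
  expect_equal(evaluate_component(m3, st, "D"), 1L)
  expect_equal(evaluate_component(m3, st, "E"), 0L) # D is still 0 in the state
  expect_equal(evaluate_component(parse_model("A, !A"), c(A = 1), "A"), 0L)
})

test_that("successors implement stepwise synchronous/asynchronous updating", {
  m3 <- parse_model(fig3_text)
  st <- c(A = 0, B = 0, C = 1, F = 0, D = 0, E = 0)
  sync <- successors(m3, st, "synchronous")
  expect_equal(nrow(sync), 1L)
  want <- c(A = 0L, B = 0L, C = 1L, F = 0L, D = 1L, E = 0L)
  expect_equal(unlist(sync[1, ])[names(want)], want)

  async <- successors(parse_model("A, !A"), c(A = 0), "asynchronous")
  expect_equal(unlist(async[1, ]), c(A = 1L))

  # a stable state has no asynchronous successor and is its own synchronous one
  stable <- c(A = 0, B = 0, C = 0, F = 0, D = 0, E = 0)
  expect_equal(nrow(successors(m3, stable, "asynchronous")), 0L)
  s1 <- unlist(successors(m3, stable, "synchronous")[1, ])
  expect_equal(s1[names(stable)], stable + 0L)

  # ternary components move one level at a time
  tern <- parse_model('{
    "components": [{"name": "X", "max_level": 2}],
    "rules": {"X": [{"condition": "1", "target": 2}]}
  }', "json")
  s2 <- successors(tern, c(X = 0), "synchronous")
  expect_equal(s2$X, 1L)
})

test_that("validate_model reports unreachable cases and bad thresholds", {
  m3 <- parse_model(fig3_text)
  expect_equal(nrow(validate_model(m3)), 0L)

  dup <- logimodel:::new_logical_model(
    tibble::tibble(name = c("A", "B"), max_level = c(1L, 2L), input = c(TRUE, NA)),
    list(
      A = logimodel:::identity_function("A", 1L),
      B = logimodel:::new_function(list(
        list(cond = logimodel:::x_atom("A", 1L), target = 2L),
        list(cond = logimodel:::x_atom("A", 1L), target = 1L) # shadowed
      ))
    )
  )
  expect_true(any(validate_model(dup)$kind == "unreachable_case"))

  bad_th <- logimodel:::new_logical_model(
    tibble::tibble(name = c("A", "B"), max_level = 1L, input = c(NA, TRUE)),
    list(
      A = logimodel:::new_function(list(list(cond = logimodel:::x_atom("B", 2L), target = 1L))),
      B = logimodel:::identity_function("B", 1L)
    ),
    validate = FALSE
  )
  d <- validate_model(bad_th)
  expect_true(any(d$kind == "threshold_out_of_range"))
})

test_that("evaluate_component agrees with direct truth-table evaluation", {
  for (seed in 1:20) {
    m <- random_model(2L + seed %% 7L, n_inputs = seed %% 3L, max_in_degree = 3, seed = seed)
    mat <- all_states_matrix(m)
    for (cn in logimodel:::component_names(m)) {
      direct <- oracle_targets(m, cn, mat)
      stepped <- vapply(seq_len(nrow(mat)), function(i) {
        evaluate_component(m, mat[i, ], cn)
      }, integer(1))
      expect_equal(stepped, direct)
    }
  }
})

test_that("empty asynchronous successor set coincides with synchronous fixpoints", {
  for (seed in 21:35) {
    m <- random_model(2L + seed %% 5L, n_inputs = 1, max_level = 1L + seed %% 2L, seed = seed)
    mat <- all_states_matrix(m)
    pick <- seq_len(min(nrow(mat), 16L))
    for (i in pick) {
      st <- mat[i, ]
      no_async <- nrow(successors(m, st, "asynchronous")) == 0L
      sync <- unlist(successors(m, st, "synchronous")[1, ])
      expect_equal(no_async, all(sync == st))
    }
  }
})
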