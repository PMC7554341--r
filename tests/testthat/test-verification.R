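# The specification harness: YAML suites, oracles, quantifiers, reports.

suite_yaml <- '
suite:
  name: demo
  cases:
    - name: quiescent_without_stimulation
      context: {S: 0}
      oracle: stable_states
      quantifier: all
      expect: {A: active}
'

test_that("YAML suites load, with schema violations reported by path", {
  suite <- load_suite(suite_yaml)
  expect_s3_class(suite, "test_suite")
  expect_equal(suite$cases[[1]]$context, c(S = 0L))
  expect_equal(suite$cases[[1]]$expect, c(A = "active"))

  expect_error(load_suite("suite:\n  name: empty\n  cases: []"), "at least one case")
  expect_error(
    load_suite("suite:\n  cases:\n    - name: a\n      expect: {X: active}\n    - name: a\n      expect: {X: active}"),
    "duplicate"
  )
  expect_error(
    load_suite("suite:\n  cases:\n    - name: a\n      oracle: psychic\n      expect: {X: active}"),
    "oracle"
  )
  expect_error(
    load_suite("suite:\n  cases:\n    - name: a\n      frobnicate: yes\n      expect: {X: active}"),
    "unknown field"
  )
  expect_error(
    load_suite("suite:\n  cases:\n    - name: a\n      expect: {X: sideways}"),
    "active, inactive or level=k"
  )
})

test_that("run_case compares oracle solutions against expectations", {
  m <- parse_model("S, S\nA, !S")
  spec <- specification("quiescence", context = c(S = 0), oracle = "stable_states",
    quantifier = "all", expect = c(A = "active"))
  r <- run_case(m, spec)
  expect_equal(r$status, "pass")
  expect_equal(r$n_solutions, 1L)

  # all-quantifier failure names a witness
  bad <- specification("wrong", context = c(S = 0), oracle = "stable_states",
    quantifier = "all", expect = c(A = "inactive"))
  rb <- run_case(m, bad)
  expect_equal(rb$status, "fail")
  expect_equal(rb$diagnostics$component[[1]], "A")
  expect_match(rb$diagnostics$reason[[1]], "observed level 1")
})

test_that("a context with no attractor is vacuous, not a silent pass", {
  m <- parse_model("A, !A")
  spec <- specification("no_fixpoint", oracle = "stable_states",
    quantifier = "all", expect = c(A = "active"))
  expect_equal(run_case(m, spec)$status, "vacuous")
  # exists cannot be witnessed
  spec2 <- specification("no_witness", oracle = "stable_states",
    quantifier = "exists", expect = c(A = "active"))
  expect_equal(run_case(m, spec2)$status, "fail")
})

test_that("propagation oracle treats free components as unconstrained failures", {
  m <- toy_model("figure3")
  spec <- specification("e_must_freeze", context = c(C = 1), oracle = "propagation",
    quantifier = "all", expect = c(D = "active", E = "inactive"))
  r <- run_case(m, spec)
  expect_equal(r$status, "fail")
  expect_equal(r$diagnostics$component, "E")
  expect_equal(r$diagnostics$reason, "unconstrained")

  ok <- specification("d_frozen_on", context = c(C = 1), oracle = "propagation",
    expect = c(D = "active", C = "active"))
  expect_equal(run_case(m, ok)$status, "pass")
})

test_that("select triggers sub-model extraction before testing", {
  m <- toy_model("calcium_corrected")
  spec <- specification("local_rest",
    select = "Calcium_ER",
    context = c(IP3R1 = 0), # a boundary input of the sub-model
    oracle = "stable_states", quantifier = "exists",
    expect = c(Calcium_ER = "active", SERCA = "inactive")
  )
  expect_equal(run_case(m, spec)$status, "pass")
  # the same context is not a legal clamp on the full model's IP3R1-regulating input
  expect_equal(run_case(m, specification("x", context = c(NOPE = 1), expect = c()))$status, "error")
})

test_that("the calcium regression pair fails on the default rule and passes corrected", {
  spec <- specification("rest_full_reservoir_without_pumping",
    context = c(IP3R_stim = 0), oracle = "stable_states", quantifier = "exists",
    expect = c(Calcium_ER = "active", SERCA = "inactive")
  )
  expect_equal(run_case(toy_model("calcium_default"), spec)$status, "fail")
  expect_equal(run_case(toy_model("calcium_corrected"), spec)$status, "pass")
})

test_that("the shipped calcium suite passes on the corrected fixture", {
  suite <- load_suite(system.file("extdata", "calcium_suite.yaml", package = "logimodel"))
  rep_ok <- run_suite(toy_model("calcium_corrected"), suite)
  expect_equal(glance(rep_ok)$pass, 3L)
  rep_bad <- run_suite(toy_model("calcium_default"), suite)
  expect_gte(glance(rep_bad)$fail, 1L)
})

test_that("suites run cases independently with stable totals", {
  m <- parse_model("S, S\nA, !S")
  specs <- list(
    specification("ok", context = c(S = 0), oracle = "stable_states", expect = c(A = "active")),
    specification("broken", context = c(S = 0), oracle = "stable_states", expect = c(A = "inactive")),
    specification("missing", expect = c(ZZZ = "active"))
  )
  rep <- run_suite(m, specs)
  g <- glance(rep)
  expect_equal(g$pass, 1L)
  expect_equal(g$fail, 1L)
  expect_equal(g$error, 1L)
  expect_equal(g$total, 3L)

  # totals invariant under case reordering
  g2 <- glance(run_suite(m, rev(specs)))
  expect_equal(g2[c("pass", "fail", "vacuous", "error")], g[c("pass", "fail", "vacuous", "error")])

  js <- jsonlite::fromJSON(report_json(rep))
  expect_equal(js$totals$pass, 1L)
  expect_equal(nrow(js$cases), 3L)
})

test_that("empty expectations never fail and trap spaces refine stable-state checks", {
  for (seed in 1:12) {
    m <- random_model(2L + seed %% 6L, n_inputs = seed %% 3L, max_in_degree = 2, seed = 1100 + seed)
    empty <- run_case(m, specification("empty", expect = c()))
    expect_true(empty$status %in% c("pass", "vacuous"))

    # every constraint satisfied by all minimal trap spaces also holds in all
    # stable states (stable states are minimal trap spaces)
    comps <- logimodel:::component_names(m)
    cn <- comps[[1L + seed %% length(comps)]]
    for (constraint in c("active", "inactive")) {
      via_traps <- run_case(m, specification("t", oracle = "trap_spaces",
        quantifier = "all", expect = stats::setNames(constraint, cn)))
      via_stable <- run_case(m, specification("s", oracle = "stable_states",
        quantifier = "all", expect = stats::setNames(constraint, cn)))
      if (via_traps$status == "pass") {
        expect_true(via_stable$status %in% c("pass", "vacuous"))
      }
    }
  }
})
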