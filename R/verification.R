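# Specification-based model verification: biological expectations encoded as
# machine-checkable test cases over contexts, assembled into suites.
#
# YAML schema (canonical form):
#   suite:
#     name: <string>
#     model: <free-form reference, optional>
#     cases:
#       - name: <string, unique>
#         select: [A, B]            # optional: extract a sub-model first
#         context: {S: 0, KO: 0}    # clamps: inputs and perturbations alike
#         oracle: trap_spaces       # stable_states | trap_spaces | propagation
#         quantifier: all           # all | exists
#         expect: {X: active, Y: inactive, Z: level=2}
# Unknown fields are rejected. Unknown component names are model-dependent and
# surface at run time as case status "error".

SPEC_ORACLES <- c("stable_states", "trap_spaces", "propagation")
SPEC_QUANTIFIERS <- c("all", "exists")

#' Load a verification suite from YAML
#'
#' @param source Path to a YAML file, or a YAML string.
#' @return A `test_suite`: list with `name`, `model` (reference string or
#'   `NULL`) and `cases`, each case a validated specification.
#' @export
load_suite <- function(source) {
  doc <- if (length(source) == 1L && !grepl("\n", source) && file.exists(source)) {
    yaml::read_yaml(source)
  } else {
    yaml::yaml.load(paste(source, collapse = "\n"))
  }
  if (!is.list(doc) || is.null(doc$suite)) stop("schema violation at $: expected top-level 'suite'")
  suite <- doc$suite
  reject_unknown(suite, c("name", "model", "cases"), "$suite")
  if (is.null(suite$cases) || length(suite$cases) == 0L) {
    stop("schema violation at $suite.cases: suite must contain at least one case")
  }
  cases <- lapply(seq_along(suite$cases), function(i) {
    validate_case(suite$cases[[i]], paste0("$suite.cases[", i, "]"))
  })
  nm <- vapply(cases, `[[`, character(1), "name")
  if (anyDuplicated(nm)) {
    stop("schema violation at $suite.cases: duplicate case name(s): ",
      paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  structure(
    list(name = suite$name %||% "suite", model = suite$model, cases = cases),
    class = "test_suite"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

reject_unknown <- function(x, allowed, path) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown)) {
    stop("schema violation at ", path, ": unknown field(s): ", paste(unknown, collapse = ", "))
  }
  invisible(x)
}

validate_case <- function(case, path) {
  reject_unknown(case, c("name", "select", "context", "oracle", "quantifier", "expect"), path)
  if (is.null(case$name)) stop("schema violation at ", path, ": case needs a name")
  oracle <- case$oracle %||% "trap_spaces"
  if (!oracle %in% SPEC_ORACLES) {
    stop("schema violation at ", path, ".oracle: must be one of ", paste(SPEC_ORACLES, collapse = ", "))
  }
  quantifier <- case$quantifier %||% "all"
  if (!quantifier %in% SPEC_QUANTIFIERS) {
    stop("schema violation at ", path, ".quantifier: must be 'all' or 'exists'")
  }
  context <- case$context %||% list()
  if (length(context) && (is.null(names(context)) || any(names(context) == ""))) {
    stop("schema violation at ", path, ".context: expected a NAME: LEVEL map")
  }
  expect <- case$expect %||% list()
  for (en in names(expect)) {
    v <- expect[[en]]
    if (!is.character(v) || !(v %in% c("active", "inactive") || grepl("^level=[0-9]+$", v))) {
      stop("schema violation at ", path, ".expect.", en, ": expected active, inactive or level=k")
    }
  }
  specification(
    name = as.character(case$name),
    select = if (is.null(case$select)) NULL else as.character(unlist(case$select)),
    context = vapply(context, as.integer, integer(1)),
    oracle = oracle,
    quantifier = quantifier,
    expect = vapply(expect, as.character, character(1))
  )
}

#' Build a single specification
#'
#' A specification pairs a context (clamped inputs and perturbations) with
#' expected component activities, to be checked against an oracle: the stable
#' states, the minimal trap spaces, or the value-propagation result of the
#' (sub)model under that context.
#'
#' @param name Case name.
#' @param select Optional component selection; when given, the sub-model
#'   around these components is extracted before testing.
#' @param context Named vector of clamped levels.
#' @param oracle `"stable_states"`, `"trap_spaces"` or `"propagation"`.
#' @param quantifier `"all"` (every solution must satisfy the expectations) or
#'   `"exists"` (at least one solution must).
#' @param expect Named character vector: `"active"` (level >= 1), `"inactive"`
#'   (level 0) or `"level=k"`.
#' @return A `specification`.
#' @export
specification <- function(name, select = NULL, context = NULL,
                          oracle = c("trap_spaces", "stable_states", "propagation"),
                          quantifier = c("all", "exists"), expect = character(0)) {
  oracle <- match.arg(oracle)
  quantifier <- match.arg(quantifier)
  if (is.null(context)) context <- stats::setNames(integer(0), character(0))
  structure(
    list(
      name = name, select = select, context = context,
      oracle = oracle, quantifier = quantifier, expect = expect
    ),
    class = "specification"
  )
}

constraint_bounds <- function(constraint) {
  if (constraint == "active") return(c(1L, NA_integer_)) # level >= 1
  if (constraint == "inactive") return(c(0L, 0L))
  lv <- as.integer(sub("^level=", "", constraint))
  c(lv, lv)
}

# Does `value` (possibly NA = unconstrained/free) satisfy a constraint?
satisfies <- function(value, constraint) {
  if (is.na(value)) return(FALSE)
  b <- constraint_bounds(constraint)
  if (is.na(b[[2L]])) value >= b[[1L]] else value == b[[1L]]
}

#' Run one specification against a model
#'
#' If the specification selects components, the sub-model around them is
#' extracted first. The oracle solutions are computed under the context
#' clamps: total states for `stable_states`, partial assignments for
#' `trap_spaces` (minimal trap spaces of the clamped model; a component left
#' free by a trap space satisfies no constraint) and the single frozen
#' assignment for `propagation` (a constraint on a free component fails as
#' "unconstrained"). Under `all`, every solution must satisfy every
#' expectation; with no solutions the case is *vacuous*, not a pass. Under
#' `exists`, some solution must satisfy all expectations.
#'
#' @param model A `logical_model`.
#' @param spec A [specification()].
#' @return A list with `name`, `status` (`"pass"`, `"fail"`, `"vacuous"` or
#'   `"error"`), `n_solutions` and a `diagnostics` tibble naming, for
#'   failures, a witness solution and the violated constraint.
#' @export
run_case <- function(model, spec) {
  stopifnot(inherits(spec, "specification"))
  result <- tryCatch(
    {
      m <- model
      if (!is.null(spec$select)) m <- extract_submodel(m, spec$select)
      unknown <- setdiff(names(spec$expect), component_names(m))
      if (length(unknown)) {
        stop("expectation on unknown component(s): ", paste(unknown, collapse = ", "))
      }
      context <- as_assignment(m, spec$context)

      solutions <- switch(spec$oracle,
        stable_states = {
          st <- stable_states(m, context)
          lapply(seq_len(nrow(st)), function(i) unlist(st[i, ]))
        },
        trap_spaces = {
          ts <- minimal_trap_spaces(apply_clamps(m, context))
          lapply(seq_len(nrow(ts)), function(i) unlist(ts[i, ]))
        },
        propagation = {
          pr <- propagate(m, context)
          full <- stats::setNames(rep(NA_integer_, length(component_names(m))), component_names(m))
          full[names(pr$frozen)] <- pr$frozen
          list(full)
        }
      )

      diag <- list()
      if (length(solutions) == 0L) {
        status <- if (spec$quantifier == "all") "vacuous" else "fail"
        if (status == "fail") {
          diag[[1L]] <- list(NA_integer_, NA_character_, NA_character_, "no solution to witness the expectation")
        }
      } else if (spec$quantifier == "all") {
        status <- "pass"
        for (i in seq_along(solutions)) {
          for (en in names(spec$expect)) {
            v <- solutions[[i]][[en]]
            if (!satisfies(v, spec$expect[[en]])) {
              status <- "fail"
              reason <- if (is.na(v)) "unconstrained" else paste0("observed level ", v)
              diag[[length(diag) + 1L]] <- list(i, en, unname(spec$expect[[en]]), reason)
            }
          }
        }
      } else { # exists
        ok <- vapply(solutions, function(s) {
          all(vapply(names(spec$expect), function(en) satisfies(s[[en]], spec$expect[[en]]), logical(1)))
        }, logical(1))
        if (any(ok)) {
          status <- "pass"
        } else {
          status <- "fail"
          diag[[1L]] <- list(NA_integer_, NA_character_, NA_character_,
            paste0("none of the ", length(solutions), " solution(s) satisfies all expectations"))
        }
      }
      diagnostics <- tibble::tibble(
        solution = vapply(diag, function(d) as.integer(d[[1L]]), integer(1)),
        component = vapply(diag, function(d) as.character(d[[2L]]), character(1)),
        expected = vapply(diag, function(d) as.character(d[[3L]]), character(1)),
        reason = vapply(diag, function(d) as.character(d[[4L]]), character(1))
      )
      list(name = spec$name, status = status, n_solutions = length(solutions), diagnostics = diagnostics)
    },
    error = function(e) {
      list(
        name = spec$name, status = "error", n_solutions = NA_integer_,
        diagnostics = tibble::tibble(
          solution = NA_integer_, component = NA_character_,
          expected = NA_character_, reason = conditionMessage(e)
        )
      )
    }
  )
  result
}

#' Run a verification suite
#'
#' Cases run independently, in suite order; one case erroring does not abort
#' the others. The suite passes when no case fails or errors.
#'
#' @param model A `logical_model`.
#' @param suite A `test_suite` from [load_suite()], or a list of
#'   [specification()]s.
#' @return A `verification_report`; [tidy()] gives one row per case,
#'   [glance()] the totals, and `report_json()` a machine-readable document.
#' @export
run_suite <- function(model, suite) {
  cases <- if (inherits(suite, "test_suite")) suite$cases else suite
  stopifnot(length(cases) > 0L)
  results <- lapply(cases, function(spec) run_case(model, spec))
  structure(
    list(
      suite = if (inherits(suite, "test_suite")) suite$name else "suite",
      results = results
    ),
    class = "verification_report"
  )
}

report_totals <- function(report) {
  st <- vapply(report$results, `[[`, character(1), "status")
  tibble::tibble(
    pass = sum(st == "pass"),
    fail = sum(st == "fail"),
    vacuous = sum(st == "vacuous"),
    error = sum(st == "error"),
    total = length(st)
  )
}

#' @export
print.verification_report <- function(x, ...) {
  tot <- report_totals(x)
  cat("<verification_report> '", x$suite, "': ",
    tot$pass, " pass, ", tot$fail, " fail, ", tot$vacuous, " vacuous, ",
    tot$error, " error\n",
    sep = ""
  )
  for (r in x$results) {
    cat(format(paste0("  [", r$status, "]"), width = 12), r$name, "\n")
    if (r$status %in% c("fail", "error") && nrow(r$diagnostics)) {
      d <- r$diagnostics[1L, ]
      cat("             ",
        if (!is.na(d$component)) paste0(d$component, " expected ", d$expected, ": ") else "",
        d$reason, "\n",
        sep = ""
      )
    }
  }
  invisible(x)
}

#' Serialise a verification report to JSON
#'
#' @param report A `verification_report`.
#' @param file Optional output path.
#' @return JSON string, invisibly when `file` is given.
#' @export
report_json <- function(report, file = NULL) {
  stopifnot(inherits(report, "verification_report"))
  doc <- list(
    suite = report$suite,
    totals = as.list(report_totals(report)),
    cases = lapply(report$results, function(r) {
      list(
        name = r$name, status = r$status, n_solutions = r$n_solutions,
        diagnostics = r$diagnostics
      )
    })
  )
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE, na = "null")
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}
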