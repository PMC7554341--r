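#' Logical models
#'
#' A logical model is a set of named components, each with a maximum activity
#' level (`1` = Boolean, `2` = ternary, ...) and one logical update function.
#' Update functions are ordered lists of cases `(condition, target_level)`:
#' the component's target is the target level of the first case whose condition
#' holds in the current state, and `0` when no condition holds. Conditions are
#' expressions over threshold atoms (`X` is true iff the level of `X` is at
#' least 1, `X:2` iff it is at least 2), `!`, `&`, `|`, parentheses and the
#' constants `0`/`1`.
#'
#' A component whose rule is exactly itself (`A, A`), or that is flagged
#' `input` in the JSON dialect, is an *input*: its level is an environmental
#' degree of freedom. Inputs are reported separately in all tallies.
#'
#' @section Structure:
#' Objects of class `logical_model` are lists with
#' \describe{
#'   \item{components}{a tibble with columns `name`, `max_level`, `input`}
#'   \item{functions}{a named list of update functions, one per component}
#' }
#'
#' @name logical_model
NULL

NAME_RX <- "^[A-Za-z_][A-Za-z0-9_]*$"

new_function <- function(cases) list(cases = cases)

# Multivalued identity rule: level k when self >= k, scanned from the top.
identity_function <- function(name, max_level) {
  new_function(lapply(rev(seq_len(max_level)), function(k) {
    list(cond = x_atom(name, k), target = as.integer(k))
  }))
}

is_identity_function <- function(fn, name, max_level) {
  identical(fn, identity_function(name, max_level))
}

# Validating constructor. `functions` must be a named list covering every
# component; `input` may be NA to auto-detect identity rules. `validate =
# FALSE` skips the reference/threshold checks so that validate_model() can be
# exercised on deliberately broken models.
new_logical_model <- function(components, functions, validate = TRUE) {
  stopifnot(is.data.frame(components), all(c("name", "max_level") %in% names(components)))
  name <- components$name
  max_level <- as.integer(components$max_level)
  if (anyDuplicated(name)) {
    stop("duplicate component definition: ", paste(unique(name[duplicated(name)]), collapse = ", "))
  }
  bad <- name[!grepl(NAME_RX, name)]
  if (length(bad)) stop("invalid component name(s): ", paste(bad, collapse = ", "))
  if (any(max_level < 1L)) stop("max_level must be >= 1")
  missing_fn <- setdiff(name, names(functions))
  if (length(missing_fn)) stop("no update function for component(s): ", paste(missing_fn, collapse = ", "))

  functions <- functions[name]
  ml <- stats::setNames(max_level, name)
  if (validate) for (cn in name) {
    fn <- functions[[cn]]
    if (length(fn$cases) == 0L) stop("component '", cn, "' has no cases")
    for (cs in fn$cases) {
      if (cs$target < 1L || cs$target > ml[[cn]]) {
        stop("target level ", cs$target, " out of range for component '", cn, "'")
      }
      for (a in expr_atoms(cs$cond)) {
        if (!a %in% name) stop("undeclared component referenced: '", a, "' in rule of '", cn, "'")
        th <- expr_max_threshold(cs$cond, a)
        if (th > ml[[a]]) {
          stop("threshold ", th, " on '", a, "' exceeds its max_level ", ml[[a]], " (rule of '", cn, "')")
        }
      }
    }
    if (ml[[cn]] == 1L && (length(fn$cases) != 1L || fn$cases[[1L]]$target != 1L)) {
      stop("Boolean component '", cn, "' must have exactly one case with target 1")
    }
  }

  input <- if ("input" %in% names(components)) components$input else rep(NA, length(name))
  input <- vapply(seq_along(name), function(i) {
    flag <- input[[i]]
    auto <- is_identity_function(functions[[name[[i]]]], name[[i]], ml[[name[[i]]]])
    if (is.na(flag)) auto else isTRUE(flag) || auto
  }, logical(1))

  structure(
    list(
      components = tibble::tibble(name = name, max_level = max_level, input = input),
      functions = functions
    ),
    class = "logical_model"
  )
}

is_logical_model <- function(x) inherits(x, "logical_model")

component_names <- function(model) model$components$name

max_levels <- function(model) {
  stats::setNames(model$components$max_level, model$components$name)
}

input_names <- function(model) model$components$name[model$components$input]

#' @export
print.logical_model <- function(x, ...) {
  n <- nrow(x$components)
  mv <- sum(x$components$max_level > 1L)
  cat("<logical_model> ", n, " components (", sum(x$components$input), " inputs",
    if (mv) paste0(", ", mv, " multivalued") else "", ")\n",
    sep = ""
  )
  for (i in seq_len(min(n, 12L))) {
    nm <- x$components$name[[i]]
    cat("  ", nm, if (x$components$max_level[[i]] > 1L) paste0(" [0..", x$components$max_level[[i]], "]"),
      " <- ", deparse_function(x$functions[[nm]], x$components$max_level[[i]]), "\n",
      sep = ""
    )
  }
  if (n > 12L) cat("  ... and", n - 12L, "more\n")
  invisible(x)
}

# Canonical structural form used for equality: drops tibble attributes so that
# models built through different code paths compare with identical().
canonical_model <- function(model) {
  list(
    name = model$components$name,
    max_level = as.integer(model$components$max_level),
    input = model$components$input,
    functions = model$functions
  )
}

#' Test two logical models for structural equality
#'
#' Compares component declarations (in order), max levels, input flags and
#' update functions node-by-node.
#'
#' @param a,b Logical models.
#' @return `TRUE` or `FALSE`.
#' @export
model_identical <- function(a, b) {
  identical(canonical_model(a), canonical_model(b))
}

#' Regulators of a component
#'
#' The regulators `R(c)` of a component are exactly the components appearing
#' in atoms of its update function; components with constant rules have none.
#'
#' @param model A `logical_model`.
#' @param component Component name.
#' @return Character vector of component names, in declaration order.
#' @export
#' @examples
#' m <- parse_model("D, A | B | C\nE, D & !F\nA, A\nB, B\nC, C\nF, F")
#' regulators(m, "E")
regulators <- function(model, component) {
  check_component(model, component)
  fn <- model$functions[[component]]
  regs <- unique(unlist(lapply(fn$cases, function(cs) expr_atoms(cs$cond))))
  if (is.null(regs)) regs <- character(0)
  intersect(component_names(model), regs)
}

check_component <- function(model, component) {
  if (!component %in% component_names(model)) {
    stop("unknown component: '", component, "'")
  }
  invisible(component)
}

# Coerce a user-supplied state (named vector or list) to a validated total
# state: named integer vector in declaration order.
as_state <- function(model, state) {
  s <- unlist(state)
  missing_c <- setdiff(component_names(model), names(s))
  if (length(missing_c)) stop("state is not total; missing: ", paste(missing_c, collapse = ", "))
  extra <- setdiff(names(s), component_names(model))
  if (length(extra)) stop("state assigns unknown component(s): ", paste(extra, collapse = ", "))
  s <- stats::setNames(as.integer(s[component_names(model)]), component_names(model))
  check_bounds(model, s)
  s
}

# Validate a partial assignment (clamps / subspace): named integer vector.
as_assignment <- function(model, assignment) {
  if (length(assignment) == 0L) {
    return(stats::setNames(integer(0), character(0)))
  }
  a <- unlist(assignment)
  if (is.null(names(a)) || any(names(a) == "")) stop("assignment must be named")
  if (anyDuplicated(names(a))) {
    dups <- unique(names(a)[duplicated(names(a))])
    vals <- split(as.integer(a), names(a))
    for (d in dups) {
      if (length(unique(vals[[d]])) > 1L) stop("conflicting levels for component '", d, "'")
    }
    a <- a[!duplicated(names(a))]
  }
  extra <- setdiff(names(a), component_names(model))
  if (length(extra)) stop("unknown component(s): ", paste(extra, collapse = ", "))
  a <- stats::setNames(as.integer(a), names(a))
  check_bounds(model, a)
  a
}

check_bounds <- function(model, assignment) {
  ml <- max_levels(model)[names(assignment)]
  bad <- names(assignment)[assignment < 0L | assignment > ml]
  if (length(bad)) {
    stop("level out of range for component(s): ", paste(bad, collapse = ", "))
  }
  invisible(assignment)
}

# Target level of a component's rule in a total state (first matching case).
target_level <- function(model, state, component) {
  fn <- model$functions[[component]]
  for (cs in fn$cases) {
    if (eval_expr(cs$cond, state)) return(cs$target)
  }
  0L
}

#' Evaluate a component's update function in a state
#'
#' Returns the *target* level of the component: the target of the first case
#' of its rule whose condition is satisfied, or 0 when none holds. A threshold
#' atom `X:k` is true iff the state level of `X` is at least `k`.
#'
#' @param model A `logical_model`.
#' @param state Named vector giving a level for every component.
#' @param component Component name.
#' @return Integer target level.
#' @export
evaluate_component <- function(model, state, component) {
  check_component(model, component)
  target_level(model, as_state(model, state), component)
}

#' Successor states under synchronous or asynchronous updating
#'
#' Multivalued components move stepwise: one level per update toward the
#' target computed by their rule. Synchronous updating moves every unstable
#' component at once (a single successor, equal to the state itself at a
#' stable state); asynchronous updating yields one successor per unstable
#' component (none at a stable state).
#'
#' @param model A `logical_model`.
#' @param state Named vector giving a level for every component.
#' @param mode `"asynchronous"` (default) or `"synchronous"`.
#' @return A tibble with one row per successor state, columns the components.
#' @export
successors <- function(model, state, mode = c("asynchronous", "synchronous")) {
  mode <- match.arg(mode)
  s <- as_state(model, state)
  succ <- successor_states(model, s, mode)
  states_to_tibble(model, succ)
}

# Internal: list of named integer vectors.
successor_states <- function(model, s, mode) {
  comps <- component_names(model)
  tgt <- vapply(comps, function(cn) target_level(model, s, cn), integer(1))
  step <- sign(tgt - s)
  unstable <- comps[step != 0L]
  if (mode == "synchronous") {
    nxt <- s + step
    return(list(stats::setNames(as.integer(nxt), comps)))
  }
  lapply(unstable, function(cn) {
    nxt <- s
    nxt[[cn]] <- nxt[[cn]] + step[[cn]]
    nxt
  })
}

states_to_tibble <- function(model, states) {
  comps <- component_names(model)
  if (length(states) == 0L) {
    cols <- stats::setNames(rep(list(integer(0)), length(comps)), comps)
    return(tibble::as_tibble(cols))
  }
  m <- do.call(rbind, lapply(states, function(s) s[comps]))
  out <- tibble::as_tibble(as.data.frame(m))
  names(out) <- comps
  out
}

#' Diagnose structural problems in a model
#'
#' Checks for references to undeclared components, atom thresholds above the
#' regulator's maximum level, and unreachable cases (a case whose condition is
#' implied by the disjunction of earlier case conditions, decided exhaustively
#' over the rule's regulators). An empty result means the model is clean.
#'
#' @param model A `logical_model`.
#' @return A tibble with columns `component`, `kind`, `message`; zero rows if
#'   no diagnostic applies.
#' @export
validate_model <- function(model) {
  out <- list()
  ml <- max_levels(model)
  comps <- component_names(model)
  for (cn in comps) {
    fn <- model$functions[[cn]]
    regs <- character(0)
    has_undeclared <- FALSE
    for (cs in fn$cases) {
      for (a in expr_atoms(cs$cond)) {
        if (!a %in% comps) {
          has_undeclared <- TRUE
          out[[length(out) + 1L]] <- list(cn, "undeclared_reference", paste0("rule references undeclared component '", a, "'"))
        } else {
          regs <- union(regs, a)
          th <- expr_max_threshold(cs$cond, a)
          if (th > ml[[a]]) {
            out[[length(out) + 1L]] <- list(cn, "threshold_out_of_range", paste0("threshold ", th, " on '", a, "' exceeds max_level ", ml[[a]]))
          }
        }
      }
    }
    # unreachable case: condition implied by the disjunction of earlier ones,
    # checked over all combinations of regulator levels
    if (length(fn$cases) > 1L && !has_undeclared) {
      grid <- level_grid(ml[regs])
      sat <- lapply(fn$cases, function(cs) {
        apply(grid, 1L, function(row) eval_expr(cs$cond, stats::setNames(as.integer(row), regs)))
      })
      seen <- rep(FALSE, nrow(grid))
      for (i in seq_along(fn$cases)) {
        if (all(!sat[[i]] | seen)) {
          out[[length(out) + 1L]] <- list(cn, "unreachable_case", paste0("case ", i, " (target ", fn$cases[[i]]$target, ") is subsumed by earlier cases"))
        }
        seen <- seen | sat[[i]]
      }
    }
  }
  tibble::tibble(
    component = vapply(out, `[[`, character(1), 1L),
    kind = vapply(out, `[[`, character(1), 2L),
    message = vapply(out, `[[`, character(1), 3L)
  )
}

# All combinations of levels 0..max for the named max-level vector. Rows are
# states over `names(ml)`; a 1-row, 0-column frame when ml is empty.
level_grid <- function(ml) {
  if (length(ml) == 0L) {
    return(as.data.frame(matrix(integer(0), nrow = 1L, ncol = 0L)))
  }
  g <- expand.grid(lapply(ml, function(m) 0:m), KEEP.OUT.ATTRS = FALSE)
  names(g) <- names(ml)
  g
}

deparse_function <- function(fn, max_level) {
  if (max_level == 1L) {
    return(deparse_expr(fn$cases[[1L]]$cond))
  }
  paste(vapply(fn$cases, function(cs) {
    paste0(cs$target, " @ ", deparse_expr(cs$cond))
  }, character(1)), collapse = "; ")
}
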