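# Stable states and minimal trap spaces.
#
# Stable states are enumerated by depth-first search over component
# assignments, using value propagation as a constraint propagator: each
# decision is percolated, and a branch is pruned as soon as percolation
# contradicts the partial assignment. Minimal trap spaces are found by
# branch-and-prune over subspaces using the closure condition "every fixed
# component's rule is constantly equal to its fixed value within the
# subspace", decided by the complete constancy test of simplify_under().
# Both have exhaustive small-model oracles in the test suite.

#' Replace rules of clamped components by constants
#'
#' Clamping follows mutant semantics: the clamped component's rule is
#' discarded and replaced by the constant level, and the component stops being
#' an input. Useful to reason about "the clamped model" explicitly.
#'
#' @param model A `logical_model`.
#' @param clamps Named vector of levels.
#' @return A `logical_model`.
#' @export
apply_clamps <- function(model, clamps) {
  clamps <- as_assignment(model, clamps)
  if (length(clamps) == 0L) return(model)
  functions <- model$functions
  input <- model$components$input
  for (cn in names(clamps)) {
    v <- clamps[[cn]]
    functions[[cn]] <- if (v == 0L) {
      new_function(list(list(cond = x_const(0L), target = 1L)))
    } else {
      new_function(list(list(cond = x_const(1L), target = as.integer(v))))
    }
    input[[match(cn, model$components$name)]] <- FALSE
  }
  new_logical_model(
    tibble::tibble(name = model$components$name, max_level = model$components$max_level, input = input),
    functions
  )
}

#' Enumerate the stable states of a model
#'
#' A stable state (fixed point) is a total state in which every component's
#' rule returns its current level. Optional clamps are applied with mutant
#' semantics first. The search branches over components in declaration order
#' and percolates every decision, pruning branches whose percolation
#' contradicts an earlier decision; the enumeration is complete and the
#' output is sorted lexicographically by component declaration order.
#'
#' @param model A `logical_model`.
#' @param clamps Optional named vector of clamped levels.
#' @return A tibble with one row per stable state, one column per component.
#' @export
#' @examples
#' stable_states(parse_model("A, A")) # both Boolean levels
#' stable_states(parse_model("A, !A")) # none
stable_states <- function(model, clamps = NULL) {
  clamps <- as_assignment(model, clamps)
  comps <- component_names(model)
  ml <- max_levels(model)
  mutant <- names(clamps)

  targets <- stats::setNames(vector("list", length(comps)), comps)
  for (cn in comps) {
    for (r in regulators(model, cn)) targets[[r]] <- c(targets[[r]], cn)
  }

  found <- list()

  # Percolation closure with consistency checking. `frozen` holds both
  # decisions and derived values; rules of mutant-clamped components are
  # never evaluated. Returns the extended assignment or NULL on contradiction.
  closure <- function(frozen, queue) {
    queued <- stats::setNames(logical(length(comps)), comps)
    queued[queue] <- TRUE
    while (length(queue) > 0L) {
      cn <- queue[[1L]]
      queue <- queue[-1L]
      queued[[cn]] <- FALSE
      if (cn %in% mutant) next
      res <- fold_function(model, model$functions[[cn]], frozen)
      if (res$kind == "constant") {
        if (cn %in% names(frozen)) {
          if (frozen[[cn]] != res$level) return(NULL)
        } else {
          frozen[[cn]] <- res$level
          for (t in c(targets[[cn]], cn)) {
            if (!queued[[t]] && !t %in% mutant) {
              queue <- c(queue, t)
              queued[[t]] <- TRUE
            }
          }
        }
      }
    }
    frozen
  }

  dfs <- function(frozen, queue) {
    frozen <- closure(frozen, queue)
    if (is.null(frozen)) return(invisible(NULL))
    free <- setdiff(comps, names(frozen))
    if (length(free) == 0L) {
      found[[length(found) + 1L]] <<- frozen[comps]
      return(invisible(NULL))
    }
    cn <- free[[1L]]
    for (v in 0:ml[[cn]]) {
      nxt <- frozen
      nxt[[cn]] <- as.integer(v)
      dfs(nxt, unique(c(cn, targets[[cn]])))
    }
    invisible(NULL)
  }

  dfs(clamps, setdiff(comps, mutant))

  if (length(found) > 1L) {
    keys <- vapply(found, function(s) paste(sprintf("%03d", s), collapse = ""), character(1))
    found <- found[order(keys)]
  }
  states_to_tibble(model, found)
}

#' Is a subspace a trap space?
#'
#' Exhaustively checks that every synchronous and asynchronous successor of
#' every state in the subspace stays in the subspace. Intended as an oracle
#' for small models; errors out above `max_states` enumerated states.
#'
#' @param model A `logical_model`.
#' @param subspace Named vector fixing some components (free components are
#'   unrestricted). An empty vector denotes the full state space.
#' @param max_states Enumeration cap (default `2^20`).
#' @return `TRUE` or `FALSE`.
#' @export
is_trap_space <- function(model, subspace = NULL, max_states = 2^20) {
  subspace <- as_assignment(model, subspace)
  comps <- component_names(model)
  ml <- max_levels(model)
  free <- setdiff(comps, names(subspace))
  n_states <- prod(ml[free] + 1)
  if (n_states > max_states) {
    stop("subspace too large for exhaustive check (", n_states, " states > cap ", max_states, ")")
  }
  grid <- level_grid(ml[free])
  fixed <- names(subspace)
  for (i in seq_len(nrow(grid))) {
    st <- stats::setNames(integer(length(comps)), comps)
    st[fixed] <- subspace
    if (length(free)) st[free] <- as.integer(unlist(grid[i, free]))
    succ <- successor_states(model, st, "asynchronous")
    succ <- c(succ, successor_states(model, st, "synchronous"))
    for (s in succ) {
      if (length(fixed) && any(s[fixed] != subspace)) return(FALSE)
    }
  }
  TRUE
}

#' Enumerate the minimal trap spaces of a model
#'
#' Trap spaces are subspaces (hypercubes) of the state space closed under the
#' dynamics for any updating mode; the minimal (most specific) ones
#' approximate the attractors, and every stable state is a minimal trap space
#' with no free component. The search branches over fixing each component at
#' a level or leaving it free, pruning branches in which an already-fixed
#' component's rule is constantly different from its fixed value (such a
#' branch cannot be repaired by fixing more components), then filters the
#' closed subspaces down to the minimal ones.
#'
#' @param model A `logical_model` (Boolean or multivalued).
#' @return A tibble with one row per minimal trap space and one column per
#'   component; `NA` marks a free component.
#' @export
#' @examples
#' minimal_trap_spaces(parse_model("A, A\nB, !A"))
#' minimal_trap_spaces(parse_model("A, !A")) # only the full space
minimal_trap_spaces <- function(model) {
  comps <- component_names(model)
  ml <- max_levels(model)
  traps <- list()

  dfs <- function(i, fixed) {
    if (i > length(comps)) {
      # closure: every fixed component constant at its own value
      for (cn in names(fixed)) {
        res <- fold_function(model, model$functions[[cn]], fixed)
        if (res$kind != "constant" || res$level != fixed[[cn]]) return(invisible(NULL))
      }
      traps[[length(traps) + 1L]] <<- fixed
      return(invisible(NULL))
    }
    cn <- comps[[i]]
    dfs(i + 1L, fixed) # leave free
    for (v in 0:ml[[cn]]) {
      nxt <- fixed
      nxt[[cn]] <- as.integer(v)
      # prune: any fixed component already constant at a different value can
      # never become consistent by fixing more components
      ok <- TRUE
      for (dn in names(nxt)) {
        res <- fold_function(model, model$functions[[dn]], nxt)
        if (res$kind == "constant" && res$level != nxt[[dn]]) {
          ok <- FALSE
          break
        }
      }
      if (ok) dfs(i + 1L, nxt)
    }
    invisible(NULL)
  }
  dfs(1L, stats::setNames(integer(0), character(0)))

  minimal <- Filter(function(t) {
    !any(vapply(traps, function(o) {
      length(o) > length(t) && all(names(t) %in% names(o)) && all(o[names(t)] == t)
    }, logical(1)))
  }, traps)

  rows <- lapply(minimal, function(t) {
    s <- stats::setNames(rep(NA_integer_, length(comps)), comps)
    s[names(t)] <- t
    s
  })
  if (length(rows) > 1L) {
    keys <- vapply(rows, function(s) {
      paste(ifelse(is.na(s), "***", sprintf("%03d", s)), collapse = "")
    }, character(1))
    rows <- rows[order(keys)]
  }
  states_to_tibble(model, rows)
}

#' Encode a multivalued model as a Boolean one
#'
#' Each component with maximum level `m > 1` becomes `m` Boolean threshold
#' indicators `name_b1 .. name_bm` (`name_bk` is on iff the original level is
#' at least `k`); atoms `X:k` translate to the indicator `X_bk`. States where
#' a higher indicator is on without the lower ones are inadmissible and are
#' excluded when mapping results back. Stable states of the Boolean encoding
#' restricted to admissible states correspond exactly to stable states of the
#' multivalued model.
#'
#' @param model A `logical_model`.
#' @return A list with `model` (Boolean `logical_model`) and `mapping`
#'   (a tibble with columns `component`, `indicator`, `threshold`).
#' @export
booleanize <- function(model) {
  ml <- max_levels(model)
  if (all(ml == 1L)) {
    mapping <- tibble::tibble(
      component = component_names(model),
      indicator = component_names(model),
      threshold = 1L
    )
    return(list(model = model, mapping = mapping))
  }
  indicator_name <- function(cn, k) if (ml[[cn]] == 1L) cn else paste0(cn, "_b", k)

  translate <- function(e) {
    switch(e$k,
      const = e,
      atom = x_atom(indicator_name(e$comp, e$th), 1L),
      not = x_not(translate(e$x)),
      and = x_and(lapply(e$xs, translate)),
      or = x_or(lapply(e$xs, translate)),
      stop("unknown expression node kind: ", e$k)
    )
  }

  # Boolean rule for indicator k of component c: "target of f_c is >= k",
  # unrolled over the ordered cases (first match wins).
  indicator_rule <- function(fn, k) {
    build <- function(i) {
      if (i > length(fn$cases)) return(x_const(0L))
      cs <- fn$cases[[i]]
      cond <- translate(cs$cond)
      if (cs$target >= k) x_or(list(cond, build(i + 1L))) else x_and(list(x_not(cond), build(i + 1L)))
    }
    build(1L)
  }

  names_out <- character(0)
  input_out <- logical(0)
  functions <- list()
  map <- list()
  for (cn in component_names(model)) {
    is_input <- cn %in% input_names(model)
    if (ml[[cn]] == 1L) {
      names_out <- c(names_out, cn)
      input_out <- c(input_out, is_input)
      fn <- model$functions[[cn]]
      functions[[cn]] <- new_function(list(list(cond = translate(fn$cases[[1L]]$cond), target = 1L)))
      map[[length(map) + 1L]] <- list(cn, cn, 1L)
    } else {
      for (k in seq_len(ml[[cn]])) {
        ind <- indicator_name(cn, k)
        names_out <- c(names_out, ind)
        input_out <- c(input_out, FALSE)
        functions[[ind]] <- new_function(list(list(cond = indicator_rule(model$functions[[cn]], k), target = 1L)))
        map[[length(map) + 1L]] <- list(cn, ind, as.integer(k))
      }
    }
  }
  mapping <- tibble::tibble(
    component = vapply(map, `[[`, character(1), 1L),
    indicator = vapply(map, `[[`, character(1), 2L),
    threshold = vapply(map, `[[`, integer(1), 3L)
  )
  bool_model <- new_logical_model(
    tibble::tibble(name = names_out, max_level = 1L, input = input_out),
    functions
  )
  list(model = bool_model, mapping = mapping)
}

#' Map Boolean-encoded states back to multivalued levels
#'
#' Rows whose indicators are inadmissible (a threshold-`k+1` indicator on
#' while the threshold-`k` one is off) are dropped; for admissible rows the
#' original component's level is the highest threshold whose indicator is on.
#' Works for total states and for partial rows with `NA` entries (a
#' component's level is `NA` unless all of its indicators are determined).
#'
#' @param states A tibble of states of the booleanized model (columns =
#'   indicators), e.g. from [stable_states()].
#' @param mapping The `mapping` tibble returned by [booleanize()].
#' @return A tibble of states over the original components.
#' @export
debooleanize <- function(states, mapping) {
  comps <- unique(mapping$component)
  out <- lapply(comps, function(cn) {
    m <- mapping[mapping$component == cn, ]
    m <- m[order(m$threshold), ]
    inds <- as.matrix(states[, m$indicator, drop = FALSE])
    apply(inds, 1L, function(b) {
      if (anyNA(b)) return(NA_integer_)
      as.integer(sum(b))
    })
  })
  names(out) <- comps
  res <- tibble::as_tibble(lapply(out, function(x) as.integer(x)))
  # admissibility: indicators of each component must be monotone in threshold
  admissible <- rep(TRUE, nrow(states))
  for (cn in comps) {
    m <- mapping[mapping$component == cn, ]
    if (nrow(m) == 1L) next
    m <- m[order(m$threshold), ]
    inds <- as.matrix(states[, m$indicator, drop = FALSE])
    ok <- apply(inds, 1L, function(b) {
      if (anyNA(b)) return(TRUE)
      all(diff(b) <= 0L) # once off, stays off for higher thresholds
    })
    admissible <- admissible & ok
  }
  res[admissible, , drop = FALSE]
}
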