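#' Simplify a component's rule under a partial assignment
#'
#' Atoms on assigned components are replaced by constants and folded; cases
#' whose condition folds to 0 are dropped and a condition folding to 1 cuts
#' off the later cases. The rule is declared constant if and only if it
#' evaluates to a single level over *every* combination of its remaining free
#' regulators (decided by exhaustive evaluation, so the constancy test is
#' complete rather than syntactic); otherwise the constant-folded residual is
#' returned.
#'
#' @param model A `logical_model`.
#' @param component Component whose rule is simplified.
#' @param assignment Named vector of fixed levels (a clamp set or subspace).
#' @return A list: either `list(kind = "constant", level = <int>)` or
#'   `list(kind = "residual", fn = <folded function>)`.
#' @export
#' @examples
#' m <- toy_model("figure3")
#' simplify_under(m, "D", c(C = 1)) # constant 1
#' simplify_under(m, "E", c(D = 1)) # residual !F
simplify_under <- function(model, component, assignment) {
  check_component(model, component)
  assignment <- as_assignment(model, assignment)
  fold_function(model, model$functions[[component]], assignment)
}

# Internal core, assignment already validated.
fold_function <- function(model, fn, assignment) {
  cases <- list()
  for (cs in fn$cases) {
    cond <- fold_expr(cs$cond, assignment)
    if (cond$k == "const") {
      if (cond$v == 0L) next
      cases[[length(cases) + 1L]] <- list(cond = cond, target = cs$target)
      break # first always-true case shadows the rest
    }
    cases[[length(cases) + 1L]] <- list(cond = cond, target = cs$target)
  }
  if (length(cases) == 0L) {
    return(list(kind = "constant", level = 0L))
  }
  free <- unique(unlist(lapply(cases, function(cs) expr_atoms(cs$cond))))
  if (is.null(free)) free <- character(0)
  if (length(free) == 0L) {
    # first case condition is const 1
    return(list(kind = "constant", level = cases[[1L]]$target))
  }
  # complete constancy test: evaluate over all free-regulator combinations
  grid <- level_grid(max_levels(model)[free])
  vals <- apply(as.matrix(grid), 1L, function(row) {
    st <- stats::setNames(as.integer(row), free)
    for (cs in cases) {
      if (eval_expr(cs$cond, st)) return(cs$target)
    }
    0L
  })
  u <- unique(vals)
  if (length(u) == 1L) {
    return(list(kind = "constant", level = as.integer(u)))
  }
  list(kind = "residual", fn = new_function(cases))
}

#' Propagate clamped values through a model
#'
#' Starting from a set of clamped components, values are inserted into the
#' rules of target components; every rule that thereby becomes constant
#' freezes its component, whose value is propagated further, until no rule
#' simplifies any more. Clamps override the clamped components' own rules
#' (mutant semantics) and are conserved throughout. The fixpoint is
#' independent of the order in which components are examined.
#'
#' @param model A `logical_model`.
#' @param clamps Named vector of clamped levels, e.g. `c(C = 1)`; may be empty
#'   (constant rules still percolate).
#' @param worklist_order Optional integer seed; when given, the worklist is
#'   processed in a seeded random order instead of first-in-first-out. The
#'   result is identical either way (confluence); the knob exists to make that
#'   property testable.
#' @return A `propagation_result`: list with `clamps`, `frozen` (named vector,
#'   a superset of the clamps), `residuals` (named list of simplified
#'   functions of the free non-input components) and the model. Unclamped
#'   inputs are never frozen and carry no residual. Use [tidy()] for a
#'   per-component tibble and [tally_propagation()] for Table-style counts.
#' @export
#' @examples
#' m <- toy_model("figure3")
#' propagate(m, c(C = 1))
propagate <- function(model, clamps = NULL, worklist_order = NULL) {
  clamps <- as_assignment(model, clamps)
  comps <- component_names(model)
  inputs <- input_names(model)
  frozen <- clamps

  # targets[[r]]: components whose rule mentions r
  targets <- stats::setNames(vector("list", length(comps)), comps)
  for (cn in comps) {
    for (r in regulators(model, cn)) targets[[r]] <- c(targets[[r]], cn)
  }

  rng <- if (!is.null(worklist_order)) local_rng(worklist_order) else NULL
  queue <- setdiff(comps, c(inputs, names(frozen)))
  queued <- stats::setNames(comps %in% queue, comps)
  while (length(queue) > 0L) {
    idx <- if (is.null(rng)) 1L else rng$int(length(queue))
    cn <- queue[[idx]]
    queue <- queue[-idx]
    queued[[cn]] <- FALSE
    if (cn %in% names(frozen)) next
    res <- fold_function(model, model$functions[[cn]], frozen)
    if (res$kind == "constant") {
      frozen[[cn]] <- res$level
      for (t in targets[[cn]]) {
        if (!t %in% names(frozen) && !t %in% inputs && !queued[[t]]) {
          queue <- c(queue, t)
          queued[[t]] <- TRUE
        }
      }
    }
  }

  free <- setdiff(comps, c(names(frozen), inputs))
  residuals <- lapply(stats::setNames(free, free), function(cn) {
    fold_function(model, model$functions[[cn]], frozen)$fn
  })
  # keep frozen in declaration order for reproducible output
  frozen <- frozen[order(match(names(frozen), comps))]

  structure(
    list(model = model, clamps = clamps, frozen = frozen, residuals = residuals),
    class = "propagation_result"
  )
}

#' @export
print.propagation_result <- function(x, ...) {
  cat("<propagation_result> ", length(x$clamps), " clamp(s); ",
    length(x$frozen), " frozen, ", length(x$residuals), " free (non-input)\n",
    sep = ""
  )
  print(tidy(x), ...)
  invisible(x)
}

#' Tally frozen and free components after propagation
#'
#' Counts are over non-input components only (inputs are environmental
#' degrees of freedom, reported separately); a clamped non-input component is
#' counted at its clamped level. "Frozen active" means frozen at level 1 or
#' above.
#'
#' @param result A `propagation_result`.
#' @return A one-row tibble with columns `frozen_inactive`, `frozen_active`,
#'   `free`.
#' @export
tally_propagation <- function(result) {
  stopifnot(inherits(result, "propagation_result"))
  model <- result$model
  counted <- setdiff(component_names(model), input_names(model))
  fr <- result$frozen[intersect(names(result$frozen), counted)]
  tibble::tibble(
    frozen_inactive = sum(fr == 0L),
    frozen_active = sum(fr >= 1L),
    free = length(counted) - length(fr)
  )
}

#' Differential comparison of two propagation results
#'
#' Classifies every component of the model by how two alternative
#' perturbations freeze it: frozen OFF/ON under both, under only one
#' condition, frozen at conflicting values (OFF under one, ON under the
#' other), free under both, or input. Unclamped inputs always classify as
#' `input`.
#'
#' @param result_a,result_b `propagation_result`s computed on the same model.
#' @return A `propagation_comparison`; [tidy()] gives the per-component
#'   categories, [comparison_table()] the 3x3 frozen-inactive / frozen-active
#'   / free counts for condition A, condition B and their intersection.
#' @export
compare_propagations <- function(result_a, result_b) {
  stopifnot(inherits(result_a, "propagation_result"), inherits(result_b, "propagation_result"))
  if (!model_identical(result_a$model, result_b$model)) {
    stop("propagation results come from different models")
  }
  model <- result_a$model
  comps <- component_names(model)
  inputs <- input_names(model)
  fa <- result_a$frozen
  fb <- result_b$frozen

  category <- vapply(comps, USE.NAMES = FALSE, FUN.VALUE = character(1), FUN = function(cn) {
    a <- if (cn %in% names(fa)) fa[[cn]] else NA_integer_
    b <- if (cn %in% names(fb)) fb[[cn]] else NA_integer_
    if (cn %in% inputs && is.na(a) && is.na(b)) return("input")
    if (is.na(a) && is.na(b)) return("free_both")
    if (is.na(b)) return(if (a == 0L) "frozen_off_A_only" else "frozen_on_A_only")
    if (is.na(a)) return(if (b == 0L) "frozen_off_B_only" else "frozen_on_B_only")
    if (a == 0L && b == 0L) return("frozen_off_both")
    if (a >= 1L && b >= 1L) return("frozen_on_both")
    "frozen_conflict"
  })

  per_component <- tibble::tibble(
    component = comps,
    input = comps %in% inputs,
    frozen_a = vapply(comps, function(cn) if (cn %in% names(fa)) fa[[cn]] else NA_integer_, integer(1), USE.NAMES = FALSE),
    frozen_b = vapply(comps, function(cn) if (cn %in% names(fb)) fb[[cn]] else NA_integer_, integer(1), USE.NAMES = FALSE),
    category = category
  )

  structure(
    list(model = model, components = per_component,
         clamps_a = result_a$clamps, clamps_b = result_b$clamps),
    class = "propagation_comparison"
  )
}

#' 3x3 differential tally of a propagation comparison
#'
#' Rows are frozen-inactive, frozen-active and free; columns count non-input
#' components under condition A, condition B, and in the intersection
#' (frozen at the *same* level under both conditions, split at level 0 vs
#' level >= 1; the free intersection counts components free under both). The A
#' and B columns each sum to the number of non-input components.
#'
#' @param comparison A `propagation_comparison`.
#' @return A tibble with columns `impact`, `A`, `B`, `intersection`.
#' @export
comparison_table <- function(comparison) {
  stopifnot(inherits(comparison, "propagation_comparison"))
  d <- comparison$components[!comparison$components$input, ]
  col <- function(fr) {
    c(
      sum(!is.na(fr) & fr == 0L),
      sum(!is.na(fr) & fr >= 1L),
      sum(is.na(fr))
    )
  }
  same <- !is.na(d$frozen_a) & !is.na(d$frozen_b) & d$frozen_a == d$frozen_b
  tibble::tibble(
    impact = c("frozen_inactive", "frozen_active", "free"),
    A = col(d$frozen_a),
    B = col(d$frozen_b),
    intersection = c(
      sum(same & d$frozen_a == 0L),
      sum(same & d$frozen_a >= 1L),
      sum(is.na(d$frozen_a) & is.na(d$frozen_b))
    )
  )
}

# Fig-5 style palette for the annotated regulatory graph.
CATEGORY_FILL <- c(
  input = "gray",
  frozen_off_both = "yellow",
  frozen_on_both = "orange",
  frozen_off_A_only = "lightblue",
  frozen_on_A_only = "darkblue",
  frozen_off_B_only = "green",
  frozen_on_B_only = "darkgreen",
  frozen_conflict = "red",
  free_both = "white"
)

#' Export a differential comparison as an annotated regulatory graph
#'
#' Emits a graph document with one node per component, coloured by its
#' differential category (inputs gray, frozen-OFF-both yellow,
#' frozen-ON-both orange, A-only OFF light blue, A-only ON dark blue, B-only
#' frozen green/dark green, free white), and one edge per regulator-target
#' pair.
#'
#' @param comparison A `propagation_comparison`.
#' @param file Optional output path.
#' @param format `"dot"` (Graphviz) or `"graphml"`.
#' @return The document as a single string, invisibly when `file` is given.
#' @export
export_annotated_graph <- function(comparison, file = NULL, format = c("dot", "graphml")) {
  stopifnot(inherits(comparison, "propagation_comparison"))
  format <- match.arg(format)
  model <- comparison$model
  d <- comparison$components
  edges <- do.call(rbind, lapply(component_names(model), function(cn) {
    regs <- regulators(model, cn)
    if (length(regs) == 0L) return(NULL)
    data.frame(from = regs, to = cn)
  }))
  doc <- if (format == "dot") {
    nodes <- vapply(seq_len(nrow(d)), function(i) {
      fill <- CATEGORY_FILL[[d$category[[i]]]]
      fontcolor <- if (fill %in% c("darkblue", "darkgreen", "red")) "white" else "black"
      sprintf(
        "  %s [style=filled, fillcolor=%s, fontcolor=%s, class=\"%s\"];",
        d$component[[i]], fill, fontcolor, d$category[[i]]
      )
    }, character(1))
    arcs <- if (is.null(edges)) character(0) else {
      sprintf("  %s -> %s;", edges$from, edges$to)
    }
    paste(c("digraph logical_model {", nodes, arcs, "}"), collapse = "\n")
  } else {
    nodes <- vapply(seq_len(nrow(d)), function(i) {
      paste0(
        "    <node id=\"", d$component[[i]], "\"><data key=\"category\">",
        d$category[[i]], "</data><data key=\"fill\">",
        CATEGORY_FILL[[d$category[[i]]]], "</data></node>"
      )
    }, character(1))
    arcs <- if (is.null(edges)) character(0) else {
      paste0("    <edge source=\"", edges$from, "\" target=\"", edges$to, "\"/>")
    }
    paste(c(
      "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
      "<graphml xmlns=\"http://graphml.graphdrawing.org/xmlns\">",
      "  <key id=\"category\" for=\"node\" attr.name=\"category\" attr.type=\"string\"/>",
      "  <key id=\"fill\" for=\"node\" attr.name=\"fill\" attr.type=\"string\"/>",
      "  <graph edgedefault=\"directed\">",
      nodes, arcs,
      "  </graph>", "</graphml>"
    ), collapse = "\n")
  }
  if (!is.null(file)) {
    writeLines(doc, file)
    return(invisible(doc))
  }
  doc
}

# Minimal deterministic RNG (xorshift-ish via R's own, isolated from the
# global stream) used for seeded worklist scrambling.
local_rng <- function(seed) {
  env <- new.env()
  env$state <- as.integer(seed)
  list(
    int = function(n) {
      # linear congruential step, constants from Numerical Recipes
      env$state <- as.integer((1664525 * as.double(env$state) + 1013904223) %% 2^31)
      1L + (env$state %% n)
    }
  )
}
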