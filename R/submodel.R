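#' Extract a sub-model around selected components
#'
#' Builds the sub-model `M' = (S, f')` where `S` is the selection plus the
#' regulators of every selected component (one regulator layer, no
#' recursion). A component of `S` keeps its original rule when all of its
#' regulators lie in `S`; otherwise it becomes an external input (identity
#' rule), so that the verification harness can explore every valuation of the
#' sub-model boundary. Maximum levels are preserved and components stay in
#' their original declaration order.
#'
#' @param model A `logical_model`.
#' @param keep Character vector of selected component names (non-empty).
#' @return A `logical_model` over `S`.
#' @export
#' @examples
#' m <- parse_model("A, Z\nB, A\nZ, Z")
#' extract_submodel(m, "B") # keeps B's rule, turns A into an input
extract_submodel <- function(model, keep) {
  keep <- unique(as.character(keep))
  if (length(keep) == 0L) stop("selection must be non-empty")
  unknown <- setdiff(keep, component_names(model))
  if (length(unknown)) stop("unknown component(s): ", paste(unknown, collapse = ", "))

  s <- keep
  for (cn in keep) s <- union(s, regulators(model, cn))
  s <- intersect(component_names(model), s) # declaration order

  ml <- max_levels(model)
  functions <- list()
  input <- logical(length(s))
  for (i in seq_along(s)) {
    cn <- s[[i]]
    if (all(regulators(model, cn) %in% s)) {
      functions[[cn]] <- model$functions[[cn]]
      input[[i]] <- model$components$input[[match(cn, model$components$name)]]
    } else {
      functions[[cn]] <- identity_function(cn, ml[[cn]])
      input[[i]] <- TRUE
    }
  }
  new_logical_model(
    tibble::tibble(name = s, max_level = unname(ml[s]), input = input),
    functions
  )
}
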