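# Built-in toy models and a seeded random-model generator.

TOY_FIGURE3 <- "A, A
B, B
C, C
F, F
D, A | B | C
E, D & !F"

# Calcium handling at the endoplasmic reticulum, as a matched fail/pass pair:
# the default rule for the ER calcium reservoir ("filled when the SERCA pumps
# are on and the IP3 receptor is closed") wrongly requires SERCA to stay on
# for the reservoir to stay full; the corrected rule lets a full reservoir
# persist as long as IP3R1 is closed. Both fixtures give IP3R1 and SERCA toy
# upstream inputs so that stable states can be explored per context.
TOY_CALCIUM_DEFAULT <- "IP3R_stim, IP3R_stim
SERCA_stim, SERCA_stim
IP3R1, IP3R_stim
SERCA, SERCA_stim
Calcium_ER, SERCA & !IP3R1"

TOY_CALCIUM_CORRECTED <- "IP3R_stim, IP3R_stim
SERCA_stim, SERCA_stim
IP3R1, IP3R_stim
SERCA, SERCA_stim
Calcium_ER, (SERCA | Calcium_ER) & !IP3R1"

#' Built-in toy models
#'
#' * `figure3`: six Boolean components — four inputs `A`, `B`, `C`, `F` and
#'   two core nodes with `D = A | B | C` and `E = D & !F`. Clamping `C` at 1
#'   freezes `D` on and reduces `E`'s rule to `!F`.
#' * `calcium_default`: a small ER-calcium module in which the reservoir rule
#'   `Calcium_ER = SERCA & !IP3R1` makes a full reservoir with inactive pumps
#'   impossible — the buggy rule a verification suite should catch.
#' * `calcium_corrected`: same module with
#'   `Calcium_ER = (SERCA | Calcium_ER) & !IP3R1`, letting the reservoir stay
#'   full whenever the IP3 receptor is closed.
#'
#' The exact rules of these toys are reconstructions of the published
#' behaviour (the sources describe the behaviour, not the rule text).
#'
#' @param name One of `"figure3"`, `"calcium_default"`, `"calcium_corrected"`.
#' @return A `logical_model`.
#' @export
toy_model <- function(name) {
  txt <- switch(name,
    figure3 = TOY_FIGURE3,
    calcium_default = TOY_CALCIUM_DEFAULT,
    calcium_corrected = TOY_CALCIUM_CORRECTED,
    stop("unknown toy model: '", name, "'")
  )
  parse_model(txt, dialect = "bnet")
}

#' Generate a seeded random logical model
#'
#' The first `n_inputs` components get identity rules (inputs); every other
#' component gets a random expression tree over up to `max_in_degree` distinct
#' regulators, combining literals with `&` or `|` (probability
#' `expression_bias` of `&` at each internal node) and negating literals with
#' probability `negation_prob`. When `max_level > 1`, each non-input
#' component draws a maximum level in `1..max_level`; multivalued components
#' get one random condition per level, in random case order. Rules are built
#' from expression trees (not random truth tables) so generated models stay
#' readable in rule-table form. The same seed always yields the same model;
#' the global RNG stream is left untouched.
#'
#' @param n_components Total number of components (>= 1).
#' @param n_inputs Number of input components (<= `n_components`).
#' @param max_in_degree Maximum number of distinct regulators per rule.
#' @param max_level Maximum activity level a component may get (1 = Boolean).
#' @param expression_bias Probability of `&` over `|` at each internal node.
#' @param negation_prob Probability a literal is negated.
#' @param seed Integer seed.
#' @return A `logical_model` that passes [validate_model()].
#' @export
#' @examples
#' m <- random_model(8, n_inputs = 2, seed = 42)
#' nrow(validate_model(m)) # 0
random_model <- function(n_components, n_inputs = 0L, max_in_degree = 2L,
                         max_level = 1L, expression_bias = 0.5,
                         negation_prob = 0.25, seed = 1L) {
  stopifnot(
    n_components >= 1L, n_inputs >= 0L, n_inputs <= n_components,
    max_in_degree >= 1L, max_level >= 1L,
    expression_bias >= 0, expression_bias <= 1,
    negation_prob >= 0, negation_prob <= 1
  )
  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(seed)

  name <- sprintf("v%02d", seq_len(n_components))
  is_input <- seq_len(n_components) <= n_inputs
  ml <- ifelse(is_input | max_level == 1L, 1L,
    vapply(seq_len(n_components), function(i) sample.int(max_level, 1L), integer(1))
  )
  ml <- as.integer(ml)
  names(ml) <- name

  # random binary tree whose leaves are literals on each regulator (every
  # chosen regulator appears at least once)
  random_tree <- function(regs) {
    leaves <- lapply(regs, function(r) {
      a <- x_atom(r, sample.int(ml[[r]], 1L))
      if (stats::runif(1) < negation_prob) x_not(a) else a
    })
    while (length(leaves) > 1L) {
      i <- sample.int(length(leaves) - 1L, 1L)
      op <- if (stats::runif(1) < expression_bias) x_and else x_or
      merged <- op(list(leaves[[i]], leaves[[i + 1L]]))
      leaves[[i]] <- merged
      leaves[[i + 1L]] <- NULL
    }
    leaves[[1L]]
  }

  functions <- list()
  for (i in seq_len(n_components)) {
    cn <- name[[i]]
    if (is_input[[i]]) {
      functions[[cn]] <- identity_function(cn, ml[[cn]])
      next
    }
    k <- min(sample.int(max_in_degree, 1L), n_components)
    regs <- sample(name, k)
    if (ml[[cn]] == 1L) {
      functions[[cn]] <- new_function(list(list(cond = random_tree(regs), target = 1L)))
    } else {
      # each case gets a read-once condition over its own disjoint regulator
      # group, so every case is reachable (no condition can be subsumed by the
      # disjunction of the others); distinct target levels, random case order
      n_cases <- sample.int(min(ml[[cn]], k), 1L)
      groups <- split(regs, sort(rep_len(seq_len(n_cases), k)))
      levels <- sample(seq_len(ml[[cn]]), n_cases)
      cases <- lapply(seq_len(n_cases), function(j) {
        list(cond = random_tree(groups[[j]]), target = as.integer(levels[[j]]))
      })
      functions[[cn]] <- new_function(cases)
    }
  }
  new_logical_model(tibble::tibble(name = name, max_level = unname(ml), input = is_input), functions)
}

#' Express a perturbation as a clamp set
#'
#' A knockout clamps the component at 0; ectopic expression clamps it at the
#' given level (defaults to the component's maximum). The returned clamp set
#' composes with other clamps and feeds directly into [propagate()],
#' [stable_states()] or a specification context.
#'
#' @param model A `logical_model`.
#' @param component Component to perturb.
#' @param kind `"knockout"` or `"ectopic"`.
#' @param level Level for ectopic expression (default: the component's
#'   `max_level`).
#' @return A named integer vector of length 1.
#' @export
apply_perturbation <- function(model, component, kind = c("knockout", "ectopic"), level = NULL) {
  kind <- match.arg(kind)
  check_component(model, component)
  ml <- max_levels(model)[[component]]
  v <- switch(kind,
    knockout = 0L,
    ectopic = {
      if (is.null(level)) level <- ml
      if (level < 1L || level > ml) {
        stop("ectopic level ", level, " out of bounds for '", component, "' (max ", ml, ")")
      }
      as.integer(level)
    }
  )
  stats::setNames(v, component)
}
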