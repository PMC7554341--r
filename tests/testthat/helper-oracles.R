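# Brute-force oracles, independent of the search-based implementations:
# stable states by full state enumeration, minimal trap spaces by full
# subspace enumeration with the successor-based closure check.

# Matrix of all states of a model (rows = states, named columns).
all_states_matrix <- function(model) {
  ml <- logimodel:::max_levels(model)
  g <- expand.grid(lapply(ml, function(m) 0:m), KEEP.OUT.ATTRS = FALSE)
  as.matrix(g)
}

# Vector of target levels of one component over a state matrix (first
# matching case wins, default 0), evaluated columnwise.
oracle_targets <- function(model, component, mat) {
  fn <- model$functions[[component]]
  out <- integer(nrow(mat))
  undecided <- rep(TRUE, nrow(mat))
  for (cs in fn$cases) {
    hit <- undecided & logimodel:::eval_expr_mat(cs$cond, mat)
    out[hit] <- cs$target
    undecided <- undecided & !hit
  }
  out
}

# Exhaustive stable states (optionally of the clamped model, mutant
# semantics), as a tibble sorted the same way as stable_states().
oracle_stable_states <- function(model, clamps = NULL) {
  comps <- logimodel:::component_names(model)
  mat <- all_states_matrix(model)
  stable <- rep(TRUE, nrow(mat))
  for (cn in comps) {
    tgt <- if (!is.null(clamps) && cn %in% names(clamps)) {
      rep(as.integer(clamps[[cn]]), nrow(mat))
    } else {
      oracle_targets(model, cn, mat)
    }
    stable <- stable & (tgt == mat[, cn])
  }
  m <- mat[stable, , drop = FALSE]
  if (nrow(m) > 1L) {
    keys <- apply(m, 1L, function(s) paste(sprintf("%03d", s), collapse = ""))
    m <- m[order(keys), , drop = FALSE]
  }
  out <- tibble::as_tibble(as.data.frame(m))
  names(out) <- comps
  out
}

# All subspaces as partial assignments: per component either free or a level.
enumerate_subspaces <- function(model) {
  comps <- logimodel:::component_names(model)
  ml <- logimodel:::max_levels(model)
  choices <- lapply(comps, function(cn) c(NA_integer_, 0:ml[[cn]]))
  g <- expand.grid(choices, KEEP.OUT.ATTRS = FALSE)
  names(g) <- comps
  lapply(seq_len(nrow(g)), function(i) {
    row <- unlist(g[i, ])
    row[!is.na(row)]
  })
}

# Exhaustive minimal trap spaces via is_trap_space (successor enumeration),
# as a tibble sorted the same way as minimal_trap_spaces().
oracle_minimal_trap_spaces <- function(model) {
  comps <- logimodel:::component_names(model)
  subs <- enumerate_subspaces(model)
  closed <- Filter(function(p) is_trap_space(model, p), subs)
  minimal <- Filter(function(t) {
    !any(vapply(closed, function(o) {
      length(o) > length(t) && all(names(t) %in% names(o)) && all(o[names(t)] == t)
    }, logical(1)))
  }, closed)
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
  logimodel:::states_to_tibble(model, rows)
}

# Seeded random clamp set over a model: about `k` components at random levels.
random_clamps <- function(model, k, seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  comps <- logimodel:::component_names(model)
  ml <- logimodel:::max_levels(model)
  picked <- sample(comps, min(k, length(comps)))
  stats::setNames(
    vapply(picked, function(cn) sample(0:ml[[cn]], 1L), integer(1)),
    picked
  )
}

# Total frozen assignment of a propagation result as a partial assignment.
frozen_of <- function(result) result$frozen
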