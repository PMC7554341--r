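# Expression trees for logical rules.
#
# An expression is a plain nested list with a `k` discriminator:
#   const : list(k = "const", v = 0L | 1L)
#   atom  : list(k = "atom", comp = <name>, th = <threshold >= 1>)
#   not   : list(k = "not", x = <expr>)
#   and   : list(k = "and", xs = list(<expr>, ...))   # >= 2 children
#   or    : list(k = "or",  xs = list(<expr>, ...))   # >= 2 children
#
# ATOM(x, th) is true in a state s iff s[x] >= th. Boolean literals are atoms
# with threshold 1. The smart constructors fold degenerate cases so that
# simplification never produces 0/1-ary connectives.

x_const <- function(v) list(k = "const", v = as.integer(v))

x_atom <- function(comp, th = 1L) list(k = "atom", comp = comp, th = as.integer(th))

x_not <- function(x) {
  if (x$k == "const") return(x_const(1L - x$v))
  if (x$k == "not") return(x$x)
  list(k = "not", x = x)
}

x_and <- function(xs) {
  out <- list()
  for (x in xs) {
    if (x$k == "const") {
      if (x$v == 0L) return(x_const(0L))
      next # drop neutral 1
    }
    if (x$k == "and") out <- c(out, x$xs) else out <- c(out, list(x))
  }
  if (length(out) == 0L) return(x_const(1L))
  if (length(out) == 1L) return(out[[1L]])
  list(k = "and", xs = out)
}

x_or <- function(xs) {
  out <- list()
  for (x in xs) {
    if (x$k == "const") {
      if (x$v == 1L) return(x_const(1L))
      next # drop neutral 0
    }
    if (x$k == "or") out <- c(out, x$xs) else out <- c(out, list(x))
  }
  if (length(out) == 0L) return(x_const(0L))
  if (length(out) == 1L) return(out[[1L]])
  list(k = "or", xs = out)
}

# Evaluate an expression in a total (or sufficient) state: named integer vector.
eval_expr <- function(e, state) {
  switch(e$k,
    const = e$v == 1L,
    atom = {
      v <- state[[e$comp]]
      if (is.null(v) || is.na(v)) stop("state does not assign component '", e$comp, "'")
      v >= e$th
    },
    not = !eval_expr(e$x, state),
    and = {
      for (x in e$xs) if (!eval_expr(x, state)) return(FALSE)
      TRUE
    },
    or = {
      for (x in e$xs) if (eval_expr(x, state)) return(TRUE)
      FALSE
    },
    stop("unknown expression node kind: ", e$k)
  )
}

# Vectorised evaluation over a state matrix (rows = states, named columns).
# Returns a logical vector of length nrow(mat). Used by the exhaustive oracles.
eval_expr_mat <- function(e, mat) {
  switch(e$k,
    const = rep(e$v == 1L, nrow(mat)),
    atom = mat[, e$comp] >= e$th,
    not = !eval_expr_mat(e$x, mat),
    and = {
      acc <- eval_expr_mat(e$xs[[1L]], mat)
      for (x in e$xs[-1L]) acc <- acc & eval_expr_mat(x, mat)
      acc
    },
    or = {
      acc <- eval_expr_mat(e$xs[[1L]], mat)
      for (x in e$xs[-1L]) acc <- acc | eval_expr_mat(x, mat)
      acc
    },
    stop("unknown expression node kind: ", e$k)
  )
}

# Substitute assigned components (named integer vector) by constants and
# constant-fold. Atoms on unassigned components are kept untouched.
fold_expr <- function(e, assignment) {
  switch(e$k,
    const = e,
    atom = {
      if (e$comp %in% names(assignment)) {
        x_const(as.integer(assignment[[e$comp]] >= e$th))
      } else {
        e
      }
    },
    not = x_not(fold_expr(e$x, assignment)),
    and = x_and(lapply(e$xs, fold_expr, assignment = assignment)),
    or = x_or(lapply(e$xs, fold_expr, assignment = assignment)),
    stop("unknown expression node kind: ", e$k)
  )
}

# Components appearing in atoms of an expression.
expr_atoms <- function(e) {
  switch(e$k,
    const = character(0),
    atom = e$comp,
    not = expr_atoms(e$x),
    and = unique(unlist(lapply(e$xs, expr_atoms))),
    or = unique(unlist(lapply(e$xs, expr_atoms))),
    stop("unknown expression node kind: ", e$k)
  )
}

# Maximum threshold used on a given component within an expression (0 if absent).
expr_max_threshold <- function(e, comp) {
  switch(e$k,
    const = 0L,
    atom = if (e$comp == comp) e$th else 0L,
    not = expr_max_threshold(e$x, comp),
    and = max(vapply(e$xs, expr_max_threshold, integer(1), comp = comp)),
    or = max(vapply(e$xs, expr_max_threshold, integer(1), comp = comp)),
    stop("unknown expression node kind: ", e$k)
  )
}

# Render an expression in rule syntax. Thresholds > 1 are written `name:th`
# (native JSON dialect); the bnet dialect only ever sees threshold-1 atoms.
# Precedence: `!` > `&` > `|`. A connective nested directly under a connective
# of the same kind is parenthesised so that parsing the output reproduces the
# tree exactly (the parser flattens unparenthesised chains).
deparse_expr <- function(e, parent = "top") {
  prec <- c(top = 0L, or = 1L, and = 2L, not = 3L, atom = 4L, const = 4L)
  s <- switch(e$k,
    const = as.character(e$v),
    atom = if (e$th == 1L) e$comp else paste0(e$comp, ":", e$th),
    not = paste0("!", deparse_expr(e$x, "not")),
    and = paste(vapply(e$xs, deparse_expr, character(1), parent = "and"), collapse = " & "),
    or = paste(vapply(e$xs, deparse_expr, character(1), parent = "or"), collapse = " | "),
    stop("unknown expression node kind: ", e$k)
  )
  if (prec[[e$k]] < prec[[parent]] || (e$k == parent && e$k %in% c("and", "or"))) {
    s <- paste0("(", s, ")")
  }
  s
}

expr_identical <- function(a, b) identical(a, b)
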