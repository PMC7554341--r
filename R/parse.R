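# Rule-table parsing: bnet dialect and native JSON dialect.
#
# bnet grammar (Boolean only), one rule per line:
#   line   := target "," expr
#   expr   := term ("|" term)*            # lowest precedence
#   term   := factor ("&" factor)*
#   factor := "!" factor | "(" expr ")" | "0" | "1" | IDENT
# `#` starts a comment; blank lines are ignored. A component whose rule is
# exactly itself ("A, A") is an input. Identifiers are case-sensitive.
#
# The native JSON dialect adds multivalued components:
#   {"components": [{"name": "X", "max_level": 2, "input": false}, ...],
#    "rules": {"X": [{"condition": "A & Y:2", "target": 2}, ...], ...}}
# Cases are tried in order; the first matching condition gives the target
# level, and 0 applies when none matches. `Y:2` is a threshold atom (true iff
# the level of Y is >= 2). Input components may omit their rules entry (an
# identity rule is filled in).

tokenize_expr <- function(text, line = NA, allow_threshold = FALSE) {
  toks <- list()
  i <- 1L
  n <- nchar(text)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^\\s$", ch)) {
      i <- i + 1L
    } else if (ch %in% c("&", "|", "!", "(", ")")) {
      toks[[length(toks) + 1L]] <- list(t = ch)
      i <- i + 1L
    } else if (ch %in% c("0", "1") && !grepl("[A-Za-z0-9_]", substr(text, i + 1L, i + 1L))) {
      toks[[length(toks) + 1L]] <- list(t = "const", v = as.integer(ch))
      i <- i + 1L
    } else if (grepl("[A-Za-z_]", ch)) {
      m <- regmatches(substr(text, i, n), regexpr("^[A-Za-z_][A-Za-z0-9_]*", substr(text, i, n)))
      i <- i + nchar(m)
      th <- 1L
      if (allow_threshold && substr(text, i, i) == ":") {
        tm <- regmatches(substr(text, i + 1L, n), regexpr("^[0-9]+", substr(text, i + 1L, n)))
        if (length(tm) == 0L) parse_err("expected level after ':'", line)
        th <- as.integer(tm)
        i <- i + 1L + nchar(tm)
      }
      toks[[length(toks) + 1L]] <- list(t = "ident", name = m, th = th)
    } else {
      parse_err(paste0("unexpected character '", ch, "'"), line)
    }
  }
  toks
}

parse_err <- function(msg, line = NA) {
  if (is.na(line)) stop("syntax error: ", msg, call. = FALSE)
  stop("syntax error at line ", line, ": ", msg, call. = FALSE)
}

# Recursive-descent parser over the token list. Returns an expression tree.
parse_expr_tokens <- function(toks, line = NA) {
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]]$t else NA_character_
  advance <- function() {
    tok <- toks[[pos]]
    pos <<- pos + 1L
    tok
  }
  p_or <- function() {
    xs <- list(p_and())
    while (!is.na(peek()) && peek() == "|") {
      advance()
      xs[[length(xs) + 1L]] <- p_and()
    }
    if (length(xs) == 1L) xs[[1L]] else list(k = "or", xs = xs)
  }
  p_and <- function() {
    xs <- list(p_factor())
    while (!is.na(peek()) && peek() == "&") {
      advance()
      xs[[length(xs) + 1L]] <- p_factor()
    }
    if (length(xs) == 1L) xs[[1L]] else list(k = "and", xs = xs)
  }
  p_factor <- function() {
    t <- peek()
    if (is.na(t)) parse_err("unexpected end of expression", line)
    if (t == "!") {
      advance()
      return(x_not(p_factor()))
    }
    if (t == "(") {
      advance()
      e <- p_or()
      if (is.na(peek()) || peek() != ")") parse_err("expected ')'", line)
      advance()
      return(e)
    }
    if (t == "const") {
      return(x_const(advance()$v))
    }
    if (t == "ident") {
      tok <- advance()
      return(x_atom(tok$name, tok$th))
    }
    parse_err(paste0("unexpected token '", t, "'"), line)
  }
  e <- p_or()
  if (!is.na(peek())) parse_err(paste0("unexpected token '", peek(), "' after expression"), line)
  e
}

parse_expression <- function(text, line = NA, allow_threshold = FALSE) {
  toks <- tokenize_expr(text, line, allow_threshold)
  if (length(toks) == 0L) parse_err("empty expression", line)
  parse_expr_tokens(toks, line)
}

#' Parse a logical model from text
#'
#' @param text Model source: a bnet-style rule table (`"target, expression"`
#'   lines) or a native JSON document with multivalued components.
#' @param dialect `"bnet"` (Boolean rule table) or `"json"` (native dialect).
#' @return A validated [logical_model].
#' @export
#' @examples
#' m <- parse_model("A, B\nB, !A")
#' regulators(m, "A")
parse_model <- function(text, dialect = c("bnet", "json")) {
  dialect <- match.arg(dialect)
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text))) {
    stop("model text must be a non-empty string")
  }
  switch(dialect,
    bnet = parse_bnet(text),
    json = parse_native_json(text)
  )
}

parse_bnet <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  names <- character(0)
  exprs <- list()
  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[[i]])
    if (!nzchar(trimws(ln))) next
    comma <- regexpr(",", ln, fixed = TRUE)
    if (comma < 0L) parse_err("expected 'target, expression'", i)
    target <- trimws(substr(ln, 1L, comma - 1L))
    if (!grepl(NAME_RX, target)) parse_err(paste0("invalid target name '", target, "'"), i)
    if (target %in% names) parse_err(paste0("duplicate definition of '", target, "'"), i)
    rhs <- substr(ln, comma + 1L, nchar(ln))
    e <- parse_expression(rhs, line = i, allow_threshold = FALSE)
    names <- c(names, target)
    exprs[[target]] <- e
  }
  if (length(names) == 0L) stop("model text contains no rules")
  functions <- lapply(exprs, function(e) new_function(list(list(cond = e, target = 1L))))
  new_logical_model(
    tibble::tibble(name = names, max_level = 1L, input = NA),
    functions
  )
}

parse_native_json <- function(text) {
  doc <- jsonlite::fromJSON(text, simplifyVector = FALSE)
  if (!is.list(doc) || is.null(doc$components)) stop("native JSON model needs a 'components' array")
  comps <- doc$components
  name <- vapply(comps, function(c) as.character(c$name), character(1))
  max_level <- vapply(comps, function(c) {
    if (is.null(c$max_level)) 1L else as.integer(c$max_level)
  }, integer(1))
  input <- vapply(comps, function(c) {
    if (is.null(c$input)) NA else isTRUE(c$input)
  }, logical(1))
  rules <- if (is.null(doc$rules)) list() else doc$rules
  functions <- list()
  for (i in seq_along(name)) {
    cn <- name[[i]]
    r <- rules[[cn]]
    if (is.null(r)) {
      if (!isTRUE(input[[i]])) stop("no rule for non-input component '", cn, "'")
      functions[[cn]] <- identity_function(cn, max_level[[i]])
    } else {
      cases <- lapply(r, function(cs) {
        if (is.null(cs$condition) || is.null(cs$target)) {
          stop("each case needs 'condition' and 'target' (component '", cn, "')")
        }
        list(
          cond = parse_expression(as.character(cs$condition), allow_threshold = TRUE),
          target = as.integer(cs$target)
        )
      })
      functions[[cn]] <- new_function(cases)
    }
  }
  new_logical_model(tibble::tibble(name = name, max_level = max_level, input = input), functions)
}

#' Serialise a logical model
#'
#' Writing then re-parsing yields a structurally identical model; components
#' are emitted in declaration order. The bnet dialect is Boolean-only.
#'
#' @param model A `logical_model`.
#' @param dialect `"bnet"` or `"json"`.
#' @param file Optional path; when given the text is also written to it.
#' @return The model text, invisibly when `file` is given.
#' @export
write_model <- function(model, dialect = c("bnet", "json"), file = NULL) {
  dialect <- match.arg(dialect)
  txt <- switch(dialect,
    bnet = write_bnet(model),
    json = write_native_json(model)
  )
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

write_bnet <- function(model) {
  if (any(model$components$max_level > 1L)) {
    stop("bnet dialect is Boolean-only; use dialect = \"json\" for multivalued models")
  }
  lines <- vapply(component_names(model), function(cn) {
    paste0(cn, ", ", deparse_expr(model$functions[[cn]]$cases[[1L]]$cond))
  }, character(1))
  paste(lines, collapse = "\n")
}

write_native_json <- function(model) {
  comps <- lapply(seq_len(nrow(model$components)), function(i) {
    list(
      name = model$components$name[[i]],
      max_level = model$components$max_level[[i]],
      input = model$components$input[[i]]
    )
  })
  rules <- lapply(stats::setNames(component_names(model), component_names(model)), function(cn) {
    lapply(model$functions[[cn]]$cases, function(cs) {
      list(condition = deparse_expr(cs$cond), target = cs$target)
    })
  })
  jsonlite::toJSON(list(components = comps, rules = rules), auto_unbox = TRUE, pretty = TRUE)
}

#' Read a model from a file
#'
#' @param path File path.
#' @param dialect `"bnet"`, `"json"`, or `NULL` to guess from the extension
#'   (`.json` is native JSON, anything else bnet).
#' @return A [logical_model].
#' @export
read_model <- function(path, dialect = NULL) {
  if (is.null(dialect)) {
    dialect <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "bnet"
  }
  parse_model(paste(readLines(path, warn = FALSE), collapse = "\n"), dialect = dialect)
}
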