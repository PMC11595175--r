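# Atom selection language
#
# A small MDAnalysis/VMD-flavoured grammar, enough to express the subsets the
# analyses need (e.g. "chain A and resid 64-78 and name CA"):
#
#   expr      := term ("or" term)*
#   term      := factor ("and" factor)*
#   factor    := "not" factor | "(" expr ")" | predicate
#   predicate := "chain" values | "resid" ranges | "resname" values
#              | "name" values | "element" values
#              | "hydrogen" | "heavy" | "protein" | "nucleic" | "all"
#
# Values are whitespace-separated; resid accepts single numbers and a-b / a:b
# ranges.  Keywords are case-insensitive; atom/residue/chain values are not.

tokenize_selection <- function(expression) {
  pat <- "\\(|\\)|[^()[:space:]]+"
  m <- gregexpr(pat, expression)[[1]]
  if (m[1] == -1) stop("selection syntax error: empty expression")
  tokens <- regmatches(expression, gregexpr(pat, expression))[[1]]
  list(tokens = tokens, pos = as.integer(m))
}

#' Select atoms of a model
#'
#' Evaluates a selection expression (grammar documented in the README) against
#' a model and returns a `selection`: a deterministic, duplicate-free set of
#' 1-based atom indices plus the provenance expression.
#'
#' @param model `structure_model`
#' @param expression selection text, e.g. `"chain C and resid 118-129 and heavy"`.
#' @return object of class `selection` with elements `indices` and `expression`.
#' @export
select_atoms <- function(model, expression) {
  stopifnot(inherits(model, "structure_model"), is.character(expression))
  tk <- tokenize_selection(expression)
  st <- new.env(parent = emptyenv())
  st$tokens <- tk$tokens
  st$pos <- tk$pos
  st$i <- 1L
  mask <- parse_expr(st, model)
  if (st$i <= length(st$tokens)) {
    sel_error(st, "unexpected token '", st$tokens[st$i], "'")
  }
  idx <- which(mask)
  if (!length(idx)) warning("selection '", expression, "' matched no atoms")
  structure(list(indices = idx, expression = expression), class = "selection")
}

#' @export
print.selection <- function(x, ...) {
  cat("selection:", length(x$indices), "atoms ['", x$expression, "']\n", sep = "")
  invisible(x)
}

sel_error <- function(st, ...) {
  at <- if (st$i <= length(st$pos)) st$pos[st$i] else st$pos[length(st$pos)] + 1L
  stop("selection syntax error at position ", at, ": ", ...)
}

peek <- function(st) if (st$i <= length(st$tokens)) tolower(st$tokens[st$i]) else NA_character_
advance <- function(st) { tok <- st$tokens[st$i]; st$i <- st$i + 1L; tok }

SEL_KEYWORDS <- c("and", "or", "not", "(", ")", "chain", "resid", "resname",
                  "name", "element", "hydrogen", "heavy", "protein", "nucleic", "all")

parse_expr <- function(st, model) {
  mask <- parse_term(st, model)
  while (!is.na(peek(st)) && peek(st) == "or") {
    advance(st)
    mask <- mask | parse_term(st, model)
  }
  mask
}

parse_term <- function(st, model) {
  mask <- parse_factor(st, model)
  while (!is.na(peek(st)) && peek(st) == "and") {
    advance(st)
    mask <- mask & parse_factor(st, model)
  }
  mask
}

parse_factor <- function(st, model) {
  tok <- peek(st)
  if (is.na(tok)) sel_error(st, "unexpected end of expression")
  if (tok == "not") {
    advance(st)
    return(!parse_factor(st, model))
  }
  if (tok == "(") {
    advance(st)
    mask <- parse_expr(st, model)
    if (is.na(peek(st)) || peek(st) != ")") sel_error(st, "expected ')'")
    advance(st)
    return(mask)
  }
  parse_predicate(st, model)
}

collect_values <- function(st) {
  vals <- character()
  while (!is.na(peek(st)) && !(peek(st) %in% SEL_KEYWORDS)) {
    vals <- c(vals, advance(st))
  }
  if (!length(vals)) sel_error(st, "expected one or more values")
  vals
}

parse_predicate <- function(st, model) {
  a <- model$atoms
  tok <- peek(st)
  switch(tok,
    chain = { advance(st); a$chain %in% collect_values(st) },
    resname = { advance(st); toupper(a$resname) %in% toupper(collect_values(st)) },
    name = { advance(st); toupper(a$name) %in% toupper(collect_values(st)) },
    element = { advance(st); toupper(a$element) %in% toupper(collect_values(st)) },
    resid = {
      advance(st)
      vals <- collect_values(st)
      mask <- rep(FALSE, nrow(a))
      for (v in vals) {
        if (grepl("^-?[0-9]+[-:]-?[0-9]+$", v) && !grepl("^-?[0-9]+$", v)) {
          sep <- if (grepl(":", v)) ":" else "-"
          parts <- if (sep == ":") strsplit(v, ":", fixed = TRUE)[[1]] else {
            # split on the range dash, honouring a leading minus sign
            mm <- regmatches(v, regexec("^(-?[0-9]+)-(-?[0-9]+)$", v))[[1]]
            mm[2:3]
          }
          lo <- as.integer(parts[1]); hi <- as.integer(parts[2])
          if (is.na(lo) || is.na(hi)) sel_error(st, "bad resid range '", v, "'")
          if (lo > hi) sel_error(st, "reversed resid range '", v, "'")
          mask <- mask | (a$resid >= lo & a$resid <= hi)
        } else if (grepl("^-?[0-9]+$", v)) {
          mask <- mask | (a$resid == as.integer(v))
        } else {
          sel_error(st, "bad resid value '", v, "'")
        }
      }
      mask
    },
    hydrogen = { advance(st); a$is_hydrogen },
    heavy = { advance(st); !a$is_hydrogen },
    protein = { advance(st); toupper(a$resname) %in% PROTEIN_RESNAMES },
    nucleic = { advance(st); toupper(a$resname) %in% NUCLEIC_RESNAMES },
    all = { advance(st); rep(TRUE, nrow(a)) },
    sel_error(st, "unknown keyword '", st$tokens[st$i], "'")
  )
}
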