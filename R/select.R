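## Atom selection mini-language.
##
## Grammar (case-insensitive keywords, atom/residue values case-sensitive):
##   expr    := and_expr ('or' and_expr)*
##   and_expr:= unary ('and' unary)*
##   unary   := 'not' unary | '(' expr ')' | primary
##   primary := 'chain' <ids> | 'name' <names> | 'resname' <names>
##            | 'resid' <ids-or-ranges>       e.g. resid 185-200 30 42
##            | 'all' | 'none' | 'water'
## 'water' matches the shipped water residue names (TIP3, HOH, SOL, WAT).

.sel_keywords <- c("chain", "name", "resname", "resid", "and", "or", "not",
                   "all", "none", "water", "(", ")")

tokenize_selection <- function(expr) {
  spaced <- gsub("\\)", " ) ", gsub("\\(", " ( ", expr))
  raw <- regmatches(spaced, gregexpr("\\S+", spaced))[[1]]
  pos <- gregexpr("\\S+", spaced)[[1]]
  list(tokens = raw, pos = as.integer(pos))
}

#' Select atoms by expression
#'
#' Evaluates a selection expression against a topology and returns the
#' matching atom indices, in topology order. The expression grammar supports
#' `chain`, `name`, `resname`, `resid` (single ids and `low-high` ranges),
#' the keywords `all`, `none` and `water`, and the boolean operators
#' `and`, `or`, `not` with parentheses.
#'
#' The same expression on the same topology always yields the same indices.
#' An expression that matches nothing returns an empty selection with a
#' warning; a syntax error reports the offending token and its position.
#'
#' @param top A [topology()] tibble.
#' @param expr Selection expression, e.g.
#'   `"chain D and resid 185-200 and name CA"`.
#' @return An [atom_selection()] (integer indices with the expression kept
#'   as an attribute).
#' @examples
#' top <- topology(name = rep("CA", 4), resname = "GLY", resid = 1:4,
#'                 chain = c("A", "A", "B", "B"))
#' select_atoms(top, "chain B")
#' select_atoms(top, "resid 2-3 and not chain B")
#' @export
select_atoms <- function(top, expr) {
  top <- validate_topology(top)
  tk <- tokenize_selection(expr)
  tokens <- tk$tokens
  if (length(tokens) == 0) abort("empty selection expression")
  i <- 1L

  peek <- function() if (i <= length(tokens)) tokens[i] else NA_character_
  advance <- function() { t <- tokens[i]; i <<- i + 1L; t }
  fail <- function(msg, at = i) {
    where <- if (at <= length(tokens))
      sprintf("near '%s' (position %d)", tokens[at], tk$pos[at])
    else "at end of expression"
    abort(sprintf("selection syntax error in \"%s\": %s %s", expr, msg, where))
  }
  is_kw <- function(t) !is.na(t) && tolower(t) %in% .sel_keywords

  take_values <- function() {
    vals <- character(0)
    while (!is.na(peek()) && !is_kw(peek())) vals <- c(vals, advance())
    if (length(vals) == 0) fail("expected one or more values")
    vals
  }

  parse_primary <- function() {
    t <- peek()
    if (is.na(t)) fail("unexpected end of expression")
    kw <- tolower(t)
    if (kw == "(") {
      advance()
      m <- parse_or()
      if (is.na(peek()) || peek() != ")") fail("expected ')'")
      advance()
      return(m)
    }
    if (kw == "all") { advance(); return(rep(TRUE, nrow(top))) }
    if (kw == "none") { advance(); return(rep(FALSE, nrow(top))) }
    if (kw == "water") { advance(); return(top$resname %in% .water_resnames) }
    if (kw == "chain") { advance(); return(top$chain %in% take_values()) }
    if (kw == "name") { advance(); return(top$name %in% take_values()) }
    if (kw == "resname") { advance(); return(top$resname %in% take_values()) }
    if (kw == "resid") {
      advance()
      vals <- take_values()
      m <- rep(FALSE, nrow(top))
      for (v in vals) {
        if (grepl("^[0-9]+-[0-9]+$", v)) {
          lohi <- as.integer(strsplit(v, "-", fixed = TRUE)[[1]])
          if (anyNA(lohi) || length(lohi) != 2 || lohi[1] > lohi[2])
            fail(sprintf("bad resid range '%s'", v), at = i - 1L)
          m <- m | (top$resid >= lohi[1] & top$resid <= lohi[2])
        } else {
          id <- suppressWarnings(as.integer(v))
          if (is.na(id)) fail(sprintf("bad resid '%s'", v), at = i - 1L)
          m <- m | top$resid == id
        }
      }
      return(m)
    }
    fail("expected a selection keyword")
  }

  parse_unary <- function() {
    if (!is.na(peek()) && tolower(peek()) == "not") {
      advance()
      return(!parse_unary())
    }
    parse_primary()
  }

  parse_and <- function() {
    m <- parse_unary()
    while (!is.na(peek()) && tolower(peek()) == "and") {
      advance()
      m <- m & parse_unary()
    }
    m
  }

  parse_or <- function() {
    m <- parse_and()
    while (!is.na(peek()) && tolower(peek()) == "or") {
      advance()
      m <- m | parse_and()
    }
    m
  }

  mask <- parse_or()
  if (!is.na(peek())) fail("trailing input")
  if (!any(mask))
    warn(sprintf("selection \"%s\" matched no atoms", expr))
  atom_selection(which(mask), expression = expr)
}
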