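# Gene-protein-reaction (GPR) rules: boolean AND/OR expressions over gene
# symbols.  AND joins subunits of a complex, OR joins isozymes.

#' Parse a GPR rule into an AND/OR tree
#'
#' Grammar: `expr := term (or term)*`, `term := factor (and factor)*`,
#' `factor := gene | "(" expr ")"`. Operators are case-insensitive; gene
#' symbols may contain letters, digits, `_`, `.`, `-`.
#'
#' @param rule GPR string; `""` or `NA` yields `NULL` (spontaneous reaction).
#' @return `NULL`, a gene symbol (character scalar), or a list
#'   `list(op = "and"|"or", args = list(...))`.
#' @export
parse_gpr <- function(rule) {
  if (is.null(rule) || is.na(rule) || !nzchar(trimws(rule))) return(NULL)
  tokens <- regmatches(rule, gregexpr("\\(|\\)|[A-Za-z0-9_.-]+", rule))[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tokens[pos] else NA_character_
  advance <- function() { tok <- tokens[pos]; pos <<- pos + 1L; tok }
  parse_expr <- function() {
    args <- list(parse_term())
    while (!is.na(peek()) && tolower(peek()) == "or") {
      advance()
      args[[length(args) + 1L]] <- parse_term()
    }
    if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
  }
  parse_term <- function() {
    args <- list(parse_factor())
    while (!is.na(peek()) && tolower(peek()) == "and") {
      advance()
      args[[length(args) + 1L]] <- parse_factor()
    }
    if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
  }
  parse_factor <- function() {
    tok <- peek()
    if (is.na(tok)) stop("malformed GPR rule: unexpected end in ", sQuote(rule))
    if (tok == "(") {
      advance()
      inner <- parse_expr()
      if (is.na(peek()) || peek() != ")") {
        stop("malformed GPR rule: missing ')' in ", sQuote(rule))
      }
      advance()
      return(inner)
    }
    if (tok == ")" || tolower(tok) %in% c("and", "or")) {
      stop("malformed GPR rule: unexpected ", sQuote(tok), " in ", sQuote(rule))
    }
    advance()
  }
  tree <- parse_expr()
  if (pos <= length(tokens)) {
    stop("malformed GPR rule: trailing ", sQuote(tokens[pos]), " in ",
         sQuote(rule))
  }
  tree
}

#' Gene symbols referenced by a GPR rule
#' @param rule GPR string or parsed tree.
#' @return character vector of unique gene symbols (empty for spontaneous).
#' @export
gpr_genes <- function(rule) {
  tree <- if (is.character(rule) && length(rule) == 1L) parse_gpr(rule) else rule
  walk <- function(node) {
    if (is.null(node)) return(character(0))
    if (is.character(node)) return(node)
    unlist(lapply(node$args, walk))
  }
  unique(walk(tree))
}

#' Render a GPR tree back to a string
#' @param tree parsed GPR tree (see [parse_gpr()]).
#' @return GPR string; `""` for `NULL`.
#' @export
deparse_gpr <- function(tree) {
  if (is.null(tree)) return("")
  if (is.character(tree)) return(tree)
  parts <- vapply(tree$args, function(a) {
    s <- deparse_gpr(a)
    if (is.list(a) && a$op != tree$op) paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = paste0(" ", tree$op, " "))
}

#' Expand a GPR tree to isozyme alternatives (disjunctive normal form)
#'
#' Each alternative is one candidate catalytic unit: a set of genes that must
#' all be present (AND-conjuncts); distinct alternatives are isozymes.
#'
#' @param tree parsed GPR tree.
#' @return list of character vectors of gene symbols; empty list for `NULL`.
#' @export
gpr_alternatives <- function(tree) {
  if (is.null(tree)) return(list())
  if (is.character(tree)) return(list(tree))
  branches <- lapply(tree$args, gpr_alternatives)
  if (tree$op == "or") {
    alts <- do.call(c, branches)
  } else {
    alts <- Reduce(function(acc, nxt) {
      out <- list()
      for (a in acc) for (b in nxt) out[[length(out) + 1L]] <- c(a, b)
      out
    }, branches)
  }
  unique(lapply(alts, function(g) sort(unique(g))))
}
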