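#' Gene-protein-reaction (GPR) rules
#'
#' A GPR rule states which genes must be intact for a reaction to be
#' catalysed. Internally a rule is an expression tree whose internal nodes
#' are `and` (enzyme complex: all subunits required) or `or` (isoenzymes:
#' alternative enzymes), and whose leaves name genes. Two distinguished
#' markers exist: `spontaneous` for gene-independent reactions (always
#' active) and `unknown` for reactions whose catalysing gene has been
#' masked (inactive unless a hypothesis supplies a gene).
#'
#' @name gpr
#' @keywords internal
NULL

gpr_gene <- function(gene) {
  stopifnot(is.character(gene), length(gene) == 1L, nzchar(gene))
  structure(list(op = "gene", gene = gene), class = "gpr_rule")
}

gpr_node <- function(op, args) {
  stopifnot(op %in% c("and", "or"), length(args) >= 1L)
  if (length(args) == 1L) return(args[[1L]])
  structure(list(op = op, args = args), class = "gpr_rule")
}

gpr_and <- function(...) gpr_node("and", list(...))
gpr_or <- function(...) gpr_node("or", list(...))
gpr_spontaneous <- function() structure(list(op = "spontaneous"), class = "gpr_rule")
gpr_unknown <- function() structure(list(op = "unknown"), class = "gpr_rule")

is_gpr_rule <- function(x) inherits(x, "gpr_rule")

#' Parse a GPR rule string
#'
#' Grammar: `expr := term (" or " term)*`, `term := atom (" and " atom)*`,
#' `atom := gene-id | "(" expr ")"`. `and` binds tighter than `or`;
#' parentheses override. The empty string denotes a spontaneous reaction
#' and `"?"` a masked (unknown) one. Keywords are case-insensitive.
#'
#' @param text rule string, e.g. `"g1 and (g2 or g3)"`.
#' @return a `gpr_rule` expression tree.
#' @export
#' @examples
#' parse_gpr("g1 or g2")
#' parse_gpr("")   # spontaneous
#' parse_gpr("?")  # unknown / masked
parse_gpr <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text)) return(gpr_spontaneous())
  if (identical(text, "?")) return(gpr_unknown())

  padded <- gsub("\\)", " ) ", gsub("\\(", " ( ", text))
  toks <- strsplit(trimws(padded), "[[:space:]]+")[[1L]]
  pos <- 1L

  peek <- function() if (pos <= length(toks)) toks[[pos]] else NA_character_
  advance <- function() {
    tok <- peek()
    pos <<- pos + 1L
    tok
  }
  fail <- function(msg) stop("GPR parse error in '", text, "': ", msg, call. = FALSE)

  parse_expr <- function() {
    terms <- list(parse_term())
    while (!is.na(peek()) && tolower(peek()) == "or") {
      advance()
      terms[[length(terms) + 1L]] <- parse_term()
    }
    gpr_node("or", terms)
  }
  parse_term <- function() {
    atoms <- list(parse_atom())
    while (!is.na(peek()) && tolower(peek()) == "and") {
      advance()
      atoms[[length(atoms) + 1L]] <- parse_atom()
    }
    gpr_node("and", atoms)
  }
  parse_atom <- function() {
    tok <- advance()
    if (is.na(tok)) fail("unexpected end of rule")
    if (tok == "(") {
      inner <- parse_expr()
      if (is.na(peek()) || advance() != ")") fail("unbalanced parenthesis")
      return(inner)
    }
    if (tok == ")") fail("unexpected ')'")
    if (tolower(tok) %in% c("and", "or")) fail(paste0("unexpected keyword '", tok, "'"))
    gpr_gene(tok)
  }

  rule <- parse_expr()
  if (!is.na(peek())) fail(paste0("trailing token '", peek(), "'"))
  rule
}

#' Evaluate a GPR rule under a gene deletion set
#'
#' A gene leaf is true iff the gene is not deleted; `and`/`or` nodes are
#' evaluated recursively; `spontaneous` is always true; `unknown` is
#' always false (a masked reaction with no hypothesised gene has no
#' enzyme).
#'
#' @param rule a `gpr_rule`.
#' @param deleted character vector of deleted gene ids.
#' @return logical scalar: is the reaction catalysed?
#' @export
evaluate_gpr <- function(rule, deleted = character()) {
  stopifnot(is_gpr_rule(rule))
  switch(rule$op,
    gene = !(rule$gene %in% deleted),
    and = all(vapply(rule$args, evaluate_gpr, logical(1L), deleted = deleted)),
    or = any(vapply(rule$args, evaluate_gpr, logical(1L), deleted = deleted)),
    spontaneous = TRUE,
    unknown = FALSE,
    stop("corrupt GPR node: ", rule$op)
  )
}

gpr_genes <- function(rule) {
  switch(rule$op,
    gene = rule$gene,
    and = ,
    or = unique(unlist(lapply(rule$args, gpr_genes))),
    character()
  )
}

#' @export
format.gpr_rule <- function(x, ...) {
  fmt <- function(rule, parent_op) {
    out <- switch(rule$op,
      gene = rule$gene,
      spontaneous = "",
      unknown = "?",
      and = paste(vapply(rule$args, fmt, character(1L), parent_op = "and"),
                  collapse = " and "),
      or = paste(vapply(rule$args, fmt, character(1L), parent_op = "or"),
                 collapse = " or ")
    )
    # parenthesise an OR nested under an AND to keep precedence on re-parse
    if (rule$op == "or" && parent_op == "and") out <- paste0("(", out, ")")
    out
  }
  fmt(x, parent_op = "")
}

#' @export
print.gpr_rule <- function(x, ...) {
  s <- format(x)
  cat("<gpr>", if (nzchar(s)) s else "(spontaneous)", "\n")
  invisible(x)
}
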