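## Gene-reaction rule grammar: identifiers, AND, OR, parentheses.
## Keywords are case-insensitive; AND binds tighter than OR (the HMR / COBRA
## convention for isozymes vs complexes).

rule_tokenize <- function(rule) {
  rule <- trimws(rule)
  if (!nzchar(rule)) return(character(0))
  pattern <- "\\(|\\)|[A-Za-z0-9_.:-]+"
  m <- gregexpr(pattern, rule, perl = TRUE)[[1]]
  tokens <- regmatches(rule, list(m))[[1]]
  consumed <- sum(attr(m, "match.length"))
  residue <- gsub(pattern, "", rule, perl = TRUE)
  residue <- gsub("[[:space:]]", "", residue)
  if (nzchar(residue)) {
    stop(sprintf("unparsable gene rule: '%s' (stray characters '%s')",
                 rule, residue), call. = FALSE)
  }
  tokens
}

#' Parse a gene-reaction rule into an expression tree
#'
#' Rules are boolean expressions over gene identifiers with `AND`, `OR` and
#' parentheses (case-insensitive keywords). `AND` binds tighter than `OR`.
#' An empty rule parses to `NULL` (spontaneous or orphan reaction).
#'
#' @param rule Rule string, e.g. `"(A AND B) OR C"`.
#' @return `NULL` for an empty rule; otherwise a nested list tree with
#'   elements `op` (`"gene"`, `"and"`, `"or"`), and either `gene` or `args`.
#' @examples
#' parse_gene_rule("(GLS AND SLC25A12) OR GLUL")
#' @export
parse_gene_rule <- function(rule) {
  if (is.null(rule) || is.na(rule) || !nzchar(trimws(rule))) return(NULL)
  tokens <- rule_tokenize(rule)
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tokens[pos] else NA_character_
  advance <- function() {
    tok <- peek()
    pos <<- pos + 1L
    tok
  }
  is_keyword <- function(tok, kw) !is.na(tok) && tolower(tok) == kw

  parse_or <- function() {
    left <- parse_and()
    args <- list(left)
    while (is_keyword(peek(), "or")) {
      advance()
      args[[length(args) + 1L]] <- parse_and()
    }
    if (length(args) == 1L) left else list(op = "or", args = args)
  }
  parse_and <- function() {
    left <- parse_atom()
    args <- list(left)
    while (is_keyword(peek(), "and")) {
      advance()
      args[[length(args) + 1L]] <- parse_atom()
    }
    if (length(args) == 1L) left else list(op = "and", args = args)
  }
  parse_atom <- function() {
    tok <- advance()
    if (is.na(tok)) stop(sprintf("unparsable gene rule: '%s' (unexpected end)", rule), call. = FALSE)
    if (tok == "(") {
      inner <- parse_or()
      closing <- advance()
      if (is.na(closing) || closing != ")") {
        stop(sprintf("unparsable gene rule: '%s' (missing ')')", rule), call. = FALSE)
      }
      return(inner)
    }
    if (tok == ")" || tolower(tok) %in% c("and", "or")) {
      stop(sprintf("unparsable gene rule: '%s' (unexpected token '%s')", rule, tok), call. = FALSE)
    }
    list(op = "gene", gene = tok)
  }

  tree <- parse_or()
  if (pos <= length(tokens)) {
    stop(sprintf("unparsable gene rule: '%s' (trailing tokens)", rule), call. = FALSE)
  }
  tree
}

#' Genes referenced by a gene rule
#'
#' Flattens the rule, ignoring AND/OR structure.
#'
#' @param rule Rule string.
#' @return Character vector of unique gene ids (empty for an empty rule).
#' @export
rule_genes <- function(rule) {
  tree <- parse_gene_rule(rule)
  walk <- function(node) {
    if (is.null(node)) return(character(0))
    if (node$op == "gene") return(node$gene)
    unlist(lapply(node$args, walk))
  }
  unique(walk(tree))
}

#' Evaluate a gene rule over numeric gene scores
#'
#' `OR` takes the maximum of its arguments (any isozyme supports the
#' reaction), `AND` the minimum (a complex is only as supported as its
#' weakest subunit). Genes missing from `scores` get `default`.
#'
#' @param rule Rule string.
#' @param scores Named numeric vector of per-gene scores.
#' @param default Score for genes absent from `scores`.
#' @param empty Value returned for an empty rule (default 0).
#' @return A single numeric score.
#' @export
evaluate_gene_rule <- function(rule, scores, default = NA_real_, empty = 0) {
  tree <- parse_gene_rule(rule)
  if (is.null(tree)) return(empty)
  walk <- function(node) {
    if (node$op == "gene") {
      s <- if (node$gene %in% names(scores)) scores[[node$gene]] else default
      if (is.na(s)) s <- default
      return(s)
    }
    vals <- vapply(node$args, walk, numeric(1))
    if (node$op == "and") min(vals) else max(vals)
  }
  walk(tree)
}
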