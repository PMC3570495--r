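#' Boolean rule language over pathway identifiers
#'
#' Phenotype rules are boolean expressions whose leaves are pathway
#' identifiers, combined with \code{NOT}, \code{AND} and \code{OR}
#' (case-insensitive keywords) and grouped with parentheses.  Precedence is
#' the conventional \code{NOT > AND > OR}, both binary operators
#' left-associative; identifiers are case-sensitive and match
#' \code{[A-Za-z0-9_.]+}.
#'
#' \code{parseRule} returns an abstract syntax tree: nested lists with a
#' \code{kind} field of \code{"var"} (with \code{id}), \code{"not"} (with
#' \code{x}) or \code{"and"}/\code{"or"} (with \code{lhs}, \code{rhs}).
#' \code{deparseRule} renders a tree back to text (fully parenthesised except
#' around leaves) such that re-parsing reproduces the tree.
#'
#' @param text a single rule string.
#' @return \code{parseRule}: the AST; \code{deparseRule}: a string;
#'   \code{ruleVariables}: character vector of distinct pathway ids in
#'   first-occurrence order.
#' @examples
#' ast <- parseRule("(P_146 OR P_519) AND (P_272 OR P_147)")
#' ast$kind                       # "and"
#' ruleVariables(ast)
#' deparseRule(parseRule("NOT P_162"))
#' @export
parseRule <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(trimws(text)))
    stop("rule text must be a single non-empty string", call. = FALSE)
  toks <- tokenizeRule(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  ast <- parseOr(st)
  tk <- peekTok(st)
  if (tk$type != "eof")
    stop("syntax error at position ", tk$at, ": unexpected '", tk$text,
         "'", call. = FALSE)
  ast
}

tokenizeRule <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  toks <- list()
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (grepl("^[[:space:]]$", ch)) { i <- i + 1L; next }
    if (ch == "(" || ch == ")") {
      toks[[length(toks) + 1L]] <- list(type = ch, text = ch, at = i)
      i <- i + 1L
      next
    }
    if (grepl("^[A-Za-z0-9_.]$", ch)) {
      j <- i
      while (j <= n && grepl("^[A-Za-z0-9_.]$", chars[j])) j <- j + 1L
      word <- paste(chars[i:(j - 1L)], collapse = "")
      up <- toupper(word)
      type <- if (up %in% c("AND", "OR", "NOT")) up else "ident"
      toks[[length(toks) + 1L]] <- list(type = type, text = word, at = i)
      i <- j
      next
    }
    stop("unknown token at position ", i, ": '", ch, "'", call. = FALSE)
  }
  toks[[length(toks) + 1L]] <- list(type = "eof", text = "<end>", at = n + 1L)
  toks
}

peekTok <- function(st) st$toks[[st$pos]]
nextTok <- function(st) {
  tk <- st$toks[[st$pos]]
  st$pos <- st$pos + 1L
  tk
}

parseOr <- function(st) {
  lhs <- parseAnd(st)
  while (peekTok(st)$type == "OR") {
    nextTok(st)
    lhs <- list(kind = "or", lhs = lhs, rhs = parseAnd(st))
  }
  lhs
}

parseAnd <- function(st) {
  lhs <- parseUnary(st)
  while (peekTok(st)$type == "AND") {
    nextTok(st)
    lhs <- list(kind = "and", lhs = lhs, rhs = parseUnary(st))
  }
  lhs
}

parseUnary <- function(st) {
  tk <- peekTok(st)
  if (tk$type == "NOT") {
    nextTok(st)
    return(list(kind = "not", x = parseUnary(st)))
  }
  parsePrimary(st)
}

parsePrimary <- function(st) {
  tk <- nextTok(st)
  if (tk$type == "ident")
    return(list(kind = "var", id = tk$text))
  if (tk$type == "(") {
    inner <- parseOr(st)
    cl <- nextTok(st)
    if (cl$type != ")")
      stop("syntax error at position ", cl$at, ": expected ')', got '",
           cl$text, "'", call. = FALSE)
    return(inner)
  }
  stop("syntax error at position ", tk$at, ": expected identifier, NOT or ",
       "'(', got '", tk$text, "'", call. = FALSE)
}

#' @rdname parseRule
#' @param ast a rule AST as returned by \code{parseRule}.
#' @export
deparseRule <- function(ast) {
  switch(ast$kind,
    var = ast$id,
    not = paste0("NOT ", wrapLeaf(ast$x)),
    and = paste0(wrapLeaf(ast$lhs), " AND ", wrapLeaf(ast$rhs)),
    or  = paste0(wrapLeaf(ast$lhs), " OR ", wrapLeaf(ast$rhs)),
    stop("invalid AST node kind: ", ast$kind)
  )
}

wrapLeaf <- function(ast) {
  if (ast$kind == "var") ast$id else paste0("(", deparseRule(ast), ")")
}

#' @rdname parseRule
#' @export
ruleVariables <- function(ast) {
  switch(ast$kind,
    var = ast$id,
    not = ruleVariables(ast$x),
    unique(c(ruleVariables(ast$lhs), ruleVariables(ast$rhs)))
  )
}

#' Evaluate a rule over pathway statuses
#'
#' Bottom-up strong-Kleene evaluation of a parsed rule.  \code{statuses} maps
#' pathway identifiers to tri-state values (use \code{\link{statusToTri}} to
#' convert assertion statuses first).  In strict mode an identifier absent
#' from \code{statuses} is an error; in lenient mode it evaluates to
#' \code{"unknown"} and is reported in the \code{"missing"} attribute of the
#' result.
#'
#' @param ast a rule AST from \code{\link{parseRule}}.
#' @param statuses named character vector of tri-state values keyed by
#'   pathway id.
#' @param strict logical; error on unmapped identifiers (default) or map
#'   them to \code{"unknown"}.
#' @return A single tri-state value; in lenient mode with unmapped ids, the
#'   value carries a \code{"missing"} character-vector attribute.
#' @examples
#' evaluateRule(parseRule("NOT P_162"), c(P_162 = "false"))  # "true"
#' @export
evaluateRule <- function(ast, statuses, strict = TRUE) {
  checkTri(statuses, "statuses")
  missing <- character(0)
  evalNode <- function(node) {
    switch(node$kind,
      var = {
        if (node$id %in% names(statuses)) {
          unname(statuses[[node$id]])
        } else if (strict) {
          stop("no status for pathway '", node$id, "'", call. = FALSE)
        } else {
          missing <<- union(missing, node$id)
          "unknown"
        }
      },
      not = triNot(evalNode(node$x)),
      and = triAnd(evalNode(node$lhs), evalNode(node$rhs)),
      or  = triOr(evalNode(node$lhs), evalNode(node$rhs))
    )
  }
  out <- evalNode(ast)
  if (length(missing)) attr(out, "missing") <- missing
  out
}
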