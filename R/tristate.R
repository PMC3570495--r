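#' Three-valued (Kleene) truth values
#'
#' Pathway presence in a genome is a three-valued judgement: a pathway with a
#' full complement of genes is \emph{asserted}, one whose missing terms have
#' candidate genes is \emph{unknown}, and one with neither is
#' \emph{not asserted}.  Rule evaluation identifies these statuses with the
#' Kleene truth values \code{"true"}, \code{"false"} and \code{"unknown"},
#' and combines them with the strong-Kleene connectives: \code{triNot} flips
#' definite values and preserves \code{unknown}; \code{triOr} is true as soon
#' as one operand is true and false only when both are; \code{triAnd} is the
#' dual, with false absorbing.
#'
#' All three functions are vectorised with the usual recycling rules.
#'
#' @param a,x character vector(s) of tri-state values
#'   (\code{"true"}, \code{"false"}, \code{"unknown"}).
#' @param b second operand, recycled against \code{a}.
#' @return A character vector of tri-state values.
#' @examples
#' triNot("true")
#' triOr("false", "unknown")   # unknown
#' triAnd("true", "unknown")   # unknown
#' triAnd("false", "unknown")  # false: false absorbs
#' @name tristate
NULL

TRI_VALUES <- c("true", "false", "unknown")

checkTri <- function(x, arg = deparse(substitute(x))) {
  bad <- !(x %in% TRI_VALUES)
  if (any(bad))
    stop("invalid tri-state value(s) in `", arg, "`: ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  x
}

#' @rdname tristate
#' @export
triNot <- function(x) {
  checkTri(x)
  out <- rep("unknown", length(x))
  out[x == "true"] <- "false"
  out[x == "false"] <- "true"
  out
}

#' @rdname tristate
#' @export
triOr <- function(a, b) {
  checkTri(a); checkTri(b)
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  out <- rep("unknown", n)
  out[a == "true" | b == "true"] <- "true"
  out[a == "false" & b == "false"] <- "false"
  out
}

#' @rdname tristate
#' @export
triAnd <- function(a, b) {
  checkTri(a); checkTri(b)
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  out <- rep("unknown", n)
  out[a == "false" | b == "false"] <- "false"
  out[a == "true" & b == "true"] <- "true"
  out
}

#' Fold a vector of tri-state values with AND or OR
#'
#' Convenience reductions used by pathway and reaction evaluation.  The empty
#' AND is \code{"true"} (a requirement with no clauses is vacuously met); the
#' empty OR is \code{"false"}.
#'
#' @param x character vector of tri-state values.
#' @return A single tri-state value.
#' @keywords internal
triAll <- function(x) {
  if (length(x) == 0L) return("true")
  Reduce(triAnd, x)
}

#' @rdname triAll
#' @keywords internal
triAny <- function(x) {
  if (length(x) == 0L) return("false")
  Reduce(triOr, x)
}

#' Map pathway assertion statuses to tri-state values and back
#'
#' Assertion statuses map one-to-one onto truth values
#' (\code{asserted} = true, \code{not_asserted} = false, \code{unknown} =
#' unknown); the manual status \code{absent} maps to false for rule
#' evaluation.
#'
#' @param status character vector of statuses
#'   (\code{asserted}, \code{not_asserted}, \code{unknown}, \code{absent}).
#' @param tri character vector of tri-state values.
#' @return \code{statusToTri}: tri-state values; \code{triToStatus}:
#'   assertion statuses.
#' @export
statusToTri <- function(status) {
  map <- c(asserted = "true", not_asserted = "false",
           unknown = "unknown", absent = "false")
  bad <- !(status %in% names(map))
  if (any(bad))
    stop("invalid assertion status: ",
         paste(unique(status[bad]), collapse = ", "), call. = FALSE)
  unname(map[status])
}

#' @rdname statusToTri
#' @export
triToStatus <- function(tri) {
  checkTri(tri)
  map <- c(true = "asserted", false = "not_asserted", unknown = "unknown")
  unname(map[tri])
}
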