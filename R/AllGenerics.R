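#' Accessors for AnnotationStore and HitTable
#'
#' Read-only accessors returning the underlying data.frames.
#' \code{genomeMetadata} returns the organism attribute/value table.
#'
#' @param x an \code{AnnotationStore} or \code{HitTable}.
#' @return A data.frame.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("genomes", function(x) standardGeneric("genomes"))
#' @rdname accessors
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))
#' @rdname accessors
#' @export
setGeneric("familyAssignments",
           function(x) standardGeneric("familyAssignments"))
#' @rdname accessors
#' @export
setGeneric("termAssignments", function(x) standardGeneric("termAssignments"))
#' @rdname accessors
#' @export
setGeneric("genomeMetadata", function(x) standardGeneric("genomeMetadata"))
#' @rdname accessors
#' @export
setGeneric("hits", function(x) standardGeneric("hits"))

#' @rdname accessors
#' @export
setMethod("genomes", "AnnotationStore", function(x) x@genomes)
#' @rdname accessors
#' @export
setMethod("genes", "AnnotationStore", function(x) x@genes)
#' @rdname accessors
#' @export
setMethod("familyAssignments", "AnnotationStore",
          function(x) x@familyAssignments)
#' @rdname accessors
#' @export
setMethod("termAssignments", "AnnotationStore", function(x) x@termAssignments)
#' @rdname accessors
#' @export
setMethod("genomeMetadata", "AnnotationStore", function(x) x@metadata)
#' @rdname accessors
#' @export
setMethod("hits", "HitTable", function(x) x@hits)

setMethod("show", "AnnotationStore", function(object) {
  cat("AnnotationStore with", nrow(object@genomes), "genome(s),",
      nrow(object@genes), "gene(s)\n")
  cat("  family assignments:", nrow(object@familyAssignments),
      " term assignments:", nrow(object@termAssignments),
      " metadata rows:", nrow(object@metadata), "\n")
})

setMethod("show", "HitTable", function(object) {
  cat("HitTable with", nrow(object@hits), "hit record(s) over",
      length(unique(c(object@hits$query_gene_id,
                      object@hits$subject_gene_id))), "gene(s)\n")
})

setMethod("show", "PathwayCatalog", function(object) {
  cat("PathwayCatalog:", nrow(object@terms), "term(s),",
      length(object@reactions), "reaction(s),",
      length(object@pathways), "pathway(s),",
      nrow(object@overrides), "manual override(s)\n")
})
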