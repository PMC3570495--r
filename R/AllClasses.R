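#' @import methods
NULL

FAMILY_NAMESPACES <- c("COG", "Pfam", "TIGRfam", "KO", "FIGfam")
PROVENANCES <- c("manual", "propagated", "candidate")
COMPLETENESS <- c("finished", "draft")

emptyDf <- function(...) {
  cols <- list(...)
  as.data.frame(lapply(cols, function(type) vector(type, 0L)),
                stringsAsFactors = FALSE)
}

#' AnnotationStore: genomes, genes and their annotations
#'
#' The central container for a set of microbial genomes: genome records,
#' protein-coding genes, sequence-family assignments (COG / Pfam / TIGRfam /
#' KO / FIGfam), functional-term assignments with provenance (\code{manual},
#' \code{propagated} or \code{candidate}), and organism metadata
#' (attribute/value pairs such as \emph{Oxygen Requirement = aerobic}).
#' All downstream analyses consume this object; no other function reads the
#' raw annotation TSVs.
#'
#' Validity enforces referential integrity (every gene's \code{genome_id}
#' is a declared genome, every assignment's \code{gene_id} a declared gene),
#' uniqueness of genome and gene ids, the closed vocabularies for namespaces,
#' provenance and genome completeness, and the rule that a (gene, term) pair
#' never carries both a candidate and a manual/propagated assignment.
#'
#' @slot genomes data.frame with columns \code{genome_id}, \code{name},
#'   \code{completeness} (\code{finished} or \code{draft}).
#' @slot genes data.frame with columns \code{gene_id}, \code{genome_id},
#'   \code{product_name}, \code{length_aa}.
#' @slot familyAssignments data.frame with columns \code{gene_id},
#'   \code{namespace}, \code{family_id}.
#' @slot termAssignments data.frame with columns \code{gene_id},
#'   \code{term_id}, \code{provenance}.
#' @slot metadata data.frame with columns \code{genome_id},
#'   \code{attribute}, \code{value}.
#' @seealso \code{\link{readAnnotationStore}}, \code{\link{writeAnnotationStore}}
#' @aliases AnnotationStore
#' @exportClass AnnotationStore
setClass("AnnotationStore",
  representation(genomes = "data.frame", genes = "data.frame",
                 familyAssignments = "data.frame",
                 termAssignments = "data.frame", metadata = "data.frame"),
  prototype(
    genomes = emptyDf(genome_id = "character", name = "character",
                      completeness = "character"),
    genes = emptyDf(gene_id = "character", genome_id = "character",
                    product_name = "character", length_aa = "integer"),
    familyAssignments = emptyDf(gene_id = "character",
                                namespace = "character",
                                family_id = "character"),
    termAssignments = emptyDf(gene_id = "character", term_id = "character",
                              provenance = "character"),
    metadata = emptyDf(genome_id = "character", attribute = "character",
                       value = "character")
  ))

setValidity("AnnotationStore", function(object) {
  msgs <- character(0)
  g <- object@genomes; gn <- object@genes
  fa <- object@familyAssignments; ta <- object@termAssignments
  md <- object@metadata
  if (anyDuplicated(g$genome_id))
    msgs <- c(msgs, "duplicate genome_id in genomes")
  if (anyDuplicated(gn$gene_id))
    msgs <- c(msgs, "duplicate gene_id in genes")
  bad <- setdiff(gn$genome_id, g$genome_id)
  if (length(bad))
    msgs <- c(msgs, paste0("genes reference undeclared genome(s): ",
                           paste(bad, collapse = ", ")))
  if (nrow(gn) && any(!is.na(gn$length_aa) & gn$length_aa <= 0))
    msgs <- c(msgs, "length_aa must be positive")
  for (nm in c("familyAssignments", "termAssignments")) {
    tab <- slot(object, nm)
    bad <- setdiff(tab$gene_id, gn$gene_id)
    if (length(bad))
      msgs <- c(msgs, paste0(nm, " reference undeclared gene(s): ",
                             paste(utils::head(bad, 5), collapse = ", ")))
  }
  if (nrow(fa) && !all(fa$namespace %in% FAMILY_NAMESPACES))
    msgs <- c(msgs, paste0("invalid namespace(s): ",
                           paste(setdiff(fa$namespace, FAMILY_NAMESPACES),
                                 collapse = ", ")))
  if (nrow(ta) && !all(ta$provenance %in% PROVENANCES))
    msgs <- c(msgs, paste0("invalid provenance(s): ",
                           paste(setdiff(ta$provenance, PROVENANCES),
                                 collapse = ", ")))
  if (nrow(ta)) {
    key <- paste(ta$gene_id, ta$term_id)
    cand <- unique(key[ta$provenance == "candidate"])
    firm <- unique(key[ta$provenance != "candidate"])
    both <- intersect(cand, firm)
    if (length(both))
      msgs <- c(msgs, paste0("candidate assignment coexists with ",
                             "manual/propagated for: ",
                             paste(utils::head(both, 5), collapse = "; ")))
  }
  if (nrow(g) && !all(g$completeness %in% COMPLETENESS))
    msgs <- c(msgs, "completeness must be 'finished' or 'draft'")
  bad <- setdiff(md$genome_id, g$genome_id)
  if (length(bad))
    msgs <- c(msgs, paste0("metadata reference undeclared genome(s): ",
                           paste(bad, collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' HitTable: pairwise protein similarity records
#'
#' Directed pairwise similarity hits (query, subject) with percent identity
#' on the 0--100 scale, alignment coverage of query and subject as 0--1
#' fractions, and a non-negative alignment score.  Construction drops
#' self-hits, keeps the highest-scoring record per ordered (query, subject)
#' pair, and validates bounds.  Hit tables drive term propagation, BBH
#' detection and paralog clustering.
#'
#' @slot hits data.frame with columns \code{query_gene_id},
#'   \code{subject_gene_id}, \code{percent_identity}, \code{query_coverage},
#'   \code{subject_coverage}, \code{score}.
#' @seealso \code{\link{readHitTable}}
#' @aliases HitTable
#' @exportClass HitTable
setClass("HitTable",
  representation(hits = "data.frame"),
  prototype(hits = emptyDf(query_gene_id = "character",
                           subject_gene_id = "character",
                           percent_identity = "numeric",
                           query_coverage = "numeric",
                           subject_coverage = "numeric",
                           score = "numeric")))

setValidity("HitTable", function(object) {
  h <- object@hits
  msgs <- character(0)
  need <- c("query_gene_id", "subject_gene_id", "percent_identity",
            "query_coverage", "subject_coverage", "score")
  miss <- setdiff(need, names(h))
  if (length(miss))
    return(paste0("missing hit column(s): ", paste(miss, collapse = ", ")))
  if (nrow(h)) {
    if (any(h$percent_identity < 0 | h$percent_identity > 100))
      msgs <- c(msgs, "percent_identity outside [0, 100]")
    if (any(h$query_coverage < 0 | h$query_coverage > 1) ||
        any(h$subject_coverage < 0 | h$subject_coverage > 1))
      msgs <- c(msgs, "coverage fractions outside [0, 1]")
    if (any(h$score < 0))
      msgs <- c(msgs, "negative score")
    if (any(h$query_gene_id == h$subject_gene_id))
      msgs <- c(msgs, "self-hit present")
    if (anyDuplicated(paste(h$query_gene_id, h$subject_gene_id)))
      msgs <- c(msgs, "duplicate ordered (query, subject) pair")
  }
  if (length(msgs)) msgs else TRUE
})

#' PathwayCatalog: terms, reactions, pathways and manual overrides
#'
#' The definition side of pathway inference.  A \emph{term} is a functional
#' unit a gene can be assigned to (protein product, modified protein or
#' protein complex).  A \emph{reaction} requires one of several alternative
#' term sets: alternatives are OR-combined, and the terms within one
#' alternative (e.g. the subunits of a complex) are AND-combined.  A
#' \emph{pathway} is an ordered sequence of steps, each step a set of
#' alternative reactions; the pathway is present when every step has at
#' least one present reaction.  Manual overrides pin a (genome, pathway)
#' status to \code{asserted} or \code{absent} regardless of gene content.
#'
#' @slot terms data.frame with columns \code{term_id}, \code{name},
#'   \code{kind} (\code{protein_product}, \code{modified_protein},
#'   \code{protein_complex}).
#' @slot reactions named list; each element has \code{reaction_id},
#'   \code{name} and \code{requirements}, a list of character vectors of
#'   term ids (OR over list elements, AND within each).
#' @slot pathways named list; each element has \code{pathway_id},
#'   \code{name} and \code{steps}, a list of character vectors of reaction
#'   ids (AND over steps, OR within each step).
#' @slot overrides data.frame with columns \code{genome_id},
#'   \code{pathway_id}, \code{status} (\code{asserted} or \code{absent}).
#' @seealso \code{\link{readPathwayDefinitions}}
#' @aliases PathwayCatalog
#' @exportClass PathwayCatalog
setClass("PathwayCatalog",
  representation(terms = "data.frame", reactions = "list",
                 pathways = "list", overrides = "data.frame"),
  prototype(
    terms = emptyDf(term_id = "character", name = "character",
                    kind = "character"),
    reactions = structure(list(), names = character(0)),
    pathways = structure(list(), names = character(0)),
    overrides = emptyDf(genome_id = "character", pathway_id = "character",
                        status = "character")
  ))

setValidity("PathwayCatalog", function(object) {
  msgs <- character(0)
  termIds <- object@terms$term_id
  if (anyDuplicated(termIds)) msgs <- c(msgs, "duplicate term_id")
  for (r in object@reactions) {
    if (length(r$requirements) == 0L)
      msgs <- c(msgs, paste0("reaction ", r$reaction_id,
                             " has no requirement alternatives"))
    for (alt in r$requirements) {
      if (length(alt) == 0L)
        msgs <- c(msgs, paste0("reaction ", r$reaction_id,
                               " has an empty term set"))
      bad <- setdiff(alt, termIds)
      if (length(bad))
        msgs <- c(msgs, paste0("reaction ", r$reaction_id,
                               " references undefined term(s): ",
                               paste(bad, collapse = ", ")))
    }
  }
  for (p in object@pathways) {
    if (length(p$steps) == 0L)
      msgs <- c(msgs, paste0("pathway ", p$pathway_id, " has no steps"))
    for (stp in p$steps) {
      if (length(stp) == 0L)
        msgs <- c(msgs, paste0("pathway ", p$pathway_id,
                               " has an empty step"))
      bad <- setdiff(stp, names(object@reactions))
      if (length(bad))
        msgs <- c(msgs, paste0("pathway ", p$pathway_id,
                               " references undefined reaction(s): ",
                               paste(bad, collapse = ", ")))
    }
  }
  ov <- object@overrides
  if (nrow(ov)) {
    if (!all(ov$status %in% c("asserted", "absent")))
      msgs <- c(msgs, "override status must be 'asserted' or 'absent'")
    bad <- setdiff(ov$pathway_id, names(object@pathways))
    if (length(bad))
      msgs <- c(msgs, paste0("override references undefined pathway(s): ",
                             paste(bad, collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})
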