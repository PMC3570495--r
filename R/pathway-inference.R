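#' Three-valued status of a functional term in a genome
#'
#' A term is \code{"true"} in a genome when at least one of the genome's
#' genes carries it with manual or propagated provenance, \code{"unknown"}
#' when only candidate genes support it, and \code{"false"} otherwise.
#'
#' @param store an \code{\link{AnnotationStore}}.
#' @param genomeId a single genome id.
#' @param termId a single term id (must exist in \code{catalog}).
#' @param catalog a \linkS4class{PathwayCatalog}.
#' @return A tri-state value.
#' @export
termStatus <- function(store, genomeId, termId, catalog) {
  stopifnot(is(catalog, "PathwayCatalog"))
  if (!termId %in% catalog@terms$term_id)
    stop("unknown term id: ", termId, call. = FALSE)
  termStatusMap(store, genomeId, termId)[[termId]]
}

# statuses of several terms in one genome, as a named tri-state vector
termStatusMap <- function(store, genomeId, termIds) {
  gn <- genes(store)
  genomeGenes <- gn$gene_id[gn$genome_id == genomeId]
  ta <- termAssignments(store)
  ta <- ta[ta$gene_id %in% genomeGenes & ta$term_id %in% termIds, ,
           drop = FALSE]
  out <- stats::setNames(rep("false", length(termIds)), termIds)
  out[unique(ta$term_id[ta$provenance == "candidate"])] <- "unknown"
  out[unique(ta$term_id[ta$provenance != "candidate"])] <- "true"
  out
}

#' Three-valued status of a reaction in a genome
#'
#' A reaction is present when one of its alternative term sets is fully
#' present: alternatives are OR-combined and the terms within an
#' alternative (e.g. complex subunits) AND-combined, under the Kleene
#' connectives, so candidate-only terms yield \code{"unknown"}.
#'
#' @inheritParams termStatus
#' @param reactionId a single reaction id defined in \code{catalog}.
#' @return A tri-state value.
#' @export
reactionStatus <- function(store, genomeId, reactionId, catalog) {
  stopifnot(is(catalog, "PathwayCatalog"))
  rxn <- catalog@reactions[[reactionId]]
  if (is.null(rxn))
    stop("undefined reaction id: ", reactionId, call. = FALSE)
  terms <- unique(unlist(rxn$requirements, use.names = FALSE))
  reactionStatusFrom(rxn, termStatusMap(store, genomeId, terms))
}

reactionStatusFrom <- function(rxn, termTri) {
  triAny(vapply(rxn$requirements,
                function(alt) triAll(termTri[alt]), character(1)))
}

pathwayTerms <- function(catalog, pathwayId) {
  pw <- catalog@pathways[[pathwayId]]
  rids <- unique(unlist(pw$steps, use.names = FALSE))
  unique(unlist(lapply(catalog@reactions[rids],
                       function(r) unlist(r$requirements)),
                use.names = FALSE))
}

#' Assert a pathway in a genome
#'
#' Computes the three-valued assertion status of one pathway in one genome:
#' AND over the pathway's steps of OR over each step's alternative
#' reactions, evaluated over the genome's term statuses and mapped to
#' \code{asserted} / \code{unknown} / \code{not_asserted}.  A manual
#' override in the catalog (status \code{asserted} or \code{absent})
#' replaces the computed status and is flagged \code{source = "manual"}.
#'
#' @inheritParams termStatus
#' @param pathwayId a single pathway id defined in \code{catalog}.
#' @return A list with \code{genome_id}, \code{pathway_id}, \code{status}
#'   (\code{asserted}, \code{unknown}, \code{not_asserted} or, for a manual
#'   override, \code{absent}), \code{source} (\code{computed} or
#'   \code{manual}), and \code{evidence}: one entry per step listing the
#'   step's \code{satisfied}, \code{candidate} and \code{missing} terms.
#' @export
assertPathway <- function(store, genomeId, pathwayId, catalog) {
  stopifnot(is(catalog, "PathwayCatalog"))
  pw <- catalog@pathways[[pathwayId]]
  if (is.null(pw))
    stop("undefined pathway id: ", pathwayId, call. = FALSE)
  termTri <- termStatusMap(store, genomeId, pathwayTerms(catalog, pathwayId))
  stepTri <- vapply(pw$steps, function(stp) {
    triAny(vapply(catalog@reactions[stp],
                  function(r) reactionStatusFrom(r, termTri), character(1)))
  }, character(1))
  status <- triToStatus(triAll(stepTri))
  source <- "computed"
  ov <- catalog@overrides
  hit <- ov$genome_id == genomeId & ov$pathway_id == pathwayId
  if (any(hit)) {
    status <- ov$status[which(hit)[1]]
    source <- "manual"
  }
  evidence <- lapply(pw$steps, function(stp) {
    stepTerms <- unique(unlist(lapply(catalog@reactions[stp],
                                      function(r) unlist(r$requirements)),
                               use.names = FALSE))
    tri <- termTri[stepTerms]
    list(satisfied = stepTerms[tri == "true"],
         candidate = stepTerms[tri == "unknown"],
         missing = stepTerms[tri == "false"])
  })
  list(genome_id = genomeId, pathway_id = pathwayId, status = status,
       source = source, evidence = evidence)
}

#' Assert all pathways across all genomes
#'
#' Applies \code{\link{assertPathway}} to every (genome, pathway)
#' combination and returns a flat table suitable for
#' \code{\link{predictPhenotypes}} and for writing to
#' \code{assertions.tsv}.  The \code{missing_terms} and
#' \code{candidate_terms} columns flatten the per-step evidence
#' (comma-joined, de-duplicated, input order).
#'
#' @param store an \code{\link{AnnotationStore}}.
#' @param catalog a \code{PathwayCatalog}.
#' @param genomeIds,pathwayIds subsets to evaluate; default all genomes in
#'   the store and all pathways in the catalog, in input order.
#' @return data.frame with columns \code{genome_id}, \code{pathway_id},
#'   \code{status}, \code{source}, \code{missing_terms},
#'   \code{candidate_terms}.
#' @export
assertPathways <- function(store, catalog,
                           genomeIds = genomes(store)$genome_id,
                           pathwayIds = names(catalog@pathways)) {
  rows <- list()
  for (g in genomeIds) {
    for (p in pathwayIds) {
      rec <- assertPathway(store, g, p, catalog)
      flat <- function(field) paste(unique(unlist(
        lapply(rec$evidence, `[[`, field), use.names = FALSE)),
        collapse = ",")
      rows[[length(rows) + 1L]] <- data.frame(
        genome_id = g, pathway_id = p, status = rec$status,
        source = rec$source, missing_terms = flat("missing"),
        candidate_terms = flat("candidate"), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(genome_id = character(0), pathway_id = character(0),
                      status = character(0), source = character(0),
                      missing_terms = character(0),
                      candidate_terms = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Genome-by-pathway profile of assertion status and gene counts
#'
#' For each (genome, pathway) cell, the assertion status and the number of
#' distinct genes of that genome assigned (manually or by propagation) to
#' any term referenced by the pathway.  Row and column order follow the
#' input order of \code{genomeIds} and \code{pathwayIds}.
#'
#' @inheritParams assertPathways
#' @return A list with two character/integer matrices, \code{status} and
#'   \code{geneCount}, rows = genomes, columns = pathways.
#' @export
pathwayProfile <- function(store, catalog,
                           genomeIds = genomes(store)$genome_id,
                           pathwayIds = names(catalog@pathways)) {
  status <- matrix("", nrow = length(genomeIds), ncol = length(pathwayIds),
                   dimnames = list(genomeIds, pathwayIds))
  geneCount <- matrix(0L, nrow = length(genomeIds),
                      ncol = length(pathwayIds),
                      dimnames = list(genomeIds, pathwayIds))
  gn <- genes(store)
  firm <- firmTermAssignments(store)
  for (p in pathwayIds) {
    pTerms <- pathwayTerms(catalog, p)
    pGenes <- unique(firm$gene_id[firm$term_id %in% pTerms])
    byGenome <- table(gn$genome_id[match(pGenes, gn$gene_id)])
    for (g in genomeIds) {
      rec <- assertPathway(store, g, p, catalog)
      status[g, p] <- rec$status
      geneCount[g, p] <- if (g %in% names(byGenome))
        as.integer(byGenome[[g]]) else 0L
    }
  }
  list(status = status, geneCount = geneCount)
}

#' Write / read a pathway assertion table
#'
#' @param assertions data.frame as returned by \code{\link{assertPathways}}.
#' @param path TSV file path.
#' @return \code{readAssertions}: the assertion data.frame.
#' @export
writeAssertions <- function(assertions, path) {
  writeTsv(assertions, path)
  invisible(path)
}

#' @rdname writeAssertions
#' @export
readAssertions <- function(path) {
  readTsv(path, c("genome_id", "pathway_id", "status", "source"))
}
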