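#' Parameters for automated term propagation and candidate detection
#'
#' \code{propagationParams} holds the thresholds of the standard operating
#' procedure for automated term assignment: a gene receives a term when it
#' has at least \code{minHomologs} homologs with identity strictly above
#' \code{minIdentityPct} percent and alignment coverage strictly above
#' \code{minCoverageFrac} of both query and subject length, and at least
#' \code{minSupporting} of the top \code{minHomologs} such homologs already
#' carry the term.  \code{candidateParams} holds the weaker evidence
#' thresholds for candidate genes: at least \code{minSupporting} of the top
#' \code{topK} bidirectional best hits carry the term, coverage is strictly
#' above \code{minCoverageFrac} on both sides, and at least one term-bearing
#' hit has identity strictly above \code{minBestIdentityPct} percent.
#'
#' All inequalities are strict: boundary equality never satisfies a
#' threshold.
#'
#' @param minHomologs minimum number of qualifying homologs (default 5).
#' @param minIdentityPct exclusive percent-identity threshold (default 50).
#' @param minCoverageFrac exclusive coverage threshold on both query and
#'   subject, as a fraction (default 0.70).
#' @param minSupporting minimum number of term-bearing homologs/BBH
#'   partners among the top set (default 2).
#' @param topK number of top BBH partners considered (default 5).
#' @param minBestIdentityPct exclusive threshold the best term-bearing BBH
#'   partner must exceed (default 25).
#' @return A named list of class \code{propagationParams} /
#'   \code{candidateParams}.
#' @export
propagationParams <- function(minHomologs = 5L, minIdentityPct = 50,
                              minCoverageFrac = 0.70, minSupporting = 2L) {
  stopifnot(minHomologs >= 1, minSupporting >= 1,
            minIdentityPct >= 0, minIdentityPct <= 100,
            minCoverageFrac >= 0, minCoverageFrac <= 1)
  structure(list(minHomologs = as.integer(minHomologs),
                 minIdentityPct = minIdentityPct,
                 minCoverageFrac = minCoverageFrac,
                 minSupporting = as.integer(minSupporting)),
            class = "propagationParams")
}

#' @rdname propagationParams
#' @export
candidateParams <- function(topK = 5L, minSupporting = 2L,
                            minCoverageFrac = 0.70,
                            minBestIdentityPct = 25) {
  stopifnot(topK >= 1, minSupporting >= 1,
            minCoverageFrac >= 0, minCoverageFrac <= 1,
            minBestIdentityPct >= 0, minBestIdentityPct <= 100)
  structure(list(topK = as.integer(topK),
                 minSupporting = as.integer(minSupporting),
                 minCoverageFrac = minCoverageFrac,
                 minBestIdentityPct = minBestIdentityPct),
            class = "candidateParams")
}

# firm = assignments that count as "the gene carries the term"
firmTermAssignments <- function(store) {
  ta <- termAssignments(store)
  ta[ta$provenance %in% c("manual", "propagated"), , drop = FALSE]
}

emptyAssignmentDf <- function(provenance = character(0)) {
  data.frame(gene_id = character(0), term_id = character(0),
             provenance = provenance[0], stringsAsFactors = FALSE)
}

#' Propagate functional terms by strict sequence similarity
#'
#' Applies the automated assignment rule to every gene that carries no
#' manual or propagated term: its homologs passing the identity and
#' bidirectional-coverage thresholds are collected; if there are at least
#' \code{minHomologs} of them, the top \code{minHomologs} (ranked by
#' identity, then score, then gene id) vote, and every term carried by at
#' least \code{minSupporting} of them is assigned with provenance
#' \code{propagated}.  When several terms reach the support threshold for
#' one gene, all are assigned and a warning names the gene.  Output is
#' deterministic and invariant under permutation of input rows.
#'
#' @param store an \code{\link{AnnotationStore}}.
#' @param hitTable a \code{\link{HitTable}}.
#' @param params a \code{\link{propagationParams}} object.
#' @param iterate logical; repeat propagation until no new assignment is
#'   produced (capped at \code{maxRounds}).  Default is a single round.
#' @param maxRounds round cap when \code{iterate = TRUE}.
#' @return data.frame of new assignments (\code{gene_id}, \code{term_id},
#'   \code{provenance = "propagated"}), sorted by gene then term.
#' @export
propagateTerms <- function(store, hitTable, params = propagationParams(),
                           iterate = FALSE, maxRounds = 10L) {
  stopifnot(is(store, "AnnotationStore"), is(hitTable, "HitTable"),
            inherits(params, "propagationParams"))
  h <- hits(hitTable)
  h <- h[h$percent_identity > params$minIdentityPct &
         h$query_coverage > params$minCoverageFrac &
         h$subject_coverage > params$minCoverageFrac, , drop = FALSE]
  firm <- firmTermAssignments(store)[, c("gene_id", "term_id")]
  out <- emptyAssignmentDf()
  rounds <- if (iterate) maxRounds else 1L
  for (round in seq_len(rounds)) {
    newRows <- propagateOneRound(store, h, firm, params)
    if (!nrow(newRows)) break
    out <- rbind(out, newRows)
    firm <- rbind(firm, newRows[, c("gene_id", "term_id")])
  }
  out <- sortDf(unique(out))
  multi <- unique(out$gene_id[duplicated(out$gene_id)])
  if (length(multi))
    warning("multiple terms propagated to gene(s): ",
            paste(multi, collapse = ", "), call. = FALSE)
  out
}

propagateOneRound <- function(store, qualifyingHits, firm, params) {
  assignedGenes <- unique(firm$gene_id)
  h <- qualifyingHits[!(qualifyingHits$query_gene_id %in% assignedGenes), ,
                      drop = FALSE]
  if (!nrow(h)) return(emptyAssignmentDf())
  # deterministic homolog ranking: identity desc, score desc, id asc
  h <- h[order(h$query_gene_id, -h$percent_identity, -h$score,
               h$subject_gene_id), , drop = FALSE]
  termsByGene <- split(firm$term_id, firm$gene_id)
  res <- lapply(split(h, h$query_gene_id), function(hh) {
    if (nrow(hh) < params$minHomologs) return(NULL)
    top <- hh$subject_gene_id[seq_len(params$minHomologs)]
    carried <- unlist(lapply(termsByGene[top], unique), use.names = FALSE)
    if (is.null(carried)) return(NULL)
    support <- table(carried)
    winners <- names(support)[support >= params$minSupporting]
    if (!length(winners)) return(NULL)
    data.frame(gene_id = hh$query_gene_id[1], term_id = winners,
               provenance = "propagated", stringsAsFactors = FALSE)
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) return(emptyAssignmentDf())
  do.call(rbind, unname(res))
}

#' Bidirectional best hits between genomes
#'
#' Two genes from different genomes form a BBH pair when each is the
#' other's best hit within the partner's genome, "best" meaning highest
#' score, ties broken by higher identity and then by lexicographically
#' smaller subject gene id.
#'
#' @param hitTable a \code{\link{HitTable}}.
#' @param genomeOf named character vector mapping gene id to genome id
#'   (e.g. built from \code{genes(store)}).
#' @return data.frame of unordered pairs with columns \code{gene1},
#'   \code{gene2} (\code{gene1 < gene2}), sorted.
#' @export
computeBBH <- function(hitTable, genomeOf) {
  stopifnot(is(hitTable, "HitTable"))
  h <- hits(hitTable)
  if (!nrow(h))
    return(data.frame(gene1 = character(0), gene2 = character(0),
                      stringsAsFactors = FALSE))
  unknown <- setdiff(unique(c(h$query_gene_id, h$subject_gene_id)),
                     names(genomeOf))
  if (length(unknown))
    stop("hit table references gene(s) with no genome mapping: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  h$qGenome <- unname(genomeOf[h$query_gene_id])
  h$sGenome <- unname(genomeOf[h$subject_gene_id])
  h <- h[h$qGenome != h$sGenome, , drop = FALSE]
  if (!nrow(h))
    return(data.frame(gene1 = character(0), gene2 = character(0),
                      stringsAsFactors = FALSE))
  h <- h[order(h$query_gene_id, h$sGenome, -h$score, -h$percent_identity,
               h$subject_gene_id), , drop = FALSE]
  best <- h[!duplicated(paste(h$query_gene_id, h$sGenome)), , drop = FALSE]
  key <- paste(best$query_gene_id, best$subject_gene_id)
  revKey <- paste(best$subject_gene_id, best$query_gene_id)
  mutual <- best[key %in% revKey, , drop = FALSE]
  if (!nrow(mutual))
    return(data.frame(gene1 = character(0), gene2 = character(0),
                      stringsAsFactors = FALSE))
  pairs <- data.frame(
    gene1 = pmin(mutual$query_gene_id, mutual$subject_gene_id),
    gene2 = pmax(mutual$query_gene_id, mutual$subject_gene_id),
    stringsAsFactors = FALSE)
  sortDf(unique(pairs))
}

#' Detect candidate genes for functional terms
#'
#' A candidate gene is weaker evidence than an automated assignment: for a
#' gene \code{g} lacking term \code{t}, its BBH partners with coverage above
#' \code{minCoverageFrac} on both sides are ranked by identity and the top
#' \code{topK} kept; \code{g} becomes a candidate for \code{t} when at
#' least \code{minSupporting} of them carry \code{t} (manually or by
#' propagation) and at least one of those carriers exceeds
#' \code{minBestIdentityPct} percent identity.  Candidate assignments never
#' override manual or propagated ones.
#'
#' @param store an \code{\link{AnnotationStore}}; its term assignments
#'   (including any committed propagation results) supply the term-bearing
#'   partners.
#' @param hitTable a \code{\link{HitTable}}.
#' @param params a \code{\link{candidateParams}} object.
#' @return data.frame of candidate assignments (\code{gene_id},
#'   \code{term_id}, \code{provenance = "candidate"}), sorted.
#' @export
detectCandidates <- function(store, hitTable, params = candidateParams()) {
  stopifnot(is(store, "AnnotationStore"), is(hitTable, "HitTable"),
            inherits(params, "candidateParams"))
  gn <- genes(store)
  genomeOf <- stats::setNames(gn$genome_id, gn$gene_id)
  bbh <- computeBBH(hitTable, genomeOf)
  if (!nrow(bbh)) return(emptyAssignmentDf("candidate"))
  h <- hits(hitTable)
  hKey <- paste(h$query_gene_id, h$subject_gene_id)
  firm <- firmTermAssignments(store)
  termsByGene <- split(firm$term_id, firm$gene_id)
  # partner view: one row per (gene, BBH partner), using the gene->partner
  # hit record for identity and coverage
  long <- data.frame(
    gene = c(bbh$gene1, bbh$gene2),
    partner = c(bbh$gene2, bbh$gene1), stringsAsFactors = FALSE)
  idx <- match(paste(long$gene, long$partner), hKey)
  long$identity <- h$percent_identity[idx]
  long$qcov <- h$query_coverage[idx]
  long$scov <- h$subject_coverage[idx]
  long <- long[!is.na(idx) &
               long$qcov > params$minCoverageFrac &
               long$scov > params$minCoverageFrac, , drop = FALSE]
  if (!nrow(long)) return(emptyAssignmentDf("candidate"))
  long <- long[order(long$gene, -long$identity, long$partner), ,
               drop = FALSE]
  firmKey <- paste(firm$gene_id, firm$term_id)
  res <- lapply(split(long, long$gene), function(ll) {
    top <- ll[seq_len(min(nrow(ll), params$topK)), , drop = FALSE]
    carried <- lapply(top$partner, function(p) {
      t <- termsByGene[[p]]
      if (is.null(t)) character(0) else unique(t)
    })
    allTerms <- unique(unlist(carried, use.names = FALSE))
    if (!length(allTerms)) return(NULL)
    keep <- vapply(allTerms, function(t) {
      bearer <- vapply(carried, function(ts) t %in% ts, logical(1))
      sum(bearer) >= params$minSupporting &&
        max(top$identity[bearer]) > params$minBestIdentityPct
    }, logical(1))
    winners <- allTerms[keep]
    if (!length(winners)) return(NULL)
    winners <- winners[!(paste(ll$gene[1], winners) %in% firmKey)]
    if (!length(winners)) return(NULL)
    data.frame(gene_id = ll$gene[1], term_id = winners,
               provenance = "candidate", stringsAsFactors = FALSE)
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) return(emptyAssignmentDf("candidate"))
  sortDf(unique(do.call(rbind, unname(res))))
}

#' Commit new assignments into a store
#'
#' Returns a new \code{AnnotationStore} with the rows of \code{assignments}
#' appended to its term-assignment table (duplicates collapsed).  Candidate
#' rows that would duplicate an existing manual/propagated (gene, term)
#' pair are dropped to preserve the disjointness invariant.
#'
#' @param store an \code{AnnotationStore}.
#' @param assignments data.frame with \code{gene_id}, \code{term_id},
#'   \code{provenance}.
#' @return The updated \code{AnnotationStore}.
#' @export
addTermAssignments <- function(store, assignments) {
  stopifnot(is(store, "AnnotationStore"))
  if (!nrow(assignments)) return(store)
  ta <- rbind(termAssignments(store),
              assignments[, c("gene_id", "term_id", "provenance")])
  firmKey <- with(ta[ta$provenance != "candidate", , drop = FALSE],
                  paste(gene_id, term_id))
  drop <- ta$provenance == "candidate" &
    paste(ta$gene_id, ta$term_id) %in% firmKey
  ta <- unique(ta[!drop, , drop = FALSE])
  initialize(store, termAssignments = sortDf(ta))
}
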