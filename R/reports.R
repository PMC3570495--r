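#' @importFrom stats setNames
NULL

# per-gene (COG, Pfam, TIGRfam) family combinations, as canonical keys.
# A gene's combination is the full sorted *set* of its ids per namespace
# (possibly empty); equality is set-wise.
familyCombinations <- function(store, geneIds = genes(store)$gene_id) {
  fa <- familyAssignments(store)
  fa <- fa[fa$namespace %in% c("COG", "Pfam", "TIGRfam") &
           fa$gene_id %in% geneIds, , drop = FALSE]
  byGene <- split(fa[, c("namespace", "family_id")], fa$gene_id)
  part <- function(tab, ns)
    paste(sort(unique(tab$family_id[tab$namespace == ns])), collapse = ",")
  keys <- setNames(rep("||", length(geneIds)), geneIds)
  for (g in names(byGene)) {
    tab <- byGene[[g]]
    keys[[g]] <- paste(part(tab, "COG"), part(tab, "Pfam"),
                       part(tab, "TIGRfam"), sep = "|")
  }
  keys
}

koAssignments <- function(store) {
  fa <- familyAssignments(store)
  fa[fa$namespace == "KO", c("gene_id", "family_id"), drop = FALSE]
}

#' KO term distribution across protein-family combinations
#'
#' For each KO term, counts the distinct COGs, Pfams and TIGRfams
#' co-assigned with it on the same genes, plus the number of distinct
#' (COG set, Pfam set, TIGRfam set) combinations among those genes.  A KO
#' term associated with many families or combinations points at an
#' annotation-consistency problem (or at a broad family harbouring several
#' activities).
#'
#' @param store an \code{\link{AnnotationStore}}.
#' @param koIds KO ids to report on; default all KO terms assigned in the
#'   store.  Ids without genes report zero counts.
#' @return data.frame with columns \code{ko_id}, \code{n_genes},
#'   \code{n_cogs}, \code{n_pfams}, \code{n_tigrfams},
#'   \code{n_combinations}, sorted by \code{ko_id}.
#' @export
koFamilySummary <- function(store, koIds = NULL) {
  ko <- koAssignments(store)
  if (is.null(koIds)) koIds <- sort(unique(ko$family_id))
  fa <- familyAssignments(store)
  combos <- familyCombinations(store)
  rows <- lapply(koIds, function(k) {
    kg <- unique(ko$gene_id[ko$family_id == k])
    sub <- fa[fa$gene_id %in% kg, , drop = FALSE]
    nDistinct <- function(ns)
      length(unique(sub$family_id[sub$namespace == ns]))
    data.frame(ko_id = k, n_genes = length(kg),
               n_cogs = nDistinct("COG"), n_pfams = nDistinct("Pfam"),
               n_tigrfams = nDistinct("TIGRfam"),
               n_combinations = length(unique(combos[kg])),
               stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(ko_id = character(0), n_genes = integer(0),
                      n_cogs = integer(0), n_pfams = integer(0),
                      n_tigrfams = integer(0), n_combinations = integer(0),
                      stringsAsFactors = FALSE))
  sortDf(do.call(rbind, rows))
}

#' Details of one KO term's family combinations
#'
#' Enumerates the family combinations of the genes carrying the query KO
#' term and classifies, for each combination, every gene bearing it:
#' \code{n_with_query_ko} carry the query KO; \code{n_with_other_ko_incl}
#' carry some other KO (whether or not they also carry the query);
#' \code{n_with_other_ko_excl} carry another KO but not the query;
#' \code{n_without_ko} carry no KO at all.  All counts are of distinct
#' genes.
#'
#' @param store an \code{\link{AnnotationStore}}.
#' @param koId a single KO id present in the store.
#' @return data.frame with columns \code{cog_ids}, \code{pfam_ids},
#'   \code{tigrfam_ids} (comma-joined sorted sets) and the four counts.
#' @export
koCombinationDetails <- function(store, koId) {
  ko <- koAssignments(store)
  if (!koId %in% ko$family_id)
    stop("unknown KO id: ", koId, call. = FALSE)
  combos <- familyCombinations(store)
  queryGenes <- unique(ko$gene_id[ko$family_id == koId])
  queryCombos <- sort(unique(combos[queryGenes]))
  kosByGene <- split(ko$family_id, ko$gene_id)
  rows <- lapply(queryCombos, function(cmb) {
    carriers <- names(combos)[combos == cmb]
    hasQuery <- vapply(carriers, function(g) koId %in% kosByGene[[g]],
                       logical(1))
    hasOther <- vapply(carriers, function(g) {
      ks <- kosByGene[[g]]
      !is.null(ks) && length(setdiff(ks, koId)) > 0
    }, logical(1))
    hasNone <- vapply(carriers,
                      function(g) is.null(kosByGene[[g]]), logical(1))
    parts <- strsplit(cmb, "|", fixed = TRUE)[[1]]
    parts <- c(parts, rep("", 3 - length(parts)))
    data.frame(cog_ids = parts[1], pfam_ids = parts[2],
               tigrfam_ids = parts[3],
               n_with_query_ko = sum(hasQuery),
               n_with_other_ko_incl = sum(hasOther),
               n_with_other_ko_excl = sum(hasOther & !hasQuery),
               n_without_ko = sum(hasNone), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Within-genome paralog clusters from pairwise similarities
#'
#' For each genome, builds a similarity graph over its genes from the
#' intra-genome hit records passing the identity and bidirectional-coverage
#' filters (edge weight = the higher score of the two directed records)
#' and clusters it with \code{\link{mclCluster}}.  Genes sharing a cluster
#' are called paralogs.
#'
#' @param store an \code{\link{AnnotationStore}}.
#' @param hitTable a \code{\link{HitTable}}.
#' @param minIdentityPct exclusive percent-identity filter for graph edges
#'   (default 30).
#' @param minCoverageFrac exclusive coverage filter on both sides
#'   (default 0.70).
#' @param inflation MCL inflation (default 2).
#' @return data.frame with columns \code{genome_id}, \code{cluster_id},
#'   \code{gene_id}; clusters have >= 2 members and are disjoint within a
#'   genome.
#' @export
buildParalogClusters <- function(store, hitTable, minIdentityPct = 30,
                                 minCoverageFrac = 0.70, inflation = 2) {
  stopifnot(is(store, "AnnotationStore"), is(hitTable, "HitTable"))
  gn <- genes(store)
  genomeOf <- setNames(gn$genome_id, gn$gene_id)
  h <- hits(hitTable)
  h <- h[h$query_gene_id %in% names(genomeOf) &
         h$subject_gene_id %in% names(genomeOf), , drop = FALSE]
  h <- h[genomeOf[h$query_gene_id] == genomeOf[h$subject_gene_id] &
         h$percent_identity > minIdentityPct &
         h$query_coverage > minCoverageFrac &
         h$subject_coverage > minCoverageFrac, , drop = FALSE]
  out <- list()
  if (nrow(h)) {
    h$genome <- unname(genomeOf[h$query_gene_id])
    for (g in sort(unique(h$genome))) {
      hg <- h[h$genome == g, , drop = FALSE]
      nodes <- sort(unique(c(hg$query_gene_id, hg$subject_gene_id)))
      adj <- matrix(0, length(nodes), length(nodes),
                    dimnames = list(nodes, nodes))
      for (i in seq_len(nrow(hg))) {
        a <- hg$query_gene_id[i]; b <- hg$subject_gene_id[i]
        w <- max(adj[a, b], hg$score[i])
        adj[a, b] <- w; adj[b, a] <- w
      }
      clusters <- mclCluster(adj, inflation = inflation)
      for (j in seq_along(clusters))
        out[[length(out) + 1L]] <- data.frame(
          genome_id = g, cluster_id = paste0(g, ".", j),
          gene_id = clusters[[j]], stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(genome_id = character(0), cluster_id = character(0),
                      gene_id = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' KO term distribution across genomes and paralog clusters
#'
#' For each KO term: the number of genes carrying it, the number of genomes
#' holding such genes, the average number of such genes per genome (over
#' genomes with at least one), how many of those genes sit in a paralog
#' cluster, how many share a cluster with another gene carrying the same
#' KO, and the average percent identity over all unordered same-cluster
#' same-KO gene pairs (identity = the higher of the two directed hit
#' records; a pair with no hit record is skipped with a warning).  A high
#' per-genome average or many same-KO paralogs can indicate
#' over-annotation; low identity between same-KO paralogs suggests
#' functional divergence.
#'
#' @param store an \code{\link{AnnotationStore}}.
#' @param clusters data.frame from \code{\link{buildParalogClusters}}.
#' @param hitTable a \code{\link{HitTable}} supplying pair identities.
#' @param koIds KO ids to report on; default all assigned in the store.
#' @return data.frame with columns \code{ko_id}, \code{n_genes},
#'   \code{n_genomes}, \code{avg_genes_per_genome},
#'   \code{n_genes_in_paralog_clusters},
#'   \code{n_genes_with_same_ko_paralog},
#'   \code{avg_identity_same_ko_paralogs} (NA when there are no pairs).
#' @export
koGenomeParalogSummary <- function(store, clusters, hitTable,
                                   koIds = NULL) {
  ko <- koAssignments(store)
  if (is.null(koIds)) koIds <- sort(unique(ko$family_id))
  gn <- genes(store)
  genomeOf <- setNames(gn$genome_id, gn$gene_id)
  clusterOf <- setNames(clusters$cluster_id, clusters$gene_id)
  h <- hits(hitTable)
  hKey <- paste(h$query_gene_id, h$subject_gene_id)
  pairIdentity <- function(a, b) {
    ij <- match(c(paste(a, b), paste(b, a)), hKey)
    if (all(is.na(ij))) return(NA_real_)
    max(h$percent_identity[ij[!is.na(ij)]])
  }
  rows <- lapply(koIds, function(k) {
    kg <- sort(unique(ko$gene_id[ko$family_id == k]))
    nGenomes <- length(unique(genomeOf[kg]))
    inCluster <- kg[kg %in% names(clusterOf)]
    # genes sharing a cluster with another gene carrying the same KO
    byCluster <- split(inCluster, unname(clusterOf[inCluster]))
    withParalog <- unlist(byCluster[vapply(byCluster, length,
                                           integer(1)) >= 2L],
                          use.names = FALSE)
    idents <- c()
    for (members in byCluster) {
      if (length(members) < 2L) next
      for (i in seq_len(length(members) - 1L))
        for (j in seq(i + 1L, length(members))) {
          pid <- pairIdentity(members[i], members[j])
          if (is.na(pid))
            warning("no hit record for paralog pair ", members[i], " / ",
                    members[j], call. = FALSE)
          else idents <- c(idents, pid)
        }
    }
    data.frame(
      ko_id = k, n_genes = length(kg), n_genomes = nGenomes,
      avg_genes_per_genome = if (nGenomes) length(kg) / nGenomes else
        NA_real_,
      n_genes_in_paralog_clusters = length(inCluster),
      n_genes_with_same_ko_paralog = length(withParalog),
      avg_identity_same_ko_paralogs = if (length(idents)) mean(idents)
        else NA_real_,
      stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(ko_id = character(0), n_genes = integer(0),
                      n_genomes = integer(0),
                      avg_genes_per_genome = numeric(0),
                      n_genes_in_paralog_clusters = integer(0),
                      n_genes_with_same_ko_paralog = integer(0),
                      avg_identity_same_ko_paralogs = numeric(0),
                      stringsAsFactors = FALSE))
  sortDf(do.call(rbind, rows))
}
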