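#' Run the full annotation pipeline on a fixture-style directory
#'
#' Composes the package's stages over a directory laid out like the output
#' of \code{\link{generateFixture}}: load the annotation store and hit
#' table, propagate terms, detect candidate genes, assert all pathways,
#' predict phenotypes, compare predictions with metadata, and compute the
#' consistency reports (KO/family summary, paralog clusters, KO/paralog
#' summary).  All result tables are written as TSVs into \code{outDir}.
#'
#' @param dir input directory with \code{genomes.tsv}, \code{genes.tsv},
#'   \code{family_assignments.tsv}, \code{term_assignments.tsv},
#'   \code{hits.tsv}, \code{metadata.tsv}, \code{pathways.dsl},
#'   \code{rules.tsv}.
#' @param outDir output directory (default \code{file.path(dir, "out")}).
#' @param propagation a \code{\link{propagationParams}}.
#' @param candidates a \code{\link{candidateParams}}.
#' @param iterate propagate to fixpoint instead of a single round.
#' @param verbose log row counts and parameters to standard error.
#' @return Invisibly, a list with \code{store} (the store after committing
#'   propagated and candidate assignments), \code{propagated},
#'   \code{candidates}, \code{assertions}, \code{predictions},
#'   \code{agreement}, \code{clusters}, \code{koFamilySummary},
#'   \code{koParalogSummary}.
#' @export
runPipeline <- function(dir, outDir = file.path(dir, "out"),
                        propagation = propagationParams(),
                        candidates = candidateParams(),
                        iterate = FALSE, verbose = FALSE) {
  say <- function(...) if (verbose) message("[phenoassert] ", ...)
  hitsPath <- file.path(dir, "hits.tsv")
  if (!file.exists(hitsPath))
    stop("missing hits file: ", hitsPath, call. = FALSE)
  store <- readAnnotationStore(dir)
  say("loaded store: ", nrow(genomes(store)), " genomes, ",
      nrow(genes(store)), " genes")
  hitTable <- readHitTable(hitsPath)
  say("loaded hits: ", nrow(hits(hitTable)), " records")
  catalog <- readPathwayDefinitions(file.path(dir, "pathways.dsl"))
  rules <- readPhenotypeRules(file.path(dir, "rules.tsv"))

  propagated <- propagateTerms(store, hitTable, propagation,
                               iterate = iterate)
  say("propagated ", nrow(propagated), " term assignment(s)")
  store <- addTermAssignments(store, propagated)
  cand <- detectCandidates(store, hitTable, candidates)
  say("detected ", nrow(cand), " candidate assignment(s)")
  store <- addTermAssignments(store, cand)

  assertions <- assertPathways(store, catalog)
  say("asserted ", nrow(assertions), " genome x pathway cell(s)")
  predictions <- predictPhenotypes(assertions, rules)
  agreement <- compareWithMetadata(predictions, rules,
                                   genomeMetadata(store))
  clusters <- buildParalogClusters(store, hitTable)
  koFam <- koFamilySummary(store)
  koPar <- koGenomeParalogSummary(store, clusters, hitTable)

  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeTsv(sortDf(propagated), file.path(outDir, "propagated_terms.tsv"))
  writeTsv(sortDf(cand), file.path(outDir, "candidate_terms.tsv"))
  writeAssertions(sortDf(assertions), file.path(outDir, "assertions.tsv"))
  writeTsv(sortDf(predictions), file.path(outDir, "predictions.tsv"))
  writeTsv(sortDf(agreement), file.path(outDir, "metadata_agreement.tsv"))
  writeTsv(sortDf(clusters), file.path(outDir, "paralog_clusters.tsv"))
  writeTsv(koFam, file.path(outDir, "ko_family_summary.tsv"))
  writeTsv(koPar, file.path(outDir, "ko_paralog_summary.tsv"))
  say("results written to ", outDir)
  invisible(list(store = store, propagated = propagated,
                 candidates = cand, assertions = assertions,
                 predictions = predictions, agreement = agreement,
                 clusters = clusters, koFamilySummary = koFam,
                 koParalogSummary = koPar))
}
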