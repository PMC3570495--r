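#' Construct an AnnotationStore from data.frames
#'
#' Duplicate rows in the assignment and metadata tables are collapsed;
#' validity (referential integrity, vocabularies, candidate/assignment
#' disjointness) is checked on construction.
#'
#' @param genomes,genes,familyAssignments,termAssignments,metadata
#'   data.frames with the columns documented in
#'   \linkS4class{AnnotationStore}; missing tables default to empty.
#' @return An \code{AnnotationStore}.
#' @export
AnnotationStore <- function(genomes = NULL, genes = NULL,
                            familyAssignments = NULL,
                            termAssignments = NULL, metadata = NULL) {
  proto <- new("AnnotationStore")
  fill <- function(x, template, what) {
    if (is.null(x)) return(template)
    x <- as.data.frame(x, stringsAsFactors = FALSE)
    miss <- setdiff(names(template), names(x))
    if (length(miss))
      stop("missing column(s) in ", what, ": ",
           paste(miss, collapse = ", "), call. = FALSE)
    x <- x[names(template)]
    for (nm in names(template)) {
      if (is.integer(template[[nm]])) x[[nm]] <- as.integer(x[[nm]])
      else if (is.character(template[[nm]])) x[[nm]] <- as.character(x[[nm]])
    }
    unique(x)
  }
  new("AnnotationStore",
      genomes = fill(genomes, proto@genomes, "genomes"),
      genes = fill(genes, proto@genes, "genes"),
      familyAssignments = fill(familyAssignments, proto@familyAssignments,
                               "familyAssignments"),
      termAssignments = fill(termAssignments, proto@termAssignments,
                             "termAssignments"),
      metadata = fill(metadata, proto@metadata, "metadata"))
}

readTsv <- function(path, required, what = basename(path)) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("schema error in ", what, ": missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  df
}

#' Read / write an annotation store as a directory of TSV files
#'
#' \code{readAnnotationStore} loads \code{genomes.tsv}, \code{genes.tsv},
#' \code{family_assignments.tsv}, \code{term_assignments.tsv} and
#' \code{metadata.tsv} (the last three optional: a missing file means an
#' empty table) from \code{dir}; \code{writeAnnotationStore} writes them
#' back, sorted on their key columns so identical stores produce identical
#' files.  A store written and re-read round-trips exactly.
#'
#' @param dir directory holding (or receiving) the TSV files.
#' @param store an \code{AnnotationStore}.
#' @return \code{readAnnotationStore}: an \code{AnnotationStore};
#'   \code{writeAnnotationStore}: \code{dir}, invisibly.
#' @export
readAnnotationStore <- function(dir) {
  req <- function(file, cols) readTsv(file.path(dir, file), cols)
  opt <- function(file, cols) {
    p <- file.path(dir, file)
    if (file.exists(p)) readTsv(p, cols) else NULL
  }
  genomes <- req("genomes.tsv", c("genome_id", "name", "completeness"))
  genesDf <- req("genes.tsv",
                 c("gene_id", "genome_id", "product_name", "length_aa"))
  if (nrow(genesDf)) {
    lens <- suppressWarnings(as.integer(genesDf$length_aa))
    bad <- which(is.na(lens) | lens <= 0)
    if (length(bad))
      stop("schema error in genes.tsv, line ", bad[1] + 1L,
           ": length_aa must be a positive integer", call. = FALSE)
    genesDf$length_aa <- lens
  }
  AnnotationStore(
    genomes = genomes, genes = genesDf,
    familyAssignments = opt("family_assignments.tsv",
                            c("gene_id", "namespace", "family_id")),
    termAssignments = opt("term_assignments.tsv",
                          c("gene_id", "term_id", "provenance")),
    metadata = opt("metadata.tsv", c("genome_id", "attribute", "value")))
}

writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

sortDf <- function(df) {
  if (!nrow(df)) return(df)
  o <- do.call(order, unname(as.list(df)))
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' @rdname readAnnotationStore
#' @export
writeAnnotationStore <- function(store, dir) {
  stopifnot(is(store, "AnnotationStore"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeTsv(sortDf(store@genomes), file.path(dir, "genomes.tsv"))
  writeTsv(sortDf(store@genes), file.path(dir, "genes.tsv"))
  writeTsv(sortDf(store@familyAssignments),
           file.path(dir, "family_assignments.tsv"))
  writeTsv(sortDf(store@termAssignments),
           file.path(dir, "term_assignments.tsv"))
  writeTsv(sortDf(store@metadata), file.path(dir, "metadata.tsv"))
  invisible(dir)
}

#' Construct a HitTable from a data.frame
#'
#' Self-hits are dropped, duplicate ordered (query, subject) pairs are
#' resolved by keeping the highest-scoring record, and identity/coverage
#' bounds are validated.  Coverage columns are 0--1 fractions; pass
#' \code{coverageScale = 100} if they are on the 0--100 percent scale.
#'
#' @param df data.frame with columns \code{query_gene_id},
#'   \code{subject_gene_id}, \code{percent_identity}, \code{query_coverage},
#'   \code{subject_coverage}, \code{score}.
#' @param coverageScale 1 (fractions, default) or 100 (percent).
#' @return A \code{HitTable}.
#' @export
HitTable <- function(df = NULL, coverageScale = 1) {
  proto <- new("HitTable")
  if (is.null(df) || nrow(df) == 0L) return(proto)
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- names(proto@hits)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing hit column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df <- df[need]
  for (nm in c("percent_identity", "query_coverage", "subject_coverage",
               "score"))
    df[[nm]] <- as.numeric(df[[nm]])
  if (coverageScale == 100) {
    df$query_coverage <- df$query_coverage / 100
    df$subject_coverage <- df$subject_coverage / 100
  } else if (coverageScale != 1) {
    stop("coverageScale must be 1 or 100", call. = FALSE)
  }
  if (any(df$percent_identity < 0 | df$percent_identity > 100))
    stop("percent_identity outside [0, 100]", call. = FALSE)
  if (any(df$query_coverage < 0 | df$query_coverage > 1) ||
      any(df$subject_coverage < 0 | df$subject_coverage > 1))
    stop("coverage outside bounds", call. = FALSE)
  if (any(df$score < 0)) stop("negative score", call. = FALSE)
  df <- df[df$query_gene_id != df$subject_gene_id, , drop = FALSE]
  if (nrow(df)) {
    # max-score dedup per ordered pair, deterministic under row permutation
    o <- order(df$query_gene_id, df$subject_gene_id, -df$score,
               -df$percent_identity)
    df <- df[o, , drop = FALSE]
    df <- df[!duplicated(paste(df$query_gene_id, df$subject_gene_id)), ,
             drop = FALSE]
    rownames(df) <- NULL
  }
  new("HitTable", hits = df)
}

#' Read / write a hit table TSV
#'
#' The TSV must carry a header with the \linkS4class{HitTable} columns.
#' Coverage columns named \code{query_coverage}/\code{subject_coverage} are
#' read as 0--1 fractions; if the header instead names them
#' \code{query_coverage_pct}/\code{subject_coverage_pct} they are read as
#' percentages and rescaled.
#'
#' @param path TSV file path.
#' @param hitTable a \code{HitTable}.
#' @return \code{readHitTable}: a \code{HitTable}.
#' @export
readHitTable <- function(path) {
  df <- readTsv(path, c("query_gene_id", "subject_gene_id",
                        "percent_identity", "score"))
  scale <- 1
  if (all(c("query_coverage_pct", "subject_coverage_pct") %in% names(df))) {
    names(df)[names(df) == "query_coverage_pct"] <- "query_coverage"
    names(df)[names(df) == "subject_coverage_pct"] <- "subject_coverage"
    scale <- 100
  }
  miss <- setdiff(c("query_coverage", "subject_coverage"), names(df))
  if (length(miss))
    stop("schema error in ", basename(path), ": missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  HitTable(df, coverageScale = scale)
}

#' @rdname readHitTable
#' @export
writeHitTable <- function(hitTable, path) {
  stopifnot(is(hitTable, "HitTable"))
  writeTsv(sortDf(hitTable@hits), path)
  invisible(path)
}
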