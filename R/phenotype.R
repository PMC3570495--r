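#' Read a phenotype rule catalog
#'
#' A rules TSV has columns \code{rule_id}, \code{phenotype_name},
#' \code{category}, \code{category_value} and \code{expression}, where the
#' expression is a boolean rule over pathway ids (see
#' \code{\link{parseRule}}).  The category / category value pair names the
#' organism-metadata attribute the phenotype can be checked against (e.g.
#' category \emph{Oxygen Requirement}, value \emph{aerobic}).  All
#' expressions are parsed on read, so syntax errors surface immediately
#' with the offending rule id.
#'
#' @param path rules TSV path.
#' @return data.frame of rules (expressions kept as text).
#' @export
readPhenotypeRules <- function(path) {
  rules <- readTsv(path, c("rule_id", "phenotype_name", "category",
                           "category_value", "expression"))
  for (i in seq_len(nrow(rules))) {
    tryCatch(parseRule(rules$expression[i]), error = function(e)
      stop("rule ", rules$rule_id[i], ": ", conditionMessage(e),
           call. = FALSE))
  }
  rules
}

#' Predict phenotypes from pathway assertions
#'
#' Evaluates every rule against every genome's pathway statuses under the
#' Kleene connectives.  Assertion statuses map to truth values as
#' asserted = true, not_asserted = false, unknown = unknown; the manual
#' status \code{absent} maps to false.  The verdict is \code{predicted}
#' when the rule evaluates true, \code{not_predicted} when false, and
#' \code{unknown} otherwise.  In strict mode (default) a rule naming a
#' pathway with no assertion for a genome is an error; in lenient mode the
#' missing pathway evaluates to unknown and appears in the evidence as
#' \code{missing}.
#'
#' @param assertions data.frame from \code{\link{assertPathways}} (or read
#'   back with \code{\link{readAssertions}}).
#' @param rules data.frame from \code{\link{readPhenotypeRules}}.
#' @param strict logical; see Details.
#' @return data.frame with columns \code{genome_id}, \code{rule_id},
#'   \code{verdict} and \code{evidence} (semicolon-joined
#'   \code{pathway=status} pairs for the rule's leaves).
#' @export
predictPhenotypes <- function(assertions, rules, strict = TRUE) {
  asts <- lapply(rules$expression, parseRule)
  genomeIds <- unique(assertions$genome_id)
  rows <- vector("list", length(genomeIds) * nrow(rules))
  k <- 0L
  for (g in genomeIds) {
    sub <- assertions[assertions$genome_id == g, , drop = FALSE]
    statusOf <- stats::setNames(sub$status, sub$pathway_id)
    tri <- stats::setNames(statusToTri(sub$status), sub$pathway_id)
    for (i in seq_len(nrow(rules))) {
      val <- evaluateRule(asts[[i]], tri, strict = strict)
      verdict <- c(true = "predicted", false = "not_predicted",
                   unknown = "unknown")[[as.character(val)]]
      leaves <- ruleVariables(asts[[i]])
      shown <- ifelse(leaves %in% names(statusOf),
                      unname(statusOf[leaves]), "missing")
      k <- k + 1L
      rows[[k]] <- data.frame(
        genome_id = g, rule_id = rules$rule_id[i], verdict = verdict,
        evidence = paste(paste0(leaves, "=", shown), collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows[seq_len(k)])
}

#' Default metadata value synonyms
#'
#' Named character vector mapping lower-case synonym to canonical form,
#' applied to both predicted category values and metadata values before
#' comparison.  Users can extend or replace it.
#'
#' @return Named character vector.
#' @export
defaultSynonyms <- function() {
  c(aerobe = "aerobic", anaerobe = "anaerobic")
}

normalizeValue <- function(x, synonyms) {
  x <- tolower(trimws(x))
  hit <- match(x, names(synonyms))
  x[!is.na(hit)] <- unname(synonyms[hit[!is.na(hit)]])
  x
}

#' Compare predicted phenotypes with organism metadata
#'
#' For each \code{predicted} phenotype, looks up the genome's metadata
#' attribute matching the rule's category (exact attribute-name equality
#' after whitespace trimming) and classifies the pair as \code{agree},
#' \code{conflict} or \code{no_metadata}.  Value comparison is
#' case-insensitive after synonym normalisation.
#'
#' @param predictions data.frame from \code{\link{predictPhenotypes}}.
#' @param rules data.frame from \code{\link{readPhenotypeRules}}.
#' @param metadata data.frame with \code{genome_id}, \code{attribute},
#'   \code{value} (e.g. \code{genomeMetadata(store)}).
#' @param synonyms named character vector; see
#'   \code{\link{defaultSynonyms}}.
#' @return data.frame with columns \code{genome_id}, \code{rule_id},
#'   \code{category}, \code{category_value}, \code{metadata_value},
#'   \code{agreement}.
#' @export
compareWithMetadata <- function(predictions, rules, metadata,
                                synonyms = defaultSynonyms()) {
  pred <- predictions[predictions$verdict == "predicted", , drop = FALSE]
  ri <- match(pred$rule_id, rules$rule_id)
  if (anyNA(ri))
    stop("prediction references unknown rule id: ",
         paste(unique(pred$rule_id[is.na(ri)]), collapse = ", "),
         call. = FALSE)
  rows <- vector("list", nrow(pred))
  mdAttr <- trimws(metadata$attribute)
  for (i in seq_len(nrow(pred))) {
    cat <- trimws(rules$category[ri[i]])
    catVal <- rules$category_value[ri[i]]
    md <- metadata[metadata$genome_id == pred$genome_id[i] &
                   mdAttr == cat, , drop = FALSE]
    if (!nrow(md)) {
      agreement <- "no_metadata"; mdVal <- NA_character_
    } else {
      match_ <- normalizeValue(md$value, synonyms) ==
        normalizeValue(catVal, synonyms)
      agreement <- if (any(match_)) "agree" else "conflict"
      mdVal <- md$value[1]
    }
    rows[[i]] <- data.frame(
      genome_id = pred$genome_id[i], rule_id = pred$rule_id[i],
      category = cat, category_value = catVal, metadata_value = mdVal,
      agreement = agreement, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(genome_id = character(0), rule_id = character(0),
                      category = character(0),
                      category_value = character(0),
                      metadata_value = character(0),
                      agreement = character(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Search genomes by metadata attribute/value conjunctions
#'
#' Returns the genomes satisfying every clause of the query, matching
#' values case-insensitively (after whitespace trimming).  The query is
#' either a named character vector (names = attributes) or a string such
#' as \code{"Oxygen Requirement=aerobic AND Temperature Range=mesophile"}.
#' An attribute absent from the metadata table triggers a warning (and an
#' empty result); an empty query returns all genomes in the table.
#'
#' @param metadata data.frame with \code{genome_id}, \code{attribute},
#'   \code{value}.
#' @param query named character vector or query string.
#' @return Character vector of genome ids, sorted.
#' @export
searchGenomesByMetadata <- function(metadata, query = character(0)) {
  if (is.character(query) && is.null(names(query)) && length(query) == 1 &&
      nzchar(trimws(query))) {
    clauses <- strsplit(query, "\\s+[Aa][Nn][Dd]\\s+")[[1]]
    parts <- strsplit(clauses, "=", fixed = TRUE)
    bad <- vapply(parts, length, integer(1)) != 2L
    if (any(bad))
      stop("malformed query clause: ", clauses[bad][1], call. = FALSE)
    query <- stats::setNames(
      trimws(vapply(parts, `[`, character(1), 2)),
      trimws(vapply(parts, `[`, character(1), 1)))
  }
  all <- sort(unique(metadata$genome_id))
  if (!length(query) || (length(query) == 1 && !nzchar(query[[1]]) &&
                         is.null(names(query))))
    return(all)
  mdAttr <- trimws(metadata$attribute)
  result <- all
  for (i in seq_along(query)) {
    attrName <- trimws(names(query)[i])
    if (!attrName %in% mdAttr) {
      warning("unknown metadata attribute: ", attrName, call. = FALSE)
      return(character(0))
    }
    sel <- metadata$genome_id[mdAttr == attrName &
      tolower(trimws(metadata$value)) == tolower(trimws(query[[i]]))]
    result <- intersect(result, sel)
  }
  sort(unique(result))
}
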