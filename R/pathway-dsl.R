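#' Read a pathway definition file
#'
#' Parses the plain-text definition DSL into a
#' \linkS4class{PathwayCatalog}.  One declaration per line; blank lines and
#' lines starting with \code{#} are ignored:
#'
#' \preformatted{
#' term T_0001 "glucose dehydrogenase, NADP-dependent" kind=protein_product
#' reaction R_977 "D-glucose + NADP+ <=> ..." requires (T_0001) | (T_0002 & T_0003)
#' pathway P_339 "6-phosphogluconate synthesis via gluconate" steps: [R_977|R_978|R_979|R_980] -> [R_981] -> [R_982]
#' override genome=G_001 pathway=P_339 status=asserted
#' }
#'
#' Reaction requirements are OR-separated (\code{|}) parenthesised groups of
#' AND-separated (\code{&}) term ids; pathway steps are \code{->}-separated
#' bracketed groups of \code{|}-separated reaction ids.  Referential
#' integrity (pathway to reaction to term) is validated; dangling references
#' and empty requirement sets are errors naming the offending line.
#'
#' @param path definition file path.
#' @return A \code{PathwayCatalog}.
#' @export
readPathwayDefinitions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  terms <- list(); reactions <- list(); pathways <- list()
  overrides <- list()
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line) || startsWith(line, "#")) next
    err <- function(msg) stop("parse error at ", basename(path), ":", i,
                              ": ", msg, call. = FALSE)
    if (grepl("^term\\s", line)) {
      m <- regmatches(line, regexec(
        '^term\\s+(\\S+)\\s+"([^"]*)"\\s+kind=(\\S+)\\s*$', line))[[1]]
      if (length(m) != 4) err("malformed term declaration")
      if (!m[4] %in% c("protein_product", "modified_protein",
                       "protein_complex"))
        err(paste0("unknown term kind '", m[4], "'"))
      terms[[length(terms) + 1L]] <-
        data.frame(term_id = m[2], name = m[3], kind = m[4],
                   stringsAsFactors = FALSE)
    } else if (grepl("^reaction\\s", line)) {
      m <- regmatches(line, regexec(
        '^reaction\\s+(\\S+)\\s+"([^"]*)"\\s+requires\\s+(.+)$', line))[[1]]
      if (length(m) != 4) err("malformed reaction declaration")
      alts <- strsplit(m[4], "|", fixed = TRUE)[[1]]
      reqs <- lapply(alts, function(alt) {
        alt <- trimws(alt)
        if (!grepl("^\\(.*\\)$", alt))
          err("requirement alternative must be parenthesised")
        inner <- substr(alt, 2, nchar(alt) - 1)
        ids <- trimws(strsplit(inner, "&", fixed = TRUE)[[1]])
        ids <- ids[nzchar(ids)]
        if (!length(ids)) err("empty requirement set")
        ids
      })
      reactions[[m[2]]] <- list(reaction_id = m[2], name = m[3],
                                requirements = reqs)
    } else if (grepl("^pathway\\s", line)) {
      m <- regmatches(line, regexec(
        '^pathway\\s+(\\S+)\\s+"([^"]*)"\\s+steps:\\s*(.+)$', line))[[1]]
      if (length(m) != 4) err("malformed pathway declaration")
      stepTexts <- trimws(strsplit(m[4], "->", fixed = TRUE)[[1]])
      steps <- lapply(stepTexts, function(stp) {
        if (!grepl("^\\[.*\\]$", stp))
          err("pathway step must be bracketed")
        inner <- substr(stp, 2, nchar(stp) - 1)
        ids <- trimws(strsplit(inner, "|", fixed = TRUE)[[1]])
        ids <- ids[nzchar(ids)]
        if (!length(ids)) err("empty pathway step")
        ids
      })
      pathways[[m[2]]] <- list(pathway_id = m[2], name = m[3],
                               steps = steps)
    } else if (grepl("^override\\s", line)) {
      m <- regmatches(line, regexec(
        "^override\\s+genome=(\\S+)\\s+pathway=(\\S+)\\s+status=(\\S+)\\s*$",
        line))[[1]]
      if (length(m) != 4) err("malformed override declaration")
      if (!m[4] %in% c("asserted", "absent"))
        err("override status must be 'asserted' or 'absent'")
      overrides[[length(overrides) + 1L]] <-
        data.frame(genome_id = m[2], pathway_id = m[3], status = m[4],
                   stringsAsFactors = FALSE)
    } else {
      err(paste0("unrecognised declaration '",
                 strsplit(line, "\\s+")[[1]][1], "'"))
    }
  }
  catalog <- new("PathwayCatalog",
      terms = if (length(terms)) do.call(rbind, terms) else
        new("PathwayCatalog")@terms,
      reactions = reactions, pathways = pathways,
      overrides = if (length(overrides)) unique(do.call(rbind, overrides))
        else new("PathwayCatalog")@overrides)
  validObject(catalog)
  catalog
}

#' Write a pathway catalog back to the definition DSL
#'
#' @param catalog a \code{PathwayCatalog}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writePathwayDefinitions <- function(catalog, path) {
  stopifnot(is(catalog, "PathwayCatalog"))
  lines <- character(0)
  tm <- catalog@terms
  for (i in seq_len(nrow(tm)))
    lines <- c(lines, sprintf('term %s "%s" kind=%s', tm$term_id[i],
                              tm$name[i], tm$kind[i]))
  for (r in catalog@reactions) {
    req <- paste(vapply(r$requirements, function(alt)
      paste0("(", paste(alt, collapse = " & "), ")"), character(1)),
      collapse = " | ")
    lines <- c(lines, sprintf('reaction %s "%s" requires %s',
                              r$reaction_id, r$name, req))
  }
  for (p in catalog@pathways) {
    stp <- paste(vapply(p$steps, function(s)
      paste0("[", paste(s, collapse = "|"), "]"), character(1)),
      collapse = " -> ")
    lines <- c(lines, sprintf('pathway %s "%s" steps: %s',
                              p$pathway_id, p$name, stp))
  }
  ov <- catalog@overrides
  for (i in seq_len(nrow(ov)))
    lines <- c(lines, sprintf("override genome=%s pathway=%s status=%s",
                              ov$genome_id[i], ov$pathway_id[i],
                              ov$status[i]))
  writeLines(lines, path)
  invisible(path)
}
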