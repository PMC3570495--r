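# Independent oracles and random-input generators used across the suite.
# These deliberately avoid the package's own evaluation code paths.

# --- two-valued evaluation of a rule AST over a logical environment
evalBool <- function(ast, env) {
  switch(ast$kind,
    var = env[[ast$id]],
    not = !evalBool(ast$x, env),
    and = evalBool(ast$lhs, env) && evalBool(ast$rhs, env),
    or  = evalBool(ast$lhs, env) || evalBool(ast$rhs, env))
}

# --- completion oracle: enumerate all TRUE/FALSE completions of the
# UNKNOWN variables; "true" iff all completions are true, "false" iff
# none are, otherwise "unknown"
completionOracle <- function(ast, statuses) {
  vars <- ruleVariables(ast)
  unk <- vars[statuses[vars] == "unknown"]
  base <- as.list(statuses[vars] == "true")
  names(base) <- vars
  if (!length(unk))
    return(if (evalBool(ast, base)) "true" else "false")
  results <- logical(0)
  for (mask in 0:(2^length(unk) - 1L)) {
    env <- base
    for (j in seq_along(unk))
      env[[unk[j]]] <- bitwAnd(mask, bitwShiftL(1L, j - 1L)) > 0L
    results <- c(results, evalBool(ast, env))
  }
  if (all(results)) "true" else if (!any(results)) "false" else "unknown"
}

# --- random expression in which each variable occurs exactly once
randomSingleOccurrenceExpr <- function(vars, pNot = 0.3) {
  node <- if (length(vars) == 1L) {
    list(kind = "var", id = vars)
  } else {
    cut <- sample(seq_len(length(vars) - 1L), 1L)
    list(kind = sample(c("and", "or"), 1L),
         lhs = randomSingleOccurrenceExpr(vars[seq_len(cut)], pNot),
         rhs = randomSingleOccurrenceExpr(vars[-seq_len(cut)], pNot))
  }
  if (stats::runif(1) < pNot) list(kind = "not", x = node) else node
}

# --- random annotation store for report-count oracles
randomStore <- function(nGenomes = sample(2:5, 1), maxGenes = 200L,
                        koPool = paste0("K", 1:6),
                        cogPool = paste0("C", 1:4),
                        pfamPool = paste0("pf", 1:5),
                        tigrPool = paste0("TIGR", 1:3)) {
  genomeIds <- sprintf("RG%02d", seq_len(nGenomes))
  perGenome <- sample(3:floor(maxGenes / nGenomes), nGenomes,
                      replace = TRUE)
  genesDf <- do.call(rbind, lapply(seq_len(nGenomes), function(i) {
    data.frame(gene_id = sprintf("%s.g%03d", genomeIds[i],
                                 seq_len(perGenome[i])),
               genome_id = genomeIds[i], product_name = "protein",
               length_aa = sample(100:500, perGenome[i], replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  fam <- list()
  for (g in genesDf$gene_id) {
    nKo <- sample(0:2, 1, prob = c(0.4, 0.5, 0.1))
    for (k in if (nKo) sample(koPool, nKo) else character(0))
      fam[[length(fam) + 1L]] <- data.frame(gene_id = g, namespace = "KO",
                                            family_id = k)
    if (stats::runif(1) < 0.7)
      fam[[length(fam) + 1L]] <- data.frame(gene_id = g, namespace = "COG",
                                            family_id = sample(cogPool, 1))
    for (p in if (stats::runif(1) < 0.6)
           sample(pfamPool, sample(1:2, 1)) else character(0))
      fam[[length(fam) + 1L]] <- data.frame(gene_id = g,
                                            namespace = "Pfam",
                                            family_id = p)
    if (stats::runif(1) < 0.3)
      fam[[length(fam) + 1L]] <- data.frame(gene_id = g,
                                            namespace = "TIGRfam",
                                            family_id = sample(tigrPool, 1))
  }
  AnnotationStore(
    genomes = data.frame(genome_id = genomeIds, name = genomeIds,
                         completeness = "finished",
                         stringsAsFactors = FALSE),
    genes = genesDf,
    familyAssignments = if (length(fam)) do.call(rbind, fam) else NULL)
}

# --- naive quadruple-loop recount of the per-KO family summary
naiveKoFamilySummary <- function(store) {
  fa <- familyAssignments(store)
  kos <- sort(unique(fa$family_id[fa$namespace == "KO"]))
  comboOf <- function(g) {
    sub <- fa[fa$gene_id == g, , drop = FALSE]
    paste(paste(sort(unique(sub$family_id[sub$namespace == "COG"])),
                collapse = ","),
          paste(sort(unique(sub$family_id[sub$namespace == "Pfam"])),
                collapse = ","),
          paste(sort(unique(sub$family_id[sub$namespace == "TIGRfam"])),
                collapse = ","), sep = "|")
  }
  do.call(rbind, lapply(kos, function(k) {
    kg <- unique(fa$gene_id[fa$namespace == "KO" & fa$family_id == k])
    ids <- function(ns) unique(fa$family_id[fa$gene_id %in% kg &
                                            fa$namespace == ns])
    data.frame(ko_id = k, n_genes = length(kg),
               n_cogs = length(ids("COG")), n_pfams = length(ids("Pfam")),
               n_tigrfams = length(ids("TIGRfam")),
               n_combinations = length(unique(vapply(kg, comboOf,
                                                     character(1)))),
               stringsAsFactors = FALSE)
  }))
}

# --- naive recount of the per-combination details for one KO
naiveKoCombinationDetails <- function(store, koId) {
  fa <- familyAssignments(store)
  allGenes <- genes(store)$gene_id
  comboOf <- function(g) {
    sub <- fa[fa$gene_id == g, , drop = FALSE]
    paste(paste(sort(unique(sub$family_id[sub$namespace == "COG"])),
                collapse = ","),
          paste(sort(unique(sub$family_id[sub$namespace == "Pfam"])),
                collapse = ","),
          paste(sort(unique(sub$family_id[sub$namespace == "TIGRfam"])),
                collapse = ","), sep = "|")
  }
  kosOf <- function(g) unique(fa$family_id[fa$gene_id == g &
                                           fa$namespace == "KO"])
  combos <- vapply(allGenes, comboOf, character(1))
  queryGenes <- allGenes[vapply(allGenes,
                                function(g) koId %in% kosOf(g),
                                logical(1))]
  queryCombos <- sort(unique(combos[queryGenes]))
  do.call(rbind, lapply(queryCombos, function(cmb) {
    carriers <- allGenes[combos == cmb]
    a <- b <- c_ <- d <- 0L
    for (g in carriers) {
      ks <- kosOf(g)
      if (koId %in% ks) a <- a + 1L
      if (length(setdiff(ks, koId)) > 0) b <- b + 1L
      if (length(setdiff(ks, koId)) > 0 && !(koId %in% ks)) c_ <- c_ + 1L
      if (length(ks) == 0) d <- d + 1L
    }
    data.frame(combo = cmb, n_with_query_ko = a,
               n_with_other_ko_incl = b, n_with_other_ko_excl = c_,
               n_without_ko = d, stringsAsFactors = FALSE)
  }))
}

# --- independent reference implementation of the MCL update rule
referenceMcl <- function(adj, inflation = 2, maxIter = 100, tol = 1e-6) {
  A <- pmax(adj, t(adj))
  diag(A) <- 0
  d <- apply(A, 1, max)
  d[d == 0] <- 1
  diag(A) <- d
  M <- t(t(A) / colSums(A))
  for (i in seq_len(maxIter)) {
    Mn <- (M %*% M)^inflation
    Mn[Mn < 1e-9] <- 0
    cs <- colSums(Mn); cs[cs == 0] <- 1
    Mn <- t(t(Mn) / cs)
    if (max(abs(Mn - M)) < tol) { M <- Mn; break }
    M <- Mn
  }
  g <- igraph::graph_from_adjacency_matrix((M > tol) | t(M > tol),
                                           mode = "undirected",
                                           diag = FALSE)
  memb <- igraph::components(g)$membership
  unname(lapply(split(names(memb), memb), sort))
}

# --- small store/hits builders for propagation tests
sweepStore <- function(nDonors, nCarriers, term = "T1",
                       donorGenome = "GD") {
  geneRows <- data.frame(
    gene_id = c("q", paste0("d", seq_len(nDonors))),
    genome_id = c("GQ", rep(donorGenome, nDonors)),
    product_name = "p", length_aa = 300L, stringsAsFactors = FALSE)
  termRows <- if (nCarriers > 0)
    data.frame(gene_id = paste0("d", seq_len(nCarriers)), term_id = term,
               provenance = "manual", stringsAsFactors = FALSE) else NULL
  AnnotationStore(
    genomes = data.frame(genome_id = c("GQ", donorGenome),
                         name = c("query", "donor"),
                         completeness = "finished",
                         stringsAsFactors = FALSE),
    genes = geneRows, termAssignments = termRows)
}

sweepHits <- function(nDonors, identity, coverage = 0.8, score = 100) {
  HitTable(data.frame(
    query_gene_id = "q", subject_gene_id = paste0("d", seq_len(nDonors)),
    percent_identity = identity, query_coverage = coverage,
    subject_coverage = coverage, score = score, stringsAsFactors = FALSE))
}

# store/hits for candidate sweeps: gene q in G0, one term-bearing donor in
# each of nDonors genomes, mutual hits at the given identity
candidateSweepFixture <- function(nDonors = 2, identity, coverage = 0.8,
                                  term = "T1") {
  donorGenomes <- paste0("GD", seq_len(nDonors))
  donors <- paste0("d", seq_len(nDonors))
  store <- AnnotationStore(
    genomes = data.frame(genome_id = c("G0", donorGenomes),
                         name = "x", completeness = "finished",
                         stringsAsFactors = FALSE),
    genes = data.frame(gene_id = c("q", donors),
                       genome_id = c("G0", donorGenomes),
                       product_name = "p", length_aa = 300L,
                       stringsAsFactors = FALSE),
    termAssignments = data.frame(gene_id = donors, term_id = term,
                                 provenance = "manual",
                                 stringsAsFactors = FALSE))
  ht <- HitTable(data.frame(
    query_gene_id = c(rep("q", nDonors), donors),
    subject_gene_id = c(donors, rep("q", nDonors)),
    percent_identity = identity, query_coverage = coverage,
    subject_coverage = coverage, score = 100, stringsAsFactors = FALSE))
  list(store = store, hits = ht)
}
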