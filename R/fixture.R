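#' Configuration for the synthetic fixture generator
#'
#' The generator emits a complete miniature annotation set — genomes,
#' genes, family and term assignments, a similarity hit table, pathway
#' definitions, phenotype rules and organism metadata — together with a
#' ground-truth table (\code{truth.tsv}) of the pathway statuses and
#' phenotype verdicts it planted.  Eight core genomes carry a hand-designed
#' plan covering every assertion status, manual overrides, a
#' propagation-delivered term, candidate-only terms, all four OR-branches
#' of the cellulose-utilisation rule, and prototroph/auxotroph pairs for
#' histidine, phenylalanine and lysine; additional genomes (when
#' \code{nGenomes} > 8) are unannotated background.  Similarity values are
#' sampled directly (no sequences are materialised): homolog pairs meant to
#' propagate draw identities from 55--95\%, candidate-evidence pairs from
#' 30--45\%, and decoy pairs stay at or below 25\%.
#'
#' @param nGenomes total number of genomes, >= 8 (default 8).
#' @param genesPerGenome gene count each genome is padded to (default 30).
#' @param fractionDraft fraction of the extra (non-core) genomes marked
#'   draft (default 0.25); core genomes have fixed completeness.
#' @param plantedParalogGroups number of within-genome paralog groups with
#'   shared KO terms, 0..2 (default 2).
#' @param koInconsistencyRate fraction of filler genes given a KO term with
#'   deliberately inconsistent family combinations (default 0.1).
#' @param seed integer RNG seed; the same configuration and seed produce
#'   byte-identical files.
#' @return A list of class \code{fixtureConfig}.
#' @export
fixtureConfig <- function(nGenomes = 8L, genesPerGenome = 30L,
                          fractionDraft = 0.25, plantedParalogGroups = 2L,
                          koInconsistencyRate = 0.1, seed = 42L) {
  stopifnot(nGenomes >= 8L, genesPerGenome >= 1L,
            fractionDraft >= 0, fractionDraft <= 1,
            plantedParalogGroups %in% 0:2,
            koInconsistencyRate >= 0, koInconsistencyRate <= 1)
  structure(list(nGenomes = as.integer(nGenomes),
                 genesPerGenome = as.integer(genesPerGenome),
                 fractionDraft = fractionDraft,
                 plantedParalogGroups = as.integer(plantedParalogGroups),
                 koInconsistencyRate = koInconsistencyRate,
                 seed = as.integer(seed)),
            class = "fixtureConfig")
}

# ---- built-in catalog -------------------------------------------------

fixtureDefinitionLines <- function() {
  simple <- function(pid, rid, tid, pname, rname, tname) {
    c(sprintf('term %s "%s" kind=protein_product', tid, tname),
      sprintf('reaction %s "%s" requires (%s)', rid, rname, tid),
      sprintf('pathway %s "%s" steps: [%s]', pid, pname, rid))
  }
  lines <- c(
    "# synthetic pathway catalog",
    'term T_977 "glucose 1-dehydrogenase (NADP+)" kind=protein_product',
    'term T_978 "glucose 1-dehydrogenase (NAD+)" kind=protein_product',
    'term T_979 "glucose oxidase" kind=protein_product',
    'term T_980 "quinoprotein glucose dehydrogenase" kind=protein_product',
    'term T_981 "gluconolactonase" kind=protein_product',
    'term T_982A "gluconate kinase, catalytic subunit" kind=protein_complex',
    'term T_982B "gluconate kinase, regulatory subunit" kind=protein_complex',
    'reaction R_977 "D-glucose + NADP+ <=> D-glucono-1,5-lactone + NADPH + H+" requires (T_977)',
    'reaction R_978 "D-glucose + NAD+ <=> D-glucono-1,5-lactone + NADH + H+" requires (T_978)',
    'reaction R_979 "D-glucose + O2 <=> D-glucono-1,5-lactone + H2O2" requires (T_979)',
    'reaction R_980 "D-glucose + ubiquinone <=> D-glucono-1,5-lactone + ubiquinol" requires (T_980)',
    'reaction R_981 "D-glucono-1,5-lactone + H2O <=> D-gluconate" requires (T_981)',
    'reaction R_982 "ATP + D-gluconate <=> ADP + 6-phospho-D-gluconate" requires (T_982A & T_982B)',
    'pathway P_339 "6-phosphogluconate synthesis via gluconate" steps: [R_977|R_978|R_979|R_980] -> [R_981] -> [R_982]',
    simple("P_162", "R_162", "T_162", "L-histidine biosynthesis",
           "histidine biosynthesis from PRPP", "histidinol dehydrogenase module"),
    simple("P_146", "R_146", "T_146", "chorismate biosynthesis via shikimate",
           "chorismate from erythrose 4-phosphate", "chorismate synthase module"),
    simple("P_519", "R_519", "T_519", "chorismate biosynthesis, alternative",
           "chorismate alternative route", "alternative chorismate module"),
    simple("P_272", "R_272", "T_272", "phenylalanine from chorismate via phenylpyruvate",
           "chorismate to phenylalanine (phenylpyruvate)", "prephenate dehydratase module"),
    simple("P_147", "R_147", "T_147", "phenylalanine from chorismate via arogenate",
           "chorismate to phenylalanine (arogenate)", "arogenate dehydratase module"),
    simple("P_169", "R_169", "T_169", "lysine biosynthesis via diaminopimelate, succinylase",
           "DAP pathway, succinylase branch", "succinyl-DAP module"),
    simple("P_170", "R_170", "T_170", "lysine biosynthesis via diaminopimelate, acetylase",
           "DAP pathway, acetylase branch", "acetyl-DAP module"),
    simple("P_0171", "R_0171", "T_0171", "lysine biosynthesis via diaminopimelate, dehydrogenase",
           "DAP pathway, dehydrogenase branch", "DAP dehydrogenase module"),
    simple("P_199", "R_199", "T_199", "lysine biosynthesis via diaminopimelate, aminotransferase",
           "DAP pathway, aminotransferase branch", "DAP aminotransferase module"),
    simple("P_333", "R_333", "T_333", "lysine biosynthesis via alpha-aminoadipate, fungal type",
           "AAA pathway, fungal type", "alpha-aminoadipate reductase module"),
    simple("P_465", "R_465", "T_465", "lysine biosynthesis via alpha-aminoadipate, thermophilic",
           "AAA pathway, thermophilic type", "LysX module"),
    simple("P_770", "R_770", "T_770", "plastoquinol oxidation with oxygen",
           "plastoquinol + O2 -> plastoquinone + H2O", "plastoquinol terminal oxidase"),
    simple("P_CDEG", "R_CDEG", "T_CDEG", "cellulose degradation to cellobiose",
           "cellulose -> cellobiose", "extracellular cellulase module"),
    simple("P_ABCUP", "R_ABCUP", "T_ABCUP", "ATP-dependent cellobiose uptake",
           "cellobiose(out) + ATP -> cellobiose(in)", "cellobiose ABC transporter"),
    simple("P_CBH", "R_CBH", "T_CBH", "cellobiose hydrolysis",
           "cellobiose + H2O -> 2 D-glucose", "beta-glucosidase module"),
    simple("P_CB1P", "R_CB1P", "T_CB1P", "cellobiose conversion to glucose and glucose 1-phosphate",
           "cellobiose + Pi -> glucose + glucose 1-phosphate", "cellobiose phosphorylase module"),
    simple("P_BGK", "R_BGK", "T_BGK", "cellobiose phosphorylation via beta-glucoside kinase",
           "cellobiose + ATP -> cellobiose 6-phosphate", "beta-glucoside kinase module"),
    simple("P_CB6P", "R_CB6P", "T_CB6P", "cellobiose 6-phosphate conversion to glucose and glucose 6-phosphate",
           "cellobiose 6-phosphate + H2O -> glucose + glucose 6-phosphate", "phospho-beta-glucosidase module"),
    simple("P_PTS", "R_PTS", "T_PTS", "cellobiose uptake via phosphotransferase system",
           "cellobiose(out) + PEP -> cellobiose 6-phosphate(in)", "cellobiose PTS module"),
    "override genome=G_005 pathway=P_339 status=asserted",
    "override genome=G_006 pathway=P_162 status=absent")
  lines
}

fixtureRules <- function() {
  data.frame(
    rule_id = c("his_prototroph", "his_auxotroph", "phe_prototroph",
                "lys_prototroph", "lys_auxotroph", "cellulose_cellobiose",
                "aerobe"),
    phenotype_name = c("L-histidine prototroph", "L-histidine auxotroph",
                       "L-phenylalanine prototroph",
                       "L-lysine prototroph", "L-lysine auxotroph",
                       "Growth on cellulose via cellobiose", "Aerobe"),
    category = c("Histidine Requirement", "Histidine Requirement",
                 "Phenylalanine Requirement", "Lysine Requirement",
                 "Lysine Requirement", "Carbon Source",
                 "Oxygen Requirement"),
    category_value = c("prototroph", "auxotroph", "prototroph",
                       "prototroph", "auxotroph", "cellulose", "aerobic"),
    expression = c(
      "P_162",
      "NOT P_162",
      "(P_146 OR P_519) AND (P_272 OR P_147)",
      "(P_169 OR P_170 OR P_0171 OR P_199 OR P_333 OR P_465)",
      paste("(NOT P_169) AND (NOT P_170) AND (NOT P_0171) AND",
            "(NOT P_199) AND (NOT P_333) AND (NOT P_465)"),
      paste("(P_CDEG AND P_ABCUP AND P_CBH) OR",
            "(P_CDEG AND P_ABCUP AND P_CB1P) OR",
            "(P_CDEG AND P_ABCUP AND P_BGK AND P_CB6P) OR",
            "(P_CDEG AND P_PTS AND P_CB6P)"),
      "P_770"),
    stringsAsFactors = FALSE)
}

# per-core-genome plan: complete / candidate_only / missing
fixturePlan <- function() {
  g <- paste0("G_00", 1:8)
  plan <- function(pid, plans)
    data.frame(genome_id = g, pathway_id = pid, plan = plans,
               stringsAsFactors = FALSE)
  rbind(
    plan("P_339",  c("complete", "candidate_only", "missing", "complete",
                     "missing", "missing", "missing", "complete")),
    plan("P_162",  c("complete", "missing", "candidate_only", "complete",
                     "missing", "complete", "complete", "complete")),
    plan("P_146",  c("complete", "missing", "missing", "missing",
                     "missing", "missing", "complete", "missing")),
    plan("P_519",  c("missing", "missing", "complete", "missing",
                     "missing", "missing", "missing", "missing")),
    plan("P_272",  c("complete", "missing", "missing", "missing",
                     "missing", "missing", "complete", "missing")),
    plan("P_147",  c("missing", "missing", "complete", "missing",
                     "missing", "missing", "missing", "missing")),
    plan("P_169",  c("complete", "missing", "missing", "complete",
                     "missing", "candidate_only", "missing", "missing")),
    plan("P_170",  rep("missing", 8)),
    plan("P_0171", rep("missing", 8)),
    plan("P_199",  rep("missing", 8)),
    plan("P_333",  c("missing", "missing", "complete", rep("missing", 5))),
    plan("P_465",  c(rep("missing", 3), "complete", rep("missing", 4))),
    plan("P_770",  c("complete", "complete", "complete", "missing",
                     "missing", "missing", "missing", "complete")),
    plan("P_CDEG", c(rep("complete", 4), rep("missing", 4))),
    plan("P_ABCUP", c(rep("complete", 3), rep("missing", 5))),
    plan("P_CBH",  c("complete", rep("missing", 7))),
    plan("P_CB1P", c("missing", "complete", rep("missing", 6))),
    plan("P_BGK",  c("missing", "missing", "complete", rep("missing", 5))),
    plan("P_CB6P", c("missing", "missing", "complete", "complete",
                     rep("missing", 4))),
    plan("P_PTS",  c(rep("missing", 3), "complete", rep("missing", 4))))
}

# terms delivered by propagation rather than a direct manual assignment
fixturePropagated <- function() {
  data.frame(genome_id = c("G_001", "G_007"),
             term_id = c("T_981", "T_146"), stringsAsFactors = FALSE)
}

# the satisfying path a "complete"/"candidate_only" plan materialises:
# one alternative reaction per step, one requirement alternative per
# reaction, rotated by genome index for variety
chosenPathTerms <- function(catalog, pathwayId, genomeIndex) {
  pw <- catalog@pathways[[pathwayId]]
  terms <- character(0)
  for (s in seq_along(pw$steps)) {
    alts <- pw$steps[[s]]
    rid <- alts[((genomeIndex + s) %% length(alts)) + 1L]
    reqs <- catalog@reactions[[rid]]$requirements
    terms <- c(terms, reqs[[(genomeIndex %% length(reqs)) + 1L]])
  }
  unique(terms)
}

#' Generate a synthetic annotation fixture with known ground truth
#'
#' Writes all input files of the analysis pipeline into \code{dir}:
#' \code{genomes.tsv}, \code{genes.tsv}, \code{family_assignments.tsv},
#' \code{term_assignments.tsv} (manual assignments only),
#' \code{hits.tsv}, \code{metadata.tsv}, \code{pathways.dsl},
#' \code{rules.tsv}, and the fixture-only ground truth \code{truth.tsv}
#' (columns \code{kind} = \code{pathway_status} / \code{phenotype_verdict},
#' \code{genome_id}, \code{item_id}, \code{expected}).  See
#' \code{\link{fixtureConfig}} for what is planted.  Output is
#' deterministic: the same configuration and seed give byte-identical
#' files.
#'
#' @param config a \code{\link{fixtureConfig}}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
generateFixture <- function(config = fixtureConfig(), dir) {
  stopifnot(inherits(config, "fixtureConfig"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)

  defLines <- fixtureDefinitionLines()
  defPath <- file.path(dir, "pathways.dsl")
  writeLines(defLines, defPath)
  catalog <- readPathwayDefinitions(defPath)
  rules <- fixtureRules()
  writeTsv(rules, file.path(dir, "rules.tsv"))

  genomeIds <- sprintf("G_%03d", seq_len(config$nGenomes))
  coreCompleteness <- c("finished", "finished", "draft", "finished",
                        "draft", "finished", "draft", "finished")
  completeness <- c(coreCompleteness,
                    ifelse(stats::runif(config$nGenomes - 8L) <
                             config$fractionDraft, "draft", "finished"))
  genomesDf <- data.frame(
    genome_id = genomeIds,
    name = sprintf("Synthetica exemplaris str. %03d",
                   seq_len(config$nGenomes)),
    completeness = completeness, stringsAsFactors = FALSE)

  plan <- fixturePlan()
  propagatedPlan <- fixturePropagated()
  pathwayOf <- local({
    map <- character(0)
    for (p in names(catalog@pathways))
      map[pathwayTerms(catalog, p)] <- p
    map
  })

  geneCounter <- stats::setNames(rep(0L, config$nGenomes), genomeIds)
  geneRows <- list(); termRows <- list(); famRows <- list()
  hitRows <- list()
  newGene <- function(genomeId, product) {
    geneCounter[[genomeId]] <<- geneCounter[[genomeId]] + 1L
    gid <- sprintf("%s_g%03d", genomeId, geneCounter[[genomeId]])
    geneRows[[length(geneRows) + 1L]] <<- data.frame(
      gene_id = gid, genome_id = genomeId, product_name = product,
      length_aa = sample(100:800, 1L), stringsAsFactors = FALSE)
    gid
  }
  addTerm <- function(geneId, termId)
    termRows[[length(termRows) + 1L]] <<- data.frame(
      gene_id = geneId, term_id = termId, provenance = "manual",
      stringsAsFactors = FALSE)
  addFam <- function(geneId, ns, famId)
    famRows[[length(famRows) + 1L]] <<- data.frame(
      gene_id = geneId, namespace = ns, family_id = famId,
      stringsAsFactors = FALSE)
  addHitPair <- function(a, b, identity, qcov, scov, score) {
    hitRows[[length(hitRows) + 1L]] <<- data.frame(
      query_gene_id = c(a, b), subject_gene_id = c(b, a),
      percent_identity = identity, query_coverage = c(qcov, scov),
      subject_coverage = c(scov, qcov), score = score,
      stringsAsFactors = FALSE)
  }

  # --- materialise the plan: manual term genes, skipping terms that are
  #     scheduled for propagation or candidate-only evidence
  propagatedKey <- paste(propagatedPlan$genome_id, propagatedPlan$term_id)
  candidateCells <- plan[plan$plan == "candidate_only", , drop = FALSE]
  candidateTargets <- list()   # genome_id, term_id
  for (i in seq_len(nrow(plan))) {
    if (plan$plan[i] == "missing") next
    gIdx <- match(plan$genome_id[i], genomeIds)
    terms <- sort(chosenPathTerms(catalog, plan$pathway_id[i], gIdx))
    candTerm <- character(0)
    if (plan$plan[i] == "candidate_only") {
      candTerm <- terms[length(terms)]   # lexicographically last
      candidateTargets[[length(candidateTargets) + 1L]] <-
        data.frame(genome_id = plan$genome_id[i], term_id = candTerm,
                   stringsAsFactors = FALSE)
    }
    for (t in terms) {
      if (t %in% candTerm) next
      if (paste(plan$genome_id[i], t) %in% propagatedKey) next
      gid <- newGene(plan$genome_id[i], catalog@terms$name[
        match(t, catalog@terms$term_id)])
      addTerm(gid, t)
    }
  }
  candidateTargets <- if (length(candidateTargets))
    do.call(rbind, candidateTargets) else NULL

  completeGenomesFor <- function(pathwayId, exclude) {
    sel <- plan$genome_id[plan$pathway_id == pathwayId &
                          plan$plan == "complete"]
    setdiff(sel, exclude)
  }

  # --- propagation structures: recipient + 5 homologs (3 term-bearing)
  for (i in seq_len(nrow(propagatedPlan))) {
    gr <- propagatedPlan$genome_id[i]; t <- propagatedPlan$term_id[i]
    donorGenome <- completeGenomesFor(pathwayOf[[t]], gr)[1]
    recipient <- newGene(gr, "conserved protein, propagation target")
    ids <- sort(stats::runif(5, 55, 95), decreasing = TRUE)
    for (j in 1:5) {
      donor <- newGene(donorGenome, "term donor protein")
      if (j <= 3) addTerm(donor, t)
      addHitPair(recipient, donor, ids[j],
                 stats::runif(1, 0.75, 0.95), stats::runif(1, 0.75, 0.95),
                 round(ids[j] * 10 + stats::runif(1, 0, 5), 1))
    }
  }

  # --- candidate structures: recipient + 2 BBH donors in two genomes
  for (i in seq_len(NROW(candidateTargets))) {
    gr <- candidateTargets$genome_id[i]; t <- candidateTargets$term_id[i]
    donors <- completeGenomesFor(pathwayOf[[t]], gr)[1:2]
    recipient <- newGene(gr, "distant homolog, candidate target")
    for (dg in donors) {
      donor <- newGene(dg, "term donor protein")
      addTerm(donor, t)
      pid <- stats::runif(1, 30, 45)
      addHitPair(recipient, donor, pid,
                 stats::runif(1, 0.75, 0.95), stats::runif(1, 0.75, 0.95),
                 round(pid * 10, 1))
    }
  }

  # --- planted paralog groups (within-genome, shared KO term)
  paralogGroups <- list(
    list(genome = "G_001", ko = "K00004", n = 2L, identity = 80),
    list(genome = "G_004", ko = "K00007", n = 3L, identity = 75))
  for (grp in utils::head(paralogGroups, config$plantedParalogGroups)) {
    members <- vapply(seq_len(grp$n), function(j)
      newGene(grp$genome, "paralogous dehydrogenase"), character(1))
    for (m in members) addFam(m, "KO", grp$ko)
    for (a in seq_len(grp$n - 1L)) for (b in seq(a + 1L, grp$n))
      addHitPair(members[a], members[b],
                 grp$identity + stats::runif(1, -3, 3),
                 stats::runif(1, 0.85, 0.95), stats::runif(1, 0.85, 0.95),
                 round(stats::runif(1, 400, 500), 1))
  }

  # --- KO/family-combination structure (1 COG, 2 Pfams, 4 combinations)
  comboSets <- list(c("COG0371"),
                    c("COG0371", "pfam01761"),
                    c("COG0371", "pfam01762"),
                    c("COG0371", "pfam01761", "pfam01762"))
  for (cs in comboSets) {
    gid <- newGene("G_005", "glycerol dehydrogenase")
    addFam(gid, "KO", "K00005")
    for (f in cs)
      addFam(gid, if (startsWith(f, "COG")) "COG" else "Pfam", f)
  }
  # same combination as combo 2, but other KO / no KO
  gid <- newGene("G_005", "alcohol dehydrogenase, other family")
  addFam(gid, "KO", "K00100")
  addFam(gid, "COG", "COG0371"); addFam(gid, "Pfam", "pfam01761")
  gid <- newGene("G_005", "uncharacterised dehydrogenase")
  addFam(gid, "COG", "COG0371"); addFam(gid, "Pfam", "pfam01761")

  # --- filler genes up to the quota; a fraction get an inconsistent KO
  fillerIds <- character(0)
  for (g in genomeIds) {
    while (geneCounter[[g]] < config$genesPerGenome)
      fillerIds <- c(fillerIds, newGene(g, "hypothetical protein"))
  }
  nBad <- round(config$koInconsistencyRate * length(fillerIds))
  if (nBad > 0) {
    bad <- sort(sample(fillerIds, nBad))
    for (i in seq_along(bad)) {
      addFam(bad[i], "KO", "K11111")
      addFam(bad[i], "COG", c("COG9001", "COG9002")[(i %% 2L) + 1L])
    }
  }

  # --- decoy cross-genome hits, all at or below 25% identity
  if (length(fillerIds) >= 4) {
    genomeOfFiller <- sub("_g[0-9]+$", "", fillerIds)
    for (k in seq_len(min(10L, length(fillerIds) %/% 2L))) {
      pair <- sample(fillerIds, 2L)
      if (genomeOfFiller[match(pair[1], fillerIds)] ==
          genomeOfFiller[match(pair[2], fillerIds)]) next
      addHitPair(pair[1], pair[2], stats::runif(1, 10, 24),
                 stats::runif(1, 0.3, 0.6), stats::runif(1, 0.3, 0.6),
                 round(stats::runif(1, 30, 60), 1))
    }
  }

  # --- metadata
  md <- rbind(
    data.frame(genome_id = "G_001", attribute = "Oxygen Requirement",
               value = "aerobic", stringsAsFactors = FALSE),
    data.frame(genome_id = "G_001", attribute = "Temperature Range",
               value = "mesophile"),
    data.frame(genome_id = "G_002", attribute = "Oxygen Requirement",
               value = "anaerobic"),
    data.frame(genome_id = "G_002", attribute = "Temperature Range",
               value = "mesophile"),
    data.frame(genome_id = "G_003", attribute = "Temperature Range",
               value = "thermophile"),
    data.frame(genome_id = "G_004", attribute = "Oxygen Requirement",
               value = "anaerobic"),
    data.frame(genome_id = "G_005", attribute = "Habitat",
               value = "soil"),
    data.frame(genome_id = "G_008", attribute = "Oxygen Requirement",
               value = "Aerobe"),
    data.frame(genome_id = "G_008", attribute = "Temperature Range",
               value = "mesophile"))

  store <- AnnotationStore(
    genomes = genomesDf, genes = do.call(rbind, geneRows),
    familyAssignments = if (length(famRows)) do.call(rbind, famRows) else
      NULL,
    termAssignments = if (length(termRows)) do.call(rbind, termRows) else
      NULL,
    metadata = md)
  writeAnnotationStore(store, dir)
  writeHitTable(HitTable(do.call(rbind, hitRows)),
                file.path(dir, "hits.tsv"))

  # --- ground truth: statuses from the plan (+ overrides), verdicts by
  #     Kleene evaluation of the shipped rules over those statuses
  planStatus <- c(complete = "asserted", candidate_only = "unknown",
                  missing = "not_asserted")
  truthStatus <- expand.grid(genome_id = genomeIds,
                             item_id = names(catalog@pathways),
                             stringsAsFactors = FALSE)
  truthStatus$expected <- "not_asserted"
  for (i in seq_len(nrow(plan))) {
    sel <- truthStatus$genome_id == plan$genome_id[i] &
      truthStatus$item_id == plan$pathway_id[i]
    truthStatus$expected[sel] <- planStatus[[plan$plan[i]]]
  }
  ov <- catalog@overrides
  for (i in seq_len(nrow(ov))) {
    sel <- truthStatus$genome_id == ov$genome_id[i] &
      truthStatus$item_id == ov$pathway_id[i]
    truthStatus$expected[sel] <- ov$status[i]
  }
  truthVerdict <- list()
  asts <- lapply(rules$expression, parseRule)
  for (g in genomeIds) {
    sub <- truthStatus[truthStatus$genome_id == g, , drop = FALSE]
    tri <- stats::setNames(statusToTri(sub$expected), sub$item_id)
    for (i in seq_len(nrow(rules))) {
      val <- evaluateRule(asts[[i]], tri)
      truthVerdict[[length(truthVerdict) + 1L]] <- data.frame(
        genome_id = g, item_id = rules$rule_id[i],
        expected = c(true = "predicted", false = "not_predicted",
                     unknown = "unknown")[[as.character(val)]],
        stringsAsFactors = FALSE)
    }
  }
  truth <- rbind(
    cbind(kind = "pathway_status", truthStatus, stringsAsFactors = FALSE),
    cbind(kind = "phenotype_verdict", do.call(rbind, truthVerdict),
          stringsAsFactors = FALSE))
  writeTsv(sortDf(truth), file.path(dir, "truth.tsv"))
  invisible(dir)
}
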