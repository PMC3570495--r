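# minimal catalog: P_339-style three-step pathway with four alternative
# first-step reactions, plus a complex-requiring reaction (R_982)
p339Dsl <- function() {
  c(paste0('term T_', c(977:981), ' "t" kind=protein_product'),
    'term T_982A "t" kind=protein_complex',
    'term T_982B "t" kind=protein_complex',
    'reaction R_977 "r" requires (T_977)',
    'reaction R_978 "r" requires (T_978)',
    'reaction R_979 "r" requires (T_979)',
    'reaction R_980 "r" requires (T_980)',
    'reaction R_981 "r" requires (T_981)',
    'reaction R_982 "r" requires (T_982A & T_982B)',
    paste0('pathway P_339 "6-phosphogluconate synthesis via gluconate" ',
           'steps: [R_977|R_978|R_979|R_980] -> [R_981] -> [R_982]'))
}

readTestCatalog <- function(lines) {
  f <- withr::local_tempfile(fileext = ".dsl",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  readPathwayDefinitions(f)
}

# one-genome store with the given firm / candidate term assignments
termStore <- function(present, candidate = character(0)) {
  all <- c(present, candidate)
  if (!length(all))
    return(AnnotationStore(
      genomes = data.frame(genome_id = "G1", name = "g",
                           completeness = "finished")))
  AnnotationStore(
    genomes = data.frame(genome_id = "G1", name = "g",
                         completeness = "finished"),
    genes = data.frame(gene_id = paste0("g", seq_along(all)),
                       genome_id = "G1", product_name = "p",
                       length_aa = 300L),
    termAssignments = data.frame(
      gene_id = paste0("g", seq_along(all)), term_id = all,
      provenance = rep(c("manual", "candidate"),
                       c(length(present), length(candidate)))))
}

test_that("definition DSL parses the three-step pathway structure", {
  catalog <- readTestCatalog(p339Dsl())
  pw <- catalog@pathways[["P_339"]]
  expect_length(pw$steps, 3L)
  expect_identical(pw$steps[[1]], c("R_977", "R_978", "R_979", "R_980"))
  expect_identical(pw$steps[[2]], "R_981")
  expect_identical(catalog@reactions[["R_982"]]$requirements[[1]],
                   c("T_982A", "T_982B"))
})

test_that("dangling references and empty sets are parse errors", {
  expect_error(readTestCatalog(c(p339Dsl(),
                                 'pathway P_9 "x" steps: [R_999]')),
               "R_999")
  expect_error(readTestCatalog('reaction R_1 "r" requires ()'),
               "empty requirement")
  expect_error(readTestCatalog('reaction R_1 "r" requires (T_none)'),
               "T_none")
  expect_error(readTestCatalog("frobnicate X"), "unrecognised")
})

test_that("term status distinguishes firm, candidate-only and absent", {
  catalog <- readTestCatalog(p339Dsl())
  store <- termStore(present = "T_981", candidate = "T_977")
  expect_identical(termStatus(store, "G1", "T_981", catalog), "true")
  expect_identical(termStatus(store, "G1", "T_977", catalog), "unknown")
  expect_identical(termStatus(store, "G1", "T_978", catalog), "false")
  expect_error(termStatus(store, "G1", "T_nope", catalog), "unknown term")
})

test_that("reaction status: alternatives OR-combine, subunits AND-combine", {
  catalog <- readTestCatalog(c(
    'term T_a "t" kind=protein_product', 'term T_b "t" kind=protein_product',
    'term T_c "t" kind=protein_product',
    'reaction R_1 "r" requires (T_a & T_b) | (T_c)',
    'pathway P_1 "p" steps: [R_1]'))
  # both subunits of the complex present
  expect_identical(reactionStatus(termStore(c("T_a", "T_b")), "G1", "R_1",
                                  catalog), "true")
  # one full alternative present, the other absent
  expect_identical(reactionStatus(termStore("T_c"), "G1", "R_1", catalog),
                   "true")
  # single subunit present, partner candidate-only: AND(T, U) = U
  expect_identical(reactionStatus(termStore("T_a", candidate = "T_b"),
                                  "G1", "R_1", catalog), "unknown")
  # one subunit entirely missing and no alternative
  expect_identical(reactionStatus(termStore("T_a"), "G1", "R_1", catalog),
                   "false")
  expect_error(reactionStatus(termStore("T_a"), "G1", "R_9", catalog),
               "undefined reaction")
})

test_that("pathway assertion composes steps with AND over OR", {
  catalog <- readTestCatalog(p339Dsl())
  # one first-step alternative plus both later steps: asserted
  rec <- assertPathway(termStore(c("T_978", "T_981", "T_982A", "T_982B")),
                       "G1", "P_339", catalog)
  expect_identical(rec$status, "asserted")
  expect_identical(rec$source, "computed")
  expect_identical(rec$evidence[[2]]$satisfied, "T_981")
  # a required step with neither genes nor candidates: not asserted
  rec <- assertPathway(termStore(c("T_978", "T_982A", "T_982B")), "G1",
                       "P_339", catalog)
  expect_identical(rec$status, "not_asserted")
  expect_identical(rec$evidence[[2]]$missing, "T_981")
  # candidate-only evidence for the last step: unknown
  rec <- assertPathway(
    termStore(c("T_978", "T_981", "T_982A"), candidate = "T_982B"),
    "G1", "P_339", catalog)
  expect_identical(rec$status, "unknown")
  expect_identical(rec$evidence[[3]]$candidate, "T_982B")
})

test_that("the 64-combination census of the three-step pathway", {
  # over all presence/absence combinations of the six reactions, the
  # pathway is asserted iff some first-step alternative is present and
  # both later steps are: (2^4 - 1) * 1 * 1 = 15 of 64
  catalog <- readTestCatalog(p339Dsl())
  reactionTerms <- list(R_977 = "T_977", R_978 = "T_978", R_979 = "T_979",
                        R_980 = "T_980", R_981 = "T_981",
                        R_982 = c("T_982A", "T_982B"))
  nAsserted <- 0L
  for (mask in 0:63) {
    present <- unlist(reactionTerms[bitwAnd(mask, bitwShiftL(1L, 0:5)) >
                                      0L], use.names = FALSE)
    rec <- assertPathway(termStore(present), "G1", "P_339", catalog)
    if (rec$status == "asserted") nAsserted <- nAsserted + 1L
  }
  expect_identical(nAsserted, 15L)
})

test_that("pathway status agrees with the completion oracle", {
  # enumerate TRUE/FALSE completions of candidate-only terms; works
  # because the AND-of-ORs formula is monotone and each term status
  # enters once per occurrence
  catalog <- readTestCatalog(p339Dsl())
  allTerms <- catalog@terms$term_id
  oracle <- function(present, candidate) {
    evalOnce <- function(extra) {
      have <- union(present, extra)
      stepOk <- c(any(c("T_977", "T_978", "T_979", "T_980") %in% have),
                  "T_981" %in% have,
                  all(c("T_982A", "T_982B") %in% have))
      all(stepOk)
    }
    res <- vapply(0:(2^length(candidate) - 1L), function(mask)
      evalOnce(candidate[bitwAnd(mask, bitwShiftL(1L,
        seq_along(candidate) - 1L)) > 0L]), logical(1))
    if (all(res)) "asserted" else if (!any(res)) "not_asserted" else
      "unknown"
  }
  set.seed(21)
  for (i in 1:60) {
    present <- sample(allTerms, sample(0:4, 1))
    candidate <- sample(setdiff(allTerms, present), sample(0:3, 1))
    rec <- assertPathway(termStore(present, candidate), "G1", "P_339",
                         catalog)
    expect_identical(rec$status, oracle(present, candidate))
  }
})

test_that("adding an assignment never demotes a computed status", {
  catalog <- readTestCatalog(p339Dsl())
  rank <- c(not_asserted = 0L, unknown = 1L, asserted = 2L)
  allTerms <- catalog@terms$term_id
  set.seed(31)
  for (i in 1:40) {
    present <- sample(allTerms, sample(0:4, 1))
    candidate <- sample(setdiff(allTerms, present), sample(0:2, 1))
    before <- assertPathway(termStore(present, candidate), "G1", "P_339",
                            catalog)$status
    extra <- sample(setdiff(allTerms, present), 1)
    after <- assertPathway(termStore(c(present, extra),
                                     setdiff(candidate, extra)), "G1",
                           "P_339", catalog)$status
    expect_gte(rank[[after]], rank[[before]])
  }
})

test_that("manual overrides replace the computed status", {
  catalog <- readTestCatalog(c(p339Dsl(),
    "override genome=G1 pathway=P_339 status=absent"))
  # full gene complement, but the curator marked the pathway absent
  rec <- assertPathway(termStore(c("T_978", "T_981", "T_982A", "T_982B")),
                       "G1", "P_339", catalog)
  expect_identical(rec$status, "absent")
  expect_identical(rec$source, "manual")
  # overrides survive recomputation via the bulk interface
  tab <- assertPathways(termStore(c("T_978", "T_981", "T_982A", "T_982B")),
                        catalog)
  expect_identical(tab$status, "absent")
  expect_identical(tab$source, "manual")
})

test_that("genome x pathway profile carries statuses and gene counts", {
  catalog <- readTestCatalog(c(p339Dsl(),
    'term T_x "t" kind=protein_product',
    'reaction R_x "r" requires (T_x)',
    'pathway P_x "p" steps: [R_x]'))
  store <- AnnotationStore(
    genomes = data.frame(genome_id = c("G1", "G2"), name = "g",
                         completeness = "finished"),
    genes = data.frame(gene_id = paste0("g", 1:4),
                       genome_id = c("G1", "G1", "G1", "G2"),
                       product_name = "p", length_aa = 300L),
    termAssignments = data.frame(
      gene_id = paste0("g", 1:4),
      term_id = c("T_978", "T_981", "T_982A", "T_x"),
      provenance = "manual"))
  prof <- pathwayProfile(store, catalog, c("G1", "G2"),
                         c("P_339", "P_x"))
  expect_identical(dimnames(prof$status), list(c("G1", "G2"),
                                               c("P_339", "P_x")))
  expect_identical(prof$status["G1", "P_339"], "not_asserted")
  expect_identical(prof$geneCount["G1", "P_339"], 3L)
  expect_identical(prof$geneCount["G2", "P_339"], 0L)
  expect_identical(prof$status["G2", "P_x"], "asserted")
  expect_identical(prof$geneCount["G2", "P_x"], 1L)
})
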