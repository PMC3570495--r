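test_that("KO family summary reproduces the hand-built combination case", {
  # four genes under one KO spanning 1 COG and 2 Pfams in four distinct
  # per-gene sets, mirroring a glycerol-dehydrogenase-like KO
  fam <- rbind(
    data.frame(gene_id = "g1", namespace = c("KO", "COG"),
               family_id = c("K00005", "COG0371")),
    data.frame(gene_id = "g2", namespace = c("KO", "COG", "Pfam"),
               family_id = c("K00005", "COG0371", "pfam01761")),
    data.frame(gene_id = "g3", namespace = c("KO", "COG", "Pfam"),
               family_id = c("K00005", "COG0371", "pfam01762")),
    data.frame(gene_id = "g4", namespace = c("KO", "COG", "Pfam", "Pfam"),
               family_id = c("K00005", "COG0371", "pfam01761",
                             "pfam01762")))
  store <- AnnotationStore(
    genomes = data.frame(genome_id = "G1", name = "g",
                         completeness = "finished"),
    genes = data.frame(gene_id = paste0("g", 1:4), genome_id = "G1",
                       product_name = "p", length_aa = 300L),
    familyAssignments = fam)
  s <- koFamilySummary(store)
  expect_identical(s[s$ko_id == "K00005",
                     c("n_cogs", "n_pfams", "n_tigrfams",
                       "n_combinations")],
                   data.frame(n_cogs = 1L, n_pfams = 2L, n_tigrfams = 0L,
                              n_combinations = 4L),
                   ignore_attr = TRUE)
  # identically annotated genes collapse to one combination
  expect_identical(
    koFamilySummary(store)[1, "n_combinations"] >= 1L, TRUE)
  expect_identical(koFamilySummary(store, "K_absent")$n_combinations, 0L)
})

test_that("combination details classify genes into the four columns", {
  # g1 carries the query KO, g2 a different KO, g3 none -- all share one
  # combination
  fam <- rbind(
    data.frame(gene_id = c("g1", "g2", "g3"), namespace = "COG",
               family_id = "C1"),
    data.frame(gene_id = c("g1", "g2"), namespace = "KO",
               family_id = c("K1", "K2")))
  store <- AnnotationStore(
    genomes = data.frame(genome_id = "G1", name = "g",
                         completeness = "finished"),
    genes = data.frame(gene_id = paste0("g", 1:3), genome_id = "G1",
                       product_name = "p", length_aa = 300L),
    familyAssignments = fam)
  det <- koCombinationDetails(store, "K1")
  expect_identical(nrow(det), 1L)
  expect_identical(det$n_with_query_ko, 1L)
  expect_identical(det$n_with_other_ko_incl, 1L)
  expect_identical(det$n_with_other_ko_excl, 1L)
  expect_identical(det$n_without_ko, 1L)
  expect_error(koCombinationDetails(store, "K99"), "unknown KO")
  # a multi-KO gene carrying the query KO counts in the first two
  # columns but not the third
  fam2 <- rbind(fam, data.frame(gene_id = "g1", namespace = "KO",
                                family_id = "K2"))
  store2 <- AnnotationStore(genomes = genomes(store),
                            genes = genes(store),
                            familyAssignments = fam2)
  det2 <- koCombinationDetails(store2, "K1")
  expect_identical(det2$n_with_query_ko, 1L)
  expect_identical(det2$n_with_other_ko_incl, 2L)
  expect_identical(det2$n_with_other_ko_excl, 1L)
})

test_that("report counts match naive recounts on random stores", {
  set.seed(97)
  for (i in 1:8) {
    store <- randomStore()
    expect_identical(as.data.frame(koFamilySummary(store)[,
                       c("ko_id", "n_genes", "n_cogs", "n_pfams",
                         "n_tigrfams", "n_combinations")]),
                     naiveKoFamilySummary(store), ignore_attr = TRUE)
    kos <- unique(koFamilySummary(store)$ko_id)
    for (k in utils::head(kos, 2)) {
      got <- koCombinationDetails(store, k)
      want <- naiveKoCombinationDetails(store, k)
      expect_identical(got[, 4:7], want[, 2:5], ignore_attr = TRUE)
      # count conservation: first + third + fourth = carriers
      combos <- phenoassert:::familyCombinations(store)
      carriers <- vapply(want$combo, function(cmb) sum(combos == cmb),
                         integer(1))
      expect_identical(got$n_with_query_ko + got$n_with_other_ko_excl +
                         got$n_without_ko, unname(carriers))
    }
  }
})

test_that("MCL recovers disjoint cliques and splits weak bridges", {
  nodes <- c(letters[1:3], LETTERS[1:3])
  adj <- matrix(0, 6, 6, dimnames = list(nodes, nodes))
  for (p in combn(1:3, 2, simplify = FALSE)) {
    adj[p[1], p[2]] <- adj[p[2], p[1]] <- 10
    adj[p[1] + 3, p[2] + 3] <- adj[p[2] + 3, p[1] + 3] <- 10
  }
  expect_identical(mclCluster(adj),
                   list(c("A", "B", "C"), c("a", "b", "c")))
  # weighted path a-b-c-d (10, 1, 10) splits at the weak middle edge
  nodes <- letters[1:4]
  path <- matrix(0, 4, 4, dimnames = list(nodes, nodes))
  path["a", "b"] <- path["b", "a"] <- 10
  path["b", "c"] <- path["c", "b"] <- 1
  path["c", "d"] <- path["d", "c"] <- 10
  expect_identical(mclCluster(path), list(c("a", "b"), c("c", "d")))
  expect_identical(mclCluster(path), referenceMcl(path))
  # singleton inputs emit no paralog cluster
  expect_identical(mclCluster(matrix(0, 1, 1,
                                     dimnames = list("x", "x"))), list())
})

test_that("MCL output partitions nodes and ignores node order", {
  set.seed(41)
  for (i in 1:10) {
    n <- sample(5:12, 1)
    nodes <- paste0("n", sample(100, n))
    adj <- matrix(0, n, n, dimnames = list(nodes, nodes))
    for (j in seq_len(n - 1)) for (k in seq(j + 1, n)) {
      if (runif(1) < 0.35) {
        w <- runif(1, 1, 20)
        adj[j, k] <- adj[k, j] <- w
      }
    }
    cl <- mclCluster(adj, dropSingletons = FALSE)
    members <- unlist(cl)
    expect_identical(sort(members), sort(nodes))     # partition
    expect_identical(anyDuplicated(members), 0L)     # disjoint
    perm <- sample(n)
    cl2 <- mclCluster(adj[perm, perm], dropSingletons = FALSE)
    canon <- function(x) x[order(vapply(x, `[`, character(1), 1))]
    expect_identical(canon(lapply(cl2, sort)), canon(lapply(cl, sort)))
  }
})

test_that("paralog clusters are built per genome from filtered hits", {
  store <- AnnotationStore(
    genomes = data.frame(genome_id = c("G1", "G2"), name = "g",
                         completeness = "finished"),
    genes = data.frame(gene_id = c("a", "b", "c", "z"),
                       genome_id = c("G1", "G1", "G1", "G2"),
                       product_name = "p", length_aa = 300L))
  ht <- HitTable(data.frame(
    query_gene_id = c("a", "b", "a", "c"),
    subject_gene_id = c("b", "a", "z", "z"),
    percent_identity = c(80, 80, 85, 90),
    query_coverage = 0.9, subject_coverage = 0.9, score = 400))
  cl <- buildParalogClusters(store, ht)
  # only the intra-genome pair clusters; cross-genome hits are ignored
  expect_identical(cl$gene_id, c("a", "b"))
  expect_identical(unique(cl$genome_id), "G1")
  # low-identity intra-genome hits are filtered out
  ht2 <- HitTable(data.frame(
    query_gene_id = "a", subject_gene_id = "b", percent_identity = 20,
    query_coverage = 0.9, subject_coverage = 0.9, score = 400))
  expect_identical(nrow(buildParalogClusters(store, ht2)), 0L)
})

test_that("KO paralog summary computes per-genome and pair statistics", {
  # 4 genes with one KO across 2 genomes; the two genes in G1 are
  # clustered paralogs at 80% identity
  store <- AnnotationStore(
    genomes = data.frame(genome_id = c("G1", "G2"), name = "g",
                         completeness = "finished"),
    genes = data.frame(gene_id = c("a", "b", "c", "d"),
                       genome_id = c("G1", "G1", "G2", "G2"),
                       product_name = "p", length_aa = 300L),
    familyAssignments = data.frame(gene_id = c("a", "b", "c", "d"),
                                   namespace = "KO",
                                   family_id = "K00004"))
  ht <- HitTable(data.frame(
    query_gene_id = c("a", "b"), subject_gene_id = c("b", "a"),
    percent_identity = 80, query_coverage = 0.9, subject_coverage = 0.9,
    score = 400))
  cl <- buildParalogClusters(store, ht)
  s <- koGenomeParalogSummary(store, cl, ht)
  expect_identical(s$n_genes, 4L)
  expect_identical(s$n_genomes, 2L)
  expect_equal(s$avg_genes_per_genome, 2.0)
  expect_identical(s$n_genes_in_paralog_clusters, 2L)
  expect_identical(s$n_genes_with_same_ko_paralog, 2L)
  expect_equal(s$avg_identity_same_ko_paralogs, 80)
  # all-singleton KO reports empty paralog columns
  s2 <- koGenomeParalogSummary(store,
                               cl[0, , drop = FALSE], ht)
  expect_identical(s2$n_genes_with_same_ko_paralog, 0L)
  expect_true(is.na(s2$avg_identity_same_ko_paralogs))
})
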