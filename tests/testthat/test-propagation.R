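test_that("propagation follows the similarity SOP", {
  # 6 qualifying homologs at 60% identity, 3 of the top 5 carry T1
  store <- sweepStore(nDonors = 6, nCarriers = 3)
  out <- propagateTerms(store, sweepHits(6, identity = 60))
  expect_identical(out,
                   data.frame(gene_id = "q", term_id = "T1",
                              provenance = "propagated",
                              stringsAsFactors = FALSE))
  # 4 qualifying homologs: below the homolog minimum
  out <- propagateTerms(sweepStore(4, 2), sweepHits(4, 60))
  expect_identical(nrow(out), 0L)
  # 5 homologs but single supporter
  out <- propagateTerms(sweepStore(5, 1), sweepHits(5, 60))
  expect_identical(nrow(out), 0L)
})

test_that("thresholds are strict: boundary equality never fires", {
  # exactly 50% identity fails the > 50 criterion
  expect_identical(nrow(propagateTerms(sweepStore(5, 2),
                                       sweepHits(5, 50))), 0L)
  expect_identical(nrow(propagateTerms(sweepStore(5, 2),
                                       sweepHits(5, 50.1))), 1L)
  # exactly 0.70 coverage fails the > 0.70 criterion
  expect_identical(nrow(propagateTerms(sweepStore(5, 2),
                                       sweepHits(5, 60, coverage = 0.70))),
                   0L)
  # one fewer than the required homolog count never fires
  p <- propagationParams()
  expect_identical(nrow(propagateTerms(
    sweepStore(p$minHomologs - 1L, 2),
    sweepHits(p$minHomologs - 1L, 60))), 0L)
})

test_that("support is counted among the top-ranked homologs only", {
  # 7 qualifying homologs; the two T1 carriers rank 6th and 7th by
  # identity, so they fall outside the top-5 vote
  store <- AnnotationStore(
    genomes = data.frame(genome_id = c("GQ", "GD"), name = "x",
                         completeness = "finished"),
    genes = data.frame(gene_id = c("q", paste0("d", 1:7)),
                       genome_id = c("GQ", rep("GD", 7)),
                       product_name = "p", length_aa = 300L),
    termAssignments = data.frame(gene_id = c("d6", "d7"), term_id = "T1",
                                 provenance = "manual"))
  ht <- HitTable(data.frame(
    query_gene_id = "q", subject_gene_id = paste0("d", 1:7),
    percent_identity = c(90, 88, 86, 84, 82, 60, 58),
    query_coverage = 0.8, subject_coverage = 0.8, score = 100))
  expect_identical(nrow(propagateTerms(store, ht)), 0L)
})

test_that("propagation is idempotent and order-invariant", {
  store <- sweepStore(6, 3)
  ht <- sweepHits(6, 60)
  out1 <- propagateTerms(store, ht)
  expect_identical(propagateTerms(store, ht), out1)
  perm <- hits(ht)[sample(nrow(hits(ht))), ]
  expect_identical(propagateTerms(store, HitTable(perm)), out1)
})

test_that("iterated propagation reaches a fixpoint through chains", {
  # q2 only becomes assignable after q1 has received T1
  store <- AnnotationStore(
    genomes = data.frame(genome_id = c("G1", "G2", "G3"), name = "x",
                         completeness = "finished"),
    genes = data.frame(
      gene_id = c("q1", "q2", paste0("d", 1:5), paste0("e", 1:4)),
      genome_id = c("G1", "G2", rep("G3", 9)),
      product_name = "p", length_aa = 300L),
    termAssignments = data.frame(gene_id = c("d1", "d2"), term_id = "T1",
                                 provenance = "manual"))
  ht <- HitTable(data.frame(
    query_gene_id = c(rep("q1", 5), rep("q2", 5)),
    subject_gene_id = c(paste0("d", 1:5), paste0("e", 1:4), "q1"),
    percent_identity = 60, query_coverage = 0.8, subject_coverage = 0.8,
    score = 100))
  one <- propagateTerms(store, ht)
  expect_identical(one$gene_id, "q1")
  # q2 has 5 homologs but only one (q1, after round 1) carries T1 --
  # support stays below 2, so the fixpoint adds nothing more for q2
  iter <- propagateTerms(store, ht, iterate = TRUE)
  expect_identical(iter$gene_id, "q1")
})

test_that("BBH pairs require mutual best hits across genomes", {
  genomeOf <- c(a = "G1", b = "G2", c = "G1", d = "G1")
  # symmetric two-gene case
  ht <- HitTable(data.frame(
    query_gene_id = c("a", "b"), subject_gene_id = c("b", "a"),
    percent_identity = 80, query_coverage = 0.9, subject_coverage = 0.9,
    score = 100))
  expect_identical(computeBBH(ht, genomeOf),
                   data.frame(gene1 = "a", gene2 = "b",
                              stringsAsFactors = FALSE))
  # a's best in G2 is b, but b's best in G1 is c: no (a, b) pair
  ht <- HitTable(data.frame(
    query_gene_id = c("a", "b", "b"), subject_gene_id = c("b", "a", "c"),
    percent_identity = 80, query_coverage = 0.9, subject_coverage = 0.9,
    score = c(100, 90, 95)))
  expect_identical(nrow(computeBBH(ht, genomeOf)), 0L)
  # same-genome genes never pair
  ht <- HitTable(data.frame(
    query_gene_id = c("a", "c"), subject_gene_id = c("c", "a"),
    percent_identity = 90, query_coverage = 0.9, subject_coverage = 0.9,
    score = 100))
  expect_identical(nrow(computeBBH(ht, genomeOf)), 0L)
})

test_that("candidate detection follows the BBH evidence rule", {
  # two term-bearing BBH partners at 30% and 20%: 30 > 25 qualifies
  fx <- candidateSweepFixture(2, identity = c(30, 20, 30, 20))
  out <- detectCandidates(fx$store, fx$hits)
  expect_identical(out$gene_id, "q")
  expect_identical(out$term_id, "T1")
  expect_identical(out$provenance, "candidate")
  # bearers at 24% and 20%: nobody exceeds the 25% floor
  fx <- candidateSweepFixture(2, identity = c(24, 20, 24, 20))
  expect_identical(nrow(detectCandidates(fx$store, fx$hits)), 0L)
  # a gene already assigned the term is not re-emitted as candidate
  fx <- candidateSweepFixture(2, identity = c(30, 28, 30, 28))
  st <- addTermAssignments(fx$store, data.frame(
    gene_id = "q", term_id = "T1", provenance = "manual"))
  expect_identical(nrow(detectCandidates(st, fx$hits)), 0L)
  # coverage at exactly 0.70 fails the strict threshold
  fx <- candidateSweepFixture(2, identity = 30, coverage = 0.70)
  expect_identical(nrow(detectCandidates(fx$store, fx$hits)), 0L)
})

test_that("candidate and firm assignments stay disjoint after commit", {
  fx <- candidateSweepFixture(2, identity = c(30, 28, 30, 28))
  cand <- detectCandidates(fx$store, fx$hits)
  st <- addTermAssignments(fx$store, cand)
  expect_true(validObject(st))
  # committing a manual assignment for the same pair drops the candidate
  st2 <- addTermAssignments(st, data.frame(gene_id = "q", term_id = "T1",
                                           provenance = "manual"))
  ta <- termAssignments(st2)
  expect_identical(ta$provenance[ta$gene_id == "q" & ta$term_id == "T1"],
                   "manual")
})
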