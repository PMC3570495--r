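# phenoassert

Annotation consistency auditing and rule-based phenotype inference for
microbial genomes.

## The problem

Microbial genome annotations are stitched together from several partially
redundant classification systems — COG, Pfam, TIGRfam, KEGG Orthology (KO)
and FIGfam — that frequently disagree, and pathway presence calls built
naively on top of them inherit those disagreements. `phenoassert` is a
workbench for scientists who curate such annotations. It provides:

* **Term propagation.** A gene with no functional-term assignment receives
  one automatically when it has at least 5 homologs at > 50 % identity,
  aligned over > 70 % of both protein lengths, and at least 2 of the top 5
  such homologs already carry the term. The strict thresholds are chosen
  to keep false positives (over-annotation) rare.
* **Candidate genes.** Weaker evidence — at least 2 of a gene's top 5
  bidirectional best hits (BBH) carrying a term, overlap > 70 %, best
  bearer > 25 % identity — marks a gene as a *candidate* rather than
  assigning the term.
* **Three-valued pathway assertion.** A pathway is an ordered sequence of
  steps, each an OR of alternative reactions; a reaction is an OR of
  AND-sets of terms (alternative transformations vs. complex subunits).
  Evaluated under strong-Kleene logic over term statuses (present /
  candidate-only / absent), a pathway is **asserted**, **unknown** (its
  gaps have candidate genes) or **not asserted**. Curators can override a
  status to *asserted* or *absent*.
* **Phenotype rules.** Boolean AND/OR/NOT expressions over pathway
  statuses predict organism traits (e.g. *L-histidine prototroph* =
  pathway P_162 asserted, auxotroph = NOT P_162), again under Kleene
  semantics, so incomplete genomes yield *unknown* rather than a false
  call. Predictions carry a metadata category/value pair
  (e.g. Oxygen Requirement = aerobic) and are compared against recorded
  organism metadata as agree / conflict / no-metadata.
* **Consistency reports.** Per-KO distributions over (COG, Pfam, TIGRfam)
  combinations, and per-KO paralog statistics using within-genome clusters
  computed with an in-package Markov Cluster Algorithm (MCL).
* **A deterministic fixture generator** that plants all of the above with
  known ground truth, so every stage is testable end to end.

For two pathway statuses *p₁*, *p₂* the connectives are the strong-Kleene
tables: ¬T = F, ¬F = T, ¬U = U; *p₁* ∨ *p₂* = T if either is T, F iff both
are F, else U; *p₁* ∧ *p₂* dually with F absorbing.

## Worked example

```r
library(phenoassert)

dir <- tempfile("fixture")
generateFixture(fixtureConfig(seed = 1), dir)
res <- runPipeline(dir)

head(res$assertions[res$assertions$genome_id == "G_002", c(1:4, 6)], 3)
#>    genome_id pathway_id       status   source candidate_terms
#> 21     G_002      P_339      unknown computed          T_982B
#> 22     G_002      P_162 not_asserted computed
#> 23     G_002      P_146 not_asserted computed
```

Genome G_002 lacks a gluconate-kinase subunit gene (T_982B), but a
candidate gene for it was detected via BBH evidence, so the
6-phosphogluconate pathway P_339 is *unknown* rather than *not asserted*;
the histidine pathway has neither genes nor candidates.

```r
subset(res$predictions,
       genome_id == "G_002" &
       rule_id %in% c("his_auxotroph", "cellulose_cellobiose"))
#>    genome_id              rule_id   verdict  evidence
#> 9      G_002        his_auxotroph predicted  P_162=not_asserted
#> 13     G_002 cellulose_cellobiose predicted  P_CDEG=asserted;P_ABCUP=asserted;...
```

G_002 is predicted a histidine auxotroph (NOT P_162 evaluates true) and
grows on cellulose through the ABC-uptake / phosphorylase branch of the
four-branch rule.

```r
subset(res$agreement, agreement != "no_metadata")
#>    genome_id rule_id           category category_value metadata_value agreement
#> 5      G_001  aerobe Oxygen Requirement        aerobic        aerobic     agree
#> 9      G_002  aerobe Oxygen Requirement        aerobic      anaerobic  conflict
#> 25     G_008  aerobe Oxygen Requirement        aerobic         Aerobe     agree
```

Predicted aerobes are checked against recorded metadata; "Aerobe" matches
"aerobic" through the built-in synonym map, and the G_002 conflict flags
either a wrong annotation or wrong metadata for a curator to resolve.

```r
res$koFamilySummary[res$koFamilySummary$ko_id == "K00005", ]
#>    ko_id n_genes n_cogs n_pfams n_tigrfams n_combinations
#> 2 K00005       4      1       2          0              4
```

KO term K00005 maps to a single COG and two Pfams but in four distinct
per-gene combinations — the signature of a family worth inspecting.

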