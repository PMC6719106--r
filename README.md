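# lncTempo

Temporal analysis of long non-coding RNAs (lncRNAs) across a staged
bulk RNA-seq design — identification, positional classification,
conservation contrasts, stage-wise differential expression, signed
weighted co-expression modules with temporal classes, lncRNA–mRNA target
networks with hub extraction, and hypergeometric enrichment.  The package
targets developmental surveys of the 7-stage × 3-replicate kind (fetal
days F45–F135 plus post-natal B1, B90, as in skeletal-muscle development
studies) and is aimed at transcriptomics analysts who have assembled
transcripts, FPKM matrices and upstream tool outputs in hand and want the
downstream chain as tested, reusable functions.

## The model at the core

Candidates are lncRNAs when longer than 200 nt, multi-exonic, and
non-coding by the consensus of three predictors (CPC, CNCI, Pfam —
consumed as verdicts).  On the differentially expressed set (Welch's t on
log2(FPKM+1), p < 0.05 over all stage pairs), a **signed** weighted
network is built:

    a_ij = ((1 + cor(x_i, x_j)) / 2)^beta

and transformed to the topological overlap matrix

    TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij),
    l_ij   = sum_u a_iu a_uj,   k_i = sum_u a_iu

whose dissimilarity 1 − TOM is clustered by average linkage; a static
branch cut (0.995 of the top merge height, minimum module size 20) yields
modules, summarised by eigengenes (first singular vector of the
standardised module submatrix).  Module–stage association is the Pearson
correlation r between an eigengene and a one-hot stage indicator over all
n = 21 samples with the Student-t p-value at n − 2 df
(t = r·√((n−2)/(1−r²))); modules are called early / late / stage-specific
from the pattern of significant stages (r > 0.6, p < 0.05).  Targets are
predicted in cis (gene span within 100 kb of the lncRNA locus, inclusive)
and by co-expression (|r| > 0.95, exclusive); the bipartite network is
restricted to lncRNAs with |FC| > 2 and p < 0.05, and hub lncRNAs have
degree > 10.  Enrichment is an upper-tail hypergeometric test with BH
correction.

A synthetic-data generator (`simulateBundle()`) plants known temporal
modules, positional classes, coding contaminants, homology hits and
enriched terms, so the whole chain is testable end to end; see the
methods vignette (`vignettes/lncTempo-methods.Rmd`) for the model and
every design decision.

## Worked example

```r
library(lncTempo)

design <- simulationDesign(nMrna = 600, nLncrna = 200,
    plantedModules = list(
      plantedModule("earlyA", "early", c("F45", "F65"), size = 30),
      plantedModule("lateA", "late", c("B1", "B90"), size = 30),
      plantedModule("peakF90", "stage_specific", "F90", size = 25)),
    seed = 42)
run <- runPipeline(design)
pipelineReport(run, topN = 3)
```

```
== lncTempo pipeline report ==
seed: 42
steps: identify, conserve, de, modules, targets, enrich

lncRNA candidates retained: 180 (dropped: short=0, few_exons=0, coding=20)
  antisense_lncRNA     48  (26.7%)
  intronic_lncRNA      36  (20.0%)
  lincRNA              96  (53.3%)

matched to cow      48 (26.67%) loose, 14 strict
matched to human    78 (43.33%) loose, 53 strict
matched to mouse    46 (25.56%) loose, 15 strict

DE lncRNAs: 129, DE mRNA genes: 278
detected in all stages: 180 (100%)

modules (beta = 12):
  turquoise      44 features, class early
  blue           43 features, class late
  brown          35 features, class stage_specific
  adjusted Rand index vs planted: 1.000

target network: 2353 edges, 85 hub lncRNAs
       lncrna degree
1  LNC_000060     40
2  LNC_000031     39
...

top terms, module turquoise:
       term_id  k  K      p_value      q_value
26 TERM_earlyA 30 30 2.125685e-42 5.951919e-41
...
```

Reading it: of 200 simulated candidates, the 20 planted coding
contaminants are dropped; the positional mix matches the planted
50/30/20 linc/antisense/intronic proportions; the three recovered
modules carry the planted temporal classes with a planted-label adjusted
Rand index of 1.0; each module's planted term tops its enrichment table
(k = K study hits); and hub lncRNAs are exactly the densely connected
planted members.

Real data enter through the same readers the generator writes for:
`readGtf()`, `readExpressionTsv()`, `readCodingVerdicts()`,
`readHomologyHits()`, `readConservationScores()`, `readTerm2Genes()` —
then the same per-stage functions apply.  A thin command-line wrapper
lives at `inst/scripts/lnctempo.R`.

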