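# foldspec

Fold-change-specific functional and motif enrichment analysis for
directional differential-expression lists.

## The problem

Classical over-representation analysis asks whether a functional gene group
(a GO term) is enriched among differentially expressed genes. It ignores a
second, quantitative dimension: genes of the same functional group often
respond to a stimulus with *similar amplitude*, and different groups respond
in different amplitude windows. `foldspec` detects this
**fold-change-specific** regulation and the promoter hexamers associated
with it. It was designed with plant hormone-response transcriptomes in mind
(up- and down-regulated lists of several hundred genes with linear fold
changes spanning roughly 1.5–150×), but it runs on any directional DEG table
plus a gene→term annotation, and optionally a genome FASTA + GFF3 for
promoter analysis.

## The method

Up- and down-regulated genes (UGs, DGs) are analysed separately. Each list
is ranked by linear fold-change magnitude and split into *q* equal-size
quantiles (default *q* = 6, labelled `vw, w, m, i, s, vs` — very weak to
very strong). Quantile *k* spans ranks (⌈(k−1)n/q⌉, ⌈kn/q⌉]. A
**fold-change interval** is any contiguous run of quantiles; for *q* = 6
there are 21 intervals including the full list and 20 *component* intervals
excluding it.

Enrichment is tested in two steps, each with a one-sided Fisher exact test
(exact hypergeometric upper tail, `P(X ≥ a)`) and Bonferroni family-wise
control:

1. **Interval enrichment.** For every term *t* and interval *I*, the 2×2
   table {genes in *I* vs rest of the background universe} × {in *t* vs
   not}. P-values are multiplied by (terms tested × intervals); terms with
   adjusted *p* < 0.001 anywhere become candidates.
2. **Fold-change specificity.** Each candidate is re-tested per component
   interval against the directional list itself:

   |                    | in interval | outside | total |
   |--------------------|------------:|--------:|------:|
   | DEGs in the term   |       a     |    b    |  a+b  |
   | the rest of the DEGs |     c     |    d    |  c+d  |

   with Bonferroni multiplier (candidates × 20). A term is
   **fold-change-specific** when its minimal adjusted *p* < 0.05; it is
   assigned to the best interval (minimal adjusted *p*; ties go to the
   shorter, then weaker interval). The full interval is excluded here —
   every term gene lies inside it, so its one-sided *p* is identically 1.

The same two-step design applies to promoter motifs: the 4096 hexamers
collapse into 2080 canonical reverse-complement classes (64 palindromic),
each promoter ([−1500 bp; end of 5′UTR], strand-aware) is scanned for
presence, step 1 tests each hexamer × interval against the whole-genome
promoter set, and step 2 tests survivors against the directional DEG
promoters.

A synthetic-data module generates DEG tables, annotations and promoters
with *planted* fold-change-specific structure and full ground truth, so
type-I error and parameter recovery are measurable end to end.

## Worked example

Plant a 60-gene term concentrated (π = 0.85) in the weakest two quantiles
of 300 up-regulated genes, among 20 random background terms, and recover
it:

```r
library(foldspec)
cfg <- synthetic_config(
  n_up = 300, n_down = 200, seed = 7,
  planted_terms = list(list(term_id = "PLT:0001", size = 60,
                            direction = "up", interval = c(1, 2),
                            concentration = 0.85)),
  n_background_terms = 20)
sim <- gen_deg_table(cfg)
ann <- gen_annotation(cfg, sim$deg, genome_size = 2000)
fit <- fcs_go(sim$deg, ann$annotation, background = ann$universe)
fit
#> Fold-change-specific gene-set enrichment (q = 6, background = 2000 genes)
#>     up: n = 300; 1 term(s) enriched in >= 1 interval (adj p < 0.001); 1 fold-change-specific (adj p < 0.05)
#>   down: n = 200; 0 term(s) enriched in >= 1 interval (adj p < 0.001); 0 fold-change-specific (adj p < 0.05)
summary(fit, specific_only = TRUE)
#>    term_id direction n_genes    min_adj_p fold_change_specific best_lo best_hi
#> 1 PLT:0001        up      60 2.689735e-19                 TRUE       1       2
#>   best_interval name namespace
#> 1          vw-w <NA>      <NA>
```

Reading: of the 21 terms only the planted one survives both steps; its 60
member genes concentrate in the `vw-w` interval (quantiles 1–2), exactly
where they were planted, with a step-2 Bonferroni-adjusted *p* of 2.7e-19.
None of the 20 uniform background terms is flagged.

File-based runs (`run_go_pipeline()`, `run_motif_pipeline()`,
`run_simulate()`, `run_benchmark()`) write TSV results, a serialized config
and a log recording every Bonferroni multiplier. A thin command-line
wrapper is installed at `inst/scripts/foldspec.R`:

```sh
Rscript inst/scripts/foldspec.R go --deg deg.tsv --annotation ann.tsv --out run/
Rscript inst/scripts/foldspec.R motif --deg deg.tsv --genome g.fa --gff g.gff3 --out run/
```

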