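# lncTFnet

Inference of cis-acting lncRNA → transcription-factor → target-gene
regulatory networks from small-cohort bulk RNA-seq.

## The problem

Long noncoding RNAs (lncRNAs) can regulate nearby genes in *cis*. When the
nearby gene encodes a transcription factor (TF), a differentially
expressed lncRNA can propagate its effect to a whole downstream program.
`lncTFnet` implements, as a tested and reusable pipeline, the genome-wide
screen that turns a gene-level fragment count matrix from a two-group
cohort (e.g. disease vs control kidney biopsies) into a tripartite
lncRNA–TF–target network:

1. **Quantification** — FPKM per gene,
   `fpkm = counts · 10⁹ / (exonic length · mapped fragments)`; a gene is
   *detected* if FPKM > 0 in at least one sample.
2. **Differential expression** — a simplified negative-binomial Wald test
   (median-of-ratios size factors, method-of-moments dispersion,
   delta-method variance on log₂FC, t reference with n₁+n₂−2 df,
   Benjamini–Hochberg FDR). A gene is called if FC ≥ 2 or ≤ 0.5 with
   FDR < 0.05. An externally produced DE table can be substituted.
3. **Candidate lncRNAs** — the Venn intersection of four coding-potential
   predictors (CPC2/LGC/CNCI/CPAT-style call tables are consumed as
   input), minus transcripts < 200 nt, transcripts overlapping a
   protein-coding gene on the same strand, and transcripts < 1,000 bp
   from the nearest gene.
4. **Cis targets** — the intersection of *co-location* (target span
   within 100 kb up- or downstream of the lncRNA span) and
   *co-expression* (Pearson |r| > 0.6, p ≤ 0.01 on log₂(FPKM+1) across
   all samples), then restricted to a TF catalogue (e.g. the HumanTFDB
   list).
5. **TF–DEG tier** — cis-TFs paired with DE genes at |r| ≥ 0.8,
   p ≤ 0.01, intersected with curated TF–target databases
   (TRRUST-style tables), and joined through the shared TF into
   regulatory triples.
6. **Enrichment** — hypergeometric over-representation of term sets (GMT)
   in any gene selection, with BH FDR.

Because cohorts of this kind are small (the motivating design is 5 cases
vs 4 controls), every stage is validated by *recovery*: a synthetic-data
generator (`sim_config()`, `simulate_experiment()`) plants a known
network — co-located lncRNA–TF pairs, latent-factor-induced
co-expression calibrated to a target Pearson r, negative-binomial counts
with planted fold changes — and the pipeline's precision and recall
against the planted truth are the test statistics.

## Worked example

```r
library(lncTFnet)

cfg <- preset_config("recovery", seed = 42)   # 20 vs 20 samples
sim <- simulate_experiment(cfg)               # all six pipeline inputs
res <- run_pipeline(sim$ann, sim$counts, sim$tool_calls,
                    sim$tf_catalogue, sim$db_pairs)
res
#> PipelineResult:
#>   DE genes: 58 ( 35 up / 23 down )
#>   retained lncRNA genes: 20 | DE lncRNAs: 8 | DE mRNAs: 50
#>   cis edges: 3 -> cis-TF edges: 3 | TF-DEG edges: 9 | triples: 9

head(res$network$triples[, c("lncrna", "tf", "target",
                             "r_lnc_tf", "r_tf_target")])
#>   lncrna   tf  target  r_lnc_tf r_tf_target
#> 1 LNCP01 TF15 GENE045 0.8862080   0.9315143
#> 2 LNCP01 TF15 GENE049 0.8862080   0.9048657
#> 3 LNCP01 TF15 GENE154 0.8862080   0.8920966
#> 4 LNCP02 TF14 GENE008 0.9532556   0.8799792
#> 5 LNCP02 TF14 GENE071 0.9532556   0.9357796
#> 6 LNCP02 TF14 GENE082 0.9532556   0.9295265

evaluate_recovery(res, sim$truth)[c("recall", "precision")]
#> $recall
#> [1] 1
#> $precision
#> [1] 1
```

The 58 DE calls are the genes passing FC ≥ 2 (or ≤ 0.5) at FDR < 0.05;
three lncRNAs pass the candidate screen, sit within 100 kb of a TF gene
and survive the cis co-expression filter; each cis-TF carries three
database-supported TF–DEG edges, giving the 9 recovered triples — here
exactly the 9 planted ones. `write_network()` exports the triple table
as TSV and the typed graph as GraphML.

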