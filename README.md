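# epidrugsig

Epigenetic drugs — DNMT inhibitors (guadecitabine, decitabine), HDAC
inhibitors (givinostat), BET inhibitors (JQ1, OTX-015) and EZH2 inhibitors
(GSK126) — reshape the immune-related transcriptome of tumor cells, and
that reshaping can decide whether immune checkpoint blockade works.
`epidrugsig` implements the full comparative analysis that takes such a
study from raw panel counts to clinically interpretable signatures:

1. **Modulation calls** — treated/control expression ratios per gene, cell
   line and drug on housekeeping-normalized panel counts, called *up* when
   the ratio `r > τ` and *down* when `r < 1/τ` (default `τ = 1.5`).
2. **Class metrics** — per functional gene class, the fraction of genes
   modulated, `(n_up + n_down) / n_genes`, and the direction index,
   `d = (n_up − n_down) / (n_up + n_down) ∈ [−1, 1]`.
3. **Drug signatures** — genes modulated in a consistent direction in at
   least a minimum fraction of evaluable cell lines (default 0.5), plus
   Venn-region partitions across drugs and overlap scoring against
   external gene lists.
4. **Upstream regulators (URs)** — on a signed regulator→target causal
   network, each regulator gets a hypergeometric overlap p-value and an
   activation z-score, `z = (N_consistent − N_inconsistent) / √N` over its
   differentially expressed targets; *activated* requires `z > 2` and
   `p < 0.05`, *inhibited* the mirror. UR calls aggregate across cell
   lines (≥ 6/10 lines), compare between drugs by scatter quadrant, and
   discriminate responders from non-responders along a w0/w4/w12 biopsy
   timecourse.
5. **Pre-ranked GSEA** — weighted Kolmogorov–Smirnov running enrichment
   score of a signature in a log2-fold-change ranking, with a
   gene-permutation p-value and NES.
6. **Prognostic screen** — univariate Cox proportional-hazards model per
   gene (standardized expression, Efron ties) and the fraction of a
   signature that is significant with reduced risk (`z < 0`, `p < 0.05`).

Every input the pipeline consumes can be generated synthetically with
planted ground truth — responsive gene classes, active regulators,
responder-specific induction, protective genes — so each stage is
verifiable end-to-end by parameter recovery.

## Worked example

```r
library(epidrugsig)

cfg  <- sim_config(seed = 1)                    # 731 genes / 21 classes,
sim  <- simulate_counts(cfg)                    # 10 cell lines, 4 drugs
hk   <- sim$annotation$gene[sim$annotation$is_housekeeping]
norm <- normalize_counts(sim$counts, hk)
mods <- compute_modulation(norm, sim$samples, tau = 1.5)

cm  <- class_metrics(mods, sim$annotation)
gua <- cm[cm$drug == "guadecitabine", ]
head(aggregate(cbind(frac_modulated, direction_index) ~ class, gua, mean))
```

The two planted responsive classes dominate, with the planted (upward)
direction:

```
   class frac_modulated direction_index
1    C01          0.629           0.900
2    C02          0.609           1.000
19   C19          0.065          -0.083
18   C18          0.053           0.400
```

`frac_modulated ≈ 0.6` says ~60 % of the genes in classes C01/C02 crossed
the 1.5-fold threshold in the average cell line; `direction_index ≈ 1`
says essentially all of them moved up. The other classes sit at the
noise floor. Deriving the drug signature and the aggregated UR signature:

```r
sig <- derive_signature(mods, "guadecitabine", min_support = 0.5,
                        annotation = sim$annotation)
sig
#> Drug signature: guadecitabine (54 genes, min_support = 0.5)
#>   up: 54  down: 0

net <- simulate_causal_network(cfg, sim$truth)
res <- lapply(cfg$cell_lines, function(cl) {
  de <- mods[mods$drug == "guadecitabine" & mods$cell_line == cl &
               mods$call != "none", ]
  score_regulators(net, data.frame(gene = de$gene,
                                   direction = ifelse(de$call == "up", 1L, -1L)),
                   universe = rownames(sim$counts))
})
aggregate_ur_signature(res, min_lines = 6)
#>   regulator direction n_supporting n_evaluable
#> 1     UR001 activated            8          10
#> ...
#> 8     UR008 activated            8          10
```

The 54 signature genes are a subset of the 56 planted responsive genes
(sensitivity 0.96, precision 1.00 at this seed), and all 8 planted
regulators — and no decoys — are called activated in 8 of 10 cell lines
(they were planted as responsive in 8 lines). See the methods vignette
(`vignettes/epidrugsig-methods.Rmd`) for the model, the parameter
choices, and the clinical-cohort and survival stages.

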