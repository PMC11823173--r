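# colxnet

Anchor-gene co-expression module discovery, sample stratification and
survival analysis for bulk transcriptomics.

Tumor stroma rich in collagen type X (*COL10A1*) has been associated with
aggressive disease in several solid cancers. `colxnet` packages the full
analysis path for interrogating such an anchor gene in an expression
cohort:

1. **Module discovery.** A signed weighted co-expression network is built
   from gene–gene correlations, `a_ij = ((1 + cor(x_i, x_j))/2)^β`, with
   the soft power β chosen for approximate scale-free topology. Genes are
   clustered on topological-overlap dissimilarity (1 − TOM), and the
   module that co-clusters with the anchor gene (default `COL10A1`) is
   extracted together with its eigengene (ME, the first principal
   component of the standardized member expression).
2. **Preservation.** The anchor module is validated in a second cohort by
   permutation Z statistics over density (mean intramodular correlation
   and adjacency) and connectivity (cross-cohort correlation of
   intramodular connectivity and of correlation structure), summarized as
   `Z_summary`; values above 10 indicate strong preservation.
3. **Stratification.** Each sample is scored by **%G.A.M.E.** — the
   percentage of module genes expressed strictly above their cohort-wide
   median — and samples are split into low/medium/high strata at exact
   Fisher–Jenks natural breaks (dynamic programming, provably optimal).
4. **Characterization.** Strata are profiled by Fisher-exact gene-set
   overlap screens (BH-adjusted, odds-ratio gated), a
   correlation-corrected gene-set activity test (variance inflation
   factor `1 + (m−1)ρ̄`), cell-type fraction imputation by non-negative
   least squares against a four-fold marker signature, and multivariate
   Cox proportional hazards / Kaplan–Meier log-rank survival models, with
   hazards reported as percent change per standard deviation,
   `(e^β − 1)·100`.

A synthetic-cohort generator (`sim_config()`, `simulate_cohort()`,
`simulate_celltype_counts()`, `simulate_mixtures()`) plants known module,
survival and cell-type structure so every stage is testable end to end
without external downloads.

## Worked example

```r
library(colxnet)

cfg <- sim_config(n_genes = 300, n_samples = 300, module_sizes = c(50, 50),
                  loading_range = c(0.7, 0.9), seed = 42)
sim <- simulate_cohort(cfg)

sp   <- select_soft_power(sim$expression, network_config(candidate_powers = c(2, 4, 6, 8, 10, 12)))
A    <- signed_adjacency(sim$expression, sp$beta)
part <- detect_modules(topological_overlap(A), network_config(),
                       X = sim$expression, anchor_gene = "COL10A1")
part
#> ModulePartition: 300 genes, 2 modules (label 0: 200 unassigned)
#> anchor module: 1

anchor <- extract_anchor_module(part, "COL10A1")
strata <- stratify_samples(sim$expression, anchor$genes)
strata
#> SampleStrata: 300 samples; breaks (0.320, 0.620); low=85, medium=113, high=102

fit <- fit_coxph(sim$clinical, strata$game, outcome = "os", signal_name = "game")
fit
#> CoxFit [os]: n = 300, events = 216
#>              term    beta      se      z        p hazard_pct
#> 1             age  0.0196 0.00664  2.945 3.23e-03       1.98
#> 2      gendermale -0.0912 0.13679 -0.667 5.05e-01      -8.72
#> 3 stage_binary3-4  0.3947 0.13824  2.855 4.30e-03      48.39
#> 4            game  0.6119 0.07887  7.758 8.60e-15      84.39

km <- km_estimate(sim$clinical$os_time, sim$clinical$os_event, strata$km_label)
km
#> KMResult: log-rank chisq = 29.102, p = 6.865e-08
#>      high       low
#>  4.617585 12.704073
```

The generator planted two 50-gene modules (plus 200 noise genes); both are
recovered exactly, with noise genes unassigned (label 0). The anchor
module's %G.A.M.E. score carries the planted survival signal: +84% hazard
per standard deviation in the multivariate Cox model, and a median
time-to-event of 4.6 versus 12.7 in the high versus low %G.A.M.E. strata
(log-rank p ≈ 7e-8) — the generator planted a hazard ratio of 2 per SD of
the module's latent factor.

The full pipeline (filters → network → anchor module → preservation →
%G.A.M.E. → enrichment/activity → survival) also runs from a single YAML
config via `run_pipeline()`, or from the shell through the thin wrapper in
`inst/cli/colxnet.R`; every output table is checksummed into a JSON run
manifest that is identical for identical (config, seed).

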