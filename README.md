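# tempomics

Temporal multi-omics analysis of how cancer cells build up and resolve
drug-induced stress.

## The problem

A brief pulse of a proteotoxic drug (e.g. a proteasome inhibitor in multiple
myeloma) kills a fraction of tumor cells; the survivors spend more than a week
resolving the damage. Profiling transcripts, proteins and metabolites at
baseline and on days 1, 2, 4, 6, 8 and 10 after the pulse produces a
feature-by-sample matrix per omic layer with a shared day grid. `tempomics`
turns such a study into:

- **Per-day deregulation calls** against day 0, per layer, with an
  empirical-Bayes moderated t-statistic, Benjamini–Hochberg FDR control
  (Q ≤ 0.05) and, for transcripts, an additional fold-change > 2 cutoff.
- **A gene-to-gene network** whose nodes are deregulated transcripts and whose
  edge weights are the similarity of their temporal responses, built as the
  minimum spanning tree of the correlation distance union each node's
  k nearest neighbours (connected by construction).
- **Multiscale Markov stability clustering** of that network. For a partition
  H at Markov time t the stability is
  `r(t, H) = trace[ Hᵀ(Π exp(−tL) − ππᵀ)H ]`, with `L = I − D⁻¹A` the
  random-walk Laplacian and π the stationary distribution; the linearised
  form `r(t, H) = (1 − t) + t Σ_c in_c / 2m − Σ_c π_c²` equals
  Newman–Girvan modularity at t = 1 and is the optimised objective
  (Louvain-style greedy with random restarts). Scanning t from fine to coarse
  and selecting the longest plateau with a constant cluster count and low
  restart variation-of-information yields the robust partition and its
  cluster mean temporal profiles.
- **Single-sample gene-set enrichment** (rank-based KS running-sum score,
  scaled per set to [−1, 1]) over the time course.
- **Metabolite exchange rates** from supernatant concentrations and
  viable-cell densities: `rate = ΔC · V / ∫N(t)dt` in nmol per 10⁶ cells per
  hour, negative = consumption, positive = release.
- **Dependency signatures**: from a CRISPR dependency screen, select the most
  and least dependent (tissue-matched) cell lines for a target gene, derive a
  directional gene-expression signature (moderated t, BH, top |t|), and
  project it onto tumor transcriptomes; a tumor is classified dependent when
  strictly more than 80% of signature genes agree in z-score sign.

A synthetic-data module (`simulate_timecourse_study`, `simulate_supernatant`,
`simulate_dependency_cohort`) generates all inputs with known ground truth,
so the whole pipeline is testable without any external download.

## Worked example

```r
library(tempomics)

study <- simulate_timecourse_study(
  synthetic_study_config(n_features = 600, fraction_null = 0, seed = 1))
res <- run_recovery(study$transcripts, study$proteins, study$metabolites,
                    supernatant = simulate_supernatant(supernatant_config(seed = 1)),
                    config = pipeline_config(seed = 1))

res$manifest$n_clusters
#> [1] 6
res$cluster_profiles$sizes
#> cluster1 cluster2 cluster3 cluster4 cluster5 cluster6
#>       96       93      115      103       87      106
round(exchange_rates(simulate_supernatant(supernatant_config(seed = 1)),
                     metabolite = "lactate")$rate, 2)
#> [1] -12.12   2.97  39.94  24.86  12.13   4.81
```

The six clusters recover the six planted temporal archetypes (adjusted Rand
index 1.0 against the ground truth at this seed); the lactate series flips
from consumption (negative) at baseline to release peaking over the interval
ending on day 4, as the generator plants.

For the dependency workflow:

```r
coh <- simulate_dependency_cohort(dependency_cohort_config(seed = 1))
dep <- run_dependency(coh, pipeline_config(seed = 1))
dep$summary$dependent_tumor_fraction
#> [1] 0.1466667   # 22 of 150 tumors carry the planted signature at this seed
dep$signature
#> dependency_signature[EIF2AK4]: 56 genes (26 up, 30 down)
```

## Documentation

The methods vignette (`vignettes/stress-recovery-methods.Rmd`) describes the
statistical model behind each stage, what the synthetic generators emulate
(and what they deliberately do not), and every tunable parameter with its
default and rationale.
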