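# chromnet

Network analysis of Hi-C contact domains in R.

Chromosomes in the interphase nucleus fold into contact domains
(TAD-scale units, median ~185 kb in human GM12878 cells) that interact
with one another both along each chromosome and across chromosomes.
`chromnet` treats those domains as nodes of a weighted network whose
edges are the length-normalized contact frequencies

    I(a, b) = sum of shared Hi-C entries / (L_a * L_b)

and provides the statistics that characterize this network of networks:

* **I/O and balancing** — BED-style domain lists and subcompartment
  annotations (A1–B4), sparse-triple or dense binned contact matrices,
  and Knight–Ruiz-style matrix balancing to equal row sums.
* **Domain statistics** — removal of internal (nested) domains,
  subcompartment labeling (single-overlap or majority rule), all
  pairwise I(a, b) networks, and the cis/trans mean interaction ratio
  (≈850 in GM12878).
* **Network characterization** — normalized degree above a
  trans-percentile noise threshold; maximum-likelihood power-law tail
  fits with KS-optimal xmin (cis, γ ≈ 2); exponential tail fits
  (trans); R²-based model comparison; rescaled distribution collapse
  across chromosomes.
* **Subcompartment enrichment** — H_ij = (⟨I⟩_ij − H0)/H0 heatmaps for
  cis and trans, top-5% interactor selection, compartment composition.
* **Trans structure** — chromosome-pair interaction matrix, RSS-elbow
  k-means clustering, and the differential interaction score
  DR_k = (S_k − ⟨S⟩)/⟨S⟩ with a value-permuting bootstrap null and
  coherent-sign run-length statistics.
* **Synthetic genomes** — a seeded generator that reproduces the
  statistical structure of the real system (power-law cis, exponential
  trans ~850× weaker, nested domains, banded trans enrichment,
  homotypic and A1 boosts), so the whole pipeline is testable offline.

Coordinates are 0-based half-open (BED convention) throughout.

## Worked example

```r
library(chromnet)

# a 3-chromosome synthetic genome with the default statistical structure
genome  <- generate_genome(synthetic_genome_spec(
  n_chromosomes = 3, domains_per_chromosome = 100), seed = 1)
domains <- filter_internal_domains(genome$domains)

cis   <- pool_interactions(genome$nets$cis)
trans <- pool_interactions(genome$nets$trans)

cis_trans_ratio(cis, trans)
#> [1] 850

fit_power_law(cis)
#> tail_fit (power_law): gamma = 1.9886, xmin = 1.685e-06, n_tail = 9045,
#>   R2 = 0.9958, KS = 0.0083

fit_exponential(trans)
#> tail_fit (exponential): I0 = 1.21e-08, xmin = 7.519e-09,
#>   n_tail = 15000, R2 = 0.9000, KS = NA

thr <- interaction_threshold(trans, 25)
connectivity(genome$nets$cis, thr)$n_mean    # cis net is complete
#> [1] 1

d <- dr_bootstrap(genome$nets$trans[["chr1|chr2"]],
                  replicates = 50, seed = 1)
c(sigma = d$sigma, sigma_rand = d$sigma_rand,
  run = d$mean_run, run_rand = d$mean_run_rand)
#>      sigma sigma_rand        run   run_rand
#>  0.3084750  0.1075189  4.1666667  1.9815844
```

The cis pool is power-law with exponent ≈ 2 (scale-free, hub-dominated);
the trans pool is exponential and ~850× weaker; the banded trans
enrichment makes the DR score's spread and sign-run lengths clearly
exceed their value-permuted bootstrap null.

Or run everything at once and write all tables:

```r
res <- run_analysis(analysis_config(seed = 1), outdir = "out/")
str(res$summary)
```

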