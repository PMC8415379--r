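# meiorec

Integrative analysis of meiotic 3D chromatin organization and
recombination activity.

During meiotic prophase I, chromosomes fold into a brush-loop
architecture: chromatin loops emanating from an axis that carries the
recombination machinery. Recombination starts at hotspots bound by
PRDM9; only some hotspots receive a double-strand break (DSB, read out
by DMC1-SSDS ChIP-seq), and only a few DSBs per chromosome resolve as
crossovers. `meiorec` is for genomicists who want to quantify how
chromosome folding — measured by Hi-C — relates to which hotspots are
favored at each transition (PRDM9 → DSB, DSB → crossover).

## What it computes

For a genome tiled into fixed bins (5 kb by default):

* **cis/total ratio** per bin, `cis / (cis + trans)` — low values mark
  spatially accessible chromatin;
* **A/B compartment score** — the leading eigenvector of the
  observed/expected correlation matrix computed on 10-Mb diagonal
  chunks ("fine-grain eigenvectors", needed when long-range signal
  decays too fast for whole-chromosome eigendecomposition), oriented so
  positive = active (A);
* **insulation score** — log2 diamond-window contact ratio, minima at
  domain boundaries;
* **FIRE score** — z-scored near-cis (15–200 kb) interaction frequency;
* **P(s) curves** — contact probability versus separation on a log
  grid, optionally masked to pairs sharing a compartment label, with
  the average **loop length** estimated as the distance of the maximum
  of d log P / d log s;
* **crossover score map** — every crossover resolution interval
  distributes unit mass 1/k over the k bins it intersects (sharply
  mapped crossovers gain prominence); normalized by the median over
  nonzero bins.

On top of these: hotspot site sets (bins holding peak centers),
top/bottom quartile partitions by DSB or crossover activity,
enrichment tables (log2 fold over genome median, Bonferroni-adjusted
rank-sum tests), symmetric-averaged site profiles and
observed/expected contact pileups with seeded bootstrap CIs, and
forward-selection OLS models of DSB / crossover activity on principal
components of the chromatin features (entry threshold 0.001/n, naive
baselines reported alongside).

A seeded synthetic-genome generator (`sim_config()`, `simulate_all()`)
produces all inputs with known ground truth — compartment blocks,
seven-state segmentation, contact maps with compartment-specific loop
shoulders (A 0.7 Mb, B 2.1 Mb by default: a threefold difference),
peak sets and crossovers — so every estimator is tested by recovery
against the injected truth. `run_all()` drives the whole pipeline and
writes per-stage TSVs plus a bitwise-reproducible `results.json`.

## Worked example

```r
library(meiorec)

cfg <- sim_config(chrom_lengths = c(chrA = 20e6, chrB = 20e6),
                  read_depth = 2e6, n_prdm9_peaks = 800,
                  n_crossovers = 500, seed = 42)
sim <- simulate_all(cfg, stages = c("ES", "zygonema"))

## spatial accessibility: A-compartment bins have lower cis/total
ct <- cis_total_ratio(sim$contacts$zygonema)
tapply(as.numeric(ct), sim$truth$compartment, mean, na.rm = TRUE)
#>         A         B
#> 0.7500974 0.8499033

## compartment recovery from the interphase-strength map
states <- chromhmm_overlap_tracks(sim$chromhmm, sim$bins)
ref <- binned_track(rowSums(states[, c("promoter", "prom_enh",
                                       "enh_gene_body", "gene_body")]),
                    "activity")
comp <- fine_grain_compartment(sim$contacts$ES, ref)
cor(as.numeric(comp), ifelse(sim$truth$compartment == "A", 1, -1),
    use = "complete.obs")
#> [1] 0.9717218

## loop lengths from masked P(s) derivative maxima (injected: 0.7 / 2.1 Mb)
ll <- compartment_loop_lengths(sim$contacts$zygonema, sim$truth$compartment)
c(A = ll$loop_A, B = ll$loop_B, ratio = ll$ratio_BA)
#>            A            B        ratio
#> 6.920382e+05 1.713380e+06 2.475846e+00

## crossover map + quartile partition of PRDM9 sites by DSB activity
xo <- crossover_score_map(sim$crossovers, sim$bins)
sites <- define_sites(sim$peaks$prdm9_peaks, sim$bins,
                      score_tracks = list(dmc1_score = sim$peaks$tracks$dmc1,
                                          crossover_score = xo))
part <- partition_quartiles(sites, "dmc1_score")
enrichment_summary(part, sites,
                   list(crossover = xo, rnapii = sim$peaks$tracks$rnapii))
#>    variable ref_stat log2fc_all log2fc_top log2fc_bottom            p
#> 1 crossover   median  2.8112277  3.1456973     2.2446388 4.639519e-15
#> 2    rnapii   median  0.9307972  0.9795934     0.9061982 8.670814e-01
#>          p_adj significant
#> 1 9.279037e-15        TRUE
#> 2 1.000000e+00       FALSE
```

Read: the mean cis/total ratio is 0.750 in A versus 0.850 in B — the
injected accessibility contrast; compartment labels are recovered from
the contact map alone at r = 0.97; the masked P(s) derivative maxima
land at 0.69 Mb (A) and 1.7 Mb (B), recovering the injected threefold
loop-size difference to within the estimator's grid. In the quartile
comparison, DSB-favored (top-quartile) PRDM9 sites carry ~0.9 log2
units more crossover score than disfavored sites (Bonferroni-adjusted
p ≈ 1e-14); the RNAPII contrast is positive but, at 200 sites per
quartile in this small example, not significant.

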