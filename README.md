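# breedsim

Simulation framework for genetic-mapping study design in purebred dogs.

Complex-disease GWAS in dogs faces a peculiar trade-off: within one breed,
long-range linkage disequilibrium gives high power at small sample sizes but
poor resolution, while pooling cases and controls across breeds gives fine
mapping but demands bigger cohorts and denser arrays. `breedsim` quantifies
that trade-off end to end. It simulates breed-structured genomes under an
explicit wolf → village-dog → 30-breed demography with a fragment-based
discrete-generation coalescent (the GENOME model, re-implemented in C++),
ascertains SNP-array-like markers through a two-individual discovery panel,
simulates a liability-threshold disease with five causal loci of effect
0.25–1.25 σ plus a null control locus (h² = 0.5, 20% prevalence), samples
within-breed and across-breed case/control cohorts, runs a mixed-model
association scan, and reports detection power and false discovery rate per
effect size, design, sample size and array density.

The model at the core of the association step is the standard univariate
linear mixed model

    y = 1·α + x·β + u + ε,   u ~ N(0, σ²_g K),   ε ~ N(0, σ²_e I)

with K = ZZ'/p the centered genotype relatedness matrix over markers with
cohort MAF > 0.05. Per marker, the restricted likelihood is maximized over
δ = σ²_e/σ²_g (Brent search on log δ ∈ [−10, 10]) and significance is the
Wald test β̂²/se² against χ²₁. Power counting uses the study thresholds
(P ≤ 5 × 10⁻⁷ for ~13 kb and 10 kb arrays, P ≤ 1 × 10⁻⁷ for the dense
array) and credits a causal locus detected within 1 Mb (across-breed) or
5 Mb (within-breed). Population differentiation and LD are validated with
the Weir–Cockerham weighted F_ST estimator and genotypic r² by distance
bin.

Population sizes throughout follow the chromosome-count convention of
fragment-based coalescent simulators (a population of size N holds N/2
diploids); see the methods vignette (`vignettes/breedsim-methods.Rmd`) for
why this reading is the one consistent with the published F_ST and LD
levels in purebred dogs.

## Worked example

Simulate a reduced panel (2 chromosomes × 10 Mb, 30 diploids per breed),
ascertain array-like markers, and compute the validation statistics:

```r
library(breedsim)

model  <- build_demography("purebred30", seed = 1)
genome <- genome_spec(n_chromosomes = 2, chrom_length = 1e7)
panel  <- simulate_panel(model, genome, samples_per_pop = 30, seed = 11)
panel
#> haplotype_panel: 1800 haplotypes (900 diploids, 30 populations),
#>   68556 segregating sites on 2 chromosome(s)

markers <- ascertain_arrays(panel, arrays = "arraylike", seed = 5)$arraylike
markers
#> marker_panel (arraylike): 1489 markers, mean spacing 13444 bp

X   <- panel_dosage(panel, sites = markers$sites)
fst <- weighted_fst(X, panel$ind_pop, subsample = 25, seed = 3)
round(fst$weighted, 3)
#> [1] 0.247
round(range(fst$pairwise[upper.tri(fst$pairwise)]), 3)
#> [1] 0.111 0.560

ld <- ld_decay(X, markers$pos, markers$chrom, panel$ind_pop,
               bins = c(95000, 112500), subsample = 25, seed = 4)
round(ld$mean, 3); round(ld$range, 3)
#> 95000-112500
#>        0.215
#>       [,1]
#> [1,] 0.119
#> [2,] 0.454
```

The weighted F_ST across the 30 simulated breeds (~0.24–0.25, pairwise
~0.11–0.56) and the mean within-breed r² at 95–112.5 kb (~0.21–0.22, breed
range ~0.12–0.45) sit at the levels genotyping arrays measure in real
purebred-dog panels, which is what makes the downstream power numbers
meaningful.

A power study on a simulated panel:

```r
markers <- ascertain_arrays(panel, arrays = c("arraylike", "dense2kb"), seed = 5)
study <- run_power_study(panel, markers,
                         designs = data.frame(kind = "random", n = 500),
                         n_iter = 25, seed = 1)
study_power(study, "random", 500, "arraylike", multiplier = 0.75)
study_fdr(study, "random", 500, "arraylike")
plot(study$reports[["random|500|arraylike"]])
```

(The test suite runs this at its full fixture scale: 6 chromosomes × 10 Mb,
500 diploids per breed, the 2,100/8,400 case/control pool, 25 iterations.)

Simulated panels can be exported as PLINK BED/BIM/FAM (plus a breed-label
sidecar TSV) with `write_panel_plink()`, and array-format data — real or
simulated — can be pushed through the genotype QC filters (`snp_filters()`)
and genotypic sex inference (`infer_sex()`).

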