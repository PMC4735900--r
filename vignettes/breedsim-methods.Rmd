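---
title: "Simulating GWAS power in breed-structured dog populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating GWAS power in breed-structured dog populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`breedsim` asks a concrete study-design question: given the strong population
structure of purebred dogs, how many cases and controls, which cohort design
(within one breed, or pooled across many), and which SNP-array density are
needed to detect causal loci of moderate effect behind a complex disease?
It answers by simulation: breed-structured genomes are generated under an
explicit demographic model, array-like markers are ascertained the way real
arrays are built, a liability-threshold disease is simulated with known
causal loci, and a mixed-model GWAS is scored against that ground truth.

## The demographic model

Thirty purebred populations split 200 generations ago from a "village dog"
population of size 30,000, which itself derives from a wolf population of
size 15,000 through a 150-generation bottleneck of size 600 immediately
preceding the village expansion (4,200-4,350 generations before present;
total depth 4,350 generations). Breed sizes span 250-1,500 — evenly spaced
across the 30 breeds and assigned by a seeded shuffle — with a terminal
expansion to 2,000 for the final four generations so that 500 diploids can
be sampled per breed.

**Population sizes are numbers of chromosomes**, the convention of
fragment-based whole-genome coalescent simulators of the GENOME family, in
which a population is a pool of N chromosome slots (N/2 diploid
individuals). This reading is adopted deliberately. Three observations pin
it down. First, the terminal expansion to exactly 2,000 is what one needs to
draw 1,000 haplotypes, which is impossible from populations of 250-1,500
chromosomes but trivial from 2,000. Second, under the diploid reading a
200-generation split from breeds of 250+ diploids caps pairwise
Weir-Cockerham FST near 0.33 and the evenly spaced assignment yields a
weighted FST of about 0.13 — half the differentiation that array data show
among purebred dogs — whereas the chromosome reading predicts pairwise
values of roughly 0.12-0.54 with a weighted mean near 0.25, exactly the
observed range. Third, the same halving of effective size doubles
within-breed linkage disequilibrium, moving the 95-112.5 kb mean r^2 from
~0.13 to ~0.21-0.25, again in line with array estimates (~0.23-0.25). The
package's validation statistics (below) confirm all three quantitatively.

## The coalescent engine

The simulator is a discrete-generation backward Wright-Fisher coalescent on
a fragmented genome: each chromosome is a row of fixed-length fragments
(default 1,000 bp), recombination occurs only at fragment boundaries with
probability 1e-5 per boundary per generation (~1e-8/bp, about 1 cM/Mb), and
every lineage draws a parent chromosome uniformly from its population's
slots each generation. Lineages meeting in the same parent coalesce;
daughter populations merge into their parents at split times. Mutations
(1e-8 per bp per generation) are dropped on branches as Poisson counts and
placed uniformly with infinite-sites behaviour inside a fragment (a repeated
position is re-drawn). A fragment is retired once a single lineage carries
its ancestral material, since mutations above the sample MRCA cannot
segregate. Only segregating sites are returned, bit-packed site-major.

Numerical notes: the ancestral-graph lineage count legitimately exceeds a
population's size when recombination has fragmented many lineages and a
bottleneck shrinks the parent pool (the village bottleneck routinely
receives ~1,500 lineages into 600 slots at desk scale); the backward step
then simply mass-coalesces, as a forward Wright-Fisher generation would.
When a single generation places more than one breakpoint in a lineage, each
recombinant boundary hands the downstream material to a freshly drawn parent
chromosome. Sampling more haplotypes than a population's terminal size is
rejected up front.

Against an independent continuous-time coalescent (msprime) on matched
two-deme configurations the simulator agrees in mean pairwise diversity and
Weir-Cockerham FST within Monte-Carlo error; in the single-deme limit its
site-frequency spectrum is 1/i and, without recombination, no pair of sites
shows all four gametes. These checks run in the test suite.

## Marker ascertainment

Real arrays are designed from variants discovered in a few individuals, so
the package ascertains markers the same way: two diploids from two different
breeds are drawn, and any site at which their four haplotypes are not
identical is a candidate. Markers are then picked by a greedy walk along
each chromosome — choose the candidate closest to the current position plus
a target distance (ties toward the smaller position) — with three spacing
schemes: uniform 2 kb, uniform 10 kb, and "array-like", where the target
distances are a permuted sample of inter-marker distances with mean 13 kb
(an exponential stand-in truncated to [100 bp, 200 kb] is built in; real
BIM-file distances can be supplied). The walk restarts at the first
candidate of each chromosome. Ascertainment shifts the marker MAF spectrum
strongly toward common variants (mean pooled MAF ~0.25 versus ~0.06 across
all segregating sites), which is the bias the power study needs to capture.
One consequence at these parameters: two diploids are heterozygous or
discordant at roughly one site per 3.4 kb, so the "2 kb" dense scheme
saturates the candidate list and realizes ~3.4 kb spacing; it remains ~4x
denser than the array-like panel.

## Disease model

Six loci are drawn uniformly from all variants with pooled MAF in
[0.05, 0.10] (pooled = individual-weighted across the 30 breeds; the
variants need not be array markers). Effect multipliers {0.25, 0.5, 0.75,
1.0, 1.25} in liability-SD units, plus one zero-effect null control, are
assigned by a seeded permutation. The genetic value is the additive dosage
score; environmental noise has variance Var(g)(1-h2)/h2 so that liability
heritability is h2 = 0.5 on the realized genetic variance (per-allele
effects then deviate from their nominal sigma-multiples only through the
total-variance standardization, a few percent at these MAFs). The liability
is standardized and thresholded at its realized 80th percentile
(prevalence K = 0.2); using the realized quantile rather than the normal
one keeps the case fraction exact even when g is skewed. The degenerate
all-null set falls back to unit-variance noise.

The study pool retains 2,100 cases and 8,400 controls (drawn uniformly from
the 15,000 simulated individuals). Across-breed cohorts (balanced, random,
semibalanced, unbalanced) sample from this pool. The two near-identical
prevalence-proportional designs are disambiguated as: *semibalanced* scales
only cases by breed prevalence with controls split equally over the 20
highest-prevalence breeds; *unbalanced* scales cases and controls jointly.
Within-breed cohorts draw on a breed's full 500 simulated diploids rather
than the pool: a 500-diploid breed cannot contain 200 cases and 200 controls
after a 70% pool draw (it would need prevalence both above 57% and below
43%), so the pool constraint would make the within-breed n = 200 design
unrunnable; eligibility (>= n cases and >= n controls, i.e. prevalence
40-60% at n = 200) leaves one to five qualifying breeds per iteration, and
each iteration analyzes up to two of them. Largest-remainder rounding makes
per-breed quotas sum exactly to the totals.

## Association and scoring

The GWAS is a univariate linear mixed model with a centered relatedness
matrix G = ZZ'/p over markers with cohort MAF > 0.05 as the random-effect
covariance, intercept-only fixed effects, case/control status analyzed as
0/1, and a per-marker Wald test. G is eigendecomposed once per cohort; for
each marker the restricted likelihood is maximized over
log(delta) = log(sigma_e^2/sigma_g^2) in [-10, 10] by a 21-point bracket
plus Brent refinement to 1e-6 (per-marker REML, the behaviour of the
reference mixed-model GWAS tools). Markers with MAF < 0.05 are skipped;
singular rotated designs are reported untested rather than as NaN. The
inflation factor is the median Wald statistic over 0.4549 (the 1-df
chi-square median). With an identity kinship the fit reduces exactly to
OLS, and a brute-force delta-grid GLS oracle reproduces beta and P to four
significant figures — both are test-suite checks. A PLINK-style
`--indep 100 10 10` pruning (sliding 100-SNP windows, step 10, removing the
worst SNP until all VIFs are at most 10) supplies the LD-pruned Bonferroni
threshold used for within-breed significance in array data.

Power scoring uses fixed thresholds of 5e-7 (array-like and 10 kb panels)
and 1e-7 (dense panel). Significant markers are merged into loci by single
linkage within the detection window — 1 Mb for across-breed designs, 5 Mb
for within-breed — because long-range LD in a single breed spreads one
signal over megabases; the merge window defaults to the detection window
since the counting unit ("a locus") is otherwise undefined. A causal locus
is detected if any significant locus lies within the window; a significant
locus is a true positive if it lies within the window of any nonzero-effect
causal locus (the null locus never confers TP status). Power per effect size
is the detected fraction of iterations; FDR pools false and true positives
over iterations (micro-average), matching "false positives over all
significant loci".

## Validation statistics

`weighted_fst()` implements the Weir-Cockerham variance-components
estimator; the genome-wide value is the ratio of summed components
(the "weighted" form) and pairwise values use the same estimator per pair.
`ld_decay()` reports composite genotypic r^2 (squared dosage correlation,
usable on unphased data) averaged over marker pairs per distance bin and
population; both subsample 25 diploids per population. On the validation
panel (2 chromosomes x 10 Mb, 30 diploids per breed, array-like markers)
the package obtains weighted FST ~0.24 (pairwise ~0.11-0.51 across seeds)
and a 95-112.5 kb mean r^2 of ~0.21-0.22 with a breed range of ~0.11-0.49 —
against array-data reference values of 0.226 (0.08-0.30) and 0.235
(0.126-0.411), and matching the simulated-study references of 0.24
(0.12-0.51) and 0.247 (0.14-0.47) to within the scales used here.

## Quality control

`snp_filters()` applies, in order: call rate < 95% removal; removal of SNPs
with MAF > 2% whose heterozygosity ratio (observed over 2pqn expected,
computed from called genotypes after the call-rate filter) falls outside
[0.25, 1.0]; and removal of Y/mitochondrial SNPs with any heterozygous
call. The het-ratio filter skips haploid chromosomes, which carry no HWE
signal. Note the upper bound 1.0 is only sensible for heterozygote-deficient
(structured or inbred) cohorts — pooled breed data easily satisfy it, while
an idealized panmictic HWE sample would lose half its SNPs to sampling
fluctuation above 1.0. `infer_sex()` calls a sample male iff its
Y-missingness is below 50% and its X homozygosity above 60%; female iff
Y-missingness exceeds 50% regardless of X homozygosity (so inbred females
are not misread as males); Y-present-but-X-heterozygous samples are
ambiguous (XXY-like), never female. Samples over 10% missing are removed
first. A PAR boundary can be supplied; by default all X markers count as
non-PAR, appropriate for simulated data.

## Problem sizes and reproducibility

The package's own test suite and the acceptance script run everything at
desk scale, chosen once: the popgen validation panel uses 2 chromosomes x
10 Mb with 30 diploids per breed; the power study uses 6 chromosomes x
10 Mb with the full 500 diploids per breed (15,000 individuals, the full
2,100/8,400 pool) and 25 phenotype iterations. Shrinking the genome, not
the model, keeps every structural feature — 30 breeds, the bottleneck,
ascertainment, the liability model — while making run times reasonable; the
genome is kept to several independent chromosomes because the kinship
matrix is estimated from all markers, and with too few chromosomes the
causal chromosome dominates it (proximal contamination), visibly depressing
power. Remaining scale effects to keep in mind when comparing to full-scale
numbers: false-positive space is limited (six detection windows cover a
third of the 60 Mb genome, deflating FDR), the within-breed 5 Mb window
spans half of a 10 Mb chromosome, and 25 iterations put a binomial
confidence interval of roughly +/-0.17 on a power of 0.24. The generator
emulates neutral drift, ascertainment bias and the liability disease model;
it does not model genotyping error, missingness, selection, migration
between breeds, or mutation-rate heterogeneity, so passing tests speak to
the mapping-design question, not to those features of real data.

Every stochastic stage takes a seed derived from one master seed and a
stage name (`derive_seed()`), which makes full pipelines — including output
files — byte-for-byte reproducible; `run_config()` serializes a whole study
configuration to JSON losslessly.

## Limitations

Fragment-level recombination cannot represent crossover interference or
sub-kilobase breakpoints; the array-like spacing stand-in is exponential
rather than the true array spacing distribution; the dense scheme is
candidate-limited (above); GEMMA-style REML is per-marker, so
genome-partitioned variance components are out of scope; and the package
deliberately omits phasing, imputation, PCA outlier handling and
real-data association workflows.
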