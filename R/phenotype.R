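#' Choose causal loci for the liability trait
#'
#' Draws six distinct sites uniformly from all panel variants whose pooled
#' (individual-weighted) MAF lies in `maf_window`, and assigns the effect
#' multipliers {0, 0.25, 0.5, 0.75, 1, 1.25} (in liability-SD units per
#' derived allele) to them by a seeded permutation. The zero-effect locus is
#' the null control. Causal sites are drawn from all segregating variants,
#' not only ascertained markers.
#'
#' @param panel a `haplotype_panel`
#' @param maf_window inclusive pooled-MAF window, default `[0.05, 0.10]`
#' @param multipliers effect multipliers to permute over the loci
#' @param seed integer seed
#' @return an object of class `causal_set`: data.frame with columns `site`,
#'   `chrom`, `pos`, `maf`, `multiplier`
#' @export
choose_causal_loci <- function(panel, maf_window = c(0.05, 0.10),
                               multipliers = c(0, 0.25, 0.5, 0.75, 1, 1.25),
                               seed = 1L) {
  maf <- pooled_maf(panel)
  eligible <- which(maf >= maf_window[1] & maf <= maf_window[2])
  k <- length(multipliers)
  if (length(eligible) < k)
    stop("only ", length(eligible), " sites in the MAF window [",
         maf_window[1], ", ", maf_window[2], "]; need ", k)
  set.seed(seed)
  sites <- if (length(eligible) == k) eligible else
    eligible[sample.int(length(eligible), k)]
  m <- sample(multipliers)
  out <- data.frame(site = sites, chrom = panel$chrom[sites],
                    pos = panel$pos[sites], maf = maf[sites], multiplier = m)
  class(out) <- c("causal_set", "data.frame")
  out
}

#' Simulate a liability-threshold case/control trait
#'
#' Genetic value g_i = sum_j x_ij m_j over the causal loci (x = derived-allele
#' dosage). Environmental noise is drawn with variance Var(g) (1 - h2) / h2 so
#' the trait has heritability `h2` on the realized genetic variance; the total
#' liability is standardized to SD 1 in the pooled population, and individuals
#' above the (1 - prevalence) realized pooled quantile are cases. If the
#' causal set is entirely null (Var(g) = 0) the liability is pure unit-variance
#' noise. Deterministic given `seed`.
#'
#' @param panel a `haplotype_panel`
#' @param causal a `causal_set`
#' @param h2 liability heritability in (0, 1]
#' @param prevalence liability prevalence K in (0, 1)
#' @param seed integer seed
#' @return an object of class `phenotype_set`: data.frame with columns
#'   `individual`, `pop`, `liability`, `status` (0 control / 1 case); the
#'   causal set, h2, prevalence and realized heritability are attached as
#'   attributes
#' @export
simulate_liability <- function(panel, causal, h2 = 0.5, prevalence = 0.2,
                               seed = 1L) {
  if (h2 <= 0 || h2 > 1) stop("h2 must lie in (0, 1]")
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must lie in (0, 1)")
  X <- panel_dosage(panel, sites = causal$site)
  g <- drop(X %*% causal$multiplier)
  vg <- var(g)
  ve <- if (vg > 0) vg * (1 - h2) / h2 else 1
  set.seed(seed)
  l <- g + rnorm(length(g), 0, sqrt(ve))
  l <- (l - mean(l)) / sd(l)
  thr <- quantile(l, 1 - prevalence, names = FALSE)
  status <- as.integer(l > thr)
  out <- data.frame(individual = seq_along(g), pop = panel$ind_pop,
                    liability = l, status = status)
  class(out) <- c("phenotype_set", "data.frame")
  attr(out, "causal") <- causal
  attr(out, "h2") <- h2
  attr(out, "prevalence") <- prevalence
  attr(out, "realized_h2") <- if (vg > 0) vg / (vg + ve) else 0
  out
}

#' Draw the case/control study pool
#'
#' Uniform draw without replacement of `n_cases` cases and `n_controls`
#' controls from the pooled simulated population, retaining breed labels.
#' The defaults are the study's pool of 2,100 cases and 8,400 controls.
#'
#' @param phenos a `phenotype_set`
#' @param n_cases,n_controls pool sizes
#' @param seed integer seed
#' @return an object of class `cohort_pool`: data.frame with columns
#'   `individual`, `pop`, `status`
#' @export
draw_pool <- function(phenos, n_cases = 2100, n_controls = 8400, seed = 1L) {
  cases <- phenos$individual[phenos$status == 1L]
  controls <- phenos$individual[phenos$status == 0L]
  if (length(cases) < n_cases)
    stop("pool has ", length(cases), " cases; ", n_cases, " requested")
  if (length(controls) < n_controls)
    stop("pool has ", length(controls), " controls; ", n_controls, " requested")
  set.seed(seed)
  keep <- c(if (n_cases > 0) sample(cases, n_cases),
            if (n_controls > 0) sample(controls, n_controls))
  out <- phenos[match(keep, phenos$individual),
                c("individual", "pop", "status")]
  rownames(out) <- NULL
  class(out) <- c("cohort_pool", "data.frame")
  out
}
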