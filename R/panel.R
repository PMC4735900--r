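#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("haplotype_panel: %d haplotypes (%d diploids, %d populations), %d segregating sites on %d chromosome(s)\n",
              x$n_hap, x$n_hap / 2L, length(x$pop_levels), x$n_site,
              x$genome$n_chromosomes))
  invisible(x)
}

#' Number of diploid individuals in a panel
#' @param panel a `haplotype_panel`
#' @return integer count
#' @export
n_individuals <- function(panel) panel$n_hap %/% 2L

#' Pooled minor-allele frequency per site
#'
#' Frequencies are pooled over all sampled individuals (individual-weighted),
#' the reading used for the causal-locus MAF window.
#'
#' @param panel a `haplotype_panel`
#' @return numeric vector of per-site MAF
#' @export
pooled_maf <- function(panel) {
  f <- panel$count / panel$n_hap
  pmin(f, 1 - f)
}

#' Extract diploid dosages from a panel
#'
#' @param panel a `haplotype_panel`
#' @param sites site indices (default all)
#' @param individuals individual indices (default all); individual k owns
#'   haplotypes 2k-1 and 2k
#' @return integer matrix, individuals x sites, derived-allele counts 0/1/2
#' @export
panel_dosage <- function(panel, sites = seq_len(panel$n_site),
                         individuals = seq_len(n_individuals(panel))) {
  m <- .panel_dosage_cpp(panel$bits, panel$n_hap, as.integer(sites),
                         as.integer(individuals))
  dimnames(m) <- NULL
  m
}

#' Extract 0/1 haplotypes from a panel
#'
#' @param panel a `haplotype_panel`
#' @param sites site indices (default all)
#' @param haplotypes haplotype indices (default all)
#' @return integer matrix, haplotypes x sites
#' @export
panel_haplotypes <- function(panel, sites = seq_len(panel$n_site),
                             haplotypes = seq_len(panel$n_hap)) {
  .panel_haplotypes_cpp(panel$bits, panel$n_hap, as.integer(sites),
                        as.integer(haplotypes))
}

# derived-allele counts over a haplotype subset, all sites
panel_subset_counts <- function(panel, haplotypes) {
  .panel_subset_counts_cpp(panel$bits, panel$n_hap, panel$n_site,
                           as.integer(haplotypes))
}

#' Mean pairwise difference per haplotype pair
#'
#' Nucleotide diversity of the panel in per-panel units: the average number of
#' differing sites between two haplotypes, i.e. sum over sites of
#' 2 f (1 - f) n / (n - 1).
#'
#' @param panel a `haplotype_panel`
#' @return numeric scalar
#' @export
mean_pairwise_diversity <- function(panel) {
  n <- panel$n_hap
  f <- panel$count / n
  sum(2 * f * (1 - f)) * n / (n - 1)
}
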