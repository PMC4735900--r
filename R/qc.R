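#' Sequential SNP quality-control filters
#'
#' Applies, in order: (1) removal of SNPs with genotyping call rate below
#' `min_call_rate`; (2) among the remaining SNPs with MAF above `maf_gate`,
#' removal of SNPs whose heterozygosity ratio (observed heterozygotes over the
#' Hardy-Weinberg expectation 2 p q n_called) falls outside `het_ratio_range`;
#' (3) removal of Y-chromosome and mitochondrial SNPs with any heterozygous
#' call. Frequencies for the het-ratio gate are computed after the call-rate
#' filter, from called genotypes only.
#'
#' @param genotypes dosage matrix, individuals x SNPs, `NA` = missing
#' @param chrom per-SNP chromosome labels; autosomes numeric, `"X"`, `"Y"`,
#'   `"MT"` (or the dog codes 39/40/41)
#' @param min_call_rate SNP call-rate floor (default 0.95)
#' @param maf_gate MAF above which the het-ratio filter applies (default 0.02)
#' @param het_ratio_range allowed het-ratio interval (default `[0.25, 1.0]`)
#' @return an object of class `qc_report`: list with `keep` (retained SNP
#'   indices) and `removed` (named list of removal indices per filter stage)
#' @export
snp_filters <- function(genotypes, chrom, min_call_rate = 0.95,
                        maf_gate = 0.02, het_ratio_range = c(0.25, 1.0)) {
  stopifnot(is.matrix(genotypes), ncol(genotypes) == length(chrom))
  m <- ncol(genotypes)
  if (m == 0)
    return(structure(list(keep = integer(0),
                          removed = list(call_rate = integer(0),
                                         het_ratio = integer(0),
                                         haploid_het = integer(0))),
                     class = "qc_report"))
  chrom <- as.character(chrom)
  chrom[chrom == "39"] <- "X"; chrom[chrom == "40"] <- "Y"
  chrom[chrom == "41"] <- "MT"
  n_called <- colSums(!is.na(genotypes))
  call_rate <- n_called / nrow(genotypes)
  rm1 <- which(call_rate < min_call_rate)
  alive <- setdiff(seq_len(m), rm1)

  f <- colMeans(genotypes, na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  het_obs <- colSums(genotypes == 1, na.rm = TRUE)
  het_exp <- 2 * f * (1 - f) * n_called
  ratio <- ifelse(het_exp > 0, het_obs / het_exp, NA_real_)
  diploid <- !(chrom %in% c("Y", "MT"))  # haploid SNPs carry no HWE signal
  rm2 <- alive[diploid[alive] & !is.na(maf[alive]) & maf[alive] > maf_gate &
                 !is.na(ratio[alive]) &
                 (ratio[alive] < het_ratio_range[1] |
                    ratio[alive] > het_ratio_range[2])]
  alive <- setdiff(alive, rm2)

  hap <- alive[chrom[alive] %in% c("Y", "MT")]
  rm3 <- hap[colSums(genotypes[, hap, drop = FALSE] == 1, na.rm = TRUE) > 0]
  alive <- setdiff(alive, rm3)

  structure(list(keep = alive,
                 removed = list(call_rate = rm1, het_ratio = rm2,
                                haploid_het = rm3)),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("qc_report:", length(x$keep), "SNPs retained; removed:",
      paste(sprintf("%s=%d", names(x$removed),
                    lengths(x$removed)), collapse = ", "), "\n")
  invisible(x)
}

#' Genotypic sex inference
#'
#' A sample is called male iff its Y-chromosome missingness is below 0.5 and
#' its X-chromosome homozygosity exceeds 0.6; it is called female iff its
#' Y missingness exceeds 0.5 (regardless of X homozygosity, so females with
#' highly inbred X chromosomes are not misidentified as males); a sample with
#' Y genotypes present but a heterozygous X (homozygosity at or below 0.6) is
#' called ambiguous (XXY-like), never female. Samples missing more than
#' `max_missing` of all genotypes are removed before inference.
#'
#' @param genotypes dosage matrix, individuals x SNPs, `NA` = missing
#' @param chrom per-SNP chromosome labels (see [snp_filters()])
#' @param pos per-SNP bp positions, needed only when `par_boundary` is set
#' @param recorded_sex optional vector (`"male"`/`"female"`) to flag conflicts
#' @param par_boundary X positions at or below this bp are pseudo-autosomal
#'   and excluded from the homozygosity computation; `NULL` (default) treats
#'   all X markers as non-PAR, appropriate for simulated data without a PAR
#' @param max_missing per-sample missingness ceiling (default 0.10)
#' @return data.frame with per-sample `y_missing`, `x_homozygosity`,
#'   `inferred_sex` (male/female/ambiguous, `NA` for removed samples),
#'   `removed`, and `sex_conflict` when `recorded_sex` was given
#' @export
infer_sex <- function(genotypes, chrom, pos = NULL, recorded_sex = NULL,
                      par_boundary = NULL, max_missing = 0.10) {
  stopifnot(is.matrix(genotypes), ncol(genotypes) == length(chrom))
  chrom <- as.character(chrom)
  chrom[chrom == "39"] <- "X"; chrom[chrom == "40"] <- "Y"
  chrom[chrom == "41"] <- "MT"
  ycol <- which(chrom == "Y")
  xcol <- which(chrom == "X")
  if (!is.null(par_boundary)) {
    stopifnot(!is.null(pos))
    xcol <- xcol[pos[xcol] > par_boundary]
  }
  n <- nrow(genotypes)
  if (!length(ycol) || !length(xcol)) {
    warning("no X or Y markers: all sex calls ambiguous")
    return(data.frame(y_missing = NA_real_, x_homozygosity = NA_real_,
                      inferred_sex = rep("ambiguous", n), removed = FALSE))
  }
  miss <- rowMeans(is.na(genotypes))
  removed <- miss > max_missing
  y_missing <- rowMeans(is.na(genotypes[, ycol, drop = FALSE]))
  xg <- genotypes[, xcol, drop = FALSE]
  x_hom <- rowSums(xg != 1, na.rm = TRUE) / rowSums(!is.na(xg))
  sex <- rep("ambiguous", n)
  sex[y_missing > 0.5] <- "female"
  sex[y_missing < 0.5 & x_hom > 0.6] <- "male"
  sex[removed] <- NA_character_
  out <- data.frame(y_missing = y_missing, x_homozygosity = x_hom,
                    inferred_sex = sex, removed = removed)
  if (!is.null(recorded_sex))
    out$sex_conflict <- !removed & !is.na(sex) & sex != "ambiguous" &
      sex != as.character(recorded_sex)
  out
}
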