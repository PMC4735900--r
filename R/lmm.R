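#' Centered genotype relatedness (kinship) matrix
#'
#' G = Z Z' / p over the p markers with cohort MAF strictly above `maf_min`,
#' where Z is the column-centered 0/1/2 dosage matrix. Built only from the
#' analyzed individuals, matching the convention of mixed-model GWAS tools.
#'
#' @param genotypes dosage matrix, individuals x markers
#' @param maf_min markers with MAF <= `maf_min` are excluded (default 0.05)
#' @return n x n kinship matrix with the marker indices used attached as
#'   attribute `markers_used`
#' @export
compute_kinship <- function(genotypes, maf_min = 0.05) {
  stopifnot(is.matrix(genotypes), nrow(genotypes) >= 2)
  f <- colMeans(genotypes) / 2
  maf <- pmin(f, 1 - f)
  use <- which(maf > maf_min)
  if (!length(use)) stop("no markers pass the MAF filter")
  Z <- scale(genotypes[, use, drop = FALSE], center = TRUE, scale = FALSE)
  G <- tcrossprod(Z) / length(use)
  attr(G, "markers_used") <- use
  G
}

#' Genomic inflation factor
#'
#' lambda = median(observed chi-square statistics) / 0.4549364, the median of
#' the 1-df chi-square distribution; 1.0 indicates no inflation.
#'
#' @param stats Wald chi-square statistics (1 df), or P-values with
#'   `type = "p"`
#' @param type `"chisq"` (default) or `"p"`
#' @return numeric scalar lambda
#' @export
inflation_factor <- function(stats, type = c("chisq", "p")) {
  type <- match.arg(type)
  stats <- stats[is.finite(stats)]
  if (!length(stats)) stop("no finite statistics")
  if (type == "p") stats <- qchisq(stats, df = 1, lower.tail = FALSE)
  median(stats) / qchisq(0.5, df = 1)
}

#' Mixed-model association scan with Wald tests
#'
#' Fits, per marker, y = a + x b + u + e with u ~ N(0, sg2 K) and
#' e ~ N(0, se2 I). K is eigendecomposed once; per marker the restricted
#' likelihood is maximized over log(delta) = log(se2/sg2) in \[-10, 10\]
#' (Brent search, tolerance 1e-6), and the GLS estimate, its standard error
#' and the Wald chi-square P-value are reported. Case/control phenotypes are
#' analyzed as 0/1 quantitative values. Markers with cohort MAF below
#' `test_maf` are skipped; markers whose rotated design is singular are
#' reported untested (`tested = FALSE`) rather than propagating NaN.
#'
#' @param genotypes dosage matrix, individuals x markers
#' @param phenotype numeric vector (0/1 status or quantitative), length n
#' @param kinship n x n kinship matrix ([compute_kinship()]); identity gives
#'   ordinary least squares
#' @param positions,chrom optional per-marker bp positions and chromosome
#'   indices carried into the result
#' @param test_maf markers with MAF < `test_maf` are skipped (default 0.05)
#' @return an `assoc_result` data.frame with columns `marker`, `chrom`, `pos`,
#'   `maf`, `beta`, `se`, `chi2`, `p`, `logdelta`, `tested`; the inflation
#'   factor `lambda`, sample size and tested-marker count are attributes
#' @export
lmm_gwas <- function(genotypes, phenotype, kinship, positions = NULL,
                     chrom = NULL, test_maf = 0.05) {
  stopifnot(is.matrix(genotypes), length(phenotype) == nrow(genotypes),
            all(dim(kinship) == nrow(genotypes)))
  n <- nrow(genotypes)
  m <- ncol(genotypes)
  f <- colMeans(genotypes) / 2
  maf <- pmin(f, 1 - f)
  test <- maf >= test_maf
  eg <- eigen(kinship, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  Ut <- t(eg$vectors)
  Uty <- drop(Ut %*% phenotype)
  Utone <- drop(Ut %*% rep(1, n))
  UtX <- Ut %*% genotypes[, test, drop = FALSE]
  fit <- .lmm_reml_cpp(d, Uty, Utone, UtX)
  out <- data.frame(marker = seq_len(m),
                    chrom = if (is.null(chrom)) NA_integer_ else chrom,
                    pos = if (is.null(positions)) NA_real_ else positions,
                    maf = maf, beta = NA_real_, se = NA_real_,
                    chi2 = NA_real_, p = NA_real_, logdelta = NA_real_,
                    tested = FALSE)
  out$beta[test] <- fit$beta
  out$se[test] <- fit$se
  out$chi2[test] <- fit$chi2
  out$logdelta[test] <- fit$logdelta
  out$tested[test] <- fit$ok
  out$p[out$tested] <- pchisq(out$chi2[out$tested], df = 1, lower.tail = FALSE)
  out$p[out$tested & out$p == 0] <- .Machine$double.xmin  # keep P in (0, 1]
  class(out) <- c("assoc_result", "data.frame")
  attr(out, "n") <- n
  attr(out, "n_tested") <- sum(out$tested)
  attr(out, "lambda") <- if (any(out$tested))
    inflation_factor(out$chi2[out$tested]) else NA_real_
  out
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("assoc_result: %d markers (%d tested), n = %d, lambda = %.3f\n",
              nrow(x), attr(x, "n_tested"), attr(x, "n"), attr(x, "lambda")))
  top <- x[x$tested, ]
  top <- top[order(top$p), ][seq_len(min(5, sum(x$tested))), ]
  print.data.frame(top, digits = 3, row.names = FALSE)
  invisible(x)
}

#' @export
summary.assoc_result <- function(object, ...) {
  list(n = attr(object, "n"), n_tested = attr(object, "n_tested"),
       lambda = attr(object, "lambda"),
       min_p = suppressWarnings(min(object$p, na.rm = TRUE)))
}

#' LD-pruned Bonferroni significance threshold
#'
#' Greedy sliding-window LD pruning in the style of PLINK `--indep 100 10 10`:
#' in each window of `window` SNPs (advancing by `step`), the SNP with the
#' largest variance inflation factor is removed repeatedly until all VIFs are
#' at most `vif` (VIF 10 corresponds to multiple-correlation R^2 of 0.9). The
#' threshold is `alpha` divided by the number of retained SNPs.
#'
#' @param genotypes dosage matrix, individuals x markers (marker order =
#'   genome order)
#' @param alpha family-wise error rate (default 0.05)
#' @param window,step window size and slide in SNP counts
#' @param vif variance-inflation-factor cutoff
#' @return the significance threshold, with `n_retained` and the retained
#'   marker indices as attributes
#' @export
pruned_bonferroni <- function(genotypes, alpha = 0.05, window = 100L,
                              step = 10L, vif = 10) {
  stopifnot(is.matrix(genotypes), ncol(genotypes) >= 1)
  m <- ncol(genotypes)
  keep <- rep(TRUE, m)
  # constant columns carry no LD information; retain them untouched
  informative <- apply(genotypes, 2, function(x) var(x) > 0)
  vifs_of <- function(C) {
    inv <- tryCatch(solve(C), error = function(e) NULL)
    if (is.null(inv))
      inv <- solve(C + diag(1e-8, nrow(C)))
    diag(inv)
  }
  starts <- seq(1L, max(1L, m - 1L), by = step)
  for (s in starts) {
    repeat {
      idx <- which(keep & informative)
      idx <- idx[idx >= s & idx <= min(m, s + window - 1L)]
      if (length(idx) < 2) break
      C <- suppressWarnings(cor(genotypes[, idx, drop = FALSE]))
      v <- vifs_of(C)
      v[!is.finite(v)] <- Inf
      if (max(v) <= vif) break
      keep[idx[which.max(v)]] <- FALSE
    }
    if (s + window - 1L >= m) break
  }
  n_ret <- sum(keep)
  structure(alpha / n_ret, n_retained = n_ret, retained = which(keep))
}
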