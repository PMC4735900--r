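#' Weir-Cockerham FST (weighted, multi-population) and pairwise matrix
#'
#' Variance-components estimator of Weir & Cockerham (1984) for biallelic
#' loci. The headline "weighted" value is the ratio of sums over loci,
#' sum(a) / sum(a + b + c); the pairwise matrix applies the same estimator to
#' every population pair. Monomorphic data yield `NA`.
#'
#' @param genotypes dosage matrix, individuals x loci (0/1/2)
#' @param pops population label per individual
#' @param subsample diploids randomly drawn per population before estimation
#'   (`NULL` uses everyone); the study subsamples 25 per population
#' @param seed integer seed for the subsample
#' @return list with `weighted` (scalar), `pairwise` (symmetric matrix) and
#'   `n_loci`
#' @export
weighted_fst <- function(genotypes, pops, subsample = NULL, seed = 1L) {
  stopifnot(is.matrix(genotypes), nrow(genotypes) == length(pops))
  pops <- as.character(pops)
  if (length(unique(pops)) < 2) stop("need at least two populations")
  if (!is.null(subsample)) {
    set.seed(seed)
    keep <- unlist(lapply(split(seq_along(pops), pops), function(i)
      if (length(i) <= subsample) i else sample(i, subsample)))
    genotypes <- genotypes[keep, , drop = FALSE]
    pops <- pops[keep]
  }
  if (any(table(pops) < 2)) stop("every population needs at least two individuals")

  components <- function(G, lab) {
    lv <- unique(lab)
    r <- length(lv)
    ni <- vapply(lv, function(p) sum(lab == p), numeric(1))
    pmat <- vapply(lv, function(p) colMeans(G[lab == p, , drop = FALSE]) / 2,
                   numeric(ncol(G)))
    hmat <- vapply(lv, function(p) colMeans(G[lab == p, , drop = FALSE] == 1),
                   numeric(ncol(G)))
    if (is.null(dim(pmat))) { pmat <- matrix(pmat, nrow = 1); hmat <- matrix(hmat, nrow = 1) }
    nbar <- mean(ni)
    nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
    pbar <- drop(pmat %*% ni) / (r * nbar)
    s2 <- drop((pmat - pbar)^2 %*% ni) / ((r - 1) * nbar)
    hbar <- drop(hmat %*% ni) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
    cc <- hbar / 2
    list(a = a, b = b, c = cc)
  }
  ratio <- function(cmp) {
    den <- sum(cmp$a + cmp$b + cmp$c)
    if (den <= 0) NA_real_ else sum(cmp$a) / den
  }
  all_cmp <- components(genotypes, pops)
  lv <- sort(unique(pops))
  pw <- matrix(NA_real_, length(lv), length(lv), dimnames = list(lv, lv))
  for (i in seq_along(lv)) for (j in seq_along(lv)) {
    if (j <= i) next
    sel <- pops %in% lv[c(i, j)]
    pw[i, j] <- pw[j, i] <-
      ratio(components(genotypes[sel, , drop = FALSE], pops[sel]))
  }
  diag(pw) <- 0
  list(weighted = ratio(all_cmp), pairwise = pw, n_loci = ncol(genotypes))
}

#' Within-population LD decay (genotypic r-squared by distance bin)
#'
#' Composite genotypic r^2 (squared Pearson correlation of 0/1/2 dosages)
#' between all marker pairs on the same chromosome whose bp distance falls in
#' each bin, averaged within population. The study's reference bin is
#' 95,000-112,500 bp with 25 diploids per population.
#'
#' @param genotypes dosage matrix, individuals x markers
#' @param pos,chrom per-marker bp position and chromosome index
#' @param pops population label per individual
#' @param bins two-column matrix (or vector of length 2) of inclusive bin
#'   bounds in bp
#' @param subsample diploids per population (`NULL` = all)
#' @param seed integer seed for the subsample
#' @return list with `per_pop` (populations x bins matrix of mean r^2),
#'   `mean` and `range` (across-population summary per bin), `n_pairs`
#' @export
ld_decay <- function(genotypes, pos, chrom, pops,
                     bins = c(95000, 112500), subsample = 25, seed = 1L) {
  stopifnot(is.matrix(genotypes), nrow(genotypes) == length(pops),
            ncol(genotypes) == length(pos), length(pos) == length(chrom))
  if (is.null(dim(bins))) bins <- matrix(bins, ncol = 2)
  pops <- as.character(pops)
  lv <- sort(unique(pops))
  set.seed(seed)
  keep_by_pop <- lapply(lv, function(p) {
    i <- which(pops == p)
    if (!is.null(subsample) && length(i) > subsample) sample(i, subsample) else i
  })
  names(keep_by_pop) <- lv

  o <- order(chrom, pos)
  pos <- pos[o]; chrom <- chrom[o]
  G <- genotypes[, o, drop = FALSE]
  pair_idx <- lapply(seq_len(nrow(bins)), function(b) {
    lo <- bins[b, 1]; hi <- bins[b, 2]
    ii <- jj <- integer(0)
    for (c_i in unique(chrom)) {
      w <- which(chrom == c_i)
      pc <- pos[w]
      lo_j <- findInterval(pc + lo - 1e-9, pc) + 1L
      hi_j <- findInterval(pc + hi + 1e-9, pc)
      for (k in seq_along(w)) {
        if (hi_j[k] >= lo_j[k]) {
          jj <- c(jj, w[lo_j[k]:hi_j[k]])
          ii <- c(ii, rep(w[k], hi_j[k] - lo_j[k] + 1L))
        }
      }
    }
    cbind(ii, jj)
  })

  per_pop <- matrix(NA_real_, length(lv), nrow(bins),
                    dimnames = list(lv, apply(bins, 1, paste, collapse = "-")))
  n_pairs <- per_pop
  for (p in lv) {
    Gp <- G[keep_by_pop[[p]], , drop = FALSE]
    n <- nrow(Gp)
    sds <- apply(Gp, 2, sd)
    Z <- scale(Gp)
    for (b in seq_len(nrow(bins))) {
      pi <- pair_idx[[b]]
      if (!nrow(pi)) next
      ok <- sds[pi[, 1]] > 0 & sds[pi[, 2]] > 0
      pi <- pi[ok, , drop = FALSE]
      if (!nrow(pi)) next
      r <- colSums(Z[, pi[, 1], drop = FALSE] * Z[, pi[, 2], drop = FALSE]) /
        (n - 1)
      per_pop[p, b] <- mean(r^2)
      n_pairs[p, b] <- nrow(pi)
    }
  }
  list(per_pop = per_pop,
       mean = colMeans(per_pop, na.rm = TRUE),
       range = apply(per_pop, 2, function(v)
         if (all(is.na(v))) c(NA_real_, NA_real_) else range(v, na.rm = TRUE)),
       n_pairs = n_pairs)
}
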