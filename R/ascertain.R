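#' Discover array candidate variants in a two-individual panel
#'
#' Mimics SNP-array ascertainment: two diploid discovery individuals are drawn
#' from two different breed populations, and a site is a candidate marker iff
#' its four discovery haplotypes are not all identical (it segregates within
#' the discovery panel). This biases candidates toward common variants.
#'
#' @param panel a `haplotype_panel`
#' @param seed integer seed
#' @return an object of class `candidate_set` with elements `sites` (panel
#'   site indices), `individuals` and `populations`
#' @export
discover_candidates <- function(panel, seed = 1L) {
  if (panel$n_hap == 0) stop("empty panel")
  pops <- unique(panel$ind_pop)
  if (length(pops) < 2) stop("discovery requires at least two populations")
  set.seed(seed)
  chosen_pops <- sample(pops, 2)
  inds <- vapply(chosen_pops, function(p) {
    cand <- which(panel$ind_pop == p)
    cand[sample.int(length(cand), 1)]
  }, integer(1))
  haps <- as.integer(c(2 * inds[1] - 1, 2 * inds[1], 2 * inds[2] - 1, 2 * inds[2]))
  c4 <- panel_subset_counts(panel, haps)
  sites <- which(c4 > 0L & c4 < 4L)
  structure(list(sites = sites, individuals = inds, populations = chosen_pops),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("candidate_set: %d candidate sites discovered in individuals %s (populations %s)\n",
              length(x$sites), paste(x$individuals, collapse = ", "),
              paste(x$populations, collapse = ", ")))
  invisible(x)
}

# greedy spacing walk over candidate positions of one chromosome.
# `spacing` is either a single target or a function(k) returning the k-th
# target distance. Ties break toward the smaller position.
greedy_walk <- function(pos, next_spacing) {
  m <- length(pos)
  if (m == 0) return(integer(0))
  picked <- integer(m)
  picked[1] <- 1L
  np <- 1L
  cur <- 1L
  k <- 0L
  while (cur < m) {
    k <- k + 1L
    target <- pos[cur] + next_spacing(k)
    lo <- cur + 1L
    j <- findInterval(target, pos)
    if (j < lo) {
      best <- lo
    } else if (j >= m) {
      best <- m
    } else {
      # pos[j] <= target < pos[j+1]; j >= lo here
      best <- if (target - pos[j] <= pos[j + 1L] - target) j else j + 1L
    }
    np <- np + 1L
    picked[np] <- best
    cur <- best
  }
  picked[seq_len(np)]
}

make_marker_panel <- function(panel, sites, scheme) {
  o <- order(panel$chrom[sites], panel$pos[sites])
  sites <- sites[o]
  d <- diff(panel$pos[sites])
  d[diff(panel$chrom[sites]) != 0] <- NA
  structure(list(sites = sites, scheme = scheme,
                 chrom = panel$chrom[sites], pos = panel$pos[sites],
                 spacing = d),
            class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  cat(sprintf("marker_panel (%s): %d markers, mean spacing %.0f bp\n",
              x$scheme, length(x$sites), mean(x$spacing, na.rm = TRUE)))
  invisible(x)
}

#' Select uniformly spaced markers from ascertained candidates
#'
#' Greedy per-chromosome walk: starting from the first candidate, repeatedly
#' select the candidate closest to (current position + `target_spacing`),
#' ties broken toward the smaller position.
#'
#' @param candidates a `candidate_set`
#' @param panel the `haplotype_panel` the candidates index into
#' @param target_spacing target inter-marker distance in bp (2,000 and 10,000
#'   are the uniform schemes studied)
#' @return an object of class `marker_panel`
#' @export
select_uniform <- function(candidates, panel, target_spacing) {
  stopifnot(target_spacing > 0)
  sel <- integer(0)
  for (c_i in unique(panel$chrom[candidates$sites])) {
    sidx <- candidates$sites[panel$chrom[candidates$sites] == c_i]
    sidx <- sidx[order(panel$pos[sidx])]
    w <- greedy_walk(panel$pos[sidx], function(k) target_spacing)
    sel <- c(sel, sidx[w])
  }
  make_marker_panel(panel, sel,
                    sprintf("uniform%gkb", target_spacing / 1000))
}

#' Built-in stand-in for CanineHD inter-marker distances
#'
#' Distances drawn from an exponential distribution with mean 13,000 bp,
#' truncated to \[100, 200,000\] bp, emulating the published array's average
#' density of one SNP every 13 kb. Supply distances taken from a real BIM
#' file to `select_array_like()` instead when available.
#'
#' @param n number of distances
#' @param mean_spacing mean inter-marker distance in bp
#' @param range truncation bounds in bp
#' @return numeric vector of distances
#' @export
synthetic_array_spacings <- function(n, mean_spacing = 13000,
                                     range = c(100, 200000)) {
  out <- numeric(0)
  while (length(out) < n) {
    d <- rexp(2 * n, rate = 1 / mean_spacing)
    out <- c(out, d[d >= range[1] & d <= range[2]])
  }
  out[seq_len(n)]
}

#' Select markers with array-like (permuted) spacing
#'
#' The supplied inter-marker distances are permuted and the greedy walk of
#' [select_uniform()] is run with each step using the next permuted distance,
#' reproducing the spacing distribution of a real genotyping array.
#'
#' @param candidates a `candidate_set`
#' @param panel the `haplotype_panel` the candidates index into
#' @param spacing_sample positive distances (bp), e.g. consecutive-marker
#'   distances from an array BIM file; `NULL` uses
#'   [synthetic_array_spacings()] with mean 13 kb
#' @param seed integer seed for the permutation
#' @return an object of class `marker_panel`
#' @export
select_array_like <- function(candidates, panel, spacing_sample = NULL,
                              seed = 1L) {
  set.seed(seed)
  if (is.null(spacing_sample)) {
    need <- ceiling(panel$genome$n_chromosomes * panel$genome$chrom_length / 6000)
    spacing_sample <- synthetic_array_spacings(max(need, 10))
  }
  if (!length(spacing_sample) || any(spacing_sample <= 0))
    stop("spacing_sample must be non-empty and positive")
  dists <- sample(spacing_sample)
  nd <- length(dists)
  sel <- integer(0)
  used <- 0L
  for (c_i in unique(panel$chrom[candidates$sites])) {
    sidx <- candidates$sites[panel$chrom[candidates$sites] == c_i]
    sidx <- sidx[order(panel$pos[sidx])]
    base <- used
    w <- greedy_walk(panel$pos[sidx],
                     function(k) dists[((base + k - 1L) %% nd) + 1L])
    used <- used + length(w) - 1L
    sel <- c(sel, sidx[w])
  }
  make_marker_panel(panel, sel, "arraylike")
}
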