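#' Evaluation rule for significant loci
#'
#' The study's thresholds: P <= 5e-7 for the array-like (13 kb) and 10 kb
#' arrays and P <= 1e-7 for the dense 2 kb array (approximately 5% Bonferroni
#' cutoffs); causal loci count as detected within 1 Mb of a significant locus
#' for across-breed designs and within 5 Mb for within-breed designs.
#' Significant markers are merged into loci by single-linkage within
#' `merge_window` (defaults to the detection window).
#'
#' @param p_threshold significance cutoff in (0, 1)
#' @param detection_window bp distance within which a causal locus is credited
#' @param merge_window single-linkage merge distance for significant markers
#' @return an object of class `eval_spec`
#' @export
eval_spec <- function(p_threshold = 5e-7, detection_window = 1e6,
                      merge_window = detection_window) {
  stopifnot(p_threshold > 0, p_threshold < 1, detection_window > 0,
            merge_window > 0)
  structure(list(p_threshold = p_threshold,
                 detection_window = detection_window,
                 merge_window = merge_window), class = "eval_spec")
}

#' Default evaluation rule for an array scheme and design kind
#'
#' @param array `"dense2kb"`, `"uniform10kb"` or `"arraylike"`
#' @param design `"within"` or any across-breed kind
#' @return an `eval_spec`
#' @export
eval_spec_for <- function(array = c("arraylike", "uniform10kb", "dense2kb"),
                          design = "random") {
  array <- match.arg(array)
  thr <- if (array == "dense2kb") 1e-7 else 5e-7
  win <- if (identical(design, "within")) 5e6 else 1e6
  eval_spec(p_threshold = thr, detection_window = win)
}

#' Merge significant markers into loci
#'
#' Markers with P at or below the threshold are clustered per chromosome by
#' single linkage within `merge_window`; each locus is reported at its most
#' significant marker.
#'
#' @param assoc an `assoc_result`
#' @param spec an `eval_spec`
#' @return data.frame with columns `chrom`, `pos`, `p`, `n_markers`
#' @export
call_loci <- function(assoc, spec) {
  sig <- assoc[assoc$tested & !is.na(assoc$p) & assoc$p <= spec$p_threshold, ]
  if (!nrow(sig))
    return(data.frame(chrom = integer(), pos = numeric(), p = numeric(),
                      n_markers = integer()))
  sig <- sig[order(sig$chrom, sig$pos), ]
  new_locus <- c(TRUE, diff(sig$pos) > spec$merge_window |
                   diff(sig$chrom) != 0)
  grp <- cumsum(new_locus)
  out <- do.call(rbind, lapply(split(sig, grp), function(g) {
    best <- which.min(g$p)
    data.frame(chrom = g$chrom[best], pos = g$pos[best], p = g$p[best],
               n_markers = nrow(g))
  }))
  rownames(out) <- NULL
  out
}

#' Score called loci against the causal set
#'
#' A causal locus is detected iff at least one significant locus lies within
#' the detection window of it on the same chromosome. A significant locus is
#' a true positive iff it lies within the window of any nonzero-effect causal
#' locus; the zero-effect null locus never confers true-positive status.
#'
#' @param loci output of [call_loci()]
#' @param causal a `causal_set`
#' @param spec an `eval_spec`
#' @return list with `detected` (named logical per causal multiplier,
#'   including the null locus as `"0"`), `tp`, `fp`
#' @export
classify_and_score <- function(loci, causal, spec) {
  w <- spec$detection_window
  near <- function(c_chrom, c_pos)
    loci$chrom == c_chrom & abs(loci$pos - c_pos) <= w
  detected <- vapply(seq_len(nrow(causal)), function(i)
    any(near(causal$chrom[i], causal$pos[i])), logical(1))
  names(detected) <- as.character(causal$multiplier)
  real <- causal[causal$multiplier > 0, ]
  tp_flag <- vapply(seq_len(nrow(loci)), function(j)
    any(loci$chrom[j] == real$chrom &
          abs(loci$pos[j] - real$pos) <= w), logical(1))
  list(detected = detected, tp = sum(tp_flag), fp = sum(!tp_flag))
}

#' Aggregate per-iteration scores into a power report
#'
#' Power per effect multiplier is the fraction of iterations in which that
#' causal locus was detected; the false discovery rate pools counts over
#' iterations, FDR = sum(FP) / sum(FP + TP), reported as `NA` when no locus
#' was significant in any iteration.
#'
#' @param scores list of [classify_and_score()] results
#' @param meta optional named list recorded in the report (design, array, n)
#' @return an object of class `power_report`
#' @export
aggregate_power <- function(scores, meta = list()) {
  stopifnot(length(scores) >= 1)
  det <- do.call(rbind, lapply(scores, function(s)
    s$detected[order(as.numeric(names(s$detected)))]))
  power <- colMeans(det)
  tp <- sum(vapply(scores, `[[`, numeric(1), "tp"))
  fp <- sum(vapply(scores, `[[`, numeric(1), "fp"))
  fdr <- if (tp + fp > 0) fp / (tp + fp) else NA_real_
  structure(list(
    power = data.frame(multiplier = as.numeric(colnames(det)), power = power,
                       row.names = NULL),
    fdr = fdr, tp = tp, fp = fp, n_iter = length(scores), meta = meta),
    class = "power_report")
}

#' @export
print.power_report <- function(x, ...) {
  hdr <- if (length(x$meta))
    paste(names(x$meta), unlist(x$meta), sep = "=", collapse = ", ") else ""
  cat(sprintf("power_report (%s): %d iterations, FDR = %s (TP=%d, FP=%d)\n",
              hdr, x$n_iter,
              if (is.na(x$fdr)) "NA" else sprintf("%.3f", x$fdr), x$tp, x$fp))
  print(x$power, row.names = FALSE)
  invisible(x)
}

#' @export
plot.power_report <- function(x, ...) {
  pw <- x$power[x$power$multiplier > 0, ]
  plot(pw$multiplier, pw$power, type = "b", pch = 19, ylim = c(0, 1),
       xlab = "effect size (liability SD per allele)",
       ylab = "power (detected iterations / total)", ...)
  invisible(x)
}
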