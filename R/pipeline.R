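#' Ascertain the standard marker panels from a simulated panel
#'
#' Runs the two-individual discovery step once and derives the requested
#' marker schemes from the shared candidate set: `"dense2kb"` and
#' `"uniform10kb"` via the uniform greedy walk, `"arraylike"` via permuted
#' array-like inter-marker distances (mean 13 kb).
#'
#' @param panel a `haplotype_panel`
#' @param arrays subset of `c("arraylike", "dense2kb", "uniform10kb")`
#' @param seed master seed (stage seeds derived from it)
#' @param spacing_sample optional distances for the array-like scheme
#' @return named list of `marker_panel` objects
#' @export
ascertain_arrays <- function(panel, arrays = c("arraylike", "dense2kb"),
                             seed = 1L, spacing_sample = NULL) {
  arrays <- match.arg(arrays, c("arraylike", "dense2kb", "uniform10kb"),
                      several.ok = TRUE)
  cand <- discover_candidates(panel, seed = derive_seed(seed, "discover"))
  out <- lapply(arrays, function(a) switch(a,
    dense2kb = select_uniform(cand, panel, 2000),
    uniform10kb = select_uniform(cand, panel, 10000),
    arraylike = select_array_like(cand, panel, spacing_sample,
                                  seed = derive_seed(seed, "arraylike"))))
  names(out) <- arrays
  attr(out, "candidates") <- cand
  out
}

default_thresholds <- c(arraylike = 5e-7, uniform10kb = 5e-7, dense2kb = 1e-7)

#' Run the full power/FDR simulation study on a panel
#'
#' For each iteration: draw a causal set and liability phenotypes, draw the
#' case/control study pool, build each requested cohort design, and for each
#' array scheme run the mixed-model GWAS, call significant loci and score them
#' against the causal set. Within-breed designs run on (up to) two breeds per
#' iteration, chosen among the breeds whose pool holds enough cases and
#' controls; every other design yields one cohort per iteration. All stage
#' seeds are derived from `seed`, making the study reproducible end to end.
#'
#' @param panel a `haplotype_panel`
#' @param markers named list of `marker_panel` objects ([ascertain_arrays()])
#' @param designs data.frame with columns `kind` and `n` (cases = controls)
#' @param n_iter number of phenotype iterations
#' @param seed master seed
#' @param h2,prevalence liability model parameters
#' @param maf_window causal-locus pooled-MAF window
#' @param pool_cases,pool_controls study pool sizes; `NULL` scales the
#'   reference pool (2,100 cases / 8,400 controls out of 15,000) to the panel
#' @param p_thresholds named per-array significance cutoffs (defaults: 5e-7,
#'   1e-7 for `dense2kb`)
#' @param test_maf GWAS MAF filter
#' @param verbose print per-iteration progress
#' @return an object of class `power_study`: list with `runs` (one row per
#'   GWAS run: tp, fp, lambda, n significant), `detections` (one row per run
#'   x causal locus), `reports` (named list of [aggregate_power()] reports per
#'   design/n/array), and the call parameters
#' @export
run_power_study <- function(panel, markers, designs, n_iter = 100L, seed = 1L,
                            h2 = 0.5, prevalence = 0.2,
                            maf_window = c(0.05, 0.10),
                            pool_cases = NULL, pool_controls = NULL,
                            p_thresholds = default_thresholds,
                            test_maf = 0.05, verbose = FALSE) {
  stopifnot(is.list(markers), !is.null(names(markers)),
            all(c("kind", "n") %in% names(designs)))
  N <- n_individuals(panel)
  if (is.null(pool_cases)) pool_cases <- round(2100 / 15000 * N)
  if (is.null(pool_controls)) pool_controls <- round(8400 / 15000 * N)

  runs <- list()
  detections <- list()
  scores <- list()  # keyed by design|n|array
  for (it in seq_len(n_iter)) {
    causal <- choose_causal_loci(panel, maf_window = maf_window,
                                 seed = derive_seed(seed, paste0("causal", it)))
    phenos <- simulate_liability(panel, causal, h2 = h2,
                                 prevalence = prevalence,
                                 seed = derive_seed(seed, paste0("liab", it)))
    pool <- draw_pool(phenos, pool_cases, pool_controls,
                      seed = derive_seed(seed, paste0("pool", it)))
    prev <- breed_prevalence(pool)
    # within-breed cohorts draw on the breed's full simulated population: a
    # 500-diploid breed cannot hold 200 cases plus 200 controls after the
    # 70% pool draw, so the pool constraint applies to across-breed designs
    full <- phenos[, c("individual", "pop", "status")]
    class(full) <- c("cohort_pool", "data.frame")
    prev_full <- breed_prevalence(full)
    for (di in seq_len(nrow(designs))) {
      kind <- as.character(designs$kind[di])
      n <- designs$n[di]
      cohorts <- list()
      if (kind == "within") {
        ok <- prev_full$pop[prev_full$cases >= n &
                              (prev_full$n - prev_full$cases) >= n]
        ok <- ok[order(-prev_full$cases[match(ok, prev_full$pop)], ok)]
        for (b in head(ok, 2L))
          cohorts[[b]] <- sample_design(full, "within", n, n, breed = b,
                                        seed = derive_seed(seed,
                                          paste0("coh", it, kind, n, b)))
      } else {
        cohorts[["all"]] <- sample_design(pool, kind, n, n, prevalences = prev,
                                          seed = derive_seed(seed,
                                            paste0("coh", it, kind, n)))
      }
      for (bname in names(cohorts)) {
        cohort <- cohorts[[bname]]
        for (a in names(markers)) {
          thr <- if (a %in% names(p_thresholds)) p_thresholds[[a]] else 5e-7
          mp <- markers[[a]]
          X <- panel_dosage(panel, sites = mp$sites,
                            individuals = cohort$individual)
          K <- compute_kinship(X, maf_min = 0.05)
          assoc <- lmm_gwas(X, cohort$status, K, positions = mp$pos,
                            chrom = mp$chrom, test_maf = test_maf)
          spec <- eval_spec(p_threshold = thr,
                            detection_window = if (kind == "within") 5e6 else 1e6)
          loci <- call_loci(assoc, spec)
          sc <- classify_and_score(loci, causal, spec)
          key <- paste(kind, n, a, sep = "|")
          scores[[key]] <- c(scores[[key]], list(sc))
          runs[[length(runs) + 1L]] <- data.frame(
            iter = it, design = kind, n = n, array = a, breed = bname,
            tp = sc$tp, fp = sc$fp, n_sig = nrow(loci),
            lambda = attr(assoc, "lambda"))
          detections[[length(detections) + 1L]] <- data.frame(
            iter = it, design = kind, n = n, array = a, breed = bname,
            multiplier = as.numeric(names(sc$detected)),
            detected = unname(sc$detected))
        }
      }
    }
    if (verbose)
      message("iteration ", it, "/", n_iter, " done")
  }
  runs <- do.call(rbind, runs)
  detections <- do.call(rbind, detections)
  reports <- lapply(names(scores), function(key) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    aggregate_power(scores[[key]],
                    meta = list(design = parts[1], n = as.numeric(parts[2]),
                                array = parts[3]))
  })
  names(reports) <- names(scores)
  structure(list(runs = runs, detections = detections, reports = reports,
                 n_iter = n_iter, seed = seed,
                 pool = c(cases = pool_cases, controls = pool_controls)),
            class = "power_study")
}

#' @export
print.power_study <- function(x, ...) {
  cat(sprintf("power_study: %d iterations, pool %d cases / %d controls\n",
              x$n_iter, x$pool["cases"], x$pool["controls"]))
  for (r in x$reports) print(r)
  invisible(x)
}

#' Power for one effect multiplier from a power study
#'
#' @param study a `power_study`
#' @param design,n,array run identifiers
#' @param multiplier effect multiplier (default 0.75)
#' @return detection rate over runs (numeric scalar, `NA` if absent)
#' @export
study_power <- function(study, design, n, array, multiplier = 0.75) {
  rep <- study$reports[[paste(design, n, array, sep = "|")]]
  if (is.null(rep)) return(NA_real_)
  pw <- rep$power
  out <- pw$power[abs(pw$multiplier - multiplier) < 1e-9]
  if (length(out)) out else NA_real_
}

#' False discovery rate from a power study
#'
#' @inheritParams study_power
#' @return pooled FDR over iterations (`NA` when nothing was significant)
#' @export
study_fdr <- function(study, design, n, array) {
  rep <- study$reports[[paste(design, n, array, sep = "|")]]
  if (is.null(rep)) NA_real_ else rep$fdr
}
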