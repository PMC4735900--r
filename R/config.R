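#' Derive a stage seed from a master seed
#'
#' Deterministic hash of the master seed and a stage name, so every stochastic
#' stage of a run draws from its own reproducible stream. Results stay below
#' 2^31.
#'
#' @param master integer master seed
#' @param stage character stage name (e.g. `"ascertain"`, `"iter3.liability"`)
#' @return integer seed
#' @export
derive_seed <- function(master, stage) {
  h <- 0
  for (ch in utf8ToInt(as.character(stage)[1]))
    h <- (h * 31 + ch) %% 2147483647
  as.integer(((as.numeric(master) %% 2147483647) * 69069 + h) %% 2147483647)
}

#' Assemble a reproducible run configuration
#'
#' Bundles every tunable of a simulation study (demography preset and
#' overrides, genome layout, sampling, array scheme, phenotype model, designs,
#' evaluation rule and the master seed) into one serializable object; see
#' [write_run_config()]. All stage seeds are derived from `seed` via
#' [derive_seed()], so a config reproduces a study byte-for-byte.
#'
#' @param seed master seed
#' @param genome named list of [genome_spec()] arguments
#' @param demography named list of [build_demography()] arguments
#' @param samples_per_pop diploids sampled per breed population
#' @param arrays character vector of array schemes to ascertain
#'   (`"arraylike"`, `"dense2kb"`, `"uniform10kb"`)
#' @param phenotype named list: `h2`, `prevalence`, `maf_window`
#' @param pool named list: `n_cases`, `n_controls` (`NULL` scales the study's
#'   2,100/8,400 pool to the simulated population size)
#' @param designs data.frame with columns `kind`, `n`
#' @param n_iter phenotype/GWAS iterations
#' @return an object of class `run_config`
#' @export
run_config <- function(seed = 1L,
                       genome = list(n_chromosomes = 38, chrom_length = 5e7),
                       demography = list(preset = "purebred30"),
                       samples_per_pop = 500,
                       arrays = c("arraylike", "dense2kb"),
                       phenotype = list(h2 = 0.5, prevalence = 0.2,
                                        maf_window = c(0.05, 0.10)),
                       pool = list(n_cases = NULL, n_controls = NULL),
                       designs = data.frame(kind = "random", n = 500),
                       n_iter = 100L) {
  structure(list(seed = as.integer(seed), genome = genome,
                 demography = demography, samples_per_pop = samples_per_pop,
                 arrays = arrays, phenotype = phenotype, pool = pool,
                 designs = designs, n_iter = as.integer(n_iter)),
            class = "run_config")
}

#' Write/read a run configuration as JSON
#'
#' The round trip is lossless for the fields of [run_config()].
#'
#' @param config a `run_config`
#' @param path JSON file path
#' @return `path` (write) or the `run_config` (read)
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$seed <- as.integer(x$seed)
  x$n_iter <- as.integer(x$n_iter)
  x$designs <- as.data.frame(x$designs)
  x$pool <- lapply(x$pool, function(v) if (is.null(v)) NULL else v)
  structure(x, class = "run_config")
}
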