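#' Genome layout for the fragment-based coalescent
#'
#' Describes the simulated genome: number of chromosomes, chromosome length,
#' the recombination fragment length (recombination occurs only at fragment
#' boundaries), per-bp mutation rate and per-boundary recombination
#' probability. The defaults are the dog-like genome used throughout:
#' 38 chromosomes of 50 Mb, mu = 1e-8 per bp per generation and rec = 1e-5
#' per fragment boundary per generation, which with 1 kb fragments is about
#' 1e-8 per bp (~1 cM/Mb).
#'
#' @param n_chromosomes number of independently simulated chromosomes
#' @param chrom_length chromosome length in bp; must be divisible by
#'   `fragment_length`
#' @param fragment_length recombination unit in bp
#' @param mu mutation rate per bp per generation
#' @param rec recombination probability per adjacent-fragment boundary per
#'   generation, in `[0, 0.5]`
#' @return an object of class `genome_spec`
#' @export
genome_spec <- function(n_chromosomes = 38, chrom_length = 5e7,
                        fragment_length = 1000, mu = 1e-8, rec = 1e-5) {
  stopifnot(n_chromosomes >= 1, chrom_length > 0, fragment_length > 0)
  if (chrom_length %% fragment_length != 0)
    stop("chrom_length must be divisible by fragment_length")
  if (mu < 0) stop("mu must be >= 0")
  if (rec < 0 || rec > 0.5) stop("rec must lie in [0, 0.5]")
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 chrom_length = chrom_length,
                 fragment_length = fragment_length, mu = mu, rec = rec),
            class = "genome_spec")
}

#' @export
print.genome_spec <- function(x, ...) {
  cat(sprintf("genome_spec: %d chromosome(s) x %g bp, fragment %g bp, mu=%g, rec=%g\n",
              x$n_chromosomes, x$chrom_length, x$fragment_length, x$mu, x$rec))
  invisible(x)
}

validate_epochs <- function(ep, id) {
  if (!is.matrix(ep) || ncol(ep) != 3)
    stop("epochs for population '", id, "' must be a matrix with columns t0, t1, Ne")
  if (any(ep[, 3] <= 0)) stop("population '", id, "' has non-positive Ne")
  if (any(ep[, 2] <= ep[, 1]))
    stop("population '", id, "' has an epoch with t1 <= t0")
  o <- order(ep[, 1])
  ep <- ep[o, , drop = FALSE]
  if (nrow(ep) > 1 && any(ep[-1, 1] < ep[-nrow(ep), 2]))
    stop("population '", id, "' has overlapping Ne epochs")
  ep
}

#' Build a demographic model
#'
#' The `"purebred30"` preset builds the dog demography used throughout: 30 breed
#' populations founded 200 generations ago from a village-dog population
#' (size 30,000), itself founded from a wolf population (size 15,000) 4,000
#' generations earlier after a 150-generation bottleneck (size 600). Breed
#' sizes are evenly spaced over \[250, 1,500\] and shuffled deterministically
#' by `seed`; every breed expands to 2,000 for the final four generations so
#' that 500 diploids (1,000 haplotypes) can be sampled per breed. Total depth
#' is 4,350 generations.
#'
#' Population sizes follow the convention of fragment-based whole-genome
#' coalescent simulators (the GENOME model): a size is the number of
#' *chromosomes* in the population — the parent pool a lineage draws from —
#' so a population of size N holds N/2 diploid individuals.
#'
#' For `preset = "custom"`, supply `populations` (data.frame with columns
#' `id` and `role` in wolf/village/breed), `epochs` (named list of matrices
#' with columns t0, t1, Ne; generations before present, half-open `[t0, t1)`)
#' and `splits` (data.frame with columns `daughter`, `parent`, `time`).
#'
#' @param preset `"purebred30"` or `"custom"`
#' @param seed integer seed controlling the breed Ne assignment
#' @param n_breeds number of breed populations for the purebred30 preset
#' @param breed_ne_range range of breed effective sizes
#' @param populations,epochs,splits custom model components (see Details)
#' @return an object of class `demography_model`
#' @export
build_demography <- function(preset = c("purebred30", "custom"), seed = 1L,
                             n_breeds = 30L,
                             breed_ne_range = c(250, 1500),
                             populations = NULL, epochs = NULL, splits = NULL) {
  preset <- match.arg(preset)
  if (preset == "purebred30") {
    n_breeds <- as.integer(n_breeds)
    ne_values <- round(seq(breed_ne_range[1], breed_ne_range[2],
                           length.out = n_breeds))
    set.seed(seed)
    ne_values <- sample(ne_values)
    ids <- c(sprintf("breed%02d", seq_len(n_breeds)), "village", "wolf")
    populations <- data.frame(
      id = ids,
      role = c(rep("breed", n_breeds), "village", "wolf"),
      stringsAsFactors = FALSE)
    epochs <- c(
      lapply(seq_len(n_breeds), function(i)
        rbind(c(0, 4, 2000), c(4, 200, ne_values[i]))),
      list(rbind(c(0, 4200, 30000), c(4200, 4350, 600))),
      list(rbind(c(0, Inf, 15000))))
    names(epochs) <- ids
    splits <- data.frame(
      daughter = c(sprintf("breed%02d", seq_len(n_breeds)), "village"),
      parent = c(rep("village", n_breeds), "wolf"),
      time = c(rep(200, n_breeds), 4350),
      stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(populations), all(c("id", "role") %in% names(populations)))
  if (anyDuplicated(populations$id)) stop("duplicate population ids")
  if (!all(populations$role %in% c("wolf", "village", "breed")))
    stop("population roles must be wolf, village or breed")
  epochs <- epochs[populations$id]
  if (any(vapply(epochs, is.null, logical(1))))
    stop("every population needs an epoch schedule")
  epochs <- Map(validate_epochs, epochs, populations$id)
  if (is.null(splits))
    splits <- data.frame(daughter = character(), parent = character(),
                         time = numeric(), stringsAsFactors = FALSE)
  if (nrow(splits)) {
    if (!all(splits$daughter %in% populations$id) ||
        !all(splits$parent %in% populations$id))
      stop("split events reference unknown populations")
    if (any(splits$time <= 0)) stop("split times must be positive")
    if (anyDuplicated(splits$daughter)) stop("a population can split only once")
    # every breed must split no later than its host village splits upstream
    for (i in seq_len(nrow(splits))) {
      d <- splits$daughter[i]; p <- splits$parent[i]
      j <- which(splits$daughter == p)
      if (length(j) && splits$time[i] >= splits$time[j])
        stop("population '", d, "' splits at or after its parent '", p,
             "' has itself merged upstream")
    }
  }
  structure(list(populations = populations, epochs = epochs, splits = splits),
            class = "demography_model")
}

#' @export
print.demography_model <- function(x, ...) {
  tab <- table(x$populations$role)
  cat("demography_model:", nrow(x$populations), "populations (",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      "),", nrow(x$splits), "split event(s)\n")
  if (nrow(x$splits))
    cat("  depth:", max(x$splits$time), "generations\n")
  invisible(x)
}

terminal_ne <- function(model, pop_id) {
  ep <- model$epochs[[pop_id]]
  ep[which.min(ep[, 1]), 3]
}

#' Simulate a haplotype panel under a demographic model
#'
#' Runs the fragment-based discrete-generation backward Wright-Fisher
#' coalescent: every lineage draws a parent chromosome uniformly among the
#' Ne(t) chromosomes of its current population each generation (population
#' sizes are chromosome counts; see [build_demography()]), with an
#' independent recombination event at each fragment boundary; lineages meeting
#' in the same parent chromosome coalesce, and daughter populations merge into
#' their parent at split times. Mutations are Poisson on branches
#' (infinite sites within a fragment). Only segregating sites are returned.
#' Deterministic given `seed`.
#'
#' @param model a `demography_model`
#' @param genome a `genome_spec`
#' @param samples_per_pop diploid individuals sampled per population: either a
#'   single count applied to every breed population, or a named vector keyed
#'   by population id (populations absent or 0 are unsampled)
#' @param seed integer seed
#' @param max_gen safety cap on simulated generations
#' @return an object of class `haplotype_panel`
#' @export
simulate_panel <- function(model, genome, samples_per_pop, seed = 1L,
                           max_gen = 5e6) {
  stopifnot(inherits(model, "demography_model"), inherits(genome, "genome_spec"))
  ids <- model$populations$id
  if (is.null(names(samples_per_pop))) {
    stopifnot(length(samples_per_pop) == 1)
    ns <- setNames(ifelse(model$populations$role == "breed",
                          as.integer(samples_per_pop), 0L), ids)
  } else {
    ns <- setNames(rep(0L, length(ids)), ids)
    ns[names(samples_per_pop)] <- as.integer(samples_per_pop)
  }
  if (sum(ns) < 1) stop("no individuals sampled")
  for (id in ids[ns > 0]) {
    if (2 * ns[[id]] > terminal_ne(model, id))
      stop("cannot sample ", ns[[id]], " diploids (", 2 * ns[[id]],
           " haplotypes) from population '", id, "' whose terminal size is ",
           terminal_ne(model, id), " chromosomes")
  }
  pop_index <- setNames(seq_along(ids) - 1L, ids)
  hap_pop <- rep(pop_index[ids], times = 2L * ns[ids])
  split_time <- rep(Inf, length(ids))
  split_parent <- rep(-1L, length(ids))
  if (nrow(model$splits)) {
    split_time[match(model$splits$daughter, ids)] <- model$splits$time
    split_parent[match(model$splits$daughter, ids)] <-
      pop_index[model$splits$parent]
  }
  set.seed(seed)
  raw <- .simulate_genome_cpp(as.integer(hap_pop), unname(model$epochs),
                              split_time, as.integer(split_parent),
                              genome$n_chromosomes, genome$chrom_length,
                              genome$fragment_length, genome$mu, genome$rec,
                              max_gen)
  hap_pop_id <- rep(ids, times = 2L * ns[ids])
  ind_pop_id <- rep(ids, times = ns[ids])
  structure(list(
    bits = raw$bits, n_hap = raw$n_hap, n_site = length(raw$pos),
    chrom = raw$chrom, pos = raw$pos, count = raw$count,
    hap_pop = hap_pop_id, ind_pop = ind_pop_id,
    pop_levels = ids[ns > 0], genome = genome, seed = seed),
    class = "haplotype_panel")
}
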