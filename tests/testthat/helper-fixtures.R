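# shared fixture cache (built once per test run) and small builders

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# build a haplotype_panel directly from a 0/1 haplotype matrix (rows =
# haplotypes, cols = sites); pop = population label per haplotype (pairs of
# consecutive haplotypes form individuals)
panel_from_matrix <- function(H, pos = seq_len(ncol(H)) * 1000,
                              chrom = rep(1L, ncol(H)), pop = NULL,
                              genome = genome_spec(1, 1e7, 1000)) {
  n_hap <- nrow(H)
  stopifnot(n_hap %% 2 == 0)
  if (is.null(pop)) pop <- rep("p1", n_hap)
  nbytes <- ceiling(n_hap / 8)
  bits <- as.raw(unlist(lapply(seq_len(ncol(H)), function(j) {
    v <- as.logical(c(H[, j], rep(0L, nbytes * 8 - n_hap)))
    packBits(v, "raw")
  })))
  structure(list(bits = bits, n_hap = n_hap, n_site = ncol(H),
                 chrom = as.integer(chrom), pos = as.numeric(pos),
                 count = as.integer(colSums(H)), hap_pop = pop,
                 ind_pop = pop[seq(1, n_hap, by = 2)],
                 pop_levels = unique(pop), genome = genome, seed = NA),
            class = "haplotype_panel")
}

single_deme_model <- function(ne) {
  build_demography("custom",
    populations = data.frame(id = "p1", role = "breed"),
    epochs = list(p1 = rbind(c(0, Inf, ne))))
}

two_deme_model <- function(ne = 2000, split = 400) {
  build_demography("custom",
    populations = data.frame(id = c("a", "b", "anc"),
                             role = c("breed", "breed", "village")),
    epochs = list(a = rbind(c(0, Inf, ne)), b = rbind(c(0, Inf, ne)),
                  anc = rbind(c(0, Inf, ne))),
    splits = data.frame(daughter = c("a", "b"), parent = "anc", time = split))
}

# the popgen-validation panel: the purebred30 demography on a reduced genome,
# 30 diploids per breed, with array-like ascertained markers
validation_panel <- function() memo("validation_panel", function() {
  model <- build_demography("purebred30", seed = 1)
  g <- genome_spec(n_chromosomes = 2, chrom_length = 1e7)
  panel <- simulate_panel(model, g, samples_per_pop = 30, seed = 11)
  markers <- ascertain_arrays(panel, arrays = c("arraylike", "dense2kb"),
                              seed = 5)
  list(panel = panel, markers = markers)
})

# the power-study panel: the purebred30 demography on a reduced genome (6 x 10 Mb)
# with the full per-breed sampling (500 diploids each, 15,000 individuals)
power_panel <- function() memo("power_panel", function() {
  model <- build_demography("purebred30", seed = 1)
  g <- genome_spec(n_chromosomes = 6, chrom_length = 1e7)
  panel <- simulate_panel(model, g, samples_per_pop = 500, seed = 11)
  markers <- ascertain_arrays(panel, arrays = c("arraylike", "dense2kb"),
                              seed = 5)
  list(panel = panel, markers = markers)
})

# study A: across-breed random design, 500 cases/controls, both arrays;
# study B: across-breed and within-breed at 200, array-like markers.
# Both share seeds, so iterations are paired across designs and arrays.
power_study_fixture <- function() memo("power_study", function() {
  px <- power_panel()
  list(
    A = run_power_study(px$panel, px$markers,
                        designs = data.frame(kind = "random", n = 500),
                        n_iter = 25, seed = 1),
    B = run_power_study(px$panel, px$markers["arraylike"],
                        designs = data.frame(kind = c("random", "within"),
                                             n = c(200, 200)),
                        n_iter = 25, seed = 1))
})
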