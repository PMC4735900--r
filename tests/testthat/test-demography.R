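test_that("genome_spec validates its invariants", {
  g <- genome_spec()
  expect_s3_class(g, "genome_spec")
  expect_equal(g$n_chromosomes, 38L)
  expect_equal(g$chrom_length, 5e7)
  expect_error(genome_spec(chrom_length = 1500, fragment_length = 1000),
               "divisible")
  expect_error(genome_spec(mu = -1e-8), "mu")
  expect_error(genome_spec(rec = 0.6), "rec")
  expect_error(genome_spec(n_chromosomes = 0))
})

test_that("purebred30 preset builds the full dog demography", {
  m <- build_demography("purebred30", seed = 1)
  expect_equal(nrow(m$populations), 32L)  # 30 breeds + village + wolf
  expect_equal(sum(m$populations$role == "breed"), 30L)
  expect_true(all(m$splits$time[m$splits$daughter != "village"] == 200))
  expect_equal(max(m$splits$time), 4350)  # total depth in generations
  breed_ne <- vapply(m$epochs[m$populations$role == "breed"],
                     function(e) e[e[, 1] == 4, 3], numeric(1))
  expect_true(all(breed_ne >= 250 & breed_ne <= 1500))
  terminal <- vapply(m$epochs[m$populations$role == "breed"],
                     function(e) e[e[, 1] == 0, 3], numeric(1))
  expect_true(all(terminal == 2000))
  vil <- m$epochs[["village"]]
  expect_equal(vil[vil[, 1] == 4200, 3], 600)  # 150-generation bottleneck
  # Ne assignment is deterministic given the seed
  m2 <- build_demography("purebred30", seed = 1)
  expect_identical(m$epochs, m2$epochs)
})

test_that("custom models are validated", {
  # single population, one constant epoch: valid degenerate model
  m <- single_deme_model(1000)
  expect_s3_class(m, "demography_model")
  expect_equal(nrow(m$splits), 0L)
  # non-overlapping breed epochs accepted, overlapping rejected
  ok <- build_demography("custom",
    populations = data.frame(id = "b", role = "breed"),
    epochs = list(b = rbind(c(0, 4, 2000), c(4, 200, 800), c(200, Inf, 1e4))))
  expect_s3_class(ok, "demography_model")
  expect_error(build_demography("custom",
    populations = data.frame(id = "b", role = "breed"),
    epochs = list(b = rbind(c(0, 4, 2000), c(3, 200, 800)))), "overlap")
  expect_error(build_demography("custom",
    populations = data.frame(id = "b", role = "breed"),
    epochs = list(b = rbind(c(0, Inf, -5)))), "Ne")
  # a breed may not split at/after its parent village has itself merged
  expect_error(build_demography("custom",
    populations = data.frame(id = c("b", "v", "w"),
                             role = c("breed", "village", "wolf")),
    epochs = list(b = rbind(c(0, Inf, 500)), v = rbind(c(0, Inf, 3e4)),
                  w = rbind(c(0, Inf, 1.5e4))),
    splits = data.frame(daughter = c("b", "v"), parent = c("v", "w"),
                        time = c(500, 400))), "splits at or after")
})

test_that("sampling more than a population holds is rejected", {
  m <- single_deme_model(100)  # 100 chromosomes = 50 diploids
  g <- genome_spec(1, 1e5, 1000, mu = 1e-8, rec = 0)
  expect_error(simulate_panel(m, g, samples_per_pop = c(p1 = 60)),
               "cannot sample")
  expect_silent(p <- simulate_panel(m, g, samples_per_pop = c(p1 = 50),
                                    seed = 1))
})

test_that("no mutation means no segregating sites", {
  m <- single_deme_model(1000)
  g <- genome_spec(1, 1e5, 1000, mu = 0, rec = 0)
  p <- simulate_panel(m, g, samples_per_pop = c(p1 = 1), seed = 3)
  expect_equal(p$n_site, 0L)
  expect_equal(p$n_hap, 2L)
})

test_that("panel output satisfies its structural invariants", {
  m <- single_deme_model(2000)
  g <- genome_spec(2, 2e5, 1000, mu = 1e-8, rec = 1e-5)
  p <- simulate_panel(m, g, samples_per_pop = c(p1 = 20), seed = 5)
  expect_gt(p$n_site, 0)
  # every site segregating, positions strictly increasing per chromosome,
  # and packed bits consistent with the reported derived counts
  expect_true(all(p$count > 0 & p$count < p$n_hap))
  for (ch in unique(p$chrom))
    expect_false(is.unsorted(p$pos[p$chrom == ch], strictly = TRUE))
  H <- panel_haplotypes(p)
  expect_equal(colSums(H), p$count)
  # diploid dosage is the sum of the two haplotypes of each individual
  D <- panel_dosage(p)
  expect_equal(D, H[seq(1, p$n_hap, 2), ] + H[seq(2, p$n_hap, 2), ])
})

test_that("simulation is deterministic given the seed", {
  m <- two_deme_model()
  g <- genome_spec(1, 2e5, 1000)
  p1 <- simulate_panel(m, g, samples_per_pop = c(a = 10, b = 10), seed = 77)
  p2 <- simulate_panel(m, g, samples_per_pop = c(a = 10, b = 10), seed = 77)
  expect_identical(p1$bits, p2$bits)
  expect_identical(p1$pos, p2$pos)
  p3 <- simulate_panel(m, g, samples_per_pop = c(a = 10, b = 10), seed = 78)
  expect_false(identical(p1$pos, p3$pos))
})

test_that("single-deme diversity matches the neutral coalescent expectation", {
  # 2,000 chromosomes (1,000 diploids), mu = 1e-8, L = 100 kb:
  # E[pairwise difference] = 2 N mu L = 4.0
  m <- single_deme_model(2000)
  g <- genome_spec(1, 1e5, 1000, mu = 1e-8, rec = 0)
  divs <- vapply(1:120, function(s)
    mean_pairwise_diversity(simulate_panel(m, g, samples_per_pop = c(p1 = 25),
                                           seed = s)), numeric(1))
  # MC sd of a single replicate is ~1.7; 3 SEs around the target
  expect_lt(abs(mean(divs) - 4.0), 3 * sd(divs) / sqrt(length(divs)))
})

test_that("single-deme SFS is proportional to 1/i", {
  m <- single_deme_model(2000)
  g <- genome_spec(1, 2e5, 1000, mu = 1e-8, rec = 0)
  set.seed(99)
  cnt <- integer(0)
  # one site per replicate tree: independent draws from the SFS
  for (s in 1:500) {
    p <- simulate_panel(m, g, samples_per_pop = c(p1 = 10), seed = s)
    if (p$n_site) cnt <- c(cnt, p$count[sample.int(p$n_site, 1)])
  }
  sfs <- tabulate(cnt, 19)
  expect_gt(length(cnt), 400)
  pval <- chisq.test(sfs, p = (1 / 1:19) / sum(1 / 1:19))$p.value
  expect_gt(pval, 0.01)
})

test_that("no four-gamete violations without recombination", {
  m <- single_deme_model(2000)
  g <- genome_spec(1, 2e5, 1000, mu = 1e-8, rec = 0)
  p <- simulate_panel(m, g, samples_per_pop = c(p1 = 25), seed = 42)
  H <- panel_haplotypes(p)
  S <- ncol(H)
  viol <- 0L
  for (i in seq_len(S - 1)) for (j in (i + 1):S) {
    if (length(unique(paste(H[, i], H[, j]))) == 4L) viol <- viol + 1L
  }
  expect_identical(viol, 0L)
})

test_that("two-deme FST matches an independent coalescent simulator", {
  # Frozen oracle: msprime 1.4.2, 2 demes of 1,000 diploids (2,000
  # chromosomes here), split 400 generations, 1 Mb, mu = r = 1e-8/bp,
  # 25 diploids sampled per deme, 200 replicates:
  # Weir-Cockerham weighted FST mean 0.16908 (replicate sd 0.0617, se 0.0044)
  oracle_mean <- 0.16908
  oracle_se <- 0.00437
  m <- two_deme_model(ne = 2000, split = 400)
  g <- genome_spec(1, 1e6, 1000, mu = 1e-8, rec = 1e-5)
  fsts <- vapply(1:30, function(s) {
    p <- simulate_panel(m, g, samples_per_pop = c(a = 25, b = 25), seed = s)
    weighted_fst(panel_dosage(p), p$ind_pop)$weighted
  }, numeric(1))
  se <- sqrt(sd(fsts)^2 / length(fsts) + oracle_se^2)
  expect_lt(abs(mean(fsts) - oracle_mean), 3 * se)
})
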