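make_freq_panel <- function(n_ind, freqs, seed = 1) {
  # haplotypes drawn independently at the given derived-allele frequencies
  set.seed(seed)
  H <- vapply(freqs, function(f) rbinom(2 * n_ind, 1, f), numeric(2 * n_ind))
  panel_from_matrix(H, pos = seq_along(freqs) * 1e5,
                    pop = rep("p1", 2 * n_ind))
}

test_that("causal loci come from the pooled MAF window", {
  p <- make_freq_panel(2000, c(0.07, 0.3, 0.08, 0.06, 0.09, 0.065, 0.075, 0.5))
  cs <- choose_causal_loci(p, seed = 3)
  expect_equal(nrow(cs), 6L)
  expect_true(all(cs$maf >= 0.05 & cs$maf <= 0.10))
  expect_setequal(cs$multiplier, c(0, 0.25, 0.5, 0.75, 1, 1.25))
  expect_equal(sum(cs$multiplier == 0), 1L)
  # every site outside the window: error
  p2 <- make_freq_panel(500, rep(0.3, 10))
  expect_error(choose_causal_loci(p2), "MAF window")
  # exactly six eligible sites: forced choice
  p3 <- make_freq_panel(2000, rep(0.075, 6), seed = 5)
  cs3 <- choose_causal_loci(p3, seed = 9)
  expect_setequal(cs3$site, 1:6)
})

test_that("multiplier assignment is a uniform seeded permutation", {
  p <- make_freq_panel(2000, rep(0.075, 6), seed = 5)
  first <- vapply(1:200, function(s)
    choose_causal_loci(p, seed = s)$multiplier[1], numeric(1))
  counts <- table(factor(first, levels = c(0, 0.25, 0.5, 0.75, 1, 1.25)))
  expect_gt(chisq.test(counts)$p.value, 0.01)
})

test_that("liability simulation hits the prevalence and heritability targets", {
  p <- make_freq_panel(3000, rep(0.075, 6), seed = 5)
  cs <- choose_causal_loci(p, seed = 2)
  ph <- simulate_liability(p, cs, h2 = 0.5, prevalence = 0.2, seed = 7)
  expect_equal(mean(ph$status), 0.2, tolerance = 0.01)
  expect_equal(sd(ph$liability), 1)
  # construction sets Ve = Vg (1 - h2)/h2, so the realized ratio is exact
  expect_equal(attr(ph, "realized_h2"), 0.5, tolerance = 1e-9)
  # with all six loci at MAF 0.075 the closed-form genetic variance is
  # sum(2 p q m^2) = 2 * 0.075 * 0.925 * 3.4375 = 0.477 in multiplier units
  X <- panel_dosage(p, sites = cs$site)
  g <- drop(X %*% cs$multiplier)
  expect_equal(var(g), 0.477, tolerance = 0.05)
  # narrow-sense heritability of the returned (standardized) liability
  gl <- cor(g, ph$liability)^2
  expect_gt(gl, 0.45)
  expect_lt(gl, 0.55)
  expect_error(simulate_liability(p, cs, h2 = 0), "h2")
  expect_error(simulate_liability(p, cs, prevalence = 1), "prevalence")
})

test_that("an all-null causal set gives genotype-independent status", {
  p <- make_freq_panel(1000, rep(0.075, 6), seed = 8)
  cs <- choose_causal_loci(p, seed = 2)
  cs$multiplier <- rep(0, 6)
  pvals <- vapply(1:40, function(s) {
    ph <- simulate_liability(p, cs, seed = s)
    X <- panel_dosage(p, sites = cs$site[1])
    suppressWarnings(chisq.test(table(drop(X), ph$status))$p.value)
  }, numeric(1))
  # uniform P-values under the null: no excess below 0.05
  expect_lt(mean(pvals < 0.05), 0.2)
  ph <- simulate_liability(p, cs, seed = 1)
  expect_equal(attr(ph, "realized_h2"), 0)
})

test_that("risk alleles are enriched in cases, ordered by effect size", {
  p <- make_freq_panel(3000, rep(0.075, 6), seed = 5)
  cs <- choose_causal_loci(p, seed = 2)
  diffs <- matrix(0, 10, 6)
  for (s in 1:10) {
    ph <- simulate_liability(p, cs, seed = s)
    X <- panel_dosage(p, sites = cs$site)
    diffs[s, ] <- colMeans(X[ph$status == 1, , drop = FALSE]) / 2 -
      colMeans(X[ph$status == 0, , drop = FALSE]) / 2
  }
  md <- colMeans(diffs)
  o <- order(cs$multiplier)
  expect_true(all(diff(md[o]) > -0.005))      # monotone up to noise
  expect_gt(md[which.max(cs$multiplier)], 0)  # largest effect clearly positive
  expect_lt(abs(md[which(cs$multiplier == 0)]), 0.01)
})

test_that("draw_pool enforces availability and keeps labels", {
  p <- make_freq_panel(500, rep(0.075, 6), seed = 5)
  cs <- choose_causal_loci(p, seed = 2)
  ph <- simulate_liability(p, cs, seed = 3)
  n_cases <- sum(ph$status)
  expect_error(draw_pool(ph, n_cases + 1, 10), "cases")
  expect_error(draw_pool(ph, 0, nrow(ph)), "controls")
  pool <- draw_pool(ph, 0, 10, seed = 1)
  expect_equal(nrow(pool), 10L)
  expect_true(all(pool$status == 0L))
  pool2 <- draw_pool(ph, 50, 100, seed = 1)
  expect_equal(sum(pool2$status), 50L)
  expect_true(all(pool2$pop %in% ph$pop))
  expect_false(anyDuplicated(pool2$individual) > 0)
})

test_that("the study phenotype preset meets prevalence and h2 on simulated genomes", {
  v <- validation_panel()
  panel <- v$panel
  h2s <- prevs <- numeric(5)
  for (s in 1:5) {
    cs <- choose_causal_loci(panel, seed = s)
    ph <- simulate_liability(panel, cs, h2 = 0.5, prevalence = 0.2, seed = s)
    prevs[s] <- mean(ph$status)
    X <- panel_dosage(panel, sites = cs$site)
    g <- drop(X %*% cs$multiplier)
    h2s[s] <- cor(g, ph$liability)^2
  }
  expect_true(all(abs(prevs - 0.2) < 0.005))
  expect_true(all(h2s > 0.45 & h2s < 0.55))
})
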