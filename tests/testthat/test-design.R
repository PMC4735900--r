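toy_pool <- function(breeds, cases_per, controls_per) {
  pop <- rep(breeds, times = cases_per + controls_per)
  status <- unlist(Map(function(ca, co) c(rep(1L, ca), rep(0L, co)),
                       cases_per, controls_per))
  out <- data.frame(individual = seq_along(pop), pop = pop, status = status)
  class(out) <- c("cohort_pool", "data.frame")
  out
}

test_that("breed prevalence is cases over individuals per breed", {
  pool <- toy_pool(c("a", "b"), c(2, 0), c(8, 10))
  prev <- breed_prevalence(pool)
  expect_equal(prev$prevalence[prev$pop == "a"], 0.2)
  expect_equal(prev$prevalence[prev$pop == "b"], 0)
  expect_error(breed_prevalence(pool[0, ]), "empty")
})

test_that("largest-remainder apportionment conserves totals", {
  lr <- breedsim:::largest_remainder
  expect_equal(lr(c(0.1, 0.3), 40), c(10L, 30L))
  expect_equal(sum(lr(runif(7), 123)), 123)
  expect_equal(lr(rep(1, 30), 300), rep(10L, 30))
})

test_that("balanced design takes equal numbers from every breed", {
  pool <- toy_pool(sprintf("b%02d", 1:30), rep(20, 30), rep(40, 30))
  coh <- sample_design(pool, "balanced", 300, 300, seed = 1)
  tab <- table(coh$pop, coh$status)
  expect_true(all(tab[, "1"] == 10))
  expect_true(all(tab[, "0"] == 10))
  # identical per-breed composition across seeds, up to individual identity
  coh2 <- sample_design(pool, "balanced", 300, 300, seed = 99)
  expect_equal(table(coh2$pop, coh2$status), tab)
  expect_false(identical(sort(coh$individual), sort(coh2$individual)))
})

test_that("random design ignores breed and meets its counts", {
  pool <- toy_pool(sprintf("b%02d", 1:30), rep(20, 30), rep(40, 30))
  coh <- sample_design(pool, "random", 100, 100, seed = 4)
  expect_equal(sum(coh$status == 1), 100L)
  expect_equal(sum(coh$status == 0), 100L)
  expect_false(anyDuplicated(coh$individual) > 0)
})

test_that("unbalanced design scales cases and controls by prevalence", {
  pool <- toy_pool(c("a", "b"), c(20, 60), c(180, 140))
  prev <- breed_prevalence(pool)  # 0.1 and 0.3
  coh <- sample_design(pool, "unbalanced", 40, 40, prevalences = prev,
                       n_breeds_used = 2, seed = 1)
  tab <- table(coh$pop, coh$status)
  expect_equal(unname(tab["a", "1"]), 10)   # 40 * 0.1/0.4
  expect_equal(unname(tab["b", "1"]), 30)   # 40 * 0.3/0.4
  expect_equal(tab[, "0"], tab[, "1"])      # equal controls per breed
  expect_error(sample_design(pool, "unbalanced", 40, 30, prevalences = prev),
               "n_cases == n_controls")
})

test_that("semibalanced design scales only cases by prevalence", {
  pool <- toy_pool(c("a", "b"), c(20, 60), c(180, 140))
  prev <- breed_prevalence(pool)
  coh <- sample_design(pool, "semibalanced", 40, 40, prevalences = prev,
                       n_breeds_used = 2, seed = 1)
  tab <- table(coh$pop, coh$status)
  expect_equal(unname(tab["a", "1"]), 10)
  expect_equal(unname(tab["b", "1"]), 30)
  expect_equal(unname(tab["a", "0"]), 20)   # controls split equally
  expect_equal(unname(tab["b", "0"]), 20)
})

test_that("semibalanced and unbalanced use the highest-prevalence breeds", {
  pool <- toy_pool(c("lo", "mid", "hi"), c(5, 30, 60), c(95, 70, 40))
  prev <- breed_prevalence(pool)
  coh <- sample_design(pool, "semibalanced", 30, 30, prevalences = prev,
                       n_breeds_used = 2, seed = 2)
  expect_setequal(unique(coh$pop), c("mid", "hi"))
})

test_that("within design stays inside one breed and reports shortfalls", {
  pool <- toy_pool(c("a", "b"), c(80, 150), c(200, 150))
  coh <- sample_design(pool, "within", 100, 100, breed = "b", seed = 3)
  expect_true(all(coh$pop == "b"))
  expect_equal(sum(coh$status == 1), 100L)
  expect_error(sample_design(pool, "within", 100, 100, breed = "a"),
               "shortfall 20")
  # default breed choice requires both quotas
  coh2 <- sample_design(pool, "within", 100, 100, seed = 3)
  expect_true(all(coh2$pop == "b"))
  expect_error(sample_design(pool, "within", 200, 200), "no breed holds")
})

test_that("every design conserves its case and control counts", {
  pool <- toy_pool(sprintf("b%02d", 1:30), rep(30, 30), rep(60, 30))
  prev <- breed_prevalence(pool)
  for (kind in c("balanced", "random", "semibalanced", "unbalanced")) {
    coh <- sample_design(pool, kind, 200, 200, prevalences = prev, seed = 7)
    expect_equal(sum(coh$status == 1), 200L, info = kind)
    expect_equal(sum(coh$status == 0), 200L, info = kind)
    expect_false(anyDuplicated(coh$individual) > 0, info = kind)
  }
})
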