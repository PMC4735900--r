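# seeded two-deme-structured dataset for the oracle comparisons
lmm_dataset <- function(n = 60, m = 50, seed = 314) {
  set.seed(seed)
  deme <- rep(0:1, each = n / 2)
  f1 <- runif(m, 0.1, 0.9)
  f2 <- pmin(pmax(f1 + rnorm(m, 0, 0.2), 0.05), 0.95)
  X <- t(vapply(deme, function(d)
    rbinom(m, 2, if (d == 0) f1 else f2), numeric(m)))
  y <- 0.5 * deme + X[, 1] * 0.4 + rnorm(n)
  list(X = X, y = y)
}

# independent GLS oracle: grid-search delta over 2,001 log-spaced points
# (plus one local grid refinement), direct solve of the mixed-model normal
# equations at each grid point
gls_grid_oracle <- function(X, y, K, j, grid_n = 2001) {
  n <- length(y)
  C <- cbind(1, X[, j])
  best <- list(crit = Inf)
  for (ld in seq(-10, 10, length.out = grid_n)) {
    H <- K + exp(ld) * diag(n)
    cH <- tryCatch(chol(H), error = function(e) NULL)
    if (is.null(cH)) next
    Hi_C <- backsolve(cH, forwardsolve(t(cH), C))
    Hi_y <- backsolve(cH, forwardsolve(t(cH), y))
    A <- crossprod(C, Hi_C)
    beta <- solve(A, crossprod(C, Hi_y))
    R <- drop(crossprod(y, Hi_y) - crossprod(beta, crossprod(C, Hi_y)))
    crit <- (n - 2) * log(R) + 2 * sum(log(diag(cH))) + determinant(A)$modulus
    if (crit < best$crit) {
      sg2 <- R / (n - 2)
      Ai <- solve(A)
      best <- list(crit = crit, beta = beta[2],
                   se = sqrt(sg2 * Ai[2, 2]), logdelta = ld)
    }
  }
  best$chi2 <- (best$beta / best$se)^2
  best$p <- pchisq(best$chi2, 1, lower.tail = FALSE)
  best
}

gls_oracle_refined <- function(X, y, K, j) {
  o1 <- gls_grid_oracle(X, y, K, j)
  step <- 20 / 2000
  # refine on a 401-point grid spanning one coarse step around the optimum
  C <- cbind(1, X[, j])
  best <- o1
  for (ld in seq(o1$logdelta - step, o1$logdelta + step, length.out = 401)) {
    H <- K + exp(ld) * diag(length(y))
    cH <- tryCatch(chol(H), error = function(e) NULL)
    if (is.null(cH)) next
    Hi_C <- backsolve(cH, forwardsolve(t(cH), C))
    Hi_y <- backsolve(cH, forwardsolve(t(cH), y))
    A <- crossprod(C, Hi_C)
    beta <- solve(A, crossprod(C, Hi_y))
    R <- drop(crossprod(y, Hi_y) - crossprod(beta, crossprod(C, Hi_y)))
    crit <- (length(y) - 2) * log(R) + 2 * sum(log(diag(cH))) +
      determinant(A)$modulus
    if (crit < best$crit) {
      sg2 <- R / (length(y) - 2)
      Ai <- solve(A)
      best <- list(crit = crit, beta = beta[2],
                   se = sqrt(sg2 * Ai[2, 2]), logdelta = ld)
    }
  }
  best$chi2 <- (best$beta / best$se)^2
  best$p <- pchisq(best$chi2, 1, lower.tail = FALSE)
  best
}

test_that("kinship matrix follows the centered ZZ'/p definition", {
  set.seed(21)
  X <- matrix(rbinom(200 * 1000, 2, 0.3), 200, 1000)
  G <- compute_kinship(X, maf_min = 0.05)
  # mean diagonal ~ 2 p q = 0.42; brute-force matrix product oracle
  expect_equal(mean(diag(G)), 0.42, tolerance = 0.02)
  Z <- sweep(X, 2, colMeans(X))
  expect_equal(unclass(G), Z %*% t(Z) / ncol(X), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_true(isSymmetric(G))
  expect_gt(min(eigen(G, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  # identical individuals are maximally related
  X2 <- rbind(X[1, ], X[1, ], X[2:6, ])
  G2 <- compute_kinship(X2)
  expect_equal(G2[1, 2], G2[1, 1])
  # markers at MAF <= 0.05 are excluded
  X3 <- cbind(rep(c(0, 1), c(96, 4)), matrix(rbinom(100 * 50, 2, 0.4), 100))
  expect_false(1 %in% attr(compute_kinship(X3), "markers_used"))
  expect_error(compute_kinship(matrix(0, 10, 3)), "MAF")
})

test_that("with identity kinship the LMM reduces to ordinary least squares", {
  d <- lmm_dataset()
  res <- lmm_gwas(d$X, d$y, diag(length(d$y)))
  for (j in c(1, 7, 23)) {
    fit <- summary(lm(d$y ~ d$X[, j]))$coefficients
    expect_equal(res$beta[j], fit[2, 1], tolerance = 1e-6)
    expect_equal(res$se[j], fit[2, 2], tolerance = 1e-6)
    expect_equal(res$p[j],
                 pchisq((fit[2, 1] / fit[2, 2])^2, 1, lower.tail = FALSE),
                 tolerance = 1e-6)
  }
})

test_that("LMM matches the brute-force delta-grid GLS oracle", {
  d <- lmm_dataset()
  K <- compute_kinship(d$X)
  res <- lmm_gwas(d$X, d$y, K, test_maf = 0)
  for (j in c(1, 5, 19, 33)) {
    o <- gls_oracle_refined(d$X, d$y, K, j)
    # agreement to 4 significant figures
    expect_equal(res$beta[j], o$beta, tolerance = 5e-4)
    expect_equal(res$se[j], o$se, tolerance = 5e-4)
    expect_equal(res$p[j], o$p, tolerance = 1e-3)
  }
})

test_that("monomorphic markers are reported untested, not NaN", {
  d <- lmm_dataset()
  X <- cbind(d$X, 0L)
  res <- lmm_gwas(X, d$y, compute_kinship(d$X), test_maf = 0)
  last <- nrow(res)
  expect_false(res$tested[last])
  expect_true(is.na(res$p[last]))
  expect_false(anyNA(res$p[res$tested]))
  expect_true(all(res$p[res$tested] > 0 & res$p[res$tested] <= 1))
  expect_equal(res$chi2[res$tested], (res$beta / res$se)[res$tested]^2)
})

test_that("markers below the test MAF are skipped", {
  d <- lmm_dataset()
  maf <- pmin(colMeans(d$X) / 2, 1 - colMeans(d$X) / 2)
  res <- lmm_gwas(d$X, d$y, diag(length(d$y)), test_maf = 0.3)
  expect_true(all(!res$tested[maf < 0.3]))
  expect_true(all(res$tested[maf >= 0.3]))
})

test_that("inflation factor is the median statistic over the chi-square median", {
  expect_equal(inflation_factor(rep(0.4549364, 10)), 1.0, tolerance = 1e-6)
  set.seed(5)
  x <- rchisq(10000, 1)
  expect_equal(inflation_factor(x), 1.0, tolerance = 0.05)
  expect_equal(inflation_factor(2 * x), 2 * inflation_factor(x))
  expect_equal(inflation_factor(pchisq(x, 1, lower.tail = FALSE), type = "p"),
               inflation_factor(x))
  expect_error(inflation_factor(numeric(0)), "finite")
})

test_that("lambda is near 1 for permuted phenotypes under structure", {
  set.seed(88)
  n <- 120
  deme <- rep(0:1, each = n / 2)
  f <- cbind(runif(300, 0.1, 0.9), runif(300, 0.1, 0.9))
  X <- t(vapply(deme, function(d) rbinom(300, 2, f[, d + 1]), numeric(300)))
  y0 <- rnorm(n) + deme  # structured trait
  K <- compute_kinship(X)
  lambdas <- vapply(1:30, function(s) {
    set.seed(1000 + s)
    attr(lmm_gwas(X, sample(y0), K), "lambda")
  }, numeric(1))
  expect_gt(mean(lambdas), 0.9)
  expect_lt(mean(lambdas), 1.1)
})

test_that("type-I error is nominal on null phenotypes with kinship correction", {
  v <- validation_panel()
  panel <- v$panel
  mp <- v$markers$arraylike
  set.seed(3)
  ids <- sample(n_individuals(panel), 300)
  X <- panel_dosage(panel, sites = mp$sites, individuals = ids)
  K <- compute_kinship(X)
  y <- rnorm(300)  # h2 = 0 trait
  res <- lmm_gwas(X, y, K)
  frac <- mean(res$p[res$tested] < 0.05)
  ntest <- sum(res$tested)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / ntest) + 0.01)
  expect_gt(attr(res, "lambda"), 0.9)
  expect_lt(attr(res, "lambda"), 1.1)
})

test_that("LD pruning reproduces the toy retention counts", {
  set.seed(11)
  base <- matrix(rbinom(200 * 6, 2, 0.5), 200, 6)
  # mutually independent markers: nothing pruned
  thr <- pruned_bonferroni(base)
  expect_equal(attr(thr, "n_retained"), 6L)
  expect_equal(as.numeric(thr), 0.05 / 6)
  # two perfectly duplicated markers among m: one pruned
  dup <- cbind(base, base[, 1])
  thr2 <- pruned_bonferroni(dup)
  expect_equal(attr(thr2, "n_retained"), 6L)
  expect_equal(as.numeric(thr2), 0.05 / 6)
  # a perfectly correlated triple among 6 markers: 2 pruned, threshold 0.0125
  trip <- cbind(base[, 1], base[, 1], base[, 1], base[, 2:4])
  thr3 <- pruned_bonferroni(trip)
  expect_equal(attr(thr3, "n_retained"), 4L)
  expect_equal(as.numeric(thr3), 0.0125)
})
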