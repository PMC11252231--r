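test_that("Kaiser retention finds the planted dimensionality", {
  # three latent sources, small noise: exactly 3 retained components
  g <- generate_mixing(n_sites = 129, k_sources = 3, noise_cv = 0.05,
                       seed = 101)
  fit <- suppressWarnings(fit_pca_varimax(g$table))
  expect_equal(ncol(fit$loadings), 3)
  expect_gt(sum(fit$variance_explained), 75)
  # a single dominant factor: one component, sign-fixed positive
  g1 <- generate_mixing(n_sites = 80, k_sources = 1, noise_cv = 0.05,
                        seed = 102)
  fit1 <- suppressWarnings(fit_pca_varimax(g1$table))
  expect_equal(ncol(fit1$loadings), 1)
  expect_gt(fit1$loadings[which.max(abs(fit1$loadings[, 1])), 1], 0)
})

test_that("rotated loadings agree with a pairwise-Jacobi varimax oracle", {
  g <- generate_mixing(seed = 103)
  m <- te_matrix(g$table)
  R <- cor(m)
  e <- eigen(R, symmetric = TRUE)
  A <- e$vectors[, 1:3] %*% diag(sqrt(e$values[1:3]))
  fit <- suppressWarnings(fit_pca_varimax(g$table))
  oracle <- oracle_varimax(A)
  aligned <- align_loadings(oracle, fit$loadings)
  expect_lt(max(abs(aligned - unclass(fit$loadings))), 1e-6)
  # same varimax criterion value at the optimum
  expect_equal(varimax_criterion(unclass(fit$loadings)),
               varimax_criterion(oracle), tolerance = 1e-10)
})

test_that("regression-method scores have exact zero mean and unit variance", {
  g <- generate_mixing(seed = 104)
  fit <- suppressWarnings(fit_pca_varimax(g$table))
  expect_equal(unname(colMeans(fit$scores)), rep(0, 3), tolerance = 1e-10)
  expect_equal(unname(apply(fit$scores, 2, sd)), rep(1, 3),
               tolerance = 1e-10)
})

test_that("absolute scores shift by the zero-concentration sample's score", {
  g <- generate_mixing(seed = 105)
  fit <- suppressWarnings(fit_pca_varimax(g$table))
  apcs <- absolute_scores(fit)
  s0 <- drop((-fit$means / fit$sds) %*% fit$weights)
  expect_equal(apcs, sweep(fit$scores, 2, s0), tolerance = 1e-12)
  # between-site differences are unchanged by the shift
  expect_equal(apcs[2, ] - apcs[1, ], fit$scores[2, ] - fit$scores[1, ],
               tolerance = 1e-12)
  # single-source data: APCS tracks the true source strength
  g1 <- generate_mixing(n_sites = 100, k_sources = 1, noise_cv = 0.02,
                        seed = 106)
  fit1 <- suppressWarnings(fit_pca_varimax(g1$table))
  apcs1 <- absolute_scores(fit1)
  expect_gt(cor(apcs1[, 1], g1$truth$strengths[, 1]), 0.99)
})

test_that("element regressions satisfy the OLS identities", {
  g <- generate_mixing(seed = 107)
  fit <- suppressWarnings(fit_pca_varimax(g$table))
  apcs <- absolute_scores(fit)
  # exact linear response: r2 = 1, zero residuals
  y <- drop(2 + apcs %*% c(3, -1, 0.5))
  reg <- regress_element(y, apcs)
  expect_equal(reg$r2, 1, tolerance = 1e-12)
  expect_equal(reg$fitted, y, tolerance = 1e-9)
  expect_equal(unname(reg$coef), c(3, -1, 0.5), tolerance = 1e-9)
  # independent noise: r2 near zero across seeds
  r2s <- vapply(1:10, function(s) {
    set.seed(s)
    regress_element(rnorm(nrow(apcs)), apcs)$r2
  }, numeric(1))
  expect_lt(mean(r2s), 0.05)
  expect_error(regress_element(y, cbind(apcs, apcs[, 1])), "degenerate")
})

test_that("M/P equals 1 for every element on any input", {
  for (s in c(108, 109)) {
    g <- generate_mixing(seed = s)
    fit <- suppressWarnings(apcs_mlr(g$table))
    expect_lt(max(abs(fit$summary$mp_ratio - 1)), 1e-9)
    expect_equal(unname(rowSums(fit$contribution_pct)),
                 rep(100, 10), tolerance = 1e-9)
    expect_equal(sum(fit$mean_contribution_pct), 100, tolerance = 1e-9)
  }
})

test_that("contribution normalization takes absolute values", {
  # raw contributions {+3, -1} -> {75%, 25%}
  apcs <- cbind(a = rep(2, 10), b = rep(0.5, 10)) +
    matrix(rnorm(20, 0, 1e-9), 10, 2)
  pct <- source_contributions(c(a = 3 / 2, b = -1 / 0.5), apcs)
  expect_equal(unname(pct), c(75, 25), tolerance = 1e-6)
  expect_error(source_contributions(c(0, 0), apcs), "all-zero")
  # identical rows average to themselves; disjoint rows average evenly
  expect_equal(unname(mean_source_contributions(rbind(c(40, 60), c(40, 60)))),
               c(40, 60))
  expect_equal(unname(mean_source_contributions(rbind(c(100, 0), c(0, 100)))),
               c(50, 50))
})

test_that("fit is invariant to row permutation and element rescaling", {
  g <- generate_mixing(seed = 110)
  fit <- suppressWarnings(apcs_mlr(g$table))
  set.seed(1)
  tab2 <- as_sample_table(te_matrix(g$table)[sample(129), , drop = FALSE])
  fit2 <- suppressWarnings(apcs_mlr(tab2))
  expect_equal(fit2$contribution_pct, fit$contribution_pct, tolerance = 1e-8)
  # rescaling one element's units rescales its coefficients, not its shares
  m3 <- te_matrix(g$table)
  m3[, "Cd"] <- m3[, "Cd"] * 1000
  fit3 <- suppressWarnings(apcs_mlr(as_sample_table(m3)))
  expect_equal(fit3$contribution_pct["Cd", ], fit$contribution_pct["Cd", ],
               tolerance = 1e-8)
  expect_equal(unname(fit3$coef["Cd", ]), unname(fit$coef["Cd", ]) * 1000,
               tolerance = 1e-6)
})

test_that("weak-prerequisite inputs trigger diagnostics, not failures", {
  set.seed(111)
  # nearly independent columns: low KMO and a Bartlett warning expected
  m <- matrix(rlnorm(300 * 4, 1, 0.3), 300, 4,
              dimnames = list(NULL, c("Cd", "Ni", "Pb", "Zn")))
  expect_warning(fit_pca_varimax(as_sample_table(m)), "Bartlett|KMO|n =")
})
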