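test_that("summary statistics use the sample conventions that reproduce the survey table", {
  # a column with exact first two moments at n = 129
  al <- exact_moments_column(22521, 5623, 129, seed = 1)
  tab <- as_sample_table(cbind(Al = al, Cd = rlnorm(129, -1.7, 0.4)))
  s <- summarize_te(tab)
  expect_equal(s$cv_percent[s$element == "Al"], 100 * 5623 / 22521,
               tolerance = 1e-12)
  expect_equal(round(s$cv_percent[s$element == "Al"], 2), 24.97)
  expect_equal(s$se[s$element == "Al"], 5623 / sqrt(129), tolerance = 1e-12)
  expect_equal(round(s$se[s$element == "Al"]), 495)
  expect_true(all(s$min <= s$median & s$median <= s$max))
})

test_that("summarize is row-order invariant and scales correctly under unit change", {
  tab <- toy_table(n = 20, elements = c("Cd", "Ni", "Pb"))
  s1 <- summarize_te(tab)
  shuffled <- as_sample_table(as.data.frame(tab[sample(nrow(tab)), ]))
  s2 <- summarize_te(shuffled)
  expect_equal(s1[, -1], s2[, -1], tolerance = 1e-12)
  k <- 1000  # mg/kg -> ug/kg
  tabk <- as_sample_table(te_matrix(tab) * k)
  sk <- summarize_te(tabk)
  expect_equal(sk$mean, s1$mean * k, tolerance = 1e-12)
  expect_equal(sk$sd, s1$sd * k, tolerance = 1e-12)
  expect_equal(sk$cv_percent, s1$cv_percent, tolerance = 1e-12)
  expect_equal(sk$skewness, s1$skewness, tolerance = 1e-12)
})

test_that("skewness follows the adjusted Fisher-Pearson convention", {
  skip_if_not_installed("e1071")
  set.seed(11)
  for (i in 1:5) {
    x <- rlnorm(40, 0, runif(1, 0.2, 1))
    expect_equal(sample_skewness(x), e1071::skewness(x, type = 2),
                 tolerance = 1e-12)
  }
  expect_error(sample_skewness(c(1, 2)), "insufficient")
})

test_that("constant columns are summarized as degenerate with a warning", {
  tab <- as_sample_table(cbind(Cd = rep(2, 10), Ni = rlnorm(10, 3)))
  expect_warning(s <- summarize_te(tab), "degenerate")
  expect_equal(s$sd[s$element == "Cd"], 0)
  expect_equal(s$cv_percent[s$element == "Cd"], 0)
  expect_equal(s$skewness[s$element == "Cd"], 0)
})

test_that("spearman matrix matches a rank-and-Pearson oracle and is symmetric", {
  tab <- toy_table(n = 8, elements = c("Cd", "Ni", "Pb", "Zn"), seed = 5)
  co <- spearman_matrix(tab)
  m <- te_matrix(tab)
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(co$r[i, j], oracle_spearman(m[, i], m[, j]),
                 tolerance = 1e-12)
  }
  expect_equal(co$r, t(co$r))
  expect_equal(unname(diag(co$r)), rep(1, 4))
  expect_true(all(abs(co$r) <= 1))

  x <- sort(rlnorm(10))
  mono <- as_sample_table(cbind(A = x, B = exp(x), C = max(x) + 1 - x))
  cm <- spearman_matrix(mono)
  expect_equal(cm$r["A", "B"], 1)
  expect_equal(cm$r["A", "C"], -1)
})

test_that("spearman r is invariant under strictly monotone transforms", {
  tab <- toy_table(n = 15, elements = c("Cd", "Ni"), seed = 9)
  m <- te_matrix(tab)
  r0 <- spearman_matrix(tab)$r["Cd", "Ni"]
  warped <- as_sample_table(cbind(Cd = log(m[, "Cd"]) + 10,
                                  Ni = m[, "Ni"]^3))
  expect_equal(spearman_matrix(warped)$r["Cd", "Ni"], r0, tolerance = 1e-12)
})

test_that("constant columns yield missing correlations, not errors", {
  tab <- as_sample_table(cbind(Cd = rep(2, 8), Ni = rlnorm(8, 3),
                               Pb = rlnorm(8, 2)))
  co <- spearman_matrix(tab)
  expect_true(all(is.na(co$r["Cd", ])))
  expect_false(is.na(co$r["Ni", "Pb"]))
})

test_that("normality flags hold their nominal error rates", {
  normal_flags <- logical(40)
  heavy_flags <- logical(40)
  for (s in 1:40) {
    set.seed(s)
    tab <- as_sample_table(cbind(A = rnorm(200, 50, 5),
                                 B = rlnorm(200, 0, 1)))
    nf <- normality_flags(tab)
    normal_flags[s] <- nf$normal[nf$element == "A"]
    heavy_flags[s] <- nf$normal[nf$element == "B"]
  }
  expect_gte(mean(normal_flags), 0.90)  # type-I error near alpha = 0.05
  expect_false(any(heavy_flags))        # lognormal always rejected at n = 200
})

test_that("KMO equals 0.5 for any 2-variable system and matches the oracle", {
  for (r in c(-0.8, 0.3, 0.95)) {
    R <- matrix(c(1, r, r, 1), 2)
    expect_equal(kmo_statistic(R), 0.5, tolerance = 1e-12)
  }
  # block-structured 6-variable matrix
  B <- diag(6)
  B[1:3, 1:3] <- 0.7; B[4:6, 4:6] <- 0.6
  B[1:3, 4:6] <- 0.1; B[4:6, 1:3] <- 0.1
  diag(B) <- 1
  expect_equal(kmo_statistic(B), oracle_kmo(B), tolerance = 1e-10)
  # random SPD correlation matrices
  set.seed(21)
  for (i in 1:5) {
    A <- matrix(rnorm(25), 5)
    R <- cov2cor(crossprod(A) + diag(5))
    expect_equal(kmo_statistic(R), oracle_kmo(R), tolerance = 1e-10)
  }
  expect_error(kmo_statistic(diag(4)), "undefined")
})

test_that("Bartlett sphericity matches the closed form and the oracle", {
  idr <- bartlett_sphericity(diag(5), n = 50)
  expect_equal(idr$chisq, 0)
  expect_equal(idr$p_value, 1)
  # m = 3, n = 50, det(R) = 0.5 -> chi2 = (50 - 1 - 11/6) log 2
  r <- sqrt(1 - 0.5)  # det of [[1, r], [r, 1]] extended keeps it simple:
  R <- diag(3); R[1, 2] <- R[2, 1] <- r
  expect_equal(det(R), 0.5, tolerance = 1e-12)
  b <- bartlett_sphericity(R, n = 50)
  expect_equal(b$chisq, (50 - 1 - 11 / 6) * log(2), tolerance = 1e-12)
  expect_equal(b$df, 3)
  set.seed(31)
  for (i in 1:5) {
    A <- matrix(rnorm(16), 4)
    R <- cov2cor(crossprod(A) + diag(4))
    expect_equal(bartlett_sphericity(R, 40)$chisq,
                 oracle_bartlett(R, 40)$chisq, tolerance = 1e-10)
  }
  expect_error(bartlett_sphericity(diag(5), n = 4), "n >")
})

test_that("Bartlett type-I error is near nominal on independent data", {
  rejections <- logical(100)
  for (s in 1:100) {
    set.seed(s)
    X <- matrix(rnorm(30 * 4), 30, 4)
    rejections[s] <- bartlett_sphericity(cor(X), 30)$p_value < 0.05
  }
  expect_lt(mean(rejections), 0.15)
})
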