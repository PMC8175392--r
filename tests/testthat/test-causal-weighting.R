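test_that("just-identified CBPS balances first moments to machine tolerance", {
  for (s in 1:8) {
    d <- simulate_treatment_cohort(150, effect = 1, confounding = 1, seed = s)
    fit <- cbps(treat ~ x1 + x2 + x3 + x4, d)
    w <- stabilized_weights(fit)
    for (v in c("x1", "x2", "x3", "x4")) {
      diff <- weighted.mean(d[[v]][d$treat == 1], w[d$treat == 1]) -
        weighted.mean(d[[v]][d$treat == 0], w[d$treat == 0])
      expect_lt(abs(diff), 1e-6)
    }
    expect_true(all(fit$propensities > 0 & fit$propensities < 1))
  }
})

test_that("without confounding the fitted propensities approach the treated fraction", {
  set.seed(60)
  d <- data.frame(treat = rbinom(4000, 1, 0.4),
                  x1 = rnorm(4000), x2 = rnorm(4000))
  fit <- cbps(treat ~ x1 + x2, d)
  expect_lt(max(abs(fit$propensities - mean(d$treat))), 0.05)
})

test_that("CBPS with one binary covariate matches the closed-form cell solution", {
  # moment equations decouple by covariate level: pi(x) = treated fraction
  # within each cell
  d <- data.frame(treat = c(1, 1, 1, 0, 0, 1, 1, 0, 0, 0, 0),
                  x = c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0, 0))
  fit <- cbps(treat ~ x, d)
  pi1 <- 3 / 5   # treated fraction among x = 1
  pi0 <- 2 / 6   # treated fraction among x = 0
  b1 <- qlogis(pi1) - qlogis(pi0)
  b0 <- qlogis(pi0)
  expect_equal(unname(coef(fit)), c(b0, b1), tolerance = 1e-6)
  expect_equal(unname(predict(fit)[d$x == 1][1]), pi1, tolerance = 1e-8)
})

test_that("stabilized weights are one when propensities equal the treated fraction", {
  treat <- rep(c(1, 0), c(4, 6))
  w <- stabilized_weights(rep(0.4, 10), treat)
  expect_equal(w, rep(1, 10))
  expect_error(stabilized_weights(c(0, 0.5), c(1, 0)), "strictly inside")
})

test_that("arm-wise mean stabilized weights equal one and match across arms", {
  d <- simulate_treatment_cohort(200, confounding = 1, seed = 17)
  fit <- cbps(treat ~ x1 + x2 + x3 + x4, d)
  w <- stabilized_weights(fit)  # Hajek-normalized
  expect_equal(as.vector(tapply(w, d$treat, mean)), c(1, 1), tolerance = 1e-12)
  # unnormalized: the intercept moment makes the two arm means coincide
  w_raw <- stabilized_weights(fit, normalize = FALSE)
  m <- tapply(w_raw, d$treat, mean)
  expect_lt(abs(m[[1]] - m[[2]]), 1e-6)
})

test_that("weights are invariant to rescaling a covariate", {
  d <- simulate_treatment_cohort(150, confounding = 1, seed = 23)
  f1 <- cbps(treat ~ x1 + x2 + x3 + x4, d)
  d2 <- d; d2$x1 <- d2$x1 * 100
  f2 <- cbps(treat ~ x1 + x2 + x3 + x4, d2)
  expect_equal(f1$propensities, f2$propensities, tolerance = 1e-6)
  expect_equal(unname(coef(f2))[2], unname(coef(f1))[2] / 100,
               tolerance = 1e-6)
})

test_that("identical arms give zero standardized differences and zero KS", {
  x <- data.frame(a = rep(rnorm(30), 2), b = rep(runif(30), 2))
  treat <- rep(c(1, 0), each = 30)
  rep_ <- balance_report(x, treat)
  expect_true(all(abs(rep_$terms$smd_unweighted) < 1e-12))
  expect_true(all(rep_$ks$ks_weighted < 1e-12))
})

test_that("unit weights reproduce the classical standardized difference", {
  set.seed(3)
  x <- data.frame(a = rnorm(80, 1), b = runif(80))
  treat <- rep(c(1, 0), each = 40)
  rep_ <- balance_report(x, treat)
  classical <- (mean(x$a[treat == 1]) - mean(x$a[treat == 0])) /
    sqrt((var(x$a[treat == 1]) + var(x$a[treat == 0])) / 2)
  row_a <- rep_$terms[rep_$terms$term == "a", ]
  expect_equal(row_a$smd_unweighted, classical, tolerance = 1e-12)
  expect_equal(row_a$smd_weighted, classical, tolerance = 1e-12)
  # squared terms and pairwise interactions are reported
  expect_true(all(c("a^2", "b^2", "a:b") %in% rep_$terms$term))
  # zero-variance terms are skipped with warnings (the constant and its square)
  x$c <- 1
  w <- capture_warnings(balance_report(x, treat))
  expect_true(all(grepl("zero-variance", w)))
  expect_gte(length(w), 1)
})

test_that("CBPS weighting drives raw-covariate balance below 1e-6", {
  d <- simulate_treatment_cohort(180, confounding = 1.2, seed = 31)
  fit <- cbps(treat ~ x1 + x2 + x3 + x4, d)
  rep_ <- balance_report(d[, c("x1", "x2", "x3", "x4")], d$treat,
                         stabilized_weights(fit))
  raw <- rep_$terms[rep_$terms$type == "mean", ]
  expect_true(all(abs(raw$smd_weighted) < 1e-6))
  expect_true(any(abs(raw$smd_unweighted) > 0.2))  # it was confounded
})

test_that("PMM imputation returns observed donor values and respects MCAR means", {
  set.seed(41)
  n <- 150
  d <- data.frame(a = rnorm(n, 10), b = rnorm(n, 5), c = rnorm(n))
  d$b <- d$a * 0.5 + d$b
  expect_identical(impute_pmm(d), d)  # no missing cells -> unchanged

  d_miss <- d
  d_miss$b[sample(n, 15)] <- NA
  imp <- impute_pmm(d_miss, seed = 7)
  expect_false(anyNA(imp$b))
  # every imputed value is an observed value of the variable
  expect_true(all(imp$b[is.na(d_miss$b)] %in% d_miss$b[!is.na(d_miss$b)]))

  expect_error(impute_pmm(data.frame(a = c(NA_real_, NA_real_),
                                     b = c(1, 2))),
               "entirely missing")
})

test_that("PMM recovers complete-data means under MCAR missingness", {
  set.seed(55)
  reps <- 200
  err <- replicate(reps, {
    n <- 120
    a <- rnorm(n, 10); b <- 0.6 * a + rnorm(n, 0, 1); c <- rnorm(n)
    d <- data.frame(a = a, b = b, c = c)
    d$b[runif(n) < 0.10] <- NA
    imp <- impute_pmm(d, n_cycles = 5, seed = sample.int(1e6, 1))
    mean(imp$b) - mean(b)
  })
  # imputed-variable mean is unbiased within Monte-Carlo error
  expect_lt(abs(mean(err)), 3 * sd(err) / sqrt(reps))
})

test_that("imputation is deterministic under a fixed seed", {
  d <- data.frame(a = rnorm(60), b = rnorm(60))
  d$a[1:6] <- NA
  expect_identical(impute_pmm(d, seed = 3), impute_pmm(d, seed = 3))
})

test_that("cbps rejects degenerate inputs with clear errors", {
  d <- simulate_treatment_cohort(100, seed = 2)
  d$x5 <- 1
  expect_error(cbps(treat ~ x1 + x5, d), "constant covariate")
  d$t2 <- 2 * d$treat
  expect_error(cbps(t2 ~ x1, d), "binary")
})
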