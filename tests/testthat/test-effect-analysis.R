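table2_rows <- function() {
  # the ten top-ranked screening rows: names, weighted mean difference,
  # unweighted SD and standardized ATE
  data.frame(
    mir = c("miR-133b", "miR-140-5p", "miR-142-3p", "let-7d-5p",
            "miR-199a-5p", "miR-146a-5p", "miR-103a-3p", "miR-424-5p",
            "let-7e-5p", "miR-155-5p"),
    ate = c(11.30, 5.70, 5.15, 4.19, 3.25, 2.96, 1.80, 1.15, 0.52, 0.76),
    unweighted_sd = c(5.15, 2.26, 2.21, 1.94, 1.53, 1.51, 0.80, 0.61,
                      0.28, 0.27),
    standardized_ate = c(4.38, 4.37, 5.29, 5.33, 5.44, 4.82, 4.17, 4.50,
                         4.20, 5.02),
    stringsAsFactors = FALSE)
}

test_that("two-step selection keeps the high-dispersion members of the top ranks", {
  sel <- rank_and_select(table2_rows())
  expect_setequal(sel$selected,
                  c("miR-133b", "miR-140-5p", "miR-142-3p", "let-7d-5p",
                    "miR-199a-5p"))
  expect_equal(sel$ranked$rank[sel$ranked$mir == "miR-133b"], 7)
  expect_equal(sel$ranked$mir[1], "miR-199a-5p")  # largest |standardized ATE|
})

test_that("selection degrades gracefully below the nominal sizes", {
  small <- table2_rows()[1:4, ]
  sel <- rank_and_select(small)
  expect_setequal(sel$top, small$mir)
  expect_setequal(sel$selected, small$mir)
})

test_that("ranking matches an exhaustive sort oracle on random tables", {
  set.seed(14)
  for (i in 1:5) {
    tab <- data.frame(mir = sprintf("m%02d", 1:84),
                      ate = rnorm(84), boot_sd = runif(84, 0.1, 2),
                      unweighted_sd = runif(84, 0.05, 5))
    tab$standardized_ate <- tab$ate / tab$boot_sd
    sel <- rank_and_select(tab)
    o <- order(-abs(tab$standardized_ate), -abs(tab$ate), tab$mir)
    top10 <- tab$mir[o][1:10]
    expect_identical(sel$top, top10)
    sd10 <- tab$unweighted_sd[match(top10, tab$mir)]
    expect_setequal(sel$selected, top10[order(-sd10)][1:5])
  }
})

test_that("unit weights reduce the ATE to the simple mean difference", {
  set.seed(21)
  y <- rnorm(40); t <- rep(c(1, 0), 20)
  expect_equal(sitmir:::weighted_ate(matrix(y, 1), t, rep(1, 40))[1],
               mean(y[t == 1]) - mean(y[t == 0]), tolerance = 1e-12)
  # with hand-set weights the weighted mean difference is plain arithmetic
  w <- c(1, 2, 1, 1, 3, 1)
  y6 <- c(5, 7, 3, 2, 4, 6); t6 <- c(1, 1, 1, 0, 0, 0)
  expect_equal(sitmir:::weighted_ate(matrix(y6, 1), t6, w),
               wmd_oracle(y6, t6, w))
  # hand-check: (5*1 + 7*2 + 3*1) / 4 - (2*1 + 4*3 + 6*1) / 5 = 5.5 - 4
  expect_equal(sitmir:::weighted_ate(matrix(y6, 1), t6, w), 1.5)
})

test_that("normal-approximation CIs reconstruct printed validation bounds", {
  # ATE and standardized ATE pairs as printed; boot SD = ATE / standardized
  ate <- c(0.168, 0.056)
  std <- c(5.462, 1.332)
  sd_ <- ate / std
  upper <- ate + 1.96 * sd_
  lower <- ate - 1.96 * sd_
  expect_equal(round(upper[1], 3), 0.228)
  expect_equal(round(lower[2], 3), -0.026)
})

test_that("significance requires strict zero exclusion", {
  tab <- data.frame(
    mir = c("a", "b", "c"),
    ci_lower = c(0.108, -0.026, 0.000),
    ci_upper = c(0.228, 0.138, 0.0206))
  out <- validate_significance(tab)
  expect_equal(out$significant, c(TRUE, FALSE, FALSE))
  # a zero ATE can never be significant under the rule
  tab0 <- data.frame(mir = "z", ci_lower = -0.1, ci_upper = 0.1)
  expect_false(validate_significance(tab0)$significant)
})

test_that("bootstrap SD stabilizes as B grows", {
  d <- simulate_treatment_cohort(60, effect = 1, confounding = 0.6, seed = 77)
  r1 <- ate_bootstrap(d$y, d[, c("x1", "x2", "x3", "x4")], d$treat,
                      B = 800, seed = 5)
  r2 <- ate_bootstrap(d$y, d[, c("x1", "x2", "x3", "x4")], d$treat,
                      B = 1600, seed = 5)
  expect_lt(abs(r2$boot_sd - r1$boot_sd) / r1$boot_sd, 0.05)
})

test_that("the ATE is scale-equivariant in the expression values", {
  d <- simulate_treatment_cohort(80, effect = 1, confounding = 0.5, seed = 19)
  r1 <- ate_bootstrap(d$y, d[, c("x1", "x2", "x3", "x4")], d$treat,
                      B = 100, seed = 8)
  r2 <- ate_bootstrap(10 * d$y, d[, c("x1", "x2", "x3", "x4")], d$treat,
                      B = 100, seed = 8)
  expect_equal(r2$ate, 10 * r1$ate, tolerance = 1e-10)
  expect_equal(r2$boot_sd, 10 * r1$boot_sd, tolerance = 1e-10)
  expect_equal(r2$standardized_ate, r1$standardized_ate, tolerance = 1e-10)
})

test_that("Pearson correlation matches the covariance formula and handles strata", {
  x <- rnorm(30)
  expect_equal(pearson_correlation(x, x)$r, 1)
  expect_equal(pearson_correlation(x, -2 * x + 3)$r, -1)
  set.seed(6)
  y <- 0.3 * x + rnorm(30)
  r <- pearson_correlation(x, y)$r
  expect_equal(r, cov(x, y) / (sd(x) * sd(y)), tolerance = 1e-12)
  g <- rep(c("A", "B"), 15)
  out <- pearson_correlation(x, y, g)
  expect_equal(out$stratum, c("combined", "A", "B"))
  expect_equal(out$r[2], cor(x[g == "A"], y[g == "A"]), tolerance = 1e-12)
  expect_true(is.na(pearson_correlation(rep(1, 5), rnorm(5))$r))
})

test_that("interaction regression reduces to OLS with unit weights", {
  set.seed(10)
  n <- 80
  g <- rbinom(n, 1, 0.5); h <- rbinom(n, 1, 0.4)
  y <- 1 + 0.5 * g + 0.2 * h + 0.7 * g * h + rnorm(n)
  tab <- interaction_wls(y, g, h)
  ols <- coef(lm(y ~ g * h))
  expect_equal(tab$estimate, unname(ols), tolerance = 1e-12)
  # empty cell raises an error naming the cell
  h2 <- h; h2[g == 1] <- 0
  expect_error(interaction_wls(y, g, h2), "empty design cell")
})

test_that("interaction Wald test holds its size under the null", {
  set.seed(123)
  reps <- 500
  pvals <- replicate(reps, {
    n <- 200
    g <- rbinom(n, 1, 0.5); h <- rbinom(n, 1, 0.4)
    y <- 0.5 * g + 0.3 * h + rnorm(n)
    tab <- interaction_wls(y, g, h)
    tab$p_value[tab$term == "group:hispanic"]
  })
  rate <- mean(pvals < 0.05)
  expect_gte(rate, 0.02)
  expect_lte(rate, 0.09)
})

test_that("interaction coefficient is recovered within sampling error", {
  set.seed(321)
  n <- 400
  g <- rbinom(n, 1, 0.5); h <- rbinom(n, 1, 0.5)
  y <- 0.5 * g + 0.3 * h + 1.0 * g * h + rnorm(n)
  tab <- interaction_wls(y, g, h)
  row <- tab[tab$term == "group:hispanic", ]
  expect_lt(abs(row$estimate - 1.0), 3 * row$se_hc0)
})

test_that("records with an unusable arm are marked inestimable", {
  set.seed(9)
  expr <- matrix(rnorm(40), nrow = 2,
                 dimnames = list(c("m1", "m2"), NULL))
  expr[2, 1:18] <- NA  # only 2 usable values, both in one arm
  t <- rep(c(1, 0), each = 10)
  d <- data.frame(x1 = rnorm(20))
  rec <- ate_bootstrap(expr, d, t, B = 30, seed = 2)
  expect_true(is.na(rec$ate[rec$mir == "m2"]))
  expect_false(is.na(rec$ate[rec$mir == "m1"]))
})
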