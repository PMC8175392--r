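test_that("generators are deterministic under a fixed seed", {
  cfg <- cohort_config(n_participants = 30, n_days = 2, seed = 12)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1, c2)
  expect_identical(generate_activity(c1, cfg), generate_activity(c2, cfg))
  expect_identical(generate_ct(c1, config = cfg)$ct,
                   generate_ct(c2, config = cfg)$ct)
})

test_that("configuration errors name the offending field", {
  expect_error(cohort_config(n_participants = 4), "n_participants")
  expect_error(cohort_config(n_participants = 20, missing_rate = 1.2),
               "missing_rate")
  expect_error(cohort_config(n_participants = 20,
                             true_effect_mirs = c(nope = 1)),
               "true_effect_mirs")
  expect_error(cohort_config(n_participants = 20, sit_fraction = 1.5),
               "sit_fraction")
})

test_that("zero missing rate leaves no missing covariate cells", {
  cfg <- cohort_config(n_participants = 40, missing_rate = 0, seed = 2)
  expect_false(anyNA(generate_cohort(cfg)$covariates))
  cfg2 <- cohort_config(n_participants = 400, missing_rate = 0.1, seed = 2)
  cov <- generate_cohort(cfg2)$covariates
  expect_gt(sum(is.na(cov$waist)), 0)
  expect_gt(sum(is.na(cov$phys_func)), 0)
})

test_that("cohort covariates track the configured population moments", {
  cfg <- cohort_config(n_participants = 2000, seed = 8, missing_rate = 0)
  cov <- generate_cohort(cfg)$covariates
  # age: truncated normal at 55 calibrated to a population mean of 65.9
  se <- sd(cov$age) / sqrt(nrow(cov))
  expect_lt(abs(mean(cov$age) - 65.9), 3 * se)
  expect_true(all(cov$age >= 55))
  expect_true(all(cov$bmi >= 25))
  expect_true(all(cov$phys_func >= 0 & cov$phys_func <= 100))
  expect_gt(cor(cov$bmi, cov$waist), 0.5)
  expect_true(all(cov$parent_study %in% c("CoM", "RFH", "MENU")))
  # physical functioning declines with the latent sitting propensity
  z <- generate_cohort(cfg)$truth$z
  expect_lt(cor(z, cov$phys_func), -0.1)
})

one_person_cohort <- function(bout_mean, mvpa = 10, sit_frac = 0.65) {
  list(covariates = data.frame(participant_id = "P1",
                               stringsAsFactors = FALSE),
       truth = list(bout_mean_true = c(P1 = bout_mean),
                    mvpa_true = c(P1 = mvpa),
                    walking_true = c(P1 = 30),
                    sit_fraction_true = c(P1 = sit_frac)))
}

test_that("accelerometry metrics recover the configured bout mean", {
  cfg <- cohort_config(n_participants = 8, n_days = 5, seed = 17,
                       wear_short_prob = 0)
  ep <- generate_activity(one_person_cohort(60), cfg)
  s <- summarize_activity(ep)
  expect_true(s$adherent)
  expect_lt(abs(s$mean_sitting_bout - 60) / 60, 0.20)
  # sitting fraction of wear time lands near the configured value
  expect_lt(abs(s$total_sitting / s$mean_wear_time - 0.65), 0.10)
})

test_that("configured zero MVPA yields zero analyzed MVPA minutes", {
  cfg <- cohort_config(n_participants = 8, n_days = 3, seed = 18,
                       wear_short_prob = 0)
  ep <- generate_activity(one_person_cohort(40, mvpa = 0), cfg)
  s <- summarize_activity(ep, min_days = 3)
  expect_equal(s$mvpa, 0)
})

test_that("an injected 120-minute zero run is flagged non-wear", {
  cfg0 <- cohort_config(n_participants = 8, n_days = 6, seed = 19,
                        wear_short_prob = 0)
  cfg1 <- cohort_config(n_participants = 8, n_days = 6, seed = 19,
                        wear_short_prob = 0, nonwear_minutes = 120)
  s0 <- summarize_activity(generate_activity(one_person_cohort(45), cfg0),
                           min_days = 3)
  s1 <- summarize_activity(generate_activity(one_person_cohort(45), cfg1),
                           min_days = 3)
  # injection removes at least ~120 minutes of wear per day on average
  expect_lt(s1$mean_wear_time, s0$mean_wear_time - 100)
})

test_that("wear windows span roughly 14-16 hours with edge non-wear", {
  cfg <- cohort_config(n_participants = 10, n_days = 2, seed = 21,
                       wear_short_prob = 0)
  ep <- generate_activity(generate_cohort(cfg), cfg)
  s <- summarize_activity(ep, min_days = 2)
  expect_true(all(s$mean_wear_time >= 780 & s$mean_wear_time <= 980))
})

test_that("a null Ct generator produces no group expression differences", {
  cfg <- cohort_config(n_participants = 200, seed = 30,
                       confounding_strength = 0, missing_rate = 0)
  co <- generate_cohort(cfg)
  ctd <- generate_ct(co, config = cfg)
  z <- co$truth$z
  hi <- z > quantile(z, 0.75); lo <- z < quantile(z, 0.25)
  log2e <- -(ctd$ct[cfg$panel, ] - 26)
  diffs <- rowMeans(log2e[, hi]) - rowMeans(log2e[, lo])
  # all 84 group contrasts within Monte-Carlo error of zero
  expect_lt(max(abs(diffs)), 0.45)
})

test_that("a planted single-microRNA effect is recovered by the group contrast", {
  cfg <- cohort_config(n_participants = 200, seed = 31,
                       confounding_strength = 0, missing_rate = 0,
                       true_effect_mirs = c("miR-sim-010" = 1.0))
  co <- generate_cohort(cfg)
  ctd <- generate_ct(co, config = cfg)
  z <- co$truth$z
  hi <- z > quantile(z, 0.75); lo <- z < quantile(z, 0.25)
  log2e <- -(ctd$ct["miR-sim-010", ] - 26)
  est <- mean(log2e[hi]) - mean(log2e[lo])
  se <- sqrt(var(log2e[hi]) / sum(hi) + var(log2e[lo]) / sum(lo))
  expect_lt(abs(est - 1.0), 3 * se)
})

test_that("control assays are present with low variance", {
  cfg <- cohort_config(n_participants = 50, seed = 33)
  ctd <- generate_ct(generate_cohort(cfg), config = cfg)
  expect_setequal(unique(ctd$assays$role),
                  c("target", "array_control", "snord61", "cel_mir_39"))
  ctrl <- ctd$ct[ctd$assays$role != "target", ]
  expect_true(all(apply(ctrl, 1, sd) < 0.5))
})

test_that("epoch and Ct artifacts round-trip through their CSV formats", {
  cfg <- cohort_config(n_participants = 8, n_days = 1, seed = 40)
  bundle <- generate_study(cfg)
  f1 <- tempfile(fileext = ".csv")
  write_epochs(bundle$epochs, f1)
  back <- read_epochs(f1)
  expect_equal(back, bundle$epochs)
  f2 <- tempfile(fileext = ".csv")
  write_ct_matrix(bundle$ct, bundle$assays, f2)
  back2 <- read_ct_matrix(f2)
  expect_equal(unname(back2$ct), unname(bundle$ct), tolerance = 1e-12)
  expect_equal(back2$assays$role, bundle$assays$role)
  unlink(c(f1, f2))
})
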